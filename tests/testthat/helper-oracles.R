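# Independent reference implementations used as oracles. These deliberately
# use naive algorithms (loops, enumeration, grids) and never call the
# package code paths they check.

# Logistic regression by hand-written iteratively reweighted least squares.
irls_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, X * w), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  beta
}

# Connected components by union-find over an edge list (undirected view).
union_find_components <- function(edges) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_len(nrow(edges))) {
    a <- find(match(edges$from[k], nodes))
    b <- find(match(edges$to[k], nodes))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  split(nodes, roots)
}

# Restricted log-likelihood of the random-effects meta-analysis model.
meta_reml_ll <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

# tau^2 by brute-force grid search + golden-section refinement.
grid_reml_tau2 <- function(y, v, upper = NULL) {
  if (is.null(upper)) upper <- max(10 * stats::var(y), 1)
  grid <- seq(0, upper, length.out = 2001)
  ll <- vapply(grid, meta_reml_ll, numeric(1), y = y, v = v)
  t0 <- grid[which.max(ll)]
  opt <- stats::optimize(meta_reml_ll, y = y, v = v,
                         lower = max(0, t0 - upper / 1000),
                         upper = t0 + upper / 1000, maximum = TRUE,
                         tol = 1e-10)
  max(opt$maximum, 0)
}

# Exact hypergeometric right tail P(K >= k) by enumeration with choose().
hyper_tail_enum <- function(k, focus_total, universe, n_draw) {
  kk <- k:min(n_draw, focus_total)
  sum(choose(focus_total, kk) * choose(universe - focus_total, n_draw - kk)) /
    choose(universe, n_draw)
}

# Marginal likelihood of a random-intercept logistic model by Gauss-Hermite
# quadrature (nodes via eigendecomposition of the Jacobi matrix), maximized
# with optim. theta = (beta vector, log sd of intercepts).
gh_nodes <- function(k) {
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = e$vectors[1, ]^2 * sqrt(pi))
}

mixed_logit_loglik <- function(theta, X, y, fam, k = 31) {
  gh <- gh_nodes(k)
  beta <- theta[-length(theta)]
  sdu <- exp(theta[length(theta)])
  eta0 <- drop(X %*% beta)
  ll <- 0
  for (f in unique(fam)) {
    i <- fam == f
    contrib <- vapply(seq_len(k), function(q) {
      u <- sqrt(2) * sdu * gh$x[q]
      p <- 1 / (1 + exp(-(eta0[i] + u)))
      gh$w[q] / sqrt(pi) * prod(ifelse(y[i] == 1, p, 1 - p))
    }, numeric(1))
    ll <- ll + log(sum(contrib))
  }
  ll
}

fit_mixed_logit_oracle <- function(X, y, fam) {
  init <- c(irls_logistic(X, y), log(0.5))
  opt <- stats::optim(init, function(th) -mixed_logit_loglik(th, X, y, fam),
                      method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  list(beta = opt$par[-length(opt$par)], sd_u = exp(opt$par[length(opt$par)]))
}

# Small genotype fixture: n x m dosage matrix with given alleles.
toy_geno <- function(dosages, ref = NULL, alt = NULL, info = NULL) {
  m <- ncol(dosages)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("s%02d", seq_len(nrow(dosages)))
  v <- data.frame(id = sprintf("v%03d", seq_len(m)), chrom = "1",
                  pos = seq_len(m) * 1000L, ref = ref, alt = alt,
                  stringsAsFactors = FALSE)
  if (!is.null(info)) v$info <- info
  genotype_matrix(dosages, v)
}

toy_weights <- function(gene, variant, eff, other, w) {
  weight_model(data.frame(gene = gene, variant = variant, ref_allele = other,
                          eff_allele = eff, weight = w,
                          stringsAsFactors = FALSE))
}
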