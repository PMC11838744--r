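test_that("Nagelkerke formula matches direct evaluation and its limits", {
  # hand-specified likelihood triple
  ll0 <- -100; ll_null <- -95; ll_full <- -88; n <- 200
  r2 <- function(ll) (1 - exp(2 * (ll0 - ll) / n)) / (1 - exp(2 * ll0 / n))
  expect_equal(nagelkerke_r2(ll_full, ll0, n), r2(ll_full), tolerance = 1e-12)
  expect_equal(nagelkerke_delta(ll0, ll_null, ll_full, n),
               r2(ll_full) - r2(ll_null), tolerance = 1e-12)
  # full = null -> delta 0
  expect_equal(nagelkerke_delta(ll0, ll_null, ll_null, n), 0)
  # perfectly predictive model: L_full -> 1 (ll_full -> 0), R2 -> 1
  expect_equal(nagelkerke_r2(0, ll0, n), 1, tolerance = 1e-12)
})

test_that("logistic fit reproduces the 2x2 cross-product odds ratio", {
  # male counts by onset group: 131/223 early, 224/372 late
  d <- data.frame(
    onset = rep(c(1, 1, 0, 0), c(131, 92, 224, 148)),
    sex = rep(c(1, 0, 1, 0), c(131, 92, 224, 148))
  )
  fit <- fit_logistic(d, "sex")
  or_oracle <- (131 * 148) / (92 * 224)
  expect_equal(fit$aOR, or_oracle, tolerance = 1e-6)
  se_oracle <- sqrt(1 / 131 + 1 / 92 + 1 / 224 + 1 / 148)
  expect_equal(fit$se, se_oracle, tolerance = 1e-4)
  expect_equal(fit$p, 2 * pnorm(-abs(log(or_oracle)) / se_oracle),
               tolerance = 1e-3)
})

test_that("logistic coefficients match a hand-written IRLS oracle to 1e-6", {
  set.seed(51)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4), x3 = runif(n))
  eta <- -0.5 + 0.8 * d$x1 - 0.4 * d$x2 + 0.2 * d$x3
  d$onset <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(d, "x1", c("x2", "x3"))
  X <- cbind(1, d$x1, d$x2, d$x3)
  beta <- irls_logistic(X, d$onset)
  expect_equal(fit$estimate, beta[2], tolerance = 1e-6)
})

test_that("separation is flagged, not reported as a finite effect", {
  d <- data.frame(onset = rep(c(0, 1), each = 20),
                  s = c(rnorm(20, -3), rnorm(20, 3)))
  fit <- suppressWarnings(fit_logistic(d, "s"))
  expect_equal(fit$flag, "separation")
})

test_that("mixed fit collapses to plain logistic for singleton families", {
  set.seed(52)
  n <- 300
  d <- data.frame(x = rnorm(n), family = sprintf("f%03d", 1:n))
  d$onset <- rbinom(n, 1, plogis(-0.2 + 0.5 * d$x))
  fm <- fit_mixed_logistic(d, "x")
  fp <- fit_logistic(d, "x")
  expect_equal(fm$estimate, fp$estimate, tolerance = 1e-4)
  expect_equal(fm$se, fp$se, tolerance = 1e-3)
  expect_lt(fm$tau2, 1e-3)
})

test_that("mixed fit agrees with a Gauss-Hermite quadrature oracle", {
  set.seed(53)
  nf <- 150
  fam <- rep(sprintf("f%03d", 1:nf), each = 2)
  u <- rep(rnorm(nf, 0, 0.8), each = 2)
  x <- rnorm(2 * nf)
  y <- rbinom(2 * nf, 1, plogis(-0.3 + 0.6 * x + u))
  d <- data.frame(onset = y, x = x, family = fam)
  fit <- fit_mixed_logistic(d, "x", nAGQ = 25L)
  oracle <- fit_mixed_logit_oracle(cbind(1, x), y, fam)
  expect_equal(fit$estimate, unname(oracle$beta[2]), tolerance = 1e-3)
  expect_equal(sqrt(fit$tau2), unname(oracle$sd_u), tolerance = 0.02)
})

test_that("mixed-model estimates are unbiased for sibship data", {
  # modest replicate check of the estimator itself (known scores)
  set.seed(54)
  ests <- replicate(40, {
    nf <- 200
    fam <- rep(seq_len(nf), each = 2)
    u <- rep(rnorm(nf, 0, sqrt(0.5)), each = 2)
    x <- rnorm(2 * nf)
    y <- rbinom(2 * nf, 1, plogis(-0.4 + 0.5 * x + u))
    d <- data.frame(onset = y, x = x, family = fam)
    fit_mixed_logistic(d, "x", pseudo_r2 = FALSE)$estimate
  })
  expect_equal(mean(ests), 0.5, tolerance = 0.05)
})

test_that("best threshold maximizes delta pseudo-R2 with smaller-threshold ties", {
  mk <- function(t, d) {
    r <- list(score = paste0("prs:", t), delta_r2 = d)
    class(r) <- "association_result"
    r
  }
  expect_equal(as.numeric(best_threshold(list(mk(0.05, 0.01)))), 0.05)
  res <- list(mk(1e-4, 0.002), mk(0.01, 0.004), mk(0.1, 0.011))
  expect_equal(as.numeric(best_threshold(res)), 0.1)
  tie <- list(mk(0.01, 0.011), mk(0.1, 0.011))
  expect_equal(as.numeric(best_threshold(tie)), 0.01)
})

test_that("meta-analysis closed forms and REML grid oracle hold", {
  # two identical studies: pooled = y, tau2 = 0, SE = SE/sqrt(2)
  m <- meta_analyze(c(0.3, 0.3), c(0.1, 0.1))
  expect_equal(m$estimate, 0.3, tolerance = 1e-10)
  expect_equal(m$tau2, 0, tolerance = 1e-8)
  expect_equal(m$se, 0.1 / sqrt(2), tolerance = 1e-8)

  # pooled lies between study extremes
  m2 <- meta_analyze(c(0.1, 0.5), c(0.1, 0.2))
  expect_gt(m2$estimate, 0.1)
  expect_lt(m2$estimate, 0.5)

  # heterogeneous studies: tau2 equals a grid-search REML maximizer
  set.seed(55)
  for (k in 1:5) {
    y <- rnorm(3 + k, 0.2, 0.3)
    v <- runif(3 + k, 0.01, 0.1)
    m3 <- meta_analyze(y, sqrt(v))
    expect_equal(m3$tau2, grid_reml_tau2(y, v), tolerance = 1e-4)
  }
  expect_error(meta_analyze(0.3, 0.1), "2 studies")
  expect_error(meta_analyze(c(0.3, 0.2), c(0.1, 0)), "positive")
})

test_that("the model ladder attributes effects to the right scores", {
  set.seed(56)
  n <- 600
  fam <- rep(sprintf("f%03d", 1:(n / 2)), each = 2)
  gers <- rnorm(n)
  prs_z <- rnorm(n)        # pure noise score
  u <- rep(rnorm(n / 2, 0, 0.5), each = 2)
  d <- data.frame(
    onset = rbinom(n, 1, plogis(-0.4 + 0.45 * gers + u)),
    gers_sub = gers, gers_hub = gers + rnorm(n, 0, 0.6),
    prs = prs_z, sex = rbinom(n, 1, 0.5), education = rnorm(n, 11, 2),
    PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n), PC4 = rnorm(n),
    family = fam
  )
  res <- run_models(d, "gers_sub", "gers_hub", "prs", mode = "mixed")
  expect_named(res, paste0("model", 0:4))
  # planted module effect: Model 1 recovers it, Model 0 (noise PRS) does not
  expect_gt(res$model1$aOR, 1.2)
  expect_lt(res$model1$p, 0.01)
  expect_gt(res$model0$p, 0.05)
  # adding a noise PRS barely changes the GeRS effect (Model 3 vs Model 1)
  expect_equal(res$model3$estimate, res$model1$estimate, tolerance = 0.05)
  expect_equal(res$model3$delta_r2, res$model1$delta_r2, tolerance = 0.02)
  # pseudo-R2 change is non-negative for nested ML fits
  for (r in res) expect_gte(r$delta_r2, -1e-8)
})
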