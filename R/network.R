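#' Construct a network graph
#'
#' Directed gene-interaction graph with relation tags (direct/indirect).
#' Self-loops are removed and parallel edges (same regulator, target and
#' direction) collapsed. Focus genes are the genes of the input set the
#' network was built around.
#'
#' @param edges data frame with columns `from`, `to` and optionally
#'   `directed` (logical, default TRUE) and `relation`
#'   ("direct"/"indirect", default "direct").
#' @param focus character vector of focus genes.
#' @return an object of class `network_graph` with elements `edges`,
#'   `nodes`, `focus`.
#' @export
network_graph <- function(edges, focus = character()) {
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (is.null(edges$directed)) edges$directed <- TRUE
  if (is.null(edges$relation)) edges$relation <- "direct"
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  edges <- edges[!duplicated(edges[, c("from", "to", "directed")]), , drop = FALSE]
  nodes <- sort(unique(c(edges$from, edges$to, focus)))
  structure(list(edges = edges, nodes = nodes,
                 focus = intersect(nodes, focus)),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("network_graph: %d nodes (%d focus), %d edges\n",
              length(x$nodes), length(x$focus), nrow(x$edges)))
  invisible(x)
}

#' Assemble candidate networks around a focus gene set
#'
#' Induces the subgraph of the edge database on the focus genes plus their
#' direct interactors, splits it into connected components (ignoring edge
#' direction) and returns one `network_graph` per component, sorted by
#' enrichment score (ties broken by larger focus-gene count, then by the
#' lexicographically smallest node set).
#'
#' @param focus_genes character vector of genes of interest.
#' @param edge_db data frame of known interactions (`from`, `to`, optional
#'   `directed`, `relation`).
#' @param universe_size number of genes in the scoring universe; defaults to
#'   the number of distinct genes in the edge database plus any focus genes
#'   absent from it.
#' @return list of `network_graph` objects, each with a `score` attribute;
#'   empty (with a warning) when no focus gene occurs in the database.
#' @export
build_networks <- function(focus_genes, edge_db, universe_size = NULL) {
  if (nrow(edge_db) == 0) stop("edge database is empty")
  all_genes <- unique(c(edge_db$from, edge_db$to))
  if (!any(focus_genes %in% all_genes)) {
    warning("no focus gene appears in the edge database")
    return(list())
  }
  if (is.null(universe_size))
    universe_size <- length(union(all_genes, focus_genes))
  touch <- edge_db$from %in% focus_genes | edge_db$to %in% focus_genes
  nodes <- unique(c(edge_db$from[touch], edge_db$to[touch]))
  sub <- edge_db[edge_db$from %in% nodes & edge_db$to %in% nodes, , drop = FALSE]
  g <- igraph::graph_from_data_frame(sub[, c("from", "to")], directed = TRUE)
  comp <- igraph::components(g, mode = "weak")
  nets <- lapply(seq_len(comp$no), function(k) {
    members <- names(comp$membership)[comp$membership == k]
    e <- sub[sub$from %in% members & sub$to %in% members, , drop = FALSE]
    net <- network_graph(e, focus = intersect(members, focus_genes))
    attr(net, "score") <- score_network(net, universe_size, length(focus_genes))
    net
  })
  ord <- order(
    -vapply(nets, function(n) attr(n, "score"), numeric(1)),
    -vapply(nets, function(n) length(n$focus), numeric(1)),
    vapply(nets, function(n) paste(sort(n$nodes), collapse = ","), character(1))
  )
  nets[ord]
}

#' Focus-gene enrichment score of a network
#'
#' Minus log10 of the hypergeometric right-tail probability of observing at
#' least the network's number of focus genes among its nodes, given
#' `focus_total` focus genes in a universe of `universe_size` genes. This is
#' an open, documented stand-in for proprietary network scores of the same
#' family: larger means more focus-enriched, and it is monotone in the
#' focus count.
#'
#' @param net a `network_graph`.
#' @param universe_size genes in the universe.
#' @param focus_total total number of focus genes.
#' @return non-negative score.
#' @export
score_network <- function(net, universe_size, focus_total) {
  stopifnot(inherits(net, "network_graph"))
  n <- length(net$nodes)
  k <- length(net$focus)
  if (focus_total > universe_size || n > universe_size || k > min(n, focus_total))
    stop("inconsistent counts: focus/universe/network sizes disagree")
  if (k == 0) return(0)
  p <- stats::phyper(k - 1, focus_total, universe_size - focus_total, n,
                     lower.tail = FALSE)
  -log10(max(p, .Machine$double.xmin))
}

#' Identify hub genes by out-degree
#'
#' A hub is a focus gene regulating at least `min_regulated` distinct other
#' genes in the network (out-edges; direct and indirect relations both
#' count; self excluded; the boundary is inclusive, "four or more" under
#' the default). With `count_undirected = TRUE` undirected edges incident
#' to a gene also count toward its degree.
#'
#' @param net a `network_graph`.
#' @param min_regulated minimum number of regulated genes (default 4).
#' @param count_undirected also count undirected edges (default FALSE).
#' @return character vector of hub genes sorted by degree descending then
#'   lexicographically, with a `degree` attribute.
#' @export
identify_hubs <- function(net, min_regulated = 4L, count_undirected = FALSE) {
  stopifnot(inherits(net, "network_graph"))
  if (length(net$nodes) == 0) stop("network is empty")
  e <- net$edges
  deg <- vapply(net$focus, function(g) {
    targets <- e$to[e$from == g & (e$directed | count_undirected)]
    if (count_undirected)
      targets <- c(targets, e$from[e$to == g & !e$directed])
    length(setdiff(unique(targets), g))
  }, integer(1))
  hubs <- names(deg)[deg >= min_regulated]
  hubs <- hubs[order(-deg[hubs], hubs)]
  attr(hubs, "degree") <- deg[hubs]
  hubs
}
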