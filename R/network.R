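#' Spearman-correlation distance between probes
#'
#' d(x, y) = 1 - |rho_S(x, y)| over the tumour samples. A constant probe has
#' no rank correlation; its distance to every other probe is set to 1 and
#' the probe is flagged in `attr(, "flagged")`.
#'
#' @param expr An `expr_mat`.
#' @param probes Probe ids (default all); normally the probe signature.
#' @param samples Sample ids (default tumour samples).
#' @return Symmetric weight matrix with zero diagonal.
#' @export
correlation_distance <- function(expr, probes = NULL, samples = NULL) {
  if (is.null(samples)) samples <- tumour_ids(expr)
  if (length(samples) < 3) stop("need at least 3 samples")
  m <- expr_values(expr_subset(expr, probes = probes, samples = samples))
  rho <- suppressWarnings(stats::cor(t(m), method = "spearman"))
  flagged <- rownames(m)[apply(m, 1, function(v) length(unique(v)) == 1)]
  d <- 1 - abs(rho)
  d[is.na(d)] <- 1
  diag(d) <- 0
  attr(d, "flagged") <- flagged
  d
}

#' Minimum spanning tree over a probe distance matrix
#'
#' Kruskal construction: edges are sorted by weight, with equal-weight edges
#' taken in lexicographic (probe_a, probe_b) order so the tree is
#' deterministic. Weights below 1e-12 are treated as exactly 0 (perfect
#' correlation).
#'
#' @param d Symmetric non-negative weight matrix with probe dimnames.
#' @return Object of class `mst_graph`: `nodes`, `edges` tibble
#'   (`probe_a`, `probe_b`, `weight`) with exactly n - 1 rows, `total_weight`.
#' @export
build_mst <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least two nodes")
  nodes <- rownames(d)
  if (is.null(nodes)) nodes <- paste0("N", seq_len(n))
  if (any(d < 0)) stop("weights must be non-negative")
  if (max(abs(d - t(d))) > 1e-12) stop("weight matrix must be symmetric")
  ii <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[ii]
  w[w < 1e-12] <- 0
  a <- nodes[ii[, 1]]
  b <- nodes[ii[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  ord <- order(w, a, b)
  a <- a[ord]; b <- b[ord]; w <- w[ord]

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- stats::setNames(seq_len(n), nodes)
  keep <- logical(length(w))
  taken <- 0
  for (e in seq_along(w)) {
    ra <- find(idx[[a[e]]])
    rb <- find(idx[[b[e]]])
    if (ra != rb) {
      parent[ra] <- rb
      keep[e] <- TRUE
      taken <- taken + 1
      if (taken == n - 1) break
    }
  }
  edges <- tibble::tibble(probe_a = a[keep], probe_b = b[keep],
                          weight = w[keep])
  structure(list(nodes = nodes, edges = edges,
                 total_weight = sum(edges$weight)),
            class = "mst_graph")
}

#' @export
print.mst_graph <- function(x, ...) {
  cat("<mst_graph>", length(x$nodes), "nodes,", nrow(x$edges),
      "edges, total weight", signif(x$total_weight, 6), "\n")
  invisible(x)
}

mst_igraph <- function(mst) {
  igraph::graph_from_data_frame(
    mst$edges[, c("probe_a", "probe_b")], directed = FALSE,
    vertices = data.frame(name = mst$nodes))
}

#' Betweenness centrality and degree of tree nodes
#'
#' Betweenness counts the node-interior shortest paths (unique in a tree)
#' through each node, normalized by (n-1)(n-2)/2 so leaves score 0 and the
#' most traversed nodes approach 1. Candidate key probes are flagged at the
#' conventional screen of betweenness >= 0.1 and degree >= 4.
#'
#' @param mst An `mst_graph`.
#' @param b_min,nd_min Key-probe screen thresholds on betweenness and degree.
#' @return Tibble sorted by betweenness desc, degree desc, probe id:
#'   `probe_id`, `betweenness`, `degree`, `key_centrality`, `key_degree`,
#'   `key_flag`.
#' @export
centrality_report <- function(mst, b_min = 0.1, nd_min = 4) {
  g <- mst_igraph(mst)
  n <- length(mst$nodes)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = n > 2)
  if (n <= 2) btw[] <- 0
  deg <- igraph::degree(g)
  out <- tibble::tibble(
    probe_id = igraph::V(g)$name,
    betweenness = unname(btw),
    degree = unname(deg))
  out$key_centrality <- out$betweenness >= b_min
  out$key_degree <- out$degree >= nd_min
  out$key_flag <- out$key_centrality & out$key_degree
  out[order(-out$betweenness, -out$degree, out$probe_id), ]
}
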