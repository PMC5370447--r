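#' Square-root Jensen-Shannon divergence between two distributions
#'
#' JSD(p, q) = H(m) - (H(p) + H(q))/2 with m = (p + q)/2, computed with
#' base-2 logarithms so the divergence is bounded by 1 bit and its square
#' root — a metric — lies in [0, 1].
#'
#' @param p,q Non-negative vectors summing to 1.
#' @return sqrt(JSD(p, q)).
#' @export
sqrt_jsd <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8) {
    stop("p and q must each sum to 1")
  }
  m <- (p + q) / 2
  kl <- function(a) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / m[nz]))
  }
  sqrt(max(0, (kl(p) + kl(q)) / 2))
}

#' Pairwise sqrt-JSD distance matrix between samples
#'
#' Each sample's probe vector is shifted by the global minimum over the
#' submatrix plus an epsilon of 1e-6 (log2 expression can be negative; JSD
#' needs distributions), normalized to sum 1, and compared pairwise by
#' [sqrt_jsd()].
#'
#' @param expr An `expr_mat`.
#' @param probes Probe ids to use (default: all probes in `expr`).
#' @param samples Sample ids to compare (default: tumour samples).
#' @return Symmetric distance matrix with zero diagonal, entries in [0, 1].
#' @export
jsd_distance_matrix <- function(expr, probes = NULL, samples = NULL) {
  if (is.null(samples)) samples <- tumour_ids(expr)
  sub <- expr_subset(expr, probes = probes, samples = samples)
  m <- expr_values(sub)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >=2 probes and >=2 samples")
  shifted <- m - min(m) + 1e-6
  cs <- colSums(shifted)
  if (any(cs <= 0)) stop("sample with non-positive probability mass")
  pm <- sweep(shifted, 2, cs, "/")
  n <- ncol(pm)
  d <- matrix(0, n, n, dimnames = list(colnames(pm), colnames(pm)))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      d[i, j] <- d[j, i] <- sqrt_jsd(pm[, i], pm[, j])
    }
  }
  d
}

#' Ward hierarchical clustering of tumours, cut into two subgroups
#'
#' Agglomerates with the Ward minimum-variance criterion (Lance-Williams
#' update on squared input distances, `stats::hclust(method = "ward.D2")`)
#' and cuts the dendrogram at k = 2. The label "Basal I" goes to the cluster
#' with the longer Kaplan-Meier median survival when a clinical table is
#' supplied, otherwise to the larger cluster; remaining ties fall to the
#' larger cluster, then to the cluster containing the lexicographically
#' smallest sample id.
#'
#' @param d Symmetric distance matrix (e.g. from [jsd_distance_matrix()]).
#' @param clinical Optional data frame with `sample_id`, `survival_time`,
#'   `event` used to orient the labels.
#' @param k Number of clusters to cut (2 is the supported resolution;
#'   deeper cuts are exposed but only k = 2 receives Basal I/II labels).
#' @return Object of class `subgroup_labeling`: `labels` tibble
#'   (`sample_id`, `subgroup`), `hclust` (the merge tree), `cut_k`.
#' @export
ward_cluster <- function(d, clinical = NULL, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least two samples to cluster")
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  if (n == 2) {
    cl <- stats::setNames(1:2, ids)
    hc <- NULL
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
    cl <- stats::cutree(hc, k = k)
    names(cl) <- ids
  }
  if (k != 2) {
    labels <- tibble::tibble(sample_id = ids,
                             subgroup = paste0("cluster_", unname(cl[ids])))
    return(structure(list(labels = labels, hclust = hc, cut_k = k),
                     class = "subgroup_labeling"))
  }
  basal_I <- orient_basal_I(cl, clinical)
  labels <- tibble::tibble(
    sample_id = ids,
    subgroup = ifelse(unname(cl[ids]) == basal_I, "Basal I", "Basal II"))
  structure(list(labels = labels, hclust = hc, cut_k = k),
            class = "subgroup_labeling")
}

# pick which of clusters 1/2 is Basal I: longer KM median survival when
# clinical data is available, else the larger cluster
orient_basal_I <- function(cl, clinical) {
  if (!is.null(clinical)) {
    med <- vapply(1:2, function(g) {
      ids_g <- names(cl)[cl == g]
      sub <- clinical[clinical$sample_id %in% ids_g, ]
      if (nrow(sub) == 0) return(NA_real_)
      km_median(km_estimate(sub))
    }, numeric(1))
    if (!anyNA(med) && med[1] != med[2]) return(which.max(med))
  }
  sizes <- tabulate(cl, 2)
  if (sizes[1] != sizes[2]) return(which.max(sizes))
  unname(cl[order(names(cl))][1])
}

#' @export
print.subgroup_labeling <- function(x, ...) {
  tb <- table(x$labels$subgroup)
  cat("<subgroup_labeling> ", paste(names(tb), tb, sep = " = ",
                                    collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname ward_cluster
#' @param x A `subgroup_labeling`.
#' @param ... Unused.
#' @method tidy subgroup_labeling
#' @export
tidy.subgroup_labeling <- function(x, ...) x$labels

#' Refine the survival probe set into the discriminating signature
#'
#' Two-sided rank-sum p-value per probe between the two subgroups; probes
#' sorted ascending by p (degenerate, i.e. constant, probes get p = 1 and
#' sort last) and the signature sized by the same elbow rule as the filters.
#'
#' @param expr An `expr_mat` restricted (or restrictable) to tumour samples.
#' @param labels Subgroup labels (`subgroup_labeling`, data frame, or named
#'   vector).
#' @param probes Probe ids to consider (default all probes in `expr`);
#'   normally the survival probe set.
#' @param threshold As in [differential_filter()].
#' @return Tibble of class `signature`: `probe_id`, `p_value`, `rank`,
#'   `in_signature`, `degenerate`; elbow decision in `attr(, "threshold")`.
#' @export
refine_signature <- function(expr, labels, probes = NULL, threshold = "auto") {
  lab <- as_label_vector(labels)
  samples <- intersect(expr_samples(expr), names(lab))
  sub <- expr_subset(expr, probes = probes, samples = samples)
  m <- expr_values(sub)
  gI <- samples[lab[samples] == "Basal I"]
  gII <- samples[lab[samples] == "Basal II"]
  if (length(gI) == 0 || length(gII) == 0) {
    stop("both subgroups must be non-empty")
  }
  res <- purrr::map(rownames(m), function(pid) {
    v <- m[pid, ]
    if (length(unique(v)) == 1) {
      return(tibble::tibble(probe_id = pid, p_value = 1, degenerate = TRUE))
    }
    p <- rank_sum_test(m[pid, gI], m[pid, gII], "two.sided")$p_value
    tibble::tibble(probe_id = pid, p_value = p, degenerate = FALSE)
  })
  out <- dplyr::bind_rows(res)
  out <- out[order(out$degenerate, out$p_value, out$probe_id), ]
  out$rank <- seq_len(nrow(out))
  el <- if (identical(threshold, "auto")) curvature_threshold(out$p_value)
        else list(k = min(as.integer(threshold), nrow(out)),
                  p_value = NA_real_, distance = NA_real_, no_elbow = NA)
  out$in_signature <- out$rank <= el$k
  out <- tibble::as_tibble(out)[, c("probe_id", "p_value", "rank",
                                    "in_signature", "degenerate")]
  attr(out, "threshold") <- el
  class(out) <- c("signature", class(out))
  out
}

#' Signature probe ids
#'
#' @param x A `signature` tibble from [refine_signature()].
#' @return Character vector of probes inside the signature, in rank order.
#' @export
signature_probes <- function(x) x$probe_id[x$in_signature]

#' Cluster signature probes into three co-expression blocks
#'
#' Probes are clustered hierarchically with distance 1 - Spearman rho and
#' Ward linkage, cut at k = 3. The correlation is computed over every
#' available sample (tumours and controls): controls carry each module's
#' co-expression without the subgroup-shift component that is collinear
#' between blocks, which sharpens the block separation. Blocks are
#' named by their expression pattern across subgroups: G1 is the block with
#' the largest mean(Basal II) - mean(Basal I) (over-expressed in Basal II);
#' of the remaining two, G2 is the block with the higher overall tumour mean
#' (over-expressed in Basal I with Basal II near control level) and G3 the
#' rest (under-expressed in Basal II).
#'
#' @param expr An `expr_mat`.
#' @param signature A `signature` tibble, or a character vector of probe ids.
#' @param labels Subgroup labels.
#' @return The signature tibble with a `block` column in {G1, G2, G3}
#'   (probes outside the signature get NA).
#' @export
group_probes <- function(expr, signature, labels) {
  sig_ids <- if (is.character(signature)) signature
             else signature_probes(signature)
  if (length(sig_ids) < 3) stop("need at least 3 signature probes for k = 3")
  lab <- as_label_vector(labels)
  samples <- intersect(tumour_ids(expr), names(lab))
  mc <- expr_values(expr_subset(expr, probes = sig_ids))
  rho <- suppressWarnings(stats::cor(t(mc), method = "spearman"))
  rho[is.na(rho)] <- 0  # constant probes: no rank correlation signal
  d <- 1 - rho
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  cl <- stats::cutree(hc, k = 3)
  m <- mc[, samples, drop = FALSE]
  gI <- samples[lab[samples] == "Basal I"]
  gII <- samples[lab[samples] == "Basal II"]
  diff_by_block <- vapply(1:3, function(b) {
    mean(m[cl == b, gII, drop = FALSE]) - mean(m[cl == b, gI, drop = FALSE])
  }, numeric(1))
  mean_by_block <- vapply(1:3, function(b) mean(m[cl == b, , drop = FALSE]),
                          numeric(1))
  g1 <- which.max(diff_by_block)
  rest <- setdiff(1:3, g1)
  g2 <- rest[which.max(mean_by_block[rest])]
  g3 <- setdiff(rest, g2)
  block_name <- character(3)
  block_name[c(g1, g2, g3)] <- c("G1", "G2", "G3")
  if (is.character(signature)) {
    signature <- tibble::tibble(probe_id = signature,
                                in_signature = TRUE)
  }
  signature$block <- NA_character_
  signature$block[match(sig_ids, signature$probe_id)] <-
    block_name[unname(cl[sig_ids])]
  signature
}
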