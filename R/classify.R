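#' Subgroup centroids over the probe signature
#'
#' Per-probe arithmetic mean of expression within each subgroup.
#'
#' @param expr An `expr_mat` containing the training samples.
#' @param labels Subgroup labels covering the training tumours.
#' @param signature A `signature` tibble or character vector of probe ids.
#' @return Tibble of class `centroid_set` with columns `probe_id`,
#'   `basal_I`, `basal_II`; attributes `standardized` (FALSE) and
#'   `reference_n` (NA until standardized).
#' @export
compute_centroids <- function(expr, labels, signature) {
  sig_ids <- if (is.character(signature)) signature
             else signature_probes(signature)
  missing <- setdiff(sig_ids, expr_probes(expr))
  if (length(missing)) {
    stop("signature probes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  lab <- as_label_vector(labels)
  samples <- intersect(expr_samples(expr), names(lab))
  gI <- samples[lab[samples] == "Basal I"]
  gII <- samples[lab[samples] == "Basal II"]
  if (length(gI) == 0 || length(gII) == 0) {
    stop("both subgroups must be non-empty")
  }
  m <- expr_values(expr)[sig_ids, , drop = FALSE]
  out <- tibble::tibble(
    probe_id = sig_ids,
    basal_I = unname(rowMeans(m[, gI, drop = FALSE])),
    basal_II = unname(rowMeans(m[, gII, drop = FALSE])))
  attr(out, "standardized") <- FALSE
  attr(out, "reference_n") <- NA_integer_
  class(out) <- c("centroid_set", class(out))
  out
}

#' Per-probe mean standardization for cross-platform transfer
#'
#' Divides every value of probe j by that probe's mean expression over the N
#' reference basal-like samples, so a probe's standardized reference mean is
#' exactly 1 and platform-specific scale cancels. For an expression matrix
#' the reference defaults to the cohort itself (all of its samples — an
#' external validation cohort consists of basal-like tumours); for a
#' `centroid_set` a reference cohort must be supplied (the training cohort).
#'
#' @param x An `expr_mat` or `centroid_set`.
#' @param reference An `expr_mat` providing the reference samples; default
#'   `x` itself when `x` is an expression matrix.
#' @param reference_samples Sample ids to average over (default: all samples
#'   of `reference`).
#' @return `x` with values divided probe-wise by the reference mean;
#'   `attr(, "standardized")` set and `attr(, "reference_n")` recorded.
#' @export
standardize <- function(x, reference = NULL, reference_samples = NULL) {
  UseMethod("standardize")
}

ref_means <- function(x, reference, reference_samples, probes) {
  if (is.null(reference_samples)) reference_samples <- expr_samples(reference)
  m <- expr_values(expr_subset(reference, probes = probes,
                               samples = reference_samples))
  mu <- rowMeans(m)
  if (any(mu <= 0)) {
    stop("non-positive reference mean for probe(s): ",
         paste(names(mu)[mu <= 0], collapse = ", "))
  }
  list(mu = mu, n = length(reference_samples))
}

#' @rdname standardize
#' @export
standardize.expr_mat <- function(x, reference = NULL,
                                 reference_samples = NULL) {
  if (isTRUE(attr(x, "standardized"))) stop("already standardized")
  if (is.null(reference)) reference <- x
  r <- ref_means(x, reference, reference_samples, probes = expr_probes(x))
  m <- sweep(expr_values(x), 1, r$mu, "/")
  out <- expression_matrix(m, expr_probes(x), expr_samples(x),
                           sample_role = unname(expr_roles(x)),
                           platform = attr(x, "platform"))
  attr(out, "standardized") <- TRUE
  attr(out, "reference_n") <- r$n
  out
}

#' @rdname standardize
#' @export
standardize.centroid_set <- function(x, reference = NULL,
                                     reference_samples = NULL) {
  if (isTRUE(attr(x, "standardized"))) stop("already standardized")
  if (is.null(reference)) {
    stop("standardizing centroids requires a reference cohort")
  }
  r <- ref_means(x, reference, reference_samples, probes = x$probe_id)
  out <- x
  out$basal_I <- x$basal_I / r$mu
  out$basal_II <- x$basal_II / r$mu
  attr(out, "standardized") <- TRUE
  attr(out, "reference_n") <- r$n
  out
}

#' Nearest-centroid subgroup assignment
#'
#' Each sample is assigned to the subgroup whose centroid is nearest in
#' Euclidean distance over the shared probe list. Exact distance ties go to
#' Basal I (lexicographic) with `tie_flag` set. Samples and centroids must
#' agree in standardization state.
#'
#' @param expr An `expr_mat` of samples to classify.
#' @param centroids A `centroid_set`.
#' @return Tibble: `sample_id`, `label`, `distance_to_I`, `distance_to_II`,
#'   `tie_flag`.
#' @export
assign_subgroups <- function(expr, centroids) {
  if (isTRUE(attr(expr, "standardized")) !=
      isTRUE(attr(centroids, "standardized"))) {
    stop("standardization state mismatch between samples and centroids")
  }
  missing <- setdiff(centroids$probe_id, expr_probes(expr))
  if (length(missing)) {
    stop("centroid probes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  m <- expr_values(expr)[centroids$probe_id, , drop = FALSE]
  dI <- sqrt(colSums((m - centroids$basal_I)^2))
  dII <- sqrt(colSums((m - centroids$basal_II)^2))
  tie <- dI == dII
  tibble::tibble(
    sample_id = colnames(m),
    label = unname(ifelse(dI <= dII, "Basal I", "Basal II")),
    distance_to_I = unname(dI),
    distance_to_II = unname(dII),
    tie_flag = unname(tie))
}

#' Map a probe signature across platforms via an annotation table
#'
#' The annotation table joins source probes to target-platform probes
#' (optionally through a gene-symbol column). A signature probe with one or
#' more candidate targets keeps exactly one — the lexicographically smallest
#' target id; probes without a match are dropped. The attached report lists
#' the matched count, dropped probe ids, and many-to-one collisions (target
#' probes chosen by more than one source probe).
#'
#' @param signature A `signature` tibble or character vector of probe ids.
#' @param annotation Data frame with columns `source_probe`, `target_probe`
#'   and optionally `gene`.
#' @return Tibble `probe_id` (source), `target_probe`, with
#'   `attr(, "report")` = list(matched, dropped, collisions).
#' @export
map_probes <- function(signature, annotation) {
  sig_ids <- if (is.character(signature)) signature
             else signature_probes(signature)
  if (!all(c("source_probe", "target_probe") %in% names(annotation))) {
    stop("annotation table needs columns source_probe and target_probe")
  }
  ann <- annotation[annotation$source_probe %in% sig_ids, ]
  if (nrow(ann) == 0) stop("no probes mapped")
  mapped <- ann |>
    dplyr::group_by(.data$source_probe) |>
    dplyr::summarise(target_probe = min(.data$target_probe),
                     .groups = "drop")
  out <- tibble::tibble(probe_id = sig_ids) |>
    dplyr::inner_join(mapped, by = c(probe_id = "source_probe"))
  if (nrow(out) == 0) stop("no probes mapped")
  dropped <- setdiff(sig_ids, out$probe_id)
  collided <- out$target_probe[duplicated(out$target_probe)]
  attr(out, "report") <- list(
    matched = nrow(out),
    dropped = dropped,
    collisions = unique(collided))
  out
}
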