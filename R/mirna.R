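#' Replicated miRNA differential-expression screen across two cohorts
#'
#' Two-sided rank-sum p-value per miRNA probe between Basal I and Basal II,
#' computed independently in the training and validation cohorts. A probe is
#' selected when p < `alpha` in both cohorts. Direction is defined by the
#' median difference in the training cohort (`up_in_I` when the Basal I
#' median is at least the Basal II median).
#'
#' @param mirna_train,mirna_valid `expr_mat` objects sharing probe ids.
#' @param labels Subgroup labels covering the samples of both cohorts.
#' @param alpha Per-cohort selection threshold (default 0.01).
#' @return Tibble sorted by max(p_train, p_valid): `mirna_probe`, `p_train`,
#'   `p_valid`, `direction`, `selected`.
#' @export
mirna_de <- function(mirna_train, mirna_valid, labels, alpha = 0.01) {
  lab <- as_label_vector(labels)
  shared <- intersect(expr_probes(mirna_train), expr_probes(mirna_valid))
  only <- c(setdiff(expr_probes(mirna_train), shared),
            setdiff(expr_probes(mirna_valid), shared))
  if (length(only)) {
    warning("probes present in only one cohort excluded: ",
            paste(utils::head(only, 5), collapse = ", "),
            if (length(only) > 5) ", ...")
  }
  if (length(shared) == 0) stop("no shared probes between cohorts")
  cohort_p <- function(expr) {
    samples <- intersect(expr_samples(expr), names(lab))
    if (length(samples) == 0) stop("no labeled samples in cohort")
    m <- expr_values(expr)[shared, samples, drop = FALSE]
    gI <- samples[lab[samples] == "Basal I"]
    gII <- samples[lab[samples] == "Basal II"]
    if (length(gI) == 0 || length(gII) == 0) {
      stop("both subgroups must be present in each cohort")
    }
    t(apply(m, 1, function(v) {
      if (length(unique(v)) == 1) return(c(1, 0))
      c(rank_sum_test(v[gI], v[gII], "two.sided")$p_value,
        stats::median(v[gI]) - stats::median(v[gII]))
    }))
  }
  tr <- cohort_p(mirna_train)
  va <- cohort_p(mirna_valid)
  out <- tibble::tibble(
    mirna_probe = shared,
    p_train = unname(tr[, 1]),
    p_valid = unname(va[, 1]),
    direction = unname(ifelse(tr[, 2] >= 0, "up_in_I", "up_in_II")))
  out$selected <- out$p_train < alpha & out$p_valid < alpha
  out[order(pmax(out$p_train, out$p_valid), out$mirna_probe), ]
}

#' Per-subgroup miRNA-target gene correlation
#'
#' Spearman correlation between each miRNA and each of its user-supplied
#' target genes, computed within each subgroup separately over the samples
#' shared by the two matrices. A pair is flagged `replicated` when its
#' correlation p-value falls below `alpha` in both subgroups
#' (multiplicity-unadjusted).
#'
#' @param mirna_expr,gene_expr `expr_mat` objects sharing sample ids.
#' @param targets Data frame with columns `mirna_probe`, `gene` and
#'   optionally `database` (a free-text source tag; reported, not filtered
#'   on).
#' @param labels Subgroup labels.
#' @param alpha Per-subgroup significance threshold (default 0.05).
#' @param min_n Minimum shared samples per subgroup (default 4); pairs with
#'   fewer are skipped with a warning.
#' @return Tibble: `mirna_probe`, `gene`, `subgroup`, `n`, `rho`, `p_value`,
#'   `replicated`, `n_databases`.
#' @export
mirna_gene_correlation <- function(mirna_expr, gene_expr, targets, labels,
                                   alpha = 0.05, min_n = 4) {
  stopifnot(all(c("mirna_probe", "gene") %in% names(targets)))
  lab <- as_label_vector(labels)
  shared <- intersect(expr_samples(mirna_expr), expr_samples(gene_expr))
  shared <- intersect(shared, names(lab))
  if (length(shared) == 0) stop("no shared labeled samples")
  mm <- expr_values(mirna_expr)[, shared, drop = FALSE]
  gm <- expr_values(gene_expr)[, shared, drop = FALSE]
  pairs <- unique(targets[targets$mirna_probe %in% rownames(mm) &
                          targets$gene %in% rownames(gm),
                          c("mirna_probe", "gene")])
  if (nrow(pairs) == 0) stop("no target pairs present in both matrices")
  db_counts <- if ("database" %in% names(targets)) {
    targets |>
      dplyr::distinct(.data$mirna_probe, .data$gene, .data$database) |>
      dplyr::count(.data$mirna_probe, .data$gene, name = "n_databases")
  } else {
    dplyr::mutate(pairs, n_databases = NA_integer_)
  }
  groups <- sort(unique(lab[shared]))
  rows <- purrr::pmap(pairs, function(mirna_probe, gene) {
    purrr::map(groups, function(g) {
      ids <- shared[lab[shared] == g]
      if (length(ids) < min_n) {
        warning("pair (", mirna_probe, ", ", gene, ") skipped in ", g,
                ": fewer than ", min_n, " shared samples")
        return(NULL)
      }
      x <- mm[mirna_probe, ids]
      y <- gm[gene, ids]
      if (length(unique(x)) == 1 || length(unique(y)) == 1) {
        rho <- NA_real_
        p <- NA_real_
      } else {
        ct <- suppressWarnings(
          stats::cor.test(x, y, method = "spearman", exact = FALSE))
        rho <- unname(ct$estimate)
        p <- ct$p.value
      }
      tibble::tibble(mirna_probe = mirna_probe, gene = gene, subgroup = g,
                     n = length(ids), rho = rho, p_value = p)
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop("no testable pairs")
  rep_tbl <- out |>
    dplyr::group_by(.data$mirna_probe, .data$gene) |>
    dplyr::summarise(
      replicated = dplyr::n() == length(groups) &&
        all(!is.na(.data$p_value)) && all(.data$p_value < alpha),
      .groups = "drop")
  out |>
    dplyr::left_join(rep_tbl, by = c("mirna_probe", "gene")) |>
    dplyr::left_join(db_counts, by = c("mirna_probe", "gene"))
}
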