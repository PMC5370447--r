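#' Run the full stratification pipeline
#'
#' Executes every stage end-to-end: differential probe filter, survival
#' probe filter on the differential set, sqrt-JSD/Ward clustering of tumours
#' into two subgroups, signature refinement with co-expression blocks,
#' centroid computation (raw and standardized), self-assignment of the
#' training tumours, minimum-spanning-tree network report, replicated miRNA
#' screen, cytoband rates/binomial tests/PGA, subgroup log-rank comparison,
#' and clinical-feature association. All reports are written as
#' tab-separated files (p-values in scientific notation with 6 significant
#' digits) plus a JSON survival report, and every threshold decision is
#' appended to `pipeline.log` with its rank and p-value.
#'
#' The pipeline is a pure function of (inputs, config, seed): two runs with
#' the same config produce byte-identical reports.
#'
#' @param config A list or path to a YAML file. Recognized fields:
#' \describe{
#'   \item{cohort}{a `synthetic_cohort` object (in-memory input), or}
#'   \item{simulate}{list of [generate_cohort()] parameters, or}
#'   \item{inputs}{list of file paths: `expression`, `roles`, `clinical`,
#'     `mirna_train`, `mirna_valid`, `cna_states`, `cytobands`, and
#'     optionally `targets`, `annotation`.}
#'   \item{thresholds}{list with `differential` and `survival`, each
#'     `"auto"`, an integer rank, or a p cutoff (default `"auto"`).}
#'   \item{seed}{integer RNG seed (default 1).}
#'   \item{out_dir}{output directory (required).}
#' }
#' @return Invisibly, a list with every stage result plus `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must name out_dir")
  thresholds <- config$thresholds %||% list()
  thr_diff <- thresholds$differential %||% "auto"
  thr_surv <- thresholds$survival %||% "auto"
  seed <- config$seed %||% 1L

  # validate paths before any computation
  if (!is.null(config$inputs)) {
    paths <- unlist(config$inputs)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
    }
    required <- c("expression", "roles", "clinical", "mirna_train",
                  "mirna_valid", "cna_states", "cytobands")
    absent <- setdiff(required, names(config$inputs))
    if (length(absent)) {
      stop("config missing input path(s): ", paste(absent, collapse = ", "))
    }
  } else if (is.null(config$cohort) && is.null(config$simulate)) {
    stop("config must provide inputs, a cohort, or simulate parameters")
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character(0)
  log_it <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  set.seed(seed)
  log_it("seed\t", seed)

  data <- stage("load", {
    if (!is.null(config$cohort)) {
      config$cohort
    } else if (!is.null(config$simulate)) {
      do.call(generate_cohort, c(config$simulate, list(seed = seed)))
    } else {
      ip <- config$inputs
      list(expr = read_expression(ip$expression, ip$roles),
           clinical = readr::read_tsv(ip$clinical, show_col_types = FALSE),
           mirna_train = read_expression(ip$mirna_train),
           mirna_valid = read_expression(ip$mirna_valid),
           cna = readr::read_tsv(ip$cna_states, show_col_types = FALSE),
           cytobands = read_cytobands(ip$cytobands),
           targets = if (!is.null(ip$targets))
             readr::read_tsv(ip$targets, show_col_types = FALSE),
           valid_labels = if (!is.null(ip$valid_labels))
             readr::read_tsv(ip$valid_labels, show_col_types = FALSE))
    }
  })

  diff_res <- stage("filter-differential",
                    differential_filter(data$expr, threshold = thr_diff))
  log_elbow(log_it, "differential", attr(diff_res, "threshold"))
  write_report(diff_res, file.path(out_dir, "filter_differential.tsv"))

  surv_res <- stage("filter-survival", {
    keep <- passed_probes(diff_res)
    if (length(keep) < 3) stop("fewer than 3 probes passed differential")
    survival_filter(expr_subset(data$expr, probes = keep), data$clinical,
                    threshold = thr_surv)
  })
  log_elbow(log_it, "survival", attr(surv_res, "threshold"))
  write_report(surv_res, file.path(out_dir, "filter_survival.tsv"))

  labeling <- stage("cluster", {
    surv_probes <- passed_probes(surv_res)
    if (length(surv_probes) < 2) stop("fewer than 2 survival probes")
    d <- jsd_distance_matrix(data$expr, probes = surv_probes)
    ward_cluster(d, clinical = data$clinical)
  })
  write_report(labeling$labels, file.path(out_dir, "subgroups.tsv"))

  signature <- stage("signature", {
    sig <- refine_signature(
      expr_subset(data$expr, samples = tumour_ids(data$expr)),
      labeling, probes = passed_probes(surv_res))
    if (sum(sig$in_signature) >= 3) {
      sig <- group_probes(data$expr, sig, labeling)
    } else {
      # too few probes to split into co-expression blocks
      sig$block <- NA_character_
    }
    sig
  })
  log_elbow(log_it, "signature", attr(signature, "threshold"))
  write_report(signature, file.path(out_dir, "signature.tsv"))

  centroids <- stage("centroids", {
    compute_centroids(data$expr, labeling, signature)
  })
  cent_std <- stage("centroids", {
    standardize(centroids, reference = data$expr,
                reference_samples = tumour_ids(data$expr))
  })
  cent_out <- dplyr::bind_rows(
    dplyr::mutate(centroids, standardized = FALSE),
    dplyr::mutate(cent_std, standardized = TRUE))
  readr::write_csv(format_pvals(cent_out), file.path(out_dir, "centroids.csv"))

  assignments <- stage("classify", {
    assign_subgroups(
      expr_subset(data$expr, probes = centroids$probe_id,
                  samples = tumour_ids(data$expr)),
      centroids)
  })
  write_report(assignments, file.path(out_dir, "assignments.tsv"))

  network <- stage("network", {
    d <- correlation_distance(data$expr, probes = signature_probes(signature))
    mst <- build_mst(d)
    list(mst = mst, report = centrality_report(mst))
  })
  write_report(network$report, file.path(out_dir, "network_centrality.tsv"))
  write_report(network$mst$edges, file.path(out_dir, "network_edges.tsv"))

  mirna <- stage("mirna", {
    lab <- as_label_vector(labeling)
    # the validation cohort needs its own labels: the generator's truth, an
    # explicit label file, or overlap with the training samples
    lab_valid <- if (!is.null(data$truth$subgroup_valid)) {
      data$truth$subgroup_valid
    } else if (!is.null(data$valid_labels)) {
      as_label_vector(data$valid_labels)
    } else {
      stats::setNames(character(0), character(0))
    }
    mirna_de(data$mirna_train, data$mirna_valid, c(lab, lab_valid))
  })
  write_report(mirna, file.path(out_dir, "mirna_de.tsv"))

  cna <- stage("cna", {
    st <- data$cna
    if (any(st$state %in% c("homdel", "hetdel", "amp"))) {
      st <- collapse_states(st)
    }
    list(rates = cytoband_rates(st, labeling),
         binomial = cytoband_binomial(st, labeling),
         pga = pga(st, data$cytobands, labeling))
  })
  write_report(cna$rates, file.path(out_dir, "cna_rates.tsv"))
  write_report(cna$binomial, file.path(out_dir, "cna_binomial.tsv"))
  write_report(cna$pga, file.path(out_dir, "cna_pga.tsv"))

  surv_report <- stage("survival", {
    cl <- dplyr::inner_join(data$clinical, labeling$labels, by = "sample_id")
    lr <- logrank_test(cl)
    assoc <- clinical_association(data$clinical, labeling)
    list(logrank = lr, association = assoc)
  })
  write_report(surv_report$association,
               file.path(out_dir, "clinical_association.tsv"))
  jsonlite::write_json(
    list(logrank_statistic = surv_report$logrank$statistic,
         logrank_p = surv_report$logrank$p_value,
         n = surv_report$logrank$n,
         subgroup_sizes = as.list(table(labeling$labels$subgroup))),
    file.path(out_dir, "survival_report.json"),
    auto_unbox = TRUE, digits = NA)

  pt <- attr(cna$pga, "subgroup_test")
  log_it("pga_gain_p\t", format_sci(pt$p_value[pt$type == "gain"]))
  log_it("pga_loss_p\t", format_sci(pt$p_value[pt$type == "loss"]))
  log_it("logrank_p\t", format_sci(surv_report$logrank$p_value))
  writeLines(log_lines, log_path)

  invisible(list(
    differential = diff_res, survival = surv_res, labeling = labeling,
    signature = signature, centroids = centroids,
    centroids_standardized = cent_std, assignments = assignments,
    network = network, mirna = mirna, cna = cna,
    survival_report = surv_report, out_dir = out_dir))
}

log_elbow <- function(log_it, name, thr) {
  if (is.null(thr)) return(invisible())
  log_it("threshold\t", name, "\tk=", thr$k,
         "\tp=", format_sci(thr$p_value),
         "\tdistance=", format_sci(thr$distance),
         if (isTRUE(thr$no_elbow)) "\tno_elbow" else "")
}

format_sci <- function(p) {
  ifelse(is.na(p), "NA", sprintf("%.5e", p))
}

# p-value columns rendered in scientific notation with 6 significant digits
format_pvals <- function(df) {
  pcols <- grep("^(p_value|p_train|p_valid|p0)$", names(df), value = TRUE)
  for (cc in pcols) df[[cc]] <- format_sci(df[[cc]])
  df
}

write_report <- function(df, path) {
  df <- format_pvals(as.data.frame(df))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
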