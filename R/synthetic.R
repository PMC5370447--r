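#' Generate a synthetic basal-like cohort with full ground truth
#'
#' Emits every input the stratification pipeline consumes — a tumour/control
#' expression matrix with planted differential probes of three response
#' shapes, two latent tumour subgroups carrying a block-structured probe
#' signature, exponential survival with a subgroup hazard ratio, two miRNA
#' cohorts sharing planted differential probes, and per-cytoband copy-number
#' states with subgroup-specific gain/loss probabilities — together with the
#' ground truth needed to score recovery.
#'
#' Planting scheme (all shifts in units of `delta`, on top of a common
#' baseline of `baseline` log2 units with Normal(0, noise_sd) noise):
#' * case-a probes: -delta in every tumour;
#' * case-b probes: +delta in every tumour;
#' * case-c probes: +delta in half of the tumours (alternating), -delta in
#'   the other half, controls at the centre;
#' * G1 probes: +delta in Basal II tumours only;
#' * G2 probes: +delta in Basal I tumours, Basal II at control level;
#' * G3 probes: -delta in Basal II tumours only.
#'
#' Survival is exponential with Basal I median `median_survival` months and
#' Basal II hazard `hazard_ratio` times higher; each subject is independently
#' censored with probability `censor_rate`, the censoring time drawn
#' uniformly over (0, event time).
#'
#' @param n_tumour,n_control Cohort sizes.
#' @param n_probes Total mRNA probes (differential + signature + null).
#' @param n_diff Named integer vector `c(a=, b=, c=)` of planted differential
#'   probe counts per response shape.
#' @param n_signature Named integer vector `c(G1=, G2=, G3=)` of planted
#'   signature block sizes.
#' @param delta Effect size, in SD units of the noise.
#' @param subgroup_fraction Fraction of tumours in Basal I (the smaller,
#'   longer-surviving subgroup by default).
#' @param hazard_ratio Basal II hazard relative to Basal I.
#' @param censor_rate Probability a subject is censored.
#' @param median_survival Basal I median survival, months.
#' @param n_mirna Total miRNA probes per cohort.
#' @param n_mirna_diff Planted subgroup-differential miRNAs (direction
#'   alternates up_in_I / up_in_II).
#' @param mirna_delta miRNA effect size in SD units. The default 1.5 makes
#'   every planted miRNA reliably detectable at the two-cohort p < 0.01
#'   replication screen, mirroring that a study's reported miRNAs are the
#'   survivors of exactly that screen.
#' @param n_mirna_valid Samples in the miRNA validation cohort.
#' @param n_cytobands Number of cytobands (spread over 22 chromosomes with
#'   lengths uniform on 20-40 Mb).
#' @param gain_prob,loss_prob Named numeric vectors
#'   `c("Basal I" = , "Basal II" = )` of per-band per-sample aberration
#'   probabilities.
#' @param noise_sd Noise standard deviation (log2 units).
#' @param block_factor_sd Standard deviation (in units of `noise_sd`) of the
#'   latent per-sample factor shared within each signature block, making the
#'   blocks genuine co-expression modules on top of their subgroup shifts.
#'   The default 0.25 keeps module noise subordinate to the subgroup signal
#'   (the regime the clustering stage assumes) while still separating the
#'   blocks by mutual correlation. Set 0 to disable.
#' @param baseline Baseline expression level, log2 units; 8.0 keeps all
#'   values positive so per-probe reference means stay positive.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return Object of class `synthetic_cohort`: list with `expr`, `clinical`,
#'   `mirna_train`, `mirna_valid`, `cna` (long tibble sample_id/cytoband/
#'   state), `cytobands`, `truth`, `params`.
#' @export
generate_cohort <- function(n_tumour = 115, n_control = 144, n_probes = 400,
                            n_diff = c(a = 40, b = 40, c = 40),
                            n_signature = c(G1 = 30, G2 = 30, G3 = 20),
                            delta = 1, subgroup_fraction = 0.3,
                            hazard_ratio = 3, censor_rate = 0.3,
                            median_survival = 60,
                            n_mirna = 853, n_mirna_diff = 17, mirna_delta = 1.5,
                            n_mirna_valid = n_tumour, n_cytobands = 100,
                            gain_prob = c("Basal I" = 0.03, "Basal II" = 0.09),
                            loss_prob = c("Basal I" = 0.01, "Basal II" = 0.03),
                            noise_sd = 1, baseline = 8,
                            block_factor_sd = 0.25, seed = 1L) {
  stopifnot(n_tumour > 0, n_control > 0, n_probes > 0,
            subgroup_fraction > 0, subgroup_fraction < 1,
            hazard_ratio > 0, censor_rate >= 0, censor_rate < 1,
            all(n_diff >= 0), all(n_signature >= 0), noise_sd > 0)
  n_planted <- sum(n_diff) + sum(n_signature)
  if (n_planted > n_probes) {
    stop("n_diff + n_signature (", n_planted, ") exceeds n_probes (",
         n_probes, ")")
  }
  set.seed(seed)

  tum <- sprintf("T%03d", seq_len(n_tumour))
  ctl <- sprintf("C%03d", seq_len(n_control))
  probes <- sprintf("P%04d", seq_len(n_probes))

  n_I <- max(1, round(subgroup_fraction * n_tumour))
  subgroup <- stats::setNames(
    rep(c("Basal I", "Basal II"), c(n_I, n_tumour - n_I)), tum)

  # probe bookkeeping: planted sets first, nulls after
  idx <- 0
  take <- function(k) {
    out <- probes[seq_len(k) + idx]
    idx <<- idx + k
    out
  }
  diff_ids <- list(a = take(n_diff[["a"]]), b = take(n_diff[["b"]]),
                   c = take(n_diff[["c"]]))
  sig_ids <- list(G1 = take(n_signature[["G1"]]),
                  G2 = take(n_signature[["G2"]]),
                  G3 = take(n_signature[["G3"]]))

  m <- matrix(stats::rnorm(n_probes * (n_tumour + n_control), baseline,
                           noise_sd),
              nrow = n_probes, dimnames = list(probes, c(tum, ctl)))
  is_II <- subgroup[tum] == "Basal II"
  m[diff_ids$a, tum] <- m[diff_ids$a, tum] - delta * noise_sd
  m[diff_ids$b, tum] <- m[diff_ids$b, tum] + delta * noise_sd
  if (length(diff_ids$c)) {
    # parity split keeps the up/down halves balanced across both subgroups,
    # so case-c probes carry no subgroup signal
    up <- seq_len(n_tumour) %% 2 == 1
    m[diff_ids$c, tum[up]] <- m[diff_ids$c, tum[up]] + delta * noise_sd
    m[diff_ids$c, tum[!up]] <- m[diff_ids$c, tum[!up]] - delta * noise_sd
  }
  m[sig_ids$G1, tum[is_II]] <- m[sig_ids$G1, tum[is_II]] + delta * noise_sd
  m[sig_ids$G2, tum[!is_II]] <- m[sig_ids$G2, tum[!is_II]] + delta * noise_sd
  m[sig_ids$G3, tum[is_II]] <- m[sig_ids$G3, tum[is_II]] - delta * noise_sd
  # each signature block shares a latent per-sample factor so blocks are
  # genuine co-expression modules, not just mean shifts
  for (block in sig_ids) {
    if (length(block) == 0 || block_factor_sd <= 0) next
    f <- stats::rnorm(n_tumour + n_control, 0, block_factor_sd * noise_sd)
    m[block, ] <- m[block, ] + rep(f, each = length(block))
  }

  expr <- expression_matrix(m, probes, c(tum, ctl),
                            sample_role = rep(c("tumour", "control"),
                                              c(n_tumour, n_control)),
                            platform = "synthetic")

  # survival: exponential, Basal II hazard = hazard_ratio x Basal I hazard
  lambda_I <- log(2) / median_survival
  rate <- ifelse(is_II, hazard_ratio * lambda_I, lambda_I)
  t_event <- stats::rexp(n_tumour, rate)
  censored <- stats::runif(n_tumour) < censor_rate
  obs_time <- ifelse(censored, stats::runif(n_tumour) * t_event, t_event)
  clinical <- tibble::tibble(
    sample_id = tum,
    survival_time = obs_time,
    event = as.integer(!censored),
    age = round(stats::rnorm(n_tumour, 55, 10), 1),
    grade = sample(1:3, n_tumour, replace = TRUE,
                   prob = c(0.1, 0.3, 0.6))
  )

  mirna <- gen_mirna_cohort(n_mirna, n_mirna_diff, mirna_delta, tum,
                            subgroup[tum], prefix = "T", noise_sd = noise_sd,
                            baseline = baseline)
  val_ids <- sprintf("V%03d", seq_len(n_mirna_valid))
  n_I_val <- max(1, round(subgroup_fraction * n_mirna_valid))
  subgroup_val <- stats::setNames(
    rep(c("Basal I", "Basal II"), c(n_I_val, n_mirna_valid - n_I_val)),
    val_ids)
  mirna_v <- gen_mirna_cohort(n_mirna, n_mirna_diff, mirna_delta, val_ids,
                              subgroup_val, prefix = "V",
                              noise_sd = noise_sd, baseline = baseline)

  cytobands <- gen_cytobands(n_cytobands)
  states <- expand.grid(sample_id = tum, cytoband = cytobands$cytoband,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- gain_prob[subgroup[states$sample_id]]
  l <- loss_prob[subgroup[states$sample_id]]
  u <- stats::runif(nrow(states))
  states$state <- ifelse(u < g, "gain", ifelse(u < g + l, "loss", "neutral"))
  states <- tibble::as_tibble(states)

  truth <- list(
    subgroup = subgroup,
    subgroup_valid = subgroup_val,
    differential = diff_ids,
    signature = sig_ids,
    mirna = mirna$truth,
    gain_prob = gain_prob,
    loss_prob = loss_prob,
    delta = delta,
    block_factor_sd = block_factor_sd,
    mirna_delta = mirna_delta,
    hazard_ratio = hazard_ratio,
    lambda_I = lambda_I
  )
  structure(list(expr = expr, clinical = clinical,
                 mirna_train = mirna$expr, mirna_valid = mirna_v$expr,
                 cna = states, cytobands = cytobands, truth = truth,
                 params = as.list(environment())[c(
                   "n_tumour", "n_control", "n_probes", "delta",
                   "subgroup_fraction", "hazard_ratio", "censor_rate",
                   "noise_sd", "baseline", "seed")]),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(tumour_ids(x$expr)), " tumours + ",
      length(control_ids(x$expr)), " controls, ", nrow(x$expr), " probes; ",
      nrow(x$mirna_train), " miRNA probes; ", nrow(x$cytobands),
      " cytobands (seed ", x$params$seed, ")\n", sep = "")
  invisible(x)
}

gen_mirna_cohort <- function(n_mirna, n_diff, delta, sample_ids, subgroup,
                             prefix, noise_sd, baseline) {
  probes <- sprintf("mir%04d", seq_len(n_mirna))
  m <- matrix(stats::rnorm(n_mirna * length(sample_ids), baseline, noise_sd),
              nrow = n_mirna, dimnames = list(probes, sample_ids))
  direction <- character(0)
  if (n_diff > 0) {
    direction <- rep(c("up_in_I", "up_in_II"), length.out = n_diff)
    is_I <- subgroup == "Basal I"
    for (i in seq_len(n_diff)) {
      target <- if (direction[i] == "up_in_I") is_I else !is_I
      m[i, target] <- m[i, target] + delta * noise_sd
    }
  }
  list(expr = expression_matrix(m, probes, sample_ids,
                                sample_role = "tumour",
                                platform = paste0("synthetic-mirna-", prefix)),
       truth = tibble::tibble(mirna_probe = probes[seq_len(n_diff)],
                              direction = direction))
}

gen_cytobands <- function(n_cytobands) {
  chrom_of <- rep(paste0("chr", 1:22), length.out = n_cytobands)
  chrom_of <- sort(factor(chrom_of, levels = paste0("chr", 1:22)))
  lens <- round(stats::runif(n_cytobands, 20e6, 40e6))
  rows <- lapply(split(seq_len(n_cytobands), chrom_of), function(ii) {
    if (!length(ii)) return(NULL)
    ends <- cumsum(lens[ii])
    tibble::tibble(
      chrom = as.character(chrom_of[ii]),
      start_bp = c(0, utils::head(ends, -1)),
      end_bp = ends,
      band_name = paste0("q", 10 + seq_along(ii)),
      stain = "gneg")
  })
  tbl <- dplyr::bind_rows(rows)
  tbl$cytoband <- paste0(tbl$chrom, tbl$band_name)
  tbl$length_bp <- tbl$end_bp - tbl$start_bp
  tbl
}

#' Write a synthetic cohort as the pipeline's standard input files
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly. Writes expression + role map, clinical table,
#'   two miRNA matrices, CNA state table, cytoband file, and a `truth.json`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression(cohort$expr, p("expression.tsv"), p("roles.tsv"))
  readr::write_tsv(cohort$clinical, p("clinical.tsv"))
  write_expression(cohort$mirna_train, p("mirna_train.tsv"))
  write_expression(cohort$mirna_valid, p("mirna_valid.tsv"))
  readr::write_tsv(cohort$cna, p("cna_states.tsv"))
  utils::write.table(
    cohort$cytobands[, c("chrom", "start_bp", "end_bp", "band_name", "stain")],
    p("cytobands.txt"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  truth <- cohort$truth
  truth$subgroup <- as.list(truth$subgroup)
  truth$subgroup_valid <- as.list(truth$subgroup_valid)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
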