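#' Collapse five-state copy-number calls to gain/neutral/loss
#'
#' Homozygous and heterozygous deletions become `loss`; gains and
#' amplifications become `gain`; `neutral` stays.
#'
#' @param states Long tibble with columns `sample_id`, `cytoband`, `state`
#'   where `state` is one of `homdel`, `hetdel`, `neutral`, `gain`, `amp`.
#' @return The same tibble with `state` in `{loss, neutral, gain}`.
#' @export
collapse_states <- function(states) {
  stopifnot(all(c("sample_id", "cytoband", "state") %in% names(states)))
  map <- c(homdel = "loss", hetdel = "loss", neutral = "neutral",
           gain = "gain", amp = "gain")
  bad <- !(states$state %in% names(map))
  if (any(bad)) {
    i <- which(bad)[1]
    stop("unknown copy-number state '", states$state[i], "' at sample '",
         states$sample_id[i], "', cytoband '", states$cytoband[i], "'")
  }
  states$state <- unname(map[states$state])
  states
}

check_states <- function(states) {
  stopifnot(all(c("sample_id", "cytoband", "state") %in% names(states)))
  ok <- states$state %in% c("loss", "neutral", "gain")
  if (!all(ok)) {
    stop("states must be in {loss, neutral, gain}; found '",
         states$state[which(!ok)[1]], "' (collapse 5-state input first)")
  }
  invisible(states)
}

#' Per-cytoband gain/loss occurrence rates by subgroup
#'
#' @param states Long tibble `sample_id`, `cytoband`, `state` in
#'   {loss, neutral, gain}.
#' @param labels Subgroup labels covering every sample in `states`.
#' @return Tibble: `cytoband`, `subgroup`, `n`, `gain_count`, `loss_count`,
#'   `gain_rate`, `loss_rate`.
#' @export
cytoband_rates <- function(states, labels) {
  check_states(states)
  lab <- as_label_vector(labels)
  unlabeled <- setdiff(unique(states$sample_id), names(lab))
  if (length(unlabeled)) {
    stop("samples without subgroup label: ",
         paste(utils::head(unlabeled, 5), collapse = ", "))
  }
  st <- dplyr::mutate(states, subgroup = unname(lab[.data$sample_id]))
  if (any(table(lab[unique(states$sample_id)]) == 0)) {
    stop("empty subgroup")
  }
  st |>
    dplyr::group_by(.data$cytoband, .data$subgroup) |>
    dplyr::summarise(
      n = dplyr::n(),
      gain_count = sum(.data$state == "gain"),
      loss_count = sum(.data$state == "loss"),
      .groups = "drop") |>
    dplyr::mutate(gain_rate = .data$gain_count / .data$n,
                  loss_rate = .data$loss_count / .data$n)
}

#' Binomial test of per-cytoband aberration enrichment in each subgroup
#'
#' For each cytoband and aberration type the pooled occurrence rate p0 over
#' all labeled samples is the null; each subgroup's count k out of n is then
#' tested with an exact binomial test, two-sided by doubling the smaller
#' tail probability (capped at 1). Bands whose pooled rate is 0 or 1 are
#' untestable and reported with `testable = FALSE`.
#'
#' @inheritParams cytoband_rates
#' @param report_threshold Significance-screen threshold used for the
#'   `significant` flag in the report (default 0.15, a deliberately relaxed
#'   screen).
#' @return Tibble: `cytoband`, `type`, `subgroup`, `k`, `n`, `p0`,
#'   `p_value`, `testable`, `significant`.
#' @export
cytoband_binomial <- function(states, labels, report_threshold = 0.15) {
  check_states(states)
  lab <- as_label_vector(labels)
  rates <- cytoband_rates(states, labels)
  pooled <- states |>
    dplyr::group_by(.data$cytoband) |>
    dplyr::summarise(
      gain = mean(.data$state == "gain"),
      loss = mean(.data$state == "loss"), .groups = "drop") |>
    tidyr::pivot_longer(c("gain", "loss"), names_to = "type",
                        values_to = "p0")
  long <- rates |>
    tidyr::pivot_longer(c("gain_count", "loss_count"), names_to = "type",
                        values_to = "k") |>
    dplyr::mutate(type = sub("_count", "", .data$type)) |>
    dplyr::select("cytoband", "subgroup", "type", "k", "n") |>
    dplyr::left_join(pooled, by = c("cytoband", "type"))
  long$testable <- long$p0 > 0 & long$p0 < 1
  long$p_value <- NA_real_
  idx <- which(long$testable)
  long$p_value[idx] <- vapply(idx, function(i) {
    binom_twosided(long$k[i], long$n[i], long$p0[i])
  }, numeric(1))
  long$significant <- !is.na(long$p_value) & long$p_value < report_threshold
  long
}

#' Percent genome altered per sample, with a between-subgroup test
#'
#' PGA is length-weighted: the summed genomic length of a sample's gained
#' (or lost) cytobands as a percentage of the total genome length (the sum
#' of all band lengths). When labels are supplied a two-sided rank-sum test
#' compares the two subgroups for each aberration type; the result sits in
#' `attr(, "subgroup_test")`.
#'
#' @inheritParams cytoband_rates
#' @param cytobands Cytoband table with `cytoband` and `length_bp` columns
#'   (see [read_cytobands()]) covering every band in `states`.
#' @param labels Optional subgroup labels.
#' @return Tibble of class `pga_result`: `sample_id`, `pga_gain`, `pga_loss`
#'   (percent), plus `subgroup` when labels are given.
#' @export
pga <- function(states, cytobands, labels = NULL) {
  check_states(states)
  stopifnot(all(c("cytoband", "length_bp") %in% names(cytobands)))
  if (any(cytobands$length_bp <= 0)) stop("cytoband lengths must be positive")
  missing <- setdiff(unique(states$cytoband), cytobands$cytoband)
  if (length(missing)) {
    stop("cytobands without coordinates: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  total <- sum(cytobands$length_bp)
  len <- stats::setNames(cytobands$length_bp, cytobands$cytoband)
  out <- states |>
    dplyr::mutate(length_bp = unname(len[.data$cytoband])) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      pga_gain = 100 * sum(.data$length_bp[.data$state == "gain"]) / total,
      pga_loss = 100 * sum(.data$length_bp[.data$state == "loss"]) / total,
      .groups = "drop")
  if (!is.null(labels)) {
    lab <- as_label_vector(labels)
    out$subgroup <- unname(lab[out$sample_id])
    gI <- out$subgroup == sort(unique(out$subgroup))[1]
    test <- tibble::tibble(
      type = c("gain", "loss"),
      p_value = c(
        rank_sum_test(out$pga_gain[gI], out$pga_gain[!gI])$p_value,
        rank_sum_test(out$pga_loss[gI], out$pga_loss[!gI])$p_value))
    attr(out, "subgroup_test") <- test
  }
  class(out) <- c("pga_result", class(out))
  out
}

#' Quantize per-sample segment calls to cytoband states by majority overlap
#'
#' A band's state is the state covering the largest fraction of its length;
#' exact ties resolve to neutral. Uncovered length counts as neutral.
#'
#' @param segments Tibble: `sample_id`, `chrom`, `start_bp`, `end_bp`,
#'   `state` in {loss, neutral, gain} (0-based half-open coordinates).
#' @param cytobands Cytoband table from [read_cytobands()].
#' @return Long state tibble as consumed by [cytoband_rates()] etc.
#' @export
quantize_segments <- function(segments, cytobands) {
  stopifnot(all(c("sample_id", "chrom", "start_bp", "end_bp", "state")
                %in% names(segments)))
  ok <- segments$state %in% c("loss", "neutral", "gain")
  if (!all(ok)) stop("segment states must be in {loss, neutral, gain}")
  samples <- unique(segments$sample_id)
  rows <- purrr::map(samples, function(s) {
    seg <- segments[segments$sample_id == s, ]
    st <- vapply(seq_len(nrow(cytobands)), function(i) {
      b <- cytobands[i, ]
      ov <- seg[seg$chrom == b$chrom &
                seg$end_bp > b$start_bp & seg$start_bp < b$end_bp, ]
      cover <- c(loss = 0, neutral = 0, gain = 0)
      if (nrow(ov)) {
        w <- pmin(ov$end_bp, b$end_bp) - pmax(ov$start_bp, b$start_bp)
        for (typ in names(cover)) cover[typ] <- sum(w[ov$state == typ])
      }
      cover["neutral"] <- cover["neutral"] +
        (b$length_bp - sum(cover))  # uncovered length is neutral
      best <- max(cover)
      winners <- names(cover)[cover == best]
      if (length(winners) > 1) "neutral" else winners
    }, character(1))
    tibble::tibble(sample_id = s, cytoband = cytobands$cytoband, state = st)
  })
  dplyr::bind_rows(rows)
}
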