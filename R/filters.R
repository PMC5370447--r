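#' Differential probe filter (three-case tumour/control screen)
#'
#' For each probe three one-sided rank-sum tests are run between tumours and
#' controls: (a) tumours lower, (b) tumours higher, and (c) tumours both
#' lower and higher with controls in between. Case (c) folds every value x
#' to |x - m|, m being that probe's control mean, so that tumours deviating
#' in either direction become uniformly larger than controls, then tests
#' folded tumours greater. A probe's separation power is the minimal p-value
#' over the three cases, reported with its case label.
#'
#' The probe set passing the filter is sized by [curvature_threshold()] on
#' the ordered p-values unless an explicit `threshold` is given.
#'
#' @param expr An `expr_mat` containing both tumour and control samples.
#' @param threshold `"auto"` (elbow rule), an integer rank cutoff, or a
#'   p-value cutoff in (0, 1).
#' @return Tibble of class `filter_result`: `probe_id`, `filter`, `case`
#'   (`lower` / `higher` / `both`), `p_value` (the minimal case p — a
#'   ranking score, anti-conservative as a p-value since it is a minimum
#'   over three dependent tests), the individual `p_lower`, `p_higher`,
#'   `p_both` (each a calibrated one-sided rank-sum p), `rank`, `passed`,
#'   `degenerate`; sorted by ascending `p_value`. The elbow decision (cutoff
#'   rank, its p-value, chord distance) is in `attr(, "threshold")`.
#' @export
differential_filter <- function(expr, threshold = "auto") {
  tum <- tumour_ids(expr)
  ctl <- control_ids(expr)
  if (length(tum) < 2 || length(ctl) < 2) {
    stop("differential filter needs at least 2 tumours and 2 controls")
  }
  m <- expr_values(expr)
  res <- purrr::map(rownames(m), function(pid) {
    tv <- m[pid, tum]
    cv <- m[pid, ctl]
    if (stats::var(c(tv, cv)) == 0) {
      return(tibble::tibble(probe_id = pid, case = "higher", p_value = 1,
                            p_lower = 1, p_higher = 1, p_both = 1,
                            degenerate = TRUE))
    }
    p_lower <- rank_sum_test(tv, cv, "less")$p_value
    p_higher <- rank_sum_test(tv, cv, "greater")$p_value
    ctl_mean <- mean(cv)
    p_both <- rank_sum_test(abs(tv - ctl_mean), abs(cv - ctl_mean),
                            "greater")$p_value
    ps <- c(lower = p_lower, higher = p_higher, both = p_both)
    best <- which.min(ps)  # ties: first of (lower, higher, both)
    tibble::tibble(probe_id = pid, case = names(ps)[best],
                   p_value = unname(ps[best]), p_lower = p_lower,
                   p_higher = p_higher, p_both = p_both, degenerate = FALSE)
  })
  out <- dplyr::bind_rows(res)
  finish_filter(out, filter = "differential", threshold = threshold)
}

#' Survival probe filter (tertile log-rank screen)
#'
#' For each probe, tumour samples are ordered by expression (ties broken by
#' ascending sample id); the first floor(n/3) samples form the relatively
#' under-expressed group and the last floor(n/3) the relatively
#' over-expressed group (middle samples discarded). A log-rank test between
#' the two groups gives the probe's stratification power.
#'
#' @param expr An `expr_mat`; only its tumour samples are used.
#' @param clinical Data frame with `sample_id`, `survival_time`, `event`
#'   covering every tumour sample.
#' @inheritParams differential_filter
#' @return Tibble of class `filter_result` with `case = "na"`, sorted by
#'   ascending p-value; see [differential_filter()].
#' @export
survival_filter <- function(expr, clinical, threshold = "auto") {
  tum <- tumour_ids(expr)
  if (length(tum) < 6) stop("survival filter needs at least 6 tumour samples")
  missing <- setdiff(tum, clinical$sample_id)
  if (length(missing)) {
    stop("tumour samples without clinical record: ",
         paste(missing, collapse = ", "))
  }
  cl <- clinical[match(tum, clinical$sample_id), ]
  if (anyNA(cl$survival_time) || anyNA(cl$event)) {
    stop("every tumour sample needs survival_time and event")
  }
  m <- expr_values(expr)[, tum, drop = FALSE]
  n3 <- floor(length(tum) / 3)
  res <- purrr::map(rownames(m), function(pid) {
    v <- m[pid, ]
    ord <- order(v, tum)  # ties broken by ascending sample id
    degenerate <- length(unique(v)) == 1
    low <- ord[seq_len(n3)]
    high <- ord[seq.int(length(tum) - n3 + 1, length(tum))]
    idx <- c(low, high)
    grp <- rep(c("low", "high"), each = n3)
    lr <- suppressWarnings(
      logrank_core(cl$survival_time[idx], cl$event[idx], grp))
    tibble::tibble(probe_id = pid, case = "na", p_value = lr$p_value,
                   degenerate = degenerate)
  })
  out <- dplyr::bind_rows(res)
  finish_filter(out, filter = "survival", threshold = threshold)
}

# sort by p (probe id tie-break), rank, apply threshold, classify
finish_filter <- function(out, filter, threshold) {
  out <- out[order(out$p_value, out$probe_id), ]
  out$rank <- seq_len(nrow(out))
  if (identical(threshold, "auto")) {
    el <- curvature_threshold(out$p_value)
    k <- el$k
    thr_info <- el
  } else if (is.numeric(threshold) && threshold >= 1) {
    k <- min(as.integer(threshold), nrow(out))
    thr_info <- list(k = k, p_value = out$p_value[k], distance = NA_real_,
                     no_elbow = NA)
  } else if (is.numeric(threshold) && threshold > 0 && threshold < 1) {
    k <- sum(out$p_value <= threshold)
    thr_info <- list(k = k, p_value = threshold, distance = NA_real_,
                     no_elbow = NA)
  } else {
    stop("threshold must be 'auto', an integer rank, or a p cutoff in (0,1)")
  }
  out$passed <- out$rank <= k
  out <- tibble::as_tibble(out)
  keep <- intersect(c("probe_id", "filter", "case", "p_value", "p_lower",
                      "p_higher", "p_both", "rank", "passed", "degenerate"),
                    c(names(out), "filter"))
  out <- dplyr::bind_cols(tibble::tibble(filter = filter), out)[, keep]
  attr(out, "threshold") <- thr_info
  class(out) <- c("filter_result", class(out))
  out
}

#' Elbow rule on an ordered p-value curve
#'
#' With y_r = -log10(p_r) plotted against rank r, the cutoff is the rank
#' maximizing the perpendicular distance from (r, y_r) to the chord joining
#' (1, y_1) and (n, y_n) — the point of highest curvature of the ordered
#' p-value curve. When the curve is collinear (all distances below 1e-12)
#' there is no elbow and the cutoff falls back to n with a warning.
#'
#' @param p_values Numeric vector of p-values in (0, 1], sorted ascending.
#' @return List of class `elbow`: `k` (rank cutoff), `p_value` (p at the
#'   cutoff), `distance` (maximal chord distance), `no_elbow` flag.
#' @export
curvature_threshold <- function(p_values) {
  n <- length(p_values)
  if (n < 3) stop("need >=3 points to locate an elbow")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  if (is.unsorted(p_values)) stop("p-values must be sorted ascending")
  y <- -log10(p_values)
  r <- seq_len(n)
  dy <- y[n] - y[1]
  dr <- n - 1
  dist <- abs(dy * (r - 1) - dr * (y - y[1])) / sqrt(dr^2 + dy^2)
  if (all(dist <= 1e-12)) {
    warning("no elbow: ordered p-value curve is collinear; returning n")
    out <- list(k = n, p_value = p_values[n], distance = 0, no_elbow = TRUE)
  } else {
    k <- which.max(dist)
    out <- list(k = k, p_value = p_values[k], distance = max(dist),
                no_elbow = FALSE)
  }
  class(out) <- "elbow"
  out
}

#' @export
print.elbow <- function(x, ...) {
  cat("<elbow> rank cutoff k =", x$k, "at p =", format(x$p_value, digits = 4),
      "(chord distance", signif(x$distance, 4),
      if (x$no_elbow) ", no elbow)" else ")", "\n")
  invisible(x)
}

#' @rdname curvature_threshold
#' @param x An `elbow`.
#' @param ... Unused.
#' @method glance elbow
#' @export
glance.elbow <- function(x, ...) {
  tibble::tibble(k = x$k, p_value = x$p_value, distance = x$distance,
                 no_elbow = x$no_elbow)
}

#' Probes passing a filter
#'
#' @param x A `filter_result` tibble.
#' @return Character vector of probe ids with `passed = TRUE`, in rank order.
#' @export
passed_probes <- function(x) x$probe_id[x$passed]
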