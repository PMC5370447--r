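#' Kaplan-Meier product-limit estimate
#'
#' Fits the product-limit estimator S(t) = prod over event times <= t of
#' (1 - d_i / n_i) to right-censored survival data via [survival::survfit()].
#'
#' @param clinical Data frame with one row per subject.
#' @param time_col,event_col Column names holding follow-up time (months,
#'   non-negative) and the event indicator (1 = death, 0 = censored).
#' @return An object of class `km_fit`; use [tidy()] for the step function
#'   as a tibble (`time`, `n_risk`, `n_event`, `n_censor`, `survival`).
#' @export
km_estimate <- function(clinical, time_col = "survival_time",
                        event_col = "event") {
  stopifnot(is.data.frame(clinical))
  if (nrow(clinical) == 0) stop("km_estimate: empty input")
  times <- clinical[[time_col]]
  events <- clinical[[event_col]]
  if (is.null(times) || is.null(events)) {
    stop("km_estimate: columns '", time_col, "' and '", event_col,
         "' are required")
  }
  if (any(times < 0)) stop("km_estimate: negative survival time")
  if (!all(events %in% c(0, 1))) stop("km_estimate: event must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(fit = fit, n = length(times)), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> n =", x$n, ", events =", sum(x$fit$n.event), "\n")
  invisible(x)
}

#' @rdname km_estimate
#' @param x A `km_fit`.
#' @param ... Unused.
#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) {
  f <- x$fit
  tibble::tibble(time = f$time, n_risk = f$n.risk, n_event = f$n.event,
                 n_censor = f$n.censor, survival = f$surv)
}

#' Survival probability at a time point
#'
#' @param x A `km_fit`.
#' @param t Time at which to evaluate the step function.
#' @return S(t).
#' @export
km_survival_at <- function(x, t) {
  tb <- tidy(x)
  keep <- tb$time <= t
  if (!any(keep)) return(1)
  tb$survival[max(which(keep))]
}

#' Median survival time from a Kaplan-Meier fit
#'
#' First time the survival curve drops to 0.5 or below; `Inf` when the curve
#' never reaches 0.5.
#'
#' @param x A `km_fit`.
#' @return Median survival time (possibly `Inf`).
#' @export
km_median <- function(x) {
  tb <- tidy(x)
  idx <- which(tb$survival <= 0.5 + 1e-12)
  if (length(idx) == 0) return(Inf)
  tb$time[min(idx)]
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square statistic with 1 degree of
#' freedom, computed with [survival::survdiff()]; ties are aggregated at tied
#' event times with the usual hypergeometric variance.
#'
#' @param clinical Data frame with survival columns and a grouping column.
#' @param group_col Name of the column holding exactly two groups.
#' @inheritParams km_estimate
#' @return Object of class `logrank_test` with fields `statistic`, `p_value`,
#'   `df`, `n`; see [glance()].
#' @export
logrank_test <- function(clinical, group_col = "subgroup",
                         time_col = "survival_time", event_col = "event") {
  times <- clinical[[time_col]]
  events <- clinical[[event_col]]
  groups <- as.character(clinical[[group_col]])
  logrank_core(times, events, groups)
}

logrank_core <- function(times, events, groups) {
  g <- unique(groups)
  if (length(g) != 2 || any(table(groups) == 0)) {
    stop("log-rank test needs exactly two non-empty groups")
  }
  if (sum(events) == 0) {
    warning("no events in either group; log-rank statistic undefined, p = 1")
    return(structure(list(statistic = 0, p_value = 1, df = 1,
                          n = length(times)), class = "logrank_test"))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  stat <- unname(sd$chisq)
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 df = 1, n = length(times)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("<logrank_test> chisq =", signif(x$statistic, 6), "df = 1, p =",
      format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' @rdname logrank_test
#' @param x A `logrank_test`.
#' @param ... Unused.
#' @method glance logrank_test
#' @export
glance.logrank_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value, df = x$df,
                 n = x$n)
}

#' Clinical feature association with subgroups
#'
#' For numeric features, a Kruskal-Wallis rank test between the two
#' subgroups (equivalent to a two-sided rank-sum test for two groups). For
#' categorical features, an exact binomial test of the Basal I count of the
#' modal pooled category against the pooled proportion, two-sided by tail
#' doubling. Rows with a missing value are excluded per feature (pairwise
#' deletion).
#'
#' @param clinical Data frame with a `sample_id` column and feature columns.
#' @param labels Data frame (`sample_id`, `subgroup`) or named character
#'   vector of subgroup labels.
#' @param features Character vector of feature column names to test; default
#'   all columns other than `sample_id`, `survival_time`, `event`.
#' @param types Optional named character vector declaring each feature
#'   `"numeric"` or `"categorical"`; by default numeric columns are numeric,
#'   everything else categorical.
#' @return Tibble with columns `feature`, `type`, `n_used`, `p_value`,
#'   `degenerate` (constant feature).
#' @export
clinical_association <- function(clinical, labels, features = NULL,
                                 types = NULL) {
  lab <- as_label_vector(labels)
  keep <- clinical$sample_id %in% names(lab)
  clin <- clinical[keep, , drop = FALSE]
  grp <- unname(lab[clin$sample_id])
  if (length(unique(grp)) != 2) stop("need exactly two subgroups")
  if (is.null(features)) {
    features <- setdiff(names(clin), c("sample_id", "survival_time", "event"))
  }
  rows <- purrr::map(features, function(f) {
    v <- clin[[f]]
    ftype <- if (!is.null(types) && f %in% names(types)) types[[f]]
             else if (is.numeric(v)) "numeric" else "categorical"
    ok <- !is.na(v)
    vv <- v[ok]
    gg <- grp[ok]
    degenerate <- length(unique(vv)) <= 1 || length(unique(gg)) < 2
    if (degenerate) {
      p <- 1
    } else if (ftype == "numeric") {
      p <- stats::kruskal.test(vv, factor(gg))$p.value
    } else {
      cats <- sort(unique(as.character(vv)))
      counts <- table(factor(as.character(vv), levels = cats))
      positive <- cats[which.max(counts)]  # modal pooled category
      p0 <- mean(vv == positive)
      gI <- sort(unique(gg))[1]
      in_I <- gg == gI
      k <- sum(vv[in_I] == positive)
      n <- sum(in_I)
      p <- if (p0 <= 0 || p0 >= 1) 1 else binom_twosided(k, n, p0)
    }
    tibble::tibble(feature = f, type = ftype, n_used = sum(ok),
                   p_value = p, degenerate = degenerate)
  })
  dplyr::bind_rows(rows)
}

# labels as named character vector (names = sample ids)
as_label_vector <- function(labels) {
  if (inherits(labels, "subgroup_labeling")) labels <- labels$labels
  if (is.data.frame(labels)) {
    stopifnot(all(c("sample_id", "subgroup") %in% names(labels)))
    return(stats::setNames(as.character(labels$subgroup), labels$sample_id))
  }
  if (is.null(names(labels))) stop("labels must be named by sample id")
  stats::setNames(as.character(labels), names(labels))
}
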