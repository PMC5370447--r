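#' Elbow plot of ordered filter p-values
#'
#' Plots -log10(p) against probe rank with the chord and the chosen cutoff,
#' visualizing the highest-curvature threshold.
#'
#' @param filter_result A `filter_result` or `signature` tibble carrying an
#'   elbow decision in `attr(, "threshold")`.
#' @return A ggplot object.
#' @export
plot_pvalue_elbow <- function(filter_result) {
  thr <- attr(filter_result, "threshold")
  df <- tibble::tibble(rank = filter_result$rank,
                       neg_log10_p = -log10(filter_result$p_value))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                        y = .data$neg_log10_p)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::annotate("segment", x = 1, y = df$neg_log10_p[1],
                      xend = nrow(df), yend = df$neg_log10_p[nrow(df)],
                      linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = "probe rank", y = expression(-log[10](p)),
                  title = "Ordered p-value curve and elbow cutoff")
  if (!is.null(thr) && is.finite(thr$k)) {
    p <- p + ggplot2::geom_vline(xintercept = thr$k, colour = "firebrick",
                                 linetype = "dotted")
  }
  p
}

#' @rdname plot_pvalue_elbow
#' @param object A `filter_result`.
#' @param ... Unused.
#' @method autoplot filter_result
#' @export
autoplot.filter_result <- function(object, ...) plot_pvalue_elbow(object)

#' Kaplan-Meier step curve
#'
#' @param object A `km_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  tb <- tidy(object)
  df <- dplyr::bind_rows(tibble::tibble(time = 0, survival = 1),
                         tb[, c("time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  title = "Kaplan-Meier estimate")
}

#' Kaplan-Meier curves by subgroup
#'
#' @param clinical Data frame with survival columns.
#' @param labels Subgroup labels.
#' @inheritParams km_estimate
#' @return A ggplot object with one step curve per subgroup.
#' @export
plot_km_subgroups <- function(clinical, labels, time_col = "survival_time",
                              event_col = "event") {
  lab <- as_label_vector(labels)
  cl <- clinical[clinical$sample_id %in% names(lab), ]
  cl$subgroup <- unname(lab[cl$sample_id])
  curves <- purrr::map(split(cl, cl$subgroup), function(sub) {
    tb <- tidy(km_estimate(sub, time_col, event_col))
    dplyr::bind_rows(tibble::tibble(time = 0, survival = 1),
                     tb[, c("time", "survival")]) |>
      dplyr::mutate(subgroup = sub$subgroup[1])
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data$subgroup)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  colour = NULL)
}

#' Percent-genome-altered boxplots by subgroup
#'
#' @param object A `pga_result` with a `subgroup` column.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pga_result
#' @export
autoplot.pga_result <- function(object, ...) {
  if (is.null(object$subgroup)) stop("pga result has no subgroup column")
  long <- tidyr::pivot_longer(object, c("pga_gain", "pga_loss"),
                              names_to = "type", values_to = "pga")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subgroup, y = .data$pga,
                                     fill = .data$subgroup)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~type, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "percent genome altered")
}

#' Minimum spanning tree plot
#'
#' Node size tracks degree, colour tracks betweenness centrality.
#'
#' @param mst An `mst_graph`.
#' @param seed Layout seed for reproducibility.
#' @return Invisibly, the igraph object; draws with base graphics.
#' @export
plot_mst <- function(mst, seed = 1L) {
  g <- mst_igraph(mst)
  rep <- centrality_report(mst)
  b <- rep$betweenness[match(igraph::V(g)$name, rep$probe_id)]
  dg <- rep$degree[match(igraph::V(g)$name, rep$probe_id)]
  pal <- grDevices::colorRampPalette(c("mistyrose", "red3"))(101)
  set.seed(seed)
  igraph::plot.igraph(
    g, vertex.size = 4 + 3 * dg,
    vertex.color = pal[1 + round(100 * b)],
    vertex.label.cex = 0.6)
  invisible(g)
}

#' @rdname compute_centroids
#' @param x A `centroid_set`.
#' @param ... Unused.
#' @method tidy centroid_set
#' @export
tidy.centroid_set <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)), -"probe_id",
                      names_to = "subgroup", values_to = "value")
}
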