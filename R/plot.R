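#' Plot a T2* time curve
#'
#' Line plot of the ROI-mean T2* time course with the three paradigm phases
#' (rest, occlusion, reperfusion) shaded, and flagged frames marked.
#'
#' @param object A `t2star_curve`.
#' @param features Optional [extract_features()] result to annotate the
#'   baseline level and the detected peak.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.t2star_curve <- function(object, features = NULL, ...) {
  sched <- curve_schedule(object)
  phases <- tibble::tibble(
    phase = factor(c("rest", "occlusion", "reperfusion"),
                   levels = c("rest", "occlusion", "reperfusion")),
    xmin = c(0, sched$occlusion_start, sched$release_time),
    xmax = c(sched$occlusion_start, sched$release_time,
             sched$total_duration)
  )
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$time_s, y = .data$t2star_ms)) +
    ggplot2::geom_rect(
      data = phases, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$phase),
      alpha = 0.12) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_point(data = dplyr::filter(object, .data$flagged),
                        colour = "red", size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "T2* (ms)",
                  title = attr(object, "roi_label")) +
    ggplot2::theme_minimal()
  if (!is.null(features)) {
    p <- p +
      ggplot2::geom_hline(yintercept = features$bl_ms, linetype = 2) +
      ggplot2::annotate("point", x = features$peak_time_s,
                        y = features$hpv_ms, shape = 4, size = 3)
  }
  p
}

#' @export
plot.t2star_curve <- function(x, ...) print(autoplot.t2star_curve(x, ...))

#' QC boxplot of cohort TTP by group
#'
#' @param table A cohort feature table as accepted by [summarize_cohort()].
#' @param feature Feature column to plot (default `"ttp_s"`).
#' @return A ggplot object: boxplots per group, faceted by ROI.
#' @export
plot_cohort_feature <- function(table, feature = "ttp_s") {
  stopifnot(feature %in% names(table))
  ggplot2::ggplot(table, ggplot2::aes(x = .data$group,
                                      y = .data[[feature]],
                                      fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::facet_wrap(~roi_label) +
    ggplot2::labs(y = feature, x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
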