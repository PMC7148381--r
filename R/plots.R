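# Presentation-only figures; no numbers are read back from them.

#' Plot per-patient organ RBE with cohort medians and CI envelopes
#'
#' One panel-less scatter in the style of a cohort RBE summary: per-patient
#' markers of a chosen RBE metric by organ and model, a dashed cohort-median
#' line per group, and (optionally) a shaded band showing the metric
#' envelope over the (alpha/beta)x confidence interval.
#'
#' @param metrics metrics data.frame from \code{\link{cohortMetrics}}.
#' @param metric \code{"rbe_d"} or \code{"rbe_d2pct"}.
#' @param envelopes optional data.frame with columns organ, model,
#'   envelope_min, envelope_max (e.g. the pipeline's sweep output).
#' @return A ggplot object.
#' @export
plotRBESummary <- function(metrics, metric = c("rbe_d", "rbe_d2pct"),
                           envelopes = NULL) {
  metric <- match.arg(metric)
  df <- metrics[metrics$model != "constant_1p1", ]
  med <- stats::aggregate(df[[metric]],
                          by = list(organ = df$organ, model = df$model),
                          FUN = stats::median)
  names(med)[3] <- "median"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[["organ"]],
                                        y = .data[[metric]],
                                        colour = .data[["model"]]))
  if (!is.null(envelopes))
    p <- p + ggplot2::geom_rect(
      data = envelopes,
      ggplot2::aes(xmin = as.numeric(factor(.data[["organ"]],
                                            levels = levels(factor(df$organ)))) - 0.35,
                   xmax = as.numeric(factor(.data[["organ"]],
                                            levels = levels(factor(df$organ)))) + 0.35,
                   ymin = .data[["envelope_min"]],
                   ymax = .data[["envelope_max"]]),
      inherit.aes = FALSE, fill = "grey80", alpha = 0.5)
  p +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 2, alpha = 0.8) +
    ggplot2::geom_errorbar(
      data = med,
      ggplot2::aes(x = .data[["organ"]], ymin = .data[["median"]],
                   ymax = .data[["median"]], colour = .data[["model"]]),
      inherit.aes = FALSE, linetype = "dashed", width = 0.6) +
    ggplot2::labs(x = NULL,
                  y = if (metric == "rbe_d") "dose-weighted organ-mean RBE"
                      else "RBE of the near-maximum dose (D2%)") +
    ggplot2::theme_minimal()
}

#' Plot individual vs population vs constant-1.1 dose estimates
#'
#' @param comparison output of \code{\link{compareDoseEstimates}}.
#' @return A ggplot object.
#' @export
plotDoseEstimates <- function(comparison) {
  long <- do.call(rbind, lapply(
    c("individual", "population", "constant_1p1"), function(k)
      data.frame(patient_id = comparison$patient_id,
                 estimate = k, dose = comparison[[k]],
                 stringsAsFactors = FALSE)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data[["patient_id"]],
                                     y = .data[["dose"]],
                                     colour = .data[["estimate"]],
                                     shape = .data[["estimate"]])) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = NULL, y = "RBE-weighted mean dose [Gy(RBE)]",
                  title = unique(comparison$organ)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
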