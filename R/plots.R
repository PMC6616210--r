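#' Plot a time-intensity curve
#'
#' Gray-level TIC with the destructive burst marked; optionally overlays
#' the low-pass filtered curve.
#'
#' @param object A [tic()] object.
#' @param smooth Overlay the filtered curve? Default `TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot usmi_tic
#' @export
autoplot.usmi_tic <- function(object, smooth = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$gray)) +
    ggplot2::geom_point(shape = 8, alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = t_flash_of(object), linetype = 3) +
    ggplot2::labs(x = "time (s)", y = "gray level (g.l.)") +
    ggplot2::theme_minimal()
  if (smooth) {
    sm <- smooth_tic(object)
    p <- p + ggplot2::geom_line(data = sm, colour = "grey40",
                                linetype = 2)
  }
  p
}

#' Plot an FPB model fit
#'
#' Observed linearized wash-in samples with the fitted first-pass binding
#' curve; the legend reports the estimated binding rate in 1/min.
#'
#' @param object An `fpb_fit` from [fit_fpb()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fpb_fit
#' @export
autoplot.fpb_fit <- function(object, ...) {
  lab <- if (!is.null(object$params)) {
    sprintf("FPB fit: k_b = %.3g 1/min, R² = %.2f",
            object$params$k_b * 60, object$r_squared)
  } else "FPB fit (failed)"
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), shape = 8,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linewidth = 0.8) +
    ggplot2::labs(x = "time (s)", y = "linear intensity", subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Box plots of USMI parameters over the study days
#'
#' One panel per group x parameter, the layout used to read longitudinal
#' treatment effects at a glance.
#'
#' @param observations A cohort observation table (as in
#'   [longitudinal_report()]).
#' @param parameters Parameter columns to show.
#' @return A ggplot.
#' @export
plot_longitudinal <- function(observations,
                              parameters = intersect(
                                c("k_b", "dTE", "LE", "volume"),
                                names(observations))) {
  long <- observations %>%
    mutate(group = paste(.data$model, .data$arm)) %>%
    tidyr::pivot_longer(dplyr::all_of(parameters), names_to = "parameter",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$day),
                                     y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_grid(parameter ~ group, scales = "free_y") +
    ggplot2::labs(x = "day", y = NULL) +
    ggplot2::theme_minimal()
}

#' Fold-change trajectories of treated mice
#'
#' Mean fold change (with standard error bars) per day for treated
#' responders vs non-responders, with the classification cutoff marked.
#'
#' @param fold_changes Output of [fold_changes()].
#' @param cutoff Cutoff line, default 0.7.
#' @return A ggplot.
#' @export
plot_fold_changes <- function(fold_changes, cutoff = 0.7) {
  sub <- filter(fold_changes, .data$arm == "treated")
  agg <- sub %>%
    group_by(.data$parameter, .data$model, .data$day) %>%
    summarise(mean_fc = mean(.data$fold_change),
              sem = sd(.data$fold_change) / sqrt(n()), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$day, y = .data$mean_fc,
                                    colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_fc - .data$sem,
                                          ymax = .data$mean_fc + .data$sem)) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = 3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "day", y = "fold change vs baseline") +
    ggplot2::theme_minimal()
}
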