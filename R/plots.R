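#' Kaplan-Meier step plot by arm
#'
#' @param km Tibble from [km_by_arm()] (columns `arm`, `time`,
#'   `survival`).
#' @return A ggplot.
#' @examples
#' trial <- generate_trial(trial_config(), seed = 1)
#' plot_km(km_by_arm(trial))
#' @export
plot_km <- function(km) {
  start <- km |> dplyr::distinct(.data$arm) |>
    mutate(time = 0, survival = 1)
  ggplot2::ggplot(bind_rows(start, km[, c("arm", "time", "survival")]),
                  ggplot2::aes(.data$time, .data$survival,
                               colour = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years since surgery", y = "Survival probability",
                  colour = "Arm") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane scatter of a PSA cloud
#'
#' @param cloud A `psa_cloud` from [run_psa()].
#' @param wtp Willingness-to-pay line to overlay (GBP/QALY); `NULL` for
#'   none.
#' @return A ggplot.
#' @export
plot_ce_plane <- function(cloud, wtp = 30000) {
  p <- ggplot2::ggplot(cloud, ggplot2::aes(.data$delta_effect,
                                           .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Incremental QALYs (ERP - standard)",
                  y = "Incremental cost (GBP)") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  colour = "grey40")
  }
  p
}

#' @rdname plot_ce_plane
#' @param object A `psa_cloud`.
#' @param ... Unused.
#' @method autoplot psa_cloud
#' @export
autoplot.psa_cloud <- function(object, ...) plot_ce_plane(object)

#' Cost-effectiveness acceptability curve plot
#'
#' @param curve Tibble from [ceac()].
#' @return A ggplot.
#' @export
plot_ceac <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$wtp, .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay (GBP/QALY)",
                  y = "Probability ERP is cost-effective") +
    ggplot2::theme_minimal()
}
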