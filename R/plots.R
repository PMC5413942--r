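#' Plot a processed force curve
#'
#' Force vs tip-sample separation for a zeroed retraction trace.
#'
#' @param object A `processed_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.processed_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$separation_nm, y = .data$force_pN)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Tip-sample separation (nm)", y = "Force (pN)",
                  title = attr(object, "curve_id")) +
    ggplot2::theme_minimal()
}

#' Plot a Gaussian modal fit over its histogram
#'
#' @param object A `gaussian_mode_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gaussian_mode_fit <- function(object, ...) {
  dat <- object$histogram
  xx <- seq(min(dat$mid), max(dat$mid), length.out = 200)
  curve <- tibble(
    x = xx,
    y = object$amplitude * exp(-(xx - object$mode)^2 / (2 * object$sigma^2))
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width, fill = "grey70",
                      colour = "grey30") +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "black") +
    ggplot2::geom_vline(xintercept = object$mode, linetype = "dashed") +
    ggplot2::labs(x = "Value", y = "Count",
                  subtitle = sprintf("mode = %.3g, n = %d",
                                     object$mode, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot an Lc-FU density scatter with hotspots
#'
#' @param object A `density_scatter`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_scatter <- function(object, ...) {
  p <- ggplot2::ggplot(object$grid,
                       ggplot2::aes(x = .data$lc_nm, y = .data$fu_pN,
                                    fill = .data$count)) +
    ggplot2::geom_tile(width = object$bin_lc_nm, height = object$bin_fu_pN) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Contour length (nm)", y = "Rupture force (pN)",
                  fill = "Events") +
    ggplot2::theme_minimal()
  if (nrow(object$hotspots)) {
    p <- p + ggplot2::geom_point(
      data = object$hotspots,
      ggplot2::aes(x = .data$lc_nm, y = .data$fu_pN),
      inherit.aes = FALSE, shape = 4, size = 3, colour = "red")
  }
  p
}

#' Plot a dynamic force spectrum with its Bell-Evans regression
#'
#' @param object A `bell_evans_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bell_evans_fit <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean_ln_loading_rate,
                                    y = .data$modal_FU_pN)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$modal_FU_pN - .data$error_pN,
                                        ymax = .data$modal_FU_pN + .data$error_pN),
                           width = 0.05, na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::labs(x = "ln(loading rate / pN s^-1)",
                  y = "Modal rupture force (pN)",
                  subtitle = sprintf("xbeta = %.3g nm, k0 = %.3g /s",
                                     object$xbeta_nm, object$k0_per_s)) +
    ggplot2::theme_minimal()
}

#' Plot an MST binding fit
#'
#' Data and fitted mass-action curve against log10 titrant concentration.
#'
#' @param object A `binding_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.binding_fit <- function(object, ...) {
  dat <- object$data
  L <- 10^seq(log10(min(dat$L)), log10(max(dat$L)), length.out = 200)
  fb <- fraction_bound(object$labeled_concentration_M, L, object$KD_M)
  curve <- tibble(
    L = L,
    fnorm = object$fnorm_unbound +
      fb * (object$fnorm_bound - object$fnorm_unbound)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$L, y = .data$fnorm)) +
    ggplot2::geom_point(shape = 1, colour = "red") +
    ggplot2::geom_line(data = curve) +
    ggplot2::geom_vline(xintercept = object$KD_M, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Titrant concentration (M)", y = "Fnorm",
                  subtitle = sprintf("KD = %.3g M", object$KD_M)) +
    ggplot2::theme_minimal()
}

#' Histogram of per-curve contour-length increments
#'
#' @param delta_lc Output of [compute_delta_lc()].
#' @param bin_width_nm Bin width (nm). Default 2.
#' @return A ggplot.
#' @export
plot_delta_lc <- function(delta_lc, bin_width_nm = 2) {
  long <- tidyr::pivot_longer(
    delta_lc, dplyr::any_of(c("dLc1", "dLc2", "dLc_total")),
    names_to = "increment", values_to = "dLc_nm") |>
    dplyr::filter(is.finite(.data$dLc_nm))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dLc_nm,
                                     fill = .data$increment)) +
    ggplot2::geom_histogram(binwidth = bin_width_nm, position = "identity",
                            alpha = 0.6, colour = "grey30") +
    ggplot2::labs(x = expression(Delta * L[c] ~ "(nm)"), y = "Curves") +
    ggplot2::theme_minimal()
}
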