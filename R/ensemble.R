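#' Single-Gaussian modal fit of a histogram
#'
#' Bins `values` at the stated bin width and fits a single Gaussian
#' `a * exp(-(x - mu)^2 / (2 sigma^2))` to the bin counts by nonlinear least
#' squares; the mode reported for a distribution (rupture force, contour
#' length, delta-Lc) is the fitted mean `mu`. Raw (unweighted) bin counts
#' are used.
#'
#' @param values Numeric sample.
#' @param bin_width Histogram bin width in the units of `values`.
#' @param min_n Minimum sample size. Default 30.
#' @return Object of class `gaussian_mode_fit` with elements `mode`, `sigma`,
#'   `amplitude`, `bin_width`, `n` and the binned data.
#' @examples
#' \donttest{
#' fit <- fit_gaussian_mode(rnorm(1000, 113, 13), bin_width = 10)
#' fit$mode
#' }
#' @export
fit_gaussian_mode <- function(values, bin_width, min_n = 30) {
  values <- values[is.finite(values)]
  if (length(values) < min_n) {
    abort(sprintf("Need at least %d values for a modal fit (got %d).",
                  min_n, length(values)))
  }
  if (diff(range(values)) == 0) {
    abort("Degenerate sample: all values equal.")
  }
  if (bin_width <= 0) abort("`bin_width` must be positive.")
  # pad with one empty bin each side so narrow distributions (fewer occupied
  # bins than Gaussian parameters) still give a well-posed fit
  lo <- (floor(min(values) / bin_width) - 1) * bin_width
  breaks <- seq(lo, max(values) + 2 * bin_width, by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  dat <- tibble(mid = h$mids, count = h$counts)

  start <- list(a = max(dat$count),
                mu = dat$mid[which.max(dat$count)],
                s = max(sd(values), bin_width / 2))
  fit <- minpack.lm::nlsLM(
    count ~ a * exp(-(mid - mu)^2 / (2 * s^2)),
    data = dat, start = start,
    lower = c(a = 0, mu = min(dat$mid) - bin_width,
              s = bin_width / 10),
    upper = c(a = Inf, mu = max(dat$mid) + bin_width, s = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- coef(fit)
  structure(
    list(mode = unname(est["mu"]), sigma = unname(est["s"]),
         amplitude = unname(est["a"]), bin_width = bin_width,
         n = length(values), histogram = dat, fit = fit),
    class = "gaussian_mode_fit"
  )
}

#' @export
print.gaussian_mode_fit <- function(x, ...) {
  cat(sprintf("<gaussian_mode_fit> mode = %.3g, sigma = %.3g (n = %d, bin = %g)\n",
              x$mode, x$sigma, x$n, x$bin_width))
  invisible(x)
}

#' @export
tidy.gaussian_mode_fit <- function(x, ...) {
  tibble(term = c("mode", "sigma", "amplitude"),
         estimate = c(x$mode, x$sigma, x$amplitude))
}

#' @export
glance.gaussian_mode_fit <- function(x, ...) {
  tibble(mode = x$mode, sigma = x$sigma, amplitude = x$amplitude,
         n = x$n, bin_width = x$bin_width)
}

#' Per-curve contour-length increments (delta-Lc)
#'
#' For every curve with at least two accepted events, the fitted contour
#' lengths are ordered by rupture separation and differenced per curve:
#' `dLc1 = Lc2 - Lc1`, `dLc2 = Lc3 - Lc2` (triple events) and
#' `dLc_total = Lc_last - Lc1`. Differencing is done per curve, not between
#' ensemble modes, so each record reflects how much additional polymer one
#' molecule released between its ruptures. Curves with fewer than two
#' accepted events, or whose contour lengths are not strictly increasing,
#' are skipped with a message.
#'
#' @param events Accepted-event table with `curve_id`, `x_r_nm`, `Lc_nm`
#'   (e.g. `analysis$events` filtered to `accepted`), or a `map_analysis`.
#' @return Tibble: `curve_id`, `n_events`, `Lc1`, `Lc2`, `Lc3`, `dLc1`,
#'   `dLc2`, `dLc_total`.
#' @export
compute_delta_lc <- function(events) {
  if (inherits(events, "map_analysis")) events <- events$events
  ev <- dplyr::filter(events, .data$accepted)
  recs <- ev |>
    dplyr::group_by(.data$curve_id) |>
    dplyr::arrange(.data$x_r_nm, .by_group = TRUE) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      Lc = list(.data$Lc_nm),
      .groups = "drop"
    )
  skipped <- 0L
  out <- purrr::map_dfr(seq_len(nrow(recs)), function(i) {
    Lc <- recs$Lc[[i]]
    if (length(Lc) < 2 || any(diff(Lc) <= 0)) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    tibble(
      curve_id = recs$curve_id[i],
      n_events = length(Lc),
      Lc1 = Lc[1], Lc2 = Lc[2],
      Lc3 = if (length(Lc) >= 3) Lc[3] else NA_real_,
      dLc1 = Lc[2] - Lc[1],
      dLc2 = if (length(Lc) >= 3) Lc[3] - Lc[2] else NA_real_,
      dLc_total = Lc[length(Lc)] - Lc[1]
    )
  })
  if (skipped > 0) {
    inform(sprintf(
      "compute_delta_lc: skipped %d curve(s) with < 2 usable events or non-increasing Lc.",
      skipped))
  }
  out
}

#' Aggregate replicate modal values
#'
#' Experiments are aggregated as the mean of the per-replicate Gaussian modes
#' plus/minus half the range across replicates (not a standard error).
#'
#' @param modes Numeric vector of per-replicate modal values.
#' @return Tibble: `mean`, `half_range`, `n_replicates`, `single_replicate`.
#' @examples
#' aggregate_replicates(c(100, 113, 126))  # 113 +/- 13
#' @export
aggregate_replicates <- function(modes) {
  modes <- modes[is.finite(modes)]
  if (!length(modes)) abort("No replicate modes supplied.")
  single <- length(modes) == 1
  if (single) {
    warn("Single replicate: error term undefined.")
  }
  tibble(mean = mean(modes),
         half_range = if (single) NA_real_ else diff(range(modes)) / 2,
         n_replicates = length(modes),
         single_replicate = single)
}

#' Contour-length / rupture-force density scatter and hotspot report
#'
#' Bins paired (Lc, FU) observations on a 2D grid (default 5 nm x 10 pN) and
#' reports hotspots: connected clusters of bins whose count exceeds
#' `hotspot_factor` times the median count of occupied bins. A specific,
#' reproducible interaction shows up as one or two such hotspots; uniform
#' scatter shows none.
#'
#' @param Lc_nm Contour lengths (nm).
#' @param FU_pN Rupture forces (pN), same length.
#' @param bin_lc_nm Lc bin width (nm). Default 5.
#' @param bin_fu_pN FU bin width (pN). Default 10.
#' @param hotspot_factor Multiple of the median occupied-bin density a bin
#'   must exceed to count as hot. Default 5.
#' @param min_n Minimum number of points. Default 30.
#' @return Object of class `density_scatter`: `grid` (tibble of bin centres
#'   and counts), `hotspots` (tibble of cluster centroids), parameters.
#' @export
density_scatter <- function(Lc_nm, FU_pN, bin_lc_nm = 5, bin_fu_pN = 10,
                            hotspot_factor = 5, min_n = 30) {
  ok <- is.finite(Lc_nm) & is.finite(FU_pN)
  Lc_nm <- Lc_nm[ok]; FU_pN <- FU_pN[ok]
  if (length(Lc_nm) != length(FU_pN)) abort("Inputs must be paired.")
  if (length(Lc_nm) < min_n) {
    abort(sprintf("Need at least %d points (got %d).", min_n, length(Lc_nm)))
  }
  ix <- floor(Lc_nm / bin_lc_nm)
  iy <- floor(FU_pN / bin_fu_pN)
  grid <- tibble(ix = ix, iy = iy) |>
    dplyr::count(.data$ix, .data$iy, name = "count") |>
    dplyr::mutate(
      lc_nm = (.data$ix + 0.5) * bin_lc_nm,
      fu_pN = (.data$iy + 0.5) * bin_fu_pN
    )
  med <- median(grid$count)
  hot <- dplyr::filter(grid, .data$count > hotspot_factor * med)

  # cluster hot bins by 8-connectivity (flood fill on bin indices)
  hotspots <- tibble(cluster = integer(), lc_nm = numeric(),
                     fu_pN = numeric(), n_bins = integer(),
                     n_points = integer(), peak_count = integer())
  if (nrow(hot)) {
    cl <- rep(NA_integer_, nrow(hot))
    nxt <- 0L
    for (i in seq_len(nrow(hot))) {
      if (!is.na(cl[i])) next
      nxt <- nxt + 1L
      queue <- i
      cl[i] <- nxt
      while (length(queue)) {
        j <- queue[1]; queue <- queue[-1]
        nb <- which(is.na(cl) &
                      abs(hot$ix - hot$ix[j]) <= 1 &
                      abs(hot$iy - hot$iy[j]) <= 1)
        cl[nb] <- nxt
        queue <- c(queue, nb)
      }
    }
    hotspots <- hot |>
      dplyr::mutate(cluster = cl) |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(
        lc_nm = sum(.data$lc_nm * .data$count) / sum(.data$count),
        fu_pN = sum(.data$fu_pN * .data$count) / sum(.data$count),
        n_bins = dplyr::n(),
        n_points = sum(.data$count),
        peak_count = max(.data$count),
        .groups = "drop"
      )
  }
  structure(
    list(grid = dplyr::select(grid, "lc_nm", "fu_pN", "count"),
         hotspots = hotspots,
         n = length(Lc_nm),
         bin_lc_nm = bin_lc_nm, bin_fu_pN = bin_fu_pN,
         hotspot_factor = hotspot_factor,
         median_density = med),
    class = "density_scatter"
  )
}

#' @export
print.density_scatter <- function(x, ...) {
  cat(sprintf("<density_scatter> %d points, %d hotspot(s)\n",
              x$n, nrow(x$hotspots)))
  if (nrow(x$hotspots)) print(x$hotspots)
  invisible(x)
}

#' Build a dynamic force spectrum from per-event data
#'
#' Groups events by retraction velocity (and replicate, when present),
#' Gaussian-fits the modal rupture force per velocity, and pairs it with the
#' mean natural log of the per-event loading rates at that velocity.
#' Replicate spread is summarised as half the range of replicate modes.
#'
#' @param events Accepted events with columns `retraction_velocity_nm_s`,
#'   `FU_pN`, `loading_rate_pN_s` and optionally `replicate`.
#' @param fu_bin_width_pN Rupture-force bin width for the modal fits (pN).
#'   Default 10.
#' @param min_n Minimum events per (velocity, replicate) group. Default 30.
#' @return Tibble of DFS points: `retraction_velocity_nm_s`,
#'   `mean_ln_loading_rate`, `modal_FU_pN`, `error_pN`, `n`.
#' @export
build_dfs <- function(events, fu_bin_width_pN = 10, min_n = 30) {
  has_rep <- "replicate" %in% names(events)
  if (!has_rep) events$replicate <- "r1"
  per_rep <- events |>
    dplyr::group_by(.data$retraction_velocity_nm_s, .data$replicate) |>
    dplyr::summarise(
      modal_FU_pN = fit_gaussian_mode(.data$FU_pN, fu_bin_width_pN,
                                      min_n = min_n)$mode,
      mean_ln_loading_rate = mean(log(.data$loading_rate_pN_s)),
      n = dplyr::n(),
      .groups = "drop"
    )
  per_rep |>
    dplyr::group_by(.data$retraction_velocity_nm_s) |>
    dplyr::summarise(
      mean_ln_loading_rate = mean(.data$mean_ln_loading_rate),
      error_pN = if (dplyr::n() > 1) diff(range(.data$modal_FU_pN)) / 2
                 else NA_real_,
      modal_FU_pN = mean(.data$modal_FU_pN),
      n = sum(.data$n),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mean_ln_loading_rate)
}

#' Bell-Evans fit of a dynamic force spectrum
#'
#' Linear regression of the modal rupture force on the natural log of the
#' loading rate. Under the Bell-Evans model the modal force is
#' \deqn{F^* = (k_B T / x_\beta) \ln( x_\beta r / (k_0 k_B T) )}
#' so the slope gives the distance to the transition state
#' `xbeta = kBT / slope` and the intercept gives the intrinsic off rate
#' `k0 = (xbeta / kBT) exp(-intercept / slope)`. Both the raw regression
#' coefficients and the derived kinetic parameters are reported.
#'
#' @param points DFS points from [build_dfs()] (needs `mean_ln_loading_rate`
#'   and `modal_FU_pN`; at least 3 rows).
#' @param temperature_K Temperature (K). Default 298.
#' @return Object of class `bell_evans_fit`: `slope`, `intercept`,
#'   `xbeta_nm`, `k0_per_s`, `temperature_K`, `points`, `lm`.
#' @export
fit_bell_evans <- function(points, temperature_K = 298) {
  if (nrow(points) < 3) abort("Need at least 3 DFS points.")
  fit <- lm(modal_FU_pN ~ mean_ln_loading_rate, data = points)
  slope <- coef(fit)[[2]]
  intercept <- coef(fit)[[1]]
  if (!is.finite(slope) || slope <= 0) {
    abort("Non-positive DFS slope: data are not Bell-Evans-like.",
          class = "tonbpull_dfs_error")
  }
  kBT <- thermal_energy(temperature_K)
  xbeta <- kBT / slope
  k0 <- xbeta / kBT * exp(-intercept / slope)
  structure(
    list(slope = slope, intercept = intercept,
         xbeta_nm = xbeta, k0_per_s = k0,
         temperature_K = temperature_K, points = points, lm = fit),
    class = "bell_evans_fit"
  )
}

#' @export
print.bell_evans_fit <- function(x, ...) {
  cat(sprintf(
    "<bell_evans_fit> slope = %.3g pN, intercept = %.3g pN, xbeta = %.3g nm, k0 = %.3g /s\n",
    x$slope, x$intercept, x$xbeta_nm, x$k0_per_s))
  invisible(x)
}

#' @export
tidy.bell_evans_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept", "xbeta_nm", "k0_per_s"),
         estimate = c(x$slope, x$intercept, x$xbeta_nm, x$k0_per_s))
}

#' @export
glance.bell_evans_fit <- function(x, ...) {
  tibble(xbeta_nm = x$xbeta_nm, k0_per_s = x$k0_per_s,
         slope = x$slope, intercept = x$intercept,
         r_squared = suppressWarnings(summary(x$lm)$r.squared),
         n_points = nrow(x$points))
}

#' Closed-form Bell-Evans modal rupture force
#'
#' Most probable rupture force under a constant loading rate `r`:
#' `F* = (kBT/xbeta) ln(xbeta r / (k0 kBT))`. Used as the independent check
#' for the Monte-Carlo rupture generator and the DFS fit.
#'
#' @param k0_per_s Intrinsic off rate (1/s).
#' @param x_beta_nm Distance to the transition state (nm).
#' @param loading_rate_pN_s Loading rate (pN/s), vectorised.
#' @param temperature_K Temperature (K). Default 298.
#' @return Modal force in pN.
#' @export
bell_evans_modal_force <- function(k0_per_s, x_beta_nm, loading_rate_pN_s,
                                   temperature_K = 298) {
  kBT <- thermal_energy(temperature_K)
  (kBT / x_beta_nm) * log(x_beta_nm * loading_rate_pN_s / (k0_per_s * kBT))
}
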