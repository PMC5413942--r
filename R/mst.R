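#' Exact 1:1 fraction bound with ligand depletion
#'
#' Solves the law of mass action for a 1:1 complex without assuming excess
#' titrant, i.e. accounting for depletion of the labelled species A:
#' \deqn{F_B = \frac{A + L + K_D - \sqrt{(A + L + K_D)^2 - 4 A L}}{2A}}
#' evaluated in the numerically stable conjugate form
#' `2L / (A + L + KD + sqrt((A + L + KD)^2 - 4 A L))`.
#'
#' @param A_total Total labelled-species concentration (M), > 0.
#' @param L_total Total titrant (ligand) concentration (M), > 0; vectorised.
#' @param KD Dissociation constant (M), > 0.
#' @return Fraction of A bound, in `[0, 1]`.
#' @examples
#' fraction_bound(250e-9, 9.4e-6, 9.4e-6)  # near half-saturation
#' @export
fraction_bound <- function(A_total, L_total, KD) {
  if (any(c(A_total, L_total, KD) <= 0)) {
    abort("`A_total`, `L_total` and `KD` must all be positive.")
  }
  s <- A_total + L_total + KD
  disc <- s^2 - 4 * A_total * L_total
  2 * L_total / (s + sqrt(pmax(disc, 0)))
}

#' MST signal model
#'
#' The normalised fluorescence of a thermophoresis experiment is a linear
#' two-state reporter of the fraction bound. The separate physical
#' contributions (temperature-jump sensitivity, temperature change, Soret
#' coefficient) are not individually identifiable from a titration, so the
#' fit works with composite bound/unbound signal amplitudes; the physical
#' fields may be populated for signal synthesis and bookkeeping.
#'
#' @param fnorm_unbound Signal of the free labelled species (per-mille units
#'   as exported by MST instruments).
#' @param fnorm_bound Signal of the fully bound species; must differ from
#'   `fnorm_unbound` for a fittable series.
#' @param temperature_jump_sensitivity Optional dF/dT.
#' @param delta_T Optional temperature change.
#' @param soret_coefficient Optional Soret coefficient.
#' @return List of class `mst_signal`.
#' @export
mst_signal <- function(fnorm_unbound, fnorm_bound,
                       temperature_jump_sensitivity = NULL,
                       delta_T = NULL, soret_coefficient = NULL) {
  if (fnorm_unbound == fnorm_bound) {
    abort("`fnorm_bound` must differ from `fnorm_unbound`.")
  }
  structure(list(fnorm_unbound = fnorm_unbound, fnorm_bound = fnorm_bound,
                 temperature_jump_sensitivity = temperature_jump_sensitivity,
                 delta_T = delta_T, soret_coefficient = soret_coefficient),
            class = "mst_signal")
}

#' Normalised fluorescence from fraction bound
#'
#' `Fnorm = fnorm_unbound + FB * (fnorm_bound - fnorm_unbound)`.
#'
#' @param FB Fraction bound in `[0, 1]`, vectorised.
#' @param signal An [mst_signal()].
#' @return Fnorm values.
#' @export
fnorm_model <- function(FB, signal) {
  stopifnot(inherits(signal, "mst_signal"))
  if (any(FB < -1e-12 | FB > 1 + 1e-12)) abort("`FB` must lie in [0, 1].")
  signal$fnorm_unbound + FB * (signal$fnorm_bound - signal$fnorm_unbound)
}

#' MST titration series
#'
#' @param ligand_concentration_M Final in-capillary titrant concentrations
#'   (M), strictly positive; stored sorted ascending.
#' @param fnorm Normalised fluorescence values, same length.
#' @param labeled_concentration_M Final labelled-species concentration (M).
#'   Default 250e-9 (250 nM in-capillary).
#' @param replicate Replicate label.
#' @return Tibble of class `titration_series` with metadata attributes.
#' @export
titration_series <- function(ligand_concentration_M, fnorm,
                             labeled_concentration_M = 250e-9,
                             replicate = "r1") {
  if (length(ligand_concentration_M) != length(fnorm)) {
    abort("Concentration and fnorm vectors must have equal length.")
  }
  if (any(ligand_concentration_M <= 0)) {
    abort("Concentrations must be strictly positive.")
  }
  if (labeled_concentration_M <= 0) {
    abort("`labeled_concentration_M` must be positive.")
  }
  ord <- order(ligand_concentration_M)
  out <- tibble(ligand_concentration_M = ligand_concentration_M[ord],
                fnorm = fnorm[ord])
  structure(out,
            labeled_concentration_M = labeled_concentration_M,
            replicate = replicate,
            class = c("titration_series", class(out)))
}

#' Fit a dissociation constant to an MST titration
#'
#' Unweighted nonlinear least squares of
#' `fnorm ~ fnorm_unbound + FB(A, L, KD) * (fnorm_bound - fnorm_unbound)`
#' with [fraction_bound()] for FB, fitted against the log10 of the titrant
#' concentration. KD is optimised on the log10 scale (it spans decades);
#' the starting KD is the concentration at half signal amplitude. A seeded
#' residual-resampling bootstrap provides the confidence interval.
#'
#' @param series A [titration_series()] (or tibble with columns
#'   `ligand_concentration_M`, `fnorm` plus `labeled_concentration_M`
#'   passed explicitly).
#' @param labeled_concentration_M Labelled-species concentration (M); taken
#'   from the series attribute when absent.
#' @param n_boot Bootstrap resamples for the CI. Default 200.
#' @param conf_level Confidence level. Default 0.95.
#' @param seed Seed for the bootstrap. Default 1.
#' @param min_points Minimum number of concentrations. Default 8.
#' @return Object of class `binding_fit`: `KD_M`, `fnorm_unbound`,
#'   `fnorm_bound`, `residual_rms`, `ci` (named numeric, M), `n`, `data`,
#'   `fit`.
#' @export
fit_kd <- function(series, labeled_concentration_M = NULL,
                   n_boot = 200, conf_level = 0.95, seed = 1,
                   min_points = 8) {
  A <- labeled_concentration_M %||% attr(series, "labeled_concentration_M")
  if (is.null(A)) abort("Labelled-species concentration is required.")
  dat <- tibble(L = series$ligand_concentration_M, fnorm = series$fnorm)
  if (nrow(dat) < min_points) {
    abort(sprintf("Need at least %d concentrations.", min_points))
  }

  amp <- diff(range(dat$fnorm))
  noise0 <- sd(resid(lm(fnorm ~ poly(log10(L), 2), data = dat)))
  if (amp < 4 * noise0) {
    abort("Signal amplitude indistinguishable from noise; fit rejected.",
          class = "tonbpull_mst_error")
  }

  # starting KD: concentration at half amplitude
  f_lo <- mean(head(dat$fnorm, 2))
  f_hi <- mean(tail(dat$fnorm, 2))
  half <- (f_lo + f_hi) / 2
  kd0 <- tryCatch(
    10^approx(dat$fnorm, log10(dat$L), xout = half, ties = "ordered")$y,
    error = function(e) NA_real_)
  if (!is.finite(kd0)) kd0 <- exp(mean(log(range(dat$L))))

  fitfun <- function(d) {
    minpack.lm::nlsLM(
      fnorm ~ fu + (fb - fu) * fraction_bound(A, L, 10^lkd),
      data = d,
      start = list(fu = f_lo, fb = f_hi, lkd = log10(kd0)),
      lower = c(fu = -Inf, fb = -Inf, lkd = log10(min(dat$L)) - 3),
      upper = c(fu = Inf, fb = Inf, lkd = log10(max(dat$L)) + 3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
  }
  fit <- fitfun(dat)
  est <- coef(fit)
  KD <- unname(10^est["lkd"])
  res <- resid(fit)
  rms <- sqrt(mean(res^2))

  if (max(dat$L) < 10 * KD || min(dat$L) > KD / 10) {
    warn("Titration spans less than one decade either side of the fitted KD.")
  }

  boot_kd <- withr::with_seed(seed, {
    fitted_vals <- predict(fit)
    vapply(seq_len(n_boot), function(b) {
      d <- dat
      d$fnorm <- fitted_vals + sample(res, length(res), replace = TRUE)
      out <- tryCatch(coef(fitfun(d))["lkd"], error = function(e) NA_real_)
      unname(10^out)
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  ci <- quantile(boot_kd, c(alpha, 1 - alpha), na.rm = TRUE)

  structure(
    list(KD_M = KD,
         fnorm_unbound = unname(est["fu"]),
         fnorm_bound = unname(est["fb"]),
         residual_rms = rms,
         ci = setNames(as.numeric(ci), c("lower", "upper")),
         conf_level = conf_level,
         n = nrow(dat),
         labeled_concentration_M = A,
         data = dat,
         fit = fit),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "<binding_fit> KD = %.3g M (%d%% CI %.3g-%.3g), amplitude %.3g -> %.3g, rms %.3g\n",
    x$KD_M, round(100 * x$conf_level), x$ci[["lower"]], x$ci[["upper"]],
    x$fnorm_unbound, x$fnorm_bound, x$residual_rms))
  invisible(x)
}

#' @export
tidy.binding_fit <- function(x, ...) {
  tibble(term = c("KD_M", "fnorm_unbound", "fnorm_bound"),
         estimate = c(x$KD_M, x$fnorm_unbound, x$fnorm_bound),
         conf.low = c(x$ci[["lower"]], NA, NA),
         conf.high = c(x$ci[["upper"]], NA, NA))
}

#' @export
glance.binding_fit <- function(x, ...) {
  tibble(KD_M = x$KD_M, KD_uM = x$KD_M * 1e6,
         residual_rms = x$residual_rms, n = x$n)
}
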