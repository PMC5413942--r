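#' Worm-like-chain parameter set
#'
#' Bundles the three quantities that define an inextensible worm-like chain
#' (WLC): persistence length p, contour length Lc and temperature T. The
#' thermal energy kB*T is derived internally ([thermal_energy()]); kB is a
#' fixed constant. Throughout the package forces are in pN and lengths in nm,
#' the natural units of AFM force spectroscopy, and the persistence length
#' defaults to 0.4 nm, the value used for polypeptide + PEG tethers.
#'
#' @param contour_length_nm Contour length Lc (nm), > 0.
#' @param persistence_length_nm Persistence length p (nm), > 0. Default 0.4.
#' @param temperature_K Temperature (K), > 0. Default 298.
#' @return An object of class `wlc_params`.
#' @seealso [wlc_force()], [wlc_extension()], [wlc_stiffness()]
#' @examples
#' wlc_params(contour_length_nm = 47)
#' @export
wlc_params <- function(contour_length_nm,
                       persistence_length_nm = 0.4,
                       temperature_K = 298) {
  if (!is.numeric(contour_length_nm) || length(contour_length_nm) != 1 ||
      !is.finite(contour_length_nm) || contour_length_nm <= 0) {
    abort("`contour_length_nm` must be a single positive number.")
  }
  if (!is.numeric(persistence_length_nm) || persistence_length_nm <= 0) {
    abort("`persistence_length_nm` must be positive.")
  }
  if (!is.numeric(temperature_K) || temperature_K <= 0) {
    abort("`temperature_K` must be positive.")
  }
  structure(
    list(
      persistence_length_nm = persistence_length_nm,
      contour_length_nm = contour_length_nm,
      temperature_K = temperature_K,
      kBT_pN_nm = thermal_energy(temperature_K)
    ),
    class = "wlc_params"
  )
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf(
    "<wlc_params> p = %g nm, Lc = %g nm, T = %g K (kBT = %.4f pN nm)\n",
    x$persistence_length_nm, x$contour_length_nm, x$temperature_K, x$kBT_pN_nm
  ))
  invisible(x)
}

.check_extension <- function(params, extension_nm) {
  if (!is.numeric(extension_nm)) abort("`extension_nm` must be numeric.")
  if (any(extension_nm < 0)) {
    abort("Extension must be non-negative.")
  }
  if (any(extension_nm >= params$contour_length_nm)) {
    abort("Extension must be strictly less than the contour length Lc.")
  }
  invisible(TRUE)
}

#' WLC restoring force (Marko-Siggia interpolation)
#'
#' Entropic restoring force of a worm-like chain at extension x:
#' \deqn{F(x) = (k_B T / p) [ 1/4 (1 - x/L_c)^{-2} - 1/4 + x/L_c ]}
#' The force vanishes at zero extension, is strictly increasing in x and
#' diverges as x approaches Lc. This interpolation is accurate to a few
#' percent over the full extension range and is the form conventionally
#' fitted to AFM rising edges with p held fixed.
#'
#' @param params A [wlc_params()] object.
#' @param extension_nm Extension x (nm), vectorised; must satisfy
#'   `0 <= x < Lc`.
#' @return Force in pN (same length as `extension_nm`).
#' @examples
#' p <- wlc_params(contour_length_nm = 40)
#' wlc_force(p, 20)  # half extension
#' @export
wlc_force <- function(params, extension_nm) {
  stopifnot(inherits(params, "wlc_params"))
  .check_extension(params, extension_nm)
  u <- extension_nm / params$contour_length_nm
  (params$kBT_pN_nm / params$persistence_length_nm) *
    (0.25 * (1 - u)^-2 - 0.25 + u)
}

#' WLC stiffness (derivative of the force-extension relation)
#'
#' Slope dF/dx of the Marko-Siggia force law:
#' \deqn{dF/dx = (k_B T / p) [ 1/2 L_c^{-1} (1 - x/L_c)^{-3} + L_c^{-1} ]}
#' Used to turn a fitted rising edge into a loading rate: the force loading
#' rate at rupture is this slope (evaluated at the extension at rupture)
#' multiplied by the retraction velocity.
#'
#' @inheritParams wlc_force
#' @return Stiffness in pN/nm.
#' @export
wlc_stiffness <- function(params, extension_nm) {
  stopifnot(inherits(params, "wlc_params"))
  .check_extension(params, extension_nm)
  Lc <- params$contour_length_nm
  u <- extension_nm / Lc
  (params$kBT_pN_nm / params$persistence_length_nm) *
    (0.5 / Lc * (1 - u)^-3 + 1 / Lc)
}

#' Inverse WLC: extension at a given force
#'
#' Numerically inverts [wlc_force()] on its monotone domain by safeguarded
#' bisection (stats::uniroot) on the bracket `[0, Lc (1 - 1e-12)]`, to a
#' relative tolerance of 1e-9. Needed by the pulling simulator and anywhere
#' the force balance is posed in terms of force rather than extension.
#'
#' @param params A [wlc_params()] object.
#' @param force_pN Force (pN), vectorised; must be >= 0.
#' @return Extension in nm, `0 <= x < Lc`.
#' @export
wlc_extension <- function(params, force_pN) {
  stopifnot(inherits(params, "wlc_params"))
  if (!is.numeric(force_pN)) abort("`force_pN` must be numeric.")
  if (any(force_pN < 0)) abort("Force must be non-negative.")
  Lc <- params$contour_length_nm
  upper <- Lc * (1 - 1e-12)
  vapply(force_pN, function(f) {
    if (f == 0) return(0)
    uniroot(
      function(x) wlc_force(params, x) - f,
      lower = 0, upper = upper,
      tol = Lc * 1e-12, maxiter = 2000L
    )$root
  }, numeric(1))
}
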