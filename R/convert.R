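#' Convert a raw retraction trace to force vs tip-sample separation
#'
#' Moves a curve from the instrument frame (piezo displacement, deflection)
#' to the analysis frame (force vs tip-sample separation) in three steps:
#'
#' 1. force: `kc * deflection` (or the pre-converted force channel);
#' 2. baseline zeroing: the mean force over the far-from-surface tail of the
#'    retraction (final `baseline_fraction` of samples) is subtracted, so the
#'    detached baseline sits at 0 pN;
#' 3. contact-point zeroing: a straight line is fitted to the steepest part
#'    of the repulsive contact wall (the most repulsive `wall_fraction` of
#'    wall samples); its zero-force intercept defines zero separation.
#'
#' Separation is then `piezo - force/kc - contact_offset`, i.e. the piezo
#' travel corrected for cantilever bending. If no contact wall is present
#' (no samples more repulsive than `-wall_threshold_pN`, e.g. an already
#' zeroed curve or an empty trace) the contact offset is 0 and the curve is
#' flagged `contact_found = FALSE`.
#'
#' @param raw A [force_curve()] (segment "retract").
#' @param baseline_fraction Fraction of trailing samples used for the force
#'   baseline. Default 0.2.
#' @param wall_fraction Fraction of the repulsive wall (steepest part) used
#'   for the contact fit. Default 0.25.
#' @param wall_threshold_pN Repulsive force (pN) beyond which a sample counts
#'   as contact wall. Default 20.
#' @return A tibble of class `processed_curve` with columns `time_s`,
#'   `separation_nm`, `force_pN` and attributes `baseline_offset_pN`,
#'   `contact_offset_nm`, `contact_found` plus the curve metadata.
#' @export
convert_to_force_separation <- function(raw,
                                        baseline_fraction = 0.2,
                                        wall_fraction = 0.25,
                                        wall_threshold_pN = 20) {
  stopifnot(inherits(raw, "force_curve") || inherits(raw, "processed_curve"))
  meta <- curve_meta(raw)
  if (!identical(meta$segment, "retract")) {
    abort(sprintf("Curve %s has no retract segment (segment = '%s').",
                  meta$curve_id, meta$segment))
  }
  kc <- meta$spring_constant_pN_nm
  n <- nrow(raw)
  n_base <- floor(n * baseline_fraction)
  if (n_base < 4) {
    abort(sprintf("Curve %s: fewer samples than the baseline window needs.",
                  meta$curve_id))
  }

  pre_converted <- inherits(raw, "processed_curve") ||
    (!is.null(raw[["force_pN"]]) && is.null(raw[["deflection_nm"]]))
  force_raw <- if (!is.null(raw[["deflection_nm"]])) {
    kc * raw$deflection_nm
  } else {
    raw$force_pN
  }
  piezo <- raw[["piezo_nm"]] %||% raw[["separation_nm"]]

  baseline <- mean(tail(force_raw, n_base))
  force <- force_raw - baseline

  wall <- which(force < -wall_threshold_pN)
  contact_found <- length(wall) >= 3
  contact_offset <- 0
  if (contact_found) {
    steep <- wall[force[wall] <= quantile(force[wall], wall_fraction)]
    if (length(steep) < 2) steep <- wall
    fit <- lm(force[steep] ~ piezo[steep])
    slope <- coef(fit)[[2]]
    if (!is.finite(slope) || slope <= 0) {
      contact_found <- FALSE
    } else {
      contact_offset <- -coef(fit)[[1]] / slope
    }
  }

  # for pre-converted input the piezo channel is already a separation;
  # only the (re-estimated, ~0) offsets are applied, making conversion
  # idempotent
  separation <- if (pre_converted) {
    piezo - contact_offset
  } else {
    piezo - force / kc - contact_offset
  }

  out <- tibble(time_s = raw$time_s, separation_nm = separation,
                force_pN = force)
  structure(
    out,
    baseline_offset_pN = baseline,
    contact_offset_nm = contact_offset,
    contact_found = contact_found,
    spring_constant_pN_nm = kc,
    retraction_velocity_nm_s = meta$retraction_velocity_nm_s,
    approach_velocity_nm_s = meta$approach_velocity_nm_s,
    temperature_K = meta$temperature_K,
    curve_id = meta$curve_id,
    segment = "retract",
    provenance = list(curve_id = meta$curve_id,
                      baseline_fraction = baseline_fraction,
                      wall_fraction = wall_fraction,
                      wall_threshold_pN = wall_threshold_pN),
    class = c("processed_curve", class(out))
  )
}
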