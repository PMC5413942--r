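#' Event-detection configuration
#'
#' Rupture candidates are located on the smoothed force signal: a
#' Savitzky-Golay filter (local polynomial, `sg_order`, window `sg_window`
#' samples) suppresses sampling noise, and any index where the smoothed force
#' falls by more than the detection threshold within `drop_window` samples
#' marks a sharp negative transition (a force drop). The threshold is the
#' larger of `min_drop_pN` and `prominence_sigmas` times the robust noise
#' scale (median absolute deviation of the residual around the smooth).
#'
#' @param sg_window Savitzky-Golay window length (odd, samples). Default 11.
#' @param sg_order Savitzky-Golay polynomial order. Default 2.
#' @param min_drop_pN Minimum force drop for a candidate (pN). Default 20.
#' @param prominence_sigmas Multiple of the robust noise sigma a drop must
#'   exceed. Default 3.
#' @param drop_window Samples over which the drop is measured. Default 6.
#' @return List of class `detection_config`.
#' @export
detection_config <- function(sg_window = 11, sg_order = 2,
                             min_drop_pN = 20, prominence_sigmas = 3,
                             drop_window = 6) {
  stopifnot(sg_window %% 2 == 1, sg_window > sg_order,
            min_drop_pN > 0, prominence_sigmas > 0, drop_window >= 1)
  structure(list(sg_window = sg_window, sg_order = sg_order,
                 min_drop_pN = min_drop_pN,
                 prominence_sigmas = prominence_sigmas,
                 drop_window = drop_window),
            class = "detection_config")
}

#' Detect rupture candidates on a processed curve
#'
#' @param curve A `processed_curve` (see [convert_to_force_separation()]).
#' @param config A [detection_config()].
#' @return Tibble of candidates ordered by separation: `event_index`,
#'   `sample_index`, `separation_nm`, `force_pN` (raw force at the last
#'   pre-rupture sample), `drop_pN`, `noise_sigma_pN`.
#' @export
detect_events <- function(curve, config = detection_config()) {
  stopifnot(inherits(curve, "processed_curve"))
  f <- curve$force_pN
  n <- length(f)
  if (n < config$sg_window) {
    abort("Curve is shorter than the smoothing window.")
  }
  fs <- signal::sgolayfilt(f, p = config$sg_order, n = config$sg_window)
  sigma <- mad(f - fs)
  thr <- max(config$min_drop_pN, config$prominence_sigmas * sigma)

  w <- config$drop_window
  drop <- rep(0, n)
  for (k in seq_len(w)) {
    lead_k <- c(fs[-seq_len(k)], rep(fs[n], k))
    drop <- pmax(drop, fs - lead_k)
  }
  hit <- which(drop >= thr & curve$separation_nm > 0)
  empty <- tibble(event_index = integer(), sample_index = integer(),
                  separation_nm = numeric(), force_pN = numeric(),
                  drop_pN = numeric(), noise_sigma_pN = numeric())
  if (!length(hit)) return(empty)

  # group contiguous hits (gap > drop_window starts a new candidate); the
  # rupture sample is the steepest descent of the smoothed force within the
  # run, i.e. the last pre-rupture sample of the underlying step
  grp <- cumsum(c(1, diff(hit) > w))
  dfs <- diff(fs)
  draw <- diff(f)
  idx <- vapply(split(hit, grp), function(run) {
    lo <- max(1L, min(run) - 1L)
    hi <- min(n - 1L, max(run) + w)
    cliff <- (lo:hi)[which.min(dfs[lo:hi])]
    # refine on the raw channel: the rupture itself is the largest
    # single-step drop near the smoothed cliff
    lo2 <- max(1L, cliff - 4L)
    hi2 <- min(n - 1L, cliff + 4L)
    (lo2:hi2)[which.min(draw[lo2:hi2])]
  }, integer(1))
  idx <- sort(unique(idx))
  tibble(
    event_index = seq_along(idx),
    sample_index = idx,
    separation_nm = curve$separation_nm[idx],
    force_pN = f[idx],
    drop_pN = drop[pmax(1L, idx - 1L)],
    noise_sigma_pN = sigma
  )
}

#' Fit the rising edge of each candidate with a fixed-persistence WLC
#'
#' For every candidate the rising edge is taken from the end of the previous
#' event (or the last baseline crossing of the smoothed force, whichever is
#' later - ties broken toward the longer window) up to the last pre-rupture
#' sample, and fitted by least squares with [wlc_force()], the persistence
#' length held fixed and the contour length Lc the only free mechanical
#' parameter. The rupture force FU is read from the raw force at the last
#' pre-rupture sample, not from the WLC value there.
#'
#' A straight line is fitted to the same edge alongside the WLC; both R^2
#' values are kept so the downstream nonlinearity filter can reject linear
#' (non-WLC-like) profiles.
#'
#' @param curve A `processed_curve`.
#' @param candidates Output of [detect_events()].
#' @param persistence_length_nm Fixed persistence length (nm). Default 0.4.
#' @param min_edge_samples Minimum rising-edge length; shorter edges are
#'   flagged unfittable. Default 8.
#' @return Tibble with one row per candidate: `event_index`, `sample_index`,
#'   `x_r_nm`, `FU_pN`, `Lc_nm`, `residual_pN`, `r2_wlc`, `r2_linear`,
#'   `rel_extension`, `fittable`.
#' @export
fit_event_wlc <- function(curve, candidates,
                          persistence_length_nm = 0.4,
                          min_edge_samples = 8) {
  stopifnot(inherits(curve, "processed_curve"))
  meta <- curve_meta(curve)
  f <- curve$force_pN
  s <- curve$separation_nm
  fs <- signal::sgolayfilt(f, p = 2, n = min(11, 2 * (length(f) %/% 2) - 1))

  prev_end <- 0L
  purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    ri <- candidates$sample_index[i]
    lo <- prev_end + 1L
    # last baseline crossing of the smoothed force before the rupture
    seg <- lo:ri
    below <- seg[fs[seg] <= 0 & seq_along(seg) < length(seg)]
    if (length(below)) lo <- max(below)
    seg <- lo:ri
    seg <- seg[s[seg] > 0]
    prev_end <<- ri + 1L

    base <- tibble(event_index = candidates$event_index[i],
                   sample_index = ri,
                   x_r_nm = s[ri], FU_pN = f[ri])
    if (length(seg) < min_edge_samples) {
      return(dplyr::mutate(base, Lc_nm = NA_real_, residual_pN = NA_real_,
                           r2_wlc = NA_real_, r2_linear = NA_real_,
                           rel_extension = NA_real_, fittable = FALSE))
    }
    xe <- s[seg]
    fe <- f[seg]
    x_max <- max(xe)
    rss <- function(Lc) {
      p <- wlc_params(Lc, persistence_length_nm, meta$temperature_K)
      sum((fe - wlc_force(p, xe))^2)
    }
    opt <- optimize(rss, lower = x_max * 1.0005, upper = max(500, 3 * x_max),
                    tol = 1e-6)
    Lc <- opt$minimum
    at_bound <- Lc > 0.999 * max(500, 3 * x_max) || Lc < x_max * 1.001
    tss <- sum((fe - mean(fe))^2)
    r2_wlc <- if (tss > 0) 1 - opt$objective / tss else NA_real_
    lin <- lm(fe ~ xe)
    r2_lin <- if (tss > 0) 1 - sum(resid(lin)^2) / tss else NA_real_
    dplyr::mutate(base,
      Lc_nm = Lc,
      residual_pN = sqrt(opt$objective / length(seg)),
      r2_wlc = r2_wlc, r2_linear = r2_lin,
      rel_extension = x_r_nm / Lc,
      fittable = !at_bound && is.finite(Lc)
    )
  })
}

#' Loading rate at rupture
#'
#' Per the standard constant-velocity analysis, the force loading rate of an
#' event is the WLC stiffness ([wlc_stiffness()]) evaluated at the fitted
#' contour length and the extension at rupture, multiplied by the retraction
#' velocity.
#'
#' @param events Tibble from [fit_event_wlc()] (needs `Lc_nm`, `x_r_nm`).
#' @param retraction_velocity_nm_s Retraction velocity (nm/s).
#' @param persistence_length_nm Fixed persistence length (nm). Default 0.4.
#' @param temperature_K Temperature (K). Default 298.
#' @return `events` with columns `wlc_slope_pN_nm` and `loading_rate_pN_s`
#'   appended.
#' @export
loading_rate_at_rupture <- function(events, retraction_velocity_nm_s,
                                    persistence_length_nm = 0.4,
                                    temperature_K = 298) {
  if (is.null(retraction_velocity_nm_s) || is.na(retraction_velocity_nm_s) ||
      retraction_velocity_nm_s <= 0) {
    abort("Missing or invalid retraction velocity metadata.")
  }
  slope <- purrr::map2_dbl(events$Lc_nm, events$x_r_nm, function(Lc, xr) {
    if (is.na(Lc) || is.na(xr) || xr >= Lc) return(NA_real_)
    wlc_stiffness(wlc_params(Lc, persistence_length_nm, temperature_K), xr)
  })
  dplyr::mutate(events,
    wlc_slope_pN_nm = slope,
    loading_rate_pN_s = slope * retraction_velocity_nm_s
  )
}

#' Event acceptance criteria
#'
#' Operationalises the experiment's binning rules: events closer to the
#' surface than `min_separation_nm` are discarded as non-specific tip-sample
#' adhesion; events whose fitted contour length does not exceed the PEG
#' linker pair (`min_Lc_nm`) cannot contain the complex; edges whose WLC fit
#' does not beat a straight line by `nonlinearity_delta_r2` in R^2, or that
#' were only sampled at small fractional extension
#' (`min_relative_extension`), are rejected as linear force-distance
#' profiles; and edges with an RMS fit residual above `max_fit_residual_pN`
#' are rejected as poor fits.
#'
#' @param min_separation_nm Minimum rupture separation (nm). Default 10.
#' @param min_Lc_nm Minimum fitted contour length (nm). Default 19, the PEG24
#'   linker pair.
#' @param max_fit_residual_pN Maximum RMS WLC residual (pN). Default 15.
#' @param nonlinearity_delta_r2 Required R^2 margin of WLC over linear.
#'   Default 0.01.
#' @param min_relative_extension Minimum x_r / Lc. Default 0.2.
#' @param persistence_length_nm Fixed persistence length (nm). Default 0.4.
#' @return List of class `filter_criteria`.
#' @export
filter_criteria <- function(min_separation_nm = 10,
                            min_Lc_nm = 19,
                            max_fit_residual_pN = 15,
                            nonlinearity_delta_r2 = 0.01,
                            min_relative_extension = 0.2,
                            persistence_length_nm = 0.4) {
  vals <- c(min_separation_nm, min_Lc_nm, max_fit_residual_pN,
            nonlinearity_delta_r2, min_relative_extension,
            persistence_length_nm)
  if (any(vals <= 0)) abort("All filter thresholds must be positive.")
  structure(list(min_separation_nm = min_separation_nm,
                 min_Lc_nm = min_Lc_nm,
                 max_fit_residual_pN = max_fit_residual_pN,
                 nonlinearity_delta_r2 = nonlinearity_delta_r2,
                 min_relative_extension = min_relative_extension,
                 persistence_length_nm = persistence_length_nm),
            class = "filter_criteria")
}

.rejection_reasons <- c("unfittable", "below_min_separation",
                        "contour_below_linker", "linear_profile", "poor_fit")

#' Apply acceptance filters to fitted events
#'
#' Filtering is total: every detected candidate comes out exactly once,
#' either accepted or rejected with a reason drawn from a fixed enumeration
#' (`"unfittable"`, `"below_min_separation"`, `"contour_below_linker"`,
#' `"linear_profile"`, `"poor_fit"`). The first failing rule (in that order)
#' is recorded.
#'
#' @param events Tibble from [fit_event_wlc()] (optionally with loading
#'   rates).
#' @param criteria A [filter_criteria()].
#' @return `events` with logical `accepted` and character `reason`
#'   (`NA` when accepted) appended; event order is preserved.
#' @export
apply_filters <- function(events, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  reason <- purrr::pmap_chr(
    list(events$fittable, events$x_r_nm, events$Lc_nm, events$r2_wlc,
         events$r2_linear, events$rel_extension, events$residual_pN),
    function(fit_ok, xr, Lc, r2w, r2l, relx, res) {
      if (!isTRUE(fit_ok)) return("unfittable")
      if (xr < criteria$min_separation_nm) return("below_min_separation")
      if (Lc <= criteria$min_Lc_nm) return("contour_below_linker")
      if (is.na(r2w) || is.na(r2l) ||
          (r2w - r2l) < criteria$nonlinearity_delta_r2 ||
          relx <= criteria$min_relative_extension) {
        return("linear_profile")
      }
      if (res > criteria$max_fit_residual_pN) return("poor_fit")
      NA_character_
    }
  )
  dplyr::mutate(events, accepted = is.na(reason), reason = reason)
}

#' Classify curves by accepted event count and compute the hit rate
#'
#' @param events Filtered events table carrying a `curve_id` column (events
#'   from all curves of a map, after [apply_filters()]).
#' @param curve_ids Character vector of all analysed curve ids, so curves
#'   with zero detected events are classified too.
#' @return Tibble: `curve_id`, `n_accepted_events`, `accepted`,
#'   `rejection_reasons` (comma-joined reasons of rejected events).
#' @export
classify_curves <- function(events, curve_ids) {
  if (!length(curve_ids)) abort("`curve_ids` must be non-empty.")
  per <- events |>
    dplyr::group_by(.data$curve_id) |>
    dplyr::summarise(
      n_accepted_events = sum(.data$accepted),
      rejection_reasons = paste(stats::na.omit(.data$reason), collapse = ","),
      .groups = "drop"
    )
  tibble(curve_id = curve_ids) |>
    dplyr::left_join(per, by = "curve_id") |>
    dplyr::mutate(
      n_accepted_events = dplyr::coalesce(.data$n_accepted_events, 0L),
      rejection_reasons = dplyr::coalesce(.data$rejection_reasons, ""),
      accepted = .data$n_accepted_events >= 1L
    ) |>
    dplyr::select("curve_id", "n_accepted_events", "accepted",
                  "rejection_reasons")
}

#' @param classifications Output of [classify_curves()].
#' @rdname classify_curves
#' @export
hit_rate <- function(classifications) {
  if (!nrow(classifications)) abort("Empty classification table.")
  mean(classifications$accepted)
}

#' Analyse one processed curve end to end
#'
#' Convenience chain detect -> fit -> loading rate -> filter for a single
#' curve; returns the filtered event table with the curve id attached.
#'
#' @param curve A `processed_curve`.
#' @param detection A [detection_config()].
#' @param criteria A [filter_criteria()].
#' @return Filtered events tibble (possibly zero rows) with `curve_id`.
#' @export
analyze_curve <- function(curve, detection = detection_config(),
                          criteria = filter_criteria()) {
  meta <- curve_meta(curve)
  cand <- detect_events(curve, detection)
  if (!nrow(cand)) {
    return(tibble(curve_id = character(), event_index = integer(),
                  sample_index = integer(), x_r_nm = numeric(),
                  FU_pN = numeric(), Lc_nm = numeric(),
                  residual_pN = numeric(), r2_wlc = numeric(),
                  r2_linear = numeric(), rel_extension = numeric(),
                  fittable = logical(), wlc_slope_pN_nm = numeric(),
                  loading_rate_pN_s = numeric(), accepted = logical(),
                  reason = character()))
  }
  fit_event_wlc(curve, cand,
                persistence_length_nm = criteria$persistence_length_nm) |>
    loading_rate_at_rupture(meta$retraction_velocity_nm_s,
                            persistence_length_nm = criteria$persistence_length_nm,
                            temperature_K = meta$temperature_K) |>
    apply_filters(criteria) |>
    dplyr::mutate(curve_id = meta$curve_id, .before = 1)
}

#' Analyse a collection of curves
#'
#' Runs [convert_to_force_separation()] (when given raw curves) and
#' [analyze_curve()] over a [force_map()] or list of curves and assembles the
#' map-level result: the pooled event table, the per-curve classification and
#' the hit rate.
#'
#' @param map A [force_map()], or a list of `force_curve` /
#'   `processed_curve` objects.
#' @param detection A [detection_config()].
#' @param criteria A [filter_criteria()].
#' @return List of class `map_analysis`: `events`, `classification`,
#'   `hit_rate`, `n_curves`.
#' @export
analyze_map <- function(map, detection = detection_config(),
                        criteria = filter_criteria()) {
  curves <- if (inherits(map, "force_map")) map$curves else map
  if (!length(curves)) abort("no curves found", class = "tonbpull_no_curves")
  processed <- lapply(curves, function(cv) {
    if (inherits(cv, "processed_curve")) cv else convert_to_force_separation(cv)
  })
  events <- purrr::map_dfr(processed, analyze_curve,
                           detection = detection, criteria = criteria)
  ids <- vapply(processed, function(cv) attr(cv, "curve_id"), character(1))
  cls <- classify_curves(events, ids)
  structure(
    list(events = events, classification = cls,
         hit_rate = hit_rate(cls), n_curves = length(curves)),
    class = "map_analysis"
  )
}

#' @export
print.map_analysis <- function(x, ...) {
  cat(sprintf(
    "<map_analysis> %d curves, %d detected events (%d accepted), hit rate %.1f%%\n",
    x$n_curves, nrow(x$events), sum(x$events$accepted), 100 * x$hit_rate
  ))
  invisible(x)
}
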