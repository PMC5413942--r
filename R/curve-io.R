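#' Raw force curve
#'
#' A raw (instrument-frame) approach-retract trace: sampled time, piezo
#' displacement and either cantilever deflection or a pre-converted force
#' channel, plus the per-curve metadata the downstream analysis needs. The
#' data live in a tibble; metadata are carried as attributes and read back
#' with [curve_meta()].
#'
#' Sign conventions: piezo displacement increases as the probe retracts from
#' the surface; deflection is positive when the cantilever is bent towards
#' the surface by a tethered molecule, so tensile force is positive
#' (`force = kc * deflection`) and the repulsive contact wall is negative.
#'
#' @param time_s Sample times (s), strictly increasing.
#' @param piezo_nm Piezo displacement (nm).
#' @param deflection_nm Cantilever deflection (nm); omit if `force_pN` given.
#' @param force_pN Pre-converted force channel (pN); omit if `deflection_nm`
#'   given.
#' @param spring_constant_pN_nm Cantilever spring constant kc (pN/nm), > 0.
#' @param retraction_velocity_nm_s Retraction velocity (nm/s), > 0.
#' @param approach_velocity_nm_s Approach velocity (nm/s), > 0. Default 1000.
#' @param temperature_K Temperature (K). Default 298.
#' @param curve_id Identifier string.
#' @param segment Segment label, one of "retract", "approach", "dwell".
#' @return A tibble of class `force_curve` with metadata attributes.
#' @export
force_curve <- function(time_s, piezo_nm,
                        deflection_nm = NULL, force_pN = NULL,
                        spring_constant_pN_nm,
                        retraction_velocity_nm_s,
                        approach_velocity_nm_s = 1000,
                        temperature_K = 298,
                        curve_id = "curve",
                        segment = "retract") {
  if (is.null(deflection_nm) && is.null(force_pN)) {
    abort("Provide `deflection_nm` or `force_pN`.")
  }
  n <- length(time_s)
  chans <- list(piezo_nm = piezo_nm, deflection_nm = deflection_nm,
                force_pN = force_pN)
  chans <- chans[!vapply(chans, is.null, logical(1))]
  if (any(vapply(chans, length, integer(1)) != n)) {
    abort("All channels must have the same length as `time_s`.")
  }
  if (n < 16) abort("A force curve needs at least 16 samples.")
  if (any(diff(time_s) <= 0)) abort("`time_s` must be strictly increasing.")
  if (!is.numeric(spring_constant_pN_nm) || spring_constant_pN_nm <= 0) {
    abort("`spring_constant_pN_nm` must be positive.")
  }
  if (retraction_velocity_nm_s <= 0 || approach_velocity_nm_s <= 0) {
    abort("Velocities must be positive.")
  }
  segment <- match.arg(segment, c("retract", "approach", "dwell"))
  out <- as_tibble(c(list(time_s = time_s), chans))
  structure(
    out,
    spring_constant_pN_nm = spring_constant_pN_nm,
    retraction_velocity_nm_s = retraction_velocity_nm_s,
    approach_velocity_nm_s = approach_velocity_nm_s,
    temperature_K = temperature_K,
    curve_id = curve_id,
    segment = segment,
    class = c("force_curve", class(out))
  )
}

.meta_fields <- c("spring_constant_pN_nm", "retraction_velocity_nm_s",
                  "approach_velocity_nm_s", "temperature_K", "curve_id",
                  "segment")

#' Metadata of a force curve
#'
#' @param curve A `force_curve` or `processed_curve`.
#' @return Named list of metadata fields.
#' @export
curve_meta <- function(curve) {
  setNames(lapply(.meta_fields, function(f) attr(curve, f)), .meta_fields)
}

#' Read / write force curves in the package TSV dialect
#'
#' The on-disk dialect is plain TSV: `#`-prefixed header lines of the form
#' `# key<TAB>value` carry the metadata, followed by a tab-separated column
#' header and the sample rows. Columns are `time_s`, `piezo_nm` and either
#' `deflection_nm` or `force_pN`. The round trip is lossless (values are
#' written at full double precision).
#'
#' @param path File path.
#' @return `read_force_curve()` returns a [force_curve()];
#'   `write_force_curve()` returns `path` invisibly.
#' @export
read_force_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta_raw <- sub("^#\\s*", "", lines[hdr])
  kv <- strsplit(meta_raw, "\t", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) abort(sprintf("Malformed header line in %s", path))
  meta <- setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, 1, FUN.VALUE = ""))
  required <- c("spring_constant_pN_nm", "retraction_velocity_nm_s")
  for (f in required) {
    if (is.null(meta[[f]])) {
      abort(sprintf("Curve file %s is missing mandatory metadata field '%s'.",
                    path, sub("_pN_nm$|_nm_s$", "", f)),
            class = "tonbpull_parse_error")
    }
  }
  body <- lines[!hdr]
  # base parser: correctly rounded doubles, so the round trip is bit-exact
  dat <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           colClasses = "numeric")
  if (!all(c("time_s", "piezo_nm") %in% names(dat)) ||
      !any(c("deflection_nm", "force_pN") %in% names(dat))) {
    abort(sprintf("Curve file %s lacks required columns.", path),
          class = "tonbpull_parse_error")
  }
  force_curve(
    time_s = dat$time_s, piezo_nm = dat$piezo_nm,
    deflection_nm = dat[["deflection_nm"]],
    force_pN = dat[["force_pN"]],
    spring_constant_pN_nm = as.numeric(meta$spring_constant_pN_nm),
    retraction_velocity_nm_s = as.numeric(meta$retraction_velocity_nm_s),
    approach_velocity_nm_s =
      as.numeric(meta$approach_velocity_nm_s %||% 1000),
    temperature_K = as.numeric(meta$temperature_K %||% 298),
    curve_id = meta$curve_id %||% basename(path),
    segment = meta$segment %||% "retract"
  )
}

#' @param curve A [force_curve()].
#' @rdname read_force_curve
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  meta <- curve_meta(curve)
  fmt <- function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }
  hdr <- vapply(names(meta), function(k) {
    sprintf("# %s\t%s", k, fmt(meta[[k]]))
  }, character(1))
  cols <- names(curve)
  body <- c(
    paste(cols, collapse = "\t"),
    do.call(paste, c(lapply(curve, fmt), sep = "\t"))
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Force map: a collection of curves from one scan area
#'
#' @param curves List of [force_curve()] objects.
#' @param cycles Declared number of approach-retract cycles; must equal
#'   `length(curves)` when given.
#' @param map_area_um2 Scanned area (um^2), metadata only.
#' @return A list of class `force_map`.
#' @export
force_map <- function(curves, cycles = length(curves), map_area_um2 = NA_real_) {
  if (!length(curves) || !all(vapply(curves, inherits, logical(1), "force_curve"))) {
    abort("`curves` must be a non-empty list of force_curve objects.")
  }
  if (cycles != length(curves)) {
    abort("Declared `cycles` must equal the number of curves.")
  }
  structure(list(curves = curves, cycles = cycles,
                 map_area_um2 = map_area_um2),
            class = "force_map")
}

#' @export
print.force_map <- function(x, ...) {
  cat(sprintf("<force_map> %d curves (area %s um^2)\n", x$cycles,
              format(x$map_area_um2)))
  invisible(x)
}

#' Read a directory (or manifest) of curve files as a force map
#'
#' @param dir Directory containing `*.tsv` curve files in the package
#'   dialect, or a manifest file (one curve path per line, relative to the
#'   manifest's directory).
#' @param pattern Filename pattern for directory ingestion.
#' @return A [force_map()].
#' @export
read_force_map <- function(dir, pattern = "\\.tsv$") {
  if (dir.exists(dir)) {
    paths <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
    # sidecar files written next to simulated datasets are not curves
    paths <- paths[!grepl("^(truth_|manifest)", basename(paths))]
  } else if (file.exists(dir)) {
    paths <- file.path(dirname(dir), readLines(dir))
    paths <- paths[nzchar(basename(paths))]
  } else {
    abort(sprintf("No such directory or manifest: %s", dir))
  }
  if (!length(paths)) abort("no curves found", class = "tonbpull_no_curves")
  force_map(lapply(paths, read_force_curve))
}

#' Write a rupture-event table as TSV
#'
#' Column set: curve_id, event_index, x_r_nm, FU_pN, Lc_nm,
#' loading_rate_pN_s, residual_pN, accepted, reason (missing columns are
#' filled with NA so partial tables written mid-pipeline stay readable).
#'
#' @param events Tibble of events.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_table <- function(events, path) {
  cols <- c("curve_id", "event_index", "x_r_nm", "FU_pN", "Lc_nm",
            "loading_rate_pN_s", "residual_pN", "accepted", "reason")
  for (cl in setdiff(cols, names(events))) events[[cl]] <- NA
  readr::write_tsv(events[cols], path, progress = FALSE)
  invisible(path)
}
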