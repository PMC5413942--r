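#' Run configuration
#'
#' Assembles the tunable parameters of a pipeline run with defaults equal to
#' the experiment's stated values where one exists (persistence length
#' 0.4 nm, PEG linker pair 19 nm, minimum specific separation 10 nm, scatter
#' bins 5 nm x 10 pN). Accepts overrides from a YAML or JSON config file;
#' explicit arguments override file values.
#'
#' @param path Optional YAML/JSON config file.
#' @param ... Named overrides of the defaults (see [filter_criteria()],
#'   [detection_config()] plus `fu_bin_width_pN`, `lc_bin_width_nm`,
#'   `dlc_bin_width_nm`, `scatter_bin_lc_nm`, `scatter_bin_fu_pN`, `seed`).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(
    persistence_length_nm = 0.4,
    min_separation_nm = 10,
    min_Lc_nm = 19,
    max_fit_residual_pN = 15,
    nonlinearity_delta_r2 = 0.01,
    min_relative_extension = 0.2,
    sg_window = 11, sg_order = 2,
    min_drop_pN = 20, prominence_sigmas = 3, drop_window = 6,
    fu_bin_width_pN = 10,
    lc_bin_width_nm = 2,
    dlc_bin_width_nm = 2,
    scatter_bin_lc_nm = 5,
    scatter_bin_fu_pN = 10,
    min_mode_n = 30,
    seed = 1
  )
  from_file <- list()
  if (!is.null(path)) {
    from_file <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
  }
  cfg <- modifyList(modifyList(defaults, from_file), list(...))
  structure(cfg, class = c("run_config", "list"))
}

.criteria_from_config <- function(cfg) {
  filter_criteria(
    min_separation_nm = cfg$min_separation_nm,
    min_Lc_nm = cfg$min_Lc_nm,
    max_fit_residual_pN = cfg$max_fit_residual_pN,
    nonlinearity_delta_r2 = cfg$nonlinearity_delta_r2,
    min_relative_extension = cfg$min_relative_extension,
    persistence_length_nm = cfg$persistence_length_nm
  )
}

.detection_from_config <- function(cfg) {
  detection_config(sg_window = cfg$sg_window, sg_order = cfg$sg_order,
                   min_drop_pN = cfg$min_drop_pN,
                   prominence_sigmas = cfg$prominence_sigmas,
                   drop_window = cfg$drop_window)
}

.provenance <- function(cfg) {
  plain <- cfg[!vapply(cfg, is.null, logical(1))]
  list(package = "tonbpull",
       version = as.character(utils::packageVersion("tonbpull")),
       config_hash = rlang::hash(plain),
       seed = cfg$seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

.write_resolved_config <- function(cfg, out_dir) {
  plain <- cfg[!vapply(cfg, is.null, logical(1))]
  jsonlite::write_json(c(plain, list(provenance = .provenance(cfg))),
                       file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Analyze a directory (or in-memory set) of force curves
#'
#' Full chain: read -> convert to force vs separation -> detect -> WLC fit
#' -> loading rates -> filters -> per-curve classification -> modal
#' statistics (FU, Lc, delta-Lc where enough curves carry multiple events).
#' Writes `events.tsv`, `classification.tsv`, `summary.json` and the
#' resolved config next to them, and logs curve/event counts at every filter
#' stage.
#'
#' @param input A directory of curve TSVs, a manifest file, a [force_map()],
#'   a [simulate_map()] result or a list of curves.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param config A [run_config()].
#' @return List of class `analysis_report`: `analysis` (the
#'   [analyze_map()] result), `delta_lc`, `modes` (named list of
#'   `gaussian_mode_fit`s), `summary` (the list written as JSON).
#' @export
run_analyze <- function(input, out_dir = NULL, config = run_config()) {
  map <- if (is.character(input)) read_force_map(input)
         else if (inherits(input, "simulated_dataset")) input$curves
         else input
  analysis <- analyze_map(map,
                          detection = .detection_from_config(config),
                          criteria = .criteria_from_config(config))
  ev <- analysis$events
  inform(sprintf(
    "analyze: %d curves -> %d detected events -> %d accepted (hit rate %.1f%%)",
    analysis$n_curves, nrow(ev), sum(ev$accepted), 100 * analysis$hit_rate))
  if (nrow(ev)) {
    rej <- table(ev$reason[!ev$accepted])
    if (length(rej)) {
      inform(paste0("analyze: rejections - ",
                    paste(sprintf("%s: %d", names(rej), rej), collapse = ", ")))
    }
  }

  acc <- dplyr::filter(ev, .data$accepted)
  modes <- list()
  if (nrow(acc) >= config$min_mode_n) {
    modes$FU <- fit_gaussian_mode(acc$FU_pN, config$fu_bin_width_pN,
                                  min_n = config$min_mode_n)
    modes$Lc <- fit_gaussian_mode(acc$Lc_nm, config$lc_bin_width_nm,
                                  min_n = config$min_mode_n)
  }
  dlc <- compute_delta_lc(ev)
  if (nrow(dlc) >= config$min_mode_n) {
    modes$dLc1 <- fit_gaussian_mode(dlc$dLc1, config$dlc_bin_width_nm,
                                    min_n = config$min_mode_n)
    if (sum(is.finite(dlc$dLc2)) >= config$min_mode_n) {
      modes$dLc2 <- fit_gaussian_mode(dlc$dLc2[is.finite(dlc$dLc2)],
                                      config$dlc_bin_width_nm,
                                      min_n = config$min_mode_n)
      modes$dLc_total <- fit_gaussian_mode(dlc$dLc_total,
                                           config$dlc_bin_width_nm,
                                           min_n = config$min_mode_n)
    }
  }

  summary <- list(
    n_curves = analysis$n_curves,
    n_detected_events = nrow(ev),
    n_accepted_events = sum(ev$accepted),
    hit_rate = analysis$hit_rate,
    event_counts = as.list(table(analysis$classification$n_accepted_events)),
    modes = lapply(modes, function(m)
      list(mode = m$mode, sigma = m$sigma, n = m$n, bin_width = m$bin_width)),
    bin_widths = list(FU_pN = config$fu_bin_width_pN,
                      Lc_nm = config$lc_bin_width_nm,
                      dLc_nm = config$dlc_bin_width_nm),
    provenance = .provenance(config)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_events_table(ev, file.path(out_dir, "events.tsv"))
    readr::write_tsv(analysis$classification,
                     file.path(out_dir, "classification.tsv"),
                     progress = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    .write_resolved_config(config, out_dir)
  }
  structure(list(analysis = analysis, delta_lc = dlc, modes = modes,
                 summary = summary),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  print(x$analysis)
  for (nm in names(x$modes)) {
    cat(sprintf("  modal %s = %.3g +/- %.3g (n = %d)\n", nm,
                x$modes[[nm]]$mode, x$modes[[nm]]$sigma, x$modes[[nm]]$n))
  }
  invisible(x)
}

#' Simulate a dataset and optionally write it to disk
#'
#' @param scenario Scenario name (see [scenario_presets()]).
#' @param n_curves Number of approach-retract cycles.
#' @param out_dir Output directory; `NULL` keeps the dataset in memory.
#' @param fractions Curve-type mixture, as in [simulate_map()].
#' @param config A [pulling_config()].
#' @param seed Integer seed.
#' @return The [simulate_map()] result, invisibly when written.
#' @export
run_simulate <- function(scenario, n_curves, out_dir = NULL,
                         fractions = c(specific = 0.075, adhesion = 0.1),
                         config = pulling_config(), seed = 1) {
  ds <- simulate_map(config, scenario, n_curves, fractions, seed = seed)
  inform(sprintf("simulate: %d curves, scenario %s", n_curves, ds$scenario))
  if (!is.null(out_dir)) {
    write_simulated_dataset(ds, out_dir)
    return(invisible(ds))
  }
  ds
}

#' Dynamic force spectrum + Bell-Evans report over multiple velocities
#'
#' @param events Accepted-events table pooled over velocities (columns
#'   `retraction_velocity_nm_s`, `FU_pN`, `loading_rate_pN_s`, optional
#'   `replicate`).
#' @param out_dir Output directory; `NULL` skips writing.
#' @param fu_bin_width_pN Force bin width for modal fits. Default 10.
#' @param temperature_K Temperature (K). Default 298.
#' @param min_n Minimum events per velocity. Default 30.
#' @return List: `points` (DFS tibble), `fit` (`bell_evans_fit`).
#' @export
run_dfs <- function(events, out_dir = NULL, fu_bin_width_pN = 10,
                    temperature_K = 298, min_n = 30) {
  points <- build_dfs(events, fu_bin_width_pN = fu_bin_width_pN,
                      min_n = min_n)
  fit <- fit_bell_evans(points, temperature_K = temperature_K)
  inform(sprintf("dfs: %d velocities, slope %.3g pN, xbeta %.3g nm, k0 %.3g /s",
                 nrow(points), fit$slope, fit$xbeta_nm, fit$k0_per_s))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(points, file.path(out_dir, "dfs.tsv"), progress = FALSE)
    jsonlite::write_json(
      c(as.list(glance(fit)), list(provenance = .provenance(run_config()))),
      file.path(out_dir, "bell_evans.json"), auto_unbox = TRUE, digits = NA)
  }
  list(points = points, fit = fit)
}

#' Fit a KD to a titration file or series
#'
#' @param titration A [titration_series()], or a TSV path with columns
#'   `concentration_M`, `fnorm` and optional `replicate`.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param labeled_concentration_M Labelled-species concentration (M) when
#'   reading from file. Default 250e-9.
#' @param ... Passed to [fit_kd()].
#' @return The `binding_fit`.
#' @export
run_mstfit <- function(titration, out_dir = NULL,
                       labeled_concentration_M = 250e-9, ...) {
  series <- if (is.character(titration)) {
    dat <- readr::read_tsv(titration, show_col_types = FALSE, progress = FALSE)
    if (!all(c("concentration_M", "fnorm") %in% names(dat))) {
      abort("Titration TSV needs columns 'concentration_M' and 'fnorm'.")
    }
    titration_series(dat$concentration_M, dat$fnorm,
                     labeled_concentration_M = labeled_concentration_M)
  } else {
    titration
  }
  fit <- fit_kd(series, ...)
  inform(sprintf("mstfit: KD = %.3g M (n = %d)", fit$KD_M, fit$n))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(KD_M = fit$KD_M, fnorm_unbound = fit$fnorm_unbound,
           fnorm_bound = fit$fnorm_bound, residual_rms = fit$residual_rms,
           ci = as.list(fit$ci), n = fit$n,
           provenance = .provenance(run_config())),
      file.path(out_dir, "binding_fit.json"), auto_unbox = TRUE, digits = NA)
  }
  fit
}

#' Write a titration series as TSV
#'
#' @param series A [titration_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path) {
  readr::write_tsv(
    tibble(concentration_M = series$ligand_concentration_M,
           fnorm = series$fnorm,
           replicate = attr(series, "replicate") %||% "r1"),
    path, progress = FALSE)
  invisible(path)
}
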