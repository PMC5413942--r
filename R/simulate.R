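#' Mechanical segment of the pulled construct
#'
#' The simulated construct is a serial mechanical network described as a list
#' of segments: passive contour contributions (PEG linkers, the folded
#' complex, any pre-unfolded polypeptide) and rupturable elements governed by
#' Bell kinetics, `k(F) = k0 exp(F x_beta / kBT)`. A folded-subdomain
#' rupture releases `released_residues` amino acids into the stretched chain
#' (delta-Lc = n x 0.4 nm by default); a complex-unbinding rupture terminates
#' the curve.
#'
#' @param name Segment label.
#' @param kind One of "linker", "complex-unbinding", "folded-subdomain",
#'   "pre-unfolded".
#' @param contour_contribution_nm Contour length the segment contributes
#'   while intact (nm), >= 0.
#' @param released_residues Residues released when the segment ruptures,
#'   >= 0.
#' @param k0_per_s Intrinsic rupture rate (1/s), >= 0 (0 = never ruptures).
#' @param x_beta_nm Distance to the transition state (nm), >= 0.
#' @param rupture_terminates_curve Does rupture detach the tether? Default
#'   `TRUE` for kind "complex-unbinding".
#' @return List of class `segment_spec`.
#' @export
segment_spec <- function(name,
                         kind = c("linker", "complex-unbinding",
                                  "folded-subdomain", "pre-unfolded"),
                         contour_contribution_nm = 0,
                         released_residues = 0,
                         k0_per_s = 0,
                         x_beta_nm = 0,
                         rupture_terminates_curve =
                           match.arg(kind) == "complex-unbinding") {
  kind <- match.arg(kind)
  if (contour_contribution_nm < 0 || released_residues < 0 ||
      k0_per_s < 0 || x_beta_nm < 0) {
    abort("Segment parameters must be non-negative.")
  }
  structure(list(name = name, kind = kind,
                 contour_contribution_nm = contour_contribution_nm,
                 released_residues = released_residues,
                 k0_per_s = k0_per_s, x_beta_nm = x_beta_nm,
                 rupture_terminates_curve = rupture_terminates_curve),
            class = "segment_spec")
}

#' Constant-velocity pulling configuration
#'
#' @param cantilever_spring_pN_nm Cantilever spring constant (pN/nm).
#'   Default 30.
#' @param retraction_velocity_nm_s Retraction velocity (nm/s). Default 1000.
#' @param sampling_rate_Hz Sampling rate (Hz). Default 25000.
#' @param force_noise_sigma_pN Gaussian noise added to the force channel
#'   (pN). Default 5.
#' @param persistence_length_nm WLC persistence length (nm). Default 0.4.
#' @param temperature_K Temperature (K). Default 298.
#' @param contact_depth_nm Indentation depth at the start of the retraction
#'   (nm); produces the repulsive hard-contact wall. Default 3.
#' @param wall_stiffness_pN_nm Slope of the contact wall (pN/nm).
#'   Default 500.
#' @param baseline_offset_pN Constant force offset added to the raw channel
#'   (what baseline zeroing must remove). Default 0.
#' @param contact_offset_nm Offset added to the recorded piezo channel (what
#'   contact zeroing must remove). Default 0.
#' @param pull_distance_nm Total retraction distance past contact (nm);
#'   `NULL` (default) picks 1.6x the final contour length so every curve
#'   ends with a long detached baseline.
#' @param seed Optional integer seed.
#' @return List of class `pulling_config`.
#' @export
pulling_config <- function(cantilever_spring_pN_nm = 30,
                           retraction_velocity_nm_s = 1000,
                           sampling_rate_Hz = 25000,
                           force_noise_sigma_pN = 5,
                           persistence_length_nm = 0.4,
                           temperature_K = 298,
                           contact_depth_nm = 3,
                           wall_stiffness_pN_nm = 500,
                           baseline_offset_pN = 0,
                           contact_offset_nm = 0,
                           pull_distance_nm = NULL,
                           seed = NULL) {
  pos <- c(cantilever_spring_pN_nm, retraction_velocity_nm_s,
           sampling_rate_Hz, persistence_length_nm, temperature_K,
           wall_stiffness_pN_nm)
  if (any(pos <= 0)) abort("Mechanical parameters must be positive.")
  if (force_noise_sigma_pN < 0) abort("Noise sigma must be >= 0.")
  structure(list(cantilever_spring_pN_nm = cantilever_spring_pN_nm,
                 retraction_velocity_nm_s = retraction_velocity_nm_s,
                 sampling_rate_Hz = sampling_rate_Hz,
                 force_noise_sigma_pN = force_noise_sigma_pN,
                 persistence_length_nm = persistence_length_nm,
                 temperature_K = temperature_K,
                 contact_depth_nm = contact_depth_nm,
                 wall_stiffness_pN_nm = wall_stiffness_pN_nm,
                 baseline_offset_pN = baseline_offset_pN,
                 contact_offset_nm = contact_offset_nm,
                 pull_distance_nm = pull_distance_nm,
                 seed = seed),
            class = "pulling_config")
}

#' Scenario presets for the pulling simulator
#'
#' Segment lists emulating the experimental constructs:
#'
#' * `"wild-type"`: PEG linker pair (19 nm) + folded complex (5.5 nm,
#'   unbinding k0 = 0.1 /s, xbeta = 0.35 nm, terminating) + a 33.5 nm
#'   force-resistant partially extended linker conformation + a mechanically
#'   weak plug subdomain releasing 50 residues (k0 = 1 /s, xbeta = 0.5 nm):
#'   double-rupture curves with delta-Lc ground truth 20 nm.
#' * `"XL_barrel"`: as wild-type with unfolding disabled (crosslink pins the
#'   plug to the barrel): single-rupture curves.
#' * `"XL_loop"`: weak subdomain shortened by a covalent 15-residue loop, so
#'   35 residues release (delta-Lc ground truth 14 nm).
#' * `"3A"`: destabilised strong subdomain added: 50 then 64 residues unfold
#'   before unbinding (triple-rupture curves).
#' * `"L8P-control"`: binding-deficient control; same segment list as
#'   wild-type but intended for maps with a specific fraction of 0
#'   (adhesion/empty only).
#'
#' Kinetic defaults keep the mechanical hierarchy of the system: at loading
#' rates near 1e4 pN/s the modal unfolding force (~58 pN for the weak
#' subdomain, ~78 pN for the destabilised strong subdomain) stays below the
#' modal unbinding force (~105 pN).
#'
#' @param name Scenario name.
#' @param residue_length_nm Stretched length per residue (nm). Default 0.4.
#' @return List of [segment_spec()]s with attribute `scenario`.
#' @export
scenario_presets <- function(name = c("wild-type", "XL_barrel", "XL_loop",
                                      "3A", "L8P-control"),
                             residue_length_nm = 0.4) {
  name <- match.arg(name)
  linker <- segment_spec("PEG24_pair", "linker", contour_contribution_nm = 19)
  prelinker <- segment_spec("linker_remnant", "pre-unfolded",
                            contour_contribution_nm = 33.5)
  complex_seg <- segment_spec("TonB_TonBox", "complex-unbinding",
                              contour_contribution_nm = 5.5,
                              k0_per_s = 0.1, x_beta_nm = 0.35)
  weak <- function(n_res) {
    segment_spec("weak_plug_subdomain", "folded-subdomain",
                 released_residues = n_res, k0_per_s = 1, x_beta_nm = 0.5)
  }
  strong_3a <- segment_spec("destabilized_strong_subdomain",
                            "folded-subdomain",
                            released_residues = 64,
                            k0_per_s = 0.5, x_beta_nm = 0.4)
  segs <- switch(name,
    "wild-type"   = list(linker, prelinker, complex_seg, weak(50)),
    "XL_barrel"   = list(linker, prelinker, complex_seg),
    "XL_loop"     = list(linker, prelinker, complex_seg, weak(35)),
    "3A"          = list(linker, prelinker, complex_seg, weak(50), strong_3a),
    "L8P-control" = list(linker, prelinker, complex_seg, weak(50))
  )
  structure(segs, scenario = name, residue_length_nm = residue_length_nm)
}

# dense closed-form force/distance map for the cantilever + WLC series:
# z(x) = x + F(x)/kc, sampled on an extension grid and linearly interpolated
.series_force_of_z <- function(Lc, kc, p, T, f_cap = 2000, n_grid = 2500) {
  params <- wlc_params(Lc, p, T)
  u_hi <- 1 - sqrt(params$kBT_pN_nm / (4 * p * f_cap))
  u <- c(seq(0, 0.95, length.out = floor(n_grid / 2)),
         seq(0.95 + 1e-6, u_hi, length.out = ceiling(n_grid / 2)))
  x <- u * Lc
  fF <- wlc_force(params, x)
  z <- x + fF / kc
  approxfun(z, fF, yleft = 0, yright = f_cap, rule = 2)
}

#' Simulate one constant-velocity pulling curve
#'
#' Monte-Carlo constant-velocity retraction through a serial mechanical
#' network. At each sample the piezo position advances by `v dt`; the force
#' follows the closed-form balance `z = F/kc + x_wlc(F; Lc)` for the current
#' total contour length (cantilever and WLC in series). Every intact
#' rupturable segment carries a Bell hazard `k0 exp(F x_beta / kBT)`;
#' rupture times are drawn by inverse sampling of the cumulative hazard on
#' the force trajectory. A folded-subdomain rupture adds
#' `released_residues x residue_length` to the total contour length (the
#' force relaxes accordingly); a terminating rupture drops the force to the
#' baseline for the rest of the trace. Gaussian noise is added to the force
#' channel, and the configured baseline/contact offsets are applied so the
#' preprocessing stage has real work to do.
#'
#' @param config A [pulling_config()].
#' @param segments List of [segment_spec()]s (e.g. [scenario_presets()]);
#'   at least one terminating segment is required.
#' @param curve_id Curve identifier.
#' @param residue_length_nm Stretched length per released residue (nm).
#'   Default 0.4.
#' @return List of class `simulated_pull`: `curve` (a [force_curve()] in the
#'   instrument frame), `truth` (tibble logging every rupture: time, sample
#'   index, clean force, Lc before/after, segment, terminating) and
#'   `clean_force_pN` (the noise-free force vector).
#' @export
simulate_pull <- function(config, segments, curve_id = "sim",
                          residue_length_nm = 0.4) {
  stopifnot(inherits(config, "pulling_config"))
  if (!any(vapply(segments, function(s) s$rupture_terminates_curve,
                  logical(1)))) {
    abort("At least one terminating segment is required.")
  }
  runner <- function() {
    .simulate_pull_impl(config, segments, curve_id, residue_length_nm)
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, runner())
  else runner()
}

.simulate_pull_impl <- function(config, segments, curve_id,
                                residue_length_nm) {
  kc <- config$cantilever_spring_pN_nm
  v <- config$retraction_velocity_nm_s
  dt <- 1 / config$sampling_rate_Hz
  p <- config$persistence_length_nm
  Temp <- config$temperature_K
  kBT <- thermal_energy(Temp)

  Lc0 <- sum(vapply(segments, function(s) s$contour_contribution_nm,
                    numeric(1)))
  released_total <- sum(vapply(segments, function(s)
    s$released_residues * residue_length_nm, numeric(1)))
  Lc_final <- Lc0 + released_total
  z_max <- config$pull_distance_nm %||% (1.6 * Lc_final)

  time_s <- seq(0, (z_max + config$contact_depth_nm) / v, by = dt)
  n <- length(time_s)
  z <- -config$contact_depth_nm + v * time_s
  force <- numeric(n)
  # repulsive hard-contact wall while indented
  in_contact <- z < 0
  force[in_contact] <- config$wall_stiffness_pN_nm * z[in_contact]

  rupturable <- Filter(function(s) s$k0_per_s > 0, segments)
  intact <- rep(TRUE, length(rupturable))
  Lc <- Lc0
  i0 <- which(!in_contact)[1]
  truth <- tibble(time_s = numeric(), sample_index = integer(),
                  force_pN = numeric(), Lc_before_nm = numeric(),
                  Lc_after_nm = numeric(), segment = character(),
                  terminates = logical())
  detached <- FALSE
  i <- i0
  while (!detached && i <= n) {
    fmap <- .series_force_of_z(Lc, kc, p, Temp)
    idx <- i:n
    f_seg <- fmap(z[idx])
    # inverse-sample each intact segment's rupture time on this trajectory
    rupture_at <- rep(Inf, length(rupturable))
    for (j in seq_along(rupturable)) {
      if (!intact[j]) next
      s <- rupturable[[j]]
      haz <- s$k0_per_s * exp(pmax(f_seg, 0) * s$x_beta_nm / kBT) * dt
      H <- cumsum(haz)
      thr <- rexp(1)
      hitpos <- which(H >= thr)
      if (length(hitpos)) rupture_at[j] <- hitpos[1]
    }
    if (all(is.infinite(rupture_at))) {
      force[idx] <- f_seg
      break
    }
    j_star <- which.min(rupture_at)
    kpos <- rupture_at[j_star]
    rupt_i <- idx[kpos]
    force[i:rupt_i] <- f_seg[seq_len(kpos)]
    s <- rupturable[[j_star]]
    Lc_new <- Lc + if (s$rupture_terminates_curve) 0 else
      s$released_residues * residue_length_nm
    truth <- dplyr::bind_rows(truth, tibble(
      time_s = time_s[rupt_i], sample_index = rupt_i,
      force_pN = force[rupt_i], Lc_before_nm = Lc, Lc_after_nm = Lc_new,
      segment = s$name, terminates = s$rupture_terminates_curve
    ))
    intact[j_star] <- FALSE
    if (s$rupture_terminates_curve) {
      detached <- TRUE
      if (rupt_i < n) force[(rupt_i + 1):n] <- 0
    } else {
      Lc <- Lc_new
      i <- rupt_i + 1L
    }
  }

  noisy <- force + rnorm(n, 0, config$force_noise_sigma_pN)
  deflection <- (noisy + config$baseline_offset_pN) / kc
  curve <- force_curve(
    time_s = time_s,
    piezo_nm = z + config$contact_offset_nm,
    deflection_nm = deflection,
    spring_constant_pN_nm = kc,
    retraction_velocity_nm_s = v,
    temperature_K = Temp,
    curve_id = curve_id
  )
  structure(list(curve = curve, truth = truth, clean_force_pN = force,
                 Lc_initial_nm = Lc0, Lc_final_nm = Lc),
            class = "simulated_pull")
}

# non-specific adhesion: linear force-distance spring detaching below 10 nm
.simulate_adhesion <- function(config, curve_id) {
  kc <- config$cantilever_spring_pN_nm
  v <- config$retraction_velocity_nm_s
  dt <- 1 / config$sampling_rate_Hz
  z_max <- config$pull_distance_nm %||% 80
  time_s <- seq(0, (z_max + config$contact_depth_nm) / v, by = dt)
  z <- -config$contact_depth_nm + v * time_s
  x_det <- runif(1, 2, 9)
  f_det <- runif(1, 40, 120)
  slope <- f_det / x_det
  force <- numeric(length(z))
  in_contact <- z < 0
  force[in_contact] <- config$wall_stiffness_pN_nm * z[in_contact]
  pulled <- !in_contact
  x <- z[pulled] / (1 + slope / kc)   # series balance for a linear tether
  f <- slope * x
  f[x >= x_det] <- 0
  force[pulled] <- f
  noisy <- force + rnorm(length(z), 0, config$force_noise_sigma_pN)
  force_curve(
    time_s = time_s, piezo_nm = z + config$contact_offset_nm,
    deflection_nm = (noisy + config$baseline_offset_pN) / kc,
    spring_constant_pN_nm = kc, retraction_velocity_nm_s = v,
    temperature_K = config$temperature_K, curve_id = curve_id
  )
}

.simulate_empty <- function(config, curve_id) {
  kc <- config$cantilever_spring_pN_nm
  v <- config$retraction_velocity_nm_s
  dt <- 1 / config$sampling_rate_Hz
  z_max <- config$pull_distance_nm %||% 80
  time_s <- seq(0, (z_max + config$contact_depth_nm) / v, by = dt)
  z <- -config$contact_depth_nm + v * time_s
  force <- numeric(length(z))
  force[z < 0] <- config$wall_stiffness_pN_nm * z[z < 0]
  noisy <- force + rnorm(length(z), 0, config$force_noise_sigma_pN)
  force_curve(
    time_s = time_s, piezo_nm = z + config$contact_offset_nm,
    deflection_nm = (noisy + config$baseline_offset_pN) / kc,
    spring_constant_pN_nm = kc, retraction_velocity_nm_s = v,
    temperature_K = config$temperature_K, curve_id = curve_id
  )
}

#' Simulate a force map: a mixture of specific, adhesion and empty curves
#'
#' Each approach-retract cycle is independently assigned a type with the
#' stated probabilities: "specific" (the scenario's mechanical network,
#' [simulate_pull()]), "adhesion" (a linear tether detaching at a uniform
#' random separation in 2-9 nm) or "empty" (noise only). The whole dataset
#' is deterministic under the seed.
#'
#' @param config A [pulling_config()] (its `seed` field is ignored here; use
#'   the `seed` argument).
#' @param scenario Scenario name for [scenario_presets()], or a list of
#'   [segment_spec()]s.
#' @param n_curves Number of curves.
#' @param fractions Named numeric `c(specific =, adhesion =)`; the remainder
#'   are empty. Must be in `[0, 1]` and sum to <= 1.
#' @param seed Integer seed. Default 1.
#' @return List of class `simulated_dataset`: `curves` (list of
#'   [force_curve()]s), `truth` (per-curve type and rupture log),
#'   `scenario`, `fractions`, `config`, `seed`.
#' @export
simulate_map <- function(config, scenario = "wild-type", n_curves,
                         fractions = c(specific = 0.075, adhesion = 0.1),
                         seed = 1) {
  stopifnot(inherits(config, "pulling_config"))
  fr_s <- unname(fractions["specific"])
  fr_a <- unname(fractions["adhesion"])
  if (is.na(fr_s) || is.na(fr_a) || fr_s < 0 || fr_a < 0 || fr_s + fr_a > 1) {
    abort("`fractions` must have non-negative 'specific' and 'adhesion' summing to <= 1.")
  }
  segments <- if (is.character(scenario)) scenario_presets(scenario)
              else scenario
  scen_name <- attr(segments, "scenario") %||% "custom"
  if (identical(scen_name, "L8P-control") && fr_s > 0) {
    warn("L8P-control is a binding-deficient scenario; specific fraction is usually 0.")
  }
  # one shared pull distance so all curve types share a frame
  Lc_final <- sum(vapply(segments, function(s)
    s$contour_contribution_nm + s$released_residues * 0.4, numeric(1)))
  cfg <- config
  cfg$pull_distance_nm <- config$pull_distance_nm %||% (1.6 * Lc_final)
  cfg$seed <- NULL

  withr::with_seed(seed, {
    types <- sample(c("specific", "adhesion", "empty"), n_curves,
                    replace = TRUE, prob = c(fr_s, fr_a, 1 - fr_s - fr_a))
    ids <- sprintf("%s_%04d", gsub("[^A-Za-z0-9]", "_", scen_name),
                   seq_len(n_curves))
    curves <- vector("list", n_curves)
    logs <- vector("list", n_curves)
    for (i in seq_len(n_curves)) {
      if (types[i] == "specific") {
        sim <- .simulate_pull_impl(cfg, segments, ids[i], 0.4)
        curves[[i]] <- sim$curve
        if (nrow(sim$truth)) {
          logs[[i]] <- dplyr::mutate(sim$truth, curve_id = ids[i],
                                     .before = 1)
        }
      } else if (types[i] == "adhesion") {
        curves[[i]] <- .simulate_adhesion(cfg, ids[i])
      } else {
        curves[[i]] <- .simulate_empty(cfg, ids[i])
      }
    }
    structure(
      list(curves = curves,
           truth = list(types = tibble(curve_id = ids, type = types),
                        events = dplyr::bind_rows(logs)),
           scenario = scen_name,
           fractions = c(specific = fr_s, adhesion = fr_a,
                         empty = 1 - fr_s - fr_a),
           config = cfg, seed = seed),
      class = "simulated_dataset"
    )
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> scenario %s: %d curves (%s)\n",
              x$scenario, length(x$curves),
              paste(sprintf("%s %.1f%%", names(x$fractions),
                            100 * x$fractions), collapse = ", ")))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits each curve in the TSV dialect, the ground-truth event log as TSV and
#' a scenario manifest as JSON.
#'
#' @param dataset A [simulate_map()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cv in dataset$curves) {
    write_force_curve(cv, file.path(dir, paste0(attr(cv, "curve_id"), ".tsv")))
  }
  readr::write_tsv(dataset$truth$types, file.path(dir, "truth_types.tsv"),
                   progress = FALSE)
  ev <- dataset$truth$events
  if (is.null(ev) || !nrow(ev)) {
    ev <- tibble(curve_id = character(), time_s = numeric(),
                 sample_index = integer(), force_pN = numeric(),
                 Lc_before_nm = numeric(), Lc_after_nm = numeric(),
                 segment = character(), terminates = logical())
  }
  readr::write_tsv(ev, file.path(dir, "truth_events.tsv"), progress = FALSE)
  manifest <- list(scenario = dataset$scenario,
                   n_curves = length(dataset$curves),
                   fractions = as.list(dataset$fractions),
                   seed = dataset$seed,
                   config = dataset$config[!vapply(dataset$config, is.null,
                                                   logical(1))])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Sample Bell-Evans rupture forces at a constant loading rate
#'
#' Inverse-transform sampling of the rupture-force distribution for a bond
#' with Bell kinetics under a constant force ramp `F = r t`:
#' `F = (kBT / x_beta) ln(1 - ln(U) x_beta r / (k0 kBT))`, `U ~ U(0,1)`.
#' This closed form is the independent oracle for the curve-level
#' Monte-Carlo and the input generator for dynamic-force-spectrum recovery
#' tests.
#'
#' @param n Number of ruptures.
#' @param k0_per_s Intrinsic off rate (1/s).
#' @param x_beta_nm Distance to the transition state (nm).
#' @param loading_rate_pN_s Loading rate (pN/s).
#' @param temperature_K Temperature (K). Default 298.
#' @param seed Optional seed.
#' @return Numeric vector of rupture forces (pN).
#' @export
simulate_rupture_forces <- function(n, k0_per_s, x_beta_nm,
                                    loading_rate_pN_s,
                                    temperature_K = 298, seed = NULL) {
  kBT <- thermal_energy(temperature_K)
  a <- k0_per_s * kBT / (x_beta_nm * loading_rate_pN_s)
  runner <- function() {
    u <- runif(n)
    (kBT / x_beta_nm) * log1p(-log(u) / a)
  }
  if (!is.null(seed)) withr::with_seed(seed, runner()) else runner()
}

#' Simulate an MST titration
#'
#' Serial-dilution titration of the labelled species with the titrant:
#' concentrations descend from `conc_max_M` by `dilution_factor` over
#' `n_points` points (defaults reproduce a 16-point two-fold series from
#' 244 uM down to ~7.4 nM), Fnorm comes from [fraction_bound()] +
#' [fnorm_model()], and Gaussian noise is added.
#'
#' @param KD_M True dissociation constant (M).
#' @param n_points Number of concentrations. Default 16.
#' @param conc_max_M Highest in-capillary titrant concentration (M).
#'   Default 244e-6.
#' @param dilution_factor Serial dilution factor. Default 2.
#' @param labeled_concentration_M Labelled-species concentration (M).
#'   Default 250e-9.
#' @param signal An [mst_signal()]. Default amplitudes 800 -> 850.
#' @param noise_sigma Gaussian noise sd on Fnorm; default 2% of the signal
#'   amplitude.
#' @param seed Optional seed.
#' @param replicate Replicate label.
#' @return A [titration_series()] with attributes `true_KD_M`,
#'   `true_signal`, `noise_sigma`.
#' @export
simulate_mst <- function(KD_M, n_points = 16, conc_max_M = 244e-6,
                         dilution_factor = 2,
                         labeled_concentration_M = 250e-9,
                         signal = mst_signal(800, 850),
                         noise_sigma = NULL, seed = NULL,
                         replicate = "r1") {
  if (KD_M <= 0) abort("`KD_M` must be positive.")
  if (n_points < 2 || conc_max_M <= 0 || dilution_factor <= 1) {
    abort("Invalid titration design.")
  }
  conc <- conc_max_M / dilution_factor^(seq_len(n_points) - 1)
  fb <- fraction_bound(labeled_concentration_M, conc, KD_M)
  f0 <- fnorm_model(fb, signal)
  amp <- abs(signal$fnorm_bound - signal$fnorm_unbound)
  noise_sigma <- noise_sigma %||% (0.02 * amp)
  noise <- if (noise_sigma > 0) {
    runner <- function() rnorm(n_points, 0, noise_sigma)
    if (!is.null(seed)) withr::with_seed(seed, runner()) else runner()
  } else rep(0, n_points)
  out <- titration_series(conc, f0 + noise,
                          labeled_concentration_M = labeled_concentration_M,
                          replicate = replicate)
  attr(out, "true_KD_M") <- KD_M
  attr(out, "true_signal") <- signal
  attr(out, "noise_sigma") <- noise_sigma
  out
}
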