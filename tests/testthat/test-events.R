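wt_sim <- function(seed, noise = 5, scenario = "wild-type", v = 1000) {
  cfg <- pulling_config(force_noise_sigma_pN = noise,
                        retraction_velocity_nm_s = v, seed = seed)
  simulate_pull(cfg, scenario_presets(scenario), paste0("s", seed))
}

test_that("detected candidates match the generator event log to +/- 2 samples", {
  n_checked <- 0
  for (s in 1:10) {
    sim <- wt_sim(s)
    pc <- convert_to_force_separation(sim$curve)
    cand <- detect_events(pc)
    # every simulated rupture strong enough to clear the 20 pN drop
    # threshold must be found at its logged position; no extras appear
    visible <- sim$truth[sim$truth$force_pN >= 45, ]
    expect_lte(nrow(cand), nrow(sim$truth))
    for (k in seq_len(nrow(visible))) {
      d <- abs(cand$sample_index - visible$sample_index[k])
      expect_lte(min(d), 2)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 10)
})

test_that("smooth or flat traces yield no candidates", {
  # monotone WLC rise, no rupture: all rates zero
  segs <- list(
    segment_spec("tether", "linker", contour_contribution_nm = 40),
    segment_spec("bond", "complex-unbinding", contour_contribution_nm = 5,
                 k0_per_s = 0, x_beta_nm = 0.35)
  )
  cfg <- pulling_config(force_noise_sigma_pN = 0, pull_distance_nm = 40,
                        seed = 2)
  sim <- simulate_pull(cfg, segs, "norupt")
  expect_equal(nrow(sim$truth), 0)
  pc <- convert_to_force_separation(sim$curve)
  expect_equal(nrow(detect_events(pc)), 0)

  # pure-noise flat trace at sigma = 5 pN
  withr::with_seed(3, {
    t <- seq(0, 0.1, length.out = 2000)
    flat <- force_curve(t, piezo_nm = t * 1000,
                        deflection_nm = rnorm(2000, 0, 5 / 30),
                        spring_constant_pN_nm = 30,
                        retraction_velocity_nm_s = 1000)
  })
  pcf <- convert_to_force_separation(flat)
  expect_equal(nrow(detect_events(pcf)), 0)

  expect_error(detect_events(pcf[1:5, ]), "smoothing window")
})

test_that("noise-free edges recover the configured contour length", {
  sim <- wt_sim(4, noise = 0, scenario = "XL_barrel")
  ev <- analyze_curve(convert_to_force_separation(sim$curve))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$Lc_nm, 58, tolerance = 0.5 / 58)
  expect_true(ev$accepted)

  # double rupture: both contour lengths within 1 nm of ground truth
  # (use the first seed whose unfolding is strong enough to detect)
  sim2 <- NULL
  for (s in 1:10) {
    cand <- wt_sim(s, noise = 0)
    if (nrow(cand$truth) == 2 && all(cand$truth$force_pN >= 45)) {
      sim2 <- cand
      break
    }
  }
  ev2 <- analyze_curve(convert_to_force_separation(sim2$curve))
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$Lc_nm, c(58, 78), tolerance = 1 / 58)
})

test_that("fitted Lc is invariant to retraction velocity within 1%", {
  lc <- vapply(c(500, 2000), function(v) {
    sim <- wt_sim(7, noise = 0, scenario = "XL_barrel", v = v)
    ev <- analyze_curve(convert_to_force_separation(sim$curve))
    ev$Lc_nm[1]
  }, numeric(1))
  expect_equal(lc[1], lc[2], tolerance = 0.01)
})

test_that("loading rates follow the WLC slope times the velocity", {
  sim <- wt_sim(8, noise = 0, scenario = "XL_barrel")
  ev <- analyze_curve(convert_to_force_separation(sim$curve))

  # order 1e4 pN/s at 1000 nm/s, as in the experiments
  expect_gt(ev$loading_rate_pN_s, 3e3)
  expect_lt(ev$loading_rate_pN_s, 1e5)

  # doubling the velocity doubles the rate for the identical fit
  ev2 <- loading_rate_at_rupture(ev, 2000)
  expect_equal(ev2$loading_rate_pN_s, 2 * ev$loading_rate_pN_s)

  # slope agrees with a finite difference of the fitted WLC at rupture
  p <- wlc_params(ev$Lc_nm, 0.4, 298)
  h <- 1e-4
  fd <- (wlc_force(p, ev$x_r_nm + h) - wlc_force(p, ev$x_r_nm - h)) / (2 * h)
  expect_equal(ev$wlc_slope_pN_nm / fd, 1, tolerance = 1e-3)

  expect_error(loading_rate_at_rupture(ev, NA), "velocity")
})

test_that("filters reject adhesion, short contour lengths and linear edges", {
  # threshold rules on a hand-built event table
  ev <- tibble::tibble(
    event_index = 1:4,
    x_r_nm = c(6, 30, 30, 30),
    Lc_nm = c(8, 15, 60, 60),
    FU_pN = 80, residual_pN = c(3, 3, 3, 30),
    r2_wlc = c(0.99, 0.99, 0.995, 0.99),
    r2_linear = c(0.995, 0.9, 0.9, 0.9),
    rel_extension = c(0.7, 0.8, 0.5, 0.5),
    fittable = TRUE
  )
  out <- apply_filters(ev)
  expect_equal(out$reason,
               c("below_min_separation", "contour_below_linker",
                 NA, "poor_fit"))
  expect_equal(out$accepted, is.na(out$reason))

  # simulated non-specific adhesion detaches < 10 nm and is rejected
  ds <- simulate_map(pulling_config(), "wild-type", 25,
                     fractions = c(specific = 0, adhesion = 1), seed = 21)
  an <- analyze_map(ds$curves)
  expect_equal(sum(an$events$accepted), 0)
  expect_equal(an$hit_rate, 0)
  if (nrow(an$events)) {
    expect_true(all(an$events$reason %in%
                      c("below_min_separation", "linear_profile",
                        "contour_below_linker", "unfittable")))
    expect_true(all(an$events$x_r_nm[an$events$reason ==
                                       "below_min_separation"] < 10))
  }
})

test_that("filtering conserves events and classification counts them", {
  ds <- simulate_map(pulling_config(), "wild-type", 40,
                     fractions = c(specific = 0.5, adhesion = 0.3), seed = 31)
  an <- analyze_map(ds$curves)
  ev <- an$events
  # conservation: each detected candidate is accepted xor rejected-with-reason
  expect_equal(sum(ev$accepted) + sum(!is.na(ev$reason)), nrow(ev))
  expect_true(all(ev$accepted == is.na(ev$reason)))
  # ordering by separation survives the pipeline within each curve
  by_curve <- split(ev, ev$curve_id)
  for (b in by_curve) expect_true(all(diff(b$x_r_nm) > 0))
  # classification tallies accepted events per curve
  agg <- tapply(ev$accepted, ev$curve_id, sum)
  cls <- an$classification
  for (id in names(agg)) {
    expect_equal(cls$n_accepted_events[cls$curve_id == id],
                 unname(agg[id]))
  }
  expect_equal(an$hit_rate, mean(cls$n_accepted_events >= 1))

  expect_error(hit_rate(cls[0, ]), "Empty")
})

test_that("triple-rupture curves classify as three events", {
  found <- FALSE
  for (s in 1:6) {
    sim <- wt_sim(s + 40, scenario = "3A")
    if (nrow(sim$truth) == 3 && all(sim$truth$force_pN >= 45)) {
      ev <- analyze_curve(convert_to_force_separation(sim$curve))
      cls <- classify_curves(ev, attr(sim$curve, "curve_id"))
      expect_equal(cls$n_accepted_events, 3L)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})
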