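test_that("rupture kinetics behave in their limits", {
  # all rates zero: no ruptures, monotone rising clean force
  segs <- list(
    segment_spec("tether", "linker", contour_contribution_nm = 40),
    segment_spec("bond", "complex-unbinding", contour_contribution_nm = 5,
                 k0_per_s = 0)
  )
  cfg <- pulling_config(force_noise_sigma_pN = 0, pull_distance_nm = 42,
                        seed = 1)
  sim <- simulate_pull(cfg, segs, "none")
  expect_equal(nrow(sim$truth), 0)
  pulled <- sim$clean_force_pN[sim$curve$piezo_nm > 0]
  expect_true(all(diff(pulled) >= 0))

  # enormous intrinsic rate: rupture in the first steps at ~zero force
  segs_fast <- list(
    segment_spec("tether", "linker", contour_contribution_nm = 40),
    segment_spec("bond", "complex-unbinding", contour_contribution_nm = 5,
                 k0_per_s = 1e9, x_beta_nm = 0.35)
  )
  sim2 <- simulate_pull(cfg, segs_fast, "fast")
  expect_equal(nrow(sim2$truth), 1)
  expect_lt(sim2$truth$force_pN, 2)

  expect_error(
    simulate_pull(cfg, list(segment_spec("t", "linker",
                                         contour_contribution_nm = 40))),
    "terminating")
})

test_that("the series force balance closes: piezo = deflection + extension", {
  cfg <- pulling_config(force_noise_sigma_pN = 0, seed = 3)
  sim <- simulate_pull(cfg, scenario_presets("XL_barrel"), "bal")
  f <- sim$clean_force_pN
  z <- sim$curve$piezo_nm
  kc <- 30
  pre <- which(z > 1 & f > 1)
  pre <- pre[pre < sim$truth$sample_index[1]]
  par <- wlc_params(58, 0.4, 298)
  x <- wlc_extension(par, f[pre])
  expect_lt(max(abs(z[pre] - (f[pre] / kc + x))), 0.1)
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- simulate_map(pulling_config(), "wild-type", 12,
                    fractions = c(specific = 0.5, adhesion = 0.2), seed = 99)
  b <- simulate_map(pulling_config(), "wild-type", 12,
                    fractions = c(specific = 0.5, adhesion = 0.2), seed = 99)
  expect_identical(a$truth$types, b$truth$types)
  for (i in seq_along(a$curves)) {
    expect_identical(a$curves[[i]]$deflection_nm, b$curves[[i]]$deflection_nm)
  }

  m1 <- simulate_mst(9.4e-6, seed = 7)
  m2 <- simulate_mst(9.4e-6, seed = 7)
  expect_identical(m1$fnorm, m2$fnorm)

  expect_error(simulate_map(pulling_config(), "wild-type", 5,
                            fractions = c(specific = 0.9, adhesion = 0.5)),
               "fractions")
})

test_that("scenario presets carry the documented unfolding ground truths", {
  released <- function(segs) {
    sum(vapply(segs, function(s) s$released_residues, numeric(1)))
  }
  wt <- scenario_presets("wild-type")
  expect_equal(released(wt) * 0.4, 20)              # 50 residues
  expect_equal(released(scenario_presets("XL_loop")) * 0.4, 14)  # 35 residues
  expect_equal(released(scenario_presets("XL_barrel")), 0)
  a3 <- scenario_presets("3A")
  res3 <- vapply(a3, function(s) s$released_residues, numeric(1))
  expect_equal(sort(res3[res3 > 0]), c(50, 64))
  expect_error(scenario_presets("nope"))

  # mechanical hierarchy: modal unfolding force < modal unbinding force
  # at the experimental ~1e4 pN/s loading rate
  kin <- function(segs, nm) Filter(function(s) s$name == nm, segs)[[1]]
  weak <- kin(wt, "weak_plug_subdomain")
  bond <- kin(wt, "TonB_TonBox")
  expect_lt(bell_evans_modal_force(weak$k0_per_s, weak$x_beta_nm, 1e4),
            bell_evans_modal_force(bond$k0_per_s, bond$x_beta_nm, 1e4))
})

test_that("sampled rupture forces match the closed-form Bell-Evans mode", {
  for (r in c(1e3, 1e4, 1e5)) {
    FU <- simulate_rupture_forces(4000, 0.05, 0.35, r, seed = 17)
    fit <- fit_gaussian_mode(FU, bin_width = 5)
    expect_equal(fit$mode, bell_evans_modal_force(0.05, 0.35, r),
                 tolerance = 0.05)
  }
})

test_that("written datasets round-trip through the map reader", {
  dir <- withr::local_tempdir()
  ds <- simulate_map(pulling_config(), "XL_barrel", 6,
                     fractions = c(specific = 0.5, adhesion = 0.2), seed = 5)
  write_simulated_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "truth_events.tsv")))
  fm <- read_force_map(dir)
  expect_equal(fm$cycles, 6)
  ids_disk <- sort(vapply(fm$curves, function(cv) attr(cv, "curve_id"),
                          character(1)))
  ids_mem <- sort(vapply(ds$curves, function(cv) attr(cv, "curve_id"),
                         character(1)))
  expect_identical(ids_disk, ids_mem)
})
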