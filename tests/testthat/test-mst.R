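test_that("fraction bound obeys the mass-action limits", {
  A <- 250e-9; KD <- 9.4e-6

  # saturation: L >> KD and L >> A
  expect_equal(fraction_bound(A, 1, KD), 1, tolerance = 1e-5)

  # dilute-label limit matches the hyperbola to < 1e-6
  L <- 10^seq(-8, -3, length.out = 30)
  fb_quad <- fraction_bound(1e-12, L, KD)
  fb_hyp <- L / (L + KD)
  expect_equal(fb_quad, fb_hyp, tolerance = 1e-6)

  # half saturation at L = KD for A << KD
  expect_equal(fraction_bound(1e-9, KD, KD), 0.5, tolerance = 1e-3)

  # monotone in L, decreasing in KD; mass conservation
  fb <- fraction_bound(A, L, KD)
  expect_true(all(diff(fb) > 0))
  expect_true(all(fraction_bound(A, L, KD * 10) < fb))
  expect_true(all(fb * A <= pmin(A, L) + 1e-18))

  expect_error(fraction_bound(-1, 1, 1), "positive")
  expect_error(fraction_bound(A, L, 0), "positive")
})

test_that("the signal model is linear between its endpoints", {
  sig <- mst_signal(800, 850)
  expect_equal(fnorm_model(0, sig), 800)
  expect_equal(fnorm_model(1, sig), 850)
  expect_equal(fnorm_model(0.5, sig), 825)
  expect_error(mst_signal(800, 800), "differ")
  expect_error(fnorm_model(1.5, sig), "\\[0, 1\\]")

  # generator round trip at zero noise reproduces the model exactly
  ts <- simulate_mst(9.4e-6, noise_sigma = 0)
  fb <- fraction_bound(attr(ts, "labeled_concentration_M"),
                       ts$ligand_concentration_M, 9.4e-6)
  expect_equal(ts$fnorm, fnorm_model(fb, attr(ts, "true_signal")))
})

test_that("KD is recovered exactly from noiseless titrations across decades", {
  for (kd in c(0.1, 1, 10, 100) * 1e-6) {
    ts <- simulate_mst(kd, noise_sigma = 0)
    fit <- suppressWarnings(fit_kd(ts, n_boot = 20))
    expect_equal(fit$KD_M, kd, tolerance = 1e-3)
  }
  # the reference design: 16 points, 7 nM - 244 uM, label 250 nM
  ts <- simulate_mst(9.4e-6, noise_sigma = 0)
  expect_equal(nrow(ts), 16)
  expect_equal(max(ts$ligand_concentration_M), 244e-6)
  expect_equal(min(ts$ligand_concentration_M), 244e-6 / 2^15)
  fit <- fit_kd(ts, n_boot = 20)
  expect_equal(fit$KD_M, 9.4e-6, tolerance = 1e-3)
  # half-signal inflection sits between 1e-6 and 1e-5 M
  half <- (fit$fnorm_unbound + fit$fnorm_bound) / 2
  cross <- ts$ligand_concentration_M[which.min(abs(ts$fnorm - half))]
  expect_gt(cross, 1e-6)
  expect_lt(cross, 1e-5)
})

test_that("degenerate titrations are rejected with diagnostics", {
  withr::with_seed(14, {
    conc <- 244e-6 / 2^(0:15)
    flat <- titration_series(conc, rnorm(16, 800, 0.5))
  })
  expect_error(fit_kd(flat), "amplitude", class = "tonbpull_mst_error")

  ts <- simulate_mst(9.4e-6, noise_sigma = 0)
  expect_error(fit_kd(ts[1:5, ], labeled_concentration_M = 250e-9),
               "at least")

  # titration spanning less than a decade either side of KD warns
  kd <- 9.4e-6
  conc <- kd * 2^seq(-2, 2, by = 0.5)
  fb <- fraction_bound(250e-9, conc, kd)
  narrow <- titration_series(conc, fnorm_model(fb, mst_signal(800, 850)))
  expect_warning(fit_kd(narrow, n_boot = 0,
                        labeled_concentration_M = 250e-9),
                 "decade")
})

test_that("the bootstrap interval brackets the estimate deterministically", {
  ts <- simulate_mst(9.4e-6, seed = 30)
  f1 <- fit_kd(ts, n_boot = 50, seed = 4)
  f2 <- fit_kd(ts, n_boot = 50, seed = 4)
  expect_identical(f1$ci, f2$ci)
  expect_lt(f1$ci[["lower"]], f1$KD_M)
  expect_gt(f1$ci[["upper"]], f1$KD_M)
})
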