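test_that("Gaussian modal fit recovers the centre of symmetric samples", {
  withr::with_seed(11, {
    x <- rnorm(10000, 113, 13)
  })
  fit <- fit_gaussian_mode(x, bin_width = 10)
  expect_equal(fit$mode, 113, tolerance = 1 / 113)
  expect_equal(fit$sigma, 13, tolerance = 0.1)
  expect_equal(fit$n, 10000)

  # bias below half a bin width on symmetric samples
  expect_lt(abs(fit$mode - 113), 10 / 2)

  # perfectly symmetric three-bin histogram: mode is the central bin centre
  sym <- c(rep(0.5, 10), rep(1.5, 20), rep(2.5, 10))
  fit3 <- fit_gaussian_mode(sym, bin_width = 1)
  expect_equal(fit3$mode, 1.5, tolerance = 1e-6)

  expect_error(fit_gaussian_mode(rnorm(10), 1), "at least")
  expect_error(fit_gaussian_mode(rep(5, 100), 1), "Degenerate")

  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "mode"], fit$mode)
  expect_equal(glance(fit)$n, 10000)
})

test_that("delta-Lc records difference per curve and add up exactly", {
  ev <- tibble::tibble(
    curve_id = c("a", "a", "b", "b", "b", "c", "d", "d"),
    x_r_nm   = c(40, 55, 35, 50, 70, 30, 40, 50),
    Lc_nm    = c(47, 67, 58, 78, 103.6, 58, 60, 55),
    accepted = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  expect_message(rec <- compute_delta_lc(ev), "skipped")
  # curve c has one event, curve d non-increasing Lc: both skipped
  expect_equal(sort(rec$curve_id), c("a", "b"))
  expect_equal(rec$dLc1[rec$curve_id == "a"], 20)
  b <- rec[rec$curve_id == "b", ]
  expect_equal(b$dLc1, 20)
  expect_equal(b$dLc2, 25.6)
  expect_equal(b$dLc_total, b$dLc1 + b$dLc2)
  expect_true(all(rec$dLc1 > 0))
})

test_that("replicate modes aggregate as mean +/- half range", {
  agg <- aggregate_replicates(c(100, 113, 126))
  expect_equal(agg$mean, 113)
  expect_equal(agg$half_range, 13)

  same <- aggregate_replicates(c(20, 20, 20))
  expect_equal(same$half_range, 0)

  expect_warning(single <- aggregate_replicates(47), "Single replicate")
  expect_true(single$single_replicate)
  expect_true(is.na(single$half_range))
  expect_error(aggregate_replicates(numeric(0)), "No replicate")
})

test_that("hotspot detection finds planted clusters and ignores uniform noise", {
  withr::with_seed(12, {
    lc <- c(rnorm(150, 47, 1.5), rnorm(150, 74, 2))
    fu <- c(rnorm(150, 113, 6), rnorm(150, 113, 6))
    ulc <- runif(2000, 20, 120)
    ufu <- runif(2000, 20, 220)
  })
  ds <- density_scatter(lc, fu)
  expect_equal(nrow(ds$hotspots), 2)
  cent <- ds$hotspots[order(ds$hotspots$lc_nm), ]
  expect_lt(abs(cent$lc_nm[1] - 47), 5)   # within one Lc bin
  expect_lt(abs(cent$lc_nm[2] - 74), 5)
  expect_lt(abs(cent$fu_pN[1] - 113), 10) # within one FU bin
  expect_lt(abs(cent$fu_pN[2] - 113), 10)

  expect_equal(nrow(density_scatter(ulc, ufu)$hotspots), 0)

  # hotspot count is invariant under joint translation of the cloud
  ds_shift <- density_scatter(lc + 7.5, fu + 15)
  expect_equal(nrow(ds_shift$hotspots), 2)

  expect_error(density_scatter(lc[1:5], fu[1:5]), "at least")
})

test_that("Bell-Evans regression is exact on exact points and inverts the model", {
  kBT <- thermal_energy(298)
  xb <- 0.35; k0 <- 0.05
  r <- c(1e3, 5e3, 2e4, 1e5)
  pts <- tibble::tibble(
    retraction_velocity_nm_s = 1:4,
    mean_ln_loading_rate = log(r),
    modal_FU_pN = bell_evans_modal_force(k0, xb, r),
    error_pN = NA_real_, n = 100L
  )
  fit <- fit_bell_evans(pts)
  expect_equal(fit$slope, kBT / xb, tolerance = 1e-10)
  expect_equal(fit$xbeta_nm, xb, tolerance = 1e-10)
  expect_equal(fit$k0_per_s, k0, tolerance = 1e-8)
  expect_true(all(diff(pts$modal_FU_pN) > 0))  # mode grows with loading rate

  bad <- pts
  bad$modal_FU_pN <- rev(bad$modal_FU_pN)
  expect_error(fit_bell_evans(bad), "Non-positive")
  expect_error(fit_bell_evans(pts[1:2, ]), "at least 3")

  gl <- glance(fit)
  expect_equal(gl$xbeta_nm, xb, tolerance = 1e-10)
})

test_that("build_dfs summarises per-velocity events with replicate spread", {
  withr::with_seed(13, {
    ev <- do.call(rbind, lapply(1:3, function(rep) {
      do.call(rbind, lapply(c(1e3, 1e4, 1e5), function(r) {
        data.frame(retraction_velocity_nm_s = r / 10,
                   replicate = paste0("r", rep),
                   FU_pN = simulate_rupture_forces(200, 0.05, 0.35, r),
                   loading_rate_pN_s = r)
      }))
    }))
  })
  pts <- build_dfs(ev)
  expect_equal(nrow(pts), 3)
  expect_true(all(diff(pts$modal_FU_pN) > 0))
  expect_true(all(is.finite(pts$error_pN)))
  # modal forces near the closed-form Bell-Evans mode
  expected <- bell_evans_modal_force(0.05, 0.35, c(1e3, 1e4, 1e5))
  expect_equal(pts$modal_FU_pN, expected, tolerance = 0.05)
})
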