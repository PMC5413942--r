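make_curve <- function(n = 64, id = "c1", force = FALSE) {
  t <- seq(0, 1, length.out = n)
  if (force) {
    force_curve(t, piezo_nm = t * 100, force_pN = sin(t * 6) * 20,
                spring_constant_pN_nm = 30, retraction_velocity_nm_s = 1000,
                curve_id = id)
  } else {
    force_curve(t, piezo_nm = t * 100, deflection_nm = cos(t * 3),
                spring_constant_pN_nm = 30, retraction_velocity_nm_s = 1000,
                curve_id = id)
  }
}

test_that("curve TSV round trip is lossless for arrays and metadata", {
  dir <- withr::local_tempdir()
  for (pre in c(FALSE, TRUE)) {
    cv <- make_curve(48, "round", force = pre)
    path <- file.path(dir, "c.tsv")
    write_force_curve(cv, path)
    back <- read_force_curve(path)
    expect_identical(back$time_s, cv$time_s)
    expect_identical(back$piezo_nm, cv$piezo_nm)
    if (pre) expect_identical(back$force_pN, cv$force_pN)
    else expect_identical(back$deflection_nm, cv$deflection_nm)
    expect_identical(curve_meta(back), curve_meta(cv))
  }
})

test_that("curve validation and parse errors name the problem", {
  t <- seq(0, 1, length.out = 32)
  expect_error(force_curve(t[1:8], piezo_nm = 1:8, deflection_nm = 1:8,
                           spring_constant_pN_nm = 30,
                           retraction_velocity_nm_s = 1000),
               "at least 16")
  expect_error(force_curve(rev(t), piezo_nm = t, deflection_nm = t,
                           spring_constant_pN_nm = 30,
                           retraction_velocity_nm_s = 1000),
               "strictly increasing")
  expect_error(force_curve(t, piezo_nm = t, deflection_nm = t,
                           spring_constant_pN_nm = -1,
                           retraction_velocity_nm_s = 1000),
               "positive")
  expect_error(force_curve(t, piezo_nm = t[1:10], deflection_nm = t,
                           spring_constant_pN_nm = 30,
                           retraction_velocity_nm_s = 1000),
               "same length")

  # file missing the spring constant is rejected, naming the field
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.tsv")
  write_force_curve(make_curve(32), path)
  lines <- readLines(path)
  writeLines(lines[!grepl("spring_constant", lines)], path)
  expect_error(read_force_curve(path), "spring_constant")
})

test_that("a directory of curve files reads back as a force map", {
  dir <- withr::local_tempdir()
  n_curves <- 12
  for (i in seq_len(n_curves)) {
    write_force_curve(make_curve(32, sprintf("m%02d", i)),
                      file.path(dir, sprintf("m%02d.tsv", i)))
  }
  fm <- read_force_map(dir)
  expect_s3_class(fm, "force_map")
  expect_equal(fm$cycles, n_curves)
  expect_equal(length(fm$curves), n_curves)

  expect_error(read_force_map(withr::local_tempdir()), "no curves found")
  expect_error(force_map(fm$curves, cycles = 5), "must equal")
})

test_that("events tables are written with the documented column set", {
  dir <- withr::local_tempdir()
  ev <- tibble::tibble(curve_id = "c1", event_index = 1L, x_r_nm = 45,
                       FU_pN = 110, Lc_nm = 58, loading_rate_pN_s = 1.4e4,
                       residual_pN = 4.2, accepted = TRUE,
                       reason = NA_character_)
  path <- write_events_table(ev, file.path(dir, "ev.tsv"))
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_named(back, c("curve_id", "event_index", "x_r_nm", "FU_pN", "Lc_nm",
                       "loading_rate_pN_s", "residual_pN", "accepted",
                       "reason"))
  expect_equal(back$Lc_nm, 58)
})
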