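# Synthetic hemodynamics generator.

test_that("simulation is deterministic given the seed", {
  a <- simulate_cohort(4, 3, 0.5, seed = 99)
  b <- simulate_cohort(4, 3, 0.5, seed = 99)
  expect_identical(a$profiles, b$profiles)
  expect_identical(lapply(a$boluses, `[[`, "abp_pre"),
                   lapply(b$boluses, `[[`, "abp_pre"))
  expect_identical(sapply(a$boluses, `[[`, "true_delta_sv_pct"),
                   sapply(b$boluses, `[[`, "true_delta_sv_pct"))
})

test_that("adding pigs does not reshuffle earlier pigs' boluses", {
  a <- simulate_cohort(4, 3, 0.5, seed = 99)
  b <- simulate_cohort(6, 3, 0.5, seed = 99)
  ids_a <- sapply(a$boluses, `[[`, "bolus_id")
  ids_b <- sapply(b$boluses, `[[`, "bolus_id")
  common <- intersect(ids_a, ids_b)
  expect_gt(length(common), 0)
  for (id in common[1:3]) {
    expect_identical(a$boluses[[match(id, ids_a)]]$abp_pre$samples,
                     b$boluses[[match(id, ids_b)]]$abp_pre$samples)
  }
})

test_that("study-scale cohort matches the design conditions", {
  co <- fixture_study_cohort()
  expect_equal(nrow(co$profiles), 58)
  n_bolus <- length(co$boluses)
  expect_gt(n_bolus, 330)
  expect_lt(n_bolus, 460)
  fr <- mean(sapply(co$boluses, `[[`, "true_delta_sv_pct") >= 15)
  expect_lt(abs(fr - 0.5), 0.1)
  expect_setequal(unique(co$profiles$injury_model), c("HEM", "IRI", "EPACC"))
  # EPACC is the largest arm, as in the study design mix
  expect_equal(unname(sort(table(co$profiles$injury_model))["EPACC"]),
               max(table(co$profiles$injury_model)))
})

test_that("pig profiles respect their physiologic invariants", {
  co <- fixture_study_cohort()
  p <- co$profiles
  expect_true(all(p$baseline_hr_bpm >= 60 & p$baseline_hr_bpm <= 180))
  expect_true(all(p$resp_rate_bpm >= 10 & p$resp_rate_bpm <= 25))
  expect_true(all(p$preload_reserve >= 0 & p$preload_reserve <= 1))
  expect_true(all(p$vascular_compliance > 0 & p$vascular_resistance > 0))
})

test_that("bolus segments span 60 s with in-range pressures and ordered fiducials", {
  co <- fixture_clean_cohort()
  for (b in co$boluses[1:4]) {
    for (nm in c("abp_pre", "abp_post", "co_pre", "co_post", "hr_pre", "hr_post")) {
      expect_equal(segment_duration(b[[nm]]), 60, tolerance = 1e-6)
    }
    expect_true(all(b$abp_pre$samples > 0 & b$abp_pre$samples < 300))
    f <- b$true_fiducials_pre
    expect_true(all(f$foot_time_s < f$peak_time_s))
    expect_true(all(f$peak_time_s < f$notch_time_s))
    expect_true(all(diff(f$foot_time_s) > 0))
  }
})

test_that("without modulation or noise the pulse pressure is constant", {
  co <- simulate_cohort(3, 2, 0.5, seed = 13, params = dead_calm_params())
  expect_true(all(abs(sapply(co$boluses, `[[`, "true_delta_sv_pct")) < 1e-9))
  b <- co$boluses[[1]]
  seg <- preprocess_segment(b$abp_pre)
  beats <- beat_quality_filter(detect_beats(seg))
  expect_lt(compute_ppv(beats), 0.5)
  expect_lt(diff(range(beats$pulse_pressure)), 0.3)
})

test_that("mean stroke-volume response is nondecreasing in preload reserve", {
  p <- dead_calm_params()
  p$g_intercept <- sim_defaults()$g_intercept
  p$g_slope <- sim_defaults()$g_slope
  prof <- simulate_cohort(2, 2, 0.5, seed = 17, params = p)$profiles[1, ]
  grid <- seq(0.05, 0.95, by = 0.15)
  deltas <- sapply(grid, function(r) {
    prof$preload_reserve <- r
    fluidresp:::simulate_bolus(prof, 1, "euvolemic", 17, p)$true_delta_sv_pct
  })
  expect_true(all(diff(deltas) >= -1e-9))
})

test_that("realized beat count per 60 s segment tracks the heart rate", {
  co <- fixture_clean_cohort()
  for (b in co$boluses[1:6]) {
    n_true <- nrow(b$true_fiducials_pre)
    period <- diff(b$true_fiducials_pre$foot_time_s[1:2])
    hr_realized <- 60 / period # bpm of the realized beat grid
    expect_lte(abs(n_true - hr_realized), 1.5)
  }
})

test_that("cohort write/read round trip preserves waveforms and manifest", {
  co <- simulate_cohort(2, 2, 0.5, seed = 23)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(manifest), length(co$boluses))
  back <- read_cohort(dir)
  expect_equal(back$boluses[[1]]$abp_pre$samples,
               co$boluses[[1]]$abp_pre$samples, tolerance = 1e-6)
  expect_equal(back$boluses[[1]]$true_delta_sv_pct,
               co$boluses[[1]]$true_delta_sv_pct, tolerance = 1e-6)
})

test_that("an empty cohort writes a header-only manifest", {
  dir <- withr::local_tempdir()
  write_cohort(structure(list(profiles = NULL, boluses = list()),
                         class = "sim_cohort"), dir)
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(manifest), 0)
  expect_true("bolus_id" %in% names(manifest))
})

test_that("invalid generator arguments are rejected", {
  expect_error(simulate_cohort(1, 3, 0.5, 1), "n_pigs")
  expect_error(simulate_cohort(4, -1, 0.5, 1), "positive")
  expect_error(simulate_cohort(4, 3, 1.2, 1), "prevalence")
})
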