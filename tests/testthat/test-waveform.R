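# Waveform containers, I/O and the preprocessing chain.

test_that("segment file round trip preserves samples and rate", {
  seg <- waveform_segment(sin(seq(0, 6 * pi, length.out = 2000)) * 20 + 80,
                          1000, channel = "ABP")
  path <- withr::local_tempfile(fileext = ".csv")
  write_segment(seg, path)
  back <- load_segment(path, "ABP", expected_rate_hz = 1000)
  expect_equal(back$samples, seg$samples, tolerance = 1e-6)
  expect_equal(back$sample_rate_hz, seg$sample_rate_hz, tolerance = 1e-6)
})

test_that("malformed waveform files are rejected with descriptive errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  # a 0.5 s gap in an otherwise uniform 100 Hz series
  t <- c(seq(0, 1, by = 0.01), seq(1.51, 2, by = 0.01))
  utils::write.csv(data.frame(time_s = t, value = rnorm(length(t)) + 80),
                   path, row.names = FALSE)
  expect_error(load_segment(path, "ABP"), "non-uniform sampling")
  writeLines("time_s,value", path)
  expect_error(load_segment(path, "ABP"), "empty")
  writeLines(c("time_s,value", "0,80", "0.01,abc"), path)
  expect_error(load_segment(path, "ABP"))
})

test_that("downsampling decimates by integer factors only and keeps tones", {
  n <- 60000
  seg <- waveform_segment(rep(80, n), 1000, channel = "ABP")
  out <- downsample(seg, 100)
  expect_length(out$samples, 6000)
  expect_equal(out$sample_rate_hz, 100)
  # a 1 Hz tone passes the anti-alias filter with amplitude intact
  tone <- waveform_segment(80 + 10 * sin(2 * pi * 1 * (0:(n - 1)) / 1000),
                           1000, channel = "ABP")
  dn <- downsample(tone, 100)
  mid <- dn$samples[1000:5000]
  expect_equal(max(mid) - min(mid), 20, tolerance = 0.01 * 20)
  expect_error(downsample(seg, 300), "evenly")
  # downsampling to the current rate is the identity
  expect_identical(downsample(out, 100)$samples, out$samples)
})

test_that("Savitzky-Golay smoothing preserves low-order polynomials", {
  x <- seq(0, 10, length.out = 500)
  const <- waveform_segment(rep(80, 500), 100, channel = "ABP")
  expect_equal(smooth_segment(const)$samples, const$samples, tolerance = 1e-9)
  quad <- waveform_segment(2 + 3 * x + 0.5 * x^2, 100, channel = "ABP")
  expect_equal(smooth_segment(quad)$samples, quad$samples, tolerance = 1e-9)
  set.seed(5)
  noise <- waveform_segment(rnorm(2000), 100, channel = "ABP")
  expect_lt(var(smooth_segment(noise)$samples), var(noise$samples))
  expect_error(smooth_segment(const, window = 18), "odd")
  expect_error(smooth_segment(const, window = 3, polyorder = 3), "exceed")
})

test_that("preprocessing chain leaves constants unchanged in either order", {
  const <- waveform_segment(rep(80, 60000), 1000, channel = "ABP")
  a <- smooth_segment(downsample(const, 100))
  b <- downsample(smooth_segment(const, 19, 2), 100)
  expect_equal(a$samples, rep(80, 6000), tolerance = 1e-6)
  expect_equal(b$samples, rep(80, 6000), tolerance = 1e-6)
})

test_that("quality control flags range violations, flatlines and PP collapse", {
  clean <- preprocess_segment(fixture_clean_cohort()$boluses[[1]]$abp_pre)
  expect_true(qc_segment(clean)$pass)

  flat <- clean
  flat$samples[1000:1400] <- 80 # 4 s of flat 80 mmHg
  v <- qc_segment(flat)
  expect_false(v$pass)
  expect_true("flatline" %in% v$reasons)

  neg <- clean
  neg$samples[10] <- -5
  v <- qc_segment(neg)
  expect_false(v$pass)
  expect_true("range" %in% v$reasons)

  collapsed <- clean
  collapsed$samples <- 80 + 0.5 * sin(seq_along(collapsed$samples) / 20)
  v <- qc_segment(collapsed)
  expect_false(v$pass)
  expect_true("pulse_pressure" %in% v$reasons)
})
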