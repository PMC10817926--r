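# Shared fixtures, generated once per test run and cached in-process.
# All fixture seeds are fixed constants.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Noise-free simulator parameters (no measurement noise, no baseline drift).
noise_free_params <- function() {
  modifyList(sim_defaults(), list(
    noise_sd_range = c(0, 0), drift_mmhg = 0,
    co_noise_sd = 0, hr_noise_sd = 0
  ))
}

# Fully deterministic-response parameters: no modulation, no noise, flat
# response g(r) = 0 for every pig.
dead_calm_params <- function() {
  modifyList(noise_free_params(), list(
    delta_max = 0, gamma_max = 0, eta_max = 0,
    eps_sd = 0, r_bolus_jitter_sd = 0, phase_shift = 0,
    bolus_dbp_jitter = 0, bolus_hr_jitter = 0, bolus_sv_jitter = 0,
    phase_sv_shift = c(hypovolemic = 0, euvolemic = 0, hypervolemic = 0,
                       epacc = 0),
    g_intercept = 0, g_slope = 0
  ))
}

# Small noise-free cohort with planted fiducials (detection validation).
fixture_clean_cohort <- function() {
  fixture("clean_cohort", function() {
    simulate_cohort(6, 3, 0.5, seed = 11, params = noise_free_params())
  })
}

# Small noisy cohort plus its labeled feature table (fast module tests).
fixture_small_features <- function() {
  fixture("small_features", function() {
    co <- simulate_cohort(10, 4, 0.5, seed = 21)
    suppressWarnings(featurize_cohort(co))
  })
}

# Study-scale cohort: 58 pigs, ~394 boluses (the end-to-end fixture).
fixture_study_cohort <- function() {
  fixture("study_cohort", function() {
    simulate_cohort(58, 6.8, 0.5, seed = 7)
  })
}

fixture_study_features <- function() {
  fixture("study_features", function() {
    suppressWarnings(featurize_cohort(fixture_study_cohort()))
  })
}

# One preprocessed bolus from the clean cohort with its detected beats.
fixture_clean_detection <- function() {
  fixture("clean_detection", function() {
    b <- fixture_clean_cohort()$boluses[[1]]
    seg <- preprocess_segment(b$abp_pre)
    beats <- beat_quality_filter(detect_beats(seg))
    list(bolus = b, seg = seg, beats = beats)
  })
}

# Synthetic labeled feature table with one planted informative feature and
# the rest pure noise (selection and model tests).
make_planted_table <- function(n_per_class = 60, n_noise = 49, effect = 3,
                               seed = 33) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    y <- rep(c("FR", "NR"), each = n_per_class)
    x <- as.data.frame(matrix(rnorm(2 * n_per_class * n_noise),
                              ncol = n_noise))
    names(x) <- paste0("noise", seq_len(n_noise))
    x$signal <- rnorm(2 * n_per_class) + ifelse(y == "FR", effect, 0)
    list(x = x[c("signal", names(x)[seq_len(n_noise)])], y = y)
  })
}

# Brute-force pairwise-ranking AUROC oracle (Mann-Whitney with half credit
# for ties), independent of the package implementation.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == "FR"]
  neg <- scores[labels != "FR"]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
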