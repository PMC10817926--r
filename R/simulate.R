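# Seeded synthetic hemodynamics: multi-pig cohorts of fluid boluses with
# arterial pressure, cardiac output and heart rate channels, planted beat
# fiducials, and a latent preload reserve that drives both respiratory
# stroke-volume modulation and the stroke-volume response to a bolus.
#
# The beat template (see beat_pressure) is a raised-cosine systolic upstroke
# with a symmetric peak shoulder, a Hermite systolic decline into a symmetric
# parabolic dicrotic notch trough, and a windkessel-scale exponential
# diastolic runoff that arrives steeply at the next foot. Its constants were
# fixed by a numerical conditioning study so that all three fiducials
# survive the fixed preprocessing chain (decimation to 100 Hz plus
# Savitzky-Golay 19/2) to within a sample or two.

#' Default simulator parameters
#'
#' All tunable knobs of the synthetic hemodynamics generator in one list.
#' Waveform-shape constants are expressed as fractions of the beat period so
#' the template scales with heart rate.
#'
#' @return Named list of simulator parameters.
#' @export
sim_defaults <- function() {
  list(
    duration_s = 60,          # window length pre and post bolus
    abp_rate_hz = 1000,       # acquisition rate for ABP
    aux_rate_hz = 100,        # CO / HR channel rate
    # beat template (fractions of beat period T unless noted)
    rise_frac = 0.25,         # systolic rise time / T
    tau_soft_frac = 0.075,    # decay softening constant / T
    notch_frac = 0.40,        # notch center as a fraction of the span between
                              # the systolic shoulder and the late-diastolic
                              # reserve (see notch_center)
    shoulder_frac = 0.35,     # post-peak cosine continuation / rise time
    notch_height_frac = 0.45, # notch trough height above the foot / A
    # the notch trough is a symmetric parabola; its half-width is fixed in
    # seconds (the smoothing kernel span does not depend on heart rate) but
    # capped as a fraction of the period so the template fits fast beats
    notch_width_s = 0.105, notch_width_cap = 0.14,
    notch_edge_frac = 0.15,   # notch parabola edge height above trough / A
    decay_asym_frac = 2.0,    # decay asymptote depth below baseline / A;
                              # deep asymptote + long tau = near-linear
                              # diastolic runoff, steep at the foot
    # respiratory modulation and latent-signal mixing
    delta_max = 0.15,         # max peak-to-trough relative SV modulation
    gamma_max = 0.45,         # max relative decay-constant modulation
    eta_max = 0.35,           # max relative notch-timing modulation
    # between-bolus baseline drift (a pig's hemodynamic state evolves over
    # the experiment: hemorrhage, transfusion, vasopressor titration), so
    # absolute pressure levels do not act as a static pig fingerprint
    bolus_dbp_jitter = 0.07,
    bolus_hr_jitter = 0.04,
    bolus_sv_jitter = 0.08,
    phase_sv_shift = c(hypovolemic = -0.10, euvolemic = 0,
                       hypervolemic = 0.08, epacc = 0),
    signal_weight = 0.35,     # weight of preload reserve in each modulation
                              # channel (the 0.65 complement is independent
                              # noise, keeping any single channel - e.g.
                              # PPV - a mid-range discriminator on its own)
    post_modulation_factor = 0.7, # modulation damping after a bolus
    # bolus response: true delta SV% = g(r) + eps, g linear -5% .. +35%
    g_intercept = -5, g_slope = 40,
    eps_sd = 3,               # Gaussian noise on the SV response (%)
    r_bolus_jitter_sd = 0.08, # per-bolus jitter of preload reserve
    phase_shift = 0.06,       # preload shift: +hypovolemic, -hypervolemic
    # measurement noise
    noise_sd_range = c(0.6, 1.4), # per-pig ABP white noise sd (mmHg)
    drift_mmhg = 1.5,         # slow baseline drift amplitude (mmHg)
    drift_freq_hz = 0.03,
    co_noise_sd = 0.15,       # L/min
    hr_noise_sd = 1.0,        # bpm
    # per-pig archetype ranges keyed by injury model
    archetypes = list(
      HEM   = list(sv_ml = c(25, 35), hr_bpm = c(85, 100), tau_frac = c(1.00, 1.20),
                   compliance = c(0.80, 1.10), dbp_mmhg = c(50, 65)),
      IRI   = list(sv_ml = c(30, 45), hr_bpm = c(75, 92),  tau_frac = c(1.05, 1.30),
                   compliance = c(0.90, 1.25), dbp_mmhg = c(55, 70)),
      EPACC = list(sv_ml = c(35, 50), hr_bpm = c(68, 85),  tau_frac = c(1.15, 1.45),
                   compliance = c(0.85, 1.15), dbp_mmhg = c(60, 75))
    ),
    injury_mix = c(HEM = 13, IRI = 13, EPACC = 32) / 58,
    resp_rate_range = c(12, 20) # breaths/min
  )
}

# Template geometry for one beat period: rise time, post-peak shoulder
# length, notch parabola half-width (seconds, capped by a period fraction)
# and the decay softening constant.
template_geometry <- function(T, p) {
  tr <- p$rise_frac * T
  list(tr = tr, wb = p$shoulder_frac * tr,
       Wn = min(p$notch_width_s, p$notch_width_cap * T),
       c0 = p$tau_soft_frac * T)
}

# Piecewise beat pressure at elapsed time s within a beat of period T.
# s and the per-beat parameters Ps (start/foot pressure), Pe (end pressure =
# next beat's foot), A, tau, nf are vectors of equal length (per-sample
# values). Five phases, each shaped so its fiducial survives the zero-phase
# preprocessing chain:
#   1. raised-cosine systolic upstroke, foot -> peak (peak = Ps + A);
#   2. brief symmetric continuation of the upstroke cosine past the peak -
#      a locally symmetric, high-curvature maximum keeps its position under
#      any zero-phase smoother;
#   3. cubic-Hermite systolic decline to the notch trough edge;
#   4. parabolic notch trough, exactly symmetric over +/- Wn around tn;
#   5. exponential diastolic runoff with time constant tau (of windkessel
#      order, longer than the beat) toward an asymptote decay_asym_frac * A
#      below the baseline: within one diastole the decay is near-linear and
#      arrives at the next foot still falling steeply (~2 A / T), giving the
#      foot a sharp corner against the flat start of the next upstroke.
beat_pressure <- function(s, T, Pd, Ps, Pe, A, tau, nf, p) {
  g <- template_geometry(T, p)
  tr <- g$tr; wb <- g$wb; Wn <- g$Wn; c0 <- g$c0
  tn <- notch_center(T, nf, p)
  fN <- p$notch_edge_frac * A
  P_notch <- Ps + p$notch_height_frac * A
  # asymptote anchored to the segment baseline (not the per-beat foot), so
  # the foot-pressure recursion across beats is a contraction
  casym <- Pd - p$decay_asym_frac * A
  out <- numeric(length(s))

  up <- s < tr + wb # upstroke plus symmetric post-peak shoulder
  out[up] <- Ps[up] + A[up] * 0.5 * (1 - cos(pi * s[up] / tr))

  sys <- !up & s < tn - Wn
  p1 <- Ps[sys] + A[sys] * 0.5 * (1 - cos(pi * (1 + wb / tr)))
  m1 <- A[sys] * pi / (2 * tr) * sin(pi * (1 + wb / tr)) # negative: downslope
  L <- tn[sys] - Wn - tr - wb
  u <- (s[sys] - tr - wb) / L
  out[sys] <- p1 * (2 * u^3 - 3 * u^2 + 1) + m1 * L * (u^3 - 2 * u^2 + u) +
    (P_notch[sys] + fN[sys]) * (-2 * u^3 + 3 * u^2) +
    (-2 * fN[sys] / Wn) * L * (u^3 - u^2)

  trough <- !up & abs(s - tn) <= Wn # symmetric notch trough
  out[trough] <- P_notch[trough] + fN[trough] * ((s[trough] - tn[trough]) / Wn)^2

  dia <- s > tn + Wn
  v <- s[dia] - tn[dia] - Wn
  out[dia] <- casym[dia] + (P_notch[dia] + fN[dia] - casym[dia]) *
    exp(-v^2 / (tau[dia] * (v + c0)))
  out
}

# Next beat's foot pressure: the diastolic decay evaluated at the end of the
# beat. The per-beat recursion Ps[k+1] = beat_end_pressure(..., Ps[k], ...)
# is a contraction (the asymptote is anchored to the segment baseline), so
# foot pressures stay near the baseline while breathing-driven amplitude
# modulation leaves a realistic respiratory wander on them.
beat_end_pressure <- function(T, Pd, Ps, A, tau, nf, p) {
  g <- template_geometry(T, p)
  tn <- notch_center(T, nf, p)
  casym <- Pd - p$decay_asym_frac * A
  amp <- Ps + (p$notch_height_frac + p$notch_edge_frac) * A - casym
  v_end <- T - tn - g$Wn
  casym + amp * exp(-v_end^2 / (tau * (v_end + g$c0)))
}

# Synthesize one noise-free ABP segment plus its per-beat ground truth.
# The window opens mid-beat (phase_frac of a period before the first full
# foot), as a real recording would, so no complete beat's foot sits on a
# segment boundary. Returns list(samples, fiducials = data.frame(foot_time_s,
# peak_time_s, notch_time_s), beat = per-beat parameter table).
synth_abp_segment <- function(duration_s, fs, hr_bpm, dbp, amp, tau_frac,
                              delta, gamma, eta, f_resp_hz, phases, p,
                              phase_frac = 0.35) {
  T <- 60 / hr_bpm
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  first_foot <- (phase_frac - 1) * T # the opening (partial) beat's foot
  n_beats <- ceiling((duration_s - first_foot) / T) + 1L
  foot_t <- first_foot + (seq_len(n_beats) - 1) * T
  # per-beat modulated parameters (evaluated at the beat foot)
  A_i <- amp * (1 + 0.5 * delta * sin(2 * pi * f_resp_hz * foot_t + phases[1]))
  tau_i <- tau_frac * T * (1 + 0.5 * gamma * sin(2 * pi * f_resp_hz * foot_t + phases[2]))
  nf_i <- p$notch_frac * (1 + 0.5 * eta * sin(2 * pi * f_resp_hz * foot_t + phases[3]))
  beat_of <- pmin(pmax(floor((t - first_foot) / T) + 1L, 1L), n_beats)
  s <- t - foot_t[beat_of]
  # per-beat foot pressures: each beat starts where the previous decay
  # landed (warm-started at the identical-beat fixed point)
  Ps_i <- numeric(n_beats)
  ps <- dbp
  for (it in 1:40) ps <- beat_end_pressure(T, dbp, ps, A_i[1], tau_i[1], nf_i[1], p)
  Ps_i[1] <- ps
  if (n_beats > 1) for (k in 2:n_beats)
    Ps_i[k] <- beat_end_pressure(T, dbp, Ps_i[k - 1], A_i[k - 1], tau_i[k - 1],
                                 nf_i[k - 1], p)
  Pe_i <- c(Ps_i[-1], beat_end_pressure(T, dbp, Ps_i[n_beats], A_i[n_beats],
                                        tau_i[n_beats], nf_i[n_beats], p))
  x <- beat_pressure(s, T, dbp, Ps_i[beat_of], Pe_i[beat_of], A_i[beat_of],
                     tau_i[beat_of], nf_i[beat_of], p)
  # ground-truth fiducials for complete beats strictly inside the window
  keep <- which(foot_t >= 0 & foot_t + T <= duration_s - 1 / fs + 1e-9)
  fid <- planted_fiducials(T, dbp, Ps_i[keep], A_i[keep], tau_i[keep],
                           nf_i[keep], foot_t[keep], p)
  list(samples = x, fiducials = fid,
       beat = data.frame(foot_time_s = foot_t[keep], foot_p = Ps_i[keep],
                         amp = A_i[keep], tau = tau_i[keep],
                         notch_frac = nf_i[keep]))
}

# Notch trough center within the beat, anchored inside the span remaining
# after the peak cap (tr + Wp), the trough half-width Wn on both sides, and
# a late-diastolic reserve (foot parabola + 0.05 T), so the geometry stays
# valid at every heart rate and notch-timing modulation depth.
notch_center <- function(T, nf, p) {
  g <- template_geometry(T, p)
  shoulder <- g$tr + g$wb
  shoulder + g$Wn + nf * (T - shoulder - 2 * g$Wn - 0.05 * T)
}

# Locate the template's true peak and notch per beat on a 1 ms grid
# (vectorized across beats; grids have equal length per beat).
planted_fiducials <- function(T, Pd, Ps_i, A_i, tau_i, nf_i, foot_t, p,
                              grid_dt = 0.001) {
  nb <- length(foot_t)
  tr <- template_geometry(T, p)$tr
  nw <- 0.06 * T # truth search half-window around the nominal notch center
  # peak grid: [tr - 0.03, tr + 0.35 * (T - tr)]
  pk_grid <- seq(max(tr - 0.03, 0), tr + 0.35 * (T - tr), by = grid_dt)
  gp <- length(pk_grid)
  sp <- rep(pk_grid, times = nb)
  idx <- rep(seq_len(nb), each = gp)
  yp <- beat_pressure(sp, T, Pd, Ps_i[idx], Ps_i[idx], A_i[idx], tau_i[idx],
                      nf_i[idx], p)
  pk_off <- pk_grid[max.col(matrix(yp, nrow = nb, byrow = TRUE), ties.method = "first")]
  # notch grid: tn +/- nw per beat (beat-specific center)
  ng_off <- seq(-nw, nw, by = grid_dt)
  gn <- length(ng_off)
  tn_i <- notch_center(T, nf_i, p)
  sn <- rep(tn_i, each = gn) + rep(ng_off, times = nb)
  idx2 <- rep(seq_len(nb), each = gn)
  yn <- beat_pressure(sn, T, Pd, Ps_i[idx2], Ps_i[idx2], A_i[idx2],
                      tau_i[idx2], nf_i[idx2], p)
  nmin <- max.col(matrix(-yn, nrow = nb, byrow = TRUE), ties.method = "first")
  notch_off <- tn_i + ng_off[nmin]
  data.frame(foot_time_s = foot_t, peak_time_s = foot_t + pk_off,
             notch_time_s = foot_t + notch_off)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a multi-pig cohort of fluid boluses
#'
#' Generates pig profiles across three shock injury models (HEM, IRI, EPACC)
#' and, for each pig, a set of fluid boluses with 60 s pre- and post-bolus
#' arterial pressure (1000 Hz), cardiac output and heart rate channels. A
#' latent per-bolus preload reserve drives (imperfectly, through independent
#' mixing noise) the respiratory pulse-pressure modulation, the beat-to-beat
#' variability of the diastolic decay constant and of the notch timing, and
#' the true stroke-volume response to the bolus. Pulse pressure variation is
#' therefore predictive of fluid responsiveness but not sufficient for it,
#' which is the regime in which a multivariate waveform classifier can add
#' discrimination.
#'
#' @param n_pigs Number of pigs (>= 2).
#' @param boluses_per_pig Expected boluses per pig (Poisson mean, min 2 drawn).
#' @param fr_prevalence_target Target marginal prevalence of fluid-responsive
#'   boluses, in (0, 1).
#' @param seed Master seed; per-pig and per-bolus substreams are derived by
#'   counter-based mixing so earlier pigs are unaffected by cohort growth.
#' @param params Simulator parameters, see [sim_defaults()]. Pass overrides
#'   via `modifyList(sim_defaults(), list(...))`.
#' @return A list of class `sim_cohort` with elements `profiles` (data.frame,
#'   one row per pig) and `boluses` (list of `sim_bolus` objects, each holding
#'   the six segments, ground-truth fiducials and the true delta-SV%).
#' @export
simulate_cohort <- function(n_pigs, boluses_per_pig = 6.8,
                            fr_prevalence_target = 0.5, seed = 1,
                            params = sim_defaults()) {
  if (!is.numeric(n_pigs) || n_pigs < 2 || n_pigs != round(n_pigs))
    stopf("n_pigs must be an integer >= 2")
  if (!is.numeric(boluses_per_pig) || boluses_per_pig <= 0)
    stopf("boluses_per_pig must be positive")
  if (!is.numeric(fr_prevalence_target) || fr_prevalence_target <= 0 ||
      fr_prevalence_target >= 1)
    stopf("fr_prevalence_target must lie in (0, 1)")
  p <- params
  models <- allocate_injury_models(n_pigs, p$injury_mix, seed)
  profiles <- do.call(rbind, lapply(seq_len(n_pigs), function(i) {
    draw_pig_profile(i, models[i], fr_prevalence_target, seed, p)
  }))
  boluses <- list()
  for (i in seq_len(n_pigs)) {
    prof <- profiles[i, ]
    nb <- with_seed(derive_seed(seed, i, 10000L),
                    max(2L, stats::rpois(1, boluses_per_pig)))
    phases <- phase_labels(prof$injury_model, nb)
    for (j in seq_len(nb)) {
      boluses[[length(boluses) + 1L]] <-
        simulate_bolus(prof, j, phases[j], seed, p)
    }
  }
  structure(list(profiles = profiles, boluses = boluses,
                 seed = seed, fr_prevalence_target = fr_prevalence_target),
            class = "sim_cohort")
}

# Injury model per pig: an independent categorical draw from the study mix
# on the pig's own substream, so growing the cohort never reassigns the
# model (or any downstream draw) of an existing pig.
allocate_injury_models <- function(n_pigs, mix, seed) {
  vapply(seq_len(n_pigs), function(i) {
    with_seed(derive_seed(seed, i, 20000L),
              sample(names(mix), 1, prob = mix))
  }, character(1))
}

draw_pig_profile <- function(i, model, target, seed, p) {
  with_seed(derive_seed(seed, i, 0L), {
    a <- p$archetypes[[model]]
    runif1 <- function(r) stats::runif(1, r[1], r[2])
    hr <- round(runif1(a$hr_bpm)) # whole bpm: a 60 s window then holds
                                  # exactly hr - 1 complete beats
    sv <- runif1(a$sv_ml)
    compliance <- runif1(a$compliance)
    tau_frac <- runif1(a$tau_frac)
    T <- 60 / hr
    # preload reserve: mixture giving marginal P(r >= 0.5) ~= target
    r <- if (stats::runif(1) < target) stats::runif(1, 0.5, 1) else stats::runif(1, 0, 0.5)
    data.frame(
      pig_id = sprintf("pig%03d", i), injury_model = model,
      baseline_sv_ml = sv, baseline_hr_bpm = hr,
      vascular_compliance = compliance,
      vascular_resistance = tau_frac * T / compliance,
      preload_reserve = r,
      resp_rate_bpm = runif1(p$resp_rate_range),
      dbp_mmhg = runif1(a$dbp_mmhg),
      noise_sd_mmhg = runif1(p$noise_sd_range),
      tau_frac = tau_frac,
      stringsAsFactors = FALSE
    )
  })
}

# HEM / IRI pigs cycle hypovolemic -> euvolemic -> hypervolemic phases; EPACC
# boluses are all drawn under the occlusion protocol phase.
phase_labels <- function(model, nb) {
  if (model == "EPACC") return(rep("epacc", nb))
  rep(c("hypovolemic", "euvolemic", "hypervolemic"), length.out = nb)
}

simulate_bolus <- function(prof, j, phase, seed, p) {
  i <- as.integer(sub("pig", "", prof$pig_id))
  with_seed(derive_seed(seed, i, j), {
    shift <- switch(phase, hypovolemic = p$phase_shift,
                    hypervolemic = -p$phase_shift, 0)
    r_b <- clamp(prof$preload_reserve + shift +
                   stats::rnorm(1, 0, p$r_bolus_jitter_sd), 0.02, 0.98)
    true_delta <- p$g_intercept + p$g_slope * r_b + stats::rnorm(1, 0, p$eps_sd)
    mix <- function(r) clamp(p$signal_weight * r +
                               (1 - p$signal_weight) * stats::runif(1), 0, 1)
    delta_b <- p$delta_max * mix(r_b)
    gamma_b <- p$gamma_max * mix(r_b)
    eta_b <- p$eta_max * mix(r_b)
    f_resp <- prof$resp_rate_bpm / 60
    # the pig's hemodynamic state drifts between boluses (blood loss,
    # transfusion, vasopressor titration): per-bolus baselines
    sv_b <- prof$baseline_sv_ml *
      (1 + (p$phase_sv_shift[[phase]] %||% 0) +
         stats::rnorm(1, 0, p$bolus_sv_jitter))
    hr_b <- round(prof$baseline_hr_bpm * (1 + stats::rnorm(1, 0, p$bolus_hr_jitter)))
    dbp_b <- prof$dbp_mmhg * (1 + stats::rnorm(1, 0, p$bolus_dbp_jitter))
    amp <- sv_b / prof$vascular_compliance
    ph_pre <- stats::runif(3, 0, 2 * pi)
    ph_post <- stats::runif(3, 0, 2 * pi)
    pre <- synth_abp_segment(p$duration_s, p$abp_rate_hz, hr_b,
                             dbp_b, amp, prof$tau_frac,
                             delta_b, gamma_b, eta_b, f_resp, ph_pre, p)
    amp_post <- amp * (1 + true_delta / 100)
    mod_post <- p$post_modulation_factor
    post <- synth_abp_segment(p$duration_s, p$abp_rate_hz, hr_b,
                              dbp_b, amp_post, prof$tau_frac,
                              delta_b * mod_post, gamma_b * mod_post,
                              eta_b * mod_post, f_resp, ph_post, p)
    n_abp <- length(pre$samples)
    noisy <- function(x) {
      x + stats::rnorm(length(x), 0, prof$noise_sd_mmhg) +
        p$drift_mmhg *
          sin(2 * pi * p$drift_freq_hz * (seq_along(x) - 1) / p$abp_rate_hz +
                stats::runif(1, 0, 2 * pi))
    }
    abp_pre <- waveform_segment(clamp(noisy(pre$samples), 1e-3, 299.999),
                                p$abp_rate_hz, 0, "ABP")
    abp_post <- waveform_segment(clamp(noisy(post$samples), 1e-3, 299.999),
                                 p$abp_rate_hz, 0, "ABP")
    co_hr <- function(sv_ml, delta_mod, phase1) {
      t <- (seq_len(p$duration_s * p$aux_rate_hz) - 1) / p$aux_rate_hz
      sv_t <- sv_ml * (1 + 0.5 * delta_mod * sin(2 * pi * f_resp * t + phase1))
      co <- hr_b * sv_t / 1000 + stats::rnorm(length(t), 0, p$co_noise_sd)
      hr <- hr_b + stats::rnorm(length(t), 0, p$hr_noise_sd)
      list(co = waveform_segment(pmax(co, 0.05), p$aux_rate_hz, 0, "CO"),
           hr = waveform_segment(pmax(hr, 5), p$aux_rate_hz, 0, "HR"))
    }
    pre_ch <- co_hr(sv_b, delta_b, ph_pre[1])
    post_ch <- co_hr(sv_b * (1 + true_delta / 100),
                     delta_b * mod_post, ph_post[1])
    structure(list(
      bolus_id = sprintf("%s_b%02d", prof$pig_id, j),
      pig_id = prof$pig_id, injury_model = prof$injury_model, phase = phase,
      true_delta_sv_pct = true_delta, preload_reserve_bolus = r_b,
      true_fiducials_pre = pre$fiducials,
      abp_pre = abp_pre, abp_post = abp_post,
      co_pre = pre_ch$co, co_post = post_ch$co,
      hr_pre = pre_ch$hr, hr_post = post_ch$hr
    ), class = "sim_bolus")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d pigs, %d boluses (seed %d)\n",
              nrow(x$profiles), length(x$boluses), x$seed))
  print(table(x$profiles$injury_model))
  invisible(x)
}

#' Write a simulated cohort to a directory of delimited-text files
#'
#' Emits `manifest.csv` (one row per bolus: ids, injury model, phase, segment
#' file names and rates, and the true delta-SV% for test use only),
#' `profiles.csv`, and one two-column waveform file per segment, all readable
#' back with [load_segment()] / [read_cohort()].
#'
#' @param cohort A `sim_cohort`.
#' @param directory_path Destination directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, directory_path) {
  ok <- dir.exists(directory_path) ||
    dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stopf("cannot create directory: %s", directory_path)
  seg_names <- c("abp_pre", "abp_post", "co_pre", "co_post", "hr_pre", "hr_post")
  rows <- lapply(cohort$boluses, function(b) {
    files <- sprintf("%s_%s.csv", b$bolus_id, seg_names)
    for (k in seq_along(seg_names)) {
      write_segment(b[[seg_names[k]]], file.path(directory_path, files[k]))
    }
    rates <- vapply(seg_names, function(s) b[[s]]$sample_rate_hz, numeric(1))
    df <- data.frame(pig_id = b$pig_id, bolus_id = b$bolus_id,
                     injury_model = b$injury_model, phase = b$phase,
                     true_delta_sv_pct = b$true_delta_sv_pct,
                     stringsAsFactors = FALSE)
    df[paste0("file_", seg_names)] <- as.list(files)
    df[paste0("rate_", seg_names)] <- as.list(rates)
    df
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pig_id = character(), bolus_id = character(),
               injury_model = character(), phase = character(),
               true_delta_sv_pct = numeric())
  mpath <- file.path(directory_path, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  if (!is.null(cohort$profiles))
    utils::write.csv(cohort$profiles,
                     file.path(directory_path, "profiles.csv"), row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Ground-truth fiducials are not serialized; the returned boluses carry the
#' six segments plus manifest metadata.
#'
#' @param directory_path Cohort directory containing `manifest.csv`.
#' @return A `sim_cohort`-shaped list (profiles may be `NULL` if absent).
#' @export
read_cohort <- function(directory_path) {
  mpath <- file.path(directory_path, "manifest.csv")
  if (!file.exists(mpath)) stopf("no manifest.csv under %s", directory_path)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  seg_names <- c("abp_pre", "abp_post", "co_pre", "co_post", "hr_pre", "hr_post")
  chan <- c("ABP", "ABP", "CO", "CO", "HR", "HR")
  boluses <- lapply(seq_len(nrow(manifest)), function(r) {
    b <- as.list(manifest[r, c("bolus_id", "pig_id", "injury_model", "phase",
                               "true_delta_sv_pct")])
    for (k in seq_along(seg_names)) {
      b[[seg_names[k]]] <- load_segment(
        file.path(directory_path, manifest[r, paste0("file_", seg_names[k])]),
        channel = chan[k],
        expected_rate_hz = manifest[r, paste0("rate_", seg_names[k])])
    }
    structure(b, class = "sim_bolus")
  })
  ppath <- file.path(directory_path, "profiles.csv")
  profiles <- if (file.exists(ppath)) utils::read.csv(ppath, stringsAsFactors = FALSE)
  structure(list(profiles = profiles, boluses = boluses), class = "sim_cohort")
}
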