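#' Configuration for the synthetic-recording generator
#'
#' Defines the acquisition conditions emulated by [generate_recording()]:
#' a five-stage intraoperative protocol with a recording gap between stages
#' 3 and 4 (cardiopulmonary bypass, during which pulsatile analysis is
#' impossible), electrocautery recording pauses inside stages, two
#' tetrapolar impedance channels (forehead and arm) hardware-split into
#' baseline (Ohm) and pulsatile (mOhm) components, one ECG channel and one
#' laser-Doppler-flowmetry (LDF) channel.
#'
#' Stage durations default to one second per minute of the published median
#' stage durations of the emulated protocol, which keeps a full recording
#' near three minutes while preserving the relative stage weighting. Stage
#' effects are multiplicative modifiers applied to the pulse amplitude
#' (`dz`), the LDF cardiac-band amplitude (`mc_amp`) and the LDF mean
#' (`mc_mean`); their defaults follow the qualitative intraoperative pattern
#' of a rise in LDF pulsatility toward mid-surgery and a marked fall of
#' impedance pulse amplitude after bypass.
#'
#' @param fs Sampling rate, Hz.
#' @param duration_per_stage Numeric length-5, seconds per stage.
#' @param hr_by_stage Mean heart rate per stage, bpm, each in (20, 250).
#' @param hr_jitter Fractional R-R variability (coefficient of variation).
#' @param z_base_forehead,z_base_arm Baseline impedance, Ohm.
#' @param dz_forehead,dz_arm Pulse impedance amplitude, mOhm.
#' @param pulse_shape List with elements `rise` (pulse foot to systolic peak,
#'   s), `decay` (log-width of the lognormal systolic wave, dimensionless),
#'   `dicrotic_amp` (relative amplitude of the dicrotic bump),
#'   `dicrotic_delay` (foot to dicrotic bump, s), `dicrotic_width` (s).
#' @param rtt_forehead,rtt_arm R peak to pulse foot delay, s.
#' @param ldf_mc_mean Mean microcirculation index, perfusion units (0-99).
#' @param ldf_cardiac_amp Amplitude of the cardiac LDF oscillation,
#'   perfusion units.
#' @param noise_snr_db Per-channel additive white noise level, dB relative
#'   to the clean signal RMS; `Inf` disables noise.
#' @param cautery_gaps List of electrocautery pauses, each
#'   `c(stage, start_s, length_s)` with `start_s` relative to stage onset.
#' @param cpb_gap_s Length of the unrecorded cardiopulmonary-bypass interval
#'   between stages 3 and 4, s.
#' @param stage_effects List with numeric length-5 elements `dz`, `mc_amp`,
#'   `mc_mean`: multiplicative per-stage modifiers.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   recordings.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(fs = 500,
                         duration_per_stage = c(25, 60, 9, 81, 21),
                         hr_by_stage = c(72, 68, 62, 80, 76),
                         hr_jitter = 0.03,
                         z_base_forehead = 110, z_base_arm = 45,
                         dz_forehead = 100, dz_arm = 160,
                         pulse_shape = list(rise = 0.13, decay = 0.45,
                                            dicrotic_amp = 0.20,
                                            dicrotic_delay = 0.33,
                                            dicrotic_width = 0.045),
                         rtt_forehead = 0.15, rtt_arm = 0.25,
                         ldf_mc_mean = 12, ldf_cardiac_amp = 1.2,
                         noise_snr_db = 25,
                         cautery_gaps = list(c(2, 20, 5), c(4, 30, 5)),
                         cpb_gap_s = 60,
                         stage_effects = list(
                           dz      = c(1.00, 0.95, 1.00, 0.65, 0.35),
                           mc_amp  = c(1.00, 2.00, 1.40, 1.30, 0.95),
                           mc_mean = c(1.00, 1.15, 1.10, 0.90, 0.85)),
                         seed = 1L) {
  cfg <- list(fs = fs, duration_per_stage = duration_per_stage,
              hr_by_stage = hr_by_stage, hr_jitter = hr_jitter,
              z_base_forehead = z_base_forehead, z_base_arm = z_base_arm,
              dz_forehead = dz_forehead, dz_arm = dz_arm,
              pulse_shape = pulse_shape,
              rtt_forehead = rtt_forehead, rtt_arm = rtt_arm,
              ldf_mc_mean = ldf_mc_mean, ldf_cardiac_amp = ldf_cardiac_amp,
              noise_snr_db = noise_snr_db, cautery_gaps = cautery_gaps,
              cpb_gap_s = cpb_gap_s, stage_effects = stage_effects,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  chk <- function(cond, field)
    if (!cond) abort_rheo(sprintf("invalid synth_config field: %s", field),
                          "config_error")
  chk(is.numeric(cfg$fs) && cfg$fs > 0, "fs")
  chk(length(cfg$duration_per_stage) == 5L && all(cfg$duration_per_stage > 0),
      "duration_per_stage")
  chk(length(cfg$hr_by_stage) == 5L &&
        all(cfg$hr_by_stage > 20 & cfg$hr_by_stage < 250), "hr_by_stage")
  chk(cfg$hr_jitter >= 0, "hr_jitter")
  chk(cfg$z_base_forehead > 0, "z_base_forehead")
  chk(cfg$z_base_arm > 0, "z_base_arm")
  chk(cfg$dz_forehead >= 0, "dz_forehead")
  chk(cfg$dz_arm >= 0, "dz_arm")
  ps <- cfg$pulse_shape
  chk(all(c("rise", "decay", "dicrotic_amp", "dicrotic_delay",
            "dicrotic_width") %in% names(ps)) &&
        ps$rise > 0 && ps$decay > 0 && ps$dicrotic_amp >= 0 &&
        ps$dicrotic_delay > 0 && ps$dicrotic_width > 0, "pulse_shape")
  chk(cfg$rtt_forehead >= 0, "rtt_forehead")
  chk(cfg$rtt_arm >= 0, "rtt_arm")
  chk(cfg$ldf_mc_mean >= 0 && cfg$ldf_mc_mean <= 99, "ldf_mc_mean")
  chk(cfg$ldf_cardiac_amp >= 0, "ldf_cardiac_amp")
  chk(cfg$cpb_gap_s >= 0, "cpb_gap_s")
  for (g in cfg$cautery_gaps)
    chk(length(g) == 3L && g[1] %in% 1:5 && g[2] >= 0 && g[3] > 0,
        "cautery_gaps")
  se <- cfg$stage_effects
  chk(all(c("dz", "mc_amp", "mc_mean") %in% names(se)) &&
        all(vapply(se[c("dz", "mc_amp", "mc_mean")],
                   function(v) length(v) == 5L && all(v >= 0), logical(1))),
      "stage_effects")
  invisible(TRUE)
}

# Pulse kernel on a cycle of length L seconds: lognormal systolic wave
# (peak 1 at tau = rise) plus a Gaussian dicrotic bump, smoothly tapered to
# zero over the last 15% of the cycle so that consecutive pulses meet at the
# foot and the per-cycle peak-to-trough equals the systolic amplitude.
pulse_kernel <- function(tau, L, shape) {
  k <- numeric(length(tau))
  pos <- tau > 0
  k[pos] <- exp(-(log(tau[pos] / shape$rise))^2 / (2 * shape$decay^2))
  k <- k + shape$dicrotic_amp *
    exp(-0.5 * ((tau - shape$dicrotic_delay) / shape$dicrotic_width)^2)
  tail_start <- 0.85 * L
  idx <- tau > tail_start
  k[idx] <- k[idx] * 0.5 * (1 + cos(pi * (tau[idx] - tail_start) /
                                      (L - tail_start)))
  k[tau >= L | tau < 0] <- 0
  k
}

# One synthetic PQRST complex centred on the R peak (tau = 0), in mV.
ecg_complex <- function(tau) {
  0.12 * exp(-0.5 * ((tau + 0.20) / 0.025)^2) -   # P
  0.10 * exp(-0.5 * ((tau + 0.026) / 0.010)^2) +  # Q
  1.00 * exp(-0.5 * (tau / 0.011)^2) -            # R
  0.18 * exp(-0.5 * ((tau - 0.028) / 0.012)^2) +  # S
  0.30 * exp(-0.5 * ((tau - 0.30) / 0.060)^2)     # T
}

# Ground-truth fiducials read off a clean per-cycle pulsatile window
# (window starts at the R peak). Direct argmax/zero-crossing/tangent
# definitions applied to the noise-free waveform; the reported RTT truth is
# the intersecting-tangent foot, i.e. the operational fiducial (a smooth
# pulse onset has no unique "first instant", so the configured kernel onset
# is not itself a measurable time).
truth_fiducials <- function(pulse, fs) {
  d <- central_diff(pulse, 1 / fs)
  i_ad <- which.max(d)
  t_ad <- (i_ad - 1L) / fs
  foot <- if (d[i_ad] > 0)
    t_ad - (pulse[i_ad] - min(pulse[seq_len(i_ad)])) / d[i_ad] else NA_real_
  before <- which(d[seq_len(i_ad)] <= 0.01 * d[i_ad])
  b <- if (length(before)) max(before) else NA_integer_
  xs <- d[i_ad:length(d)]
  x <- i_ad + which.min(xs) - 1L
  lvet <- if (is.na(b) || x >= length(d)) NA_real_ else (x - b) / fs
  list(t_ad = t_ad, lvet = lvet, foot = foot)
}

#' Generate one synthetic subject recording
#'
#' Builds the full synchronized channel set at `fs`: a PQRST ECG train with
#' jittered R-R intervals, per-channel pulsatile impedance as a train of
#' pulse kernels delayed by the channel's pulse-wave transit time (stored in
#' the positive-up rheogram convention: systolic inflow is an upward
#' deflection), slowly drifting baseline impedance, and an LDF channel whose
#' cardiac component is phase-locked to the cycle. The cardiopulmonary-bypass
#' interval between stages 3 and 4 and any configured electrocautery pauses
#' are masked on every channel, and no ground-truth cycles are reported
#' inside them.
#'
#' The embedded ground truth holds the visible R-peak times, per-cycle true
#' pulse amplitude, baseline impedance, transit time, time-to-peak of the
#' differential rheogram and (arm) ejection interval, plus per-stage true
#' LDF mean and cardiac-band amplitude — the oracle for parameter-recovery
#' tests.
#'
#' @param config A [synth_config()].
#' @return A [subject_recording] with `ground_truth`.
#' @export
generate_recording <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  validate_synth_config(config)
  set.seed(config$seed)
  fs <- config$fs
  dur <- config$duration_per_stage

  # stage timeline: stages 1-3 contiguous, CPB gap, stages 4-5 contiguous
  stage_start <- numeric(5)
  stage_start[1] <- 0
  for (s in 2:5) stage_start[s] <- stage_start[s - 1] + dur[s - 1] +
      if (s == 4) config$cpb_gap_s else 0
  stage_end <- stage_start + dur
  total_s <- stage_end[5]
  n <- round(total_s * fs)
  t <- (0:(n - 1)) / fs
  stages <- stage_annotation(1:5, stage_start, stage_end)

  stage_of_time <- function(tt) {
    s <- rep(NA_integer_, length(tt))
    for (k in 1:5) s[tt >= stage_start[k] & tt < stage_end[k]] <- k
    s
  }

  # masked intervals: CPB gap plus cautery pauses (samples, 0-based half-open)
  gaps <- list(c(stage_end[3], stage_start[4]))
  for (g in config$cautery_gaps) {
    a <- stage_start[g[1]] + g[2]
    b <- min(a + g[3], stage_end[g[1]])
    if (b > a) gaps[[length(gaps) + 1L]] <- c(a, b)
  }
  gaps <- gaps[order(vapply(gaps, `[`, numeric(1), 1))]
  mask <- lapply(gaps, function(g) c(round(g[1] * fs), round(g[2] * fs)))
  in_gap <- function(tt, margin = 0) {
    bad <- logical(length(tt))
    for (g in gaps) bad <- bad | (tt > g[1] - margin & tt < g[2] + margin)
    bad
  }

  # R-peak times over the two recorded blocks (heart beats through cautery
  # pauses; those beats are simply not recorded). R-R variability is
  # band-limited: a very-low-frequency modulation plus a small white term,
  # with total coefficient of variation hr_jitter. White per-beat jitter
  # would give the R-R series a flat spectrum; in anesthetized, mechanically
  # ventilated patients residual heart-rate variability is concentrated in
  # the very-low-frequency band (vagal respiratory arrhythmia and the
  # baroreflex low-frequency component are suppressed).
  phi_lf <- stats::runif(1, 0, 2 * pi)
  f_lf <- 0.035  # Hz, very-low-frequency heart-rate modulation
  r_all <- numeric(0)
  for (block in list(c(0, stage_end[3]), c(stage_start[4], stage_end[5]))) {
    tt <- block[1] + 0.3
    while (tt < block[2]) {
      r_all <- c(r_all, tt)
      st_here <- stage_of_time(tt)
      hr <- config$hr_by_stage[if (is.na(st_here)) 5L else st_here]
      mod <- sqrt(2) * 0.97 * sin(2 * pi * f_lf * tt + phi_lf) +
        0.25 * stats::rnorm(1)
      rr <- 60 / hr * (1 + config$hr_jitter * mod)
      rr <- min(max(rr, 0.35), 1.9)
      tt <- tt + rr
    }
  }

  se <- config$stage_effects
  clean <- list()

  # --- ECG ---
  ecg <- numeric(n)
  for (rp in r_all) {
    i0 <- max(1L, floor((rp - 0.35) * fs) + 1L)
    i1 <- min(n, ceiling((rp + 0.45) * fs) + 1L)
    idx <- i0:i1
    ecg[idx] <- ecg[idx] + ecg_complex(t[idx] - rp)
  }
  ecg <- ecg + 0.04 * sin(2 * pi * 0.25 * t + 1.1)  # baseline wander
  clean$ecg <- ecg

  # --- pulsatile impedance channels + per-cycle ground truth ---
  r_stage <- stage_of_time(r_all)
  n_cyc_all <- length(r_all) - 1L
  build_pulse <- function(rtt, dz0) {
    sig <- numeric(n)
    true_dz <- rep(NA_real_, n_cyc_all)
    for (i in seq_len(n_cyc_all)) {
      # same-block consecutive peaks only
      if (r_all[i + 1] - r_all[i] > 2.5) next
      foot <- r_all[i] + rtt
      L <- r_all[i + 1] - r_all[i]
      i0 <- floor(foot * fs) + 1L
      i1 <- min(n, ceiling((foot + L) * fs) + 1L)
      if (i0 > n) next
      idx <- i0:i1
      k <- pulse_kernel(t[idx] - foot, L, config$pulse_shape)
      rng <- max(k) - min(k)
      if (rng <= 0) next
      st <- if (is.na(r_stage[i])) 5L else r_stage[i]
      amp <- dz0 * se$dz[st]
      sig[idx] <- sig[idx] + k / rng * amp
      true_dz[i] <- amp
    }
    list(sig = sig, true_dz = true_dz)
  }
  fore <- build_pulse(config$rtt_forehead, config$dz_forehead)
  arm <- build_pulse(config$rtt_arm, config$dz_arm)
  clean$z_forehead_pulse <- fore$sig
  clean$z_arm_pulse <- arm$sig

  # --- baseline impedance with slow drift ---
  clean$z_forehead_base <- config$z_base_forehead * (1 + 0.003 * sin(2 * pi * t / 97))
  clean$z_arm_base <- config$z_base_arm * (1 + 0.003 * sin(2 * pi * t / 83 + 0.7))

  # --- LDF: mean level + cardiac oscillation phase-locked to the cycle ---
  stage_t <- stage_of_time(t)
  stage_t[is.na(stage_t)] <- 5L
  mc_level <- config$ldf_mc_mean * se$mc_mean[stage_t]
  amp_level <- config$ldf_cardiac_amp * se$mc_amp[stage_t]
  phase <- rep(NA_real_, n)
  for (i in seq_len(n_cyc_all)) {
    if (r_all[i + 1] - r_all[i] > 2.5) next
    i0 <- floor(r_all[i] * fs) + 1L
    i1 <- min(n, ceiling(r_all[i + 1] * fs))
    idx <- i0:i1
    phase[idx] <- (t[idx] - r_all[i]) / (r_all[i + 1] - r_all[i])
  }
  card <- ifelse(is.na(phase), 0, sin(2 * pi * phase))
  clean$ldf <- mc_level + amp_level * card

  # --- per-cycle ground truth (clean signals, visible cycles only) ---
  keep <- logical(n_cyc_all)
  gt_rows <- vector("list", n_cyc_all)
  for (i in seq_len(n_cyc_all)) {
    if (is.na(fore$true_dz[i])) next
    if (in_gap(r_all[i]) || in_gap(r_all[i + 1]) ||
        any(in_gap(c(r_all[i], (r_all[i] + r_all[i + 1]) / 2, r_all[i + 1]))))
      next
    # window must not touch a masked interval at all
    if (any(vapply(gaps, function(g)
      r_all[i] < g[2] && r_all[i + 1] > g[1], logical(1)))) next
    i0 <- floor(r_all[i] * fs) + 1L
    i1 <- min(n, floor(r_all[i + 1] * fs))
    ff <- truth_fiducials(clean$z_forehead_pulse[i0:i1], fs)
    fa <- truth_fiducials(clean$z_arm_pulse[i0:i1], fs)
    st <- if (is.na(r_stage[i])) 5L else r_stage[i]
    keep[i] <- TRUE
    gt_rows[[i]] <- data.frame(
      start_time = r_all[i], end_time = r_all[i + 1], stage_id = st,
      dz_forehead = fore$true_dz[i], dz_arm = arm$true_dz[i],
      z_base_forehead = mean(clean$z_forehead_base[i0:i1]),
      z_base_arm = mean(clean$z_arm_base[i0:i1]),
      rtt_forehead = ff$foot, rtt_arm = fa$foot,
      onset_forehead = config$rtt_forehead, onset_arm = config$rtt_arm,
      t_ad_forehead = ff$t_ad, t_ad_arm = fa$t_ad, lvet_arm = fa$lvet)
  }
  gt_cycles <- do.call(rbind, gt_rows[keep])
  # a peak is "visible" only if its whole QRS support is unmasked
  r_visible <- r_all[!in_gap(r_all, margin = 0.06)]
  gt_stages <- data.frame(
    stage_id = 1:5,
    mc_mean = config$ldf_mc_mean * se$mc_mean,
    mc_cardiac_amp = config$ldf_cardiac_amp * se$mc_amp)
  ground_truth <- list(r_peak_times = r_visible, cycles = gt_cycles,
                       stages = gt_stages)

  # --- additive noise ---
  add_noise <- function(x, snr_db) {
    if (!is.finite(snr_db)) return(x)
    s <- stats::sd(x)
    x + stats::rnorm(length(x), sd = s / 10^(snr_db / 20))
  }
  noisy <- lapply(clean, add_noise, snr_db = config$noise_snr_db)

  units <- c(ecg = "mV", z_forehead_base = "Ohm", z_forehead_pulse = "mOhm",
             z_arm_base = "Ohm", z_arm_pulse = "mOhm", ldf = "perf.units")
  channels <- lapply(RECORDING_CHANNELS, function(nm)
    channel_signal(noisy[[nm]], fs = fs, units = units[[nm]], mask = mask))
  names(channels) <- RECORDING_CHANNELS

  subject_recording(sprintf("synth_%d", config$seed), channels, stages,
                    anthropometrics = list(), ground_truth = ground_truth)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject physiology and anthropometrics, then calls
#' [generate_recording()] per subject with a seed derived deterministically
#' from the cohort seed. Baseline impedance, pulse amplitude, heart rate and
#' LDF levels are sampled uniformly within physiological ranges (forehead
#' pulse amplitude 50-150 mOhm, forehead baseline 80-150 Ohm, heart rate
#' scaled so cohort rates span roughly 60-100 bpm); head circumference and
#' superficial tissue thickness are sampled within the observed 54-61 cm and
#' 3-4 mm ranges. Per-subject multiplicative stage-effect jitter is applied
#' on top of the configured stage effects; with `share_stage_effects = TRUE`
#' the same per-subject random stage modifier multiplies both the impedance
#' pulse amplitude and the LDF cardiac amplitude, giving the cohort a
#' common intraoperative trajectory across the two modalities.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param config Base [synth_config()]; per-subject fields are resampled.
#' @param seed Cohort seed.
#' @param share_stage_effects Couple impedance and LDF stage modifiers.
#' @return List of [subject_recording] objects.
#' @export
generate_cohort <- function(n_subjects, config = synth_config(), seed = 1L,
                            share_stage_effects = FALSE) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    abort_rheo("n_subjects must be >= 1", "config_error")
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  set.seed(as.integer(seed))
  n_subjects <- as.integer(n_subjects)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  draws <- lapply(seq_len(n_subjects), function(i) {
    list(
      hr_mult = stats::runif(1, 0.88, 1.12),
      dz_forehead = stats::runif(1, 50, 150),
      dz_arm = stats::runif(1, 100, 250),
      z_base_forehead = stats::runif(1, 80, 150),
      z_base_arm = stats::runif(1, 30, 70),
      ldf_mc_mean = stats::runif(1, 8, 20),
      ldf_cardiac_amp = stats::runif(1, 0.6, 2.0),
      rtt_forehead = stats::runif(1, 0.12, 0.18),
      rtt_arm = stats::runif(1, 0.20, 0.30),
      eff_shared = stats::runif(5, 0.85, 1.15),
      eff_extra = stats::runif(5, 0.85, 1.15),
      anthro = list(
        head_circumference_cm = round(stats::runif(1, 54, 61)),
        tissue_thickness_mm = round(stats::runif(1, 3, 4)),
        age = round(stats::runif(1, 41, 74)),
        sex = sample(c("male", "female"), 1, prob = c(0.8, 0.2)),
        height_cm = round(stats::runif(1, 163, 195)),
        weight_kg = round(stats::runif(1, 60, 129)))
    )
  })
  lapply(seq_len(n_subjects), function(i) {
    d <- draws[[i]]
    cfg <- unclass(config)
    cfg$seed <- subj_seeds[i]
    cfg$hr_by_stage <- pmin(pmax(config$hr_by_stage * d$hr_mult, 45), 110)
    cfg$dz_forehead <- d$dz_forehead
    cfg$dz_arm <- d$dz_arm
    cfg$z_base_forehead <- d$z_base_forehead
    cfg$z_base_arm <- d$z_base_arm
    cfg$ldf_mc_mean <- d$ldf_mc_mean
    cfg$ldf_cardiac_amp <- d$ldf_cardiac_amp
    cfg$rtt_forehead <- d$rtt_forehead
    cfg$rtt_arm <- d$rtt_arm
    cfg$stage_effects$dz <- config$stage_effects$dz * d$eff_shared
    cfg$stage_effects$mc_amp <- config$stage_effects$mc_amp *
      (if (share_stage_effects) d$eff_shared else d$eff_extra)
    rec <- generate_recording(do.call(synth_config, cfg))
    rec$subject_id <- sprintf("S%02d", i)
    rec$anthropometrics <- d$anthro
    rec
  })
}
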