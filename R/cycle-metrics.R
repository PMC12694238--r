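# Per-cardiac-cycle metric battery: rheographic impedance parameters,
# two-channel complex parameters, volumetric blood filling, LDF parameters.

#' Impedance metrics for one cardiac cycle
#'
#' Computes, for one R-R window of a baseline/pulsatile impedance channel
#' pair: mean baseline impedance `z_base` (Ohm), pulse amplitude
#' `dz = max - min` of the pulsatile component (mOhm), area under the pulse
#' curve above the cycle minimum `s_z` (mOhm s, offset-invariant), the
#' rheographic index `ri = dz / (z_base * 1000)` (dimensionless, with the
#' explicit mOhm-to-Ohm conversion), the differential-rheogram amplitude
#' `ad = max dZ/dt` (mOhm/s, central differences) and its latency `t_ad`
#' from cycle start (s), and the pulse-wave transit time `rtt` from the R
#' peak (cycle start) to the pulse foot located by the intersecting-tangent
#' method (horizontal tangent at the pre-systolic minimum crossed with the
#' maximum-upslope tangent). For the forehead role the descending-limb fall
#' angle `alpha` (degrees) is added: the arctangent of the mean slope of the
#' dz-normalised pulse between the systolic peak and its `decay_frac` decay.
#' For the arm role the left-ventricular ejection time `lvet` is added via
#' [lvet_from_dzdt()].
#'
#' A cycle whose pulse amplitude is below `noise_floor_mohm` is flagged
#' degenerate: `valid = FALSE`, all metrics `NA`.
#'
#' @param pulse Numeric vector, pulsatile component over the cycle, mOhm.
#' @param base Numeric vector, baseline component over the cycle, Ohm.
#' @param fs Sampling rate, Hz.
#' @param channel_role `"forehead"` or `"arm"`.
#' @param noise_floor_mohm Degeneracy threshold on `dz`, mOhm.
#' @param decay_frac Fractional decay defining the descending-limb end for
#'   `alpha`, default 0.63.
#' @return Named list: valid, z_base, dz, s_z, ri, ad, t_ad, rtt, and
#'   alpha (forehead) or lvet (arm).
#' @export
impedance_metrics <- function(pulse, base, fs,
                              channel_role = c("forehead", "arm"),
                              noise_floor_mohm = 1, decay_frac = 0.63) {
  channel_role <- match.arg(channel_role)
  out <- list(valid = FALSE, z_base = NA_real_, dz = NA_real_, s_z = NA_real_,
              ri = NA_real_, ad = NA_real_, t_ad = NA_real_, rtt = NA_real_)
  if (channel_role == "forehead") out$alpha <- NA_real_ else out$lvet <- NA_real_
  n <- length(pulse)
  if (n < 5L || anyNA(pulse) || anyNA(base)) return(out)
  dz <- max(pulse) - min(pulse)
  if (!is.finite(dz) || dz < noise_floor_mohm) return(out)
  dt <- 1 / fs
  tt <- (seq_len(n) - 1L) * dt
  out$valid <- TRUE
  out$z_base <- mean(base)
  out$dz <- dz
  out$s_z <- trapz_int(tt, pulse - min(pulse))
  out$ri <- dz / (out$z_base * 1000)
  d <- central_diff(pulse, dt)
  i_ad <- which.max(d)
  out$ad <- d[i_ad]
  out$t_ad <- tt[i_ad]
  # intersecting-tangent pulse foot: horizontal tangent at the pre-upslope
  # minimum crossed with the maximum-upslope tangent
  pre_min <- min(pulse[seq_len(i_ad)])
  if (out$ad > 0) {
    t_foot <- tt[i_ad] - (pulse[i_ad] - pre_min) / out$ad
    out$rtt <- min(max(t_foot, 0), tt[n])
  }
  i_pk <- which.max(pulse)
  if (channel_role == "forehead") {
    target <- pulse[i_pk] - decay_frac * dz
    after <- which(pulse[i_pk:n] <= target)
    if (length(after) && after[1] > 1L) {
      i63 <- i_pk + after[1] - 1L
      slope <- decay_frac / (tt[i63] - tt[i_pk])
      out$alpha <- atan(slope) * 180 / pi
    }
  } else {
    out$lvet <- lvet_from_dzdt(pulse, fs)
  }
  out
}

#' Left-ventricular ejection time from the differential rheogram
#'
#' Impedance-cardiography convention on the arm channel: the B point is the
#' last zero-crossing of dZ/dt before its maximum (taken with a small
#' relative threshold, `b_frac` of the dZ/dt maximum, so that a flat
#' pre-systolic baseline with numerical ripple yields a stable crossing);
#' the X point is the global minimum of dZ/dt after the maximum. LVET is
#' the B-to-X interval.
#'
#' @param pulse Pulsatile impedance over one cycle, mOhm.
#' @param fs Sampling rate, Hz.
#' @param b_frac Relative dZ/dt threshold defining the B crossing.
#' @return LVET in seconds, or `NA` when the B or X point is undetectable
#'   (e.g. a monotone ramp with no post-peak minimum).
#' @export
lvet_from_dzdt <- function(pulse, fs, b_frac = 0.01) {
  n <- length(pulse)
  if (n < 5L || anyNA(pulse)) return(NA_real_)
  d <- central_diff(pulse, 1 / fs)
  i_max <- which.max(d)
  before <- which(d[seq_len(i_max)] <= b_frac * d[i_max])
  if (!length(before)) return(NA_real_)
  b <- max(before)
  i_x <- i_max + which.min(d[i_max:n]) - 1L
  if (i_x >= n) return(NA_real_)  # still falling at cycle end: no X point
  (i_x - b) / fs
}

#' Complex two-channel metrics
#'
#' Inter-channel transit-time difference `dt_z = rtt_arm - rtt_forehead`,
#' central-peripheral ratio index `icp = dz_forehead / dz_arm`, and baseline
#' impedance ratio `rz = z_base_forehead / z_base_arm`, computed exactly
#' from the per-channel metrics of the same cycle.
#'
#' @param fore,arm Metric lists from [impedance_metrics()] for the same
#'   cycle.
#' @return Named list dt_z, icp, rz (`NA` with both channels not valid, or
#'   when an arm denominator is zero).
#' @export
cross_channel_metrics <- function(fore, arm) {
  out <- list(dt_z = NA_real_, icp = NA_real_, rz = NA_real_)
  if (!isTRUE(fore$valid) || !isTRUE(arm$valid)) return(out)
  if (is.finite(fore$rtt) && is.finite(arm$rtt)) out$dt_z <- arm$rtt - fore$rtt
  if (is.finite(arm$dz) && arm$dz > 0) out$icp <- fore$dz / arm$dz
  if (is.finite(arm$z_base) && arm$z_base > 0) out$rz <- fore$z_base / arm$z_base
  out
}

#' Parameters of the volumetric blood-filling model
#'
#' Impedance-plethysmography conversion of forehead pulse impedance into an
#' absolute perfusion estimate. The per-beat volume follows the classical
#' cylindrical-conductor relation
#' `dV_beat = k * rho * L^2 / Z_base^2 * dZ`, with blood resistivity `rho`
#' (Ohm cm), inter-electrode distance `L` (cm) and the baseline impedance
#' of the sensed segment; `k` is a dimensionless calibration constant. The
#' sensed tissue mass defaults to the scalp volume interrogated by the
#' tetrapolar array (sensed area x superficial tissue thickness x tissue
#' density) and converts per-beat volume into mL/min per 100 g.
#'
#' @param rho_blood Blood resistivity, Ohm cm.
#' @param inter_electrode_distance_cm Potential-electrode spacing, cm.
#' @param sensed_area_cm2 Effective scalp area contributing to the signal,
#'   cm^2.
#' @param tissue_thickness_mm Superficial soft-tissue thickness, mm.
#' @param tissue_density_g_cm3 Soft-tissue density, g/cm^3.
#' @param calibration_k Dimensionless calibration constant.
#' @param sensed_tissue_mass_g Override for the sensed mass; when `NULL` it
#'   is derived from the geometry fields.
#' @return List of class `dv_model_params`.
#' @export
dv_model_params <- function(rho_blood = 135,
                            inter_electrode_distance_cm = 2.5,
                            sensed_area_cm2 = 54,
                            tissue_thickness_mm = 3.5,
                            tissue_density_g_cm3 = 1.05,
                            calibration_k = 2.0,
                            sensed_tissue_mass_g = NULL) {
  mass <- sensed_tissue_mass_g %||%
    (sensed_area_cm2 * tissue_thickness_mm / 10 * tissue_density_g_cm3)
  p <- list(rho_blood = rho_blood,
            inter_electrode_distance_cm = inter_electrode_distance_cm,
            sensed_tissue_mass_g = mass, calibration_k = calibration_k)
  if (any(vapply(p, function(v) !is.numeric(v) || v <= 0, logical(1))))
    abort_rheo("all volumetric-model parameters must be positive",
               "parameter_error")
  structure(p, class = "dv_model_params")
}

#' Volumetric blood filling of the forehead tissues
#'
#' Converts one cycle's pulse amplitude and baseline impedance into
#' volumetric blood filling in mL/min per 100 g of tissue:
#' `dV = k * rho * L^2 / Z_base^2 * dZ[Ohm] * HR * 100 / mass_g`.
#' Linear in `dZ`, inverse-quadratic in `Z_base`, linear in heart rate.
#'
#' @param dz_mohm Pulse impedance amplitude, mOhm.
#' @param z_base_ohm Baseline impedance, Ohm.
#' @param heart_rate Beats per minute (> 0).
#' @param params A [dv_model_params()].
#' @return dV in mL/min per 100 g.
#' @export
volumetric_blood_filling <- function(dz_mohm, z_base_ohm, heart_rate,
                                     params = dv_model_params()) {
  if (!inherits(params, "dv_model_params")) params <- do.call(dv_model_params, params)
  if (any(heart_rate <= 0, na.rm = TRUE))
    abort_rheo("heart_rate must be positive", "parameter_error")
  dv_beat <- params$calibration_k * params$rho_blood *
    params$inter_electrode_distance_cm^2 / z_base_ohm^2 * (dz_mohm / 1000)
  dv_beat * heart_rate * 100 / params$sensed_tissue_mass_g
}

#' LDF metrics of one analysis epoch
#'
#' `mc` is the epoch mean of the microcirculation index. The amplitude
#' spectrum uses a Hann window with amplitude-density normalisation: a pure
#' sinusoid of amplitude A integrates to A over its spectral neighbourhood,
#' so the cardiac-band amplitude
#' `a_mc = integral of S(f) over band` (trapezoid rule on bin centres)
#' carries perfusion units.
#'
#' @param x LDF samples of the epoch, perfusion units.
#' @param fs Sampling rate, Hz.
#' @param band Cardiac band, Hz, default `c(0.6, 1.6)`.
#' @param min_epoch_s Minimum epoch length, s (frequency resolution).
#' @return List: mc, a_mc, spectrum (data.frame freq, amplitude_density).
#' @export
ldf_metrics <- function(x, fs, band = c(0.6, 1.6), min_epoch_s = 10) {
  n <- length(x)
  if (n < min_epoch_s * fs || anyNA(x))
    abort_rheo(sprintf("LDF epoch must be at least %g s of valid signal",
                       min_epoch_s), "insufficient_data_error")
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))  # Hann
  xc <- x - mean(x)
  # zero-pad 4x so the trapezoid integral samples the continuous spectrum
  # densely and the result is independent of tone-to-bin alignment
  np <- 4L * n
  X <- stats::fft(c(xc * w, numeric(np - n)))
  half <- seq_len(floor(np / 2))
  amp <- 2 * Mod(X[half + 1L]) / sum(w)  # amplitude per analysis bin
  df <- fs / np
  freq <- half * df
  # continuous-spectrum mass of the Hann kernel: a tone of amplitude A has
  # integral A * c_h * (fs / n) of `amp` over frequency
  dens <- amp / (hann_kernel_mass(n, np) * fs / n)
  sel <- freq >= band[1] & freq <= band[2]
  a_mc <- if (sum(sel) >= 2L) trapz_int(freq[sel], dens[sel]) else 0
  list(mc = mean(x), a_mc = a_mc,
       spectrum = data.frame(freq = freq, amplitude_density = dens))
}

# Dimensionless mass of the Hann window's amplitude kernel, i.e. the
# integral of |W(f)| over frequency in units of (W(0) / T): the calibration
# constant that makes the amplitude-density integral of a pure tone equal
# its amplitude regardless of bin alignment. Computed once per (n, np).
hann_kernel_mass <- local({
  cache <- new.env(parent = emptyenv())
  function(n, np) {
    key <- paste(n, np)
    if (!is.null(cache[[key]])) return(cache[[key]])
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
    W <- Mod(stats::fft(c(w, numeric(np - n))))
    # one DTFT period of |W| (kernel plus all sidelobes), relative to W(0),
    # in units of the fundamental bin width 1/T
    val <- sum(W) / W[1] * n / np
    cache[[key]] <- val
    val
  }
})

# Sliding-epoch LDF metrics over all valid runs of the LDF channel.
# Returns one row per epoch centre.
ldf_epoch_table <- function(ldf, epoch_s = 10, step_s = 1,
                            band = c(0.6, 1.6)) {
  fs <- ldf$fs
  runs <- valid_runs(ldf$samples, ldf$mask)
  rows <- list()
  len <- round(epoch_s * fs)
  step <- max(1L, round(step_s * fs))
  for (i in seq_len(nrow(runs))) {
    a <- runs$start[i]; b <- runs$end[i]
    if (b - a < len) next
    starts <- seq(a, b - len, by = step)
    for (s0 in starts) {
      seg <- ldf$samples[(s0 + 1L):(s0 + len)]
      m <- ldf_metrics(seg, fs, band = band, min_epoch_s = epoch_s)
      rows[[length(rows) + 1L]] <- data.frame(
        center_time = (s0 + len / 2) / fs, mc = m$mc, a_mc = m$a_mc)
    }
  }
  if (!length(rows)) return(data.frame(center_time = numeric(0),
                                       mc = numeric(0), a_mc = numeric(0)))
  do.call(rbind, rows)
}

#' Compute the full per-cycle feature table for one recording
#'
#' Runs the whole metric battery over the kept cycles of a recording: the
#' pulsatile channels are band-limited (zero-phase low-pass at
#' `smooth_hz`) before derivative-based fiducials are extracted, impedance
#' metrics are computed for both channels, complex metrics and volumetric
#' blood filling are derived, and each cycle inherits the LDF metrics of
#' the 10 s sliding epoch centred nearest its R peak.
#'
#' @param rec A [subject_recording].
#' @param cycles Optional [extract_cycles()] result; computed from
#'   [detect_r_peaks()] when missing.
#' @param dv_params A [dv_model_params()]; its tissue thickness defaults to
#'   the recording's anthropometrics when available.
#' @param smooth_hz Low-pass cutoff applied to pulsatile channels before
#'   metric extraction, Hz.
#' @param ldf_epoch_s,ldf_band LDF epoch length (s) and cardiac band (Hz).
#' @param criteria Cycle-rejection criteria passed to [extract_cycles()].
#' @return data.frame with one row per kept cycle: subject_id, stage_id,
#'   cycle_index, r_time, heart_rate, all per-channel impedance metrics
#'   (suffixed `_forehead` / `_arm`), alpha, lvet, dt_z, icp, rz, dv, mc,
#'   a_mc.
#' @export
compute_cycle_metrics <- function(rec, cycles = NULL, dv_params = NULL,
                                  smooth_hz = 20, ldf_epoch_s = 10,
                                  ldf_band = c(0.6, 1.6), criteria = list()) {
  fs <- recording_fs(rec)
  if (is.null(cycles)) {
    peaks <- detect_r_peaks(rec$channels$ecg)
    cycles <- extract_cycles(peaks, rec, criteria)
  }
  if (is.null(dv_params)) {
    th <- rec$anthropometrics$tissue_thickness_mm
    dv_params <- if (is.null(th)) dv_model_params() else
      dv_model_params(tissue_thickness_mm = th)
  }
  lp <- signal::butter(2, smooth_hz / (fs / 2), type = "low")
  pad <- round(fs)
  sm_fore <- filter_runs(rec$channels$z_forehead_pulse$samples,
                         rec$channels$z_forehead_pulse$mask, lp, pad)
  sm_arm <- filter_runs(rec$channels$z_arm_pulse$samples,
                        rec$channels$z_arm_pulse$mask, lp, pad)
  ldf_tab <- ldf_epoch_table(rec$channels$ldf, epoch_s = ldf_epoch_s,
                             band = ldf_band)
  kept <- which(cycles$kept)
  rows <- vector("list", length(kept))
  for (j in seq_along(kept)) {
    i <- kept[j]
    idx <- (cycles$start[i] + 1L):cycles$end[i]
    fore <- impedance_metrics(sm_fore[idx],
                              rec$channels$z_forehead_base$samples[idx],
                              fs, "forehead")
    arm <- impedance_metrics(sm_arm[idx],
                             rec$channels$z_arm_base$samples[idx],
                             fs, "arm")
    cc <- cross_channel_metrics(fore, arm)
    hr <- 60 / cycles$duration_s[i]
    dv <- if (isTRUE(fore$valid))
      volumetric_blood_filling(fore$dz, fore$z_base, hr, dv_params) else NA_real_
    if (nrow(ldf_tab)) {
      k <- which.min(abs(ldf_tab$center_time - cycles$r_time[i]))
      mc <- ldf_tab$mc[k]; a_mc <- ldf_tab$a_mc[k]
    } else { mc <- NA_real_; a_mc <- NA_real_ }
    rows[[j]] <- data.frame(
      subject_id = rec$subject_id, stage_id = cycles$stage_id[i],
      cycle_index = i, r_time = cycles$r_time[i], heart_rate = hr,
      z_base_forehead = fore$z_base, dz_forehead = fore$dz,
      s_z_forehead = fore$s_z, ri_forehead = fore$ri, ad_forehead = fore$ad,
      t_ad_forehead = fore$t_ad, rtt_forehead = fore$rtt, alpha = fore$alpha,
      z_base_arm = arm$z_base, dz_arm = arm$dz, s_z_arm = arm$s_z,
      ri_arm = arm$ri, ad_arm = arm$ad, t_ad_arm = arm$t_ad,
      rtt_arm = arm$rtt, lvet = arm$lvet,
      dt_z = cc$dt_z, icp = cc$icp, rz = cc$rz, dv = dv,
      mc = mc, a_mc = a_mc, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(out)) {
    out <- data.frame(subject_id = character(0))
  }
  rownames(out) <- NULL
  out
}
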