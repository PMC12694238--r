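# Filtering, R-peak detection (Pan-Tompkins) and cardiac-cycle windowing.

# Zero-phase Butterworth filtering with odd (antisymmetric) reflection
# padding, applied independently to each contiguous unmasked run. Reflection
# padding suppresses the start-up transients that plain forward-backward
# filtering produces on signals with a large DC offset.
zero_phase <- function(x, filt, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad < 1L) return(signal::filtfilt(filt, x))
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(filt, c(front, x, back))
  y[(pad + 1):(pad + n)]
}

filter_runs <- function(samples, mask, filt, pad) {
  out <- rep(NA_real_, length(samples))
  runs <- valid_runs(samples, mask)
  for (i in seq_len(nrow(runs))) {
    idx <- (runs$start[i] + 1L):runs$end[i]
    out[idx] <- zero_phase(samples[idx], filt, pad)
  }
  out
}

#' Split a full impedance channel into baseline and pulsatile components
#'
#' Emulates in software the hardware separation of the impedance signal:
#' the baseline is the low-pass component below `band[1]`, the pulsatile
#' component is the band-pass content within `band`. Both filters are
#' zero-phase Butterworth (order 2 applied forward-backward), so baseline
#' plus pulsatile reconstructs the input up to the stop-band residual.
#' Output units equal the input units.
#'
#' @param z A [channel_signal] carrying a full (unseparated) impedance
#'   signal.
#' @param band Length-2 pass band in Hz, default `c(0.3, 20)`; must lie
#'   strictly inside (0, fs/2).
#' @return List with elements `baseline` and `pulsatile`, both
#'   [channel_signal] objects sharing the input mask.
#' @export
split_pulsatile <- function(z, band = c(0.3, 20)) {
  fs <- z$fs
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fs / 2)
    abort_rheo("band must satisfy 0 < low < high < fs/2", "parameter_error")
  lp <- signal::butter(2, band[1] / (fs / 2), type = "low")
  bp <- signal::butter(2, band / (fs / 2), type = "pass")
  pad <- round(3 * fs / band[1])
  base <- filter_runs(z$samples, z$mask, lp, pad)
  puls <- filter_runs(z$samples, z$mask, bp, pad)
  list(
    baseline = channel_signal(base, fs = fs, units = z$units,
                              start_time = z$start_time, mask = z$mask),
    pulsatile = channel_signal(puls, fs = fs, units = z$units,
                               start_time = z$start_time, mask = z$mask)
  )
}

#' Detect ECG R peaks with the Pan-Tompkins algorithm
#'
#' Classic stage sequence: band-pass (default 5-15 Hz, zero-phase
#' Butterworth), five-point derivative, squaring, 150 ms moving-window
#' integration, then adaptive dual thresholds with running signal/noise
#' peak estimates, a 200 ms refractory period and a search-back pass at
#' half threshold when more than 1.66 times the running average R-R elapses
#' without a detection. Each accepted detection is finally refined to the
#' local maximum of the band-passed ECG. Masked intervals are processed as
#' independent segments and never produce detections.
#'
#' @param ecg A [channel_signal] in mV.
#' @param band ECG pass band, Hz.
#' @param refractory_s Minimum inter-peak distance, s.
#' @return Strictly increasing integer vector of 0-based sample indices.
#' @export
detect_r_peaks <- function(ecg, band = c(5, 15), refractory_s = 0.2) {
  fs <- ecg$fs
  runs <- valid_runs(ecg$samples, ecg$mask)
  if (nrow(runs) == 0L || sum(runs$end - runs$start) < 2 * fs)
    abort_rheo("ECG shorter than 2 s of valid signal", "insufficient_data_error")
  bp <- signal::butter(2, band / (fs / 2), type = "pass")
  peaks <- integer(0)
  for (ri in seq_len(nrow(runs))) {
    if (runs$end[ri] - runs$start[ri] < 2 * fs) next
    idx <- (runs$start[ri] + 1L):runs$end[ri]
    x <- ecg$samples[idx]
    f <- zero_phase(x, bp, round(fs))
    # five-point derivative, squaring, moving-window integration (150 ms)
    d <- c(0, 0, (2 * f[5:length(f)] + f[4:(length(f) - 1)] -
                    f[2:(length(f) - 3)] - 2 * f[1:(length(f) - 4)]) / 8, 0, 0)
    sq <- d^2
    w <- max(1L, round(0.150 * fs))
    mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
    mwi[is.na(mwi)] <- 0
    p <- pt_threshold(mwi, f, fs, refractory_s)
    peaks <- c(peaks, idx[p] - 1L)  # to 0-based global indices
  }
  sort(unique(peaks))
}

# Adaptive dual-threshold peak picking on the integrated signal, with
# search-back; returns 1-based local indices refined on the filtered ECG.
pt_threshold <- function(mwi, f, fs, refractory_s) {
  n <- length(mwi)
  refr <- round(refractory_s * fs)
  # candidate local maxima of the integrated waveform
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (!length(cand)) return(integer(0))
  init <- seq_len(min(n, 2L * fs))
  spk <- 0.25 * max(mwi[init])
  npk <- 0.5 * mean(mwi[init])
  thr1 <- function() npk + 0.25 * (spk - npk)
  qrs <- integer(0)
  rr_avg <- fs  # running average R-R in samples, init 1 s
  noise_buf <- integer(0)
  for (c0 in cand) {
    p <- mwi[c0]
    if (length(qrs) && (c0 - qrs[length(qrs)]) < refr) next
    if (p > thr1()) {
      spk <- 0.125 * p + 0.875 * spk
      if (length(qrs)) {
        rr <- c0 - qrs[length(qrs)]
        rr_avg <- 0.875 * rr_avg + 0.125 * rr
      }
      qrs <- c(qrs, c0)
      noise_buf <- integer(0)
    } else {
      npk <- 0.125 * p + 0.875 * npk
      noise_buf <- c(noise_buf, c0)
      # search-back: long pause since the last QRS
      if (length(qrs) && (c0 - qrs[length(qrs)]) > 1.66 * rr_avg &&
          length(noise_buf)) {
        vals <- mwi[noise_buf]
        best <- noise_buf[which.max(vals)]
        if (max(vals) > 0.5 * thr1() && (best - qrs[length(qrs)]) >= refr) {
          spk <- 0.25 * max(vals) + 0.75 * spk
          rr_avg <- 0.875 * rr_avg + 0.125 * (best - qrs[length(qrs)])
          qrs <- sort(c(qrs, best))
          noise_buf <- noise_buf[noise_buf > best]
        }
      }
    }
  }
  # refine each detection to the local maximum of the band-passed ECG
  half <- round(0.075 * fs)
  ref <- vapply(qrs, function(c0) {
    a <- max(1L, c0 - half); b <- min(n, c0 + half)
    as.integer(a + which.max(f[a:b]) - 1L)
  }, integer(1))
  ref <- sort(unique(ref))
  if (length(ref) > 1L) ref <- ref[c(TRUE, diff(ref) >= refr)]
  ref
}

#' Score detected R peaks against reference peak times
#'
#' Matches detections to reference peaks greedily within a tolerance and
#' reports sensitivity and positive predictive value. Detections or
#' references falling within `guard_s` of a masked interval are excluded
#' from scoring, since a truncated QRS at a recording-gap edge is not a
#' scoreable event.
#'
#' @param detected 0-based sample indices from [detect_r_peaks()].
#' @param reference_times Reference R-peak times, s.
#' @param fs Sampling rate, Hz.
#' @param tol_s Matching tolerance, s.
#' @param mask Masked intervals (samples) to guard around.
#' @param guard_s Guard band around masks, s.
#' @return List with `sensitivity`, `ppv`, `n_ref`, `n_det`, `mean_abs_err_s`.
#' @export
score_r_peaks <- function(detected, reference_times, fs, tol_s = 0.05,
                          mask = list(), guard_s = 0.1) {
  det_t <- detected / fs
  if (length(mask)) {
    near <- function(tt) Reduce(`|`, lapply(mask, function(iv)
      tt > iv[1] / fs - guard_s & tt < iv[2] / fs + guard_s), logical(length(tt)))
    det_t <- det_t[!near(det_t)]
    reference_times <- reference_times[!near(reference_times)]
  }
  used <- logical(length(det_t))
  errs <- numeric(0)
  tp <- 0L
  for (rt in reference_times) {
    dd <- abs(det_t - rt)
    dd[used] <- Inf
    j <- which.min(dd)
    if (length(j) && is.finite(dd[j]) && dd[j] <= tol_s) {
      used[j] <- TRUE
      tp <- tp + 1L
      errs <- c(errs, dd[j])
    }
  }
  list(sensitivity = if (length(reference_times)) tp / length(reference_times) else NA_real_,
       ppv = if (length(det_t)) tp / length(det_t) else NA_real_,
       n_ref = length(reference_times), n_det = length(det_t),
       mean_abs_err_s = if (length(errs)) mean(errs) else NA_real_)
}

#' Delimit cardiac cycles from consecutive R peaks and reject artifacts
#'
#' One half-open window per consecutive R-peak pair. A window is rejected
#' (kept in the output with `kept = FALSE` and a reason) when its R-R
#' duration is outside the physiological bounds, when it overlaps a masked
#' interval on any channel, when its forehead pulse amplitude exceeds
#' `amp_k` times the median amplitude of neighbouring cycles within a 30 s
#' context (motion artifact) or falls below the noise floor, or when its
#' starting R peak lies outside every annotated stage. Stage attribution
#' uses the starting R peak.
#'
#' @param r_peaks 0-based R-peak sample indices.
#' @param rec A [subject_recording].
#' @param criteria List: `rr_bounds` (s, default `c(0.33, 2)`), `amp_k`
#'   (default 3), `noise_floor_mohm` (default 1), `context_s` (default 30).
#' @return data.frame of class `cycle_windows` with columns `start`, `end`
#'   (0-based half-open samples), `r_time`, `duration_s`, `stage_id`,
#'   `kept`, `reject_reason`.
#' @export
extract_cycles <- function(r_peaks, rec, criteria = list()) {
  crit <- utils::modifyList(list(rr_bounds = c(0.33, 2), amp_k = 3,
                                 noise_floor_mohm = 1, context_s = 30),
                            criteria)
  fs <- recording_fs(rec)
  nr <- length(r_peaks)
  if (nr < 2L)
    return(structure(data.frame(start = integer(0), end = integer(0),
                                r_time = numeric(0), duration_s = numeric(0),
                                stage_id = integer(0), kept = logical(0),
                                reject_reason = character(0)),
                     class = c("cycle_windows", "data.frame")))
  start <- r_peaks[-nr]
  end <- r_peaks[-1]
  dur <- (end - start) / fs
  r_time <- start / fs
  stage_id <- vapply(r_time, function(tt) {
    hit <- which(rec$stages$start_time <= tt & tt < rec$stages$end_time)
    if (length(hit)) rec$stages$stage_id[hit[1]] else NA_integer_
  }, integer(1))
  # union of masks over all channels
  masks <- do.call(c, lapply(rec$channels, function(ch) ch$mask))
  overlaps_mask <- vapply(seq_along(start), function(i) {
    any(vapply(masks, function(iv) start[i] < iv[2] && end[i] > iv[1],
               logical(1)))
  }, logical(1))
  pulse <- rec$channels$z_forehead_pulse$samples
  amp <- vapply(seq_along(start), function(i) {
    seg <- pulse[(start[i] + 1L):end[i]]
    if (all(is.na(seg))) NA_real_ else
      max(seg, na.rm = TRUE) - min(seg, na.rm = TRUE)
  }, numeric(1))
  # neighbourhood median amplitude within the context window
  med_amp <- vapply(seq_along(start), function(i) {
    nb <- which(abs(r_time - r_time[i]) <= crit$context_s / 2 &
                  seq_along(start) != i & !overlaps_mask)
    if (!length(nb)) return(NA_real_)
    stats::median(amp[nb], na.rm = TRUE)
  }, numeric(1))
  reason <- rep(NA_character_, length(start))
  reason[dur < crit$rr_bounds[1] | dur > crit$rr_bounds[2]] <- "rr_out_of_bounds"
  reason[is.na(reason) & overlaps_mask] <- "mask_overlap"
  reason[is.na(reason) & is.na(stage_id)] <- "no_stage"
  art <- is.na(reason) & !is.na(med_amp) & !is.na(amp) &
    (amp > crit$amp_k * med_amp)
  reason[art] <- "amplitude_artifact"
  low <- is.na(reason) & !is.na(amp) & amp < crit$noise_floor_mohm
  reason[low] <- "below_noise_floor"
  structure(data.frame(start = start, end = end, r_time = r_time,
                       duration_s = dur, stage_id = stage_id,
                       kept = is.na(reason), reject_reason = reason,
                       stringsAsFactors = FALSE),
            class = c("cycle_windows", "data.frame"))
}
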