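#' Single-channel physiological signal
#'
#' A uniformly sampled signal with units, an acquisition start time and an
#' optional set of invalid ("masked") intervals. Masked samples are stored as
#' `NA` and additionally listed in `mask` so that downstream segmentation can
#' treat recording pauses (electrocautery, device disconnection) as
#' first-class gaps rather than data.
#'
#' @param samples Numeric vector of samples. Values inside `mask` are forced
#'   to `NA`.
#' @param fs Sampling rate in Hz (> 0).
#' @param units One of `"mV"`, `"Ohm"`, `"mOhm"`, `"perf.units"`.
#' @param start_time Acquisition start, seconds since an arbitrary epoch
#'   shared by all devices of a recording session.
#' @param mask List of half-open 0-based sample intervals `c(start, end)`
#'   marking invalid spans; must be non-overlapping and inside the signal.
#' @return An object of class `channel_signal`.
#' @export
channel_signal <- function(samples, fs, units, start_time = 0, mask = list()) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    abort_rheo("fs must be a single positive number", "config_error")
  units <- match.arg(units, c("mV", "Ohm", "mOhm", "perf.units"))
  samples <- as.numeric(samples)
  mask <- lapply(mask, function(iv) as.integer(iv))
  validate_mask(mask, length(samples))
  if (length(mask)) samples[mask_to_logical(mask, length(samples))] <- NA_real_
  if (any(!is.finite(samples[!is.na(samples)])))
    abort_rheo("samples must be finite outside masked intervals", "format_error")
  structure(
    list(samples = samples, fs = fs, units = units,
         start_time = as.numeric(start_time), mask = mask),
    class = "channel_signal"
  )
}

#' @export
print.channel_signal <- function(x, ...) {
  cat(sprintf("<channel_signal> %d samples @ %g Hz [%s], %d masked interval(s)\n",
              length(x$samples), x$fs, x$units, length(x$mask)))
  invisible(x)
}

# Required channel set, in canonical order.
RECORDING_CHANNELS <- c("ecg", "z_forehead_base", "z_forehead_pulse",
                        "z_arm_base", "z_arm_pulse", "ldf")

#' Stage annotation table
#'
#' @param stage_id Integer vector with values in 1..5.
#' @param start_time,end_time Stage boundaries in seconds on the recording
#'   clock; intervals must be ordered, non-overlapping and non-empty. Gaps
#'   between consecutive stages are allowed (the cardiopulmonary-bypass pause
#'   sits between stages 3 and 4).
#' @return A data.frame with columns stage_id, start_time, end_time.
#' @export
stage_annotation <- function(stage_id, start_time, end_time) {
  stage_id <- as.integer(stage_id)
  if (any(!stage_id %in% 1:5))
    abort_rheo("stage_id must be in 1..5", "format_error")
  if (any(end_time <= start_time))
    abort_rheo("stage end_time must exceed start_time", "format_error")
  df <- data.frame(stage_id = stage_id, start_time = as.numeric(start_time),
                   end_time = as.numeric(end_time))
  df <- df[order(df$start_time), , drop = FALSE]
  if (is.unsorted(df$stage_id, strictly = TRUE))
    abort_rheo("stages must be ordered 1..5 in time", "format_error")
  if (nrow(df) > 1L && any(df$start_time[-1] < df$end_time[-nrow(df)]))
    abort_rheo("stage intervals overlap", "format_error")
  rownames(df) <- NULL
  df
}

#' Synchronized multichannel subject recording
#'
#' Container for one subject's synchronized channels (ECG in mV, two
#' impedance channels split into baseline Ohm / pulsatile mOhm components,
#' LDF in perfusion units), the surgical-stage annotations, anthropometrics,
#' and — for synthetic recordings — the generator's ground truth.
#'
#' @param subject_id Character scalar.
#' @param channels Named list of [channel_signal] objects; must contain
#'   exactly the channels `ecg`, `z_forehead_base`, `z_forehead_pulse`,
#'   `z_arm_base`, `z_arm_pulse`, `ldf`, all at a common sampling rate.
#' @param stages Stage annotation data.frame from [stage_annotation()].
#' @param anthropometrics Named list (head_circumference_cm,
#'   tissue_thickness_mm, age, sex, height_cm, weight_kg); may be empty.
#' @param ground_truth Optional list produced by the synthetic generator.
#' @return An object of class `subject_recording`.
#' @export
subject_recording <- function(subject_id, channels, stages,
                              anthropometrics = list(), ground_truth = NULL) {
  missing_ch <- setdiff(RECORDING_CHANNELS, names(channels))
  if (length(missing_ch))
    abort_rheo(paste0("missing channel(s): ", paste(missing_ch, collapse = ", ")),
               "format_error")
  channels <- channels[RECORDING_CHANNELS]
  fss <- vapply(channels, function(ch) ch$fs, numeric(1))
  if (length(unique(fss)) != 1L)
    abort_rheo("all channels must share one sampling rate; use align_streams() first",
               "format_error")
  ns <- vapply(channels, function(ch) length(ch$samples), numeric(1))
  if (length(unique(ns)) != 1L)
    abort_rheo("all channels must have the same length after alignment", "format_error")
  expected_units <- c(ecg = "mV", z_forehead_base = "Ohm", z_forehead_pulse = "mOhm",
                      z_arm_base = "Ohm", z_arm_pulse = "mOhm", ldf = "perf.units")
  for (nm in RECORDING_CHANNELS) {
    if (channels[[nm]]$units != expected_units[[nm]])
      abort_rheo(sprintf("channel %s must be in %s, got %s",
                         nm, expected_units[[nm]], channels[[nm]]$units),
                 "format_error")
  }
  structure(
    list(subject_id = as.character(subject_id), channels = channels,
         stages = stages, anthropometrics = anthropometrics,
         ground_truth = ground_truth),
    class = "subject_recording"
  )
}

#' @export
print.subject_recording <- function(x, ...) {
  n <- length(x$channels$ecg$samples)
  cat(sprintf("<subject_recording> %s: %d samples @ %g Hz, %d stage(s)%s\n",
              x$subject_id, n, x$channels$ecg$fs, nrow(x$stages),
              if (!is.null(x$ground_truth)) ", with ground truth" else ""))
  invisible(x)
}

#' Sampling rate of a recording (Hz)
#' @param rec A [subject_recording].
#' @export
recording_fs <- function(rec) rec$channels$ecg$fs

#' Write a recording to disk as delimited text plus a JSON sidecar
#'
#' One CSV holds the sample table (one column per channel, one row per
#' sample; masked samples are empty cells); the sidecar JSON holds sampling
#' rate, units, start times, masks, stage annotations, anthropometrics and
#' any embedded ground truth. The pair round-trips through
#' [read_recording()].
#'
#' @param rec A [subject_recording].
#' @param path Directory to write into (created if absent).
#' @return Invisibly, the two file paths written.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "subject_recording"))
    abort_rheo("rec must be a subject_recording", "format_error")
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort_rheo(sprintf("cannot create directory %s", path), "io_error")
  csv <- file.path(path, paste0(rec$subject_id, "_signals.csv"))
  sidecar <- file.path(path, paste0(rec$subject_id, "_meta.json"))
  tab <- data.table::as.data.table(lapply(rec$channels, function(ch) ch$samples))
  data.table::fwrite(tab, csv, na = "")
  meta <- list(
    subject_id = rec$subject_id,
    fs = recording_fs(rec),
    n_samples = length(rec$channels$ecg$samples),
    channels = lapply(rec$channels, function(ch)
      list(units = ch$units, start_time = ch$start_time, mask = ch$mask)),
    stages = rec$stages,
    anthropometrics = rec$anthropometrics,
    ground_truth = rec$ground_truth
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(c(signals = csv, sidecar = sidecar))
}

#' Read a recording written by [write_recording()]
#'
#' @param path Directory containing `<subject_id>_signals.csv` and
#'   `<subject_id>_meta.json`, or the path of the sidecar itself.
#' @param subject_id Optional; required when the directory holds several
#'   recordings.
#' @return A validated [subject_recording].
#' @export
read_recording <- function(path, subject_id = NULL) {
  if (dir.exists(path)) {
    sidecars <- list.files(path, pattern = "_meta\\.json$", full.names = TRUE)
    if (!is.null(subject_id))
      sidecars <- sidecars[basename(sidecars) == paste0(subject_id, "_meta.json")]
    if (length(sidecars) != 1L)
      abort_rheo("expected exactly one recording sidecar; pass subject_id", "io_error")
    sidecar <- sidecars[[1]]
  } else sidecar <- path
  if (!file.exists(sidecar)) abort_rheo(sprintf("no sidecar at %s", sidecar), "io_error")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  csv <- sub("_meta\\.json$", "_signals.csv", sidecar)
  if (!file.exists(csv)) abort_rheo(sprintf("no signal table at %s", csv), "io_error")
  tab <- data.table::fread(csv, na.strings = "")
  if (nrow(tab) != meta$n_samples)
    abort_rheo(sprintf("signal table has %d rows but sidecar states %d samples",
                       nrow(tab), meta$n_samples), "format_error")
  channels <- list()
  for (nm in names(meta$channels)) {
    info <- meta$channels[[nm]]
    if (!nm %in% names(tab))
      abort_rheo(sprintf("channel %s listed in sidecar but absent from table", nm),
                 "format_error")
    mask <- info$mask
    if (is.matrix(mask)) mask <- lapply(seq_len(nrow(mask)), function(i) mask[i, ])
    if (is.null(mask)) mask <- list()
    channels[[nm]] <- channel_signal(tab[[nm]], fs = meta$fs, units = info$units,
                                     start_time = info$start_time, mask = mask)
  }
  stages <- stage_annotation(meta$stages$stage_id, meta$stages$start_time,
                             meta$stages$end_time)
  subject_recording(meta$subject_id, channels, stages,
                    anthropometrics = meta$anthropometrics,
                    ground_truth = meta$ground_truth)
}

#' Align independently timestamped device streams onto one clock
#'
#' Devices store their own start timestamps on the shared PC clock; this
#' resamples every stream to the master (ECG) sampling rate by linear
#' interpolation, crops all streams to their common time span, and rebases
#' start times so that sample 0 is the start of the overlap. Mask intervals
#' are propagated (any output sample interpolated from a masked input sample
#' is masked).
#'
#' @param streams Named list of [channel_signal] objects; must contain all
#'   recording channels. The `ecg` channel defines the master clock.
#' @param subject_id,stages,anthropometrics,ground_truth Passed through to
#'   [subject_recording()]. `stages` times are interpreted on the shared
#'   clock and rebased to the overlap start.
#' @return A [subject_recording] on the common clock.
#' @export
align_streams <- function(streams, subject_id = "aligned", stages = NULL,
                          anthropometrics = list(), ground_truth = NULL) {
  missing_ch <- setdiff(RECORDING_CHANNELS, names(streams))
  if (length(missing_ch))
    abort_rheo(paste0("missing channel(s): ", paste(missing_ch, collapse = ", ")),
               "format_error")
  fs <- streams$ecg$fs
  t0 <- max(vapply(streams, function(s) s$start_time, numeric(1)))
  t1 <- min(vapply(streams, function(s) s$start_time + length(s$samples) / s$fs,
                   numeric(1)))
  if (t1 <= t0) abort_rheo("streams have no temporal overlap", "alignment_error")
  n_out <- floor((t1 - t0) * fs + 1e-9)
  t_out <- t0 + (0:(n_out - 1L)) / fs
  out <- list()
  for (nm in RECORDING_CHANNELS) {
    s <- streams[[nm]]
    t_in <- s$start_time + (seq_along(s$samples) - 1L) / s$fs
    y <- stats::approx(t_in, s$samples, xout = t_out, rule = 2)$y
    # a masked input interval [a,b) maps onto every output sample whose
    # interpolation support touches it
    mask <- list()
    for (iv in s$mask) {
      ta <- s$start_time + iv[1] / s$fs
      tb <- s$start_time + iv[2] / s$fs
      a_out <- max(0L, ceiling((ta - 1 / s$fs - t0) * fs))
      b_out <- min(n_out, floor((tb + 1 / s$fs - t0) * fs))
      if (b_out > a_out) mask[[length(mask) + 1L]] <- c(a_out, b_out)
    }
    out[[nm]] <- channel_signal(y, fs = fs, units = s$units, start_time = t0,
                                mask = mask)
  }
  if (is.null(stages))
    stages <- stage_annotation(1L, 0, n_out / fs)
  else
    stages <- stage_annotation(stages$stage_id, stages$start_time - t0,
                               stages$end_time - t0)
  subject_recording(subject_id, out, stages, anthropometrics, ground_truth)
}
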