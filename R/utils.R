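# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal conditions with machine-readable classes
#'
#' All validation failures in the package raise conditions whose class
#' carries the failure kind (e.g. "rheomicro_config_error"), so callers can
#' branch on them programmatically.
#' @noRd
abort_rheo <- function(msg, class) {
  stop(structure(
    class = c(paste0("rheomicro_", class), "rheomicro_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Convert a list of half-open 0-based [start, end) intervals into a logical
# vector of length n that is TRUE inside any interval.
mask_to_logical <- function(mask, n) {
  bad <- logical(n)
  for (iv in mask) {
    if (iv[2] > iv[1]) bad[(iv[1] + 1L):iv[2]] <- TRUE
  }
  bad
}

# Contiguous runs of valid (unmasked, non-NA) samples, as a data.frame of
# half-open 0-based [start, end) sample intervals.
valid_runs <- function(x, mask = list()) {
  ok <- !is.na(x)
  if (length(mask)) ok <- ok & !mask_to_logical(mask, length(x))
  if (!any(ok)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Validate that intervals are within [0, n), integer-valued, non-overlapping.
validate_mask <- function(mask, n, what = "mask") {
  if (length(mask) == 0L) return(invisible(TRUE))
  ivs <- do.call(rbind, lapply(mask, as.numeric))
  if (ncol(ivs) != 2L || any(ivs[, 2] <= ivs[, 1]))
    abort_rheo(sprintf("%s intervals must be half-open [start, end) with end > start", what),
               "format_error")
  if (any(ivs[, 1] < 0) || any(ivs[, 2] > n))
    abort_rheo(sprintf("%s intervals must lie within [0, %d)", what, n), "format_error")
  o <- order(ivs[, 1])
  ivs <- ivs[o, , drop = FALSE]
  if (nrow(ivs) > 1L && any(ivs[-1, 1] < ivs[-nrow(ivs), 2]))
    abort_rheo(sprintf("%s intervals overlap", what), "format_error")
  invisible(TRUE)
}

# Trapezoid-rule integral of y over x (uniform or not).
trapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Central-difference derivative at the sample spacing dt; one-sided at ends.
central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 3L) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}
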