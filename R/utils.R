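# Internal helpers shared across modules.

#' @importFrom stats var rnorm runif plogis fft median qnorm sd
#' @importFrom utils tail head read.csv write.csv
#' @importFrom withr with_seed
NULL

# Sampling constants of the acquisition chain: 125 Hz, 10 s strips,
# 5 microvolt per least-significant bit.
FS_HZ <- 125
STRIP_SECONDS <- 10
STRIP_LEN <- FS_HZ * STRIP_SECONDS
LSB_UV <- 5

stop_ccshock <- function(class, msg, ...) {
  stop(structure(class = c(class, "ccshock_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Round to the 5 uV quantization grid (returned as integer microvolts).
quantize_uv <- function(x) {
  as.integer(round(x / LSB_UV)) * LSB_UV
}

# Rescale a waveform so its post-quantization peak-to-peak amplitude is
# exactly `pp_uv` (snapped to the 5 uV grid): min and max are mapped onto
# grid points, and a grid-aligned offset roughly centers the strip, so
# rounding preserves the extremes.
scale_to_pp <- function(x, pp_uv) {
  pp <- LSB_UV * round(pp_uv / LSB_UV)
  rng <- max(x) - min(x)
  if (rng <= 0) stop_ccshock("degenerate_input", "waveform has zero peak-to-peak amplitude")
  y <- (x - min(x)) / rng * pp
  y - LSB_UV * round(mean(y) / LSB_UV)
}

# Zero-phase Butterworth band-pass (applied forward and backward).
bandpass <- function(x, low_hz, high_hz, fs = FS_HZ, order = 2) {
  w <- c(low_hz, high_hz) / (fs / 2)
  bf <- signal::butter(order, w, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

lowpass <- function(x, high_hz, fs = FS_HZ, order = 2) {
  bf <- signal::butter(order, high_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# Hann-windowed, zero-padded periodogram. Returns freq (Hz) and power.
periodogram <- function(x, fs = FS_HZ, nfft = 16384) {
  x <- x - mean(x)
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  xp <- c(x * w, numeric(max(0, nfft - n)))
  sp <- abs(fft(xp))^2
  nb <- floor(length(xp) / 2)
  list(freq = (seq_len(nb) - 1) * fs / length(xp), power = sp[seq_len(nb)])
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop_ccshock("invalid_parameter", "`seed` must be a single finite number")
  }
  as.integer(seed)
}
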