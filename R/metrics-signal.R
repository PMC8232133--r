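# Corruption and compression-rate metrics used to stratify performance:
# the SNR of a corrupted strip relative to its clean counterpart, the four
# artifact-strength levels, and spectral compression-rate estimation with its
# four rate ranges.

#' Signal-to-noise ratio of a corrupted strip
#'
#' `SNR = 10*log10(P_clean / P_corrupted)`, where each power is the variance
#' of the 10 s signal about its own mean. More negative values mean stronger
#' compression artifacts relative to the underlying rhythm.
#'
#' @param clean Numeric waveform or [ecg_strip()] (clean ECG).
#' @param corrupted Numeric waveform or [ecg_strip()] of the same length
#'   (ECG during compressions).
#' @return List with `snr_db`, `p_clean`, `p_corrupted` (powers in uV^2).
#' @export
compute_snr <- function(clean, corrupted) {
  x <- if (inherits(clean, "ecg_strip")) as.numeric(clean$samples) else as.numeric(clean)
  z <- if (inherits(corrupted, "ecg_strip")) as.numeric(corrupted$samples) else as.numeric(corrupted)
  if (length(x) != length(z)) stop_ccshock("invalid_parameter", "waveforms must have equal length")
  p_clean <- stats::var(x)
  p_corr <- stats::var(z)
  if (p_clean <= 0 || p_corr <= 0) {
    stop_ccshock("degenerate_input", "zero-variance input: SNR undefined")
  }
  list(snr_db = 10 * log10(p_clean / p_corr), p_clean = p_clean, p_corrupted = p_corr)
}

#' Artifact-strength level of an SNR value
#'
#' Four levels of compression-artifact corruption: very strong (<= -9 dB),
#' strong (-9, -6], moderate (-6, -3], weak (> -3 dB).
#'
#' @param snr_db Finite SNR value(s) in dB.
#' @return Ordered factor with levels `VERY_STRONG < STRONG < MODERATE < WEAK`.
#' @export
snr_bin <- function(snr_db) {
  if (any(!is.finite(snr_db))) stop_ccshock("invalid_parameter", "SNR must be finite")
  lev <- c("VERY_STRONG", "STRONG", "MODERATE", "WEAK")
  idx <- ifelse(snr_db <= -9, 1L, ifelse(snr_db <= -6, 2L, ifelse(snr_db <= -3, 3L, 4L)))
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Estimate the chest-compression rate of a corrupted strip
#'
#' The dominant peak of a Hann-windowed, zero-padded periodogram is searched
#' in the 1.33-2.67 Hz band (80-160 compressions/min). The peak must stand
#' out from the in-band spectral floor (peak power at least `min_peak_ratio`
#' times the in-band median), otherwise no compression activity is detectable.
#'
#' @param waveform Numeric waveform or [ecg_strip()] at 125 Hz.
#' @param min_peak_ratio Dominance required of the spectral peak relative to
#'   the in-band median power.
#' @return Estimated rate in compressions/min.
#' @export
estimate_cc_rate <- function(waveform, min_peak_ratio = 10) {
  x <- if (inherits(waveform, "ecg_strip")) as.numeric(waveform$samples) else as.numeric(waveform)
  pg <- periodogram(x)
  band <- pg$freq >= 80 / 60 & pg$freq <= 160 / 60
  pw <- pg$power[band]
  fq <- pg$freq[band]
  med <- stats::median(pw)
  if (med <= 0 || max(pw) < min_peak_ratio * med) {
    stop_ccshock("rate_undetectable", "no dominant spectral peak in the 80-160 /min band")
  }
  60 * fq[which.max(pw)]
}

#' Compression-rate range
#'
#' Four ranges: slow (< 100 /min), normal-low (100-110), normal-high
#' (110-120) and rapid (> 120 /min); the 110 /min metronome boundary is
#' assigned to the upper normal range.
#'
#' @param rate_cpm Positive compression rate(s) in compressions/min.
#' @return Ordered factor with levels `SLOW < NORM_LOW < NORM_HIGH < RAPID`.
#' @export
cc_rate_bin <- function(rate_cpm) {
  if (any(!is.finite(rate_cpm)) || any(rate_cpm <= 0)) {
    stop_ccshock("invalid_parameter", "compression rate must be positive")
  }
  lev <- c("SLOW", "NORM_LOW", "NORM_HIGH", "RAPID")
  idx <- ifelse(rate_cpm < 100, 1L, ifelse(rate_cpm < 110, 2L, ifelse(rate_cpm <= 120, 3L, 4L)))
  factor(lev[idx], levels = lev, ordered = TRUE)
}
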