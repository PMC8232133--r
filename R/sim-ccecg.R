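# Synthetic CC-ECG simulator: clean cardiac-arrest rhythms, chest-compression
# artifacts, and SNR-controlled mixtures.
#
# The real OHCA recordings behind shock-advisory studies are restricted, so
# this module emulates their statistical structure: 10 s single-lead strips at
# 125 Hz, quantized at 5 uV/LSB and band-limited to the AED monitoring
# bandwidth (1-30 Hz), with coarse VF (peak-to-peak > 200 uV), organized
# rhythms carrying QRS complexes, asystole (peak-to-peak < 100 uV), and
# quasi-periodic compression artifacts at 80-160 compressions/min mixed at a
# controlled SNR. Waveform morphologies are simulator stand-ins constrained by
# the amplitude/rate definitions, not physiological models.

#' Construct a labeled 10 s ECG strip
#'
#' Container for one labeled CC-ECG (or clean ECG) strip with its provenance.
#' Samples are integer microvolts on the 5 uV quantization grid; strips are
#' always 1250 samples (10 s at 125 Hz).
#'
#' @param samples Integer vector of 1250 microvolt samples (multiples of 5).
#' @param rhythm One of `"VF"`, `"OR"`, `"ASYSTOLE"`.
#' @param snr_db Achieved SNR in dB for corrupted strips, `NA` for clean ones.
#' @param target_snr_db Requested SNR, `NA` for clean strips.
#' @param cc_rate_cpm Compression rate of the embedded artifact, `NA` if none.
#' @param seed Integer seed the strip was generated from.
#' @return An object of class `ecg_strip`.
#' @export
ecg_strip <- function(samples, rhythm, snr_db = NA_real_, target_snr_db = NA_real_,
                      cc_rate_cpm = NA_real_, seed = NA_integer_) {
  rhythm <- match.arg(rhythm, c("VF", "OR", "ASYSTOLE"))
  samples <- as.integer(samples)
  if (length(samples) != STRIP_LEN) {
    stop_ccshock("invalid_parameter", "a strip must have exactly %d samples", STRIP_LEN)
  }
  if (any(samples %% LSB_UV != 0L)) {
    stop_ccshock("invalid_parameter", "samples must be integer multiples of %d uV", LSB_UV)
  }
  structure(list(samples = samples, fs = FS_HZ, rhythm = rhythm,
                 shockable = identical(rhythm, "VF"), snr_db = snr_db,
                 target_snr_db = target_snr_db, cc_rate_cpm = cc_rate_cpm,
                 seed = seed),
            class = "ecg_strip")
}

#' @export
print.ecg_strip <- function(x, ...) {
  pp <- diff(range(x$samples))
  cat(sprintf("<ecg_strip> %s%s, %d samples @ %d Hz, p-p %d uV", x$rhythm,
              if (isTRUE(x$shockable)) " (shockable)" else "", length(x$samples), x$fs, pp))
  if (!is.na(x$snr_db)) cat(sprintf(", SNR %.1f dB", x$snr_db))
  if (!is.na(x$cc_rate_cpm)) cat(sprintf(", CC %.0f /min", x$cc_rate_cpm))
  cat("\n")
  invisible(x)
}

check_duration <- function(duration_s) {
  if (!identical(as.numeric(duration_s), as.numeric(STRIP_SECONDS))) {
    stop_ccshock("invalid_parameter", "only %d s strips are supported", STRIP_SECONDS)
  }
}

#' Generate a coarse ventricular fibrillation strip
#'
#' Band-limited (1-30 Hz) irregular fibrillatory waveform whose dominant
#' energy drifts inside 3-8 Hz. Built from white noise filtered through a
#' narrow band whose center frequency performs a slow random walk across the
#' strip (three cross-faded segments), plus a weak broadband floor. The
#' post-quantization peak-to-peak amplitude equals `amplitude_uV` snapped to
#' the 5 uV grid, and must exceed the 200 uV coarse-VF limit.
#'
#' @param duration_s Strip duration; only 10 s is supported.
#' @param seed Integer seed; the same seed reproduces the strip exactly.
#' @param amplitude_uV Target peak-to-peak amplitude in microvolts (> 200).
#' @return An [ecg_strip()] with rhythm `"VF"`.
#' @export
gen_vf <- function(duration_s = 10, seed = 1, amplitude_uV = 500) {
  check_duration(duration_s)
  seed <- check_seed(seed)
  if (!is.finite(amplitude_uV) || amplitude_uV <= 200) {
    stop_ccshock("invalid_parameter", "coarse VF requires peak-to-peak amplitude > 200 uV")
  }
  x <- withr::with_seed(seed, {
    noise <- rnorm(STRIP_LEN)
    f0 <- runif(1, 4.2, 6.8)
    drift <- cumsum(c(0, runif(2, -0.7, 0.7)))
    centers <- pmin(7.2, pmax(3.8, f0 + drift))
    tt <- seq(0, 1, length.out = STRIP_LEN)
    anchors <- c(1 / 6, 3 / 6, 5 / 6)
    y <- numeric(STRIP_LEN)
    wsum <- numeric(STRIP_LEN)
    for (k in 1:3) {
      w <- 0.5 * (1 + cos(pi * pmin(1, abs(tt - anchors[k]) * 3)))
      seg <- bandpass(noise, centers[k] - 1.2, centers[k] + 1.2, order = 2)
      y <- y + w * seg / stats::sd(seg)
      wsum <- wsum + w
    }
    y <- y / pmax(wsum, 1e-9)
    floor_bb <- bandpass(rnorm(STRIP_LEN), 1, 30, order = 2)
    y <- y + 0.08 * stats::sd(y) / stats::sd(floor_bb) * floor_bb
    bandpass(y, 1, 30, order = 2)
  })
  pp <- max(205, LSB_UV * round(amplitude_uV / LSB_UV))
  ecg_strip(quantize_uv(scale_to_pp(x, pp)), "VF", seed = seed)
}

# PQRST template at 125 Hz, R-wave amplitude 1, spanning about [-0.25, 0.4] s.
pqrst_template <- function(fs = FS_HZ) {
  t <- seq(-0.25, 0.4, by = 1 / fs)
  g <- function(a, mu, sig) a * exp(-(t - mu)^2 / (2 * sig^2))
  w <- g(0.10, -0.17, 0.030) +  # P
    g(-0.12, -0.026, 0.011) +   # Q
    g(1.00, 0.000, 0.013) +     # R
    g(-0.22, 0.030, 0.012) +    # S
    g(0.28, 0.230, 0.055)       # T
  list(t = t, w = w, r_index = which.max(w))
}

#' Generate an organized-rhythm strip
#'
#' QRS-template train (PQRST built from Gaussian deflections) at the
#' requested heart rate with small RR-interval jitter, low-amplitude baseline
#' wander and noise. Organized rhythms are the non-shockable class with
#' preserved heart electrical activity.
#'
#' @inheritParams gen_vf
#' @param heart_rate_bpm Mean heart rate in beats/min, within `[30, 180]`.
#' @param qrs_amplitude_uV R-wave amplitude in microvolts.
#' @param rr_jitter_frac Standard deviation of per-beat RR jitter, as a
#'   fraction of the RR interval.
#' @return An [ecg_strip()] with rhythm `"OR"`.
#' @export
gen_or <- function(duration_s = 10, seed = 1, heart_rate_bpm = 75,
                   qrs_amplitude_uV = 800, rr_jitter_frac = 0.03) {
  check_duration(duration_s)
  seed <- check_seed(seed)
  if (!is.finite(heart_rate_bpm) || heart_rate_bpm < 30 || heart_rate_bpm > 180) {
    stop_ccshock("invalid_parameter", "heart rate must lie in [30, 180] beats/min")
  }
  x <- withr::with_seed(seed, {
    tpl <- pqrst_template()
    rr <- 60 / heart_rate_bpm
    beats <- runif(1, 0, rr)
    while (tail(beats, 1) < STRIP_SECONDS + 0.4) {
      beats <- c(beats, tail(beats, 1) + rr * (1 + rnorm(1, 0, rr_jitter_frac)))
    }
    y <- numeric(STRIP_LEN)
    for (bt in beats) {
      idx <- round((bt + tpl$t) * FS_HZ) + 1
      keep <- idx >= 1 & idx <= STRIP_LEN
      y[idx[keep]] <- y[idx[keep]] + tpl$w[keep] * qrs_amplitude_uV
    }
    tt <- seq_len(STRIP_LEN) / FS_HZ
    wander <- 25 * sin(2 * pi * runif(1, 0.2, 0.4) * tt + runif(1, 0, 2 * pi))
    y <- y + wander + 8 * lowpass(rnorm(STRIP_LEN), 12)
    bandpass(y, 1, 30, order = 2)
  })
  ecg_strip(quantize_uv(x), "OR", seed = seed)
}

#' Generate an asystole strip
#'
#' Low-amplitude baseline noise and slow drift; the post-quantization
#' peak-to-peak amplitude is kept strictly below the 100 uV asystole limit
#' (and at least 5 uV, so strips are never identically flat).
#'
#' @inheritParams gen_vf
#' @param amplitude_uV Target peak-to-peak amplitude in microvolts (< 100).
#' @return An [ecg_strip()] with rhythm `"ASYSTOLE"`.
#' @export
gen_asystole <- function(duration_s = 10, seed = 1, amplitude_uV = NULL) {
  check_duration(duration_s)
  seed <- check_seed(seed)
  if (!is.null(amplitude_uV) && (!is.finite(amplitude_uV) || amplitude_uV >= 100 || amplitude_uV < 5)) {
    stop_ccshock("invalid_parameter", "asystole peak-to-peak amplitude must lie in [5, 100) uV")
  }
  x <- withr::with_seed(seed, {
    if (is.null(amplitude_uV)) amplitude_uV <- runif(1, 30, 85)
    tt <- seq_len(STRIP_LEN) / FS_HZ
    drift <- sin(2 * pi * runif(1, 0.15, 0.5) * tt + runif(1, 0, 2 * pi))
    y <- drift + 0.8 * lowpass(rnorm(STRIP_LEN), 8)
    structure(bandpass(y, 1, 30, order = 2), pp = amplitude_uV)
  })
  pp <- min(90, max(5, LSB_UV * round(attr(x, "pp") / LSB_UV)))
  ecg_strip(quantize_uv(scale_to_pp(as.numeric(x), pp)), "ASYSTOLE", seed = seed)
}

#' Generate a chest-compression artifact waveform
#'
#' Quasi-periodic artifact at `cc_rate_cpm / 60` Hz with decaying harmonics
#' and per-cycle amplitude/period jitter, emulating how manual compressions
#' couple into the ECG through the skin-electrode interface. Morphologies:
#' `"sinusoidal"` (harmonic series), `"spiky"` (one narrow biphasic pulse per
#' compression over a weak fundamental), `"mixed"` (both). The `"30:2"` pause
#' pattern inserts one ~4 s ventilation gap inside the 10 s window with
#' tapered edges; `"continuous"` (the default) keeps compressions over the
#' full strip, matching the inclusion criterion of uninterrupted CC over the
#' analysis window.
#'
#' @inheritParams gen_vf
#' @param cc_rate_cpm Mean compression rate, compressions/min in `[80, 160]`.
#' @param morphology One of `"sinusoidal"`, `"spiky"`, `"mixed"`.
#' @param pause_pattern `"continuous"` or `"30:2"`.
#' @return Numeric waveform in microvolts (1250 samples, not quantized);
#'   amplitude is nominal since [mix_at_snr()] rescales it.
#' @export
gen_cc_artifact <- function(duration_s = 10, cc_rate_cpm = 110,
                            morphology = c("sinusoidal", "spiky", "mixed"),
                            pause_pattern = c("continuous", "30:2"), seed = 1) {
  check_duration(duration_s)
  seed <- check_seed(seed)
  morphology <- match.arg(morphology)
  pause_pattern <- match.arg(pause_pattern)
  if (!is.finite(cc_rate_cpm) || cc_rate_cpm < 80 || cc_rate_cpm > 160) {
    stop_ccshock("invalid_parameter", "compression rate must lie in [80, 160] /min")
  }
  withr::with_seed(seed, {
    t0 <- 60 / cc_rate_cpm
    starts <- -runif(1, 0, t0)
    repeat {
      nxt <- tail(starts, 1) + t0 * (1 + rnorm(1, 0, 0.015))
      starts <- c(starts, nxt)
      if (nxt > STRIP_SECONDS + t0) break
    }
    periods <- diff(c(starts, tail(starts, 1) + t0))
    gains <- runif(length(starts), 0.85, 1.15)
    tt <- (seq_len(STRIP_LEN) - 1) / FS_HZ
    cyc <- findInterval(tt, starts)
    cyc[cyc < 1] <- 1
    phase <- (tt - starts[cyc]) / periods[cyc]   # within-cycle phase in [0,1)
    g <- gains[cyc]
    harm_amp <- c(1, 0.45, 0.2, 0.08)
    theta <- runif(4, 0, 2 * pi)
    harm <- rowSums(vapply(1:4, function(h) {
      harm_amp[h] * cos(2 * pi * h * phase + theta[h])
    }, numeric(STRIP_LEN))) * g
    spikes <- numeric(STRIP_LEN)
    if (morphology %in% c("spiky", "mixed")) {
      for (i in seq_along(starts)) {
        ct <- starts[i] + 0.25 * periods[i]
        ts <- tt - ct
        spikes <- spikes - gains[i] * 3 * ts / 0.035 * exp(-ts^2 / (2 * 0.035^2))
      }
    }
    x <- switch(morphology,
                sinusoidal = harm,
                spiky = 0.25 * harm + spikes,
                mixed = harm + 0.8 * spikes)
    if (pause_pattern == "30:2") {
      tp <- runif(1, 2, 4)
      mask <- rep(1, STRIP_LEN)
      ramp <- 0.2
      inside <- tt >= tp & tt <= tp + 4
      mask[inside] <- 0
      lo <- tt >= tp - ramp & tt < tp
      mask[lo] <- 0.5 * (1 + cos(pi * (tt[lo] - (tp - ramp)) / ramp))
      hi <- tt > tp + 4 & tt <= tp + 4 + ramp
      mask[hi] <- 0.5 * (1 - cos(pi * (tt[hi] - (tp + 4)) / ramp))
      x <- x * mask
    }
    300 * x
  })
}

#' Mix a clean strip with a compression artifact at a target SNR
#'
#' The corruption level is measured as `SNR = 10*log10(P_clean / P_corrupted)`
#' where power is the variance of each 10 s signal about its mean. Because the
#' corrupted strip contains the clean signal, targets below 0 dB are met
#' exactly (before quantization) by removing the artifact's projection onto
#' the centered clean signal and scaling the orthogonalized artifact to power
#' `P_clean * (10^(-SNR/10) - 1)`. A target of 0 dB or more cannot be reached
#' by adding an artifact, so the artifact's own power is instead set to
#' `P_clean * 10^(-SNR/10)` and the achieved value of the metric is recorded
#' in the strip's `snr_db`. The mixture is re-quantized to the 5 uV grid.
#'
#' @param clean An [ecg_strip()] with nonzero variance.
#' @param artifact Numeric artifact waveform of the same length.
#' @param target_snr_db Finite target SNR in dB.
#' @param cc_rate_cpm Optional compression rate recorded on the output strip.
#' @return An [ecg_strip()] with the same rhythm/label as `clean`, achieved
#'   `snr_db` (measured on the quantized mixture) and the requested
#'   `target_snr_db`.
#' @export
mix_at_snr <- function(clean, artifact, target_snr_db, cc_rate_cpm = NA_real_) {
  if (!inherits(clean, "ecg_strip")) stop_ccshock("invalid_parameter", "`clean` must be an ecg_strip")
  if (!is.finite(target_snr_db)) stop_ccshock("invalid_parameter", "`target_snr_db` must be finite")
  x <- as.numeric(clean$samples)
  a <- as.numeric(artifact)
  if (length(a) != length(x)) stop_ccshock("invalid_parameter", "clean strip and artifact must have equal length")
  p_clean <- stats::var(x)
  if (p_clean <= 0) stop_ccshock("degenerate_input", "clean strip has zero power")
  if (all(a == a[1])) stop_ccshock("invalid_parameter", "artifact is constant; cannot reach a finite SNR")
  xc <- x - mean(x)
  ac <- a - mean(a)
  if (target_snr_db < 0) {
    ao <- ac - sum(ac * xc) / sum(xc * xc) * xc
    p_ao <- stats::var(ao)
    if (p_ao <= .Machine$double.eps * p_clean) {
      stop_ccshock("invalid_parameter", "artifact is collinear with the clean strip")
    }
    s <- sqrt(p_clean * (10^(-target_snr_db / 10) - 1) / p_ao)
    mix <- x + s * ao
  } else {
    s <- sqrt(p_clean * 10^(-target_snr_db / 10) / stats::var(ac))
    mix <- x + s * ac
  }
  samples <- quantize_uv(mix)
  achieved <- compute_snr(x, as.numeric(samples))$snr_db
  ecg_strip(samples, clean$rhythm, snr_db = achieved, target_snr_db = target_snr_db,
            cc_rate_cpm = cc_rate_cpm, seed = clean$seed)
}

# Draw one value from a distribution spec: length-1 numeric (constant) or
# length-2 c(mean, sd) normal, optionally truncated to [lo, hi].
draw_dist <- function(d, lo = -Inf, hi = Inf) {
  v <- if (length(d) == 1) d else rnorm(1, d[1], d[2])
  for (k in 1:50) {
    if (v >= lo && v <= hi) break
    v <- if (length(d) == 1) d else rnorm(1, d[1], d[2])
  }
  min(hi, max(lo, v))
}

#' Default per-rhythm target-SNR distributions
#'
#' Normal distributions `c(mean, sd)` in dB for each rhythm, reflecting how
#' compression artifacts dominate asystole (tiny intrinsic power) far more
#' than rhythms with preserved electrical activity: VF -6.7 +/- 4.8 dB,
#' OR -6.3 +/- 6.4 dB, Asystole -22.4 +/- 10.1 dB.
#'
#' @return Named list of length-2 numeric vectors.
#' @export
default_snr_distribution <- function() {
  list(VF = c(-6.7, 4.8), OR = c(-6.3, 6.4), ASYSTOLE = c(-22.4, 10.1))
}

#' Generate a labeled synthetic CC-ECG dataset
#'
#' Builds `class_counts` strips per rhythm, corrupts each with a compression
#' artifact mixed at a per-rhythm target SNR, and records full provenance in
#' a manifest. Per-strip seeds are derived from `seed`, so the same call
#' reproduces the dataset byte for byte.
#'
#' @param class_counts Named vector `c(VF =, OR =, ASYSTOLE =)` of strip counts.
#' @param snr_distribution Named list (per rhythm) of length-1 (constant) or
#'   length-2 `c(mean, sd)` normal target-SNR specs in dB; defaults to
#'   [default_snr_distribution()]. A single unnamed numeric applies to all
#'   rhythms.
#' @param cc_rate_distribution Length-1 or `c(mean, sd)` compressions/min,
#'   truncated to `[80, 160]`; default `c(110, 15)` around the metronome rate.
#' @param seed Master seed.
#' @param morphologies Artifact morphologies sampled uniformly per strip.
#' @param pause_pattern Artifact pause pattern (default `"continuous"`,
#'   matching the requirement of compressions over the full 10 s window).
#' @param clean If `TRUE`, skip artifact mixing and return clean strips.
#' @return A `ccecg_dataset`: list with `x` (n x 1250 integer microvolt
#'   matrix), `manifest` (one row per strip: id, rhythm, shockable, snr_db,
#'   target_snr_db, cc_rate_cpm, morphology, seed), and `meta`.
#' @export
make_dataset <- function(class_counts = c(VF = 50, OR = 50, ASYSTOLE = 50),
                         snr_distribution = default_snr_distribution(),
                         cc_rate_distribution = c(110, 15),
                         seed = 1,
                         morphologies = c("sinusoidal", "spiky", "mixed"),
                         pause_pattern = "continuous",
                         clean = FALSE) {
  seed <- check_seed(seed)
  counts <- c(VF = 0, OR = 0, ASYSTOLE = 0)
  counts[names(class_counts)] <- class_counts
  if (any(counts < 0) || sum(counts) == 0) {
    stop_ccshock("invalid_parameter", "class counts must be non-negative and not all zero")
  }
  if (is.numeric(snr_distribution)) {
    snr_distribution <- list(VF = snr_distribution, OR = snr_distribution,
                             ASYSTOLE = snr_distribution)
  }
  rhythms <- rep(names(counts), counts)
  n <- length(rhythms)
  plan <- withr::with_seed(seed, {
    data.frame(
      rhythm = rhythms,
      strip_seed = sample.int(.Machine$integer.max - 1L, n),
      art_seed = sample.int(.Machine$integer.max - 1L, n),
      target_snr_db = vapply(rhythms, function(r) draw_dist(snr_distribution[[r]], -40, 25), 0),
      cc_rate_cpm = vapply(seq_len(n), function(i) draw_dist(cc_rate_distribution, 80, 160), 0),
      morphology = vapply(seq_len(n), function(i) sample(morphologies, 1), ""),
      hr_bpm = round(vapply(seq_len(n), function(i) draw_dist(c(90, 30), 30, 180), 0)),
      vf_amp = vapply(seq_len(n), function(i) runif(1, 300, 900), 0),
      stringsAsFactors = FALSE
    )
  })
  x <- matrix(0L, n, STRIP_LEN)
  man <- vector("list", n)
  for (i in seq_len(n)) {
    p <- plan[i, ]
    strip <- switch(p$rhythm,
                    VF = gen_vf(seed = p$strip_seed, amplitude_uV = p$vf_amp),
                    OR = gen_or(seed = p$strip_seed, heart_rate_bpm = p$hr_bpm),
                    ASYSTOLE = gen_asystole(seed = p$strip_seed))
    if (!clean) {
      art <- gen_cc_artifact(cc_rate_cpm = p$cc_rate_cpm, morphology = p$morphology,
                             pause_pattern = pause_pattern, seed = p$art_seed)
      strip <- mix_at_snr(strip, art, p$target_snr_db, cc_rate_cpm = p$cc_rate_cpm)
    }
    x[i, ] <- strip$samples
    man[[i]] <- data.frame(
      strip_id = sprintf("s%05d", i), rhythm = p$rhythm,
      shockable = strip$shockable,
      snr_db = if (clean) NA_real_ else strip$snr_db,
      target_snr_db = if (clean) NA_real_ else p$target_snr_db,
      cc_rate_cpm = if (clean) NA_real_ else p$cc_rate_cpm,
      morphology = if (clean) NA_character_ else p$morphology,
      seed = p$strip_seed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, man)
  structure(list(x = x, manifest = manifest,
                 meta = list(fs = FS_HZ, lsb_uV = LSB_UV, master_seed = seed,
                             generator = "ccshock-sim", version = "0.1.0")),
            class = "ccecg_dataset")
}

#' @export
print.ccecg_dataset <- function(x, ...) {
  tab <- table(x$manifest$rhythm)
  cat(sprintf("<ccecg_dataset> %d strips (%s), fs %d Hz, seed %d\n",
              nrow(x$x), paste(names(tab), tab, sep = "=", collapse = ", "),
              x$meta$fs, x$meta$master_seed))
  invisible(x)
}

# n x 1250 matrix + 0/1 labels from a dataset (or pass-through list(x, y)).
as_xy <- function(ds) {
  if (inherits(ds, "ccecg_dataset")) {
    list(x = ds$x, y = as.integer(ds$manifest$shockable))
  } else if (is.list(ds) && all(c("x", "y") %in% names(ds))) {
    list(x = as.matrix(ds$x), y = as.integer(ds$y))
  } else {
    stop_ccshock("invalid_input", "expected a ccecg_dataset or a list(x, y)")
  }
}

#' Extract one strip from a dataset
#'
#' @param ds A `ccecg_dataset`.
#' @param i Strip row index.
#' @return An [ecg_strip()].
#' @export
get_strip <- function(ds, i) {
  m <- ds$manifest[i, ]
  ecg_strip(ds$x[i, ], m$rhythm, snr_db = m$snr_db, target_snr_db = m$target_snr_db,
            cc_rate_cpm = m$cc_rate_cpm, seed = m$seed)
}
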