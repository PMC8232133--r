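# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: spectra via stats::fft directly, AUC via pair
# counting, threshold selection via exhaustive scan, peak counting via a
# plain threshold detector.

# Power spectrum of a detrended, Hann-windowed, zero-padded signal.
oracle_spectrum <- function(x, fs = 125, nfft = 16384) {
  x <- x - mean(x)
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  xp <- c(x * w, numeric(nfft - n))
  p <- Mod(fft(xp))^2
  nb <- nfft %/% 2
  list(freq = (seq_len(nb) - 1) * fs / nfft, power = p[seq_len(nb)])
}

oracle_dominant_freq <- function(x, fmin, fmax, fs = 125) {
  sp <- oracle_spectrum(x, fs)
  sel <- sp$freq >= fmin & sp$freq <= fmax
  sp$freq[sel][which.max(sp$power[sel])]
}

# Power-weighted mean frequency over the 1-30 Hz analysis band.
oracle_spectral_centroid <- function(x, fs = 125) {
  sp <- oracle_spectrum(x, fs)
  sel <- sp$freq >= 0.5 & sp$freq <= 31
  sum(sp$freq[sel] * sp$power[sel]) / sum(sp$power[sel])
}

# Count prominent positive peaks: above frac*max, local maximum, with a
# refractory period.
oracle_count_peaks <- function(x, frac = 0.6, refractory_s = 0.25, fs = 125) {
  thr <- frac * max(x)
  n <- length(x)
  cand <- which(x > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[x[cand] >= x[cand - 1] & x[cand] >= x[cand + 1]]
  if (length(cand) == 0) return(0L)
  keep <- cand[1]
  for (i in cand[-1]) if (i - tail(keep, 1) > refractory_s * fs) keep <- c(keep, i)
  length(keep)
}

# Longest run (seconds) during which a moving-RMS envelope stays below
# frac*overall RMS.
oracle_longest_quiet_gap <- function(x, frac = 0.2, win_s = 0.4, fs = 125) {
  w <- as.integer(win_s * fs)
  env <- sqrt(stats::filter(x^2, rep(1 / w, w), sides = 2))
  quiet <- !is.na(env) & env < frac * sqrt(mean(x^2))
  r <- rle(as.vector(quiet))
  if (!any(r$values)) return(0)
  max(r$lengths[r$values]) / fs
}

# AUC as the Mann-Whitney pair statistic with ties counted one half.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exhaustive threshold scan maximizing balanced accuracy with the package's
# documented tie-breaks (higher Se, then lower threshold), recomputing Se/Sp
# from scratch at every candidate.
oracle_best_threshold <- function(scores, labels) {
  cand <- sort(unique(scores))
  best <- NULL
  for (th in cand) {
    dec <- as.integer(scores >= th)
    se <- sum(dec == 1 & labels == 1) / sum(labels == 1)
    sp <- sum(dec == 0 & labels == 0) / sum(labels == 0)
    bac <- (se + sp) / 2
    if (is.null(best) || bac > best$bac + 1e-12 ||
        (abs(bac - best$bac) <= 1e-12 && (se > best$se + 1e-12 ||
         (abs(se - best$se) <= 1e-12 && th < best$th)))) {
      best <- list(bac = bac, se = se, th = th)
    }
  }
  best
}

# Brute-force check of the seven admissible depth trends.
oracle_valid_trend <- function(v) {
  n <- length(v)
  strictly_inc <- function(z) all(diff(z) > 0)
  strictly_dec <- function(z) all(diff(z) < 0)
  if (length(unique(v)) == 1) return(TRUE)
  if (strictly_inc(v) || strictly_dec(v)) return(TRUE)
  for (a in 2:(n - 1)) {
    pre <- v[1:a]; post <- v[a:n]
    if (length(unique(pre)) == 1 && strictly_inc(post)) return(TRUE)
    if (length(unique(pre)) == 1 && strictly_dec(post)) return(TRUE)
    if (strictly_inc(v[1:(n - a + 1)]) && length(unique(v[(n - a + 1):n])) == 1) return(TRUE)
    if (strictly_dec(v[1:(n - a + 1)]) && length(unique(v[(n - a + 1):n])) == 1) return(TRUE)
  }
  FALSE
}

# Tiny labeled dataset shared by training-path tests (weak artifacts, fast).
tiny_easy_dataset <- function(n_per_class, seed, snr = -2) {
  make_dataset(c(VF = n_per_class, OR = n_per_class, ASYSTOLE = n_per_class),
               snr_distribution = snr, seed = seed)
}
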