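# Synthetic CC-ECG simulator: strip contracts, amplitude classes, artifact
# periodicity, and SNR-controlled mixing.

test_that("every generator emits quantized 1250-sample strips, deterministically", {
  gens <- list(
    VF = function(s) gen_vf(seed = s, amplitude_uV = 600),
    OR = function(s) gen_or(seed = s, heart_rate_bpm = 75),
    ASYSTOLE = function(s) gen_asystole(seed = s))
  for (rhythm in names(gens)) {
    a <- gens[[rhythm]](11)
    b <- gens[[rhythm]](11)
    expect_identical(a$samples, b$samples)
    expect_length(a$samples, 1250)
    expect_true(all(a$samples %% 5 == 0))
    expect_identical(a$rhythm, rhythm)
    expect_identical(a$shockable, rhythm == "VF")
    expect_false(identical(a$samples, gens[[rhythm]](12)$samples))
  }
})

test_that("amplitude classes hold across seeds: coarse VF > 200 uV, asystole in [5, 100) uV", {
  for (s in 0:99) {
    expect_gt(diff(range(gen_vf(seed = s, amplitude_uV = 300 + 6 * s)$samples)), 200)
    pp <- diff(range(gen_asystole(seed = s)$samples))
    expect_lt(pp, 100)
    expect_gte(pp, 5)
  }
})

test_that("VF spectral centroid stays in the 3-8 Hz fibrillation band across seeds", {
  cents <- vapply(0:99, function(s) {
    oracle_spectral_centroid(gen_vf(seed = s, amplitude_uV = 600)$samples)
  }, 0)
  expect_true(all(cents > 3 & cents < 8))
})

test_that("organized rhythm carries the requested number of QRS complexes", {
  expect_equal(oracle_count_peaks(gen_or(seed = 7, heart_rate_bpm = 60)$samples),
               10, tolerance = 0, ignore_attr = TRUE)
  n30 <- oracle_count_peaks(gen_or(seed = 7, heart_rate_bpm = 30)$samples)
  expect_true(abs(n30 - 5) <= 1)
  for (s in 1:10) {
    n60 <- oracle_count_peaks(gen_or(seed = s, heart_rate_bpm = 60)$samples)
    expect_true(abs(n60 - 10) <= 1)
  }
  expect_error(gen_or(heart_rate_bpm = 20), class = "ccshock_error")
  expect_error(gen_or(heart_rate_bpm = 200), class = "ccshock_error")
})

test_that("compression artifact is periodic at the requested rate with harmonics", {
  art <- gen_cc_artifact(cc_rate_cpm = 110, seed = 5)
  expect_equal(oracle_dominant_freq(art, 1.2, 2.6), 110 / 60, tolerance = 0.05 / (110 / 60))
  expect_identical(art, gen_cc_artifact(cc_rate_cpm = 110, seed = 5))
  for (morph in c("sinusoidal", "spiky", "mixed")) {
    a <- gen_cc_artifact(cc_rate_cpm = 120, morphology = morph, seed = 9)
    expect_equal(oracle_dominant_freq(a, 1.2, 2.8), 2, tolerance = 0.04)
  }
  expect_error(gen_cc_artifact(cc_rate_cpm = 70), class = "ccshock_error")
  expect_error(gen_cc_artifact(cc_rate_cpm = 170), class = "ccshock_error")
})

test_that("30:2 pause pattern inserts a ventilation gap of at least 2 s", {
  for (s in 1:5) {
    art <- gen_cc_artifact(cc_rate_cpm = 110, pause_pattern = "30:2", seed = s)
    expect_gte(oracle_longest_quiet_gap(art), 2)
    cont <- gen_cc_artifact(cc_rate_cpm = 110, pause_pattern = "continuous", seed = s)
    expect_lt(oracle_longest_quiet_gap(cont), 2)
  }
})

test_that("mixing hits negative SNR targets exactly via the orthogonalized artifact", {
  clean <- gen_vf(seed = 3, amplitude_uV = 600)
  art <- gen_cc_artifact(cc_rate_cpm = 110, seed = 4)
  # -6.02 dB: the added component's power must be (10^0.602 - 1) = 3.00x the
  # clean power, and the measured SNR must round-trip.
  mixed <- mix_at_snr(clean, art, -6.02)
  p_clean <- var(as.numeric(clean$samples))
  p_added <- var(as.numeric(mixed$samples)) - p_clean
  expect_equal(p_added / p_clean, 10^0.602 - 1, tolerance = 0.01)
  expect_equal(compute_snr(clean, mixed)$snr_db, -6.02, tolerance = 0.2 / 6.02)
  m10 <- mix_at_snr(clean, art, -10)
  expect_equal(compute_snr(clean, m10)$snr_db, -10, tolerance = 0.02)
  expect_equal(m10$snr_db, compute_snr(clean, m10)$snr_db)
})

test_that("SNR round-trips within 0.2 dB for targets in [-20, -1] dB on all rhythms", {
  strips <- list(gen_vf(seed = 1, amplitude_uV = 500),
                 gen_or(seed = 2, heart_rate_bpm = 80),
                 gen_asystole(seed = 3))
  art <- gen_cc_artifact(cc_rate_cpm = 105, seed = 6)
  for (target in seq(-20, -1, by = 2)) {
    for (clean in strips) {
      m <- mix_at_snr(clean, art, target)
      expect_equal(compute_snr(clean, m)$snr_db, target, tolerance = 0.2 / abs(target))
    }
  }
})

test_that("non-negative SNR targets fall back to artifact-relative scaling and record the achieved value", {
  clean <- gen_vf(seed = 8, amplitude_uV = 500)
  art <- gen_cc_artifact(cc_rate_cpm = 110, seed = 9)
  m <- mix_at_snr(clean, art, 5)
  # artifact scaled to a tenth of a... 10^(-5/10) of the clean power
  p_clean <- var(as.numeric(clean$samples))
  added <- as.numeric(m$samples) - as.numeric(clean$samples)
  expect_equal(var(added) / p_clean, 10^(-0.5), tolerance = 0.02)
  # the recorded value is the achieved metric, necessarily below the request
  expect_lt(m$snr_db, 5)
  expect_equal(m$snr_db, compute_snr(clean, m)$snr_db)
})

test_that("mixing rejects degenerate inputs", {
  flat <- ecg_strip(rep(0L, 1250), "ASYSTOLE")
  art <- gen_cc_artifact(seed = 1)
  expect_error(mix_at_snr(flat, art, -5), class = "ccshock_error")
  clean <- gen_vf(seed = 1, amplitude_uV = 400)
  expect_error(mix_at_snr(clean, rep(0, 1250), -5), class = "ccshock_error")
  expect_error(mix_at_snr(clean, art[1:100], -5), class = "ccshock_error")
  expect_error(gen_vf(amplitude_uV = 150), class = "ccshock_error")
  expect_error(gen_vf(duration_s = 8), class = "ccshock_error")
})

test_that("datasets conserve counts, reproduce bit for bit, and land in the requested SNR bin", {
  ds <- make_dataset(c(VF = 5, OR = 5, ASYSTOLE = 5), snr_distribution = -4.5, seed = 42)
  expect_equal(nrow(ds$x), 15)
  expect_equal(nrow(ds$manifest), 15)
  expect_equal(as.vector(table(ds$manifest$rhythm)[c("VF", "OR", "ASYSTOLE")]), c(5, 5, 5))
  expect_true(all(ds$x %% 5 == 0))
  ds2 <- make_dataset(c(VF = 5, OR = 5, ASYSTOLE = 5), snr_distribution = -4.5, seed = 42)
  expect_identical(ds$x, ds2$x)
  expect_identical(ds$manifest, ds2$manifest)
  expect_true(all(snr_bin(ds$manifest$snr_db) == "MODERATE"))
  expect_true(all(abs(ds$manifest$snr_db - (-4.5)) < 0.2))
})
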