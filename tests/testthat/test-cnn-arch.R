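# Architecture calculus: shape trace, closed-form parameter count, the
# three-block preset, model construction and feature extraction contracts.

test_that("the preset's shape trace and parameter counts are exact", {
  hp <- cnn3_preset()
  tr <- shape_trace(hp)
  expect_equal(tr$conv_len, c(1241, 601, 281))
  expect_equal(tr$pool_len, c(620, 300, 140))
  expect_equal(attr(tr, "gmp_len"), 50)
  expect_equal(unname(ccshock:::count_params_by_block(hp)), c(55, 2525, 25050, 51))
  expect_equal(count_params(hp), 27681)
  expect_true(validate_trend(hp$filters))
  expect_true(validate_trend(hp$kernels))
})

test_that("seven minimal-kernel blocks shrink a 1250-sample input to 5 samples", {
  hp <- hp_config(filters = rep(5, 7), kernels = rep(5, 7))
  tr <- shape_trace(hp)
  expect_equal(tr$pool_len[7], 5)
  expect_true(all(diff(tr$pool_len) < 0))
})

test_that("parameter count matches hand evaluation and rejects over-budget or infeasible configs", {
  hp <- hp_config(filters = c(5, 5), kernels = c(5, 5))
  expect_equal(count_params(hp), 5 * 6 + 5 * 26 + 6)  # 166
  expect_error(hp_config(filters = rep(5, 5), kernels = c(100, 100, 100, 100, 100)),
               class = "ccshock_error")  # runs out of samples
  expect_error(hp_config(filters = c(5, 50, 5), kernels = c(5, 5, 5)),
               class = "ccshock_error")  # invalid trend
  expect_error(hp_config(filters = c(7, 7), kernels = c(5, 5)),
               class = "ccshock_error")  # off-grid filters
})

test_that("built models allocate exactly the closed-form number of weights", {
  expect_equal(n_trainable(build_model(cnn3_preset(), init_seed = 1)), 27681)
  for (s in 1:20) {
    hp <- sample_hp(seed = 1000 + s)
    expect_equal(n_trainable(build_model(hp, init_seed = s)), count_params(hp))
  }
})

test_that("initialization is deterministic and inference stays in [0, 1]", {
  m1 <- build_model(cnn3_preset(), init_seed = 5)
  m2 <- build_model(cnn3_preset(), init_seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cnn3_preset(), init_seed = 6)
  expect_false(identical(m1$params$W[[1]], m3$params$W[[1]]))
  strip <- gen_vf(seed = 1, amplitude_uV = 700)
  p <- predict(m1, strip)
  expect_true(p >= 0 && p <= 1)
  expect_identical(p, predict(m2, strip))
})

test_that("realized activation shapes equal the shape trace", {
  for (s in c(3, 14, 15)) {
    hp <- sample_hp(seed = 900 + s)
    model <- build_model(hp, init_seed = s)
    tr <- shape_trace(hp)
    act <- layer_activations(model, gen_or(seed = s, heart_rate_bpm = 70))
    for (i in seq_len(hp$n_blocks)) {
      expect_equal(nrow(act$conv[[i]]), tr$conv_len[i])
      expect_equal(ncol(act$conv[[i]]), hp$filters[i])
      expect_equal(nrow(act$pool[[i]]), tr$pool_len[i])
    }
    expect_length(act$gmp, attr(tr, "gmp_len"))
  }
})

test_that("each global-max-pool feature equals the brute-force maximum of its filter activation", {
  model <- build_model(cnn3_preset(), init_seed = 9)
  strip <- gen_vf(seed = 4, amplitude_uV = 500)
  act <- layer_activations(model, strip)
  gmp_brute <- apply(act$pool[[3]], 2, max)
  expect_equal(act$gmp, unname(gmp_brute))
  feats <- extract_gmp_features(model, strip)
  expect_equal(feats$gmp, act$gmp)
})

test_that("feature ordering sorts classifier weights from most negative to most positive", {
  model <- build_model(hp_config(filters = c(5, 5), kernels = c(5, 5)), init_seed = 2)
  model$params$w_dense <- c(1, -2, 0.5, 0.1, -0.3)
  feats <- extract_gmp_features(model, gen_asystole(seed = 2))
  expect_equal(feats$order, c(2, 5, 4, 3, 1))
  expect_true(all(diff(feats$weights_ordered) >= 0))
  expect_equal(feats$gmp_ordered[order(feats$order)], feats$gmp)  # permutation inverts cleanly
  expect_equal(feats$n_nsh, 2)
})

test_that("the decision rule advises a shock exactly at and above the threshold", {
  model <- build_model(cnn3_preset(), init_seed = 3)
  strips <- rbind(gen_vf(seed = 1, amplitude_uV = 600)$samples,
                  gen_or(seed = 2, heart_rate_bpm = 90)$samples)
  p <- predict(model, strips)
  dec <- classify(model, strips, pthr = p[1])  # boundary case: pSh == pthr
  expect_equal(dec[1], "Sh", ignore_attr = TRUE)
  expect_true(all(classify(model, strips, pthr = 1 - 1e-9) == "NSh"))
  expect_error(classify(model, strips, pthr = 0), class = "ccshock_error")
  expect_error(classify(model, strips, pthr = 1.2), class = "ccshock_error")
})
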