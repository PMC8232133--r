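# Oversampling, detection metrics, ROC/threshold machinery, stratified
# evaluation, and the degenerate training contract.

fake_dataset <- function(n_sh, n_nsh) {
  # minimal dataset skeleton: oversampling and metric code only touch rows
  n <- n_sh + n_nsh
  man <- data.frame(strip_id = sprintf("s%05d", seq_len(n)),
                    rhythm = c(rep("VF", n_sh), rep(c("OR", "ASYSTOLE"), length.out = n_nsh)),
                    shockable = c(rep(TRUE, n_sh), rep(FALSE, n_nsh)),
                    snr_db = NA_real_, target_snr_db = NA_real_,
                    cc_rate_cpm = NA_real_, morphology = NA_character_,
                    seed = seq_len(n), stringsAsFactors = FALSE)
  structure(list(x = matrix(0L, n, 4), manifest = man, meta = list()),
            class = "ccecg_dataset")
}

test_that("oversampling replicates the shockable minority to factor times its count", {
  ds <- fake_dataset(408, 2593)
  bal <- oversample_balance(ds, factor = 6, seed = 1)
  expect_equal(sum(bal$manifest$shockable), 2448)      # 6 x 408
  expect_equal(sum(!bal$manifest$shockable), 2593)
  expect_equal(nrow(bal$x), 2593 + 6 * 408)
  expect_false(any(duplicated(bal$manifest$strip_id)))
  same <- oversample_balance(ds, factor = 1, seed = 2)
  expect_equal(sort(same$manifest$strip_id), sort(ds$manifest$strip_id))
  expect_error(oversample_balance(fake_dataset(5, 0), factor = 2),
               class = "ccshock_error")
})

test_that("sensitivity, specificity and balanced accuracy follow their exact ratios", {
  m <- sensitivity_specificity(tp = 268, fn = 33, tn = 4830, fp = 460)
  expect_equal(round(100 * m[["se"]], 1), 89.0)
  expect_equal(round(100 * m[["sp"]], 1), 91.3)
  expect_equal(round(100 * balanced_accuracy(m[["se"]], m[["sp"]]), 1), 90.2)
  expect_equal(sensitivity_specificity(10, 0, 5, 5)[["se"]], 1)
  expect_equal(balanced_accuracy(1, 0), 0.5)
  expect_equal(balanced_accuracy(1, 1), 1)
  expect_error(sensitivity_specificity(0, 0, 5, 5), class = "ccshock_error")
  expect_error(balanced_accuracy(1.2, 0.5), class = "ccshock_error")
})

test_that("ROC handles separation, ties, and the four-score worked example", {
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  r2 <- roc_curve(rep(0.5, 10), rep(c(1, 0), 5))
  expect_equal(r2$auc, 0.5)
  r3 <- roc_curve(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0))
  expect_equal(r3$auc, 0.75)
  expect_error(roc_curve(c(0.4, 0.5), c(1, 1)), class = "ccshock_error")
})

test_that("AUC equals the Mann-Whitney pair statistic on random score sets", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(6:40, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(c(1, 2, 7), 1))  # coarse rounding forces ties
    expect_equal(roc_curve(s, y)$auc, oracle_auc_pairs(s, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(19)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
    expect_equal(roc_curve(s, y)$auc, ref, tolerance = 1e-12)
  }
})

test_that("threshold selection matches exhaustive scanning with the documented tie-breaks", {
  set.seed(12)
  for (i in 1:30) {
    n <- sample(6:40, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(c(1, 2), 1))
    expect_equal(select_threshold(roc_curve(s, y)), oracle_best_threshold(s, y)$th)
  }
  # tie between (se .5, sp 1) and (se 1, sp .5): higher sensitivity wins
  expect_equal(select_threshold(roc_curve(c(0.8, 0.6, 0.4, 0.2), c(1, 0, 1, 0))), 0.4)
  # separable scores: the selected threshold achieves perfect balanced accuracy
  r <- roc_curve(c(0.9, 0.7, 0.3, 0.1), c(1, 1, 0, 0))
  th <- select_threshold(r)
  expect_equal(th, 0.7)
  pt <- r$points[r$points$threshold == th, ]
  expect_equal((pt$se + pt$sp) / 2, 1)
})

test_that("Wilson intervals bracket the point estimate inside [0, 1]", {
  ci <- wilson_ci(268, 301)
  expect_true(ci[["lower"]] < 268 / 301 && 268 / 301 < ci[["upper"]])
  expect_true(ci[["lower"]] >= 0 && ci[["upper"]] <= 1)
  expect_true(all(is.na(wilson_ci(0, 0))))
  wide <- wilson_ci(4, 5); narrow <- wilson_ci(400, 500)
  expect_lt(narrow[["upper"]] - narrow[["lower"]], wide[["upper"]] - wide[["lower"]])
  full <- wilson_ci(10, 10)
  expect_equal(full[["upper"]], 1)
})

test_that("stratified evaluation reproduces a manual confusion tally and conserves counts", {
  ds <- tiny_easy_dataset(6, seed = 401, snr = c(-8, 4))
  model <- build_model(cnn3_preset(), init_seed = 1)
  pthr <- 0.5
  rep <- evaluate_model(model, ds, pthr)
  p <- predict(model, ds)
  dec <- as.integer(p >= pthr)
  y <- as.integer(ds$manifest$shockable)
  expect_equal(unname(rep$counts),
               c(sum(dec & y), sum(!dec & y), sum(!dec & !y), sum(dec & !y)))
  expect_equal(rep$bac, (rep$se + rep$sp) / 2)
  # per-rhythm specificities tally against the manifest
  for (r in c("OR", "ASYSTOLE")) {
    sel <- ds$manifest$rhythm == r
    expect_equal(if (r == "OR") rep$sp_or else rep$sp_asystole,
                 sum(dec[sel] == 0) / sum(sel))
  }
  # strata conserve the overall counts
  expect_equal(sum(rep$by_snr$se$n), sum(y))
  expect_equal(sum(rep$by_snr$sp$n), sum(!y))
  expect_equal(sum(rep$by_snr$se$correct), rep$counts[["tp"]])
  expect_equal(sum(rep$by_snr$sp$correct), rep$counts[["tn"]])
  expect_equal(sum(rep$by_cc_rate$sp$n), sum(!y))
  expect_true(all(c("bin", "n", "correct", "rate", "ci_lower", "ci_upper")
                  %in% names(rep$by_snr$se)))
})

test_that("evaluation of a perfect decision rule reports unity metrics with CIs capped at 1", {
  ds <- tiny_easy_dataset(4, seed = 402)
  model <- build_model(cnn3_preset(), init_seed = 2)
  p <- predict(model, ds)
  y <- as.integer(ds$manifest$shockable)
  # pick a threshold only if this untrained model separates; otherwise force
  # separation by relabeling to match the scores (the report logic under test
  # is threshold application + tallying, not the model)
  ds$manifest$shockable <- p >= median(p)
  rep <- evaluate_model(model, ds, median(p))
  expect_equal(rep$se, 1)
  expect_equal(rep$sp, 1)
  expect_equal(rep$bac, 1)
  expect_true(all(rep$by_snr$se$ci_upper <= 1))
})

test_that("degenerate single-class training stops early and yields the constant behaviour", {
  ds <- tiny_easy_dataset(3, seed = 403)
  keep <- !ds$manifest$shockable
  ds0 <- structure(list(x = ds$x[keep, ], manifest = ds$manifest[keep, ],
                        meta = ds$meta), class = "ccecg_dataset")
  model <- build_model(hp_config(filters = c(5, 5), kernels = c(5, 5)), init_seed = 4)
  cfg <- train_config(max_epochs = 6, patience = 2, seed = 1)
  expect_warning(fit <- train_cnn(model, ds0, ds0, cfg))
  expect_true(fit$stopped_early)
  expect_lte(nrow(fit$history), 6)
  p <- predict(fit$model, ds0)
  expect_true(all(p < 0.5))  # learned the all-non-shockable majority
})

test_that("training history is bounded and the monitor improves on an easy task", {
  tr <- tiny_easy_dataset(6, seed = 404)
  va <- tiny_easy_dataset(3, seed = 405)
  model <- build_model(hp_config(filters = c(10, 10), kernels = c(10, 10)), init_seed = 5)
  cfg <- train_config(max_epochs = 8, patience = 7, seed = 2)
  fit <- train_cnn(model, tr, va, cfg)
  expect_lte(nrow(fit$history), 8)
  expect_true(all(c("epoch", "train_loss", "train_bac", "val_loss", "val_bac")
                  %in% names(fit$history)))
  expect_equal(fit$val_bac, max(fit$history$val_bac))
  expect_gte(fit$best_epoch, 1)
  expect_error(train_cnn(model, list(x = tr$x[0, ], y = integer(0)), va, cfg),
               class = "ccshock_error")
})
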