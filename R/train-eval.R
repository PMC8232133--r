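# Training protocol and evaluation suite: minority oversampling, Adam with
# binary cross-entropy and early stopping on validation balanced accuracy,
# then sensitivity/specificity/BAC, ROC with AUC, operating-threshold
# selection at maximal BAC, and reports stratified by artifact SNR and
# compression rate with Wilson confidence intervals.

#' Training configuration
#'
#' Defaults follow the study protocol: batches of 256, at most 400 epochs,
#' early stopping after 150 epochs without improvement of the validation
#' balanced accuracy, Adam with learning rate 0.001 and moment decays 0.9 /
#' 0.999, and shockable-minority oversampling factor 6.
#'
#' @param batch_size Batch size.
#' @param max_epochs Epoch budget.
#' @param patience Epochs without strict validation improvement before
#'   stopping (must be below `max_epochs`).
#' @param learning_rate,beta1,beta2 Adam settings.
#' @param oversample_factor Minority replication factor used by callers via
#'   [oversample_balance()].
#' @param seed Seed controlling shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 256, max_epochs = 400, patience = 150,
                         learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         oversample_factor = 6, seed = 1) {
  if (patience >= max_epochs) stop_ccshock("invalid_parameter", "patience must be below max_epochs")
  if (oversample_factor < 1) stop_ccshock("invalid_parameter", "oversample factor must be >= 1")
  structure(list(batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2,
                 oversample_factor = as.integer(oversample_factor),
                 seed = check_seed(seed)),
            class = "train_config")
}

#' Balance a dataset by minority oversampling
#'
#' Replicates the minority-class strips so that their final count equals
#' `factor` times the original count, then shuffles the rows. Replicated
#' strips get suffixed ids so manifest ids stay unique.
#'
#' @param dataset A `ccecg_dataset` containing both classes.
#' @param factor Integer replication factor (1 leaves counts unchanged).
#' @param seed Shuffle seed.
#' @return A `ccecg_dataset`.
#' @export
oversample_balance <- function(dataset, factor = 6, seed = 1) {
  if (!inherits(dataset, "ccecg_dataset")) stop_ccshock("invalid_input", "expected a ccecg_dataset")
  factor <- as.integer(factor)
  if (factor < 1) stop_ccshock("invalid_parameter", "factor must be >= 1")
  y <- dataset$manifest$shockable
  if (length(unique(y)) < 2) stop_ccshock("invalid_input", "dataset contains a single class")
  minority <- if (sum(y) <= sum(!y)) TRUE else FALSE
  idx_min <- which(y == minority)
  extra <- rep(idx_min, factor - 1L)
  idx <- c(seq_along(y), extra)
  man <- dataset$manifest[idx, , drop = FALSE]
  reps <- c(rep(0L, length(y)), rep(seq_len(factor - 1L), each = length(idx_min)))
  dup <- reps > 0L
  man$strip_id[dup] <- sprintf("%s#rep%d", man$strip_id[dup], reps[dup])
  ord <- withr::with_seed(check_seed(seed), sample.int(length(idx)))
  structure(list(x = dataset$x[idx, , drop = FALSE][ord, , drop = FALSE],
                 manifest = man[ord, , drop = FALSE],
                 meta = dataset$meta),
            class = "ccecg_dataset")
}

# Validation monitor: balanced accuracy at threshold 0.5; falls back to plain
# accuracy when only one class is present (BAC is undefined there).
monitor_metric <- function(p, y, thr = 0.5) {
  d <- as.integer(p >= thr)
  if (length(unique(y)) < 2) return(mean(d == y))
  se <- sum(d == 1 & y == 1) / sum(y == 1)
  sp <- sum(d == 0 & y == 0) / sum(y == 0)
  (se + sp) / 2
}

#' Train a model
#'
#' Minimizes the binary cross-entropy with Adam on shuffled batches. After
#' every epoch the full validation set is scored at threshold 0.5 and the
#' balanced accuracy recorded; the weights of the best-validation epoch are
#' retained, and training stops early once `patience` epochs pass without a
#' strict improvement. Training-set loss/BAC per epoch are aggregated over
#' the epoch's batches (scored with the weights in effect at each batch).
#'
#' @param model A [build_model()] object.
#' @param train_ds,val_ds `ccecg_dataset`s (or `list(x, y)`), both non-empty
#'   and labeled.
#' @param cfg A [train_config()].
#' @return List with `model` (best-epoch weights, marked trained), `history`
#'   (per-epoch data frame), `best_epoch`, `val_bac`, `val_se`, `val_sp`,
#'   and `stopped_early`.
#' @export
train_cnn <- function(model, train_ds, val_ds, cfg = train_config()) {
  tr <- as_xy(train_ds)
  va <- as_xy(val_ds)
  if (nrow(tr$x) == 0 || nrow(va$x) == 0) stop_ccshock("invalid_input", "empty dataset")
  if (length(unique(tr$y)) < 2) {
    # Degenerate single-class training: the monitor cannot improve, so the
    # early-stopping contract still produces a majority-behaviour model.
    warning("training set contains a single class; model will learn the constant behaviour")
  }
  n <- nrow(tr$x)
  state <- adam_init(model)
  params <- model$params
  best <- list(metric = -Inf, epoch = 0L, params = params)
  hist <- vector("list", cfg$max_epochs)
  stopped <- FALSE
  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- 0
      ep_p <- numeric(n)
      for (s in starts) {
        bi <- ord[s:min(s + cfg$batch_size - 1L, n)]
        model$params <- params
        fw <- cnn_forward(model, tr$x[bi, , drop = FALSE], training = TRUE)
        gr <- cnn_backward(model, fw$cache, fw$p, tr$y[bi])
        upd <- adam_step(params, gr, state, lr = cfg$learning_rate,
                         beta1 = cfg$beta1, beta2 = cfg$beta2)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + bce_loss(fw$p, tr$y[bi]) * length(bi)
        ep_p[s:min(s + cfg$batch_size - 1L, n)] <- fw$p
      }
      model$params <- params
      vp <- cnn_forward(model, va$x, training = FALSE)$p
      val_metric <- monitor_metric(vp, va$y)
      hist[[epoch]] <- data.frame(
        epoch = epoch,
        train_loss = ep_loss / n,
        train_bac = monitor_metric(ep_p, tr$y[ord]),
        val_loss = bce_loss(vp, va$y),
        val_bac = val_metric)
      if (val_metric > best$metric) {
        best <- list(metric = val_metric, epoch = epoch, params = params)
      }
      if (epoch - best$epoch >= cfg$patience) {
        stopped <- TRUE
        break
      }
    }
  })
  model$params <- best$params
  model$trained <- TRUE
  vp <- cnn_forward(model, va$x, training = FALSE)$p
  d <- as.integer(vp >= 0.5)
  two_class <- length(unique(va$y)) == 2
  list(model = model,
       history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]),
       best_epoch = best$epoch,
       val_bac = best$metric,
       val_se = if (two_class) sum(d == 1 & va$y == 1) / sum(va$y == 1) else NA_real_,
       val_sp = if (two_class) sum(d == 0 & va$y == 0) / sum(va$y == 0) else NA_real_,
       stopped_early = stopped)
}

#' Sensitivity and specificity from confusion counts
#'
#' `Se = TP / (TP + FN)` over shockable strips and `Sp = TN / (TN + FP)` over
#' non-shockable strips.
#'
#' @param tp,fn,tn,fp Confusion counts.
#' @return Named vector `c(se, sp)`.
#' @export
sensitivity_specificity <- function(tp, fn, tn, fp) {
  if (tp + fn <= 0 || tn + fp <= 0) {
    stop_ccshock("undefined_metric", "both classes must be represented")
  }
  c(se = tp / (tp + fn), sp = tn / (tn + fp))
}

#' Balanced accuracy
#'
#' Arithmetic mean of sensitivity and specificity; the selection score for
#' both model ranking and operating-threshold choice.
#'
#' @param se,sp Fractions in `[0, 1]`.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(se, sp) {
  if (any(c(se, sp) < 0) || any(c(se, sp) > 1)) {
    stop_ccshock("invalid_parameter", "se and sp must lie in [0, 1]")
  }
  (se + sp) / 2
}

#' ROC curve with trapezoidal AUC
#'
#' Sweeps every unique score as a threshold (decision shockable iff
#' `score >= threshold`, plus the degenerate all-negative point) and reports
#' `(threshold, se, sp)` per operating point. AUC is the trapezoidal integral
#' over (1 - sp, se), which equals the Mann-Whitney pair statistic with ties
#' counted one half.
#'
#' @param scores Numeric scores (higher = more shockable).
#' @param labels Logical/0-1 labels (TRUE = shockable).
#' @return List of class `roc_curve` with `points` (data frame) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as.logical(labels)
  if (length(scores) != length(y)) stop_ccshock("invalid_parameter", "scores and labels differ in length")
  P <- sum(y); N <- sum(!y)
  if (P == 0 || N == 0) stop_ccshock("undefined_metric", "ROC requires both classes")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yy <- y[o]
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(yy)[keep]
  fp <- cumsum(!yy)[keep]
  pts <- data.frame(threshold = c(Inf, s[keep]),
                    se = c(0, tp / P),
                    sp = c(1, 1 - fp / N))
  fpr <- 1 - pts$sp
  auc <- sum(diff(fpr) * (pts$se[-1] + pts$se[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points, AUC = %.3f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Select the operating threshold at maximal balanced accuracy
#'
#' Scans the ROC operating points for the threshold maximizing
#' `(se + sp) / 2`. Ties are broken towards higher sensitivity, then towards
#' the lower threshold.
#'
#' @param roc A [roc_curve()].
#' @return The selected probability threshold.
#' @export
select_threshold <- function(roc) {
  pts <- roc$points[is.finite(roc$points$threshold), , drop = FALSE]
  if (nrow(pts) == 0) stop_ccshock("invalid_input", "empty ROC curve")
  # round away last-ulp noise so mathematically tied points tie exactly
  bac <- round((pts$se + pts$sp) / 2, 10)
  ord <- order(-bac, -round(pts$se, 10), pts$threshold)
  pts$threshold[ord[1]]
}

#' Wilson 95% confidence interval for a proportion
#'
#' @param k Successes.
#' @param n Trials.
#' @param conf Confidence level.
#' @return Named vector `c(lower, upper)` (both `NA` when `n == 0`).
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

strat_table <- function(dec, y, bins, which_class) {
  # Per-bin Se (shockable strata) or Sp (non-shockable strata) with Wilson CIs.
  out <- NULL
  for (lv in levels(bins)) {
    sel <- !is.na(bins) & bins == lv & (y == which_class)
    n <- sum(sel)
    if (n == 0) next
    k <- if (which_class == 1) sum(dec[sel] == 1) else sum(dec[sel] == 0)
    ci <- wilson_ci(k, n)
    out <- rbind(out, data.frame(bin = lv, n = n, correct = k, rate = k / n,
                                 ci_lower = ci[["lower"]], ci_upper = ci[["upper"]]))
  }
  out
}

#' Evaluate a model on a labeled dataset
#'
#' Applies the fixed operating threshold (chosen on validation data, never on
#' the set being evaluated) and reports confusion counts, sensitivity over
#' shockable strips, specificity overall and per non-shockable rhythm, BAC,
#' the ROC with AUC, and sensitivity/specificity stratified by artifact SNR
#' level and compression-rate range with Wilson 95% confidence intervals.
#' Strata with no strips are omitted from the tables rather than reported as
#' zero; strips lacking an SNR or rate key are left out of the corresponding
#' table only.
#'
#' @param model A trained `cc_cnn`.
#' @param test_ds A `ccecg_dataset`.
#' @param pthr Operating threshold from validation.
#' @return An `eval_report` list.
#' @export
evaluate_model <- function(model, test_ds, pthr) {
  if (!inherits(test_ds, "ccecg_dataset")) stop_ccshock("invalid_input", "expected a ccecg_dataset")
  if (!is.numeric(pthr) || pthr <= 0 || pthr >= 1) {
    stop_ccshock("invalid_parameter", "`pthr` must lie strictly inside (0, 1)")
  }
  man <- test_ds$manifest
  y <- as.integer(man$shockable)
  p <- predict.cc_cnn(model, test_ds)
  dec <- as.integer(p >= pthr)
  tp <- sum(dec == 1 & y == 1); fn <- sum(dec == 0 & y == 1)
  tn <- sum(dec == 0 & y == 0); fp <- sum(dec == 1 & y == 0)
  sesp <- sensitivity_specificity(tp, fn, tn, fp)
  per_rhythm <- lapply(c(OR = "OR", ASYSTOLE = "ASYSTOLE"), function(r) {
    sel <- man$rhythm == r
    n <- sum(sel)
    if (n == 0) return(NULL)
    k <- sum(dec[sel] == 0)
    ci <- wilson_ci(k, n)
    list(n = n, tn = k, fp = n - k, sp = k / n,
         ci = c(ci[["lower"]], ci[["upper"]]))
  })
  roc <- roc_curve(p, y == 1)
  by_snr <- by_rate <- NULL
  if (any(!is.na(man$snr_db))) {
    ok <- !is.na(man$snr_db)
    bins <- snr_bin(man$snr_db[ok])
    by_snr <- list(se = strat_table(dec[ok], y[ok], bins, 1L),
                   sp = strat_table(dec[ok], y[ok], bins, 0L))
  }
  if (any(!is.na(man$cc_rate_cpm))) {
    ok <- !is.na(man$cc_rate_cpm)
    bins <- cc_rate_bin(man$cc_rate_cpm[ok])
    by_rate <- list(se = strat_table(dec[ok], y[ok], bins, 1L),
                    sp = strat_table(dec[ok], y[ok], bins, 0L))
  }
  structure(list(counts = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 se = sesp[["se"]], sp = sesp[["sp"]],
                 sp_or = if (is.null(per_rhythm$OR)) NA_real_ else per_rhythm$OR$sp,
                 sp_asystole = if (is.null(per_rhythm$ASYSTOLE)) NA_real_ else per_rhythm$ASYSTOLE$sp,
                 bac = balanced_accuracy(sesp[["se"]], sesp[["sp"]]),
                 pthr = pthr, per_rhythm = per_rhythm,
                 roc = roc, auc = roc$auc,
                 by_snr = by_snr, by_cc_rate = by_rate,
                 psh = p, decisions = dec),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  pct <- function(v) sprintf("%.1f%%", 100 * v)
  cat("<eval_report>\n")
  cat(sprintf("  Se  (Sh)        %s (%d/%d)\n", pct(x$se), x$counts[["tp"]],
              x$counts[["tp"]] + x$counts[["fn"]]))
  cat(sprintf("  Sp  (NSh)       %s (%d/%d)\n", pct(x$sp), x$counts[["tn"]],
              x$counts[["tn"]] + x$counts[["fp"]]))
  if (!is.na(x$sp_or)) cat(sprintf("  Sp  (OR)        %s\n", pct(x$sp_or)))
  if (!is.na(x$sp_asystole)) cat(sprintf("  Sp  (Asystole)  %s\n", pct(x$sp_asystole)))
  cat(sprintf("  BAC             %s at pthr = %.2f; AUC %.3f\n", pct(x$bac), x$pthr, x$auc))
  invisible(x)
}
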