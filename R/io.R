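# Dataset and model persistence: human-inspectable CSV samples with a JSON
# manifest for datasets, and JSON weight/sidecar files for models, so every
# artifact on disk is reconstructible and carries its provenance.

#' Write a dataset to disk
#'
#' Writes `samples.csv` (header row; `strip_id` then 1250 integer microvolt
#' columns) and `manifest.json` (per-strip provenance plus dataset-level
#' generator version and master seed).
#'
#' @param dataset A `ccecg_dataset`.
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  if (!inherits(dataset, "ccecg_dataset")) stop_ccshock("invalid_input", "expected a ccecg_dataset")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(strip_id = dataset$manifest$strip_id, dataset$x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("strip_id", sprintf("s%04d", seq_len(ncol(dataset$x))))
  utils::write.csv(df, file.path(path, "samples.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(meta = dataset$meta, strips = dataset$manifest),
                       file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dataset from disk
#'
#' Validates that the manifest and the sample table agree row for row and
#' that all samples are on the 5 uV integer grid; a truncated or inconsistent
#' pair raises a corrupt-dataset error.
#'
#' @param path Directory written by [write_dataset()].
#' @return A `ccecg_dataset`.
#' @export
read_dataset <- function(path) {
  fs <- file.path(path, "samples.csv")
  fm <- file.path(path, "manifest.json")
  if (!file.exists(fs) || !file.exists(fm)) {
    stop_ccshock("corrupt_dataset", "missing samples.csv or manifest.json under %s", path)
  }
  df <- tryCatch(utils::read.csv(fs, check.names = FALSE, stringsAsFactors = FALSE),
                 error = function(e) stop_ccshock("corrupt_dataset", "unreadable samples.csv: %s", conditionMessage(e)))
  man_all <- jsonlite::read_json(fm, simplifyVector = TRUE)
  manifest <- as.data.frame(man_all$strips, stringsAsFactors = FALSE)
  if (ncol(df) != STRIP_LEN + 1L) {
    stop_ccshock("corrupt_dataset", "expected %d sample columns, found %d", STRIP_LEN, ncol(df) - 1L)
  }
  if (nrow(df) != nrow(manifest)) {
    stop_ccshock("corrupt_dataset", "manifest rows (%d) do not match sample rows (%d)",
                 nrow(manifest), nrow(df))
  }
  if (!identical(df$strip_id, manifest$strip_id)) {
    stop_ccshock("corrupt_dataset", "strip ids differ between manifest and samples")
  }
  x <- as.matrix(df[, -1L, drop = FALSE])
  if (anyNA(x) || any(x != round(x))) stop_ccshock("format_error", "non-integer samples in CSV")
  storage.mode(x) <- "integer"
  if (any(x %% LSB_UV != 0L)) stop_ccshock("format_error", "samples are not multiples of %d uV", LSB_UV)
  dimnames(x) <- NULL
  for (col in c("snr_db", "target_snr_db", "cc_rate_cpm")) {
    if (!is.null(manifest[[col]])) manifest[[col]] <- as.numeric(manifest[[col]])
  }
  structure(list(x = x, manifest = manifest, meta = man_all$meta),
            class = "ccecg_dataset")
}

model_to_list <- function(model) {
  out <- list(hp = list(filters = model$hp$filters, kernels = model$hp$kernels,
                        mp = model$hp$mp, dropout = model$hp$dropout),
              input_len = model$input_len, lsb_uV = model$lsb_uV,
              init_seed = model$init_seed, trained = model$trained)
  if (!is.na(model$pthr)) out$pthr <- model$pthr
  out
}

#' Save a model with its configuration sidecar
#'
#' Writes `weights.json` (all weight arrays at full precision) and
#' `config.json` (architecture, seeds, training status, operating threshold),
#' so the saved model is reconstructible from text alone.
#'
#' @param model A `cc_cnn`.
#' @param path Directory to create/fill.
#' @param train_cfg Optional [train_config()] recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, train_cfg = NULL) {
  if (!inherits(model, "cc_cnn")) stop_ccshock("invalid_input", "expected a cc_cnn model")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  side <- model_to_list(model)
  if (!is.null(train_cfg)) side$train_config <- unclass(train_cfg)
  jsonlite::write_json(side, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  w <- list(W = lapply(model$params$W, function(m) list(dim = dim(m), data = as.numeric(m))),
            b = model$params$b, w_dense = model$params$w_dense,
            b_dense = model$params$b_dense)
  jsonlite::write_json(w, file.path(path, "weights.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' Rebuilds the model and verifies every weight array against the shapes the
#' sidecar configuration implies; a missing sidecar or a shape mismatch
#' raises an unloadable-model error.
#'
#' @param path Directory containing `config.json` and `weights.json`.
#' @return A `cc_cnn`.
#' @export
load_model <- function(path) {
  fc <- file.path(path, "config.json")
  fw <- file.path(path, "weights.json")
  if (!file.exists(fc)) stop_ccshock("unloadable_model", "missing sidecar config.json under %s", path)
  if (!file.exists(fw)) stop_ccshock("unloadable_model", "missing weights.json under %s", path)
  side <- jsonlite::read_json(fc, simplifyVector = TRUE)
  hp <- hp_config(side$hp$filters, side$hp$kernels, check_trend = FALSE)
  wj <- jsonlite::read_json(fw, simplifyVector = TRUE)
  f_prev <- c(1L, hp$filters[-hp$n_blocks])
  W <- vector("list", hp$n_blocks)
  b <- vector("list", hp$n_blocks)
  for (i in seq_len(hp$n_blocks)) {
    wi <- if (is.data.frame(wj$W)) wj$W[i, ] else wj$W[[i]]
    dims <- unlist(wi$dim)
    dat <- unlist(wi$data)
    want <- c(hp$kernels[i] * f_prev[i], hp$filters[i])
    if (!identical(as.integer(dims), as.integer(want)) || length(dat) != prod(want)) {
      stop_ccshock("unloadable_model", "block %d weight shape does not match the sidecar architecture", i)
    }
    W[[i]] <- matrix(dat, dims[1], dims[2])
    bi <- if (is.list(wj$b)) unlist(wj$b[[i]]) else wj$b[[i]]
    if (length(bi) != hp$filters[i]) {
      stop_ccshock("unloadable_model", "block %d bias length does not match the sidecar architecture", i)
    }
    b[[i]] <- as.numeric(bi)
  }
  wd <- as.numeric(unlist(wj$w_dense))
  if (length(wd) != hp$filters[hp$n_blocks]) {
    stop_ccshock("unloadable_model", "dense weight length does not match the sidecar architecture")
  }
  structure(list(hp = hp,
                 params = list(W = W, b = b, w_dense = wd,
                               b_dense = as.numeric(wj$b_dense)),
                 trace = shape_trace(hp, side$input_len),
                 input_len = as.integer(side$input_len), lsb_uV = side$lsb_uV,
                 init_seed = side$init_seed,
                 trained = isTRUE(side$trained),
                 pthr = if (is.null(side$pthr) || !is.numeric(side$pthr))
                   NA_real_ else as.numeric(side$pthr)),
            class = "cc_cnn")
}
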