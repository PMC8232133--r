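# Parameterized fully convolutional architecture for 10 s single-lead strips:
# N blocks of (valid-padding 1D convolution -> ReLU -> max-pool 2 -> dropout),
# then global max pooling over time and a one-unit sigmoid dense classifier
# producing the shock probability pSh. The exact temporal-shape calculus and
# the closed-form trainable-parameter count are the contracts every built
# model must satisfy.

F_GRID <- c(5L, 10L, 15L, 20L, 25L, 30L, 40L, 50L)
K_GRID <- c(5L, 10L, 15L, 20L, 25L, 30L, 40L, 50L, 60L, 70L, 85L, 100L)
PARAMS_CAP <- 250000L
INPUT_LEN <- 1250L

#' Hyperparameter configuration of one CNN candidate
#'
#' Defines the depth `N` (2-7 blocks) and per-block filter counts and kernel
#' sizes. Pool size (2) and dropout rate (0.3) are fixed across the search.
#' Filters and kernels must come from the search grids and each vector must
#' follow one of the seven allowed depth trends (see [validate_trend()]);
#' the configuration must be shape-feasible for a 1250-sample input and stay
#' within the 250,000 trainable-parameter budget.
#'
#' @param filters Integer vector of filter counts, one per block, from
#'   `{5, 10, 15, 20, 25, 30, 40, 50}`.
#' @param kernels Integer vector of kernel sizes, one per block, from
#'   `{5, 10, 15, 20, 25, 30, 40, 50, 60, 70, 85, 100}`.
#' @param check_trend Enforce the depth-trend constraint (disable only for
#'   ad-hoc architectures outside the search space).
#' @return An object of class `hp_config`.
#' @export
hp_config <- function(filters, kernels, check_trend = TRUE) {
  filters <- as.integer(filters)
  kernels <- as.integer(kernels)
  n <- length(filters)
  if (length(kernels) != n) stop_ccshock("invalid_parameter", "filters and kernels must have equal length")
  if (n < 2 || n > 7) stop_ccshock("invalid_parameter", "depth must be between 2 and 7 blocks")
  if (!all(filters %in% F_GRID)) stop_ccshock("invalid_parameter", "filter counts must come from the search grid")
  if (!all(kernels %in% K_GRID)) stop_ccshock("invalid_parameter", "kernel sizes must come from the search grid")
  if (check_trend && !(validate_trend(filters) && validate_trend(kernels))) {
    stop_ccshock("invalid_parameter", "filters and kernels must each follow an allowed depth trend")
  }
  hp <- structure(list(n_blocks = n, filters = filters, kernels = kernels,
                       mp = 2L, dropout = 0.3),
                  class = "hp_config")
  shape_trace(hp)  # errors if shape-infeasible
  if (count_params(hp) > PARAMS_CAP) {
    stop_ccshock("invalid_parameter", "configuration exceeds the %d trainable-parameter budget", PARAMS_CAP)
  }
  hp
}

#' @export
print.hp_config <- function(x, ...) {
  cat(sprintf("<hp_config> N=%d, filters@kernels: %s; %s params\n", x$n_blocks,
              paste(sprintf("%d@%d", x$filters, x$kernels), collapse = ", "),
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Temporal shape trace of a configuration
#'
#' Propagates the input length through every block: a valid-padding
#' convolution with kernel `K_i` maps length `L` to `L - K_i + 1`, and the
#' non-overlapping max-pool of size 2 to `floor((L - K_i + 1) / 2)` (a
#' trailing odd sample is dropped). Errors if any convolution output would be
#' shorter than one sample.
#'
#' @param hp An [hp_config()].
#' @param input_len Input length in samples (1250 for a 10 s strip at 125 Hz).
#' @return Data frame with one row per block (`block`, `in_len`, `conv_len`,
#'   `pool_len`, `filters`, `kernel`); the attribute `gmp_len` holds the
#'   final feature count.
#' @export
shape_trace <- function(hp, input_len = INPUT_LEN) {
  l <- as.integer(input_len)
  rows <- vector("list", hp$n_blocks)
  for (i in seq_len(hp$n_blocks)) {
    conv_len <- l - hp$kernels[i] + 1L
    if (conv_len < 1L) {
      stop_ccshock("shape_infeasible",
                   "block %d: input length %d is shorter than kernel %d", i, l, hp$kernels[i])
    }
    pool_len <- conv_len %/% 2L
    if (pool_len < 1L) stop_ccshock("shape_infeasible", "block %d pools to zero length", i)
    rows[[i]] <- data.frame(block = i, in_len = l, conv_len = conv_len,
                            pool_len = pool_len, filters = hp$filters[i],
                            kernel = hp$kernels[i])
    l <- pool_len
  }
  out <- do.call(rbind, rows)
  attr(out, "gmp_len") <- hp$filters[hp$n_blocks]
  out
}

#' Closed-form trainable parameter count
#'
#' `sum_i F_i * (K_i * F_(i-1) + 1) + (F_N + 1)` with `F_0 = 1` for the
#' single-lead input: each block holds `K_i * F_(i-1)` kernel weights plus one
#' bias per filter, and the dense head holds one weight per final filter plus
#' its bias.
#'
#' @param hp An [hp_config()].
#' @return Integer parameter count.
#' @export
count_params <- function(hp) {
  f_prev <- c(1L, hp$filters[-hp$n_blocks])
  sum(hp$filters * (hp$kernels * f_prev + 1L)) + hp$filters[hp$n_blocks] + 1L
}

# Per-block parameter counts plus the dense head (used for reporting).
count_params_by_block <- function(hp) {
  f_prev <- c(1L, hp$filters[-hp$n_blocks])
  c(hp$filters * (hp$kernels * f_prev + 1L), dense = hp$filters[hp$n_blocks] + 1L)
}

#' The selected three-block network preset
#'
#' The best architecture from the trend-constrained random search: three
#' blocks with filters (5, 25, 50) and kernels (10, 20, 20), 27,681 trainable
#' parameters, feature shapes (620, 5) -> (300, 25) -> (140, 50) and a
#' 50-feature global-max-pool output. The published description of this
#' network prints a first-block kernel of 5, which is inconsistent with its
#' own printed parameter count (55) and shape chain (1250 -> 1241 -> 620);
#' only K = (10, 20, 20) satisfies both, so that reading is used here.
#'
#' @return An [hp_config()].
#' @export
cnn3_preset <- function() {
  hp_config(filters = c(5L, 25L, 50L), kernels = c(10L, 20L, 20L))
}

#' Build a model from a configuration
#'
#' Instantiates the network weights: per-block convolution kernels (stored as
#' `(K_i * F_(i-1)) x F_i` matrices) and biases, plus the dense head. Kernel
#' and dense weights are initialized uniformly on `[-0.05, 0.05]`, biases at
#' zero. The model ingests raw strips kept at their native 5 uV/LSB
#' resolution (samples are divided by 5 so one unit is one LSB; no other
#' normalization is applied, preserving absolute amplitude information that
#' separates asystole from coarse VF).
#'
#' @param hp An [hp_config()].
#' @param init_seed Integer seed for weight initialization.
#' @param input_len Input length in samples.
#' @return An object of class `cc_cnn`.
#' @export
build_model <- function(hp, init_seed = 1, input_len = INPUT_LEN) {
  if (!inherits(hp, "hp_config")) stop_ccshock("invalid_parameter", "`hp` must be an hp_config")
  init_seed <- check_seed(init_seed)
  trace <- shape_trace(hp, input_len)
  f_prev <- c(1L, hp$filters[-hp$n_blocks])
  params <- withr::with_seed(init_seed, {
    p <- list(W = vector("list", hp$n_blocks), b = vector("list", hp$n_blocks))
    for (i in seq_len(hp$n_blocks)) {
      p$W[[i]] <- matrix(runif(hp$kernels[i] * f_prev[i] * hp$filters[i], -0.05, 0.05),
                         hp$kernels[i] * f_prev[i], hp$filters[i])
      p$b[[i]] <- numeric(hp$filters[i])
    }
    p$w_dense <- runif(hp$filters[hp$n_blocks], -0.05, 0.05)
    p$b_dense <- 0
    p
  })
  structure(list(hp = hp, params = params, trace = trace,
                 input_len = as.integer(input_len), lsb_uV = LSB_UV,
                 init_seed = init_seed, trained = FALSE, pthr = NA_real_),
            class = "cc_cnn")
}

#' Trainable parameter count reported by the model itself
#'
#' Counts the elements of every weight array actually allocated in the model,
#' independently of the closed-form calculus in [count_params()].
#'
#' @param model A [build_model()] object.
#' @return Integer count.
#' @export
n_trainable <- function(model) {
  sum(vapply(model$params$W, length, 0L)) +
    sum(vapply(model$params$b, length, 0L)) +
    length(model$params$w_dense) + 1L
}

#' @export
print.cc_cnn <- function(x, ...) {
  cat(sprintf("<cc_cnn> N=%d (%s), %s trainable params, input %d samples%s\n",
              x$hp$n_blocks,
              paste(sprintf("%d@%d", x$hp$filters, x$hp$kernels), collapse = ", "),
              format(n_trainable(x), big.mark = ","), x$input_len,
              if (isTRUE(x$trained)) ", trained" else ""))
  invisible(x)
}

#' Shock probability for a batch of strips
#'
#' Inference forward pass (dropout inactive). Accepts a dataset, a matrix of
#' microvolt samples (one strip per row), or a single [ecg_strip()].
#'
#' @param object A `cc_cnn` model.
#' @param newdata Input strips.
#' @param ... Unused.
#' @return Numeric vector of probabilities `pSh` in `[0, 1]`.
#' @export
predict.cc_cnn <- function(object, newdata, ...) {
  x <- strip_matrix(newdata)
  cnn_forward(object, x, training = FALSE)$p
}

strip_matrix <- function(newdata) {
  if (inherits(newdata, "ccecg_dataset")) return(newdata$x)
  if (inherits(newdata, "ecg_strip")) return(matrix(newdata$samples, 1))
  if (is.numeric(newdata) && is.null(dim(newdata))) return(matrix(newdata, 1))
  as.matrix(newdata)
}

#' Classify strips as shockable or not
#'
#' A strip is called shockable (`"Sh"`) when `pSh >= pthr`; the threshold
#' boundary itself advises a shock.
#'
#' @param model A `cc_cnn` model.
#' @param strips Input strips (dataset, matrix, or single strip).
#' @param pthr Decision threshold in (0, 1).
#' @return Character vector of `"Sh"` / `"NSh"` with attribute `psh`.
#' @export
classify <- function(model, strips, pthr) {
  if (!is.numeric(pthr) || length(pthr) != 1 || pthr <= 0 || pthr >= 1) {
    stop_ccshock("invalid_parameter", "`pthr` must lie strictly inside (0, 1)")
  }
  p <- predict.cc_cnn(model, strips)
  structure(ifelse(p >= pthr, "Sh", "NSh"), psh = p)
}

#' Global-max-pool features with classifier-weight ordering
#'
#' Returns the final feature vector (one global temporal maximum per last-
#' block filter) together with the permutation that sorts the dense-layer
#' weights from most negative to most positive. Under the sigmoid head,
#' negative-weight filters push the decision towards non-shockable and
#' positive-weight filters towards shockable, so the ordered view groups
#' NSh-supporting features before Sh-supporting ones.
#'
#' @param model A `cc_cnn` model.
#' @param strip A single [ecg_strip()], numeric vector, or one-row matrix.
#' @return List with `gmp` (raw feature vector, length `F_N`), `order`
#'   (permutation of filters by ascending classifier weight), `gmp_ordered`,
#'   `weights_ordered`, and `n_nsh` (number of negative-weight filters).
#' @export
extract_gmp_features <- function(model, strip) {
  x <- strip_matrix(strip)
  if (nrow(x) != 1) stop_ccshock("invalid_parameter", "feature extraction expects a single strip")
  fw <- cnn_forward(model, x, training = FALSE, keep = TRUE)
  g <- as.numeric(fw$gmp)
  ord <- order(model$params$w_dense)
  list(gmp = g, order = ord, gmp_ordered = g[ord],
       weights_ordered = model$params$w_dense[ord],
       n_nsh = sum(model$params$w_dense < 0))
}

#' Per-layer activations of one strip
#'
#' Exposes every block's post-ReLU convolution output and pooled output
#' (dropout is inactive at inference, so pooled and block outputs coincide),
#' for inspecting what the filters respond to.
#'
#' @param model A `cc_cnn` model.
#' @param strip A single strip.
#' @return List with per-block `conv` (`conv_len x F_i`) and `pool`
#'   (`pool_len x F_i`) matrices, plus `gmp` and `psh`.
#' @export
layer_activations <- function(model, strip) {
  x <- strip_matrix(strip)
  if (nrow(x) != 1) stop_ccshock("invalid_parameter", "activation inspection expects a single strip")
  fw <- cnn_forward(model, x, training = FALSE, keep = TRUE)
  list(conv = fw$conv_acts, pool = fw$pool_acts, gmp = as.numeric(fw$gmp), psh = fw$p)
}
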