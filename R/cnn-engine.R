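# Numerical engine for the fully convolutional network: valid-padding 1D
# convolution realized as a single indexed gather (im2col) followed by one
# BLAS matrix product per block, with the exact reverse pass. All state lives
# in plain R arrays, so a run is reproducible bit for bit given its seeds.
#
# Layout conventions (chosen so no array transposition is ever needed):
#   activations  P : matrix (L*B, C), row index (j, b) = j + (b-1)*L,
#                    one column per channel/filter
#   im2col       M : matrix (Lc*B, K*C), column index (c-1)*K + k
#                    (kernel tap fastest), Lc = L - K + 1
#   conv weights W : matrix (K*C, F), rows matching the im2col column order
# With column order (c-1)*K + k, the gather P[v, ] with v the concatenated
# per-tap row indices lands in im2col layout by a plain dim<-, copying each
# window element exactly once.

# Cache of gather/pool index vectors keyed by (L, K or Lc, B): index
# construction is pure arithmetic, but batches of fixed shape recur every
# epoch, so reuse pays.
.idx_cache <- new.env(parent = emptyenv())

gather_idx <- function(L, K, B) {
  key <- sprintf("g%d_%d_%d", L, K, B)
  v <- .idx_cache[[key]]
  if (is.null(v)) {
    Lc <- L - K + 1L
    base <- rep.int(seq_len(Lc), B) + rep((seq_len(B) - 1L) * L, each = Lc)
    v <- rep.int(base, K) + rep(0:(K - 1L), each = Lc * B)
    .idx_cache[[key]] <- v
  }
  v
}

# Odd-member rows of non-overlapping pool pairs in a (Lc*B, F) matrix.
pool_idx <- function(Lc, B) {
  key <- sprintf("p%d_%d", Lc, B)
  io <- .idx_cache[[key]]
  if (is.null(io)) {
    Lp <- Lc %/% 2L
    io <- rep(seq(1L, 2L * Lp, by = 2L), times = B) + rep((seq_len(B) - 1L) * Lc, each = Lp)
    .idx_cache[[key]] <- io
  }
  io
}

# Gather sliding windows: P (L*B, C) -> (Lc*B, K*C).
im2col <- function(P, L, C, B, K) {
  M <- P[gather_idx(L, K, B), , drop = FALSE]
  dim(M) <- c((L - K + 1L) * B, K * C)
  M
}

# Scatter-add the adjoint of im2col: dM (Lc*B, K*C) -> (L*B, C).
col2im_add <- function(dM, L, C, B, K) {
  Lc <- L - K + 1L
  dP <- matrix(0, L * B, C)
  base <- gather_idx(L, K, B)[seq_len(Lc * B)]
  for (k in seq_len(K)) {
    sel <- seq.int(k, K * C, by = K)
    dP[base + (k - 1L), ] <- dP[base + (k - 1L), , drop = FALSE] +
      dM[, sel, drop = FALSE]
  }
  dP
}

add_bias <- function(Z, b) {
  for (f in seq_along(b)) Z[, f] <- Z[, f] + b[f]
  Z
}

# Forward pass. X: (B, input_len) microvolt matrix. When `training`, dropout
# is active (inverted scaling) and the caches needed by cnn_backward are
# kept. When `keep`, per-block activations (single strip) are recorded.
cnn_forward <- function(model, X, training = FALSE, keep = FALSE) {
  hp <- model$hp
  B <- nrow(X)
  if (ncol(X) != model$input_len) {
    stop_ccshock("invalid_parameter", "input must have %d samples per strip", model$input_len)
  }
  P <- matrix(as.vector(t(X)) / model$lsb_uV, ncol = 1L)
  L <- model$input_len
  n_blocks <- hp$n_blocks
  cache <- if (training) list(blocks = vector("list", n_blocks)) else NULL
  conv_acts <- pool_acts <- if (keep) vector("list", n_blocks) else NULL
  for (i in seq_len(n_blocks)) {
    C <- ncol(P)
    K <- hp$kernels[i]
    Lc <- L - K + 1L
    Lp <- Lc %/% 2L
    M <- im2col(P, L, C, B, K)
    Z <- add_bias(M %*% model$params$W[[i]], model$params$b[[i]])
    relu_mask <- Z > 0
    Z <- Z * relu_mask
    io <- pool_idx(Lc, B)
    P1 <- Z[io, , drop = FALSE]
    P2 <- Z[io + 1L, , drop = FALSE]
    take1 <- P1 >= P2
    P <- pmax(P1, P2)
    drop_mask <- NULL
    if (training && hp$dropout > 0) {
      drop_mask <- runif(length(P)) >= hp$dropout
      P <- P * drop_mask / (1 - hp$dropout)
    }
    if (training) {
      cache$blocks[[i]] <- list(M = M, relu_mask = relu_mask, take1 = take1,
                                drop_mask = drop_mask, L = L, C = C, K = K,
                                Lc = Lc, Lp = Lp, io = io)
    }
    if (keep) {
      conv_acts[[i]] <- Z
      pool_acts[[i]] <- P
    }
    L <- Lp
  }
  Fn <- hp$filters[n_blocks]
  Lp <- L
  G <- matrix(0, B, Fn)
  amax <- matrix(0L, B, Fn)
  for (f in seq_len(Fn)) {
    V <- P[, f]
    dim(V) <- c(Lp, B)
    j <- max.col(t(V), ties.method = "first")
    amax[, f] <- j
    G[, f] <- V[cbind(j, seq_len(B))]
  }
  xlin <- as.numeric(G %*% model$params$w_dense) + model$params$b_dense
  p <- stats::plogis(xlin)
  out <- list(p = p, gmp = G)
  if (training) {
    cache$G <- G; cache$amax <- amax; cache$Lp_final <- Lp; cache$B <- B
    out$cache <- cache
  }
  if (keep) {
    out$conv_acts <- conv_acts; out$pool_acts <- pool_acts
  }
  out
}

# Reverse pass for one batch. Returns gradients in the same structure as
# model$params. `p` and `y` are the forward probabilities and 0/1 labels;
# the loss is the batch mean of the binary cross-entropy, so dL/dx = (p-y)/B
# at the sigmoid input.
cnn_backward <- function(model, cache, p, y) {
  hp <- model$hp
  B <- cache$B
  n_blocks <- hp$n_blocks
  gW <- vector("list", n_blocks)
  gb <- vector("list", n_blocks)
  dx <- (p - y) / B
  gw_dense <- as.numeric(crossprod(cache$G, dx))
  gb_dense <- sum(dx)
  Fn <- hp$filters[n_blocks]
  dG <- outer(dx, model$params$w_dense)            # (B, Fn)
  Lp <- cache$Lp_final
  dP <- matrix(0, Lp * B, Fn)
  rows <- cache$amax + matrix((seq_len(B) - 1L) * Lp, B, Fn)
  dP[cbind(as.vector(rows), rep(seq_len(Fn), each = B))] <- as.vector(dG)
  for (i in rev(seq_len(n_blocks))) {
    blk <- cache$blocks[[i]]
    if (!is.null(blk$drop_mask)) {
      dP <- dP * blk$drop_mask / (1 - hp$dropout)
    }
    dZ <- matrix(0, blk$Lc * B, hp$filters[i])
    dZ[blk$io, ] <- dP * blk$take1
    dZ[blk$io + 1L, ] <- dP * (!blk$take1)
    dZ <- dZ * blk$relu_mask
    gW[[i]] <- crossprod(blk$M, dZ)
    gb[[i]] <- colSums(dZ)
    if (i > 1L) {
      dM <- tcrossprod(dZ, model$params$W[[i]])    # (Lc*B, K*C)
      dP <- col2im_add(dM, blk$L, blk$C, B, blk$K)
    }
  }
  list(W = gW, b = gb, w_dense = gw_dense, b_dense = gb_dense)
}

# Flat views of the parameter/gradient structure, used by the optimizer.
param_names <- function(hp) {
  c(sprintf("W%d", seq_len(hp$n_blocks)), sprintf("b%d", seq_len(hp$n_blocks)),
    "w_dense", "b_dense")
}

get_param <- function(params, nm) {
  if (nm == "w_dense") return(params$w_dense)
  if (nm == "b_dense") return(params$b_dense)
  i <- as.integer(substring(nm, 2))
  if (startsWith(nm, "W")) params$W[[i]] else params$b[[i]]
}

set_param <- function(params, nm, value) {
  if (nm == "w_dense") params$w_dense <- value
  else if (nm == "b_dense") params$b_dense <- value
  else {
    i <- as.integer(substring(nm, 2))
    if (startsWith(nm, "W")) params$W[[i]] <- value else params$b[[i]] <- value
  }
  params
}

adam_init <- function(model) {
  nms <- param_names(model$hp)
  st <- list(t = 0L, m = list(), v = list())
  for (nm in nms) {
    z <- get_param(model$params, nm)
    st$m[[nm]] <- z * 0
    st$v[[nm]] <- z * 0
  }
  st
}

adam_step <- function(params, grads, state, lr = 0.001, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    g <- get_param(grads, nm)
    m <- beta1 * state$m[[nm]] + (1 - beta1) * g
    v <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    upd <- lr * (m / bc1) / (sqrt(v / bc2) + eps)
    params <- set_param(params, nm, get_param(params, nm) - upd)
  }
  list(params = params, state = state)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
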