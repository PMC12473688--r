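# Neural-network engine for the sequence classifier.
#
# Implements the forward and backward passes of a 1-D CNN + bidirectional
# LSTM stack directly on BLAS-backed matrix operations. Batches are laid
# out time-major: a batch of B sequences of length T with C channels is a
# (B*T) x C matrix whose row (t-1)*B + b is sample b at time t, so one
# GEMM per time step covers the whole batch and shifting the time index is
# a B-row shift. The backward pass is verified against numerical gradients
# in the test suite.

# ---- time-major helpers ----------------------------------------------------

# Shift a time-major matrix by `s` steps: s = +1 gives the value at t-1
# (zeros at t = 1), s = -1 the value at t+1 (zeros at t = T).
shift_tm <- function(A, B, s) {
  out <- matrix(0, nrow(A), ncol(A))
  n <- nrow(A)
  if (s == 1L) out[(B + 1L):n, ] <- A[1L:(n - B), ]
  else if (s == -1L) out[1L:(n - B), ] <- A[(B + 1L):n, ]
  else stop("s must be +1 or -1")
  out
}

# Reverse the time axis of a time-major matrix.
rev_tm <- function(A, B) {
  Tn <- nrow(A) %/% B
  idx <- rep((Tn - 1L):0L, each = B) * B + seq_len(B)
  A[idx, , drop = FALSE]
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

# ---- conv1d (kernel 3, same padding) ---------------------------------------

conv1d_init <- function(cin, cout) {
  list(W1 = glorot(cin, cout), W2 = glorot(cin, cout),
       W3 = glorot(cin, cout), b = rep(0, cout))
}

conv1d_forward <- function(p, A, B) {
  Z <- shift_tm(A, B, 1L) %*% p$W1 + A %*% p$W2 + shift_tm(A, B, -1L) %*% p$W3
  Z <- sweep(Z, 2L, p$b, "+")
  list(Z = Z)
}

conv1d_backward <- function(p, A, dZ, B) {
  list(
    grads = list(W1 = crossprod(shift_tm(A, B, 1L), dZ),
                 W2 = crossprod(A, dZ),
                 W3 = crossprod(shift_tm(A, B, -1L), dZ),
                 b = colSums(dZ)),
    dA = shift_tm(dZ, B, -1L) %*% t(p$W1) + dZ %*% t(p$W2) +
      shift_tm(dZ, B, 1L) %*% t(p$W3)
  )
}

# ---- LSTM (one direction) --------------------------------------------------

lstm_init <- function(din, H) {
  b <- rep(0, 4 * H)
  b[(H + 1L):(2L * H)] <- 1          # forget-gate bias starts open
  list(W = glorot(din, 4 * H), U = glorot(H, 4 * H), b = b)
}

# X time-major (B*T) x D. Returns hidden states time-major (B*T) x H plus
# the cached gate activations needed for backprop. The time loop runs in
# the compiled kernel (src/lstm_kernels.cpp); the projections are BLAS
# calls either way.
lstm_forward <- function(p, X, B) {
  r <- .lstm_fwd_cpp(X, p$W, p$U, p$b, as.integer(B))
  list(H = r$H, cache = list(X = X, r = r, B = as.integer(B)))
}

# dH: upstream gradient on the hidden states, time-major (zeros where the
# consumer only used the final state).
lstm_backward <- function(p, cache, dH) {
  r <- cache$r
  bk <- .lstm_bwd_cpp(cache$X, p$W, p$U, r$Gi, r$Gf, r$Gg, r$Go, r$Cs, r$Tc,
                      r$Hc, dH, cache$B)
  list(grads = list(W = bk$dW, U = bk$dU, b = as.numeric(bk$db)),
       dX = bk$dX)
}

# Bidirectional wrapper. `return_sequences` concatenates per-step states of
# both directions; otherwise the output is the concatenated final states
# (forward at t = T, backward at t = 1), one row per sample.
bilstm_forward <- function(p, X, B, return_sequences) {
  fw <- lstm_forward(p$fwd, X, B)
  bw <- lstm_forward(p$bwd, rev_tm(X, B), B)
  if (return_sequences) {
    out <- cbind(fw$H, rev_tm(bw$H, B))
  } else {
    n <- nrow(X)
    last <- (n - B + 1L):n
    out <- cbind(fw$H[last, , drop = FALSE], bw$H[last, , drop = FALSE])
  }
  list(out = out, fw = fw, bw = bw)
}

bilstm_backward <- function(p, fwres, dOut, B, return_sequences) {
  H <- ncol(fwres$fw$H)
  n <- nrow(fwres$fw$H)
  if (return_sequences) {
    dHf <- dOut[, 1L:H, drop = FALSE]
    dHb <- rev_tm(dOut[, (H + 1L):(2L * H), drop = FALSE], B)
  } else {
    dHf <- matrix(0, n, H); dHb <- matrix(0, n, H)
    last <- (n - B + 1L):n
    dHf[last, ] <- dOut[, 1L:H]
    dHb[last, ] <- dOut[, (H + 1L):(2L * H)]
  }
  bf <- lstm_backward(p$fwd, fwres$fw$cache, dHf)
  bb <- lstm_backward(p$bwd, fwres$bw$cache, dHb)
  list(grads = list(fwd = bf$grads, bwd = bb$grads),
       dX = bf$dX + rev_tm(bb$dX, B))
}

# ---- full network ----------------------------------------------------------

net_init <- function(config) {
  set.seed(config$seed)
  cf <- config$conv_filters
  cin <- c(config$n_channels, cf[-length(cf)])
  convs <- mapply(conv1d_init, cin, cf, SIMPLIFY = FALSE)
  names(convs) <- paste0("conv", seq_along(convs))
  l1 <- list(fwd = lstm_init(cf[length(cf)], config$lstm1_units),
             bwd = lstm_init(cf[length(cf)], config$lstm1_units))
  l2 <- list(fwd = lstm_init(2L * config$lstm1_units, config$lstm2_units),
             bwd = lstm_init(2L * config$lstm1_units, config$lstm2_units))
  dense <- list(W = glorot(2L * config$lstm2_units, config$n_classes),
                b = rep(0, config$n_classes))
  list(convs = convs, lstm1 = l1, lstm2 = l2, dense = dense)
}

# Forward pass; X time-major (B*T) x C. Returns class probabilities (B x K)
# and, when `training`, the caches for the backward pass.
net_forward <- function(params, X, B, training = FALSE) {
  caches <- list(conv = list())
  A <- X
  for (li in seq_along(params$convs)) {
    cf <- conv1d_forward(params$convs[[li]], A, B)
    Z <- cf$Z
    R <- pmax(Z, 0)
    caches$conv[[li]] <- list(A_in = A, relu_mask = Z > 0)
    A <- R
  }
  r1 <- bilstm_forward(params$lstm1, A, B, return_sequences = TRUE)
  r2 <- bilstm_forward(params$lstm2, r1$out, B, return_sequences = FALSE)
  logits <- sweep(r2$out %*% params$dense$W, 2L, params$dense$b, "+")
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  if (!training) return(list(probs = probs))
  caches$r1 <- r1; caches$r2 <- r2; caches$dense_in <- r2$out
  list(probs = probs, caches = caches)
}

# Cross-entropy loss + full backward pass. y: integer class labels 1..K.
net_backward <- function(params, fw, y, B) {
  probs <- fw$probs
  K <- ncol(probs)
  eps <- 1e-12
  loss <- -mean(log(probs[cbind(seq_len(B), y)] + eps))
  dlogits <- probs
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  dlogits <- dlogits / B

  gdense <- list(W = crossprod(fw$caches$dense_in, dlogits),
                 b = colSums(dlogits))
  dr2 <- dlogits %*% t(params$dense$W)
  b2 <- bilstm_backward(params$lstm2, fw$caches$r2, dr2, B,
                        return_sequences = FALSE)
  b1 <- bilstm_backward(params$lstm1, fw$caches$r1, b2$dX, B,
                        return_sequences = TRUE)
  dA <- b1$dX
  gconvs <- vector("list", length(params$convs))
  names(gconvs) <- names(params$convs)
  for (li in length(params$convs):1L) {
    cc <- fw$caches$conv[[li]]
    dZ <- dA * cc$relu_mask
    cb <- conv1d_backward(params$convs[[li]], cc$A_in, dZ, B)
    gconvs[[li]] <- cb$grads
    dA <- cb$dA
  }
  list(loss = loss,
       grads = list(convs = gconvs,
                    lstm1 = b1$grads, lstm2 = b2$grads, dense = gdense))
}

# ---- Adam over nested parameter lists --------------------------------------

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (k in names(p)) {
    v <- p[[k]]
    key <- paste0(prefix, k)
    if (is.list(v)) out <- c(out, flatten_params(v, paste0(key, ".")))
    else out[[key]] <- v
  }
  out
}

# Flat lists from flatten_params share names, so the update walks them in
# lock-step and writes back through the same paths. The fused numeric loop
# runs in the compiled kernel; the moment estimates are updated in place
# (they are owned solely by the training loop).
adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, clipnorm = 5) {
  fp <- flatten_params(params); fg <- flatten_params(grads)
  state$t <- state$t + 1L
  if (is.null(state$m[[names(fp)[1]]]))
    for (k in names(fp)) { state$m[[k]] <- fp[[k]] * 0
                           state$v[[k]] <- fp[[k]] * 0 }
  fp_new <- .adam_step_cpp(fp, fg[names(fp)], state$m, state$v,
                           state$t, lr, beta1, beta2, eps, clipnorm)
  unflatten <- function(p, prefix = "") {
    for (k in names(p)) {
      key <- paste0(prefix, k)
      if (is.list(p[[k]])) p[[k]] <- unflatten(p[[k]], paste0(key, "."))
      else p[[k]] <- fp_new[[key]]
    }
    p
  }
  list(params = unflatten(params), state = state)
}
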