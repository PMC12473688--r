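# Shared helpers for building small tracks and networks in code.

# A minimal hand-built track: every keypoint visible, body translating
# rightward, hooves on the ground line. Raw image coordinates (y down).
make_plain_track <- function(n = 20L, fps = 30, direction = "rightward",
                             speed = 3) {
  sk <- cow_skeleton()
  kp <- array(NA_real_, c(n, 22L, 2L))
  base_y <- c(
    Eye = 240, Neck = 220, Spine_1 = 220, Spine_2 = 220, Spine_3 = 220,
    Spine_4 = 220,
    FR_Hoof = 420, FR_Fetlock = 390, FR_Carpal = 350, FR_Elbow = 310,
    FL_Hoof = 420, FL_Fetlock = 390, FL_Carpal = 350, FL_Elbow = 310,
    BL_Hoof = 420, BL_Fetlock = 390, BL_Ankle = 350, BL_Knee = 310,
    BR_Hoof = 420, BR_Fetlock = 390, BR_Ankle = 350, BR_Knee = 310)
  base_x <- c(
    Eye = 170, Neck = 130, Spine_1 = 65, Spine_2 = 0, Spine_3 = -65,
    Spine_4 = -130,
    FR_Hoof = 100, FR_Fetlock = 98, FR_Carpal = 95, FR_Elbow = 90,
    FL_Hoof = 80, FL_Fetlock = 78, FL_Carpal = 75, FL_Elbow = 72,
    BL_Hoof = -80, BL_Fetlock = -78, BL_Ankle = -75, BL_Knee = -72,
    BR_Hoof = -100, BR_Fetlock = -98, BR_Ankle = -95, BR_Knee = -90)
  for (i in seq_len(n)) {
    xc <- 200 + speed * (i - 1)
    kp[i, , 1] <- xc + base_x[sk$names]
    kp[i, , 2] <- base_y[sk$names]
  }
  if (direction == "leftward") {
    C <- min(kp[, , 1]) + max(kp[, , 1])
    kp[, , 1] <- C - kp[, , 1]
  }
  vis <- matrix(TRUE, n, 22L)
  xs <- matrix(kp[, , 1], nrow = n); ys <- matrix(kp[, , 2], nrow = n)
  bbox <- cbind(apply(xs, 1, min) - 5, apply(ys, 1, min) - 5,
                apply(xs, 1, max) + 5, apply(ys, 1, max) + 5)
  passage_track(kp, vis, bbox, fps = fps, direction = direction,
                passage_id = "plain")
}

# A track whose named hoof follows a prescribed x trajectory while all
# other points ride along rigidly; used to force specific stance masks.
make_hoof_track <- function(hoof_x, hoof = "FR_Hoof") {
  tr <- make_plain_track(n = length(hoof_x), speed = 0)
  k <- match(hoof, cow_skeleton()$names)
  tr$kp[, k, 1] <- hoof_x
  tr
}

# Apply a similarity transform (uniform scale + translation) to a raw track.
transform_track <- function(track, scale = 1, dx = 0, dy = 0) {
  track$kp[, , 1] <- track$kp[, , 1] * scale + dx
  track$kp[, , 2] <- track$kp[, , 2] * scale + dy
  track$bbox[, c(1, 3)] <- track$bbox[, c(1, 3)] * scale + dx
  track$bbox[, c(2, 4)] <- track$bbox[, c(2, 4)] * scale + dy
  track
}

# Features of one noiseless synthetic passage, end to end.
features_of <- function(grade, seed = 1, noise_sigma = 0, ...) {
  sim <- simulate_passage(gait_params(grade, noise_sigma = noise_sigma,
                                      seed = seed, ...))
  tr <- canonicalize_track(sim$track)
  ser <- suppressWarnings(compute_indicators(tr))
  f <- build_features(ser)
  f$label <- grade
  f
}

# Small labeled feature table (3 passages per grade, default noise),
# built once per test session.
.feature_cache <- new.env(parent = emptyenv())
readRDS_or_build_features <- function() {
  if (is.null(.feature_cache$feats)) {
    coh <- simulate_cohort(3L, seed = 19L)
    feats <- pipeline_features(coh$tracks)
    feats$label <- coh$manifest$grade
    .feature_cache$feats <- feats
  }
  .feature_cache$feats
}

# Add small Gaussian jitter to every parameter of a nested parameter list,
# so no ReLU pre-activation sits exactly on its kink during gradient checks.
jitter_params <- function(p, sd = 0.01) {
  for (k in names(p))
    p[[k]] <- if (is.list(p[[k]])) jitter_params(p[[k]], sd)
              else p[[k]] + stats::rnorm(length(p[[k]]), 0, sd)
  p
}

# Double-precision reference LSTM (single direction), written independently
# of the compiled kernels: the oracle for both the kernel outputs and the
# gradient formulas. X is time-major (B*T) x D.
ref_lstm_forward <- function(p, X, B) {
  n <- nrow(X); Tn <- n / B; H <- ncol(p$W) / 4
  sig <- function(x) 1 / (1 + exp(-x))
  cache <- vector("list", Tn)
  Hs <- matrix(0, n, H)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  for (t in seq_len(Tn)) {
    rows <- ((t - 1) * B + 1):(t * B)
    z <- X[rows, , drop = FALSE] %*% p$W + h %*% p$U +
      matrix(p$b, B, 4 * H, byrow = TRUE)
    i <- sig(z[, 1:H, drop = FALSE])
    f <- sig(z[, H + 1:H, drop = FALSE])
    g <- tanh(z[, 2 * H + 1:H, drop = FALSE])
    o <- sig(z[, 3 * H + 1:H, drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = cc, tc = tc,
                       h_prev = h)
    cc <- c_new
    h <- o * tc
    Hs[rows, ] <- h
  }
  list(H = Hs, cache = cache)
}

ref_lstm_backward <- function(p, X, B, cache, dH) {
  n <- nrow(X); Tn <- n / B; H <- ncol(p$W) / 4
  dW <- matrix(0, nrow(p$W), 4 * H); dU <- matrix(0, H, 4 * H)
  db <- rep(0, 4 * H); dX <- matrix(0, n, ncol(X))
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in Tn:1) {
    rows <- ((t - 1) * B + 1):(t * B)
    cc <- cache[[t]]
    dh <- dH[rows, , drop = FALSE] + dh_next
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    dz <- cbind(dc * cc$g * cc$i * (1 - cc$i),
                dc * cc$c_prev * cc$f * (1 - cc$f),
                dc * cc$i * (1 - cc$g^2),
                dh * cc$tc * cc$o * (1 - cc$o))
    dW <- dW + crossprod(X[rows, , drop = FALSE], dz)
    dU <- dU + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dh_next <- dz %*% t(p$U)
    dc_next <- dc * cc$f
    dX[rows, ] <- dz %*% t(p$W)
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}
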