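tiny_config <- function(seed = 11L)
  net_config(conv_filters = c(4L, 6L), lstm1_units = 3L, lstm2_units = 5L,
             n_classes = 7L, seq_len = 8L, epochs = 3L, batch_size = 4L,
             seed = seed)

test_that("sequence building resamples channels deterministically", {
  sim <- simulate_passage(gait_params(3, seed = 14))
  ser <- suppressWarnings(compute_indicators(canonicalize_track(sim$track)))
  n <- nrow(ser$values)
  # identity resample: same length leaves values at the sample points
  s_same <- build_sequence(ser, n)
  expect_equal(s_same[1, "spine_distance_ratio"],
               ser$values[1, "spine_distance_ratio"], tolerance = 1e-9)
  # constant channel stays constant; no non-finite entries anywhere
  s <- build_sequence(ser, 120L)
  expect_true(all(is.finite(s)))
  expect_equal(dim(s), c(120L, 5L))
  ser2 <- ser
  ser2$values[, "head_norm"] <- 0.42
  ser2$valid[, "head_norm"] <- TRUE
  expect_equal(build_sequence(ser2, 50L)[, "head_norm"], rep(0.42, 50L))
  # linear ramp resampled is still the same ramp
  ser3 <- ser
  ser3$values[, "leg_dist_FR_BR"] <- seq(0, 1, length.out = n)
  ser3$valid[, "leg_dist_FR_BR"] <- TRUE
  expect_equal(build_sequence(ser3, 30L)[, "leg_dist_FR_BR"],
               seq(0, 1, length.out = 30L), tolerance = 1e-9)
  # deterministic
  expect_identical(build_sequence(ser, 120L), build_sequence(ser, 120L))
})

test_that("augmentation is seeded and shuts off cleanly", {
  set.seed(1)
  s <- matrix(stats::runif(120 * 5), 120, 5)
  # identity when every transform is off
  expect_equal(augment_sequence(s, noise_sigma = 0, smooth_window = 1L,
                                dropout_frac = 0, seed = 5L), s)
  # same seed, same output; different seed differs
  a1 <- augment_sequence(s, 0.02, 3L, 0.1, seed = 9L)
  a2 <- augment_sequence(s, 0.02, 3L, 0.1, seed = 9L)
  a3 <- augment_sequence(s, 0.02, 3L, 0.1, seed = 10L)
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))
  expect_error(augment_sequence(s, dropout_frac = 1), "< 1")
  # jitter standard deviation behaves as specified over many entries
  big <- matrix(0, 400, 5)  # 2000 entries
  j <- augment_sequence(big, noise_sigma = 0.01, smooth_window = 1L,
                        dropout_frac = 0, seed = 3L)
  expect_gt(stats::sd(j - big), 0.008)
  expect_lt(stats::sd(j - big), 0.012)
})

test_that("LSTM kernels match an independent double-precision reference", {
  set.seed(21)
  B <- 4L; Tn <- 6L; D <- 3L; H <- 5L
  X <- matrix(stats::rnorm(B * Tn * D), B * Tn, D)
  p <- jitter_params(lstm_init(D, H), sd = 0.05)
  ref_f <- ref_lstm_forward(p, X, B)
  got_f <- lstm_forward(p, X, B)
  expect_equal(got_f$H, ref_f$H, tolerance = 1e-4)
  dH <- matrix(stats::rnorm(B * Tn * H), B * Tn, H)
  ref_b <- ref_lstm_backward(p, X, B, ref_f$cache, dH)
  got_b <- lstm_backward(p, got_f$cache, dH)
  expect_equal(got_b$grads$W, ref_b$dW, tolerance = 1e-3)
  expect_equal(got_b$grads$U, ref_b$dU, tolerance = 1e-3)
  expect_equal(got_b$grads$b, ref_b$db, tolerance = 1e-3)
  expect_equal(got_b$dX, ref_b$dX, tolerance = 1e-3)
})

test_that("the reference gradient formulas match numerical gradients", {
  # validates the shared backprop formulas in double precision, where
  # finite differences are trustworthy to 1e-6
  set.seed(22)
  B <- 3L; Tn <- 5L; D <- 2L; H <- 3L
  X <- matrix(stats::rnorm(B * Tn * D), B * Tn, D)
  p <- jitter_params(lstm_init(D, H), sd = 0.05)
  dH_w <- matrix(stats::rnorm(B * Tn * H), B * Tn, H)  # fixed projection
  loss_of <- function(p) sum(ref_lstm_forward(p, X, B)$H * dH_w)
  fwd <- ref_lstm_forward(p, X, B)
  grads <- ref_lstm_backward(p, X, B, fwd$cache, dH_w)
  for (nm in c("W", "U", "b")) {
    gana <- grads[[paste0("d", nm)]]
    for (j in sample.int(length(p[[nm]]), min(6L, length(p[[nm]])))) {
      p1 <- p; p1[[nm]][j] <- p1[[nm]][j] + 1e-6
      p2 <- p; p2[[nm]][j] <- p2[[nm]][j] - 1e-6
      gnum <- (loss_of(p1) - loss_of(p2)) / 2e-6
      expect_lt(abs(gnum - gana[j]) / max(1e-6, abs(gnum) + abs(gana[j])),
                1e-5, label = paste("gradient of", nm))
    }
  }
})

test_that("full-network backpropagation matches numerical gradients", {
  # end-to-end check through conv + BiLSTM + softmax; the forward pass runs
  # in single precision, so finite differences use a wide step and a
  # correspondingly loose tolerance (the per-layer kernels are held to
  # tight tolerances against the double-precision reference above)
  cfg <- tiny_config()
  set.seed(2)
  B <- 3L
  samples <- lapply(1:B, function(i) matrix(stats::rnorm(8 * 5), 8, 5))
  y <- c(1L, 4L, 7L)
  params <- jitter_params(net_init(cfg))
  X <- stack_time_major(samples)
  fw <- net_forward(params, X, B, training = TRUE)
  bk <- net_backward(params, fw, y, B)
  loss_at <- function(p) {
    f <- net_forward(p, X, B, training = TRUE)
    -mean(log(f$probs[cbind(1:B, y)] + 1e-12))
  }
  fp <- flatten_params(params); fg <- flatten_params(bk$grads)
  expect_setequal(names(fp), names(fg))
  bump <- function(p, path, j, d) {
    walk <- function(node, depth) {
      key <- path[depth]
      if (depth == length(path)) node[[key]][j] <- node[[key]][j] + d
      else node[[key]] <- walk(node[[key]], depth + 1)
      node
    }
    walk(p, 1)
  }
  set.seed(3)
  for (k in names(fp)) {
    path <- strsplit(k, ".", fixed = TRUE)[[1]]
    for (j in sample.int(length(fp[[k]]), min(3L, length(fp[[k]])))) {
      gnum <- (loss_at(bump(params, path, j, 1e-2)) -
               loss_at(bump(params, path, j, -1e-2))) / 2e-2
      gana <- fg[[k]][j]
      expect_lt(abs(gnum - gana) / max(0.05, abs(gnum) + abs(gana)), 0.15,
                label = paste("gradient of", k))
    }
  }
})

test_that("training produces calibrated softmax output and a loss trace", {
  set.seed(4)
  samples <- lapply(1:14, function(i) matrix(stats::rnorm(8 * 5), 8, 5))
  labels <- rep(1:7, 2)
  m <- train_cnn_bilstm(samples, labels, tiny_config())
  probs <- predict_proba(m, samples)
  expect_equal(dim(probs), c(14L, 7L))
  expect_equal(rowSums(probs), rep(1, 14L), tolerance = 1e-6)
  expect_length(m$loss_trace, 3L)
  expect_true(all(is.finite(m$loss_trace)))
  # forward pass is deterministic given fixed weights and input
  expect_identical(predict_proba(m, samples), probs)
})

test_that("the architecture matches its contract", {
  cfg <- net_config()
  expect_equal(cfg$kernel_size, 3L)
  expect_error(net_config(kernel_size = 5L), "fixed at 3")
  expect_error(net_config(conv_filters = c(320L, 128L)), "non-decreasing")
  set.seed(4)
  samples <- lapply(1:8, function(i) matrix(stats::rnorm(8 * 5), 8, 5))
  m <- train_cnn_bilstm(samples, rep(1:4, 2), tiny_config())
  arch <- m$architecture
  recurrent <- Filter(function(l) l$type == "bilstm", arch)
  expect_length(recurrent, 2L)
  expect_true(recurrent[[1]]$return_sequences)
  expect_false(recurrent[[2]]$return_sequences)
  convs <- Filter(function(l) l$type == "conv1d", arch)
  expect_true(all(vapply(convs, function(l) l$kernel_size, 0L) == 3L))
  expect_equal(arch[[length(arch)]]$units, 7L)
  # default (full-size) layer widths follow the published stack
  m$config <- net_config()
  expect_equal(net_config()$lstm1_units, 256L)
  expect_equal(net_config()$lstm2_units, 512L)
  expect_equal(net_config()$conv_filters, c(128L, 192L, 320L))
})

test_that("training learns separable sequences above chance (small scale)", {
  # two grade groups with very different spine dynamics; a scaled-down net
  # must fit the training set and beat chance on held-out samples
  set.seed(6)
  seqs <- list(); labels <- integer()
  for (g in c(1L, 7L)) for (r in 1:8) {
    sim <- simulate_passage(gait_params(g, seed = 600 + 16 * g + r))
    ser <- suppressWarnings(compute_indicators(canonicalize_track(sim$track)))
    seqs[[length(seqs) + 1L]] <- build_sequence(ser, 40L)
    labels <- c(labels, g)
  }
  hold <- c(1L, 2L, 9L, 10L)
  tr <- setdiff(seq_along(seqs), hold)
  cfg <- net_config(conv_filters = c(8L, 12L), lstm1_units = 8L,
                    lstm2_units = 12L, seq_len = 40L, epochs = 25L,
                    batch_size = 6L, seed = 5L, learning_rate = 5e-3)
  m <- train_cnn_bilstm(seqs[tr], labels[tr], cfg)
  expect_gte(mean(predict_grades(m, seqs[tr]) == labels[tr]), 0.9)
  expect_gte(mean(predict_grades(m, seqs[hold]) == labels[hold]), 0.5)
})
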