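# Sequence classifier over the per-frame indicator series: three 1-D
# convolutional layers (filters rising 128 -> 192 -> 320, kernel 3, ReLU)
# feeding two bidirectional LSTM layers (256 units returning sequences,
# then 512 units summarizing), and a dense softmax over the seven grades;
# categorical cross-entropy loss with the Adam optimizer. Passages are
# resampled to a fixed length so batch shapes are static.

SEQ_CHANNELS <- c("spine_angle_ratio", "spine_distance_ratio", "head_norm",
                  "leg_dist_FR_BR", "leg_dist_FL_BL")

#' Network configuration for the sequence classifier
#'
#' @param conv_filters filter counts of the convolutional stack, rising
#'   within 128..320 (default `c(128, 192, 320)`).
#' @param kernel_size convolution kernel width; fixed at 3.
#' @param lstm1_units units per direction of the first (sequence-returning)
#'   bidirectional LSTM (default 256).
#' @param lstm2_units units per direction of the second (summarizing)
#'   bidirectional LSTM (default 512).
#' @param n_classes number of output grades (default 7).
#' @param seq_len fixed sequence length T after resampling (default 120,
#'   about 4 s at 30 fps).
#' @param learning_rate Adam learning rate (default 2e-3).
#' @param dropout dropout fraction on the conv stack output during training
#'   (default 0).
#' @param epochs training epochs (default 30).
#' @param batch_size minibatch size (default 16).
#' @param seed seed for initialization and batch shuffling.
#' @return A list of class `net_config`.
#' @export
net_config <- function(conv_filters = c(128L, 192L, 320L), kernel_size = 3L,
                       lstm1_units = 256L, lstm2_units = 512L,
                       n_classes = 7L, seq_len = 120L,
                       learning_rate = 2e-3, dropout = 0,
                       epochs = 30L, batch_size = 16L, seed = 7L) {
  if (kernel_size != 3L) stop("kernel_size is fixed at 3")
  if (is.unsorted(conv_filters))
    stop("conv_filters must be non-decreasing")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(conv_filters = as.integer(conv_filters), kernel_size = 3L,
                 lstm1_units = as.integer(lstm1_units),
                 lstm2_units = as.integer(lstm2_units),
                 n_classes = as.integer(n_classes),
                 seq_len = as.integer(seq_len),
                 n_channels = length(SEQ_CHANNELS),
                 learning_rate = learning_rate, dropout = dropout,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "net_config")
}

#' Resample an indicator series into a fixed-length sequence sample
#'
#' Each of the five channels is linearly resampled onto `T` uniform time
#' points spanning the passage. Invalid frames are first filled by linear
#' interpolation between valid neighbors (constant extension at the ends);
#' a channel with fewer than 2 valid frames is filled with its single value,
#' or zeros, with a warning. Deterministic; the result carries no
#' non-finite entries.
#'
#' @param series an [compute_indicators()] result.
#' @param T target length (default 120).
#' @return A `T x 5` matrix with the channel names as columns.
#' @export
build_sequence <- function(series, T = 120L) {
  fi <- series$frame_index
  grid <- seq(fi[1], fi[length(fi)], length.out = T)
  out <- matrix(0, T, length(SEQ_CHANNELS),
                dimnames = list(NULL, SEQ_CHANNELS))
  for (j in seq_along(SEQ_CHANNELS)) {
    x <- series$values[, SEQ_CHANNELS[j]]
    ok <- series$valid[, SEQ_CHANNELS[j]] & !is.na(x)
    if (sum(ok) == 0L) {
      warning("channel ", SEQ_CHANNELS[j], " has no valid frames; zeros used")
      next
    }
    if (sum(ok) == 1L) {
      warning("channel ", SEQ_CHANNELS[j],
              " has a single valid frame; constant fill")
      out[, j] <- x[ok]
      next
    }
    out[, j] <- stats::approx(fi[ok], x[ok], xout = grid, rule = 2)$y
  }
  out
}

#' Augment a sequence sample
#'
#' Time-series augmentation with three transforms: additive Gaussian
#' jitter, optional moving-average smoothing, and random time-point dropout
#' with linear re-interpolation of the dropped points. The label is
#' unchanged; deterministic given the seed.
#'
#' @param sample a `T x C` sequence matrix (see [build_sequence()]).
#' @param noise_sigma jitter standard deviation (0 disables).
#' @param smooth_window odd moving-average window (1 disables).
#' @param dropout_frac fraction of time points to drop and re-interpolate,
#'   in `[0, 1)`.
#' @param seed RNG seed.
#' @return Matrix of the same shape.
#' @export
augment_sequence <- function(sample, noise_sigma = 0.01, smooth_window = 1L,
                             dropout_frac = 0.1, seed = 1L) {
  if (dropout_frac >= 1) stop("dropout fraction must be < 1")
  set.seed(seed)
  T <- nrow(sample)
  out <- sample
  if (noise_sigma > 0)
    out <- out + matrix(stats::rnorm(length(out), 0, noise_sigma),
                        T, ncol(out))
  if (smooth_window > 1L)
    for (j in seq_len(ncol(out)))
      out[, j] <- smooth_series(out[, j], smooth_window)
  if (dropout_frac > 0) {
    nd <- floor(dropout_frac * T)
    if (nd > 0) {
      drop <- sample.int(T, nd)
      keep <- setdiff(seq_len(T), drop)
      if (length(keep) >= 2L)
        for (j in seq_len(ncol(out)))
          out[drop, j] <- stats::approx(keep, out[keep, j], xout = drop,
                                        rule = 2)$y
    }
  }
  out
}

# Stack a list of T x C samples into the time-major (B*T) x C layout.
stack_time_major <- function(samples) {
  B <- length(samples)
  T <- nrow(samples[[1]]); C <- ncol(samples[[1]])
  X <- matrix(0, B * T, C)
  for (b in seq_len(B))
    X[seq(b, B * T, by = B), ] <- samples[[b]]
  X
}

#' Train the CNN-BiLSTM sequence classifier
#'
#' Trains the convolutional/recurrent stack with categorical cross-entropy
#' and Adam on minibatches, recording the training-loss trace. Channels are
#' standardized with training-set statistics (stored in the model). Aborts
#' with diagnostics if the loss becomes non-finite.
#'
#' @param samples list of `T x 5` sequence matrices ([build_sequence()]).
#' @param labels integer grades 1..7 (more precisely, values in
#'   `1..n_classes`).
#' @param config a [net_config()].
#' @param verbose print per-epoch loss and accuracy.
#' @return An object of class `cnn_bilstm` with the fitted parameters, the
#'   config, the standardization constants, the loss trace, and an
#'   `architecture` summary (layer types, units, kernel sizes).
#' @export
train_cnn_bilstm <- function(samples, labels, config = net_config(),
                             verbose = FALSE) {
  stopifnot(inherits(config, "net_config"))
  y <- as.integer(labels)
  if (any(y < 1L | y > config$n_classes)) stop("labels out of range")
  if (length(unique(y)) < 2L) stop("need at least 2 classes to train")
  N <- length(samples)
  T <- config$seq_len
  if (any(vapply(samples, nrow, 0L) != T))
    stop("all samples must have seq_len rows")

  all_mat <- do.call(rbind, samples)
  ch_mean <- colMeans(all_mat)
  ch_sd <- pmax(apply(all_mat, 2L, stats::sd), 1e-8)
  samples <- lapply(samples, function(s) sweep(sweep(s, 2L, ch_mean), 2L,
                                               ch_sd, "/"))

  params <- net_init(config)
  state <- list(t = 0L, m = list(), v = list())
  loss_trace <- numeric()
  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, N, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, N)]
      B <- length(idx)
      X <- stack_time_major(samples[idx])
      if (config$dropout > 0) {
        mask <- matrix(stats::rbinom(length(X), 1L, 1 - config$dropout) /
                         (1 - config$dropout), nrow(X), ncol(X))
        X <- X * mask
      }
      fw <- net_forward(params, X, B, training = TRUE)
      bk <- net_backward(params, fw, y[idx], B)
      if (!is.finite(bk$loss))
        stop(sprintf("non-finite loss at epoch %d (batch of %d); %s",
                     ep, B, "try a lower learning rate"))
      up <- adam_update(params, bk$grads, state, config$learning_rate)
      params <- up$params; state <- up$state
      ep_loss <- ep_loss + bk$loss; nb <- nb + 1L
    }
    loss_trace[ep] <- ep_loss / nb
    if (verbose) {
      acc <- mean(predict_grades(
        structure(list(params = params, config = config, ch_mean = ch_mean,
                       ch_sd = ch_sd), class = "cnn_bilstm"),
        lapply(samples, function(s) sweep(sweep(s, 2L, ch_sd, "*"),
                                          2L, -ch_mean)), raw = FALSE) == y)
      message(sprintf("epoch %3d  loss %.4f  train acc %.3f",
                      ep, loss_trace[ep], acc))
    }
  }

  arch <- c(
    lapply(seq_along(config$conv_filters), function(i) list(
      type = "conv1d", filters = config$conv_filters[i],
      kernel_size = config$kernel_size, activation = "relu")),
    list(list(type = "bilstm", units = config$lstm1_units,
              return_sequences = TRUE),
         list(type = "bilstm", units = config$lstm2_units,
              return_sequences = FALSE),
         list(type = "dense", units = config$n_classes,
              activation = "softmax"))
  )
  structure(list(params = params, config = config, ch_mean = ch_mean,
                 ch_sd = ch_sd, loss_trace = loss_trace,
                 architecture = arch),
            class = "cnn_bilstm")
}

#' @export
print.cnn_bilstm <- function(x, ...) {
  cat("CNN-BiLSTM sequence classifier\n")
  for (l in x$architecture)
    cat("  ", paste(names(l), unlist(l), sep = "=", collapse = " "), "\n")
  if (length(x$loss_trace))
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                length(x$loss_trace), utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Class probabilities from a trained sequence classifier
#'
#' @param model a [train_cnn_bilstm()] model.
#' @param samples list of `T x 5` sequence matrices.
#' @return `N x n_classes` matrix of probabilities (rows sum to 1).
#' @export
predict_proba <- function(model, samples) {
  stopifnot(inherits(model, "cnn_bilstm"))
  samples <- lapply(samples, function(s)
    sweep(sweep(s, 2L, model$ch_mean), 2L, model$ch_sd, "/"))
  B <- length(samples)
  X <- stack_time_major(samples)
  net_forward(model$params, X, B)$probs
}

#' Predicted grades from a trained sequence classifier
#'
#' @param model a [train_cnn_bilstm()] model.
#' @param samples list of `T x 5` sequence matrices.
#' @param raw unused; kept for internal calls.
#' @return Integer grade per sample (argmax of the class probabilities).
#' @export
predict_grades <- function(model, samples, raw = FALSE) {
  max.col(predict_proba(model, samples), ties.method = "first")
}
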