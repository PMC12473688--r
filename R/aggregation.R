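# Collapse per-frame indicator series into the per-passage scalars consumed
# by the expert tree and the ML backend.

#' Smooth a series over its valid frames
#'
#' Centered moving average with an odd window and reflect padding at the
#' boundaries, computed over valid frames only: invalid frames neither
#' contribute to nor receive values. The valid frames are treated as a
#' contiguous subsequence for padding purposes. Window 1 is the identity
#' and constants are preserved for any window.
#'
#' @param x numeric vector.
#' @param window odd integer >= 1.
#' @param valid logical vector; defaults to the non-`NA` entries of `x`.
#' @return Numeric vector of the same length; invalid entries are `NA`.
#' @export
smooth_series <- function(x, window = 5L, valid = !is.na(x)) {
  if (window %% 2L == 0L) stop("window must be odd")
  if (window < 1L) stop("window must be >= 1")
  out <- rep(NA_real_, length(x))
  idx <- which(valid)
  m <- length(idx)
  if (m == 0L) return(out)
  v <- x[idx]
  if (window == 1L || m == 1L) {
    out[idx] <- v
    return(out)
  }
  half <- min(window %/% 2L, m - 1L)
  # reflect padding: v[2], v[1] | v | v[m], v[m-1]
  padded <- c(v[(half + 1L):2L], v, v[(m - 1L):(m - half)])
  out[idx] <- moving_average_exact(padded, 2L * half + 1L)[(half + 1L):(half + m)]
  out
}

# Moving average where every output is a full-window mean (input is assumed
# already padded); centered window of odd length.
moving_average_exact <- function(x, window) {
  n <- length(x)
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  i <- (half + 1L):(n - half)
  out <- rep(NA_real_, n)
  out[i] <- (cs[i + half + 1L] - cs[i - half]) / window
  out
}

#' Local minima of a smoothed series
#'
#' Indices (into the vector) of entries strictly smaller than both their
#' nearest valid neighbors. A constant plateau flanked on both sides by
#' larger values yields a single index at the plateau center (floor of the
#' midpoint). Endpoints of the valid subsequence are never minima.
#'
#' @param x numeric vector.
#' @param valid logical vector; defaults to non-`NA` entries.
#' @return Integer vector of indices (possibly empty).
#' @export
local_minima <- function(x, valid = !is.na(x)) {
  idx <- which(valid)
  v <- x[idx]
  m <- length(v)
  if (m < 3L) return(integer())
  out <- integer()
  # collapse runs of equal values, then test each interior run
  r <- rle(v)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  for (j in seq_len(nr)) {
    if (j == 1L || j == nr) next
    if (r$values[j] < r$values[j - 1L] && r$values[j] < r$values[j + 1L])
      out <- c(out, idx[(starts[j] + ends[j]) %/% 2L])
  }
  out
}

#' Aggregate the spine channels of a passage
#'
#' Each spine channel (angle ratio, distance ratio) is smoothed, its local
#' minima are identified and averaged (the gait's arching is strongest at
#' these minima); when no interior minimum exists (short or monotone
#' passages) the global minimum of the smoothed series is used. The two
#' channel aggregates are then blended:
#' `blend_weight * angle + (1 - blend_weight) * distance`.
#'
#' @param series an [compute_indicators()] result.
#' @param blend_weight weight of the angle aggregate in `[0, 1]`
#'   (default 0.5).
#' @param window smoothing window (odd, default 5 frames, about 167 ms at
#'   30 fps).
#' @return The blended spine value in (0, 1].
#' @export
aggregate_spine <- function(series, blend_weight = 0.5, window = 5L) {
  agg_one <- function(col) {
    x <- series$values[, col]; valid <- series$valid[, col]
    if (!any(valid)) return(NA_real_)
    s <- smooth_series(x, window, valid)
    mins <- local_minima(s)
    if (length(mins)) mean(s[mins]) else min(s, na.rm = TRUE)
  }
  a <- agg_one("spine_angle_ratio")
  d <- agg_one("spine_distance_ratio")
  if (is.na(a) && is.na(d)) stop("no valid spine frames")
  if (is.na(a)) return(d)
  if (is.na(d)) return(a)
  blend_weight * a + (1 - blend_weight) * d
}

#' Aggregate the head channel of a passage
#'
#' The step-gated normalized head height is smoothed, then two summaries
#' are taken:
#' \describe{
#'   \item{head_min}{the global minimum of the smoothed values, separating
#'     severe head bobbing (grade 7) from the rest;}
#'   \item{head_drop}{for each hoof, the mean over its steps of (mean head
#'     height during the step's initial phase minus the minimum within the
#'     stance interval); `head_drop` is the largest per-hoof mean. The head
#'     bob of a lame cow is phase-locked to loading of the affected limb, so
#'     the per-limb maximum reads out the affected limb without requiring
#'     its identity; pooling all limbs' steps would dilute the drop with
#'     limbs whose stance is out of phase.}
#' }
#'
#' @param series an [compute_indicators()] result.
#' @param window smoothing window (odd, default 5).
#' @param initial_phase_frac fraction of the stance interval treated as the
#'   step's initial phase (default 0.2).
#' @return List with `head_min` and `head_drop`; both `NA` (sentinel "not
#'   computable") when no step has valid head frames. Downstream consumers
#'   treat the sentinel as absence of evidence of head bobbing.
#' @export
aggregate_head <- function(series, window = 5L, initial_phase_frac = 0.2) {
  x <- series$values[, "head_norm"]; valid <- series$valid[, "head_norm"]
  st <- step_table(series$steps)
  if (nrow(st) == 0L || !any(valid))
    return(list(head_min = NA_real_, head_drop = NA_real_))
  s <- smooth_series(x, window, valid)
  head_min <- min(s, na.rm = TRUE)

  drops <- c()
  for (h in unique(st$hoof)) {
    hd <- st[st$hoof == h, , drop = FALSE]
    step_drops <- c()
    for (j in seq_len(nrow(hd))) {
      init_f <- initial_phase_frames(hd$start[j], hd$end[j], initial_phase_frac)
      init_i <- match(init_f, series$frame_index)
      win_i <- which(series$frame_index >= hd$start[j] &
                     series$frame_index <= hd$end[j])
      iv <- s[init_i[!is.na(init_i)]]
      wv <- s[win_i]
      if (all(is.na(iv)) || all(is.na(wv))) next
      step_drops <- c(step_drops,
                      mean(iv, na.rm = TRUE) - min(wv, na.rm = TRUE))
    }
    if (length(step_drops)) drops[h] <- mean(step_drops)
  }
  head_drop <- if (length(drops)) max(drops) else NA_real_
  list(head_min = head_min, head_drop = head_drop)
}

#' Aggregate the leg channels of a passage
#'
#' For each leg pair, every step contributes the minimum normalized
#' distance over its touchdown window; the per-step minima are averaged
#' over steps, and the two pair values are averaged. If only one pair has
#' usable steps its value is returned with a warning; with no valid leg
#' data at all the sentinel `NA` ("not computable") is returned.
#'
#' @param series an [compute_indicators()] result.
#' @return Mean per-step minimum normalized inter-hoof distance (>= 0), or
#'   `NA`.
#' @export
aggregate_legs <- function(series) {
  st <- step_table(series$steps)
  w <- series$leg_window
  pair_val <- function(col, hoof) {
    td <- st$touchdown_frame[st$hoof == hoof]
    if (!length(td)) return(NA_real_)
    x <- series$values[, col]; valid <- series$valid[, col]
    mins <- c()
    for (t in td) {
      i <- which(series$frame_index >= t - w & series$frame_index <= t + w &
                 valid)
      if (length(i)) mins <- c(mins, min(x[i]))
    }
    if (length(mins)) mean(mins) else NA_real_
  }
  a <- pair_val("leg_dist_FR_BR", "BR_Hoof")
  b <- pair_val("leg_dist_FL_BL", "BL_Hoof")
  if (is.na(a) && is.na(b)) return(NA_real_)
  if (is.na(a) || is.na(b)) {
    warning("only one leg pair has usable steps")
    return(if (is.na(a)) b else a)
  }
  (a + b) / 2
}

#' Bundle the per-passage aggregated features
#'
#' Deterministically collapses an indicator series into the feature vector
#' consumed by the expert tree and the ML backend: the blended spine value,
#' the two head summaries, the leg value, and the step count. Sentinel `NA`
#' values (zero-step passages) are propagated, never raised as errors.
#'
#' @param series an [compute_indicators()] result.
#' @param blend_weight,window,initial_phase_frac see [aggregate_spine()] and
#'   [aggregate_head()].
#' @return One-row data frame with columns `passage_id`, `spine_value`,
#'   `head_min`, `head_drop`, `legs_value`, `n_steps`, `label`.
#' @export
build_features <- function(series, blend_weight = 0.5, window = 5L,
                           initial_phase_frac = 0.2) {
  spine <- tryCatch(aggregate_spine(series, blend_weight, window),
                    error = function(e) NA_real_)
  head <- aggregate_head(series, window, initial_phase_frac)
  legs <- suppressWarnings(aggregate_legs(series))
  data.frame(
    passage_id = series$passage_id,
    spine_value = spine,
    head_min = head$head_min,
    head_drop = head$head_drop,
    legs_value = legs,
    n_steps = nrow(step_table(series$steps)),
    label = if (is.null(series$label)) NA_real_ else series$label
  )
}
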