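# Step detection: a step is the swing -> stance transition of a hoof.
# The head and leg indicators are only meaningful around steps, so the whole
# downstream pipeline is gated on the events found here.

# Centered moving average with window truncated at the series ends.
moving_average <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n == 0L) return(x)
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Per-frame stance mask for one hoof
#'
#' A frame is labelled stance when the smoothed horizontal hoof speed
#' (central difference, then moving average over 5 frames) is at or below
#' `speed_frac` times the track-wide 95th percentile of that speed, for at
#' least `min_run` consecutive frames; all other frames are swing. The
#' threshold is relative, so the detector is invariant to uniform spatial
#' scaling of the track. `min_run` is interpreted at 30 fps and scaled for
#' other frame rates.
#'
#' @param track a canonical [passage_track()].
#' @param hoof one of `"FR_Hoof"`, `"FL_Hoof"`, `"BR_Hoof"`, `"BL_Hoof"`.
#' @param speed_frac stance threshold as a fraction of the 95th-percentile
#'   hoof speed (default 0.15).
#' @param min_run minimum stance run length in frames at 30 fps (default 3).
#' @return Logical vector, one element per frame (`TRUE` = stance).
#' @export
stance_mask <- function(track, hoof, speed_frac = 0.15, min_run = 3L) {
  stopifnot(inherits(track, "passage_track"))
  k <- kp_index(hoof)
  v <- track$vis[, k]
  if (mean(v) < 0.5)
    stop("insufficient hoof visibility for ", hoof,
         sprintf(" (%.0f%% of frames)", 100 * mean(v)))
  x <- track$kp[, k, 1]
  n <- length(x)
  if (n < 3L) stop("track too short for step detection")
  # central-difference speed, one-sided at the ends
  sp <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
  sp <- abs(moving_average(sp, 5L))
  thr <- speed_frac * stats::quantile(sp, 0.95, names = FALSE, type = 7)
  mask <- sp <= thr
  mr <- max(1L, as.integer(round(min_run * track$fps / 30)))
  if (mr > 1L && any(mask)) {
    r <- rle(mask)
    r$values[r$values & r$lengths < mr] <- FALSE
    mask <- inverse.rle(r)
  }
  mask
}

#' Detect steps (swing-to-stance transitions) for each hoof
#'
#' One step event is emitted per swing-to-stance transition of each hoof;
#' its touchdown frame is the first frame of the stance run. A stance run at
#' the very start of the track (with no preceding swing) yields a stance
#' interval but no step event. Frames are reported as the track's frame
#' indices (0-based).
#'
#' @param track a canonical [passage_track()].
#' @param speed_frac,min_run see [stance_mask()].
#' @param hooves which hooves to process (default all four).
#' @return A list of class `step_events` with
#'   \describe{
#'     \item{events}{data frame `hoof, touchdown_frame, start, end`
#'       (stance interval, inclusive)}
#'     \item{stance}{named list of per-hoof logical stance masks}
#'   }
#' @export
detect_steps <- function(track, speed_frac = 0.15, min_run = 3L,
                         hooves = cow_skeleton()$hoof_set) {
  ev <- list(); masks <- list()
  for (h in hooves) {
    mask <- stance_mask(track, h, speed_frac, min_run)
    masks[[h]] <- mask
    ev[[h]] <- events_from_mask(mask, track$frame_index, h)
  }
  events <- do.call(rbind, unname(ev))
  if (is.null(events))
    events <- data.frame(hoof = character(), touchdown_frame = integer(),
                         start = integer(), end = integer())
  structure(list(events = events, stance = masks), class = "step_events")
}

# Stance intervals and step events implied by a stance mask: one event per
# swing->stance transition; an interval at the mask start (no preceding
# swing) is kept for gating but carries no touchdown.
events_from_mask <- function(mask, frame_index = seq_along(mask) - 1L,
                             hoof = "hoof") {
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep))
    return(data.frame(hoof = character(), touchdown_frame = integer(),
                      start = integer(), end = integer()))
  data.frame(
    hoof = hoof,
    touchdown_frame = ifelse(keep == 1L, NA_integer_,
                             frame_index[starts[keep]]),
    start = frame_index[starts[keep]],
    end = frame_index[ends[keep]]
  )
}

#' @export
print.step_events <- function(x, ...) {
  st <- x$events[!is.na(x$events$touchdown_frame), ]
  cat(sprintf("Step events: %d steps over %d stance intervals\n",
              nrow(st), nrow(x$events)))
  if (nrow(st)) print(table(st$hoof))
  invisible(x)
}

# Steps only (stance intervals that begin with a detected touchdown).
step_table <- function(steps) {
  ev <- steps$events
  ev[!is.na(ev$touchdown_frame), , drop = FALSE]
}

# First ceil(frac * stance length) frames of a stance interval: the step's
# initial phase, during which the head has not yet dipped.
initial_phase_frames <- function(start, end, frac = 0.2) {
  len <- end - start + 1L
  start:(start + max(1L, ceiling(frac * len)) - 1L)
}
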