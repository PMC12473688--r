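#' Construct a passage track
#'
#' A passage track holds one cow crossing the field of view: per-frame
#' bounding boxes and 22 keypoints with visibility flags, plus recording
#' metadata. Coordinates as read from pose-model output are raw image pixels
#' (y increases downward); [canonicalize_track()] converts to the canonical
#' analysis frame (y up, motion rightward).
#'
#' @param kp numeric array `n_frames x 22 x 2` of keypoint (x, y) positions.
#' @param vis logical matrix `n_frames x 22`; `FALSE` marks untagged points.
#' @param bbox numeric matrix `n_frames x 4` of corners (x1, y1, x2, y2),
#'   with `x1 < x2`, `y1 < y2`.
#' @param frame_index integer vector of frame indices (0-based, strictly
#'   increasing).
#' @param fps frames per second (default 30).
#' @param direction `"rightward"`, `"leftward"`, or `NA` to infer later from
#'   bounding-box motion.
#' @param passage_id identifier string.
#' @param label optional ground-truth locomotion grade in 1..7.
#' @param canonical `TRUE` if coordinates are already in the canonical frame.
#' @param imputed optional logical matrix marking interpolated points.
#' @return An object of class `passage_track`.
#' @export
passage_track <- function(kp, vis, bbox, frame_index = NULL, fps = 30,
                          direction = NA_character_, passage_id = "passage",
                          label = NULL, canonical = FALSE, imputed = NULL) {
  kp <- unname(kp); vis <- unname(vis); bbox <- unname(bbox)
  if (length(dim(kp)) != 3L || dim(kp)[2] != 22L || dim(kp)[3] != 2L)
    stop("kp must be an n x 22 x 2 array")
  n <- dim(kp)[1]
  if (n < 1L) stop("no frames")
  if (!is.matrix(vis) || !all(dim(vis) == c(n, 22L)))
    stop("vis must be an n x 22 logical matrix")
  if (!is.matrix(bbox) || !all(dim(bbox) == c(n, 4L)))
    stop("bbox must be an n x 4 matrix")
  if (any(bbox[, 1] >= bbox[, 3]) || any(bbox[, 2] >= bbox[, 4]))
    stop("bbox must satisfy x1 < x2 and y1 < y2 in every frame")
  if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != n) stop("frame_index length mismatch")
  if (any(frame_index < 0L)) stop("frame_index must be >= 0")
  if (any(duplicated(frame_index))) stop("duplicate frame_index")
  o <- order(frame_index)
  if (is.unsorted(frame_index)) {
    kp <- kp[o, , , drop = FALSE]; vis <- vis[o, , drop = FALSE]
    bbox <- bbox[o, , drop = FALSE]; frame_index <- frame_index[o]
    if (!is.null(imputed)) imputed <- imputed[o, , drop = FALSE]
  }
  if (!is.null(fps) && fps <= 0) stop("fps must be > 0")
  if (!is.na(direction) && !direction %in% c("rightward", "leftward"))
    stop("direction must be 'rightward' or 'leftward'")
  if (!is.null(label) && !is.na(label) &&
      (label < 1 || label > 7)) stop("label must be a grade in 1..7")
  if (is.null(imputed)) imputed <- matrix(FALSE, n, 22L)
  structure(
    list(kp = kp, vis = vis, bbox = bbox, frame_index = frame_index,
         fps = fps, direction = direction, passage_id = passage_id,
         label = label, canonical = isTRUE(canonical), imputed = imputed),
    class = "passage_track"
  )
}

#' @export
print.passage_track <- function(x, ...) {
  cat(sprintf(
    "Passage track '%s': %d frames @ %g fps, direction %s%s%s\n",
    x$passage_id, nrow(x$vis), x$fps,
    ifelse(is.na(x$direction), "unknown", x$direction),
    if (x$canonical) ", canonical frame" else ", raw image frame",
    if (!is.null(x$label)) sprintf(", grade %s", format(x$label)) else ""
  ))
  cat(sprintf("  keypoint visibility: %.1f%%\n", 100 * mean(x$vis)))
  invisible(x)
}

n_frames <- function(track) dim(track$kp)[1]

#' Bring a track into the canonical analysis frame
#'
#' The canonical frame has the vertical axis increasing upward (ground near
#' zero) and the cow moving rightward. The vertical flip uses the track-wide
#' maximum bounding-box bottom edge as reference (a per-frame reference would
#' inject bounding-box jitter into the kinematics); a leftward passage is
#' mirrored about the track-wide horizontal extent. Both operations are
#' isometries, so all within-frame distances are preserved. Idempotent:
#' calling it on an already-canonical track returns the track unchanged.
#'
#' If the track's direction is unknown it is inferred from the sign of the
#' median per-frame displacement of the bounding-box center, which is robust
#' to keypoint noise.
#'
#' @param track a [passage_track()].
#' @return The track in the canonical frame, with `direction = "rightward"`
#'   and `canonical = TRUE`.
#' @export
canonicalize_track <- function(track) {
  stopifnot(inherits(track, "passage_track"))
  if (track$canonical) return(track)
  if (n_frames(track) < 2L) stop("cannot infer motion: track has < 2 frames")

  dir <- track$direction
  if (is.na(dir)) {
    cx <- (track$bbox[, 1] + track$bbox[, 3]) / 2
    med <- stats::median(diff(cx))
    dir <- if (med < 0) "leftward" else "rightward"
  }

  H <- max(track$bbox[, 4])
  kp <- track$kp
  kp[, , 2] <- H - kp[, , 2]
  bbox <- track$bbox
  y1 <- H - bbox[, 4]; y2 <- H - bbox[, 2]
  bbox[, 2] <- y1; bbox[, 4] <- y2

  if (dir == "leftward") {
    C <- min(track$bbox[, 1]) + max(track$bbox[, 3])
    kp[, , 1] <- C - kp[, , 1]
    x1 <- C - bbox[, 3]; x2 <- C - bbox[, 1]
    bbox[, 1] <- x1; bbox[, 3] <- x2
  }

  passage_track(kp, track$vis, bbox, track$frame_index, track$fps,
                direction = "rightward", passage_id = track$passage_id,
                label = track$label, canonical = TRUE,
                imputed = track$imputed)
}

#' Fill short runs of missing keypoints by linear interpolation
#'
#' For each keypoint, runs of invisible frames no longer than `max_gap` that
#' are flanked by visible frames on both sides are filled by linear
#' interpolation between the flanking positions; filled points are marked
#' visible and flagged in the track's `imputed` matrix. Longer runs and runs
#' touching the start or end of the track are left untouched (no
#' extrapolation). Visible points are never modified.
#'
#' @param track a [passage_track()].
#' @param max_gap maximum run length (frames) to fill; 0 disables filling.
#' @return The track with short gaps filled.
#' @export
interpolate_missing <- function(track, max_gap = 3L) {
  stopifnot(inherits(track, "passage_track"), max_gap >= 0)
  n <- n_frames(track)
  kp <- track$kp; vis <- track$vis; imputed <- track$imputed
  for (k in seq_len(22L)) {
    v <- vis[, k]
    if (!any(v)) {
      warning(sprintf("keypoint %s never visible; left missing",
                      cow_skeleton()$names[k]))
      next
    }
    if (all(v) || max_gap == 0) next
    r <- rle(v)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j]) next
      if (j == 1L || j == length(r$values)) next  # no extrapolation
      if (r$lengths[j] > max_gap) next
      a <- starts[j] - 1L; b <- ends[j] + 1L
      idx <- starts[j]:ends[j]
      # interpolate in frame-index time so irregular sampling is respected
      t0 <- track$frame_index[a]; t1 <- track$frame_index[b]
      w <- (track$frame_index[idx] - t0) / (t1 - t0)
      kp[idx, k, 1] <- (1 - w) * kp[a, k, 1] + w * kp[b, k, 1]
      kp[idx, k, 2] <- (1 - w) * kp[a, k, 2] + w * kp[b, k, 2]
      vis[idx, k] <- TRUE
      imputed[idx, k] <- TRUE
    }
  }
  track$kp <- kp; track$vis <- vis; track$imputed <- imputed
  track
}
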