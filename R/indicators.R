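# Per-frame locomotion indicators.
#
# Three families of indicator are computed from the canonical-frame
# keypoints: spine curvature (an inscribed-angle ratio from a circle fitted
# to the five spine points, and the chord/path distance ratio), the head
# height normalized between the lowest hoof and the highest spine point, and
# the height-normalized horizontal distance between same-side hooves.

#' Algebraic least-squares circle fit
#'
#' Fits a circle to 2-D points by the Kasa formulation: minimize
#' \eqn{\sum_i (x_i^2 + y_i^2 + D x_i + E y_i + F)^2}, a linear least-squares
#' problem whose solution gives center \eqn{(-D/2, -E/2)} and radius
#' \eqn{\sqrt{D^2/4 + E^2/4 - F}}. Points are centered before solving so the
#' normal equations stay well conditioned for circles far from the origin.
#' Collinear (or nearly collinear) points have no finite circle: the fit is
#' flagged `degenerate` when the normal-equation condition number exceeds
#' 1e8 or the fitted radius exceeds 1e6 times the point spread.
#'
#' @param points numeric matrix with 2 columns (x, y), at least 3 rows.
#' @return A list of class `circle_fit`: `center` (x, y), `radius`,
#'   `rms_residual` (root-mean-square radial residual), `degenerate`.
#' @examples
#' fit_circle(rbind(c(0, 0), c(2, 0), c(1, 1)))  # center (1,0), radius 1
#' @export
fit_circle <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 points")
  if (ncol(points) != 2L) stop("points must have 2 columns")
  spread <- max(dist(points))
  if (spread == 0) stop("all points coincident")

  ctr <- colMeans(points)
  x <- points[, 1] - ctr[1]; y <- points[, 2] - ctr[2]
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  AtA <- crossprod(A)
  kappa <- tryCatch(kappa(AtA, exact = TRUE), error = function(e) Inf)
  degenerate <- !is.finite(kappa) || kappa > 1e8
  if (!degenerate) {
    z <- tryCatch(solve(AtA, crossprod(A, b)),
                  error = function(e) NULL)
    if (is.null(z)) degenerate <- TRUE
  }
  if (!degenerate) {
    D <- z[1]; E <- z[2]; Fc <- z[3]
    r2 <- (D^2 + E^2) / 4 - Fc
    if (r2 <= 0) degenerate <- TRUE
  }
  if (!degenerate) {
    center <- c(-D / 2 + ctr[1], -E / 2 + ctr[2])
    radius <- sqrt(r2)
    if (radius > 1e6 * spread) degenerate <- TRUE
  }
  if (degenerate) {
    return(structure(list(center = c(NA_real_, NA_real_), radius = Inf,
                          rms_residual = NA_real_, degenerate = TRUE),
                     class = "circle_fit"))
  }
  d <- sqrt((points[, 1] - center[1])^2 + (points[, 2] - center[2])^2)
  structure(list(center = unname(center), radius = radius,
                 rms_residual = sqrt(mean((d - radius)^2)),
                 degenerate = FALSE),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  if (x$degenerate) cat("Circle fit: degenerate (collinear points)\n")
  else cat(sprintf("Circle fit: center (%.6g, %.6g), radius %.6g, rms %.3g\n",
                   x$center[1], x$center[2], x$radius, x$rms_residual))
  invisible(x)
}

# Interior angle at b between rays b->a and b->c, in degrees.
angle_at <- function(a, b, c) {
  u <- a - b; v <- c - b
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Spine angle ratio of a five-point spine chain
#'
#' The angle at Spine_2 between rays to the Neck and to Spine_4, in degrees
#' divided by 180. A straight spine gives ratio 1; stronger arching gives
#' smaller values. In `"projected"` mode a circle is first fitted to all
#' five spine points and the three landmarks are radially projected onto it
#' before the angle is taken (falling back to the raw angle when the fit is
#' degenerate, i.e. the spine is straight); the two modes agree in the
#' noiseless limit. The raw mode is the default: on noisy near-straight
#' spines the algebraic circle fit latches onto small circles through the
#' noise and the projection amplifies rather than suppresses it.
#'
#' @param spine numeric 5 x 2 matrix, rows ordered Neck, Spine_1..Spine_4.
#'   Callers working from full frames should pass bounding-box-normalized
#'   coordinates (see [compute_indicators()]).
#' @param mode `"raw"` (default) or `"projected"`.
#' @return Ratio in (0, 1].
#' @export
spine_angle_ratio <- function(spine, mode = c("raw", "projected")) {
  mode <- match.arg(mode)
  spine <- as.matrix(spine)
  stopifnot(nrow(spine) == 5L, ncol(spine) == 2L)
  neck <- spine[1, ]; s2 <- spine[3, ]; s4 <- spine[5, ]
  if (mode == "projected") {
    fit <- fit_circle(spine)
    if (!fit$degenerate) {
      proj <- function(p) {
        d <- p - fit$center
        nd <- sqrt(sum(d^2))
        if (nd == 0) p else fit$center + fit$radius * d / nd
      }
      neck <- proj(neck); s2 <- proj(s2); s4 <- proj(s4)
    }
  }
  ang <- angle_at(neck, s2, s4)
  ang / 180
}

#' Spine distance ratio (chord over path)
#'
#' Ratio of the straight-line distance between the outermost spine points
#' (Neck and Spine_4) to the total length of the polyline through all five
#' spine points. Equal to 1 iff the chain is straight and monotone;
#' decreases as the spine arches. Invariant to translation, rotation and
#' uniform scaling.
#'
#' @inheritParams spine_angle_ratio
#' @return Ratio in (0, 1], or `NA` if the chain has zero length.
#' @export
spine_distance_ratio <- function(spine) {
  spine <- as.matrix(spine)
  stopifnot(nrow(spine) == 5L, ncol(spine) == 2L)
  seg <- diff(spine)
  path <- sum(sqrt(rowSums(seg^2)))
  if (path == 0) return(NA_real_)
  chord <- sqrt(sum((spine[5, ] - spine[1, ])^2))
  chord / path
}

# Vertical reference of a frame in the canonical (y-up) frame:
# ground = lowest visible hoof, back = highest visible spine point.
frame_vertical_refs <- function(kp, vis, sk = cow_skeleton()) {
  hoof_i <- kp_index(sk$hoof_set, sk)
  spine_i <- kp_index(sk$groups$spine, sk)
  hv <- hoof_i[vis[hoof_i]]
  sv <- spine_i[vis[spine_i]]
  if (!length(hv) || !length(sv)) return(c(NA_real_, NA_real_))
  c(ground = min(kp[hv, 2]), back = max(kp[sv, 2]))
}

#' Normalized head height of a single frame
#'
#' The Eye keypoint (the only cranial landmark in the skeleton) is used as
#' the head proxy. Its height is scaled between the lowest visible hoof
#' (ground reference, 0) and the highest visible spine point (back line, 1):
#' `(y_head - y_ground) / (y_back - y_ground)`, not clamped. Requires the
#' canonical y-up frame.
#'
#' @param kp 22 x 2 keypoint matrix of one canonical frame.
#' @param vis logical visibility vector of length 22.
#' @return Normalized head height, or `NA` if the frame is invalid (Eye or
#'   references missing, or back not above ground).
#' @export
head_position_norm <- function(kp, vis) {
  sk <- cow_skeleton()
  eye <- kp_index("Eye", sk)
  if (!vis[eye]) return(NA_real_)
  refs <- frame_vertical_refs(kp, vis, sk)
  if (anyNA(refs) || refs["back"] <= refs["ground"]) return(NA_real_)
  unname((kp[eye, 2] - refs["ground"]) / (refs["back"] - refs["ground"]))
}

#' Same-side inter-hoof distance of a single frame
#'
#' Absolute horizontal distance between the front and rear hoof of one body
#' side, divided by the cow's height (highest spine point minus lowest hoof,
#' an anatomical height proxy). Small values around a rear-hoof touchdown
#' mean the rear hoof lands in or near the front hoof's track ("track-up"),
#' a sign of soundness; the distance grows with lameness.
#'
#' @inheritParams head_position_norm
#' @param pair `"FR_BR"` or `"FL_BL"`.
#' @return Non-negative normalized distance, or `NA` if invalid.
#' @export
leg_pair_distance <- function(kp, vis, pair = c("FR_BR", "FL_BL")) {
  pair <- match.arg(pair)
  sk <- cow_skeleton()
  labs <- if (pair == "FR_BR") c("FR_Hoof", "BR_Hoof") else c("FL_Hoof", "BL_Hoof")
  ii <- kp_index(labs, sk)
  if (!all(vis[ii])) return(NA_real_)
  refs <- frame_vertical_refs(kp, vis, sk)
  if (anyNA(refs)) return(NA_real_)
  height <- refs["back"] - refs["ground"]
  if (height <= 0) return(NA_real_)
  unname(abs(kp[ii[1], 1] - kp[ii[2], 1]) / height)
}

#' Compute the per-frame indicator series of a passage
#'
#' Applies the four per-frame indicators to every frame of a canonical
#' track and gates the step-dependent channels on the detected steps:
#' the head channel is valid only on frames inside a detected stance
#' interval; each leg channel is valid only on the touchdown frame of its
#' rear hoof (BR for FR-BR, BL for FL-BL) and the `leg_window` frames before
#' and after it (window interpreted at 30 fps and scaled with the track's
#' frame rate). Spine coordinates are normalized to the frame's bounding box
#' before the curvature computations. Frames with missing required
#' keypoints are flagged invalid, never silently zero-filled.
#'
#' @param track a canonical [passage_track()] (see [canonicalize_track()]).
#' @param steps step events from [detect_steps()]; detected automatically
#'   when `NULL`.
#' @param angle_mode `"raw"` or `"projected"`, see [spine_angle_ratio()].
#' @param leg_window half-width in frames of the leg-distance window around
#'   each rear-hoof touchdown (default 10 at 30 fps).
#' @param speed_frac,min_run step-detector settings, used when `steps` is
#'   `NULL`.
#' @return An object of class `indicator_series`: per-frame matrix `values`
#'   with columns `spine_angle_ratio`, `spine_distance_ratio`, `head_norm`,
#'   `leg_dist_FR_BR`, `leg_dist_FL_BL`, a parallel logical `valid` matrix,
#'   the frame indices, fps, and the attached step events.
#' @export
compute_indicators <- function(track, steps = NULL,
                               angle_mode = c("raw", "projected"),
                               leg_window = 10L,
                               speed_frac = 0.15, min_run = 3L) {
  angle_mode <- match.arg(angle_mode)
  stopifnot(inherits(track, "passage_track"))
  if (!track$canonical)
    stop("track must be canonicalized first (see canonicalize_track)")
  if (is.null(steps))
    steps <- detect_steps(track, speed_frac = speed_frac, min_run = min_run)

  sk <- cow_skeleton()
  n <- n_frames(track)
  chan <- c("spine_angle_ratio", "spine_distance_ratio", "head_norm",
            "leg_dist_FR_BR", "leg_dist_FL_BL")
  values <- matrix(NA_real_, n, 5L, dimnames = list(NULL, chan))
  spine_i <- kp_index(sk$groups$spine, sk)

  for (i in seq_len(n)) {
    kp <- track$kp[i, , ]; vis <- track$vis[i, ]
    if (all(vis[spine_i])) {
      bb <- track$bbox[i, ]
      sp <- cbind((kp[spine_i, 1] - bb[1]) / (bb[3] - bb[1]),
                  (kp[spine_i, 2] - bb[2]) / (bb[4] - bb[2]))
      values[i, 1] <- spine_angle_ratio(sp, mode = angle_mode)
      values[i, 2] <- spine_distance_ratio(sp)
    }
    values[i, 3] <- head_position_norm(kp, vis)
    values[i, 4] <- leg_pair_distance(kp, vis, "FR_BR")
    values[i, 5] <- leg_pair_distance(kp, vis, "FL_BL")
  }

  valid <- !is.na(values)
  st <- step_table(steps)
  if (nrow(st) == 0L)
    warning("zero detected steps; head and leg channels entirely invalid")

  # head: only frames inside a detected step's stance interval
  in_stance <- rep(FALSE, n)
  for (j in seq_len(nrow(st)))
    in_stance <- in_stance |
      (track$frame_index >= st$start[j] & track$frame_index <= st$end[j])
  valid[, 3] <- valid[, 3] & in_stance

  # legs: touchdown +/- window frames of the pair's rear hoof
  w <- max(1L, as.integer(round(leg_window * track$fps / 30)))
  for (col_hoof in list(c(4L, "BR_Hoof"), c(5L, "BL_Hoof"))) {
    cc <- as.integer(col_hoof[1]); hoof <- col_hoof[2]
    td <- st$touchdown_frame[st$hoof == hoof]
    keep <- rep(FALSE, n)
    for (t in td)
      keep <- keep | (track$frame_index >= t - w & track$frame_index <= t + w)
    valid[, cc] <- valid[, cc] & keep
  }
  values[!valid] <- NA_real_

  structure(list(values = values, valid = valid,
                 frame_index = track$frame_index, fps = track$fps,
                 steps = steps, passage_id = track$passage_id,
                 label = track$label, leg_window = w),
            class = "indicator_series")
}

#' @export
print.indicator_series <- function(x, ...) {
  cat(sprintf("Indicator series '%s': %d frames, %d steps\n",
              x$passage_id, nrow(x$values), nrow(step_table(x$steps))))
  cat("  valid frames per channel:",
      paste(sprintf("%s %d", colnames(x$values), colSums(x$valid)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write an indicator series to a wide CSV
#'
#' One row per frame with the five indicator channels and their validity
#' flags; consumable by the sequence classifier and inspectable by users.
#'
#' @param series an [compute_indicators()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_indicators <- function(series, path) {
  df <- data.frame(frame = series$frame_index, series$values,
                   check.names = FALSE)
  vf <- as.data.frame(series$valid)
  names(vf) <- paste0("valid_", colnames(series$values))
  utils::write.csv(cbind(df, vf), path, row.names = FALSE)
  invisible(path)
}
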