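# Synthetic gait simulator.
#
# Generates 22-keypoint passage tracks with grade-controlled pathology and
# known ground truth: spine points on a circular arc whose sagitta grows
# with grade, hooves following periodic stance/swing cycles, a rear-hoof
# landing offset relative to the front track growing with grade, and a
# vertical head bob phase-locked to the affected limb's stance for severe
# grades. Tracks are emitted in raw image coordinates (y down), so the
# full ingestion path including canonicalization is exercised.

#' Grade-controlled gait parameters
#'
#' The per-grade default maps operationalize the 7-grade locomotion scale:
#' grade 1 is a straight spine with the rear hooves landing in the front
#' hoof tracks; curvature and the landing shortfall grow monotonically with
#' grade; vertical head bobbing appears at grade 6 (slight) and 7 (severe).
#' The maps are calibration constants of the simulator, not claims about
#' real cows; every one is overridable.
#'
#' @param grade locomotion grade 1..7.
#' @param arch_sagitta spine-arc sagitta as a fraction of the spine chord;
#'   default per-grade map `c(0, .02, .05, .08, .11, .14, .18)`.
#' @param head_bob_amp head-bob amplitude as a fraction of cow height;
#'   default 0 for grades 1-5, 0.08 for 6, 0.25 for 7.
#' @param track_up_offset rear-hoof landing offset behind the front track as
#'   a fraction of cow height; default map
#'   `c(0, .02, .06, .12, .18, .26, .35)`.
#' @param stance_frames,swing_frames stance and swing phase lengths in
#'   frames at `fps` (defaults 20 and 14, a 1.13 s stride at 30 fps).
#' @param n_cycles number of full gait cycles in the passage (default 4).
#' @param speed body speed in px/frame (default 3).
#' @param noise_sigma Gaussian keypoint noise in px (default 2).
#' @param fps frames per second (default 30).
#' @param seed RNG seed for the noise.
#' @param affected affected limb's hoof (default `"BR_Hoof"`).
#' @param direction emitted movement direction (default rightward).
#' @return A list of class `gait_params`.
#' @export
gait_params <- function(grade,
                        arch_sagitta = c(0, .02, .05, .08, .11, .14, .18)[grade],
                        head_bob_amp = c(0, 0, 0, 0, 0, .08, .25)[grade],
                        track_up_offset = c(0, .02, .06, .12, .18, .26, .35)[grade],
                        stance_frames = 20L, swing_frames = 14L,
                        n_cycles = 4L, speed = 3, noise_sigma = 2,
                        fps = 30, seed = 1L,
                        affected = "BR_Hoof",
                        direction = c("rightward", "leftward")) {
  direction <- match.arg(direction)
  if (!grade %in% 1:7) stop("grade must be in 1..7")
  if (n_cycles < 1L) stop("n_cycles must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(grade = grade, arch_sagitta = arch_sagitta,
                 head_bob_amp = head_bob_amp,
                 track_up_offset = track_up_offset,
                 stance_frames = as.integer(stance_frames),
                 swing_frames = as.integer(swing_frames),
                 n_cycles = as.integer(n_cycles), speed = speed,
                 noise_sigma = noise_sigma, fps = fps, seed = seed,
                 affected = affected, direction = direction),
            class = "gait_params")
}

smoothstep <- function(u) u * u * (3 - 2 * u)

# Hoof trajectory with touchdown phase offset `phase` (frames) and spatial
# track base `x_base`: stance holds the current print, swing advances one
# stride along a smoothstep with a sinusoidal lift.
hoof_xy <- function(t, phase, x_base, stride, stance, swing, ground, lift = 12) {
  tt <- t - phase
  k <- floor(tt / (stance + swing))
  local <- tt - k * (stance + swing)
  in_stance <- local < stance
  u <- pmax(0, (local - stance) / swing)
  x <- x_base + k * stride + ifelse(in_stance, 0, stride * smoothstep(u))
  y <- ifelse(in_stance, ground, ground - lift * sin(pi * u))
  cbind(x, y)
}

#' Simulate one synthetic cow passage
#'
#' Emits a passage track at the given frame rate in raw image coordinates
#' (y increases downward, as a camera records), together with the ground
#' truth that generated it. Deterministic given the seed. Geometry: cow
#' height 200 px (ground line at y = 420), spine chord 260 px; rear hooves
#' land `track_up_offset * height` behind the print the ipsilateral front
#' hoof currently occupies, so the per-step minimum front-rear hoof
#' x-distance equals the injected offset exactly on noiseless data; the Eye
#' dips by `head_bob_amp * height` during the affected limb's mid-stance,
#' after the step's initial phase.
#'
#' @param params a [gait_params()].
#' @return List with `track` (a [passage_track()], label set to the grade)
#'   and `truth` (the params plus per-hoof true stance intervals as a data
#'   frame `hoof, start, end` in frame indices).
#' @export
simulate_passage <- function(params) {
  stopifnot(inherits(params, "gait_params"))
  p <- params
  sk <- cow_skeleton()
  Tcyc <- p$stance_frames + p$swing_frames
  n <- p$n_cycles * Tcyc
  t <- seq_len(n) - 1
  G <- 420; height <- 200; top <- G - height  # raw y-down: top = 220
  L <- 260
  stride <- p$speed * Tcyc
  xc <- 150 + p$speed * t
  off <- p$track_up_offset * height
  d <- floor(0.6 * p$stance_frames)          # rear touchdown inside front stance

  kp <- array(NA_real_, c(n, 22L, 2L))

  # spine: five points on a circular arc, chord horizontal, apex fixed at
  # `top` so cow height is grade-independent
  h <- p$arch_sagitta * L
  y0 <- top + h
  fr <- c(0, 0.25, 0.5, 0.75, 1)             # Neck .. Spine_4, front to rear
  xs_rel <- 130 - L * fr
  ys <- if (h > 0) {
    R <- ((L / 2)^2 + h^2) / (2 * h)
    y0 - (sqrt(R^2 - xs_rel^2) - (R - h))
  } else rep(y0, 5L)
  spine_i <- kp_index(sk$groups$spine, sk)
  for (j in 1:5) {
    kp[, spine_i[j], 1] <- xc + xs_rel[j]
    kp[, spine_i[j], 2] <- ys[j]
  }

  # head: Eye ahead of the neck at 0.9 height, dipping during the affected
  # limb's mid-stance (outside the step's initial phase)
  phase_map <- c(FR_Hoof = 0, FL_Hoof = Tcyc / 2, BR_Hoof = d,
                 BL_Hoof = d + Tcyc / 2)
  aff_phase <- phase_map[[p$affected]]
  s_local <- ((t - aff_phase) %% Tcyc) / p$stance_frames
  bump <- ifelse(s_local >= 0.25 & s_local <= 0.95,
                 sin(pi * (s_local - 0.25) / 0.7)^2, 0)
  kp[, kp_index("Eye", sk), 1] <- xc + 170
  kp[, kp_index("Eye", sk), 2] <- (G - 0.9 * height) +
    p$head_bob_amp * height * bump

  # hooves: front hooves define the track; rear hooves touch down while the
  # ipsilateral front hoof is still in stance, `off` px behind its print
  x_front <- 150 + 100
  traj <- list(
    FR_Hoof = hoof_xy(t, 0, x_front, stride, p$stance_frames, p$swing_frames, G),
    FL_Hoof = hoof_xy(t, Tcyc / 2, x_front, stride, p$stance_frames,
                      p$swing_frames, G),
    BR_Hoof = hoof_xy(t - d, 0, x_front - off, stride, p$stance_frames,
                      p$swing_frames, G),
    BL_Hoof = hoof_xy(t - d, Tcyc / 2, x_front - off, stride, p$stance_frames,
                      p$swing_frames, G)
  )
  anchors <- list(FR_Hoof = c(85, 90), FL_Hoof = c(85, 90),
                  BR_Hoof = c(-85, 90), BL_Hoof = c(-85, 90))
  joint_frac <- c(0.18, 0.45, 0.75)
  for (hname in sk$hoof_set) {
    leg <- sk$groups[[paste0("leg_", sub("_Hoof", "", hname))]]
    hx <- traj[[hname]][, 1]; hy <- traj[[hname]][, 2]
    ax <- xc + anchors[[hname]][1]; ay <- G - anchors[[hname]][2]
    kp[, kp_index(leg[1], sk), 1] <- hx
    kp[, kp_index(leg[1], sk), 2] <- hy
    for (jj in 2:4) {
      f <- joint_frac[jj - 1]
      kp[, kp_index(leg[jj], sk), 1] <- hx + f * (ax - hx)
      kp[, kp_index(leg[jj], sk), 2] <- hy + f * (ay - hy)
    }
  }

  set.seed(p$seed)
  if (p$noise_sigma > 0)
    kp <- kp + stats::rnorm(length(kp), 0, p$noise_sigma)

  if (p$direction == "leftward") {
    C <- min(kp[, , 1]) + max(kp[, , 1])
    kp[, , 1] <- C - kp[, , 1]
  }

  vis <- matrix(TRUE, n, 22L)
  bbox <- cbind(apply(kp[, , 1], 1, min) - 5, apply(kp[, , 2], 1, min) - 5,
                apply(kp[, , 1], 1, max) + 5, apply(kp[, , 2], 1, max) + 5)

  track <- passage_track(kp, vis, bbox, fps = p$fps,
                         direction = p$direction,
                         passage_id = sprintf("sim_g%d_s%d", p$grade, p$seed),
                         label = p$grade)

  truth_stance <- do.call(rbind, lapply(sk$hoof_set, function(hname) {
    mask <- ((t - phase_map[[hname]]) %% Tcyc) < p$stance_frames
    r <- rle(mask)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(hoof = hname, start = t[starts[keep]], end = t[ends[keep]])
  }))
  list(track = track,
       truth = list(params = p, stance = truth_stance))
}

#' Simulate a labeled cohort of passages
#'
#' Generates `7 * n_per_grade` passages with deterministic per-passage seeds
#' derived from (`seed`, grade, replicate), and a manifest with the ground
#' truth. Two calls with the same arguments produce identical cohorts.
#'
#' @param n_per_grade passages per grade (>= 1).
#' @param seed cohort seed.
#' @param ... overrides forwarded to [gait_params()] (e.g. `noise_sigma`).
#' @param out_dir optional directory; when given, each track is written as
#'   COCO keypoint JSON and the manifest as `manifest.csv`.
#' @return List with `tracks` (list of [passage_track()]) and `manifest`
#'   (data frame `passage_id, grade, seed, arch_sagitta, head_bob_amp,
#'   track_up_offset`).
#' @export
simulate_cohort <- function(n_per_grade, seed = 42L, ..., out_dir = NULL) {
  if (n_per_grade < 1L) stop("n_per_grade must be >= 1")
  tracks <- list(); rows <- list()
  for (g in 1:7) for (r in seq_len(n_per_grade)) {
    pseed <- (seed * 7919L + g * 1009L + r * 101L) %% 2147483647L
    p <- gait_params(grade = g, seed = pseed, ...)
    sim <- simulate_passage(p)
    sim$track$passage_id <- sprintf("g%d_r%03d", g, r)
    tracks[[length(tracks) + 1L]] <- sim$track
    rows[[length(rows) + 1L]] <- data.frame(
      passage_id = sim$track$passage_id, grade = g, seed = pseed,
      arch_sagitta = p$arch_sagitta, head_bob_amp = p$head_bob_amp,
      track_up_offset = p$track_up_offset)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (tr in tracks)
      write_track(tr, file.path(out_dir, paste0(tr$passage_id, ".json")))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(tracks = tracks, manifest = manifest)
}
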