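test_that("circle fit recovers exact circles and flags collinear input", {
  # circumcircle of (0,0),(2,0),(1,1): center (1,0), radius 1
  f <- fit_circle(rbind(c(0, 0), c(2, 0), c(1, 1)))
  expect_false(f$degenerate)
  expect_equal(f$center, c(1, 0), tolerance = 1e-9)
  expect_equal(f$radius, 1, tolerance = 1e-9)
  # 5 points sampled exactly on center (3,-2) radius 5
  ang <- c(10, 60, 90, 120, 170) * pi / 180
  pts <- cbind(3 + 5 * cos(ang), -2 + 5 * sin(ang))
  f2 <- fit_circle(pts)
  expect_equal(f2$center, c(3, -2), tolerance = 1e-6)
  expect_equal(f2$radius, 5, tolerance = 1e-6)
  expect_lt(f2$rms_residual, 1e-9)
  # oracle equivalence across five decades of radius
  for (r in c(0.1, 1, 10, 1000, 1e4)) {
    cx <- r * 0.3; cy <- -r * 1.7
    pts <- cbind(cx + r * cos(ang), cy + r * sin(ang))
    fr <- fit_circle(pts)
    expect_equal(fr$radius, r, tolerance = 1e-6 * r)
    expect_equal(fr$center, c(cx, cy), tolerance = 1e-6 * max(1, r))
  }
  # collinear points are degenerate, not a crash
  f3 <- fit_circle(cbind(0:3, 0))
  expect_true(f3$degenerate)
  expect_error(fit_circle(rbind(c(1, 1), c(1, 1), c(1, 1))), "coincident")
  expect_error(fit_circle(rbind(c(0, 0), c(1, 1))), "at least 3")
})

test_that("spine angle ratio matches closed-form geometry", {
  # collinear spine: straight-back limit, ratio 1
  straight <- cbind(seq(0, 4), 0)
  expect_equal(spine_angle_ratio(straight), 1.0, tolerance = 1e-12)
  expect_equal(spine_angle_ratio(straight, "projected"), 1.0,
               tolerance = 1e-12)
  # right angle at Spine_2 (raw three-point angle)
  bent <- rbind(c(0, 0), c(0.5, 0.5), c(1, 1), c(1.5, 0.5), c(2, 0))
  expect_equal(spine_angle_ratio(bent, "raw"), 0.5, tolerance = 1e-12)
  # inscribed-angle case: 5 points on the unit circle, Spine_2 at 90 deg;
  # the chord Neck-Spine_4 spans a 200-degree far arc, so the inscribed
  # angle is 100 degrees and the ratio 100/180
  ang <- c(170, 120, 90, 60, 10) * pi / 180
  arc <- cbind(cos(ang), sin(ang))
  expect_equal(spine_angle_ratio(arc, "raw"), 100 / 180, tolerance = 1e-6)
  expect_equal(spine_angle_ratio(arc, "projected"), 100 / 180,
               tolerance = 1e-6)
})

test_that("spine distance ratio matches hand-computed chord and path", {
  # equally spaced collinear points: chord equals path
  expect_equal(spine_distance_ratio(cbind(0:4, 2)), 1.0, tolerance = 1e-12)
  # worked 5-point chain: chord 4 over path 2*(sqrt(2) + sqrt(1.09))
  chain <- rbind(c(0, 0), c(1, 1), c(2, 1.3), c(3, 1), c(4, 0))
  expect_equal(spine_distance_ratio(chain), 4 / (2 * (sqrt(2) + sqrt(1.09))),
               tolerance = 1e-12)
  expect_lt(abs(spine_distance_ratio(chain) - 0.813588), 1e-6)
  # similarity invariance
  chain2 <- chain * 3.123 + 17
  expect_equal(spine_distance_ratio(chain2), spine_distance_ratio(chain),
               tolerance = 1e-9)
  # never exceeds 1
  set.seed(5)
  for (r in 1:50) {
    p <- matrix(stats::rnorm(10), 5, 2)
    expect_lte(spine_distance_ratio(p), 1)
  }
})

test_that("head height normalizes between lowest hoof and highest spine", {
  tr <- canonicalize_track(make_plain_track())
  kp <- tr$kp[1, , ]; vis <- tr$vis[1, ]
  sk <- cow_skeleton()
  eye <- match("Eye", sk$names)
  ground <- min(kp[match(sk$hoof_set, sk$names), 2])
  back <- max(kp[match(sk$groups$spine, sk$names), 2])
  # head at ground level -> 0; level with the back -> 1; 3/4 height -> 0.75
  kp[eye, 2] <- ground
  expect_equal(head_position_norm(kp, vis), 0)
  kp[eye, 2] <- back
  expect_equal(head_position_norm(kp, vis), 1)
  kp[eye, 2] <- ground + 0.75 * (back - ground)
  expect_equal(head_position_norm(kp, vis), 0.75)
  # implausible posture (back below ground) flags the frame invalid
  kp2 <- kp; kp2[match(sk$groups$spine, sk$names), 2] <- ground - 1
  expect_true(is.na(head_position_norm(kp2, vis)))
  # invisible eye flags the frame invalid
  vis2 <- vis; vis2[eye] <- FALSE
  expect_true(is.na(head_position_norm(kp, vis2)))
})

test_that("leg pair distance is the height-normalized hoof x-distance", {
  tr <- canonicalize_track(make_plain_track())
  kp <- tr$kp[1, , ]; vis <- tr$vis[1, ]
  sk <- cow_skeleton()
  fr <- match("FR_Hoof", sk$names); br <- match("BR_Hoof", sk$names)
  ground <- min(kp[match(sk$hoof_set, sk$names), 2])
  back <- max(kp[match(sk$groups$spine, sk$names), 2])
  h <- back - ground
  # same x -> 0
  kp[br, 1] <- kp[fr, 1]
  expect_equal(leg_pair_distance(kp, vis, "FR_BR"), 0)
  # dx = 0.3 * height
  kp[br, 1] <- kp[fr, 1] - 0.3 * h
  expect_equal(leg_pair_distance(kp, vis, "FR_BR"), 0.3, tolerance = 1e-12)
  # translation and uniform scaling invariance
  kp2 <- kp * 2.5 + 40
  expect_equal(leg_pair_distance(kp2, vis, "FR_BR"), 0.3, tolerance = 1e-9)
})

test_that("indicator series gates head and legs on detected steps", {
  sim <- simulate_passage(gait_params(1, noise_sigma = 0, seed = 6))
  tr <- canonicalize_track(sim$track)
  ser <- compute_indicators(tr)
  n <- dim(tr$kp)[1]
  # shape contract: every channel spans every frame
  expect_equal(dim(ser$values), c(n, 5L))
  expect_equal(dim(ser$valid), c(n, 5L))
  # straight-spine generator: near-unity distance ratio on all frames
  expect_true(all(ser$values[, "spine_distance_ratio"] >= 0.999,
                  na.rm = TRUE))
  # head frames restricted to stance intervals; legs to touchdown windows
  expect_lt(sum(ser$valid[, "head_norm"]), n + 1L)
  expect_true(any(ser$valid[, "leg_dist_FR_BR"]))
  # invalid frames are NA, never zero-filled
  expect_true(all(is.na(ser$values[!ser$valid])))
  # all-stance hooves produce no touchdowns -> head and leg channels
  # entirely invalid, with a warning rather than an error
  tr2 <- canonicalize_track(make_plain_track(n = 30L))
  expect_warning(ser2 <- compute_indicators(tr2), "zero detected steps")
  expect_false(any(ser2$valid[, "head_norm"]))
  expect_false(any(ser2$valid[, "leg_dist_FR_BR"]))
})

test_that("all four indicators are similarity-invariant end to end", {
  set.seed(12)
  for (r in 1:8) {
    g <- sample(1:7, 1)
    sim <- simulate_passage(gait_params(g, seed = 100 + r))
    tr1 <- canonicalize_track(sim$track)
    s <- stats::runif(1, 0.3, 4)
    tr2 <- canonicalize_track(transform_track(sim$track, scale = s,
                                              dx = stats::runif(1, -200, 200),
                                              dy = stats::runif(1, -200, 200)))
    s1 <- suppressWarnings(compute_indicators(tr1))
    s2 <- suppressWarnings(compute_indicators(tr2))
    expect_equal(s2$values, s1$values, tolerance = 1e-9)
  }
})
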