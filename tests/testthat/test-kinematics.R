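test_that("trunk flexion angle matches closed-form constructions", {
  n <- 3
  t <- seq_len(n) / 30
  base <- matrix(0, n, 3)
  mk <- function(vec) {
    make_skeleton(t, list(
      spine_base = base,
      shoulder_center = matrix(rep(vec, each = n), n, 3),
      acromion_left = base, acromion_right = base,
      elbow = base, wrist = base, hand = base
    ))
  }
  expect_equal(trunk_flexion_angle(mk(c(0, 1, 0)))$angle, rep(0, n))
  expect_equal(trunk_flexion_angle(mk(c(0, cos(pi / 6), sin(pi / 6))))$angle,
               rep(30, n), tolerance = 1e-9)
  expect_equal(trunk_flexion_angle(mk(c(0, 0, 1)))$angle, rep(90, n))
})

test_that("elbow angle matches closed-form constructions", {
  n <- 2
  t <- seq_len(n) / 30
  base <- matrix(0, n, 3)
  mk <- function(sh, wr) {
    make_skeleton(t, list(
      spine_base = base, shoulder_center = base,
      acromion_left = base,
      acromion_right = matrix(rep(sh, each = n), n, 3),
      elbow = base,
      wrist = matrix(rep(wr, each = n), n, 3),
      hand = matrix(rep(wr, each = n), n, 3)
    ))
  }
  # collinear: elbow between shoulder and wrist on a line -> 180
  expect_equal(mk(c(0, 1, 0), c(0, -1, 0)) |> elbow_angle() |> _$angle,
               rep(180, n))
  # perpendicular segments -> 90
  expect_equal(mk(c(0, 1, 0), c(0, 0, 1)) |> elbow_angle() |> _$angle,
               rep(90, n))
  # folded back -> 0
  expect_equal(mk(c(0, 1, 0), c(0, 1, 0)) |> elbow_angle() |> _$angle,
               rep(0, n))
})

test_that("angles are invariant to translation and vertical-axis rotation", {
  prof <- reach_profile(trunk_range_deg = 20, elbow_range_deg = 30,
                        jitter_sd = 1)
  sched <- generate_block_schedule("reach", "paretic", "SAU", 1)
  tr <- generate_reach_skeleton(prof, sched, seed = 5)
  trunk0 <- trunk_flexion_angle(tr)$angle
  elbow0 <- elbow_angle(tr)$angle

  rot <- function(x, z, phi) list(x = cos(phi) * x - sin(phi) * z,
                                  z = sin(phi) * x + cos(phi) * z)
  tr2 <- as.data.frame(tr)
  for (j in c("spine_base", "shoulder_center", "acromion_left",
              "acromion_right", "elbow", "wrist", "hand")) {
    tr2[[paste0(j, "_x")]] <- tr2[[paste0(j, "_x")]] + 137
    tr2[[paste0(j, "_y")]] <- tr2[[paste0(j, "_y")]] - 42
    tr2[[paste0(j, "_z")]] <- tr2[[paste0(j, "_z")]] + 88
  }
  tr2 <- structure(tibble::as_tibble(tr2), rate = 30, side = "right",
                   class = c("skeleton_trace", class(tibble::tibble())))
  # translation leaves both angles unchanged
  expect_equal(trunk_flexion_angle(tr2)$angle, trunk0, tolerance = 1e-9)
  expect_equal(elbow_angle(tr2)$angle, elbow0, tolerance = 1e-9)

  # a rigid rotation about any axis leaves the elbow interior angle unchanged
  phi <- 0.7
  tr3 <- as.data.frame(tr)
  for (j in c("acromion_right", "elbow", "wrist")) {
    r <- rot(tr3[[paste0(j, "_x")]], tr3[[paste0(j, "_z")]], phi)
    tr3[[paste0(j, "_x")]] <- r$x
    tr3[[paste0(j, "_z")]] <- r$z
  }
  tr3 <- structure(tibble::as_tibble(tr3), rate = 30, side = "right",
                   class = c("skeleton_trace", class(tibble::tibble())))
  expect_equal(elbow_angle(tr3)$angle, elbow0, tolerance = 1e-9)
})

test_that("segment_reaches yields one clipped window per cue", {
  sched <- generate_block_schedule("reach", "paretic", "SAU", 1)
  prof <- reach_profile(jitter_sd = 0)
  tr <- generate_reach_skeleton(prof, sched, seed = 1)
  segs <- segment_reaches(tr, sched)
  expect_equal(nrow(segs), 5)
  expect_equal(segs$end - segs$start, rep(2, 5))

  # cue near the recording end is clipped with a warning
  short <- tr[tr$time <= 17, ]
  short <- structure(short, rate = 30, side = "right",
                     class = c("skeleton_trace", class(short)))
  expect_warning(segs2 <- segment_reaches(short, sched), "clipped")
  expect_equal(nrow(segs2), 5)
  expect_lt(segs2$end[5] - segs2$start[5], 2)
})

test_that("reach metrics match an independently coded brute-force pass", {
  sched <- generate_block_schedule("reach", "paretic", "SAU", 2)
  prof <- reach_profile(trunk_range_deg = 18, elbow_range_deg = 35,
                        jitter_sd = 3)
  tr <- generate_reach_skeleton(prof, sched, seed = 9)
  rm <- reach_metrics(tr, sched, smooth_hz = 2)

  # brute force on the identically smoothed trace
  sm <- smooth_skeleton(tr, cutoff = 2)
  cues <- movement_cues(sched)$onset
  seg_vals <- t(vapply(cues, function(cue) {
    idx <- which(sm$time >= cue & sm$time <= cue + 2)
    vy <- sm$shoulder_center_y[idx] - sm$spine_base_y[idx]
    vz <- sm$shoulder_center_z[idx] - sm$spine_base_z[idx]
    trunk <- atan2(vz, vy) * 180 / pi
    ux <- sm$acromion_right_x[idx] - sm$elbow_x[idx]
    uy <- sm$acromion_right_y[idx] - sm$elbow_y[idx]
    uz <- sm$acromion_right_z[idx] - sm$elbow_z[idx]
    vx2 <- sm$wrist_x[idx] - sm$elbow_x[idx]
    vy2 <- sm$wrist_y[idx] - sm$elbow_y[idx]
    vz2 <- sm$wrist_z[idx] - sm$elbow_z[idx]
    cosang <- (ux * vx2 + uy * vy2 + uz * vz2) /
      (sqrt(ux^2 + uy^2 + uz^2) * sqrt(vx2^2 + vy2^2 + vz2^2))
    elb <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    sp <- mean(sqrt(diff(sm$hand_x[idx])^2 + diff(sm$hand_y[idx])^2 +
                      diff(sm$hand_z[idx])^2) / diff(sm$time[idx]))
    c(max(trunk) - min(trunk), max(elb) - min(elb), sp)
  }, numeric(3)))
  blocks <- movement_cues(sched)$block
  by_block <- apply(seg_vals, 2, function(v) tapply(v, blocks, mean))
  expect_equal(rm$trunk_flexion_range, mean(by_block[, 1]), tolerance = 1e-9)
  expect_equal(rm$elbow_extension_range, mean(by_block[, 2]), tolerance = 1e-9)
  expect_equal(rm$hand_mean_velocity, mean(by_block[, 3]), tolerance = 1e-9)
})

test_that("PANU follows its arm-use construction", {
  sched <- generate_block_schedule("reach", "paretic", "SAU", 1)
  # identical kinematics in both conditions: PANU = 0
  tr <- generate_reach_skeleton(reach_profile(jitter_sd = 0), sched, seed = 1)
  m <- reach_metrics(tr, sched, smooth_hz = NULL)
  expect_equal(panu(m, m), 0)

  # SAU with trunk contribution, MAU without: PANU equals the analytic gap.
  # With zero jitter the arm-use share is a deterministic geometric ratio.
  sau_prof <- reach_profile(trunk_range_deg = 15, elbow_range_deg = 30,
                            jitter_sd = 0)
  mau_prof <- reach_profile(trunk_range_deg = 0, elbow_range_deg = 30,
                            jitter_sd = 0)
  m_sau <- reach_metrics(generate_reach_skeleton(sau_prof, sched, seed = 1),
                         sched, smooth_hz = NULL)
  m_mau <- reach_metrics(generate_reach_skeleton(mau_prof, sched, seed = 1),
                         sched, smooth_hz = NULL)
  # analytic arm use for the SAU profile: trunk (acromion) forward share
  p <- sau_prof
  d2r <- pi / 180
  trunk_fwd <- p$trunk_len * sin(p$trunk_range_deg * d2r)
  hand_z <- function(theta, alpha, phi) {
    p$trunk_len * sin(theta) + p$upper_arm * sin(alpha) +
      (p$forearm + p$hand_offset) * sin(alpha + pi - phi)
  }
  z0 <- hand_z(0, p$shoulder_start_deg * d2r, p$elbow_start_deg * d2r)
  z1 <- hand_z(p$trunk_range_deg * d2r,
               (p$shoulder_start_deg + p$shoulder_range_deg) * d2r,
               (p$elbow_start_deg + p$elbow_range_deg) * d2r)
  au_sau <- 100 * (z1 - z0 - trunk_fwd) / (z1 - z0)
  expect_equal(m_sau$arm_use, au_sau, tolerance = 1e-6)
  expect_equal(m_mau$arm_use, 100, tolerance = 1e-6)
  expect_equal(panu(m_sau, m_mau), 100 - au_sau, tolerance = 1e-6)

  # MAU with less arm use than SAU: negative PANU, allowed but flagged
  expect_warning(p_neg <- panu(m_mau, m_sau), "negative PANU")
  expect_lt(p_neg, 0)
})

test_that("steering metrics honour the effective-width identities", {
  geom <- circle_geometry()
  # 2 laps in 10 s: speed 0.2 laps/s, MT 5 s/lap
  n <- 2000
  th <- -seq(0, 4 * pi, length.out = n)
  tr <- make_cursor(seq(0, 10, length.out = n), rep(geom$radius, n), th, geom)
  sm <- steering_metrics(tr)
  expect_equal(sm$speed, 0.2, tolerance = 1e-9)
  expect_equal(sm$MT, 5, tolerance = 1e-9)
  # perfect circle: We = 0, bias = 0, no errors, IPe undefined
  expect_equal(sm$We, 0)
  expect_equal(sm$bias, 0)
  expect_equal(sm$error_rate, 0)
  expect_true(is.na(sm$IDe) && is.na(sm$IPe))

  # arithmetic oracle at known sigma / R / MT
  set.seed(4)
  r <- rnorm(n, geom$radius, 2)
  tr2 <- make_cursor(seq(0, 10, length.out = n), r, th, geom)
  sm2 <- steering_metrics(tr2)
  We_o <- sqrt(2 * pi * exp(1)) * sd(r)
  IDe_o <- 2 * pi * mean(r) / We_o
  expect_equal(sm2$We, We_o, tolerance = 1e-12)
  expect_equal(sm2$IDe, IDe_o, tolerance = 1e-12)
  expect_equal(sm2$IPe, IDe_o / 5, tolerance = 1e-12)
  expect_equal(sm2$bias, We_o / geom$tunnel_width, tolerance = 1e-12)
  expect_equal(sm2$error_rate,
               mean(abs(r - geom$radius) > geom$tunnel_width / 2),
               tolerance = 1e-12)
})

test_that("IPe responds monotonically to precision and speed", {
  geom <- circle_geometry()
  n <- 5000
  th <- -seq(0, 6 * pi, length.out = n)
  tt <- seq(0, 12, length.out = n)
  set.seed(8)
  noise <- rnorm(n)
  ipe_at <- function(sigma, dur_scale = 1) {
    tr <- make_cursor(tt * dur_scale, geom$radius + sigma * noise, th, geom)
    steering_metrics(tr)$IPe
  }
  # smaller sigma at fixed R, MT -> strictly larger IPe
  expect_gt(ipe_at(1), ipe_at(2))
  expect_gt(ipe_at(2), ipe_at(4))
  # faster laps (smaller MT) at fixed geometry -> larger IPe
  expect_gt(ipe_at(2, dur_scale = 0.5), ipe_at(2, dur_scale = 1))
  # speed x MT = 1 whenever both defined
  tr <- make_cursor(tt, geom$radius + noise, th, geom)
  sm <- steering_metrics(tr)
  expect_equal(sm$speed * sm$MT, 1, tolerance = 1e-12)
})

test_that("steering error rate is invariant to angular speed", {
  geom <- circle_geometry()
  n <- 20000
  set.seed(12)
  r <- geom$radius + rnorm(n, 0, 8)
  tt <- seq(0, 40, length.out = n)
  rates <- vapply(c(1, 3, 9), function(k) {
    th <- -seq(0, k * 2 * pi, length.out = n)
    steering_metrics(make_cursor(tt, r, th, geom))$error_rate
  }, numeric(1))
  expect_equal(rates[1], rates[2], tolerance = 1e-12)
  expect_equal(rates[2], rates[3], tolerance = 1e-12)
})
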