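#' Motion profile for a synthetic paced reach
#'
#' Parameterises the forward model used by [generate_reach_skeleton()]: a
#' rigid trunk hinged at the spine base flexing forward in the sagittal
#' plane, and a two-segment arm (shoulder elevation + elbow extension)
#' hinged at the acromion. During each cued movement the trunk, shoulder and
#' elbow ramp from their resting posture to their peak with a minimum-jerk
#' time course over the 2 s "go" phase and return during the 2 s "stop"
#' phase. Maximal arm-use (MAU) runs are emulated with `trunk_range_deg = 0`.
#'
#' @param trunk_range_deg Peak forward trunk flexion (degrees, >= 0).
#' @param elbow_range_deg Elbow extension excursion (degrees); the elbow
#'   opens from `elbow_start_deg` to `elbow_start_deg + elbow_range_deg`.
#' @param shoulder_range_deg Shoulder elevation excursion (degrees).
#' @param elbow_start_deg Resting interior elbow angle (degrees).
#' @param shoulder_start_deg Resting shoulder elevation from vertical
#'   (degrees).
#' @param jitter_sd Gaussian position noise added to every joint coordinate
#'   (mm, >= 0); emulates marker/depth-sensor noise.
#' @param trunk_len,upper_arm,forearm,hand_offset,shoulder_halfwidth Segment
#'   lengths (mm); adult-scale defaults.
#' @param side Which arm reaches, `"right"` or `"left"`.
#' @return A list of class `reach_profile`.
#' @export
reach_profile <- function(trunk_range_deg = 10, elbow_range_deg = 40,
                          shoulder_range_deg = 50, elbow_start_deg = 90,
                          shoulder_start_deg = 10, jitter_sd = 1,
                          trunk_len = 500, upper_arm = 300, forearm = 260,
                          hand_offset = 80, shoulder_halfwidth = 180,
                          side = "right") {
  assert_number(trunk_range_deg, "trunk_range_deg", 0, 85)
  assert_number(elbow_range_deg, "elbow_range_deg", 0)
  assert_number(shoulder_range_deg, "shoulder_range_deg", 0)
  assert_number(jitter_sd, "jitter_sd", 0)
  for (len in c(trunk_len, upper_arm, forearm, hand_offset, shoulder_halfwidth)) {
    assert_number(len, "segment length", 0, strict_lower = TRUE)
  }
  if (elbow_start_deg < 0 || elbow_start_deg + elbow_range_deg > 180) {
    abort("elbow angle range must stay inside [0, 180] degrees (non-physical otherwise)")
  }
  if (shoulder_start_deg + shoulder_range_deg > 170) {
    abort("shoulder elevation beyond 170 degrees is non-physical")
  }
  side <- match_label(side, c("left", "right"), "side")
  structure(as.list(environment()), class = "reach_profile")
}

skeleton_joints <- c(
  "spine_base", "shoulder_center", "acromion_left", "acromion_right",
  "elbow", "wrist", "hand"
)

# minimum-jerk ramp 0 -> 1 on s in [0, 1]
minjerk <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  10 * s^3 - 15 * s^4 + 6 * s^5
}

# normalized movement phase (0 rest, 1 fully reached) for times t given cues
reach_phase <- function(t, cues, move_s = 2, return_s = 2) {
  phase <- numeric(length(t))
  for (cue in cues) {
    up <- t >= cue & t < cue + move_s
    down <- t >= cue + move_s & t < cue + move_s + return_s
    phase[up] <- minjerk((t[up] - cue) / move_s)
    phase[down] <- minjerk(1 - (t[down] - cue - move_s) / return_s)
  }
  phase
}

#' Generate a synthetic skeleton trace for a paced reaching run
#'
#' Forward-simulates 30 Hz joint positions (spine base, shoulder center,
#' both acromions, reaching-side elbow, wrist and hand) executing the cued
#' reaches of `schedule`. The coordinate frame is right-handed with +y
#' vertical up and +z anterior (toward the target). The injected angular
#' excursions are recorded in the trace's `ground_truth` attribute so that
#' pipeline recovery can be validated.
#'
#' @param profile A [reach_profile()].
#' @param schedule A reach [generate_block_schedule()].
#' @param seed Integer seed; identical seeds give identical traces.
#' @param rate Sampling rate (Hz), nominally 30.
#' @param pre_roll Seconds of recording before the first task onset.
#' @return A `skeleton_trace` tibble: `time` plus `<joint>_x/_y/_z` columns
#'   in mm, with attributes `rate`, `side` and `ground_truth`.
#' @examples
#' sched <- generate_block_schedule("reach", "paretic", "SAU", 1)
#' trace <- generate_reach_skeleton(reach_profile(trunk_range_deg = 20),
#'                                  sched, seed = 1)
#' range(trunk_flexion_angle(trace)$angle)
#' @export
generate_reach_skeleton <- function(profile, schedule, seed,
                                    rate = 30, pre_roll = 5) {
  stopifnot(inherits(profile, "reach_profile"))
  if (attr(schedule, "task") != "reach") abort("schedule is not a reach schedule")
  assert_number(rate, "rate", 0, strict_lower = TRUE)

  p <- profile
  t <- seq(-pre_roll, schedule_duration(schedule), by = 1 / rate)
  cues <- movement_cues(schedule)$onset
  s <- reach_phase(t, cues)

  d2r <- pi / 180
  theta <- (p$trunk_range_deg * s) * d2r              # trunk flexion
  alpha <- (p$shoulder_start_deg + p$shoulder_range_deg * s) * d2r
  phi <- (p$elbow_start_deg + p$elbow_range_deg * s) * d2r

  sgn <- if (p$side == "right") 1 else -1
  spine <- cbind(x = 0, y = 800, z = 0)[rep(1, length(t)), , drop = FALSE]
  shoulder_center <- cbind(
    x = 0,
    y = 800 + p$trunk_len * cos(theta),
    z = p$trunk_len * sin(theta)
  )
  acr_r <- shoulder_center + cbind(rep(p$shoulder_halfwidth, length(t)), 0, 0)
  acr_l <- shoulder_center - cbind(rep(p$shoulder_halfwidth, length(t)), 0, 0)
  acr <- if (p$side == "right") acr_r else acr_l

  # sagittal-plane arm: direction at angle psi from vertical-down
  dirv <- function(psi) cbind(x = 0, y = -cos(psi), z = sin(psi))
  elbow <- acr + p$upper_arm * dirv(alpha)
  fore_ang <- alpha + (pi - phi)            # interior elbow angle = phi
  wrist <- elbow + p$forearm * dirv(fore_ang)
  hand <- wrist + p$hand_offset * dirv(fore_ang)

  joints <- list(
    spine_base = spine, shoulder_center = shoulder_center,
    acromion_left = acr_l, acromion_right = acr_r,
    elbow = elbow, wrist = wrist, hand = hand
  )
  out <- withr::with_seed(seed, {
    cols <- purrr::imap(joints, function(m, nm) {
      m <- m + matrix(rnorm(length(m), sd = p$jitter_sd), ncol = 3)
      colnames(m) <- paste(nm, c("x", "y", "z"), sep = "_")
      as_tibble(m)
    })
    dplyr::bind_cols(tibble(time = t), cols)
  })
  structure(out,
    rate = rate, side = p$side,
    ground_truth = list(
      trunk_range_deg = p$trunk_range_deg,
      elbow_range_deg = p$elbow_range_deg,
      shoulder_range_deg = p$shoulder_range_deg,
      trunk_len = p$trunk_len
    ),
    class = c("skeleton_trace", class(out))
  )
}

#' Circle geometry of the steering task
#'
#' Defaults follow the task screen: a circular track of 33 in (838.2 mm)
#' circumference, i.e. nominal radius `838.2 / (2 * pi)` mm, with a 2 cm
#' tunnel.
#'
#' @param center Circle center, length-2 numeric (mm).
#' @param radius Nominal track radius R0 (mm).
#' @param tunnel_width Tunnel width W (mm), > 0.
#' @return A list of class `circle_geometry`.
#' @export
circle_geometry <- function(center = c(0, 0), radius = 838.2 / (2 * pi),
                            tunnel_width = 20) {
  stopifnot(length(center) == 2, is.numeric(center))
  assert_number(radius, "radius", 0, strict_lower = TRUE)
  assert_number(tunnel_width, "tunnel_width", 0, strict_lower = TRUE)
  structure(list(center = as.numeric(center), radius = radius,
                 tunnel_width = tunnel_width),
            class = "circle_geometry")
}

#' Generate a synthetic cursor trace for the circular steering task
#'
#' The cursor advances clockwise at a constant angular rate
#' `2 * pi * lap_rate` rad/s on a circle of the given geometry, with
#' independent Gaussian radial noise per sample. `lap_rate` and `radial_sd`
#' are stored in the `ground_truth` attribute.
#'
#' @param lap_rate Laps per second (> 0).
#' @param radial_sd Radial noise SD (mm, >= 0).
#' @param geometry A [circle_geometry()].
#' @param duration Trace duration (s, > 0).
#' @param seed Integer seed.
#' @param rate Cursor sampling rate (Hz).
#' @param t0 Time of the first sample (s); defaults to 0.
#' @return A `cursor_trace` tibble with `time`, `x`, `y` (mm) and
#'   attributes `geometry`, `rate`, `ground_truth`.
#' @examples
#' tr <- generate_steering_trace(0.5, 3, duration = 20, seed = 1)
#' steering_metrics(tr)
#' @export
generate_steering_trace <- function(lap_rate, radial_sd,
                                    geometry = circle_geometry(),
                                    duration, seed, rate = 60, t0 = 0) {
  assert_number(lap_rate, "lap_rate", 0, strict_lower = TRUE)
  assert_number(radial_sd, "radial_sd", 0)
  assert_number(duration, "duration", 0, strict_lower = TRUE)
  stopifnot(inherits(geometry, "circle_geometry"))

  t <- seq(t0, t0 + duration, by = 1 / rate)
  out <- withr::with_seed(seed, {
    theta0 <- runif(1, 0, 2 * pi)
    theta <- theta0 - 2 * pi * lap_rate * (t - t0)   # clockwise
    r <- geometry$radius + rnorm(length(t), sd = radial_sd)
    tibble(
      time = t,
      x = geometry$center[1] + r * cos(theta),
      y = geometry$center[2] + r * sin(theta)
    )
  })
  structure(out,
    geometry = geometry, rate = rate,
    ground_truth = list(lap_rate = lap_rate, radial_sd = radial_sd),
    class = c("cursor_trace", class(out))
  )
}
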