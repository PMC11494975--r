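#' Trunk anterior-flexion angle series
#'
#' Angle between the spine-base to shoulder-center vector and the vertical
#' axis, projected into the sagittal (vertical-anterior) plane: 0 deg is
#' upright, positive is forward lean. Used as the trunk-compensation
#' measure in both functional tasks.
#'
#' @param trace A `skeleton_trace` (see [generate_reach_skeleton()] or
#'   [import_session()]).
#' @return A tibble with `time` and `angle` (degrees). Frames with a
#'   degenerate zero-length trunk vector are dropped.
#' @export
trunk_flexion_angle <- function(trace) {
  need <- c("spine_base_y", "spine_base_z", "shoulder_center_y",
            "shoulder_center_z")
  if (!all(need %in% names(trace))) {
    abort("trace lacks spine_base / shoulder_center columns")
  }
  vy <- trace$shoulder_center_y - trace$spine_base_y
  vz <- trace$shoulder_center_z - trace$spine_base_z
  len <- sqrt(vy^2 + vz^2)
  ok <- len > .Machine$double.eps^0.5
  # sagittal-plane angle from vertical; anterior (+z) lean is positive
  angle <- atan2(vz[ok], vy[ok]) * 180 / pi
  tibble(time = trace$time[ok], angle = angle)
}

#' Interior elbow angle series
#'
#' Per-frame interior angle at the elbow between the elbow-to-shoulder
#' (acromion of the reaching side) and elbow-to-wrist vectors; 180 deg is a
#' fully extended arm. Its within-reach range is the whole-arm-use measure.
#'
#' @inheritParams trunk_flexion_angle
#' @param side Reaching side; defaults to the trace's `side` attribute.
#' @return A tibble with `time` and `angle` (degrees); frames with a
#'   zero-length segment are dropped.
#' @export
elbow_angle <- function(trace, side = NULL) {
  side <- side %||% attr(trace, "side") %||% "right"
  acr <- paste0("acromion_", side, "_", c("x", "y", "z"))
  need <- c(acr, paste0("elbow_", c("x", "y", "z")),
            paste0("wrist_", c("x", "y", "z")))
  if (!all(need %in% names(trace))) {
    abort("trace lacks acromion / elbow / wrist columns for the reaching side")
  }
  u <- cbind(trace[[acr[1]]] - trace$elbow_x,
             trace[[acr[2]]] - trace$elbow_y,
             trace[[acr[3]]] - trace$elbow_z)
  v <- cbind(trace$wrist_x - trace$elbow_x,
             trace$wrist_y - trace$elbow_y,
             trace$wrist_z - trace$elbow_z)
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  ok <- nu > .Machine$double.eps^0.5 & nv > .Machine$double.eps^0.5
  cosang <- rowSums(u * v)[ok] / (nu[ok] * nv[ok])
  angle <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  tibble(time = trace$time[ok], angle = angle)
}

#' Low-pass smooth a skeleton trace
#'
#' Zero-phase Butterworth low-pass on every joint coordinate. Functional
#' reaching lives well below a few Hz, while sensor jitter is broadband;
#' without smoothing, min/max angle ranges and frame-to-frame velocities
#' are inflated by noise extremes.
#'
#' @param trace A `skeleton_trace`.
#' @param cutoff Low-pass cutoff (Hz).
#' @param order Butterworth order.
#' @return The smoothed `skeleton_trace` (attributes preserved).
#' @export
smooth_skeleton <- function(trace, cutoff = 2, order = 2) {
  rate <- attr(trace, "rate") %||% 30
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  out <- as_tibble(trace)
  for (col in setdiff(names(out), "time")) {
    out[[col]] <- as.numeric(signal::filtfilt(bf, out[[col]]))
  }
  structure(out,
    rate = rate, side = attr(trace, "side"),
    ground_truth = attr(trace, "ground_truth"),
    class = c("skeleton_trace", class(out))
  )
}

#' Segment a recording into outward-reach movement windows
#'
#' One window per movement cue, from cue onset to onset + `move_s`
#' (the "go" phase of the 4 s pacing), clipped to the recording span.
#' Cues entirely outside the recording are dropped with a warning.
#'
#' @param trace A `skeleton_trace`.
#' @param schedule A reach [generate_block_schedule()].
#' @param move_s Outward-movement duration after each cue (s).
#' @return A tibble with `block`, `segment`, `start`, `end` (s).
#' @export
segment_reaches <- function(trace, schedule, move_s = 2) {
  cues <- movement_cues(schedule)
  if (nrow(cues) == 0) {
    return(tibble(block = integer(), segment = integer(),
                  start = numeric(), end = numeric()))
  }
  span <- range(trace$time)
  ti <- task_intervals(schedule)
  segs <- tibble(
    block = cues$block,
    segment = seq_len(nrow(cues)),
    start = cues$onset,
    end = pmin(cues$onset + move_s,
               ti$onset[match(cues$block, ti$block)] +
                 ti$duration[match(cues$block, ti$block)])
  )
  out_of_span <- segs$start >= span[2] | segs$end <= span[1]
  if (any(out_of_span)) {
    warn(sprintf("%d movement cue(s) outside the recording span were dropped",
                 sum(out_of_span)))
    segs <- segs[!out_of_span, ]
  }
  clipped <- segs$end > span[2] | segs$start < span[1]
  if (any(clipped)) {
    warn(sprintf("%d movement segment(s) clipped at the recording boundary",
                 sum(clipped)))
    segs$start <- pmax(segs$start, span[1])
    segs$end <- pmin(segs$end, span[2])
  }
  segs
}

#' Reach kinematics: trunk/elbow ranges, hand velocity, arm use
#'
#' Per movement segment (see [segment_reaches()]) computes the range
#' (max - min) of the trunk-flexion and elbow angles, the mean
#' frame-to-frame Euclidean speed of the hand joint, and the arm-use share
#' of the forward hand displacement; segment values are averaged within
#' block and then across blocks.
#'
#' Arm use (AU, %) is `100 * (hand forward displacement - acromion forward
#' displacement) / hand forward displacement` over the outward reach: the
#' fraction of target approach produced by the arm rather than by trunk
#' flexion. Segments with non-positive hand forward displacement are
#' excluded from AU.
#'
#' @param trace A `skeleton_trace`.
#' @param schedule A reach [generate_block_schedule()].
#' @param move_s Outward-movement duration after each cue (s).
#' @param smooth_hz Low-pass cutoff applied via [smooth_skeleton()] before
#'   metric computation; `NULL` disables smoothing.
#' @return A one-row tibble of class `reach_metrics`: `trunk_flexion_range`
#'   and `elbow_extension_range` (degrees), `hand_mean_velocity` (mm/s),
#'   `arm_use` (%), `n_segments`.
#' @export
reach_metrics <- function(trace, schedule, move_s = 2, smooth_hz = 2) {
  if (!is.null(smooth_hz)) trace <- smooth_skeleton(trace, cutoff = smooth_hz)
  segs <- segment_reaches(trace, schedule, move_s = move_s)
  if (nrow(segs) == 0) abort("no valid movement segments in this trial")
  trunk <- trunk_flexion_angle(trace)
  elbow <- elbow_angle(trace)
  side <- attr(trace, "side") %||% "right"
  acr_z <- paste0("acromion_", side, "_z")

  per_seg <- purrr::map_dfr(seq_len(nrow(segs)), function(i) {
    inw <- function(tt) tt >= segs$start[i] & tt <= segs$end[i]
    tr <- trunk$angle[inw(trunk$time)]
    el <- elbow$angle[inw(elbow$time)]
    idx <- which(inw(trace$time))
    if (length(idx) < 2 || length(tr) < 2 || length(el) < 2) {
      return(tibble(block = segs$block[i], trunk_range = NA_real_,
                    elbow_range = NA_real_, velocity = NA_real_,
                    arm_use = NA_real_))
    }
    dx <- diff(trace$hand_x[idx])
    dy <- diff(trace$hand_y[idx])
    dz <- diff(trace$hand_z[idx])
    dt <- diff(trace$time[idx])
    speed <- mean(sqrt(dx^2 + dy^2 + dz^2) / dt)
    hand_fwd <- trace$hand_z[idx[length(idx)]] - trace$hand_z[idx[1]]
    acr_fwd <- trace[[acr_z]][idx[length(idx)]] - trace[[acr_z]][idx[1]]
    au <- if (hand_fwd > 0) 100 * (hand_fwd - acr_fwd) / hand_fwd else NA_real_
    tibble(block = segs$block[i], trunk_range = max(tr) - min(tr),
           elbow_range = max(el) - min(el), velocity = speed, arm_use = au)
  })
  if (all(is.na(per_seg$trunk_range))) {
    abort("all movement segments invalid in this trial")
  }
  by_block <- per_seg |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(dplyr::across(
      c("trunk_range", "elbow_range", "velocity", "arm_use"),
      ~ mean(.x, na.rm = TRUE)
    ), .groups = "drop")
  out <- tibble(
    trunk_flexion_range = mean(by_block$trunk_range, na.rm = TRUE),
    elbow_extension_range = mean(by_block$elbow_range, na.rm = TRUE),
    hand_mean_velocity = mean(by_block$velocity, na.rm = TRUE),
    arm_use = mean(by_block$arm_use, na.rm = TRUE),
    n_segments = sum(!is.na(per_seg$trunk_range))
  )
  class(out) <- c("reach_metrics", class(out))
  out
}

#' Proximal-arm non-use from the two reaching conditions
#'
#' PANU is the arm-use gap between the maximal (trunk-restrained, MAU) and
#' spontaneous (SAU) conditions of the same subject and hand:
#' `AU_MAU - AU_SAU`, in percent. A positive PANU means the subject can use
#' the arm more than they spontaneously do; negative values are allowed
#' (and flagged with a warning) but unusual.
#'
#' @param sau,mau [reach_metrics()] rows for the spontaneous and maximal
#'   conditions of one subject/hand.
#' @return PANU in percent (scalar).
#' @export
panu <- function(sau, mau) {
  if (is.na(sau$arm_use) || is.na(mau$arm_use)) {
    abort("arm_use missing in one of the conditions")
  }
  p <- mau$arm_use - sau$arm_use
  if (p < 0) warn(sprintf("negative PANU (%.1f%%): MAU arm use below SAU", p))
  p
}

#' Steering-law performance metrics for the circular steering task
#'
#' From the cursor's polar coordinates about the circle center: mean radius
#' `R`, radius SD `sigma`, effective width `We = sqrt(2*pi*e) * sigma`,
#' effective difficulty `IDe = 2*pi*R / We` (bits), laps from the unwrapped
#' angle, movement time `MT` (s/lap), effective index of performance
#' `IPe = IDe / MT` (bits/s), `speed = 1/MT` (laps/s), accuracy
#' `bias = We / W`, and the fraction of samples outside the tunnel
#' (`|r - R0| > W/2`).
#'
#' Degenerate inputs follow the contract: `sigma = 0` gives `We = 0` and
#' undefined (`NA`) `IDe`/`IPe`; zero laps give undefined `MT`/`IPe`.
#'
#' @param trace A `cursor_trace`.
#' @param schedule Optional `block_schedule`; when given, metrics are
#'   computed per task interval and averaged across blocks.
#' @param geometry A [circle_geometry()]; defaults to the trace's attribute.
#' @return A one-row tibble of class `steering_metrics` with columns `R`,
#'   `sigma`, `We`, `IDe`, `MT`, `IPe`, `speed`, `bias`, `error_rate`,
#'   `laps`, `duration`.
#' @export
steering_metrics <- function(trace, schedule = NULL, geometry = NULL) {
  geometry <- geometry %||% attr(trace, "geometry")
  if (is.null(geometry)) abort("no circle geometry available for this trace")

  one <- function(tt, x, y) {
    if (length(tt) < 2) abort("need >= 2 samples inside the task interval")
    r <- sqrt((x - geometry$center[1])^2 + (y - geometry$center[2])^2)
    theta <- atan2(y - geometry$center[2], x - geometry$center[1])
    # unwrap
    dtheta <- diff(theta)
    dtheta <- dtheta - 2 * pi * round(dtheta / (2 * pi))
    sweep <- sum(dtheta)
    duration <- tt[length(tt)] - tt[1]
    R <- mean(r)
    sigma <- sd(r)
    if (sigma <= 1e-9 * max(R, 1)) sigma <- 0 # numerically perfect circle
    We <- sqrt(2 * pi * exp(1)) * sigma
    laps <- abs(sweep) / (2 * pi)
    MT <- if (laps > 0) duration / laps else NA_real_
    IDe <- if (We > 0) 2 * pi * R / We else NA_real_
    IPe <- if (!is.na(IDe) && !is.na(MT)) IDe / MT else NA_real_
    tibble(
      R = R, sigma = sigma, We = We, IDe = IDe, MT = MT, IPe = IPe,
      speed = if (!is.na(MT)) 1 / MT else NA_real_,
      bias = We / geometry$tunnel_width,
      error_rate = mean(abs(r - geometry$radius) >
                          geometry$tunnel_width / 2),
      laps = laps, duration = duration
    )
  }

  if (is.null(schedule)) {
    out <- one(trace$time, trace$x, trace$y)
  } else {
    ti <- task_intervals(schedule)
    rows <- purrr::map_dfr(seq_len(nrow(ti)), function(i) {
      inw <- trace$time >= ti$onset[i] &
        trace$time <= ti$onset[i] + ti$duration[i]
      one(trace$time[inw], trace$x[inw], trace$y[inw])
    })
    out <- dplyr::summarise(rows, dplyr::across(dplyr::everything(),
                                                ~ mean(.x, na.rm = FALSE)))
  }
  class(out) <- c("steering_metrics", class(out))
  out
}
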