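#' Build the timed block schedule for a task run
#'
#' Both functional tasks follow the same block design: 20 s of task
#' alternating with 20 s of rest. Paced reaching additionally carries five
#' movement cues per task block at 4 s spacing ("go" for 2 s, "stop" for
#' 2 s); circular steering is continuous over the task interval. The
#' schedule anchors every downstream epoching step (kinematic segmentation,
#' fNIRS block averaging, EEG spectral perturbation windows).
#'
#' Time zero is the onset of the first task block, so `n_blocks` reach
#' blocks span `n_blocks * 40` seconds. Recordings are expected to start a
#' few seconds before zero (see the `pre_roll` argument of the signal
#' generators) so that pre-onset baselines exist for the first block.
#'
#' @param task `"reach"` or `"steer"`.
#' @param hand Hand label: one of `"dominant"`, `"non-dominant"`,
#'   `"non-paretic"`, `"paretic"`.
#' @param condition Arm-use condition, `"SAU"` (spontaneous) or `"MAU"`
#'   (maximal, shoulders restrained). Steering runs are conventionally
#'   labelled `"SAU"`.
#' @param n_blocks Number of task blocks (>= 1); the protocol default is 3
#'   per hand (and per condition for reaching).
#' @param block_s,rest_s Task and rest interval durations in seconds.
#' @param cue_spacing_s Cue spacing within a reach block (seconds).
#'
#' @return A `block_schedule`: a tibble with columns `event`
#'   (`"task"`/`"rest"`/`"cue"`), `block`, `onset` and `duration` (seconds),
#'   with the run labels stored as attributes `task`, `hand`, `condition`.
#' @examples
#' sched <- generate_block_schedule("reach", "paretic", "SAU", n_blocks = 3)
#' schedule_duration(sched)       # 120 s
#' sum(sched$event == "cue")      # 15 movement cues
#' @export
generate_block_schedule <- function(task, hand, condition, n_blocks,
                                    block_s = 20, rest_s = 20,
                                    cue_spacing_s = 4) {
  task <- match_label(task, task_levels, "task")
  hand <- match_label(hand, hand_levels, "hand")
  condition <- match_label(condition, condition_levels, "condition")
  if (!is.numeric(n_blocks) || length(n_blocks) != 1 || n_blocks < 1 ||
      n_blocks != round(n_blocks)) {
    abort("n_blocks must be a whole number >= 1")
  }
  assert_number(block_s, "block_s", 0, strict_lower = TRUE)
  assert_number(rest_s, "rest_s", 0, strict_lower = TRUE)

  blocks <- purrr::map_dfr(seq_len(n_blocks), function(b) {
    onset <- (b - 1) * (block_s + rest_s)
    rows <- tibble(
      event = c("task", "rest"),
      block = b,
      onset = c(onset, onset + block_s),
      duration = c(block_s, rest_s)
    )
    if (task == "reach") {
      cue_onsets <- onset + seq(0, block_s - cue_spacing_s, by = cue_spacing_s)
      rows <- dplyr::bind_rows(rows, tibble(
        event = "cue", block = b, onset = cue_onsets,
        duration = cue_spacing_s / 2
      ))
    }
    rows
  })
  blocks <- dplyr::arrange(blocks, .data$onset, .data$event)
  structure(blocks,
    task = task, hand = hand, condition = condition,
    class = c("block_schedule", class(blocks))
  )
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf(
    "<block_schedule> task=%s hand=%s condition=%s (%d block(s), %.0f s)\n",
    attr(x, "task"), attr(x, "hand"), attr(x, "condition"),
    max(x$block), schedule_duration(x)
  ))
  NextMethod()
}

#' Total scheduled duration in seconds
#' @param schedule A [generate_block_schedule()] result.
#' @return Scalar duration (s) from time 0 to the end of the last interval.
#' @export
schedule_duration <- function(schedule) {
  iv <- schedule[schedule$event %in% c("task", "rest"), ]
  max(iv$onset + iv$duration)
}

#' Task / rest intervals and movement cues of a schedule
#'
#' Convenience accessors returning one row per interval or cue.
#' @inheritParams schedule_duration
#' @return A tibble with `block`, `onset`, `duration`.
#' @export
task_intervals <- function(schedule) {
  as_tibble(schedule[schedule$event == "task",
                     c("block", "onset", "duration")])
}

#' @rdname task_intervals
#' @export
rest_intervals <- function(schedule) {
  as_tibble(schedule[schedule$event == "rest",
                     c("block", "onset", "duration")])
}

#' @rdname task_intervals
#' @export
movement_cues <- function(schedule) {
  as_tibble(schedule[schedule$event == "cue",
                     c("block", "onset", "duration")])
}

#' Write / read a block schedule as JSON
#'
#' @param schedule A `block_schedule`.
#' @param path File path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns the `block_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  payload <- list(
    task = attr(schedule, "task"),
    hand = attr(schedule, "hand"),
    condition = attr(schedule, "condition"),
    events = as.data.frame(schedule)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- as_tibble(payload$events)
  structure(ev,
    task = payload$task, hand = payload$hand, condition = payload$condition,
    class = c("block_schedule", class(ev))
  )
}
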