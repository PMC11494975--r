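#' Default EEG band definitions and sensorimotor montage
#'
#' Alpha (8-13 Hz) and beta (14-29 Hz) rhythms over the bilateral primary
#' sensorimotor cortex; 8 electrodes of the 10-10 system (right: C4, FC2,
#' FC6, CP2; left: C3, FC1, FC3, CP1).
#'
#' @return `eeg_bands()`: a named list of `c(low, high)` Hz pairs.
#'   `eeg_montage()`: a tibble with `channel`, `hemisphere`.
#' @export
eeg_bands <- function() {
  list(alpha = c(8, 13), beta = c(14, 29))
}

#' @rdname eeg_bands
#' @export
eeg_montage <- function() {
  tibble(
    channel = c("C3", "FC1", "FC3", "CP1", "C4", "FC2", "FC6", "CP2"),
    hemisphere = rep(c("left", "right"), each = 4)
  )
}

#' Movement / post-movement / baseline windows implied by a schedule
#'
#' For paced reaching, each 4 s cue splits into a 2 s movement ("go") and a
#' 2 s post-movement ("stop") window. For circular steering, the whole 20 s
#' task interval is movement and the first `steer_post_s` seconds of the
#' following rest are the post-movement (synchronization) window. The
#' spectral baseline is the rest interval trimmed by `baseline_trim`
#' (seconds cut from its start and end) so that post-movement
#' synchronization never leaks into the baseline.
#'
#' @param schedule A [generate_block_schedule()] result.
#' @param move_s,post_s Movement / post-movement window lengths per reach
#'   cue (s).
#' @param steer_post_s Post-task synchronization window for steering (s).
#' @param baseline_trim Length-2: seconds trimmed from the start and end of
#'   each rest interval for the baseline.
#' @return A list of tibbles (`onset`, `duration`, seconds): `move`, `post`,
#'   `baseline` in absolute time, and `move_rel`, `post_rel` relative to the
#'   task-block onset.
#' @export
erd_ers_windows <- function(schedule, move_s = 2, post_s = 2,
                            steer_post_s = 4, baseline_trim = c(6, 2)) {
  task <- attr(schedule, "task")
  ti <- task_intervals(schedule)
  ri <- rest_intervals(schedule)
  if (task == "reach") {
    cues <- movement_cues(schedule)
    move <- tibble(onset = cues$onset, duration = move_s)
    post <- tibble(onset = cues$onset + move_s, duration = post_s)
    cue_rel <- cues$onset - ti$onset[match(cues$block, ti$block)]
    move_rel <- tibble(onset = sort(unique(cue_rel)), duration = move_s)
    post_rel <- tibble(onset = move_rel$onset + move_s, duration = post_s)
  } else {
    move <- tibble(onset = ti$onset, duration = ti$duration)
    post <- tibble(onset = ri$onset, duration = steer_post_s)
    move_rel <- tibble(onset = 0, duration = ti$duration[1])
    post_rel <- tibble(onset = ti$duration[1], duration = steer_post_s)
  }
  baseline <- tibble(
    onset = ri$onset + baseline_trim[1],
    duration = pmax(ri$duration - sum(baseline_trim), 0)
  )
  list(move = move, post = post, baseline = baseline,
       move_rel = move_rel, post_rel = post_rel)
}

# 1/f (pink) amplitude-shaped Gaussian noise, sd-scaled.
# Synthesised at the next highly composite length (fft is O(n^2) at prime n)
# and truncated.
pink_noise <- function(n, sd = 1) {
  m <- stats::nextn(n, c(2, 3, 5))
  nf <- floor(m / 2)
  amps <- 1 / sqrt(seq_len(nf))
  phases <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amps, argument = phases)
  full <- c(0, spec, if (m %% 2 == 0) Conj(rev(spec[-nf])) else Conj(rev(spec)))
  x <- Re(fft(full, inverse = TRUE))[seq_len(n)]
  x / sd(x) * sd
}

#' Generate a synthetic 8-channel EEG recording for one run
#'
#' Each channel is a 1/f background plus independent band-limited Gaussian
#' alpha and beta oscillators. Oscillator amplitude is modulated so that
#' band power is multiplied by `10^(erd_db/10)` inside the movement windows
#' and `10^(ers_db/10)` inside the post-movement windows of the schedule
#' (see [erd_ers_windows()]), relative to rest. The injected modulation
#' depths are stored in `ground_truth`.
#'
#' @param schedule A [generate_block_schedule()] result.
#' @param erd_db Named vector of movement-related power changes in dB per
#'   band (must be <= 0), e.g. `c(alpha = -2, beta = -3)`.
#' @param ers_db Named vector of post-movement power changes in dB per band
#'   (must be >= 0).
#' @param montage Channel map tibble (`channel`, `hemisphere`).
#' @param seed Integer seed.
#' @param rate Sampling rate (Hz), nominally 500.
#' @param pre_roll Seconds recorded before the first task onset.
#' @param bands Band definitions, as [eeg_bands()]; bands must not touch
#'   0 Hz.
#' @param osc_sd Oscillator amplitude at rest (uV, per band).
#' @param background_sd 1/f background amplitude (uV).
#' @param windows Window definition, defaults to `erd_ers_windows(schedule)`.
#' @return An `eeg_recording`: a tibble `time` plus one column per channel
#'   (uV), with attributes `rate`, `montage`, `bands`, `ground_truth`.
#' @export
generate_eeg <- function(schedule, erd_db = c(alpha = -2, beta = -3),
                         ers_db = c(alpha = 1, beta = 2),
                         montage = eeg_montage(), seed, rate = 500,
                         pre_roll = 5, bands = eeg_bands(),
                         osc_sd = 10, background_sd = 1.5,
                         windows = NULL) {
  stopifnot(all(names(erd_db) %in% names(bands)),
            all(names(ers_db) %in% names(bands)))
  if (any(erd_db > 0)) abort("erd_db must be <= 0 (desynchronization)")
  if (any(ers_db < 0)) abort("ers_db must be >= 0 (synchronization)")
  for (b in bands) {
    if (b[1] <= 0) abort("band specs must not overlap 0 Hz")
    if (b[2] >= rate / 2) abort("band specs must stay below the Nyquist rate")
  }
  windows <- windows %||% erd_ers_windows(schedule)

  t <- seq(-pre_roll, schedule_duration(schedule), by = 1 / rate)
  n <- length(t)

  in_windows <- function(w) {
    inside <- rep(FALSE, n)
    for (i in seq_len(nrow(w))) {
      inside <- inside | (t >= w$onset[i] & t < w$onset[i] + w$duration[i])
    }
    inside
  }
  move_mask <- in_windows(windows$move)
  post_mask <- in_windows(windows$post) & !move_mask

  data <- withr::with_seed(seed, {
    purrr::map(montage$channel, function(ch) {
      x <- pink_noise(n, sd = background_sd)
      for (bn in names(bands)) {
        bf <- signal::butter(4, bands[[bn]] / (rate / 2), type = "pass")
        osc <- as.numeric(signal::filtfilt(bf, rnorm(n)))
        osc <- osc / sd(osc) * osc_sd
        gain <- rep(1, n)
        if (bn %in% names(erd_db)) gain[move_mask] <- 10^(erd_db[[bn]] / 20)
        if (bn %in% names(ers_db)) gain[post_mask] <- 10^(ers_db[[bn]] / 20)
        x <- x + osc * gain
      }
      x
    })
  })
  out <- dplyr::bind_cols(
    tibble(time = t),
    setNames(as_tibble(data, .name_repair = "minimal"), montage$channel)
  )
  structure(out,
    rate = rate, montage = as_tibble(montage), bands = bands,
    ground_truth = list(erd_db = as.list(erd_db), ers_db = as.list(ers_db)),
    class = c("eeg_recording", class(out))
  )
}
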