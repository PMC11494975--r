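#' Preprocess an EEG recording
#'
#' Zero-phase Butterworth band-pass (default 1-40 Hz, order 4) per channel,
#' optional common-average re-reference, and block-epoch artifact rejection:
#' a block whose filtered amplitude exceeds `reject_uv` on any channel is
#' marked rejected and excluded from spectral averaging. More than 50%
#' rejected blocks is an error.
#'
#' @param rec An `eeg_recording` (see [generate_eeg()]).
#' @param low,high Band-pass corners (Hz).
#' @param order Butterworth order.
#' @param reject_uv Absolute amplitude rejection threshold (uV).
#' @param reference `"car"` (common average) or `"none"`.
#' @param schedule Optional `block_schedule` for epoch rejection; without
#'   it no epochs are rejected.
#' @return A filtered `eeg_recording` with attribute `rejected_blocks`.
#' @export
preprocess_eeg <- function(rec, low = 1, high = 40, order = 4,
                           reject_uv = 100, reference = c("car", "none"),
                           schedule = NULL) {
  reference <- match.arg(reference)
  rate <- attr(rec, "rate")
  chans <- attr(rec, "montage")$channel
  if (anyDuplicated(chans)) abort("channel labels must be unique")

  out <- as_tibble(rec)
  for (ch in chans) {
    out[[ch]] <- zerophase_bandpass(out[[ch]], rate, low, high, order)
  }
  if (reference == "car") {
    avg <- rowMeans(as.matrix(out[, chans]))
    for (ch in chans) out[[ch]] <- out[[ch]] - avg
  }

  rejected <- integer(0)
  if (!is.null(schedule)) {
    ti <- task_intervals(schedule)
    ri <- rest_intervals(schedule)
    for (b in ti$block) {
      from <- ti$onset[ti$block == b]
      to <- ri$onset[ri$block == b] + ri$duration[ri$block == b]
      idx <- out$time >= from & out$time < to
      if (max(abs(as.matrix(out[idx, chans]))) > reject_uv) {
        rejected <- c(rejected, b)
      }
    }
    if (length(rejected) > nrow(ti) / 2) {
      abort(sprintf("more than half of the epochs rejected (%d of %d)",
                    length(rejected), nrow(ti)))
    }
  }
  structure(out,
    rate = rate, montage = attr(rec, "montage"), bands = attr(rec, "bands"),
    ground_truth = attr(rec, "ground_truth"), rejected_blocks = rejected,
    class = c("eeg_recording", class(out))
  )
}

# Hann short-time power spectrum. Returns list(power[freq, frame], freq,
# centers) with frame center times on the recording's clock.
stft_power <- function(x, time, rate, window_s = 1, overlap = 0.9,
                       fmin = 1, fmax = 40) {
  n <- round(window_s * rate)
  hop <- max(1, round(n * (1 - overlap)))
  if (n > length(x)) abort("spectral window longer than the recording/epoch")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n) # periodic Hann
  starts <- seq(1, length(x) - n + 1, by = hop)
  freq <- (seq_len(n) - 1) * rate / n
  keep <- which(freq >= fmin & freq <= fmax)
  pw <- vapply(starts, function(s) {
    X <- fft(w * x[s:(s + n - 1)])
    (Mod(X)^2)[keep]
  }, numeric(length(keep)))
  centers <- time[starts] + (n - 1) / (2 * rate)
  list(power = matrix(pw, nrow = length(keep)), freq = freq[keep],
       centers = centers, window_s = window_s, hop_s = hop / rate)
}

#' Spectral estimator settings for [ersp()]
#'
#' @param window_s Hann window length (s).
#' @param overlap Fractional window overlap.
#' @param fmin,fmax Frequency range retained (Hz).
#' @param epoch_window Epoch span relative to task onset (s); must reach
#'   past the post-movement window of interest.
#' @return A list of class `ersp_spec`.
#' @export
ersp_spec <- function(window_s = 1, overlap = 0.9, fmin = 1, fmax = 40,
                      epoch_window = c(-2, 24)) {
  structure(as.list(environment()), class = "ersp_spec")
}

#' Event-related spectral perturbation map
#'
#' Per channel: sliding Hann short-time spectra over the whole recording;
#' the baseline power `B(f)` is the mean over all frames fully inside the
#' schedule's rest-baseline windows; epochs are cut around each retained
#' task-block onset and powers averaged across epochs in the power domain;
#' the map is `10*log10(P(t, f) / B(f))` in dB. Averaging power before
#' taking logs keeps the stationary-input map unbiased around 0 dB.
#'
#' @param rec A (preprocessed) `eeg_recording`.
#' @param schedule The run's `block_schedule`.
#' @param spec An [ersp_spec()].
#' @param windows Window definitions, defaults to
#'   [erd_ers_windows()]`(schedule)`.
#' @return An `ersp_map` tibble (`rel_time`, `frequency`, `channel`, `db`)
#'   with attributes `bands`, `windows`, `window_s`, `n_epochs`.
#' @export
ersp <- function(rec, schedule, spec = ersp_spec(), windows = NULL) {
  rate <- attr(rec, "rate")
  windows <- windows %||% erd_ers_windows(schedule)
  chans <- attr(rec, "montage")$channel
  rejected <- attr(rec, "rejected_blocks") %||% integer(0)
  ti <- task_intervals(schedule)
  onsets <- ti$onset[!ti$block %in% rejected]
  if (length(onsets) == 0) abort("no retained task epochs")
  if (round(spec$window_s * rate) > nrow(rec)) {
    abort("spectral window longer than the recording/epoch")
  }

  half <- spec$window_s / 2
  maps <- purrr::map(chans, function(ch) {
    sp <- stft_power(rec[[ch]], rec$time, rate, spec$window_s, spec$overlap,
                     spec$fmin, spec$fmax)
    in_baseline <- rep(FALSE, length(sp$centers))
    for (i in seq_len(nrow(windows$baseline))) {
      w0 <- windows$baseline$onset[i]
      w1 <- w0 + windows$baseline$duration[i]
      in_baseline <- in_baseline |
        (sp$centers >= w0 + half & sp$centers <= w1 - half)
    }
    if (!any(in_baseline)) abort("no spectral frames inside the baseline")
    B <- rowMeans(sp$power[, in_baseline, drop = FALSE])

    # epoch frame powers on a shared relative-time grid
    acc <- NULL
    count <- 0
    for (on in onsets) {
      rel <- sp$centers - on
      sel <- which(rel >= spec$epoch_window[1] & rel <= spec$epoch_window[2])
      bins <- round(rel[sel] / sp$hop_s)
      if (is.null(acc)) {
        bin_grid <- bins
        acc <- sp$power[, sel, drop = FALSE]
        count <- 1
      } else if (identical(bins, bin_grid)) {
        acc <- acc + sp$power[, sel, drop = FALSE]
        count <- count + 1
      }
    }
    P <- acc / count
    db <- 10 * log10(sweep(P, 1, B, "/"))
    tibble(
      rel_time = rep(bin_grid * sp$hop_s, each = length(sp$freq)),
      frequency = rep(sp$freq, length(bin_grid)),
      channel = ch,
      db = as.numeric(db)
    )
  })
  out <- dplyr::bind_rows(maps)
  structure(out,
    bands = attr(rec, "bands") %||% eeg_bands(), windows = windows,
    window_s = spec$window_s, n_epochs = length(onsets),
    class = c("ersp_map", class(out))
  )
}

#' Alpha/beta ERD and ERS band summaries of an ERSP map
#'
#' ERD is the mean dB change over the movement windows and ERS over the
#' post-movement windows, per frequency band and channel. Only map cells
#' whose full spectral-window support lies inside the requested time window
#' contribute; frames straddling a window edge would dilute the estimate
#' toward 0 dB. Signs are not clamped: ERD is expected negative, ERS
#' positive.
#'
#' @param map An [ersp()] result.
#' @param windows Windows relative to the task onset; defaults to the map's
#'   own `windows` attribute (`move_rel`, `post_rel`).
#' @param bands Band definitions; defaults to the map's `bands` attribute.
#' @return A `band_summary` tibble: `channel`, `band`, `erd_db`, `ers_db`.
#' @export
band_erd_ers <- function(map, windows = NULL, bands = NULL) {
  windows <- windows %||% attr(map, "windows")
  bands <- bands %||% attr(map, "bands")
  half <- (attr(map, "window_s") %||% 1) / 2

  cell_mean <- function(w, band) {
    inside <- rep(FALSE, nrow(map))
    for (i in seq_len(nrow(w))) {
      w0 <- w$onset[i]
      w1 <- w0 + w$duration[i]
      inside <- inside |
        (map$rel_time >= w0 + half & map$rel_time <= w1 - half)
    }
    inside <- inside & map$frequency >= band[1] & map$frequency <= band[2]
    if (!any(inside)) abort("empty window x band intersection in the ERSP map")
    # average in the power domain: the mean of per-cell dB is biased away
    # from the true power ratio when each cell averages few epochs
    map[inside, ] |>
      dplyr::group_by(.data$channel) |>
      dplyr::summarise(db = 10 * log10(mean(10^(.data$db / 10))),
                       .groups = "drop")
  }

  out <- purrr::map_dfr(names(bands), function(bn) {
    erd <- cell_mean(windows$move_rel, bands[[bn]])
    ers <- cell_mean(windows$post_rel, bands[[bn]])
    dplyr::full_join(
      dplyr::rename(erd, erd_db = "db"),
      dplyr::rename(ers, ers_db = "db"),
      by = "channel"
    ) |>
      dplyr::mutate(band = bn, .after = "channel")
  })
  class(out) <- c("band_summary", class(out))
  out
}

#' Hemisphere-averaged ERD/ERS with functional roles
#'
#' Same role algebra as [hemisphere_summary()]: the hemisphere opposite the
#' moving hand is contralateral; for stroke subjects the lesioned
#' hemisphere is ipsilesional.
#'
#' @param summary A [band_erd_ers()] result.
#' @param montage Channel map (`channel`, `hemisphere`).
#' @inheritParams hemisphere_summary
#' @return A tibble with `band`, `hemisphere`, `role`, `lesion_role`,
#'   `erd_db`, `ers_db`.
#' @export
hemisphere_summary_eeg <- function(summary, montage, moving_side,
                                   lesion_side = NULL) {
  purrr::map_dfr(unique(summary$band), function(bn) {
    hemisphere_summary(
      summary[summary$band == bn, c("channel", "erd_db", "ers_db")],
      montage, moving_side, lesion_side
    ) |>
      dplyr::mutate(band = bn, .before = 1)
  })
}
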