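# shared internal helpers

#' Match one of a set of labels, with an informative error
#' @noRd
match_label <- function(x, choices, what) {
  if (length(x) != 1 || is.na(x) || !x %in% choices) {
    abort(sprintf(
      "unknown %s '%s'; must be one of: %s",
      what, paste(x, collapse = ","), paste(choices, collapse = ", ")
    ))
  }
  x
}

assert_number <- function(x, what, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper
  if (!ok) {
    abort(sprintf(
      "%s must be a single finite number %s %s%s", what,
      if (strict_lower) ">" else ">=", lower,
      if (is.finite(upper)) paste0(" and <= ", upper) else ""
    ))
  }
  invisible(x)
}

hand_levels <- c("dominant", "non-dominant", "non-paretic", "paretic")
condition_levels <- c("SAU", "MAU")
task_levels <- c("reach", "steer")

# zero-phase Butterworth band-pass; falls back to high/low cascade
zerophase_bandpass <- function(x, fs, low, high, order = 3) {
  stopifnot(low > 0, high > low, high < fs / 2)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# linear interpolation of runs of NA up to max_gap consecutive samples;
# returns NULL if a longer gap remains
fill_small_gaps <- function(x, max_gap = 3) {
  if (!anyNA(x)) return(x)
  r <- rle(is.na(x))
  if (any(r$values & r$lengths > max_gap)) return(NULL)
  idx <- seq_along(x)
  out <- approx(idx[!is.na(x)], x[!is.na(x)], xout = idx, rule = 2)$y
  out
}
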