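#' Default extinction coefficients for the two measurement wavelengths
#'
#' Molar extinction coefficients (cm^-1 M^-1) of oxy- and deoxy-hemoglobin
#' at 760 and 850 nm, the standard continuous-wave NIRS wavelength pair.
#' Values are the commonly used compiled spectra; override per instrument if
#' calibrated coefficients are available.
#'
#' @return A 2 x 2 matrix with rows named by wavelength (`"760"`, `"850"`)
#'   and columns `hbo`, `hbr`.
#' @export
extinction_coefficients <- function() {
  matrix(
    c(
      1486.59, 3843.71, # 760 nm: hbo, hbr
      2526.39, 1798.64  # 850 nm
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("760", "850"), c("hbo", "hbr"))
  )
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style double-gamma: response peak near 6 s, undershoot near 16 s,
#' undershoot amplitude 1/6 of the peak. Normalised to a maximum of 1.
#'
#' @param t Time in seconds (>= 0 contributes; negative times return 0).
#' @param peak,undershoot Gamma shape peaks (s).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return Numeric vector of HRF values, max 1.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  g <- function(tt, m) {
    # gamma density with mode m, shape a (dispersion 1 s): a = m + 1
    a <- m + 1
    tt^(a - 1) * exp(-tt) / gamma(a) # rate 1; mode at a-1 = m
  }
  h[pos] <- g(tp, peak) - g(tp, undershoot) / ratio
  if (max(h) > 0) h <- h / max(h)
  h
}

#' Default bilateral fNIRS montage
#'
#' Four source-detector channels over each primary sensorimotor cortex.
#'
#' @return A tibble with columns `channel`, `hemisphere`.
#' @export
fnirs_montage <- function() {
  tibble(
    channel = c(paste0("L", 1:4), paste0("R", 1:4)),
    hemisphere = rep(c("left", "right"), each = 4)
  )
}

#' Physiological-noise specification for the fNIRS generator
#'
#' Sinusoidal cardiac, respiratory and Mayer-wave components plus a linear
#' drift and white measurement noise, all expressed in the oxy-hemoglobin
#' concentration domain (uM); deoxy-hemoglobin receives the same components
#' scaled by `hbr_scale`. Component frequencies are drawn once per channel
#' from the given ranges: physiological rhythms are not phase-locked to the
#' 40 s block cycle, and a fixed frequency commensurate with the block
#' length would never average out.
#'
#' @param cardiac_amp,resp_amp,mayer_amp Component amplitudes (uM).
#' @param cardiac_freq,resp_freq,mayer_freq Frequency ranges (Hz), length 2.
#' @param drift_amp Linear drift over the whole recording (uM).
#' @param white_sd White noise SD (uM).
#' @param hbr_scale Scale of the same components on HbR.
#' @param enabled Set `FALSE` for a noise-free forward model.
#' @return A list of class `fnirs_noise`.
#' @export
fnirs_noise <- function(cardiac_amp = 0.2, cardiac_freq = c(1.0, 1.2),
                        resp_amp = 0.3, resp_freq = c(0.25, 0.35),
                        mayer_amp = 0.4, mayer_freq = c(0.08, 0.12),
                        drift_amp = 0.5, white_sd = 0.1,
                        hbr_scale = 0.3, enabled = TRUE) {
  structure(as.list(environment()), class = "fnirs_noise")
}

#' Generate synthetic dual-wavelength optical densities for one run
#'
#' Builds the true per-channel oxy/deoxy-hemoglobin responses as a canonical
#' double-gamma HRF convolved with the task boxcar of `schedule`, scaled so
#' the clean response peaks at `hrf_amp` uM (HbR at `-hbr_ratio` times
#' that), adds physiological noise, and maps concentrations to
#' optical-density changes at 760/850 nm through the same extinction
#' matrix, source-detector distance and DPF that [od_to_hemoglobin()]
#' inverts. The clean (noise-free) response is kept in the `clean_response`
#' attribute and the injected amplitude in `ground_truth`.
#'
#' @param schedule A [generate_block_schedule()] result.
#' @param hrf_amp Peak amplitude of the clean HbO2 response (uM, >= 0).
#' @param noise A [fnirs_noise()] spec (use `enabled = FALSE` to disable).
#' @param montage Channel map tibble (`channel`, `hemisphere`).
#' @param seed Integer seed.
#' @param rate Sampling rate (Hz), nominally 10.
#' @param pre_roll Seconds recorded before the first task onset.
#' @param hbr_ratio HbR peak as a fraction of the HbO2 peak (applied with a
#'   negative sign).
#' @param distance_mm Source-detector distance (mm).
#' @param dpf Differential pathlength factor.
#' @return A `raw_optical` long tibble (`time`, `channel`, `wavelength`,
#'   `od`) with attributes `montage`, `distance_mm`, `dpf`, `rate`,
#'   `clean_response`, `ground_truth`.
#' @export
generate_fnirs <- function(schedule, hrf_amp, noise = fnirs_noise(),
                           montage = fnirs_montage(), seed,
                           rate = 10, pre_roll = 5, hbr_ratio = 1 / 3,
                           distance_mm = 30, dpf = 6) {
  assert_number(hrf_amp, "hrf_amp", 0)
  if (is.null(noise)) noise <- fnirs_noise(enabled = FALSE)
  if (!all(c("channel", "hemisphere") %in% names(montage)) ||
      any(is.na(montage$hemisphere)) ||
      !all(montage$hemisphere %in% c("left", "right"))) {
    abort("every montage channel needs a hemisphere label ('left'/'right')")
  }

  t <- seq(-pre_roll, schedule_duration(schedule), by = 1 / rate)
  # task boxcar convolved with the HRF, normalised to peak hrf_amp
  box <- rep(0, length(t))
  for (i in seq_len(nrow(task_intervals(schedule)))) {
    iv <- task_intervals(schedule)[i, ]
    box[t >= iv$onset & t < iv$onset + iv$duration] <- 1
  }
  kern <- hrf_double_gamma(seq(0, 32, by = 1 / rate))
  resp <- stats::convolve(box, rev(kern), type = "open")[seq_along(t)]
  if (max(resp) > 0 && hrf_amp > 0) {
    resp <- resp / max(resp) * hrf_amp
  } else {
    resp <- resp * 0
  }
  clean <- tibble(time = t, hbo = resp, hbr = -hbr_ratio * resp)

  E <- extinction_coefficients()
  path <- (distance_mm / 10) * dpf # cm

  od <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(montage)), function(i) {
      ch <- montage$channel[i]
      hbo <- clean$hbo
      hbr <- clean$hbr
      if (isTRUE(noise$enabled)) {
        comp <- function(amp, frange) {
          f <- runif(1, frange[1], frange[2])
          amp * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
        }
        n_hbo <- comp(noise$cardiac_amp, noise$cardiac_freq) +
          comp(noise$resp_amp, noise$resp_freq) +
          comp(noise$mayer_amp, noise$mayer_freq) +
          noise$drift_amp * (t - t[1]) / diff(range(t)) +
          rnorm(length(t), sd = noise$white_sd)
        hbo <- hbo + n_hbo
        hbr <- hbr + noise$hbr_scale *
          (comp(noise$cardiac_amp, noise$cardiac_freq) +
             comp(noise$resp_amp, noise$resp_freq) +
             comp(noise$mayer_amp, noise$mayer_freq) +
             noise$drift_amp * (t - t[1]) / diff(range(t)) +
             rnorm(length(t), sd = noise$white_sd))
      }
      # uM -> M, distances in cm: dOD = E %*% c * d * DPF
      od760 <- (E["760", "hbo"] * hbo + E["760", "hbr"] * hbr) * 1e-6 * path
      od850 <- (E["850", "hbo"] * hbo + E["850", "hbr"] * hbr) * 1e-6 * path
      tibble(
        time = rep(t, 2),
        channel = ch,
        wavelength = rep(c(760, 850), each = length(t)),
        od = c(od760, od850)
      )
    })
  })
  structure(od,
    montage = as_tibble(montage), distance_mm = distance_mm, dpf = dpf,
    rate = rate, clean_response = clean,
    ground_truth = list(hrf_amp = hrf_amp, hbr_ratio = hbr_ratio),
    class = c("raw_optical", class(od))
  )
}
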