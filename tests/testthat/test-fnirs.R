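sched <- generate_block_schedule("steer", "dominant", "SAU", 3)

test_that("MBLL inversion is linear and exactly inverts the forward model", {
  od <- generate_fnirs(sched, hrf_amp = 1,
                       noise = fnirs_noise(enabled = FALSE), seed = 1)
  hemo <- od_to_hemoglobin(od)
  clean <- attr(od, "clean_response")
  for (ch in unique(hemo$channel)) {
    d <- hemo[hemo$channel == ch, ]
    expect_equal(d$hbo, clean$hbo, tolerance = 1e-9)
    expect_equal(d$hbr, clean$hbr, tolerance = 1e-9)
  }
  # zero OD -> zero concentrations
  od0 <- od
  od0$od <- 0
  h0 <- od_to_hemoglobin(od0)
  expect_equal(max(abs(c(h0$hbo, h0$hbr))), 0)
  # doubling OD doubles concentrations
  od2 <- od
  od2$od <- 2 * od2$od
  h2 <- od_to_hemoglobin(od2)
  expect_equal(h2$hbo, 2 * hemo$hbo, tolerance = 1e-9)
  expect_equal(h2$hbr, 2 * hemo$hbr, tolerance = 1e-9)
})

test_that("MBLL rejects singular extinction tables and bad wavelengths", {
  od <- generate_fnirs(sched, hrf_amp = 1,
                       noise = fnirs_noise(enabled = FALSE), seed = 1)
  singular <- matrix(c(1, 2, 2, 4), 2, byrow = TRUE,
                     dimnames = list(c("760", "850"), c("hbo", "hbr")))
  expect_error(od_to_hemoglobin(od, extinction = singular), "singular")
  wrong <- extinction_coefficients()
  rownames(wrong) <- c("690", "830")
  expect_error(od_to_hemoglobin(od, extinction = wrong), "wavelength")
})

test_that("band-pass removes cardiac oscillation and keeps the HRF band", {
  rate <- 10
  t <- seq(0, 200, by = 1 / rate)
  mk_series <- function(x) {
    out <- tibble::tibble(time = rep(t, 2),
                          channel = rep(c("L1", "R1"), each = length(t)),
                          hbo = rep(x, 2), hbr = rep(-x / 3, 2))
    structure(out,
      montage = tibble::tibble(channel = c("L1", "R1"),
                               hemisphere = c("left", "right")),
      rate = rate, quality = tibble::tibble(channel = c("L1", "R1"), cv = 0),
      class = c("hemo_series", class(out))
    )
  }
  # 1.1 Hz sinusoid: residual < 1% after filtering
  cardiac <- preprocess_hemo(mk_series(sin(2 * pi * 1.1 * t)))
  mid <- cardiac$time > 20 & cardiac$time < 180
  expect_lt(max(abs(cardiac$hbo[mid])), 0.01)
  # 0.025 Hz component (40 s block cycle fundamental): amplitude kept
  slow <- preprocess_hemo(mk_series(sin(2 * pi * 0.025 * t)))
  expect_gt(max(abs(slow$hbo[mid])), 0.8)
  expect_lt(max(abs(slow$hbo[mid])), 1.2)
  # flat zero signal passes through unchanged
  flat <- preprocess_hemo(mk_series(rep(0, length(t))))
  expect_equal(max(abs(flat$hbo)), 0)
})

test_that("channel QC rejects high-variability channels, errors when none left", {
  od <- generate_fnirs(sched, hrf_amp = 1, seed = 2)
  hemo <- od_to_hemoglobin(od)
  q <- attr(hemo, "quality")
  q$cv[q$channel == "L1"] <- 0.5
  attr(hemo, "quality") <- q
  pp <- preprocess_hemo(hemo)
  expect_false("L1" %in% pp$channel)
  expect_true("L2" %in% pp$channel)
  q$cv <- 1
  attr(hemo, "quality") <- q
  expect_error(preprocess_hemo(hemo), "all channels")
})

test_that("block averaging obeys its algebraic identities", {
  rate <- 10
  epoch_shape <- hrf_double_gamma(seq(0, 22, by = 1 / rate))
  t <- seq(-5, schedule_duration(sched), by = 1 / rate)
  onsets <- task_intervals(sched)$onset
  sig <- rep(0, length(t))
  for (on in onsets) {
    idx <- which(t >= on & t <= on + 22)
    sig[idx] <- sig[idx] + epoch_shape[seq_along(idx)]
  }
  mk <- function(x) {
    out <- tibble::tibble(time = t, channel = "L1", hbo = x, hbr = -x / 3)
    structure(out,
      montage = tibble::tibble(channel = "L1", hemisphere = "left"),
      rate = rate, class = c("hemo_series", class(out))
    )
  }
  # identical epochs: the average is the single epoch (baseline is zero)
  ba <- block_average(mk(sig), sched)
  idx20 <- ba$rel_time >= 0 & ba$rel_time <= 20
  expect_equal(max(abs(ba$hbo[idx20] - epoch_shape[seq_len(sum(idx20))])),
               0, tolerance = 1e-9)
  # +A and -A epochs average to zero
  alt <- rep(0, length(t))
  for (i in seq_along(onsets)) {
    idx <- which(t >= onsets[i] & t <= onsets[i] + 20)
    alt[idx] <- (-1)^i
  }
  # use only two blocks (one +, one -) for exact cancellation
  sched2 <- generate_block_schedule("steer", "dominant", "SAU", 2)
  t2 <- seq(-5, schedule_duration(sched2), by = 1 / rate)
  alt2 <- rep(0, length(t2))
  on2 <- task_intervals(sched2)$onset
  for (i in 1:2) {
    idx <- which(t2 >= on2[i] & t2 < on2[i] + 20)
    alt2[idx] <- (-1)^i
  }
  out2 <- tibble::tibble(time = t2, channel = "L1", hbo = alt2, hbr = alt2)
  out2 <- structure(out2,
    montage = tibble::tibble(channel = "L1", hemisphere = "left"),
    rate = rate, class = c("hemo_series", class(out2))
  )
  ba2 <- block_average(out2, sched2)
  expect_equal(max(abs(ba2$hbo)), 0, tolerance = 1e-12)

  # white-noise epochs: residual sd shrinks like 1/sqrt(N)
  sched9 <- generate_block_schedule("steer", "dominant", "SAU", 9)
  t9 <- seq(-5, schedule_duration(sched9), by = 1 / rate)
  sds <- vapply(1:40, function(k) {
    set.seed(k)
    x <- rnorm(length(t9))
    s9 <- tibble::tibble(time = t9, channel = "L1", hbo = x, hbr = x)
    s9 <- structure(s9,
      montage = tibble::tibble(channel = "L1", hemisphere = "left"),
      rate = rate, class = c("hemo_series", class(s9))
    )
    sd(block_average(s9, sched9)$hbo)
  }, numeric(1))
  # baseline correction inflates the per-epoch variance slightly; compare
  # to the averaged-epoch prediction sqrt(1/9 + 1/(9 * 20))
  pred <- sqrt(1 / 9 + 1 / (9 * 20))
  expect_lt(abs(mean(sds) - pred) / pred, 0.25)
})

test_that("peak extraction honours its contract", {
  rate <- 10
  rel <- seq(-2, 20, by = 1 / rate)
  mk_epoch <- function(x) {
    out <- tibble::tibble(rel_time = rel, channel = "L1", hbo = x, hbr = -x)
    structure(out, rate = rate,
              class = c("hemo_epoch", class(out)))
  }
  shape <- hrf_double_gamma(pmax(rel, 0)) * (rel >= 0)
  expect_equal(peak_hbo2(mk_epoch(shape))$peak_hbo2, 1, tolerance = 1e-6)
  # strictly negative epoch: its own (negative) maximum, not zero
  neg <- -1 - 0.5 * abs(sin(rel))
  expect_lt(peak_hbo2(mk_epoch(neg))$peak_hbo2, 0)
  expect_equal(peak_hbo2(mk_epoch(neg))$peak_hbo2, max(neg[rel >= 0]))
  expect_error(peak_hbo2(mk_epoch(shape), window = c(30, 40)), "window")
})

test_that("hemisphere roles follow hand laterality and lesion side", {
  vals <- tibble::tibble(channel = c(paste0("L", 1:4), paste0("R", 1:4)),
                         peak_hbo2 = c(1, 2, 3, 4, 10, 20, 30, 40))
  mont <- fnirs_montage()
  # left-hand movement: right hemisphere is contralateral
  hs <- hemisphere_summary(vals, mont, moving_side = "left")
  expect_equal(hs$role[hs$hemisphere == "right"], "contralateral")
  expect_equal(hs$role[hs$hemisphere == "left"], "ipsilateral")
  expect_true(all(is.na(hs$lesion_role)))
  # known channel values average arithmetically
  expect_equal(hs$peak_hbo2[hs$hemisphere == "left"], 2.5)
  expect_equal(hs$peak_hbo2[hs$hemisphere == "right"], 25)
  # stroke, right lesion, left (paretic) hand: right hemisphere is both
  # contralateral and ipsilesional
  hs2 <- hemisphere_summary(vals, mont, moving_side = "left",
                            lesion_side = "right")
  r <- hs2[hs2$hemisphere == "right", ]
  expect_equal(r$role, "contralateral")
  expect_equal(r$lesion_role, "ipsilesional")
})

test_that("pipeline output is invariant to channel order and OD offset", {
  od <- generate_fnirs(sched, hrf_amp = 1, seed = 3)
  peaks <- function(x) {
    p <- peak_hbo2(block_average(preprocess_hemo(od_to_hemoglobin(x)), sched))
    p[order(p$channel), ]
  }
  base <- peaks(od)
  # shuffled channel rows
  shuffled <- od[sample(nrow(od)), ]
  attributes(shuffled) <- c(attributes(shuffled)[c("names", "row.names")],
                            attributes(od)[c("montage", "distance_mm",
                                             "dpf", "rate", "class")])
  expect_equal(peaks(shuffled)$peak_hbo2, base$peak_hbo2, tolerance = 1e-9)
  # constant OD offset is removed by filtering + baseline correction
  offset <- od
  offset$od <- offset$od + 0.05
  expect_equal(peaks(offset)$peak_hbo2, base$peak_hbo2, tolerance = 1e-6)
})

test_that("injected amplitudes 0.5/1/2 uM are recovered in order", {
  ok <- vapply(1:8, function(k) {
    pk <- vapply(c(0.5, 1, 2), function(a) {
      od <- generate_fnirs(sched, hrf_amp = a, seed = 100 * k + a * 10)
      mean(peak_hbo2(block_average(preprocess_hemo(od_to_hemoglobin(od)),
                                   sched))$peak_hbo2)
    }, numeric(1))
    pk[1] < pk[2] && pk[2] < pk[3]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
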