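#' Stroke-like group effects for the synthetic cohort
#'
#' Named list of mean shifts applied to stroke subjects, scaled per subject
#' by a latent severity factor. Shifts tagged `_paretic` apply only when the
#' paretic (non-dominant) hand moves; `ipe_main` and `speed_main` apply to
#' both hands. Directions follow the qualitative clinical picture (more
#' trunk compensation, lower steering performance and hand velocity with
#' the paretic arm, larger oxy-hemoglobin response and attenuated beta
#' desynchronization during paretic reaching, lower post-movement beta
#' synchronization after paretic steering); magnitudes are generator
#' configuration, not empirical claims.
#'
#' @param trunk_flexion Added trunk-flexion range, paretic hand (degrees).
#' @param ipe_main,ipe_paretic Steering IPe shift for both hands / extra for
#'   the paretic hand (bits/s).
#' @param speed_main,speed_paretic Steering speed shifts (laps/s).
#' @param radial_sd Added radial dispersion, paretic hand (mm).
#' @param elbow Elbow-extension range shift, paretic hand (degrees).
#' @param velocity Reaching hand-velocity shift, paretic hand (mm/s).
#' @param panu Added proximal-arm non-use, paretic hand (%).
#' @param hbo2 Added peak oxy-hemoglobin response, paretic reaching (uM).
#' @param beta_erd Beta-desynchronization attenuation, paretic reaching
#'   (dB, positive = shallower ERD).
#' @param beta_ers Post-movement beta-synchronization shift, paretic
#'   steering (dB).
#' @return A named list of class `group_effects`.
#' @seealso [zero_group_effects()] for a null (exchangeable-groups) cohort.
#' @export
group_effects <- function(trunk_flexion = 5, ipe_main = -2,
                          ipe_paretic = -2, speed_main = -0.04,
                          speed_paretic = -0.06, radial_sd = 2,
                          elbow = -8, velocity = -120, panu = 10,
                          hbo2 = 0.4, beta_erd = 1.5, beta_ers = -0.8) {
  structure(as.list(environment()), class = "group_effects")
}

#' @rdname group_effects
#' @export
zero_group_effects <- function() {
  ge <- group_effects()
  ge[] <- purrr::map(ge, ~0)
  ge
}

#' Configuration of a synthetic two-group cohort
#'
#' Encodes the acquisition design: two groups of `n_per_group` subjects
#' (healthy, stroke), two tasks, two hands, two reaching conditions,
#' `n_blocks` 20 s task / 20 s rest blocks per cell, at the native sampling
#' rates (skeleton 30 Hz, fNIRS 10 Hz, EEG 500 Hz). Stroke subjects carry a
#' latent severity factor that scales their `group_effects` and drives the
#' synthetic clinical scores.
#'
#' @param n_per_group Subjects per group (>= 1); protocol default 21.
#' @param seed Integer seed; identical configs and seeds give identical
#'   cohorts.
#' @param effects A [group_effects()] list.
#' @param n_blocks Task blocks per (task, hand, condition) cell.
#' @param rates Named sampling rates (Hz): `skeleton`, `fnirs`, `eeg`.
#' @param noise A [fnirs_noise()] spec for the optical generator.
#' @param jitter_sd Skeleton position noise (mm).
#' @param severity_sd SD of the stroke severity factor (mean 1).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 21, seed = 1,
                          effects = group_effects(), n_blocks = 3,
                          rates = c(skeleton = 30, fnirs = 10, eeg = 500),
                          noise = fnirs_noise(), jitter_sd = 1,
                          severity_sd = 0.25) {
  if (!is.numeric(n_per_group) || n_per_group < 1 ||
      n_per_group != round(n_per_group)) {
    abort("n_per_group must be a whole number >= 1")
  }
  if (any(rates <= 0)) abort("sampling rates must be positive")
  assert_number(severity_sd, "severity_sd", 0)
  assert_number(jitter_sd, "jitter_sd", 0)
  structure(as.list(environment()), class = "cohort_config")
}

# One row per generated metric cell type. Stroke shifts are resolved from
# the group_effects list so that zeroing it makes the groups exchangeable.
metric_definitions <- function(ge = group_effects()) {
  g <- function(key) if (is.null(ge[[key]])) 0 else ge[[key]]
  tibble::tribble(
    ~metric, ~task, ~has_cond, ~has_hemi,
    ~base_sau, ~base_mau, ~hand_shift, ~contra_shift,
    ~par_sau, ~par_mau, ~main, ~subject_sd, ~residual_sd,

    "ipe", "steer", FALSE, FALSE,
    14, NA, -1.5, NA,
    g("ipe_paretic"), NA, g("ipe_main"), 2, 1.5,

    "speed", "steer", FALSE, FALSE,
    0.5, NA, -0.04, NA,
    g("speed_paretic"), NA, g("speed_main"), 0.07, 0.04,

    "radial_sd", "steer", FALSE, FALSE,
    6, NA, 0.5, NA,
    g("radial_sd"), NA, 0, 1, 0.5,

    "trunk_flexion_range", "steer", FALSE, FALSE,
    5, NA, 0.5, NA,
    g("trunk_flexion"), NA, 0, 2, 1.5,

    "elbow_extension_range", "steer", FALSE, FALSE,
    30, NA, -3, NA,
    g("elbow"), NA, 0, 5, 3,

    "trunk_flexion_range", "reach", TRUE, FALSE,
    10, 2, 0.5, NA,
    g("trunk_flexion"), g("trunk_flexion") * 0.2, 0, 2, 1.5,

    "elbow_extension_range", "reach", TRUE, FALSE,
    40, 55, -2, NA,
    g("elbow"), g("elbow"), 0, 6, 3,

    "hand_mean_velocity", "reach", TRUE, FALSE,
    600, 650, -30, NA,
    g("velocity"), g("velocity"), 0, 60, 40,

    "panu", "reach", FALSE, FALSE,
    5, NA, 1, NA,
    g("panu"), NA, 0, 4, 3,

    "peak_hbo2", "reach", TRUE, TRUE,
    0.8, 0.8, 0, 0.3,
    g("hbo2"), g("hbo2"), 0, 0.2, 0.15,

    "peak_hbo2", "steer", FALSE, TRUE,
    0.8, NA, 0, 0.3,
    0, NA, 0, 0.2, 0.15,

    "alpha_erd", "reach", TRUE, TRUE,
    -2, -2, 0, -0.5,
    0, 0, 0, 0.5, 0.4,

    "alpha_erd", "steer", FALSE, TRUE,
    -2, NA, 0, -0.5,
    0, NA, 0, 0.5, 0.4,

    "beta_erd", "reach", TRUE, TRUE,
    -3, -3, 0, -0.5,
    g("beta_erd"), g("beta_erd"), 0, 0.5, 0.4,

    "beta_erd", "steer", FALSE, TRUE,
    -3, NA, 0, -0.5,
    0, NA, 0, 0.5, 0.4,

    "alpha_ers", "reach", TRUE, TRUE,
    1, 1, 0, 0,
    0, 0, 0, 0.4, 0.3,

    "alpha_ers", "steer", FALSE, TRUE,
    1, NA, 0, 0,
    0, NA, 0, 0.4, 0.3,

    "beta_ers", "reach", TRUE, TRUE,
    2, 2, 0, 0,
    0, 0, 0, 0.5, 0.4,

    "beta_ers", "steer", FALSE, TRUE,
    2, NA, 0, 0,
    g("beta_ers"), NA, 0, 0.5, 0.4
  )
}

# subject roster with lesion sides, severity and synthetic clinical scores
cohort_subjects <- function(config) {
  n <- config$n_per_group
  subjects <- tibble(
    subject = sprintf("S%02d", seq_len(2 * n)),
    group = rep(c("healthy", "stroke"), each = n)
  )
  subjects$lesion_side <- ifelse(
    subjects$group == "stroke",
    sample(c("left", "right"), 2 * n, replace = TRUE), NA
  )[seq_len(2 * n)]
  sev <- pmin(pmax(rnorm(2 * n, 1, config$severity_sd), 0.3), 1.7)
  subjects$severity <- ifelse(subjects$group == "stroke", sev, 0)
  is_stroke <- subjects$group == "stroke"
  subjects$fm_ue <- NA_real_
  subjects$wmft <- NA_real_
  subjects$bbt_ratio <- NA_real_
  subjects$bi <- NA_real_
  ns <- sum(is_stroke)
  subjects$fm_ue[is_stroke] <-
    pmin(pmax(round(66 - 18 * sev[is_stroke] + rnorm(ns, 0, 3)), 15), 66)
  subjects$wmft[is_stroke] <-
    pmin(pmax(round(75 - 15 * sev[is_stroke] + rnorm(ns, 0, 4)), 5), 75)
  subjects$bbt_ratio[is_stroke] <-
    pmin(pmax(round(100 - 40 * sev[is_stroke] + rnorm(ns, 0, 10)), 5), 100)
  subjects$bi[is_stroke] <-
    pmin(pmax(round(100 - 10 * sev[is_stroke] + rnorm(ns, 0, 5)), 40), 100)
  subjects
}

# all design cells for one subject: task x hand (x condition)
design_cells <- function() {
  dplyr::bind_rows(
    tidyr::expand_grid(task = "steer", hand = c("dominant", "non-dominant"),
                       condition = "SAU"),
    tidyr::expand_grid(task = "reach", hand = c("dominant", "non-dominant"),
                       condition = c("SAU", "MAU"))
  )
}

# which physical side moves: healthy subjects are right-dominant; for stroke
# the paretic side (opposite the lesion) maps to the "non-dominant" slot
moving_side_of <- function(hand, group, lesion_side) {
  if (group == "stroke") {
    paretic <- ifelse(lesion_side == "left", "right", "left")
    if (hand == "non-dominant") paretic else setdiff(c("left", "right"), paretic)
  } else {
    if (hand == "non-dominant") "left" else "right"
  }
}

# cell mean for one metric row given group/hand/condition/severity
cell_mean <- function(def, group, hand, condition, severity) {
  base <- if (def$has_cond && condition == "MAU") def$base_mau else def$base_sau
  m <- base + def$hand_shift * (hand == "non-dominant")
  if (group == "stroke") {
    m <- m + def$main * severity
    if (hand == "non-dominant") {
      par <- if (def$has_cond && condition == "MAU") def$par_mau else def$par_sau
      m <- m + par * severity
    }
  }
  m
}

#' Simulate a synthetic two-group cohort
#'
#' At `level = "metrics"` the per-subject metric table is drawn directly
#' from the generative model (cell mean + subject random effect + residual)
#' -- the statistical structure downstream ANOVAs see, at negligible cost;
#' use it for calibration and power studies. At `level = "signals"` every
#' cell is realised as full multimodal streams (skeleton, cursor, optical
#' densities, EEG) via the forward generators, and the injected per-session
#' parameters are recorded as ground truth; use it to validate the
#' extraction pipeline end to end.
#'
#' @param config A [cohort_config()].
#' @param level `"metrics"` or `"signals"`.
#' @param metrics Optional character vector restricting the metrics-level
#'   draw to a subset of metric names (used by large simulation studies).
#' @return A list of class `neuromove_cohort`: `subjects` (roster with
#'   clinical scores), `metrics` (tidy table: subject, group, task, hand,
#'   condition, hemisphere_role, metric, value), `ground_truth` (signals
#'   level: injected parameters per session), `sessions` (signals level:
#'   list of session bundles), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            level = c("metrics", "signals"),
                            metrics = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    subjects <- cohort_subjects(config)
    if (level == "metrics") {
      metrics <- simulate_metrics_level(config, subjects, metrics)
      out <- list(subjects = subjects, metrics = metrics,
                  ground_truth = NULL, sessions = NULL, config = config)
    } else {
      sig <- simulate_signals_level(config, subjects)
      out <- list(subjects = subjects, metrics = sig$metrics,
                  ground_truth = sig$ground_truth, sessions = sig$sessions,
                  config = config)
    }
  })
  structure(out, class = "neuromove_cohort")
}

#' @export
print.neuromove_cohort <- function(x, ...) {
  cat(sprintf(
    "<neuromove_cohort> %d subjects (%d/group), %d metric rows%s\n",
    nrow(x$subjects), x$config$n_per_group, nrow(x$metrics),
    if (is.null(x$sessions)) "" else
      sprintf(", %d signal sessions", length(x$sessions))
  ))
  invisible(x)
}

simulate_metrics_level <- function(config, subjects, metrics = NULL) {
  defs <- metric_definitions(config$effects)
  if (!is.null(metrics)) defs <- defs[defs$metric %in% metrics, ]
  cells <- design_cells()
  purrr::map_dfr(seq_len(nrow(defs)), function(k) {
    def <- defs[k, ]
    dcells <- cells[cells$task == def$task, ]
    if (!def$has_cond) dcells <- dcells[dcells$condition == "SAU", ]
    hemis <- if (def$has_hemi) c("contralateral", "ipsilateral") else NA
    b <- rnorm(nrow(subjects), 0, def$subject_sd)
    grid <- tidyr::expand_grid(
      tibble(subject = subjects$subject, group = subjects$group,
             severity = subjects$severity, b = b),
      dcells, hemisphere_role = hemis
    )
    is_mau <- grid$condition == "MAU" & def$has_cond
    is_str <- grid$group == "stroke"
    is_nd <- grid$hand == "non-dominant"
    base <- ifelse(is_mau, def$base_mau, def$base_sau)
    par <- ifelse(is_mau, def$par_mau, def$par_sau)
    mu <- base + def$hand_shift * is_nd +
      is_str * def$main * grid$severity +
      (is_str & is_nd) * par * grid$severity
    if (def$has_hemi) {
      mu <- mu + def$contra_shift * (grid$hemisphere_role == "contralateral")
    }
    tibble(
      subject = grid$subject, group = grid$group,
      task = grid$task, hand = grid$hand, condition = grid$condition,
      hemisphere_role = grid$hemisphere_role,
      metric = def$metric,
      value = mu + grid$b + rnorm(nrow(grid), 0, def$residual_sd)
    )
  })
}

# truncate a session truth draw to its physical range
truth_draw <- function(def, group, hand, condition, severity, b,
                       lo = -Inf, hi = Inf) {
  m <- cell_mean(def, group, hand, condition, severity) + b +
    rnorm(1, 0, def$residual_sd)
  min(max(m, lo), hi)
}

simulate_signals_level <- function(config, subjects) {
  defs <- metric_definitions(config$effects)
  def_of <- function(metric, task) {
    defs[defs$metric == metric & defs$task == task, ][1, ]
  }
  cells <- design_cells()
  sessions <- list()
  truths <- list()

  for (s in seq_len(nrow(subjects))) {
    su <- subjects[s, ]
    # per-subject random effects, one per generative parameter
    b <- list(
      trunk_r = rnorm(1, 0, def_of("trunk_flexion_range", "reach")$subject_sd),
      trunk_s = rnorm(1, 0, def_of("trunk_flexion_range", "steer")$subject_sd),
      elbow_r = rnorm(1, 0, def_of("elbow_extension_range", "reach")$subject_sd),
      speed = rnorm(1, 0, def_of("speed", "steer")$subject_sd),
      rsd = rnorm(1, 0, def_of("radial_sd", "steer")$subject_sd),
      hbo = rnorm(1, 0, def_of("peak_hbo2", "reach")$subject_sd),
      aerd = rnorm(1, 0, def_of("alpha_erd", "reach")$subject_sd),
      berd = rnorm(1, 0, def_of("beta_erd", "reach")$subject_sd),
      aers = rnorm(1, 0, def_of("alpha_ers", "reach")$subject_sd),
      bers = rnorm(1, 0, def_of("beta_ers", "reach")$subject_sd)
    )
    for (c_i in seq_len(nrow(cells))) {
      cl <- cells[c_i, ]
      seed_s <- sample.int(.Machine$integer.max, 1)
      truth <- if (cl$task == "reach") {
        list(
          trunk_range_deg = truth_draw(
            def_of("trunk_flexion_range", "reach"), su$group, cl$hand,
            cl$condition, su$severity, b$trunk_r, lo = 0, hi = 60
          ),
          elbow_range_deg = truth_draw(
            def_of("elbow_extension_range", "reach"), su$group, cl$hand,
            cl$condition, su$severity, b$elbow_r, lo = 5, hi = 85
          )
        )
      } else {
        list(
          lap_rate = truth_draw(def_of("speed", "steer"), su$group, cl$hand,
                                cl$condition, su$severity, b$speed,
                                lo = 0.1, hi = 2),
          radial_sd = truth_draw(def_of("radial_sd", "steer"), su$group,
                                 cl$hand, cl$condition, su$severity, b$rsd,
                                 lo = 0.5, hi = 20)
        )
      }
      truth$hrf_amp <- truth_draw(def_of("peak_hbo2", cl$task), su$group,
                                  cl$hand, cl$condition, su$severity, b$hbo,
                                  lo = 0.05, hi = 3)
      truth$erd_db <- c(
        alpha = truth_draw(def_of("alpha_erd", cl$task), su$group, cl$hand,
                           cl$condition, su$severity, b$aerd, hi = 0),
        beta = truth_draw(def_of("beta_erd", cl$task), su$group, cl$hand,
                          cl$condition, su$severity, b$berd, hi = 0)
      )
      truth$ers_db <- c(
        alpha = truth_draw(def_of("alpha_ers", cl$task), su$group, cl$hand,
                           cl$condition, su$severity, b$aers, lo = 0),
        beta = truth_draw(def_of("beta_ers", cl$task), su$group, cl$hand,
                          cl$condition, su$severity, b$bers, lo = 0)
      )
      ses <- simulate_session(
        task = cl$task, hand = cl$hand, condition = cl$condition,
        truth = truth, seed = seed_s, n_blocks = config$n_blocks,
        rates = config$rates, noise = config$noise,
        jitter_sd = config$jitter_sd,
        subject = su$subject, group = su$group,
        lesion_side = if (is.na(su$lesion_side)) NULL else su$lesion_side
      )
      sessions[[length(sessions) + 1]] <- ses
      truths[[length(truths) + 1]] <- tibble(
        subject = su$subject, group = su$group, task = cl$task,
        hand = cl$hand, condition = cl$condition,
        trunk_range_deg = truth$trunk_range_deg %||% NA_real_,
        elbow_range_deg = truth$elbow_range_deg %||% NA_real_,
        lap_rate = truth$lap_rate %||% NA_real_,
        radial_sd = truth$radial_sd %||% NA_real_,
        hrf_amp = truth$hrf_amp,
        erd_alpha = truth$erd_db[["alpha"]],
        erd_beta = truth$erd_db[["beta"]],
        ers_alpha = truth$ers_db[["alpha"]],
        ers_beta = truth$ers_db[["beta"]]
      )
    }
  }
  gt <- dplyr::bind_rows(truths)
  metrics <- purrr::map_dfr(sessions, extract_session_metrics)
  list(sessions = sessions, ground_truth = gt, metrics = metrics)
}

#' Simulate one multimodal session
#'
#' One (task, hand, condition) run of one subject: the block schedule plus
#' synchronized skeleton or cursor kinematics, dual-wavelength optical
#' densities and 8-channel EEG, all generated from the `truth` parameters.
#'
#' @param task `"reach"` or `"steer"`.
#' @param hand `"dominant"` or `"non-dominant"` (the non-dominant slot is
#'   the paretic hand for stroke subjects).
#' @param condition `"SAU"` or `"MAU"`.
#' @param truth Named list of injected parameters: for reaching
#'   `trunk_range_deg`, `elbow_range_deg`; for steering `lap_rate`,
#'   `radial_sd`; for both `hrf_amp`, `erd_db`, `ers_db` (named per band).
#' @param seed Integer seed.
#' @param n_blocks Task blocks.
#' @param rates Named sampling rates (Hz).
#' @param noise [fnirs_noise()] spec.
#' @param jitter_sd Skeleton position noise (mm).
#' @param subject,group,lesion_side Labels carried through to the metrics.
#' @return A list of class `neuromove_session`.
#' @export
simulate_session <- function(task, hand, condition = "SAU", truth, seed,
                             n_blocks = 3,
                             rates = c(skeleton = 30, fnirs = 10, eeg = 500),
                             noise = fnirs_noise(), jitter_sd = 1,
                             subject = "S01", group = "healthy",
                             lesion_side = NULL) {
  task <- match_label(task, task_levels, "task")
  schedule <- generate_block_schedule(task, hand, condition, n_blocks)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 3))
  kin <- if (task == "reach") {
    prof <- reach_profile(
      trunk_range_deg = truth$trunk_range_deg,
      elbow_range_deg = truth$elbow_range_deg,
      jitter_sd = jitter_sd,
      side = moving_side_of(hand, group, lesion_side %||% "left")
    )
    generate_reach_skeleton(prof, schedule, seed = seeds[1],
                            rate = rates[["skeleton"]])
  } else {
    generate_steering_trace(
      lap_rate = truth$lap_rate, radial_sd = truth$radial_sd,
      duration = schedule_duration(schedule), seed = seeds[1]
    )
  }
  od <- generate_fnirs(schedule, hrf_amp = truth$hrf_amp, noise = noise,
                       seed = seeds[2], rate = rates[["fnirs"]])
  eeg <- generate_eeg(schedule, erd_db = truth$erd_db,
                      ers_db = truth$ers_db, seed = seeds[3],
                      rate = rates[["eeg"]])
  structure(
    list(
      task = task, hand = hand, condition = condition,
      subject = subject, group = group, lesion_side = lesion_side,
      moving_side = moving_side_of(hand, group, lesion_side %||% "left"),
      schedule = schedule, kinematics = kin, od = od, eeg = eeg,
      truth = truth
    ),
    class = "neuromove_session"
  )
}

#' Run the extraction pipeline on one session
#'
#' Kinematic metrics (reach ranges/velocity/arm use or steering-law
#' performance), fNIRS peak oxy-hemoglobin per hemisphere role, and EEG
#' alpha/beta ERD/ERS per hemisphere role, as tidy rows keyed by subject,
#' group, task, hand and condition.
#'
#' @param session A [simulate_session()] or [import_session()] bundle.
#' @param eeg_reference Reference scheme passed to [preprocess_eeg()].
#' @return A tidy tibble (`subject`, `group`, `task`, `hand`, `condition`,
#'   `hemisphere_role`, `metric`, `value`).
#' @export
extract_session_metrics <- function(session, eeg_reference = "car") {
  stopifnot(inherits(session, "neuromove_session"))
  keys <- tibble(
    subject = session$subject, group = session$group,
    task = session$task, hand = session$hand, condition = session$condition
  )

  kin_rows <- if (session$task == "reach") {
    rm <- reach_metrics(session$kinematics, session$schedule)
    tibble(
      metric = c("trunk_flexion_range", "elbow_extension_range",
                 "hand_mean_velocity", "arm_use"),
      value = c(rm$trunk_flexion_range, rm$elbow_extension_range,
                rm$hand_mean_velocity, rm$arm_use)
    )
  } else {
    sm <- steering_metrics(session$kinematics, session$schedule)
    tibble(
      metric = c("ipe", "speed", "radial_sd", "bias", "error_rate"),
      value = c(sm$IPe, sm$speed, sm$sigma, sm$bias, sm$error_rate)
    )
  }
  kin_rows$hemisphere_role <- NA_character_

  hemo <- od_to_hemoglobin(session$od) |>
    preprocess_hemo() |>
    block_average(session$schedule) |>
    peak_hbo2()
  hb_rows <- hemisphere_summary(hemo, attr(session$od, "montage"),
                                session$moving_side, session$lesion_side) |>
    dplyr::transmute(hemisphere_role = .data$role, metric = "peak_hbo2",
                     value = .data$peak_hbo2)

  emap <- preprocess_eeg(session$eeg, reference = eeg_reference,
                         schedule = session$schedule) |>
    ersp(session$schedule)
  eeg_rows <- band_erd_ers(emap) |>
    hemisphere_summary_eeg(attr(session$eeg, "montage"),
                           session$moving_side, session$lesion_side) |>
    tidyr::pivot_longer(c("erd_db", "ers_db"), names_to = "kind",
                        values_to = "value") |>
    dplyr::transmute(
      hemisphere_role = .data$role,
      metric = paste0(.data$band, "_", sub("_db", "", .data$kind)),
      value = .data$value
    )

  dplyr::bind_cols(
    keys[rep(1, nrow(kin_rows) + nrow(hb_rows) + nrow(eeg_rows)), ],
    dplyr::bind_rows(kin_rows, hb_rows, eeg_rows)
  ) |>
    dplyr::relocate("hemisphere_role", .after = "condition")
}
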