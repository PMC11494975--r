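#' Derive proximal-arm non-use rows from per-condition arm use
#'
#' At the signals level the metrics table carries `arm_use` per condition;
#' PANU is the per-subject, per-hand difference `AU(MAU) - AU(SAU)`. Tables
#' that already contain a `panu` metric (metrics-level cohorts) pass
#' through unchanged.
#'
#' @param metrics Tidy metrics table.
#' @return The table with `panu` rows appended (condition `"SAU"` by
#'   convention, since PANU spans both conditions).
#' @export
derive_panu <- function(metrics) {
  if ("panu" %in% metrics$metric || !"arm_use" %in% metrics$metric) {
    return(metrics)
  }
  au <- metrics |>
    dplyr::filter(.data$metric == "arm_use") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value")
  panu_rows <- au |>
    dplyr::mutate(metric = "panu", value = .data$MAU - .data$SAU,
                  condition = "SAU") |>
    dplyr::select(-"MAU", -"SAU")
  dplyr::bind_rows(metrics, panu_rows)
}

# metrics analysed per task with their within-subject factors
anova_plan <- function(metrics) {
  metrics |>
    dplyr::distinct(.data$task, .data$metric) |>
    dplyr::filter(!.data$metric %in% c("arm_use")) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      use_condition = .data$task == "reach" && .data$metric != "panu",
      use_hemisphere = .data$metric %in%
        c("peak_hbo2", "alpha_erd", "beta_erd", "alpha_ers", "beta_ers")
    ) |>
    dplyr::ungroup()
}

#' Mixed ANOVAs over every metric of a cohort
#'
#' Runs [mixed_anova()] per metric and task with group as between-subject
#' factor, hand as within-subject factor, plus condition (reach kinematics
#' and brain metrics) and hemisphere role (brain metrics) where the design
#' provides them.
#'
#' @param metrics Tidy metrics table (see [simulate_cohort()]).
#' @return A tibble of effect rows keyed by `task` and `metric`.
#' @export
cohort_anovas <- function(metrics) {
  metrics <- derive_panu(metrics)
  plan <- anova_plan(metrics)
  purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    pl <- plan[i, ]
    d <- metrics[metrics$task == pl$task & metrics$metric == pl$metric, ]
    within <- "hand"
    if (pl$use_condition && dplyr::n_distinct(d$condition) > 1) {
      within <- c(within, "condition")
    }
    if (pl$use_hemisphere && any(!is.na(d$hemisphere_role))) {
      d <- d[!is.na(d$hemisphere_role), ]
      d$hemisphere <- d$hemisphere_role
      within <- c(within, "hemisphere")
    }
    fit <- tryCatch(
      mixed_anova(d, "value", between = "group", within = within),
      error = function(e) NULL
    )
    if (is.null(fit)) return(tibble())
    dplyr::bind_cols(tibble(task = pl$task, metric = pl$metric), tidy(fit))
  })
}

# default brain-movement / brain-clinical correlation pairs, paretic hand
correlation_plan <- function() {
  tibble::tribble(
    ~task, ~condition, ~x_metric, ~x_role, ~y_metric, ~y_role,
    "steer", "SAU", "trunk_flexion_range", NA, "alpha_erd", "contralateral",
    "steer", "SAU", "trunk_flexion_range", NA, "alpha_erd", "ipsilateral",
    "steer", "SAU", "ipe", NA, "beta_ers", "ipsilateral",
    "steer", "SAU", "ipe", NA, "beta_ers", "contralateral",
    "reach", "MAU", "elbow_extension_range", NA, "peak_hbo2", "ipsilateral",
    "reach", "MAU", "elbow_extension_range", NA, "peak_hbo2", "contralateral",
    "reach", "SAU", "elbow_extension_range", NA, "beta_ers", "ipsilateral",
    "reach", "SAU", "elbow_extension_range", NA, "beta_ers", "contralateral",
    "steer", "SAU", "fm_ue", NA, "alpha_erd", "ipsilateral",
    "steer", "SAU", "fm_ue", NA, "alpha_erd", "contralateral",
    "reach", "MAU", "fm_ue", NA, "peak_hbo2", "ipsilateral",
    "reach", "MAU", "fm_ue", NA, "peak_hbo2", "contralateral"
  )
}

#' Brain-movement and brain-clinical correlations in the stroke group
#'
#' Spearman rank (partial) correlations between movement metrics (or
#' clinical scores) and brain metrics for the paretic hand of the stroke
#' group, with the moderate-effect reporting filter `rho^2 > 0.25`.
#'
#' @param cohort A [simulate_cohort()] result (or a compatible list with
#'   `metrics` and `subjects`).
#' @param plan Pair table; see `neuromove:::correlation_plan()` for the
#'   default columns.
#' @param covariates Covariate column names for partial correlation
#'   (empty = plain Spearman; the choice is reported in the output).
#' @return A tibble of [spearman_partial()] rows with pair metadata.
#' @export
cohort_correlations <- function(cohort, plan = correlation_plan(),
                                covariates = character()) {
  metrics <- derive_panu(cohort$metrics)
  stroke <- cohort$subjects[cohort$subjects$group == "stroke", ]
  m <- metrics |>
    dplyr::filter(.data$group == "stroke", .data$hand == "non-dominant")

  value_of <- function(metric, task, condition, role) {
    if (metric %in% names(stroke)) {
      return(stroke[, c("subject", metric)] |> setNames(c("subject", "v")))
    }
    d <- m[m$metric == metric & m$task == task & m$condition == condition, ]
    if (!is.na(role)) d <- d[!is.na(d$hemisphere_role) &
                               d$hemisphere_role == role, ]
    d[, c("subject", "value")] |> setNames(c("subject", "v"))
  }

  purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    pl <- plan[i, ]
    xs <- value_of(pl$x_metric, pl$task, pl$condition, pl$x_role)
    ys <- value_of(pl$y_metric, pl$task, pl$condition, pl$y_role)
    d <- dplyr::inner_join(xs, ys, by = "subject",
                           suffix = c("_x", "_y"))
    covs <- intersect(covariates, names(stroke))
    if (length(covs) > 0) {
      d <- dplyr::inner_join(d, stroke[, c("subject", covs)], by = "subject")
    }
    if (nrow(d) < 4) return(tibble())
    res <- tryCatch(
      spearman_partial(d, "v_x", "v_y", covariates = covs),
      error = function(e) NULL
    )
    if (is.null(res)) return(tibble())
    dplyr::bind_cols(
      tibble(task = pl$task, condition = pl$condition,
             x_metric = pl$x_metric, y_metric = pl$y_metric,
             y_role = pl$y_role),
      res[, c("covariates", "n", "rho", "r_s2", "p_value", "reported",
              "method")]
    )
  })
}

#' Ground-truth vs recovered comparison for a signals-level cohort
#'
#' Joins the injected session parameters with the pipeline's extracted
#' metrics and reports per-session errors: relative for amplitudes and
#' dispersions (HRF peak, radial SD, lap rate), absolute for angles and dB
#' quantities.
#'
#' @param cohort A signals-level [simulate_cohort()] result.
#' @return A tibble with one row per session and quantity: `quantity`,
#'   `truth`, `recovered`, `error`, `error_type`.
#' @export
recovery_table <- function(cohort) {
  if (is.null(cohort$ground_truth)) {
    abort("recovery_table needs a signals-level cohort")
  }
  keys <- c("subject", "task", "hand", "condition")
  wide <- cohort$metrics |>
    dplyr::mutate(metric = ifelse(
      is.na(.data$hemisphere_role), .data$metric,
      paste(.data$metric, .data$hemisphere_role, sep = ".")
    )) |>
    dplyr::select(dplyr::all_of(keys), "metric", "value") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "value")
  gt <- cohort$ground_truth |>
    dplyr::select(-"group") |>
    dplyr::rename_with(~ paste0("true_", .x), -dplyr::all_of(keys))
  j <- dplyr::inner_join(gt, wide, by = keys)

  col_or_na <- function(nm) {
    if (nm %in% names(j)) j[[nm]] else rep(NA_real_, nrow(j))
  }
  hemi_mean <- function(stub) {
    rowMeans(cbind(col_or_na(paste0(stub, ".contralateral")),
                   col_or_na(paste0(stub, ".ipsilateral"))))
  }
  rows <- list(
    tibble(quantity = "trunk_range_deg", truth = j$true_trunk_range_deg,
           recovered = col_or_na("trunk_flexion_range"),
           error_type = "absolute"),
    tibble(quantity = "elbow_range_deg", truth = j$true_elbow_range_deg,
           recovered = col_or_na("elbow_extension_range"),
           error_type = "absolute"),
    tibble(quantity = "radial_sd", truth = j$true_radial_sd,
           recovered = col_or_na("radial_sd"), error_type = "relative"),
    tibble(quantity = "lap_rate", truth = j$true_lap_rate,
           recovered = col_or_na("speed"), error_type = "relative"),
    tibble(quantity = "hrf_amp", truth = j$true_hrf_amp,
           recovered = hemi_mean("peak_hbo2"), error_type = "relative"),
    tibble(quantity = "erd_alpha", truth = j$true_erd_alpha,
           recovered = hemi_mean("alpha_erd"), error_type = "absolute"),
    tibble(quantity = "erd_beta", truth = j$true_erd_beta,
           recovered = hemi_mean("beta_erd"), error_type = "absolute"),
    tibble(quantity = "ers_alpha", truth = j$true_ers_alpha,
           recovered = hemi_mean("alpha_ers"), error_type = "absolute"),
    tibble(quantity = "ers_beta", truth = j$true_ers_beta,
           recovered = hemi_mean("beta_ers"), error_type = "absolute")
  )
  out <- purrr::map_dfr(rows, function(r) {
    dplyr::bind_cols(j[, keys], r)
  }) |>
    dplyr::filter(!is.na(.data$truth), !is.na(.data$recovered)) |>
    dplyr::mutate(error = ifelse(
      .data$error_type == "relative",
      (.data$recovered - .data$truth) / .data$truth,
      .data$recovered - .data$truth
    ))
  out
}

#' Run the full synthetic pipeline: generate, extract, summarise, test
#'
#' Simulates a cohort, derives the metrics table, fits the mixed ANOVAs,
#' runs the stroke-group correlations and (for signals-level runs) the
#' ground-truth recovery comparison, and writes everything to `out_dir` as
#' CSV plus a JSON manifest carrying the resolved configuration, its hash
#' and the package version. Re-running with the same config and seed
#' reproduces all outputs bit-identically.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @param level `"metrics"` (fast, statistics only) or `"signals"` (full
#'   multimodal generation and extraction).
#' @param write_sessions Also write every raw session to
#'   `out_dir/sessions/<subject>_<task>_<hand>_<condition>/` (signals level
#'   only; large).
#' @return Invisibly, a list with the cohort, the result tables and the
#'   file paths.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         level = c("signals", "metrics"),
                         write_sessions = FALSE) {
  level <- match.arg(level)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  cohort <- withCallingHandlers(
    simulate_cohort(config, level = level),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  metrics <- derive_panu(cohort$metrics)
  anovas <- suppressWarnings(cohort_anovas(metrics))
  correlations <- suppressWarnings(cohort_correlations(cohort))
  posthocs <- suppressWarnings(
    posthoc_pairwise(
      metrics[metrics$metric %in% c("ipe", "trunk_flexion_range") &
                metrics$condition == "SAU", ],
      dv = "value", factor = "hand", by = c("task", "metric", "group")
    )
  )

  utils::write.csv(cohort$subjects, file.path(out_dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(anovas, file.path(out_dir, "anova.csv"),
                   row.names = FALSE)
  utils::write.csv(posthocs, file.path(out_dir, "posthoc.csv"),
                   row.names = FALSE)
  utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)

  recovery <- NULL
  if (level == "signals") {
    utils::write.csv(cohort$ground_truth,
                     file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    recovery <- recovery_table(cohort)
    utils::write.csv(recovery, file.path(out_dir, "recovery.csv"),
                     row.names = FALSE)
    if (write_sessions) {
      for (ses in cohort$sessions) {
        d <- file.path(out_dir, "sessions", paste(
          ses$subject, ses$task, gsub("[^a-z]", "", ses$hand),
          ses$condition, sep = "_"
        ))
        write_session(ses, d)
      }
    }
  }

  config_plain <- rapply(unclass(config), identity, how = "list")
  manifest <- list(
    package = "neuromove",
    version = as.character(utils::packageVersion("neuromove")),
    level = level, seed = config$seed,
    config_hash = rlang::hash(config_plain),
    n_subjects = nrow(cohort$subjects),
    n_metric_rows = nrow(metrics),
    warnings = warnings_log,
    parameters = list(
      fnirs_filter_hz = c(0.01, 0.08), fnirs_epoch_s = c(-2, 20),
      fnirs_baseline_s = c(-2, 0), fnirs_peak_window_s = c(0, 20),
      eeg_filter_hz = c(1, 40), ersp_window_s = 1, ersp_overlap = 0.9,
      ers_window = "post-movement (reach: 2-4 s after cue; steer: 0-4 s after task offset)",
      correlation_method = "spearman (no covariates unless configured)"
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(config_plain, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    cohort = cohort, metrics = metrics, anovas = anovas,
    posthocs = posthocs, correlations = correlations, recovery = recovery,
    out_dir = out_dir
  ))
}

#' Write / import one session as a directory of plain-text files
#'
#' The canonical interchange layout: `schedule.json`, `meta.json`,
#' `ground_truth.json`, `skeleton.csv` or `cursor.csv` (wide, mm),
#' `od.csv` (long: time, channel, wavelength, od) and `eeg.csv` (long:
#' time, channel, value in uV).
#'
#' @param session A `neuromove_session`.
#' @param path Session directory.
#' @return `write_session()` returns `path` invisibly; `import_session()`
#'   returns the reconstructed `neuromove_session`.
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_schedule(session$schedule, file.path(path, "schedule.json"))
  kin <- session$kinematics
  if (session$task == "reach") {
    utils::write.csv(as_tibble(kin), file.path(path, "skeleton.csv"),
                     row.names = FALSE)
  } else {
    utils::write.csv(as_tibble(kin), file.path(path, "cursor.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(as_tibble(session$od), file.path(path, "od.csv"),
                   row.names = FALSE)
  eeg_long <- as_tibble(session$eeg) |>
    tidyr::pivot_longer(-"time", names_to = "channel", values_to = "value")
  utils::write.csv(eeg_long, file.path(path, "eeg.csv"), row.names = FALSE)

  geom <- attr(kin, "geometry")
  meta <- list(
    task = session$task, hand = session$hand, condition = session$condition,
    subject = session$subject, group = session$group,
    lesion_side = session$lesion_side, moving_side = session$moving_side,
    skeleton_side = attr(kin, "side"),
    rates = list(kinematics = attr(kin, "rate"),
                 fnirs = attr(session$od, "rate"),
                 eeg = attr(session$eeg, "rate")),
    geometry = if (!is.null(geom)) unclass(geom),
    fnirs = list(distance_mm = attr(session$od, "distance_mm"),
                 dpf = attr(session$od, "dpf"),
                 montage = as.data.frame(attr(session$od, "montage"))),
    eeg_montage = as.data.frame(attr(session$eeg, "montage"))
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(session$truth, file.path(path, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session
#' @param format Only `"csv_dir"` is supported; `"xdf"` raises an error
#'   asking for conversion to the CSV layout.
#' @export
import_session <- function(path, format = c("csv_dir", "xdf")) {
  format <- match.arg(format)
  if (format == "xdf") {
    abort("XDF import is not supported in this build; export the streams to the csv_dir layout")
  }
  need <- c("schedule.json", "meta.json", "od.csv", "eeg.csv")
  found <- list.files(path)
  missing_files <- setdiff(need, found)
  if (!any(c("skeleton.csv", "cursor.csv") %in% found)) {
    missing_files <- c(missing_files, "skeleton.csv|cursor.csv")
  }
  if (length(missing_files) > 0) {
    abort(sprintf("missing required stream(s): %s (found: %s)",
                  paste(missing_files, collapse = ", "),
                  paste(found, collapse = ", ")))
  }
  schedule <- read_schedule(file.path(path, "schedule.json"))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  # JSON has no NULL scalar: empty/absent optional fields come back empty
  blank <- function(x) {
    if (is.null(x) || length(x) == 0 || identical(x, "")) NULL else x
  }
  meta$lesion_side <- blank(meta$lesion_side)

  if (meta$task == "reach") {
    kin <- as_tibble(utils::read.csv(file.path(path, "skeleton.csv")))
    kin <- structure(kin,
      rate = meta$rates$kinematics, side = meta$skeleton_side,
      class = c("skeleton_trace", class(kin))
    )
  } else {
    kin <- as_tibble(utils::read.csv(file.path(path, "cursor.csv")))
    kin <- structure(kin,
      rate = meta$rates$kinematics,
      geometry = circle_geometry(unlist(meta$geometry$center),
                                 meta$geometry$radius,
                                 meta$geometry$tunnel_width),
      class = c("cursor_trace", class(kin))
    )
  }
  od <- as_tibble(utils::read.csv(file.path(path, "od.csv")))
  od <- structure(od,
    montage = as_tibble(meta$fnirs$montage),
    distance_mm = meta$fnirs$distance_mm, dpf = meta$fnirs$dpf,
    rate = meta$rates$fnirs,
    class = c("raw_optical", class(od))
  )
  eeg_long <- utils::read.csv(file.path(path, "eeg.csv"))
  eeg <- as_tibble(eeg_long) |>
    tidyr::pivot_wider(names_from = "channel", values_from = "value")
  eeg <- structure(eeg,
    rate = meta$rates$eeg, montage = as_tibble(meta$eeg_montage),
    bands = eeg_bands(),
    class = c("eeg_recording", class(eeg))
  )
  truth <- NULL
  gt_path <- file.path(path, "ground_truth.json")
  if (file.exists(gt_path)) {
    truth <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  }
  structure(
    list(
      task = meta$task, hand = meta$hand, condition = meta$condition,
      subject = meta$subject, group = meta$group,
      lesion_side = meta$lesion_side, moving_side = meta$moving_side,
      schedule = schedule, kinematics = kin, od = od, eeg = eeg,
      truth = truth
    ),
    class = "neuromove_session"
  )
}
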