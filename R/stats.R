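#' Mixed ANOVA with partial eta-squared
#'
#' Fits the between x within factorial used throughout the analysis layer
#' (e.g. group as between-subject factor, hand and condition as
#' within-subject factors) on a tidy metrics table, via a univariate
#' repeated-measures decomposition (`aov` with `Error(subject/...)`
#' strata). Partial eta-squared is `SS_effect / (SS_effect + SS_error)`
#' with the error term of the effect's own stratum. Within-subject factors
#' are restricted to two levels, where sphericity is not at issue; subjects
#' with incomplete within-subject cells are dropped listwise.
#'
#' @param data Tidy data frame: one row per subject x within-cell.
#' @param dv Name of the numeric response column.
#' @param between Name of the between-subject factor column.
#' @param within Character vector of within-subject factor columns (each
#'   with exactly 2 levels).
#' @param subject Name of the subject identifier column.
#' @return A `mixed_anova` object; see [tidy()] for the effect table
#'   (`effect`, `df_num`, `df_den`, `statistic` (F), `p_value`, `eta2p`)
#'   and `$assumptions` for per-cell Shapiro-Wilk p-values.
#' @examples
#' df <- tidyr::expand_grid(subject = paste0("s", 1:8),
#'                          hand = c("paretic", "non-paretic"))
#' df$group <- rep(c("healthy", "stroke"), each = 8)
#' df$value <- rnorm(nrow(df))
#' tidy(mixed_anova(df, "value", "group", "hand"))
#' @export
mixed_anova <- function(data, dv, between = "group", within = "hand",
                        subject = "subject") {
  cols <- c(dv, between, within, subject)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(data[[dv]])) abort(sprintf("dv '%s' must be numeric", dv))

  df <- as_tibble(data)[cols]
  df <- df[stats::complete.cases(df), ]
  for (f in c(between, within, subject)) df[[f]] <- factor(df[[f]])
  for (f in within) {
    if (nlevels(df[[f]]) > 2) {
      abort(sprintf(
        "within factor '%s' has %d levels; sphericity handling beyond 2 levels is not supported",
        f, nlevels(df[[f]])
      ))
    }
  }

  # listwise deletion: keep subjects with every within-cell exactly once
  n_cells <- prod(vapply(within, function(f) nlevels(df[[f]]), integer(1)))
  counts <- table(df[[subject]])
  complete <- names(counts)[counts == n_cells]
  df <- df[df[[subject]] %in% complete, ]
  df[[subject]] <- droplevels(df[[subject]])
  df[[between]] <- droplevels(df[[between]])
  per_group <- table(unique(df[, c(subject, between)])[[between]])
  if (any(per_group < 2)) {
    abort("need at least 2 complete subjects per group")
  }

  fixed <- paste(c(between, within), collapse = " * ")
  err <- if (length(within) > 0) {
    sprintf("Error(%s/(%s))", subject, paste(within, collapse = " * "))
  } else {
    sprintf("Error(%s)", subject)
  }
  form <- stats::as.formula(paste(dv, "~", fixed, "+", err))
  fit <- aov(form, data = df)

  total_ss <- sum((df[[dv]] - mean(df[[dv]]))^2)
  eps <- 1e-12 * max(total_ss, 1)
  rows <- purrr::map_dfr(summary(fit), function(stratum) {
    tab <- stratum[[1]]
    effs <- trimws(rownames(tab))
    resid_i <- which(effs == "Residuals")
    if (length(resid_i) == 0) return(tibble())
    ss_err <- tab[resid_i, "Sum Sq"]
    df_err <- tab[resid_i, "Df"]
    keep <- setdiff(seq_len(nrow(tab)), resid_i)
    purrr::map_dfr(keep, function(i) {
      ss <- tab[i, "Sum Sq"]
      dfn <- tab[i, "Df"]
      if (ss < eps && ss_err < eps) {
        f <- 0; p <- 1; eta <- 0
      } else {
        f <- (ss / dfn) / (ss_err / df_err)
        p <- pf(f, dfn, df_err, lower.tail = FALSE)
        eta <- ss / (ss + ss_err)
      }
      tibble(effect = gsub(" ", "", effs[i]), df_num = dfn, df_den = df_err,
             statistic = f, p_value = p, eta2p = eta,
             ss_effect = ss, ss_error = ss_err)
    })
  })

  # per-cell normality screen (between x within cells)
  cells <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(between, within)))) |>
    dplyr::summarise(
      n = dplyr::n(),
      shapiro_p = tryCatch(shapiro.test(.data[[dv]])$p.value,
                           error = function(e) NA_real_),
      .groups = "drop"
    )

  structure(
    list(
      table = rows, assumptions = cells, dv = dv, between = between,
      within = within, subject = subject,
      n_subjects = length(complete),
      n_per_group = as.list(per_group), fit = fit
    ),
    class = "mixed_anova"
  )
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("Mixed ANOVA on '%s' (%s between; %s within; n = %d)\n",
              x$dv, x$between, paste(x$within, collapse = ", "),
              x$n_subjects))
  print(as.data.frame(x$table[, 1:6]), digits = 4)
  invisible(x)
}

#' @rdname mixed_anova
#' @param x A `mixed_anova` object.
#' @param ... Unused.
#' @method tidy mixed_anova
#' @export
tidy.mixed_anova <- function(x, ...) {
  dplyr::mutate(x$table[, c("effect", "df_num", "df_den", "statistic",
                            "p_value", "eta2p")],
                effect_size = effect_size_label(.data$eta2p))
}

#' @rdname mixed_anova
#' @method glance mixed_anova
#' @export
glance.mixed_anova <- function(x, ...) {
  tibble(
    dv = x$dv, n_subjects = x$n_subjects,
    n_effects = nrow(x$table),
    min_shapiro_p = suppressWarnings(min(x$assumptions$shapiro_p,
                                         na.rm = TRUE))
  )
}

#' Pairwise post-hoc t-tests with Benjamini-Hochberg correction
#'
#' All level pairs of `factor`, optionally within each combination of `by`
#' factors; paired t-tests when every subject contributes one observation
#' to each level (within-subject factor), independent otherwise. Adjusted
#' p-values are BH step-up over the whole returned family.
#'
#' @param data Tidy data frame.
#' @param dv Numeric response column name.
#' @param factor Factor whose levels are compared.
#' @param by Optional stratification columns.
#' @param subject Subject id column (used to decide pairing).
#' @return A tibble with one row per comparison: `by` columns, `level1`,
#'   `level2`, `n1`, `n2`, `paired`, `statistic`, `df`, `p_value`, `p_adj`.
#' @export
posthoc_pairwise <- function(data, dv, factor, by = NULL,
                             subject = "subject") {
  df <- as_tibble(data)
  strata <- if (is.null(by)) list(df) else
    dplyr::group_split(dplyr::group_by(df, dplyr::across(dplyr::all_of(by))))
  rows <- purrr::map_dfr(strata, function(d) {
    levs <- unique(as.character(d[[factor]]))
    if (length(levs) < 2) return(tibble())
    combos <- utils::combn(levs, 2, simplify = FALSE)
    purrr::map_dfr(combos, function(cmb) {
      d1 <- d[d[[factor]] == cmb[1], ]
      d2 <- d[d[[factor]] == cmb[2], ]
      shared <- intersect(d1[[subject]], d2[[subject]])
      paired <- length(shared) == nrow(d1) && length(shared) == nrow(d2) &&
        !anyDuplicated(d1[[subject]]) && !anyDuplicated(d2[[subject]])
      if (paired) {
        x <- d1[[dv]][match(shared, d1[[subject]])]
        y <- d2[[dv]][match(shared, d2[[subject]])]
        if (sd(x - y) == 0) {
          tt <- list(statistic = c(t = 0), parameter = c(df = length(x) - 1),
                     p.value = 1)
        } else {
          tt <- t.test(x, y, paired = TRUE)
        }
      } else {
        tt <- t.test(d1[[dv]], d2[[dv]])
      }
      out <- tibble(
        level1 = cmb[1], level2 = cmb[2],
        n1 = nrow(d1), n2 = nrow(d2), paired = paired,
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value
      )
      if (!is.null(by)) out <- dplyr::bind_cols(d[1, by, drop = FALSE], out)
      out
    })
  })
  if (nrow(rows) > 0) rows$p_adj <- bh_adjust(rows$p_value)
  rows
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `p.adjust(method = "BH")`; adjusted values
#' are monotone in rank and capped at 1. An empty input returns an empty
#' vector; p-values outside `[0, 1]` are an error.
#'
#' @param pvals Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (!is.numeric(pvals) || any(is.na(pvals)) ||
      any(pvals < 0 | pvals > 1)) {
    abort("p-values must be numeric in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Spearman rank (partial) correlation with the reporting filter
#'
#' Plain Spearman correlation (Pearson on average ranks) when `covariates`
#' is empty; otherwise a rank partial correlation: the ranks of `x` and `y`
#' are residualized on the ranks of the covariates and the residuals
#' correlated. Following the analysis convention, a correlation is flagged
#' `reported` only when `rho^2 > 0.25` (moderate or larger). The p-value
#' uses the t approximation with `n - 2 - n_covariates` degrees of freedom.
#'
#' @param data Data frame holding the variables.
#' @param x,y Column names of the two variables.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param report_threshold Reporting filter on `rho^2`.
#' @return A one-row tibble: `x`, `y`, `covariates`, `n`, `rho`, `r_s2`,
#'   `p_value`, `reported`, `method`.
#' @export
spearman_partial <- function(data, x, y, covariates = character(),
                             report_threshold = 0.25) {
  cols <- c(x, y, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  d <- as_tibble(data)[cols]
  d <- d[stats::complete.cases(d), ]
  n <- nrow(d)
  if (n < 4) abort("need at least 4 complete cases")
  method <- if (length(covariates) == 0) "spearman" else "spearman_partial"
  if (var(d[[x]]) == 0 || var(d[[y]]) == 0) {
    warn("zero variance in x or y; correlation undefined")
    return(tibble(x = x, y = y,
                  covariates = paste(covariates, collapse = ","),
                  n = n, rho = NA_real_, r_s2 = NA_real_,
                  p_value = NA_real_, reported = FALSE, method = method))
  }
  ranks <- purrr::map(d, rank) # average ranks for ties
  if (length(covariates) == 0) {
    rho <- cor(ranks[[x]], ranks[[y]])
  } else {
    Z <- do.call(cbind, ranks[covariates])
    rx <- residuals(lm(ranks[[x]] ~ Z))
    ry <- residuals(lm(ranks[[y]] ~ Z))
    rho <- cor(rx, ry)
  }
  dfree <- n - 2 - length(covariates)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt(dfree / (1 - rho^2))
    2 * pt(-abs(tval), dfree)
  }
  tibble(
    x = x, y = y, covariates = paste(covariates, collapse = ","),
    n = n, rho = rho, r_s2 = rho^2, p_value = p,
    reported = rho^2 > report_threshold, method = method
  )
}

#' Qualitative label for a partial eta-squared effect size
#'
#' Lower-inclusive thresholds: 0.02 (small), 0.13 (medium), 0.26 (large);
#' below 0.02 the effect is negligible (not interpreted).
#'
#' @param eta2p Numeric vector in `[0, 1]`.
#' @return A character vector of labels.
#' @export
effect_size_label <- function(eta2p) {
  if (any(!is.finite(eta2p)) || any(eta2p < 0 | eta2p > 1)) {
    abort("eta2p must be in [0, 1]")
  }
  dplyr::case_when(
    eta2p >= 0.26 ~ "large",
    eta2p >= 0.13 ~ "medium",
    eta2p >= 0.02 ~ "small",
    TRUE ~ "negligible"
  )
}

#' Shapiro-Wilk normality screen
#'
#' @param values Numeric sample, 3 <= n <= 5000, non-constant.
#' @param alpha Flagging level.
#' @return A one-row tibble: `n`, `statistic`, `p_value`, `non_normal`.
#' @export
shapiro_check <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) abort("Shapiro-Wilk requires 3 <= n <= 5000")
  if (var(values) == 0) abort("sample is constant; normality test undefined")
  sw <- shapiro.test(values)
  tibble(n = n, statistic = unname(sw$statistic),
         p_value = sw$p.value, non_normal = sw$p.value < alpha)
}
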