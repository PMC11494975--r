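test_that("mixed ANOVA matches an independent cell-means decomposition", {
  # 2 (group) x 2 (hand) toy data, 6 subjects per group, integer values
  set.seed(31)
  df <- tidyr::expand_grid(subject = sprintf("s%02d", 1:12),
                           hand = c("a", "b"))
  df$group <- rep(rep(c("g1", "g2"), each = 2), 6)[order(rep(1:12, each = 2))]
  df$group <- rep(c("g1", "g2"), each = 12)
  df$value <- as.numeric(sample(1:20, 24, replace = TRUE))

  fit <- mixed_anova(df, "value", between = "group", within = "hand")
  tb <- tidy(fit)
  oracle <- mixed_anova_oracle_2x2(df, "value", "group", "hand", "subject")

  expect_equal(tb$statistic[tb$effect == "group"], oracle$group$F,
               tolerance = 1e-9)
  expect_equal(tb$eta2p[tb$effect == "group"], oracle$group$eta,
               tolerance = 1e-9)
  expect_equal(tb$statistic[tb$effect == "hand"], oracle$within$F,
               tolerance = 1e-9)
  expect_equal(tb$eta2p[tb$effect == "hand"], oracle$within$eta,
               tolerance = 1e-9)
  expect_equal(tb$statistic[tb$effect == "group:hand"],
               oracle$interaction$F, tolerance = 1e-9)
  expect_equal(tb$eta2p[tb$effect == "group:hand"],
               oracle$interaction$eta, tolerance = 1e-9)
  # SS identity: effect + subject + error SS add up to the total
  expect_equal(oracle$ss[["total"]], oracle$ss[["parts"]],
               tolerance = 1e-9 * oracle$ss[["total"]])
})

test_that("constant responses give F = 0 and eta2p = 0 throughout", {
  df <- tidyr::expand_grid(subject = sprintf("s%d", 1:8),
                           hand = c("a", "b"))
  df$group <- rep(c("g1", "g2"), each = 8)
  df$value <- 7
  tb <- tidy(suppressWarnings(mixed_anova(df, "value", "group", "hand")))
  expect_true(all(tb$statistic == 0))
  expect_true(all(tb$eta2p == 0))
  expect_true(all(tb$p_value == 1))
})

test_that("mixed ANOVA guards its design assumptions", {
  df <- tidyr::expand_grid(subject = sprintf("s%d", 1:6),
                           hand = c("a", "b", "c"))
  df$group <- rep(c("g1", "g2"), each = 9)
  df$value <- rnorm(18)
  expect_error(mixed_anova(df, "value", "group", "hand"), "sphericity")

  df2 <- tidyr::expand_grid(subject = c("s1", "s2"), hand = c("a", "b"))
  df2$group <- c("g1", "g1", "g2", "g2")
  df2$value <- rnorm(4)
  expect_error(mixed_anova(df2, "value", "group", "hand"), "2 complete")
  expect_error(mixed_anova(df2, "hand", "group", "hand"), "numeric")
})

test_that("incomplete subjects are dropped listwise", {
  df <- tidyr::expand_grid(subject = sprintf("s%d", 1:10),
                           hand = c("a", "b"))
  df$group <- rep(c("g1", "g2"), each = 10)
  set.seed(5)
  df$value <- rnorm(20)
  df_incomplete <- df[-1, ] # s1 lacks hand "a"
  fit <- mixed_anova(df_incomplete, "value", "group", "hand")
  expect_equal(fit$n_subjects, 9)
  expect_equal(sum(unlist(fit$n_per_group)), 9)
})

test_that("BH adjustment matches the step-up oracle and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               bh_oracle(c(0.01, 0.02, 0.03, 0.04)))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.9)), c(0.01, 0.9))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    # adjusted values are monotone in the raw ranks and never below raw p
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj >= p - 1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("post-hoc pairwise t-tests pair correctly and adjust the family", {
  df <- tidyr::expand_grid(subject = sprintf("s%d", 1:10),
                           hand = c("a", "b"))
  set.seed(7)
  df$value <- rnorm(20) + 2 * (df$hand == "b")
  out <- posthoc_pairwise(df, "value", "hand")
  expect_equal(nrow(out), 1)
  expect_true(out$paired)
  # single comparison: adjusted p equals raw p
  expect_equal(out$p_adj, out$p_value)
  # agrees with a direct paired t-test
  tt <- t.test(df$value[df$hand == "a"], df$value[df$hand == "b"],
               paired = TRUE)
  expect_equal(out$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(out$p_value, tt$p.value, tolerance = 1e-12)
  # identical samples: t = 0, p = 1
  df0 <- df
  df0$value <- rep(rnorm(10), each = 2)
  out0 <- posthoc_pairwise(df0, "value", "hand")
  expect_equal(out0$statistic, 0)
  expect_equal(out0$p_value, 1)
  # independent comparison when subjects differ between levels
  df2 <- tibble::tibble(subject = sprintf("u%d", 1:20),
                        grp = rep(c("x", "y"), each = 10),
                        value = rnorm(20))
  out2 <- posthoc_pairwise(df2, "value", "grp")
  expect_false(out2$paired)
})

test_that("Spearman correlation matches the average-rank oracle with ties", {
  set.seed(8)
  for (i in 1:20) {
    x <- sample(1:6, 30, replace = TRUE) # heavy ties
    y <- sample(1:6, 30, replace = TRUE) + 0.3 * x
    d <- tibble::tibble(x = x, y = y)
    res <- spearman_partial(d, "x", "y")
    rx <- average_ranks(x)
    ry <- average_ranks(y)
    rho_oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(res$rho, rho_oracle, tolerance = 1e-12)
    expect_equal(res$r_s2, rho_oracle^2, tolerance = 1e-12)
  }
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(9)
  x <- rnorm(40)
  y <- x + rnorm(40)
  d0 <- tibble::tibble(x = x, y = y)
  base <- spearman_partial(d0, "x", "y")$rho
  expect_equal(spearman_partial(tibble::tibble(x = exp(x), y = y),
                                "x", "y")$rho, base, tolerance = 1e-12)
  expect_equal(spearman_partial(tibble::tibble(x = x, y = y^3 + 5 * y),
                                "x", "y")$rho, base, tolerance = 1e-12)
})

test_that("Spearman handles perfect, undefined and partial cases", {
  d <- tibble::tibble(x = 1:10, y = (1:10)^2)
  res <- spearman_partial(d, "x", "y")
  expect_equal(res$rho, 1)
  expect_true(res$reported)
  res_dec <- spearman_partial(tibble::tibble(x = 1:10, y = -(1:10)), "x", "y")
  expect_equal(res_dec$rho, -1)
  expect_warning(
    res0 <- spearman_partial(tibble::tibble(x = rep(1, 5), y = 1:5), "x", "y"),
    "zero variance"
  )
  expect_true(is.na(res0$rho))
  expect_false(res0$reported)
  expect_error(spearman_partial(tibble::tibble(x = 1:3, y = 1:3), "x", "y"),
               "4 complete")

  # partialling out a covariate that fully drives both leaves ~nothing
  set.seed(10)
  z <- rnorm(50)
  d2 <- tibble::tibble(x = z + 0.1 * rnorm(50), y = z + 0.1 * rnorm(50),
                       z = z)
  plain <- spearman_partial(d2, "x", "y")
  partial <- spearman_partial(d2, "x", "y", covariates = "z")
  expect_gt(plain$rho, 0.9)
  expect_lt(abs(partial$rho), 0.5)
  expect_identical(partial$method, "spearman_partial")
})

test_that("effect-size labels use lower-inclusive thresholds", {
  expect_equal(effect_size_label(c(0.01, 0.02, 0.13, 0.26, 0.3)),
               c("negligible", "small", "medium", "large", "large"))
  expect_error(effect_size_label(1.2), "0, 1")
})

test_that("Shapiro-Wilk screen is calibrated and powered", {
  set.seed(11)
  flags_norm <- vapply(1:200, function(i) {
    shapiro_check(rnorm(50))$non_normal
  }, logical(1))
  expect_gte(mean(flags_norm), 0.01)
  expect_lte(mean(flags_norm), 0.1)
  flags_exp <- vapply(1:200, function(i) {
    shapiro_check(rexp(50))$non_normal
  }, logical(1))
  expect_gt(mean(flags_exp), 0.9)
  expect_error(shapiro_check(rep(1, 10)), "constant")
  expect_error(shapiro_check(rnorm(2)), "3 <= n")
})
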