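# shared fixture builders (everything generated in code)

# skeleton trace from explicit joint positions (one list entry per joint,
# each an n x 3 matrix) -- used for closed-form geometry checks
make_skeleton <- function(time, joints, side = "right", rate = 30) {
  cols <- purrr::imap(joints, function(m, nm) {
    m <- matrix(m, ncol = 3)
    colnames(m) <- paste(nm, c("x", "y", "z"), sep = "_")
    tibble::as_tibble(m)
  })
  out <- dplyr::bind_cols(tibble::tibble(time = time), cols)
  structure(out,
    rate = rate, side = side,
    class = c("skeleton_trace", class(out))
  )
}

# cursor trace from explicit polar coordinates about the geometry center
make_cursor <- function(time, r, theta, geometry = circle_geometry()) {
  out <- tibble::tibble(
    time = time,
    x = geometry$center[1] + r * cos(theta),
    y = geometry$center[2] + r * sin(theta)
  )
  structure(out,
    geometry = geometry, rate = 1 / diff(time[1:2]),
    class = c("cursor_trace", class(out))
  )
}

# EEG recording from an explicit channel matrix
make_eeg <- function(time, channels, rate = 500, montage = eeg_montage()) {
  stopifnot(ncol(channels) == nrow(montage))
  out <- dplyr::bind_cols(
    tibble::tibble(time = time),
    stats::setNames(tibble::as_tibble(channels, .name_repair = "minimal"),
                    montage$channel)
  )
  structure(out,
    rate = rate, montage = montage, bands = eeg_bands(),
    class = c("eeg_recording", class(out))
  )
}

# independent step-up BH enumeration (oracle; no p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# independent average-rank computation (oracle; no rank())
average_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- less + (ties + 1) / 2
  }
  r
}

# independent balanced 2 (between) x 2 (within) mixed-ANOVA decomposition
# from cell/subject means (oracle for mixed_anova)
mixed_anova_oracle_2x2 <- function(df, dv, group, within, subject) {
  x <- df[[dv]]
  g <- as.character(df[[group]])
  w <- as.character(df[[within]])
  s <- as.character(df[[subject]])
  grand <- mean(x)
  subj_ids <- unique(s)
  n_w <- length(unique(w))
  m_s <- vapply(subj_ids, function(si) mean(x[s == si]), numeric(1))
  g_of_s <- vapply(subj_ids, function(si) g[s == si][1], character(1))
  m_g <- tapply(x, g, mean)
  m_w <- tapply(x, w, mean)
  m_gw <- tapply(x, list(g, w), mean)
  n_per_g <- table(g_of_s)

  ss_subj_total <- n_w * sum((m_s - grand)^2)
  ss_group <- sum(n_per_g * n_w * (m_g[names(n_per_g)] - grand)^2)
  ss_err_between <- ss_subj_total - ss_group
  ss_within_total <- sum((x - m_s[match(s, subj_ids)])^2)
  ss_w <- sum(table(w) * (m_w - grand)^2)
  ss_gw <- 0
  for (gi in names(m_g)) {
    for (wi in names(m_w)) {
      ss_gw <- ss_gw + n_per_g[[gi]] *
        (m_gw[gi, wi] - m_g[[gi]] - m_w[[wi]] + grand)^2
    }
  }
  ss_err_within <- ss_within_total - ss_w - ss_gw

  df_group <- length(m_g) - 1
  df_err_b <- length(subj_ids) - length(m_g)
  df_w <- n_w - 1
  df_gw <- df_group * df_w
  df_err_w <- df_err_b * df_w
  list(
    group = list(F = (ss_group / df_group) / (ss_err_between / df_err_b),
                 eta = ss_group / (ss_group + ss_err_between)),
    within = list(F = (ss_w / df_w) / (ss_err_within / df_err_w),
                  eta = ss_w / (ss_w + ss_err_within)),
    interaction = list(F = (ss_gw / df_gw) / (ss_err_within / df_err_w),
                       eta = ss_gw / (ss_gw + ss_err_within)),
    ss = c(total = sum((x - grand)^2),
           parts = ss_group + ss_err_between + ss_w + ss_gw + ss_err_within)
  )
}
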