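# Fixture builders and independent analytic oracles used across tests.

FS <- 100

# analytic minimum-jerk reach along azimuth theta_deg from marker, with rest
# phases before and after; returns the position matrix
mj_positions <- function(D = 0.45, T = 1.0, fs = FS, theta_deg = 0,
                         t_pre = 0.4, t_post = 0.4,
                         marker = c(0, 0, 0.75)) {
  t <- seq(0, t_pre + T + t_post, by = 1 / fs)
  s <- audioreach::min_jerk_s((t - t_pre) / T)
  dir <- c(sin(theta_deg * pi / 180), cos(theta_deg * pi / 180), 0)
  sweep(outer(D * s, dir), 2, marker, "+")
}

mj_trial <- function(D = 0.45, T = 1.0, fs = FS, theta_deg = 0,
                     condition = "A", target = 0, subject = "S01",
                     yaw_fun = NULL, t_pre = 0.4, t_post = 0.4,
                     marker = c(0, 0, 0.75)) {
  p <- mj_positions(D, T, fs, theta_deg, t_pre, t_post, marker)
  n <- nrow(p)
  t <- (seq_len(n) - 1) / fs
  yaw <- if (is.null(yaw_fun)) rep(0, n) else yaw_fun(t)
  trial_record(
    meta = trial_meta(subject, condition, target),
    hand = trajectory_series(p, fs),
    head = head_pose_series(matrix(rep(marker + c(0, -0.35, 0.55), each = n),
                                   n, 3),
                            quat_from_yaw_deg(yaw), fs),
    start_marker = marker
  )
}

# oracle: normalised time of the 3%-of-peak speed crossing of the
# minimum-jerk profile, by root finding on 30 tau^2 (1-tau)^2 = 0.03 * 1.875
mj_threshold_tau <- function(fraction = 0.03) {
  stats::uniroot(function(tau) 30 * tau^2 * (1 - tau)^2 - fraction * 1.875,
                 c(1e-6, 0.5), tol = 1e-12)$root
}

# oracle: analytic amplitude gain of the Gaussian filter at frequency f
gauss_gain <- function(f, fc = 5) {
  sigma <- sqrt(log(2)) / (2 * pi * fc)
  exp(-(2 * pi * f * sigma)^2 / 2)
}

# oracle: brute-force classical two-way within-subject ANOVA decomposition
# on a long data frame with columns subject, A, B, y (balanced, one
# observation per cell)
bf_rm_anova <- function(d) {
  gm <- mean(d$y)
  ms <- tapply(d$y, d$subject, mean)
  ma <- tapply(d$y, d$A, mean)
  mb <- tapply(d$y, d$B, mean)
  msa <- tapply(d$y, list(d$subject, d$A), mean)
  msb <- tapply(d$y, list(d$subject, d$B), mean)
  mab <- tapply(d$y, list(d$A, d$B), mean)
  ns <- length(ms); na <- length(ma); nb <- length(mb)
  ss_a <- ns * nb * sum((ma - gm)^2)
  ss_b <- ns * na * sum((mb - gm)^2)
  ss_sa <- nb * sum((msa - matrix(ms, ns, na) -
                       matrix(ma, ns, na, byrow = TRUE) + gm)^2)
  ss_sb <- na * sum((msb - matrix(ms, ns, nb) -
                       matrix(mb, ns, nb, byrow = TRUE) + gm)^2)
  ss_ab <- ns * sum((mab - matrix(ma, na, nb) -
                       matrix(mb, na, nb, byrow = TRUE) + gm)^2)
  resid <- d$y
  for (i in seq_len(nrow(d))) {
    s <- as.character(d$subject[i]); a <- as.character(d$A[i])
    b <- as.character(d$B[i])
    resid[i] <- d$y[i] - msa[s, a] - msb[s, b] - mab[a, b] +
      ms[s] + ma[a] + mb[b] - gm
  }
  ss_res <- sum(resid^2)
  list(
    condition = c(df1 = na - 1, df2 = (na - 1) * (ns - 1),
                  F = (ss_a / (na - 1)) / (ss_sa / ((na - 1) * (ns - 1)))),
    target = c(df1 = nb - 1, df2 = (nb - 1) * (ns - 1),
               F = (ss_b / (nb - 1)) / (ss_sb / ((nb - 1) * (ns - 1)))),
    interaction = c(df1 = (na - 1) * (nb - 1),
                    df2 = (na - 1) * (nb - 1) * (ns - 1),
                    F = (ss_ab / ((na - 1) * (nb - 1))) /
                      (ss_res / ((na - 1) * (nb - 1) * (ns - 1))))
  )
}

# a design table of random cell means for n subjects (balanced, complete)
fake_design_table <- function(n_subjects, seed = 1, dv_fun = NULL) {
  withr::with_seed(seed, {
    g <- expand.grid(subject_id = sprintf("S%02d", seq_len(n_subjects)),
                     condition = audioreach::CONDITIONS,
                     target_azimuth_deg = audioreach::TARGET_AZIMUTHS,
                     stringsAsFactors = FALSE)
    g$group <- ifelse(as.integer(factor(g$subject_id)) %% 2 == 1,
                      "regular", "reversed")
    g$hrtf <- "generic"
    g$dv <- if (is.null(dv_fun)) rnorm(nrow(g)) else dv_fun(g)
    tibble::as_tibble(g)
  })
}

# cohort fixture for the exclusion rules: n_ok compliant subjects plus
# 3 slow, 2 target-independent and 1 short-trajectory subject
exclusion_cohort <- function(n_ok = 18, trials_per_session = 8, seed = 5) {
  normal <- generator_params()
  slow <- generator_params(reach_duration_s = 3.3, duration_jitter_sd = 0.1)
  indep <- generator_params(gain = c(A = 0, B = 0, C = 0, D = 0),
                            bias = c(A = 90, B = 90, C = 90, D = 90),
                            noise_sd = c(A = 1, B = 1, C = 1, D = 1))
  short <- generator_params(reach_distance_m = 0.07,
                            n_submovements = c(A = 0, B = 0, C = 0, D = 0))
  kinds <- c(rep("normal", n_ok), rep("slow", 3), rep("indep", 2), "short")
  sessions <- lapply(seq_along(kinds), function(s) {
    cfg <- session_config(sprintf("S%02d", s), trials_per_session =
                            trials_per_session, seed = seed + s)
    p <- switch(kinds[s], normal = normal, slow = slow, indep = indep,
                short = short)
    generate_session(cfg, p)
  })
  list(sessions = sessions, kinds = kinds)
}
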