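# Synthetic motion-capture session generator.
#
# Hand transport is a straight minimum-jerk reach from the start marker to
# an endpoint whose azimuth is gain * target + bias + noise (multiplicative
# overshoot gain plus constant directional bias reproduce the
# eccentricity-dependent overshoot and the leftward straight-ahead bias).
# Corrective submovements are additive minimum-jerk displacements chained in
# time: the first starts in the deceleration phase of the transport and the
# rest follow at short intervals, so the tangential velocity stays above the
# segmentation threshold throughout the correction tail (isolated
# submovements separated by dead time would be cut off by the velocity
# bounds). Net submovement displacements are folded into the main transport
# target so the final endpoint is exactly the drawn pointing direction. The
# head performs a minimum-jerk yaw excursion toward the target starting
# before hand onset. Isotropic Gaussian measurement noise is added to every
# marker coordinate.

#' Normalised minimum-jerk position profile
#'
#' The standard smooth-reaching primitive: s(tau) = 10 tau^3 - 15 tau^4 +
#' 6 tau^5 on [0, 1], clamped outside. Peak rate is 1.875/T for a reach of
#' unit amplitude over duration T.
#'
#' @param tau Normalised time (vector).
#' @return s(tau) in [0, 1].
#' @export
min_jerk_s <- function(tau) {
  tau <- pmin(1, pmax(0, tau))
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Analytic minimum-jerk speed profile
#'
#' ds/dt for a reach of amplitude D and duration T:
#' v(tau) = 30 D/T * tau^2 (1 - tau)^2, maximal at tau = 1/2 with value
#' 1.875 D/T.
#'
#' @param tau Normalised time.
#' @param D Amplitude, metres.
#' @param T Duration, seconds.
#' @return Speed in m/s.
#' @export
min_jerk_speed <- function(tau, D, T) {
  tau <- pmin(1, pmax(0, tau))
  30 * D / T * tau^2 * (1 - tau)^2
}

per_condition <- function(x) {
  stopifnot(length(x) == 4)
  stats::setNames(as.numeric(x), CONDITIONS)
}

#' Generator parameters
#'
#' All per-condition parameters are length-4 vectors named A, B, C, D.
#' Defaults are the package calibration: they are tuned so that pipeline
#' means over a large generated cohort sit near the study-scale reference
#' values (mean absolute pointing error about 26 degrees in the short-sound
#' condition; heading ROM about 21.9 degrees in the long-sound condition
#' against 5.3/7.4/5.2 elsewhere; on average about 1.5 acceleration peaks
#' before and 2.8 after the peak-velocity point, with a larger total in the
#' long-sound condition; about -9.8 degrees straight-ahead bias in the
#' long-sound condition).
#'
#' @param gain Overshoot gain on target azimuth (dimensionless).
#' @param bias Constant directional bias, degrees (negative = left).
#' @param noise_sd Trial-to-trial pointing noise, degrees.
#' @param n_submovements Mean number of corrective submovements (Poisson).
#' @param head_gain Head yaw amplitude per degree of target azimuth.
#' @param head_rom_base Baseline head yaw amplitude, degrees.
#' @param reach_distance_m Reach amplitude, metres.
#' @param reach_duration_s Mean transport duration, seconds.
#' @param duration_jitter_sd Duration jitter SD, seconds.
#' @param submovement_amp_m SD of submovement net displacement, metres.
#' @param submovement_dur_s Submovement duration, seconds.
#' @param sub_onset_range Range (fractions of transport duration) in which
#'   the first submovement of the correction chain starts.
#' @param sub_spacing_s Range of inter-onset intervals between successive
#'   submovements in the chain, seconds.
#' @param head_lead_s Head onset lead before hand onset, seconds.
#' @param head_dur_s Head excursion duration, seconds.
#' @param head_rom_jitter_sd Lognormal sigma of head amplitude jitter.
#' @param yaw_noise_sd_deg Yaw measurement noise SD, degrees.
#' @param mocap_noise_sd_m Marker position noise SD, metres.
#' @param fs Sampling rate, Hz.
#' @param order_seed Seed for the pseudo-random target order (shared by all
#'   subjects, as in a fixed experimental playlist).
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(
    gain = c(A = 2.10, B = 1.35, C = 2.10, D = 2.10),
    bias = c(A = -8.0, B = -9.8, C = -8.0, D = -8.0),
    noise_sd = c(A = 10, B = 6, C = 10, D = 10),
    n_submovements = c(A = 3.3, B = 5.2, C = 3.3, D = 3.3),
    head_gain = c(A = 0.123, B = 0.612, C = 0.171, D = 0.117),
    head_rom_base = c(A = 2.5, B = 8.0, C = 3.5, D = 2.5),
    reach_distance_m = 0.45,
    reach_duration_s = 1.0,
    duration_jitter_sd = 0.08,
    submovement_amp_m = 0.05,
    submovement_dur_s = 0.20,
    sub_onset_range = c(0.45, 0.60),
    sub_spacing_s = c(0.15, 0.25),
    head_lead_s = 0.25,
    head_dur_s = 0.6,
    head_rom_jitter_sd = 0.20,
    yaw_noise_sd_deg = 0.05,
    mocap_noise_sd_m = 2.5e-4,
    fs = 100,
    order_seed = 2013L) {
  p <- list(
    gain = per_condition(gain), bias = per_condition(bias),
    noise_sd = per_condition(noise_sd),
    n_submovements = per_condition(n_submovements),
    head_gain = per_condition(head_gain),
    head_rom_base = per_condition(head_rom_base),
    reach_distance_m = reach_distance_m,
    reach_duration_s = reach_duration_s,
    duration_jitter_sd = duration_jitter_sd,
    submovement_amp_m = submovement_amp_m,
    submovement_dur_s = submovement_dur_s,
    sub_onset_range = sub_onset_range,
    sub_spacing_s = sub_spacing_s,
    head_lead_s = head_lead_s,
    head_dur_s = head_dur_s,
    head_rom_jitter_sd = head_rom_jitter_sd,
    yaw_noise_sd_deg = yaw_noise_sd_deg,
    mocap_noise_sd_m = mocap_noise_sd_m,
    fs = fs, order_seed = as.integer(order_seed)
  )
  num <- unlist(p[setdiff(names(p), "order_seed")])
  if (!all(is.finite(num))) stop("generator_params: non-finite parameter")
  if (any(c(p$noise_sd, p$mocap_noise_sd_m, p$yaw_noise_sd_deg) < 0)) {
    stop("generator_params: noise SDs must be >= 0")
  }
  if (p$fs <= 0 || p$reach_duration_s <= 0 || p$submovement_dur_s <= 0) {
    stop("generator_params: rates and durations must be positive")
  }
  structure(p, class = "generator_params")
}

#' Calibrated default generator parameters
#'
#' @return A `generator_params` object with the package calibration (see
#'   [generator_params()]).
#' @export
default_calibration <- function() generator_params()

# start marker position used by the generator (metres): table height 0.75 m
GEN_START_MARKER <- c(0, 0, 0.75)

#' Generate one synthetic pointing trial
#'
#' Draws from the current RNG state (wrap in [withr::with_seed()] or seed
#' via [generate_session()] for reproducibility).
#'
#' @param meta A [trial_meta()].
#' @param params A `generator_params`.
#' @param start_marker 3-vector marker position, metres.
#' @return A [trial_record()].
#' @export
generate_trial <- function(meta, params = default_calibration(),
                           start_marker = GEN_START_MARKER) {
  stopifnot(inherits(meta, "trial_meta"),
            inherits(params, "generator_params"))
  cc <- meta$condition
  fs <- params$fs
  theta_t <- meta$target_azimuth_deg

  # pointing direction actually produced on this trial
  theta_p <- params$gain[cc] * theta_t + params$bias[cc] +
    stats::rnorm(1, 0, params$noise_sd[cc])
  r <- params$reach_distance_m + stats::rnorm(1, 0, 0.02)
  r <- max(0.03, r)
  T_mov <- max(0.6, params$reach_duration_s +
                 stats::rnorm(1, 0, params$duration_jitter_sd))
  endpoint <- start_marker + r * c(sin(theta_p * pi / 180),
                                   cos(theta_p * pi / 180), 0)

  # timeline (seconds): rest | transport | hold | return | rest
  t_pre <- 0.5; t_hold <- 0.5; t_ret <- 0.9 * T_mov; t_post <- 0.3
  n <- ceiling((t_pre + T_mov + t_hold + t_ret + t_post) * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  t_on <- t_pre
  t_off <- t_pre + T_mov

  # corrective submovements: a chain starting in the deceleration phase,
  # successive onsets a short interval apart; net displacements folded into
  # the main target
  n_sub <- stats::rpois(1, params$n_submovements[cc])
  sub_delta <- matrix(0, max(1, n_sub), 3)
  sub_onset <- numeric(max(1, n_sub))
  if (n_sub > 0) {
    onset_k <- t_on + stats::runif(1, params$sub_onset_range[1],
                                   params$sub_onset_range[2]) * T_mov
    for (k in seq_len(n_sub)) {
      ang <- stats::runif(1, 0, 2 * pi)
      amp <- abs(stats::rnorm(1, 0, params$submovement_amp_m))
      sub_delta[k, ] <- amp * c(cos(ang), sin(ang), 0)
      sub_onset[k] <- onset_k
      onset_k <- onset_k + stats::runif(1, params$sub_spacing_s[1],
                                        params$sub_spacing_s[2])
    }
  }
  total_sub <- if (n_sub > 0) colSums(sub_delta[seq_len(n_sub), , drop = FALSE])
               else c(0, 0, 0)
  main_end <- endpoint - total_sub

  # base trajectory: transport, hold, return to the marker
  p <- matrix(rep(start_marker, each = n), n, 3)
  s_mov <- min_jerk_s((t - t_on) / T_mov)
  in_or_after <- t >= t_on & t < t_off + t_hold
  for (d in 1:3) {
    p[in_or_after, d] <- start_marker[d] +
      (main_end[d] - start_marker[d]) * s_mov[in_or_after]
  }
  ret <- t >= t_off + t_hold
  s_ret <- min_jerk_s((t - t_off - t_hold) / t_ret)
  for (d in 1:3) {
    p[ret, d] <- main_end[d] + (start_marker[d] - main_end[d]) * s_ret[ret]
  }
  if (n_sub > 0) {
    for (k in seq_len(n_sub)) {
      s_k <- min_jerk_s((t - sub_onset[k]) / params$submovement_dur_s)
      p <- p + outer(s_k, sub_delta[k, ])
    }
  }
  p <- p + matrix(stats::rnorm(3 * n, 0, params$mocap_noise_sd_m), n, 3)

  # head: minimum-jerk yaw excursion toward the target, leading the hand
  psi_amp <- (params$head_rom_base[cc] +
                params$head_gain[cc] * abs(theta_t)) *
    exp(stats::rnorm(1, 0, params$head_rom_jitter_sd))
  psi_sign <- if (theta_t != 0) sign(theta_t) else sample(c(-1, 1), 1)
  t_head_on <- t_on - params$head_lead_s
  yaw <- psi_sign * psi_amp * min_jerk_s((t - t_head_on) / params$head_dur_s)
  yaw <- yaw + stats::rnorm(n, 0, params$yaw_noise_sd_deg)
  head_p <- matrix(rep(start_marker + c(0, -0.35, 0.55), each = n), n, 3) +
    matrix(stats::rnorm(3 * n, 0, params$mocap_noise_sd_m), n, 3)
  q <- quat_from_yaw_deg(yaw)

  trial_record(
    meta = meta,
    hand = trajectory_series(p, fs),
    head = head_pose_series(head_p, q, fs),
    start_marker = start_marker
  )
}

#' Pseudo-random target order for one condition session
#'
#' 32 trials over 5 targets: each target at least 6 times, the remainder
#' drawn at random; the order is a function of `order_seed` only, so all
#' subjects hear the same playlist.
#'
#' @param trials_per_session Number of trials (default 32).
#' @param order_seed Integer seed.
#' @return Numeric vector of target azimuths, degrees.
#' @export
target_order <- function(trials_per_session = 32L, order_seed = 2013L) {
  withr::with_seed(order_seed, {
    base <- rep(TARGET_AZIMUTHS, trials_per_session %/% 5)
    extra <- sample(TARGET_AZIMUTHS, trials_per_session %% 5)
    sample(c(base, extra))
  })
}

#' Generate one subject's full session set
#'
#' Four condition sessions in the configured order, 32 trials each by
#' default, every target appearing at least 6 times per session. Generation
#' is a pure function of (config, params): the same seed yields an
#' identical session, and the target playlist is shared across subjects.
#'
#' @param config A [session_config()].
#' @param params A `generator_params`.
#' @return A list with `trials` (list of [trial_record()], presentation
#'   order) and `config`.
#' @export
generate_session <- function(config, params = default_calibration()) {
  stopifnot(inherits(config, "session_config"))
  order_az <- target_order(config$trials_per_session, params$order_seed)
  withr::with_seed(config$seed, {
    trials <- list()
    idx <- 0L
    for (cc in config$condition_order) {
      for (k in seq_len(config$trials_per_session)) {
        m <- trial_meta(config$subject_id, cc, order_az[k], trial_index = idx)
        trials[[idx + 1L]] <- generate_trial(m, params)
        idx <- idx + 1L
      }
    }
    list(trials = trials, config = config)
  })
}

#' Generate a cohort of subjects
#'
#' Subjects alternate between the regular (A-B-C-D) and reversed condition
#' order, emulating the two counterbalancing groups; roughly one in five
#' subjects is tagged as using an individual HRTF.
#'
#' @param n_subjects Number of subjects.
#' @param params A `generator_params`.
#' @param seed Base seed; subject s uses seed + s.
#' @return List of sessions as returned by [generate_session()].
#' @export
generate_cohort <- function(n_subjects, params = default_calibration(),
                            seed = 1L) {
  lapply(seq_len(n_subjects), function(s) {
    cfg <- session_config(
      subject_id = sprintf("S%02d", s),
      condition_order = if (s %% 2 == 1) CONDITIONS else rev(CONDITIONS),
      seed = seed + s,
      hrtf_individual = (s %% 5 == 0)
    )
    generate_session(cfg, params)
  })
}
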