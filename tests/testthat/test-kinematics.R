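# Filtering, differentiation, segmentation and hand features against
# analytic oracles.

test_that("Gaussian filter has unit DC gain and -3 dB at the cutoff", {
  n <- 400; t <- (0:(n - 1)) / FS
  const <- matrix(c(rep(0.1, n), rep(-2, n), rep(0.75, n)), n, 3)
  expect_equal(gaussian_lowpass(const, FS), const, tolerance = 1e-12)
  # sinusoid gains vs the analytic Gaussian frequency response
  interior <- 50:(n - 50)
  for (f in c(0.5, 2, 5)) {
    y <- gaussian_lowpass(sin(2 * pi * f * t), FS)
    gain <- max(abs(y[interior]))
    expect_equal(gain, gauss_gain(f), tolerance = 0.01)
  }
  y5 <- gaussian_lowpass(sin(2 * pi * 5 * t), FS)
  expect_equal(max(abs(y5[interior])), 1 / sqrt(2), tolerance = 0.01)
  y05 <- gaussian_lowpass(sin(2 * pi * 0.5 * t), FS)
  expect_gte(max(abs(y05[interior])), 0.99)
  expect_error(gaussian_lowpass(matrix(0, 5, 3), FS), "shorter than kernel")
  expect_error(gaussian_lowpass(matrix(0, 50, 3), FS, fc = 60), "fs > 2")
})

test_that("norms recover constant-velocity, minimum-jerk and circular motion", {
  n <- 201; t <- (0:(n - 1)) / FS
  # straight line at 0.3 m/s
  kin <- compute_norms(cbind(0.3 * t / sqrt(2), 0.3 * t / sqrt(2), 1), FS)
  inner <- 3:(n - 2)
  expect_equal(kin$v3D[inner], rep(0.3, length(inner)), tolerance = 1e-6)
  expect_lt(max(kin$a3D[inner]), 1e-9)
  expect_lt(max(kin$j3D[inner]), 1e-6)
  # minimum jerk: peak speed 1.875 D/T
  for (D in c(0.2, 0.45, 0.6)) {
    for (T in c(0.5, 1, 2)) {
      p <- mj_positions(D, T, FS, theta_deg = 25)
      kin <- compute_norms(p, FS)
      expect_equal(max(kin$v3D), 1.875 * D / T, tolerance = 0.01 * 1.875 * D / T)
    }
  }
  # circular motion: v = w r, a = w^2 r
  r <- 0.2; w <- 2 * pi * 0.8
  kin <- compute_norms(cbind(r * cos(w * t), r * sin(w * t), 0), FS)
  expect_equal(kin$v3D[inner], rep(w * r, length(inner)),
               tolerance = 0.01 * w * r)
  expect_equal(kin$a3D[inner], rep(w^2 * r, length(inner)),
               tolerance = 0.01 * w^2 * r)
  expect_error(compute_norms(matrix(0, 5, 3), FS), "at least 7")
})

test_that("primary segmentation finds the outward gesture and drops the return", {
  marker <- c(0, 0, 0.75)
  # never leaves a 1 cm neighbourhood
  n <- 100
  still <- sweep(matrix(rnorm(3 * n, 0, 0.002), n, 3), 2, marker, "+")
  expect_error(primary_segment(trajectory_series(still, FS), marker),
               "no movement")
  # out-and-back: window must end at maximum distance from the marker
  t <- seq(0, 2, by = 1 / FS)
  out_back <- cbind(0, 0.4 * sin(pi * t / 2), 0) |> sweep(2, marker, "+")
  w <- primary_segment(trajectory_series(out_back, FS), marker)
  expect_identical(w$i_hi, which.max(out_back[, 2]))
  # monotonic outward: window reaches the series end
  mono <- cbind(0, 0.4 * min_jerk_s(t / 2), 0) |> sweep(2, marker, "+")
  w2 <- primary_segment(trajectory_series(mono, FS), marker)
  expect_identical(w2$i_hi, length(t))
  expect_lt(w2$i_cross, length(t) / 2)
})

test_that("velocity bounds match the root-finding oracle across a D x T grid", {
  tau_c <- mj_threshold_tau(0.03)
  expect_equal(tau_c, 0.0453, tolerance = 0.01)
  for (D in c(0.2, 0.45, 0.6)) {
    for (T in c(0.5, 1, 2)) {
      p <- mj_positions(D, T, FS, theta_deg = -20, t_pre = 0.4, t_post = 0.4)
      kin <- compute_norms(p, FS)
      b <- detect_bounds(kin)
      expect_false(b$clipped_start); expect_false(b$clipped_end)
      # PVP at mid-movement
      expect_lte(abs((b$i_pvp - 1) - (0.4 + T / 2) * FS), 1.501)
      # onset/offset at the oracle crossing times (+- 1 sample)
      expect_lte(abs((b$i_start - 1) - (0.4 + tau_c * T) * FS), 1.001)
      expect_lte(abs((b$i_end - 1) - (0.4 + (1 - tau_c) * T) * FS), 1.001)
      # crossing bracketed: at most 3% at onset, above just after
      expect_lte(kin$v3D[b$i_start], 0.03 * b$v_peak)
      expect_gt(kin$v3D[b$i_start + 1], 0.03 * b$v_peak)
    }
  }
  still <- compute_norms(matrix(1, 50, 3), FS)
  expect_error(detect_bounds(still), "no movement")
})

test_that("hand features match the analytic minimum-jerk oracle", {
  p <- mj_positions(0.45, 1, FS, theta_deg = 0)
  kin <- compute_norms(p, FS)
  b <- detect_bounds(kin)
  f <- hand_features(kin, b)
  # |a| of minimum jerk has exactly two maxima, at tau = (5 +- sqrt(5))/10
  expect_identical(f$n_acc_peaks_total, 2L + 0L)
  expect_identical(f$n_acc_peaks_before_pvp, 1L + 0L)
  expect_identical(f$n_acc_peaks_after_pvp, 1L + 0L)
  # |a| maxima where a'(tau) = 0: 6 tau^2 - 6 tau + 1 = 0, tau = (3 +- sqrt(3))/6
  a_peaks <- find_peaks(kin$a3D[b$i_start:b$i_end]) + b$i_start - 1L
  expect_equal((a_peaks - 1) / FS, 0.4 + c((3 - sqrt(3)) / 6,
                                           (3 + sqrt(3)) / 6),
               tolerance = 0.02)
  expect_equal(f$path_length_m, 0.45, tolerance = 0.002)
  expect_equal(f$pvp_relative_position, 0.5, tolerance = 0.02)
  expect_equal(f$v_mean, mean(kin$v3D[b$i_start:b$i_end]))
})

test_that("a corrective submovement adds deceleration-phase peaks matching brute force", {
  # composite: main reach + one submovement starting at tau = 0.7
  D <- 0.45; T <- 1; d_sub <- 0.25; amp <- 0.05
  t <- seq(0, 2, by = 1 / FS)
  main <- D * min_jerk_s((t - 0.4) / T)
  sub <- amp * min_jerk_s((t - 0.4 - 0.7 * T) / d_sub)
  p <- cbind(sub, main, 0)
  kin <- compute_norms(p, FS)
  b <- detect_bounds(kin)
  f <- hand_features(kin, b)
  expect_gt(f$n_acc_peaks_after_pvp, 1)
  # brute-force enumeration of |a| local maxima on a 10x finer grid
  tf <- seq(0, 2, by = 1 / (10 * FS))
  mj_acc <- function(tau, D, T) {
    tau <- pmin(1, pmax(0, tau))
    D / T^2 * (60 * tau - 180 * tau^2 + 120 * tau^3)
  }
  ax <- mj_acc((tf - 0.4 - 0.7 * T) / d_sub, amp, d_sub)
  ay <- mj_acc((tf - 0.4) / T, D, T)
  a_norm <- sqrt(ax^2 + ay^2)
  in_b <- tf >= (b$i_start - 1) / FS & tf <= (b$i_end - 1) / FS
  cand <- which(diff(sign(diff(a_norm))) < 0) + 1L
  cand <- cand[in_b[cand]]
  prom_floor <- 0.05 * max(a_norm[in_b])
  keep <- vapply(cand, function(i) {
    v <- a_norm[i]
    lo <- max(which(a_norm[1:(i - 1)] > v), 1)
    hi <- min(which(a_norm[(i + 1):length(a_norm)] > v) + i,
              length(a_norm))
    v - max(min(a_norm[lo:i]), min(a_norm[i:hi])) >= prom_floor
  }, logical(1))
  expect_identical(as.integer(f$n_acc_peaks_total), length(cand[keep]))
})

test_that("features are scale-equivariant and time-shift invariant", {
  marker <- c(0, 0, 0.75)
  p <- mj_positions(0.3, 0.8, FS, theta_deg = 30)
  analyse <- function(p) {
    kin <- compute_norms(p, FS)
    b <- detect_bounds(kin)
    list(b = b, f = hand_features(kin, b))
  }
  base <- analyse(p)
  k <- 2.5
  scaled <- analyse(sweep(sweep(p, 2, marker), 2, marker,
                          FUN = function(x, m) k * x + m))
  expect_equal(scaled$f$v_peak, k * base$f$v_peak, tolerance = 1e-9)
  expect_equal(scaled$f$v_mean, k * base$f$v_mean, tolerance = 1e-9)
  expect_equal(scaled$f$path_length_m, k * base$f$path_length_m,
               tolerance = 1e-9)
  expect_identical(scaled$f$n_acc_peaks_total, base$f$n_acc_peaks_total)
  expect_equal(scaled$f$duration_s, base$f$duration_s)
  expect_equal(scaled$f$pvp_relative_position, base$f$pvp_relative_position)
  # prepend 30 rest samples: bounds shift, features unchanged
  shift <- 30L
  p_shift <- rbind(matrix(rep(p[1, ], each = shift), shift, 3), p)
  shifted <- analyse(p_shift)
  expect_identical(shifted$b$i_start, base$b$i_start + shift)
  expect_identical(shifted$b$i_end, base$b$i_end + shift)
  expect_identical(shifted$b$i_pvp, base$b$i_pvp + shift)
  expect_equal(shifted$f, base$f, tolerance = 1e-9)
})

test_that("small measurement noise perturbs features only mildly", {
  p <- mj_positions(0.45, 1, FS)
  base <- hand_features(compute_norms(gaussian_lowpass(p, FS), FS),
                        detect_bounds(compute_norms(gaussian_lowpass(p, FS),
                                                    FS)))
  # path length is stable up to 0.5 mm noise
  withr::with_seed(1, {
    pn <- p + matrix(rnorm(length(p), 0, 5e-4), nrow(p), 3)
    kin <- compute_norms(gaussian_lowpass(pn, FS), FS)
    f <- hand_features(kin, detect_bounds(kin))
    expect_lt(abs(f$path_length_m - base$path_length_m) /
                base$path_length_m, 0.02)
  })
  # peak counts are stable in the 0.2 mm regime (at 0.5 mm the filtered
  # noise acceleration ripple reaches the 5% prominence floor)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      pn <- p + matrix(rnorm(length(p), 0, 2e-4), nrow(p), 3)
      kin <- compute_norms(gaussian_lowpass(pn, FS), FS)
      f <- hand_features(kin, detect_bounds(kin))
      expect_lte(abs(f$n_acc_peaks_total - base$n_acc_peaks_total), 1)
    })
  }
})
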