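# Synthetic session generator: structure, determinism, and recovery of
# injected effects by the analysis pipeline.

identity_params <- function() {
  generator_params(
    gain = c(A = 1, B = 1, C = 1, D = 1),
    bias = c(A = 0, B = 0, C = 0, D = 0),
    noise_sd = c(A = 0, B = 0, C = 0, D = 0),
    n_submovements = c(A = 0, B = 0, C = 0, D = 0),
    duration_jitter_sd = 0, mocap_noise_sd_m = 0, yaw_noise_sd_deg = 0,
    head_rom_jitter_sd = 0)
}

test_that("the identity configuration points exactly at the target", {
  for (tg in TARGET_AZIMUTHS) {
    tr <- withr::with_seed(1, generate_trial(trial_meta("S01", "A", tg),
                                             identity_params()))
    row <- analyze_trial(tr)
    expect_identical(row$flag, "ok")
    expect_equal(row$signed_error_deg, 0, tolerance = 0.5)
  }
})

test_that("an injected constant bias is recovered for every target", {
  p <- generator_params(
    gain = c(A = 1, B = 1, C = 1, D = 1),
    bias = c(A = 10, B = 10, C = 10, D = 10),
    noise_sd = c(A = 0, B = 0, C = 0, D = 0),
    n_submovements = c(A = 0, B = 0, C = 0, D = 0),
    duration_jitter_sd = 0, mocap_noise_sd_m = 0, yaw_noise_sd_deg = 0,
    head_rom_jitter_sd = 0)
  for (tg in TARGET_AZIMUTHS) {
    tr <- withr::with_seed(2, generate_trial(trial_meta("S01", "C", tg), p))
    expect_equal(analyze_trial(tr)$signed_error_deg, 10, tolerance = 0.5)
  }
})

test_that("condition-D trials carry the avatar shift end to end", {
  tr <- withr::with_seed(3, generate_trial(trial_meta("S01", "D", 0)))
  expect_equal(tr$meta$avatar_shift_deg, -18.5)
  # rendered azimuth = actual + shift at the movement endpoint
  row <- analyze_trial(tr)
  kin <- kinematics(tr$hand)
  b <- detect_bounds(kin, primary_segment(tr$hand, tr$start_marker))
  rendered <- avatar_render_azimuth(kin$p_filt[b$i_end, ], tr$start_marker,
                                    tr$meta$avatar_shift_deg)
  expect_equal(rendered, row$pointed_azimuth_deg - 18.5, tolerance = 1e-6)
})

test_that("sessions have the specified trial structure", {
  cfg <- session_config("S01", seed = 4)
  sess <- generate_session(cfg)
  expect_length(sess$trials, 128)
  conds <- vapply(sess$trials, function(t) t$meta$condition, character(1))
  expect_equal(unname(table(conds)[CONDITIONS]), rep(32L, 4),
               ignore_attr = TRUE)
  az <- vapply(sess$trials[conds == "A"],
               function(t) t$meta$target_azimuth_deg, numeric(1))
  expect_true(all(table(az) >= 6))
  # same playlist in every condition and (by order_seed) every subject
  az_b <- vapply(sess$trials[conds == "B"],
                 function(t) t$meta$target_azimuth_deg, numeric(1))
  expect_identical(az, az_b)
})

test_that("generation is deterministic in the seed, with a shared playlist", {
  cfg <- session_config("S01", trials_per_session = 3L, seed = 42)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$trials[[5]]$hand$p, s2$trials[[5]]$hand$p)
  # byte-identical on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_session(s1$trials, cfg, d1); write_session(s2$trials, cfg, d2)
  for (f in setdiff(list.files(d1), "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # different seed: same targets, different noise
  cfg3 <- session_config("S01", trials_per_session = 3L, seed = 43)
  s3 <- generate_session(cfg3)
  expect_identical(
    vapply(s1$trials, function(t) t$meta$target_azimuth_deg, numeric(1)),
    vapply(s3$trials, function(t) t$meta$target_azimuth_deg, numeric(1)))
  expect_false(identical(s1$trials[[1]]$hand$p, s3$trials[[1]]$hand$p))
})

test_that("the head peaks earlier than the hand under the default head lead", {
  sess <- generate_session(session_config("S01", trials_per_session = 8L,
                                          seed = 6))
  res <- analyze_session(sess)
  ok <- res[res$flag == "ok", ]
  expect_gt(mean(ok$pvp_relative_position) -
              mean(ok$head_pvp_relative_position), 0.1)
  frac <- early_heading_fraction(ok)
  expect_true(all(frac$head_early_fraction >= frac$hand_early_fraction))
})
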