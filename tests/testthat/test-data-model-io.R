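# Trial/session data model and on-disk round trips.

test_that("type constructors enforce their invariants", {
  expect_error(trajectory_series(matrix(1, 1, 3), 100), "at least 2")
  p <- matrix(rnorm(30), 10, 3); p[4, 2] <- NaN
  expect_error(trajectory_series(p, 100), "row 4")
  q <- matrix(rep(c(1, 0, 0, 0), each = 5), 5, 4)
  q[3, ] <- c(2, 0, 0, 0)
  expect_error(head_pose_series(matrix(0.5, 5, 3), q, 100), "row 3")
  # condition/stimulus/shift contracts
  expect_equal(trial_meta("s", "B", 0)$stimulus_duration_ms, 2000)
  expect_equal(trial_meta("s", "D", 20)$avatar_shift_deg, -18.5)
  expect_error(trial_meta("s", "A", 0, stimulus_duration_ms = 2000),
               "requires stimulus_duration_ms = 250")
  expect_error(trial_meta("s", "C", 0, avatar_shift_deg = -18.5),
               "avatar_shift_deg")
  expect_error(trial_meta("s", "A", 12), "must be one of")
})

test_that("trial files round-trip to 1e-9 over randomized valid trials", {
  for (seed in 1:4) {
    tr <- withr::with_seed(seed, {
      cond <- sample(CONDITIONS, 1)
      generate_trial(trial_meta(sprintf("P%d", seed), cond,
                                sample(TARGET_AZIMUTHS, 1)))
    })
    path <- withr::local_tempfile(fileext = ".csv")
    write_trial(tr, path)
    back <- read_trial(path)
    expect_equal(back$hand$p, tr$hand$p, tolerance = 1e-9)
    expect_equal(back$head$p, tr$head$p, tolerance = 1e-9)
    expect_equal(back$head$q, tr$head$q, tolerance = 1e-9)
    expect_identical(length(back$hand), length(tr$hand))
    expect_identical(back$meta$condition, tr$meta$condition)
    expect_equal(back$meta$target_azimuth_deg, tr$meta$target_azimuth_deg)
    expect_equal(back$start_marker, tr$start_marker, tolerance = 1e-9)
  }
})

test_that("writing the same trial twice is byte-identical", {
  tr <- withr::with_seed(9, generate_trial(trial_meta("S01", "A", 20)))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_trial(tr, p1); write_trial(tr, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("condition-D files record the avatar shift in the header", {
  tr <- withr::with_seed(3, generate_trial(trial_meta("S01", "D", 0)))
  path <- withr::local_tempfile()
  write_trial(tr, path)
  hdr <- grep("^#", readLines(path), value = TRUE)
  expect_true(any(grepl("avatar_shift_deg=-18.500000000", hdr)))
})

test_that("malformed trial files are rejected with the offending row", {
  tr <- withr::with_seed(4, generate_trial(trial_meta("S01", "A", 0)))
  path <- withr::local_tempfile()
  write_trial(tr, path)
  lines <- readLines(path)
  k <- grep("^#", lines, invert = TRUE)[5]  # 4th data row
  bad <- strsplit(lines[k], ",")[[1]]; bad[2] <- "NaN"
  lines[k] <- paste(bad, collapse = ",")
  writeLines(lines, path)
  expect_error(read_trial(path), "row 4")
})

test_that("a minimal 2-sample trial file is valid", {
  marker <- c(0, 0, 0.75)
  tr <- trial_record(
    trial_meta("S01", "A", 0),
    trajectory_series(rbind(marker, marker + c(0, 0.001, 0)), 100),
    head_pose_series(rbind(marker, marker), rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)),
                     100),
    marker)
  path <- withr::local_tempfile()
  write_trial(tr, path)
  expect_identical(length(read_trial(path)$hand), 2L)
})

test_that("session load preserves manifest order and validates files", {
  cfg <- session_config("S07", trials_per_session = 3L, seed = 11)
  sess <- generate_session(cfg)
  dir <- withr::local_tempdir()
  write_session(sess$trials, cfg, dir)
  back <- load_session(dir)
  expect_length(back$trials, 12)  # 4 conditions x 3 trials
  expect_identical(
    vapply(back$trials, function(t) t$meta$trial_index, integer(1)),
    0:11)
  expect_identical(back$config$subject_id, "S07")
  # empty manifest
  dir2 <- withr::local_tempdir()
  write_session(list(), cfg, dir2)
  expect_length(load_session(dir2)$trials, 0)
  # missing file
  file.remove(file.path(dir, grep("trial_", list.files(dir), value = TRUE)[2]))
  expect_error(load_session(dir), "missing trial file")
})
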