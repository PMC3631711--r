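# S3 domain types for motion-capture pointing trials.
#
# Coordinate frame convention (fixed for the whole package): x to the
# subject's right, y forward, z up; azimuth(p) = atan2(x, y) in degrees so
# that 0 deg is straight ahead and positive angles are to the right.
# Quaternions are scalar-first (w, x, y, z), right-handed, world-from-body.
# Units at all interfaces: metres, seconds, degrees.

#' Conditions of the pointing experiment
#'
#' Four session conditions: "A" short target sound (250 ms), "B" long target
#' sound (2000 ms), "C" veridical auditory hand avatar with a 250 ms target,
#' "D" conflicting avatar whose rendered hand direction is shifted 18.5
#' degrees to the left.
#' @format Character vector of length 4.
#' @export
CONDITIONS <- c("A", "B", "C", "D")

#' Target azimuths used in the task, in degrees
#'
#' Five virtual source directions in the horizontal plane, 60 cm from the
#' start marker; negative is left of straight ahead.
#' @format Numeric vector of length 5.
#' @export
TARGET_AZIMUTHS <- c(-35, -20, 0, 20, 35)

#' Virtual target distance in metres
#' @export
TARGET_DISTANCE_M <- 0.60

#' Azimuthal shift of the conflicting avatar, degrees (negative = left)
#' @export
AVATAR_SHIFT_DEG <- -18.5

stimulus_duration_for <- function(condition) {
  switch(condition, A = 250, B = 2000, C = 250, D = 250,
         stop("unknown condition: ", condition))
}

avatar_shift_for <- function(condition) {
  if (identical(condition, "D")) AVATAR_SHIFT_DEG else 0
}

#' Uniformly sampled 3D trajectory series
#'
#' Container for a uniformly sampled 3-vector position series (typically the
#' fingertip endpoint). Time is stored implicitly as sample index over
#' sampling rate, which keeps the uniform-grid invariant exact.
#'
#' @param p Numeric matrix, n x 3, positions in metres (columns x, y, z).
#' @param fs Sampling rate in Hz.
#' @param i0 Integer index of the first sample (0-based), so that
#'   `t = (i0 + 0:(n-1)) / fs`.
#' @return An object of class `trajectory_series` with fields `p`, `fs`,
#'   `i0`, and derived `t` (seconds).
#' @export
trajectory_series <- function(p, fs, i0 = 0L) {
  p <- as.matrix(p)
  if (ncol(p) != 3) stop("trajectory_series: p must have 3 columns")
  if (nrow(p) < 2) stop("trajectory_series: need at least 2 samples")
  if (!all(is.finite(p))) {
    bad <- which(!apply(is.finite(p), 1, all))[1]
    stop(sprintf("trajectory_series: non-finite coordinate at row %d", bad))
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("trajectory_series: fs must be a positive scalar")
  }
  structure(
    list(p = unname(p), fs = as.numeric(fs), i0 = as.integer(i0),
         t = (as.integer(i0) + seq_len(nrow(p)) - 1) / fs),
    class = "trajectory_series"
  )
}

#' @export
length.trajectory_series <- function(x) nrow(x$p)

#' Head rigid-body pose series (position + unit quaternion)
#'
#' @param p Numeric matrix, n x 3, head position in metres.
#' @param q Numeric matrix, n x 4, scalar-first unit quaternions
#'   (world-from-body).
#' @param fs Sampling rate in Hz.
#' @param i0 Integer index of the first sample (0-based).
#' @param tol Unit-norm tolerance for the quaternions.
#' @return An object of class `head_pose_series`.
#' @export
head_pose_series <- function(p, q, fs, i0 = 0L, tol = 1e-6) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (ncol(q) != 4) stop("head_pose_series: q must have 4 columns (w,x,y,z)")
  if (nrow(q) != nrow(p)) stop("head_pose_series: p and q length mismatch")
  if (!all(is.finite(q))) {
    bad <- which(!apply(is.finite(q), 1, all))[1]
    stop(sprintf("head_pose_series: non-finite quaternion at row %d", bad))
  }
  nrm <- sqrt(rowSums(q^2))
  off <- which(abs(nrm - 1) > tol)
  if (length(off) > 0) {
    stop(sprintf("head_pose_series: non-unit quaternion at row %d (|q| = %.8f)",
                 off[1], nrm[off[1]]))
  }
  base <- trajectory_series(p, fs, i0)
  structure(
    list(p = base$p, q = unname(q), fs = base$fs, i0 = base$i0, t = base$t),
    class = "head_pose_series"
  )
}

#' @export
length.head_pose_series <- function(x) nrow(x$p)

#' Per-trial metadata
#'
#' @param subject_id Subject identifier (character).
#' @param condition One of "A", "B", "C", "D".
#' @param target_azimuth_deg Target azimuth in degrees, one of
#'   `TARGET_AZIMUTHS`.
#' @param trial_index Non-negative integer trial index within the session.
#' @param stimulus_duration_ms Stimulus duration; defaults to the condition's
#'   contract (250 ms for A/C/D, 2000 ms for B).
#' @param avatar_shift_deg Azimuthal shift of the rendered hand direction;
#'   defaults to -18.5 for condition D and 0 otherwise.
#' @return An object of class `trial_meta`.
#' @export
trial_meta <- function(subject_id, condition, target_azimuth_deg,
                       trial_index = 0L,
                       stimulus_duration_ms = stimulus_duration_for(condition),
                       avatar_shift_deg = avatar_shift_for(condition)) {
  condition <- match.arg(condition, CONDITIONS)
  if (!target_azimuth_deg %in% TARGET_AZIMUTHS) {
    stop("trial_meta: target_azimuth_deg must be one of ",
         paste(TARGET_AZIMUTHS, collapse = ", "))
  }
  expected_ms <- stimulus_duration_for(condition)
  if (!isTRUE(all.equal(stimulus_duration_ms, expected_ms))) {
    stop(sprintf("trial_meta: condition %s requires stimulus_duration_ms = %d",
                 condition, expected_ms))
  }
  expected_shift <- avatar_shift_for(condition)
  if (!isTRUE(all.equal(avatar_shift_deg, expected_shift))) {
    stop(sprintf("trial_meta: condition %s requires avatar_shift_deg = %g",
                 condition, expected_shift))
  }
  if (trial_index < 0) stop("trial_meta: trial_index must be >= 0")
  structure(
    list(subject_id = as.character(subject_id), condition = condition,
         target_azimuth_deg = as.numeric(target_azimuth_deg),
         stimulus_duration_ms = as.numeric(stimulus_duration_ms),
         trial_index = as.integer(trial_index),
         avatar_shift_deg = as.numeric(avatar_shift_deg)),
    class = "trial_meta"
  )
}

#' One recorded pointing trial
#'
#' @param meta A [trial_meta()].
#' @param hand A [trajectory_series()] for the fingertip endpoint.
#' @param head A [head_pose_series()] for the head rigid body.
#' @param start_marker 3-vector, position of the tactile start marker
#'   (metres).
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(meta, hand, head, start_marker) {
  stopifnot(inherits(meta, "trial_meta"),
            inherits(hand, "trajectory_series"),
            inherits(head, "head_pose_series"))
  start_marker <- as.numeric(start_marker)
  if (length(start_marker) != 3 || !all(is.finite(start_marker))) {
    stop("trial_record: start_marker must be a finite 3-vector")
  }
  # hand and head must share a common time window
  if (max(hand$t[1], head$t[1]) > min(hand$t[length(hand$t)],
                                      head$t[length(head$t)])) {
    stop("trial_record: hand and head series share no common time window")
  }
  structure(
    list(meta = meta, hand = hand, head = head, start_marker = start_marker),
    class = "trial_record"
  )
}

#' Session configuration
#'
#' Describes one synthetic (or recorded) subject session set: condition
#' order, trial count per condition, target sequence, and generator seed.
#'
#' @param subject_id Subject identifier.
#' @param condition_order Permutation of "A","B","C","D" giving session
#'   order; the regular order is A-B-C-D and the reversed group runs
#'   D-C-B-A.
#' @param trials_per_session Trials within each condition session
#'   (default 32).
#' @param seed Integer RNG seed for generation.
#' @param hrtf_individual Logical, whether the subject used an
#'   individually measured HRTF (metadata grouping factor).
#' @return An object of class `session_config`.
#' @export
session_config <- function(subject_id, condition_order = CONDITIONS,
                           trials_per_session = 32L, seed = 1L,
                           hrtf_individual = FALSE) {
  if (!setequal(condition_order, CONDITIONS) ||
      length(condition_order) != 4) {
    stop("session_config: condition_order must be a permutation of A,B,C,D")
  }
  if (trials_per_session < 1) stop("session_config: need >= 1 trial")
  structure(
    list(subject_id = as.character(subject_id),
         condition_order = as.character(condition_order),
         trials_per_session = as.integer(trials_per_session),
         seed = as.integer(seed),
         hrtf_individual = isTRUE(hrtf_individual)),
    class = "session_config"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "<trial_record> subject %s, condition %s, target %+g deg, %d samples @ %g Hz\n",
    x$meta$subject_id, x$meta$condition, x$meta$target_azimuth_deg,
    length(x$hand), x$hand$fs))
  invisible(x)
}
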