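# Head orienting analysis: heading (yaw) extraction from rigid-body
# quaternions, range of motion, final angle, and peak-velocity timing
# relative to the hand movement.

quat_forward <- function(q) {
  # world-frame forward axis (body +y) for scalar-first quaternions, row-wise
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(2 * (x * y - w * z),
        1 - 2 * (x^2 + z^2),
        2 * (y * z + w * x))
}

unwrap_rad <- function(a) {
  d <- diff(a)
  corr <- cumsum(round(d / (2 * pi)))
  c(a[1], a[-1] - 2 * pi * corr)
}

#' Yaw about the vertical axis for a scalar-first quaternion
#'
#' Convention: 0 degrees is straight ahead (+y), positive is to the
#' subject's right (+x); this is the sign convention of the task protractor.
#'
#' @param q n x 4 matrix of scalar-first quaternions.
#' @return Yaw angles in degrees (wrapped to (-180, 180]).
#' @export
quat_yaw_deg <- function(q) {
  f <- quat_forward(as.matrix(q))
  atan2(f[, 1], f[, 2]) * 180 / pi
}

#' Quaternion encoding a pure yaw rotation
#'
#' Inverse of [quat_yaw_deg()] for pitch/roll-free poses; used by the
#' synthetic generator.
#'
#' @param yaw_deg Yaw angles in degrees, positive right.
#' @return n x 4 matrix of scalar-first unit quaternions.
#' @export
quat_from_yaw_deg <- function(yaw_deg) {
  # positive-right yaw is a negative rotation about +z (right-hand rule)
  half <- -yaw_deg * pi / 180 / 2
  cbind(cos(half), 0, 0, sin(half))
}

#' Extract the heading series from a head pose series
#'
#' The heading is the azimuth of the head's forward axis (body +y rotated
#' into the world) projected on the horizontal plane; pitch and roll are
#' ignored. The yaw series is unwrapped, low-pass filtered with the same
#' Gaussian filter as the hand trajectory, and differentiated by central
#' differences.
#'
#' @param head A [head_pose_series()].
#' @param fc Filter cutoff, Hz (default 5, matching the hand pipeline).
#' @return An object of class `heading_series` with `yaw` (deg, filtered,
#'   unwrapped), `yaw_raw` (deg, unfiltered), `yaw_rate` (deg/s),
#'   `yaw_accel` (deg/s^2, signed) and `fs`.
#' @export
extract_heading <- function(head, fc = 5) {
  stopifnot(inherits(head, "head_pose_series"))
  f <- quat_forward(head$q)
  horiz <- sqrt(f[, 1]^2 + f[, 2]^2)
  degen <- which(horiz < sin(5 * pi / 180))
  if (length(degen) > 0) {
    stop(sprintf(
      "extract_heading: forward axis within 5 degrees of vertical at sample %d",
      degen[1]))
  }
  yaw_raw <- unwrap_rad(atan2(f[, 1], f[, 2])) * 180 / pi
  yaw <- gaussian_lowpass(yaw_raw, head$fs, fc)
  rate <- as.numeric(central_diff(matrix(yaw, ncol = 1), head$fs))
  accel <- as.numeric(central_diff(matrix(rate, ncol = 1), head$fs))
  structure(
    list(yaw = yaw, yaw_raw = yaw_raw, yaw_rate = rate, yaw_accel = accel,
         fs = head$fs),
    class = "heading_series"
  )
}

#' Head-movement features for one trial
#'
#' Heading range of motion (ROM) is computed over the whole trial window,
#' not only within the hand movement bounds, because head orienting starts
#' before hand onset; restricting to the hand bounds would truncate the
#' phenomenon. The final heading is read at the hand movement offset.
#' Acceleration peaks of |yaw acceleration| are counted inside the hand
#' bounds with the same prominence rule as the hand (a peak at the hand PVP
#' counts as "after"), and the head peak-velocity position is the argmax of
#' |yaw rate| over the trial window expressed relative to the hand bounds,
#' clipped to [0, 1] when the head peaks outside them.
#'
#' @param h A `heading_series` from [extract_heading()].
#' @param hand_bounds A `movement_bounds` for the hand.
#' @param trial_window Optional list with `i_lo`, `i_hi` (defaults to the
#'   full series).
#' @param prominence_fraction Relative prominence floor (default 0.05).
#' @return One-row tibble with columns `head_rom_deg`, `head_final_yaw_deg`,
#'   `head_n_acc_peaks_total`, `head_n_acc_peaks_before_pvp`,
#'   `head_n_acc_peaks_after_pvp`, `head_pvp_relative_position`.
#' @export
head_features <- function(h, hand_bounds, trial_window = NULL,
                          prominence_fraction = 0.05) {
  stopifnot(inherits(h, "heading_series"),
            inherits(hand_bounds, "movement_bounds"))
  n <- length(h$yaw)
  if (is.null(trial_window)) trial_window <- list(i_lo = 1L, i_hi = n)
  w <- trial_window$i_lo:trial_window$i_hi
  rom <- max(h$yaw[w]) - min(h$yaw[w])
  final_yaw <- h$yaw[hand_bounds$i_end]
  seg <- hand_bounds$i_start:hand_bounds$i_end
  pk <- find_peaks(abs(h$yaw_accel[seg]), prominence_fraction) +
    hand_bounds$i_start - 1L
  n_before <- sum(pk < hand_bounds$i_pvp)
  n_after <- sum(pk >= hand_bounds$i_pvp)
  i_head_pvp <- w[which.max(abs(h$yaw_rate[w]))]
  rel <- (i_head_pvp - hand_bounds$i_start) /
    (hand_bounds$i_end - hand_bounds$i_start)
  tibble::tibble(
    head_rom_deg = rom,
    head_final_yaw_deg = final_yaw,
    head_n_acc_peaks_total = n_before + n_after,
    head_n_acc_peaks_before_pvp = n_before,
    head_n_acc_peaks_after_pvp = n_after,
    head_pvp_relative_position = min(1, max(0, rel))
  )
}

#' Fraction of trials with an early peak velocity, per condition
#'
#' For each condition, the fraction of trials whose head peak-velocity
#' position falls within the first third of the hand movement, and the same
#' fraction for the hand itself. An early head peak relative to the hand is
#' the signature of anticipatory head orienting toward the target.
#'
#' @param features Tibble with columns `condition`,
#'   `head_pvp_relative_position` and `pvp_relative_position` (one row per
#'   trial).
#' @return Tibble with columns `condition`, `n`, `head_early_fraction`,
#'   `hand_early_fraction`.
#' @export
early_heading_fraction <- function(features) {
  if (nrow(features) == 0) stop("early_heading_fraction: empty input")
  features |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      head_early_fraction = mean(.data$head_pvp_relative_position <= 1 / 3),
      hand_early_fraction = mean(.data$pvp_relative_position <= 1 / 3),
      .groups = "drop"
    )
}
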