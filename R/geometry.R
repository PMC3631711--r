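# Task geometry: azimuths in the horizontal plane, pointing errors with the
# protractor sign convention (negative = left of target), and the
# conflicting-avatar rendering transform.

#' Azimuth of a horizontal offset, degrees
#'
#' `atan2(x, y)` in degrees under the package frame (x right, y forward):
#' 0 is straight ahead, positive to the right.
#'
#' @param dx,dy Offsets to the right and forward, metres.
#' @return Azimuth in degrees in (-180, 180].
#' @export
azimuth_deg <- function(dx, dy) atan2(dx, dy) * 180 / pi

#' Wrap an angle to (-180, 180] degrees
#' @param a Angle(s) in degrees.
#' @return Wrapped angle(s).
#' @export
wrap_deg <- function(a) {
  w <- (a + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

#' Pointed azimuth of a trial endpoint
#'
#' Azimuth of the (filtered) hand position at the movement offset relative
#' to the start marker, projected on the horizontal plane — the in-silico
#' equivalent of reading the table protractor centred on the start marker.
#'
#' @param p_end 3-vector (or n x 3 matrix) hand position at movement offset,
#'   metres.
#' @param start_marker 3-vector marker position, metres.
#' @param min_radius_m Minimum horizontal endpoint distance for a stable
#'   angle (default 0.05 m; a trial-level numerical guard, distinct from
#'   the cohort-level short-trajectory exclusion).
#' @return Pointed azimuth in degrees, positive right.
#' @export
pointed_azimuth <- function(p_end, start_marker, min_radius_m = 0.05) {
  p_end <- as.numeric(p_end)
  dx <- p_end[1] - start_marker[1]
  dy <- p_end[2] - start_marker[2]
  r <- sqrt(dx^2 + dy^2)
  if (r < min_radius_m) {
    stop(sprintf(
      "pointed_azimuth: endpoint %.3f m from marker; angle unstable below %.3f m",
      r, min_radius_m))
  }
  azimuth_deg(dx, dy)
}

#' Signed and absolute pointing error
#'
#' Signed error is pointed azimuth minus target azimuth: negative when the
#' subject pointed to the left of the target, positive to the right.
#'
#' @param pointed_azimuth_deg Pointed direction, degrees.
#' @param target_azimuth_deg Target direction, degrees.
#' @return One-row tibble with `pointed_azimuth_deg`, `signed_error_deg`,
#'   `abs_error_deg`.
#' @export
pointing_errors <- function(pointed_azimuth_deg, target_azimuth_deg) {
  stopifnot(is.finite(pointed_azimuth_deg), is.finite(target_azimuth_deg))
  signed <- pointed_azimuth_deg - target_azimuth_deg
  tibble::tibble(
    pointed_azimuth_deg = pointed_azimuth_deg,
    signed_error_deg = signed,
    abs_error_deg = abs(signed)
  )
}

#' Rendered azimuth of the auditory hand avatar
#'
#' The avatar is rendered at the hand's actual azimuth plus a constant
#' azimuthal shift: 0 in the veridical condition (C), -18.5 degrees (to the
#' left) in the conflicting condition (D).
#'
#' @param hand_pos 3-vector hand position, metres.
#' @param start_marker 3-vector marker position, metres.
#' @param shift_deg Azimuthal shift in degrees (negative = left).
#' @return Rendered azimuth in degrees.
#' @export
avatar_render_azimuth <- function(hand_pos, start_marker, shift_deg) {
  hand_pos <- as.numeric(hand_pos)
  dx <- hand_pos[1] - start_marker[1]
  dy <- hand_pos[2] - start_marker[2]
  if (sqrt(dx^2 + dy^2) < 0.01) {
    stop("avatar_render_azimuth: hand within 1 cm of marker, azimuth degenerate")
  }
  wrap_deg(azimuth_deg(dx, dy) + shift_deg)
}

#' World azimuth expressed relative to the head
#'
#' Bookkeeping for head-centred stimulus directions: world azimuth minus
#' head yaw, wrapped to (-180, 180].
#'
#' @param world_azimuth_deg World-frame azimuth, degrees.
#' @param head_yaw_deg Head yaw, degrees.
#' @return Head-relative azimuth in (-180, 180].
#' @export
head_relative_azimuth <- function(world_azimuth_deg, head_yaw_deg) {
  stopifnot(all(is.finite(world_azimuth_deg)), all(is.finite(head_yaw_deg)))
  wrap_deg(world_azimuth_deg - head_yaw_deg)
}
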