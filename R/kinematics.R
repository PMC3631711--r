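# Hand-trajectory kinematics: Gaussian low-pass filtering, tangential
# velocity/acceleration/jerk norms, two-stage movement segmentation
# (horizontal displacement threshold, then 3%-of-peak velocity threshold),
# and scalar per-movement features including acceleration-peak counts.

#' Gaussian low-pass filter with a -3 dB cutoff frequency
#'
#' Zero-phase Gaussian smoothing of each column of a position series. The
#' kernel scale is fixed by requiring the filter's gain to be -3 dB
#' (1/sqrt(2)) at the cutoff: with Gaussian transfer
#' H(f) = exp(-(2 pi f sigma)^2 / 2), this gives
#' sigma = sqrt(ln 2) / (2 pi fc) seconds. The kernel is truncated at
#' +/- 4 sigma, renormalised to unit sum (so DC gain is exactly 1), and the
#' series is reflection-padded at both ends.
#'
#' @param x Numeric vector or matrix (samples in rows).
#' @param fs Sampling rate, Hz.
#' @param fc Cutoff frequency, Hz (default 5).
#' @return Filtered vector/matrix of the same shape.
#' @export
gaussian_lowpass <- function(x, fs, fc = 5) {
  if (fs <= 2 * fc) stop("gaussian_lowpass: need fs > 2*fc")
  sigma <- sqrt(log(2)) / (2 * pi * fc) * fs      # in samples
  half <- max(1L, ceiling(4 * sigma))
  kern <- exp(-((-half:half)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  n <- nrow(xm)
  if (n < 2 * half + 1) {
    stop(sprintf(
      "gaussian_lowpass: series of %d samples shorter than kernel; need >= %d",
      n, 2 * half + 1))
  }
  pad_top <- xm[(half + 1):2, , drop = FALSE]
  pad_bot <- xm[(n - 1):(n - half), , drop = FALSE]
  xp <- rbind(pad_top, xm, pad_bot)
  out <- apply(xp, 2, function(col)
    stats::filter(col, kern, method = "convolution", sides = 2))
  out <- out[(half + 1):(half + n), , drop = FALSE]
  if (vec) as.numeric(out) else out
}

central_diff <- function(x, fs) {
  # per-column central differences, one-sided at the edges
  xm <- as.matrix(x)
  n <- nrow(xm)
  d <- matrix(0, n, ncol(xm))
  d[2:(n - 1), ] <- (xm[3:n, , drop = FALSE] - xm[1:(n - 2), , drop = FALSE]) *
    fs / 2
  d[1, ] <- (xm[2, ] - xm[1, ]) * fs
  d[n, ] <- (xm[n, ] - xm[n - 1, ]) * fs
  d
}

#' Tangential velocity, acceleration and jerk norms
#'
#' Differentiates a (filtered) 3D position series by successive central
#' differences and returns the Euclidean norms v3D, a3D, j3D of the
#' velocity, acceleration and jerk vectors.
#'
#' @param p_filt n x 3 matrix of filtered positions, metres.
#' @param fs Sampling rate, Hz.
#' @return An object of class `kinematic_series` with fields `p_filt`,
#'   `v3D`, `a3D`, `j3D` (all length n) and `fs`.
#' @export
compute_norms <- function(p_filt, fs) {
  p_filt <- as.matrix(p_filt)
  if (nrow(p_filt) < 7) stop("compute_norms: need at least 7 samples")
  v <- central_diff(p_filt, fs)
  a <- central_diff(v, fs)
  j <- central_diff(a, fs)
  structure(
    list(p_filt = p_filt,
         v3D = sqrt(rowSums(v^2)),
         a3D = sqrt(rowSums(a^2)),
         j3D = sqrt(rowSums(j^2)),
         fs = fs),
    class = "kinematic_series"
  )
}

#' Filter a trajectory and compute kinematic norms
#'
#' Convenience composition of [gaussian_lowpass()] and [compute_norms()].
#'
#' @param series A [trajectory_series()].
#' @param fc Filter cutoff, Hz.
#' @return A `kinematic_series`.
#' @export
kinematics <- function(series, fc = 5) {
  stopifnot(inherits(series, "trajectory_series"))
  compute_norms(gaussian_lowpass(series$p, series$fs, fc), series$fs)
}

#' Primary movement segmentation by horizontal displacement
#'
#' Locates the outward pointing gesture by thresholding the horizontal
#' (x, y) distance from the start marker and discards the return to the
#' marker: the candidate window runs from the series start to the sample of
#' maximum horizontal distance within the first suprathreshold excursion.
#' The window deliberately keeps the pre-onset samples so that the velocity
#' threshold stage can find the true onset inside it.
#'
#' @param series A [trajectory_series()] of the hand.
#' @param start_marker 3-vector marker position, metres.
#' @param threshold_m Horizontal displacement threshold, metres
#'   (default 0.02).
#' @return List with integer indices `i_lo`, `i_hi` (1-based, inclusive)
#'   and `i_cross`, the first suprathreshold sample.
#' @export
primary_segment <- function(series, start_marker, threshold_m = 0.02) {
  stopifnot(inherits(series, "trajectory_series"))
  dx <- series$p[, 1] - start_marker[1]
  dy <- series$p[, 2] - start_marker[2]
  d <- sqrt(dx^2 + dy^2)
  above <- which(d > threshold_m)
  if (length(above) == 0) {
    stop("primary_segment: no movement (hand never left the start marker ",
         "neighbourhood)")
  }
  i_cross <- above[1]
  # end of the first suprathreshold excursion (series end if no return)
  below_after <- which(d[i_cross:length(d)] <= threshold_m)
  i_excursion_end <- if (length(below_after) == 0) length(d) else
    i_cross + below_after[1] - 2L
  i_hi <- i_cross - 1L + which.max(d[i_cross:i_excursion_end])
  list(i_lo = 1L, i_hi = as.integer(i_hi), i_cross = as.integer(i_cross))
}

#' Movement bounds by relative velocity threshold
#'
#' Finds the peak-velocity point (PVP) inside the candidate window, then
#' walks outward from it: onset is the last sample at or before the PVP
#' where v3D drops to at most `threshold_fraction` of the peak, offset the
#' first such sample at or after the PVP. Walking outward from the PVP
#' (rather than inward from the edges) keeps small velocity bumps outside
#' the movement from capturing the bounds. If the velocity never falls below
#' the threshold before a window edge, the edge is used and flagged.
#'
#' @param kin A `kinematic_series` from [compute_norms()].
#' @param window List with `i_lo`, `i_hi` from [primary_segment()] (defaults
#'   to the full series).
#' @param threshold_fraction Velocity threshold as a fraction of peak
#'   velocity (default 0.03, i.e. 3%).
#' @return An object of class `movement_bounds`: `i_start`, `i_end`,
#'   `i_pvp`, `v_peak`, `threshold_fraction`, `clipped_start`,
#'   `clipped_end`.
#' @export
detect_bounds <- function(kin, window = NULL, threshold_fraction = 0.03) {
  stopifnot(inherits(kin, "kinematic_series"))
  n <- length(kin$v3D)
  if (is.null(window)) window <- list(i_lo = 1L, i_hi = n)
  i_lo <- max(1L, as.integer(window$i_lo))
  i_hi <- min(n, as.integer(window$i_hi))
  if (i_hi < i_lo) stop("detect_bounds: empty window")
  v <- kin$v3D
  i_pvp <- i_lo - 1L + which.max(v[i_lo:i_hi])
  v_peak <- v[i_pvp]
  if (v_peak <= 0) stop("detect_bounds: no movement (zero peak velocity)")
  thr <- threshold_fraction * v_peak
  below_before <- which(v[i_lo:i_pvp] <= thr)
  clipped_start <- length(below_before) == 0
  i_start <- if (clipped_start) i_lo else i_lo - 1L + max(below_before)
  below_after <- which(v[i_pvp:i_hi] <= thr)
  clipped_end <- length(below_after) == 0
  i_end <- if (clipped_end) i_hi else i_pvp - 1L + min(below_after)
  structure(
    list(i_start = as.integer(i_start), i_end = as.integer(i_end),
         i_pvp = as.integer(i_pvp), v_peak = v_peak,
         threshold_fraction = threshold_fraction,
         clipped_start = clipped_start, clipped_end = clipped_end),
    class = "movement_bounds"
  )
}

#' Local maxima with a relative prominence floor
#'
#' Strict local maxima of a series; plateaus are represented by their first
#' sample; samples at the window edges are never peaks. A peak is kept when
#' its topographic prominence is at least `prominence_fraction` times the
#' maximum of the series, which suppresses numerical ripple.
#'
#' @param x Numeric vector (e.g. a3D within movement bounds).
#' @param prominence_fraction Relative prominence floor (default 0.05).
#' @return Integer vector of peak indices into `x`.
#' @export
find_peaks <- function(x, prominence_fraction = 0.05) {
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  cand <- integer(0)
  if (k >= 3) {
    for (j in 2:(k - 1)) {
      if (r$values[j] > r$values[j - 1] && r$values[j] > r$values[j + 1]) {
        cand <- c(cand, starts[j])
      }
    }
  }
  if (length(cand) == 0) return(integer(0))
  floor_prom <- prominence_fraction * max(x)
  keep <- logical(length(cand))
  for (ci in seq_along(cand)) {
    i <- cand[ci]; v <- x[i]
    # min on each side until a strictly higher value (or the edge)
    left_min <- v
    for (l in seq(i - 1L, 1L)) {
      if (x[l] > v) break
      if (x[l] < left_min) left_min <- x[l]
    }
    right_min <- v
    for (rgt in seq(i + 1L, n)) {
      if (x[rgt] > v) break
      if (x[rgt] < right_min) right_min <- x[rgt]
    }
    prom <- v - max(left_min, right_min)
    keep[ci] <- prom >= floor_prom
  }
  cand[keep]
}

#' Scalar features of one hand movement
#'
#' Duration, peak and average tangential velocity, path length, counts of
#' acceleration peaks before/after the peak-velocity point (a peak exactly
#' at the PVP counts as "after"), and the relative position of the PVP
#' within the movement.
#'
#' @param kin A `kinematic_series`.
#' @param bounds A `movement_bounds` from [detect_bounds()].
#' @param prominence_fraction Relative prominence floor for acceleration
#'   peaks (default 0.05).
#' @return A one-row [tibble::tibble()] with columns `duration_s`,
#'   `v_peak`, `v_mean`, `path_length_m`, `n_acc_peaks_total`,
#'   `n_acc_peaks_before_pvp`, `n_acc_peaks_after_pvp`,
#'   `pvp_relative_position`.
#' @export
hand_features <- function(kin, bounds, prominence_fraction = 0.05) {
  stopifnot(inherits(kin, "kinematic_series"),
            inherits(bounds, "movement_bounds"))
  i0 <- bounds$i_start; i1 <- bounds$i_end
  seg <- i0:i1
  dur <- (i1 - i0) / kin$fs
  dp <- diff(kin$p_filt[seg, , drop = FALSE])
  path_len <- sum(sqrt(rowSums(dp^2)))
  pk <- find_peaks(kin$a3D[seg], prominence_fraction) + i0 - 1L
  n_before <- sum(pk < bounds$i_pvp)
  n_after <- sum(pk >= bounds$i_pvp)
  tibble::tibble(
    duration_s = dur,
    v_peak = bounds$v_peak,
    v_mean = mean(kin$v3D[seg]),
    path_length_m = path_len,
    n_acc_peaks_total = n_before + n_after,
    n_acc_peaks_before_pvp = n_before,
    n_acc_peaks_after_pvp = n_after,
    pvp_relative_position = (bounds$i_pvp - i0) / (i1 - i0)
  )
}
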