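#' Uniformly sampled scalar series
#'
#' Light container for a motion-capture or force-plate channel: the sampled
#' values, the sampling rate and a quantity label (`"angle-deg"` or
#' `"grf-N"`).
#'
#' @param values Numeric vector of samples.
#' @param rate Sampling frequency, Hz.
#' @param quantity Label for the physical quantity.
#' @return An object of class `sampled_series`.
#' @export
sampled_series <- function(values, rate, quantity = c("angle-deg", "grf-N",
                                                      "omega-rad_s")) {
  quantity <- match.arg(quantity)
  stopifnot(is.numeric(values), length(rate) == 1, is.finite(rate), rate > 0)
  structure(list(values = as.numeric(values), rate = rate,
                 quantity = quantity),
            class = "sampled_series")
}

#' @export
print.sampled_series <- function(x, ...) {
  cat(sprintf("sampled_series: %d samples of %s at %g Hz (%.3f s)\n",
              length(x$values), x$quantity, x$rate,
              length(x$values) / x$rate))
  invisible(x)
}

#' Zero-phase (dual-pass) Butterworth low-pass filter
#'
#' Designs a digital Butterworth low-pass filter of the given order
#' (via `signal::butter`) and applies it forward and then backward, so the
#' net response has zero phase lag and the squared single-pass magnitude.
#' Edge transients are suppressed by odd-reflection padding at both ends
#' before filtering (the padding is removed afterwards), so the output
#' length equals the input length. Defaults follow standard motion-capture
#' practice for 150 Hz kinematics: 2nd order, 10 Hz cut-off.
#'
#' @param series A [sampled_series].
#' @param cutoff Cut-off frequency, Hz; must be below the Nyquist rate.
#' @param order Filter order for each pass.
#' @return A filtered [sampled_series] of the same length and rate.
#' @export
lowpass_filter <- function(series, cutoff = 10, order = 2) {
  stopifnot(inherits(series, "sampled_series"))
  if (cutoff >= series$rate / 2) {
    stop("cutoff must be below the Nyquist frequency ", series$rate / 2,
         " Hz", call. = FALSE)
  }
  n <- length(series$values)
  bt <- signal::butter(order, cutoff / (series$rate / 2), type = "low")
  pad <- 9 * (max(length(bt$b), length(bt$a)) - 1)
  if (n <= pad) {
    stop("series too short for stable dual-pass filtering (need > ",
         pad, " samples)", call. = FALSE)
  }
  x <- series$values
  # odd reflection about the end points kills the start-up transient
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(head_pad, x, tail_pad)
  yp <- iir_pass(bt$b, bt$a, xp)
  yp <- rev(iir_pass(bt$b, bt$a, rev(yp)))
  out <- series
  out$values <- yp[(pad + 1):(pad + n)]
  out
}

# One causal IIR pass started in steady state at the first sample (so a
# constant series passes through exactly): FIR part by convolution with
# constant history, AR part by recursion initialized at the same level.
iir_pass <- function(b, a, x) {
  m <- length(a) - 1
  v <- stats::filter(c(rep(x[1], m), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[-seq_len(m)]
  y <- stats::filter(v, -a[-1], method = "recursive",
                     init = rep(x[1], m))
  as.numeric(y)
}

#' Angular-velocity series by finite differences
#'
#' Differentiates a (filtered) angle series: second-order central
#' differences in the interior, first-order one-sided differences at the
#' ends. Angle input in degrees is converted so the result is in rad/s.
#'
#' @param angle A [sampled_series] with `quantity = "angle-deg"`.
#' @return A [sampled_series] of angular velocity, rad/s, same length.
#' @export
angular_velocity_series <- function(angle) {
  stopifnot(inherits(angle, "sampled_series"),
            angle$quantity == "angle-deg")
  x <- deg2rad(angle$values)
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to differentiate", call. = FALSE)
  dt <- 1 / angle$rate
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  sampled_series(v, angle$rate, "omega-rad_s")
}

#' Angular velocity at an angle crossing, from sampled data
#'
#' Locates the single upward crossing of the target angle in the sampled
#' angle trace and linearly interpolates the angular-velocity trace at the
#' crossing. At 150 Hz the platform moves well under a degree per sample
#' near the readout, so linear interpolation is ample.
#'
#' @param angle A [sampled_series] of platform angle, degrees.
#' @param omega A [sampled_series] of angular velocity, rad/s, same
#'   sampling grid.
#' @param target_deg Crossing angle, degrees (default 70, the largest angle
#'   before mat contact).
#' @return Interpolated angular velocity at the crossing, rad/s.
#' @export
speed_at_angle_empirical <- function(angle, omega, target_deg = 70) {
  stopifnot(inherits(angle, "sampled_series"),
            inherits(omega, "sampled_series"),
            length(angle$values) == length(omega$values))
  x <- angle$values
  up <- which(x[-length(x)] < target_deg & x[-1] >= target_deg)
  if (length(up) == 0) {
    stop("malformed trial: angle never crosses ", target_deg,
         " deg from below", call. = FALSE)
  }
  if (length(up) > 1) {
    stop("malformed trial: angle crosses ", target_deg,
         " deg more than once", call. = FALSE)
  }
  i <- up
  if (x[i + 1] == x[i]) return(omega$values[i])
  frac <- (target_deg - x[i]) / (x[i + 1] - x[i])
  (1 - frac) * omega$values[i] + frac * omega$values[i + 1]
}

#' First sample where the ground reaction force exceeds a threshold
#'
#' Initial impact with the landing surface is taken as the first sample
#' where the vertical ground reaction force is strictly greater than the
#' threshold (default 10 N).
#'
#' @param grf A [sampled_series] of vertical GRF, N.
#' @param threshold Force threshold, N, `> 0`.
#' @return The 1-based sample index, or `NA_integer_` if the threshold is
#'   never exceeded.
#' @export
detect_impact <- function(grf, threshold = 10) {
  stopifnot(inherits(grf, "sampled_series"), threshold > 0)
  i <- which(grf$values > threshold)
  if (length(i) == 0) NA_integer_ else i[1]
}

#' Perturbation-onset sample from the angle trace
#'
#' Release is detected kinematically as the first sample where the platform
#' angle exceeds the initial angle (taken as the first sample) by a small
#' margin, 0.5 degrees by default.
#'
#' @param angle A [sampled_series] of platform angle, degrees.
#' @param margin_deg Detection margin above the initial angle, degrees.
#' @return The 1-based sample index, or `NA_integer_`.
#' @export
detect_release <- function(angle, margin_deg = 0.5) {
  stopifnot(inherits(angle, "sampled_series"))
  i <- which(angle$values > angle$values[1] + margin_deg)
  if (length(i) == 0) NA_integer_ else i[1]
}

#' Extract the fitting observables from raw trial series
#'
#' The standard pipeline: low-pass filter the angle trace (dual-pass
#' Butterworth, default 10 Hz / 2nd order), differentiate to angular
#' velocity, interpolate the velocity at the target crossing, and detect
#' release and (if a GRF trace is supplied) impact.
#'
#' @param angle A [sampled_series] of platform angle, degrees.
#' @param grf Optional [sampled_series] of vertical GRF, N.
#' @param target_deg Readout angle, degrees.
#' @param cutoff,order Filter settings, see [lowpass_filter()].
#' @return List with `omega_at_70` (rad/s), `release_index`,
#'   `impact_index` (`NA` if no GRF or never exceeded).
#' @export
process_trial_series <- function(angle, grf = NULL, target_deg = 70,
                                 cutoff = 10, order = 2) {
  filt <- lowpass_filter(angle, cutoff = cutoff, order = order)
  omega <- angular_velocity_series(filt)
  list(
    omega_at_70 = speed_at_angle_empirical(filt, omega, target_deg),
    release_index = detect_release(filt),
    impact_index = if (is.null(grf)) NA_integer_ else detect_impact(grf)
  )
}

#' Read and write time-series CSV files
#'
#' Schema: column `time_s` plus `angle_deg` and/or `grf_N`. The sampling
#' rate is inferred from the time column (and checked for uniformity on
#' read).
#'
#' @param path CSV path.
#' @return `read_trial_series`: named list of [sampled_series] (elements
#'   `angle`, `grf` as present). `write_trial_series` returns `path`
#'   invisibly.
#' @param angle,grf [sampled_series] channels to write (either may be
#'   `NULL`, not both).
#' @export
read_trial_series <- function(path) {
  d <- utils::read.csv(path)
  stopifnot("time_s" %in% names(d))
  dt <- diff(d$time_s)
  if (any(abs(dt - dt[1]) > 1e-8)) {
    stop("time_s is not uniformly sampled in ", path, call. = FALSE)
  }
  rate <- 1 / dt[1]
  out <- list()
  if ("angle_deg" %in% names(d)) {
    out$angle <- sampled_series(d$angle_deg, rate, "angle-deg")
  }
  if ("grf_N" %in% names(d)) {
    out$grf <- sampled_series(d$grf_N, rate, "grf-N")
  }
  if (length(out) == 0) stop("no angle_deg or grf_N column in ", path)
  out
}

#' @rdname read_trial_series
#' @export
write_trial_series <- function(path, angle = NULL, grf = NULL) {
  stopifnot(!is.null(angle) || !is.null(grf))
  ref <- if (!is.null(angle)) angle else grf
  d <- data.frame(time_s = (seq_along(ref$values) - 1) / ref$rate)
  if (!is.null(angle)) d$angle_deg <- angle$values
  if (!is.null(grf)) d$grf_N <- grf$values
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
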