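#' Simulate a released fall of the platform
#'
#' Integrates the equation of motion numerically from release at rest at the
#' initial lean angle, using an adaptive solver (deSolve's `lsodar`) with
#' solver-level root finding so that each angle landmark is located by
#' root-finding on `theta(t) - theta_landmark`, not by nearest-sample lookup.
#' Landmarks default to the 70-degree model-readout angle, the 85-degree mat
#' contact and 90 degrees (horizontal, shock absorbers); integration stops at
#' the largest landmark. The 85-degree mat contact is annotated only -- the
#' rigid-body model is not altered there, it simply stops being a description
#' of the physical system past mat contact.
#'
#' If the angular acceleration at release is non-positive (counterweight
#' torque at least the gravity torque) the configuration is "balanced": the
#' platform does not fall, and a trajectory with the single release state and
#' no crossings is returned with `balanced = TRUE`.
#'
#' @param params A [fall_params] object.
#' @param theta0_deg Initial lean angle from vertical, degrees, in (0, 90)
#'   and below every landmark.
#' @param landmarks_deg Named numeric vector of landmark angles, degrees.
#' @param dt_out Spacing of the reported state grid, s (events are located
#'   independently of this grid).
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param t_max Hard cap on integration time, s.
#' @return An object of class `fall_trajectory`: list with `states` (data
#'   frame `t`, `theta`, `theta_dot`, `theta_ddot`; angles in radians),
#'   `events` (data frame `name`, `angle_deg`, `t`, `theta_dot`, including
#'   the release), `params`, `theta0` (radians) and `balanced`.
#' @examples
#' p <- fall_params(L = 1.21, m1 = 90)
#' tr <- simulate_fall(p, theta0_deg = 65)
#' tr$events
#' @export
simulate_fall <- function(params, theta0_deg,
                          landmarks_deg = c(readout_70deg = 70,
                                            mat_contact_85deg = 85,
                                            horizontal_90deg = 90),
                          dt_out = 1 / 150,
                          rtol = 1e-10, atol = 1e-12, t_max = 60) {
  validate_fall_params(params)
  stopifnot(length(theta0_deg) == 1, is.finite(theta0_deg))
  if (theta0_deg <= 0 || theta0_deg >= min(90, landmarks_deg)) {
    stop("theta0_deg must lie in (0, 90) and below every landmark",
         call. = FALSE)
  }
  theta0 <- deg2rad(theta0_deg)
  landmarks <- sort(deg2rad(landmarks_deg))

  release <- data.frame(name = "release", angle_deg = theta0_deg,
                        t = 0, theta_dot = 0, stringsAsFactors = FALSE)

  if (angular_acceleration(params, theta0) <= 0) {
    traj <- list(
      states = data.frame(t = 0, theta = theta0, theta_dot = 0,
                          theta_ddot = angular_acceleration(params, theta0)),
      events = release[0, ], params = params, theta0 = theta0,
      balanced = TRUE)
    return(structure(traj, class = "fall_trajectory"))
  }

  rhs <- function(t, y, parms) {
    list(c(y[2], angular_acceleration(parms, y[1])))
  }

  states <- data.frame(t = 0, theta = theta0, theta_dot = 0,
                       theta_ddot = angular_acceleration(params, theta0))
  ev <- list()
  y <- c(theta = theta0, theta_dot = 0)
  t_now <- 0
  for (i in seq_along(landmarks)) {
    target <- landmarks[[i]]
    times <- seq(t_now, t_max, by = dt_out)
    if (length(times) < 2) times <- c(t_now, t_max)
    root <- function(t, y, parms) y[1] - target
    out <- deSolve::lsodar(y = y, times = times, func = rhs, parms = params,
                           rootfunc = root, rtol = rtol, atol = atol)
    last <- nrow(out)
    if (attr(out, "istate")[1] != 3) {
      stop("integration reached t_max = ", t_max,
           " s without crossing the ", signif(rad2deg(target), 4),
           " deg landmark", call. = FALSE)
    }
    seg <- as.data.frame(out)[-1, , drop = FALSE]
    if (nrow(seg) > 0) {
      if (any(diff(c(y[["theta"]], seg$theta)) < 0)) {
        stop("internal consistency failure: theta not monotone increasing ",
             "on the falling branch", call. = FALSE)
      }
      seg$theta_ddot <- angular_acceleration(params, seg$theta)
      names(seg) <- c("t", "theta", "theta_dot", "theta_ddot")
      states <- rbind(states, seg)
    }
    ev[[i]] <- data.frame(name = names(landmarks)[i],
                          angle_deg = rad2deg(target),
                          t = out[last, "time"],
                          theta_dot = out[last, "theta_dot"],
                          stringsAsFactors = FALSE)
    y <- c(theta = unname(target), theta_dot = unname(out[last, "theta_dot"]))
    t_now <- unname(out[last, "time"])
  }
  events <- rbind(release, do.call(rbind, ev))
  rownames(events) <- NULL
  # drop duplicated grid/root times
  states <- states[!duplicated(round(states$t, 12)), ]
  rownames(states) <- NULL
  structure(list(states = states, events = events, params = params,
                 theta0 = theta0, balanced = FALSE),
            class = "fall_trajectory")
}

#' Velocity at a named landmark of a simulated trajectory
#'
#' @param traj A `fall_trajectory` from [simulate_fall()].
#' @param angle_deg Landmark angle in degrees (must be one of the simulated
#'   landmarks).
#' @return Angular velocity at the crossing, rad/s.
#' @export
event_velocity <- function(traj, angle_deg = 70) {
  stopifnot(inherits(traj, "fall_trajectory"))
  if (traj$balanced) {
    stop(structure(class = c("fallfit_unreachable", "error", "condition"),
                   list(message = "balanced configuration: no crossings",
                        call = sys.call(-1))))
  }
  i <- which(abs(traj$events$angle_deg - angle_deg) < 1e-9 &
               traj$events$name != "release")
  if (length(i) != 1) {
    stop("no landmark at ", angle_deg, " deg in this trajectory",
         call. = FALSE)
  }
  traj$events$theta_dot[i]
}

#' @export
print.fall_trajectory <- function(x, ...) {
  cat("Simulated fall trajectory\n")
  cat(sprintf("  release: %.2f deg from vertical%s\n", rad2deg(x$theta0),
              if (x$balanced) "  [BALANCED: platform does not fall]" else ""))
  if (!x$balanced) {
    cat(sprintf("  %d states over %.3f s\n", nrow(x$states),
                max(x$states$t)))
    ev <- x$events[x$events$name != "release", ]
    for (i in seq_len(nrow(ev))) {
      cat(sprintf("  %-18s %5.1f deg at t = %.4f s, theta_dot = %.4f rad/s\n",
                  ev$name[i], ev$angle_deg[i], ev$t[i], ev$theta_dot[i]))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.fall_trajectory <- function(x, ...) {
  data.frame(t = x$states$t,
             theta_deg = rad2deg(x$states$theta),
             theta_dot = x$states$theta_dot,
             theta_ddot = x$states$theta_ddot)
}

#' Sample a simulated trajectory as a uniform angle series
#'
#' Resamples the integrator output onto a uniform grid at the given rate,
#' emulating a motion-capture channel over the fall (release to the stop
#' landmark). Interpolation is piecewise cubic Hermite using the angle and
#' angular velocity the integrator reports at every node, so resampling
#' error is O(dt^4) and negligible against measurement noise.
#'
#' @param traj A `fall_trajectory` from [simulate_fall()].
#' @param rate Sampling rate, Hz.
#' @return A [sampled_series] of platform angle in degrees.
#' @export
sample_trajectory <- function(traj, rate = 150) {
  stopifnot(inherits(traj, "fall_trajectory"))
  if (traj$balanced) stop("balanced trajectory has no fall to sample",
                          call. = FALSE)
  t_end <- max(traj$states$t)
  tq <- seq(0, t_end, by = 1 / rate)
  th <- hermite_interp(traj$states$t, traj$states$theta,
                       traj$states$theta_dot, tq)
  sampled_series(rad2deg(th), rate, "angle-deg")
}

#' Export a trajectory as CSV plus a JSON event block
#'
#' Writes the state grid as CSV (columns `t`, `theta_deg`, `theta_dot`,
#' `theta_ddot`) and, if `events_path` is given, the event table, the
#' parameters and the balanced flag as JSON.
#'
#' @param traj A `fall_trajectory`.
#' @param csv_path Output CSV path.
#' @param events_path Optional output JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_trajectory <- function(traj, csv_path, events_path = NULL) {
  stopifnot(inherits(traj, "fall_trajectory"))
  utils::write.csv(as.data.frame(traj), csv_path, row.names = FALSE)
  if (!is.null(events_path)) {
    jsonlite::write_json(
      list(balanced = traj$balanced,
           theta0_deg = rad2deg(traj$theta0),
           params = unclass(traj$params),
           events = traj$events),
      events_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(csv_path)
}
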