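#' Physical parameters of the counterweighted fall simulator
#'
#' Bundles the constants of the coupled pendulum--counterweight system: the
#' participant and support platform are idealized as an inverted point-mass
#' pendulum of mass `m1` with its center of mass a distance `L` from the axle,
#' coupled through a chain/cable threaded over four fixed pulleys (wrap angle
#' pi each) to a counterweight of mass `m2` hanging from a pulley of radius
#' `r`. Capstan (Euler--Eytelwein) friction at each wrap multiplies cable
#' tension by `exp(mu_F * pi)`.
#'
#' The moment of inertia is taken as `m1 * L^2` (point-mass pendulum); the
#' equation of motion then depends on the masses only through the
#' counterweight ratio `m2 / m1`.
#'
#' @param L Pendulum length / center-of-mass height above the axle, m.
#' @param m1 Pendulum mass (participant plus effective platform mass), kg.
#' @param m2 Counterweight mass, kg. Zero means no counterweight.
#' @param r Counterweight-pulley (outer sprocket) radius, m. The default is
#'   half the 14.76-inch inner sprocket diameter.
#' @param mu_F Capstan drag-friction coefficient per pulley wrap,
#'   dimensionless.
#' @param g Gravitational acceleration, m/s^2.
#'
#' @return An object of class `fall_params`: a named list with the six
#'   constants, validated against their physical ranges.
#' @examples
#' p <- fall_params(L = 1.21, m1 = 90)
#' angular_acceleration(p, pi / 4)
#' @export
fall_params <- function(L, m1, m2 = 0, r = 0.1875, mu_F = 0, g = 9.81) {
  p <- list(L = as.numeric(L), r = as.numeric(r), mu_F = as.numeric(mu_F),
            m1 = as.numeric(m1), m2 = as.numeric(m2), g = as.numeric(g))
  validate_fall_params(p)
  structure(p, class = "fall_params")
}

validate_fall_params <- function(p) {
  stopifnot(
    "L must be a single positive number" =
      length(p$L) == 1 && is.finite(p$L) && p$L > 0,
    "r must be a single nonnegative number" =
      length(p$r) == 1 && is.finite(p$r) && p$r >= 0,
    "mu_F must be a single nonnegative number" =
      length(p$mu_F) == 1 && is.finite(p$mu_F) && p$mu_F >= 0,
    "m1 must be a single positive number" =
      length(p$m1) == 1 && is.finite(p$m1) && p$m1 > 0,
    "m2 must be a single nonnegative number" =
      length(p$m2) == 1 && is.finite(p$m2) && p$m2 >= 0,
    "g must be a single positive number" =
      length(p$g) == 1 && is.finite(p$g) && p$g > 0
  )
  invisible(p)
}

#' @export
print.fall_params <- function(x, ...) {
  cat("Fall simulator parameters\n")
  cat(sprintf("  L    = %.4g m   (pendulum / CoM height)\n", x$L))
  cat(sprintf("  m1   = %.4g kg  (participant + platform)\n", x$m1))
  cat(sprintf("  m2   = %.4g kg  (counterweight; ratio m2/m1 = %.4g)\n",
              x$m2, x$m2 / x$m1))
  cat(sprintf("  r    = %.4g m   (counterweight pulley radius)\n", x$r))
  cat(sprintf("  mu_F = %.4g     (capstan friction per wrap)\n", x$mu_F))
  cat(sprintf("  g    = %.4g m/s^2\n", x$g))
  invisible(x)
}

#' Aggregate capstan friction factor of the four-pulley cascade
#'
#' The cable wraps each of four pulleys through an angle pi; the capstan
#' equation multiplies tension by `exp(mu_F * pi)` per wrap, and the total
#' force at the counterweight pulley sums the four wrapped tensions:
#' `C1 = exp(mu*pi) + exp(2*mu*pi) + exp(3*mu*pi) + exp(4*mu*pi)`.
#'
#' @param mu_F Drag-friction coefficient, dimensionless, `>= 0`.
#' @return The friction factor, `>= 4` (equal to 4 at `mu_F = 0`), strictly
#'   increasing in `mu_F`.
#' @examples
#' capstan_factor(0)     # 4: frictionless cascade
#' capstan_factor(0.18)
#' @export
capstan_factor <- function(mu_F) {
  if (any(!is.finite(mu_F)) || any(mu_F < 0)) {
    stop("mu_F must be finite and >= 0", call. = FALSE)
  }
  exp(mu_F * pi) + exp(2 * mu_F * pi) + exp(3 * mu_F * pi) + exp(4 * mu_F * pi)
}

#' Cable tensions through the pulley cascade
#'
#' Tension in the cable above the counterweight follows from the
#' counterweight's vertical dynamics (it rises four times faster than the
#' attachment point at the sprocket moves): `F = 4 m2 r theta_ddot + m2 g`.
#' Each successive pulley wrap multiplies the tension by `exp(mu_F * pi)`,
#' and the total force at the counterweight pulley is the sum of the four
#' wrapped tensions.
#'
#' @param params A [fall_params] object.
#' @param theta_ddot Angular acceleration of the pendulum, rad/s^2.
#' @return A list of class `tension_set` with elements `F` (above the
#'   counterweight), `Ff` (length-4 vector after wraps 1..4) and `F_P`
#'   (their sum, the force at the counterweight pulley), all in newtons.
#' @export
cable_tensions <- function(params, theta_ddot) {
  validate_fall_params(params)
  stopifnot(length(theta_ddot) == 1, is.finite(theta_ddot))
  F <- 4 * params$m2 * params$r * theta_ddot + params$m2 * params$g
  Ff <- F * exp((1:4) * params$mu_F * pi)
  structure(list(F = F, Ff = Ff, F_P = sum(Ff)), class = "tension_set")
}

#' Angular acceleration of the released platform
#'
#' Moment balance about the axle, with the counterweight force expressed
#' through the capstan cascade and the inertia taken as `m1 * L^2`, gives
#'
#'   theta_ddot = (g L sin(theta) - C1 r g rho) / (L^2 + 4 C1 r^2 rho)
#'
#' where `rho = m2 / m1` is the counterweight ratio and `C1` the aggregate
#' capstan factor ([capstan_factor]). With no counterweight this reduces to
#' the characteristic inverted-pendulum equation `g sin(theta) / L`. The
#' result can be negative or zero when the counterweight torque dominates
#' (a "balanced" configuration that does not fall).
#'
#' @param params A [fall_params] object.
#' @param theta Pendulum angle from vertical, radians (vectorized).
#' @return Angular acceleration, rad/s^2.
#' @export
angular_acceleration <- function(params, theta) {
  validate_fall_params(params)
  rho <- params$m2 / params$m1
  C1 <- capstan_factor(params$mu_F)
  (params$g * params$L * sin(theta) - C1 * params$r * params$g * rho) /
    (params$L^2 + 4 * C1 * params$r^2 * rho)
}

#' Closed-form angular speed of the fall (energy balance)
#'
#' Because the equation of motion has angle-independent coefficients apart
#' from the gravity torque, it admits a first integral: multiplying the
#' angular acceleration by `theta_dot` and integrating from release at rest,
#'
#'   (1/2) (L^2 + 4 C1 r^2 rho) theta_dot^2 =
#'       g L (cos(theta0) - cos(theta)) - C1 r g rho (theta - theta0).
#'
#' With `m2 = 0` this is the familiar `theta_dot = sqrt((2 g / L)
#' (cos(theta0) - cos(theta)))`. Used both as the fast forward model for
#' fitting and as the independent oracle for the numerical integrator.
#'
#' @param params A [fall_params] object.
#' @param theta0 Release angle from vertical, radians (release at rest).
#' @param theta Angle at which the speed is evaluated, radians,
#'   `>= theta0` (vectorized).
#' @return Angular speed `theta_dot >= 0`, rad/s.
#'   If the counterweight stops the fall before `theta` (negative radicand)
#'   an error of class `fallfit_unreachable` is signalled.
#' @examples
#' p <- fall_params(L = 1.21, m1 = 90)
#' closed_form_speed(p, 65 * pi / 180, 70 * pi / 180)
#' @export
closed_form_speed <- function(params, theta0, theta) {
  validate_fall_params(params)
  if (any(theta < theta0)) stop("theta must be >= theta0", call. = FALSE)
  rad2 <- speed_squared(params, theta0, theta)
  if (any(rad2 < 0)) {
    stop(structure(class = c("fallfit_unreachable", "error", "condition"),
                   list(message = paste0(
                     "fall does not reach theta = ",
                     paste(signif(theta[rad2 < 0] * 180 / pi, 4),
                           collapse = ", "),
                     " deg: counterweight stops the fall first"),
                     call = sys.call(-1))))
  }
  sqrt(rad2)
}

# theta_dot^2 from the energy balance; negative when theta is unreachable.
# Vectorized over L, rho, theta0, theta (recycled) for the fitting path.
readout_speed_sq <- function(L, rho, mu_F, r, g, theta0, theta) {
  C1 <- capstan_factor(mu_F)
  den <- L^2 + 4 * C1 * r^2 * rho
  2 * (g * L * (cos(theta0) - cos(theta)) -
         C1 * r * g * rho * (theta - theta0)) / den
}

speed_squared <- function(params, theta0, theta) {
  readout_speed_sq(params$L, params$m2 / params$m1, params$mu_F,
                   params$r, params$g, theta0, theta)
}

#' Counterweight balance threshold
#'
#' The released platform fails to fall when the counterweight torque at the
#' release angle is at least the gravity torque:
#' `g L sin(theta0) <= C1 r g (m2 / m1)`. `balance_counterweight` returns
#' the counterweight mass at which equality holds; `is_balanced` tests the
#' inequality for given parameters.
#'
#' @param params A [fall_params] object (for `balance_counterweight`, its
#'   `m2` is ignored).
#' @param theta0 Release angle from vertical, radians.
#' @return `balance_counterweight`: the threshold mass `m2`, kg.
#'   `is_balanced`: logical.
#' @export
balance_counterweight <- function(params, theta0) {
  validate_fall_params(params)
  C1 <- capstan_factor(params$mu_F)
  if (params$r == 0) return(Inf)
  params$m1 * params$L * sin(theta0) / (C1 * params$r)
}

#' @rdname balance_counterweight
#' @export
is_balanced <- function(params, theta0) {
  validate_fall_params(params)
  C1 <- capstan_factor(params$mu_F)
  params$g * params$L * sin(theta0) <=
    C1 * params$r * params$g * (params$m2 / params$m1)
}

#' Read and write model parameters as flat JSON or YAML
#'
#' Serializes a [fall_params] object to a flat mapping with SI units
#' (keys `L`, `r`, `mu_F`, `m1`, `m2`, `g`); format chosen by file
#' extension (`.json`, `.yml`/`.yaml`).
#'
#' @param params A [fall_params] object.
#' @param path File path ending in `.json`, `.yml` or `.yaml`.
#' @return `write_fall_params` returns `path` invisibly;
#'   `read_fall_params` returns a validated [fall_params] object.
#' @export
write_fall_params <- function(params, path) {
  validate_fall_params(params)
  x <- unclass(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    stop("unrecognized extension for params file: ", path, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_fall_params
#' @export
read_fall_params <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop("unrecognized extension for params file: ", path, call. = FALSE)
  }
  fall_params(L = x$L, m1 = x$m1, m2 = x$m2, r = x$r, mu_F = x$mu_F, g = x$g)
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi
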