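#' @export
print.fall_fit <- function(x, ...) {
  cat(sprintf("Fall-model fit (experiment %d, %d trials)\n",
              x$experiment, x$n_trials))
  if (x$L_mode == "height") {
    cat(sprintf("  k_hat    = %.4f  (L = k * height)\n", x$k_hat))
  } else {
    cat(sprintf("  L_hat    = %.4f m\n", x$L_hat))
  }
  if (x$experiment == 2) {
    cat(sprintf("  mu_F_hat = %.4f\n", x$mu_F_hat))
  }
  cat(sprintf("  r2       = %.4f  (variance accounted for)\n", x$r2))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.fall_fit <- function(object, ...) {
  if (object$L_mode == "height") {
    c(k = object$k_hat, mu_F = object$mu_F_hat)
  } else {
    c(L = object$L_hat, mu_F = object$mu_F_hat)
  }
}

#' @export
residuals.fall_fit <- function(object, ...) {
  object$measured - object$predicted
}

#' @export
summary.fall_fit <- function(object, ...) {
  res <- residuals(object)
  out <- list(fit = object,
              resid_summary = summary(res),
              resid_sd = stats::sd(res),
              rmse = sqrt(mean(res^2)))
  class(out) <- "summary.fall_fit"
  out
}

#' @export
print.summary.fall_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  RMSE     = %.4f rad/s  (residual sd %.4f)\n",
              x$rmse, x$resid_sd))
  cat("  residuals:\n")
  print(x$resid_summary)
  invisible(x)
}

#' Predict readout velocities from a fitted fall model
#'
#' @param object A `fall_fit`.
#' @param newdata Optional data frame with columns `theta0_deg`, `m2_kg`,
#'   `mass_kg` (and `height_cm` in height mode); defaults to the fitted
#'   trials.
#' @param ... Unused.
#' @return Predicted angular velocity at the readout angle, rad/s, per row
#'   (0 for balanced/unreachable configurations).
#' @export
predict.fall_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predicted)
  s <- object$settings
  if (object$L_mode == "height") {
    predict_trials(newdata, L = NA, mu_F = object$mu_F_hat, r = s$r,
                   g = s$g, platform_mass = s$platform_mass,
                   readout_deg = s$readout_deg,
                   heights_m = newdata$height_cm / 100, k = object$k_hat)
  } else {
    predict_trials(newdata, L = object$L_hat, mu_F = object$mu_F_hat,
                   r = s$r, g = s$g, platform_mass = s$platform_mass,
                   readout_deg = s$readout_deg)
  }
}

#' Simulate replicate measured velocities from a fitted fall model
#'
#' Draws `nsim` replicates of the measured readout-velocity vector as the
#' fitted predictions plus Gaussian noise with the residual standard
#' deviation, the same observation model the synthetic generator uses.
#'
#' @param object A `fall_fit`.
#' @param nsim Number of replicate vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns, one replicate per column.
#' @export
simulate.fall_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sd_hat <- stats::sd(residuals(object))
  n <- length(object$predicted)
  out <- as.data.frame(replicate(
    nsim, object$predicted + stats::rnorm(n, 0, sd_hat), simplify = FALSE),
    col.names = paste0("sim_", seq_len(nsim)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted fall model against its data
#'
#' Measured readout velocities against the design variable (initial lean
#' angle for experiment 1, counterweight load for experiment 2), with the
#' fitted model curve overlaid.
#'
#' @param x A `fall_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fall_fit <- function(x, ...) {
  tr <- x$trials
  s <- x$settings
  if (x$experiment == 1) {
    xs <- tr$theta0_deg
    xlab <- "initial lean angle (deg)"
    grid_x <- seq(min(xs) - 2, min(max(xs) + 2, s$readout_deg - 0.5),
                  length.out = 200)
    grid_df <- data.frame(theta0_deg = grid_x, m2_kg = 0,
                          mass_kg = mean(tr$mass_kg),
                          height_cm = mean(tr$height_cm))
  } else {
    xs <- 100 * tr$m2_kg / (tr$mass_kg + s$platform_mass)
    xlab <- "counterweight (% of corrected mass)"
    grid_x <- seq(0, max(xs) * 1.05, length.out = 200)
    m_bar <- mean(tr$mass_kg)
    grid_df <- data.frame(theta0_deg = mean(tr$theta0_deg),
                          m2_kg = grid_x / 100 * (m_bar + s$platform_mass),
                          mass_kg = m_bar,
                          height_cm = mean(tr$height_cm))
  }
  graphics::plot(xs, x$measured, xlab = xlab,
                 ylab = sprintf("angular velocity at %g deg (rad/s)",
                                s$readout_deg), ...)
  graphics::lines(grid_x, predict(x, grid_df), lty = 2)
  graphics::legend("topright", legend = c("measured", "model"),
                   pch = c(1, NA), lty = c(NA, 2), bty = "n")
  invisible(x)
}

#' Write a fit result as JSON plus a per-trial residual CSV
#'
#' @param fit A `fall_fit`.
#' @param json_path Output JSON path for the fitted parameters and
#'   diagnostics.
#' @param residuals_csv Optional CSV path for per-trial measured,
#'   predicted and residual velocities.
#' @param extra Optional named list merged into the JSON (e.g. seeds,
#'   resolved config).
#' @return `json_path`, invisibly.
#' @export
write_fit_result <- function(fit, json_path, residuals_csv = NULL,
                             extra = NULL) {
  stopifnot(inherits(fit, "fall_fit"))
  payload <- list(experiment = fit$experiment,
                  L_hat = fit$L_hat, mu_F_hat = fit$mu_F_hat,
                  k_hat = fit$k_hat, r2 = fit$r2, ss_res = fit$ss_res,
                  converged = fit$converged, n_trials = fit$n_trials,
                  L_mode = fit$L_mode, settings = fit$settings)
  if (!is.null(extra)) payload <- c(payload, extra)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  if (!is.null(residuals_csv)) {
    d <- fit$trials
    d$predicted <- fit$predicted
    d$residual <- residuals(fit)
    utils::write.csv(d, residuals_csv, row.names = FALSE)
  }
  invisible(json_path)
}
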