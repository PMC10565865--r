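#' Anthropometric cohort specification
#'
#' Describes the participant pool from which a synthetic roster is drawn:
#' truncated-normal height and mass (mean, sd, admissible range) and the
#' center-of-mass fraction used to convert height to pendulum length.
#' `cohort_exp1()` and `cohort_exp2()` return the cohorts of the two
#' validation experiments: experiment 1 pooled 14 younger adults
#' (height 173.9 +/- 10.0 cm, range 159-191; mass 78.9 +/- 4.6 kg, range
#' 54.4-103.0) and 13 older adults (175.2 +/- 9.0 cm, range 157-189;
#' 77.3 +/- 15.0 kg, range 56.3-104.8); experiment 2 had 13 younger adults
#' (185.7 +/- 6.1 cm, range 174-193; 82.4 +/- 5.6 kg, range 77.4-92.1).
#'
#' @param n Number of participants.
#' @param height_mean,height_sd,height_range Height distribution, cm.
#' @param mass_mean,mass_sd,mass_range Body-mass distribution, kg.
#' @param com_fraction Pendulum length as a fraction of height (the CoM sits
#'   at roughly 55% of standing height).
#' @param seed Optional RNG seed stored with the spec.
#' @return An object of class `cohort_spec` (a list of specs may be passed
#'   anywhere a single spec is accepted, drawing each block in turn).
#' @export
cohort_spec <- function(n, height_mean, height_sd, height_range,
                        mass_mean, mass_sd, mass_range,
                        com_fraction = 0.55, seed = NULL) {
  stopifnot(n >= 1, height_sd >= 0, mass_sd >= 0,
            com_fraction > 0, com_fraction < 1,
            length(height_range) == 2, length(mass_range) == 2)
  structure(list(n = as.integer(n),
                 height_mean = height_mean, height_sd = height_sd,
                 height_range = sort(height_range),
                 mass_mean = mass_mean, mass_sd = mass_sd,
                 mass_range = sort(mass_range),
                 com_fraction = com_fraction, seed = seed),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
cohort_exp1 <- function(com_fraction = 0.55) {
  list(
    cohort_spec(14, 173.9, 10.0, c(159, 191), 78.9, 4.6, c(54.4, 103.0),
                com_fraction = com_fraction),
    cohort_spec(13, 175.2, 9.0, c(157, 189), 77.3, 15.0, c(56.3, 104.8),
                com_fraction = com_fraction)
  )
}

#' @rdname cohort_spec
#' @export
cohort_exp2 <- function(com_fraction = 0.55) {
  cohort_spec(13, 185.7, 6.1, c(174, 193), 82.4, 5.6, c(77.4, 92.1),
              com_fraction = com_fraction)
}

rtruncnorm <- function(n, mean, sd, range) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Draw a synthetic participant roster
#'
#' Heights and masses are drawn independently from normal distributions
#' truncated to the cohort's admissible ranges; per-participant pendulum
#' length is `com_fraction * height`.
#'
#' @param spec A [cohort_spec], or a list of them (blocks are drawn in
#'   order and concatenated, as when pooling age groups).
#' @param seed RNG seed; defaults to the spec's own seed, if any.
#' @return Data frame (the roster) with columns `participant_id`,
#'   `height_cm`, `mass_kg`, `L_m`.
#' @export
generate_cohort <- function(spec, seed = NULL) {
  specs <- if (inherits(spec, "cohort_spec")) list(spec) else spec
  stopifnot(all(vapply(specs, inherits, logical(1), "cohort_spec")))
  if (is.null(seed)) seed <- specs[[1]]$seed
  if (!is.null(seed)) set.seed(seed)
  blocks <- lapply(specs, function(s) {
    data.frame(height_cm = rtruncnorm(s$n, s$height_mean, s$height_sd,
                                      s$height_range),
               mass_kg = rtruncnorm(s$n, s$mass_mean, s$mass_sd,
                                    s$mass_range),
               com_fraction = s$com_fraction)
  })
  roster <- do.call(rbind, blocks)
  roster <- data.frame(
    participant_id = sprintf("P%02d", seq_len(nrow(roster))),
    height_cm = roster$height_cm,
    mass_kg = roster$mass_kg,
    L_m = roster$com_fraction * roster$height_cm / 100)
  roster
}

#' Experiment design for synthetic fall trials
#'
#' Encodes the two validation protocols. Experiment 1 varies the initial
#' lean angle with no counterweight: two falls from each of four angles
#' (65, 52, 45, 39 degrees, achieved sd about 3 degrees). Experiment 2
#' fixes the lean angle at 37 +/- 1 degrees and varies the counterweight
#' over four levels (6.8, 12.4, 17.9, 29.1 %BW with sds 0.4, 0.8, 1.1,
#' 1.7). Condition order is randomized per participant.
#'
#' @param design `"exp1"` or `"exp2"`.
#' @param lean_angles_deg,lean_jitter_sd Condition angles and their
#'   trial-to-trial sd, degrees.
#' @param counterweight_pct,counterweight_jitter_sd Counterweight levels
#'   (% of body weight) and their sds; all zero for exp1.
#' @param trials_per_condition Falls per condition per participant.
#' @param noise_sd_omega Additive Gaussian noise sd on the measured angular
#'   velocity at the readout angle, rad/s.
#' @param pct_mode How %BW converts to kilograms: `"corrected"` uses
#'   participant mass plus the effective platform mass (the corrected-mass
#'   convention); `"body"` uses body mass alone.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(design = c("exp1", "exp2"),
                              lean_angles_deg = NULL,
                              lean_jitter_sd = NULL,
                              counterweight_pct = NULL,
                              counterweight_jitter_sd = NULL,
                              trials_per_condition = 2,
                              noise_sd_omega = 0.05,
                              pct_mode = c("corrected", "body")) {
  design <- match.arg(design)
  pct_mode <- match.arg(pct_mode)
  if (design == "exp1") {
    if (is.null(lean_angles_deg)) lean_angles_deg <- c(65, 52, 45, 39)
    if (is.null(lean_jitter_sd)) lean_jitter_sd <- 3
    counterweight_pct <- rep(0, length(lean_angles_deg))
    counterweight_jitter_sd <- rep(0, length(lean_angles_deg))
  } else {
    if (is.null(lean_angles_deg)) lean_angles_deg <- 37
    if (is.null(lean_jitter_sd)) lean_jitter_sd <- 1
    if (is.null(counterweight_pct)) {
      counterweight_pct <- c(6.8, 12.4, 17.9, 29.1)
    }
    if (is.null(counterweight_jitter_sd)) {
      counterweight_jitter_sd <- c(0.4, 0.8, 1.1, 1.7)
    }
  }
  stopifnot(all(lean_angles_deg > 0), all(lean_angles_deg < 90),
            trials_per_condition >= 1, noise_sd_omega >= 0)
  n_cond <- max(length(lean_angles_deg), length(counterweight_pct))
  structure(list(design = design,
                 lean_angles_deg = rep_len(lean_angles_deg, n_cond),
                 lean_jitter_sd = lean_jitter_sd,
                 counterweight_pct = rep_len(counterweight_pct, n_cond),
                 counterweight_jitter_sd = rep_len(counterweight_jitter_sd,
                                                   n_cond),
                 trials_per_condition = trials_per_condition,
                 noise_sd_omega = noise_sd_omega,
                 pct_mode = pct_mode),
            class = "experiment_design")
}

#' Corrected counterweight load as percent of total mass
#'
#' Expresses a counterweight mass as a percentage of the falling mass,
#' conventionally taken as participant body mass plus the effective mass of
#' the support platform.
#'
#' @param m2 Counterweight mass, kg.
#' @param participant_mass Body mass, kg.
#' @param platform_mass Effective support-platform mass, kg.
#' @return Percentage, `100 * m2 / (participant_mass + platform_mass)`.
#' @export
corrected_counterweight_pct <- function(m2, participant_mass,
                                        platform_mass = 14.4) {
  stopifnot(all(participant_mass > 0), all(platform_mass > 0), all(m2 >= 0))
  100 * m2 / (participant_mass + platform_mass)
}

#' Generate synthetic fall trials from a roster and a design
#'
#' For each participant, condition order is a random permutation of the
#' design (each condition repeated `trials_per_condition` times). Per trial
#' the realized lean angle and counterweight percentage are jittered, the
#' counterweight mass is computed from the %BW level, the forward model
#' (energy-balance solution of the equation of motion) produces the angular
#' velocity at the readout angle, and independent Gaussian noise of sd
#' `noise_sd_omega` is added to that observable. Configurations past the
#' balance threshold are flagged `balanced = TRUE` (with `omega_at_70 = NA`)
#' rather than dropped.
#'
#' The generating pendulum length is either a single global `L` (metres)
#' for every trial, or, when `L = NULL`, each participant's
#' `com_fraction * height`.
#'
#' @param roster Roster data frame from [generate_cohort()].
#' @param design An [experiment_design].
#' @param L Global pendulum length, m, or `NULL` for per-participant
#'   height-derived lengths.
#' @param mu_F Capstan friction coefficient used to generate.
#' @param r Counterweight-pulley radius, m.
#' @param g Gravitational acceleration, m/s^2.
#' @param platform_mass Effective platform mass added to body mass, kg.
#' @param readout_deg Readout angle, degrees.
#' @param seed RNG seed for jitters, ordering and noise.
#' @param raw_series If `TRUE`, also return per-trial 150 Hz angle and GRF
#'   traces (see Details); slower, since each trial is then integrated
#'   numerically.
#' @param rate Sampling rate for raw series, Hz.
#'
#' @details Raw traces emulate a capture window: a 0.5 s pre-release hold
#' at the lean angle, the integrated fall sampled at `rate`, then a 1 s
#' hold at 90 degrees after mat/absorber contact. The GRF channel is a
#' minimal step: bounded noise below the detection threshold before the
#' 90-degree contact sample, then a 50 N step (plus noise) -- only the
#' threshold rule is exercised, no impact-force realism is attempted.
#'
#' @return A list of class `experiment_dataset`: `trials` (data frame with
#'   `trial_id`, `participant_id`, `mass_kg`, `height_cm`, `condition`,
#'   `theta0_deg`, `cw_pct`, `m2_kg`, `omega_at_70`, `balanced`), `design`,
#'   `truth` (generating parameters), and `series` (named list of raw
#'   traces, if requested).
#' @export
generate_trials <- function(roster, design, L = NULL, mu_F = 0,
                            r = 0.1875, g = 9.81, platform_mass = 14.4,
                            readout_deg = 70, seed = NULL,
                            raw_series = FALSE, rate = 150) {
  stopifnot(inherits(design, "experiment_design"),
            all(c("participant_id", "mass_kg") %in% names(roster)))
  if (design$design == "exp1" && any(design$counterweight_pct != 0)) {
    stop("exp1 design must have all counterweights zero", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_cond <- length(design$lean_angles_deg)
  rows <- list()
  series <- list()
  trial_no <- 0
  for (i in seq_len(nrow(roster))) {
    order_i <- sample(rep(seq_len(n_cond), design$trials_per_condition))
    for (cond in order_i) {
      trial_no <- trial_no + 1
      theta0 <- design$lean_angles_deg[cond] +
        stats::rnorm(1, 0, design$lean_jitter_sd)
      theta0 <- min(max(theta0, 1), readout_deg - 1)
      pct <- design$counterweight_pct[cond]
      if (pct > 0) {
        pct <- max(0, pct + stats::rnorm(1, 0, design$counterweight_jitter_sd[cond]))
      }
      base_mass <- if (design$pct_mode == "corrected") {
        roster$mass_kg[i] + platform_mass
      } else {
        roster$mass_kg[i]
      }
      m2 <- pct / 100 * base_mass
      L_i <- if (is.null(L)) roster$L_m[i] else L
      p <- fall_params(L = L_i, m1 = roster$mass_kg[i] + platform_mass,
                       m2 = m2, r = r, mu_F = mu_F, g = g)
      balanced <- is_balanced(p, deg2rad(theta0))
      omega_true <- if (balanced) NA_real_ else {
        closed_form_speed(p, deg2rad(theta0), deg2rad(readout_deg))
      }
      omega_obs <- if (balanced) NA_real_ else {
        omega_true + stats::rnorm(1, 0, design$noise_sd_omega)
      }
      id <- sprintf("T%03d", trial_no)
      rows[[trial_no]] <- data.frame(
        trial_id = id, participant_id = roster$participant_id[i],
        mass_kg = roster$mass_kg[i],
        height_cm = if ("height_cm" %in% names(roster))
          roster$height_cm[i] else NA_real_,
        condition = cond, theta0_deg = theta0, cw_pct = pct, m2_kg = m2,
        omega_at_70 = omega_obs, balanced = balanced,
        stringsAsFactors = FALSE)
      if (raw_series && !balanced) {
        series[[id]] <- synth_raw_series(p, theta0, rate)
      }
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  structure(list(trials = trials, design = design,
                 truth = list(L = L, mu_F = mu_F, r = r, g = g,
                              platform_mass = platform_mass,
                              readout_deg = readout_deg, seed = seed),
                 series = if (raw_series) series else NULL),
            class = "experiment_dataset")
}

# Piecewise cubic Hermite interpolation from node values and derivatives;
# the integrator reports theta and theta_dot at every node, so resampling
# the fall onto the uniform capture grid is O(dt^4) accurate.
hermite_interp <- function(t_nodes, x_nodes, v_nodes, t_query) {
  i <- findInterval(t_query, t_nodes, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(t_nodes) - 1L)
  h <- t_nodes[i + 1] - t_nodes[i]
  s <- (t_query - t_nodes[i]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * x_nodes[i] + h10 * h * v_nodes[i] +
    h01 * x_nodes[i + 1] + h11 * h * v_nodes[i + 1]
}

# 150 Hz capture-window emulation: pre-release hold at the lean angle, the
# integrated fall, a short raised-cosine deceleration after the platform
# meets the shock absorbers at 90 degrees (no instantaneous velocity step,
# as in a real capture), then a hold. GRF is a minimal step at the contact
# sample with bounded sub-threshold noise before it.
synth_raw_series <- function(params, theta0_deg, rate = 150,
                             pre_s = 0.5, settle_s = 0.08, post_s = 1.0,
                             step_N = 50) {
  tr <- simulate_fall(params, theta0_deg, dt_out = 1 / rate)
  t90 <- tr$events$t[tr$events$name == "horizontal_90deg"]
  v90 <- tr$events$theta_dot[tr$events$name == "horizontal_90deg"]
  n_pre <- round(pre_s * rate)
  tq <- seq(0, t90 + settle_s + post_s, by = 1 / rate)
  th <- numeric(length(tq))
  fall <- tq <= t90
  th[fall] <- hermite_interp(tr$states$t, tr$states$theta,
                             tr$states$theta_dot, tq[fall])
  # shock absorber: velocity ramps v90 -> 0 with a raised-cosine profile
  settle <- tq > t90 & tq < t90 + settle_s
  ts <- tq[settle] - t90
  th[settle] <- pi / 2 +
    v90 / 2 * (ts + settle_s / pi * sin(pi * ts / settle_s))
  th[tq >= t90 + settle_s] <- pi / 2 + v90 * settle_s / 2
  ang <- c(rep(theta0_deg, n_pre), rad2deg(th))
  impact_index <- as.integer(n_pre + sum(fall) + 1)
  n_total <- length(ang)
  grf <- c(stats::runif(impact_index - 1, -3, 3),
           step_N + stats::runif(n_total - impact_index + 1, -3, 3))
  list(angle = sampled_series(ang, rate, "angle-deg"),
       grf = sampled_series(grf, rate, "grf-N"),
       impact_index = impact_index,
       release_index = as.integer(n_pre + 1))
}

#' Write an experiment dataset to CSV files
#'
#' Emits the trial-observables CSV (and optionally per-trial raw series
#' CSVs) in the schemas the fitting and processing interfaces consume.
#'
#' @param dataset An `experiment_dataset` from [generate_trials()].
#' @param trials_csv Path for the trial table.
#' @param series_dir Optional directory for per-trial `time_s, angle_deg,
#'   grf_N` CSVs (created if needed).
#' @return `trials_csv`, invisibly.
#' @export
write_trials <- function(dataset, trials_csv, series_dir = NULL) {
  stopifnot(inherits(dataset, "experiment_dataset"))
  utils::write.csv(dataset$trials, trials_csv, row.names = FALSE)
  if (!is.null(series_dir) && !is.null(dataset$series)) {
    dir.create(series_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(dataset$series)) {
      s <- dataset$series[[id]]
      write_trial_series(file.path(series_dir, paste0(id, ".csv")),
                         angle = s$angle, grf = s$grf)
    }
  }
  invisible(trials_csv)
}

#' Write a roster to CSV
#' @param roster Roster data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  utils::write.csv(roster, path, row.names = FALSE)
  invisible(path)
}
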