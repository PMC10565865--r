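test_that("variance accounted for matches hand arithmetic", {
  expect_equal(variance_accounted_for(c(1, 2, 3), c(1, 2, 3)), 1)
  m <- c(1, 2, 3)
  expect_equal(variance_accounted_for(m, rep(mean(m), 3)), 0)
  # SS_res = 1, SS_tot = 2
  expect_equal(variance_accounted_for(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(variance_accounted_for(c(2, 2), c(1, 2)), "identical")
  expect_error(variance_accounted_for(c(1, 2), c(1, 2, 3)))
})

test_that("r2 is invariant to trial ordering", {
  roster <- generate_cohort(cohort_exp1(), seed = 31)
  d <- generate_trials(roster, experiment_design("exp1"), L = 1.21,
                       seed = 32)
  f <- fit_fall_model(d, experiment = 1)
  shuffled <- d$trials[sample(nrow(d$trials)), ]
  f2 <- fit_fall_model(shuffled, experiment = 1)
  expect_equal(f2$r2, f$r2, tolerance = 1e-9)
  expect_equal(f2$L_hat, f$L_hat, tolerance = 1e-7)
})

test_that("experiment-1 fits recover the generating length from noiseless data", {
  roster <- generate_cohort(cohort_exp1(), seed = 33)
  for (L_true in c(1.21, 1.00)) {
    d <- generate_trials(roster, experiment_design("exp1",
                                                   noise_sd_omega = 0),
                         L = L_true, seed = 34)
    f <- fit_fall_model(d, experiment = 1)
    expect_lt(abs(f$L_hat - L_true), 1e-4)
    expect_lt(abs(f$r2 - 1), 1e-9)
    expect_true(f$converged)
    expect_equal(f$mu_F_hat, 0)
  }
})

test_that("experiment-2 fits recover length and friction jointly", {
  roster <- generate_cohort(cohort_exp2(), seed = 35)
  d <- generate_trials(roster, experiment_design("exp2",
                                                 noise_sd_omega = 0),
                       L = 1.30, mu_F = 0.18, seed = 36)
  f <- suppressMessages(fit_fall_model(d, experiment = 2))
  expect_lt(abs(f$L_hat - 1.30), 1e-3)
  expect_lt(abs(f$mu_F_hat - 0.18), 1e-3)
  expect_lt(abs(f$r2 - 1), 1e-9)

  # zero-friction truth pins mu at the lower bound
  d0 <- generate_trials(roster, experiment_design("exp2",
                                                  noise_sd_omega = 0),
                        L = 1.30, mu_F = 0, seed = 37)
  f0 <- suppressMessages(fit_fall_model(d0, experiment = 2))
  expect_lt(f0$mu_F_hat, 1e-6)
  expect_lt(abs(f0$L_hat - 1.30), 1e-3)
})

test_that("design mismatch and degenerate designs are reported", {
  roster <- generate_cohort(cohort_exp2(), seed = 38)
  d <- generate_trials(roster, experiment_design("exp2"), L = 1.3,
                       mu_F = 0.18, seed = 39)
  expect_error(suppressMessages(fit_fall_model(d, experiment = 1)),
               "design mismatch")

  # all trials at one lean angle: wide plateau, but the fit still reports
  des <- experiment_design("exp1", lean_angles_deg = 52,
                           lean_jitter_sd = 0)
  d1 <- generate_trials(roster, des, L = 1.21, seed = 40)
  f1 <- fit_fall_model(d1, experiment = 1)
  expect_true(is.finite(f1$r2))
  expect_true(is.logical(f1$converged))
})

test_that("balanced trials are excluded with a message, not silently", {
  roster <- generate_cohort(cohort_exp2(), seed = 41)
  d <- generate_trials(roster, experiment_design("exp2"), L = 1.3,
                       mu_F = 0.18, seed = 42)
  expect_message(f <- fit_fall_model(d, experiment = 2), "balanced")
  expect_equal(f$n_trials, sum(!d$trials$balanced))
})

test_that("height mode fits the CoM fraction instead of a global length", {
  roster <- generate_cohort(cohort_exp1(), seed = 43)
  # generate with per-participant L = 0.55 * height
  d <- generate_trials(roster, experiment_design("exp1",
                                                 noise_sd_omega = 0),
                       L = NULL, seed = 44)
  f <- fit_fall_model(d, experiment = 1, L_mode = "height")
  expect_lt(abs(f$k_hat - 0.55), 1e-4)
  expect_lt(abs(f$r2 - 1), 1e-9)
  expect_true(is.na(f$L_hat))
})

test_that("fall_fit methods are coherent", {
  roster <- generate_cohort(cohort_exp1(), seed = 45)
  d <- generate_trials(roster, experiment_design("exp1"), L = 1.21,
                       seed = 46)
  f <- fit_fall_model(d, experiment = 1)
  expect_s3_class(f, "fall_fit")
  expect_named(coef(f), c("L", "mu_F"))
  expect_equal(unname(coef(f)["L"]), f$L_hat)
  expect_equal(residuals(f), f$measured - f$predicted)
  expect_equal(predict(f), f$predicted)
  expect_equal(predict(f, f$trials), f$predicted, tolerance = 1e-12)
  s <- summary(f)
  expect_s3_class(s, "summary.fall_fit")
  expect_equal(s$rmse, sqrt(mean(residuals(f)^2)))
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(f$n_trials, 3))
  expect_identical(simulate(f, nsim = 3, seed = 1), sims)
  expect_output(print(f), "L_hat")
  pdf(NULL)
  on.exit(dev.off(), add = TRUE)
  expect_invisible(plot(f))
})

test_that("forward prediction matches the closed form and flags balance", {
  p <- p_nocw(L = 1.21)
  expect_equal(predict_impact_speed(p, 65, 70),
               closed_form_speed(p, 65 * pi / 180, 70 * pi / 180),
               tolerance = 1e-12)
  pb <- fall_params(L = 1.30, m1 = 96.8, m2 = 40, mu_F = 0.18)
  v <- predict_impact_speed(pb, 37, 70)
  expect_true(is.na(v))
  expect_equal(attr(v, "reason"), "balanced")
})

test_that("counterweight inversion round-trips through the forward model", {
  p <- fall_params(L = 1.30, m1 = 96.8, mu_F = 0.18)
  v0 <- predict_impact_speed(p, 37, 70)
  expect_equal(solve_counterweight(p, 37, v0), 0)
  m2_star <- balance_counterweight(p, 37 * pi / 180)
  expect_equal(solve_counterweight(p, 37, 0), m2_star, tolerance = 1e-6)
  for (target in c(1.3, 1.8, 2.4)) {
    m2 <- solve_counterweight(p, 37, target)
    q <- p; q$m2 <- m2
    expect_lt(abs(predict_impact_speed(q, 37, 70) - target), 1e-6)
  }
  expect_error(solve_counterweight(p, 37, v0 + 0.1), "infeasible")
  # near the balance threshold the readout speed has a positive limit;
  # targets below it cannot be realized by any counterweight
  q <- p; q$m2 <- m2_star * (1 - 1e-9)
  v_lim <- predict_impact_speed(q, 37, 70)
  expect_gt(v_lim, 0)
  expect_error(solve_counterweight(p, 37, v_lim / 2), "infeasible")
})

test_that("fit results serialize with residuals", {
  roster <- generate_cohort(cohort_exp1(), seed = 47)
  d <- generate_trials(roster, experiment_design("exp1"), L = 1.21,
                       seed = 48)
  f <- fit_fall_model(d, experiment = 1)
  js <- withr::local_tempfile(fileext = ".json")
  cs <- withr::local_tempfile(fileext = ".csv")
  write_fit_result(f, js, cs)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$L_hat, f$L_hat, tolerance = 1e-12)
  expect_equal(back$r2, f$r2, tolerance = 1e-12)
  res <- utils::read.csv(cs)
  expect_equal(res$residual, unname(residuals(f)), tolerance = 1e-10)
})
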