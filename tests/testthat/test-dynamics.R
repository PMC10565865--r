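test_that("capstan factor matches term-by-term evaluation and is monotone", {
  expect_identical(capstan_factor(0), 4)
  # frozen from independent term-by-term evaluation of the four exponentials
  expect_equal(capstan_factor(0.18), 19.91534230965903, tolerance = 1e-12)
  mu <- seq(0, 1, by = 0.01)
  expect_true(all(diff(capstan_factor(mu)) > 0))
  expect_gt(capstan_factor(0.18), capstan_factor(0.17))
  expect_error(capstan_factor(-0.1), "mu_F")
})

test_that("cable tensions follow the capstan cascade", {
  p0 <- fall_params(L = 1.3, m1 = 90, m2 = 0, mu_F = 0.2)
  t0 <- cable_tensions(p0, 3)
  expect_equal(t0$F, 0)
  expect_equal(t0$Ff, rep(0, 4))
  expect_equal(t0$F_P, 0)

  # static frictionless: weight through four wraps, factor 4
  p1 <- fall_params(L = 1.3, m1 = 90, m2 = 10, r = 0.1875, mu_F = 0,
                    g = 9.81)
  t1 <- cable_tensions(p1, 0)
  expect_equal(t1$F, 98.1)
  expect_equal(t1$F_P, 392.4)

  # with friction the total is F * C1, and the wrap sequence is increasing
  p2 <- fall_params(L = 1.3, m1 = 90, m2 = 10, r = 0.1875, mu_F = 0.18)
  t2 <- cable_tensions(p2, 0)
  expect_equal(t2$F_P, 98.1 * capstan_factor(0.18), tolerance = 1e-12)
  expect_true(all(diff(c(t2$F, t2$Ff)) > 0))
  expect_equal(sum(t2$Ff), t2$F_P)

  # accelerating: F picks up the inertial term 4 m2 r theta_ddot
  t3 <- cable_tensions(p2, 5)
  expect_equal(t3$F, 4 * 10 * 0.1875 * 5 + 10 * 9.81)
})

test_that("angular acceleration reduces to g sin(theta)/L without counterweight", {
  p <- p_nocw(L = 1.21)
  expect_equal(angular_acceleration(p, pi / 2), 9.81 / 1.21,
               tolerance = 1e-14)
  expect_equal(angular_acceleration(p, 0), 0)
  set.seed(42)
  th <- stats::runif(100, 0, pi / 2)
  expect_equal(angular_acceleration(p, th), 9.81 * sin(th) / 1.21,
               tolerance = 1e-14)
})

test_that("angular acceleration matches an independent evaluation of the moment balance", {
  # hand-coded one-liner, frozen: L=1.30, r=0.1875, mu=0.18, rho=0.30, 37 deg
  p <- fall_params(L = 1.30, m1 = 100, m2 = 30, r = 0.1875, mu_F = 0.18)
  expect_equal(angular_acceleration(p, 37 * pi / 180),
               -1.310021341639857, tolerance = 1e-12)
  # and the raw moment balance closes: I theta_ddot = m1 g L sin - F_P r
  th <- 50 * pi / 180
  a <- angular_acceleration(p, th)
  FP <- cable_tensions(p, a)$F_P
  expect_equal(p$m1 * p$L^2 * a,
               p$m1 * p$g * p$L * sin(th) - FP * p$r, tolerance = 1e-9)
  # strictly increasing in theta
  th_grid <- seq(0.05, pi / 2 - 0.01, length.out = 50)
  expect_true(all(diff(angular_acceleration(p, th_grid)) > 0))
})

test_that("closed-form speed matches the frictionless special case", {
  p <- p_nocw(L = 1.21)
  th0 <- 65 * pi / 180
  # frozen from direct evaluation of sqrt((2g/L)(cos65 - cos70))
  expect_equal(closed_form_speed(p, th0, 70 * pi / 180),
               1.143192240437906, tolerance = 1e-12)
  expect_equal(closed_form_speed(p, th0, th0), 0)
  expect_error(closed_form_speed(p, th0, 60 * pi / 180), "theta")
})

test_that("closed-form speed signals when the counterweight stops the fall", {
  # falls at release, but past horizontal the gravity torque wanes and the
  # counterweight term (linear in theta) wins before 170 degrees
  p <- fall_params(L = 1.0, m1 = 80, m2 = 14, r = 0.2, mu_F = 0.2)
  expect_false(is_balanced(p, 75 * pi / 180))
  expect_gt(closed_form_speed(p, 75 * pi / 180, 90 * pi / 180), 0)
  expect_error(closed_form_speed(p, 75 * pi / 180, 170 * pi / 180),
               class = "fallfit_unreachable")
})

test_that("integrated trajectory agrees with the closed form at every landmark", {
  p <- p_nocw(L = 1.21)
  tr <- simulate_fall(p, 65)
  for (deg in c(70, 85, 90)) {
    expect_equal(event_velocity(tr, deg),
                 closed_form_speed(p, 65 * pi / 180, deg * pi / 180),
                 tolerance = 1e-8)
  }
  expect_true(all(diff(tr$events$t) > 0))
  expect_true(all(diff(tr$states$t) > 0))
  expect_equal(tr$states$theta[1], 65 * pi / 180)
  expect_equal(tr$states$theta_dot[1], 0)

  pcw <- p_cw()
  trc <- simulate_fall(pcw, 37)
  expect_equal(event_velocity(trc, 70),
               closed_form_speed(pcw, 37 * pi / 180, 70 * pi / 180),
               tolerance = 1e-8)
})

test_that("energy is conserved along a frictionless no-counterweight fall", {
  p <- p_nocw(L = 1.21)
  tr <- simulate_fall(p, 45)
  E <- 0.5 * p$L^2 * tr$states$theta_dot^2 + p$g * p$L * cos(tr$states$theta)
  expect_lt(max(abs(E - E[1])), 1e-8)
})

test_that("balanced configurations return a flagged trajectory with no events", {
  p <- fall_params(L = 1.30, m1 = 96.8, m2 = 30, mu_F = 0.18)
  expect_true(is_balanced(p, 37 * pi / 180))
  tr <- simulate_fall(p, 37)
  expect_true(tr$balanced)
  expect_equal(nrow(tr$events), 0)
  expect_equal(nrow(tr$states), 1)
  expect_error(event_velocity(tr, 70), class = "fallfit_unreachable")
})

test_that("simulate_fall rejects out-of-range release angles", {
  p <- p_nocw()
  expect_error(simulate_fall(p, 0), "theta0")
  expect_error(simulate_fall(p, 91), "theta0")
  expect_error(simulate_fall(p, 75, landmarks_deg = c(readout = 70)),
               "theta0")
})

test_that("balance threshold mass is exact", {
  p <- fall_params(L = 1.30, m1 = 96.8, mu_F = 0.18)
  th0 <- 37 * pi / 180
  m2_star <- balance_counterweight(p, th0)
  p_above <- p; p_above$m2 <- m2_star * (1 + 1e-9)
  p_below <- p; p_below$m2 <- m2_star * (1 - 1e-9)
  expect_true(is_balanced(p_above, th0))
  expect_false(is_balanced(p_below, th0))
})

test_that("parameters serialize losslessly to JSON and YAML", {
  p <- p_cw(m2 = 12.345)
  for (ext in c("json", "yaml")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_fall_params(p, f)
    q <- read_fall_params(f)
    expect_equal(unclass(q), unclass(p))
  }
  expect_error(fall_params(L = -1, m1 = 80), "L")
  expect_error(fall_params(L = 1, m1 = 80, mu_F = -0.1), "mu_F")
})

test_that("trajectory exports round-trip through CSV and JSON", {
  tr <- simulate_fall(p_nocw(), 52)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_trajectory(tr, csv, js)
  d <- utils::read.csv(csv)
  expect_named(d, c("t", "theta_deg", "theta_dot", "theta_ddot"))
  expect_equal(nrow(d), nrow(tr$states))
  ev <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_false(ev$balanced)
  expect_equal(ev$events$theta_dot[ev$events$name == "readout_70deg"],
               event_velocity(tr, 70), tolerance = 1e-12)
})
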