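# Small builders shared across the suite. All synthetic inputs are
# generated in code; seeds are fixed per test.

p_nocw <- function(L = 1.21, m1 = 90) fall_params(L = L, m1 = m1)

p_cw <- function(L = 1.30, m1 = 96.8, m2 = 15, mu_F = 0.18, r = 0.1875) {
  fall_params(L = L, m1 = m1, m2 = m2, r = r, mu_F = mu_F)
}

# independent energy-balance evaluation, one line, never calls the package
oracle_speed <- function(L, rho, mu, r, g, th0, th) {
  C1 <- exp(mu * pi) + exp(2 * mu * pi) + exp(3 * mu * pi) + exp(4 * mu * pi)
  sqrt(2 * (g * L * (cos(th0) - cos(th)) - C1 * r * g * rho * (th - th0)) /
         (L^2 + 4 * C1 * r^2 * rho))
}

# analytic dual-pass magnitude of a bilinear-designed Butterworth low-pass
butter2_gain <- function(f, fc, fs, order = 2) {
  1 / (1 + (tan(pi * f / fs) / tan(pi * fc / fs))^(2 * order))
}

# amplitude of a sinusoid of known frequency by least squares on a basis
sine_amplitude <- function(x, f, rate, idx) {
  t <- (idx - 1) / rate
  co <- stats::coef(stats::lm(x[idx] ~ sin(2 * pi * f * t) +
                                cos(2 * pi * f * t)))
  sqrt(co[2]^2 + co[3]^2)
}
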