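## shared fixtures for the test suite; everything is generated in code

## two well-separated Gaussian incidence pulses (peaks ~2000 at days 60 and
## 160, deep trough near day 110)
two_pulse_series <- function(height = 2000, centers = c(60, 160), sd = 15,
                             horizon = 220) {
  t <- 0:horizon
  height * exp(-(t - centers[1])^2 / (2 * sd^2)) +
    height * exp(-(t - centers[2])^2 / (2 * sd^2))
}

## independent ordinary-ODE oracle for the fixed-behavior limit: the same
## vector field with m pinned at the baseline proportions, integrated with
## lsoda and no delay machinery
ode_oracle <- function(params, m_fixed, init = initial_state(),
                       horizon = 300, out_step = 0.5) {
  p <- params
  N0 <- attr(init, "N0")
  rhs <- function(t, y, parms) {
    lam <- p$beta0 * (1 - p$kappa * m_fixed) *
      (p$phi_a * y[4] + p$phi_s * y[5]) / (N0 - y[6])
    list(c(-lam[1] * y[1], -lam[2] * y[2],
           lam[1] * y[1] + lam[2] * y[2] - p$theta * y[3],
           (1 - p$sigma) * (1 - p$pi) * p$theta * y[3] -
             (p$gamma_a + p$rho_a) * y[4],
           p$sigma * (1 - p$pi) * p$theta * y[3] -
             (p$gamma_s + p$rho_s) * y[5],
           p$pi * p$theta * y[3] + p$gamma_a * y[4] + p$gamma_s * y[5] -
             p$rho_d * y[6],
           p$rho_a * y[4] + p$rho_s * y[5] + p$rho_d * y[6]))
  }
  y0 <- as.numeric(init)
  names(y0) <- names(init)
  as.data.frame(deSolve::ode(y0, seq(0, horizon, by = out_step), rhs, NULL,
                             method = "lsoda", rtol = 1e-10, atol = 1e-8))
}

## inert profile: all information weights zero, so behavior stays at m0
inert_profile <- function(alpha = 1, m0 = 0.05)
  behavior_profile(alpha = alpha, m0 = m0)

## synthetic grid-like result table with known generating coefficients
make_synthetic_rows <- function(n = 5000, seed = 42,
                                b_waves = c(-1, 1.5, -0.8, 0.05),
                                b_peak = c(7, -0.5, 0.03, 0.55),
                                b_final = c(0.5, -1.5, 0.02, 0.5),
                                phi = 20, nu = 0.01) {
  set.seed(seed)
  kappa <- sample(c(1 / 2, 3 / 5, 3 / 4, 9 / 10, 19 / 20, 1), n, TRUE)
  tau <- sample(c(1, 3, 5, 7), n, TRUE)
  beta0 <- sample(c(1 / 2, 1, 2, 3), n, TRUE)
  alpha_m1 <- sample(c(0.1, 1, 2, 3), n, TRUE)
  pi <- sample(c(1 / 4, 1 / 2, 2 / 3, 3 / 4), n, TRUE)
  lp_w <- b_waves[1] + b_waves[2] * kappa + b_waves[3] * alpha_m1 +
    b_waves[4] * tau
  lp_p <- b_peak[1] + b_peak[2] * kappa + b_peak[3] * tau + b_peak[4] * beta0
  lp_f <- b_final[1] + b_final[2] * kappa + b_final[3] * tau +
    b_final[4] * beta0
  shape <- 10
  mu_f <- stats::plogis(lp_f)
  ## the continuous beta component lies strictly inside (0, 1); ones come
  ## only from the inflation mechanism
  y_f <- stats::rbeta(n, mu_f * phi, (1 - mu_f) * phi)
  y_f <- pmin(pmax(y_f, 1e-6), 1 - 1e-6)
  y_f[stats::runif(n) < nu] <- 1
  data.frame(profile = "0", alpha_m1 = alpha_m1, alpha_p1 = alpha_m1,
             delta_alpha = 0, beta0 = beta0, pi = pi, tau = tau,
             kappa = kappa,
             epidemic = TRUE, n_waves = 1L,
             n_secondary = stats::rpois(n, exp(lp_w)),
             H_p = stats::rgamma(n, shape = shape,
                                 rate = shape / exp(lp_p)),
             T_p = 50, T_c1 = 48,
             F_T = y_f, error = "")
}
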