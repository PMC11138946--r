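test_that("with inert behavior the delay solution matches an ordinary ODE oracle", {
  params <- disease_params()
  prof <- list(inert_profile(), inert_profile())
  fit <- bseir(prof, params, horizon = 300)
  oracle <- ode_oracle(params, m_fixed = c(0.05, 0.05), horizon = 300)
  N0 <- attr(fit$init, "N0")
  for (v in c("S_m1", "S_p1", "E", "Ia", "Is", "Id", "R")) {
    expect_lt(max(abs(fit$trajectory[[v]] - oracle[[v]])) / N0, 1e-6)
  }
  ## behavior never moves off baseline
  expect_equal(fit$trajectory$m_m1, rep(0.05, nrow(fit$trajectory)),
               tolerance = 1e-12)
})

test_that("before information arrives the system ignores the behavior weights", {
  ## on [0, tau] the trajectory is identical across profiles, and behavior
  ## sits at its disease-free baseline
  s <- solver_settings(out_step = 0.25)
  f0 <- bseir("0", alpha = 0.1, horizon = 20, settings = s)
  fD <- bseir("D", alpha = 0.1, horizon = 20, settings = s)
  tau <- f0$params$tau
  on_delay <- f0$trajectory$time < tau
  expect_equal(f0$trajectory$E[on_delay], fD$trajectory$E[on_delay],
               tolerance = 1e-10)
  expect_equal(f0$trajectory$m_m1[on_delay],
               rep(0.05, sum(on_delay)), tolerance = 1e-12)
  expect_equal(f0$trajectory$P[on_delay], rep(0, sum(on_delay)))
  expect_equal(f0$trajectory$Q[on_delay], rep(0, sum(on_delay)))
})

test_that("without transmission the epidemic never grows", {
  fit <- bseir("0", params = disease_params(beta0 = 0), horizon = 100)
  tr <- fit$trajectory
  expect_equal(tr$S_m1, rep(tr$S_m1[1], nrow(tr)), tolerance = 1e-10)
  expect_true(all(diff(tr$E + tr$Ia + tr$Is) <= 1e-9))
  expect_lt(max(fit$daily$C), 1)
})

test_that("halving the tolerances leaves the peak essentially unchanged", {
  f1 <- bseir("0", alpha = 0.1, horizon = 150)
  f2 <- bseir("0", alpha = 0.1, horizon = 150,
              settings = solver_settings(rtol = 5e-9, atol = 5e-6))
  expect_lt(abs(max(f2$daily$C) - max(f1$daily$C)) / max(f1$daily$C), 1e-3)
})

test_that("the neutral term is robust to how the delayed derivative is evaluated", {
  ## solver derivative history vs central differencing of the interpolated
  ## incidence history, and halving of the difference step
  base <- bseir("D", alpha = 1, horizon = 150)
  fd1 <- bseir("D", alpha = 1, horizon = 150,
               settings = solver_settings(q_method = "fd", fd_h = 1e-3))
  fd2 <- bseir("D", alpha = 1, horizon = 150,
               settings = solver_settings(q_method = "fd", fd_h = 5e-4))
  expect_lt(max(abs(fd1$trajectory$Q - base$trajectory$Q)), 5e-4)
  expect_lt(max(abs(fd1$trajectory$Q - fd2$trajectory$Q)), 1e-4)
  expect_lt(abs(max(fd1$daily$C) - max(base$daily$C)) / max(base$daily$C),
            1e-4)
})

test_that("zero delay is accepted and behaves like instantaneous information", {
  fit <- bseir("0", alpha = 1, horizon = 120,
               params = disease_params(tau = 0))
  expect_s3_class(fit, "bseir")
  ## prevalence signal equals the concurrent detected fraction
  tr <- fit$trajectory
  expect_equal(tr$P, tr$Id / attr(fit$init, "N0"), tolerance = 1e-9)
  ## a shrinking delay approaches the zero-delay solution
  fit_eps <- bseir("0", alpha = 1, horizon = 120,
                   params = disease_params(tau = 0.05))
  expect_lt(abs(max(fit_eps$daily$C) - max(fit$daily$C)) / max(fit$daily$C),
            0.02)
})

test_that("trend signal reads exponential growth and decay correctly", {
  ## prescribed incidence histories: C = C0 e^t gives Q = 1, C = C0 e^(-t/2)
  ## gives Q = -1/2 (doubling / halving per unit time)
  tau <- 3
  tgrid <- seq(0, 20, by = 0.1)
  up <- data.frame(time = tgrid, C = 5 * exp(tgrid))
  dn <- data.frame(time = tgrid, C = 5000 * exp(-tgrid / 2))
  bu <- behavior_under_forcing(up, preset_profile("D"), tau = tau, N0 = 1e5,
                               times = seq(5, 15, by = 0.5))
  bd <- behavior_under_forcing(dn, preset_profile("D"), tau = tau, N0 = 1e5,
                               times = seq(5, 15, by = 0.5))
  expect_equal(bu$Q, rep(1, nrow(bu)), tolerance = 1e-6)
  expect_equal(bd$Q, rep(-0.5, nrow(bd)), tolerance = 1e-6)
})

test_that("solver settings are validated", {
  expect_error(solver_settings(rtol = -1), "positive")
  expect_error(solver_settings(out_step = 0.3), "divide 1 day")
  expect_error(bseir("0", horizon = -1), "positive")
  expect_error(bseir("0", settings = solver_settings(q_method = "fd",
                                                     fd_h = 5)),
               "smaller than the delay")
})
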