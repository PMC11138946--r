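test_that("detected incidence combines early detection and testing rates", {
  p <- disease_params()
  expect_equal(detected_incidence(initial_state(E0 = 0, Ia0 = 0, Is0 = 0), p), 0)
  s <- initial_state(E0 = 2, Ia0 = 1, Is0 = 1)
  expect_equal(detected_incidence(s, p), 0.25 + 2 / 70 + 4 / 70)
  ## vectorized over trajectory rows
  df <- data.frame(E = c(2, 4), Ia = c(1, 0), Is = c(1, 2))
  expect_equal(detected_incidence(df, p),
               c(0.25 + 2 / 70 + 4 / 70, 0.5 + 8 / 70))
})

test_that("force of infection scales with protection and vanishes without infectives", {
  p <- disease_params(beta0 = 1, kappa = 0, phi_a = 1, phi_s = 1)
  s <- initial_state(Ia0 = 0, Is0 = 0)
  expect_equal(force_of_infection(s, m = 0.5, p), 0)
  s2 <- initial_state(S_m1 = 49999, S_p1 = 49999, E0 = 0, Ia0 = 1, Is0 = 1)
  expect_equal(force_of_infection(s2, m = 0, p), 2e-5)
  ## linear in (1 - kappa m); full protection cuts transmission entirely
  pk <- disease_params(kappa = 1)
  expect_equal(force_of_infection(s2, m = 1, pk), 0)
  p2 <- disease_params(kappa = 0.8)
  lam0 <- force_of_infection(s2, m = 0, p2)
  expect_equal(force_of_infection(s2, m = 0.5, p2), lam0 * (1 - 0.8 * 0.5))
  expect_error(
    force_of_infection(c(Ia = 1, Is = 1, Id = 10), m = 0, p, N0 = 10),
    "degenerate")
})

test_that("reproduction numbers follow the next-generation formulas", {
  expect_equal(r_naught(disease_params()), 7)
  ## kappa = 0 removes the behavior discount entirely
  p0 <- disease_params(kappa = 0)
  prof <- list(preset_profile("0"), preset_profile("0"))
  init_s <- initial_state(S_m1 = 50000, S_p1 = 50000, E0 = 0, Ia0 = 0, Is0 = 0)
  expect_equal(basic_reproduction_number(prof, p0, init_s), r_naught(p0))
  ## equal split, m0 = 0.05, kappa = 3/4: discount 1 - 0.0375
  p34 <- disease_params(kappa = 3 / 4)
  expect_equal(basic_reproduction_number(prof, p34, init_s),
               r_naught(p34) * (1 - 0.0375))
  ## hand evaluation with modified rates
  ph <- disease_params(beta0 = 2, pi = 1 / 4, sigma = 1 / 3,
                       gamma_a = 0.1, rho_a = 0.1, gamma_s = 0.2, rho_s = 0.05)
  expect_equal(r_naught(ph),
               2 * (3 / 4) * ((2 / 3) / 0.2 + (1 / 3) / 0.25))
})

test_that("effective R(t) is the susceptible-weighted group average", {
  p <- disease_params()
  rs <- reproduction_series(S_m1 = c(40000, 30000), S_p1 = c(40000, 20000),
                            Id = c(0, 1000), m_m1 = c(0.05, 0.5),
                            m_p1 = c(0.05, 0.1), params = p, N0 = 1e5)
  w1 <- c(0.5, 0.6)
  expect_equal(rs$Rt, w1 * rs$Rt_m1 + (1 - w1) * rs$Rt_p1)
  ## homogeneous behavior collapses the average to a single group value
  expect_equal(rs$Rt_m1[1], rs$Rt_p1[1])
})

test_that("solved trajectories conserve population and stay non-negative", {
  fit <- bseir("0", alpha = 1, horizon = 300)
  tr <- fit$trajectory
  N0 <- attr(fit$init, "N0")
  tot <- rowSums(tr[, c("S_m1", "S_p1", "E", "Ia", "Is", "Id", "R")])
  expect_lt(max(abs(tot - N0)), 1e-6 * N0)
  expect_true(all(as.matrix(tr[, c("S_m1", "S_p1", "E", "Ia", "Is",
                                   "Id", "R")]) >= 0))
  ## susceptibles are non-increasing
  expect_true(all(diff(tr$S_m1) <= 1e-9))
  expect_true(all(diff(tr$S_p1) <= 1e-9))
})

test_that("the disease-free state is an equilibrium", {
  init0 <- initial_state(S_m1 = 50000, S_p1 = 50000, E0 = 0, Ia0 = 0, Is0 = 0)
  fit <- bseir("D", params = disease_params(beta0 = 2), init = init0,
               horizon = 50)
  tr <- fit$trajectory
  expect_equal(tr$S_m1, rep(50000, nrow(tr)), tolerance = 1e-10)
  expect_equal(tr$E + tr$Ia + tr$Is + tr$Id, rep(0, nrow(tr)),
               tolerance = 1e-10)
})

test_that("solved detected class matches the quadrature closed form driven by C", {
  fit <- bseir("0", alpha = 1, horizon = 200)
  tr <- fit$trajectory
  check <- seq(10, 200, by = 10)
  id_q <- id_from_incidence(data.frame(time = tr$time, C = tr$C),
                            check, rho_d = fit$params$rho_d,
                            Id0 = fit$init[["Id"]])
  id_solved <- tr$Id[match(check, tr$time)]
  expect_equal(id_solved, id_q, tolerance = 1e-4)
})

test_that("effective R(t) falls through one shortly after the first peak", {
  fit <- bseir("0", alpha = 1, horizon = 200)
  tr <- fit$trajectory
  ip <- which.max(tr$C)
  after <- tr$time >= tr$time[ip] + 5 & tr$time <= tr$time[ip] + 15
  expect_true(all(tr$Rt[after] <= 1 + 0.05))
})
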