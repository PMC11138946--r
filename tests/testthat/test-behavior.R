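test_that("information aggregate matches its quadratic form and vanishes at rest", {
  p0 <- preset_profile("0")
  pD <- preset_profile("D")
  expect_identical(information_aggregate(0, 0, p0), 0)
  expect_identical(information_aggregate(0, 0, pD), 0)
  expect_equal(information_aggregate(0.1, -0.5, p0), 2.0)
  expect_equal(information_aggregate(0.05, 0.1, pD), 2.0)
  pfull <- behavior_profile(a = 1, b = 2, c = 3, d = 4, e = 5)
  P <- 0.2; Q <- -0.3
  expect_equal(information_aggregate(P, Q, pfull),
               1 * P + 2 * P^2 + 3 * P * Q + 4 * Q^2 + 5 * Q)
  expect_error(information_aggregate(1.5, 0, p0), "0, 1")
  expect_error(information_aggregate(NA_real_, 0, p0), "finite")
})

test_that("logistic anchor delta matches the closed form and inverts m0", {
  expect_equal(delta_from_m0(0.5, 1), 0)
  expect_equal(delta_from_m0(0.05, 1), log(19))
  expect_equal(delta_from_m0(0.05, 2), log(399))
  ## inverse relation m0 = (1 + exp(delta))^(-1/alpha)
  for (m0 in c(0.01, 0.05, 0.5, 0.9)) {
    for (alpha in c(0.1, 1, 2, 3, 50)) {
      d <- delta_from_m0(m0, alpha)
      expect_equal((1 + exp(d))^(-1 / alpha), m0, tolerance = 1e-12)
    }
  }
  expect_error(delta_from_m0(0, 1), "between 0 and 1")
  expect_error(delta_from_m0(1, 1), "between 0 and 1")
  expect_error(delta_from_m0(0.5, -1), "positive")
})

test_that("prophylactic proportion is the anchored generalized logistic", {
  p <- behavior_profile(a = 20, alpha = 1, m0 = 0.05)
  expect_equal(prophylactic_proportion(0, p), 0.05)
  expect_equal(prophylactic_proportion(p$delta, p), 0.5)
  expect_equal(prophylactic_proportion(1000, p), 1, tolerance = 1e-10)
  ## strictly increasing in eta, bounded in (0, 1)
  eta <- seq(-20, 20, by = 0.25)
  m <- prophylactic_proportion(eta, p)
  expect_true(all(diff(m) > 0))
  expect_true(all(m > 0 & m < 1))
  ## anchored at m0 for every alpha
  for (alpha in c(0.1, 1, 2, 3))
    expect_equal(
      prophylactic_proportion(0, behavior_profile(alpha = alpha, m0 = 0.05)),
      0.05, tolerance = 1e-12)
})

test_that("closed form solves the Richards equation along smooth eta paths", {
  ## integrate dm/dt = m (1 - m^alpha)/alpha * deta/dt from m(0) = m0 and
  ## compare with the closed form evaluated at eta(t)
  eta_fun <- function(t) 2 * sin(t / 10) + t / 50
  deta <- function(t) 2 * cos(t / 10) / 10 + 1 / 50
  times <- seq(0, 120, by = 1)
  for (alpha in c(0.5, 1, 2)) {
    prof <- behavior_profile(alpha = alpha, m0 = 0.05)
    rhs <- function(t, y, parms)
      list(y[1] * (1 - y[1]^alpha) / alpha * deta(t))
    sol <- deSolve::ode(c(m = 0.05), times, rhs, NULL, method = "lsoda",
                        rtol = 1e-11, atol = 1e-13)
    m_ode <- sol[, "m"]
    m_closed <- prophylactic_proportion(eta_fun(times), prof)
    expect_equal(m_ode, m_closed, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("growth in m per unit eta peaks at m = (1+alpha)^(-1/alpha)", {
  for (alpha in c(0.1, 1, 2, 3)) {
    m <- seq(1e-4, 1 - 1e-4, length.out = 20001)
    growth <- m * (1 - m^alpha) / alpha
    expect_equal(m[which.max(growth)], (1 + alpha)^(-1 / alpha),
                 tolerance = 1e-3)
  }
})

test_that("in-group sensitivity matches a finite-difference oracle in alpha", {
  h <- 1e-6
  for (eta in c(2, -0.5, 0.3, 5)) {
    for (alpha in c(0.5, 1, 2)) {
      prof <- behavior_profile(a = 20, alpha = alpha, m0 = 0.05)
      up <- behavior_profile(a = 20, alpha = alpha + h, m0 = 0.05)
      dn <- behavior_profile(a = 20, alpha = alpha - h, m0 = 0.05)
      fd <- (prophylactic_proportion(eta, up) -
             prophylactic_proportion(eta, dn)) / (2 * h)
      expect_equal(dm_dalpha(eta, prof), fd, tolerance = 1e-5)
    }
  }
  prof <- behavior_profile(a = 20, alpha = 1, m0 = 0.05)
  expect_equal(dm_dalpha(0, prof), 0)
  expect_lt(dm_dalpha(2, prof), 0)
  expect_gt(dm_dalpha(-0.5, prof), 0)
})

test_that("for positive eta the response weakens as in-group drag alpha grows", {
  alphas <- c(0.1, 1, 2, 3)
  for (eta in c(0.5, 2, 10)) {
    m <- vapply(alphas, function(a)
      prophylactic_proportion(eta, behavior_profile(alpha = a, m0 = 0.05)),
      numeric(1))
    expect_true(all(diff(m) < 0))
  }
})

test_that("profile presets carry the canonical weights", {
  expect_equal(unlist(preset_profile("0")[c("a", "b", "c", "d", "e")]),
               c(a = 20, b = 0, c = 0, d = 0, e = 0))
  expect_equal(preset_profile("A")$b, 50)
  expect_equal(preset_profile("B")$c, 50)
  expect_equal(preset_profile("B", variant = "figure")$c, 150)
  expect_equal(preset_profile("C")$d, 50)
  expect_equal(preset_profile("D")$e, 10)
  expect_error(preset_profile("E"), "unknown preset")
  expect_error(behavior_profile(a = -1), "non-negative")
})
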