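#' Prophylactic proportion with fatigue and in-group inference (experimental)
#'
#' Extension of the behavior model in which (i) in-group behavior carries
#' information even when the risk signal is constant (weight `omega`), and
#' (ii) engagement decays with accumulated prophylactic effort (fatigue
#' rate `epsilon`).  The prophylactic proportion becomes
#' \deqn{m = [1 + \exp\{\delta - \eta(1-f) - \zeta\}]^{-1/\alpha}}
#' with fatigue level \eqn{f = 1 - e^{-\epsilon M}}, cumulative effort
#' \eqn{M} (\eqn{\dot M = \eta(1-f) + \zeta}, \eqn{M(0)=0}) and correction
#' \eqn{\dot\zeta = \eta(1-f)(\epsilon \dot M + \omega)}, \eqn{\zeta(0)=0}.
#'
#' With `omega = 0` and `epsilon = 0` the extension reduces exactly to
#' [prophylactic_proportion()].
#'
#' The `engagement_only` variant restricts fatigue to periods of rising
#' information (engagement indicator `g = 1` when `d eta/dt >= 0`, ties
#' counting as engagement); it has no closed form and is integrated
#' directly in `m`.
#'
#' This extension is experimental and is not used by the epidemic solver.
#'
#' @param eta Information-aggregate path: a function of time, or a numeric
#'   vector sampled on `times`.
#' @param times Increasing time grid (days) on which to report the series;
#'   `times[1]` is the epidemic outbreak (M = zeta = 0).
#' @param profile A [behavior_profile()].
#' @param omega Non-negative weight of indirectly perceived change in risk.
#' @param epsilon Non-negative fatigue rate.
#' @param engagement_only If `TRUE`, use the variant where fatigue only
#'   discounts engagement (rising `eta`), not disengagement.
#' @return A data.frame with columns `time`, `eta`, `M`, `zeta`, `f`, `m`.
#' @export
prophylactic_proportion_fatigue <- function(eta, times, profile,
                                            omega = 0, epsilon = 0,
                                            engagement_only = FALSE) {
  stopifnot(inherits(profile, "behavior_profile"))
  if (!is.finite(omega) || omega < 0) stop("'omega' must be non-negative")
  if (!is.finite(epsilon) || epsilon < 0) stop("'epsilon' must be non-negative")
  if (is.numeric(eta)) {
    if (length(eta) != length(times))
      stop("numeric 'eta' must have the same length as 'times'")
    eta_fun <- stats::approxfun(times, eta, rule = 2)
  } else if (is.function(eta)) {
    eta_fun <- eta
  } else stop("'eta' must be a function or a numeric vector")
  alpha <- profile$alpha
  m0 <- profile$m0
  delta <- profile$delta

  if (!engagement_only) {
    ## integrate the effort/correction pseudo-states; m from the closed form
    rhs <- function(t, y, parms) {
      et <- eta_fun(t)
      f <- 1 - exp(-epsilon * y[1])
      dM <- et * (1 - f) + y[2]
      dz <- et * (1 - f) * (epsilon * dM + omega)
      list(c(dM, dz))
    }
    sol <- deSolve::ode(c(M = 0, zeta = 0), times, rhs, NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    M <- sol[, "M"]; zeta <- sol[, "zeta"]
    f <- 1 - exp(-epsilon * M)
    et <- eta_fun(times)
    m <- .m_closed(et * (1 - f) + zeta, delta, alpha)
    data.frame(time = times, eta = et, M = M, zeta = zeta, f = f, m = m)
  } else {
    ## no closed form: integrate m itself with the engagement indicator
    h <- 1e-4
    deta <- function(t) (eta_fun(t + h) - eta_fun(t - h)) / (2 * h)
    rhs <- function(t, y, parms) {
      m <- min(max(y[1], 1e-12), 1 - 1e-12)
      f <- 1 - exp(-epsilon * y[2])
      dd <- deta(t)
      g <- as.numeric(dd >= 0)
      dm <- (m * (1 - m^alpha) / alpha) * (dd + omega * eta_fun(t)) * (1 - f * g)
      dM <- log(m^alpha / (1 - m^alpha)) - log(m0^alpha / (1 - m0^alpha))
      list(c(dm, dM))
    }
    sol <- deSolve::ode(c(m = m0, M = 0), times, rhs, NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    M <- sol[, "M"]
    f <- 1 - exp(-epsilon * M)
    data.frame(time = times, eta = eta_fun(times), M = M,
               zeta = NA_real_, f = f, m = sol[, "m"])
  }
}
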