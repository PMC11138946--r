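#' Logistic incidence pulse
#'
#' The synthetic single-wave forcing curve used to exercise the behavior
#' model without running the epidemic system:
#' \deqn{C(t) = N_0 \frac{e^v}{(1+e^v)^2}, \quad v = (t - \mathrm{center})/\mathrm{width}.}
#' The pulse is symmetric about `center` with analytic maximum `N0/4`
#' there, and total mass close to `N0 * width` over a wide horizon.
#'
#' @param N0 Scale (individuals); default 100,000.
#' @param center Peak day.
#' @param width Width parameter (days).
#' @param horizon Last day of the series.
#' @param step Sampling step (days); daily by default.
#' @return An object of class `"fixture_curve"`: data.frame with columns
#'   `time` and `C`, with the generating parameters as attributes.
#' @examples
#' p <- logistic_pulse()
#' max(p$C)       # 25,000 at day 50
#' @export
logistic_pulse <- function(N0 = 1e5, center = 50, width = 8,
                           horizon = 150, step = 1) {
  if (width <= 0) stop("'width' must be positive")
  time <- seq(0, horizon, by = step)
  v <- (time - center) / width
  ev <- exp(v)
  structure(data.frame(time = time, C = N0 * ev / (1 + ev)^2),
            N0 = N0, center = center, width = width,
            class = c("fixture_curve", "data.frame"))
}

#' Detected class driven by a prescribed incidence curve
#'
#' Closed-form solution of `dId/dt = C(t) - rho_d * Id` by quadrature:
#' \deqn{I_d(t) = e^{-\rho_d t}\left[ I_{d0} + \int_0^t C(u) e^{\rho_d u} du \right].}
#'
#' @param C Incidence: a function of time or a `fixture_curve`/data.frame
#'   with columns `time`, `C` (spline-interpolated).
#' @param times Times (days) at which to evaluate `Id`.
#' @param rho_d Removal rate from the detected class (per day).
#' @param Id0 Initial detected count.
#' @return Numeric vector `Id(times)`.
#' @export
id_from_incidence <- function(C, times, rho_d, Id0 = 0) {
  cf <- if (is.function(C)) C
        else stats::splinefun(C$time, C$C)
  vapply(times, function(t) {
    if (t == 0) return(Id0)
    q <- stats::integrate(function(u) cf(u) * exp(rho_d * (u - t)),
                          lower = 0, upper = t, rel.tol = 1e-8,
                          abs.tol = 1e-8, subdivisions = 1000L)$value
    exp(-rho_d * t) * Id0 + q
  }, numeric(1))
}

#' Behavioral response to a prescribed incidence curve
#'
#' Drives the behavior model with a synthetic incidence series instead of
#' the full epidemic system: the detected class is reconstructed by
#' quadrature, the delayed signals `P` and `Q` are formed exactly as in
#' the coupled model, and the prophylactic proportion is evaluated through
#' the same closed-form response.  Used to reproduce the illustration
#' figures and to test behavior-side operations in isolation.
#'
#' @param curve A [logistic_pulse()] or data.frame with `time`, `C`.
#' @param profile A [behavior_profile()].
#' @param rho_d Removal rate of detected cases (per day); the figure
#'   fixtures use 1/14.
#' @param tau Information delay (days).
#' @param N0 Population size used for the prevalence signal (defaults to
#'   the curve's scale attribute).
#' @param times Output grid; defaults to 0.1-day spacing over the curve.
#' @return A data.frame with columns `time`, `P`, `Q`, `eta`, `m`.
#' @export
behavior_under_forcing <- function(curve, profile, rho_d = 1 / 14, tau = 3,
                                   N0 = attr(curve, "N0"),
                                   times = seq(min(curve$time),
                                               max(curve$time), by = 0.1)) {
  stopifnot(inherits(profile, "behavior_profile"))
  if (is.null(N0)) stop("'N0' must be supplied for a plain data.frame curve")
  cf <- stats::splinefun(curve$time, curve$C)
  idv <- id_from_incidence(curve, pmax(times - tau, 0), rho_d = rho_d)
  seen <- times >= tau
  P <- ifelse(seen, pmin(pmax(idv / N0, 0), 1), 0)
  tl <- pmax(times - tau, 0)
  Cl <- cf(tl)
  Q <- ifelse(seen & Cl > 1e-9, cf(tl, deriv = 1) / pmax(Cl, 1e-9), 0)
  eta <- information_aggregate(P, Q, profile)
  data.frame(time = times, P = P, Q = Q, eta = eta,
             m = prophylactic_proportion(eta, profile))
}
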