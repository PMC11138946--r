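#' Behavioral response profile of a susceptible group
#'
#' A behavior profile collects the five non-negative information weights that
#' map risk information into an information aggregate, together with the
#' in-group pressure parameter and the disease-free (baseline) prophylactic
#' proportion of one susceptible group.
#'
#' The information aggregate is the quadratic form
#' \deqn{\eta = aP + bP^2 + cPQ + dQ^2 + eQ}
#' of the perceived prevalence \eqn{P \in [0,1]} and the relative rate of
#' change \eqn{Q} of new detected cases.  Non-negativity of the weights
#' guarantees that \eqn{\eta} is non-negative and non-decreasing in \eqn{P}
#' whenever \eqn{Q \ge 0}.
#'
#' The in-group parameter `alpha` shapes how the fraction already behaving
#' prophylactically modulates uptake: `alpha < 1` weakens and `alpha > 1`
#' strengthens the drag of non-prophylactic peers.  The constant
#' `delta = log(m0^(-alpha) - 1)` anchors the generalized-logistic behavior
#' curve at the baseline proportion `m0` when `eta = 0`.
#'
#' @param a,b,c,d,e Non-negative information weights: `a` linear in
#'   prevalence, `b` quadratic in prevalence, `c` prevalence-by-trend
#'   interaction, `d` quadratic in trend, `e` linear in trend.
#' @param alpha Positive in-group pressure parameter.
#' @param m0 Baseline prophylactic proportion in (0, 1), the fraction that
#'   would behave prophylactically with no evidence of disease.
#' @param name Optional label (e.g. a preset name).
#' @return An object of class `"behavior_profile"`.
#' @seealso [preset_profile()], [information_aggregate()],
#'   [prophylactic_proportion()]
#' @examples
#' p <- behavior_profile(a = 20, e = 10, alpha = 1, m0 = 0.05)
#' prophylactic_proportion(0, p)   # = m0
#' @export
behavior_profile <- function(a = 0, b = 0, c = 0, d = 0, e = 0,
                             alpha = 1, m0 = 0.05, name = NULL) {
  w <- c(a = a, b = b, c = c, d = d, e = e)
  if (!all(is.finite(w)) || any(w < 0))
    stop("information weights a, b, c, d, e must be finite and non-negative")
  if (!is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a positive real")
  if (!is.finite(m0) || m0 <= 0 || m0 >= 1)
    stop("'m0' must lie strictly between 0 and 1")
  structure(
    list(a = a, b = b, c = c, d = d, e = e,
         alpha = alpha, m0 = m0,
         delta = delta_from_m0(m0, alpha),
         name = name),
    class = "behavior_profile")
}

#' @export
print.behavior_profile <- function(x, ...) {
  nm <- if (is.null(x$name)) "" else paste0(" '", x$name, "'")
  cat(sprintf("Behavior profile%s\n", nm))
  cat(sprintf("  weights: a=%g b=%g c=%g d=%g e=%g\n", x$a, x$b, x$c, x$d, x$e))
  cat(sprintf("  in-group alpha=%g, baseline m0=%g (delta=%.4f)\n",
              x$alpha, x$m0, x$delta))
  invisible(x)
}

#' Canonical behavior-profile presets
#'
#' Named response profiles used throughout the simulation experiment:
#' `"0"` responds to prevalence only (a=20); `"A"` adds a quadratic
#' prevalence term (b=50); `"B"` adds a prevalence-by-trend interaction;
#' `"C"` adds a quadratic trend term (d=50); `"D"` adds a linear trend
#' term (e=10).
#'
#' For profile B two weights are in circulation: the experiment grid uses
#' c=50 (`variant = "grid"`, the default) while the illustration figures
#' use c=150 (`variant = "figure"`).
#'
#' @param name One of `"0"`, `"A"`, `"B"`, `"C"`, `"D"`.
#' @param alpha,m0 Passed to [behavior_profile()].
#' @param variant `"grid"` or `"figure"`; only affects profile B.
#' @return A `"behavior_profile"`.
#' @examples
#' preset_profile("D", alpha = 0.1)
#' @export
preset_profile <- function(name, alpha = 1, m0 = 0.05,
                           variant = c("grid", "figure")) {
  variant <- match.arg(variant)
  name <- as.character(name)
  w <- switch(name,
    "0" = c(20, 0, 0, 0, 0),
    "A" = c(20, 50, 0, 0, 0),
    "B" = c(20, 0, if (variant == "figure") 150 else 50, 0, 0),
    "C" = c(20, 0, 0, 50, 0),
    "D" = c(20, 0, 0, 0, 10),
    stop("unknown preset '", name, "'; use one of 0, A, B, C, D"))
  behavior_profile(a = w[1], b = w[2], c = w[3], d = w[4], e = w[5],
                   alpha = alpha, m0 = m0, name = name)
}

#' Logistic anchor constant from the baseline prophylactic proportion
#'
#' Computes `delta = log(m0^(-alpha) - 1)`, the constant that makes the
#' generalized-logistic behavior curve pass through `m0` at zero
#' information, so that `m0 = (1 + exp(delta))^(-1/alpha)`.
#'
#' @param m0 Baseline proportion in (0, 1).
#' @param alpha Positive in-group parameter.
#' @return A finite real.
#' @examples
#' delta_from_m0(0.5, 1)          # 0
#' delta_from_m0(0.05, 1)         # log(19)
#' @export
delta_from_m0 <- function(m0, alpha) {
  if (!is.finite(m0) || m0 <= 0 || m0 >= 1)
    stop("'m0' must lie strictly between 0 and 1")
  if (!is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a positive real")
  ## log(m0^(-alpha) - 1) computed as log(expm1(x)), x = -alpha*log(m0),
  ## to survive large alpha / small m0 without overflow
  x <- -alpha * log(m0)
  if (x > 30) x + log1p(-exp(-x)) else log(expm1(x))
}

#' Risk-information aggregate of a susceptible group
#'
#' Combines the perceived prevalence `P` and the relative rate of change
#' `Q` of new detected cases into the group's scalar information aggregate
#' `eta = a P + b P^2 + c P Q + d Q^2 + e Q`.
#'
#' @param P Perceived prevalence, in \[0, 1\].  Vectorized.
#' @param Q Relative rate of change of new detected cases (per day);
#'   `Q = 1` corresponds to exponential doubling per day.  Vectorized.
#' @param profile A [behavior_profile()].
#' @return `eta`, same length as `P`/`Q`.
#' @export
information_aggregate <- function(P, Q, profile) {
  stopifnot(inherits(profile, "behavior_profile"))
  if (!all(is.finite(P)) || !all(is.finite(Q)))
    stop("'P' and 'Q' must be finite")
  if (any(P < 0 | P > 1))
    stop("'P' must lie in [0, 1]")
  profile$a * P + profile$b * P^2 + profile$c * P * Q +
    profile$d * Q^2 + profile$e * Q
}

#' Prophylactic proportion as a generalized-logistic response
#'
#' The fraction of a susceptible group engaging in prophylactic behavior,
#' given its information aggregate:
#' \deqn{m = [1 + \exp(\delta - \eta)]^{-1/\alpha}.}
#' This is the closed-form solution of the Richards growth equation
#' \eqn{\partial m/\partial \eta = m(1 - m^\alpha)/\alpha} anchored at
#' `m0` when `eta = 0`.  It is strictly increasing in `eta`, with
#' `m -> 1` as `eta -> Inf` and `m -> 0` as `eta -> -Inf`.
#'
#' @param eta Information aggregate (finite real, vectorized).
#' @param profile A [behavior_profile()].
#' @return Proportion(s) in (0, 1).
#' @examples
#' p <- behavior_profile(a = 20, alpha = 1, m0 = 0.05)
#' prophylactic_proportion(c(0, p$delta), p)   # m0 and 0.5
#' @export
prophylactic_proportion <- function(eta, profile) {
  stopifnot(inherits(profile, "behavior_profile"))
  if (!all(is.finite(eta))) stop("'eta' must be finite")
  .m_closed(eta, profile$delta, profile$alpha)
}

## closed form with overflow guard; exponent clamped to +-700
.m_closed <- function(eta, delta, alpha) {
  z <- pmin(pmax(delta - eta, -700), 700)
  (1 + exp(z))^(-1 / alpha)
}

#' Sensitivity of the prophylactic proportion to in-group pressure
#'
#' Analytic derivative of the behavior curve with respect to `alpha` at
#' fixed information aggregate:
#' \deqn{\partial m/\partial \alpha = -\frac{m}{\alpha}\left[
#'   \log\frac{m}{m_0} + m^\alpha (1 - e^{-\eta}) \log m_0 \right].}
#' It is negative for `eta > 0` (stronger in-group drag weakens the
#' response above baseline), vanishes at `eta = 0`, and is positive for
#' `eta < 0`.
#'
#' @inheritParams prophylactic_proportion
#' @return Derivative value(s).
#' @export
dm_dalpha <- function(eta, profile) {
  stopifnot(inherits(profile, "behavior_profile"))
  if (!all(is.finite(eta))) stop("'eta' must be finite")
  alpha <- profile$alpha
  m0 <- profile$m0
  m <- .m_closed(eta, profile$delta, alpha)
  -(m / alpha) * (log(m / m0) + m^alpha * (1 - exp(-eta)) * log(m0))
}
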