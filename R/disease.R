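#' Disease and surveillance parameters
#'
#' Rate and probability constants of the epidemic side of the model.
#' Defaults are the reference configuration of the simulation experiment;
#' detection/removal rates are entered as exact fractions over 14 x 5 = 70
#' to avoid decimal drift.
#'
#' @param beta0 Baseline contact rate (per day).
#' @param phi_a,phi_s Probability of transmission on contact with an
#'   asymptomatic / symptomatic infective, in (0, 1\].
#' @param kappa Average efficiency of prophylactic behavior in reducing
#'   transmission, in (0, 1\].
#' @param theta Incubation exit rate (per day); mean latent period `1/theta`.
#' @param pi Probability that an exposed individual is detected early
#'   (contact tracing / targeted testing), in \[0, 1\].
#' @param sigma Fraction of non-early-detected exposed who develop
#'   symptoms, in \[0, 1\].
#' @param gamma_a,gamma_s Detection rates (per day) of asymptomatic and
#'   symptomatic infectives.
#' @param rho_a,rho_s,rho_d Removal rates (per day) from the asymptomatic,
#'   symptomatic and detected classes.
#' @param tau Delay (days, >= 0) with which case information reaches the
#'   susceptible population.
#' @return An object of class `"disease_params"`.
#' @examples
#' disease_params()              # experiment defaults; r_naught() of 7
#' @export
disease_params <- function(beta0 = 1,
                           phi_a = 1, phi_s = 1,
                           kappa = 9 / 10,
                           theta = 1 / 4,
                           pi = 1 / 2,
                           sigma = 1 / 2,
                           gamma_a = 2 / 70, gamma_s = 4 / 70,
                           rho_a = 3 / 70, rho_s = 1 / 70, rho_d = 1 / 70,
                           tau = 3) {
  p <- list(beta0 = beta0, phi_a = phi_a, phi_s = phi_s, kappa = kappa,
            theta = theta, pi = pi, sigma = sigma,
            gamma_a = gamma_a, gamma_s = gamma_s,
            rho_a = rho_a, rho_s = rho_s, rho_d = rho_d, tau = tau)
  rates <- c(beta0, theta, gamma_a, gamma_s, rho_a, rho_s, rho_d, tau)
  probs <- c(phi_a, phi_s, kappa, pi, sigma)
  if (!all(is.finite(unlist(p)))) stop("all parameters must be finite")
  if (any(rates < 0)) stop("rates and tau must be non-negative")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(p, class = "disease_params")
}

#' @export
print.disease_params <- function(x, ...) {
  cat("Disease parameters:\n")
  cat(sprintf("  beta0=%g phi_a=%g phi_s=%g kappa=%g\n",
              x$beta0, x$phi_a, x$phi_s, x$kappa))
  cat(sprintf("  theta=%g (latent %g d) pi=%g sigma=%g\n",
              x$theta, 1 / x$theta, x$pi, x$sigma))
  cat(sprintf("  gamma_a=%g gamma_s=%g rho_a=%g rho_s=%g rho_d=%g\n",
              x$gamma_a, x$gamma_s, x$rho_a, x$rho_s, x$rho_d))
  cat(sprintf("  information delay tau=%g d\n", x$tau))
  invisible(x)
}

#' Initial compartment counts
#'
#' The default initial state: a community of 100,000 with the susceptibles
#' split evenly between the two evidentiary groups and 4 infected-or-
#' incubating individuals (2 exposed, 1 asymptomatic, 1 symptomatic).
#'
#' @param S_m1,S_p1 Initial susceptibles in groups -1 and +1.
#' @param E0,Ia0,Is0,Id0,R0 Initial exposed, asymptomatic, symptomatic,
#'   detected, and removed counts.
#' @return Named numeric vector of class `"bseir_state"` with attribute
#'   `N0` (total population, constant over time).
#' @export
initial_state <- function(S_m1 = 49998, S_p1 = 49998,
                          E0 = 2, Ia0 = 1, Is0 = 1, Id0 = 0, R0 = 0) {
  y <- c(S_m1 = S_m1, S_p1 = S_p1, E = E0, Ia = Ia0, Is = Is0,
         Id = Id0, R = R0)
  if (any(!is.finite(y)) || any(y < 0))
    stop("initial compartment counts must be finite and non-negative")
  structure(y, N0 = sum(y), class = "bseir_state")
}

#' Instantaneous rate of new detected cases
#'
#' `C = pi * theta * E + gamma_a * Ia + gamma_s * Is`: early-detected
#' exposed plus infectives identified by testing.  This is the observable
#' incidence feeding the risk signals; the detected class then satisfies
#' `dId/dt = C - rho_d * Id`.
#'
#' @param state Named vector or data.frame with `E`, `Ia`, `Is` (e.g. an
#'   [initial_state()] or trajectory rows).
#' @param params A [disease_params()].
#' @return New detected cases per day (vectorized over rows).
#' @export
detected_incidence <- function(state, params) {
  stopifnot(inherits(params, "disease_params"))
  s <- as.data.frame(as.list(state))[c("E", "Ia", "Is")]
  if (is.data.frame(state)) s <- state[c("E", "Ia", "Is")]
  params$pi * params$theta * s$E + params$gamma_a * s$Ia +
    params$gamma_s * s$Is
}

#' Quarantine-adjusted force of infection for one susceptible group
#'
#' \deqn{\lambda = \beta_0 [1 - \kappa m] \frac{\phi_a I_a + \phi_s I_s}{N - I_d}}
#' Detected cases are isolated and removed from the mixing denominator.
#'
#' @param state Named vector with `Ia`, `Is`, `Id`; total population is
#'   taken from its `N0` attribute or supplied via `N0`.
#' @param m Prophylactic proportion of the group, in \[0, 1\].
#' @param params A [disease_params()].
#' @param N0 Total population (overrides the state attribute).
#' @return Force of infection (per day), non-negative.
#' @export
force_of_infection <- function(state, m, params, N0 = attr(state, "N0")) {
  stopifnot(inherits(params, "disease_params"))
  if (is.null(N0)) stop("total population 'N0' not available")
  denom <- N0 - state[["Id"]]
  if (denom <= 0) stop("degenerate population: N0 - Id must be positive")
  params$beta0 * (1 - params$kappa * m) *
    (params$phi_a * state[["Ia"]] + params$phi_s * state[["Is"]]) / denom
}

#' Behavior-free reproductive number
#'
#' The reproductive number with no prophylactic behavior and no group
#' structure:
#' \deqn{R_o = \beta_0 (1-\pi) \left[ \frac{\phi_a (1-\sigma)}{\gamma_a+\rho_a}
#'   + \frac{\phi_s \sigma}{\gamma_s+\rho_s} \right].}
#'
#' @param params A [disease_params()].
#' @return A positive scalar.
#' @examples
#' r_naught(disease_params())   # 7 under the default rates
#' @export
r_naught <- function(params) {
  stopifnot(inherits(params, "disease_params"))
  params$beta0 * (1 - params$pi) *
    (params$phi_a * (1 - params$sigma) / (params$gamma_a + params$rho_a) +
     params$phi_s * params$sigma / (params$gamma_s + params$rho_s))
}

#' Basic reproductive number at outbreak
#'
#' Discounts the behavior-free number by each group's baseline
#' prophylactic proportion:
#' \deqn{R(0) = R_o \sum_i \frac{S_{i0}}{N_0} (1 - \kappa m_{i0}).}
#'
#' @param profiles List of two [behavior_profile()]s for groups -1 and +1.
#' @param params A [disease_params()].
#' @param init An [initial_state()].
#' @return A positive scalar.
#' @export
basic_reproduction_number <- function(profiles, params, init = initial_state()) {
  profiles <- .check_profiles(profiles)
  N0 <- attr(init, "N0")
  r_naught(params) *
    (init[["S_m1"]] / N0 * (1 - params$kappa * profiles[[1]]$m0) +
     init[["S_p1"]] / N0 * (1 - params$kappa * profiles[[2]]$m0))
}

## normalizes a pair-of-profiles argument (single profile -> homogeneous)
.check_profiles <- function(profiles) {
  if (inherits(profiles, "behavior_profile")) profiles <- list(profiles, profiles)
  if (!is.list(profiles) || length(profiles) != 2L ||
      !all(vapply(profiles, inherits, TRUE, "behavior_profile")))
    stop("'profiles' must be one behavior_profile or a list of two")
  profiles
}

#' Effective reproduction number series along a trajectory
#'
#' Per-group effective reproduction numbers
#' \deqn{R_i(t) = R_o \frac{S(t)}{N_0 - I_d(t)} [1 - \kappa m_i(t)]}
#' and their susceptible-weighted average
#' \deqn{R(t) = \sum_i \frac{S_i(t)}{S(t)} R_i(t).}
#'
#' Usually accessed through the `Rt` column of a solved [bseir()]
#' trajectory; exported for use with externally assembled series.
#'
#' @param S_m1,S_p1 Susceptible counts over time.
#' @param Id Detected class over time.
#' @param m_m1,m_p1 Prophylactic proportions over time.
#' @param params A [disease_params()].
#' @param N0 Total population.
#' @return A data.frame with columns `Rt`, `Rt_m1`, `Rt_p1`.
#' @export
reproduction_series <- function(S_m1, S_p1, Id, m_m1, m_p1, params, N0) {
  Ro <- r_naught(params)
  S <- S_m1 + S_p1
  base <- Ro * S / (N0 - Id)
  R1 <- base * (1 - params$kappa * m_m1)
  R2 <- base * (1 - params$kappa * m_p1)
  w1 <- ifelse(S > 0, S_m1 / S, 0.5)
  data.frame(Rt = w1 * R1 + (1 - w1) * R2, Rt_m1 = R1, Rt_p1 = R2)
}
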