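#' Solver settings for the delay system
#'
#' @param rtol,atol Relative and absolute integration tolerances.  The
#'   absolute tolerance is in individuals (default 1e-5, i.e. 1e-10 of the
#'   default population).
#' @param out_step Output grid spacing in days.  Must divide 1 day so a
#'   daily incidence series can be extracted (severity measures and wave
#'   detection operate on daily counts; tables report half-day medians).
#' @param q_method How to evaluate the delayed derivative of the detected
#'   incidence for the trend signal `Q`: `"lagderiv"` (the solver's stored
#'   derivative history; default) or `"fd"` (central finite difference of
#'   the interpolated incidence history with half-step `fd_h`).
#' @param fd_h Half-step (days) for `q_method = "fd"`.
#' @param c_floor Incidence floor (cases/day) below which the delayed
#'   incidence is treated as zero and `Q = 0`; guards floating-point
#'   underflow near extinction.
#' @param mxhist Number of history records kept by the solver (a cyclic
#'   buffer; it only needs to cover the delay window, and 1e5 half-day
#'   records covers the longest grid delay thousands of times over).
#' @return A list of class `"solver_settings"`.
#' @export
solver_settings <- function(rtol = 1e-8, atol = 1e-5, out_step = 0.5,
                            q_method = c("lagderiv", "fd"), fd_h = 1e-3,
                            c_floor = 1e-9, mxhist = 1e5) {
  q_method <- match.arg(q_method)
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive")
  if (out_step <= 0 || abs(1 / out_step - round(1 / out_step)) > 1e-9)
    stop("'out_step' must be positive and divide 1 day")
  structure(list(rtol = rtol, atol = atol, out_step = out_step,
                 q_method = q_method, fd_h = fd_h, c_floor = c_floor,
                 mxhist = mxhist),
            class = "solver_settings")
}

#' Build the behavior-profile pair for a population
#'
#' Convenience constructor for homogeneous (`"0"`, ..., `"D"`) and
#' half-and-half heterogeneous (`"0xA"`, ..., `"0xD"`) populations.  In
#' heterogeneous populations the reference profile 0 is assigned to the
#' group labeled -1 and the variant profile to +1.
#'
#' @param population Population code: `"0"`, `"A"`, `"B"`, `"C"`, `"D"`,
#'   `"0xA"`, `"0xB"`, `"0xC"`, or `"0xD"`.
#' @param alpha In-group parameters, length 1 (shared) or 2 (groups -1, +1).
#' @param m0 Baseline prophylactic proportion (shared).
#' @param variant Profile-B weight variant, see [preset_profile()].
#' @return List of two [behavior_profile()]s.
#' @examples
#' bseir_population("0xD", alpha = 0.1)
#' @export
bseir_population <- function(population, alpha = 1, m0 = 0.05,
                             variant = "grid") {
  alpha <- rep_len(alpha, 2L)
  parts <- strsplit(as.character(population), "x", fixed = TRUE)[[1]]
  if (length(parts) == 1L) parts <- c(parts, parts)
  if (length(parts) != 2L) stop("unrecognized population code '", population, "'")
  list(preset_profile(parts[1], alpha = alpha[1], m0 = m0, variant = variant),
       preset_profile(parts[2], alpha = alpha[2], m0 = m0, variant = variant))
}

#' Simulate the behavior-coupled SEIR delay system
#'
#' Solves the seven-compartment epidemic system in which each susceptible
#' group's prophylactic proportion responds, through a generalized-logistic
#' curve, to delayed risk information: the perceived prevalence
#' `P(t) = Id(t - tau)/N` and the relative incidence trend
#' `Q(t) = C'(t - tau)/C(t - tau)`.  Because `Q` involves a delayed
#' derivative of the state, the system is a neutral delay differential
#' system; it is integrated with [deSolve::dede()] (method of steps with
#' dense history interpolation).  Before information arrives (`t < tau`)
#' both signals are zero and behavior sits at its disease-free baseline.
#'
#' @param profiles A single [behavior_profile()] (homogeneous population),
#'   a list of two (groups -1 and +1), or a population code accepted by
#'   [bseir_population()].
#' @param params A [disease_params()].
#' @param init An [initial_state()].
#' @param horizon Simulation horizon in days.
#' @param settings A [solver_settings()].
#' @param alpha Convenience override of the profile in-group parameters
#'   (length 1 or 2), applied when `profiles` is a population code.
#' @return An object of class `"bseir"`: a list with the dense
#'   `trajectory` data.frame (time, compartments, detected incidence `C`,
#'   signals `P`, `Q`, per-group `eta` and `m`, effective reproduction
#'   number `Rt`), the `daily` incidence series, the reproduction numbers
#'   `R_o` and `R0`, and the inputs.  Use `summary()` for severity
#'   measures and `plot()` for diagnostics.
#' @examples
#' \donttest{
#' fit <- bseir("0", alpha = 0.1, horizon = 200)
#' summary(fit)
#' }
#' @export
bseir <- function(profiles = "0", params = disease_params(),
                  init = initial_state(), horizon = 1000,
                  settings = solver_settings(), alpha = NULL) {
  if (is.character(profiles))
    profiles <- bseir_population(profiles, alpha = if (is.null(alpha)) 1 else alpha)
  profiles <- .check_profiles(profiles)
  stopifnot(inherits(params, "disease_params"),
            inherits(init, "bseir_state"),
            inherits(settings, "solver_settings"))
  if (horizon <= 0) stop("'horizon' must be positive")

  N0 <- attr(init, "N0")
  tau <- params$tau
  w <- vapply(profiles, function(p) c(p$a, p$b, p$c, p$d, p$e), numeric(5))
  alpha_v <- vapply(profiles, `[[`, numeric(1), "alpha")
  delta_v <- vapply(profiles, `[[`, numeric(1), "delta")
  p <- params
  cw <- c(p$pi * p$theta, p$gamma_a, p$gamma_s)  # C = cw . (E, Ia, Is)
  use_fd <- settings$q_method == "fd"
  h <- settings$fd_h
  if (use_fd && tau > 0 && h >= tau)
    stop("'fd_h' must be smaller than the delay 'tau'")
  floor_c <- settings$c_floor

  derivs <- function(y, lam) {
    c(-lam[1] * y[1], -lam[2] * y[2],
      lam[1] * y[1] + lam[2] * y[2] - p$theta * y[3],
      (1 - p$sigma) * (1 - p$pi) * p$theta * y[3] - (p$gamma_a + p$rho_a) * y[4],
      p$sigma * (1 - p$pi) * p$theta * y[3] - (p$gamma_s + p$rho_s) * y[5],
      p$pi * p$theta * y[3] + p$gamma_a * y[4] + p$gamma_s * y[5] - p$rho_d * y[6],
      p$rho_a * y[4] + p$rho_s * y[5] + p$rho_d * y[6])
  }
  behavior <- function(P, Q) {
    eta <- w[1, ] * P + w[2, ] * P^2 + w[3, ] * P * Q + w[4, ] * Q^2 + w[5, ] * Q
    .m_closed(eta, delta_v, alpha_v)
  }
  lambda_of <- function(y, m) {
    p$beta0 * (1 - p$kappa * m) *
      (p$phi_a * y[4] + p$phi_s * y[5]) / (N0 - y[6])
  }

  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    if (tau > 0) {
      if (t > tau + 1e-12) {
        yl <- deSolve::lagvalue(t - tau)
        P <- min(max(yl[6] / N0, 0), 1)
        Cl <- sum(cw * yl[3:5])
        if (Cl > floor_c) {
          if (use_fd) {
            tm <- max(t - tau - h, 0)
            tp <- t - tau + h
            Cd <- (sum(cw * deSolve::lagvalue(tp)[3:5]) -
                   sum(cw * deSolve::lagvalue(tm)[3:5])) / (tp - tm)
          } else {
            Cd <- sum(cw * deSolve::lagderiv(t - tau)[3:5])
          }
          Q <- Cd / Cl
        } else Q <- 0
      } else { P <- 0; Q <- 0 }
      list(derivs(y, lambda_of(y, behavior(P, Q))))
    } else {
      ## instantaneous information (testing only): one fixed-point pass
      ## breaks the circular dependence of Q on the current derivatives
      P <- min(max(y[6] / N0, 0), 1)
      Cl <- sum(cw * y[3:5])
      d0 <- derivs(y, lambda_of(y, behavior(P, 0)))
      Q <- if (Cl > floor_c) sum(cw * d0[3:5]) / Cl else 0
      list(derivs(y, lambda_of(y, behavior(P, Q))))
    }
  }

  times <- seq(0, horizon, by = settings$out_step)
  y0 <- as.numeric(init)
  names(y0) <- names(init)
  sol <- if (tau > 0) {
    deSolve::dede(y0, times, rhs, NULL, rtol = settings$rtol,
                  atol = settings$atol,
                  control = list(mxhist = settings$mxhist))
  } else {
    deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                 rtol = settings$rtol, atol = settings$atol)
  }
  if (nrow(sol) < length(times))
    stop("integration failed at t = ", max(sol[, 1]),
         "; consider loosening tolerances")

  traj <- as.data.frame(sol)
  names(traj)[1] <- "time"

  ## invariant checks: conservation and non-negativity
  tot <- rowSums(traj[, names(y0)])
  if (max(abs(tot - N0)) > 1e-6 * N0)
    stop("population conservation violated beyond 1e-6 * N0; solver failure")
  neg <- min(as.matrix(traj[, names(y0)]))
  if (neg < -1e-6 * N0)
    stop("negative compartment beyond tolerance; solver failure")
  traj[names(y0)] <- lapply(traj[names(y0)], pmax, 0)

  ## derived series on the output grid (post-hoc interpolation of history)
  traj$C <- cw[1] * traj$E + cw[2] * traj$Ia + cw[3] * traj$Is
  Cs <- stats::splinefun(traj$time, traj$C)
  Ids <- stats::splinefun(traj$time, traj$Id)
  tl <- pmax(traj$time - tau, 0)
  seen <- traj$time >= tau - 1e-12
  P <- ifelse(seen, pmin(pmax(Ids(tl) / N0, 0), 1), 0)
  Cl <- Cs(tl)
  Q <- ifelse(seen & Cl > floor_c, Cs(tl, deriv = 1) / pmax(Cl, floor_c), 0)
  eta1 <- information_aggregate(P, Q, profiles[[1]])
  eta2 <- information_aggregate(P, Q, profiles[[2]])
  traj$P <- P
  traj$Q <- Q
  traj$eta_m1 <- eta1
  traj$eta_p1 <- eta2
  traj$m_m1 <- prophylactic_proportion(eta1, profiles[[1]])
  traj$m_p1 <- prophylactic_proportion(eta2, profiles[[2]])
  traj$Rt <- reproduction_series(traj$S_m1, traj$S_p1, traj$Id,
                                 traj$m_m1, traj$m_p1, p, N0)$Rt

  keep <- abs(traj$time - round(traj$time)) < 1e-9
  daily <- data.frame(day = round(traj$time[keep]), C = traj$C[keep])

  structure(list(trajectory = traj, daily = daily,
                 profiles = profiles, params = params, init = init,
                 horizon = horizon, settings = settings,
                 R_o = r_naught(params),
                 R0 = basic_reproduction_number(profiles, params, init)),
            class = "bseir")
}

#' @export
print.bseir <- function(x, ...) {
  nm <- vapply(x$profiles, function(p) if (is.null(p$name)) "?" else p$name, "")
  al <- vapply(x$profiles, `[[`, numeric(1), "alpha")
  cat("Behavior-SEIR simulation\n")
  cat(sprintf("  population: %s (alpha = %g, %g), N0 = %g\n",
              if (nm[1] == nm[2] && al[1] == al[2]) nm[1]
              else paste0(nm[1], " x ", nm[2]),
              al[1], al[2], attr(x$init, "N0")))
  cat(sprintf("  horizon %g d, tau = %g d, beta0 = %g, kappa = %g, pi = %g\n",
              x$horizon, x$params$tau, x$params$beta0, x$params$kappa,
              x$params$pi))
  cat(sprintf("  R_o = %.3f, R(0) = %.3f\n", x$R_o, x$R0))
  cat(sprintf("  peak daily incidence %.1f cases/day at day %d\n",
              max(x$daily$C), x$daily$day[which.max(x$daily$C)]))
  invisible(x)
}

#' @export
as.data.frame.bseir <- function(x, ...) x$trajectory

#' Diagnostic plots for a solved trajectory
#'
#' @param x A [bseir()] object.
#' @param which Panels to draw: `"incidence"` (daily detected cases),
#'   `"behavior"` (per-group prophylactic proportions), `"rt"` (effective
#'   reproduction number), `"compartments"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bseir <- function(x, which = c("incidence", "behavior", "rt"), ...) {
  which <- match.arg(which, c("incidence", "behavior", "rt", "compartments"),
                     several.ok = TRUE)
  tr <- x$trajectory
  old <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (wk in which) {
    switch(wk,
      incidence = graphics::plot(tr$time, tr$C, type = "l",
        xlab = "day", ylab = "new detected cases / day", ...),
      behavior = {
        graphics::plot(tr$time, tr$m_m1, type = "l", ylim = c(0, 1),
          xlab = "day", ylab = "prophylactic proportion", ...)
        graphics::lines(tr$time, tr$m_p1, lty = 2)
        graphics::legend("topright", legend = c("group -1", "group +1"),
                         lty = 1:2, bty = "n")
      },
      rt = {
        graphics::plot(tr$time, tr$Rt, type = "l", xlab = "day",
          ylab = "effective R(t)", ...)
        graphics::abline(h = 1, lty = 3)
      },
      compartments = {
        graphics::matplot(tr$time, tr[, c("S_m1", "S_p1", "E", "Ia", "Is",
                                          "Id", "R")],
          type = "l", lty = 1, xlab = "day", ylab = "individuals", ...)
      })
  }
  invisible(x)
}
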