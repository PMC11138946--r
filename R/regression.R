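#' One-inflated beta regression by maximum likelihood
#'
#' Fits a mixture of a point mass at 1 and a beta distribution on (0, 1)
#' to a proportion response: a logit-linked linear predictor for the beta
#' mean, a constant precision (dispersion) parameter, and a constant
#' probability mass at 1.  Written for the final-epidemic-size summary
#' model, where complete epidemics yield exactly `F = 1`.
#'
#' With no response values equal to 1, the inflation mass is fixed at 0
#' and the likelihood reduces to ordinary beta regression.
#'
#' @param formula Model formula for the beta mean (logit link).
#' @param data Data frame; the response must lie in (0, 1].
#' @return An object of class `"oibeta"` with `coefficients` (mean model),
#'   `phi` (precision), `nu` (mass at 1), `vcov`, `logLik`, `deviance`,
#'   `null.deviance`, `df.residual`, and `pseudo_r2` (deviance based).
#' @examples
#' d <- data.frame(x = runif(200))
#' d$y <- plogis(1 + 2 * d$x + rnorm(200, 0, 0.4))
#' fit <- oibeta_reg(y ~ x, d)
#' coef(fit)
#' @export
oibeta_reg <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (any(!is.finite(y)) || any(y <= 0) || any(y > 1))
    stop("response must lie in (0, 1]")
  one <- y >= 1
  n1 <- sum(one)
  inflate <- n1 > 0L
  yc <- y[!one]
  Xc <- X[!one, , drop = FALSE]
  k <- ncol(X)

  nll_parts <- function(b, lphi, lnu) {
    phi <- exp(lphi)
    mu <- stats::plogis(drop(Xc %*% b))
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    ll <- sum(stats::dbeta(yc, mu * phi, (1 - mu) * phi, log = TRUE))
    if (inflate) {
      nu <- stats::plogis(lnu)
      ll <- ll + n1 * log(nu) + (length(yc)) * log(1 - nu)
    }
    -ll
  }
  fit_one <- function(Xd) {
    kk <- ncol(Xd)
    ystar <- stats::qlogis(pmin(pmax(yc, 1e-4), 1 - 1e-4))
    b0 <- stats::lm.fit(Xd, ystar)$coefficients
    b0[!is.finite(b0)] <- 0
    start <- c(b0, log(5), if (inflate) stats::qlogis(max(n1 / length(y), 1e-6)))
    obj <- function(par) {
      b <- par[seq_len(kk)]
      nllv <- tryCatch({
        phi <- exp(par[kk + 1L])
        mu <- stats::plogis(drop(Xd %*% b))
        mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
        ll <- sum(stats::dbeta(yc, mu * phi, (1 - mu) * phi, log = TRUE))
        if (inflate) {
          nu <- stats::plogis(par[kk + 2L])
          ll <- ll + n1 * log(nu) + length(yc) * log(1 - nu)
        }
        -ll
      }, error = function(e) Inf)
      if (!is.finite(nllv)) 1e10 else nllv
    }
    opt <- stats::optim(start, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12),
                        hessian = TRUE)
    opt
  }

  opt <- fit_one(Xc)
  if (opt$convergence != 0)
    stop("one-inflated beta fit did not converge (code ", opt$convergence,
         "); consider rescaling predictors")
  b <- opt$par[seq_len(k)]
  names(b) <- colnames(X)
  phi <- exp(opt$par[k + 1L])
  nu <- if (inflate) stats::plogis(opt$par[k + 2L]) else 0
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, k) else sqrt(pmax(diag(vc)[seq_len(k)], 0))
  ll <- -opt$value

  ## deviance against the saturated mixture (mu = y on the continuum, the
  ## point mass fitted exactly), holding phi at the model estimate
  musat <- pmin(pmax(yc, 1e-10), 1 - 1e-10)
  ll_sat <- sum(stats::dbeta(yc, musat * phi, (1 - musat) * phi, log = TRUE))
  if (inflate) {
    p1 <- n1 / length(y)
    ll_sat <- ll_sat + n1 * log(p1) + length(yc) * log(1 - p1)
  }
  dev <- 2 * (ll_sat - ll)

  ## null deviance: intercept-only mean with phi and nu held at the model
  ## estimates, so the two deviances share one saturated reference
  nll0 <- function(b0) {
    mu <- stats::plogis(b0)
    -sum(stats::dbeta(yc, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  ll0 <- -stats::optimize(nll0, c(-30, 30))$objective
  if (inflate) ll0 <- ll0 + n1 * log(nu) + length(yc) * log(1 - nu)
  dev0 <- 2 * (ll_sat - ll0)

  structure(list(coefficients = b, se = se, phi = phi, nu = nu,
                 vcov = vc, logLik = ll, deviance = dev,
                 null.deviance = dev0,
                 df.residual = length(y) - (k + 1L + as.integer(inflate)),
                 pseudo_r2 = if (dev0 > 0) 1 - dev / dev0 else 0,
                 n = length(y), n_one = n1,
                 call = match.call()),
            class = "oibeta")
}

#' @export
coef.oibeta <- function(object, ...) object$coefficients

#' @export
print.oibeta <- function(x, ...) {
  cat("One-inflated beta regression (logit mean link)\n")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se)
  print(round(tab, 4))
  cat(sprintf("precision phi = %.4f, mass at one = %.4f (%d of %d)\n",
              x$phi, x$nu, x$n_one, x$n))
  cat(sprintf("deviance %.2f on %d df; pseudo-R2 = %.4f\n",
              x$deviance, x$df.residual, x$pseudo_r2))
  invisible(x)
}

#' Deviance-based pseudo-R-squared
#'
#' `1 - deviance/null deviance` for `glm` and [oibeta_reg()] fits: the
#' fraction of the null model's deviance from the saturated fit explained
#' by the predictors.
#'
#' @param fit A `glm` or `oibeta` object.
#' @return A scalar in \[0, 1\].
#' @export
pseudo_r2 <- function(fit) {
  if (inherits(fit, "oibeta")) return(fit$pseudo_r2)
  if (inherits(fit, "glm")) {
    if (fit$null.deviance <= 0) return(0)
    return(1 - fit$deviance / fit$null.deviance)
  }
  stop("unsupported fit object")
}

#' Summary regressions for grid severity results
#'
#' Fits the three summary models of the simulation experiment to a grid
#' result table: Poisson regression (log link) for the number of secondary
#' waves, gamma regression (log link) for the epidemic peak size, and
#' one-inflated beta regression (logit link) for the final epidemic size.
#' Predictors: population profile (reference `"0"`), the group -1 in-group
#' parameter `alpha_m1`, the in-group heterogeneity `delta_alpha`, and
#' `kappa`, `tau`, `pi`, `beta0`.
#'
#' Runs with a peak below 1 case/day are excluded from the gamma fit
#' (support requirement) and reported in the result.
#'
#' @param rows A [run_grid()] result (or compatible data.frame).
#' @param delta_alpha_sign Convention for the heterogeneity term:
#'   `"m1_minus_p1"` (default, `alpha_-1 - alpha_+1`) or `"p1_minus_m1"`.
#' @return An object of class `"bseir_model_fits"`: list with elements
#'   `waves` (glm), `peak` (glm), `final` (oibeta), `excluded_peak_rows`,
#'   and a `table` of coefficients and standard errors.
#' @export
fit_summary_models <- function(rows,
                               delta_alpha_sign = c("m1_minus_p1",
                                                    "p1_minus_m1")) {
  delta_alpha_sign <- match.arg(delta_alpha_sign)
  ok <- (is.na(rows$error) | rows$error == "") & is.finite(rows$H_p)
  d <- as.data.frame(rows[ok, , drop = FALSE])
  lev <- c("0", "A", "0xA", "B", "0xB", "C", "0xC", "D", "0xD")
  d$profile <- factor(d$profile, levels = intersect(lev, unique(d$profile)))
  d$delta_alpha <- if (delta_alpha_sign == "m1_minus_p1")
    d$alpha_m1 - d$alpha_p1 else d$alpha_p1 - d$alpha_m1
  if (nlevels(d$profile) < 2L)
    form <- ~ alpha_m1 + delta_alpha + kappa + tau + pi + beta0
  else
    form <- ~ profile + alpha_m1 + delta_alpha + kappa + tau + pi + beta0
  if (length(unique(d$delta_alpha)) < 2L)
    form <- stats::update(form, . ~ . - delta_alpha)

  waves <- stats::glm(stats::update(form, n_secondary ~ .), data = d,
                      family = stats::poisson())
  keep_peak <- d$H_p >= 1
  peak <- stats::glm(stats::update(form, H_p ~ .),
                     data = d[keep_peak, , drop = FALSE],
                     family = stats::Gamma(link = "log"))
  final <- oibeta_reg(stats::update(form, F_T ~ .), data = d)

  ct <- function(fit) {
    if (inherits(fit, "glm")) {
      s <- summary(fit)$coefficients
      data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2])
    } else {
      data.frame(term = names(coef(fit)), estimate = unname(coef(fit)),
                 se = fit$se)
    }
  }
  tabs <- list(waves = ct(waves), peak = ct(peak), final = ct(final))
  terms_all <- unique(unlist(lapply(tabs, `[[`, "term")))
  table <- data.frame(term = terms_all)
  for (nm in names(tabs)) {
    m <- match(table$term, tabs[[nm]]$term)
    table[[paste0(nm, "_est")]] <- tabs[[nm]]$estimate[m]
    table[[paste0(nm, "_se")]] <- tabs[[nm]]$se[m]
  }
  structure(list(waves = waves, peak = peak, final = final,
                 excluded_peak_rows = sum(!keep_peak),
                 table = table,
                 gof = data.frame(
                   model = c("waves", "peak", "final"),
                   deviance = c(waves$deviance,
                                peak$deviance / summary(peak)$dispersion,
                                final$deviance),
                   df = c(waves$df.residual, peak$df.residual,
                          final$df.residual),
                   pseudo_r2 = c(pseudo_r2(waves), pseudo_r2(peak),
                                 pseudo_r2(final)))),
            class = "bseir_model_fits")
}

#' @export
print.bseir_model_fits <- function(x, ...) {
  cat("Severity summary models (waves: Poisson, peak: gamma, final: one-inflated beta)\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("gamma fit excluded %d run(s) with peak < 1 case/day\n",
              x$excluded_peak_rows))
  print(transform(x$gof, deviance = round(deviance, 2),
                  pseudo_r2 = round(pseudo_r2, 4)), row.names = FALSE)
  invisible(x)
}
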