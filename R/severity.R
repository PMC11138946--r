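#' Delimit epidemic waves in a daily incidence series
#'
#' Identifies epidemic waves in a daily series of new detected cases using
#' peak prominence and trough rules.  The disease is considered to die out
#' with no epidemic wave when the maximum of the series is below one plus
#' the initial number of infected individuals.  Otherwise candidate peaks
#' (local maxima; plateaus resolved to their first day) are screened by:
#'
#' * prominence of at least `min_prominence` cases/day above the higher of
#'   the flanking troughs, and
#' * prominence of at least `min_prominence_frac` of the peak height;
#'
#' then waves separated by an inadmissible trough are merged (a trough must
#' be below `trough_max` cases and lag the preceding peak by at least
#' `min_peak_trough_sep` days), and finally waves shorter than
#' `min_duration` days are dropped.  If the epidemic threshold is met but
#' screening removes every candidate (e.g. a monotone series), the global
#' maximum is reported as the single wave.
#'
#' @param C Daily series of new detected cases (non-negative, 1-day
#'   spacing).
#' @param initial_infected Number of infected-or-incubating individuals at
#'   day 0 (default 4: the standard initial state's E + Ia + Is + Id).
#' @param days Day labels for `C` (defaults to 0, 1, ...).
#' @param trough_max Maximum height (cases/day) of a trough separating two
#'   waves.
#' @param min_peak_trough_sep Minimum days from a peak to the following
#'   trough.
#' @param min_duration Minimum wave duration in days.
#' @param min_prominence Minimum absolute peak prominence (cases/day).
#' @param min_prominence_frac Minimum prominence as a fraction of peak
#'   height.
#' @return An object of class `"wave_set"`: a list with `waves` (a
#'   data.frame with columns `start`, `peak_day`, `end`, `peak_height`,
#'   `prominence`, `left_trough`, `right_trough`), `n_waves`, and
#'   `epidemic` (logical flag; `FALSE` iff zero waves).
#' @examples
#' pulse <- logistic_pulse(horizon = 150)
#' detect_waves(pulse$C)          # one wave peaking at day 50
#' @export
detect_waves <- function(C, initial_infected = 4, days = seq_along(C) - 1,
                         trough_max = 500, min_peak_trough_sep = 5,
                         min_duration = 7, min_prominence = 10,
                         min_prominence_frac = 0.5) {
  if (length(C) == 0L) stop("empty incidence series")
  if (any(!is.finite(C)) || any(C < 0))
    stop("incidence series must be finite and non-negative")
  if (length(days) != length(C)) stop("'days' must match 'C' in length")
  empty <- data.frame(start = numeric(0), peak_day = numeric(0),
                      end = numeric(0), peak_height = numeric(0),
                      prominence = numeric(0), left_trough = numeric(0),
                      right_trough = numeric(0))
  if (max(C) < 1 + initial_infected) {
    return(structure(list(waves = empty, n_waves = 0L, epidemic = FALSE,
                          series = data.frame(day = days, C = C)),
                     class = "wave_set"))
  }

  n <- length(C)
  peaks <- .local_maxima(C)

  ## prominence screen (rules on absolute and relative prominence)
  if (length(peaks)) {
    prom <- vapply(peaks, function(i) .prominence(C, i), numeric(1))
    ok <- prom >= min_prominence & prom >= min_prominence_frac * C[peaks]
    peaks <- peaks[ok]
  }

  ## merge waves separated by an inadmissible trough
  if (length(peaks) > 1L) {
    repeat {
      merged <- FALSE
      for (k in seq_len(length(peaks) - 1L)) {
        i1 <- peaks[k]; i2 <- peaks[k + 1L]
        seg <- i1:i2
        itr <- seg[which.min(C[seg])]
        bad <- C[itr] >= trough_max ||
          (days[itr] - days[i1]) < min_peak_trough_sep
        if (bad) {
          drop <- if (C[i1] >= C[i2]) k + 1L else k
          peaks <- peaks[-drop]
          merged <- TRUE
          break
        }
      }
      if (!merged || length(peaks) < 2L) break
    }
  }

  ## epidemic threshold met => at least the principal wave
  if (!length(peaks)) peaks <- which.max(C)

  ## wave boundaries: separating troughs; outermost minima at the edges
  bounds <- integer(length(peaks) + 1L)
  bounds[1] <- which.min(C[1:peaks[1]])
  if (length(peaks) > 1L)
    for (k in seq_len(length(peaks) - 1L)) {
      seg <- peaks[k]:peaks[k + 1L]
      bounds[k + 1L] <- seg[which.min(C[seg])]
    }
  bounds[length(bounds)] <- (peaks[length(peaks)] - 1L) +
    which.min(C[peaks[length(peaks)]:n])

  waves <- data.frame(
    start = days[bounds[-length(bounds)]],
    peak_day = days[peaks],
    end = days[bounds[-1L]],
    peak_height = C[peaks],
    prominence = vapply(peaks, function(i) .prominence(C, i), numeric(1)),
    left_trough = C[bounds[-length(bounds)]],
    right_trough = C[bounds[-1L]])

  ## minimum-duration rule
  waves <- waves[waves$end - waves$start >= min_duration, , drop = FALSE]
  if (nrow(waves) == 0L) {
    i <- which.max(C)
    waves <- data.frame(start = days[1], peak_day = days[i], end = days[n],
                        peak_height = C[i], prominence = .prominence(C, i),
                        left_trough = C[1], right_trough = C[n])
  }
  rownames(waves) <- NULL
  structure(list(waves = waves, n_waves = nrow(waves), epidemic = TRUE,
                 series = data.frame(day = days, C = C)),
            class = "wave_set")
}

## local maxima of a series; plateaus resolved to their first index
.local_maxima <- function(C) {
  n <- length(C)
  if (n < 3L) return(integer(0))
  d <- diff(C)
  s <- sign(d)
  ## carry the last non-zero slope through plateaus
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  idx <- which(s[-length(s)] > 0 & s[-1L] < 0) + 1L
  ## move each peak to the first index of its plateau
  vapply(idx, function(i) { while (i > 1L && C[i - 1L] == C[i]) i <- i - 1L; i },
         integer(1))
}

## topographic prominence: height above the higher of the two bases, where
## each base is the minimum between the peak and the nearest higher ground
## (or the series end)
.prominence <- function(C, i) {
  n <- length(C)
  h <- C[i]
  left_base <- if (i == 1L) h else {
    j <- i - 1L
    while (j >= 1L && C[j] <= h) j <- j - 1L
    if (j < 1L) min(C[1:(i - 1L)]) else min(C[(j + 1L):(i - 1L)])
  }
  right_base <- if (i == n) h else {
    j <- i + 1L
    while (j <= n && C[j] <= h) j <- j + 1L
    if (j > n) min(C[(i + 1L):n]) else min(C[(i + 1L):(j - 1L)])
  }
  h - max(left_base, right_base)
}

#' @export
print.wave_set <- function(x, ...) {
  cat(sprintf("Epidemic wave set: %d wave(s)%s\n", x$n_waves,
              if (!x$epidemic) " (disease died out; no epidemic)" else ""))
  if (x$n_waves > 0) print(x$waves, row.names = FALSE)
  invisible(x)
}

#' Time to curb the first outbreak
#'
#' First time at which the effective reproduction number falls through 1
#' after the outbreak, located by linear interpolation between output
#' knots.  Defined only when `R(0) > 1`; returns `NA` otherwise.
#'
#' @param time Time knots (days).
#' @param Rt Effective reproduction number at `time`.
#' @param R0 Basic reproduction number at outbreak.
#' @return Time in days, or `NA_real_`.
#' @export
time_to_curb <- function(time, Rt, R0) {
  if (!is.finite(R0) || R0 <= 1) return(NA_real_)
  below <- Rt < 1
  if (!any(below)) return(NA_real_)
  i <- which(below)[1]
  if (i == 1L) return(time[1])
  t0 <- time[i - 1L]; t1 <- time[i]
  r0 <- Rt[i - 1L]; r1 <- Rt[i]
  t0 + (r0 - 1) / (r0 - r1) * (t1 - t0)
}

#' Severity measures for a solved epidemic
#'
#' Computes the epidemic severity summary from a solved trajectory: the
#' epidemic indicator and wave count from the daily detected-incidence
#' series, the overall peak height `H_p` and time `T_p`, the time `T_c1`
#' to curb the first outbreak (first down-crossing of the effective
#' reproduction number through 1; undefined when `R(0) <= 1`), and the
#' final epidemic size `F_T = 1 - S(T)/N0`.
#'
#' This is also what `summary()` on a [bseir()] object returns.
#'
#' @param fit A [bseir()] object.
#' @param waves Optionally a precomputed [detect_waves()] result.
#' @return An object of class `"bseir_severity"` with fields `epidemic`,
#'   `n_waves`, `n_secondary`, `H_p`, `T_p`, `T_c1`, `F_T`, `waves`.
#' @export
severity_summary <- function(fit, waves = NULL) {
  stopifnot(inherits(fit, "bseir"))
  init <- fit$init
  n_inf0 <- init[["E"]] + init[["Ia"]] + init[["Is"]] + init[["Id"]]
  if (is.null(waves))
    waves <- detect_waves(fit$daily$C, initial_infected = n_inf0,
                          days = fit$daily$day)
  tr <- fit$trajectory
  ip <- which.max(fit$daily$C)
  N0 <- attr(init, "N0")
  ST <- tr$S_m1[nrow(tr)] + tr$S_p1[nrow(tr)]
  structure(list(
    epidemic = waves$epidemic,
    n_waves = waves$n_waves,
    n_secondary = max(waves$n_waves - 1L, 0L),
    H_p = fit$daily$C[ip],
    T_p = fit$daily$day[ip],
    T_c1 = time_to_curb(tr$time, tr$Rt, fit$R0),
    F_T = 1 - ST / N0,
    horizon = fit$horizon,
    waves = waves), class = "bseir_severity")
}

#' @export
#' @rdname severity_summary
#' @param object A [bseir()] object.
#' @param ... Unused.
summary.bseir <- function(object, ...) severity_summary(object)

#' @export
print.bseir_severity <- function(x, ...) {
  cat("Epidemic severity summary\n")
  cat(sprintf("  epidemic:          %s\n", if (x$epidemic) "yes" else "no"))
  cat(sprintf("  waves (secondary): %d (%d)\n", x$n_waves, x$n_secondary))
  cat(sprintf("  peak:              %.2f cases/day at day %g\n", x$H_p, x$T_p))
  cat(sprintf("  time to curb:      %s\n",
              if (is.na(x$T_c1)) "undefined (R(0) <= 1)"
              else sprintf("%.2f d", x$T_c1)))
  cat(sprintf("  final size F_%g:   %.4f\n", x$horizon, x$F_T))
  invisible(x)
}
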