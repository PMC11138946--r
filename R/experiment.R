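#' Simulation-experiment design
#'
#' Builds the full-factorial grid of the simulation experiment: population
#' response profiles crossed with in-group parameter pairs and the varied
#' disease parameters.  With the defaults each profile/alpha-pair cell
#' contains 4 x 4 x 4 x 6 = 384 runs; the default alpha-pair set is the 10
#' unordered pairs from \{0.1, 1, 2, 3\} (4 homogeneous + 6 heterogeneous,
#' the pair value for group -1 listed first and never below the value for
#' group +1).
#'
#' @param profiles Population codes (see [bseir_population()]).
#' @param alpha_pairs Two-column matrix (or list of length-2 vectors) of
#'   (alpha_-1, alpha_+1) pairs; `NULL` for the default set.
#' @param beta0,pi,tau,kappa Grid values of the varied disease parameters.
#' @param horizon Simulation horizon (days).
#' @return An object of class `"experiment_design"` whose `grid` element
#'   has one row per run.
#' @examples
#' d <- experiment_design(profiles = "0",
#'                        alpha_pairs = cbind(0.1, 0.1))
#' nrow(d$grid)    # 384
#' @export
experiment_design <- function(profiles = c("0", "A", "B", "C", "D",
                                           "0xA", "0xB", "0xC", "0xD"),
                              alpha_pairs = NULL,
                              beta0 = c(1 / 2, 1, 2, 3),
                              pi = c(1 / 4, 1 / 2, 2 / 3, 3 / 4),
                              tau = c(1, 3, 5, 7),
                              kappa = c(1 / 2, 3 / 5, 3 / 4, 9 / 10,
                                        19 / 20, 1),
                              horizon = 1000) {
  if (is.null(alpha_pairs)) {
    av <- c(0.1, 1, 2, 3)
    cmb <- expand.grid(a1 = av, a2 = av)
    cmb <- cmb[cmb$a1 >= cmb$a2, ]  # unordered pairs; group -1 value first
    alpha_pairs <- as.matrix(cmb[order(cmb$a1, cmb$a2), ])
  }
  if (is.list(alpha_pairs)) alpha_pairs <- do.call(rbind, alpha_pairs)
  alpha_pairs <- matrix(as.numeric(alpha_pairs), ncol = 2)
  ap <- data.frame(alpha_m1 = alpha_pairs[, 1], alpha_p1 = alpha_pairs[, 2])
  grid <- merge(merge(data.frame(profile = profiles, stringsAsFactors = FALSE),
                      ap, by = NULL),
                expand.grid(beta0 = beta0, pi = pi, tau = tau, kappa = kappa),
                by = NULL)
  ## deterministic, resume-friendly ordering
  grid <- grid[order(grid$profile, grid$alpha_m1, grid$alpha_p1,
                     grid$beta0, grid$pi, grid$tau, grid$kappa), ]
  rownames(grid) <- NULL
  structure(list(grid = grid, horizon = horizon),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("Experiment design: %d runs (%d profiles x %d alpha pairs x %d settings)\n",
              nrow(x$grid), length(unique(x$grid$profile)),
              nrow(unique(x$grid[c("alpha_m1", "alpha_p1")])),
              nrow(unique(x$grid[c("beta0", "pi", "tau", "kappa")]))))
  invisible(x)
}

#' Run the simulation-experiment grid
#'
#' Solves the delay system for every row of the design and records the
#' severity measures.  Fully deterministic; runs are independent and the
#' result table is reproduced bit-for-bit on re-execution.  Individual
#' solver failures are recorded in the `error` column, not fatal.
#'
#' @param design An [experiment_design()].
#' @param settings A [solver_settings()].
#' @param checkpoint Optional path to a CSV used for incremental saving;
#'   if it exists, completed rows are loaded and skipped (resume).
#' @param subset Optional integer vector of design rows to run.
#' @param progress Print a line every `progress` runs (0 = silent).
#' @return A data.frame (class `"bseir_results"`) with one row per run:
#'   the design columns, `delta_alpha = alpha_m1 - alpha_p1`, `epidemic`,
#'   `n_waves`, `n_secondary`, `H_p`, `T_p`, `T_c1`, `F_T`, `error`.
#' @export
run_grid <- function(design, settings = solver_settings(),
                     checkpoint = NULL, subset = NULL, progress = 0) {
  stopifnot(inherits(design, "experiment_design"))
  grid <- design$grid
  if (!is.null(subset)) grid <- grid[subset, , drop = FALSE]
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint, stringsAsFactors = FALSE)
    if (nrow(done) >= nrow(grid)) {
      return(structure(done[seq_len(nrow(grid)), ],
                       class = c("bseir_results", "data.frame")))
    }
  }
  n_done <- if (is.null(done)) 0L else nrow(done)
  out <- vector("list", nrow(grid))
  if (n_done > 0) out[seq_len(n_done)] <- split(done, seq_len(n_done))
  for (i in seq_len(nrow(grid))) {
    if (i <= n_done) next
    g <- grid[i, ]
    row <- data.frame(g, delta_alpha = g$alpha_m1 - g$alpha_p1,
                      epidemic = NA, n_waves = NA_integer_,
                      n_secondary = NA_integer_, H_p = NA_real_,
                      T_p = NA_real_, T_c1 = NA_real_, F_T = NA_real_,
                      error = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      fit <- bseir(bseir_population(g$profile, alpha = c(g$alpha_m1, g$alpha_p1)),
                   params = disease_params(beta0 = g$beta0, pi = g$pi,
                                           tau = g$tau, kappa = g$kappa),
                   horizon = design$horizon, settings = settings)
      severity_summary(fit)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
    } else {
      row$epidemic <- res$epidemic
      row$n_waves <- res$n_waves
      row$n_secondary <- res$n_secondary
      row$H_p <- res$H_p
      row$T_p <- res$T_p
      row$T_c1 <- res$T_c1
      row$F_T <- res$F_T
    }
    out[[i]] <- row
    if (!is.null(checkpoint))
      utils::write.table(row, checkpoint, sep = ",", append = i > 1L || n_done > 0,
                         col.names = i == 1L && n_done == 0, row.names = FALSE)
    if (progress > 0 && i %% progress == 0)
      message(sprintf("run %d / %d", i, nrow(grid)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("bseir_results", "data.frame"))
}

#' Descriptive statistics of severity measures
#'
#' Median, mean and standard deviation of the severity measures, grouped
#' by response profile or by in-group parameter pair (the layout of the
#' experiment's summary tables: epidemic indicator, number of secondary
#' waves, peak time, peak size, time to curb, final size).
#'
#' @param rows A [run_grid()] result.
#' @param by `"profile"` or `"alpha_pair"`.
#' @return A data.frame with columns `group`, `measure`, `median`,
#'   `mean`, `sd`, `n`.  Undefined times-to-curb are dropped from their
#'   cell; empty groups are omitted with a warning.
#' @export
descriptive_stats <- function(rows, by = c("profile", "alpha_pair")) {
  by <- match.arg(by)
  ok <- is.na(rows$error) | rows$error == ""
  rows <- rows[ok, , drop = FALSE]
  grp <- if (by == "profile") rows$profile
         else sprintf("(%g, %g)", rows$alpha_m1, rows$alpha_p1)
  measures <- c(epidemic = "Epidemic?", n_secondary = "Nb2. waves",
                T_p = "Peak time", H_p = "Peak size",
                T_c1 = "Time to curb", F_T = "Final size")
  res <- list()
  for (g in unique(grp)) {
    sub <- rows[grp == g, , drop = FALSE]
    if (nrow(sub) == 0L) { warning("empty group ", g, " omitted"); next }
    for (mv in names(measures)) {
      x <- as.numeric(sub[[mv]])
      x <- x[is.finite(x)]
      res[[length(res) + 1L]] <- data.frame(
        group = g, measure = measures[[mv]],
        median = stats::median(x), mean = mean(x),
        sd = if (length(x) > 1L) stats::sd(x) else 0,
        n = length(x), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
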