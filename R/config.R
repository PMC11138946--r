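#' Read a simulation configuration file
#'
#' YAML configuration with optional blocks `profiles` (either a population
#' code plus `alpha`, or two named blocks `group_m1`/`group_p1` each with
#' fields `a`, `b`, `c`, `d`, `e`, `alpha`, `m0`), `params` (fields of
#' [disease_params()]), `init` (fields of [initial_state()]), `horizon`,
#' and `settings` (fields of [solver_settings()]).
#'
#' @param path Path to a YAML file.
#' @return A list with elements `profiles`, `params`, `init`, `horizon`,
#'   `settings`, ready to pass to [bseir()].
#' @export
read_bseir_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  prof_cfg <- cfg$profiles
  profiles <- if (is.null(prof_cfg)) {
    bseir_population("0")
  } else if (!is.null(prof_cfg$population)) {
    bseir_population(prof_cfg$population,
                     alpha = if (is.null(prof_cfg$alpha)) 1
                             else unlist(prof_cfg$alpha),
                     m0 = if (is.null(prof_cfg$m0)) 0.05 else prof_cfg$m0)
  } else {
    lapply(list(prof_cfg$group_m1, prof_cfg$group_p1), function(g) {
      if (is.null(g)) stop("config 'profiles' needs 'group_m1' and 'group_p1'")
      do.call(behavior_profile, g)
    })
  }
  params <- do.call(disease_params, as.list(cfg$params))
  init <- do.call(initial_state, as.list(cfg$init))
  settings <- do.call(solver_settings, as.list(cfg$settings))
  list(profiles = profiles, params = params, init = init,
       horizon = if (is.null(cfg$horizon)) 1000 else cfg$horizon,
       settings = settings)
}

#' Write a simulation configuration file
#'
#' @param profiles List of two [behavior_profile()]s.
#' @param params A [disease_params()].
#' @param init An [initial_state()].
#' @param horizon Horizon in days.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_bseir_config <- function(path, profiles, params = disease_params(),
                               init = initial_state(), horizon = 1000) {
  profiles <- .check_profiles(profiles)
  pl <- lapply(profiles, function(p)
    list(a = p$a, b = p$b, c = p$c, d = p$d, e = p$e,
         alpha = p$alpha, m0 = p$m0))
  names(pl) <- c("group_m1", "group_p1")
  yaml::write_yaml(list(
    profiles = pl,
    params = unclass(params),
    init = as.list(unclass(init)),
    horizon = horizon), path)
  invisible(path)
}

#' Write a solved trajectory as a tidy delimited table
#'
#' @param fit A [bseir()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(fit, path) {
  stopifnot(inherits(fit, "bseir"))
  utils::write.csv(fit$trajectory, path, row.names = FALSE)
  invisible(path)
}
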