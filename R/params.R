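#' Foraging and conversion parameters of the territorial cannibal predator
#'
#' Bundles the parameters of the prey-preference-dependent Holling type II
#' functional response and of the numerical response that converts consumed
#' prey into newly hatched nymphs.
#'
#' A territorial female encounters two kinds of prey: heterospecific prey
#' (standing availability `y` per territory, constant over time) and her own
#' nymphs in the three cannibalizable cohorts (first/second, third/fourth and
#' fifth instars). An attack on a cohort-`i` nymph succeeds with probability
#' `k3`, `k4` or `k5`; a consumed nymph yields `a3`, `a4` or `a5` newly
#' hatched nymphs and a consumed heterospecific prey yields `b`.
#'
#' @param y Heterospecific prey availability per territory (count, >= 0).
#' @param b Newly hatched nymphs produced per consumed heterospecific prey
#'   (dimensionless, >= 0).
#' @param tau_a Handling time of a conspecific prey, minutes (> 0).
#' @param tau_b Handling time of a heterospecific prey, minutes (> 0).
#' @param tau_s Searching time per prey encounter, minutes (> 0).
#' @param k3,k4,k5 Probability that a maternal attack on a cohort-3/4/5 nymph
#'   succeeds (each in `[0, 1]`).
#' @param a3,a4,a5 Newly hatched nymphs produced per consumed cohort-3/4/5
#'   nymph (dimensionless, >= 0).
#'
#' @return An object of class `foraging_params` (a validated named list).
#' @seealso [real_parameters()], [illustrative_parameters()],
#'   [life_history()], [functional_response()]
#' @examples
#' fp <- foraging_params(
#'   y = 16.8, b = 0.44, tau_a = 23.3, tau_b = 16.6, tau_s = 5.3,
#'   k3 = 1, k4 = 0.8, k5 = 0.55, a3 = 0.91, a4 = 3, a5 = 6.14
#' )
#' fp$a5
#' @export
foraging_params <- function(y, b, tau_a, tau_b, tau_s,
                            k3, k4, k5, a3, a4, a5) {
  fp <- list(
    y = y, b = b, tau_a = tau_a, tau_b = tau_b, tau_s = tau_s,
    k3 = k3, k4 = k4, k5 = k5, a3 = a3, a4 = a4, a5 = a5
  )
  fp <- lapply(fp, as.numeric)
  class(fp) <- "foraging_params"
  validate_foraging_params(fp)
  fp
}

validate_foraging_params <- function(fp) {
  for (f in names(fp)) {
    v <- fp[[f]]
    if (length(v) != 1L || !is.finite(v)) {
      abort(paste0("`", f, "` must be a single finite number"))
    }
  }
  if (fp$y < 0) abort("`y` must be >= 0")
  for (f in c("tau_a", "tau_b", "tau_s")) {
    if (fp[[f]] <= 0) abort(paste0("`", f, "` must be > 0"))
  }
  for (f in c("k3", "k4", "k5")) {
    if (fp[[f]] < 0 || fp[[f]] > 1) {
      abort(paste0("`", f, "` must be a probability in [0, 1]"))
    }
  }
  for (f in c("b", "a3", "a4", "a5")) {
    if (fp[[f]] < 0) abort(paste0("`", f, "` must be >= 0"))
  }
  invisible(fp)
}

#' Life-history configuration of the cohort recursion
#'
#' Time discretization and developmental durations of the model. The time
#' unit is `unit_days` days (default 5); each female forages
#' `activity_minutes` minutes per unit (default 4800 = 16 h/day over 5 days).
#' An egg cohort needs `egg_units` units to hatch, then passes through three
#' cannibalizable nymph cohorts (`nymph_units`, one unit each by default)
#' before maturing; matured daughters spend `migration_units` units finding
#' their own territory. The mother lays and forages for
#' `reproductive_units` units; the reproductive season spans `season_units`
#' units (default 50 = 250 days).
#'
#' @param unit_days Days per time step (positive integer).
#' @param activity_minutes Foraging minutes per time step.
#' @param egg_units Steps an egg cohort needs to hatch.
#' @param nymph_units Integer vector of length 3: steps spent in each
#'   cannibalizable nymph cohort.
#' @param reproductive_units Number of steps the focal female lays and
#'   forages (her reproductive life span, L).
#' @param migration_units Lag between leaving the natal territory and
#'   founding one's own.
#' @param season_units Reproductive season length in steps.
#'
#' @return An object of class `life_history`.
#' @examples
#' life_history()               # the default configuration
#' life_history(season_units = 20)
#' @export
life_history <- function(unit_days = 5,
                         activity_minutes = 4800,
                         egg_units = 2,
                         nymph_units = c(1, 1, 1),
                         reproductive_units = 7,
                         migration_units = 1,
                         season_units = 50) {
  lh <- list(
    unit_days = unit_days,
    activity_minutes = activity_minutes,
    egg_units = egg_units,
    nymph_units = nymph_units,
    reproductive_units = reproductive_units,
    migration_units = migration_units,
    season_units = season_units
  )
  class(lh) <- "life_history"
  validate_life_history(lh)
  lh
}

validate_life_history <- function(lh) {
  scalars <- c(
    "unit_days", "activity_minutes", "egg_units",
    "reproductive_units", "migration_units", "season_units"
  )
  for (f in scalars) {
    v <- lh[[f]]
    if (length(v) != 1L || !is.finite(v) || v <= 0 || v != round(v)) {
      abort(paste0("`", f, "` must be a positive integer"))
    }
  }
  nu <- lh$nymph_units
  if (length(nu) != 3L || any(!is.finite(nu)) || any(nu <= 0) ||
      any(nu != round(nu))) {
    abort("`nymph_units` must be three positive integers")
  }
  if (lh$season_units < lh$egg_units + 3 + lh$migration_units) {
    abort("`season_units` too short for one full development + migration")
  }
  invisible(lh)
}

## steps from laying to leaving the natal territory
development_units <- function(lh) lh$egg_units + sum(lh$nymph_units)

#' Prey preference (the decision variables)
#'
#' The phenotype under selection: `p_a` is the probability that the female
#' attacks an encountered conspecific nymph (her cannibalism rate), `p_b` the
#' probability that she attacks an encountered heterospecific prey.
#'
#' @param p_a,p_b Attack probabilities in `[0, 1]`.
#' @return An object of class `prey_preference`.
#' @examples
#' prey_preference(0.17, 1)
#' @export
prey_preference <- function(p_a, p_b) {
  for (f in c("p_a", "p_b")) {
    v <- get(f)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      abort(paste0("`", f, "` must be a probability in [0, 1]"))
    }
  }
  structure(list(p_a = as.numeric(p_a), p_b = as.numeric(p_b)),
            class = "prey_preference")
}

as_preference <- function(pref) {
  if (inherits(pref, "prey_preference")) return(pref)
  if (is.numeric(pref) && length(pref) == 2L) {
    return(prey_preference(pref[[1]], pref[[2]]))
  }
  abort("`pref` must be a prey_preference or a numeric vector c(p_a, p_b)")
}

#' Validate a foraging/life-history parameter pair
#'
#' Checks every invariant of both parameter objects and returns them
#' unchanged (idempotent). Errors name the offending field.
#'
#' @param fp A [foraging_params()] object.
#' @param lh A [life_history()] object.
#' @return Invisibly, `list(foraging = fp, life_history = lh)`.
#' @export
validate_parameters <- function(fp, lh) {
  if (!inherits(fp, "foraging_params")) {
    fp <- do.call(foraging_params, as.list(unclass(fp)))
  }
  if (!inherits(lh, "life_history")) {
    lh <- do.call(life_history, as.list(unclass(lh)))
  }
  validate_foraging_params(fp)
  validate_life_history(lh)
  invisible(list(foraging = fp, life_history = lh))
}

#' Laboratory-estimated parameter set for Nabis pseudoferus
#'
#' The parameter set estimated from laboratory trials with *Nabis
#' pseudoferus* females fed on conspecific nymphs or on *Spodoptera exigua*
#' larvae, together with the default life-history configuration.
#'
#' @return `list(foraging = <foraging_params>, life_history = <life_history>)`.
#' @examples
#' p <- real_parameters()
#' p$foraging$b     # 0.44 hatched nymphs per consumed heterospecific prey
#' @export
real_parameters <- function() {
  list(
    foraging = foraging_params(
      y = 16.8, b = 0.44,
      tau_a = 23.3, tau_b = 16.6, tau_s = 5.3,
      k3 = 1.00, k4 = 0.80, k5 = 0.55,
      a3 = 0.91, a4 = 3.00, a5 = 6.14
    ),
    life_history = life_history()
  )
}

#' Illustrative parameter set
#'
#' A constructed parameter set in which conspecific nymphs are far more
#' valuable food than the heterospecific prey (large `a` coefficients, small
#' `b`, short conspecific handling time), used to demonstrate that the model
#' can make partial cannibalism optimal under both fitness definitions.
#'
#' @return `list(foraging = <foraging_params>, life_history = <life_history>)`.
#' @export
illustrative_parameters <- function() {
  list(
    foraging = foraging_params(
      y = 23.5, b = 0.04,
      tau_a = 5.0, tau_b = 80.0, tau_s = 30.0,
      k3 = 1, k4 = 0.8, k5 = 0.55,
      a3 = 2, a4 = 6, a5 = 11
    ),
    life_history = life_history()
  )
}

#' Read / write parameter sets as flat JSON
#'
#' Parameter sets are serialized as a flat key-value JSON object whose keys
#' are exactly the field names of [foraging_params()] and [life_history()]
#' (`nymph_units` is a length-3 array). The two canonical sets ship as
#' fixture files under `system.file("extdata", package = "cannfor")`.
#'
#' @param params A `list(foraging = , life_history = )` pair.
#' @param path File path.
#' @return `read_parameters()` returns the parameter pair;
#'   `write_parameters()` returns `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".json")
#' write_parameters(real_parameters(), path)
#' identical(read_parameters(path), real_parameters())
#' @export
write_parameters <- function(params, path) {
  stopifnot(is.list(params), !is.null(params$foraging),
            !is.null(params$life_history))
  flat <- c(unclass(params$foraging), unclass(params$life_history))
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  flat <- jsonlite::read_json(path, simplifyVector = TRUE)
  fp_fields <- c("y", "b", "tau_a", "tau_b", "tau_s",
                 "k3", "k4", "k5", "a3", "a4", "a5")
  lh_fields <- c("unit_days", "activity_minutes", "egg_units", "nymph_units",
                 "reproductive_units", "migration_units", "season_units")
  missing <- setdiff(fp_fields, names(flat))
  if (length(missing) > 0) {
    abort(paste0("parameter file lacks field(s): ",
                 paste(missing, collapse = ", ")))
  }
  fp <- do.call(foraging_params, flat[fp_fields])
  lh <- do.call(life_history, flat[intersect(lh_fields, names(flat))])
  list(foraging = fp, life_history = lh)
}

#' @export
print.foraging_params <- function(x, ...) {
  cat("<foraging_params>\n")
  cat(sprintf("  heterospecific availability y = %g, conversion b = %g\n",
              x$y, x$b))
  cat(sprintf("  times (min): tau_a = %g, tau_b = %g, tau_s = %g\n",
              x$tau_a, x$tau_b, x$tau_s))
  cat(sprintf("  attack success k = (%g, %g, %g)\n", x$k3, x$k4, x$k5))
  cat(sprintf("  conversion a = (%g, %g, %g)\n", x$a3, x$a4, x$a5))
  invisible(x)
}

#' @export
print.life_history <- function(x, ...) {
  cat("<life_history>\n")
  cat(sprintf("  %d days/unit, %g foraging min/unit\n",
              x$unit_days, x$activity_minutes))
  cat(sprintf("  egg %d + nymph %s units to maturity; migration %d unit(s)\n",
              x$egg_units, paste(x$nymph_units, collapse = "+"),
              x$migration_units))
  cat(sprintf("  maternal reproductive life %d units; season %d units\n",
              x$reproductive_units, x$season_units))
  invisible(x)
}

#' @export
as_tibble.foraging_params <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
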