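## Within-step foraging kernel.
##
## One female forages for `minutes` in a territory holding `avail` nymphs of
## the three cannibalizable cohorts and a constant heterospecific prey
## availability y. Encounters form renewal cycles: one search (tau_s) finds
## one prey item, drawn by relative abundance from the x + y items present;
## an encountered conspecific is attacked with probability p_a (handling
## tau_a is then paid whether or not the attack succeeds; it succeeds with
## cohort-specific probability k_i), an encountered heterospecific is
## attacked with probability p_b (handling tau_b, always successful). The
## expected cycle length is therefore
##   C = tau_s + (x/(x+y)) p_a tau_a + (y/(x+y)) p_b tau_b
## and instantaneous consumption rates are
##   dc_i/dt = -p_a k_i c_i / ((x+y) C),  dH/dt = p_b y / ((x+y) C).
## Nymph consumption depletes the cohorts within the step (y is a standing
## availability and is not depleted), so the rates are integrated over the
## activity window with a fixed-step classical Runge-Kutta scheme rather
## than evaluated once; `steps` substeps of RK4 are converged to ~1e-7
## relative at the default 16.
forage_kernel <- function(avail, y, p_a, p_b, fp, minutes, steps = 16L) {
  k <- c(fp$k3, fp$k4, fp$k5)
  tau_s <- fp$tau_s; tau_a <- fp$tau_a; tau_b <- fp$tau_b
  state <- c(avail, 0) # c3, c4, c5, cumulative heterospecific consumption
  if (minutes <= 0 || sum(avail) + y <= 0 || (p_a == 0 && p_b == 0)) {
    return(list(consumed = c(0, 0, 0), het = 0))
  }
  deriv <- function(s) {
    cc <- pmax(s[1:3], 0)
    x <- cc[1] + cc[2] + cc[3]
    tot <- x + y
    if (tot <= 0) return(c(0, 0, 0, 0))
    cyc <- tau_s + (x * p_a * tau_a + y * p_b * tau_b) / tot
    c(-p_a * k * cc / (tot * cyc), p_b * y / (tot * cyc))
  }
  h <- minutes / steps
  for (i in seq_len(steps)) {
    k1 <- deriv(state)
    k2 <- deriv(state + h / 2 * k1)
    k3 <- deriv(state + h / 2 * k2)
    k4 <- deriv(state + h * k3)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    state[1:3] <- pmin(pmax(state[1:3], 0), avail)
  }
  list(consumed = avail - state[1:3], het = state[4])
}

#' Prey-preference-dependent Holling type II consumption over one time step
#'
#' Computes the expected numbers of conspecific nymphs (per cannibalizable
#' cohort) and heterospecific prey a female consumes during one activity
#' window. Encounters are abundance-proportional, each encounter costs one
#' search time, attacked prey cost their handling time, and nymph cohorts
#' are depleted continuously within the step.
#'
#' @param available Numeric vector of length 3: nymphs of cohorts 3, 4, 5
#'   present at the start of the step.
#' @param y Heterospecific prey availability (defaults to `fp$y`).
#' @param pref A [prey_preference()] or numeric `c(p_a, p_b)`.
#' @param fp A [foraging_params()] object.
#' @param minutes Foraging time available, minutes.
#' @param steps Number of RK4 substeps for the within-step depletion
#'   integration.
#' @return A one-row tibble with columns `consumed_c3`, `consumed_c4`,
#'   `consumed_c5`, `consumed_het` (a consumption record).
#' @examples
#' fp <- real_parameters()$foraging
#' # no nymphs present: pure single-prey Holling disc consumption
#' functional_response(c(0, 0, 0), pref = c(0, 1), fp = fp, minutes = 4800)
#' @export
functional_response <- function(available, y = fp$y, pref, fp,
                                minutes, steps = 16L) {
  pref <- as_preference(pref)
  if (length(available) != 3L || any(!is.finite(available))) {
    abort("`available` must be three finite cohort counts")
  }
  if (any(available < 0)) abort("`available` counts must be >= 0")
  if (y < 0) abort("`y` must be >= 0")
  if (minutes < 0) abort("`minutes` must be >= 0")
  res <- forage_kernel(as.numeric(available), y, pref$p_a, pref$p_b,
                       fp, minutes, steps)
  tibble(
    consumed_c3 = res$consumed[1],
    consumed_c4 = res$consumed[2],
    consumed_c5 = res$consumed[3],
    consumed_het = res$het
  )
}

#' Numerical response: hatched nymphs produced from one step's consumption
#'
#' Converts a consumption record into the expected number of newly hatched
#' nymphs: `a3/a4/a5` per consumed cohort-3/4/5 nymph and `b` per consumed
#' heterospecific prey.
#'
#' @param consumption A consumption record as returned by
#'   [functional_response()] (one-row data frame with the four
#'   `consumed_*` columns).
#' @param fp A [foraging_params()] object.
#' @return The expected number of newly hatched nymphs (scalar, >= 0).
#' @examples
#' fp <- real_parameters()$foraging
#' one_c3 <- tibble::tibble(consumed_c3 = 1, consumed_c4 = 0,
#'                          consumed_c5 = 0, consumed_het = 0)
#' numerical_response(one_c3, fp)  # 0.91
#' @export
numerical_response <- function(consumption, fp) {
  cols <- c("consumed_c3", "consumed_c4", "consumed_c5", "consumed_het")
  if (!all(cols %in% names(consumption))) {
    abort("`consumption` must have the four consumed_* columns")
  }
  with(consumption,
       fp$a3 * consumed_c3 + fp$a4 * consumed_c4 +
         fp$a5 * consumed_c5 + fp$b * consumed_het)
}
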