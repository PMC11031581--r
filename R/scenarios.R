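## run code with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Seeded random parameter sets for property testing
#'
#' Draws a structurally valid random parameter pair: positive densities,
#' handling/searching times in minutes, attack-success probabilities
#' non-increasing with nymph cohort (larger nymphs escape more often) and
#' conversion coefficients non-decreasing with cohort (larger nymphs carry
#' more biomass), matching the orderings of the laboratory set.
#'
#' @param seed Integer seed; the same seed always yields the same set.
#' @param ranges Optional named list overriding the sampling bounds; each
#'   element a length-2 numeric `c(lo, hi)` with names among `y`, `b`,
#'   `times` (common bounds for `tau_a`, `tau_b`, `tau_s`), `k`, `a`.
#' @return `list(foraging = <foraging_params>, life_history = <life_history>)`.
#' @examples
#' random_parameters(42)$foraging
#' @export
random_parameters <- function(seed, ranges = NULL) {
  defaults <- list(y = c(1, 50), b = c(0.01, 2), times = c(1, 120),
                   k = c(0.1, 1), a = c(0.1, 15))
  if (!is.null(ranges)) {
    if (!is.list(ranges) || is.null(names(ranges)) ||
        !all(names(ranges) %in% names(defaults))) {
      abort("`ranges` must be a named list with names among y, b, times, k, a")
    }
    for (nm in names(ranges)) {
      r <- ranges[[nm]]
      if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) ||
          r[1] > r[2]) {
        abort(paste0("range `", nm, "` must be a finite c(lo, hi)"))
      }
      defaults[[nm]] <- r
    }
  }
  rg <- defaults
  with_local_seed(seed, {
    k <- sort(runif(3, rg$k[1], rg$k[2]), decreasing = TRUE)
    a <- sort(runif(3, rg$a[1], rg$a[2]))
    fp <- foraging_params(
      y = runif(1, rg$y[1], rg$y[2]),
      b = runif(1, rg$b[1], rg$b[2]),
      tau_a = runif(1, rg$times[1], rg$times[2]),
      tau_b = runif(1, rg$times[1], rg$times[2]),
      tau_s = runif(1, rg$times[1], rg$times[2]),
      k3 = k[1], k4 = k[2], k5 = k[3],
      a3 = a[1], a4 = a[2], a5 = a[3]
    )
    list(foraging = fp, life_history = life_history())
  })
}

## One stochastic foraging bout (exact simulation of the Markov jump
## process whose fluid limit is forage_kernel). State changes only when a
## conspecific nymph is consumed, so the bout is simulated on the skeleton
## of conspecific-consumption events; heterospecific consumption between
## consecutive events is Poisson by thinning. Returns integer conspecific
## consumption per cohort and integer heterospecific consumption.
simulate_bout <- function(avail, y, p_a, p_b, fp, minutes) {
  k <- c(fp$k3, fp$k4, fp$k5)
  cc <- as.integer(avail)
  het <- 0L
  consumed <- c(0L, 0L, 0L)
  t <- 0
  repeat {
    x <- sum(cc)
    tot <- x + y
    if (tot <= 0 || t >= minutes) break
    cyc <- fp$tau_s + (x * p_a * fp$tau_a + y * p_b * fp$tau_b) / tot
    r_con <- p_a * k * cc / (tot * cyc)   # per-cohort consumption rates
    r_het <- p_b * y / (tot * cyc)
    R <- sum(r_con)
    if (R <= 0) {
      het <- het + stats::rpois(1, (minutes - t) * r_het)
      break
    }
    dt <- rexp(1, R)
    if (t + dt >= minutes) {
      het <- het + stats::rpois(1, (minutes - t) * r_het)
      break
    }
    het <- het + stats::rpois(1, dt * r_het)
    i <- sample.int(3L, 1L, prob = r_con)
    cc[i] <- cc[i] - 1L
    consumed[i] <- consumed[i] + 1L
    t <- t + dt
  }
  list(consumed = consumed, het = het)
}

## integerize a real-valued offspring expectation: floor + Bernoulli
draw_integer_offspring <- function(mu) {
  base <- floor(mu)
  as.integer(base + rbinom(1, 1, mu - base))
}

## One individual-based territory replicate: integer cohorts, stochastic
## foraging, integer offspring. Returns integer e(tau) and a(tau) plus the
## local departure steps of the daughters.
simulate_territory_ibm <- function(p_a, p_b, fp, lh) {
  L <- lh$reproductive_units
  E <- lh$egg_units
  nu <- lh$nymph_units
  D <- E + sum(nu)
  cls_of_age <- c(rep(1L, E), rep(3L, nu[1]), rep(4L, nu[2]), rep(5L, nu[3]))
  surv <- integer(L)
  e <- integer(L)
  for (t in seq_len(L)) {
    members <- list(integer(0), integer(0), integer(0))
    cnt <- c(0L, 0L, 0L)
    for (tau in seq_len(min(t, L))) {
      s <- t - tau
      if (s >= D) next
      cl <- cls_of_age[s + 1L]
      if (cl >= 3L) {
        members[[cl - 2L]] <- c(members[[cl - 2L]], tau)
        cnt[cl - 2L] <- cnt[cl - 2L] + surv[tau]
      }
    }
    bout <- simulate_bout(cnt, fp$y, p_a, p_b, fp, lh$activity_minutes)
    for (j in 1:3) {
      n_take <- bout$consumed[j]
      if (n_take == 0L) next
      pool <- rep(members[[j]], times = surv[members[[j]]])
      take <- if (length(pool) == 1L) pool else sample(pool, n_take)
      for (tau in take) surv[tau] <- surv[tau] - 1L
    }
    mu <- fp$a3 * bout$consumed[1] + fp$a4 * bout$consumed[2] +
      fp$a5 * bout$consumed[3] + fp$b * bout$het
    e[t] <- draw_integer_offspring(mu)
    surv[t] <- e[t]
  }
  list(e = e, a = surv, leave_step = seq_len(L) + D)
}

## Full individual-based lineage: breadth-first over founders. Counts the
## descendants tree exactly as season_growth does (established founders,
## Eve excluded). Aborts if the lineage outgrows `max_founders`.
simulate_lineage_ibm <- function(p_a, p_b, fp, lh, max_founders = 1e5) {
  Tn <- lh$season_units
  d_mig <- lh$migration_units
  queue <- c(1L)                    # founding steps, Eve first
  z <- 0L
  qi <- 1L
  while (qi <= length(queue)) {
    t0 <- queue[qi]; qi <- qi + 1L
    terr <- simulate_territory_ibm(p_a, p_b, fp, lh)
    found_at <- t0 + terr$leave_step - 1L + d_mig
    for (j in seq_along(found_at)) {
      n <- terr$a[j]
      if (n > 0L && found_at[j] <= Tn) {
        z <- z + n
        queue <- c(queue, rep(found_at[j], n))
      }
    }
    if (length(queue) > max_founders) {
      abort("lineage too large for the individual-based oracle")
    }
  }
  z
}

#' Stochastic individual-based oracle for the deterministic recursion
#'
#' Simulates the territory model at the individual level -- integer nymph
#' counts, stochastic foraging cycles with Bernoulli-thinned attacks and
#' successes, integer offspring whose expectation equals the deterministic
#' conversion arithmetic -- and returns Monte-Carlo means and standard
#' errors of `e(tau)`, `a(tau)` and (optionally) the season fitness `Z`.
#' The deterministic recursion is the expected-value skeleton of this
#' process, so ensemble means should bracket it on scenarios where the
#' fluid approximation holds.
#'
#' @inheritParams run_focal_female
#' @param n_replicates Number of independent territory replicates.
#' @param seed Integer seed.
#' @param include_z If `TRUE`, also simulate the full descendants tree per
#'   replicate (only sensible at small parameter values).
#' @param z_replicates Replicates for the lineage simulation (defaults to
#'   `n_replicates`).
#' @return A list of class `cannfor_oracle`: `$per_age` tibble (`age`,
#'   `e_mean`, `e_se`, `a_mean`, `a_se`), `$z` tibble (`z_mean`, `z_se`) or
#'   `NULL`, `$n_replicates`.
#' @export
stochastic_oracle <- function(pref, fp, lh = life_history(),
                              n_replicates = 1e4, seed = 1L,
                              include_z = FALSE,
                              z_replicates = n_replicates) {
  pref <- as_preference(pref)
  validate_parameters(fp, lh)
  stopifnot(n_replicates >= 1)
  L <- lh$reproductive_units
  with_local_seed(seed, {
    em <- matrix(0, nrow = n_replicates, ncol = L)
    am <- matrix(0, nrow = n_replicates, ncol = L)
    for (r in seq_len(n_replicates)) {
      terr <- simulate_territory_ibm(pref$p_a, pref$p_b, fp, lh)
      em[r, ] <- terr$e
      am[r, ] <- terr$a
    }
    se <- function(m) apply(m, 2, stats::sd) / sqrt(nrow(m))
    per_age <- tibble(
      age = seq_len(L),
      e_mean = colMeans(em), e_se = se(em),
      a_mean = colMeans(am), a_se = se(am)
    )
    z <- NULL
    if (include_z) {
      zs <- vapply(seq_len(z_replicates), function(r) {
        as.numeric(simulate_lineage_ibm(pref$p_a, pref$p_b, fp, lh))
      }, numeric(1))
      z <- tibble(z_mean = mean(zs),
                  z_se = stats::sd(zs) / sqrt(length(zs)))
    }
    structure(list(per_age = per_age, z = z, n_replicates = n_replicates),
              class = "cannfor_oracle")
  })
}

#' @export
print.cannfor_oracle <- function(x, ...) {
  cat(sprintf("<cannfor_oracle> %d replicates\n", x$n_replicates))
  print(x$per_age)
  if (!is.null(x$z)) print(x$z)
  invisible(x)
}
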