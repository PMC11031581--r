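# Independent oracles used across the suite. These deliberately do not
# share code with the package internals they check.

# Brute-force enumeration of the descendants tree: expand founder by
# founder, generation by generation, instead of the package's renewal
# convolution. `a` is the per-maternal-age departure kernel; a daughter
# hatched from the egg laid at maternal age tau founds her own territory
# (development + migration) steps after laying. Returns the number of
# established descendants by season end, the root excluded.
brute_force_descendants <- function(a, lh) {
  d <- lh$egg_units + sum(lh$nymph_units) + lh$migration_units
  season <- lh$season_units
  total <- 0
  frontier <- list(list(t0 = 1, w = 1))
  while (length(frontier) > 0) {
    nxt <- list()
    for (node in frontier) {
      for (tau in seq_along(a)) {
        if (a[tau] == 0) next
        t_found <- node$t0 + tau + d - 1
        if (t_found > season) next
        w <- node$w * a[tau]
        total <- total + w
        nxt[[length(nxt) + 1L]] <- list(t0 = t_found, w = w)
      }
    }
    frontier <- nxt
  }
  total
}

# Plain stochastic renewal simulation of a single-prey foraging bout
# (no conspecific prey): renewal cycles with exponential duration of mean
# tau_s + p_b * tau_b, one heterospecific prey consumed per cycle with
# probability p_b. The cycle count is then Poisson, so the simulated mean
# is an unbiased estimate of minutes / cycle-time * p_b ... the single-prey
# Holling disc consumption.
simulate_single_prey_bout <- function(p_b, tau_s, tau_b, minutes) {
  cyc <- tau_s + p_b * tau_b
  n <- 0L
  t <- rexp(1, 1 / cyc)
  while (t < minutes) {
    n <- n + rbinom(1, 1, p_b)
    t <- t + rexp(1, 1 / cyc)
  }
  n
}

# Minimal stand-in territory schedule carrying a prescribed departure
# kernel, for exercising the renewal recursion with hand-chosen kernels.
fake_schedule <- function(a, lh) {
  structure(
    list(a = a, e = a, steps = NULL, life_history = lh),
    class = "territory_schedule"
  )
}

expect_all_close <- function(x, y, tol = 1e-9) {
  expect_true(all(abs(x - y) <= tol * pmax(abs(y), 1)))
}
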