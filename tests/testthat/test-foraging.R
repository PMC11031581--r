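fp_real <- real_parameters()$foraging

test_that("no attacks or no time means no consumption", {
  zero <- tibble::tibble(consumed_c3 = 0, consumed_c4 = 0,
                         consumed_c5 = 0, consumed_het = 0)
  rec <- functional_response(c(10, 5, 2), pref = c(0, 0), fp = fp_real,
                             minutes = 4800)
  expect_equal(as.data.frame(rec), as.data.frame(zero))
  rec <- functional_response(c(10, 5, 2), pref = c(1, 1), fp = fp_real,
                             minutes = 0)
  expect_equal(as.data.frame(rec), as.data.frame(zero))
  expect_error(functional_response(c(-1, 0, 0), pref = c(1, 1),
                                   fp = fp_real, minutes = 100), ">= 0")
})

test_that("single-prey consumption follows the Holling disc closed form", {
  # with no conspecific prey the cycle is exactly tau_s + p_b * tau_b
  rec <- functional_response(c(0, 0, 0), y = 16.8, pref = c(0, 1),
                             fp = fp_real, minutes = 4800)
  expect_equal(rec$consumed_het,
               4800 / (fp_real$tau_s + fp_real$tau_b), tolerance = 1e-12)
  expect_equal(rec$consumed_c3 + rec$consumed_c4 + rec$consumed_c5, 0)

  # and an independent stochastic renewal simulation agrees in the mean
  set.seed(101)
  n <- 4000
  draws <- replicate(n, simulate_single_prey_bout(
    1, fp_real$tau_s, fp_real$tau_b, 4800))
  se <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - rec$consumed_het), 3 * se)
})

test_that("consumption is monotone in activity time and preferences", {
  for (seed in 1:10) {
    fp <- random_parameters(seed)$foraging
    avail <- c(20, 10, 5)
    cons_tot <- function(p_a, p_b, minutes) {
      r <- functional_response(avail, pref = c(p_a, p_b), fp = fp,
                               minutes = minutes)
      c(con = r$consumed_c3 + r$consumed_c4 + r$consumed_c5,
        het = r$consumed_het)
    }
    t_grid <- c(0, 500, 2000, 4800)
    tt <- vapply(t_grid, function(m) cons_tot(0.6, 0.6, m), numeric(2))
    expect_true(all(diff(tt["con", ]) >= -1e-9))
    expect_true(all(diff(tt["het", ]) >= -1e-9))
    pa_grid <- seq(0, 1, length.out = 5)
    pp <- vapply(pa_grid, function(p) cons_tot(p, 0.6, 2000), numeric(2))
    expect_true(all(diff(pp["con", ]) >= -1e-9))
  }
})

test_that("consumption never exceeds availability or the time budget", {
  for (seed in 11:30) {
    fp <- random_parameters(seed)$foraging
    avail <- runif(3, 0, 30)
    r <- functional_response(avail, pref = c(runif(1), runif(1)), fp = fp,
                             minutes = 4800)
    cons <- c(r$consumed_c3, r$consumed_c4, r$consumed_c5)
    expect_true(all(cons <= avail + 1e-9))
    expect_true(all(cons >= 0) && r$consumed_het >= 0)
    # handling time alone cannot exceed the activity window
    k <- c(fp$k3, fp$k4, fp$k5)
    handling <- sum(cons / pmax(k, 1e-12)) * fp$tau_a +
      r$consumed_het * fp$tau_b
    expect_lte(handling, 4800 + 1e-6)
  }
})

test_that("deterministic consumption matches the stochastic bout in the mean", {
  # dual route: RK4 depletion kernel vs the event-level jump process
  for (seed in c(3, 14, 27)) {
    fp <- random_parameters(seed)$foraging
    set.seed(seed + 1000)
    avail <- round(runif(3, 40, 120))
    p_a <- runif(1, 0, 0.4); p_b <- runif(1, 0.3, 1)
    det <- functional_response(avail, pref = c(p_a, p_b), fp = fp,
                               minutes = 2400)
    n <- 600
    sims <- replicate(n, unlist(
      cannfor:::simulate_bout(avail, fp$y, p_a, p_b, fp, 2400)))
    tot_det <- det$consumed_c3 + det$consumed_c4 + det$consumed_c5
    tot_sim <- sims["consumed1", ] + sims["consumed2", ] + sims["consumed3", ]
    expect_lt(abs(mean(tot_sim) - tot_det),
              3 * sd(tot_sim) / sqrt(n) + 1e-9)
    expect_lt(abs(mean(sims["het", ]) - det$consumed_het),
              3 * sd(sims["het", ]) / sqrt(n) + 1e-9)
  }
})

test_that("the numerical response applies the conversion coefficients", {
  one <- function(...) {
    rec <- tibble::tibble(consumed_c3 = 0, consumed_c4 = 0,
                          consumed_c5 = 0, consumed_het = 0)
    rec[names(list(...))] <- list(...)
    rec
  }
  expect_equal(numerical_response(one(consumed_c3 = 1), fp_real), 0.91)
  expect_equal(numerical_response(one(consumed_het = 1), fp_real), 0.44)
  expect_equal(numerical_response(one(), fp_real), 0)
  expect_equal(
    numerical_response(one(consumed_c4 = 2, consumed_c5 = 0.5,
                           consumed_het = 3), fp_real),
    2 * 3.00 + 0.5 * 6.14 + 3 * 0.44
  )
  expect_error(numerical_response(tibble::tibble(x = 1), fp_real),
               "consumed_")
})
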