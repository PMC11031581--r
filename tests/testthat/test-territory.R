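p_real <- real_parameters()

test_that("no attacking means no eggs, no daughters, zero fitness", {
  sched <- run_focal_female(c(0, 0), p_real$foraging, p_real$life_history)
  expect_true(all(sched$e == 0))
  expect_true(all(sched$a == 0))
  expect_equal(life_reproductive_success(sched), 0)
})

test_that("without cannibalism every hatched nymph leaves as an adult", {
  for (p_b in c(0.3, 1)) {
    sched <- run_focal_female(c(0, p_b), p_real$foraging,
                              p_real$life_history)
    expect_equal(sched$a, sched$e, tolerance = 1e-12)
    expect_true(all(sched$e > 0))
  }
})

test_that("one-cycle hand calculation reproduces the single-step schedule", {
  # one reproductive step, one heterospecific prey unit, search and
  # handling each 2400 min: exactly one consumed prey in the 4800-min
  # window, so e(1) = b and the daughter cohort leaves intact
  fp <- foraging_params(y = 1, b = 0.44, tau_a = 10, tau_b = 2400,
                        tau_s = 2400, k3 = 1, k4 = 1, k5 = 1,
                        a3 = 1, a4 = 1, a5 = 1)
  lh <- life_history(reproductive_units = 1)
  sched <- run_focal_female(c(0, 1), fp, lh)
  expect_equal(sched$e[1], 0.44 * 1, tolerance = 1e-12)
  expect_equal(sched$a[1], sched$e[1])
  expect_equal(life_reproductive_success(sched), 0.44, tolerance = 1e-12)
})

test_that("cannibalism cannot start before the first eggs hatch", {
  sched <- run_focal_female(c(1, 1), p_real$foraging, p_real$life_history)
  stp <- sched$steps
  hatch_step <- p_real$life_history$egg_units + 1L
  early <- stp$step < hatch_step
  expect_true(all(stp$consumed_c3[early] == 0))
  expect_true(all(stp$consumed_c4[early] == 0))
  expect_true(all(stp$consumed_c5[early] == 0))
  expect_gt(stp$consumed_c3[stp$step == hatch_step], 0)
})

test_that("each cohort conserves: leaving = hatched - consumed", {
  for (seed in 1:8) {
    prm <- random_parameters(seed)
    pref <- c(runif(1), runif(1))
    sched <- run_focal_female(pref, prm$foraging, prm$life_history)
    eaten_per_cohort <- rowSums(sched$consumed)
    expect_all_close(sched$a, sched$e - eaten_per_cohort, tol = 1e-9)
    expect_true(all(sched$a >= -1e-12))
    # consumption stops with the mother's death
    L <- prm$life_history$reproductive_units
    expect_true(all(sched$steps$consumed_het[sched$steps$step > L] == 0))
  }
})

test_that("per-egg survival never increases with the cannibalism rate", {
  for (seed in c(2, 5)) {
    prm <- random_parameters(seed)
    surv_frac <- vapply(seq(0, 1, by = 0.25), function(p_a) {
      s <- run_focal_female(c(p_a, 0.8), prm$foraging, prm$life_history)
      if (sum(s$e) == 0) return(1)
      sum(s$a) / sum(s$e)
    }, numeric(1))
    expect_true(all(diff(surv_frac) <= 1e-9))
  }
})

test_that("the schedule table mirrors the cohort bookkeeping", {
  sched <- run_focal_female(c(0.17, 1), p_real$foraging,
                            p_real$life_history)
  stp <- tidy(sched)
  L <- p_real$life_history$reproductive_units
  expect_equal(nrow(stp), L + 5L)
  expect_equal(stp$e[seq_len(L)], sched$e)
  # cohorts drift one column per step: c4 today is yesterday's c3 minus
  # yesterday's cohort-3 consumption
  for (t in 2:nrow(stp)) {
    expect_equal(stp$c4[t], stp$c3[t - 1] - stp$consumed_c3[t - 1],
                 tolerance = 1e-9)
    expect_equal(stp$c5[t], stp$c4[t - 1] - stp$consumed_c4[t - 1],
                 tolerance = 1e-9)
  }
  expect_equal(sum(stp$a), life_reproductive_success(sched))

  g <- glance(sched)
  expect_equal(g$x_fitness, sum(sched$a))
  expect_equal(g$hatched, sum(sched$e))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_schedule_tsv(sched, path)
  back <- read.delim(path)
  expect_equal(back$e, stp$e, tolerance = 1e-12)
  expect_equal(nrow(back), nrow(stp))
})

test_that("autoplot returns a ggplot of the schedule", {
  sched <- run_focal_female(c(0.2, 1), p_real$foraging,
                            p_real$life_history)
  expect_s3_class(autoplot(sched), "ggplot")
})
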