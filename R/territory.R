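#' Run the single-focal-female territory recursion
#'
#' Simulates one female ("the mother") on her territory over her whole
#' reproductive life and until her last egg cohort has matured. Each step
#' while she is alive: (1) she forages on the cannibalizable nymph cohorts
#' present plus the constant heterospecific availability
#' ([functional_response()]); (2) consumed nymphs are removed; (3) the
#' consumption is converted into the newly hatched nymph cohort `e(t)` of
#' that step ([numerical_response()]); (4) every cohort advances one stage.
#' A cohort laid at maternal age `tau` hatches into the first cannibalizable
#' cohort `egg_units` steps later and leaves the territory as adult
#' daughters `a(tau)` after the full development time. After the mother's
#' death no cannibalism occurs and the remaining cohorts mature unharmed.
#'
#' @param pref A [prey_preference()] or numeric `c(p_a, p_b)`.
#' @param fp A [foraging_params()] object.
#' @param lh A [life_history()] object.
#' @param steps RK4 substeps for within-step depletion (see
#'   [functional_response()]).
#' @param table If `FALSE`, skip building the per-step tibble (used
#'   internally by the grid sweeps; `$steps` is then `NULL`).
#' @return A `territory_schedule` object: a list with the per-step tibble
#'   `$steps` (columns `step`, `age`, `e`, `c1`..`c6`,
#'   `consumed_c3`..`consumed_c5`, `consumed_het`, `a`), the laying vector
#'   `$e` and departure vector `$a` indexed by maternal age, and the
#'   parameters used.
#' @examples
#' p <- real_parameters()
#' sched <- run_focal_female(c(0.17, 1), p$foraging, p$life_history)
#' life_reproductive_success(sched)
#' @export
run_focal_female <- function(pref, fp, lh = life_history(), steps = 16L,
                             table = TRUE) {
  pref <- as_preference(pref)
  validate_parameters(fp, lh)
  L <- lh$reproductive_units
  E <- lh$egg_units
  nu <- lh$nymph_units
  D <- development_units(lh)
  ## stage-class of a cohort of age s (steps since laying):
  ## 0..E-1 egg; then nymph classes 3,4,5; age D leaves
  cls_of_age <- c(rep(1L, E), rep(3L, nu[1]), rep(4L, nu[2]), rep(5L, nu[3]))

  n_steps <- L + D
  surv <- numeric(L)                 # survivors of the cohort laid at age tau
  e <- numeric(L)
  cons_mat <- matrix(0, nrow = L, ncol = n_steps) # consumed[tau, t]
  rec <- matrix(0, nrow = n_steps, ncol = 12L)    # per-step bookkeeping

  for (t in seq_len(n_steps)) {
    ## counts present at step start, by class
    cnt <- c(0, 0, 0, 0, 0)          # egg(young), egg(old), c3, c4, c5
    share <- list(c3 = numeric(L), c4 = numeric(L), c5 = numeric(L))
    for (tau in seq_len(min(t, L))) {
      s <- t - tau
      if (s >= D || s < 0) next
      cl <- cls_of_age[s + 1L]
      if (cl == 1L) {
        if (s > 0L) cnt[2] <- cnt[2] + surv[tau]  # age-0 eggs are laid below
      } else {
        cnt[cl] <- cnt[cl] + surv[tau]
        share[[cl - 2L]][tau] <- surv[tau]
      }
    }
    avail <- cnt[3:5]

    consumed <- c(0, 0, 0); het <- 0; laid <- 0
    if (t <= L) {
      fr <- forage_kernel(avail, fp$y, pref$p_a, pref$p_b, fp,
                          lh$activity_minutes, steps)
      consumed <- fr$consumed
      het <- fr$het
      ## remove consumed nymphs, pro rata across the cohorts in each class
      for (j in 1:3) {
        if (consumed[j] <= 0) next
        w <- share[[j]]
        tot <- sum(w)
        if (tot <= 0) next
        take <- consumed[j] * w / tot
        surv <- surv - take
        cons_mat[, t] <- cons_mat[, t] + take
      }
      laid <- fp$a3 * consumed[1] + fp$a4 * consumed[2] +
        fp$a5 * consumed[3] + fp$b * het
      e[t] <- laid
      surv[t] <- laid
    }

    leaving <- 0
    tau_leave <- t - D
    if (tau_leave >= 1 && tau_leave <= L) leaving <- surv[tau_leave]

    rec[t, ] <- c(laid, laid, cnt[2], cnt[3], cnt[4], cnt[5], leaving,
                  consumed[1], consumed[2], consumed[3], het, leaving)
  }

  steps_tbl <- NULL
  if (table) {
    steps_tbl <- tibble(
      step = seq_len(n_steps),
      age = c(seq_len(L), rep(NA_integer_, D)),
      e = rec[, 1], c1 = rec[, 2], c2 = rec[, 3], c3 = rec[, 4],
      c4 = rec[, 5], c5 = rec[, 6], c6 = rec[, 7],
      consumed_c3 = rec[, 8], consumed_c4 = rec[, 9],
      consumed_c5 = rec[, 10], consumed_het = rec[, 11], a = rec[, 12]
    )
  }

  structure(
    list(
      steps = steps_tbl,
      e = e,
      a = surv,          # survivors of each laid cohort = daughters leaving
      consumed = cons_mat,
      pref = pref,
      foraging = fp,
      life_history = lh
    ),
    class = "territory_schedule"
  )
}

#' Life reproductive success of the focal female
#'
#' The total number of adult daughters that leave the focal female's
#' territory over her whole life, `X = sum(a(tau))` -- equivalently, all
#' nymphs she hatched minus all nymphs she cannibalized (there is no other
#' mortality in the model).
#'
#' @param sched A `territory_schedule` from [run_focal_female()].
#' @return The scalar fitness `X`.
#' @export
life_reproductive_success <- function(sched) {
  stopifnot(inherits(sched, "territory_schedule"))
  sum(sched$a)
}

#' @export
print.territory_schedule <- function(x, ...) {
  cat("<territory_schedule>\n")
  cat(sprintf("  preference (p_a, p_b) = (%g, %g)\n",
              x$pref$p_a, x$pref$p_b))
  cat(sprintf("  hatched per age: %s\n",
              paste(sprintf("%.3g", x$e), collapse = " ")))
  cat(sprintf("  leaving per age: %s\n",
              paste(sprintf("%.3g", x$a), collapse = " ")))
  cat(sprintf("  life reproductive success X = %.6g\n", sum(x$a)))
  invisible(x)
}

#' @export
tidy.territory_schedule <- function(x, ...) x$steps

#' @export
glance.territory_schedule <- function(x, ...) {
  tibble(
    x_fitness = sum(x$a),
    hatched = sum(x$e),
    consumed_conspecific = sum(x$consumed),
    consumed_het = sum(x$steps$consumed_het)
  )
}

#' @export
autoplot.territory_schedule <- function(object, ...) {
  L <- object$life_history$reproductive_units
  df <- tibble(
    age = rep(seq_len(L), 2L),
    count = c(object$e, object$a),
    what = rep(c("hatched e(tau)", "daughters leaving a(tau)"), each = L)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$count,
                                   colour = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "maternal reproduction age (time units)",
                  y = "individuals", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Export a territory schedule as tidy TSV
#'
#' Writes the per-step table of [run_focal_female()] (one row per time step,
#' mirroring the biological scheme table of the model) to a tab-separated
#' file.
#'
#' @param sched A `territory_schedule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_tsv <- function(sched, path) {
  stopifnot(inherits(sched, "territory_schedule"))
  write.table(sched$steps, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
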