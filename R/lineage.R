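#' Reproductive-season growth rate of a lineage (Eve's descendants)
#'
#' Computes `Z`, the number of descendants a focal female ("Eve") obtains
#' over one reproductive season, from the per-female production schedule via
#' a renewal recursion over the descendants tree.
#'
#' Because every female of the lineage shares the phenotype and an identical
#' territory environment (the heterospecific availability is fixed), each
#' founder repeats the same schedule time-shifted. A daughter hatched from
#' an egg laid at maternal age `tau` leaves her natal territory
#' `development_units` steps after laying and founds her own territory
#' `migration_units` steps later, so founders obey
#' `f(t) = sum_tau a(tau) f(t - tau - development - migration + 1)` with
#' `f(1) = 1` (Eve founds at step 1). `Z` counts the nodes of the
#' descendants tree: every descendant female that has established her own
#' territory by the end of the season, Eve herself excluded.
#'
#' @inheritParams run_focal_female
#' @param sched Optionally, a precomputed `territory_schedule` (its
#'   parameters are reused); otherwise one is computed from `pref`, `fp`,
#'   `lh`.
#' @return The scalar fitness `Z`.
#' @examples
#' p <- real_parameters()
#' season_growth(c(0, 1), p$foraging, p$life_history)
#' @export
season_growth <- function(pref, fp, lh = life_history(), steps = 16L,
                          sched = NULL) {
  tr <- lineage_trace(pref, fp, lh, steps = steps, sched = sched,
                      totals = FALSE)
  sum(tr$new_founders) - 1
}

#' Per-step expansion of the descendants tree
#'
#' Diagnostic view of the renewal recursion behind [season_growth()]:
#' founders per step, cumulative established descendants, and (optionally)
#' the total living population summed over all descendant territories.
#'
#' @inheritParams season_growth
#' @param totals If `TRUE`, also convolve the per-territory stage occupancy
#'   with the founder counts to report per-step totals of eggs, nymphs and
#'   departing adults across the whole lineage.
#' @return A tibble with columns `step`, `new_founders`, `established`
#'   (cumulative founders including Eve) and, if `totals = TRUE`, `eggs`,
#'   `nymphs`, `leaving`.
#' @export
lineage_trace <- function(pref, fp, lh = life_history(), steps = 16L,
                          sched = NULL, totals = TRUE) {
  if (is.null(sched)) {
    sched <- run_focal_female(pref, fp, lh, steps = steps)
  } else {
    stopifnot(inherits(sched, "territory_schedule"))
    lh <- sched$life_history
  }
  a <- sched$a
  L <- lh$reproductive_units
  Tn <- lh$season_units
  d <- development_units(lh) + lh$migration_units

  f <- numeric(Tn)
  f[1] <- 1
  if (Tn >= 2) {
    for (t in 2:Tn) {
      acc <- 0
      for (tau in seq_len(L)) {
        j <- t - tau - d + 1L  # mother founded at j lays e(tau) at j + tau - 1
        if (j >= 1) acc <- acc + a[tau] * f[j]
      }
      f[t] <- acc
    }
  }

  out <- tibble(step = seq_len(Tn), new_founders = f,
                established = cumsum(f))
  if (totals) {
    stp <- sched$steps
    n_local <- nrow(stp)
    eggs_u <- stp$e + stp$c2
    nymphs_u <- stp$c3 + stp$c4 + stp$c5
    leave_u <- stp$a
    conv <- function(u) {
      v <- numeric(Tn)
      for (t0 in seq_len(Tn)) {
        if (f[t0] == 0) next
        idx <- seq_len(min(n_local, Tn - t0 + 1L))
        v[t0 + idx - 1L] <- v[t0 + idx - 1L] + f[t0] * u[idx]
      }
      v
    }
    out$eggs <- conv(eggs_u)
    out$nymphs <- conv(nymphs_u)
    out$leaving <- conv(leave_u)
  }
  out
}

#' Export a lineage trace as TSV
#'
#' @param trace A tibble from [lineage_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  write.table(trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
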