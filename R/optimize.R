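#' Fitness surface over prey-preference space
#'
#' Evaluates a fitness functional -- life reproductive success `X`
#' ([life_reproductive_success()]) or reproductive-season growth rate `Z`
#' ([season_growth()]) -- on a uniform `grid_n` x `grid_n` grid of
#' preference pairs `(p_a, p_b)` in `[0, 1]^2` (grid points `i/(grid_n-1)`)
#' and records the maximizing grid point. Ties are broken towards the
#' smallest `p_a`, then the smallest `p_b`.
#'
#' @param kind `"X"` or `"Z"`.
#' @param fp A [foraging_params()] object.
#' @param lh A [life_history()] object.
#' @param grid_n Number of grid points per axis (>= 2, default 100 so that
#'   grid points are `i/99`).
#' @param steps RK4 substeps of the within-step depletion integration.
#' @return A `fitness_surface` object: tibble with columns `p_a`, `p_b`,
#'   `fitness`, plus attributes `kind`, `argmax` (named vector), `max`.
#' @examples
#' p <- illustrative_parameters()
#' surf <- fitness_surface("X", p$foraging, p$life_history, grid_n = 12)
#' glance(surf)
#' @export
fitness_surface <- function(kind = c("X", "Z"), fp, lh = life_history(),
                            grid_n = 100L, steps = 16L) {
  kind <- match.arg(kind)
  if (!is.numeric(grid_n) || length(grid_n) != 1L || grid_n < 2) {
    abort("`grid_n` must be an integer >= 2")
  }
  validate_parameters(fp, lh)
  grid_n <- as.integer(grid_n)
  pts <- (seq_len(grid_n) - 1L) / (grid_n - 1L)

  vals <- matrix(NA_real_, nrow = grid_n, ncol = grid_n)
  best <- -Inf
  arg <- c(p_a = NA_real_, p_b = NA_real_)
  for (i in seq_len(grid_n)) {       # p_a ascending (outer)
    for (j in seq_len(grid_n)) {     # p_b ascending (inner)
      sched <- run_focal_female(c(pts[i], pts[j]), fp, lh, steps = steps,
                                table = FALSE)
      v <- if (kind == "X") {
        sum(sched$a)
      } else {
        season_growth(NULL, fp, lh, sched = sched)
      }
      vals[i, j] <- v
      if (v > best) {                # strict: first max wins the tie-break
        best <- v
        arg <- c(p_a = pts[i], p_b = pts[j])
      }
    }
  }

  out <- tibble(
    p_a = rep(pts, each = grid_n),
    p_b = rep(pts, times = grid_n),
    fitness = as.vector(t(vals))
  )
  structure(out,
            class = c("fitness_surface", class(out)),
            kind = kind, argmax = arg, max = best, grid_n = grid_n)
}

#' @export
print.fitness_surface <- function(x, ...) {
  am <- attr(x, "argmax")
  cat(sprintf("<fitness_surface %s> %d x %d grid\n",
              attr(x, "kind"), attr(x, "grid_n"), attr(x, "grid_n")))
  cat(sprintf("  max %s = %.6g at (p_a, p_b) = (%.4f, %.4f)\n",
              attr(x, "kind"), attr(x, "max"), am[["p_a"]], am[["p_b"]]))
  NextMethod()
}

#' @export
tidy.fitness_surface <- function(x, ...) {
  tibble(p_a = x$p_a, p_b = x$p_b, fitness = x$fitness)
}

#' @export
glance.fitness_surface <- function(x, ...) {
  am <- attr(x, "argmax")
  tibble(
    kind = attr(x, "kind"),
    p_a_opt = am[["p_a"]],
    p_b_opt = am[["p_b"]],
    maximum = attr(x, "max"),
    grid_n = attr(x, "grid_n")
  )
}

#' @export
autoplot.fitness_surface <- function(object, ...) {
  am <- attr(object, "argmax")
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$p_a, y = .data$p_b,
                               fill = .data$fitness)) +
    ggplot2::geom_raster() +
    ggplot2::annotate("point", x = am[["p_a"]], y = am[["p_b"]],
                      shape = 4, colour = "white", size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "conspecific preference p_a",
      y = "heterospecific preference p_b",
      fill = attr(object, "kind")
    ) +
    ggplot2::theme_minimal()
}

#' Compare the optima of the two fitness definitions
#'
#' Runs both fitness surfaces on the same grid and reports the paired
#' optima: the preference maximizing life reproductive success `X` and the
#' preference maximizing the reproductive-season growth rate `Z`. With the
#' laboratory-estimated parameters the `X`-optimal cannibalism rate is
#' positive while the `Z`-optimal one is zero -- partial filial cannibalism
#' maximizes individual reproductive success but not the descendant count
#' at season end.
#'
#' @inheritParams fitness_surface
#' @return A tibble with one row per fitness kind: `kind`, `p_a_opt`,
#'   `p_b_opt`, `maximum`, `grid_n`.
#' @export
compare_fitness_optima <- function(fp, lh = life_history(), grid_n = 100L,
                                   steps = 16L) {
  sx <- fitness_surface("X", fp, lh, grid_n = grid_n, steps = steps)
  sz <- fitness_surface("Z", fp, lh, grid_n = grid_n, steps = steps)
  dplyr::bind_rows(glance(sx), glance(sz))
}

#' Export a fitness surface as TSV / its argmax as JSON
#'
#' @param surface A `fitness_surface`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surface_tsv <- function(surface, path) {
  write.table(tidy(surface), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_surface_tsv
#' @export
write_argmax_json <- function(surface, path) {
  am <- attr(surface, "argmax")
  jsonlite::write_json(
    list(kind = attr(surface, "kind"),
         p_a = am[["p_a"]], p_b = am[["p_b"]],
         maximum = attr(surface, "max"),
         grid_n = attr(surface, "grid_n")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
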