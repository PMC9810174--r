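# Figure colour conventions: B1 purple, B2 green, B3 orange; inactive cells
# drawn lighter.
.pop_colours <- c(B1 = "#7B3294", B2 = "#008837", B3 = "#E66101")

#' @export
print.ecology_preset <- function(x, ...) {
  cat("Ecology preset:", x$name,
      sprintf("[%s]\n", paste(x$interaction_signs, collapse = ",")))
  cat("Substrates (bulk mol/L):",
      paste(sprintf("%s=%.3g", x$substrates$name, x$substrates$bulk),
            collapse = ", "), "\n")
  cat("Stoichiometry (mol S / mol X):\n")
  print(round(x$stoichiometry, 3))
  invisible(x)
}

#' @export
print.aggresim_config <- function(x, ...) {
  cat("Aggregate simulation config\n")
  cat("  ecology:", x$ecology$name, "| seed:", x$seed,
      "| end time:", x$end_time, "h\n")
  cat("  inoculum:", x$n_cells, "cells in", x$inoculum_diameter, "um disc\n")
  cat("  grid:", x$grid$nx, "x", x$grid$ny, "nodes at h =", x$grid$h, "um\n")
  if (!is.null(x$detachment_radius)) {
    cat("  detachment radius:", x$detachment_radius, "um\n")
  }
  invisible(x)
}

#' @export
print.aggresim_trajectory <- function(x, ...) {
  last <- x$summary[nrow(x$summary), ]
  cat("Aggregate trajectory:", x$config$ecology$name, "| seed",
      x$config$seed, "\n")
  cat(sprintf("  %d snapshots to t = %.1f h; %d cells (%d active), R = %.1f um\n",
              nrow(x$summary), last$time, last$n_cells, last$n_active,
              last$radius))
  if (isTRUE(x$steady)) {
    cat(sprintf("  steady state reached at t = %.1f h\n", x$steady_time))
  } else {
    cat("  steady state not reached\n")
  }
  if (isTRUE(x$truncated)) cat("  (run truncated at the grid limit)\n")
  invisible(x)
}

#' @export
summary.aggresim_trajectory <- function(object, ...) {
  object$summary
}

#' @export
print.residual_report <- function(x, ...) {
  cat("Pseudo-steady-state residuals (", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", ")\n")
  print(signif(x$max_abs_residual, 3))
  invisible(x)
}

#' Plot a trajectory's community time course
#'
#' @param x an `aggresim_trajectory`
#' @param type `"abundance"` (active relative abundances), `"fitness"`
#'   (median growth rates) or `"radius"`
#' @param ... passed to [graphics::matplot()]
#' @return the input, invisibly
#' @export
plot.aggresim_trajectory <- function(x, type = c("abundance", "fitness",
                                                 "radius"), ...) {
  type <- match.arg(type)
  s <- x$summary
  pops <- x$snapshots[[1L]]$populations
  cols <- .pop_colours[pops]
  if (type == "radius") {
    plot.default(s$time, s$radius, type = "l", xlab = "time (h)",
                 ylab = "aggregate radius (um)", ...)
  } else {
    pre <- if (type == "abundance") "abund_" else "mu_"
    ylab <- if (type == "abundance") "active relative abundance" else
      "median growth rate (1/h)"
    mat <- as.matrix(s[, paste0(pre, pops)])
    matplot(s$time, mat, type = "l", lty = 1, col = cols,
            xlab = "time (h)", ylab = ylab, ...)
    legend("topright", legend = pops, col = cols, lty = 1, bty = "n")
  }
  invisible(x)
}

#' Draw an aggregate snapshot
#'
#' Cells are drawn as filled circles coloured by population; inactive cells
#' in a lighter shade.
#'
#' @param x an `aggresim_snapshot`
#' @param ... passed to [graphics::symbols()]
#' @return the input, invisibly
#' @export
plot.aggresim_snapshot <- function(x, ...) {
  cells <- x$cells
  r <- if (!is.null(x$ecology)) {
    rho <- vapply(x$ecology$populations, `[[`, numeric(1),
                  "rho")[cells$population]
    radius_from_mass(cells$mass, rho)
  } else rep(0.5, nrow(cells))
  cols <- .pop_colours[cells$population]
  cols[is.na(cols)] <- "grey40"
  cols[!cells$active] <- adjustcolor(cols[!cells$active], alpha.f = 0.3)
  lim <- x$radius * 1.1
  symbols(cells$x, cells$y, circles = r, inches = FALSE, bg = cols,
          fg = NA, xlim = x$centre[1L] + c(-lim, lim),
          ylim = x$centre[2L] + c(-lim, lim), xlab = "x (um)",
          ylab = "y (um)", asp = 1, ...)
  invisible(x)
}
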