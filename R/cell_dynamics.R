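#' Actual growth rate of a cell from local conditions
#'
#' Multiplicative Monod kinetics over the consumed substrates, optional
#' inhibition factors, minus the maintenance coefficient:
#' `mu = mu_max * prod(phi / (K_S + phi)) * prod(K_I / (K_I + phi)) - b`.
#' The result may be negative (net decay under starvation).
#'
#' @param local_conc named numeric vector of local concentrations (mol/L);
#'   must cover the consumed substrates and any configured inhibitors
#' @param spec a [population_spec()]
#' @return growth rate in 1/h
#' @examples
#' sp <- population_spec("P", mu_max = 1, K_S = c(S = 1), b_max = 0,
#'                       Y_XS = 1, rho = 1e-14, M_max = 1e-13,
#'                       M_min = 1e-14, stoichiometry = c(S = -1))
#' growth_rate(c(S = 1), sp) # 0.5 at half saturation
#' @export
growth_rate <- function(local_conc, spec) {
  stopifnot(inherits(spec, "population_spec"))
  stopifnot(all(local_conc >= 0))
  mu <- spec$mu_max
  for (s in names(spec$K_S)) {
    if (!s %in% names(local_conc)) {
      stop("missing local concentration for substrate ", s)
    }
    phi <- local_conc[[s]]
    mu <- mu * phi / (spec$K_S[[s]] + phi)
  }
  for (s in names(spec$K_I)) {
    if (!s %in% names(local_conc)) {
      stop("missing local concentration for inhibitor ", s)
    }
    phi <- local_conc[[s]]
    mu <- mu * spec$K_I[[s]] / (spec$K_I[[s]] + phi)
  }
  unname(mu - spec$b_max)
}

# Vectorised growth rates for all cells of one population.
# conc: matrix [n_cells x n_substrates] of local concentrations (mol/L),
# columns named. Returns net growth rate (1/h) per cell.
.growth_rate_many <- function(conc, spec) {
  mu <- rep(spec$mu_max, nrow(conc))
  for (s in names(spec$K_S)) {
    phi <- conc[, s]
    mu <- mu * phi / (spec$K_S[[s]] + phi)
  }
  for (s in names(spec$K_I)) {
    phi <- conc[, s]
    mu <- mu * spec$K_I[[s]] / (spec$K_I[[s]] + phi)
  }
  mu - spec$b_max
}

#' Advance a cell's mass by one forward-Euler step
#'
#' `X <- X * (1 + mu * dt)`, floored at zero.
#'
#' @param cell one row of a cell table (or any list with a `mass` element)
#' @param mu growth rate, 1/h
#' @param dt_bac biological time step, h
#' @return the cell with updated mass
#' @export
integrate_mass <- function(cell, mu, dt_bac) {
  stopifnot(dt_bac > 0)
  cell$mass <- pmax(cell$mass * (1 + mu * dt_bac), 0)
  cell
}

#' Cell radius from mass
#'
#' Perfect spherical shape at fixed cell density:
#' `r = (mass / rho * 3 / (4 * pi))^(1/3)`.
#'
#' @param mass cell mass, mol (vectorised)
#' @param rho cell density, mol/um^3
#' @return radius in um
#' @export
radius_from_mass <- function(mass, rho) {
  stopifnot(all(mass >= 0), rho > 0)
  (mass / rho * 3 / (4 * pi))^(1 / 3)
}

#' Check a cell for division
#'
#' A cell at or above the division mass `M_max` splits: the daughter receives
#' a stochastic fraction `alpha ~ U(0.45, 0.55)` of the parent's mass and is
#' placed adjacent to the parent (centre distance equal to the sum of the
#' post-split radii) at a uniformly random angle; the parent keeps the
#' remainder. Total mass is conserved exactly.
#'
#' @param cell one row of a cell table
#' @param spec the cell's [population_spec()]
#' @return `NULL` if the cell is below `M_max`, otherwise a `division_event`
#'   list with elements `parent`, `daughter` (updated/new cell rows), `alpha`
#'   and `angle`
#' @export
maybe_divide <- function(cell, spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (cell$mass < spec$M_max) return(NULL)
  alpha <- runif(1, 0.45, 0.55)
  angle <- runif(1, 0, 2 * pi)
  m_d <- alpha * cell$mass
  m_p <- (1 - alpha) * cell$mass
  r_d <- radius_from_mass(m_d, spec$rho)
  r_p <- radius_from_mass(m_p, spec$rho)
  daughter <- cell
  daughter$mass <- m_d
  daughter$x <- cell$x + (r_p + r_d) * cos(angle)
  daughter$y <- cell$y + (r_p + r_d) * sin(angle)
  parent <- cell
  parent$mass <- m_p
  structure(list(parent = parent, daughter = daughter,
                 alpha = alpha, angle = angle),
            class = "division_event")
}

# Divide every over-threshold cell in the table. Cells are processed in id
# order so the draw sequence (hence the run) is deterministic given the seed.
process_divisions <- function(cells, ecology) {
  specs <- ecology$populations
  thr <- vapply(specs, `[[`, numeric(1), "M_max")[cells$population]
  idx <- which(cells$active & cells$mass >= thr)
  if (!length(idx)) return(cells)
  idx <- idx[order(cells$id[idx])]
  new_rows <- vector("list", length(idx))
  next_id <- max(cells$id)
  for (k in seq_along(idx)) {
    i <- idx[k]
    ev <- maybe_divide(cells[i, ], specs[[cells$population[i]]])
    cells$mass[i] <- ev$parent$mass
    d <- ev$daughter
    next_id <- next_id + 1L
    d$id <- next_id
    new_rows[[k]] <- d
  }
  rbind(cells, do.call(rbind, new_rows))
}

#' Update a cell's activity state
#'
#' Active cells whose mass has fallen to the inactivation threshold `M_min`
#' become inactive: they neither grow nor decay and contribute nothing to the
#' reaction term. Inactive cells become active again when the provisional
#' growth rate evaluated from their current local conditions is positive.
#'
#' @param cell one row of a cell table
#' @param mu provisional growth rate at the cell's location, 1/h
#' @param spec the cell's [population_spec()]
#' @return the cell with updated `active` flag
#' @export
update_activity <- function(cell, mu, spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (cell$active && cell$mass <= spec$M_min) {
    cell$active <- FALSE
  } else if (!cell$active && mu > 0) {
    cell$active <- TRUE
  }
  cell
}
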