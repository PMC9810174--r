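#' Write a snapshot's cell table to CSV
#'
#' Columns: `id`, `population`, `x_um`, `y_um`, `mass_mol`, `radius_um`,
#' `mu_per_h`, `active`, plus the snapshot time as a `time_h` column.
#'
#' @param snapshot an `aggresim_snapshot`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_cells_csv <- function(snapshot, path) {
  cells <- snapshot$cells
  r <- if (!is.null(snapshot$ecology)) {
    rho <- vapply(snapshot$ecology$populations, `[[`, numeric(1),
                  "rho")[cells$population]
    radius_from_mass(cells$mass, rho)
  } else NA_real_
  out <- data.frame(id = cells$id, population = cells$population,
                    x_um = cells$x, y_um = cells$y, mass_mol = cells$mass,
                    radius_um = r, mu_per_h = cells$mu, active = cells$active,
                    time_h = snapshot$time, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a cell table written by [write_cells_csv()] back into a snapshot
#'
#' @param path CSV file
#' @param populations population names (defaults to the sorted unique
#'   labels found)
#' @return an `aggresim_snapshot` (without ecology, grid or fields)
#' @export
read_cells_csv <- function(path, populations = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cells <- data.frame(id = df$id, population = df$population, x = df$x_um,
                      y = df$y_um, mass = df$mass_mol, active = df$active,
                      mu = df$mu_per_h, stringsAsFactors = FALSE)
  if (is.null(populations)) populations <- sort(unique(cells$population))
  ctr <- aggregate_centre(cells)
  d <- sqrt((cells$x - ctr[1L])^2 + (cells$y - ctr[2L])^2)
  rad <- if (all(is.finite(df$radius_um))) max(d + df$radius_um) else max(d)
  structure(
    list(time = df$time_h[1L], cells = cells, centre = ctr, radius = rad,
         populations = populations, ecology = NULL, grid = NULL,
         fields = NULL, bulk = NULL),
    class = "aggresim_snapshot"
  )
}

#' Write concentration fields to CSV (long format)
#'
#' One row per node: `x_um`, `y_um`, then one column per substrate (mol/L).
#'
#' @param fields named list of concentration matrices
#' @param grid the [grid_spec()] the fields live on
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fields_csv <- function(fields, grid, path) {
  out <- expand.grid(x_um = grid$xc, y_um = grid$yc)
  for (s in names(fields)) out[[s]] <- as.vector(fields[[s]])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Transverse-plane concentration profile
#'
#' Extracts the substrate profiles along the horizontal line through the
#' aggregate centre (the transverse plane shown in substrate-profile
#' figures).
#'
#' @param fields named list of concentration matrices
#' @param grid the [grid_spec()]
#' @param y y-coordinate of the line, um
#' @return data frame: `x_um` plus one column per substrate (mol/L)
#' @export
transverse_profile <- function(fields, grid, y = 0) {
  j <- which.min(abs(grid$yc - y))
  out <- data.frame(x_um = grid$xc)
  for (s in names(fields)) out[[s]] <- fields[[s]][, j]
  out
}

#' Write a trajectory's per-snapshot summary to CSV
#'
#' @param trajectory an `aggresim_trajectory`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_summary_csv <- function(trajectory, path) {
  write.csv(trajectory$summary, path, row.names = FALSE)
  invisible(path)
}
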