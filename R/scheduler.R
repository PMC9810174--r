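# Total cross-sectional cell area (um^2).
.cell_area <- function(cells, ecology) {
  rho <- vapply(ecology$populations, `[[`, numeric(1),
                "rho")[cells$population]
  sum(pi * radius_from_mass(cells$mass, rho)^2)
}

# Affine radial pre-expansion of a densely packed aggregate: when cell area
# grew and the disc is packed beyond ~55% coverage, scale positions about
# the biomass centroid by the area-growth factor, leaving only local
# overlap corrections to the shoving sweeps.
.pre_expand <- function(cells, ecology, area_before) {
  area_after <- .cell_area(cells, ecology)
  if (area_after <= area_before) return(cells)
  ctr <- aggregate_centre(cells)
  R <- aggregate_radius(cells, ecology, ctr)
  coverage <- area_after / (pi * R^2)
  if (coverage < 0.55) return(cells)
  fac <- sqrt(area_after / area_before)
  cells$x <- ctr[[1L]] + fac * (cells$x - ctr[[1L]])
  cells$y <- ctr[[2L]] + fac * (cells$y - ctr[[2L]])
  cells
}

# Build an aggregate snapshot: the unit of analysis and I/O.
make_snapshot <- function(cells, ecology, grid, time, fields = NULL,
                          bulk = NULL) {
  ctr <- if (nrow(cells)) aggregate_centre(cells) else c(x = 0, y = 0)
  rad <- if (nrow(cells)) aggregate_radius(cells, ecology, ctr) else 0
  if (is.null(bulk)) bulk <- setNames(ecology$substrates$bulk,
                                      ecology$substrates$name)
  structure(
    list(time = time, cells = cells, centre = ctr, radius = rad,
         populations = names(ecology$populations), ecology = ecology,
         grid = grid, fields = fields, bulk = bulk),
    class = "aggresim_snapshot"
  )
}

# One summary row per snapshot: abundances, fitness medians, bulk values.
snapshot_summary_row <- function(cells, ecology, time, radius, bulk) {
  pops <- names(ecology$populations)
  act <- cells[cells$active, , drop = FALSE]
  n_act <- vapply(pops, function(p) sum(act$population == p), numeric(1))
  abund <- if (sum(n_act) > 0) n_act / sum(n_act) else rep(NA_real_, 3)
  mu_med <- vapply(pops, function(p) {
    v <- act$mu[act$population == p]
    if (length(v)) median(v) else NA_real_
  }, numeric(1))
  row <- data.frame(time = time, n_cells = nrow(cells), n_active = nrow(act),
                    total_mass = sum(cells$mass), radius = radius)
  for (p in pops) row[[paste0("abund_", p)]] <- abund[[p]]
  for (p in pops) row[[paste0("mu_", p)]] <- mu_med[[p]]
  for (s in names(bulk)) row[[paste0("bulk_", s)]] <- bulk[[s]]
  row
}

#' Run a full aggregate-maturation simulation
#'
#' The multi-timescale loop: (1) the substrate fields are relaxed to
#' pseudo-steady state around the current community; (2) every cell's mass is
#' advanced by one adaptive biological step using its local growth rate, and
#' activity states are updated; (3) at division-check times, cells above the
#' division mass split, overlaps are relaxed by shoving, optional shear
#' detachment is applied and the grid zones are relabelled; (4) bulk values
#' are updated according to the bulk mode (fixed Dirichlet concentrations by
#' default). Snapshots are recorded at the configured interval and the run
#' stops early once the community is steady (see [detect_steady_state()]).
#' Fully reproducible given the config seed.
#'
#' @param config an [simulation_config()] object
#' @param bulk_mode `"constant"` (default; bulk concentrations fixed for the
#'   whole run) or `"reactor"` (well-mixed bulk of volume `reactor_volume`
#'   depleted by the aggregate's boundary flux)
#' @param reactor_volume reactor liquid volume in litres (reactor mode)
#' @param verbose logical: print per-snapshot progress
#' @return an `aggresim_trajectory`: list with the config, the list of
#'   [make_snapshot()]s, a per-snapshot `summary` data frame, the
#'   steady-state flag/time, and the final concentration fields
#' @export
run_simulation <- function(config, bulk_mode = c("constant", "reactor"),
                           reactor_volume = 1e-6, verbose = FALSE) {
  stopifnot(inherits(config, "aggresim_config"))
  bulk_mode <- match.arg(bulk_mode)
  eco <- config$ecology
  grid <- config$grid
  sch <- config$scheduler
  kin <- eco$populations

  cells <- generate_inoculum(config)
  with_seed(config$seed + 1L, {
    run_out <- .run_loop(config, eco, grid, sch, cells, bulk_mode,
                         reactor_volume, verbose)
  })
  run_out
}

.run_loop <- function(config, eco, grid, sch, cells, bulk_mode,
                      reactor_volume, verbose) {
  half <- min(grid$nx, grid$ny) * grid$h / 2
  bulk <- setNames(eco$substrates$bulk, eco$substrates$name)
  M_min <- vapply(eco$populations, `[[`, numeric(1), "M_min")

  ctr <- aggregate_centre(cells)
  rad <- aggregate_radius(cells, eco, ctr)
  zones <- label_zones(grid, ctr, rad)
  fields <- NULL
  t <- 0
  next_div <- sch$dt_div
  next_snap <- config$snapshot_interval
  snapshots <- list()
  summary_rows <- list()
  truncated <- FALSE
  steady <- FALSE
  steady_time <- NA_real_

  record <- function(fields_now = NULL) {
    snap <- make_snapshot(cells, eco, grid, t, fields = fields_now,
                          bulk = bulk)
    snapshots[[length(snapshots) + 1L]] <<- snap
    summary_rows[[length(summary_rows) + 1L]] <<-
      snapshot_summary_row(cells, eco, t, snap$radius, bulk)
    if (verbose) {
      message(sprintf("t = %6.1f h: %d cells (%d active), R = %.1f um",
                      t, nrow(cells), sum(cells$active), snap$radius))
    }
  }

  solver_cache <- new.env(parent = emptyenv())
  solve_now <- function() {
    eco$substrates$bulk <- unname(bulk[eco$substrates$name])
    out <- solve_pseudo_steady(fields, cells, eco, grid, zones,
                               settings = sch$solver, cache = solver_cache)
    fields <<- out$fields
    out$report
  }

  record(NULL)
  eps_t <- 1e-9
  while (t < config$end_time - eps_t && nrow(cells) > 0) {
    solve_now()
    mu <- cell_growth_rates(cells, fields, eco, grid)
    cells$mu <- mu
    # reactivation under favourable local conditions
    cells$active[!cells$active & mu > 0] <- TRUE
    act <- cells$active
    mu_scale <- max(abs(mu[act]), 1e-12)
    dt <- min(sch$dt_bac_cap, sch$mass_change_frac / mu_scale,
              config$end_time - t, next_div - t, next_snap - t)
    dt <- max(dt, eps_t)
    area_before <- .cell_area(cells, eco)
    cells$mass[act] <- pmax(cells$mass[act] * (1 + mu[act] * dt), 0)
    cells$active[act & cells$mass <= M_min[cells$population]] <- FALSE
    t <- t + dt
    # cells shove whenever they grow, not only at division checks; a packed
    # disc first expands affinely by the area-growth factor so the pairwise
    # relaxation only has local corrections left to do
    if (sch$shoving && nrow(cells) > 1L) {
      cells <- .pre_expand(cells, eco, area_before)
      cells <- resolve_overlaps(cells, eco, sch$shoving_settings)
    }
    if (nrow(cells)) {
      ctr <- aggregate_centre(cells)
      rad <- aggregate_radius(cells, eco, ctr)
      if (rad + grid$h > half) {
        warning("aggregate reached the grid limit at t = ",
                round(t, 1), " h; run truncated")
        truncated <- TRUE
        break
      }
    }

    if (bulk_mode == "reactor") {
      flux <- boundary_flux_balance(fields, cells, eco, grid, zones)
      bulk_new <- bulk[flux$substrate] - flux$influx * dt / reactor_volume
      bulk[flux$substrate] <- pmax(bulk_new, 0)
    }

    if (t >= next_div - eps_t) {
      area_before <- .cell_area(cells, eco)
      cells <- process_divisions(cells, eco)
      if (sch$shoving && nrow(cells) > 1L) {
        cells <- .pre_expand(cells, eco, area_before)
        cells <- resolve_overlaps(cells, eco, sch$shoving_settings)
      }
      if (!is.null(config$detachment_radius) && nrow(cells)) {
        cells <- apply_detachment(cells, config$detachment_radius)
      }
      if (nrow(cells)) {
        ctr <- aggregate_centre(cells)
        rad <- aggregate_radius(cells, eco, ctr)
        zones <- label_zones(grid, ctr, rad)
      }
      next_div <- next_div + sch$dt_div
    }

    if (t >= next_snap - eps_t) {
      record(NULL)
      next_snap <- next_snap + config$snapshot_interval
      sumdf <- do.call(rbind, summary_rows)
      det <- detect_steady_state(sumdf, window = sch$steady_window,
                                 tol = sch$steady_tol)
      if (isTRUE(det$steady)) {
        steady <- TRUE
        steady_time <- det$time
        break
      }
    }
  }

  # final snapshot with fields attached (replacing a same-time snapshot)
  if (nrow(cells)) {
    solve_now()
    cells$mu <- cell_growth_rates(cells, fields, eco, grid)
  }
  n_snap <- length(snapshots)
  if (n_snap > 0 && abs(snapshots[[n_snap]]$time - t) < eps_t) {
    snapshots[[n_snap]] <- NULL
    summary_rows[[n_snap]] <- NULL
  }
  record(fields)

  structure(
    list(config = config, snapshots = snapshots,
         summary = do.call(rbind, summary_rows),
         steady = steady, steady_time = steady_time,
         truncated = truncated, final_fields = fields, final_zones = zones,
         final_bulk = bulk),
    class = "aggresim_trajectory"
  )
}

#' Detect steady state of a trajectory
#'
#' The community is steady when, over the trailing window, the relative
#' change of every population's active relative abundance, every bulk
#' concentration and every population's median growth rate stays below
#' `tol`. Relative change is (max - min) / max(|mean|, floor) per quantity.
#'
#' @param trajectory an `aggresim_trajectory` or its `summary` data frame
#' @param window trailing window length, h
#' @param tol relative-change tolerance
#' @return list with `steady` (logical; `NA` when the history is too short,
#'   flagged with the `indeterminate` element) and `time` (first time the
#'   trailing window is steady, `NA` otherwise)
#' @export
detect_steady_state <- function(trajectory, window, tol) {
  sumdf <- if (inherits(trajectory, "aggresim_trajectory"))
    trajectory$summary else trajectory
  stopifnot(is.data.frame(sumdf), window > 0, tol > 0)
  tracked <- grep("^(abund_|mu_|bulk_)", names(sumdf), value = TRUE)
  times <- sumdf$time
  if (nrow(sumdf) < 2L || diff(range(times)) < window) {
    return(list(steady = NA, time = NA_real_, indeterminate = TRUE))
  }
  window_ok <- function(T_end) {
    sel <- times >= T_end - window - 1e-9 & times <= T_end + 1e-9
    if (sum(sel) < 2L) return(FALSE)
    for (cl in tracked) {
      v <- sumdf[[cl]][sel]
      if (all(is.na(v))) next
      if (any(is.na(v))) return(FALSE)
      denom <- max(abs(mean(v)), 1e-9)
      if ((max(v) - min(v)) / denom > tol) return(FALSE)
    }
    TRUE
  }
  candidates <- times[times >= times[1L] + window - 1e-9]
  for (T_end in candidates) {
    if (window_ok(T_end)) {
      return(list(steady = TRUE, time = T_end, indeterminate = FALSE))
    }
  }
  list(steady = FALSE, time = NA_real_, indeterminate = FALSE)
}

#' Extract a snapshot from a trajectory
#'
#' @param trajectory an `aggresim_trajectory`
#' @param which snapshot index, or `"final"` (default) / `"steady"` (last
#'   snapshot not later than the detected steady time)
#' @return an `aggresim_snapshot`
#' @export
get_snapshot <- function(trajectory, which = "final") {
  stopifnot(inherits(trajectory, "aggresim_trajectory"))
  snaps <- trajectory$snapshots
  if (identical(which, "final")) return(snaps[[length(snaps)]])
  if (identical(which, "steady")) {
    if (!isTRUE(trajectory$steady)) return(snaps[[length(snaps)]])
    times <- vapply(snaps, `[[`, numeric(1), "time")
    return(snaps[[max(which(times <= trajectory$steady_time + 1e-9))]])
  }
  snaps[[which]]
}
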