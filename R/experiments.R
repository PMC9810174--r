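#' Define an experiment preset
#'
#' A grid of simulation conditions for one ecology: total substrate
#' concentrations (and, for the mixed ecology, oxygen levels), run in
#' seeded replicates, mirroring the study designs (triplicates or
#' sextuplicates over concentration series).
#'
#' @param name label of the experiment
#' @param ecology ecology preset name (see [build_ecology_preset()])
#' @param concentrations numeric vector of total substrate concentrations
#'   `[S]_T` in mol/L (applied to the fed substrate(s) of the ecology)
#' @param o2_mgL oxygen levels in mg/L (mixed ecology only; crossed with
#'   `concentrations`)
#' @param replicates replicates per condition (3 or 6 in the study designs)
#' @param end_time simulated end time per run, h
#' @param detachment_radius optional detachment cap, um
#' @param n_cells inoculum size
#' @param grid a [grid_spec()]
#' @param scheduler a [scheduler_settings()]
#' @param snapshot_interval h between snapshots
#' @return a list of class `experiment_preset` with an expanded `conditions`
#'   data frame
#' @export
experiment_preset <- function(name, ecology, concentrations, o2_mgL = NULL,
                              replicates = 3, end_time = 144,
                              detachment_radius = NULL, n_cells = 24,
                              grid = grid_spec(),
                              scheduler = scheduler_settings(),
                              snapshot_interval = 12) {
  ecology <- match.arg(ecology, c("neutralism", "competition",
                                  "commensalism", "commensalism_competition",
                                  "mixed"))
  stopifnot(is.numeric(concentrations), all(concentrations > 0),
            replicates >= 1)
  conditions <- if (is.null(o2_mgL)) {
    data.frame(S_T = concentrations, O2_mgL = NA_real_)
  } else {
    expand.grid(S_T = concentrations, O2_mgL = o2_mgL)
  }
  conditions$label <- ifelse(
    is.na(conditions$O2_mgL),
    sprintf("S_T=%g mM", conditions$S_T * 1e3),
    sprintf("S_T=%g mM, O2=%g mg/L", conditions$S_T * 1e3, conditions$O2_mgL))
  structure(
    list(name = name, ecology = ecology, conditions = conditions,
         replicates = as.integer(replicates), end_time = end_time,
         detachment_radius = detachment_radius, n_cells = n_cells,
         grid = grid, scheduler = scheduler,
         snapshot_interval = snapshot_interval),
    class = "experiment_preset"
  )
}

# Bulk concentration map for one condition of an ecology.
condition_bulk <- function(ecology, S_T, O2_mgL = NA) {
  switch(ecology,
    neutralism = c(A = S_T, B = S_T, C = S_T),
    competition = c(A = S_T),
    commensalism = c(A = S_T),
    commensalism_competition = ,
    mixed = c(A = S_T, O2 = o2_mgL_to_molL(O2_mgL))
  )
}

# Build the simulation config of one (condition, replicate) cell.
condition_config <- function(preset, cond_row, seed) {
  eco <- build_ecology_preset(
    preset$ecology,
    condition_bulk(preset$ecology, cond_row$S_T, cond_row$O2_mgL))
  simulation_config(
    eco, seed = seed, end_time = preset$end_time,
    n_cells = preset$n_cells,
    detachment_radius = preset$detachment_radius,
    grid = preset$grid, scheduler = preset$scheduler,
    snapshot_interval = preset$snapshot_interval)
}

#' Run an experiment preset
#'
#' Runs one seeded simulation per (condition, replicate); replicate `k` uses
#' seed `base_seed + k`, so replicates differ in their random inocula while
#' the same inocula recur across conditions (enabling paired comparisons,
#' e.g. with and without detachment). Failed runs are recorded and the
#' remainder continue.
#'
#' @param preset an [experiment_preset()]
#' @param base_seed integer base seed
#' @param out_dir optional directory: per-run cell tables and the merged
#'   summary are written there as CSV
#' @param keep_trajectories keep full trajectories in the return value
#' @param verbose print progress
#' @return list with `summary` (one row per condition x replicate x
#'   population: abundance, fitness, steady time, stratification indices,
#'   eco-interaction modulus where defined), `runs` (trajectories, if kept),
#'   and `failures`
#' @export
run_experiment <- function(preset, base_seed, out_dir = NULL,
                           keep_trajectories = TRUE, verbose = FALSE) {
  stopifnot(inherits(preset, "experiment_preset"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- list()
  runs <- list()
  failures <- list()
  for (ci in seq_len(nrow(preset$conditions))) {
    cond <- preset$conditions[ci, ]
    for (rep_k in seq_len(preset$replicates)) {
      seed <- as.integer(base_seed + rep_k)
      tag <- sprintf("cond%02d_rep%d", ci, rep_k)
      config <- condition_config(preset, cond, seed)
      traj <- tryCatch(run_simulation(config),
                       error = function(e) e)
      if (inherits(traj, "error")) {
        failures[[tag]] <- conditionMessage(traj)
        next
      }
      snap <- get_snapshot(traj, "final")
      ab <- relative_abundance(snap, active_only = TRUE)
      fit <- fitness_median(snap)
      idx <- stratification_indices(snap)
      phi <- if ("O2" %in% config$ecology$substrates$name)
        phi_ei_snapshot(snap) else NA_real_
      for (p in snap$populations) {
        rows[[length(rows) + 1L]] <- data.frame(
          experiment = preset$name, condition = cond$label,
          S_T = cond$S_T, O2_mgL = cond$O2_mgL, replicate = rep_k,
          seed = seed, population = p,
          abundance = unname(ab[p]), fitness = unname(fit[p]),
          steady = traj$steady, steady_time = traj$steady_time,
          end_time = snap$time, n_active = sum(snap$cells$active),
          radius = snap$radius,
          layering_index = idx$layering_index,
          segregation_index = idx$segregation_index,
          phi_EI = phi, stringsAsFactors = FALSE)
      }
      if (keep_trajectories) runs[[tag]] <- traj
      if (!is.null(out_dir)) {
        write_cells_csv(snap, file.path(out_dir, paste0(tag, "_cells.csv")))
      }
      if (verbose) {
        message(tag, ": ", cond$label, " done (t = ",
                round(snap$time, 1), " h)")
      }
    }
  }
  summary <- do.call(rbind, rows)
  if (!is.null(out_dir) && !is.null(summary)) {
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  }
  list(preset = preset, summary = summary, runs = runs, failures = failures)
}

#' Construct synthetic snapshot fixtures
#'
#' Builds snapshots with exactly prescribed spatial patterns, for testing
#' and calibrating the analysis statistics: `"concentric"` rings following
#' the commensal chain (first population outermost), `"sectors"` pie
#' sectors of given angles, `"random"` uniformly mixed labels, and
#' `"mixed"` (one half layered, one half sectored).
#'
#' @param kind fixture kind
#' @param n total number of cells
#' @param radius disc radius, um
#' @param ring_radii for `"concentric"`: ring radius per population, in
#'   `populations` order (default outermost first)
#' @param sector_angles for `"sectors"`: sector widths in degrees (must sum
#'   to 360)
#' @param populations population names
#' @param mu growth rates assigned per population
#' @param seed RNG seed
#' @return an `aggresim_snapshot`
#' @export
make_fixture <- function(kind = c("concentric", "sectors", "mixed", "random"),
                         n = 300, radius = 10, ring_radii = c(9, 6, 3),
                         sector_angles = c(120, 120, 120),
                         populations = c("B1", "B2", "B3"),
                         mu = c(0.05, 0.03, 0.01), seed = 1) {
  kind <- match.arg(kind)
  npop <- length(populations)
  stopifnot(n %% npop == 0)
  if (kind == "concentric") stopifnot(length(ring_radii) == npop,
                                      all(ring_radii <= radius))
  if (kind == "sectors") stopifnot(length(sector_angles) == npop,
                                   isTRUE(all.equal(sum(sector_angles), 360)))
  with_seed(seed, {
    if (kind == "concentric") {
      population <- rep(populations, each = n / npop)
      r <- rep(ring_radii, each = n / npop) + runif(n, -0.3, 0.3)
      th <- runif(n, 0, 2 * pi)
    } else {
      rr <- radius * sqrt(runif(n))
      th <- runif(n, 0, 2 * pi)
      r <- rr
      deg <- (th * 180 / pi) %% 360
      population <- switch(kind,
        sectors = populations[findInterval(deg, cumsum(c(0, sector_angles)),
                                           rightmost.closed = TRUE)],
        random = sample(rep(populations, each = n / npop)),
        mixed = ifelse(deg < 180,
          # layered half: chain order from outside in
          populations[pmin(npop, findInterval(-r, sort(-radius *
            seq_len(npop) / npop), rightmost.closed = TRUE) + 1L)],
          # sectored half
          populations[pmin(npop, floor((deg - 180) / (180 / npop)) + 1L)])
      )
    }
    mass <- rep(2e-14, n)
    cells <- data.frame(id = seq_len(n), population = population,
                        x = r * cos(th), y = r * sin(th), mass = mass,
                        active = TRUE,
                        mu = mu[match(population, populations)],
                        stringsAsFactors = FALSE)
    structure(
      list(time = 0, cells = cells, centre = c(x = 0, y = 0),
           radius = max(r) + 0.5, populations = populations, ecology = NULL,
           grid = NULL, fields = NULL, bulk = NULL),
      class = "aggresim_snapshot"
    )
  })
}
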