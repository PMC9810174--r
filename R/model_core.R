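#' Soluble substrate specification
#'
#' Describes one soluble component of the system: its effective diffusion
#' coefficient and its fixed concentration in the well-mixed bulk liquid
#' (the Dirichlet value at the outer edge of the boundary layer).
#'
#' @param name substrate identifier (e.g. `"A"`, `"O2"`)
#' @param diffusion effective diffusion coefficient in m^2/h (converted to
#'   um^2/h internally; the default is the value used for the small organic
#'   substrates A-D)
#' @param bulk bulk-liquid concentration in mol/L
#' @return a list of class `substrate_spec`
#' @examples
#' substrate_spec("A", diffusion = 3.6e-6, bulk = 1e-3)
#' @export
substrate_spec <- function(name, diffusion = 3.6e-6, bulk = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(diffusion), length(diffusion) == 1L, diffusion > 0)
  stopifnot(is.numeric(bulk), length(bulk) == 1L, bulk >= 0)
  structure(
    list(name = name, D = diffusion * .UM2_PER_M2, bulk = bulk),
    class = "substrate_spec"
  )
}

#' Default kinetic parameters shared by the three populations
#'
#' All populations are parameterised identically ("theoretical equal
#' fitness"), so that differences in their fate arise only from their
#' stoichiometries and the local environment. The supplementary kinetic
#' tables of the original study are not public; these values are the
#' package's own stand-ins, chosen so that substrate limitation develops
#' inside desk-scale aggregates over the 0.05-1 mM concentration window
#' (see the methods vignette for the supporting scale analysis).
#'
#' @return a named list with elements `mu_max` (1/h), `K_S` (mol/L, one value
#'   for the organic substrates and one for O2), `b_max` (1/h), `Y_XS`
#'   (mol biomass per mol substrate), `rho` (mol biomass per um^3), `M_max`
#'   and `M_min` (mol)
#' @export
default_kinetics <- function() {
  rho <- 9.549297e-15      # mol/um^3 (~0.23 g dry weight per cm^3)
  r_div <- 1.5             # um: radius at the division threshold
  M_max <- rho * 4 / 3 * pi * r_div^3
  list(
    mu_max = 0.1,                      # 1/h
    K_S = 1e-5,                        # mol/L (0.01 mM), substrates A-D
    K_S_O2 = o2_mgL_to_molL(0.5),      # 0.5 mg/L half saturation for O2
    b_max = 0.01,                      # 1/h, maintenance (0.1 * mu_max)
    Y_XS = 0.5,                        # mol X / mol S
    M_max = M_max,                     # mol; division threshold
    # dormancy threshold: a starving cell crosses it within a few days of
    # decay, yet it stays clear of the smallest division daughter (>= 0.45)
    M_min = 0.3 * M_max,
    rho = rho
  )
}

#' Population specification
#'
#' Kinetic parameters and signed stoichiometric coefficients for one microbial
#' population. Coefficients are in mol substrate per mol biomass formed;
#' negative values denote consumption, positive values production.
#'
#' @param name population identifier
#' @param mu_max maximum specific growth rate, 1/h
#' @param K_S named numeric vector of half-saturation constants (mol/L), one
#'   entry per consumed substrate
#' @param K_I named numeric vector of inhibition constants (mol/L); may be
#'   empty (none of the shipped presets use inhibition)
#' @param b_max maintenance coefficient, 1/h
#' @param Y_XS growth yield, mol biomass per mol substrate
#' @param rho cell density, mol biomass per um^3
#' @param M_max division mass threshold, mol
#' @param M_min inactivation mass threshold, mol
#' @param stoichiometry named numeric vector of signed coefficients
#' @return a list of class `population_spec`
#' @export
population_spec <- function(name, mu_max, K_S, K_I = numeric(0), b_max, Y_XS,
                            rho, M_max, M_min, stoichiometry) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(mu_max > 0, all(K_S > 0), b_max >= 0, Y_XS > 0, rho > 0)
  stopifnot(M_min > 0, M_min < M_max)
  if (length(K_S)) stopifnot(!is.null(names(K_S)))
  if (length(K_I)) stopifnot(!is.null(names(K_I)), all(K_I > 0))
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  consumed <- names(stoichiometry)[stoichiometry < 0]
  missing_ks <- setdiff(consumed, names(K_S))
  if (length(missing_ks)) {
    stop("missing K_S for consumed substrate(s): ",
         paste(missing_ks, collapse = ", "))
  }
  structure(
    list(name = name, mu_max = mu_max, K_S = K_S, K_I = K_I, b_max = b_max,
         Y_XS = Y_XS, rho = rho, M_max = M_max, M_min = M_min,
         stoichiometry = stoichiometry),
    class = "population_spec"
  )
}

#' Ecology presets: community interaction structures
#'
#' Builds the community definition for one of the four interaction
#' structures studied: `"neutralism"` `[0,0,0]` (each population consumes its
#' own substrate), `"competition"` `[-,-,-]` (all three consume substrate A),
#' `"commensalism"` `[0,+,+]` (a metabolic chain A -> B -> C -> D) and
#' `"commensalism_competition"` (alias `"mixed"`): the commensal chain plus
#' shared consumption of O2, so the realised interaction depends on which
#' substrate is limiting. Each coefficient has magnitude `1/Y_XS`.
#'
#' @param name preset name (see above)
#' @param bulk_concentrations named numeric vector of bulk concentrations in
#'   mol/L; substrates not named default to 0 (e.g. the downstream products)
#' @param kinetics optional overrides for [default_kinetics()] entries
#' @return a list of class `ecology_preset` with elements `name`,
#'   `substrates` (data frame: name, D in um^2/h, bulk in mol/L),
#'   `populations` (list of three [population_spec()]s), `stoichiometry`
#'   (3 x n signed matrix, mol S per mol X) and `interaction_signs`
#' @examples
#' eco <- build_ecology_preset("commensalism", c(A = 1e-4))
#' eco$stoichiometry
#' @export
build_ecology_preset <- function(name, bulk_concentrations = numeric(0),
                                 kinetics = list()) {
  name <- match.arg(name, c("neutralism", "competition", "commensalism",
                            "commensalism_competition", "mixed"))
  if (name == "mixed") name <- "commensalism_competition"
  kin <- utils::modifyList(default_kinetics(), kinetics)
  iY <- 1 / kin$Y_XS

  subs <- switch(name,
    neutralism = c("A", "B", "C", "D"),
    competition = c("A", "B"),
    commensalism = c("A", "B", "C", "D"),
    commensalism_competition = c("A", "B", "C", "D", "O2")
  )
  S <- matrix(0, nrow = 3, ncol = length(subs),
              dimnames = list(c("B1", "B2", "B3"), subs))
  signs <- switch(name,
    neutralism = {
      S["B1", "A"] <- -iY; S["B2", "B"] <- -iY; S["B3", "C"] <- -iY
      S[, "D"] <- iY
      c("0", "0", "0")
    },
    competition = {
      S[, "A"] <- -iY; S[, "B"] <- iY
      c("-", "-", "-")
    },
    commensalism = {
      S["B1", "A"] <- -iY; S["B1", "B"] <- iY
      S["B2", "B"] <- -iY; S["B2", "C"] <- iY
      S["B3", "C"] <- -iY; S["B3", "D"] <- iY
      c("0", "+", "+")
    },
    commensalism_competition = {
      S["B1", "A"] <- -iY; S["B1", "B"] <- iY
      S["B2", "B"] <- -iY; S["B2", "C"] <- iY
      S["B3", "C"] <- -iY; S["B3", "D"] <- iY
      # catabolic oxygen demand: only the substrate fraction not fixed into
      # biomass is oxidised, (1 - Y_XS)/Y_XS mol O2 per mol biomass
      S[, "O2"] <- S[, "O2"] - (1 - kin$Y_XS) * iY
      c("env", "env", "env")
    }
  )

  if (length(bulk_concentrations)) {
    stopifnot(is.numeric(bulk_concentrations),
              !is.null(names(bulk_concentrations)),
              all(bulk_concentrations >= 0))
    unknown <- setdiff(names(bulk_concentrations), subs)
    if (length(unknown)) {
      stop("unknown substrate(s) in bulk_concentrations: ",
           paste(unknown, collapse = ", "))
    }
  }
  bulk <- setNames(rep(0, length(subs)), subs)
  bulk[names(bulk_concentrations)] <- bulk_concentrations

  D <- ifelse(subs == "O2", 7.2e-6, 3.6e-6)
  if (!is.null(kin$D)) D[] <- kin$D
  if (!is.null(kin$D_O2)) D[subs == "O2"] <- kin$D_O2
  substrates <- data.frame(name = subs, D = D * .UM2_PER_M2, bulk = unname(bulk),
                           stringsAsFactors = FALSE)

  pops <- lapply(rownames(S), function(p) {
    st <- S[p, ]
    st <- st[st != 0]
    consumed <- names(st)[st < 0]
    K_S <- setNames(ifelse(consumed == "O2", kin$K_S_O2, kin$K_S), consumed)
    population_spec(p, mu_max = kin$mu_max, K_S = K_S, b_max = kin$b_max,
                    Y_XS = kin$Y_XS, rho = kin$rho, M_max = kin$M_max,
                    M_min = kin$M_min, stoichiometry = st)
  })
  names(pops) <- rownames(S)

  structure(
    list(name = name, substrates = substrates, populations = pops,
         stoichiometry = S, interaction_signs = signs, kinetics = kin),
    class = "ecology_preset"
  )
}

#' Spatial grid specification
#'
#' Uniform square grid centred on the origin. Nodes own the half-open
#' intervals `[x_i, x_i + h)`. The domain is partitioned into three zones
#' around the current aggregate: the aggregate itself, a diffusive boundary
#' layer of fixed thickness, and the well-mixed bulk liquid where
#' concentrations are pinned to their bulk values (Dirichlet).
#'
#' @param h node size in um
#' @param nx,ny node counts
#' @param boundary_layer boundary-layer thickness in um beyond the aggregate
#'   radius
#' @return a list of class `grid_spec` with the node-centre coordinates
#' @export
grid_spec <- function(h = 2.5, nx = 91, ny = 91, boundary_layer = 20) {
  stopifnot(h > 0, nx >= 3, ny >= 3, boundary_layer >= 0)
  x0 <- -nx * h / 2
  y0 <- -ny * h / 2
  structure(
    list(h = h, nx = as.integer(nx), ny = as.integer(ny),
         boundary_layer = boundary_layer, x0 = x0, y0 = y0,
         xc = x0 + (seq_len(nx) - 0.5) * h,
         yc = y0 + (seq_len(ny) - 0.5) * h),
    class = "grid_spec"
  )
}

#' Shoving settings
#'
#' @param max_overlap_fraction accepted overlap fraction f: two cells shove
#'   when their centre distance is below `(1 - f) * (r1 + r2)`
#' @param max_iterations cap on relaxation sweeps
#' @param bin_size spatial-hash cell size in um (`NULL`: derived from the
#'   largest cell radius)
#' @return a list of class `shoving_settings`
#' @export
shoving_settings <- function(max_overlap_fraction = 0.05, max_iterations = 200,
                             bin_size = NULL) {
  stopifnot(max_overlap_fraction >= 0, max_overlap_fraction < 1,
            max_iterations >= 1)
  structure(
    list(max_overlap_fraction = max_overlap_fraction,
         max_iterations = as.integer(max_iterations), bin_size = bin_size),
    class = "shoving_settings"
  )
}

#' Pseudo-steady-state solver settings
#'
#' @param method `"direct"` (semi-implicit Picard iteration with a sparse
#'   direct solve per refresh; the default) or `"iterative"` (damped Jacobi
#'   relaxation with the reaction term refrozen every `n_refresh` inner
#'   iterations). Both must satisfy the same residual tolerance rule.
#' @param n_refresh inner iterations between reaction-term refreshes
#'   (iterative method)
#' @param max_outer cap on Picard refreshes (direct method)
#' @param max_inner cap on total inner iterations (iterative method)
#' @param omega damping factor of the Jacobi relaxation
#' @param abs_floor absolute residual floor of the tolerance rule (mol/L)
#' @param rel_tol relative residual tolerance where concentrations are well
#'   above the floor
#' @param picard_tol additional self-consistency requirement of the direct
#'   method: the maximum relative field change between successive Picard
#'   sweeps must fall below this value (lets trace-level products of a
#'   metabolic chain propagate fully even when the residual floor would
#'   already be satisfied)
#' @return a list of class `solver_settings`
#' @export
solver_settings <- function(method = c("direct", "iterative"), n_refresh = 10,
                            max_outer = 60, max_inner = 200000, omega = 0.9,
                            abs_floor = 1e-6, rel_tol = 0.01,
                            picard_tol = 0.01) {
  method <- match.arg(method)
  stopifnot(n_refresh >= 1, max_outer >= 1, max_inner >= 1,
            omega > 0, omega <= 1, abs_floor > 0, rel_tol > 0, picard_tol > 0)
  structure(
    list(method = method, n_refresh = as.integer(n_refresh),
         max_outer = as.integer(max_outer), max_inner = as.integer(max_inner),
         omega = omega, abs_floor = abs_floor, rel_tol = rel_tol,
         picard_tol = picard_tol),
    class = "solver_settings"
  )
}

#' Multi-timescale scheduler settings
#'
#' The biological step `dt_bac` is adaptive: no active cell may change its
#' mass by more than `mass_change_frac` in one step, capped at `dt_bac_cap`.
#' Division (followed by shoving, optional detachment and zone relabelling)
#' is checked every `dt_div` hours. The run is declared steady when, over a
#' trailing `steady_window`, the relative change of every population's active
#' abundance, every bulk concentration and every population's median growth
#' rate stays below `steady_tol`.
#'
#' @param dt_bac_cap upper bound on the biological time step, h
#' @param mass_change_frac maximum relative mass change per biological step
#' @param dt_div division-check interval, h
#' @param steady_window trailing window for steady-state detection, h
#' @param steady_tol relative tolerance of steady-state detection
#' @param shoving logical: run the shoving pass (disable only for
#'   well-mixed closed-form checks)
#' @param shoving_settings a [shoving_settings()] object
#' @param solver a [solver_settings()] object
#' @return a list of class `scheduler_settings`
#' @export
scheduler_settings <- function(dt_bac_cap = 1, mass_change_frac = 0.05,
                               dt_div = 3, steady_window = 36,
                               steady_tol = 0.05, shoving = TRUE,
                               shoving_settings = aggresim::shoving_settings(),
                               solver = solver_settings()) {
  stopifnot(dt_bac_cap > 0, mass_change_frac > 0, dt_div > 0,
            steady_window > 0, steady_tol > 0)
  structure(
    list(dt_bac_cap = dt_bac_cap, mass_change_frac = mass_change_frac,
         dt_div = dt_div, steady_window = steady_window,
         steady_tol = steady_tol, shoving = isTRUE(shoving),
         shoving_settings = shoving_settings, solver = solver),
    class = "scheduler_settings"
  )
}

#' Full simulation configuration
#'
#' @param ecology an [build_ecology_preset()] object
#' @param seed integer random seed; mandatory, every source of randomness in
#'   a run derives from it
#' @param end_time simulated end time, h
#' @param inoculum_diameter diameter of the premature aggregate, um
#' @param n_cells number of inoculum cells (divisible by 3)
#' @param detachment_radius maximum aggregate radius in um beyond which cells
#'   are removed (`NULL`: no detachment)
#' @param grid a [grid_spec()] object
#' @param scheduler a [scheduler_settings()] object
#' @param snapshot_interval interval between recorded snapshots, h
#' @return a list of class `aggresim_config`
#' @export
simulation_config <- function(ecology, seed, end_time = 144,
                              inoculum_diameter = 20, n_cells = 24,
                              detachment_radius = NULL,
                              grid = grid_spec(),
                              scheduler = scheduler_settings(),
                              snapshot_interval = 12) {
  stopifnot(inherits(ecology, "ecology_preset"))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  stopifnot(end_time > 0, inoculum_diameter > 0, snapshot_interval > 0)
  stopifnot(n_cells >= 3, n_cells %% 3 == 0)
  if (!is.null(detachment_radius)) stopifnot(detachment_radius > 0)
  structure(
    list(ecology = ecology, seed = as.integer(seed), end_time = end_time,
         inoculum_diameter = inoculum_diameter, n_cells = as.integer(n_cells),
         detachment_radius = detachment_radius, grid = grid,
         scheduler = scheduler, snapshot_interval = snapshot_interval),
    class = "aggresim_config"
  )
}

#' Generate a seeded random inoculum
#'
#' Places `n_cells` cells, one third per population, uniformly at random
#' inside a disc of the configured diameter (a "premature aggregate").
#' Placement uses rejection sampling so that no two cells overlap beyond the
#' accepted shoving threshold. Initial masses are uniform in
#' `[M_min, M_max)`. The result is deterministic given the seed.
#'
#' @param config an [simulation_config()] object
#' @param n_cells number of cells (default: from the config)
#' @param seed RNG seed (default: from the config)
#' @return a cell table: data frame with columns `id`, `population`, `x`, `y`
#'   (um), `mass` (mol), `active`, `mu` (1/h)
#' @export
generate_inoculum <- function(config, n_cells = config$n_cells,
                              seed = config$seed) {
  stopifnot(inherits(config, "aggresim_config"))
  stopifnot(n_cells >= 3, n_cells %% 3 == 0)
  eco <- config$ecology
  pops <- names(eco$populations)
  kin <- eco$populations[[1]]
  R <- config$inoculum_diameter / 2
  f <- config$scheduler$shoving_settings$max_overlap_fraction

  with_seed(seed, {
    population <- sample(rep(pops, each = n_cells / 3))
    mass <- runif(n_cells, kin$M_min, kin$M_max)
    r_cell <- radius_from_mass(mass, kin$rho)
    x <- numeric(n_cells)
    y <- numeric(n_cells)
    for (k in seq_len(n_cells)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        rr <- R * sqrt(runif(1))
        th <- runif(1, 0, 2 * pi)
        xk <- rr * cos(th); yk <- rr * sin(th)
        if (k == 1L) { placed <- TRUE }
        else {
          j <- seq_len(k - 1L)
          d2 <- (x[j] - xk)^2 + (y[j] - yk)^2
          lim <- (1 - f) * (r_cell[j] + r_cell[k])
          placed <- all(d2 >= lim^2)
        }
        if (placed) { x[k] <- xk; y[k] <- yk; break }
      }
      if (!placed) {
        stop("inoculum disc too small to place ", n_cells,
             " cells without excess overlap")
      }
    }
    data.frame(id = seq_len(n_cells), population = population,
               x = x, y = y, mass = mass, active = TRUE, mu = 0,
               stringsAsFactors = FALSE)
  })
}
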