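# Shared fixtures: small, fast configurations for unit tests, and a manual
# snapshot builder for the analysis statistics.

tiny_grid <- function(h = 2.5, n = 41, bl = 15) grid_spec(h, n, n, bl)

tiny_config <- function(ecology = "commensalism", bulk = c(A = 1e-4),
                        seed = 1, end_time = 24, n_cells = 12,
                        grid = tiny_grid(), detachment = NULL, ...) {
  eco <- build_ecology_preset(ecology, bulk)
  simulation_config(eco, seed = seed, end_time = end_time, n_cells = n_cells,
                    detachment_radius = detachment, grid = grid,
                    snapshot_interval = 6, ...)
}

# Snapshot with fully prescribed cells (analysis-layer tests).
snapshot_fixture <- function(x, y, population, mu = 0.05, active = TRUE,
                             mass = 2e-14, radius = NULL,
                             populations = c("B1", "B2", "B3")) {
  n <- length(x)
  cells <- data.frame(id = seq_len(n), population = population,
                      x = x, y = y, mass = rep_len(mass, n),
                      active = rep_len(active, n), mu = rep_len(mu, n),
                      stringsAsFactors = FALSE)
  structure(
    list(time = 0, cells = cells, centre = c(x = 0, y = 0),
         radius = if (is.null(radius)) max(sqrt(x^2 + y^2)) else radius,
         populations = populations, ecology = NULL, grid = NULL,
         fields = NULL, bulk = NULL),
    class = "aggresim_snapshot"
  )
}

# One-population community with no substrate coupling: the Monod product over
# an empty consumed-substrate set is 1, so mu = mu_max - b exactly. Used for
# closed-form growth checks.
uncoupled_ecology <- function(mu_max = 0.1, b_max = 0.01) {
  kin <- default_kinetics()
  spec <- population_spec("P1", mu_max = mu_max,
                          K_S = setNames(numeric(0), character(0)),
                          b_max = b_max, Y_XS = kin$Y_XS, rho = kin$rho,
                          M_max = kin$M_max, M_min = kin$M_min,
                          stoichiometry = setNames(numeric(0), character(0)))
  structure(
    list(name = "uncoupled",
         substrates = data.frame(name = "A", D = 3.6e6, bulk = 1e-3,
                                 stringsAsFactors = FALSE),
         populations = list(P1 = spec),
         stoichiometry = matrix(0, 1, 1, dimnames = list("P1", "A")),
         interaction_signs = "0", kinetics = kin),
    class = "ecology_preset"
  )
}

# Brute-force overlap violation count (independent of the compiled shover).
count_violations <- function(cells, ecology, f = 0.05, slack = 1e-6) {
  rho <- vapply(ecology$populations, `[[`, numeric(1),
                "rho")[cells$population]
  r <- radius_from_mass(cells$mass, rho)
  n <- nrow(cells)
  if (n < 2) return(0L)
  d <- as.matrix(dist(cbind(cells$x, cells$y)))
  lim <- (1 - f) * outer(r, r, "+") * (1 - slack)
  sum(d < lim & upper.tri(d))
}
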