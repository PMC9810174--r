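test_that("zone labelling partitions the domain around the aggregate", {
  grid <- tiny_grid()
  z <- label_zones(grid, c(0, 0), radius = 10)
  expect_equal(sort(unique(as.vector(z$zone))), c(1L, 2L, 3L))
  # centre node is aggregate, far corner is bulk
  expect_equal(z$zone[21, 21], 1L)
  expect_equal(z$zone[1, 1], 3L)
  # diffusion region = aggregate + boundary layer
  expect_equal(length(z$unknown), sum(z$zone < 3L))
})

test_that("reaction term sums stoichiometry * growth * mass over node volume", {
  eco <- build_ecology_preset("commensalism", c(A = 1e-4))
  grid <- tiny_grid()
  # empty node
  none <- assemble_reaction_term(
    data.frame(id = integer(0), population = character(0), x = numeric(0),
               y = numeric(0), mass = numeric(0), active = logical(0),
               mu = numeric(0)), NULL, eco, grid)
  expect_true(all(vapply(none, function(m) all(m == 0), logical(1))))

  # one active B1 cell with mu = 0.02/h and X = 1e-14 mol, Y_XS = 0.5:
  # R_A = -(1/0.5) * 0.02 * 1e-14 / V_L with V_L = h^2 * 1 um * 1e-15 L/um^3
  cells <- data.frame(id = 1L, population = "B1", x = 0.1, y = 0.1,
                      mass = 1e-14, active = TRUE, mu = 0.02)
  R <- assemble_reaction_term(cells, NULL, eco, grid)
  V_L <- grid$h^2 * 1e-15
  expect_equal(sum(R$A), -2 * 0.02 * 1e-14 / V_L)
  expect_equal(sum(R$B), +2 * 0.02 * 1e-14 / V_L)
  expect_equal(sum(R$C), 0)

  # inactive or decaying cells contribute nothing
  cells$active <- FALSE
  expect_equal(sum(assemble_reaction_term(cells, NULL, eco, grid)$A), 0)
  cells$active <- TRUE; cells$mu <- -0.01
  expect_equal(sum(assemble_reaction_term(cells, NULL, eco, grid)$A), 0)
})

test_that("half-open node ownership assigns edge cells to exactly one node", {
  eco <- build_ecology_preset("competition", c(A = 1e-3))
  grid <- tiny_grid()
  # a cell exactly on a node boundary (x = grid$x0 + 10*h)
  edge_x <- grid$x0 + 10 * grid$h
  cells <- data.frame(id = 1:2, population = "B1",
                      x = c(edge_x, 3.21), y = c(0.5, -2.7),
                      mass = 1e-14, active = TRUE, mu = 0.05)
  R <- assemble_reaction_term(cells, NULL, eco, grid)
  V_L <- grid$h^2 * 1e-15
  # total consumption over the grid equals the sum of both contributions
  expect_equal(sum(R$A), -2 * 0.05 * (1e-14 + 1e-14) / V_L)
  expect_equal(sum(R$A != 0), 2)  # two nodes, one per cell

  # a cell outside the grid is an integrity error
  cells$x[1] <- grid$x0 - 1
  expect_error(assemble_reaction_term(cells, NULL, eco, grid), "outside")
})

no_cells <- function() {
  data.frame(id = integer(0), population = character(0), x = numeric(0),
             y = numeric(0), mass = numeric(0), active = logical(0),
             mu = numeric(0))
}

test_that("with zero reaction the field settles at the Dirichlet value", {
  eco <- build_ecology_preset("competition", c(A = 1e-3))
  grid <- tiny_grid()
  out <- solve_pseudo_steady(NULL, no_cells(), eco, grid,
                             zones = label_zones(grid, c(0, 0), 10))
  expect_true(all(abs(out$fields$A - 1e-3) < 1e-12))
  expect_true(out$report$converged)

  # doubling D changes nothing without reaction
  eco2 <- build_ecology_preset("competition", c(A = 1e-3),
                               kinetics = list(D = 7.2e-6))
  out2 <- solve_pseudo_steady(NULL, no_cells(), eco2, grid,
                              zones = label_zones(grid, c(0, 0), 10))
  expect_equal(out$fields$A, out2$fields$A)
})

test_that("the linear core matches a dense direct solve on a 21x21 grid", {
  grid <- grid_spec(h = 2, nx = 21, ny = 21, boundary_layer = 50)
  zones <- label_zones(grid, c(0, 0), 5)   # whole domain is diffusion region
  expect_equal(length(zones$unknown), 21L * 21L)
  str <- aggresim:::build_solver_structure(grid, zones)
  D <- 3.6e6
  Dh2 <- D / grid$h^2
  bulk <- 1e-3
  # frozen sink of 0.05 mol/L/h in the centre node
  src <- numeric(str$m)
  centre <- which(zones$unknown == 11 + 10 * 21)
  src[centre] <- -0.05
  phi <- aggresim:::solve_linearised(str, Dh2, lambda = numeric(str$m), src,
                                     bulk)
  # dense oracle: assemble the same 5-point system explicitly and solve()
  m <- str$m
  A <- diag(4 * Dh2, m)
  for (k in seq_along(str$rows)) A[str$rows[k], str$cols[k]] <- -Dh2
  b <- src + Dh2 * bulk * str$n_dir
  phi_dense <- solve(A, b)
  expect_lt(max(abs(phi - phi_dense)) / max(abs(phi_dense)), 1e-8)
})

test_that("iterative and direct strategies agree and both satisfy the tolerance rule", {
  eco <- build_ecology_preset("competition", c(A = 1e-4))
  grid <- grid_spec(h = 2.5, nx = 31, ny = 31, boundary_layer = 15)
  cells <- data.frame(id = 1:6, population = rep(c("B1", "B2", "B3"), 2),
                      x = c(0, 2, -3, 1, -1, 4), y = c(0, 1, 2, -2, 3, -1),
                      mass = 1e-13, active = TRUE, mu = 0)
  zones <- label_zones(grid, c(0.5, 0.5), 8)
  direct <- solve_pseudo_steady(NULL, cells, eco, grid, zones,
                                solver_settings("direct"))
  iter <- solve_pseudo_steady(NULL, cells, eco, grid, zones,
                              solver_settings("iterative", omega = 0.8))
  expect_true(direct$report$converged)
  expect_true(iter$report$converged)
  # the two fixed points may differ within the shared residual tolerance
  expect_lt(max(abs(direct$fields$A - iter$fields$A)) / 1e-4, 0.1)

  # the residual rule holds on every diffusion-region node, both strategies
  for (out in list(direct, iter)) {
    R <- assemble_reaction_term(cells, out$fields, eco, grid)
    for (k in 1:2) {
      s <- eco$substrates$name[k]
      phi <- out$fields[[s]]
      res <- (aggresim:::.nb_sum(phi, eco$substrates$bulk[k]) - 4 * phi +
                grid$h^2 / eco$substrates$D[k] * R[[s]])[zones$unknown]
      tol <- pmax(0.01 * phi[zones$unknown], 1e-6)
      expect_true(all(abs(res) <= tol))
    }
  }
  # non-negativity and pinned Dirichlet nodes
  expect_true(all(direct$fields$A >= 0))
  expect_true(all(direct$fields$A[zones$zone == 3L] == 1e-4))
})

test_that("halving the node size refines the solution consistently", {
  eco <- build_ecology_preset("competition", c(A = 1e-4))
  probe <- function(h) {
    n <- round(100 / h)
    if (n %% 2 == 0) n <- n + 1
    grid <- grid_spec(h = h, nx = n, ny = n, boundary_layer = 15)
    cells <- data.frame(id = 1:12, population = "B1",
                        x = rep(c(-4, -2, 0, 2), 3),
                        y = rep(c(-2, 0, 2), each = 4),
                        mass = 1.3e-13, active = TRUE, mu = 0)
    out <- solve_pseudo_steady(NULL, cells, eco, grid,
                               label_zones(grid, c(0, 0), 8))
    # field at the aggregate centre
    out$fields$A[(n + 1) / 2, (n + 1) / 2]
  }
  v <- vapply(c(5, 2.5, 1.25), probe, numeric(1))
  expect_lt(abs(v[3] - v[2]), abs(v[2] - v[1]))
})

test_that("boundary influx balances reaction consumption at steady state", {
  eco <- build_ecology_preset("commensalism", c(A = 1e-4))
  grid <- tiny_grid()
  cfg <- tiny_config(n_cells = 24)
  cells <- generate_inoculum(cfg)
  zones <- label_zones(grid, aggregate_centre(cells),
                       aggregate_radius(cells, eco))
  out <- solve_pseudo_steady(NULL, cells, eco, grid, zones)
  fb <- boundary_flux_balance(out$fields, cells, eco, grid, zones)
  # consumed substrate: |influx - consumption| within 1%
  a <- fb[fb$substrate == "A", ]
  expect_lt(abs(a$imbalance) / abs(a$reaction), 0.01)
  # produced substrate: net efflux equals net production within 1%
  b <- fb[fb$substrate == "B", ]
  expect_lt(abs(b$imbalance) / abs(b$reaction), 0.01)

  # zero reaction: balance is zero within solver tolerance
  fb0 <- boundary_flux_balance(
    solve_pseudo_steady(NULL, no_cells(), eco, grid, zones)$fields,
    no_cells(), eco, grid, zones)
  expect_true(all(abs(fb0$imbalance) < 1e-15))
})

test_that("non-convergence raises a solver error carrying the report", {
  eco <- build_ecology_preset("competition", c(A = 1e-4))
  grid <- tiny_grid()
  cfg <- tiny_config("competition", c(A = 1e-4), n_cells = 24)
  cells <- generate_inoculum(cfg)
  err <- tryCatch(
    solve_pseudo_steady(NULL, cells, eco, grid,
                        settings = solver_settings("iterative",
                                                   max_inner = 20)),
    error = function(e) e)
  expect_s3_class(err, "aggresim_solver_error")
  expect_s3_class(err$report, "residual_report")
  expect_false(err$report$converged)
})
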