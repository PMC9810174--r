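test_that("preset stoichiometries reproduce the interaction table exactly", {
  Y <- default_kinetics()$Y_XS
  iY <- 1 / Y

  eco <- build_ecology_preset("neutralism", c(A = 1e-3, B = 1e-3, C = 1e-3))
  expected <- rbind(B1 = c(A = -iY, B = 0, C = 0, D = iY),
                    B2 = c(0, -iY, 0, iY),
                    B3 = c(0, 0, -iY, iY))
  expect_equal(unname(eco$stoichiometry), unname(expected))
  expect_equal(eco$interaction_signs, c("0", "0", "0"))

  eco <- build_ecology_preset("competition", c(A = 1e-3))
  for (p in c("B1", "B2", "B3")) {
    expect_equal(eco$stoichiometry[p, ], c(A = -iY, B = iY))
  }
  expect_equal(eco$interaction_signs, c("-", "-", "-"))

  eco <- build_ecology_preset("commensalism", c(A = 1e-4))
  expect_equal(eco$stoichiometry["B1", ], c(A = -iY, B = iY, C = 0, D = 0))
  expect_equal(eco$stoichiometry["B2", ], c(A = 0, B = -iY, C = iY, D = 0))
  expect_equal(eco$stoichiometry["B3", ], c(A = 0, B = 0, C = -iY, D = iY))
  expect_equal(eco$interaction_signs, c("0", "+", "+"))

  eco <- build_ecology_preset("mixed", c(A = 1e-4, O2 = 3.125e-4))
  expect_equal(eco$name, "commensalism_competition")
  expect_true(all(eco$stoichiometry[, "O2"] < 0))
  # chain part identical to plain commensalism
  expect_equal(eco$stoichiometry[, c("A", "B", "C", "D")],
               build_ecology_preset("commensalism")$stoichiometry)
})

test_that("all populations of a preset share identical kinetics", {
  for (nm in c("neutralism", "competition", "commensalism", "mixed")) {
    eco <- build_ecology_preset(nm, c(A = 1e-4))
    tuples <- lapply(eco$populations, function(p)
      c(p$mu_max, p$b_max, p$Y_XS, p$rho, p$M_max, p$M_min,
        unname(p$K_S[sort(names(p$K_S))])[1]))
    expect_true(all(vapply(tuples, identical, logical(1), tuples[[1]])))
  }
})

test_that("preset construction validates its inputs", {
  expect_error(build_ecology_preset("mutualism"), "arg")
  expect_error(build_ecology_preset("neutralism", c(Z = 1e-3)), "unknown")
  expect_error(build_ecology_preset("neutralism", c(A = -1)), "negative|>= 0")
  # unspecified substrates default to zero bulk
  eco <- build_ecology_preset("commensalism", c(A = 1e-4))
  expect_equal(eco$substrates$bulk[eco$substrates$name == "D"], 0)
  # diffusivities: O2 faster than the organics, both in um^2/h
  eco <- build_ecology_preset("mixed", c(A = 1e-4, O2 = 1e-4))
  D <- setNames(eco$substrates$D, eco$substrates$name)
  expect_equal(unname(D["A"]), 3.6e6)
  expect_equal(unname(D["O2"]), 7.2e6)
})

test_that("inoculum generation is seeded, geometric and balanced", {
  cfg <- tiny_config(n_cells = 24)
  a <- generate_inoculum(cfg, seed = 7)
  b <- generate_inoculum(cfg, seed = 7)
  expect_identical(a, b)
  c2 <- generate_inoculum(cfg, seed = 8)
  expect_false(identical(a$x, c2$x))

  # centres inside the disc
  expect_true(all(a$x^2 + a$y^2 <= (cfg$inoculum_diameter / 2)^2))
  # equal representation
  expect_equal(as.integer(table(a$population)), rep(8L, 3))
  # masses in [M_min, M_max)
  kin <- cfg$ecology$populations[[1]]
  expect_true(all(a$mass >= kin$M_min & a$mass < kin$M_max))
  # placement respects the accepted-overlap threshold
  expect_equal(count_violations(a, cfg$ecology), 0L)
})

test_that("inoculum fails cleanly when the disc cannot hold the cells", {
  cfg <- tiny_config(n_cells = 24)
  cfg$inoculum_diameter <- 6
  cfg$n_cells <- 99L
  expect_error(generate_inoculum(cfg, n_cells = 99), "too small")
})

test_that("inoculum centre of mass is unbiased over many seeds", {
  cfg <- tiny_config(n_cells = 24)
  centres <- vapply(1:300, function(s) {
    cells <- generate_inoculum(cfg, seed = s)
    c(mean(cells$x), mean(cells$y))
  }, numeric(2))
  # per-seed sd of a coordinate is ~1 um; the mean of 300 should be ~0.06
  expect_lt(abs(mean(centres[1, ])), 0.25)
  expect_lt(abs(mean(centres[2, ])), 0.25)
})

test_that("configuration invariants are enforced", {
  eco <- build_ecology_preset("neutralism", c(A = 1e-3))
  expect_error(simulation_config(eco, seed = 1, end_time = -1))
  expect_error(simulation_config(eco, seed = 1, n_cells = 10), "%%|== 0")
  expect_error(grid_spec(h = 0))
  expect_error(shoving_settings(max_overlap_fraction = 1))
  expect_error(population_spec("X", mu_max = 1, K_S = c(A = 1), b_max = 0,
                               Y_XS = 1, rho = 1, M_max = 1, M_min = 2,
                               stoichiometry = c(A = -1)))
  expect_error(population_spec("X", mu_max = 1, K_S = c(B = 1), b_max = 0,
                               Y_XS = 1, rho = 1, M_max = 1, M_min = 0.1,
                               stoichiometry = c(A = -1)), "missing K_S")
})

test_that("oxygen unit conversion matches the molar mass of O2", {
  expect_equal(o2_mgL_to_molL(10), 10 * 1e-3 / 32)
  expect_equal(o2_mgL_to_molL(0), 0)
})
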