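test_that("relative abundance counts active cells and normalises", {
  snap <- snapshot_fixture(x = rnorm(30), y = rnorm(30),
                           population = rep(c("B1", "B2", "B3"), each = 10))
  expect_equal(unname(relative_abundance(snap)), rep(1 / 3, 3))

  # inactive cells excluded under the active-only flag
  snap$cells$active[snap$cells$population == "B1"][1:5] <- FALSE
  ab <- relative_abundance(snap, active_only = TRUE)
  expect_equal(unname(ab["B1"]), 5 / 25)
  expect_equal(sum(ab), 1)
  ab_all <- relative_abundance(snap, active_only = FALSE)
  expect_equal(unname(ab_all["B1"]), 1 / 3)

  snap$cells$active <- FALSE
  expect_error(relative_abundance(snap), "no counted cells")
})

test_that("fitness median summarises active growth rates", {
  snap <- snapshot_fixture(x = 1:3, y = 0 * 1:3, population = rep("B1", 3),
                           mu = c(0.1, 0.2, 0.3))
  expect_equal(fitness_median(snap, "B1"), 0.2)
  # robust to a doubled maximum
  snap$cells$mu[3] <- 0.6
  expect_equal(fitness_median(snap, "B1"), 0.2)
  expect_true(is.na(fitness_median(snap, "B2")))
})

test_that("colony sections implement the angular perimeter measure", {
  # single population ring: one full-circle section (cells at bin centres)
  th <- (seq(0, 355, by = 5) + 2.5) * pi / 180
  snap <- snapshot_fixture(8 * cos(th), 8 * sin(th), rep("B1", 72),
                           radius = 10)
  cs <- colony_sections(snap, angular_bin = 5)
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$theta, 360)
  expect_equal(cs$relative_size, 8 / 10)

  # quarter arc at the aggregate radius: relative size 0.25
  th <- seq(1, 89, by = 2) * pi / 180
  snap <- snapshot_fixture(10 * cos(th), 10 * sin(th),
                           rep("B1", length(th)), radius = 10)
  cs <- colony_sections(snap, angular_bin = 2)
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$theta, 90)
  expect_equal(cs$relative_size, 0.25)

  # three perfect 120-degree sectors of equal radius
  snap <- make_fixture("sectors", n = 900, radius = 10, seed = 3)
  cs <- colony_sections(snap, angular_bin = 10)
  expect_equal(nrow(cs), 3L)
  expect_setequal(cs$population, c("B1", "B2", "B3"))
  expect_equal(cs$theta, rep(120, 3))
  expect_lte(sum(cs$relative_size), 1)
  expect_equal(cs$relative_size, cs$mean_radius / snap$radius / 3)
  expect_equal(sum(cs$theta), 360)
})

test_that("the Thiele modulus and characteristic times follow their definitions", {
  expect_equal(thiele_modulus(1, 1, 1, 1, 1), 1)
  expect_equal(thiele_modulus(2, 1, 1, 1, 1), 2)      # linear in R
  expect_equal(tau_diffusion(10, 100), 1)             # R^2 / D
  expect_equal(tau_reaction_monod(0.5, 0.1, 1e-5, 1e-4, 2), 0.5 / 0.1 * 1.1e-4 / 2)
  expect_error(thiele_modulus(1, 1, 1, 1, 0), "positive")
})

test_that("the eco-interaction modulus is the ratio of limitation pressures", {
  expect_equal(eco_interaction_modulus(1, 1, 1, 1, 1, 1, 1, 1), 1)
  expect_equal(eco_interaction_modulus(0, 1, 1, 1, 1, 1, 1, 1), 0)
  expect_equal(eco_interaction_modulus(0.5, 2, 1, 1, 1, 1, 2, 1), 2)
  # homogeneity: scaling both uptake rates cancels
  expect_equal(eco_interaction_modulus(0.4, 3 * 2, 1, 1, 0.9, 3 * 1, 2, 1),
               eco_interaction_modulus(0.4, 2, 1, 1, 0.9, 1, 2, 1))
  expect_warning(val <- eco_interaction_modulus(0.5, 1, 1, 1, 0, 1, 1, 1),
                 "infinite")
  expect_identical(val, Inf)
})

test_that("environment classification brackets the unit threshold", {
  expect_equal(classify_environment(1.51), "commensal_layered")
  expect_equal(classify_environment(0.65), "competitive_columned")
  expect_equal(classify_environment(1.07, near_threshold_band = 0.1), "mixed")
  expect_equal(classify_environment(1.07, near_threshold_band = 0.01),
               "commensal_layered")
})

test_that("stratification indices recognise the canonical patterns", {
  conc <- make_fixture("concentric", n = 300, ring_radii = c(9, 6, 3),
                       seed = 1)
  idx <- stratification_indices(conc)
  expect_equal(idx$layering_index, -1)

  sect <- make_fixture("sectors", n = 1200, seed = 2)
  idx_s <- stratification_indices(sect, angular_bin = 30)
  expect_gt(idx_s$segregation_index, 0.95)

  # uniformly mixed labels: segregation near zero per fixture, layering near
  # zero on average over fixtures (three-rank correlations are coarse)
  segs <- numeric(20); lays <- numeric(20)
  for (k in 1:20) {
    rnd <- make_fixture("random", n = 1500, seed = 100 + k)
    i <- stratification_indices(rnd, angular_bin = 30)
    segs[k] <- i$segregation_index; lays[k] <- i$layering_index
  }
  expect_lt(max(segs), 0.1)
  expect_lt(abs(mean(lays)), 0.35)

  # single-population snapshot is flagged undefined
  solo <- snapshot_fixture(1:5, rep(0, 5), rep("B1", 5))
  expect_true(is.na(stratification_indices(solo)$layering_index))
})

test_that("the statistical suite runs Welch, paired-t and Pearson analyses", {
  df <- expand.grid(condition = "c1", replicate = 1:4,
                    population = c("B1", "B2", "B3"),
                    stringsAsFactors = FALSE)
  df$abundance <- c(0.5, 0.52, 0.48, 0.51, 0.3, 0.29, 0.31, 0.30,
                    0.2, 0.19, 0.21, 0.19)
  df$fitness <- df$abundance / 10          # perfectly collinear
  out <- stats_suite(df)
  expect_equal(out$pearson$r, 1, tolerance = 1e-12)
  expect_lt(out$pearson$p_value, 0.001)

  # paired shift of +0.1 is detected with the right mean difference
  # (zero-mean jitter keeps the paired differences non-degenerate)
  df2 <- df
  df2$fitness[df2$population == "B1"] <-
    df2$fitness[df2$population == "B2"] + 0.1 + c(-0.01, 0.01, -0.005, 0.005)
  pr <- out2 <- stats_suite(df2)$paired
  row <- pr[pr$pop1 == "B1" & pr$pop2 == "B2", ]
  expect_equal(row$mean_difference, 0.1, tolerance = 1e-12)
  expect_lt(row$p_value, 0.01)

  # degenerate (zero-variance) comparisons are flagged, not errors
  df3 <- df
  df3$abundance <- 0.333
  out3 <- stats_suite(df3)
  expect_true(all(is.na(out3$welch$p_value)))
  expect_true(is.na(out3$pearson$r))
})

test_that("snapshot-level modulus wrapper uses abundances and bulk conditions", {
  eco <- build_ecology_preset("mixed", c(A = 1e-3, O2 = o2_mgL_to_molL(10)))
  cfg <- simulation_config(eco, seed = 1, n_cells = 24, grid = tiny_grid())
  cells <- generate_inoculum(cfg)
  cells$mu <- 0.05
  snap <- aggresim:::make_snapshot(cells, eco, cfg$grid, 0)
  phi <- phi_ei_snapshot(snap)
  # reproduce by hand from the definition
  sp <- eco$populations$B1
  q_A <- (1 / sp$Y_XS) * sp$mu_max * 1e-3 / (sp$K_S[["A"]] + 1e-3)
  C_O2 <- o2_mgL_to_molL(10)
  q_O2 <- (1 / sp$Y_XS) * sp$mu_max * C_O2 / (sp$K_S[["O2"]] + C_O2)
  manual <- ((1 / 3) * q_A / (3.6e6 * 1e-3)) / (1 * q_O2 / (7.2e6 * C_O2))
  expect_equal(phi, manual)
})
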