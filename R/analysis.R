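# Per-cell distance and angle (degrees in [0, 360)) about the snapshot centre.
.polar <- function(snapshot, cells = snapshot$cells) {
  dx <- cells$x - snapshot$centre[[1L]]
  dy <- cells$y - snapshot$centre[[2L]]
  list(r = sqrt(dx^2 + dy^2),
       theta = (atan2(dy, dx) * 180 / pi) %% 360)
}

#' Relative abundance of the populations in a snapshot
#'
#' @param snapshot an `aggresim_snapshot`
#' @param active_only count only active cells (the default, as used for all
#'   abundance readouts)
#' @return named fractions summing to 1
#' @export
relative_abundance <- function(snapshot, active_only = TRUE) {
  cells <- snapshot$cells
  if (active_only) cells <- cells[cells$active, , drop = FALSE]
  if (!nrow(cells)) stop("no counted cells: relative abundance undefined")
  counts <- vapply(snapshot$populations,
                   function(p) sum(cells$population == p), numeric(1))
  counts / sum(counts)
}

#' Median microbial fitness of a population
#'
#' Microbial fitness is read as the actual growth rate of the individuals;
#' the population summary is the median over its active cells.
#'
#' @param snapshot an `aggresim_snapshot`
#' @param population population name, or `NULL` for all populations
#' @return median growth rate(s) in 1/h (`NA` flagged when a population has
#'   no active cells)
#' @export
fitness_median <- function(snapshot, population = NULL) {
  pops <- if (is.null(population)) snapshot$populations else population
  act <- snapshot$cells[snapshot$cells$active, , drop = FALSE]
  out <- vapply(pops, function(p) {
    v <- act$mu[act$population == p]
    if (!length(v)) NA_real_ else median(v)
  }, numeric(1))
  if (length(out) == 1L) unname(out) else out
}

#' Angular colony sections and relative colony sizes
#'
#' Sweeps angular bins about the aggregate centre; each bin is labelled by
#' the population of its radially outermost active cell. Maximal circularly
#' contiguous runs of one label form colony sections: a section of angle
#' `theta` (degrees) and mean labelling-cell radius `<r>` has perimeter
#' `P_c = 2 * pi * <r> * theta / 360` and relative size `P_c / P_T` with
#' `P_T = 2 * pi * R` the aggregate perimeter. Bins containing no active
#' cell are skipped and split runs.
#'
#' @param snapshot an `aggresim_snapshot`
#' @param angular_bin bin width in degrees (must divide 360)
#' @param radius_source `"labelling"` (default: `<r>` averages the outermost
#'   cell of each bin) or `"all"` (`<r>` averages every active cell of the
#'   section's population inside the section)
#' @return data frame with columns `population`, `theta`, `mean_radius`,
#'   `P_c`, `relative_size`
#' @export
colony_sections <- function(snapshot, angular_bin = 2,
                            radius_source = c("labelling", "all")) {
  radius_source <- match.arg(radius_source)
  stopifnot(angular_bin > 0, 360 %% angular_bin == 0)
  act <- snapshot$cells[snapshot$cells$active, , drop = FALSE]
  if (!nrow(act)) stop("no active cells: colony sections undefined")
  pol <- .polar(snapshot, act)
  nb <- as.integer(360 / angular_bin)
  bin <- pmin(floor(pol$theta / angular_bin) + 1L, nb)
  lab <- rep(NA_character_, nb)
  rlab <- rep(NA_real_, nb)
  for (b in unique(bin)) {
    sel <- which(bin == b)
    top <- sel[which.max(pol$r[sel])]
    lab[b] <- act$population[top]
    rlab[b] <- pol$r[top]
  }
  # circular runs over the labelled bins; NA splits
  runs <- list()
  cur <- NULL
  for (b in seq_len(nb)) {
    if (is.na(lab[b])) { if (!is.null(cur)) { runs <- c(runs, list(cur)); cur <- NULL }; next }
    if (is.null(cur)) cur <- list(pop = lab[b], bins = b)
    else if (identical(cur$pop, lab[b])) cur$bins <- c(cur$bins, b)
    else { runs <- c(runs, list(cur)); cur <- list(pop = lab[b], bins = b) }
  }
  if (!is.null(cur)) runs <- c(runs, list(cur))
  # merge wrap-around
  if (length(runs) > 1L) {
    first <- runs[[1L]]; last <- runs[[length(runs)]]
    if (identical(first$pop, last$pop) && 1L %in% first$bins &&
        nb %in% last$bins) {
      runs[[1L]]$bins <- c(last$bins, first$bins)
      runs[[length(runs)]] <- NULL
    }
  }
  R_agg <- snapshot$radius
  out <- do.call(rbind, lapply(runs, function(rn) {
    theta <- length(rn$bins) * angular_bin
    mr <- if (radius_source == "labelling") mean(rlab[rn$bins]) else {
      sel <- bin %in% rn$bins & act$population == rn$pop
      mean(pol$r[sel])
    }
    Pc <- 2 * pi * mr * theta / 360
    data.frame(population = rn$pop, theta = theta, mean_radius = mr,
               P_c = Pc, relative_size = Pc / (2 * pi * R_agg),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Biological Thiele modulus
#'
#' `phi_Bio = R * q_S * X / (D_S * C_S)`: the ratio of the characteristic
#' time for diffusion through the aggregate to the characteristic time of
#' the Monod-type reaction. Large values indicate diffusion-limited uptake.
#'
#' @param R aggregate radius, um
#' @param q_S specific substrate uptake rate, mol S / (mol X h)
#' @param X biomass concentration, mol X / L
#' @param D_S substrate diffusion coefficient, um^2/h
#' @param C_S bulk substrate concentration, mol/L
#' @return the dimensionless modulus
#' @seealso [tau_diffusion()], [tau_reaction_monod()],
#'   [eco_interaction_modulus()]
#' @export
thiele_modulus <- function(R, q_S, X, D_S, C_S) {
  stopifnot(R > 0, q_S >= 0, X >= 0, D_S > 0)
  if (any(C_S <= 0)) stop("bulk concentration must be positive")
  R * q_S * X / (D_S * C_S)
}

#' Characteristic diffusion time
#'
#' `tau_diff = R^2 / D_S`.
#'
#' @inheritParams thiele_modulus
#' @return time in the units implied by `R` and `D_S` (um, um^2/h -> h)
#' @export
tau_diffusion <- function(R, D_S) {
  stopifnot(R >= 0, D_S > 0)
  R^2 / D_S
}

#' Characteristic Monod reaction time
#'
#' `tau_r = (Y_XS / mu_max) * (K_S + C_S) / X`.
#'
#' @param Y_XS growth yield, mol X / mol S
#' @param mu_max maximum specific growth rate, 1/h
#' @param K_S half-saturation constant, mol/L
#' @param C_S bulk substrate concentration, mol/L
#' @param X biomass concentration, mol X / L
#' @return time in h
#' @export
tau_reaction_monod <- function(Y_XS, mu_max, K_S, C_S, X) {
  stopifnot(Y_XS > 0, mu_max > 0, K_S > 0, C_S >= 0, X > 0)
  (Y_XS / mu_max) * (K_S + C_S) / X
}

#' Eco-interaction modulus
#'
#' Ratio of the biological Thiele modulus of the commensal substrate (A) to
#' that of the shared competitive substrate (O2); the aggregate radius and
#' total biomass cancel:
#' `phi_EI = [(n_A q_A) / (D_A C_A)] / [(n_O2 q_O2) / (D_O2 C_O2)]`.
#' Values above 1 mean substrate A is the most limiting (commensal, layered
#' environment); below 1, O2 is (competitive, columned environment).
#'
#' @param n_A,n_O2 relative abundances of the consumers of A and of O2
#' @param q_A,q_O2 specific uptake rates, mol S / (mol X h)
#' @param D_A,D_O2 diffusion coefficients (any common unit)
#' @param C_A,C_O2 bulk concentrations, mol/L
#' @return the dimensionless modulus (`Inf` flagged with a warning when the
#'   O2-side numerator vanishes)
#' @examples
#' eco_interaction_modulus(0.5, 2, 1, 1, 1, 1, 2, 1) # 2.0
#' @export
eco_interaction_modulus <- function(n_A, q_A, D_A, C_A, n_O2, q_O2, D_O2,
                                    C_O2) {
  stopifnot(D_A > 0, C_A > 0, D_O2 > 0, C_O2 > 0,
            n_A >= 0, n_A <= 1, n_O2 >= 0, n_O2 <= 1, q_A >= 0, q_O2 >= 0)
  den <- n_O2 * q_O2 / (D_O2 * C_O2)
  if (den == 0) {
    warning("O2-side numerator is zero: eco-interaction modulus is infinite")
    return(Inf)
  }
  (n_A * q_A / (D_A * C_A)) / den
}

#' Eco-interaction modulus of a simulated snapshot
#'
#' Convenience wrapper assembling the inputs of
#' [eco_interaction_modulus()] from a mixed-ecology snapshot: `n_A` and
#' `n_O2` are the active relative abundances of the consumers of A and O2,
#' and the specific uptake rates are evaluated at bulk conditions as
#' `q_i = (1/Y_XS) * mu_max * C_i / (K_i + C_i)` (the Monod saturation of
#' the substrate in question at its bulk concentration).
#'
#' @param snapshot an `aggresim_snapshot` from a
#'   commensalism-plus-competition run
#' @return the dimensionless modulus
#' @export
phi_ei_snapshot <- function(snapshot) {
  eco <- snapshot$ecology
  stopifnot(!is.null(eco), "O2" %in% eco$substrates$name,
            "A" %in% eco$substrates$name)
  ab <- relative_abundance(snapshot, active_only = TRUE)
  consumers_of <- function(s) {
    names(which(eco$stoichiometry[, s] < 0))
  }
  n_A <- sum(ab[consumers_of("A")])
  n_O2 <- sum(ab[consumers_of("O2")])
  sp <- eco$populations[[consumers_of("A")[1L]]]
  sub <- eco$substrates
  C_A <- sub$bulk[sub$name == "A"]
  C_O2 <- sub$bulk[sub$name == "O2"]
  D_A <- sub$D[sub$name == "A"]
  D_O2 <- sub$D[sub$name == "O2"]
  K_A <- sp$K_S[["A"]]
  sp_o2 <- eco$populations[[consumers_of("O2")[1L]]]
  K_O2 <- sp_o2$K_S[["O2"]]
  q_A <- (1 / sp$Y_XS) * sp$mu_max * C_A / (K_A + C_A)
  q_O2 <- (1 / sp_o2$Y_XS) * sp_o2$mu_max * C_O2 / (K_O2 + C_O2)
  eco_interaction_modulus(n_A, q_A, D_A, C_A, n_O2, q_O2, D_O2, C_O2)
}

#' Classify the ecological environment from the eco-interaction modulus
#'
#' @param phi_EI the modulus
#' @param near_threshold_band half-width of the band around 1 classified as
#'   mixed (default 0.1)
#' @return one of `"commensal_layered"`, `"competitive_columned"`, `"mixed"`
#' @examples
#' classify_environment(1.51) # commensal_layered
#' classify_environment(0.65) # competitive_columned
#' classify_environment(1.07) # mixed
#' @export
classify_environment <- function(phi_EI, near_threshold_band = 0.1) {
  stopifnot(phi_EI >= 0, near_threshold_band >= 0)
  if (phi_EI > 1 + near_threshold_band) "commensal_layered"
  else if (phi_EI < 1 - near_threshold_band) "competitive_columned"
  else "mixed"
}

#' Spatial stratification indices
#'
#' Quantifies the two canonical aggregate patterns. The layering index is
#' the Spearman rank correlation between the commensal-chain order
#' (B1 < B2 < B3) and the median radial position of each population's active
#' cells: values near -1 mean each successor sits deeper than its
#' predecessor (layered stratification). The segregation index is one minus
#' the mean normalised Shannon entropy of population composition over
#' angular bins restricted to the outer shell of the aggregate: values near
#' 1 mean angularly segregated, pie-sector-like colonies (columned
#' stratification); uniformly mixed communities score near 0 on both.
#'
#' @param snapshot an `aggresim_snapshot`
#' @param chain population names in metabolic-chain order
#' @param angular_bin bin width in degrees for the segregation index
#' @param outer_frac outer shell = cells beyond `(1 - outer_frac)` of the
#'   aggregate radius
#' @return list with `layering_index` and `segregation_index` (`NA` flagged
#'   when fewer than two populations have active cells)
#' @export
stratification_indices <- function(snapshot, chain = c("B1", "B2", "B3"),
                                   angular_bin = 30, outer_frac = 0.25) {
  act <- snapshot$cells[snapshot$cells$active, , drop = FALSE]
  present <- intersect(chain, unique(act$population))
  if (length(present) < 2L) {
    return(list(layering_index = NA_real_, segregation_index = NA_real_))
  }
  pol <- .polar(snapshot, act)
  med_r <- vapply(present, function(p) median(pol$r[act$population == p]),
                  numeric(1))
  layering <- suppressWarnings(
    cor(match(present, chain), med_r, method = "spearman"))

  shell <- pol$r >= (1 - outer_frac) * snapshot$radius
  seg <- NA_real_
  if (any(shell)) {
    nb <- as.integer(360 / angular_bin)
    bin <- pmin(floor(pol$theta[shell] / angular_bin) + 1L, nb)
    popf <- factor(act$population[shell], levels = chain)
    tab <- table(bin, popf)
    counts <- rowSums(tab)
    p <- tab / counts
    H <- -rowSums(ifelse(p > 0, p * log(p), 0)) / log(length(chain))
    seg <- 1 - sum(H * counts) / sum(counts)
  }
  list(layering_index = unname(layering), segregation_index = unname(seg))
}

#' Statistical test suite for replicate summaries
#'
#' The comparisons used on replicate simulation outputs: Welch's
#' unequal-variance t-test for abundances (or colony sizes) between groups,
#' the paired t-test for fitness differences between populations within the
#' same simulations, and Pearson's correlation between relative abundance
#' and fitness-median pairs.
#'
#' @param summaries data frame with one row per (condition, replicate,
#'   population) and columns `condition`, `replicate`, `population`,
#'   `abundance`, `fitness`
#' @return list of tidy data frames: `welch` (pairwise population abundance
#'   comparisons within each condition), `paired` (pairwise population
#'   fitness comparisons, paired by replicate) and `pearson`
#'   (abundance-fitness correlation per condition). Degenerate comparisons
#'   (zero variance) are flagged with `NA` p-values.
#' @export
stats_suite <- function(summaries) {
  need <- c("condition", "replicate", "population", "abundance", "fitness")
  stopifnot(all(need %in% names(summaries)))
  conds <- unique(summaries$condition)
  pops <- unique(summaries$population)
  pairs <- if (length(pops) > 1L) utils::combn(sort(pops), 2L) else
    matrix(character(0), 2L)

  safe_p <- function(expr) tryCatch(expr$p.value, error = function(e) NA_real_)

  welch <- do.call(rbind, lapply(conds, function(cd) {
    df <- summaries[summaries$condition == cd, ]
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- df$abundance[df$population == pairs[1L, k]]
      b <- df$abundance[df$population == pairs[2L, k]]
      data.frame(condition = cd, pop1 = pairs[1L, k], pop2 = pairs[2L, k],
                 mean1 = mean(a), mean2 = mean(b),
                 p_value = safe_p(t.test(a, b, var.equal = FALSE)),
                 stringsAsFactors = FALSE)
    }))
  }))

  paired <- do.call(rbind, lapply(conds, function(cd) {
    df <- summaries[summaries$condition == cd, ]
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      d1 <- df[df$population == pairs[1L, k], ]
      d2 <- df[df$population == pairs[2L, k], ]
      d2 <- d2[match(d1$replicate, d2$replicate), ]
      diffs <- d1$fitness - d2$fitness
      data.frame(condition = cd, pop1 = pairs[1L, k], pop2 = pairs[2L, k],
                 mean_difference = mean(diffs),
                 p_value = safe_p(t.test(d1$fitness, d2$fitness,
                                         paired = TRUE)),
                 stringsAsFactors = FALSE)
    }))
  }))

  pearson <- do.call(rbind, lapply(conds, function(cd) {
    df <- summaries[summaries$condition == cd, ]
    ok <- complete.cases(df$abundance, df$fitness)
    r <- NA_real_; p <- NA_real_
    if (sum(ok) >= 3L && sd(df$abundance[ok]) > 0 && sd(df$fitness[ok]) > 0) {
      ct <- cor.test(df$abundance[ok], df$fitness[ok], method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(condition = cd, n = sum(ok), r = r, p_value = p,
               stringsAsFactors = FALSE)
  }))

  list(welch = welch, paired = paired, pearson = pearson)
}
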