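# --- zones ------------------------------------------------------------------

#' Label grid zones around the current aggregate
#'
#' Nodes within the aggregate radius of the aggregate centre belong to the
#' aggregate; nodes within one boundary-layer thickness beyond it form the
#' boundary layer; all remaining nodes are bulk liquid, pinned to the bulk
#' concentrations (Dirichlet). Space outside the domain edge is treated as
#' bulk as well. Zones are recomputed whenever the aggregate changes.
#'
#' @param grid a [grid_spec()]
#' @param centre aggregate centre, um
#' @param radius aggregate radius, um
#' @return a list of class `grid_zones`: `zone` (integer matrix, 1 =
#'   aggregate, 2 = boundary layer, 3 = bulk) and `unknown` (linear indices
#'   of the diffusion-region nodes)
#' @export
label_zones <- function(grid, centre, radius) {
  stopifnot(inherits(grid, "grid_spec"), radius >= 0)
  dx <- outer(grid$xc - centre[[1L]], rep(1, grid$ny))
  dy <- outer(rep(1, grid$nx), grid$yc - centre[[2L]])
  d <- sqrt(dx^2 + dy^2)
  zone <- matrix(3L, grid$nx, grid$ny)
  zone[d <= radius + grid$boundary_layer] <- 2L
  zone[d <= radius] <- 1L
  structure(list(zone = zone, unknown = which(zone < 3L)),
            class = "grid_zones")
}

# --- cell/node bookkeeping --------------------------------------------------

# Node ownership by half-open intervals [x_i, x_i + h). Errors when a cell
# centre lies outside the grid.
cell_node_index <- function(cells, grid) {
  i <- floor((cells$x - grid$x0) / grid$h) + 1
  j <- floor((cells$y - grid$y0) / grid$h) + 1
  bad <- i < 1 | i > grid$nx | j < 1 | j > grid$ny
  if (any(bad)) {
    stop("cell centre(s) outside the simulation grid (ids: ",
         paste(utils::head(cells$id[bad], 5L), collapse = ", "), ")")
  }
  as.integer(i) + (as.integer(j) - 1L) * grid$nx
}

# Local concentrations at each cell's node: matrix [n_cells x n_substrates].
local_concentrations <- function(cells, fields, grid) {
  idx <- cell_node_index(cells, grid)
  out <- vapply(fields, function(phi) phi[idx], numeric(nrow(cells)))
  if (nrow(cells) == 1L) out <- matrix(out, nrow = 1L,
                                       dimnames = list(NULL, names(fields)))
  out
}

# Net growth rate (1/h) of every cell at the current fields.
cell_growth_rates <- function(cells, fields, ecology, grid) {
  mu <- numeric(nrow(cells))
  if (!nrow(cells)) return(mu)
  conc <- local_concentrations(cells, fields, grid)
  for (p in names(ecology$populations)) {
    sel <- cells$population == p
    if (!any(sel)) next
    mu[sel] <- .growth_rate_many(conc[sel, , drop = FALSE],
                                 ecology$populations[[p]])
  }
  mu
}

# --- reaction term ----------------------------------------------------------

#' Assemble the per-node reaction term
#'
#' For every node and substrate, sums `stoich * mu * X / V` over the cells
#' whose centre lies in the node, where `V` is the node volume (node size
#' squared times 1 um unit depth). Inactive cells contribute nothing, and a
#' decaying cell (`mu < 0`) neither consumes nor releases solutes (no lysis
#' products are modelled), so `mu` enters clamped at zero.
#'
#' @param cells a cell table
#' @param fields named list of concentration matrices (mol/L); when `NULL`
#'   the growth rates stored in `cells$mu` are used instead of recomputing
#'   them from the fields
#' @param ecology the community preset
#' @param grid a [grid_spec()]
#' @return named list of reaction matrices in mol/L/h (negative =
#'   consumption)
#' @export
assemble_reaction_term <- function(cells, fields = NULL, ecology, grid) {
  subs <- ecology$substrates$name
  R <- lapply(subs, function(s) matrix(0, grid$nx, grid$ny))
  names(R) <- subs
  if (!nrow(cells)) return(R)
  idx <- cell_node_index(cells, grid)
  mu <- if (is.null(fields)) cells$mu else
    cell_growth_rates(cells, fields, ecology, grid)
  mu_eff <- pmax(mu, 0) * cells$active
  V_L <- grid$h^2 * 1 * .L_PER_UM3     # node volume, litres (1 um depth)
  for (p in names(ecology$populations)) {
    sel <- which(cells$population == p & mu_eff > 0)
    if (!length(sel)) next
    st <- ecology$stoichiometry[p, ]
    rate <- rowsum(mu_eff[sel] * cells$mass[sel] / V_L, idx[sel])
    nodes <- as.integer(rownames(rate))
    for (s in names(st)[st != 0]) {
      R[[s]][nodes] <- R[[s]][nodes] + st[[s]] * rate[, 1L]
    }
  }
  R
}

# Sum of the four neighbour values with Dirichlet ghosts at the domain edge.
.nb_sum <- function(phi, bulk) {
  nx <- nrow(phi); ny <- ncol(phi)
  down  <- rbind(phi[-1L, , drop = FALSE], rep(bulk, ny))
  up    <- rbind(rep(bulk, ny), phi[-nx, , drop = FALSE])
  right <- cbind(phi[, -1L, drop = FALSE], rep(bulk, nx))
  left  <- cbind(rep(bulk, nx), phi[, -ny, drop = FALSE])
  down + up + right + left
}

# --- residual ---------------------------------------------------------------

#' Pseudo-steady-state residual report
#'
#' Evaluates, on every diffusion-region node, the discrete steady-state
#' residual `RES = (sum of neighbour concentrations - 4 phi) + (h^2 / D) *
#' R(phi)` (concentration units), and checks the tolerance rule: where the
#' concentration is well above the absolute floor (1e-6 mol/L), `|RES|` must
#' not exceed 1% of it; elsewhere `|RES|` must not exceed the floor itself.
#' Only the diffusion region (aggregate plus boundary layer) is considered;
#' bulk nodes are pinned.
#'
#' @param fields named list of concentration matrices
#' @param cells a cell table
#' @param ecology the community preset
#' @param grid a [grid_spec()]
#' @param zones a [label_zones()] object
#' @param iterations iteration count to record in the report
#' @param settings a [solver_settings()] (for the tolerance constants)
#' @return a list of class `residual_report`: per-substrate maximum absolute
#'   residual, `converged`, `iterations`
#' @export
residual_report <- function(fields, cells, ecology, grid, zones,
                            iterations = NA_integer_,
                            settings = solver_settings()) {
  R <- assemble_reaction_term(cells, fields, ecology, grid)
  subs <- ecology$substrates
  u <- zones$unknown
  max_abs <- setNames(numeric(nrow(subs)), subs$name)
  ok <- TRUE
  for (k in seq_len(nrow(subs))) {
    s <- subs$name[k]
    phi <- fields[[s]]
    res <- (.nb_sum(phi, subs$bulk[k]) - 4 * phi +
              grid$h^2 / subs$D[k] * R[[s]])[u]
    tol <- pmax(settings$rel_tol * phi[u], settings$abs_floor)
    max_abs[k] <- if (length(res)) max(abs(res)) else 0
    ok <- ok && all(abs(res) <= tol)
  }
  structure(list(max_abs_residual = max_abs, converged = ok,
                 iterations = as.integer(iterations)),
            class = "residual_report")
}

# --- sparse structure for the direct solver ---------------------------------

# Precomputes, for a given zone labelling, the sparsity pattern of the
# 5-point Laplacian restricted to the diffusion-region nodes, plus the count
# of Dirichlet neighbours per node (bulk nodes and out-of-domain ghosts).
build_solver_structure <- function(grid, zones) {
  u <- zones$unknown
  m <- length(u)
  nx <- grid$nx; ny <- grid$ny
  pos <- integer(nx * ny)
  pos[u] <- seq_len(m)
  i <- (u - 1L) %% nx + 1L
  j <- (u - 1L) %/% nx + 1L
  rows <- integer(0); cols <- integer(0)
  n_dir <- integer(m)
  for (off in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    ii <- i + off[1L]; jj <- j + off[2L]
    inside <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny
    nb <- ifelse(inside, ii + (jj - 1L) * nx, NA_integer_)
    nb_pos <- ifelse(inside, pos[ifelse(inside, nb, 1L)], 0L)
    is_unknown <- inside & nb_pos > 0L
    rows <- c(rows, which(is_unknown))
    cols <- c(cols, nb_pos[is_unknown])
    n_dir <- n_dir + as.integer(!is_unknown)
  }
  list(m = m, unknown = u, rows = rows, cols = cols, n_dir = n_dir)
}

# Solve one substrate's linearised steady-state system directly.
# lambda: per-unknown-node linear uptake coefficient (1/h), src: constant
# source (mol/L/h), both length m. The system is symmetric positive
# definite; a CHOLMOD Cholesky factorisation is cached per substrate in
# `cache` (when supplied) and updated numerically while the sparsity
# pattern is unchanged.
solve_linearised <- function(str, Dh2, lambda, src, bulk, cache = NULL,
                             key = NULL) {
  ut <- str$rows < str$cols
  A <- Matrix::sparseMatrix(
    i = c(seq_len(str$m), str$rows[ut]),
    j = c(seq_len(str$m), str$cols[ut]),
    x = c(rep(4 * Dh2, str$m) + lambda, rep(-Dh2, sum(ut))),
    dims = c(str$m, str$m), symmetric = TRUE
  )
  b <- src + Dh2 * bulk * str$n_dir
  if (is.null(cache) || is.null(key)) {
    return(as.numeric(Matrix::solve(A, b)))
  }
  ch <- cache[[key]]
  ch <- if (is.null(ch)) Matrix::Cholesky(A, LDL = FALSE, super = TRUE)
        else tryCatch(Matrix::update(ch, A),
                      error = function(e) Matrix::Cholesky(A, LDL = FALSE,
                                                           super = TRUE))
  cache[[key]] <- ch
  as.numeric(Matrix::solve(ch, b, system = "A"))
}

# --- pseudo-steady solve ----------------------------------------------------

#' Solve the diffusion-reaction system to pseudo-steady state
#'
#' Relaxes every substrate field, with Dirichlet values pinned on the bulk
#' zone and beyond the domain edge, until the residual rule of
#' [residual_report()] is satisfied on every diffusion-region node.
#' Two solution strategies are available: the default semi-implicit Picard
#' iteration (the Monod uptake of each substrate is linearised about the
#' current field and the resulting sparse linear system solved directly,
#' with the reaction term refreshed between solves) and a damped Jacobi
#' relaxation in which the reaction term is frozen and refreshed every
#' `n_refresh` inner iterations. Concentrations are clamped non-negative.
#'
#' @param fields named list of concentration matrices (warm start); `NULL`
#'   initialises every substrate at its bulk value
#' @param cells a cell table
#' @param ecology the community preset
#' @param grid a [grid_spec()]
#' @param zones a [label_zones()] object (defaults to zones around the
#'   current cells)
#' @param settings a [solver_settings()]
#' @param cache optional environment reused across calls to cache the sparse
#'   factorisations while the zone labelling is unchanged
#' @return a list with elements `fields` (converged concentration matrices)
#'   and `report` (a [residual_report()])
#' @export
solve_pseudo_steady <- function(fields = NULL, cells, ecology, grid,
                                zones = NULL, settings = solver_settings(),
                                cache = NULL) {
  subs <- ecology$substrates
  if (is.null(zones)) {
    ctr <- if (nrow(cells)) aggregate_centre(cells) else c(0, 0)
    rad <- if (nrow(cells)) aggregate_radius(cells, ecology, ctr) else 0
    zones <- label_zones(grid, ctr, rad)
  }
  if (is.null(fields)) {
    fields <- lapply(seq_len(nrow(subs)),
                     function(k) matrix(subs$bulk[k], grid$nx, grid$ny))
    names(fields) <- subs$name
  }
  # pin bulk nodes
  for (k in seq_len(nrow(subs))) {
    fields[[k]][zones$zone == 3L] <- subs$bulk[k]
  }
  if (settings$method == "direct") {
    .solve_direct(fields, cells, ecology, grid, zones, settings, cache)
  } else {
    .solve_jacobi(fields, cells, ecology, grid, zones, settings)
  }
}

.solve_direct <- function(fields, cells, ecology, grid, zones, settings,
                          cache = NULL) {
  subs <- ecology$substrates
  str <- NULL
  if (!is.null(cache)) {
    stamp <- c(length(zones$unknown), sum(zones$unknown))
    if (identical(cache$stamp, stamp)) {
      str <- cache$str
    } else {
      rm(list = ls(cache), envir = cache)   # zones changed: drop factors
    }
  }
  if (is.null(str)) {
    str <- build_solver_structure(grid, zones)
    if (!is.null(cache)) {
      cache$str <- str
      cache$stamp <- c(length(zones$unknown), sum(zones$unknown))
    }
  }
  u <- str$unknown
  V_L <- grid$h^2 * 1 * .L_PER_UM3
  active <- which(cells$active & cells$mass > 0)
  idx_all <- if (nrow(cells)) cell_node_index(cells, grid) else integer(0)

  for (outer in seq_len(settings$max_outer)) {
    conc <- if (length(active))
      local_concentrations(cells[active, , drop = FALSE], fields, grid)
    else matrix(0, 0, nrow(subs), dimnames = list(NULL, subs$name))
    idx <- idx_all[active]

    # per-cell gross/net rates and per-substrate Monod factors
    lam <- matrix(0, str$m, nrow(subs))          # 1/h
    src <- matrix(0, str$m, nrow(subs))          # mol/L/h
    colnames(lam) <- colnames(src) <- subs$name
    if (length(active)) {
      pop <- cells$population[active]
      X <- cells$mass[active]
      for (p in names(ecology$populations)) {
        sp <- ecology$populations[[p]]
        sel <- which(pop == p)
        if (!length(sel)) next
        consumed <- names(sp$K_S)
        Fm <- vapply(consumed, function(s)
          conc[sel, s] / (sp$K_S[[s]] + conc[sel, s]), numeric(length(sel)))
        if (length(sel) == 1L) Fm <- matrix(Fm, nrow = 1L,
                                            dimnames = list(NULL, consumed))
        G <- sp$mu_max * apply(Fm, 1L, prod)     # gross specific rate
        mu_net <- G - sp$b_max
        grow <- mu_net > 0
        if (!any(grow)) next
        sg <- sel[grow]
        w <- X[sg] / V_L
        node <- match(idx[sg], u)                # unknown-node position
        st <- ecology$stoichiometry[p, ]
        for (s in consumed) {
          # net uptake |st| * (G - b) * X: linearise the Monod factor of s
          # about the current field; the maintenance part is a constant
          # offset entering the source side
          G_minus <- rep(sp$mu_max, sum(grow))
          for (s2 in setdiff(consumed, s)) G_minus <- G_minus * Fm[grow, s2]
          coef <- abs(st[[s]]) * w * G_minus / (sp$K_S[[s]] + conc[sg, s])
          agg <- rowsum(coef, node)
          lam[as.integer(rownames(agg)), s] <-
            lam[as.integer(rownames(agg)), s] + agg[, 1L]
          aggb <- rowsum(abs(st[[s]]) * w * sp$b_max, node)
          src[as.integer(rownames(aggb)), s] <-
            src[as.integer(rownames(aggb)), s] + aggb[, 1L]
        }
        produced <- names(st)[st > 0]
        if (length(produced)) {
          aggp <- rowsum(pmax(mu_net[grow], 0) * w, node)
          nd <- as.integer(rownames(aggp))
          for (s in produced) {
            src[nd, s] <- src[nd, s] + st[[s]] * aggp[, 1L]
          }
        }
      }
    }
    damp <- if (outer > 8L) 0.5 else 1
    rel_chg <- 0
    for (k in seq_len(nrow(subs))) {
      Dh2 <- subs$D[k] / grid$h^2
      phi_new <- solve_linearised(str, Dh2, lam[, k], src[, k], subs$bulk[k],
                                  cache = cache,
                                  key = paste0("chol_", subs$name[k]))
      phi_new <- pmax(phi_new, 0)
      phi_new <- damp * phi_new + (1 - damp) * fields[[k]][u]
      scale_k <- max(max(phi_new), settings$abs_floor)
      rel_chg <- max(rel_chg, max(abs(phi_new - fields[[k]][u])) / scale_k)
      fields[[k]][u] <- phi_new
    }
    rep <- residual_report(fields, cells, ecology, grid, zones,
                           iterations = outer, settings = settings)
    if (rep$converged && rel_chg <= settings$picard_tol) {
      return(list(fields = fields, report = rep))
    }
  }
  cond <- structure(
    class = c("aggresim_solver_error", "error", "condition"),
    list(message = "pseudo-steady-state solve did not converge",
         call = sys.call(-1), report = rep)
  )
  stop(cond)
}

.solve_jacobi <- function(fields, cells, ecology, grid, zones, settings) {
  subs <- ecology$substrates
  u <- zones$unknown
  bulk_mask <- zones$zone == 3L
  iter <- 0L
  repeat {
    R <- assemble_reaction_term(cells, fields, ecology, grid)
    for (inner in seq_len(settings$n_refresh)) {
      iter <- iter + 1L
      for (k in seq_len(nrow(subs))) {
        phi <- fields[[k]]
        target <- (.nb_sum(phi, subs$bulk[k]) +
                     grid$h^2 / subs$D[k] * R[[k]]) / 4
        phi[u] <- (1 - settings$omega) * phi[u] + settings$omega * target[u]
        phi[phi < 0] <- 0
        phi[bulk_mask] <- subs$bulk[k]
        fields[[k]] <- phi
      }
    }
    rep <- residual_report(fields, cells, ecology, grid, zones,
                           iterations = iter, settings = settings)
    if (rep$converged) return(list(fields = fields, report = rep))
    if (iter >= settings$max_inner) {
      cond <- structure(
        class = c("aggresim_solver_error", "error", "condition"),
        list(message = "pseudo-steady-state solve did not converge",
             call = sys.call(-1), report = rep)
      )
      stop(cond)
    }
  }
}

# --- conservation diagnostic ------------------------------------------------

#' Boundary flux balance diagnostic
#'
#' At pseudo-steady state the net diffusive influx across the Dirichlet rim
#' must balance the total reaction consumption (within the solver tolerance).
#' Returns both sides per substrate, in mol/h.
#'
#' @param fields converged concentration matrices
#' @param cells a cell table
#' @param ecology the community preset
#' @param grid a [grid_spec()]
#' @param zones a [label_zones()] object
#' @return data frame with columns `substrate`, `influx` (mol/h, positive
#'   into the diffusion region), `reaction` (mol/h, negative = net
#'   consumption) and `imbalance` (their sum)
#' @export
boundary_flux_balance <- function(fields, cells, ecology, grid, zones) {
  subs <- ecology$substrates
  R <- assemble_reaction_term(cells, fields, ecology, grid)
  u <- zones$unknown
  nx <- grid$nx; ny <- grid$ny
  pos <- logical(nx * ny)
  pos[u] <- TRUE
  i <- (u - 1L) %% nx + 1L
  j <- (u - 1L) %/% nx + 1L
  V_L <- grid$h^2 * 1 * .L_PER_UM3
  out <- data.frame(substrate = subs$name, influx = 0, reaction = 0,
                    imbalance = 0, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(subs))) {
    phi <- fields[[k]]
    influx <- 0
    for (off in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      ii <- i + off[1L]; jj <- j + off[2L]
      inside <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny
      nb <- ii + (jj - 1L) * nx
      dirichlet <- !inside | !pos[ifelse(inside, nb, 1L)]
      phi_nb <- ifelse(inside & !dirichlet, NA_real_,
                       ifelse(inside, phi[ifelse(inside, nb, 1L)],
                              subs$bulk[k]))
      dsel <- which(dirichlet)
      # flux [mol/h] per face: D * dphi * depth(1um) * litres-per-um^3
      influx <- influx +
        sum(subs$D[k] * (phi_nb[dsel] - phi[u][dsel]) * 1 * .L_PER_UM3)
    }
    reaction <- sum(R[[k]]) * V_L
    out$influx[k] <- influx
    out$reaction[k] <- reaction
    out$imbalance[k] <- influx + reaction
  }
  out
}
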