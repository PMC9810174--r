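# Candidate neighbour pairs within `cutoff` via uniform-grid spatial hashing.
# Returns a 2-column integer matrix (i < j). Exact distance filtering is left
# to the caller. For small n a dense pass is cheaper than hashing.
neighbour_pairs <- function(x, y, cutoff) {
  n <- length(x)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  if (n <= 350L) {
    d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
    hit <- which(upper.tri(d2) & d2 < cutoff^2, arr.ind = TRUE)
    return(unname(hit))
  }
  bx <- as.integer(floor(x / cutoff))
  by <- as.integer(floor(y / cutoff))
  key <- paste(bx, by, sep = ",")
  bins <- split(seq_len(n), key)
  coords <- do.call(rbind, strsplit(names(bins), ",", fixed = TRUE))
  bcoord <- matrix(as.integer(coords), ncol = 2L)
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (b in seq_along(bins)) assign(names(bins)[b], b, envir = lookup)
  offs <- rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  out_i <- vector("list", length(bins) * nrow(offs))
  out_j <- vector("list", length(bins) * nrow(offs))
  slot <- 0L
  for (b in seq_along(bins)) {
    ib <- bins[[b]]
    for (o in seq_len(nrow(offs))) {
      if (offs[o, 1L] == 0L && offs[o, 2L] == 0L) {
        if (length(ib) < 2L) next
        pr <- utils::combn(ib, 2L)
        slot <- slot + 1L
        out_i[[slot]] <- pr[1L, ]; out_j[[slot]] <- pr[2L, ]
      } else {
        nb_key <- paste(bcoord[b, 1L] + offs[o, 1L],
                        bcoord[b, 2L] + offs[o, 2L], sep = ",")
        nb <- lookup[[nb_key]]
        if (is.null(nb)) next
        jb <- bins[[nb]]
        slot <- slot + 1L
        out_i[[slot]] <- rep(ib, times = length(jb))
        out_j[[slot]] <- rep(jb, each = length(ib))
      }
    }
  }
  i <- unlist(out_i[seq_len(slot)], use.names = FALSE)
  j <- unlist(out_j[seq_len(slot)], use.names = FALSE)
  if (!length(i)) return(matrix(integer(0), ncol = 2L))
  keep <- (x[i] - x[j])^2 + (y[i] - y[j])^2 < cutoff^2
  i <- i[keep]; j <- j[keep]
  sw <- i > j
  tmp <- i[sw]; i[sw] <- j[sw]; j[sw] <- tmp
  cbind(i, j)
}

# Pairs currently violating the overlap rule: d < (1 - f) * (r_i + r_j).
violating_pairs <- function(x, y, r, f) {
  cutoff <- (1 - f) * 2 * max(r) + 1e-12
  cand <- neighbour_pairs(x, y, cutoff)
  if (!nrow(cand)) return(cand)
  i <- cand[, 1L]; j <- cand[, 2L]
  d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  lim <- (1 - f) * (r[i] + r[j])
  cand[d < lim, , drop = FALSE]
}

#' Resolve cell overlaps by shoving
#'
#' Iterative pairwise hard-sphere relaxation: every pair of cells whose
#' centre distance is below `(1 - f)` times the sum of their radii is pushed
#' apart along the centre line, each cell moving half the deficit. Sweeps
#' repeat until no violating pair remains or the iteration cap is reached
#' (then a warning is raised and the current state returned). Positions are
#' the only thing shoving changes. Deterministic given the input ordering.
#'
#' @param cells a cell table (see [generate_inoculum()])
#' @param ecology the [build_ecology_preset()] the cells belong to (for cell
#'   densities)
#' @param settings a [shoving_settings()] object
#' @return the cell table with relaxed positions
#' @export
resolve_overlaps <- function(cells, ecology, settings = shoving_settings()) {
  stopifnot(all(is.finite(cells$x)), all(is.finite(cells$y)))
  n <- nrow(cells)
  if (n < 2L) return(cells)
  f <- settings$max_overlap_fraction
  rho <- vapply(ecology$populations, `[[`, numeric(1), "rho")[cells$population]
  r <- radius_from_mass(cells$mass, rho)
  out <- .shove_cpp(cells$x, cells$y, r, f, settings$max_iterations)
  if (!isTRUE(out$converged) && out$worst_deficit_fraction > 0.02) {
    warning(sprintf(
      "shoving iteration cap reached with overlaps remaining (worst deficit %.1f%% of pair limit)",
      100 * out$worst_deficit_fraction))
  }
  cells$x <- out$x
  cells$y <- out$y
  cells
}

#' Biomass-weighted aggregate centre
#'
#' @param cells a cell table
#' @return numeric `c(x, y)` in um
#' @export
aggregate_centre <- function(cells) {
  if (!nrow(cells)) stop("no cells: aggregate centre undefined")
  w <- cells$mass / sum(cells$mass)
  c(x = sum(cells$x * w), y = sum(cells$y * w))
}

#' Aggregate radius
#'
#' Maximum over cells of (distance of the cell centre from the
#' biomass-weighted centroid, plus the cell radius).
#'
#' @param cells a cell table
#' @param ecology the community preset (for cell densities)
#' @param centre optional fixed centre; defaults to [aggregate_centre()]
#' @return radius in um
#' @export
aggregate_radius <- function(cells, ecology, centre = NULL) {
  if (!nrow(cells)) stop("no cells: aggregate radius undefined")
  if (is.null(centre)) centre <- aggregate_centre(cells)
  rho <- vapply(ecology$populations, `[[`, numeric(1), "rho")[cells$population]
  r <- radius_from_mass(cells$mass, rho)
  d <- sqrt((cells$x - centre[[1L]])^2 + (cells$y - centre[[2L]])^2)
  max(d + r)
}

#' Remove cells beyond a maximum aggregate radius (shear detachment)
#'
#' Models shear forces as an abrupt size cap: every cell whose centre lies
#' strictly more than `max_radius` from the aggregate centre is removed;
#' all other cells are untouched.
#'
#' @param cells a cell table
#' @param max_radius detachment radius in um
#' @param centre aggregate centre; defaults to the biomass-weighted centroid
#'   of the input cells
#' @return the filtered cell table
#' @export
apply_detachment <- function(cells, max_radius, centre = NULL) {
  stopifnot(max_radius > 0)
  if (!nrow(cells)) return(cells)
  if (is.null(centre)) centre <- aggregate_centre(cells)
  d <- sqrt((cells$x - centre[[1L]])^2 + (cells$y - centre[[2L]])^2)
  cells[d <= max_radius, , drop = FALSE]
}
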