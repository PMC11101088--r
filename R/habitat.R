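# Direction order for the Moore neighbourhood: (dr, dc) pairs arranged so
# that the opposite of direction d (1-based row d) is row 9 - d. The same
# order is hard-coded in src/engine.cpp; do not reorder.
.DIRS <- matrix(c(-1L, -1L,
                  -1L,  0L,
                  -1L,  1L,
                   0L, -1L,
                   0L,  1L,
                   1L, -1L,
                   1L,  0L,
                   1L,  1L), ncol = 2L, byrow = TRUE,
                dimnames = list(NULL, c("dr", "dc")))

.wrap1 <- function(i, M) ((i - 1L) %% M) + 1L

#' Moore neighbourhood of a lattice site
#'
#' Returns the 8 sites surrounding `site` on the `M x M` torus (edges wrap by
#' modular arithmetic), in the package's canonical direction order.
#'
#' @param site integer vector `c(row, col)`, 1-based.
#' @param M lattice edge size.
#' @return An 8 x 2 integer matrix with columns `row`, `col`.
#' @examples
#' moore_neighbors(c(1, 1), 100)  # wraps to rows/cols 100
#' @export
moore_neighbors <- function(site, M) {
  stopifnot(length(site) == 2L, site >= 1L, site <= M)
  out <- cbind(row = .wrap1(site[1L] + .DIRS[, "dr"], M),
               col = .wrap1(site[2L] + .DIRS[, "dc"], M))
  out
}

.new_habitat <- function(M, r0) {
  structure(list(
    M = as.integer(M),
    occ = matrix(0L, M, M),
    energy = matrix(0, M, M),
    resource = matrix(as.numeric(r0), M, M),
    links = matrix(0L, M, M)),
    class = "habitat")
}

#' Initialize a fresh habitat
#'
#' Builds an `M x M` toroidal habitat with `r0` resource units at every site
#' and the initial population placed uniformly at random on distinct sites,
#' every founder holding energy `e0` and no association links. With
#' `placement = "exact"` exactly `n0_C + n0_D` cells are placed; with
#' `"poisson"` the two counts are Poisson draws with those means (capped at
#' lattice capacity).
#'
#' @param p a `sim_params` object.
#' @return A `habitat` object: a list with elements `M`, `occ` (0 empty,
#'   1 cooperator, 2 defector), `energy`, `resource`, and `links` (the
#'   per-site 8-bit association mask).
#' @export
initialize_habitat <- function(p) {
  p <- validate_parameters(p)
  M <- p$M
  h <- .new_habitat(M, p$r0)
  nC <- p$n0_C
  nD <- p$n0_D
  if (identical(p$placement, "poisson")) {
    nC <- stats::rpois(1L, p$n0_C)
    nD <- stats::rpois(1L, p$n0_D)
    if (nC + nD > M^2) stop("drawn initial population exceeds lattice capacity",
                            call. = FALSE)
  }
  n <- nC + nD
  if (n > 0L) {
    sites <- sample.int(M^2, n)
    kinds <- rep(c(1L, 2L), c(nC, nD))
    h$occ[sites] <- kinds
    h$energy[sites] <- p$e0
  }
  h
}

#' Total resource in a habitat
#' @param h a `habitat` object.
#' @return The summed per-site resource (resource units).
#' @export
total_resource <- function(h) sum(h$resource)

#' Cooperator and defector counts
#' @param h a `habitat` object.
#' @return Named integer vector `c(coop = , def = )`.
#' @export
cell_counts <- function(h) {
  c(coop = sum(h$occ == 1L), def = sum(h$occ == 2L))
}

#' Per-site associated-neighbour counts
#'
#' Decodes the association-link masks into the per-cell link count `N_a`
#' (0 to 8; 0 at empty sites).
#'
#' @param h a `habitat` object.
#' @return An `M x M` integer matrix.
#' @export
link_count_grid <- function(h) {
  na <- matrix(0L, h$M, h$M)
  for (d in 0:7) na <- na + (bitwAnd(h$links, bitwShiftL(1L, d)) != 0L)
  na
}

# linear index (1-based, column-major) of the Moore neighbour of linear site
# i in direction d (1..8)
.neighbor_linear <- function(i, d, M) {
  r <- ((i - 1L) %% M) + 1L
  c <- ((i - 1L) %/% M) + 1L
  rr <- .wrap1(r + .DIRS[d, "dr"], M)
  cc <- .wrap1(c + .DIRS[d, "dc"], M)
  (cc - 1L) * M + rr
}

# create the symmetric link between linear sites i and its neighbour in
# direction d; both must be occupied and not already linked
.add_link <- function(h, i, d) {
  j <- .neighbor_linear(i, d, h$M)
  stopifnot(h$occ[i] != 0L, h$occ[j] != 0L)
  h$links[i] <- bitwOr(h$links[i], bitwShiftL(1L, d - 1L))
  h$links[j] <- bitwOr(h$links[j], bitwShiftL(1L, 8L - d))
  h
}

# drop every link of linear site i (reciprocal bits included)
.clear_links <- function(h, i) {
  mask <- h$links[i]
  if (mask == 0L) return(h)
  for (d in 1:8) {
    if (bitwAnd(mask, bitwShiftL(1L, d - 1L)) != 0L) {
      j <- .neighbor_linear(i, d, h$M)
      h$links[j] <- bitwAnd(h$links[j], bitwNot(bitwShiftL(1L, 8L - d)))
    }
  }
  h$links[i] <- 0L
  h
}

#' Full-scan habitat invariant check
#'
#' Brute-force oracle over the whole lattice: at most one cell per site (by
#' construction of the occupancy grid), positive energy exactly at occupied
#' sites, resource non-negative, and every association link joining two
#' Moore-adjacent occupied sites with its reciprocal bit set (symmetry).
#' Used by the test suite after long random update sequences.
#'
#' @param h a `habitat` object.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
check_habitat <- function(h) {
  M <- h$M
  if (!all(h$occ %in% c(0L, 1L, 2L))) stop("invalid occupancy values")
  if (any(h$resource < 0)) stop("negative resource")
  if (any(h$energy[h$occ != 0L] <= 0)) stop("occupied site with energy <= 0")
  if (any(h$energy[h$occ == 0L] != 0)) stop("empty site with nonzero energy")
  if (any(h$links[h$occ == 0L] != 0L)) stop("empty site with links")
  occ_sites <- which(h$occ != 0L)
  for (i in occ_sites) {
    mask <- h$links[i]
    if (mask == 0L) next
    for (d in 1:8) {
      if (bitwAnd(mask, bitwShiftL(1L, d - 1L)) != 0L) {
        j <- .neighbor_linear(i, d, M)
        if (h$occ[j] == 0L)
          stop("link from site ", i, " to unoccupied site ", j)
        if (bitwAnd(h$links[j], bitwShiftL(1L, 8L - d)) == 0L)
          stop("asymmetric link between sites ", i, " and ", j)
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.habitat <- function(x, ...) {
  cts <- cell_counts(x)
  cat(sprintf("habitat: %d x %d torus, %d cooperators, %d defectors, total resource %g\n",
              x$M, x$M, cts[["coop"]], cts[["def"]], total_resource(x)))
  cat(sprintf("  associated cells: %d\n", sum(x$links != 0L & x$occ != 0L)))
  invisible(x)
}

#' @export
plot.habitat <- function(x, which = c("cells", "resource", "association"), ...) {
  which <- match.arg(which)
  if (which == "cells") {
    graphics::image(t(x$occ)[, x$M:1, drop = FALSE], zlim = c(0, 2),
                    col = c("white", "#2166AC", "#B2182B"), axes = FALSE,
                    main = "cells (blue cooperator, red defector)", ...)
  } else if (which == "resource") {
    graphics::image(t(x$resource)[, x$M:1, drop = FALSE], axes = FALSE,
                    col = grDevices::hcl.colors(32, "YlOrBr", rev = TRUE),
                    main = "per-site resource", ...)
  } else {
    graphics::image(t(link_count_grid(x))[, x$M:1, drop = FALSE],
                    zlim = c(0, 8), axes = FALSE,
                    col = grDevices::gray.colors(9, start = 1, end = 0),
                    main = "associated neighbours (0-8)", ...)
  }
  invisible(x)
}
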