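# Propagule formation and colonization: how a subpopulation of the exhausted
# habitat is selected (randomly or by strongest aggregate) and how it is laid
# out in the fresh habitat (same coordinates, translated pattern, packed
# square, or dispersed).

.LAYOUTS <- c("preserved_coordinates", "preserved_relative_pattern",
              "packed_square", "dispersed")

.new_propagule <- function(h, sites, mechanism, layout, window_origin = NULL) {
  if (length(sites) == 0L)
    stop("propagule is empty", call. = FALSE)
  cells <- data.frame(
    row = ((sites - 1L) %% h$M) + 1L,
    col = ((sites - 1L) %/% h$M) + 1L,
    kind = h$occ[sites])
  structure(list(cells = cells, mechanism = mechanism, layout = layout,
                 window_origin = window_origin, M = h$M),
            class = "propagule")
}

#' @export
print.propagule <- function(x, ...) {
  cat(sprintf("propagule: %d cells (%d cooperators, %d defectors), mechanism %s, layout %s\n",
              nrow(x$cells), sum(x$cells$kind == 1L), sum(x$cells$kind == 2L),
              x$mechanism, x$layout))
  invisible(x)
}

# linear site indices of the edge x edge toroidal window whose top-left
# corner is at (origin[1], origin[2]) (1-based)
.window_sites <- function(origin, edge, M) {
  rows <- .wrap1(origin[1L] + 0:(edge - 1L), M)
  cols <- .wrap1(origin[2L] + 0:(edge - 1L), M)
  as.vector(outer(rows, (cols - 1L) * M, `+`))
}

# top-left corner of the window "centred" on (r, c): spans rows
# [r - edge/2, r + edge/2 - 1] (edge is even in the default design)
.window_origin_centered <- function(center, edge, M) {
  c(.wrap1(center[1L] - edge %/% 2L, M), .wrap1(center[2L] - edge %/% 2L, M))
}

#' Can the population colonize a new habitat?
#'
#' Propagule formation requires cooperators (adhesion builds the fruiting
#' body), so by default no colonization can happen once cooperators are
#' extinct, under any mechanism (`require_cooperator = FALSE` relaxes this).
#' Under `"none"` there is never colonization; under random fragmentation
#' the population must additionally exceed `min_pop_for_fragmentation`.
#'
#' @param h a `habitat` object.
#' @param p a `sim_params` object.
#' @return `TRUE` or `FALSE`.
#' @export
can_colonize <- function(h, p) {
  p <- validate_parameters(p)
  if (identical(p$mechanism, "none")) return(FALSE)
  cts <- cell_counts(h)
  pop <- sum(cts)
  if (pop == 0L) return(FALSE)
  if (p$require_cooperator && cts[["coop"]] == 0L) return(FALSE)
  if (identical(p$mechanism, "random_fragmentation") &&
      pop <= p$min_pop_for_fragmentation) return(FALSE)
  TRUE
}

#' Propagule selection mechanisms
#'
#' Each selector draws a propagule from an exhausted habitat:
#' * `select_random_dispersion`: `min(N_P, population)` cells sampled
#'   uniformly without replacement; colonists keep their coordinates
#'   (dispersed arrival).
#' * `select_random_refuge`: the same sampling, but colonists are packed in a
#'   random arrangement inside one `propagule_edge` x `propagule_edge` block
#'   (their original positions are discarded).
#' * `select_random_fragmentation`: a uniformly placed toroidal window,
#'   redrawn until non-empty; all its cells transfer with their relative
#'   pattern preserved.
#' * `select_aggregation_based`: the window is centred on a uniformly chosen
#'   cell among those with the maximal associated-neighbour count (the centre
#'   of a largest aggregate); `disperse = TRUE` (mechanism E) scatters the
#'   colonists on arrival, `disperse = FALSE` (mechanism F) preserves the
#'   pattern.
#'
#' @param h a `habitat` object (scarcity is the caller's concern).
#' @param p a `sim_params` object.
#' @param disperse scatter the window's cells on arrival (mechanism E) rather
#'   than preserving their pattern (mechanism F)?
#' @return A `propagule` object.
#' @name propagule_selection
NULL

#' @rdname propagule_selection
#' @export
select_random_dispersion <- function(h, p) {
  p <- validate_parameters(p)
  sites <- which(h$occ != 0L)
  k <- min(p$N_P, length(sites))
  pick <- sites[sample.int(length(sites), k)]
  .new_propagule(h, pick, "random_dispersion", "preserved_coordinates")
}

#' @rdname propagule_selection
#' @export
select_random_refuge <- function(h, p) {
  p <- validate_parameters(p)
  sites <- which(h$occ != 0L)
  k <- min(p$N_P, length(sites))
  pick <- sites[sample.int(length(sites), k)]
  .new_propagule(h, pick, "random_refuge", "packed_square")
}

#' @rdname propagule_selection
#' @export
select_random_fragmentation <- function(h, p, max_redraws = 10000L) {
  p <- validate_parameters(p)
  if (all(h$occ == 0L)) stop("cannot select a fragment from an empty lattice",
                             call. = FALSE)
  edge <- p$propagule_edge
  for (i in seq_len(max_redraws)) {
    origin <- c(sample.int(h$M, 1L), sample.int(h$M, 1L))
    win <- .window_sites(origin, edge, h$M)
    inside <- win[h$occ[win] != 0L]
    if (length(inside) > 0L)
      return(.new_propagule(h, inside, "random_fragmentation",
                            "preserved_relative_pattern", origin))
  }
  # vanishingly unlikely with a populated lattice: centre on a random cell
  sites <- which(h$occ != 0L)
  ctr <- sites[sample.int(length(sites), 1L)]
  origin <- .window_origin_centered(c(((ctr - 1L) %% h$M) + 1L,
                                      ((ctr - 1L) %/% h$M) + 1L), edge, h$M)
  win <- .window_sites(origin, edge, h$M)
  .new_propagule(h, win[h$occ[win] != 0L], "random_fragmentation",
                 "preserved_relative_pattern", origin)
}

#' @rdname propagule_selection
#' @export
select_aggregation_based <- function(h, p, disperse = FALSE) {
  p <- validate_parameters(p)
  sites <- which(h$occ != 0L)
  if (length(sites) == 0L)
    stop("cannot select an aggregate from an empty lattice", call. = FALSE)
  na <- link_count_grid(h)
  mx <- max(na[sites])
  centers <- sites[na[sites] == mx]
  ctr <- centers[sample.int(length(centers), 1L)]
  center_rc <- c(((ctr - 1L) %% h$M) + 1L, ((ctr - 1L) %/% h$M) + 1L)
  origin <- .window_origin_centered(center_rc, p$propagule_edge, h$M)
  win <- .window_sites(origin, p$propagule_edge, h$M)
  inside <- win[h$occ[win] != 0L]
  mech <- if (disperse) "agg_dispersion" else "agg_propagule"
  layout <- if (disperse) "dispersed" else "preserved_relative_pattern"
  .new_propagule(h, inside, mech, layout, origin)
}

#' Select a propagule according to the configured mechanism
#'
#' Dispatches to the selector matching `p$mechanism`; errors for `"none"` and
#' when [can_colonize()] is `FALSE`.
#'
#' @param h a `habitat` object.
#' @param p a `sim_params` object.
#' @return A `propagule` object.
#' @export
propagule_select <- function(h, p) {
  p <- validate_parameters(p)
  if (!can_colonize(h, p))
    stop("colonization is not possible (mechanism '", p$mechanism,
         "', cooperators ", cell_counts(h)[["coop"]], ", population ",
         sum(cell_counts(h)), ")", call. = FALSE)
  switch(p$mechanism,
         random_dispersion = select_random_dispersion(h, p),
         random_refuge = select_random_refuge(h, p),
         random_fragmentation = select_random_fragmentation(h, p),
         agg_dispersion = select_aggregation_based(h, p, disperse = TRUE),
         agg_propagule = select_aggregation_based(h, p, disperse = FALSE))
}

#' Colonize a fresh habitat with a propagule
#'
#' Builds a new habitat with `r0` resource at every site and places the
#' propagule's cells according to its layout: `preserved_coordinates` keeps
#' each cell's site; `preserved_relative_pattern` translates the source
#' window so its top-left corner lands at a fixed central anchor (any fixed
#' anchor is equivalent on a torus); `packed_square` arranges the cells
#' randomly inside one anchored window; `dispersed` scatters them on
#' uniformly sampled distinct sites. Every colonist's energy is reset to
#' `e0` and no association links exist in the new habitat (cells must
#' re-associate).
#'
#' @param propagule a `propagule` object.
#' @param p a `sim_params` object.
#' @return A `habitat` object.
#' @export
colonize <- function(propagule, p) {
  p <- validate_parameters(p)
  stopifnot(inherits(propagule, "propagule"))
  cells <- propagule$cells
  k <- nrow(cells)
  if (k == 0L) stop("propagule is empty", call. = FALSE)
  M <- p$M
  edge <- p$propagule_edge
  h <- .new_habitat(M, p$r0)
  anchor <- c(M %/% 2L - edge %/% 2L + 1L, M %/% 2L - edge %/% 2L + 1L)
  sites <- switch(propagule$layout,
    preserved_coordinates = (cells$col - 1L) * M + cells$row,
    preserved_relative_pattern = {
      o <- propagule$window_origin
      rel_r <- (cells$row - o[1L]) %% propagule$M
      rel_c <- (cells$col - o[2L]) %% propagule$M
      nr <- .wrap1(anchor[1L] + rel_r, M)
      nc <- .wrap1(anchor[2L] + rel_c, M)
      (nc - 1L) * M + nr
    },
    packed_square = {
      win <- .window_sites(anchor, edge, M)
      win[sample.int(length(win), k)]
    },
    dispersed = sample.int(M^2, k),
    stop("unknown layout: ", propagule$layout, call. = FALSE))
  if (anyDuplicated(sites))
    stop("placement collision in layout ", propagule$layout, call. = FALSE)
  h$occ[sites] <- cells$kind
  h$energy[sites] <- p$e0
  h
}

# callback handed to the C++ engine at each scarcity event: receives the
# occupancy and link vectors of the exhausted habitat, returns the freshly
# colonized habitat's state vectors
.colonization_cb <- function(p) {
  M <- p$M
  force(p)
  function(occ_vec, links_vec) {
    h <- structure(list(M = M,
                        occ = matrix(occ_vec, M, M),
                        energy = matrix(0, M, M),
                        resource = matrix(0, M, M),
                        links = matrix(links_vec, M, M)),
                   class = "habitat")
    nh <- colonize(propagule_select(h, p), p)
    list(occ = as.integer(nh$occ), energy = as.numeric(nh$energy),
         resource = as.numeric(nh$resource), links = as.integer(nh$links))
  }
}
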