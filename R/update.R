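# Pure-R reference implementation of the asynchronous update rule.
#
# The C++ engine (src/engine.cpp) is the production path; the functions here
# define the same semantics in plain R and consume R's RNG stream in exactly
# the same draw order, so that n updates run through either path from the
# same seed produce bit-identical habitats. The test suite relies on this.
# Any change to the draw order must be made in both places.

#' Predation probability under size-dependent selection
#'
#' Per-update probability that a cell with `N_a` associated neighbours is
#' captured by the (implicit, unsaturated) predator:
#' `P = 1 / (N_a + 2)^s`. Aggregated cells are effectively larger than the
#' predator's prey size, so `P` falls steeply with the link count.
#'
#' @param N_a associated-neighbour count(s), integers in 0..8 (vectorized).
#' @param s predation strength exponent, or `"off"` to disable predation.
#' @return Numeric vector of probabilities; all zero when `s = "off"`.
#' @examples
#' predation_probability(0, 5)  # 1/32
#' predation_probability(8, 5)  # 1e-5
#' @export
predation_probability <- function(N_a, s) {
  if (!is.numeric(N_a) || any(N_a < 0 | N_a > 8 | N_a != round(N_a)))
    stop("N_a must be integer(s) in 0..8", call. = FALSE)
  if (identical(s, "off")) return(rep(0, length(N_a)))
  .check_scalar(s, "s", min = 0)
  (N_a + 2)^(-s)
}

#' Has the resource-poor period commenced?
#'
#' The resource-rich period lasts while total habitat resource is at or above
#' the threshold `R`; scarcity (and hence propagule formation) triggers
#' strictly below it.
#'
#' @param h a `habitat` object.
#' @param p a `sim_params` object.
#' @return `TRUE` iff `total_resource(h) < p$R`.
#' @export
scarcity_reached <- function(h, p) total_resource(h) < p$R

# ---- internal mutable state mirroring the C++ engine -----------------------

# Occupied-list bookkeeping is replicated exactly: canonical initial order is
# increasing linear site index; cells are appended on birth and swap-removed
# on death; a moving cell keeps its list position.
.st_new <- function(h, p) {
  st <- new.env(parent = emptyenv())
  st$M <- h$M
  st$occ <- as.integer(h$occ)
  st$energy <- as.numeric(h$energy)
  st$resource <- as.numeric(h$resource)
  st$links <- as.integer(h$links)
  na <- integer(length(st$occ))
  for (d in 0:7) na <- na + (bitwAnd(st$links, bitwShiftL(1L, d)) != 0L)
  st$na <- na
  st$occ_list <- which(st$occ != 0L)
  st$pos <- integer(length(st$occ))
  st$pos[st$occ_list] <- seq_along(st$occ_list)
  st$n_coop <- sum(st$occ == 1L)
  st$n_def <- sum(st$occ == 2L)
  st$p <- p
  st
}

.st_habitat <- function(st) {
  M <- st$M
  structure(list(M = M,
                 occ = matrix(st$occ, M, M),
                 energy = matrix(st$energy, M, M),
                 resource = matrix(st$resource, M, M),
                 links = matrix(st$links, M, M)),
            class = "habitat")
}

.st_add_link <- function(st, i, d) {
  j <- .neighbor_linear(i, d, st$M)
  st$links[i] <- bitwOr(st$links[i], bitwShiftL(1L, d - 1L))
  st$links[j] <- bitwOr(st$links[j], bitwShiftL(1L, 8L - d))
  st$na[i] <- st$na[i] + 1L
  st$na[j] <- st$na[j] + 1L
  j
}

.st_remove_link <- function(st, i, d) {
  j <- .neighbor_linear(i, d, st$M)
  st$links[i] <- bitwAnd(st$links[i], bitwNot(bitwShiftL(1L, d - 1L)))
  st$links[j] <- bitwAnd(st$links[j], bitwNot(bitwShiftL(1L, 8L - d)))
  st$na[i] <- st$na[i] - 1L
  st$na[j] <- st$na[j] - 1L
}

.st_clear_links <- function(st, i) {
  mask <- st$links[i]
  if (mask == 0L) return(invisible())
  for (d in 1:8) {
    if (bitwAnd(mask, bitwShiftL(1L, d - 1L)) != 0L) {
      j <- .neighbor_linear(i, d, st$M)
      st$links[j] <- bitwAnd(st$links[j], bitwNot(bitwShiftL(1L, 8L - d)))
      st$na[j] <- st$na[j] - 1L
    }
  }
  st$links[i] <- 0L
  st$na[i] <- 0L
}

.st_add_cell <- function(st, i, kind, e) {
  st$occ[i] <- kind
  st$energy[i] <- e
  st$occ_list <- c(st$occ_list, i)
  st$pos[i] <- length(st$occ_list)
  if (kind == 1L) st$n_coop <- st$n_coop + 1L else st$n_def <- st$n_def + 1L
}

.st_remove_cell <- function(st, i) {
  .st_clear_links(st, i)
  if (st$occ[i] == 1L) st$n_coop <- st$n_coop - 1L else st$n_def <- st$n_def - 1L
  st$occ[i] <- 0L
  st$energy[i] <- 0
  pp <- st$pos[i]
  last <- length(st$occ_list)
  lastsite <- st$occ_list[last]
  st$occ_list[pp] <- lastsite
  st$pos[lastsite] <- pp
  st$occ_list <- st$occ_list[-last]
  st$pos[i] <- 0L
}

.st_move_cell <- function(st, from, to) {
  st$occ[to] <- st$occ[from]
  st$energy[to] <- st$energy[from]
  st$occ[from] <- 0L
  st$energy[from] <- 0
  pp <- st$pos[from]
  st$occ_list[pp] <- to
  st$pos[to] <- pp
  st$pos[from] <- 0L
}

# ---- sub-steps (identical draw order to src/engine.cpp) --------------------

.sub_metabolism <- function(st, i) {
  c_kind <- if (st$occ[i] == 1L) st$p$c_C else st$p$c_D
  st$energy[i] <- st$energy[i] - c_kind
  if (st$energy[i] <= 0) {
    .st_remove_cell(st, i)
    return(TRUE)  # died of starvation
  }
  FALSE
}

.sub_consume <- function(st, i) {
  take <- min(st$resource[i], st$p$uptake)
  if (take > 0) {
    st$resource[i] <- st$resource[i] - take
    st$energy[i] <- st$energy[i] + take
  }
  take
}

.sub_divide <- function(st, i) {
  out <- list(divided = FALSE, overwrote = FALSE, daughter_site = NA_integer_)
  if (st$energy[i] <= st$p$d) return(out)
  d <- as.integer(stats::runif(1) * 8) + 1L
  tgt <- .neighbor_linear(i, d, st$M)
  overwrite <- st$occ[tgt] != 0L
  fire <- if (!overwrite) stats::runif(1) < st$p$S else stats::runif(1) < st$p$S * st$p$O
  if (fire) {
    if (overwrite) .st_remove_cell(st, tgt)
    e2 <- st$energy[i] / 2
    st$energy[i] <- e2
    .st_add_cell(st, tgt, st$occ[i], e2)
    out <- list(divided = TRUE, overwrote = overwrite, daughter_site = tgt)
  }
  out
}

.sub_associate <- function(st, i) {
  A <- if (st$occ[i] == 1L) st$p$A_C else st$p$A_D
  if (A > 0 && stats::runif(1) < A) {
    cand <- integer(0)
    for (d in 1:8) {
      j <- .neighbor_linear(i, d, st$M)
      if (st$occ[j] != 0L && bitwAnd(st$links[i], bitwShiftL(1L, d - 1L)) == 0L)
        cand <- c(cand, d)
    }
    if (length(cand) > 0L) {
      d <- cand[as.integer(stats::runif(1) * length(cand)) + 1L]
      j <- .st_add_link(st, i, d)
      return(j)  # acceptor site; the cell participated in association
    }
  }
  NA_integer_
}

.sub_dissociate <- function(st, i, participated) {
  if (participated || st$links[i] == 0L) return(FALSE)
  if (stats::runif(1) < st$p$D) {
    if (identical(st$p$dissociation_mode, "all")) {
      .st_clear_links(st, i)
    } else {
      jth <- as.integer(stats::runif(1) * st$na[i])
      seen <- 0L
      for (d in 1:8) {
        if (bitwAnd(st$links[i], bitwShiftL(1L, d - 1L)) != 0L) {
          if (seen == jth) { .st_remove_link(st, i, d); break }
          seen <- seen + 1L
        }
      }
    }
    return(TRUE)
  }
  FALSE
}

# returns list(site =, moved_to =, died =): `site` is the (possibly new)
# location of the cell, NA if it died paying the relocation cost
.sub_move <- function(st, i) {
  out <- list(site = i, moved_to = NA_integer_, died = FALSE)
  if (st$links[i] != 0L) return(out)
  choice <- as.integer(stats::runif(1) * 9)
  if (choice < 8L) {
    tgt <- .neighbor_linear(i, choice + 1L, st$M)
    if (st$occ[tgt] == 0L) {
      .st_move_cell(st, i, tgt)
      st$energy[tgt] <- st$energy[tgt] - st$p$m
      out$site <- tgt
      out$moved_to <- tgt
      if (st$energy[tgt] <= 0) {
        .st_remove_cell(st, tgt)
        out$site <- NA_integer_
        out$died <- TRUE
      }
    }
  }
  out
}

.sub_predation <- function(st, i) {
  if (!predation_enabled(st$p)) return(FALSE)
  P <- (st$na[i] + 2)^(-as.numeric(st$p$s))
  if (stats::runif(1) < P) {
    .st_remove_cell(st, i)
    return(TRUE)
  }
  FALSE
}

.r_update_one <- function(st) {
  n <- length(st$occ_list)
  out <- list(site = NA_integer_, kind = NA_integer_, consumed = 0,
              divided = FALSE, overwrote = FALSE, daughter_site = NA_integer_,
              assoc_site = NA_integer_, dissociated = FALSE,
              moved_to = NA_integer_, death = "none")
  if (n == 0L) return(out)
  i <- st$occ_list[as.integer(stats::runif(1) * n) + 1L]
  out$site <- i
  out$kind <- st$occ[i]
  if (.sub_metabolism(st, i)) { out$death <- "starvation"; return(out) }
  out$consumed <- .sub_consume(st, i)
  dv <- .sub_divide(st, i)
  out$divided <- dv$divided; out$overwrote <- dv$overwrote
  out$daughter_site <- dv$daughter_site
  out$assoc_site <- .sub_associate(st, i)
  participated <- !is.na(out$assoc_site)
  out$dissociated <- .sub_dissociate(st, i, participated)
  mv <- .sub_move(st, i)
  out$moved_to <- mv$moved_to
  if (mv$died) { out$death <- "starvation"; return(out) }
  i <- mv$site
  if (.sub_predation(st, i)) out$death <- "predation"
  out
}

# ---- exported single-step operations (reference semantics) -----------------

.linear_site <- function(h, site) {
  stopifnot(length(site) == 2L, site >= 1L, site <= h$M)
  (site[2L] - 1L) * h$M + site[1L]
}

.site_rc <- function(i, M) {
  if (is.na(i)) return(NULL)
  c(row = ((i - 1L) %% M) + 1L, col = ((i - 1L) %/% M) + 1L)
}

.step_wrap <- function(h, site, p, f) {
  p <- validate_parameters(p)
  i <- .linear_site(h, site)
  if (h$occ[i] == 0L) stop("no cell at site (", site[1L], ", ", site[2L], ")",
                           call. = FALSE)
  st <- .st_new(h, p)
  res <- f(st, i)
  res$habitat <- .st_habitat(st)
  res
}

#' Single-cell update sub-steps (reference implementation)
#'
#' These functions apply one sub-step of the asynchronous update rule to the
#' cell at `site` and return the modified habitat together with the outcome
#' flags of the sub-step. They define the model's semantics in plain R; the
#' compiled engine used by [run_simulation()] implements the identical rule
#' (and the test suite checks both paths agree draw-for-draw).
#'
#' The full per-update order is: metabolism, consumption, division,
#' association, dissociation, movement, predation, with the cell removed at
#' the first death condition.
#'
#' @param h a `habitat` object.
#' @param site integer `c(row, col)` of an occupied site.
#' @param p a `sim_params` object.
#' @param participated did the cell take part in association during this same
#'   update (initiator or acceptor)? If so it cannot dissociate.
#' @return A list with element `habitat` (the updated habitat) plus
#'   step-specific outcome fields:
#'   * `step_metabolism`: `died` (starvation when energy drops to 0 or below);
#'   * `step_consume`: `consumed` (resource units moved from site to cell);
#'   * `step_divide`: `divided`, `overwrote`, `daughter_site`;
#'   * `step_associate`: `assoc_site` (acceptor `c(row, col)` or `NULL`);
#'   * `step_dissociate`: `dissociated`;
#'   * `step_move`: `moved_to` (`c(row, col)` or `NULL`), `died`;
#'   * `step_predation`: `died`.
#' @name update_steps
NULL

#' @rdname update_steps
#' @export
step_metabolism <- function(h, site, p) {
  .step_wrap(h, site, p, function(st, i) list(died = .sub_metabolism(st, i)))
}

#' @rdname update_steps
#' @export
step_consume <- function(h, site, p) {
  .step_wrap(h, site, p, function(st, i) list(consumed = .sub_consume(st, i)))
}

#' @rdname update_steps
#' @export
step_divide <- function(h, site, p) {
  .step_wrap(h, site, p, function(st, i) .sub_divide(st, i))
}

#' @rdname update_steps
#' @export
step_associate <- function(h, site, p) {
  res <- .step_wrap(h, site, p, function(st, i) list(j = .sub_associate(st, i)))
  res$assoc_site <- .site_rc(res$j, h$M)
  res$j <- NULL
  res
}

#' @rdname update_steps
#' @export
step_dissociate <- function(h, site, p, participated = FALSE) {
  .step_wrap(h, site, p,
             function(st, i) list(dissociated = .sub_dissociate(st, i, participated)))
}

#' @rdname update_steps
#' @export
step_move <- function(h, site, p) {
  res <- .step_wrap(h, site, p, function(st, i) .sub_move(st, i))
  res$moved_to <- .site_rc(res$moved_to, h$M)
  res$site <- NULL
  res
}

#' @rdname update_steps
#' @export
step_predation <- function(h, site, p) {
  .step_wrap(h, site, p, function(st, i) list(died = .sub_predation(st, i)))
}

#' One full asynchronous update (reference implementation)
#'
#' Selects a uniformly random cell and applies the whole sub-step sequence
#' (metabolism, consumption, division, association, dissociation, movement,
#' predation), removing the cell at the first death condition. An empty
#' habitat yields a no-op outcome.
#'
#' @param h a `habitat` object.
#' @param p a `sim_params` object.
#' @return A list with `habitat` and an `outcome` list (selected `site` and
#'   `kind`, `consumed`, `divided`, `overwrote`, `daughter_site`,
#'   `assoc_site`, `dissociated`, `moved_to`, and `death` in
#'   `c("none", "starvation", "predation")`).
#' @export
update_one_cell <- function(h, p) {
  p <- validate_parameters(p)
  st <- .st_new(h, p)
  out <- .r_update_one(st)
  list(habitat = .st_habitat(st), outcome = out)
}

#' Run many asynchronous updates (compiled engine)
#'
#' Applies `n` single-cell updates through the compiled engine, without
#' scarcity handling or colonization (see [run_simulation()] for full runs).
#' With `record = TRUE` a per-update outcome table is returned, including the
#' exact amount each update removed from the habitat's energy + resource
#' ledger (`sys_loss`), which the test suite uses as a conservation oracle.
#'
#' @param h a `habitat` object.
#' @param p a `sim_params` object.
#' @param n number of updates.
#' @param record keep a per-update outcome table?
#' @return A list with `habitat`, counts (`n_coop`, `n_def`, `n_linked`),
#'   `total_resource`, the engine's incremental `na` grid, and (if recorded)
#'   `outcomes`, a data frame with one row per update.
#' @export
update_cells <- function(h, p, n, record = FALSE) {
  p <- validate_parameters(p)
  res <- engine_steps(as.integer(h$occ), as.numeric(h$energy),
                      as.numeric(h$resource), as.integer(h$links),
                      .engine_par(p), as.integer(n), record)
  M <- h$M
  out <- list(
    habitat = structure(list(M = M,
                             occ = matrix(res$occ, M, M),
                             energy = matrix(res$energy, M, M),
                             resource = matrix(res$resource, M, M),
                             links = matrix(res$links, M, M)),
                        class = "habitat"),
    n_coop = res$n_coop, n_def = res$n_def, n_linked = res$n_linked,
    total_resource = res$total_resource,
    na = matrix(res$na, M, M))
  if (record) out$outcomes <- as.data.frame(res$outcomes)
  out
}
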