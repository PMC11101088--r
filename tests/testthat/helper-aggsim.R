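# Shared helpers for the aggsim test suite. All fixtures are built in code.

# small parameter set for unit tests; overrides applied on top
tiny_params <- function(...) {
  over <- list(...)
  base <- list(M = 10, n0_C = 5, n0_D = 5, N_P = 4, propagule_edge = 2,
               R = 4000, T = 1e4, seed = NULL)
  base[names(over)] <- over
  validate_parameters(do.call(sim_params, base))
}

# habitat with a single cell of given kind/energy at `site` (row, col)
one_cell_habitat <- function(M, site, kind = 2L, energy = 100,
                             r0 = 100, p = NULL) {
  h <- aggsim:::.new_habitat(M, r0)
  i <- (site[2L] - 1L) * M + site[1L]
  h$occ[i] <- kind
  h$energy[i] <- energy
  h
}

# place extra cells onto an existing habitat at (row, col) pairs
put_cells <- function(h, sites, kind = 1L, energy = 100) {
  for (k in seq_len(nrow(sites))) {
    i <- (sites[k, 2L] - 1L) * h$M + sites[k, 1L]
    h$occ[i] <- kind
    h$energy[i] <- energy
  }
  h
}

# the acceptance-scale (reduced-lattice) design used by the scaled
# reproduction checks: the full design scaled to a 50 x 50 lattice
acceptance_scaled_params <- function(mechanism, s) {
  q <- unclass(scale_params(sim_params(), 50))
  q$mechanism <- mechanism
  q$s <- s
  validate_parameters(q)
}

# cooperator survival (cooperators present at termination) over n seeded
# replicates of a reduced-scale condition; cached per condition so the
# acceptance criteria can share batches
.survival_cache <- new.env(parent = emptyenv())
scaled_survival <- function(mechanism, s, n = 20, seed_base = 1L) {
  key <- paste(mechanism, s, n, seed_base, sep = "|")
  if (!is.null(.survival_cache[[key]])) return(.survival_cache[[key]])
  p <- acceptance_scaled_params(mechanism, s)
  ex <- run_replicates(p, n, seed_base = seed_base)
  .survival_cache[[key]] <- ex
  ex
}
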