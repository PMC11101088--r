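# Experiment drivers: full simulations, replicate batches, parameter sweeps,
# and the five-way outcome classification of terminal cooperator ratios.

.TERMINATIONS <- c("t_reached", "extinction", "no_colonization_deadend",
                   "cooperator_fixation")

# counter-based seed splitting: replicate/grid-point streams are independent
# and reproducible from a single base seed; kept below 2^31 - 1
.derive_seed <- function(seed_base, counter) {
  as.integer((as.numeric(seed_base) * 48271 + as.numeric(counter) * 2654435) %%
               2147483646) + 1L
}

#' Run one full simulation
#'
#' Starts from a randomly initialized habitat and repeats asynchronous
#' single-cell updates until the configured length `T`, population
#' extinction, a scarcity event at which colonization is impossible (the
#' population is doomed), or — optionally — cooperator fixation. Whenever
#' total resource drops below `R`, a propagule is formed per `p$mechanism`
#' and instantaneously colonizes a fresh habitat; every colonization event is
#' logged in the trace.
#'
#' The terminal cooperator ratio is the cooperator fraction at the last
#' moment the population was non-empty (for runs ending in full extinction
#' this is the composition of the final survivors).
#'
#' @param p a `sim_params` object; `p$seed`, when non-`NULL`, seeds all
#'   randomness of the run.
#' @return An object of class `sim_run`: a list with `trace` (a data frame
#'   with columns `update`, `n_coop`, `n_def`, `total_resource`,
#'   `n_associated`, `event`), `final_habitat`, `termination`,
#'   `updates`, `terminal_ratio`, `n_colonizations`, `outcome`, `seed`, and
#'   `params`.
#' @examples
#' p <- sim_params(M = 20, n0_C = 8, n0_D = 8, R = 16000, N_P = 4,
#'                 propagule_edge = 2, T = 2e5, mechanism = "agg_propagule",
#'                 seed = 1)
#' r <- run_simulation(p)
#' r$terminal_ratio
#' @export
run_simulation <- function(p) {
  p <- validate_parameters(p)
  if (!is.null(p$seed)) set.seed(p$seed)
  h <- initialize_habitat(p)
  res <- engine_run(as.integer(h$occ), as.numeric(h$energy),
                    as.numeric(h$resource), as.integer(h$links),
                    .engine_par(p), .colonization_cb(p))
  ev <- res$trace_event
  trace <- data.frame(
    update = res$trace_update,
    n_coop = res$trace_n_coop,
    n_def = res$trace_n_def,
    total_resource = res$trace_total_resource,
    n_associated = res$trace_n_associated,
    event = ifelse(ev == 0L, "", mechanisms()[ev + 1L]),
    stringsAsFactors = FALSE)
  M <- p$M
  fh <- structure(list(M = M,
                       occ = matrix(res$occ, M, M),
                       energy = matrix(res$energy, M, M),
                       resource = matrix(res$resource, M, M),
                       links = matrix(res$links, M, M)),
                  class = "habitat")
  tot <- res$last_n_coop + res$last_n_def
  ratio <- if (tot > 0L) res$last_n_coop / tot else NA_real_
  structure(list(
    trace = trace,
    final_habitat = fh,
    termination = .TERMINATIONS[res$termination],
    updates = res$updates,
    terminal_ratio = ratio,
    n_colonizations = res$n_colonizations,
    outcome = classify_outcome(ratio),
    seed = p$seed,
    params = p), class = "sim_run")
}

#' Colonization events of a run
#' @param run a `sim_run` object.
#' @return A data frame with one row per colonization event: `update`,
#'   `mechanism`, and the propagule composition `n_coop`, `n_def`.
#' @export
colonization_events <- function(run) {
  stopifnot(inherits(run, "sim_run"))
  ev <- run$trace[run$trace$event != "", c("update", "event", "n_coop", "n_def")]
  names(ev)[2L] <- "mechanism"
  rownames(ev) <- NULL
  ev
}

#' Classify a terminal cooperator ratio into the five outcome classes
#'
#' The classes partition \[0, 1\]: exactly 0 (`defector_fixation`),
#' `(0, bins[1]]` (`defector_majority`), `(bins[1], bins[2])`
#' (`coexistence`), `[bins[2], 1)` (`cooperator_majority`), and exactly 1
#' (`cooperator_fixation`).
#'
#' @param terminal_ratio numeric vector of ratios in \[0, 1\] (NA allowed for
#'   runs whose population was never observed).
#' @param bins the two interior class edges, default `c(0.25, 0.75)`.
#' @return A factor with the five outcome levels.
#' @export
classify_outcome <- function(terminal_ratio, bins = c(0.25, 0.75)) {
  stopifnot(length(bins) == 2L, bins[1L] > 0, bins[2L] < 1, bins[1L] < bins[2L])
  if (any(!is.na(terminal_ratio) &
          (terminal_ratio < 0 | terminal_ratio > 1)))
    stop("terminal_ratio outside [0, 1]", call. = FALSE)
  lev <- c("defector_fixation", "defector_majority", "coexistence",
           "cooperator_majority", "cooperator_fixation")
  out <- rep(NA_character_, length(terminal_ratio))
  r <- terminal_ratio
  out[!is.na(r) & r == 0] <- lev[1L]
  out[!is.na(r) & r > 0 & r <= bins[1L]] <- lev[2L]
  out[!is.na(r) & r > bins[1L] & r < bins[2L]] <- lev[3L]
  out[!is.na(r) & r >= bins[2L] & r < 1] <- lev[4L]
  out[!is.na(r) & r == 1] <- lev[5L]
  factor(out, levels = lev)
}

#' Run independent replicate simulations
#'
#' Runs `n_reps` independent simulations whose seeds are split
#' deterministically from `seed_base`, and aggregates replicate-level
#' outcomes: terminal cooperator ratios, cooperator survival fraction,
#' colonization-event count mean and sample SD, and the five-way outcome
#' classification.
#'
#' @param p a `sim_params` object (its `seed` field is ignored).
#' @param n_reps number of replicates.
#' @param seed_base base seed from which replicate seeds are derived.
#' @param keep_runs keep the full `sim_run` objects (traces included)?
#' @return An object of class `sim_experiment`: a list with `replicates`
#'   (one row per run), `survival_fraction`, `mean_terminal_ratio`,
#'   `colonizations_mean`, `colonizations_sd`, `outcome_counts`, `params`,
#'   and optionally `runs`.
#' @export
run_replicates <- function(p, n_reps, seed_base = 1L, keep_runs = FALSE) {
  p <- validate_parameters(p)
  stopifnot(n_reps >= 1L)
  runs <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    q <- unclass(p)
    q$seed <- .derive_seed(seed_base, i)
    runs[[i]] <- run_simulation(validate_parameters(q))
  }
  reps <- data.frame(
    rep = seq_len(n_reps),
    seed = vapply(runs, function(r) as.integer(r$seed), integer(1)),
    terminal_ratio = vapply(runs, function(r) r$terminal_ratio, numeric(1)),
    n_colonizations = vapply(runs, function(r) as.integer(r$n_colonizations),
                             integer(1)),
    updates = vapply(runs, function(r) r$updates, numeric(1)),
    termination = vapply(runs, function(r) r$termination, character(1)),
    survived = vapply(runs, function(r) isTRUE(r$terminal_ratio > 0), logical(1)))
  reps$outcome <- classify_outcome(reps$terminal_ratio)
  out <- list(
    replicates = reps,
    survival_fraction = mean(reps$survived),
    mean_terminal_ratio = mean(reps$terminal_ratio, na.rm = TRUE),
    colonizations_mean = mean(reps$n_colonizations),
    colonizations_sd = stats::sd(reps$n_colonizations),
    outcome_counts = table(reps$outcome),
    params = p,
    seed_base = seed_base)
  if (keep_runs) out$runs <- runs
  structure(out, class = "sim_experiment")
}

#' Sweep association, dissociation and predation strength
#'
#' Runs [run_replicates()] over the Cartesian product of `A_C_values`,
#' `D_values` and `s_values` (each `s` may be numeric or `"off"`), in
#' deterministic row order, with independent seed streams per grid point.
#'
#' @param p a `sim_params` template.
#' @param A_C_values,D_values numeric vectors of probabilities.
#' @param s_values list or vector of predation strengths (`"off"` allowed).
#' @param n_reps replicates per grid point.
#' @param seed_base base seed; each grid point gets a derived stream.
#' @return An object of class `sim_sweep`: list with `coords` (the grid),
#'   `summaries` (one `sim_experiment` per row) and a `results` data frame
#'   (grid plus `mean_terminal_ratio`, `survival_fraction`,
#'   `colonizations_mean`).
#' @export
sweep_grid <- function(p, A_C_values, D_values, s_values, n_reps,
                       seed_base = 1L) {
  p <- validate_parameters(p)
  stopifnot(length(A_C_values) > 0, length(D_values) > 0, length(s_values) > 0)
  coords <- expand.grid(A_C = A_C_values, D = D_values,
                        s = seq_along(s_values), KEEP.OUT.ATTRS = FALSE)
  s_list <- as.list(s_values)
  summaries <- vector("list", nrow(coords))
  for (g in seq_len(nrow(coords))) {
    q <- unclass(p)
    q$A_C <- coords$A_C[g]
    q$D <- coords$D[g]
    q$s <- s_list[[coords$s[g]]]
    summaries[[g]] <- run_replicates(validate_parameters(q), n_reps,
                                     seed_base = .derive_seed(seed_base, g))
  }
  res <- coords
  res$s <- vapply(s_list[coords$s], function(s) format(s), character(1))
  res$mean_terminal_ratio <- vapply(summaries,
                                    function(x) x$mean_terminal_ratio, numeric(1))
  res$survival_fraction <- vapply(summaries,
                                  function(x) x$survival_fraction, numeric(1))
  res$colonizations_mean <- vapply(summaries,
                                   function(x) x$colonizations_mean, numeric(1))
  structure(list(coords = res[, c("A_C", "D", "s")], summaries = summaries,
                 results = res, params = p),
            class = "sim_sweep")
}

#' Sweep the initial cooperator ratio
#'
#' Varies the initial cooperator fraction at fixed total founder count
#' (`n0_C + n0_D` of the template) and reports the cooperator survival
#' fraction per ratio, to probe threshold effects of the founding
#' composition.
#'
#' @param p a `sim_params` template.
#' @param ratios numeric vector of initial cooperator fractions in \[0, 1\].
#' @param n_reps replicates per ratio.
#' @param seed_base base seed.
#' @return A data frame with `ratio`, `n0_C`, `n0_D`, `survival_fraction`,
#'   `mean_terminal_ratio`; the per-ratio `sim_experiment` objects are
#'   attached as attribute `"summaries"`.
#' @export
initial_ratio_sweep <- function(p, ratios, n_reps, seed_base = 1L) {
  p <- validate_parameters(p)
  stopifnot(all(ratios >= 0 & ratios <= 1))
  total <- p$n0_C + p$n0_D
  summaries <- vector("list", length(ratios))
  for (i in seq_along(ratios)) {
    q <- unclass(p)
    q$n0_C <- round(ratios[i] * total)
    q$n0_D <- total - q$n0_C
    summaries[[i]] <- run_replicates(validate_parameters(q), n_reps,
                                     seed_base = .derive_seed(seed_base, i))
  }
  out <- data.frame(
    ratio = ratios,
    n0_C = vapply(summaries, function(x) x$params$n0_C, numeric(1)),
    n0_D = vapply(summaries, function(x) x$params$n0_D, numeric(1)),
    survival_fraction = vapply(summaries, function(x) x$survival_fraction,
                               numeric(1)),
    mean_terminal_ratio = vapply(summaries, function(x) x$mean_terminal_ratio,
                                 numeric(1)))
  attr(out, "summaries") <- summaries
  out
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.sim_run <- function(x, ...) {
  cat("Simulation run (sim_run)\n")
  cat(sprintf("  mechanism %s, predation %s, M = %d, seed = %s\n",
              x$params$mechanism,
              if (predation_enabled(x$params)) sprintf("s = %g", x$params$s) else "off",
              x$params$M, if (is.null(x$seed)) "NULL" else format(x$seed)))
  cat(sprintf("  %s after %g updates, %d colonization event(s)\n",
              x$termination, x$updates, x$n_colonizations))
  cat(sprintf("  terminal cooperator ratio: %s (%s)\n",
              format(x$terminal_ratio), as.character(x$outcome)))
  invisible(x)
}

#' @export
summary.sim_run <- function(object, ...) {
  print(object)
  ev <- colonization_events(object)
  if (nrow(ev) > 0L) {
    cat("  colonization events:\n")
    print(ev, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.sim_run <- function(x, ...) {
  tr <- x$trace
  pop <- tr$n_coop + tr$n_def
  ratio <- ifelse(pop > 0, tr$n_coop / pop, NA_real_)
  graphics::plot(tr$update, ratio, type = "l", ylim = c(0, 1),
                 xlab = "update", ylab = "cooperator ratio",
                 main = sprintf("mechanism %s", x$params$mechanism), ...)
  ev <- tr$update[tr$event != ""]
  if (length(ev) > 0L) graphics::abline(v = ev, col = "grey70", lty = 3)
  invisible(x)
}

#' @export
print.sim_experiment <- function(x, ...) {
  n <- nrow(x$replicates)
  cat("Replicate experiment (sim_experiment)\n")
  cat(sprintf("  mechanism %s, predation %s, M = %d, %d replicates\n",
              x$params$mechanism,
              if (predation_enabled(x$params)) sprintf("s = %g", x$params$s) else "off",
              x$params$M, n))
  cat(sprintf("  cooperator survival: %.0f%% of runs; mean terminal ratio %.3f\n",
              100 * x$survival_fraction, x$mean_terminal_ratio))
  cat(sprintf("  colonization events: mean %.2f (SD %.2f)\n",
              x$colonizations_mean, x$colonizations_sd))
  cat("  outcomes: ")
  oc <- x$outcome_counts
  cat(paste(sprintf("%s=%d", names(oc), as.integer(oc)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.sim_experiment <- function(object, ...) {
  print(object)
  cat("\nPer-replicate outcomes:\n")
  print(object$replicates, row.names = FALSE)
  invisible(object)
}

#' @export
plot.sim_experiment <- function(x, ...) {
  graphics::barplot(x$outcome_counts, las = 2, ylab = "runs",
                    main = sprintf("%s, predation %s", x$params$mechanism,
                                   if (predation_enabled(x$params))
                                     sprintf("s = %g", x$params$s) else "off"),
                    ...)
  invisible(x)
}

#' @export
print.sim_sweep <- function(x, ...) {
  cat("Parameter sweep (sim_sweep):", nrow(x$results), "grid points\n")
  print(x$results, row.names = FALSE)
  invisible(x)
}
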