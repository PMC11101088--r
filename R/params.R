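#' Simulation parameters
#'
#' Constructs and validates the full parameter set of the lattice model.
#' Defaults are the reference values of the study design: a 100 x 100 toroidal
#' lattice, 100 resource units per site, cooperator/defector metabolic costs
#' 10/8, division above 190 energy units with probability 0.7 (0.7 x 0.3 onto
#' an occupied site), association probability 0.95 for cooperators and 0 for
#' defectors, dissociation probability 0.3, predation strength exponent 5, and
#' a 100-cell propagule drawn when total resource falls below 400 000.
#'
#' @param T simulation length in individual updates.
#' @param M lattice edge size (sites); the habitat is an `M x M` torus.
#' @param N_P propagule size (cells) for the sampling mechanisms.
#' @param propagule_edge side length of the square transfer window (sites).
#' @param r0 initial per-site resource (resource units).
#' @param R scarcity threshold: total resource below `R` triggers propagule
#'   formation and colonization (resource units).
#' @param s predation strength exponent (size-dependent selection), or `"off"`
#'   to disable predation. The per-update capture probability of a cell with
#'   `N_a` associated neighbours is `1 / (N_a + 2)^s`.
#' @param e0 initial cell energy (resource units), also the energy every
#'   colonist is reset to.
#' @param c_C,c_D metabolic constants of cooperators and defectors (resource
#'   units per update); the cooperator premium `c_C > c_D` pays for adhesive
#'   production.
#' @param d energy barrier of reproduction (resource units); cells divide only
#'   when energy exceeds `d`.
#' @param S division probability once above the barrier.
#' @param O overwrite probability; division onto an occupied site succeeds
#'   with `S * O` and kills the resident.
#' @param m energy cost of an actual relocation (resource units).
#' @param A_C,A_D association (adhesion) probabilities; only cooperators can
#'   initiate (`A_D = 0` unless explicitly overridden).
#' @param D dissociation probability per update.
#' @param uptake per-update cap on resource consumption (resource units).
#'   The default equals `r0`, i.e. a feeding cell takes everything available
#'   at its site in one update; lowering the cap slows division and starves
#'   immobile (linked) cells, which removes the benefit of aggregation (see
#'   the methods vignette for the sensitivity analysis).
#' @param n0_C,n0_D initial cooperator and defector counts.
#' @param mechanism colonization mechanism, one of `"none"`,
#'   `"random_dispersion"`, `"random_refuge"`, `"random_fragmentation"`,
#'   `"agg_dispersion"`, `"agg_propagule"`.
#' @param min_pop_for_fragmentation minimum population (exclusive) for a
#'   fragment to form under random fragmentation.
#' @param seed RNG seed used by [run_simulation()]; `NULL` leaves the RNG
#'   state untouched.
#' @param dissociation_mode `"all"` (a dissociating cell drops all its links)
#'   or `"single"` (drops one uniformly chosen link).
#' @param require_cooperator must at least one cooperator exist for any
#'   colonization to happen (adhesion is needed to form a fruiting body)?
#' @param early_stop_no_colonization end a run at the first scarcity event at
#'   which colonization is impossible (the population is doomed).
#' @param early_stop_cooperator_fixation end a run once defectors are extinct
#'   (without mutation they can never reappear).
#' @param trace_every sampling cadence of the time series, in updates;
#'   `NULL` means every `M^2` updates.
#' @param placement `"exact"` places exactly `n0_C + n0_D` founders;
#'   `"poisson"` draws the counts from Poisson distributions with those means.
#'
#' @return An object of class `sim_params`: a validated named list.
#' @seealso [validate_parameters()], [run_simulation()], [scale_params()]
#' @examples
#' p <- sim_params(M = 20, n0_C = 10, n0_D = 10, seed = 1)
#' p$R
#' @export
sim_params <- function(T = 3e7,
                       M = 100,
                       N_P = 100,
                       propagule_edge = 10,
                       r0 = 100,
                       R = 400000,
                       s = 5,
                       e0 = 100,
                       c_C = 10,
                       c_D = 8,
                       d = 190,
                       S = 0.7,
                       O = 0.3,
                       m = 0.875,
                       A_C = 0.95,
                       A_D = 0,
                       D = 0.3,
                       uptake = 100,
                       n0_C = 200,
                       n0_D = 200,
                       mechanism = "none",
                       min_pop_for_fragmentation = 10,
                       seed = NULL,
                       dissociation_mode = "all",
                       require_cooperator = TRUE,
                       early_stop_no_colonization = TRUE,
                       early_stop_cooperator_fixation = TRUE,
                       trace_every = NULL,
                       placement = "exact") {
  p <- list(
    T = T, M = M, N_P = N_P, propagule_edge = propagule_edge, r0 = r0, R = R,
    s = s, e0 = e0, c_C = c_C, c_D = c_D, d = d, S = S, O = O, m = m,
    A_C = A_C, A_D = A_D, D = D, uptake = uptake, n0_C = n0_C, n0_D = n0_D,
    mechanism = mechanism,
    min_pop_for_fragmentation = min_pop_for_fragmentation,
    seed = seed, dissociation_mode = dissociation_mode,
    require_cooperator = require_cooperator,
    early_stop_no_colonization = early_stop_no_colonization,
    early_stop_cooperator_fixation = early_stop_cooperator_fixation,
    trace_every = trace_every, placement = placement)
  validate_parameters(p)
}

#' The six colonization mechanisms
#' @return Character vector of valid `mechanism` values.
#' @export
mechanisms <- function() {
  c("none", "random_dispersion", "random_refuge", "random_fragmentation",
    "agg_dispersion", "agg_propagule")
}

.mechanism_code <- function(mechanism) {
  match(mechanism, mechanisms()) - 1L
}

.check_scalar <- function(x, name, min = -Inf, max = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("parameter '%s' must be a single finite number", name),
         call. = FALSE)
  if (x < min || x > max)
    stop(sprintf("parameter '%s' = %g is outside [%g, %g]", name, x, min, max),
         call. = FALSE)
  if (integerish && x != round(x))
    stop(sprintf("parameter '%s' must be an integer", name), call. = FALSE)
  invisible(TRUE)
}

#' Validate a parameter list
#'
#' Fills defaults for missing fields, checks every invariant of the parameter
#' set (probabilities in \[0, 1\], non-negative energies/resources, the
#' propagule window fitting on the lattice, `N_P` fitting in the window,
#' the cooperator cost premium `c_C > c_D`), and returns the normalized
#' `sim_params` object. Unknown fields are an error.
#'
#' @param p a named list of parameters (possibly partial).
#' @return A validated `sim_params` object.
#' @export
validate_parameters <- function(p) {
  # already-validated objects pass through (modify via unclass() + revalidate)
  if (inherits(p, "sim_params")) return(p)
  if (!is.list(p)) stop("parameters must be a named list", call. = FALSE)
  defaults <- formals(sim_params)
  known <- names(defaults)
  unknown <- setdiff(names(p), known)
  if (length(unknown) > 0L)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         "; valid names are: ", paste(known, collapse = ", "), call. = FALSE)
  for (nm in known) {
    if (is.null(p[[nm]])) {
      if (nm %in% c("seed", "trace_every")) {
        p[nm] <- list(NULL)  # keep the (optional) field present
      } else {
        p[[nm]] <- eval(defaults[[nm]])
      }
    }
  }
  p <- p[known]

  .check_scalar(p$T, "T", min = 0)
  .check_scalar(p$M, "M", min = 1, integerish = TRUE)
  .check_scalar(p$N_P, "N_P", min = 1, integerish = TRUE)
  .check_scalar(p$propagule_edge, "propagule_edge", min = 1, integerish = TRUE)
  .check_scalar(p$r0, "r0", min = 0)
  .check_scalar(p$R, "R", min = 0)
  .check_scalar(p$e0, "e0", min = 0)
  .check_scalar(p$c_C, "c_C", min = 0)
  .check_scalar(p$c_D, "c_D", min = 0)
  .check_scalar(p$d, "d", min = 0)
  .check_scalar(p$m, "m", min = 0)
  .check_scalar(p$uptake, "uptake", min = 0)
  .check_scalar(p$n0_C, "n0_C", min = 0, integerish = TRUE)
  .check_scalar(p$n0_D, "n0_D", min = 0, integerish = TRUE)
  .check_scalar(p$min_pop_for_fragmentation, "min_pop_for_fragmentation",
                min = 0, integerish = TRUE)
  for (nm in c("S", "O", "A_C", "A_D", "D"))
    .check_scalar(p[[nm]], nm, min = 0, max = 1)

  if (identical(p$s, "off")) {
    # predation disabled
  } else {
    .check_scalar(p$s, "s", min = 0)
  }

  if (p$propagule_edge > p$M)
    stop("propagule_edge (", p$propagule_edge, ") exceeds lattice size M (",
         p$M, ")", call. = FALSE)
  if (p$N_P > p$propagule_edge^2)
    stop("N_P (", p$N_P, ") exceeds propagule window capacity ",
         "propagule_edge^2 (", p$propagule_edge^2, ")", call. = FALSE)
  if (p$c_C <= p$c_D)
    stop("cooperator metabolic cost c_C (", p$c_C,
         ") must exceed defector cost c_D (", p$c_D, ")", call. = FALSE)
  if (p$n0_C + p$n0_D > p$M^2)
    stop("initial population n0_C + n0_D (", p$n0_C + p$n0_D,
         ") exceeds lattice capacity M^2 (", p$M^2, ")", call. = FALSE)
  if (!p$mechanism %in% mechanisms())
    stop("mechanism '", p$mechanism, "' is not one of: ",
         paste(mechanisms(), collapse = ", "), call. = FALSE)
  if (!p$dissociation_mode %in% c("all", "single"))
    stop("dissociation_mode must be 'all' or 'single'", call. = FALSE)
  if (!p$placement %in% c("exact", "poisson"))
    stop("placement must be 'exact' or 'poisson'", call. = FALSE)
  if (!is.null(p$seed)) .check_scalar(p$seed, "seed", integerish = TRUE)
  if (!is.null(p$trace_every)) .check_scalar(p$trace_every, "trace_every", min = 1)
  for (nm in c("require_cooperator", "early_stop_no_colonization",
               "early_stop_cooperator_fixation")) {
    if (!is.logical(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]))
      stop("parameter '", nm, "' must be TRUE or FALSE", call. = FALSE)
  }
  structure(p, class = "sim_params")
}

#' Is predation (size-dependent selection) enabled?
#' @param p a `sim_params` object.
#' @return `TRUE` unless `p$s` is `"off"`.
#' @export
predation_enabled <- function(p) !identical(p$s, "off")

#' Scale the study design down to a smaller lattice
#'
#' Produces a parameter set for a reduced lattice in which extensive
#' quantities scale with lattice area and the propagule window with lattice
#' edge: `R`, `N_P`, `n0_C`, `n0_D` and `T` are multiplied by `(M_new / M)^2`
#' and `propagule_edge` by `M_new / M`, so occupancy, the scarcity fraction
#' and the propagule's share of the lattice are preserved.
#'
#' @param p a `sim_params` object (typically at the full 100 x 100 design).
#' @param M_new new lattice edge size; must divide evenly into the scalings.
#' @return A validated `sim_params` object at the reduced scale.
#' @export
scale_params <- function(p, M_new) {
  p <- validate_parameters(p)
  a <- (M_new / p$M)^2
  l <- M_new / p$M
  q <- unclass(p)
  q$M <- M_new
  q$R <- p$R * a
  q$N_P <- max(1, round(p$N_P * a))
  q$n0_C <- round(p$n0_C * a)
  q$n0_D <- round(p$n0_D * a)
  q$T <- p$T * a
  q$propagule_edge <- max(1, round(p$propagule_edge * l))
  q$trace_every <- NULL
  validate_parameters(q)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (sim_params)\n")
  cat(sprintf("  lattice: %d x %d torus, r0 = %g/site, scarcity below R = %g\n",
              x$M, x$M, x$r0, x$R))
  cat(sprintf("  cells:   e0 = %g, c_C = %g, c_D = %g, divide > %g with S = %g (x O = %g occupied)\n",
              x$e0, x$c_C, x$c_D, x$d, x$S, x$O))
  cat(sprintf("  links:   A_C = %g, A_D = %g, D = %g (%s), move cost m = %g\n",
              x$A_C, x$A_D, x$D, x$dissociation_mode, x$m))
  cat(sprintf("  predation: %s\n",
              if (predation_enabled(x)) sprintf("s = %g", x$s) else "off"))
  cat(sprintf("  colonization: %s, N_P = %d, window %d x %d\n",
              x$mechanism, as.integer(x$N_P), as.integer(x$propagule_edge),
              as.integer(x$propagule_edge)))
  cat(sprintf("  run: T = %g updates, init %d + %d cells, seed = %s\n",
              x$T, as.integer(x$n0_C), as.integer(x$n0_D),
              if (is.null(x$seed)) "NULL" else format(x$seed)))
  invisible(x)
}

# flat parameter list handed to the C++ engine
.engine_par <- function(p) {
  list(M = as.integer(p$M),
       T = as.numeric(p$T),
       trace_every = as.numeric(if (is.null(p$trace_every)) p$M^2 else p$trace_every),
       c_C = p$c_C, c_D = p$c_D, d = p$d, S = p$S, O = p$O, m = p$m,
       A_C = p$A_C, A_D = p$A_D, D = p$D, uptake = p$uptake, R = p$R,
       predation_on = predation_enabled(p),
       s_num = if (predation_enabled(p)) as.numeric(p$s) else 0,
       dissoc_all = identical(p$dissociation_mode, "all"),
       mech = .mechanism_code(p$mechanism),
       min_pop_for_fragmentation = as.integer(p$min_pop_for_fragmentation),
       require_cooperator = p$require_cooperator,
       early_stop_no_colonization = p$early_stop_no_colonization,
       early_stop_cooperator_fixation = p$early_stop_cooperator_fixation)
}
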