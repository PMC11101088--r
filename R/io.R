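# Configuration loading, trace serialization, snapshot export and fixture
# habitats. Traces use the plain-CSV schema
# update, n_coop, n_def, total_resource, n_associated, event
# with one row per sampling point and the mechanism name in `event` at
# colonization rows.

.EXPERIMENT_KEYS <- c("n_reps", "seed_base", "output_dir", "keep_runs",
                      "snapshot")

#' Load a run configuration from YAML or JSON
#'
#' Reads a configuration file whose top-level keys are `sim_params` field
#' names (absent keys take the default values), plus an optional
#' `experiment` block (`n_reps`, `seed_base`, `output_dir`, `keep_runs`,
#' `snapshot`). Unknown keys at either level are an error, as is any failed
#' parameter validation.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file; an empty file means
#'   all defaults.
#' @return A list of class `run_config` with elements `params` (a validated
#'   `sim_params`) and `experiment` (a named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json, got: ", path, call. = FALSE)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a mapping/object", call. = FALSE)
  exp_block <- raw[["experiment"]]
  raw[["experiment"]] <- NULL
  if (is.null(exp_block)) exp_block <- list()
  unknown <- setdiff(names(exp_block), .EXPERIMENT_KEYS)
  if (length(unknown) > 0L)
    stop("unknown experiment key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- validate_parameters(raw)  # rejects unknown parameter keys
  structure(list(params = params, experiment = exp_block),
            class = "run_config")
}

#' Write and read simulation traces as CSV
#'
#' `write_trace_csv()` serializes a run's trace; `read_trace_csv()` reads it
#' back, checks the schema and enforces strictly increasing update indices.
#' The round trip is an identity on the trace data frame.
#'
#' @param trace a `sim_run` object or its `trace` data frame.
#' @param path CSV file path.
#' @return `read_trace_csv()` returns the trace data frame.
#' @export
write_trace_csv <- function(trace, path) {
  if (inherits(trace, "sim_run")) trace <- trace$trace
  stopifnot(is.data.frame(trace))
  utils::write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  cols <- c(update = "numeric", n_coop = "numeric", n_def = "numeric",
            total_resource = "numeric", n_associated = "numeric",
            event = "character")
  tr <- utils::read.csv(path, colClasses = unname(cols),
                        stringsAsFactors = FALSE)
  if (!identical(names(tr), names(cols)))
    stop("malformed trace CSV: expected columns ",
         paste(names(cols), collapse = ", "), call. = FALSE)
  tr$event[is.na(tr$event)] <- ""
  if (nrow(tr) > 1L && any(diff(tr$update) <= 0))
    stop("trace update column must be strictly increasing", call. = FALSE)
  if (any(tr$n_coop < 0 | tr$n_def < 0 | tr$total_resource < 0))
    stop("trace counts must be non-negative", call. = FALSE)
  tr
}

#' Export a habitat grid snapshot
#'
#' Writes one of the habitat's three matrices as a plain-text `M x M` grid
#' (space-separated, row per lattice row): `cells` (0 empty, 1 cooperator,
#' 2 defector), `resource` (per-site resource units), or `association`
#' (per-cell associated-neighbour count, 0 to 8).
#'
#' @param h a `habitat` object.
#' @param path output file path.
#' @param kind which grid to export.
#' @return The path, invisibly.
#' @export
export_snapshot <- function(h, path, kind = c("cells", "resource", "association")) {
  kind <- match.arg(kind)
  grid <- switch(kind,
                 cells = h$occ,
                 resource = h$resource,
                 association = link_count_grid(h))
  utils::write.table(format(grid, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Deterministic test habitats
#'
#' Builds small habitats with known structure for exercising the update and
#' colonization rules:
#' * `single_aggregate`: a `k x k` cooperator block (with `k^2 = n_coop`)
#'   centred on the lattice, all within-block Moore links present, plus
#'   `n_def` unlinked defectors scattered on free sites;
#' * `two_aggregates`: two such blocks (each `n_coop / 2` cells) in opposite
#'   lattice quadrants;
#' * `checkerboard`: `n_coop` cooperators then `n_def` defectors filled onto
#'   alternating-parity sites, no links;
#' * `random`: uniform random placement of both types, no links.
#'
#' @param kind fixture family.
#' @param M lattice edge size.
#' @param n_coop,n_def composition.
#' @param e0,r0 cell energy and per-site resource.
#' @return A `habitat` object.
#' @export
make_fixture <- function(kind = c("single_aggregate", "two_aggregates",
                                  "checkerboard", "random"),
                         M, n_coop = 0L, n_def = 0L, e0 = 100, r0 = 100) {
  kind <- match.arg(kind)
  if (n_coop + n_def > M^2) stop("composition exceeds lattice capacity",
                                 call. = FALSE)
  h <- .new_habitat(M, r0)
  place_block <- function(h, top, k) {
    sites <- .window_sites(top, k, M)
    h$occ[sites] <- 1L
    h$energy[sites] <- e0
    # saturate within-block Moore links (.add_link is idempotent on bits)
    for (i in sites) {
      for (d in 1:8) {
        j <- .neighbor_linear(i, d, M)
        if (j %in% sites) h <- .add_link(h, i, d)
      }
    }
    h
  }
  if (kind == "single_aggregate") {
    k <- as.integer(round(sqrt(n_coop)))
    if (k^2 != n_coop) stop("single_aggregate needs a square n_coop",
                            call. = FALSE)
    if (k > 0L) h <- place_block(h, c(M %/% 2L - k %/% 2L + 1L,
                                      M %/% 2L - k %/% 2L + 1L), k)
  } else if (kind == "two_aggregates") {
    k <- as.integer(round(sqrt(n_coop / 2)))
    if (2L * k^2 != n_coop) stop("two_aggregates needs n_coop = 2 k^2",
                                 call. = FALSE)
    if (k > 0L) {
      h <- place_block(h, c(2L, 2L), k)
      h <- place_block(h, c(M %/% 2L + 2L, M %/% 2L + 2L), k)
    }
    if (M %/% 2L < k + 3L) stop("lattice too small for two separated blocks",
                                call. = FALSE)
  } else if (kind == "checkerboard") {
    idx <- which((row(matrix(0, M, M)) + col(matrix(0, M, M))) %% 2L == 0L)
    if (n_coop + n_def > length(idx))
      stop("composition exceeds checkerboard capacity", call. = FALSE)
    pick <- idx[seq_len(n_coop + n_def)]
    h$occ[pick] <- rep(c(1L, 2L), c(n_coop, n_def))
    h$energy[pick] <- e0
  } else {  # random
    sites <- sample.int(M^2, n_coop + n_def)
    h$occ[sites] <- rep(c(1L, 2L), c(n_coop, n_def))
    h$energy[sites] <- e0
  }
  if (n_def > 0L && kind %in% c("single_aggregate", "two_aggregates")) {
    free <- which(h$occ == 0L)
    pick <- free[sample.int(length(free), n_def)]
    h$occ[pick] <- 2L
    h$energy[pick] <- e0
  }
  h
}
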