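test_that("colonization prerequisites gate every mechanism", {
  p <- tiny_params(mechanism = "random_dispersion")
  # all-defector population: no fruiting body, no colonization
  hd <- make_fixture("checkerboard", M = 10, n_coop = 0, n_def = 20)
  for (mech in setdiff(mechanisms(), "none")) {
    q <- tiny_params(mechanism = mech)
    expect_false(can_colonize(hd, q))
  }
  # mechanism none never colonizes
  hc <- make_fixture("checkerboard", M = 10, n_coop = 20, n_def = 0)
  expect_false(can_colonize(hc, tiny_params(mechanism = "none")))
  # fragmentation needs the population strictly above the minimum
  for (n in c(9, 10, 11)) {
    h <- make_fixture("checkerboard", M = 10, n_coop = n, n_def = 0)
    q <- tiny_params(mechanism = "random_fragmentation")
    expect_equal(can_colonize(h, q), n > 10)
  }
  # the cooperator prerequisite is a config switch
  q2 <- tiny_params(mechanism = "random_dispersion", require_cooperator = FALSE)
  expect_true(can_colonize(hd, q2))
  # empty lattice never colonizes
  h0 <- make_fixture("checkerboard", M = 10, n_coop = 0, n_def = 0)
  expect_false(can_colonize(h0, q2))
})

test_that("random dispersion samples N_P cells and keeps coordinates", {
  p <- validate_parameters(list(M = 20, N_P = 10, propagule_edge = 4,
                                mechanism = "random_dispersion",
                                n0_C = 5, n0_D = 5))
  # undersized population: everything transfers
  hs <- make_fixture("checkerboard", M = 20, n_coop = 4, n_def = 3)
  set.seed(1)
  pr <- select_random_dispersion(hs, p)
  expect_equal(nrow(pr$cells), 7L)
  # large population: exactly N_P
  hl <- make_fixture("checkerboard", M = 20, n_coop = 60, n_def = 60)
  set.seed(2)
  pr2 <- select_random_dispersion(hl, p)
  expect_equal(nrow(pr2$cells), 10L)
  # colonization preserves each colonist's coordinates
  nh <- colonize(pr2, p)
  for (k in seq_len(nrow(pr2$cells)))
    expect_equal(nh$occ[pr2$cells$row[k], pr2$cells$col[k]], pr2$cells$kind[k])
  expect_equal(sum(nh$occ != 0L), 10L)
})

test_that("sampling mechanisms are composition-unbiased (hypergeometric)", {
  p <- validate_parameters(list(M = 20, N_P = 16, propagule_edge = 4,
                                mechanism = "random_dispersion",
                                n0_C = 5, n0_D = 5))
  set.seed(11)
  h <- make_fixture("random", M = 20, n_coop = 60, n_def = 140)  # 30% coop
  ndraw <- 400
  set.seed(12)
  fr <- replicate(ndraw, {
    pr <- select_random_dispersion(h, p)
    mean(pr$cells$kind == 1L)
  })
  # mean of ndraw hypergeometric fractions: SE = sqrt(p(1-p)/N_P/ndraw)
  expect_lt(abs(mean(fr) - 0.3), 4.5 * sqrt(0.3 * 0.7 / 16 / ndraw))
})

test_that("refuge packs the sample into one anchored window", {
  p <- validate_parameters(list(M = 20, N_P = 16, propagule_edge = 4,
                                mechanism = "random_refuge",
                                n0_C = 5, n0_D = 5))
  h <- make_fixture("random", M = 20, n_coop = 30, n_def = 30)
  set.seed(3)
  pr <- select_random_refuge(h, p)
  nh <- colonize(pr, p)
  anchor <- c(20 %/% 2 - 2 + 1, 20 %/% 2 - 2 + 1)
  win <- aggsim:::.window_sites(anchor, 4, 20)
  expect_equal(sum(nh$occ != 0L), 16L)
  expect_equal(sum(nh$occ[win] != 0L), 16L)  # all inside the block
  # composition preserved in transfer
  expect_equal(sum(nh$occ == 1L), sum(pr$cells$kind == 1L))
  # a single sampled cell still lands inside the block
  h1 <- make_fixture("checkerboard", M = 20, n_coop = 1, n_def = 0)
  set.seed(4)
  n1 <- colonize(select_random_refuge(h1, p), p)
  expect_equal(sum(n1$occ[win] != 0L), 1L)
  # the within-block arrangement is seed-dependent (layout permutation)
  set.seed(5); a <- colonize(select_random_refuge(h, p), p)
  set.seed(6); b <- colonize(select_random_refuge(h, p), p)
  expect_false(identical(a$occ, b$occ))
})

test_that("fragmentation transfers a non-empty window translation-only", {
  p <- validate_parameters(list(M = 20, N_P = 16, propagule_edge = 4,
                                mechanism = "random_fragmentation",
                                n0_C = 5, n0_D = 5))
  # a lattice with one occupied site: the fragment must contain it
  h1 <- one_cell_habitat(20, c(13, 4), kind = 1L)
  set.seed(7)
  pr1 <- select_random_fragmentation(h1, p)
  expect_equal(nrow(pr1$cells), 1L)
  expect_equal(c(pr1$cells$row, pr1$cells$col), c(13, 4))
  # relative positions are preserved exactly (translation only)
  set.seed(8)
  h <- make_fixture("random", M = 20, n_coop = 40, n_def = 40)
  set.seed(9)
  pr <- select_random_fragmentation(h, p)
  nh <- colonize(pr, p)
  # pairwise toroidal offset multisets agree between source and arrival
  offsets <- function(rows, cols, M) {
    k <- length(rows)
    o <- outer(seq_len(k), seq_len(k), function(i, j)
      paste((rows[i] - rows[j]) %% M, (cols[i] - cols[j]) %% M))
    sort(o[upper.tri(o) | lower.tri(o)])
  }
  src <- offsets(pr$cells$row, pr$cells$col, 20)
  idx <- which(nh$occ != 0L)
  dst <- offsets(((idx - 1L) %% 20L) + 1L, ((idx - 1L) %/% 20L) + 1L, 20)
  expect_equal(dst, src)
  # cells outside the window are never transferred
  win <- aggsim:::.window_sites(pr$window_origin, 4, 20)
  src_idx <- (pr$cells$col - 1L) * 20L + pr$cells$row
  expect_true(all(src_idx %in% win))
  expect_equal(nrow(pr$cells), sum(h$occ[win] != 0L))
})

test_that("aggregation-based selection centres on the strongest aggregate", {
  p <- validate_parameters(list(M = 20, N_P = 25, propagule_edge = 5,
                                mechanism = "agg_propagule",
                                n0_C = 5, n0_D = 5))
  # a unique 3x3 aggregate among scattered loners: window centred on its core
  set.seed(13)
  h <- make_fixture("single_aggregate", M = 20, n_coop = 9, n_def = 12)
  set.seed(14)
  pr <- select_aggregation_based(h, p, disperse = FALSE)
  # the block centre (11, 11) holds the unique maximal N_a = 8
  expect_equal(pr$window_origin, c(11 - 2, 11 - 2))
  expect_gte(sum(pr$cells$kind == 1L), 9L)  # whole aggregate captured
  # composition bias: cooperator fraction in the propagule exceeds the
  # population fraction whenever cooperators hold the max-link cell
  expect_gt(mean(pr$cells$kind == 1L), mean(h$occ[h$occ != 0L] == 1L))
  # with no links at all the centre is uniform over cells: a lone cell's
  # window must contain it
  h1 <- one_cell_habitat(20, c(4, 17), kind = 1L)
  set.seed(15)
  pr1 <- select_aggregation_based(h1, p, disperse = TRUE)
  expect_equal(nrow(pr1$cells), 1L)
  expect_equal(pr1$layout, "dispersed")
})

test_that("ties among max-linked cells are broken uniformly", {
  # two saturated 2x2 blocks: all 8 cells share the maximal N_a = 3
  p <- validate_parameters(list(M = 12, N_P = 16, propagule_edge = 4,
                                mechanism = "agg_propagule",
                                n0_C = 4, n0_D = 4))
  h <- make_fixture("two_aggregates", M = 12, n_coop = 8)
  # identify the two blocks' windows by their origins
  set.seed(16)
  n <- 2000
  first <- 0L
  for (k in seq_len(n)) {
    pr <- select_aggregation_based(h, p, disperse = FALSE)
    # block 1 sits at rows/cols 2:3; its members' centred windows start at
    # row 12 (wrapped) or row 1; block 2's start at rows 6 or 7
    if (pr$window_origin[1L] %in% c(12, 1)) first <- first + 1L
  }
  expect_lt(abs(first / n - 0.5), 4.5 * sqrt(0.25 / n))
})

test_that("colonization resets the habitat and strips associations", {
  p <- validate_parameters(list(M = 20, N_P = 25, propagule_edge = 5,
                                mechanism = "agg_propagule",
                                n0_C = 5, n0_D = 5))
  h <- make_fixture("single_aggregate", M = 20, n_coop = 9, n_def = 6)
  h$energy[h$occ != 0L] <- 137  # arbitrary pre-transfer energies
  h$resource[] <- 3
  set.seed(17)
  pr <- select_aggregation_based(h, p, disperse = FALSE)
  nh <- colonize(pr, p)
  expect_equal(total_resource(nh), 20 * 20 * 100)
  expect_true(all(nh$resource == 100))
  expect_true(all(nh$energy[nh$occ != 0L] == 100))  # e0 reset
  expect_true(all(nh$links == 0L))                  # associations emptied
  expect_equal(sum(nh$occ == 1L), sum(pr$cells$kind == 1L))
  expect_equal(sum(nh$occ == 2L), sum(pr$cells$kind == 2L))
  expect_silent(check_habitat(nh))
  # dispersed arrival places distinct sites, composition intact
  set.seed(18)
  prE <- select_aggregation_based(h, p, disperse = TRUE)
  nhE <- colonize(prE, p)
  expect_equal(cell_counts(nhE)[["coop"]], sum(prE$cells$kind == 1L))
  expect_true(all(nhE$links == 0L))
})

test_that("propagule selection dispatches by mechanism and guards 'none'", {
  h <- make_fixture("single_aggregate", M = 20, n_coop = 9, n_def = 6)
  p <- validate_parameters(list(M = 20, N_P = 25, propagule_edge = 5,
                                mechanism = "none", n0_C = 5, n0_D = 5))
  expect_error(propagule_select(h, p), "not possible")
  for (mech in setdiff(mechanisms(), "none")) {
    q <- unclass(p); q$mechanism <- mech
    set.seed(19)
    pr <- propagule_select(h, validate_parameters(q))
    expect_s3_class(pr, "propagule")
    expect_equal(pr$mechanism, mech)
    expect_gte(nrow(pr$cells), 1L)
  }
})
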