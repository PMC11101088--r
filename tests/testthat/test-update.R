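test_that("predation probability follows the size-dependent selection law", {
  expect_equal(predation_probability(0, 5), 1 / 32)
  expect_equal(predation_probability(8, 5), 1e-5)
  expect_equal(predation_probability(0:8, 3), (2:10)^-3)
  expect_equal(predation_probability(4, "off"), 0)
  expect_error(predation_probability(9, 5), "0..8")
  expect_error(predation_probability(-1, 5), "0..8")
  # strictly decreasing in N_a and in s
  for (s in 3:7) expect_true(all(diff(predation_probability(0:8, s)) < 0))
  P <- sapply(3:7, function(s) predation_probability(3, s))
  expect_true(all(diff(P) < 0))
})

test_that("metabolism drains type-specific costs and kills at zero", {
  p <- tiny_params()
  hc <- one_cell_habitat(10, c(5, 5), kind = 1L, energy = 100)
  expect_equal(step_metabolism(hc, c(5, 5), p)$habitat$energy[5, 5], 90)
  hd <- one_cell_habitat(10, c(5, 5), kind = 2L, energy = 100)
  expect_equal(step_metabolism(hd, c(5, 5), p)$habitat$energy[5, 5], 92)
  # boundary: a defector at energy 8 hits exactly 0 and starves
  hb <- one_cell_habitat(10, c(5, 5), kind = 2L, energy = 8)
  res <- step_metabolism(hb, c(5, 5), p)
  expect_true(res$died)
  expect_equal(res$habitat$occ[5, 5], 0L)
})

test_that("consumption is a capped, strictly conserving transfer", {
  p <- tiny_params(uptake = 20)
  h <- one_cell_habitat(10, c(3, 3), kind = 1L, energy = 50, r0 = 100)
  res <- step_consume(h, c(3, 3), p)
  expect_equal(res$consumed, 20)
  expect_equal(res$habitat$energy[3, 3], 70)
  expect_equal(res$habitat$resource[3, 3], 80)
  # exhausted site
  h0 <- one_cell_habitat(10, c(3, 3), kind = 1L, energy = 50, r0 = 0)
  expect_equal(step_consume(h0, c(3, 3), p)$consumed, 0)
  # cap at availability
  h5 <- one_cell_habitat(10, c(3, 3), kind = 1L, energy = 50, r0 = 5)
  res5 <- step_consume(h5, c(3, 3), p)
  expect_equal(res5$consumed, 5)
  expect_equal(res5$habitat$resource[3, 3], 0)
  # total energy + resource unchanged by the transfer
  expect_equal(sum(res$habitat$energy) + sum(res$habitat$resource),
               sum(h$energy) + sum(h$resource))
})

test_that("division respects the energy barrier and halves energy", {
  # below the barrier: never divides, even with S = 1
  p1 <- tiny_params(S = 1)
  h <- one_cell_habitat(10, c(5, 5), kind = 1L, energy = 189)
  set.seed(1)
  for (k in 1:50) expect_false(step_divide(h, c(5, 5), p1)$divided)
  # above the barrier onto an empty site: both daughters get half
  h2 <- one_cell_habitat(10, c(5, 5), kind = 1L, energy = 200)
  set.seed(2)
  res <- step_divide(h2, c(5, 5), p1)
  expect_true(res$divided)
  expect_false(res$overwrote)
  hh <- res$habitat
  expect_equal(sum(hh$occ == 1L), 2L)
  expect_equal(hh$energy[hh$occ == 1L], c(100, 100))
  # daughter is link-free and inherits the parent's kind
  expect_true(all(hh$links == 0L))
})

test_that("division onto an occupied site fires at S*O and kills the resident", {
  p <- tiny_params()  # S = 0.7, O = 0.3
  h <- one_cell_habitat(10, c(5, 5), kind = 1L, energy = 200)
  h <- put_cells(h, moore_neighbors(c(5, 5), 10), kind = 2L)
  # frozen expectation: Monte-Carlo division frequency ~ Binomial(n, 0.21);
  # 4.5 sigma band around S*O
  n <- 30000
  set.seed(42)
  fired <- 0L
  for (k in seq_len(n)) fired <- fired + step_divide(h, c(5, 5), p)$divided
  expect_lt(abs(fired / n - 0.21), 4.5 * sqrt(0.21 * 0.79 / n))
  # deterministic overwrite: S = O = 1 always replaces the resident
  p11 <- tiny_params(S = 1, O = 1)
  set.seed(3)
  res <- step_divide(h, c(5, 5), p11)
  expect_true(res$overwrote)
  expect_equal(sum(res$habitat$occ == 2L), 7L)  # one defector lost
  expect_equal(sum(res$habitat$occ == 1L), 2L)
})

test_that("only cooperators initiate association, with one unlinked acceptor", {
  p <- tiny_params(A_C = 1)
  # defector focal cell never initiates (A_D = 0)
  hd <- one_cell_habitat(10, c(5, 5), kind = 2L)
  hd <- put_cells(hd, moore_neighbors(c(5, 5), 10)[1, , drop = FALSE], kind = 2L)
  set.seed(4)
  for (k in 1:50) expect_null(step_associate(hd, c(5, 5), p)$assoc_site)
  # cooperator with no occupied neighbour: no link
  hc <- one_cell_habitat(10, c(5, 5), kind = 1L)
  set.seed(5)
  expect_null(step_associate(hc, c(5, 5), p)$assoc_site)
  # cooperator with a neighbour: symmetric link appears
  hc2 <- put_cells(hc, matrix(c(5, 6), 1), kind = 2L)
  set.seed(6)
  res <- step_associate(hc2, c(5, 5), p)
  expect_equal(unname(res$assoc_site), c(5, 6))
  na <- link_count_grid(res$habitat)
  expect_equal(na[5, 5], 1L)
  expect_equal(na[5, 6], 1L)
  expect_silent(check_habitat(res$habitat))
  # saturation: the block centre already holds all 8 links
  hs <- make_fixture("single_aggregate", M = 10, n_coop = 9)
  ctr <- c(6, 6)  # centre of the 3x3 block placed by the fixture
  set.seed(7)
  res <- step_associate(hs, ctr, p)
  expect_null(res$assoc_site)
  expect_identical(res$habitat$links, hs$links)
})

test_that("dissociation is blocked for association participants and clears links", {
  p <- tiny_params(D = 1)
  hs <- make_fixture("single_aggregate", M = 10, n_coop = 9)
  ctr <- c(6, 6)
  # cell with no links: no-op even at D = 1
  h0 <- one_cell_habitat(10, c(2, 2), kind = 1L)
  set.seed(8)
  expect_false(step_dissociate(h0, c(2, 2), p)$dissociated)
  # a participant in this update's association cannot dissociate
  set.seed(9)
  expect_false(step_dissociate(hs, ctr, p, participated = TRUE)$dissociated)
  # D = 1, mode all: every link of the cell goes, reciprocals included
  set.seed(10)
  res <- step_dissociate(hs, ctr, p)
  expect_true(res$dissociated)
  na <- link_count_grid(res$habitat)
  expect_equal(na[6, 6], 0L)
  expect_equal(sort(na[res$habitat$occ == 1L]),
               c(0L, 2L, 2L, 2L, 2L, 4L, 4L, 4L, 4L))
  expect_silent(check_habitat(res$habitat))
  # mode single removes exactly one link
  ps <- tiny_params(D = 1, dissociation_mode = "single")
  set.seed(11)
  res1 <- step_dissociate(hs, ctr, ps)
  expect_true(res1$dissociated)
  expect_equal(link_count_grid(res1$habitat)[6, 6], 7L)
  expect_silent(check_habitat(res1$habitat))
})

test_that("movement: only unassociated cells, 1/9 stay, cost on relocation", {
  p <- tiny_params()
  # associated cells never move
  hs <- make_fixture("single_aggregate", M = 10, n_coop = 9)
  set.seed(12)
  for (k in 1:50) expect_null(step_move(hs, c(6, 6), p)$moved_to)
  # fully surrounded unassociated cell stays with probability 1
  hb <- one_cell_habitat(10, c(5, 5), kind = 2L)
  hb <- put_cells(hb, moore_neighbors(c(5, 5), 10), kind = 2L)
  set.seed(13)
  for (k in 1:50) expect_null(step_move(hb, c(5, 5), p)$moved_to)
  # lone cell on an empty lattice: frozen expectation 8/9 move frequency
  h1 <- one_cell_habitat(10, c(5, 5), kind = 2L, energy = 100)
  n <- 30000
  set.seed(14)
  moved <- 0L
  for (k in seq_len(n)) {
    res <- step_move(h1, c(5, 5), p)
    if (!is.null(res$moved_to)) {
      moved <- moved + 1L
      # relocation costs m; staying is free
      expect_equal(res$habitat$energy[res$moved_to[1], res$moved_to[2]],
                   100 - p$m)
    }
  }
  expect_lt(abs(moved / n - 8 / 9), 4.5 * sqrt((8 / 9) * (1 / 9) / n))
})

test_that("predation removes cells at the analytic rate and cleans links up", {
  # disabled predation: always survives
  poff <- tiny_params(s = "off")
  h1 <- one_cell_habitat(10, c(5, 5), kind = 2L)
  set.seed(15)
  for (k in 1:50) expect_false(step_predation(h1, c(5, 5), poff)$died)
  # frozen expectation: N_a = 0, s = 3 dies at 1/8 per update
  p3 <- tiny_params(s = 3)
  n <- 30000
  set.seed(16)
  died <- 0L
  for (k in seq_len(n)) died <- died + step_predation(h1, c(5, 5), p3)$died
  expect_lt(abs(died / n - 1 / 8), 4.5 * sqrt(0.125 * 0.875 / n))
  # s = 0 forces P = 1: the victim's neighbours lose exactly their links to it
  p0 <- tiny_params(s = 0)
  hs <- make_fixture("single_aggregate", M = 10, n_coop = 9)
  set.seed(17)
  res <- step_predation(hs, c(6, 6), p0)
  expect_true(res$died)
  expect_equal(res$habitat$occ[6, 6], 0L)
  na <- link_count_grid(res$habitat)
  expect_equal(sort(na[res$habitat$occ == 1L]),
               c(2L, 2L, 2L, 2L, 4L, 4L, 4L, 4L))
  expect_silent(check_habitat(res$habitat))
})

test_that("a full update applies the sub-steps in order", {
  # empty lattice: no-op outcome
  p <- tiny_params(n0_C = 0, n0_D = 0)
  h <- initialize_habitat(p)
  res <- update_one_cell(h, p)
  expect_true(is.na(res$outcome$site))
  expect_identical(res$habitat, h)
  # two-update starvation trace: a lone defector at energy 9 on an exhausted
  # lattice survives its first update (9 - 8 = 1) and starves at the second
  ps <- tiny_params(s = "off", r0 = 0)
  h1 <- one_cell_habitat(10, c(5, 5), kind = 2L, energy = 9, r0 = 0)
  set.seed(18)
  u1 <- update_one_cell(h1, ps)
  expect_equal(u1$outcome$death, "none")
  expect_equal(sum(u1$habitat$occ != 0L), 1L)
  u2 <- update_one_cell(u1$habitat, ps)
  expect_equal(u2$outcome$death, "starvation")
  expect_equal(sum(u2$habitat$occ != 0L), 0L)
})

test_that("compiled engine and R reference replay the same RNG stream bit-exactly", {
  p <- validate_parameters(list(M = 10, n0_C = 30, n0_D = 20, N_P = 4,
                                propagule_edge = 2, s = 5, r0 = 1000,
                                R = 0, uptake = 20))
  set.seed(7)
  h0 <- initialize_habitat(p)
  n <- 3000
  set.seed(99)
  cpp <- update_cells(h0, p, n)
  set.seed(99)
  st <- aggsim:::.st_new(h0, p)
  for (i in seq_len(n)) aggsim:::.r_update_one(st)
  hr <- aggsim:::.st_habitat(st)
  expect_identical(cpp$habitat, hr)
  expect_identical(cpp$n_coop, st$n_coop)
  expect_identical(cpp$n_def, st$n_def)
  # and the same again under disabled predation / single-link dissociation
  p2 <- validate_parameters(list(M = 10, n0_C = 30, n0_D = 20, N_P = 4,
                                 propagule_edge = 2, s = "off", r0 = 1000,
                                 R = 0, dissociation_mode = "single"))
  set.seed(8)
  h0 <- initialize_habitat(p2)
  set.seed(123)
  cpp <- update_cells(h0, p2, n)
  set.seed(123)
  st <- aggsim:::.st_new(h0, p2)
  for (i in seq_len(n)) aggsim:::.r_update_one(st)
  expect_identical(cpp$habitat, aggsim:::.st_habitat(st))
})

test_that("scarcity triggers strictly below the threshold", {
  p <- sim_params()
  set.seed(1)
  h <- initialize_habitat(p)
  expect_false(scarcity_reached(h, p))          # fresh: 1e6 >= 4e5
  h$resource[] <- 39.9999                       # total 399 999
  expect_true(scarcity_reached(h, p))
  h$resource[] <- 40                            # total exactly 400 000
  expect_false(scarcity_reached(h, p))          # "at or above" is rich
})
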