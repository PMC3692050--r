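test_that("temperature ladders interpolate geometrically with exact endpoints", {
  l <- make_ladder(3.5, 1.0, 20)
  expect_length(l, 20)
  expect_equal(l[1], 3.5)
  expect_equal(l[20], 1.0)
  expect_true(all(diff(l) < 0))
  # geometric: constant ratio
  expect_equal(var(diff(log(l))), 0, tolerance = 1e-20)

  expect_equal(make_ladder(2.0, 2.0, 20), rep(2.0, 20))
  expect_equal(make_ladder(3.0, 1.0, 2), c(3.0, 1.0))
  expect_error(make_ladder(1.0, 0), "positive")
  expect_error(make_ladder(1.0, 2.0), "t_max")
})

test_that("the Metropolis rule accepts downhill always and uphill at exp(-dE/T)", {
  set.seed(1)
  expect_true(all(vapply(1:50, function(k)
    metropolis_accept(-runif(1, 0, 10), runif(1, 0.5, 3)), logical(1))))
  expect_true(metropolis_accept(0, 1))

  # fixed dE = +1 at T = 1: empirical acceptance ~ exp(-1) within 3 sigma
  set.seed(2)
  n <- 10000
  acc <- sum(vapply(seq_len(n), function(k) metropolis_accept(1, 1),
                    logical(1)))
  p <- exp(-1)
  expect_lt(abs(acc - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("acceptance rate rises with temperature on a de novo toy run", {
  co <- random_coil(15, seed = 3)
  hot <- run_simulation(co, strrep("C", 15), 3.5, n_cycles = 100,
                        record_every = 50, seed = 4)
  cold <- run_simulation(co, strrep("C", 15), 1.0, n_cycles = 100,
                         record_every = 50, seed = 4)
  expect_gt(hot$acceptance$rate, cold$acceptance$rate)
})

test_that("exchange sweeps follow the swap probability rule", {
  reps <- list(list(state = 1, energy = 5), list(state = 2, energy = 5))
  # equal energies: swap probability exactly 1
  out <- exchange_sweep(reps, c(2, 1))
  expect_true(all(out$swaps$accepted))
  expect_equal(out$replicas[[1]]$state, 2)

  # flat ladder: every attempted swap accepted regardless of energies
  set.seed(5)
  reps2 <- lapply(1:6, function(k) list(state = k, energy = rnorm(1, sd = 9)))
  out2 <- exchange_sweep(reps2, rep(1.5, 6), phase = 0L)
  expect_true(all(out2$swaps$accepted))
  expect_equal(out2$swaps$lower, c(1, 3, 5))
  out3 <- exchange_sweep(reps2, rep(1.5, 6), phase = 1L)
  expect_equal(out3$swaps$lower, c(2, 4))
})

test_that("simulations are deterministic and record the documented series", {
  co <- random_coil(12, seed = 6)
  ss <- strrep("C", 12)
  t1 <- run_simulation(co, ss, make_ladder(2, 1, 3), n_cycles = 40,
                       record_every = 10, seed = 7)
  t2 <- run_simulation(co, ss, make_ladder(2, 1, 3), n_cycles = 40,
                       record_every = 10, seed = 7)
  expect_identical(t1$snapshots, t2$snapshots)
  expect_identical(t1$series, t2$series)
  expect_identical(t1$swaps, t2$swaps)

  # zero cycles: only the start snapshot
  t0 <- run_simulation(co, ss, make_ladder(2, 1, 3), n_cycles = 0, seed = 8)
  expect_length(t0$snapshots, 1)
  expect_equal(t0$snapshots[[1]], co)

  expect_equal(nrow(t1$series), length(t1$snapshots))
  expect_equal(t1$series$cycle, c(0, 10, 20, 30, 40))
})

test_that("recorded energies equal a from-scratch recomputation", {
  # this doubles as the cross-check of the sampling engine's energy model
  # against the reference R implementation
  fx <- generate_fixture("helix", 14, perturbation = 0.4, n_templates = 2,
                         seed = 9)
  rs <- generate_consensus_restraints(fx$templates)
  co <- build_start_from_templates(fx$templates[1], 14, seed = 10)
  tr <- run_simulation(co, fx$ss, make_ladder(2, 1, 4), rs, n_cycles = 60,
                       record_every = 15, seed = 11)
  obs <- trajectory_observables(tr, fx$ss, rs)
  expect_equal(obs$energy, tr$series$energy, tolerance = 1e-6)
  expect_equal(obs$rg, tr$series$rg, tolerance = 1e-9)
  expect_equal(obs$end_to_end, tr$series$end_to_end, tolerance = 1e-9)
})

test_that("lower t_min lowers late-run recorded energies on a restrained toy", {
  fx <- generate_fixture("helix", 10, perturbation = 0, n_templates = 1,
                         seed = 12)
  rs <- generate_single_template_restraints(fx$templates[[1]], tau = 0.5)
  late_mean <- function(t_min, seed) {
    tr <- run_simulation(random_coil(10, seed = seed), fx$ss,
                         make_ladder(2.5, t_min, 4), rs, n_cycles = 200,
                         record_every = 10, seed = seed)
    e <- tr$series$energy
    mean(utils::tail(e, ceiling(length(e) / 4)))
  }
  seeds <- 1:10
  m_hot <- mean(vapply(seeds, function(s) late_mean(2.5, s), numeric(1)))
  m_mid <- mean(vapply(seeds, function(s) late_mean(1.2, s), numeric(1)))
  m_cold <- mean(vapply(seeds, function(s) late_mean(0.5, s), numeric(1)))
  expect_gt(m_hot, m_mid)
  expect_gt(m_mid, m_cold)
})
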