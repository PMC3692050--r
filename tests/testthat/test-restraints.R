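two_point_templates <- function(d_list, i = 2L, j = 7L, n = 10L) {
  # templates whose (i, j) distance is exactly each value of d_list
  lapply(d_list, function(d) {
    co <- cbind(seq_len(n) * 20, 0, 0)  # far apart: no other close pairs
    co[j, ] <- co[i, ] + c(d, 0, 0)
    fold_template(ca_trace(co))
  })
}

test_that("pair statistics match hand values and the loop oracle", {
  # single template: degenerate stats
  tp <- rand_template_set(8, 1, 0, seed = 1)
  st <- collect_pair_stats(tp)
  expect_true(all(st$d_min == st$d_max & st$d_max == st$mean))
  expect_true(all(st$sigma == 0) && all(st$n_obs == 1))

  # two observations 5 and 9 -> min 5, max 9, mean 7, population sigma 2
  st2 <- collect_pair_stats(two_point_templates(c(5, 9)))
  row <- st2[st2$i == 2 & st2$j == 7, ]
  expect_equal(unlist(row[c("d_min", "d_max", "mean", "sigma")]),
               c(d_min = 5, d_max = 9, mean = 7, sigma = 2))

  # min_obs filtering: pair covered by fewer templates is absent
  tps <- rand_template_set(10, 3, 0.5, seed = 2, partial = TRUE)
  st3 <- collect_pair_stats(tps, min_obs = 3)
  expect_true(all(st3$n_obs >= 3))

  # full agreement with the literal loop oracle
  for (s in 1:5) {
    tps <- rand_template_set(sample(8:15, 1), sample(2:4, 1),
                             runif(1, 0.2, 2), seed = 300 + s,
                             partial = TRUE)
    got <- collect_pair_stats(tps)
    want <- oracle_pair_stats(tps)
    expect_equal(got$d_min, want$d_min, tolerance = 1e-12)
    expect_equal(got$d_max, want$d_max, tolerance = 1e-12)
    expect_equal(got$mean, want$mean, tolerance = 1e-9)
    expect_equal(got$sigma, want$sigma, tolerance = 1e-9)
  }
  expect_error(collect_pair_stats(list()), "template")
})

test_that("sample-sigma convention is available", {
  st <- collect_pair_stats(two_point_templates(c(5, 9)), sigma = "sample")
  row <- st[st$i == 2 & st$j == 7, ]
  expect_equal(row$sigma, sd(c(5, 9)))
})

test_that("regime selection gates on minimum pairwise GDT_TS at 0.3", {
  fx <- generate_fixture("helix", 20, perturbation = 0, n_templates = 2,
                         seed = 1)
  expect_equal(select_regime(fx$templates)$regime, "minmax")

  # one heavily perturbed template forces the distribution regime
  fx2 <- generate_fixture("helix", 20, perturbation = 0, n_templates = 2,
                          seed = 1)
  set.seed(99)
  bad <- fx2$templates[[2]]
  bad$trace$coords <- matrix(runif(60, -50, 50), 20, 3)
  reg <- select_regime(list(fx2$templates[[1]], bad))
  expect_lt(reg$min_gdt, 0.3)
  expect_equal(reg$regime, "distribution")

  expect_error(select_regime(fx$templates[1]), "single-template")
})

test_that("consensus restraints follow the documented per-regime ranges", {
  # identical templates: every restraint degenerates to [d, d]
  fx <- generate_fixture("helix", 15, perturbation = 0, n_templates = 2,
                         seed = 3)
  rs <- generate_consensus_restraints(fx$templates)
  expect_equal(attr(rs, "regime"), "minmax")
  expect_equal(rs$dmin, rs$dmax)

  # minmax: observed {5, 6, 9} at one pair -> [5, 9]
  tps <- two_point_templates(c(5, 6, 9))
  rs2 <- generate_consensus_restraints(tps, s_min = 5, d_cap = 1e9)
  row <- rs2[rs2$i == 2 & rs2$j == 7, ]
  expect_equal(c(row$dmin, row$dmax), c(5, 9))

  # distribution: observed {5, 7, 9} -> [7 - sigma, 7 + sigma], oracle sigma
  tps3 <- two_point_templates(c(5, 7, 9))
  # make one template dissimilar (distances at (2,7) then re-measured)
  set.seed(41)
  tps3[[3]]$trace$coords <- tps3[[3]]$trace$coords +
    matrix(rnorm(30, sd = 40), 10, 3)
  d37 <- sqrt(sum((tps3[[3]]$trace$coords[2, ] -
                     tps3[[3]]$trace$coords[7, ])^2))
  expect_equal(select_regime(tps3)$regime, "distribution")
  rs3 <- generate_consensus_restraints(tps3, s_min = 5, d_cap = 1e9)
  row3 <- rs3[rs3$i == 2 & rs3$j == 7, ]
  ds <- c(5, 7, d37)
  mu <- mean(ds); sg <- sqrt(mean((ds - mu)^2))
  expect_equal(c(row3$dmin, row3$dmax),
               c(max(3, mu - sg), mu + sg), tolerance = 1e-9)
})

test_that("eligibility rules and template-satisfaction invariant hold", {
  for (s in 1:6) {
    tps <- rand_template_set(sample(10:20, 1), sample(2:5, 1),
                             runif(1, 0.1, 1), seed = 400 + s)
    rs <- generate_consensus_restraints(tps)
    if (nrow(rs) == 0) next
    expect_true(all(rs$j - rs$i >= fold_defaults$s_min))
    expect_true(all(rs$dmin <= rs$dmax))
    if (attr(rs, "regime") == "minmax") {
      # every template conformation lies inside the min/max ranges
      for (tp in tps)
        expect_equal(restraint_energy(tp$trace$coords, rs), 0)
    }
  }
})

test_that("single-template restraints cover only the template fragment", {
  fx <- generate_fixture("helix", 30, perturbation = 0, n_templates = 1,
                         coverage = list(1:20), seed = 5)
  rs <- generate_single_template_restraints(fx$templates[[1]], tau = 0.5)
  expect_true(all(rs$i <= 20 & rs$j <= 20))
  expect_equal(attr(rs, "regime"), "single-template")

  # covered pair at its template distance d gets [d - tau, d + tau]
  tp <- fx$templates[[1]]
  d <- sqrt(sum((tp$trace$coords[1, ] - tp$trace$coords[10, ])^2))
  row <- rs[rs$i == 1 & rs$j == 10, ]
  expect_equal(c(row$dmin, row$dmax), c(d - 0.5, d + 0.5), tolerance = 1e-9)

  # full coverage: restraint count equals the oracle pair enumeration
  fx2 <- generate_fixture("helix", 12, perturbation = 0, n_templates = 1,
                          seed = 6)
  rs2 <- generate_single_template_restraints(fx2$templates[[1]],
                                             d_cap = 1e9)
  n_elig <- sum(outer(1:12, 1:12, function(i, j) j - i >= 5))
  expect_equal(nrow(rs2), n_elig)
})

test_that("the directive language parses the documented examples", {
  d1 <- parse_edit_directives("A 3 14 7.8 10.12")[[1]]
  expect_equal(d1[c("kind", "i", "j", "dmin", "dmax")],
               list(kind = "add", i = 3, j = 14, dmin = 7.8, dmax = 10.12))

  d2 <- parse_edit_directives("D 55,58,120–160")[[1]]  # en-dash
  expect_equal(d2$kind, "delete")
  expect_equal(d2$resids, sort(c(55, 58, 120:160)))
  expect_equal(parse_edit_directives("D 55,58,120-160")[[1]]$resids,
               d2$resids)

  # index normalization
  d3 <- parse_edit_directives("A 5 2 3.0 4.0")[[1]]
  expect_equal(c(d3$i, d3$j), c(2, 5))

  expect_error(parse_edit_directives("A 3 14 9.0 7.0"), "line 1")
  expect_error(parse_edit_directives("Q 1 2"), "unknown directive")
  expect_error(parse_edit_directives("A 3 14"), "line 1")
})

test_that("edits apply with delete-before-add and replacement semantics", {
  rs <- restraint_set(data.frame(
    i = c(3, 10), j = c(14, 130), dmin = c(5, 6), dmax = c(7, 8),
    weight = 1, provenance = "consensus-minmax"))

  out <- apply_edits(rs, parse_edit_directives("D 55,58,120-160"))
  expect_equal(nrow(out), 1)
  expect_equal(c(out$i, out$j), c(3, 14))

  # idempotent delete
  out2 <- apply_edits(out, parse_edit_directives("D 55,58,120-160"))
  expect_identical(as.data.frame(out2), as.data.frame(out))

  # add into an empty set
  one <- apply_edits(restraint_set(),
                     parse_edit_directives("A 3 14 7.8 10.12"))
  expect_equal(nrow(one), 1)
  expect_equal(one$provenance, "user")

  # replacement on an existing pair
  rep <- apply_edits(rs, parse_edit_directives("A 3 14 1.0 2.0"))
  expect_equal(nrow(rep), 2)
  expect_equal(rep$dmax[rep$i == 3 & rep$j == 14], 2.0)

  # delete-before-add when a file mixes both
  mixed <- apply_edits(rs, parse_edit_directives("A 10 130 1 2\nD 130"))
  expect_equal(nrow(mixed), 2)  # the add survives the delete
  expect_true(any(mixed$provenance == "user"))
})

test_that("restraint energy is flat inside, quadratic outside, oracle-equal", {
  rs <- restraint_set(data.frame(i = 1, j = 5, dmin = 5, dmax = 10,
                                 weight = 1, provenance = "user"))
  mk <- function(d) {
    co <- cbind(seq_len(5) * 30, 0, 0)
    co[5, ] <- co[1, ] + c(d, 0, 0)
    co
  }
  expect_equal(restraint_energy(mk(7), rs), 0)
  expect_equal(restraint_energy(mk(12), rs), 4)   # 2 beyond dmax, weight 1
  expect_equal(restraint_energy(mk(4), rs), 1)

  # continuity at the boundary
  eps <- 1e-8
  expect_lt(restraint_energy(mk(10 + eps), rs), 1e-12)

  # random conformations vs literal loop oracle
  for (s in 1:5) {
    co <- random_coil(15, seed = 500 + s)
    tps <- rand_template_set(15, 3, 0.5, seed = 600 + s)
    rs2 <- generate_consensus_restraints(tps, d_cap = 1e9)
    expect_equal(restraint_energy(co, rs2),
                 oracle_restraint_energy(co, rs2), tolerance = 1e-9)
  }
  expect_error(restraint_energy(matrix(0, 3, 3), rs), "outside")
})

test_that("satisfaction fraction counts in-range restraints", {
  fx <- generate_fixture("helix", 20, perturbation = 0, n_templates = 1,
                         seed = 7)
  rs <- generate_single_template_restraints(fx$templates[[1]], tau = 0.5)
  expect_equal(satisfaction_fraction(fx$templates[[1]]$trace$coords, rs), 1)

  expect_warning(v <- satisfaction_fraction(random_coil(5, 1),
                                            restraint_set()), "empty")
  expect_equal(v, 1)

  # constructed half-violated set: all restrained distances are 180 A
  co <- cbind(seq_len(20) * 30, 0, 0)
  rs2 <- restraint_set(data.frame(
    i = 1:10, j = 1:10 + 6,
    dmin = rep(1, 10),
    dmax = c(rep(1000, 5), rep(2, 5)),  # last five violated
    weight = 1, provenance = "user"))
  expect_equal(satisfaction_fraction(co, rs2), 0.5)
})
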