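# small synthetic snapshot families used throughout
snap_family <- function(base, n, sd, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(k)
    base + matrix(rnorm(length(base), sd = sd), nrow(base), 3))
}

test_that("featurization is rigid-invariant with the expected dimension", {
  co <- random_coil(6, seed = 1)
  f <- featurize(list(co, co, rigid_move(co, seed = 2)))
  expect_equal(f[1, ], f[2, ])
  expect_equal(f[1, ], f[3, ], tolerance = 1e-9)
  # pair count with |i - j| >= 3 on n = 6: enumerated directly
  n_pairs <- sum(outer(1:6, 1:6, function(i, j) j - i >= 3))
  expect_equal(ncol(f), n_pairs)
})

test_that("k-means recovers planted structure and behaves at the extremes", {
  co <- random_coil(8, seed = 3)
  far <- rigid_move(random_coil(8, seed = 4) + 50, seed = 5)
  snaps <- c(snap_family(co, 6, 0.1, 6), snap_family(far, 5, 0.1, 7))
  f <- featurize(snaps)

  one <- kmeans_cluster(f, 1, seed = 1)
  expect_equal(one$assignments, rep(1L, 11))

  blobs <- kmeans_cluster(f, 2, seed = 1)
  expect_equal(length(unique(blobs$assignments[1:6])), 1)
  expect_equal(length(unique(blobs$assignments[7:11])), 1)
  expect_false(blobs$assignments[1] == blobs$assignments[7])

  # independent cross-check: stats::kmeans finds the same partition
  ref <- stats::kmeans(f, centers = 2, nstart = 5)
  expect_equal(length(unique(ref$cluster[1:6])), 1)
  agree <- (ref$cluster == ref$cluster[1]) ==
    (blobs$assignments == blobs$assignments[1])
  expect_true(all(agree))
  # and the within-cluster objective matches
  expect_equal(blobs$withinss, ref$tot.withinss, tolerance = 1e-6)

  # k = n distinct snapshots -> singletons
  sing <- kmeans_cluster(f, 11, seed = 2)
  expect_equal(sort(sing$sizes), rep(1L, 11))

  expect_identical(kmeans_cluster(f, 3, seed = 9)$assignments,
                   kmeans_cluster(f, 3, seed = 9)$assignments)
  expect_error(kmeans_cluster(f, 12, seed = 1), "exceeds")
})

test_that("average intra-cluster RMSD matches a brute-force pairwise mean", {
  co <- random_coil(10, seed = 8)
  snaps <- snap_family(co, 5, 0.8, 9)
  got <- cluster_rmsd_stats(1:5, snaps)
  prs <- combn(5, 2)
  want <- mean(vapply(seq_len(ncol(prs)), function(c)
    superpose(ca_trace(snaps[[prs[1, c]]]),
              ca_trace(snaps[[prs[2, c]]]))$rmsd, numeric(1)))
  expect_equal(got, want, tolerance = 1e-9)
  expect_equal(cluster_rmsd_stats(3, snaps), 0)

  # two members: average is just their rmsd
  two <- snaps[1:2]
  expect_equal(cluster_rmsd_stats(1:2, two),
               superpose(ca_trace(two[[1]]), ca_trace(two[[2]]))$rmsd)
})

test_that("representative mode switches at the 2.15 A average-RMSD rule", {
  co <- random_coil(12, seed = 10)
  tight <- snap_family(co, 6, 0.4, 11)   # avg RMSD well below 2.15
  diffuse <- snap_family(co, 6, 3.5, 12) # well above

  rt <- select_representative(1:6, tight)
  expect_lt(rt$avg_rmsd, 2.15)
  expect_equal(rt$mode, "average")

  rd <- select_representative(1:6, diffuse)
  expect_gt(rd$avg_rmsd, 2.15)
  expect_equal(rd$mode, "medoid")
  # the medoid is an actual member
  expect_true(any(vapply(1:6, function(k)
    isTRUE(all.equal(rd$coords, diffuse[[k]])), logical(1))))

  # singleton: the member itself, medoid mode
  rs <- select_representative(4, tight)
  expect_equal(rs$mode, "medoid")
  expect_equal(rs$coords, tight[[4]])
})

test_that("the average representative is at least as central as the medoid", {
  co <- random_coil(10, seed = 13)
  snaps <- snap_family(co, 8, 0.5, 14)
  rep <- select_representative(1:8, snaps, repair = FALSE)
  expect_equal(rep$mode, "average")
  mean_rmsd_to <- function(x) mean(vapply(snaps, function(s)
    superpose(ca_trace(x), ca_trace(s))$rmsd, numeric(1)))
  expect_lte(mean_rmsd_to(rep$coords),
             mean_rmsd_to(snaps[[rep$medoid]]) + 1e-9)
})

test_that("clusters rank by density with deterministic tie-breaks", {
  co <- random_coil(10, seed = 15)
  snaps <- c(snap_family(co, 5, 0.2, 16),                 # tight
             snap_family(co + 40, 5, 3.0, 17))            # diffuse
  cs <- list(assignments = rep(1:2, each = 5), k = 2L,
             sizes = c(5L, 5L))
  class(cs) <- "cluster_set"
  rk <- rank_clusters(cs, snaps)
  expect_equal(rk$cluster, c(1, 2))     # equal sizes: tighter first
  expect_gt(rk$density[1], rk$density[2])
  expect_equal(rk$rank, 1:2)

  one <- list(assignments = rep(1L, 5), k = 1L, sizes = 5L)
  class(one) <- "cluster_set"
  expect_equal(rank_clusters(one, snaps[1:5])$rank, 1)
})

test_that("cross-analysis matrices are symmetric with canonical diagonals", {
  models <- list(random_coil(8, seed = 18), random_coil(8, seed = 19),
                 random_coil(8, seed = 20))
  m <- cross_analysis(models)
  expect_equal(diag(m$rmsd), rep(0, 3))
  expect_equal(diag(m$gdt_ts), rep(1, 3))
  expect_equal(m$rmsd, t(m$rmsd))
  expect_equal(m$gdt_ts, t(m$gdt_ts))
  # entries equal direct geometry calls
  expect_equal(m$rmsd[1, 2],
               superpose(ca_trace(models[[1]]), ca_trace(models[[2]]))$rmsd)
  expect_equal(m$gdt_ts[1, 3],
               gdt_ts(ca_trace(models[[1]]), ca_trace(models[[3]])))
})

test_that("end-to-end model selection returns ranked, repaired models", {
  co <- random_coil(12, seed = 21)
  tr <- run_simulation(co, strrep("C", 12), make_ladder(2, 1, 3),
                       n_cycles = 60, record_every = 5, seed = 22)
  ms <- cluster_models(tr, k = 4, n_models = 3, seed = 23)
  expect_length(ms$models, 3)
  expect_equal(ms$table$rank, 1:3)
  expect_equal(dim(ms$matrices$rmsd), c(3, 3))
  # ranking is by non-increasing density
  expect_true(all(diff(ms$ranking$density) <= 1e-12))
})
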