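#' Featurize trajectory snapshots for clustering
#'
#' Maps each snapshot to its vector of inter-residue C-alpha distances over
#' pairs with sequence separation `|i - j| >= min_sep`, a rotation- and
#' translation-invariant embedding.
#'
#' @param snapshots a `fold_trajectory` or list of n x 3 matrices.
#' @param min_sep minimum sequence separation of included pairs.
#' @return Numeric matrix, one row per snapshot.
#' @export
featurize <- function(snapshots, min_sep = 3L) {
  if (inherits(snapshots, "fold_trajectory")) snapshots <- snapshots$snapshots
  stopifnot(length(snapshots) >= 1L)
  n <- nrow(snapshots[[1]])
  pairs <- which(outer(seq_len(n), seq_len(n),
                       function(i, j) j - i >= min_sep), arr.ind = TRUE)
  t(vapply(snapshots, function(co) {
    co <- as.matrix(co)
    sqrt(rowSums((co[pairs[, 1], , drop = FALSE] -
                    co[pairs[, 2], , drop = FALSE])^2))
  }, numeric(nrow(pairs))))
}

# k-means++ center seeding (deterministic under the active RNG stream)
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, x[centers[1], ])^2)
    for (c in 2:k) {
      if (all(d2 == 0)) {
        centers[c] <- sample.int(n, 1)
      } else {
        centers[c] <- sample.int(n, 1, prob = d2 / sum(d2))
      }
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[c], ])^2))
    }
  }
  x[centers, , drop = FALSE]
}

#' K-means clustering of featurized snapshots
#'
#' Lloyd's algorithm with k-means++ seeding under a fixed seed. Clusters
#' emptied during iteration are repaired by splitting the largest cluster
#' (the emptied center is re-placed on the point farthest from the largest
#' cluster's center), so the final partition has no empty clusters.
#'
#' @param features numeric matrix from [featurize()].
#' @param k cluster count, `1 <= k <= nrow(features)`.
#' @param seed integer seed.
#' @param max_iter Lloyd iteration cap.
#' @return A `cluster_set`: list with `assignments`, `k`, `sizes`,
#'   `centers`, `withinss` (objective value) and `iterations`.
#' @export
kmeans_cluster <- function(features, k, seed = 1L, max_iter = 100L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop(sprintf("k = %d exceeds the %d snapshots", k, n))
  with_rng(seed, {
    centers <- kmeanspp_centers(features, k)
    assign_pts <- function(centers) {
      d2 <- vapply(seq_len(k), function(c)
        rowSums(sweep(features, 2, centers[c, ])^2), numeric(n))
      max.col(-matrix(d2, n, k), ties.method = "first")
    }
    lab <- assign_pts(centers)
    iters <- 0L
    repeat {
      iters <- iters + 1L
      # repair empty clusters by splitting the largest
      for (c in which(tabulate(lab, k) == 0L)) {
        big <- which.max(tabulate(lab, k))
        members <- which(lab == big)
        far <- members[which.max(rowSums(
          sweep(features[members, , drop = FALSE], 2, centers[big, ])^2))]
        centers[c, ] <- features[far, ]
        lab[far] <- c
      }
      for (c in seq_len(k))
        centers[c, ] <- colMeans(features[lab == c, , drop = FALSE])
      new_lab <- assign_pts(centers)
      if (identical(new_lab, lab) || iters >= max_iter) {
        lab <- new_lab
        break
      }
      lab <- new_lab
    }
    for (c in which(tabulate(lab, k) == 0L)) {  # final safety repair
      big <- which.max(tabulate(lab, k))
      members <- which(lab == big)
      far <- members[which.max(rowSums(
        sweep(features[members, , drop = FALSE], 2, centers[big, ])^2))]
      lab[far] <- c
    }
    wss <- sum(vapply(seq_len(k), function(c) {
      m <- features[lab == c, , drop = FALSE]
      sum(sweep(m, 2, colMeans(m))^2)
    }, numeric(1)))
    structure(list(assignments = lab, k = k, sizes = tabulate(lab, k),
                   centers = centers, withinss = wss, iterations = iters),
              class = "cluster_set")
  })
}

pairwise_rmsd <- function(members, snapshots) {
  m <- length(members)
  M <- matrix(0, m, m)
  if (m < 2) return(M)
  for (p in 1:(m - 1)) for (q in (p + 1):m) {
    M[p, q] <- M[q, p] <- kabsch(as.matrix(snapshots[[members[p]]]),
                                 as.matrix(snapshots[[members[q]]]))$rmsd
  }
  M
}

#' Average intra-cluster RMSD
#'
#' Mean over all member pairs of the optimally superposed RMSD. For
#' clusters above `max_exact` members a fixed-seed uniform subsample of
#' members is used.
#'
#' @param members integer snapshot indices of the cluster.
#' @param snapshots list of conformations.
#' @param max_exact largest member count treated exactly.
#' @param seed subsampling seed.
#' @return Average RMSD in Angstrom (0 for a singleton).
#' @export
cluster_rmsd_stats <- function(members, snapshots, max_exact = 200L,
                               seed = 1L) {
  stopifnot(length(members) >= 1L)
  if (length(members) > max_exact)
    members <- with_rng(seed, sort(sample(members, max_exact)))
  if (length(members) < 2L) return(0)
  M <- pairwise_rmsd(members, snapshots)
  mean(M[upper.tri(M)])
}

#' Select a cluster's representative model
#'
#' If the average intra-cluster RMSD exceeds the 2.15 Angstrom switch the
#' medoid is chosen (the member minimizing summed dissimilarity to all
#' members); otherwise the average cluster structure is built by superposing
#' every member onto the medoid, averaging coordinates, and repairing the
#' averaged trace against the virtual-bond window by local energy
#' minimization. Singletons return the member itself (mode `medoid`).
#'
#' @param members integer snapshot indices of the cluster.
#' @param snapshots list of conformations.
#' @param switch_rmsd mode-switch threshold (Angstrom), default 2.15.
#' @param repair repair averaged traces (logical).
#' @return List: `coords` of the representative, `mode` (`"average"` or
#'   `"medoid"`), `avg_rmsd`, `medoid` (snapshot index).
#' @export
select_representative <- function(members, snapshots,
                                  switch_rmsd = fold_defaults$rep_rmsd_switch,
                                  repair = TRUE) {
  stopifnot(length(members) >= 1L)
  if (length(members) == 1L)
    return(list(coords = as.matrix(snapshots[[members]]), mode = "medoid",
                avg_rmsd = 0, medoid = members))
  M <- pairwise_rmsd(members, snapshots)
  avg <- mean(M[upper.tri(M)])
  med_idx <- which.min(rowSums(M))
  medoid <- members[med_idx]
  if (avg > switch_rmsd)
    return(list(coords = as.matrix(snapshots[[medoid]]), mode = "medoid",
                avg_rmsd = avg, medoid = medoid))
  ref <- as.matrix(snapshots[[medoid]])
  acc <- matrix(0, nrow(ref), 3)
  for (mm in members) {
    co <- as.matrix(snapshots[[mm]])
    k <- kabsch(ref, co)
    acc <- acc + sweep(co %*% k$rotation, 2, k$translation, "+")
  }
  avg_coords <- acc / length(members)
  if (repair) avg_coords <- repair_conformation(avg_coords)
  list(coords = avg_coords, mode = "average", avg_rmsd = avg,
       medoid = medoid)
}

#' Rank clusters by density
#'
#' Density is member count divided by `1 + average intra-cluster RMSD`, so
#' it rises with occupancy and tightness. Ties break by member count, then
#' by lowest mean snapshot energy, then by cluster label.
#'
#' @param cluster_set a `cluster_set` from [kmeans_cluster()].
#' @param snapshots list of conformations.
#' @param energies optional per-snapshot energies for tie-breaking.
#' @return Data frame, one row per cluster in rank order: `rank`, `cluster`,
#'   `size`, `avg_rmsd`, `density`.
#' @export
rank_clusters <- function(cluster_set, snapshots, energies = NULL) {
  k <- cluster_set$k
  stats <- lapply(seq_len(k), function(c) {
    members <- which(cluster_set$assignments == c)
    avg <- cluster_rmsd_stats(members, snapshots)
    me <- if (is.null(energies)) 0 else mean(energies[members])
    data.frame(cluster = c, size = length(members), avg_rmsd = avg,
               density = length(members) / (1 + avg), mean_energy = me)
  })
  stats <- do.call(rbind, stats)
  ord <- order(-stats$density, -stats$size, stats$mean_energy,
               stats$cluster)
  stats <- stats[ord, , drop = FALSE]
  stats$rank <- seq_len(nrow(stats))
  rownames(stats) <- NULL
  stats[c("rank", "cluster", "size", "avg_rmsd", "density", "mean_energy")]
}

#' Cross-analysis matrices over representative models
#'
#' @param models list of representative conformations (n x 3 matrices).
#' @return List of symmetric matrices `rmsd` (zero diagonal) and `gdt_ts`
#'   (unit diagonal).
#' @export
cross_analysis <- function(models) {
  stopifnot(length(models) >= 1L)
  m <- length(models)
  RM <- matrix(0, m, m); GD <- diag(1, m)
  if (m >= 2) {
    for (p in 1:(m - 1)) for (q in (p + 1):m) {
      a <- ca_trace(as.matrix(models[[p]]))
      b <- ca_trace(as.matrix(models[[q]]))
      RM[p, q] <- RM[q, p] <- superpose(a, b)$rmsd
      GD[p, q] <- GD[q, p] <- gdt_ts(a, b)
    }
  }
  list(rmsd = RM, gdt_ts = GD)
}

#' Cluster a trajectory and select ranked models
#'
#' End-to-end model selection: featurize, K-means cluster, rank clusters by
#' density, and pick a representative per cluster (average structure below
#' the 2.15 Angstrom average-RMSD switch, medoid above). All returned
#' models are geometry-regularized against the virtual-bond window.
#'
#' @param trajectory a `fold_trajectory` (or list of conformations).
#' @param k cluster count (capped at the snapshot count).
#' @param n_models number of top-ranked models to return.
#' @param seed clustering seed.
#' @return A `model_set`: list with `models` (ranked conformations),
#'   `table` (per-model rank, cluster, size, avg RMSD, selection mode),
#'   `clusters` (the `cluster_set`), `ranking`, and cross-analysis
#'   `matrices`.
#' @export
cluster_models <- function(trajectory, k = fold_defaults$k_clusters,
                           n_models = fold_defaults$n_models, seed = 1L) {
  snapshots <- if (inherits(trajectory, "fold_trajectory"))
    trajectory$snapshots else trajectory
  energies <- if (inherits(trajectory, "fold_trajectory"))
    trajectory$series$energy else NULL
  k <- min(k, length(snapshots))
  feats <- featurize(snapshots)
  cs <- kmeans_cluster(feats, k, seed = seed)
  ranking <- rank_clusters(cs, snapshots, energies)
  n_models <- min(n_models, k)
  reps <- lapply(seq_len(n_models), function(r) {
    members <- which(cs$assignments == ranking$cluster[r])
    rep <- select_representative(members, snapshots)
    # medoids are raw snapshots; regularize their geometry like averages
    if (rep$mode == "medoid") rep$coords <- repair_conformation(rep$coords)
    rep
  })
  tab <- data.frame(
    rank = seq_len(n_models),
    cluster = ranking$cluster[seq_len(n_models)],
    size = ranking$size[seq_len(n_models)],
    avg_rmsd = vapply(reps, `[[`, numeric(1), "avg_rmsd"),
    mode = vapply(reps, `[[`, character(1), "mode"))
  structure(list(models = lapply(reps, `[[`, "coords"), table = tab,
                 clusters = cs, ranking = ranking,
                 matrices = cross_analysis(lapply(reps, `[[`, "coords"))),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("<model_set> %d model(s) from %d cluster(s)\n",
              length(x$models), x$clusters$k))
  print.data.frame(x$table)
  invisible(x)
}
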