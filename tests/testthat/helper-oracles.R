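# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive quantities with the most literal code
# possible, separate from the package implementation paths.

# random point cloud trace (not chain-like; fine for metric tests)
rand_trace <- function(n, seed, spread = 6) {
  set.seed(seed)
  ca_trace(matrix(rnorm(3 * n, sd = spread), n, 3))
}

# apply a random proper rotation + translation
rigid_move <- function(coords, seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(coords %*% R, 2, runif(3, -20, 20), "+")
}

# independent least-squares fit of b onto a (fresh SVD code), returns rmsd
# and the transformed b
oracle_fit <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  s <- svd(t(B) %*% A)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  Bt <- sweep(B %*% R, 2, ca, "+")
  list(rmsd = sqrt(mean(rowSums((Bt - sweep(A, 2, ca, "+"))^2))), bt = Bt)
}

# rotation-space grid/optim search for the minimal rmsd of b onto a:
# optimizes Euler angles from many random starts (no SVD involved)
oracle_rmsd_rotsearch <- function(a, b, n_starts = 40, seed = 1) {
  set.seed(seed)
  A <- sweep(a, 2, colMeans(a)); B <- sweep(b, 2, colMeans(b))
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((B %*% t(rot(ang)) - A)^2)))
  best <- Inf
  for (s in seq_len(n_starts)) {
    r <- optim(runif(3, -pi, pi), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

# exhaustive all-subset GDT oracle: for every residue subset of size >= 3,
# superpose b onto a on the subset and count residues within each threshold
oracle_gdt <- function(a, b, thresholds = c(1, 2, 4, 8)) {
  common <- intersect(a$resids, b$resids)
  xa <- a$coords[match(common, a$resids), , drop = FALSE]
  xb <- b$coords[match(common, b$resids), , drop = FALSE]
  m <- nrow(xa)
  counts <- matrix(0, 0, length(thresholds))
  for (sz in 3:m) {
    for (S in combn(m, sz, simplify = FALSE)) {
      fit <- oracle_fit(xa[S, , drop = FALSE], xb[S, , drop = FALSE])
      # apply the subset transform to all residues
      cb <- colMeans(xb[S, , drop = FALSE])
      ca <- colMeans(xa[S, , drop = FALSE])
      s <- svd(t(sweep(xb[S, , drop = FALSE], 2, cb)) %*%
                 sweep(xa[S, , drop = FALSE], 2, ca))
      d <- sign(det(s$u %*% t(s$v)))
      R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
      dev <- sqrt(rowSums((sweep(sweep(xb, 2, cb) %*% R, 2, ca, "+") -
                             xa)^2))
      counts <- rbind(counts, vapply(thresholds,
                                     function(t) sum(dev <= t), numeric(1)))
    }
  }
  mean(apply(counts, 2, max) / m)
}

# literal per-pair loop over templates: distance stats for each (i, j)
oracle_pair_stats <- function(templates, min_obs = 1) {
  n <- max(vapply(templates, function(t) max(t$trace$resids), integer(1)))
  rows <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ds <- c()
    for (tp in templates) {
      ri <- match(i, tp$trace$resids); rj <- match(j, tp$trace$resids)
      if (!is.na(ri) && !is.na(rj))
        ds <- c(ds, sqrt(sum((tp$trace$coords[ri, ] -
                                tp$trace$coords[rj, ])^2)))
    }
    if (length(ds) >= min_obs)
      rows[[length(rows) + 1]] <- data.frame(
        i = i, j = j, d_min = min(ds), d_max = max(ds), mean = mean(ds),
        sigma = sqrt(mean((ds - mean(ds))^2)), n_obs = length(ds))
  }
  do.call(rbind, rows)
}

# literal per-restraint loop for the flat-bottom energy
oracle_restraint_energy <- function(coords, rs) {
  e <- 0
  for (r in seq_len(nrow(rs))) {
    d <- sqrt(sum((coords[rs$i[r], ] - coords[rs$j[r], ])^2))
    if (d > rs$dmax[r]) e <- e + rs$weight[r] * (d - rs$dmax[r])^2
    if (d < rs$dmin[r]) e <- e + rs$weight[r] * (rs$dmin[r] - d)^2
  }
  e
}

# random perturbed-template set over a toy structure
rand_template_set <- function(n_res, n_templates, noise, seed,
                              partial = FALSE) {
  set.seed(seed)
  base <- random_coil(n_res, seed = seed + 1000)
  lapply(seq_len(n_templates), function(k) {
    co <- base + matrix(rnorm(3 * n_res, sd = noise), n_res, 3)
    resids <- seq_len(n_res)
    if (partial && runif(1) < 0.5) {
      keep <- sort(sample(n_res, max(3, n_res - sample(1:5, 1))))
      co <- co[keep, , drop = FALSE]; resids <- keep
    }
    fold_template(ca_trace(co, resids), source = sprintf("t%d", k))
  })
}
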