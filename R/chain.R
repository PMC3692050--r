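unit_vec <- function(v) v / sqrt(sum(v^2))

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n2 <- sum(v^2)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}

# Rodrigues rotation of row-vectors `x` about unit `axis` by `angle`.
rotate_about <- function(x, axis, angle) {
  axis <- unit_vec(axis)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  x %*% t(R)
}

#' Self-avoiding random-coil chain
#'
#' Grows an off-lattice C-alpha random walk with fixed 3.8 Angstrom bonds,
#' rejection-sampled so no two non-adjacent beads come closer than the
#' hard-clash distance. Deterministic for a given seed.
#'
#' @param n residue count, 1..900.
#' @param seed integer RNG seed.
#' @param bond_length virtual bond length (Angstrom).
#' @param clash_dist hard-core distance between non-adjacent beads.
#' @param max_restarts growth restarts before giving up.
#' @return n x 3 coordinate matrix.
#' @export
random_coil <- function(n, seed, bond_length = fold_defaults$bond_length,
                        clash_dist = fold_defaults$clash_dist,
                        max_restarts = 50L) {
  stopifnot(n >= 1L, n <= fold_defaults$max_seq_length)
  with_rng(seed, {
    for (attempt in seq_len(max_restarts)) {
      coords <- grow_walk(n, bond_length, clash_dist)
      if (!is.null(coords)) return(coords)
    }
    stop("random coil growth failed after bounded retries")
  })
}

grow_walk <- function(n, bond_length, clash_dist, tries_per_bead = 200L) {
  coords <- matrix(0, n, 3)
  if (n == 1L) return(coords)
  coords[2, ] <- bond_length * random_unit()
  if (n == 2L) return(coords)
  for (k in 3:n) {
    placed <- FALSE
    for (t in seq_len(tries_per_bead)) {
      cand <- coords[k - 1, ] + bond_length * random_unit()
      prev <- coords[seq_len(k - 2), , drop = FALSE]
      if (min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= clash_dist) {
        coords[k, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  coords
}

# Connect two fixed anchors with g intermediate beads whose bonds fall in
# the bond window: linear interpolation + transverse jitter, then iterative
# bond projection (Gauss-Seidel) holding the anchors fixed.
bridge_gap <- function(p0, p1, g, bond_window = fold_defaults$bond_window,
                       bond_length = fold_defaults$bond_length,
                       max_passes = 500L) {
  D <- sqrt(sum((p1 - p0)^2))
  if (D > bond_window[2] * (g + 1))
    stop(sprintf(
      "unbridgeable gap: anchors %.1f A apart but %d bonds reach at most %.1f A; review template numbering",
      D, g + 1L, bond_window[2] * (g + 1)))
  if (g == 0L) return(matrix(numeric(0), 0, 3))
  frac <- seq_len(g) / (g + 1)
  pts <- outer(frac, p1 - p0) + matrix(p0, g, 3, byrow = TRUE)
  # transverse jitter so compressed bridges can buckle into a zigzag
  jitter_sd <- max(0.3, (bond_length * (g + 1) - D) / (g + 1))
  pts <- pts + matrix(stats::rnorm(3 * g, sd = jitter_sd), g, 3)
  path <- rbind(matrix(p0, 1, 3), pts, matrix(p1, 1, 3))
  for (pass in seq_len(max_passes)) {
    ok <- TRUE
    for (b in seq_len(g + 1L)) {
      v <- path[b + 1L, ] - path[b, ]
      len <- sqrt(sum(v^2))
      if (len < bond_window[1] || len > bond_window[2]) {
        ok <- FALSE
        corr <- (bond_length - len) / max(len, 1e-6) * v
        w1 <- if (b == 1L) 0 else 0.5
        w2 <- if (b == g + 1L) 0 else 0.5
        if (w1 + w2 == 0) next
        path[b, ] <- path[b, ] - corr * w1 / (w1 + w2)
        path[b + 1L, ] <- path[b + 1L, ] + corr * w2 / (w1 + w2)
      }
    }
    if (ok) break
  }
  if (!ok) stop("gap bridging failed to satisfy the bond window")
  path[2:(g + 1L), , drop = FALSE]
}

#' Build a starting conformation from templates
#'
#' Template-covered residues take their coordinates from the first template
#' covering them; interior gaps are closed with coil bridges that respect
#' the virtual-bond window; uncovered leading/trailing tails are grown as
#' random coil off the first/last anchor. With no templates this falls back
#' to [random_coil()].
#'
#' @param templates list of [fold_template()] (possibly empty).
#' @param n query length (residues).
#' @param seed integer RNG seed.
#' @param bond_window allowed consecutive-bead distance range.
#' @return n x 3 coordinate matrix.
#' @export
build_start_from_templates <- function(templates, n, seed,
                                       bond_window = fold_defaults$bond_window) {
  if (length(templates) == 0L) return(random_coil(n, seed))
  bond <- fold_defaults$bond_length
  coords <- matrix(NA_real_, n, 3)
  for (tp in templates) {
    idx <- tp$trace$resids
    new <- idx[is.na(coords[idx, 1])]
    coords[new, ] <- tp$trace$coords[match(new, idx), , drop = FALSE]
  }
  covered <- which(!is.na(coords[, 1]))
  with_rng(seed, {
    # interior gaps
    gaps <- which(is.na(coords[, 1]))
    interior <- gaps[gaps > min(covered) & gaps < max(covered)]
    if (length(interior)) {
      runs <- split(interior, cumsum(c(1, diff(interior) != 1)))
      for (run in runs) {
        a <- min(run) - 1L; b <- max(run) + 1L
        coords[run, ] <- bridge_gap(coords[a, ], coords[b, ], length(run),
                                    bond_window, bond)
      }
    }
    # tails grown as coil off the anchors
    lead <- seq_len(min(covered) - 1L)
    for (k in rev(lead)) {
      repeat {
        cand <- coords[k + 1L, ] + bond * random_unit()
        ref <- coords[stats::complete.cases(coords) &
                        seq_len(n) > k + 1L, , drop = FALSE]
        if (nrow(ref) == 0L ||
            min(sqrt(rowSums(sweep(ref, 2, cand)^2))) >=
              fold_defaults$clash_dist) break
      }
      coords[k, ] <- cand
    }
    if (max(covered) < n) {
      for (k in (max(covered) + 1L):n) {
        repeat {
          cand <- coords[k - 1L, ] + bond * random_unit()
          ref <- coords[stats::complete.cases(coords) &
                          seq_len(n) < k - 1L, , drop = FALSE]
          if (nrow(ref) == 0L ||
              min(sqrt(rowSums(sweep(ref, 2, cand)^2))) >=
                fold_defaults$clash_dist) break
        }
        coords[k, ] <- cand
      }
    }
  })
  coords
}

pseudo_angles <- function(coords) {
  n <- nrow(coords)
  if (n < 3L) return(numeric())
  v1 <- coords[1:(n - 2), , drop = FALSE] - coords[2:(n - 1), , drop = FALSE]
  v2 <- coords[3:n, , drop = FALSE] - coords[2:(n - 1), , drop = FALSE]
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  acos(pmin(1, pmax(-1, cosang)))
}

#' Surrogate coarse-grained internal energy
#'
#' A transparent stand-in for a full statistical force field, with three
#' terms: a harmonic virtual-bond term about 3.8 Angstrom; a pseudo-bond-
#' angle bias toward the secondary-structure-dependent target (helix 91
#' degrees, extended 120 degrees, coil unbiased); and a soft-core repulsion
#' between non-adjacent beads closer than the clash distance. Energies are
#' dimensionless model units; only relative values are meaningful.
#'
#' @param coords n x 3 conformation coordinates.
#' @param ss a `secondary_structure` (or H/E/C string) of matching length.
#' @param params energy parameters; see `energy_defaults`.
#' @return An `energy_breakdown`: list with `local`, `excluded_volume`,
#'   `restraint` (0 here) and `total`.
#' @export
internal_energy <- function(coords, ss, params = energy_defaults) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  states <- if (inherits(ss, "secondary_structure")) ss$states else ss
  states <- strsplit(states, "")[[1]]
  if (length(states) != n)
    stop("secondary structure length does not match the conformation")
  local <- 0
  if (n >= 2) {
    b <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                         coords[-n, , drop = FALSE])^2))
    local <- local + params$k_bond * sum((b - fold_defaults$bond_length)^2)
  }
  if (n >= 3) {
    th <- pseudo_angles(coords)
    centers <- states[2:(n - 1)]
    target <- ifelse(centers == "H", params$theta_H,
                     ifelse(centers == "E", params$theta_E, NA_real_))
    biased <- !is.na(target)
    if (any(biased))
      local <- local + params$k_angle * sum((th[biased] - target[biased])^2)
  }
  ev <- 0
  if (n >= 3) {
    D <- as.matrix(stats::dist(coords))
    sep <- abs(row(D) - col(D))
    hit <- sep >= 2 & upper.tri(D) & D < fold_defaults$clash_dist
    if (any(hit))
      ev <- params$k_rep * sum((fold_defaults$clash_dist - D[hit])^2)
  }
  structure(list(local = local, excluded_volume = ev, restraint = 0,
                 total = local + ev), class = "energy_breakdown")
}

#' Propose a local Monte Carlo move
#'
#' Draws one of three reversible local modifications: a single-bead
#' displacement (uniform in a ball of radius `max_disp`), a two-bead
#' crankshaft rotation about the chord through its flanking beads, or a
#' terminal-bead pivot about a random axis through its neighbor. Move-kind
#' probabilities are renormalized when the chain is too short for a
#' crankshaft.
#'
#' @param coords n x 3 conformation (n >= 3). Uses the current RNG stream.
#' @param params move parameters; see `move_defaults`.
#' @return List with `coords` (proposed conformation), `kind`, and `beads`
#'   (indices moved).
#' @export
propose_move <- function(coords, params = move_defaults) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n >= 3L)
  p <- c(single = params$p_single, crank = params$p_crank,
         pivot = params$p_pivot)
  if (n < 4L) p["crank"] <- 0
  p <- p / sum(p)
  kind <- sample(names(p), 1, prob = p)
  out <- coords
  if (kind == "single") {
    k <- sample.int(n, 1)
    # uniform in a ball
    r <- params$max_disp * stats::runif(1)^(1 / 3)
    out[k, ] <- coords[k, ] + r * random_unit()
    beads <- k
  } else if (kind == "crank") {
    s <- sample.int(n - 3L, 1)
    axis <- coords[s + 3L, ] - coords[s, ]
    ang <- stats::runif(1, -params$max_angle, params$max_angle)
    seg <- coords[(s + 1L):(s + 2L), , drop = FALSE]
    seg <- sweep(rotate_about(sweep(seg, 2, coords[s, ]), axis, ang),
                 2, coords[s, ], "+")
    out[(s + 1L):(s + 2L), ] <- seg
    beads <- (s + 1L):(s + 2L)
  } else {
    end <- if (stats::runif(1) < 0.5) 1L else n
    nb <- if (end == 1L) 2L else n - 1L
    axis <- random_unit()
    ang <- stats::runif(1, -params$max_angle, params$max_angle)
    v <- coords[end, ] - coords[nb, ]
    out[end, ] <- coords[nb, ] + drop(rotate_about(matrix(v, 1), axis, ang))
    beads <- end
  }
  list(coords = out, kind = kind, beads = beads)
}

# Gently restore chain geometry of an averaged trace: minimize bond +
# excluded-volume energy from the given coordinates (local L-BFGS descent).
repair_conformation <- function(coords, maxit = 100L) {
  n <- nrow(coords)
  if (n < 2L) return(coords)
  ss <- strrep("C", n)
  fn <- function(x) {
    internal_energy(matrix(x, n, 3), ss)$total
  }
  res <- stats::optim(as.numeric(coords), fn, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  matrix(res$par, n, 3)
}
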