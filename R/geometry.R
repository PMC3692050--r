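# Kabsch least-squares superposition of point set b onto a (m x 3 each).
# Returns rotation (applied as x %*% R), translation, and rmsd.
kabsch <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  C <- crossprod(B, A)            # 3x3 covariance
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  Bt <- B %*% R
  rmsd <- sqrt(mean(rowSums((Bt - A)^2)))
  list(rotation = R, translation = as.numeric(ca - cb %*% R), rmsd = rmsd)
}

common_coords <- function(a, b) {
  stopifnot(inherits(a, "ca_trace"), inherits(b, "ca_trace"))
  common <- intersect(a$resids, b$resids)
  if (length(common) < 3L)
    stop("insufficient overlap: traces share fewer than 3 residues")
  list(a = a$coords[match(common, a$resids), , drop = FALSE],
       b = b$coords[match(common, b$resids), , drop = FALSE],
       resids = common)
}

#' Optimal rigid-body superposition of two C-alpha traces
#'
#' Least-squares (Kabsch) superposition of `b` onto `a` over their common
#' residues. The returned transform maps a coordinate row `x` of `b` to
#' `x %*% rotation + translation`.
#'
#' @param a,b [ca_trace()] objects sharing at least 3 residue indices.
#' @return A `superposition` list: `rotation` (proper 3 x 3), `translation`,
#'   `rmsd` (Angstrom) over the common residues, and `resids` used.
#' @export
superpose <- function(a, b) {
  cc <- common_coords(a, b)
  k <- kabsch(cc$a, cc$b)
  structure(c(k, list(resids = cc$resids)), class = "superposition")
}

# Max fraction of rows of xb superposable onto xa within `thr`, by iterative
# seed-extension: superpose on a seed subset, re-include all residues within
# the threshold, repeat to a fixed point; maximize over seeds.
gdt_fraction <- function(xa, xb, thr, seeds) {
  m <- nrow(xa)
  best <- 0
  for (S in seeds) {
    for (iter in 1:20) {
      k <- kabsch(xa[S, , drop = FALSE], xb[S, , drop = FALSE])
      dev <- sqrt(rowSums((sweep(xb %*% k$rotation, 2, k$translation, "+") -
                             xa)^2))
      inside <- which(dev <= thr)
      best <- max(best, length(inside) / m)
      if (length(inside) < 3L || identical(inside, S)) break
      S <- inside
    }
  }
  best
}

gdt_seeds <- function(m) {
  if (m <= 8L) {
    # exhaustive seeding over every subset of size >= 3 for tiny instances
    seeds <- unlist(lapply(3:m, function(sz)
      utils::combn(m, sz, simplify = FALSE)), recursive = FALSE)
  } else {
    seeds <- list()
    for (w in c(3L, 5L, 7L))
      if (m >= w)
        seeds <- c(seeds, lapply(seq_len(m - w + 1L),
                                 function(s) s:(s + w - 1L)))
  }
  c(seeds, list(seq_len(m)))
}

#' Global Distance Test Total Score (GDT_TS)
#'
#' Mean over the 1, 2, 4 and 8 Angstrom thresholds of the maximal fraction
#' of common residues that can be rigidly superposed within the threshold,
#' reported as a fraction in [0, 1]. The per-threshold maximization uses the
#' standard iterative seed-extension search (exhaustive subset seeding on
#' tiny instances, contiguous 3/5/7-residue windows otherwise).
#'
#' @param a,b [ca_trace()] objects sharing at least 3 residues.
#' @param thresholds distance cutoffs in Angstrom.
#' @return GDT_TS fraction in [0, 1].
#' @export
gdt_ts <- function(a, b, thresholds = c(1, 2, 4, 8)) {
  cc <- common_coords(a, b)
  seeds <- gdt_seeds(nrow(cc$a))
  mean(vapply(thresholds, function(thr)
    gdt_fraction(cc$a, cc$b, thr, seeds), numeric(1)))
}

#' Radius of gyration
#'
#' Root-mean-square distance of the beads from their centroid.
#'
#' @param coords n x 3 coordinate matrix (or [ca_trace()]).
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(coords) {
  if (inherits(coords, "ca_trace")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("radius of gyration needs at least one bead")
  sqrt(mean(rowSums(sweep(coords, 2, colMeans(coords))^2)))
}

#' End-to-end distance
#'
#' Euclidean distance between the first and last bead of a chain.
#'
#' @param coords n x 3 coordinate matrix (or [ca_trace()]), n >= 2.
#' @return Distance in Angstrom.
#' @export
end_to_end <- function(coords) {
  if (inherits(coords, "ca_trace")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L)
    stop("end-to-end distance undefined for a single bead")
  sqrt(sum((coords[nrow(coords), ] - coords[1, ])^2))
}
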