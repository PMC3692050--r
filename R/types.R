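#' Construct a C-alpha trace
#'
#' A trace is an ordered set of C-alpha coordinates (Angstrom) together with
#' the 1-based residue indices, into the query sequence, that they occupy.
#' Traces represent both full conformations (every residue present) and
#' partial template structures (a coverage subset).
#'
#' @param coords numeric matrix, n x 3, finite.
#' @param resids integer vector of length n, strictly increasing, >= 1. If
#'   omitted, `1:n` is used.
#' @return An object of class `ca_trace`: a list with `coords` and `resids`.
#' @export
ca_trace <- function(coords, resids = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("coords must be finite")
  if (is.null(resids)) resids <- seq_len(nrow(coords))
  resids <- as.integer(resids)
  if (length(resids) != nrow(coords))
    stop("coords and resids must have equal length")
  if (any(resids < 1L) || any(diff(resids) <= 0L))
    stop("resids must be strictly increasing positive integers")
  structure(list(coords = coords, resids = resids), class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace> %d residues (resid %d..%d)\n",
              length(x$resids), min(x$resids), max(x$resids)))
  invisible(x)
}

#' Construct a template structure
#'
#' A template is a partial C-alpha trace already aligned (by residue
#' numbering) to the query sequence, plus a source label.
#'
#' @param trace a [ca_trace()].
#' @param source free-text label, typically the originating file name.
#' @return An object of class `fold_template`.
#' @export
fold_template <- function(trace, source = "template") {
  stopifnot(inherits(trace, "ca_trace"))
  structure(list(trace = trace, source = as.character(source)[1]),
            class = "fold_template")
}

#' @export
print.fold_template <- function(x, ...) {
  cat(sprintf("<template '%s'> covering %d residues\n",
              x$source, length(x$trace$resids)))
  invisible(x)
}

#' Check conformation geometry
#'
#' Audits a full-chain conformation against the coarse-grained chain
#' invariants: consecutive-bead distances inside the virtual-bond window and
#' no non-adjacent pair closer than the hard-clash distance.
#'
#' @param coords n x 3 coordinate matrix.
#' @param bond_window length-2 numeric, allowed consecutive-bead distance
#'   range (Angstrom).
#' @param clash_dist minimum allowed distance between non-adjacent beads.
#' @return A list with logical `ok`, and character vectors `violations`.
#' @export
check_conformation <- function(coords,
                               bond_window = fold_defaults$bond_window,
                               clash_dist = fold_defaults$clash_dist) {
  coords <- as.matrix(coords)
  viol <- character()
  n <- nrow(coords)
  if (!all(is.finite(coords))) viol <- c(viol, "non-finite coordinates")
  if (n >= 2) {
    b <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                         coords[-n, , drop = FALSE])^2))
    bad <- which(b < bond_window[1] | b > bond_window[2])
    if (length(bad))
      viol <- c(viol, sprintf("bond %d-%d length %.3f outside [%.1f, %.1f]",
                              bad, bad + 1L, b[bad],
                              bond_window[1], bond_window[2]))
  }
  if (n >= 3) {
    d <- as.matrix(stats::dist(coords))
    sep <- abs(row(d) - col(d))
    bad <- which(sep >= 2 & d < clash_dist & upper.tri(d), arr.ind = TRUE)
    if (nrow(bad))
      viol <- c(viol, sprintf("clash %d-%d at %.3f A < %.1f",
                              bad[, 1], bad[, 2], d[bad], clash_dist))
  }
  list(ok = length(viol) == 0L, violations = viol)
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's stream.
with_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed in [0, 2^31): mixes a master seed with a stream tag.
derive_seed <- function(seed, tag) {
  x <- (as.double(seed) %% 2147483647) + 0
  for (ch in utf8ToInt(as.character(tag)))
    x <- (x * 31 + ch) %% 2147483647
  as.integer(x)
}
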