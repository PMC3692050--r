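ideal_helix <- function(n) {
  # Ca helix: radius 2.3 A, twist 99.1 deg, rise 1.5 A -> ~3.8 A bonds
  t <- (seq_len(n) - 1) * 99.1 * pi / 180
  cbind(2.3 * cos(t), 2.3 * sin(t), (seq_len(n) - 1) * 1.5)
}

ideal_hairpin <- function(n) {
  # two extended zigzag strands (pseudo-angle ~120 deg) joined by a turn
  half <- n %/% 2
  zig <- function(m, y0, z0, dir) {
    x <- (seq_len(m) - 1) * 3.3 * dir
    y <- y0 + rep_len(c(0, 1.9), m)
    cbind(x, y, rep(z0, m))
  }
  s1 <- zig(half, 0, 0, +1)
  s2 <- zig(n - half, 0.95, 4.8, -1)
  s2[, 1] <- s2[, 1] + s1[half, 1]
  coords <- rbind(s1, s2)
  # nudge the junction bond toward the bond window
  v <- coords[half + 1, ] - coords[half, ]
  coords[(half + 1):n, ] <- sweep(coords[(half + 1):n, , drop = FALSE], 2,
                                  v * (1 - 3.8 / sqrt(sum(v^2))))
  coords
}

#' Generate a synthetic modeling fixture
#'
#' Builds an ideal toy C-alpha geometry (`helix`, `hairpin` or `random`
#' coil) for an `n`-residue query, plus a matching sequence and secondary
#' structure, and emits `n_templates` perturbed copies (independent
#' Gaussian coordinate noise of the given standard deviation, optional
#' coverage masks) as template objects and, optionally, PDB files.
#' Deterministic for a given seed.
#'
#' @param kind `"helix"`, `"hairpin"` or `"random"`.
#' @param n residue count (<= 900).
#' @param perturbation per-coordinate Gaussian noise sd, Angstrom.
#' @param n_templates number of perturbed template copies.
#' @param coverage optional list of residue-index vectors, one per
#'   template, to mask template coverage.
#' @param seed integer seed.
#' @param dir optional output directory; when given, sequence.fasta,
#'   ss.txt and template_<k>.pdb are written there.
#' @return List: `sequence` (`protein_sequence`), `ss`
#'   (`secondary_structure`), `ideal` (n x 3 matrix), `templates` (list of
#'   [fold_template()]), and `files` (paths, when `dir` is given).
#' @export
generate_fixture <- function(kind = c("helix", "hairpin", "random"), n,
                             perturbation = 0, n_templates = 2L,
                             coverage = NULL, seed = 1L, dir = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 1L, n <= fold_defaults$max_seq_length)
  ideal <- switch(kind,
                  helix = ideal_helix(n),
                  hairpin = ideal_hairpin(n),
                  random = random_coil(n, seed = derive_seed(seed, "coil")))
  seq_txt <- paste(rep_len(strsplit("ADEKLGQSTVNIRFY", "")[[1]], n),
                   collapse = "")
  seq <- parse_sequence(seq_txt, id = sprintf("%s_%d", kind, n))
  ss_txt <- switch(kind,
                   helix = strrep("H", n),
                   hairpin = {
                     half <- n %/% 2
                     e1 <- max(0, half - 2)
                     paste0(strrep("E", e1), strrep("C", min(n, 4)),
                            strrep("E", max(0, n - e1 - 4)))
                   },
                   random = strrep("C", n))
  ss <- parse_secondary_structure(ss_txt, seq)
  templates <- with_rng(derive_seed(seed, "templates"), {
    lapply(seq_len(n_templates), function(k) {
      co <- ideal + matrix(stats::rnorm(3 * n, sd = perturbation), n, 3)
      resids <- seq_len(n)
      if (!is.null(coverage) && k <= length(coverage)) {
        resids <- sort(intersect(coverage[[k]], seq_len(n)))
        co <- co[resids, , drop = FALSE]
      }
      fold_template(ca_trace(co, resids),
                    source = sprintf("template_%d.pdb", k))
    })
  })
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "sequence.fasta")
    writeLines(c(paste0(">", seq$id), seq$residues), fa)
    sf <- file.path(dir, "ss.txt")
    writeLines(ss$states, sf)
    tps <- vapply(seq_along(templates), function(k) {
      p <- file.path(dir, sprintf("template_%d.pdb", k))
      write_ca_pdb(templates[[k]]$trace, p, sequence = seq)
      p
    }, character(1))
    files <- list(sequence = fa, ss = sf, templates = tps)
  }
  list(sequence = seq, ss = ss, ideal = ideal, templates = templates,
       files = files)
}
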