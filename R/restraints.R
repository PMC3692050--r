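#' Construct a restraint set
#'
#' A restraint set holds flat-bottom distance restraints `[dmin, dmax]`
#' between residue pairs `(i, j)`, `i < j`, at most one per pair, each with
#' a weight and a provenance tag (`consensus-minmax`,
#' `consensus-distribution`, `single-template` or `user`).
#'
#' @param df data frame with columns `i, j, dmin, dmax, weight, provenance`.
#' @return A `restraint_set` (a classed data frame).
#' @export
restraint_set <- function(df = data.frame(i = integer(), j = integer(),
                                          dmin = numeric(), dmax = numeric(),
                                          weight = numeric(),
                                          provenance = character())) {
  df <- as.data.frame(df)
  need <- c("i", "j", "dmin", "dmax", "weight", "provenance")
  stopifnot(all(need %in% names(df)))
  df <- df[need]
  df$i <- as.integer(df$i); df$j <- as.integer(df$j)
  if (any(df$i >= df$j)) stop("restraints must have i < j")
  if (any(df$dmin <= 0) || any(df$dmax < df$dmin))
    stop("restraints must satisfy 0 < dmin <= dmax")
  if (any(df$weight <= 0)) stop("restraint weights must be positive")
  if (anyDuplicated(df[c("i", "j")]))
    stop("at most one restraint per (i, j) pair")
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("restraint_set", "data.frame")
  df
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint_set> %d restraint(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Per-pair distance statistics across a template set
#'
#' For every residue pair (i < j) covered by at least `min_obs` templates,
#' records the minimum, maximum, mean and standard deviation of the
#' C-alpha--C-alpha distances observed across the covering templates.
#'
#' @param templates list of [fold_template()] (at least one).
#' @param min_obs minimum number of covering templates for a pair to be
#'   reported.
#' @param sigma one of `"population"` (divide by n; default) or `"sample"`.
#' @return Data frame with columns `i, j, d_min, d_max, mean, sigma, n_obs`.
#' @export
collect_pair_stats <- function(templates, min_obs = 1L,
                               sigma = c("population", "sample")) {
  sigma <- match.arg(sigma)
  if (length(templates) == 0L) stop("at least one template is required")
  n <- max(vapply(templates, function(t) max(t$trace$resids), integer(1)))
  cnt <- matrix(0, n, n); s1 <- matrix(0, n, n); s2 <- matrix(0, n, n)
  mn <- matrix(Inf, n, n); mx <- matrix(-Inf, n, n)
  for (tp in templates) {
    idx <- tp$trace$resids
    D <- as.matrix(stats::dist(tp$trace$coords))
    cnt[idx, idx] <- cnt[idx, idx] + 1
    s1[idx, idx] <- s1[idx, idx] + D
    s2[idx, idx] <- s2[idx, idx] + D^2
    mn[idx, idx] <- pmin(mn[idx, idx], D)
    mx[idx, idx] <- pmax(mx[idx, idx], D)
  }
  keep <- which(upper.tri(cnt) & cnt >= min_obs, arr.ind = TRUE)
  if (nrow(keep) == 0L)
    return(data.frame(i = integer(), j = integer(), d_min = numeric(),
                      d_max = numeric(), mean = numeric(), sigma = numeric(),
                      n_obs = integer()))
  nn <- cnt[keep]
  mu <- s1[keep] / nn
  var_pop <- pmax(0, s2[keep] / nn - mu^2)
  sd_out <- if (sigma == "population") sqrt(var_pop)
            else ifelse(nn > 1, sqrt(var_pop * nn / (nn - 1)), 0)
  out <- data.frame(i = keep[, 1], j = keep[, 2], d_min = mn[keep],
                    d_max = mx[keep], mean = mu, sigma = sd_out,
                    n_obs = as.integer(nn))
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the consensus restraint regime from template similarity
#'
#' Computes GDT_TS between all template pairs. If the minimum pairwise
#' GDT_TS is at least the gate (0.3), restraint ranges come from the
#' observed min/max distances (`"minmax"`); if any pair is more dissimilar,
#' the distance distribution (mean +/- sigma) is used (`"distribution"`).
#'
#' @param templates list of at least two [fold_template()].
#' @param gate GDT_TS gate, default 0.3.
#' @return List: `regime` (`"minmax"` or `"distribution"`), `min_gdt`, and
#'   the pairwise `gdt` matrix.
#' @export
select_regime <- function(templates, gate = fold_defaults$gdt_gate) {
  if (length(templates) < 2L)
    stop("regime selection needs >= 2 templates; use the single-template path")
  m <- length(templates)
  G <- diag(1, m)
  for (p in 1:(m - 1)) for (q in (p + 1):m) {
    G[p, q] <- G[q, p] <- gdt_ts(templates[[p]]$trace, templates[[q]]$trace)
  }
  mg <- min(G[upper.tri(G)])
  list(regime = if (mg >= gate) "minmax" else "distribution",
       min_gdt = mg, gdt = G)
}

eligible_pairs <- function(stats, s_min, d_cap) {
  stats[(stats$j - stats$i) >= s_min & stats$mean <= d_cap, , drop = FALSE]
}

#' Generate consensus distance restraints from multiple templates
#'
#' In the `minmax` regime (mutually similar templates) each eligible pair
#' gets the range `[d_min, d_max]` of its observed distances, requiring
#' coverage by all templates. In the `distribution` regime (at least one
#' dissimilar pair) the range is `[mean - sigma, mean + sigma]` with the
#' lower bound floored at a minimum physical distance, requiring coverage by
#' at least two templates. Pair eligibility: sequence separation
#' `|i - j| >= s_min` and mean distance `<= d_cap`.
#'
#' @param templates list of at least two [fold_template()].
#' @param s_min minimum sequence separation (default 5).
#' @param d_cap maximum mean distance in Angstrom (default 25).
#' @param weight restraint weight.
#' @param sigma_convention `"population"` or `"sample"`.
#' @param sigma_floor lower bound applied to distribution-regime `dmin`.
#' @param gate GDT_TS regime gate.
#' @return A [restraint_set()] with attributes `regime` and `min_gdt`.
#' @export
generate_consensus_restraints <- function(templates,
                                          s_min = fold_defaults$s_min,
                                          d_cap = fold_defaults$d_cap,
                                          weight = fold_defaults$restraint_weight,
                                          sigma_convention = "population",
                                          sigma_floor = fold_defaults$sigma_floor,
                                          gate = fold_defaults$gdt_gate) {
  reg <- select_regime(templates, gate = gate)
  empty_rs <- function() data.frame(i = integer(), j = integer(),
                                    dmin = numeric(), dmax = numeric(),
                                    weight = numeric(),
                                    provenance = character())
  if (reg$regime == "minmax") {
    st <- collect_pair_stats(templates, min_obs = length(templates),
                             sigma = sigma_convention)
    st <- eligible_pairs(st, s_min, d_cap)
    rs <- if (nrow(st) == 0) empty_rs() else
      data.frame(i = st$i, j = st$j, dmin = st$d_min, dmax = st$d_max,
                 weight = weight, provenance = "consensus-minmax")
  } else {
    st <- collect_pair_stats(templates, min_obs = 2L,
                             sigma = sigma_convention)
    st <- eligible_pairs(st, s_min, d_cap)
    dmin <- pmax(sigma_floor, st$mean - st$sigma)
    dmax <- pmax(dmin, st$mean + st$sigma)
    rs <- if (nrow(st) == 0) empty_rs() else
      data.frame(i = st$i, j = st$j, dmin = dmin, dmax = dmax,
                 weight = weight, provenance = "consensus-distribution")
  }
  out <- restraint_set(rs)
  attr(out, "regime") <- reg$regime
  attr(out, "min_gdt") <- reg$min_gdt
  out
}

#' Generate restraints from a single template
#'
#' Enforces the template geometry on the covered fragment only: every
#' eligible covered pair is restrained to `[d - tau, d + tau]` around its
#' template distance. Residues outside the template coverage acquire no
#' restraints and are modeled de novo.
#'
#' @param template a single [fold_template()].
#' @param tau half-width of the restraint range (Angstrom).
#' @inheritParams generate_consensus_restraints
#' @return A [restraint_set()] with attribute `regime = "single-template"`.
#' @export
generate_single_template_restraints <- function(template,
                                                tau = fold_defaults$tau,
                                                s_min = fold_defaults$s_min,
                                                d_cap = fold_defaults$d_cap,
                                                weight = fold_defaults$restraint_weight) {
  stopifnot(inherits(template, "fold_template"))
  st <- collect_pair_stats(list(template), min_obs = 1L)
  st <- eligible_pairs(st, s_min, d_cap)
  rs <- if (nrow(st) == 0)
    data.frame(i = integer(), j = integer(), dmin = numeric(),
               dmax = numeric(), weight = numeric(),
               provenance = character())
  else data.frame(i = st$i, j = st$j,
                  dmin = pmax(st$mean - tau, 0.1),
                  dmax = st$mean + tau,
                  weight = weight, provenance = "single-template")
  out <- restraint_set(rs)
  attr(out, "regime") <- "single-template"
  out
}

#' Parse restraint-edit directives
#'
#' One directive per line. `A i j dmin dmax` adds a restraint between
#' residues i and j with the given range in Angstrom (indices are
#' normalized to i < j). `D r1,r2,a-b,...` deletes every automatically
#' generated restraint touching any listed residue; both plain hyphen and
#' en-dash range separators are accepted. Blank lines and `#` comments are
#' ignored.
#'
#' @param text directive text (string or character vector of lines).
#' @return List of directives, each `list(kind = "add", i, j, dmin, dmax)`
#'   or `list(kind = "delete", resids = <integer vector>)`.
#' @export
parse_edit_directives <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  out <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw) || startsWith(raw, "#")) next
    toks <- strsplit(raw, "\\s+")[[1]]
    kind <- toupper(toks[1])
    if (kind == "A") {
      if (length(toks) != 5L)
        stop(sprintf("line %d: 'A' directive needs exactly 'A i j dmin dmax'", ln))
      i <- suppressWarnings(as.integer(toks[2]))
      j <- suppressWarnings(as.integer(toks[3]))
      dmin <- suppressWarnings(as.numeric(toks[4]))
      dmax <- suppressWarnings(as.numeric(toks[5]))
      if (anyNA(c(i, j, dmin, dmax)))
        stop(sprintf("line %d: malformed 'A' directive", ln))
      if (i == j) stop(sprintf("line %d: residue pair must be distinct", ln))
      if (dmin > dmax)
        stop(sprintf("line %d: dmin %.3f exceeds dmax %.3f", ln, dmin, dmax))
      out[[length(out) + 1L]] <- list(kind = "add", i = min(i, j),
                                      j = max(i, j), dmin = dmin, dmax = dmax)
    } else if (kind == "D") {
      spec <- paste(toks[-1], collapse = "")
      if (!nzchar(spec))
        stop(sprintf("line %d: 'D' directive needs a residue list", ln))
      parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
      resids <- integer()
      for (p in parts) {
        p <- gsub("–", "-", p)  # en-dash
        if (grepl("-", p, fixed = TRUE)) {
          ab <- suppressWarnings(as.integer(strsplit(p, "-", fixed = TRUE)[[1]]))
          if (length(ab) != 2L || anyNA(ab) || ab[1] > ab[2])
            stop(sprintf("line %d: malformed residue range '%s'", ln, p))
          resids <- c(resids, ab[1]:ab[2])
        } else {
          r <- suppressWarnings(as.integer(p))
          if (is.na(r)) stop(sprintf("line %d: malformed residue '%s'", ln, p))
          resids <- c(resids, r)
        }
      }
      out[[length(out) + 1L]] <- list(kind = "delete",
                                      resids = sort(unique(resids)))
    } else {
      stop(sprintf("line %d: unknown directive '%s' (expected 'A' or 'D')",
                   ln, toks[1]))
    }
  }
  out
}

#' Apply restraint-edit directives to a restraint set
#'
#' Deletions are applied before additions; within a kind, file order.
#' Deleting removes every restraint whose i or j falls in the delete set (a
#' no-op delete is allowed). Adding inserts a user restraint, replacing any
#' existing restraint on the pair.
#'
#' @param rs a [restraint_set()].
#' @param directives output of [parse_edit_directives()].
#' @param weight weight assigned to user-added restraints.
#' @return The edited [restraint_set()] (regime attribute preserved).
#' @export
apply_edits <- function(rs, directives,
                        weight = fold_defaults$restraint_weight) {
  regime <- attr(rs, "regime")
  df <- as.data.frame(rs)
  del <- unlist(lapply(directives,
                       function(d) if (d$kind == "delete") d$resids))
  if (length(del))
    df <- df[!(df$i %in% del | df$j %in% del), , drop = FALSE]
  for (d in directives) {
    if (d$kind != "add") next
    df <- df[!(df$i == d$i & df$j == d$j), , drop = FALSE]
    df <- rbind(df, data.frame(i = d$i, j = d$j, dmin = d$dmin,
                               dmax = d$dmax, weight = weight,
                               provenance = "user"))
  }
  out <- restraint_set(df)
  attr(out, "regime") <- regime
  out
}

restraint_distances <- function(coords, rs) {
  coords <- as.matrix(coords)
  if (nrow(rs) == 0L) return(numeric())
  if (max(rs$j) > nrow(coords))
    stop("restrained residue index outside the conformation")
  sqrt(rowSums((coords[rs$i, , drop = FALSE] -
                  coords[rs$j, , drop = FALSE])^2))
}

#' Flat-bottom restraint energy
#'
#' Each restraint contributes zero while its C-alpha distance lies inside
#' `[dmin, dmax]` and `weight * dev^2` outside, where `dev` is the distance
#' beyond the nearest bound.
#'
#' @param coords n x 3 conformation coordinates.
#' @param rs a [restraint_set()].
#' @return Total restraint energy (model units).
#' @export
restraint_energy <- function(coords, rs) {
  d <- restraint_distances(coords, rs)
  if (!length(d)) return(0)
  dev <- pmax(0, d - rs$dmax) + pmax(0, rs$dmin - d)
  sum(rs$weight * dev^2)
}

#' Fraction of satisfied restraints
#'
#' @inheritParams restraint_energy
#' @return Fraction of restraints whose distance lies inside its range; an
#'   empty set is vacuously 1 (with a warning).
#' @export
satisfaction_fraction <- function(coords, rs) {
  if (nrow(rs) == 0L) {
    warning("empty restraint set: satisfaction is vacuously 1")
    return(1)
  }
  d <- restraint_distances(coords, rs)
  mean(d >= rs$dmin & d <= rs$dmax)
}

#' Write a restraint set as TSV
#'
#' @param rs a [restraint_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_restraints_tsv <- function(rs, path) {
  utils::write.table(as.data.frame(rs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
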