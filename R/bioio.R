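#' Parse a query amino-acid sequence
#'
#' Accepts plain text or FASTA. A FASTA header, when present, supplies the
#' sequence id; whitespace is stripped and residues upper-cased. Only the 20
#' standard one-letter codes are accepted and the length is capped at 900
#' residues.
#'
#' @param text raw sequence text (single string or character vector of lines).
#' @param id fallback id when no FASTA header is present.
#' @return A `protein_sequence`: list with `id` and `residues`.
#' @export
parse_sequence <- function(text, id = "query") {
  if (length(text) == 0L || !nzchar(paste(text, collapse = "")))
    stop("empty sequence input")
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && startsWith(trimws(lines[1]), ">")) {
    id <- sub("^>\\s*", "", trimws(lines[1]))
    id <- strsplit(id, "\\s+")[[1]][1]
    lines <- lines[-1]
  }
  res <- toupper(gsub("\\s", "", paste(lines, collapse = "")))
  if (!nzchar(res)) stop("empty sequence input")
  chars <- strsplit(res, "")[[1]]
  bad <- setdiff(unique(chars), aa1)
  if (length(bad))
    stop(sprintf("invalid sequence: non-amino-acid character(s) %s",
                 paste(sQuote(bad), collapse = ", ")))
  if (nchar(res) > fold_defaults$max_seq_length)
    stop(sprintf("sequence length %d exceeds the %d AA maximum",
                 nchar(res), fold_defaults$max_seq_length))
  structure(list(id = id, residues = res), class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence '%s'> %d residues\n", x$id,
              nchar(x$residues)))
  invisible(x)
}

#' Parse a per-residue secondary-structure string
#'
#' Three-letter code: H (helix), E (extended/beta), C (coil). When `text` is
#' `NULL` the all-coil default is returned with a warning attribute, because
#' an unbiased coil state is safer than over-predicted regular structure.
#'
#' @param text raw H/E/C text, or `NULL` for the all-coil default.
#' @param seq a `protein_sequence`; the length check is made against it.
#' @return A `secondary_structure`: list with `states` (string) and
#'   `warnings`.
#' @export
parse_secondary_structure <- function(text, seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  n <- nchar(seq$residues)
  warnings <- character()
  if (is.null(text)) {
    states <- strrep("C", n)
    warnings <- "no secondary structure supplied; defaulting to all-coil"
  } else {
    states <- toupper(gsub("\\s", "", paste(text, collapse = "")))
    chars <- unique(strsplit(states, "")[[1]])
    bad <- setdiff(chars, c("H", "E", "C"))
    if (length(bad))
      stop(sprintf("secondary structure contains illegal symbol(s) %s; alphabet is H/E/C",
                   paste(sQuote(bad), collapse = ", ")))
    if (nchar(states) != n)
      stop(sprintf("secondary structure length %d does not match sequence length %d",
                   nchar(states), n))
  }
  structure(list(states = states, warnings = warnings),
            class = "secondary_structure")
}

#' Read a template structure from a PDB file
#'
#' Extracts one C-alpha per residue record (first model of multi-model
#' files, first altloc); non-CA atoms are ignored so full-backbone or
#' all-atom files are accepted. PDB residue numbers are taken as the
#' alignment to the query: numbering must not exceed the query length and
#' insertion codes are rejected.
#'
#' @param path PDB file path.
#' @param seq the query `protein_sequence` the template is aligned to.
#' @return A [fold_template()].
#' @export
read_template_pdb <- function(path, seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  if (!file.exists(path)) stop(sprintf("template file not found: %s", path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  ca <- atoms[atoms$elety == "CA" & atoms$type == "ATOM", , drop = FALSE]
  if (nrow(ca) == 0L)
    stop(sprintf("empty template: no C-alpha atoms in %s", path))
  if (any(nzchar(ca$insert) & !is.na(ca$insert)))
    stop(sprintf("template %s contains insertion codes; renumber against the query",
                 path))
  # first altloc per residue number
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  ord <- order(ca$resno)
  ca <- ca[ord, , drop = FALSE]
  if (min(ca$resno) < 1L || max(ca$resno) > nchar(seq$residues))
    stop(sprintf(
      "numbering mismatch: template %s spans residues %d-%d but the query has %d; residue numbering must correspond to the query sequence order",
      path, min(ca$resno), max(ca$resno), nchar(seq$residues)))
  trace <- ca_trace(cbind(ca$x, ca$y, ca$z), as.integer(ca$resno))
  fold_template(trace, source = basename(path))
}

#' Write a C-alpha trace or trajectory as PDB
#'
#' Writes standard fixed-width ATOM records (atom name CA, one chain),
#' residue numbers equal to the trace resids. A list of conformations is
#' written as a multi-snapshot file wrapped in MODEL/ENDMDL records.
#'
#' @param x a [ca_trace()], an n x 3 coordinate matrix (resids `1:n`), or a
#'   list of either for a multi-model trajectory.
#' @param path output file path.
#' @param sequence optional `protein_sequence` used for residue names;
#'   otherwise GLY is written.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(x, path, sequence = NULL) {
  if (!is.list(x) || inherits(x, "ca_trace")) x <- list(x)
  x <- lapply(x, function(m) {
    if (inherits(m, "ca_trace")) m else ca_trace(as.matrix(m))
  })
  for (m in x)
    if (!all(is.finite(m$coords)))
      stop("refusing to write non-finite coordinates")
  resname <- function(resids) {
    if (is.null(sequence)) return(rep("GLY", length(resids)))
    aa3[strsplit(sequence$residues, "")[[1]][resids]]
  }
  multi <- length(x) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(x)) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    tr <- x[[k]]
    rn <- resname(tr$resids)
    lines <- sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_along(tr$resids), rn, tr$resids,
      tr$coords[, 1], tr$coords[, 2], tr$coords[, 3])
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model C-alpha trajectory PDB
#'
#' @param path PDB file with one or more MODEL blocks of CA atoms.
#' @return A list of [ca_trace()] objects, one per model.
#' @export
read_trajectory_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  keep <- atoms$elety == "CA" & atoms$type == "ATOM"
  resids <- as.integer(atoms$resno[keep])
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  idx <- which(keep)
  lapply(seq_len(nrow(xyz)), function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
    ord <- order(resids)
    ca_trace(co[ord, , drop = FALSE], resids[ord])
  })
}

#' Validate a modeling job's inputs
#'
#' Pure check of sequence, secondary structure, templates and mode against
#' the protocol rules. Errors make the input unacceptable; warnings do not.
#'
#' @param seq `protein_sequence`.
#' @param ss `secondary_structure` or `NULL`.
#' @param templates list of [fold_template()] (possibly empty).
#' @param mode `"denovo"` or `"consensus"`.
#' @return A `validation_report`: list of `errors` and `warnings` character
#'   vectors; the input is accepted iff `errors` is empty.
#' @export
validate_input <- function(seq, ss = NULL, templates = list(),
                           mode = c("denovo", "consensus")) {
  mode <- match.arg(mode)
  errors <- character(); warnings <- character()
  n <- nchar(seq$residues)
  if (n > fold_defaults$max_seq_length)
    errors <- c(errors, sprintf("sequence length %d exceeds the %d AA cap",
                                n, fold_defaults$max_seq_length))
  if (!is.null(ss)) {
    if (nchar(ss$states) != n)
      errors <- c(errors, "secondary structure length does not match sequence")
    warnings <- c(warnings, ss$warnings)
  }
  if (mode == "consensus" && length(templates) == 0L)
    errors <- c(errors, "consensus mode requires at least one template")
  if (mode == "denovo" && n > fold_defaults$denovo_length_rec)
    warnings <- c(warnings, sprintf(
      "sequence length %d exceeds the ~%d-residue recommendation for de novo modeling",
      n, fold_defaults$denovo_length_rec))
  for (tp in templates) {
    if (max(tp$trace$resids) > n)
      errors <- c(errors, sprintf(
        "template '%s' numbering exceeds the query length", tp$source))
  }
  structure(list(errors = errors, warnings = warnings),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  status <- if (length(x$errors)) "REJECTED" else "accepted"
  cat(sprintf("<validation_report> %s: %d error(s), %d warning(s)\n",
              status, length(x$errors), length(x$warnings)))
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
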