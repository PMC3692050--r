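# package-local progress log collector
.fold_env <- new.env(parent = emptyenv())
.fold_env$log <- list()

#' Record pipeline progress
#'
#' Appends a timestamped stage/fraction record to the package-local
#' progress log (and emits a message when `verbose`).
#'
#' @param stage stage label.
#' @param fraction progress fraction in [0, 1].
#' @param verbose emit a message.
#' @return The record, invisibly.
#' @export
progress_log <- function(stage, fraction, verbose = FALSE) {
  stopifnot(fraction >= 0, fraction <= 1)
  rec <- list(time = Sys.time(), stage = stage, fraction = fraction)
  .fold_env$log[[length(.fold_env$log) + 1L]] <- rec
  if (verbose)
    message(sprintf("[%s] %s: %.0f%%", format(rec$time, "%H:%M:%S"),
                    stage, 100 * fraction))
  invisible(rec)
}

#' Retrieve (and optionally clear) the progress log
#'
#' @param reset clear the log after reading.
#' @return Data frame of records (`stage`, `fraction`, `time`).
#' @export
progress_records <- function(reset = FALSE) {
  recs <- .fold_env$log
  if (reset) .fold_env$log <- list()
  if (!length(recs))
    return(data.frame(stage = character(), fraction = numeric()))
  data.frame(stage = vapply(recs, `[[`, character(1), "stage"),
             fraction = vapply(recs, `[[`, numeric(1), "fraction"))
}

#' Build a validated run configuration
#'
#' Collects every tunable of the pipeline with the documented defaults:
#' mode-dependent temperature ranges (3.5-1.0 de novo, 2.0-1.0 consensus),
#' 20 replicas, restraint parameters and clustering sizes. The cycle
#' budget defaults to a total of about `2000 * n` proposals per replica
#' for an `n`-residue chain (i.e. 2000 cycles).
#'
#' @param mode `"denovo"` or `"consensus"`.
#' @param t_max,t_min temperature range; mode default when `NULL`.
#' @param n_replicas replica count.
#' @param n_cycles Monte Carlo cycles (one sweep per replica per cycle).
#' @param record_every recording stride (cycles).
#' @param k_clusters,n_models clustering sizes.
#' @param seed master seed.
#' @param s_min,d_cap,tau,weight,sigma_convention,sigma_floor restraint
#'   generation parameters (see the restraint generators).
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("denovo", "consensus"), t_max = NULL,
                       t_min = NULL,
                       n_replicas = fold_defaults$n_replicas,
                       n_cycles = 2000L, record_every = 20L,
                       k_clusters = fold_defaults$k_clusters,
                       n_models = fold_defaults$n_models, seed = 1L,
                       s_min = fold_defaults$s_min,
                       d_cap = fold_defaults$d_cap,
                       tau = fold_defaults$tau,
                       weight = fold_defaults$restraint_weight,
                       sigma_convention = "population",
                       sigma_floor = fold_defaults$sigma_floor) {
  mode <- match.arg(mode)
  range_default <- if (mode == "denovo") fold_defaults$t_denovo
                   else fold_defaults$t_consensus
  if (is.null(t_max)) t_max <- range_default[1]
  if (is.null(t_min)) t_min <- range_default[2]
  stopifnot(n_replicas >= 1, n_cycles >= 0, record_every >= 1,
            k_clusters >= 1, n_models >= 1)
  structure(list(mode = mode, t_max = t_max, t_min = t_min,
                 n_replicas = as.integer(n_replicas),
                 n_cycles = as.integer(n_cycles),
                 record_every = as.integer(record_every),
                 k_clusters = as.integer(k_clusters),
                 n_models = as.integer(n_models), seed = as.integer(seed),
                 s_min = s_min, d_cap = d_cap, tau = tau, weight = weight,
                 sigma_convention = sigma_convention,
                 sigma_floor = sigma_floor),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full modeling pipeline
#'
#' Orchestrates validation, restraint generation (consensus regimes or
#' single-template; none in de novo mode), user restraint edits, starting-
#' structure construction, replica-exchange Monte Carlo sampling,
#' trajectory clustering, representative selection and cross-analysis, and
#' writes all outputs under `out_dir`: `trajectory.pdb`, `analysis.tsv`,
#' `swaps.tsv`, `restraints.tsv`, `models/model_<r>.pdb`, `clusters.json`,
#' `matrices.tsv` and `report.json`. Deterministic for a given
#' configuration and seed.
#'
#' @param seq `protein_sequence` (see [parse_sequence()]).
#' @param config a [run_config()].
#' @param ss optional `secondary_structure`; all-coil default otherwise.
#' @param templates list of [fold_template()] (required for consensus).
#' @param restraint_edits optional directive text for
#'   [parse_edit_directives()].
#' @param out_dir output directory (created).
#' @param verbose log progress messages.
#' @return A `run_report` list: `validation`, `regime`,
#'   `restraint_counts`, `trajectory` summary, `models` table, `paths`.
#' @export
run_pipeline <- function(seq, config, ss = NULL, templates = list(),
                         restraint_edits = NULL, out_dir = tempfile("fold_"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fail <- function(stage, msg) {
    writeLines(sprintf("FAILED at stage %s: %s", stage, msg),
               file.path(out_dir, "FAILED"))
    stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
  }
  n <- nchar(seq$residues)

  progress_log("validate", 0, verbose)
  if (is.null(ss)) ss <- suppressWarnings(
    parse_secondary_structure(NULL, seq))
  report <- validate_input(seq, ss, templates, config$mode)
  if (length(report$errors))
    fail("validate", paste(report$errors, collapse = "; "))
  progress_log("validate", 1, verbose)

  progress_log("restraints", 0, verbose)
  regime <- "none"
  rs <- restraint_set()
  if (config$mode == "consensus") {
    if (length(templates) == 1L) {
      rs <- generate_single_template_restraints(
        templates[[1]], tau = config$tau, s_min = config$s_min,
        d_cap = config$d_cap, weight = config$weight)
      regime <- "single-template"
    } else {
      rs <- generate_consensus_restraints(
        templates, s_min = config$s_min, d_cap = config$d_cap,
        weight = config$weight, sigma_convention = config$sigma_convention,
        sigma_floor = config$sigma_floor)
      regime <- attr(rs, "regime")
    }
  }
  if (!is.null(restraint_edits)) {
    directives <- parse_edit_directives(restraint_edits)
    rs <- apply_edits(rs, directives, weight = config$weight)
  }
  write_restraints_tsv(rs, file.path(out_dir, "restraints.tsv"))
  progress_log("restraints", 1, verbose)

  progress_log("start_structure", 0, verbose)
  start <- if (config$mode == "consensus")
    build_start_from_templates(templates, n,
                               seed = derive_seed(config$seed, "start"))
  else random_coil(n, seed = derive_seed(config$seed, "start"))
  progress_log("start_structure", 1, verbose)

  progress_log("remc", 0, verbose)
  ladder <- make_ladder(config$t_max, config$t_min, config$n_replicas)
  traj <- run_simulation(start, ss, ladder, rs,
                         n_cycles = config$n_cycles,
                         record_every = config$record_every,
                         seed = derive_seed(config$seed, "remc"))
  write_ca_pdb(traj$snapshots, file.path(out_dir, "trajectory.pdb"),
               sequence = seq)
  write_tsv(cbind(snapshot = seq_len(nrow(traj$series)),
                  format_num(traj$series)),
            file.path(out_dir, "analysis.tsv"))
  write_tsv(traj$swaps, file.path(out_dir, "swaps.tsv"))
  progress_log("remc", 1, verbose)

  progress_log("modelsel", 0, verbose)
  ms <- cluster_models(traj, k = config$k_clusters,
                       n_models = config$n_models,
                       seed = derive_seed(config$seed, "cluster"))
  models_dir <- file.path(out_dir, "models")
  dir.create(models_dir, showWarnings = FALSE)
  model_paths <- vapply(seq_along(ms$models), function(r) {
    p <- file.path(models_dir, sprintf("model_%d.pdb", r))
    write_ca_pdb(ms$models[[r]], p, sequence = seq)
    p
  }, character(1))
  jsonlite::write_json(
    list(k = ms$clusters$k, sizes = ms$clusters$sizes,
         assignments = ms$clusters$assignments,
         ranking = ms$ranking),
    file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = 10)
  mat_df <- data.frame(
    model_a = rep(seq_along(ms$models), times = length(ms$models)),
    model_b = rep(seq_along(ms$models), each = length(ms$models)),
    rmsd = sprintf("%.6f", as.numeric(ms$matrices$rmsd)),
    gdt_ts = sprintf("%.6f", as.numeric(ms$matrices$gdt_ts)))
  write_tsv(mat_df, file.path(out_dir, "matrices.tsv"))
  progress_log("modelsel", 1, verbose)

  satisfaction <- if (nrow(rs))
    vapply(ms$models, satisfaction_fraction, numeric(1), rs = rs) else NULL
  run_report <- list(
    mode = config$mode, seed = config$seed,
    validation = report[c("errors", "warnings")],
    regime = regime,
    restraint_counts = as.list(table(rs$provenance)),
    trajectory = list(n_snapshots = length(traj$snapshots),
                      n_replicas = length(ladder),
                      final_energy = traj$series$energy[
                        length(traj$snapshots)]),
    models = cbind(ms$table,
                   satisfaction = if (is.null(satisfaction)) NA
                   else satisfaction),
    paths = list(out_dir = out_dir, models = model_paths))
  jsonlite::write_json(run_report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, force = TRUE)
  progress_log("done", 1, verbose)
  invisible(structure(c(run_report,
                        list(trajectory_object = traj, model_set = ms,
                             restraints = rs)),
                      class = "run_report"))
}

# fixed-precision numeric formatting so identical runs give identical bytes
format_num <- function(df) {
  for (nm in names(df))
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.6f", df[[nm]])
  df
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> mode=%s regime=%s seed=%d\n", x$mode, x$regime,
              x$seed))
  cat(sprintf("  %d snapshot(s), %d replica(s), final energy %.2f\n",
              x$trajectory$n_snapshots, x$trajectory$n_replicas,
              x$trajectory$final_energy))
  print.data.frame(x$models)
  invisible(x)
}
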