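#' Build a replica temperature ladder
#'
#' Geometric interpolation between `t_max` and `t_min` with exact
#' endpoints. The recommended ranges are 3.5-1.0 for de novo modeling and
#' 2.0-1.0 for consensus modeling; a flat range (for example 2.0-2.0) runs
#' all replicas at one temperature.
#'
#' @param t_max,t_min dimensionless temperatures, `t_max >= t_min > 0`.
#' @param n_replicas replica count (default 20).
#' @return Numeric vector of non-increasing temperatures.
#' @export
make_ladder <- function(t_max, t_min, n_replicas = fold_defaults$n_replicas) {
  if (t_min <= 0) stop("t_min must be positive")
  if (t_max < t_min) stop("t_max must be >= t_min")
  if (n_replicas < 1) stop("n_replicas must be >= 1")
  if (n_replicas == 1) return(t_max)
  exp(seq(log(t_max), log(t_min), length.out = n_replicas))
}

#' Metropolis acceptance rule
#'
#' Accepts an energy change `delta` at temperature `temperature` with
#' probability `min(1, exp(-delta / temperature))`, drawing from the
#' current RNG stream.
#'
#' @param delta proposed energy change.
#' @param temperature dimensionless temperature, > 0.
#' @return Logical.
#' @export
metropolis_accept <- function(delta, temperature) {
  delta <= 0 || stats::runif(1) < exp(-delta / temperature)
}

#' One Metropolis sweep over a generic state
#'
#' Proposes `n_moves` modifications with `propose_fn` and accepts each by
#' the Metropolis rule at the given temperature. States and proposals are
#' opaque: any representation works as long as `energy_fn(state)` returns a
#' scalar and `propose_fn(state)` returns a new state (symmetric
#' proposals). The chain-model fast path lives in [run_simulation()]; this
#' generic kernel backs tests and small enumerable systems.
#'
#' @param state initial state.
#' @param temperature dimensionless temperature.
#' @param energy_fn function(state) -> scalar energy.
#' @param propose_fn function(state) -> proposed state.
#' @param n_moves number of proposals in the sweep.
#' @return List: final `state`, its `energy`, `accepted` count and
#'   `proposed` count.
#' @export
metropolis_sweep <- function(state, temperature, energy_fn, propose_fn,
                             n_moves) {
  e <- energy_fn(state)
  acc <- 0L
  for (m in seq_len(n_moves)) {
    cand <- propose_fn(state)
    de <- energy_fn(cand) - e
    if (metropolis_accept(de, temperature)) {
      state <- cand
      e <- e + de
      acc <- acc + 1L
    }
  }
  list(state = state, energy = e, accepted = acc, proposed = n_moves)
}

#' One replica-exchange sweep
#'
#' Attempts swaps between adjacent replica pairs in an alternating
#' even/odd phase. A swap between replicas at temperatures `Ta`, `Tb` with
#' energies `Ea`, `Eb` is accepted with probability
#' `min(1, exp((1/Ta - 1/Tb) * (Ea - Eb)))`.
#'
#' @param replicas list of replica states, each `list(state, energy)`.
#' @param ladder temperature ladder of matching length.
#' @param phase 0 (pairs 1-2, 3-4, ...) or 1 (pairs 2-3, 4-5, ...).
#' @return List: `replicas` (possibly swapped) and a `swaps` data frame
#'   (`lower`, `accepted`).
#' @export
exchange_sweep <- function(replicas, ladder, phase = 0L) {
  stopifnot(length(replicas) == length(ladder))
  lower <- integer(); accepted <- logical()
  a <- 1L + phase
  while (a + 1L <= length(replicas)) {
    Ta <- ladder[a]; Tb <- ladder[a + 1L]
    ex <- (1 / Ta - 1 / Tb) * (replicas[[a]]$energy - replicas[[a + 1L]]$energy)
    ok <- ex >= 0 || stats::runif(1) < exp(ex)
    lower <- c(lower, a); accepted <- c(accepted, ok)
    if (ok) {
      tmp <- replicas[[a]]
      replicas[[a]] <- replicas[[a + 1L]]
      replicas[[a + 1L]] <- tmp
    }
    a <- a + 2L
  }
  list(replicas = replicas, swaps = data.frame(lower = lower,
                                               accepted = accepted))
}

ss_theta_targets <- function(ss, n, params = energy_defaults) {
  states <- if (inherits(ss, "secondary_structure")) ss$states else ss
  states <- strsplit(states, "")[[1]]
  stopifnot(length(states) == n)
  th <- rep(-1, n)
  if (n >= 3) {
    centers <- 2:(n - 1)
    th[centers] <- ifelse(states[centers] == "H", params$theta_H,
                          ifelse(states[centers] == "E", params$theta_E, -1))
  }
  th
}

#' Total model energy of a conformation
#'
#' Internal (surrogate) energy plus flat-bottom restraint energy; the
#' quantity recorded along trajectories.
#'
#' @param coords n x 3 conformation.
#' @param ss secondary structure (object or H/E/C string).
#' @param restraints a [restraint_set()] (possibly empty).
#' @param params energy parameters.
#' @return Scalar total energy (model units).
#' @export
total_energy <- function(coords, ss, restraints = restraint_set(),
                         params = energy_defaults) {
  internal_energy(coords, ss, params)$total +
    restraint_energy(coords, restraints)
}

#' Run a replica-exchange Monte Carlo simulation
#'
#' Runs `n_cycles` cycles, each one Metropolis sweep (chain-length
#' proposals) per replica followed by one alternating-phase exchange sweep.
#' Every `record_every` cycles the conformation of the currently
#' lowest-total-energy replica is recorded together with its energy, radius
#' of gyration and end-to-end distance. Fully deterministic for a given
#' seed; one RNG stream per replica is derived from the master seed.
#'
#' @param start n x 3 starting conformation (shared by all replicas).
#' @param ss secondary structure (object or H/E/C string).
#' @param ladder temperature ladder from [make_ladder()].
#' @param restraints a [restraint_set()].
#' @param n_cycles number of cycles; 0 records only the start.
#' @param record_every recording stride in cycles.
#' @param seed integer master seed.
#' @param params energy parameters; `move_params` proposal parameters.
#' @param move_params local-move parameters.
#' @return A `fold_trajectory`: list with `snapshots` (list of n x 3
#'   matrices), `series` (data frame: cycle, replica, energy, rg,
#'   end_to_end), `acceptance` per replica, `swaps` log,
#'   `replica_energies` (record points x replicas), `ladder`, `seed`, and
#'   `final_replicas`.
#' @export
run_simulation <- function(start, ss, ladder, restraints = restraint_set(),
                           n_cycles = 500L, record_every = 10L, seed = 1L,
                           params = energy_defaults,
                           move_params = move_defaults) {
  start <- as.matrix(start)
  n <- nrow(start)
  theta0 <- ss_theta_targets(ss, n, params)
  eng_params <- list(
    k_bond = params$k_bond, k_angle = params$k_angle, k_rep = params$k_rep,
    bond_length = fold_defaults$bond_length,
    clash_dist = fold_defaults$clash_dist,
    p_single = move_params$p_single, p_crank = move_params$p_crank,
    p_pivot = move_params$p_pivot, max_disp = move_params$max_disp,
    max_angle = move_params$max_angle)
  res <- .remc_engine(start, theta0,
                      as.integer(restraints$i - 1L),
                      as.integer(restraints$j - 1L),
                      as.numeric(restraints$dmin),
                      as.numeric(restraints$dmax),
                      as.numeric(restraints$weight),
                      as.numeric(ladder), as.integer(n_cycles),
                      as.integer(record_every), as.double(seed), eng_params)
  snaps <- res$snapshots
  series <- data.frame(
    cycle = res$cycle,
    replica = res$replica,
    energy = res$energies,
    rg = vapply(snaps, radius_of_gyration, numeric(1)),
    end_to_end = vapply(snaps, end_to_end, numeric(1)))
  swaps <- data.frame(cycle = res$swap_cycle, lower = res$swap_lower,
                      accepted = res$swap_accepted == 1L)
  structure(list(
    snapshots = snaps, series = series,
    acceptance = data.frame(replica = seq_along(ladder),
                            temperature = as.numeric(ladder),
                            rate = ifelse(res$proposed > 0,
                                          res$accepted / res$proposed, NA)),
    replica_energies = t(res$replica_energies),
    swaps = swaps, ladder = as.numeric(ladder), seed = seed,
    n_cycles = n_cycles, record_every = record_every,
    final_replicas = res$final_replicas,
    final_energies = as.numeric(res$final_energies)),
    class = "fold_trajectory")
}

#' @export
print.fold_trajectory <- function(x, ...) {
  cat(sprintf(
    "<fold_trajectory> %d snapshot(s), %d replica(s), %d cycle(s)\n",
    length(x$snapshots), length(x$ladder), x$n_cycles))
  cat(sprintf("  energy range [%.2f, %.2f]\n",
              min(x$series$energy), max(x$series$energy)))
  invisible(x)
}

#' Recompute trajectory observables
#'
#' Recomputes energy, radius of gyration and end-to-end distance for each
#' snapshot of a trajectory (or list of conformations) from scratch.
#'
#' @param snapshots a `fold_trajectory` or list of n x 3 matrices.
#' @param ss secondary structure used for the energy recomputation.
#' @param restraints restraint set used for the energy recomputation.
#' @return Data frame with `snapshot`, `energy`, `rg`, `end_to_end`.
#' @export
trajectory_observables <- function(snapshots, ss,
                                   restraints = restraint_set()) {
  if (inherits(snapshots, "fold_trajectory")) snapshots <- snapshots$snapshots
  data.frame(
    snapshot = seq_along(snapshots),
    energy = vapply(snapshots, total_energy, numeric(1), ss = ss,
                    restraints = restraints),
    rg = vapply(snapshots, radius_of_gyration, numeric(1)),
    end_to_end = vapply(snapshots, end_to_end, numeric(1)))
}
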