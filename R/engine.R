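#' Build a simulation configuration
#'
#' Collects every tunable of the agent-based model into one validated list.
#' Defaults reproduce the reference setup: a 100^3 lattice at 5 um spacing,
#' 100 cells seeded centrally with ages uniform on \[0, 24\] h, 0.72 h time
#' steps over a 72 h horizon (100 steps), a 24-step cell cycle, and a
#' 10-step apoptosis duration.
#'
#' @param drugs A two-row data frame with columns `name`, `half_life_h`
#'   and `initial_uM`.
#' @param lambda Mean apoptosis frequency per hour.
#' @param c1,c2 Apoptosis mixing weights (natural and dose-driven terms).
#' @param theta Length-3 dose-mortality coefficients
#'   `(theta0, theta1, theta2)`.
#' @param p_pro Proliferation probability per decision.
#' @param n_per_axis,spacing_um Lattice geometry.
#' @param n_cells,age_max_h Initial seeding.
#' @param time_step_h Hours represented by one simulation step.
#' @param horizon_steps Number of steps to simulate.
#' @param cycle_schedule Named steps per cycle phase (sums to the cycle
#'   length, default 24).
#' @param apoptosis_steps Steps from the apoptosis decision to absorption.
#' @param motility_D Motility coefficient (um^2/h) of the move kernel.
#' @param division_radius Manhattan radius of the division site search
#'   (1 = the six face neighbours).
#' @param init_cycle_from_age Start initial cells in the cycle at a
#'   position derived from their random age (default), desynchronising
#'   division waves; `FALSE` starts them quiescent.
#'
#' @return An object of class `abm_config`.
#' @examples
#' cfg <- simulation_config(drugs = tibble::tibble(
#'   name = c("gefitinib", "rosiglitazone"),
#'   half_life_h = c(48, 3.5), initial_uM = c(20, 80)
#' ))
#' @export
simulation_config <- function(drugs,
                              lambda = 1, c1 = 0.025, c2 = 0.06,
                              theta = c(0.1686, 0.0067, 0.0019),
                              p_pro = 0.8,
                              n_per_axis = 100, spacing_um = 5,
                              n_cells = 100, age_max_h = 24,
                              time_step_h = 0.72, horizon_steps = 100,
                              cycle_schedule = c(G0G1 = 11L, S = 8L, G2 = 4L, M = 1L),
                              apoptosis_steps = 10,
                              motility_D = 10, division_radius = 1,
                              init_cycle_from_age = TRUE) {
  stopifnot(
    nrow(drugs) == 2, all(c("name", "half_life_h", "initial_uM") %in% names(drugs)),
    all(drugs$half_life_h > 0), all(drugs$initial_uM >= 0),
    length(theta) == 3, lambda >= 0, c1 >= 0, c2 >= 0,
    p_pro >= 0, p_pro <= 1, time_step_h > 0, horizon_steps >= 1,
    length(cycle_schedule) == 4, apoptosis_steps >= 1
  )
  structure(
    list(
      drugs = tibble::as_tibble(drugs),
      lambda = lambda, c1 = c1, c2 = c2, theta = theta, p_pro = p_pro,
      n_per_axis = as.integer(n_per_axis), spacing_um = spacing_um,
      n_cells = as.integer(n_cells), age_max_h = age_max_h,
      time_step_h = time_step_h, horizon_steps = as.integer(horizon_steps),
      cycle_schedule = as.integer(cycle_schedule),
      apoptosis_steps = as.integer(apoptosis_steps),
      motility_D = motility_D, division_radius = as.integer(division_radius),
      init_cycle_from_age = isTRUE(init_cycle_from_age)
    ),
    class = "abm_config"
  )
}

#' @export
print.abm_config <- function(x, ...) {
  cat("<abm_config>", x$n_per_axis, "^3 lattice,", x$n_cells, "cells,",
      x$horizon_steps, "steps x", x$time_step_h, "h\n")
  cat("  drugs:", paste0(x$drugs$name, " (", x$drugs$initial_uM, " uM, T=",
                         x$drugs$half_life_h, " h)", collapse = ", "), "\n")
  cat("  lambda =", x$lambda, " c1 =", x$c1, " c2 =", x$c2,
      " theta =", paste(signif(x$theta, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Read a simulation configuration from YAML
#'
#' Reads a configuration file with keys `lattice.n_per_axis`,
#' `lattice.spacing_um`, `init.n_cells`, `init.age_max_h`, a `drugs` list
#' (each with `name`, `half_life_h`, `initial_uM`), `phenotype.*`
#' (`lambda`, `c1`, `c2`, `theta`, `p_pro`), `motility.*` (`D`,
#' `division_radius`) and `time.*` (`step_h`, `horizon_steps`). Missing
#' keys fall back to the [simulation_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return An `abm_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  drugs <- dplyr::bind_rows(lapply(y$drugs, tibble::as_tibble))
  args <- list(drugs = drugs)
  pick <- function(value, name) if (!is.null(value)) args[[name]] <<- value
  pick(y$lattice$n_per_axis, "n_per_axis")
  pick(y$lattice$spacing_um, "spacing_um")
  pick(y$init$n_cells, "n_cells")
  pick(y$init$age_max_h, "age_max_h")
  pick(y$phenotype$lambda, "lambda")
  pick(y$phenotype$c1, "c1")
  pick(y$phenotype$c2, "c2")
  if (!is.null(y$phenotype$theta)) args$theta <- as.numeric(y$phenotype$theta)
  pick(y$phenotype$p_pro, "p_pro")
  pick(y$motility$D, "motility_D")
  pick(y$motility$division_radius, "division_radius")
  pick(y$time$step_h, "time_step_h")
  pick(y$time$horizon_steps, "horizon_steps")
  do.call(simulation_config, args)
}

phase_labels <- c("G0G1", "S", "G2", "M", "quiescent", "apoptotic")

#' Run the agent-based simulation
#'
#' Executes the configured number of steps. Each step decays both drug
#' concentrations in closed form from time zero, then iterates live cells
#' in a fresh random order through four passes: apoptosis countdowns and
#' decisions; proliferation decisions and cycle advance; division attempts
#' for cells that completed M phase; migration of all non-M-phase cells.
#' Enclosed cells become reversibly quiescent. Identical seeds give
#' identical trajectories.
#'
#' @param config An [simulation_config()] object.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param snapshot_steps Integer steps at which to record per-cell
#'   snapshots (default none).
#' @param verbose Print a progress line every 10 steps?
#'
#' @return A tibble of class `abm_trajectory` with one row per step
#'   (including step 0) and columns `step`, `time_h`, `n_cells` (all cells
#'   on the lattice), `n_alive` (non-apoptotic), `n_quiescent`,
#'   `n_apoptotic`, `drug1_uM`, `drug2_uM`, `births`, `removals` and
#'   `msrate` (mortality relative to the initial live count). Attributes
#'   `config`, `final_cells` and `snapshots` carry the full end state.
#' @examples
#' cfg <- simulation_config(
#'   drugs = tibble::tibble(
#'     name = c("a", "b"), half_life_h = c(48, 18), initial_uM = c(20, 80)
#'   ),
#'   n_per_axis = 30, horizon_steps = 20
#' )
#' traj <- run_simulation(cfg, seed = 1)
#' @export
run_simulation <- function(config, seed = NULL, snapshot_steps = integer(0),
                           verbose = FALSE) {
  stopifnot(inherits(config, "abm_config"))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  cells <- init_lattice(
    n_per_axis = config$n_per_axis, n_cells = config$n_cells,
    age_max = config$age_max_h, spacing_um = config$spacing_um
  )
  res <- cpp_run_simulation(
    init_xyz = cbind(cells$x, cells$y, cells$z),
    init_age_h = cells$age_h,
    n_per_axis = config$n_per_axis, spacing_um = config$spacing_um,
    horizon_steps = config$horizon_steps, dt_h = config$time_step_h,
    lambda = config$lambda, c1 = config$c1, c2 = config$c2,
    theta = config$theta, p_pro = config$p_pro,
    schedule = config$cycle_schedule, apoptosis_steps = config$apoptosis_steps,
    d1_0 = config$drugs$initial_uM[1], half_life1 = config$drugs$half_life_h[1],
    d2_0 = config$drugs$initial_uM[2], half_life2 = config$drugs$half_life_h[2],
    motility_D = config$motility_D, kernel_dt_h = config$time_step_h,
    division_radius = config$division_radius,
    snapshot_steps = as.integer(snapshot_steps),
    init_cycle_from_age = config$init_cycle_from_age
  )
  tr <- res$trajectory
  colnames(tr) <- c(
    "step", "time_h", "n_cells", "n_alive", "n_quiescent",
    "n_apoptotic", "drug1_uM", "drug2_uM", "births", "removals"
  )
  out <- tibble::as_tibble(tr)
  n0 <- out$n_alive[1]
  out$msrate <- (n0 - out$n_alive) / n0
  if (verbose) {
    for (k in seq(1, nrow(out), by = 10)) {
      message(sprintf(
        "step %3d  N = %4d  drug1 = %.3f uM  drug2 = %.3f uM",
        out$step[k], out$n_alive[k], out$drug1_uM[k], out$drug2_uM[k]
      ))
    }
  }
  snaps <- tibble::as_tibble(res$snapshots)
  if (nrow(snaps) > 0) snaps$phase <- phase_labels[snaps$phase + 1]
  attr(out, "config") <- config
  attr(out, "final_cells") <- tibble::as_tibble(res$final_cells)
  attr(out, "snapshots") <- snaps
  class(out) <- c("abm_trajectory", class(out))
  out
}

#' Simulated mortality rate
#'
#' `(n_initial - n_final) / n_initial`: the fraction of the initial
#' population lost by the readout time. Negative under net growth.
#'
#' @param n_initial,n_final Initial and remaining live cell counts.
#' @return Mortality fraction.
#' @examples
#' msrate(100, 50)
#' @export
msrate <- function(n_initial, n_final) {
  if (any(n_initial <= 0)) {
    rlang::abort("`n_initial` must be positive.", class = "synergyabm_invalid_argument")
  }
  (n_initial - n_final) / n_initial
}

#' Endpoint mortality averaged over replicate simulations
#'
#' Runs the simulation to the assay endpoint (default 48 h, the culture
#' duration of the underlying viability assay) for each of `replicates`
#' seeds and returns the mean simulated mortality at the endpoint. Fixed
#' seed sets make the stochastic readout quasi-deterministic (common
#' random numbers), which the global calibration relies on.
#'
#' @param config An `abm_config`; its horizon is truncated to the endpoint.
#' @param endpoint_h Readout time in hours.
#' @param replicates Number of replicate seeds.
#' @param seed Base seed; replicate `r` uses `seed + r - 1`.
#' @return Mean endpoint mortality fraction, with the per-replicate values
#'   in attribute `replicates`.
#' @export
endpoint_msrate <- function(config, endpoint_h = 48, replicates = 10, seed = 1) {
  stopifnot(inherits(config, "abm_config"))
  endpoint_step <- round(endpoint_h / config$time_step_h)
  if (endpoint_step > config$horizon_steps) {
    rlang::abort("`endpoint_h` exceeds the configured horizon.",
      class = "synergyabm_invalid_argument"
    )
  }
  cfg <- config
  cfg$horizon_steps <- as.integer(max(endpoint_step, 1))
  vals <- vapply(seq_len(replicates), function(r) {
    traj <- run_simulation(cfg, seed = seed + r - 1)
    traj$msrate[nrow(traj)]
  }, numeric(1))
  out <- mean(vals)
  attr(out, "replicates") <- vals
  out
}

#' Export per-cell snapshots to CSV
#'
#' Writes the snapshots recorded by [run_simulation()] with columns
#' `time_step`, `cell_id`, `x`, `y`, `z`, `phase`, `phenotype` and
#' `age_steps`. The phenotype column collapses cycle phases to
#' `"proliferative"`.
#'
#' @param trajectory An `abm_trajectory` run with `snapshot_steps` set.
#' @param path Output CSV path.
#' @return The exported tibble, invisibly.
#' @export
write_snapshots <- function(trajectory, path) {
  snaps <- attr(trajectory, "snapshots")
  if (is.null(snaps) || nrow(snaps) == 0) {
    rlang::abort("no snapshots recorded; rerun with `snapshot_steps`.",
      class = "synergyabm_invalid_argument"
    )
  }
  cfg <- attr(trajectory, "config")
  out <- tibble::tibble(
    time_step = snaps$step,
    cell_id = snaps$cell_id,
    x = snaps$x, y = snaps$y, z = snaps$z,
    phase = snaps$phase,
    phenotype = dplyr::case_when(
      snaps$phase %in% c("G0G1", "S", "G2", "M") ~ "proliferative",
      .default = snaps$phase
    ),
    age_steps = round(snaps$age_h / cfg$time_step_h)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
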