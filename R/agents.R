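#' Natural mortality (apoptosis hazard) of a cell
#'
#' Exponential-hazard probability that a cell has entered natural apoptosis
#' by time `t`: `1 - exp(-lambda * t)` for `t > 0`, and 0 for `t <= 0`.
#' `t` is the cell's age in hours.
#'
#' @param lambda Mean apoptosis frequency per hour (non-negative).
#' @param t Time in hours; vectorised.
#' @return Probability in `[0, 1)`.
#' @examples
#' natural_mortality(1, log(2)) # 0.5
#' natural_mortality(1, 0)      # 0
#' @export
natural_mortality <- function(lambda, t) {
  if (any(lambda < 0)) {
    rlang::abort("`lambda` must be non-negative.", class = "synergyabm_invalid_argument")
  }
  ifelse(t > 0, 1 - exp(-lambda * t), 0)
}

#' Dose-driven mortality from the linear dose-mortality model
#'
#' The drug-computed mortality is linear in the two doses,
#' `theta0 + theta1 * dose1 + theta2 * dose2`. Inside the simulator this is
#' used as a probability and therefore clamped to `[0, 1]`; the raw linear
#' value is what the calibration stage fits, so set `clamp = FALSE` there.
#'
#' @param theta Numeric length-3 vector `(theta0, theta1, theta2)`;
#'   `theta0` dimensionless, `theta1`/`theta2` per uM.
#' @param dose1,dose2 Doses in uM (non-negative; vectorised).
#' @param clamp Clamp the result to `[0, 1]`? Default `TRUE`.
#' @return Mortality fraction(s).
#' @examples
#' computed_mortality(c(0.1686, 0.0067, 0.0019), 10, 10)
#' @export
computed_mortality <- function(theta, dose1, dose2, clamp = TRUE) {
  stopifnot(length(theta) == 3)
  if (any(dose1 < 0) || any(dose2 < 0)) {
    rlang::abort("doses must be non-negative.", class = "synergyabm_invalid_argument")
  }
  m <- theta[1] + theta[2] * dose1 + theta[3] * dose2
  if (clamp) m <- pmin(pmax(m, 0), 1)
  m
}

#' Per-step apoptosis decision
#'
#' A cell enters apoptosis when the mixed mortality score exceeds a uniform
#' draw: `c1 * mn + c2 * mc > u`. `mn` is the natural mortality
#' ([natural_mortality()]) and `mc` the dose-driven mortality
#' ([computed_mortality()], clamped). On a `TRUE` outcome the cell enters
#' the apoptotic phase and is absorbed `apoptosis_duration_steps` (default
#' 10) steps later.
#'
#' @param mn Natural mortality probability.
#' @param mc Dose-driven mortality fraction.
#' @param c1,c2 Non-negative mixing weights.
#' @param u Uniform draw(s) in `[0, 1]`.
#' @return Logical: does the cell start apoptosis?
#' @export
apoptosis_decision <- function(mn, mc, c1, c2, u) {
  if (any(u < 0 | u > 1)) {
    rlang::abort("`u` must lie in [0, 1].", class = "synergyabm_invalid_argument")
  }
  c1 * mn + c2 * mc > u
}

#' Per-step proliferation decision
#'
#' Decides whether a quiescent cell enters the cell cycle: ON iff
#' `u < p_pro`. A draw exactly equal to `p_pro` is OFF (the boundary is
#' measure-zero; this convention keeps the ON set half-open).
#'
#' @param u Uniform draw(s) in `[0, 1]`.
#' @param p_pro Proliferation probability per decision (default 0.8).
#' @return Logical: cell cycle ON?
#' @export
proliferation_decision <- function(u, p_pro = 0.8) {
  if (any(u < 0 | u > 1)) {
    rlang::abort("`u` must lie in [0, 1].", class = "synergyabm_invalid_argument")
  }
  if (any(p_pro < 0 | p_pro > 1)) {
    rlang::abort("`p_pro` must lie in [0, 1].", class = "synergyabm_invalid_argument")
  }
  u < p_pro
}

#' Phase schedule of the cell cycle
#'
#' Maps a position within the division cycle (in time steps, 1-based after
#' entering the cycle) to a named phase. The default 24-step cycle is split
#' G0/G1 = 11, S = 8, G2 = 4, M = 1 steps, the proportions of a canonical
#' 24 h mammalian cycle; the split is configurable.
#'
#' @param cycle_position Steps into the cycle, in `[0, sum(schedule)]`.
#'   Position 0 (just entered, not yet advanced) maps to `"G0G1"`.
#' @param schedule Named integer vector of step counts per phase.
#' @return Character vector of phases among `"G0G1"`, `"S"`, `"G2"`, `"M"`.
#' @examples
#' cycle_phase(0:24)
#' @export
cycle_phase <- function(cycle_position,
                        schedule = c(G0G1 = 11L, S = 8L, G2 = 4L, M = 1L)) {
  stopifnot(all(schedule >= 1), !is.null(names(schedule)))
  total <- sum(schedule)
  if (any(cycle_position < 0 | cycle_position > total)) {
    rlang::abort("`cycle_position` outside the cycle.", class = "synergyabm_invalid_argument")
  }
  edges <- cumsum(schedule)
  idx <- findInterval(pmax(cycle_position, 1), c(0, edges), left.open = TRUE)
  names(schedule)[idx]
}

#' Advance a cell one step through the cycle
#'
#' Increments the cycle position of a cycling cell and re-derives its phase;
#' when the cycle completes (end of M phase) the cell is flagged
#' division-ready. Quiescent cells instead re-test the proliferation
#' decision with the uniform draw `u` and enter the cycle on ON.
#'
#' @param cell A one-row tibble or named list with at least `phase`
#'   (`"quiescent"` or a cycle phase) and `cycle_position`.
#' @param p_pro Proliferation probability used when the cell is quiescent.
#' @param u Uniform draw for the quiescent re-test (default: drawn).
#' @param schedule Phase schedule as in [cycle_phase()].
#' @return The updated cell with fields `phase`, `cycle_position` and
#'   logical `division_ready`.
#' @export
advance_phase <- function(cell, p_pro = 0.8, u = stats::runif(1),
                          schedule = c(G0G1 = 11L, S = 8L, G2 = 4L, M = 1L)) {
  if (identical(cell$phase, "apoptotic")) {
    rlang::abort("apoptotic cells do not advance through the cycle.",
      class = "synergyabm_invalid_argument"
    )
  }
  total <- sum(schedule)
  cell$division_ready <- FALSE
  if (identical(cell$phase, "quiescent")) {
    if (proliferation_decision(u, p_pro)) {
      cell$cycle_position <- 0L
      cell$phase <- cycle_phase(0L, schedule)
    }
    return(cell)
  }
  cell$cycle_position <- cell$cycle_position + 1L
  cell$phase <- cycle_phase(cell$cycle_position, schedule)
  if (cell$cycle_position >= total) cell$division_ready <- TRUE
  cell
}
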