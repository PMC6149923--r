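#' Crowding preference weight for a candidate site
#'
#' A candidate lattice site is weighted by how crowded its own
#' von Neumann (6 face-neighbour) neighbourhood is: 5-6 occupied
#' neighbours -> 1/8, 3-4 -> 1/4, 1-2 -> 1, none -> 1/16. Moderately
#' accompanied sites are preferred over both isolated and saturated ones.
#'
#' @param n_neighbors Occupied count among the candidate's 6 face
#'   neighbours, in `0:6`; vectorised.
#' @return Preference weight in `{1/16, 1/8, 1/4, 1}`.
#' @export
neighbor_preference <- function(n_neighbors) {
  if (any(n_neighbors < 0 | n_neighbors > 6 | n_neighbors != floor(n_neighbors))) {
    rlang::abort("`n_neighbors` must be an integer in 0..6.",
      class = "synergyabm_invalid_argument"
    )
  }
  v <- c(1 / 16, 1, 1, 1 / 4, 1 / 4, 1 / 8, 1 / 8)
  v[n_neighbors + 1]
}

#' Distance kernel for cell movement
#'
#' The probability weight that a cell moves a distance `r` in one step,
#' `(1 / (4 pi D dt)) * exp(-r^2 / (4 pi D dt))`. For the default
#' face-neighbour candidate set every candidate shares the same distance
#' (the lattice spacing), so
#' the kernel cancels under rank normalisation; it matters only for
#' multi-radius searches.
#'
#' @param r Distance in um (non-negative; vectorised).
#' @param D Motility coefficient in um^2/h (default 10).
#' @param dt Time step in hours (default 0.72).
#' @return Kernel value(s).
#' @export
move_kernel <- function(r, D = 10, dt = 0.72) {
  if (any(r < 0)) {
    rlang::abort("`r` must be non-negative.", class = "synergyabm_invalid_argument")
  }
  if (any(D <= 0) || any(dt <= 0)) {
    rlang::abort("`D` and `dt` must be positive.", class = "synergyabm_invalid_argument")
  }
  s <- 4 * pi * D * dt
  (1 / s) * exp(-r^2 / s)
}

#' Rank free candidate sites for migration or division
#'
#' Scores each free candidate as `R_l = (1/4) * P(r_l) * V_l` — distance
#' kernel ([move_kernel()]) times crowding preference
#' ([neighbor_preference()]) — and normalises so the ranks sum to one.
#'
#' @param candidates A data frame with columns `r_um` (distance to the
#'   cell's site) and `n_neighbors` (occupied face neighbours of the
#'   candidate, the moving cell's own site excluded).
#' @param D,dt Kernel parameters as in [move_kernel()].
#' @return The input as a tibble with columns `V`, `kernel`, `rank_raw`
#'   and `rank_norm`; `sum(rank_norm) == 1`.
#' @examples
#' rank_candidates(tibble::tibble(r_um = c(5, 5), n_neighbors = c(1, 3)))
#' @export
rank_candidates <- function(candidates, D = 10, dt = 0.72) {
  if (nrow(candidates) == 0) {
    rlang::abort("no free candidate site.", class = "synergyabm_no_free_site")
  }
  out <- tibble::as_tibble(candidates)
  out$V <- neighbor_preference(out$n_neighbors)
  out$kernel <- move_kernel(out$r_um, D, dt)
  out$rank_raw <- 0.25 * out$kernel * out$V
  out$rank_norm <- out$rank_raw / sum(out$rank_raw)
  out
}

#' Build a roulette selection wheel from normalised ranks
#'
#' Partitions `[0, 1]` into contiguous half-open intervals, one per
#' candidate, with widths equal to the normalised ranks.
#'
#' @param rank_norm Normalised ranks summing to 1.
#' @return A tibble with columns `lower` and `upper`.
#' @export
selection_wheel <- function(rank_norm) {
  if (abs(sum(rank_norm) - 1) > 1e-8 || any(rank_norm < 0)) {
    rlang::abort("`rank_norm` must be non-negative and sum to 1.",
      class = "synergyabm_invalid_argument"
    )
  }
  cum <- cumsum(rank_norm)
  tibble::tibble(lower = c(0, cum[-length(cum)]), upper = cum)
}

#' Select a candidate from a roulette wheel
#'
#' Returns the index `l` whose interval contains the uniform draw `d`.
#' Intervals are half-open `[lower, upper)`; the final interval is closed
#' at 1.
#'
#' @param wheel A wheel from [selection_wheel()].
#' @param d Uniform draw in `[0, 1]`.
#' @return Integer candidate index.
#' @export
select_site <- function(wheel, d) {
  if (d < 0 || d > 1) {
    rlang::abort("`d` must lie in [0, 1].", class = "synergyabm_invalid_argument")
  }
  idx <- which(d >= wheel$lower & d < wheel$upper)
  if (length(idx) == 0) idx <- nrow(wheel) # d == 1 falls in the last interval
  idx[1]
}
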