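#' Exponential half-life decay of a drug concentration
#'
#' Drug exposure in the extracellular matrix is modelled as a single
#' well-mixed concentration per drug that decays with the drug's
#' pharmacokinetic half-life: `c(t) = c0 * (1/2)^(t / T)`.
#'
#' @param c0 Initial concentration (uM). Non-negative; vectorised.
#' @param half_life Half-life `T` (hours). Must be positive.
#' @param elapsed Time since dosing (hours). Must be non-negative.
#'
#' @return Concentration (uM) after `elapsed` hours, same length as the
#'   longest input.
#'
#' @examples
#' decay_drug(20, 48, 48) # one half-life of gefitinib -> 10
#' decay_drug(80, 18, 36) # two half-lives of imatinib -> 20
#' @export
decay_drug <- function(c0, half_life, elapsed) {
  if (any(c0 < 0)) {
    rlang::abort("`c0` must be non-negative.", class = "synergyabm_invalid_argument")
  }
  if (any(half_life <= 0)) {
    rlang::abort("`half_life` must be positive.", class = "synergyabm_invalid_argument")
  }
  if (any(elapsed < 0)) {
    rlang::abort("`elapsed` must be non-negative.", class = "synergyabm_invalid_argument")
  }
  c0 * 0.5^(elapsed / half_life)
}

#' Seed cells in the centre of a cubic lattice
#'
#' Places `n_cells` cells on distinct sites of an `n_per_axis`^3 lattice,
#' filling outward from the centre site by increasing Chebyshev distance
#' (ties within a shell broken uniformly at random), and assigns each cell
#' an age drawn uniformly on `[0, age_max]` hours. Coordinates are 0-based
#' integer triples; physical position is `coordinate * spacing_um`.
#'
#' @param n_per_axis Sites per axis (default 100).
#' @param n_cells Number of cells to seed (default 100).
#' @param age_max Maximum initial age in hours (default 24).
#' @param seed Optional integer seed for reproducible placement and ages.
#' @param spacing_um Lattice spacing in micrometres (default 5, roughly one
#'   cancer-cell radius).
#'
#' @return A tibble with one row per cell and columns `cell_id`, `x`, `y`,
#'   `z` (0-based site coordinates) and `age_h`, carrying attributes
#'   `n_per_axis` and `spacing_um`.
#'
#' @examples
#' cells <- init_lattice(n_per_axis = 100, n_cells = 100, seed = 1)
#' nrow(cells)
#' @export
init_lattice <- function(n_per_axis = 100, n_cells = 100, age_max = 24,
                         seed = NULL, spacing_um = 5) {
  if (n_per_axis < 1 || n_cells < 1) {
    rlang::abort("`n_per_axis` and `n_cells` must be at least 1.",
      class = "synergyabm_invalid_argument"
    )
  }
  if (n_cells > n_per_axis^3) {
    rlang::abort("`n_cells` exceeds the number of lattice sites.",
      class = "synergyabm_invalid_argument"
    )
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  centre <- (n_per_axis - 1) %/% 2

  # grow shells of Chebyshev distance until enough sites are collected
  sites <- matrix(integer(0), ncol = 3)
  r <- 0L
  while (nrow(sites) < n_cells) {
    shell <- chebyshev_shell(centre, r, n_per_axis)
    if (nrow(shell) == 0 && r > 3 * n_per_axis) {
      rlang::abort("not enough central sites for `n_cells`.",
        class = "synergyabm_invalid_argument"
      )
    }
    if (nrow(shell) > 1) shell <- shell[sample.int(nrow(shell)), , drop = FALSE]
    sites <- rbind(sites, shell)
    r <- r + 1L
  }
  sites <- sites[seq_len(n_cells), , drop = FALSE]

  out <- tibble::tibble(
    cell_id = seq_len(n_cells),
    x = sites[, 1], y = sites[, 2], z = sites[, 3],
    age_h = stats::runif(n_cells, 0, age_max)
  )
  attr(out, "n_per_axis") <- as.integer(n_per_axis)
  attr(out, "spacing_um") <- spacing_um
  out
}

# all sites at exactly Chebyshev distance r from the centre, in bounds,
# in lexicographic order
chebyshev_shell <- function(centre, r, n_per_axis) {
  if (r == 0L) {
    return(matrix(c(centre, centre, centre), ncol = 3))
  }
  rng <- (centre - r):(centre + r)
  g <- as.matrix(expand.grid(x = rng, y = rng, z = rng))
  d <- pmax(abs(g[, 1] - centre), abs(g[, 2] - centre), abs(g[, 3] - centre))
  g <- g[d == r, , drop = FALSE]
  ok <- g[, 1] >= 0 & g[, 2] >= 0 & g[, 3] >= 0 &
    g[, 1] < n_per_axis & g[, 2] < n_per_axis & g[, 3] < n_per_axis
  g <- g[ok, , drop = FALSE]
  g[order(g[, 1], g[, 2], g[, 3]), , drop = FALSE]
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
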