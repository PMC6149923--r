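#' Find the dose producing a target effect
#'
#' Inverts a monotone dose-effect function to the single dose whose effect
#' equals `x` percent. Deterministic responses are bisected directly;
#' stochastic responses (replicate-averaged simulated mortality) are first
#' evaluated on a dose grid, smoothed by isotonic regression to guard
#' against Monte-Carlo non-monotonicity, and the smoothed curve inverted
#' by interpolation.
#'
#' @param effect_fn Function of one dose (uM) returning an effect
#'   fraction; monotone non-decreasing over `dose_bounds` (checked by
#'   sampling).
#' @param x Target effect in percent (default 50).
#' @param dose_bounds Length-2 search interval in uM.
#' @param tol Tolerance on the achieved effect fraction (default 0.01).
#' @param stochastic Use the smoothed-grid path? Default `FALSE`.
#' @param n_grid Grid size for the stochastic path (default 12).
#' @return The iso-effective dose `D_x` (uM), with the achieved effect in
#'   attribute `effect`.
#' @examples
#' find_iso_dose(function(d) d / 100, x = 50) # 50
#' @export
find_iso_dose <- function(effect_fn, x = 50, dose_bounds = c(0, 100),
                          tol = 0.01, stochastic = FALSE, n_grid = 12) {
  stopifnot(length(dose_bounds) == 2, dose_bounds[2] > dose_bounds[1])
  target <- x / 100
  if (stochastic) {
    grid <- seq(dose_bounds[1], dose_bounds[2], length.out = n_grid)
    eff <- vapply(grid, effect_fn, numeric(1))
    fit <- stats::isoreg(grid, eff)$yf
    if (target < fit[1] || target > fit[n_grid]) {
      rlang::abort(
        sprintf(
          "target effect %.2f not bracketed; smoothed range [%.3f, %.3f].",
          target, fit[1], fit[n_grid]
        ),
        class = "synergyabm_not_bracketed"
      )
    }
    i <- max(which(fit <= target))
    if (fit[i] == target || i == n_grid) {
      d <- grid[i]
    } else {
      d <- grid[i] + (target - fit[i]) / (fit[i + 1] - fit[i]) * (grid[i + 1] - grid[i])
    }
    out <- d
    attr(out, "effect") <- target
    return(out)
  }
  lo <- dose_bounds[1]
  hi <- dose_bounds[2]
  f_lo <- effect_fn(lo)
  f_hi <- effect_fn(hi)
  probe <- vapply(seq(lo, hi, length.out = 8), effect_fn, numeric(1))
  if (any(diff(probe) < -tol)) {
    rlang::warn("effect function is not monotone over the bounds.")
  }
  if (target < min(f_lo, f_hi) || target > max(f_lo, f_hi)) {
    rlang::abort(
      sprintf(
        "target effect %.2f not bracketed; achieved range [%.3f, %.3f].",
        target, min(f_lo, f_hi), max(f_lo, f_hi)
      ),
      class = "synergyabm_not_bracketed"
    )
  }
  for (k in seq_len(200)) {
    mid <- (lo + hi) / 2
    f_mid <- effect_fn(mid)
    if (abs(f_mid - target) <= tol || (hi - lo) < 1e-9 * diff(dose_bounds)) {
      out <- mid
      attr(out, "effect") <- f_mid
      return(out)
    }
    if ((f_mid < target) == (f_lo < target)) lo <- mid else hi <- mid
  }
  out <- mid
  attr(out, "effect") <- f_mid
  out
}

#' Loewe-additivity combination index
#'
#' `CI = d1 / D_x1 + d2 / D_x2`: the combination doses expressed as
#' fractions of the single-agent iso-effective doses. Values near 1 mark
#' Loewe additivity, below 1 synergy, above 1 antagonism.
#'
#' @param d1,d2 Combination doses (uM) producing the target effect.
#' @param dx1,dx2 Single-agent iso-effective doses (uM, positive).
#' @return The combination index.
#' @examples
#' combination_index(10, 20, 40, 40) # 0.75
#' @export
combination_index <- function(d1, d2, dx1, dx2) {
  if (any(dx1 <= 0) || any(dx2 <= 0)) {
    rlang::abort("iso-effective doses must be positive.",
      class = "synergyabm_invalid_argument"
    )
  }
  if (any(d1 < 0) || any(d2 < 0)) {
    rlang::abort("doses must be non-negative.", class = "synergyabm_invalid_argument")
  }
  d1 / dx1 + d2 / dx2
}

#' Classify a combination index
#'
#' Thresholds: antagonism for `CI >= 1.1`; additive for `0.9 <= CI < 1.1`
#' (the printed bands leave CI = 0.9 unassigned; it is placed with the
#' additive band); synergism for `0.3 <= CI < 0.9`; strong synergism below
#' 0.3. The bands partition `[0, Inf)`.
#'
#' @param ci Combination index value(s), non-negative.
#' @return Character vector among `"antagonism"`, `"additive"`,
#'   `"synergism"`, `"strong synergism"`.
#' @examples
#' classify_ci(c(1.219, 0.26, 1.0694))
#' @export
classify_ci <- function(ci) {
  if (any(ci < 0)) {
    rlang::abort("`ci` must be non-negative.", class = "synergyabm_invalid_argument")
  }
  dplyr::case_when(
    ci >= 1.1 ~ "antagonism",
    ci >= 0.9 ~ "additive",
    ci >= 0.3 ~ "synergism",
    .default = "strong synergism"
  )
}

parse_ratio <- function(ratio) {
  if (is.character(ratio)) {
    parts <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
  } else {
    parts <- as.numeric(ratio)
  }
  if (length(parts) != 2 || any(is.na(parts)) || any(parts < 0) || sum(parts) == 0) {
    rlang::abort("ratios must be two non-negative numbers like '4:1'.",
      class = "synergyabm_invalid_argument"
    )
  }
  parts / sum(parts)
}

#' Combination-index report over fixed dose ratios
#'
#' For each requested drug1:drug2 ratio, searches along that ray for the
#' total dose whose combined effect reaches `x` percent, computes the
#' combination index against the single-agent iso-effective doses, and
#' classifies it. Rays on which the target effect is unreachable within
#' the dose bounds are flagged rather than dropped.
#'
#' @param effect_fn Function `(dose1, dose2)` returning the effect
#'   fraction (e.g. from [simulated_effect_fn()]).
#' @param ratios Character vector like `c("4:1", "3:2", "2:3", "1:4")`.
#' @param drug1,drug2 Drug names for the report.
#' @param x Target effect percent (default 50).
#' @param dose_bounds Search interval for each single dose and for the
#'   total combination dose (uM).
#' @param tol,stochastic,n_grid Passed to [find_iso_dose()].
#' @return A tibble of class `abm_synergy_report` with columns `drug1`,
#'   `drug2`, `ratio`, `d1_uM`, `d2_uM`, `Dx1_uM`, `Dx2_uM`, `CI`,
#'   `category` (`NA` doses and category `"unreachable"` where the ray
#'   cannot reach the target).
#' @examples
#' additive <- function(d1, d2) (d1 / 60 + d2 / 60) / 2
#' synergy_report(additive, c("4:1", "1:4"), dose_bounds = c(0, 100))
#' @export
synergy_report <- function(effect_fn, ratios = c("4:1", "3:2", "2:3", "1:4"),
                           drug1 = "drug1", drug2 = "drug2", x = 50,
                           dose_bounds = c(0, 100), tol = 0.01,
                           stochastic = FALSE, n_grid = 12) {
  iso <- function(fn) {
    find_iso_dose(fn,
      x = x, dose_bounds = dose_bounds, tol = tol,
      stochastic = stochastic, n_grid = n_grid
    )
  }
  dx1 <- iso(function(d) effect_fn(d, 0))
  dx2 <- iso(function(d) effect_fn(0, d))
  rows <- purrr::map_dfr(ratios, function(rt) {
    fr <- parse_ratio(rt)
    total <- tryCatch(
      iso(function(tt) effect_fn(tt * fr[1], tt * fr[2])),
      synergyabm_not_bracketed = function(e) NA_real_
    )
    if (is.na(total)) {
      return(tibble::tibble(
        ratio = as.character(rt), d1_uM = NA_real_, d2_uM = NA_real_,
        CI = NA_real_, category = "unreachable"
      ))
    }
    d1 <- as.numeric(total) * fr[1]
    d2 <- as.numeric(total) * fr[2]
    ci <- combination_index(d1, d2, as.numeric(dx1), as.numeric(dx2))
    tibble::tibble(
      ratio = as.character(rt), d1_uM = d1, d2_uM = d2,
      CI = ci, category = classify_ci(ci)
    )
  })
  out <- dplyr::mutate(rows,
    drug1 = drug1, drug2 = drug2,
    Dx1_uM = as.numeric(dx1), Dx2_uM = as.numeric(dx2),
    .before = 1
  )
  out <- dplyr::relocate(out, "drug1", "drug2", "ratio", "d1_uM", "d2_uM",
    "Dx1_uM", "Dx2_uM", "CI", "category")
  class(out) <- c("abm_synergy_report", class(out))
  out
}

#' Dose-effect function backed by the simulator
#'
#' Wraps a calibrated configuration into a `(dose1, dose2) -> mortality`
#' function: each call sets the initial doses and returns the
#' replicate-averaged endpoint mortality under fixed seeds, suitable for
#' [synergy_report()] with `stochastic = TRUE`.
#'
#' @param config A calibrated `abm_config` for the drug pair.
#' @param endpoint_h Readout time (hours, default 48).
#' @param replicates Replicate seeds per evaluation.
#' @param seed Base seed shared by every evaluation.
#' @return A function `(dose1, dose2)` returning a mortality fraction.
#' @export
simulated_effect_fn <- function(config, endpoint_h = 48, replicates = 5,
                                seed = 1) {
  stopifnot(inherits(config, "abm_config"))
  function(dose1, dose2) {
    cfg <- config
    cfg$drugs$initial_uM <- c(dose1, dose2)
    as.numeric(endpoint_msrate(cfg,
      endpoint_h = endpoint_h,
      replicates = replicates, seed = seed
    ))
  }
}
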