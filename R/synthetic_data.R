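#' Specification for a synthetic dose-inhibition table
#'
#' Describes one drug pair's ground truth and assay design for the
#' synthetic generator: the dose-mortality coefficients, the apoptosis
#' parameters, a 30-row dose grid over 0-100 uM (six total doses along
#' each of the ratios 4:1, 3:2, 2:3 and 1:4, plus three single-agent
#' anchors per drug), triplicate measurement and truncated-Gaussian
#' replicate noise.
#'
#' @param pair Pair label, e.g. `"gefitinib/rosiglitazone"`.
#' @param theta Ground-truth `(theta0, theta1, theta2)`.
#' @param c1,c2,lambda Ground-truth apoptosis parameters (used by the
#'   simulator-consistent generator).
#' @param half_life_h Length-2 half-lives (hours) of the two drugs.
#' @param dose_grid Optional tibble with columns `dose1_uM`, `dose2_uM`;
#'   default the 30-row grid described above.
#' @param replicates Replicate count (default 3).
#' @param noise_sd Additive Gaussian noise on inhibition (default 0.03),
#'   truncated so replicates stay in `[0, 1]`.
#' @param seed Generator seed.
#' @return An object of class `abm_generator_spec`.
#' @export
generator_spec <- function(pair, theta, c1 = 0.025, c2 = 0.06, lambda = 1,
                           half_life_h = c(48, 18), dose_grid = NULL,
                           replicates = 3, noise_sd = 0.03, seed = 1) {
  stopifnot(length(theta) == 3, noise_sd >= 0, replicates >= 1)
  if (is.null(dose_grid)) dose_grid <- default_dose_grid()
  stopifnot(
    all(c("dose1_uM", "dose2_uM") %in% names(dose_grid)),
    all(dose_grid$dose1_uM >= 0 & dose_grid$dose1_uM <= 100),
    all(dose_grid$dose2_uM >= 0 & dose_grid$dose2_uM <= 100)
  )
  structure(
    list(
      pair = pair, theta = theta, c1 = c1, c2 = c2, lambda = lambda,
      half_life_h = half_life_h, dose_grid = tibble::as_tibble(dose_grid),
      replicates = as.integer(replicates), noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "abm_generator_spec"
  )
}

# 24 ratio rows (totals 5-80 uM at 4:1, 3:2, 2:3, 1:4) + 6 single-agent
# anchors = 30 combinations, all within 0-100 uM
default_dose_grid <- function() {
  totals <- c(5, 10, 20, 40, 60, 80)
  ratios <- list(c(4, 1), c(3, 2), c(2, 3), c(1, 4))
  ray <- purrr::map_dfr(ratios, function(r) {
    fr <- r / sum(r)
    tibble::tibble(dose1_uM = totals * fr[1], dose2_uM = totals * fr[2])
  })
  anchors <- tibble::tibble(
    dose1_uM = c(20, 60, 100, 0, 0, 0),
    dose2_uM = c(0, 0, 0, 20, 60, 100)
  )
  dplyr::bind_rows(ray, anchors)
}

truncated_noise <- function(mean, sd, n) {
  reps <- matrix(mean, nrow = length(mean), ncol = n) +
    matrix(stats::rnorm(length(mean) * n, 0, sd), ncol = n)
  pmin(pmax(reps, 0), 1)
}

#' Generate a synthetic dose-inhibition table
#'
#' Emulates a triplicate viability screen: the mean inhibition of each
#' dose combination follows the clamped linear dose-mortality model
#' `clamp(theta0 + theta1 d1 + theta2 d2, 0, 1)` and replicates add
#' truncated Gaussian noise. Fully seeded; the ground truth travels in
#' the table's `truth` attribute.
#'
#' @param spec An [generator_spec()].
#' @return A tibble with columns `pair`, `dose1_uM`, `dose2_uM`,
#'   `rep1..repK`, with attribute `truth`.
#' @examples
#' spec <- generator_spec("demo", theta = c(0.1686, 0.0067, 0.0019), seed = 7)
#' generate_table(spec)
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "abm_generator_spec"))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(spec$seed)
  g <- spec$dose_grid
  mu <- computed_mortality(spec$theta, g$dose1_uM, g$dose2_uM, clamp = TRUE)
  reps <- truncated_noise(mu, spec$noise_sd, spec$replicates)
  colnames(reps) <- paste0("rep", seq_len(spec$replicates))
  out <- dplyr::bind_cols(
    tibble::tibble(pair = spec$pair, dose1_uM = g$dose1_uM, dose2_uM = g$dose2_uM),
    tibble::as_tibble(reps)
  )
  attr(out, "truth") <- spec[c("theta", "c1", "c2", "lambda")]
  out
}

#' Generate a simulator-consistent dose-inhibition table
#'
#' Like [generate_table()], but the mean inhibition per row is the
#' replicate-averaged endpoint mortality of the agent-based engine run at
#' the spec's ground-truth parameters, so a subsequent global calibration
#' can in principle recover the truth exactly up to noise.
#'
#' @param spec An [generator_spec()].
#' @param base_config Optional `abm_config` template; defaults to the
#'   reference setup with the spec's half-lives, theta and apoptosis
#'   parameters.
#' @param endpoint_h Readout time (hours, default 48).
#' @param engine_replicates Engine replicate seeds per row (default 3).
#' @return A tibble as in [generate_table()], with attribute `truth`.
#' @export
generate_simulator_consistent_table <- function(spec, base_config = NULL,
                                                endpoint_h = 48,
                                                engine_replicates = 3) {
  stopifnot(inherits(spec, "abm_generator_spec"))
  if (is.null(base_config)) {
    base_config <- simulation_config(
      drugs = tibble::tibble(
        name = strsplit(spec$pair, "/", fixed = TRUE)[[1]][c(1, 2)],
        half_life_h = spec$half_life_h, initial_uM = c(0, 0)
      ),
      theta = spec$theta, c1 = spec$c1, c2 = spec$c2, lambda = spec$lambda,
      horizon_steps = max(1, round(endpoint_h / 0.72))
    )
  }
  g <- spec$dose_grid
  mu <- purrr::map2_dbl(g$dose1_uM, g$dose2_uM, function(d1, d2) {
    cfg <- base_config
    cfg$drugs$initial_uM <- c(d1, d2)
    as.numeric(endpoint_msrate(cfg,
      endpoint_h = endpoint_h,
      replicates = engine_replicates, seed = spec$seed
    ))
  })
  mu <- pmin(pmax(mu, 0), 1)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(spec$seed + 1)
  reps <- truncated_noise(mu, spec$noise_sd, spec$replicates)
  colnames(reps) <- paste0("rep", seq_len(spec$replicates))
  out <- dplyr::bind_cols(
    tibble::tibble(pair = spec$pair, dose1_uM = g$dose1_uM, dose2_uM = g$dose2_uM),
    tibble::as_tibble(reps)
  )
  attr(out, "truth") <- c(spec[c("theta", "c1", "c2", "lambda")],
    list(mean_msrate = mu))
  out
}

#' Default synthetic specifications for the three reference drug pairs
#'
#' Three named generator specs shaped like the reference screens:
#' gefitinib/rosiglitazone, erlotinib/imatinib and gefitinib/quinacrine,
#' with the published dose-mortality coefficients as ground truth and the
#' drugs' pharmacokinetic half-lives (gefitinib 48 h, rosiglitazone 3.5 h,
#' erlotinib 36 h, imatinib 18 h, quinacrine 228 h).
#'
#' @param noise_sd Replicate noise (default 0.03).
#' @param seed Base seed; pair `k` uses `seed + k - 1`.
#' @return A named list of three [generator_spec()] objects.
#' @export
default_drug_pairs <- function(noise_sd = 0.03, seed = 11) {
  specs <- list(
    generator_spec("gefitinib/rosiglitazone",
      theta = c(0.1686, 0.0067, 0.0019),
      half_life_h = c(48, 3.5), noise_sd = noise_sd, seed = seed
    ),
    generator_spec("erlotinib/imatinib",
      theta = c(0.1789, 0.0076, 0.0031),
      half_life_h = c(36, 18), noise_sd = noise_sd, seed = seed + 1
    ),
    generator_spec("gefitinib/quinacrine",
      theta = c(0.0006, 0.0085, 0.0101),
      half_life_h = c(48, 228), noise_sd = noise_sd, seed = seed + 2
    )
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "pair"))
}
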