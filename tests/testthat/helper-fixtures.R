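# shared builders for the test suite

two_drugs <- function(half_life_h = c(48, 18), initial_uM = c(20, 80)) {
  tibble::tibble(
    name = c("drugA", "drugB"),
    half_life_h = half_life_h, initial_uM = initial_uM
  )
}

# small lattice, drug-free, inert dynamics unless overridden
quiet_config <- function(...) {
  defaults <- list(
    drugs = two_drugs(initial_uM = c(0, 0)),
    lambda = 0, c1 = 0, c2 = 0, theta = c(0, 0, 0), p_pro = 0,
    n_per_axis = 21, n_cells = 30, horizon_steps = 30,
    init_cycle_from_age = FALSE
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# random well-conditioned dose table following the linear mortality model
random_dose_table <- function(m = 12, theta = NULL, noise_sd = 0.01) {
  if (is.null(theta)) theta <- c(stats::runif(1, 0, 0.3), stats::runif(2, 0, 0.01))
  d1 <- stats::runif(m, 0, 100)
  d2 <- stats::runif(m, 0, 100)
  tibble::tibble(
    dose1_uM = d1, dose2_uM = d2,
    merate = theta[1] + theta[2] * d1 + theta[3] * d2 + stats::rnorm(m, 0, noise_sd),
    theta_true = list(theta)
  )
}
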