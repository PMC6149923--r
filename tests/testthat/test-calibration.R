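test_that("bootstrap mean is consistent, exact on constants, and seeded", {
  expect_equal(bootstrap_mean(rep(0.42, 5), B = 50, seed = 1), 0.42)
  x <- c(0.31, 0.35, 0.4, 0.28, 0.37, 0.33)
  bm <- bootstrap_mean(x, B = 1e4, seed = 2)
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(bm - mean(x)), 2 * se)
  expect_identical(
    bootstrap_mean(x, B = 500, seed = 3),
    bootstrap_mean(x, B = 500, seed = 3)
  )
  expect_error(bootstrap_mean(numeric(0)), class = "synergyabm_invalid_argument")
})

test_that("absorbance converts to mortality as one minus the ratio", {
  expect_equal(merate_from_absorbance(1, 1), 0)
  expect_equal(merate_from_absorbance(0, 1), 1)
  expect_equal(merate_from_absorbance(0.25, 0.5), 0.5)
  expect_error(merate_from_absorbance(0.5, 0), class = "synergyabm_invalid_argument")
})

test_that("dose tables read from CSV normalise percentages to fractions", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "pair,dose1_uM,dose2_uM,rep1,rep2,rep3",
    "p,10,5,42,44,40",
    "p,20,10,55,53,57"
  ), path)
  tab <- read_dose_table(path)
  expect_equal(tab$rep1, c(0.42, 0.55))
  prep <- prepare_dose_table(tab, B = 200, seed = 1)
  expect_true(all(abs(prep$merate - rowMeans(tab[c("rep1", "rep2", "rep3")])) < 0.02))
})

test_that("gradient descent reaches the closed-form least-squares fit", {
  set.seed(11)
  tab <- random_dose_table(m = 20, theta = c(0.1, 0.005, 0.002), noise_sd = 0)
  fit <- fit_local(tab)
  expect_true(fit$converged)
  expect_equal(unname(fit$theta), c(0.1, 0.005, 0.002), tolerance = 1e-4)
  expect_lt(fit$loss, 1e-10)
})

test_that("gradient descent equals the least-squares oracle on random tables", {
  set.seed(12)
  for (k in 1:100) {
    tab <- random_dose_table(m = sample(6:40, 1), noise_sd = runif(1, 0, 0.05))
    fit <- fit_local(tab)
    ols <- stats::lm(merate ~ dose1_uM + dose2_uM, data = tab)
    expect_equal(unname(fit$theta), unname(stats::coef(ols)), tolerance = 1e-6)
    # the reported p-value is the regression overall F-test
    fs <- summary(ols)$fstatistic
    expect_equal(fit$p_value,
      stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
      ignore_attr = TRUE, tolerance = 1e-6
    )
  }
})

test_that("degenerate and scaled designs behave as linear algebra dictates", {
  flat <- tibble::tibble(dose1_uM = rep(0, 6), dose2_uM = rep(0, 6),
    merate = runif(6))
  expect_error(fit_local(flat), class = "synergyabm_collinear_design")
  expect_error(fit_local(tibble::tibble(dose1_uM = 1, dose2_uM = 1, merate = 1)),
    class = "synergyabm_invalid_argument"
  )
  set.seed(13)
  tab <- random_dose_table(m = 15, noise_sd = 0.02)
  doubled <- dplyr::mutate(tab, merate = 2 * merate)
  expect_equal(fit_local(doubled)$theta, 2 * fit_local(tab)$theta,
    tolerance = 1e-6
  )
})

test_that("local fits expose tidy and glance summaries", {
  set.seed(14)
  fit <- fit_local(random_dose_table(m = 10))
  td <- generics::tidy(fit)
  expect_equal(td$term, c("theta0", "theta1", "theta2"))
  gl <- generics::glance(fit)
  expect_true(all(c("loss", "p.value", "nobs", "converged") %in% names(gl)))
})

test_that("the particle swarm solves a sphere surrogate and honours degenerate settings", {
  res <- pso_optimize(function(p) sum((p - c(0.3, -1.2, 2))^2),
    lower = c(-5, -5, -5), upper = c(5, 5, 5),
    swarm_size = 24, iters = 200, seed = 4
  )
  expect_lt(sqrt(sum((res$par - c(0.3, -1.2, 2))^2)), 1e-3)
  # the global-best objective never increases
  expect_true(all(diff(res$history) <= 0))

  # one particle with zero attraction stays at its initialisation
  calls <- new.env()
  calls$x <- list()
  frozen <- pso_optimize(function(p) {
    calls$x <- c(calls$x, list(p))
    sum(p^2)
  }, lower = c(-1, -1), upper = c(1, 1), swarm_size = 1, iters = 5,
  c_cog = 0, c_soc = 0, seed = 5)
  expect_equal(frozen$par, calls$x[[1]])
})

test_that("the weighted global objective recovers parameters on a stub simulator", {
  # stub: endpoint mortality is an analytic function of (c1, c2, lambda)
  truth <- c(0.3, 0.5, 1.2)
  stub <- function(c1, c2, lambda, d1, d2, pair) {
    c1 * 0.4 + c2 * (0.1 + 0.004 * d1 + 0.002 * d2) + 0.05 * lambda
  }
  tab <- tibble::tibble(
    pair = "p",
    dose1_uM = c(5, 10, 20, 40, 60, 80, 0, 30),
    dose2_uM = c(80, 60, 40, 20, 10, 5, 30, 0)
  )
  tab$merate <- purrr::pmap_dbl(
    list(tab$dose1_uM, tab$dose2_uM, tab$pair),
    function(d1, d2, p) stub(truth[1], truth[2], truth[3], d1, d2, p)
  )
  fit <- fit_global(tab, stub, swarm_size = 30, iters = 120, seed = 6)
  expect_lt(fit$objective, 1e-6)
  expect_equal(fit$predictions$msrate, tab$merate, tolerance = 1e-3)
  td <- generics::tidy(fit)
  expect_equal(td$term, c("c1", "c2", "lambda"))
})

test_that("cross-validated relative error matches hand-computable stubs", {
  tab <- tibble::tibble(
    pair = "p",
    dose1_uM = seq(5, 60, length.out = 9),
    dose2_uM = seq(60, 5, length.out = 9)
  )
  tab$merate <- 0.2 + 0.005 * tab$dose1_uM + 0.003 * tab$dose2_uM
  lookup <- function(c1, c2, lambda, d1, d2, pair) 0.2 + 0.005 * d1 + 0.003 * d2

  perfect <- crossvalidate(tab, lookup, swarm_size = 4, iters = 3, seed = 1)
  expect_equal(perfect$mean_abs_re, 0, tolerance = 1e-12)

  inflated <- function(c1, c2, lambda, d1, d2, pair) {
    1.1 * (0.2 + 0.005 * d1 + 0.003 * d2)
  }
  off <- crossvalidate(tab, inflated, swarm_size = 4, iters = 3, seed = 1)
  expect_equal(off$mean_abs_re, 0.1, tolerance = 1e-10)

  # zero-mortality rows are excluded from the error with a warning
  tab0 <- dplyr::mutate(tab, merate = c(0, merate[-1]))
  expect_warning(
    re <- relative_error(rep(0.5, 9), tab0$merate),
    "zero experimental mortality"
  )
  expect_true(is.na(re[1]))
})

test_that("the paired significance test behaves across null and shifted series", {
  x <- c(0.2, 0.35, 0.5, 0.41, 0.3, 0.62, 0.18, 0.55)
  expect_equal(as.numeric(significance_test(x, x)), 1)

  set.seed(15)
  noise <- 0.01
  sim <- runif(30, 0.2, 0.8)
  shifted <- sim + 10 * noise + rnorm(30, 0, noise)
  expect_lt(as.numeric(significance_test(sim, shifted)), 0.001)

  # pairing invariance under a common permutation
  perm <- sample(30)
  expect_equal(
    as.numeric(significance_test(sim, shifted)),
    as.numeric(significance_test(sim[perm], shifted[perm]))
  )

  near <- sim + rnorm(30, 0, 0.005)
  expect_equal(
    as.numeric(significance_test(sim, near, method = "t")),
    stats::t.test(sim, near, paired = TRUE)$p.value
  )
  expect_error(significance_test(1:3, 1:4), class = "synergyabm_invalid_argument")
})
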