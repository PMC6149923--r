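#' Bootstrap estimate of a mean inhibition rate
#'
#' Stabilises small-replicate inhibition measurements by averaging `B`
#' resample means (resampling with replacement at the original size).
#'
#' @param samples Numeric inhibition fractions (at least one).
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Optional seed for reproducible resampling.
#' @return The bootstrap mean.
#' @examples
#' bootstrap_mean(c(0.42, 0.45, 0.47), B = 1000, seed = 1)
#' @export
bootstrap_mean <- function(samples, B = 1000, seed = NULL) {
  if (length(samples) < 1) {
    rlang::abort("`samples` must be non-empty.", class = "synergyabm_invalid_argument")
  }
  if (B < 1) {
    rlang::abort("`B` must be at least 1.", class = "synergyabm_invalid_argument")
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  n <- length(samples)
  idx <- sample.int(n, n * B, replace = TRUE)
  mean(colMeans(matrix(samples[idx], nrow = n)))
}

#' Experimental mortality from absorbance readings
#'
#' The viability-assay inhibition rate `1 - avg_drug / avg_control`,
#' stored as a fraction.
#'
#' @param avg_drug Mean absorbance of the drug group (non-negative).
#' @param avg_control Mean absorbance of the control group (positive).
#' @return Mortality fraction(s).
#' @export
merate_from_absorbance <- function(avg_drug, avg_control) {
  if (any(avg_control <= 0)) {
    rlang::abort("`avg_control` must be positive.", class = "synergyabm_invalid_argument")
  }
  if (any(avg_drug < 0)) {
    rlang::abort("`avg_drug` must be non-negative.", class = "synergyabm_invalid_argument")
  }
  1 - avg_drug / avg_control
}

#' Read a dose-inhibition table from CSV
#'
#' Expects columns `pair`, `dose1_uM`, `dose2_uM` and one or more
#' replicate columns `rep1`, `rep2`, .... Inhibition values are
#' auto-detected as percentages (maximum above 1.5) and normalised to
#' fractions.
#'
#' @param path CSV path.
#' @return A tibble with the replicate columns as fractions.
#' @export
read_dose_table <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  reps <- grep("^rep", names(tab), value = TRUE)
  if (length(reps) == 0) {
    rlang::abort("no replicate columns (rep1, rep2, ...) found.",
      class = "synergyabm_invalid_argument"
    )
  }
  if (max(as.matrix(tab[reps]), na.rm = TRUE) > 1.5) {
    tab[reps] <- tab[reps] / 100
  }
  tab
}

#' Add a bootstrap-mean mortality column to a dose table
#'
#' Computes the experimental mortality `merate` per row as the bootstrap
#' mean ([bootstrap_mean()]) of its replicate inhibition fractions.
#'
#' @param table A dose table with replicate columns `rep*`.
#' @param B Bootstrap resamples per row.
#' @param seed Base seed; row `i` uses `seed + i`.
#' @return The table with an added `merate` column.
#' @export
prepare_dose_table <- function(table, B = 1000, seed = 1) {
  reps <- grep("^rep", names(table), value = TRUE)
  m <- as.matrix(table[reps])
  table$merate <- vapply(
    seq_len(nrow(table)),
    function(i) bootstrap_mean(m[i, ], B = B, seed = seed + i),
    numeric(1)
  )
  table
}

#' Local fit of the dose-mortality coefficients by gradient descent
#'
#' Minimises the least-squares loss
#' `J(theta) = 1/(2m) * sum((theta0 + theta1 d1 + theta2 d2 - merate)^2)`
#' over the table's dose combinations by batch gradient descent. Doses are
#' standardised internally for conditioning and the coefficients mapped
#' back to the uM scale; at convergence the result coincides with the
#' closed-form ordinary-least-squares solution. The reported p-value is
#' the overall regression F-test.
#'
#' @param table A dose table with columns `dose1_uM`, `dose2_uM` and
#'   `merate` (see [prepare_dose_table()]).
#' @param init_theta Starting coefficients (default zeros).
#' @param learning_rate Step size on the standardised scale.
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the standardised gradient norm.
#' @return An object of class `abm_local_fit` with elements `theta`
#'   (named length-3), `loss`, `p_value`, `iterations`, `converged` and
#'   the fitting table.
#' @examples
#' tab <- tibble::tibble(
#'   dose1_uM = c(0, 10, 20, 40, 5, 80), dose2_uM = c(0, 5, 10, 20, 40, 16),
#'   merate = 0.1 + 0.005 * dose1_uM + 0.002 * dose2_uM
#' )
#' fit_local(tab)
#' @export
fit_local <- function(table, init_theta = c(0, 0, 0), learning_rate = 0.3,
                      max_iter = 50000, tol = 1e-12) {
  stopifnot(all(c("dose1_uM", "dose2_uM", "merate") %in% names(table)))
  d1 <- table$dose1_uM
  d2 <- table$dose2_uM
  y <- table$merate
  m <- length(y)
  if (m < 3) {
    rlang::abort("need at least 3 dose combinations.",
      class = "synergyabm_invalid_argument"
    )
  }
  X <- cbind(1, d1, d2)
  if (qr(X)$rank < 3) {
    rlang::abort("dose design is collinear; theta1/theta2 are unidentifiable.",
      class = "synergyabm_collinear_design"
    )
  }
  # standardise doses for conditioning; theta maps back linearly
  mu <- c(mean(d1), mean(d2))
  sd2 <- c(stats::sd(d1), stats::sd(d2))
  Z <- cbind(1, (d1 - mu[1]) / sd2[1], (d2 - mu[2]) / sd2[2])
  # starting point transformed to the standardised scale
  b <- c(
    init_theta[1] + init_theta[2] * mu[1] + init_theta[3] * mu[2],
    init_theta[2] * sd2[1], init_theta[3] * sd2[2]
  )
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- crossprod(Z, Z %*% b - y) / m
    b <- b - learning_rate * g
    if (sqrt(sum(g^2)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    rlang::warn("gradient descent did not converge; returning best iterate.")
  }
  b <- drop(b)
  theta <- c(
    theta0 = b[1] - b[2] * mu[1] / sd2[1] - b[3] * mu[2] / sd2[2],
    theta1 = b[2] / sd2[1], theta2 = b[3] / sd2[2]
  )
  resid <- drop(X %*% theta) - y
  loss <- sum(resid^2) / (2 * m)
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  df2 <- m - 3
  f_stat <- if (rss <= .Machine$double.eps * tss || df2 <= 0) {
    Inf
  } else {
    ((tss - rss) / 2) / (rss / df2)
  }
  p_value <- if (is.infinite(f_stat)) 0 else stats::pf(f_stat, 2, df2, lower.tail = FALSE)
  structure(
    list(
      theta = theta, loss = loss, p_value = p_value,
      iterations = it, converged = converged,
      table = tibble::as_tibble(table), residuals = resid
    ),
    class = "abm_local_fit"
  )
}

#' @export
print.abm_local_fit <- function(x, ...) {
  cat("<abm_local_fit>  theta =", paste(signif(x$theta, 4), collapse = ", "),
      "\n  J =", signif(x$loss, 4), " p =", signif(x$p_value, 4),
      " (", x$iterations, "iterations )\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.abm_local_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta))
}

#' @export
glance.abm_local_fit <- function(x, ...) {
  tibble::tibble(
    loss = x$loss, p.value = x$p_value, nobs = nrow(x$table),
    iterations = x$iterations, converged = x$converged
  )
}

#' Global-best particle swarm optimiser
#'
#' Standard constricted PSO: each particle keeps a velocity updated by an
#' inertia term plus cognitive (personal-best) and social (global-best)
#' attractions, with velocities clamped to a fraction of the box range and
#' positions clamped to the box. Boundaries are absorbing: a velocity
#' component is zeroed whenever its position component is clamped, so
#' particles do not press against the walls with stale momentum. If the
#' global best fails to improve for `restart_stall` consecutive
#' iterations, every particle except the incumbent best is re-scattered
#' uniformly over the box (an elitist restart), which guards against
#' premature swarm collapse. The global-best objective is non-increasing
#' over iterations by construction.
#'
#' @param fn Objective function of a numeric parameter vector.
#' @param lower,upper Box bounds (equal lengths).
#' @param swarm_size Number of particles (default 24).
#' @param iters Iterations (default 100).
#' @param w Inertia weight (default 0.72).
#' @param c_cog,c_soc Cognitive and social coefficients (default 1.49).
#' @param vmax_frac Velocity clamp as a fraction of the box range.
#' @param restart_stall Consecutive non-improving iterations after which
#'   all particles but the best are re-scattered (default 8; `Inf`
#'   disables restarts).
#' @param seed Optional seed.
#' @return A list with `par`, `value`, `history` (global-best objective
#'   per iteration, including the initial evaluation) and `evaluations`.
#' @examples
#' pso_optimize(function(p) sum(p^2), c(-5, -5), c(5, 5), seed = 1)$par
#' @export
pso_optimize <- function(fn, lower, upper, swarm_size = 24, iters = 100,
                         w = 0.72, c_cog = 1.49, c_soc = 1.49,
                         vmax_frac = 0.2, restart_stall = 8, seed = NULL) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  if (swarm_size < 1 || iters < 0) {
    rlang::abort("`swarm_size` must be >= 1 and `iters` >= 0.",
      class = "synergyabm_invalid_argument"
    )
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  d <- length(lower)
  rng <- upper - lower
  vmax <- vmax_frac * rng
  pos <- matrix(stats::runif(swarm_size * d, rep(lower, each = swarm_size),
    rep(upper, each = swarm_size)), nrow = swarm_size)
  vel <- matrix(0, swarm_size, d)
  pbest <- pos
  pbest_val <- apply(pos, 1, fn)
  g <- which.min(pbest_val)
  gbest <- pbest[g, ]
  gbest_val <- pbest_val[g]
  history <- gbest_val
  evals <- swarm_size
  stall <- 0L
  lo <- matrix(lower, swarm_size, d, byrow = TRUE)
  hi <- matrix(upper, swarm_size, d, byrow = TRUE)
  for (k in seq_len(iters)) {
    r1 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
    r2 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
    vel <- w * vel + c_cog * r1 * (pbest - pos) +
      c_soc * r2 * (matrix(gbest, swarm_size, d, byrow = TRUE) - pos)
    vel <- pmin(pmax(vel, matrix(-vmax, swarm_size, d, byrow = TRUE)),
      matrix(vmax, swarm_size, d, byrow = TRUE))
    pos <- pos + vel
    hit <- pos < lo | pos > hi
    vel[hit] <- 0
    pos <- pmin(pmax(pos, lo), hi)
    val <- apply(pos, 1, fn)
    evals <- evals + swarm_size
    improved <- val < pbest_val
    pbest[improved, ] <- pos[improved, , drop = FALSE]
    pbest_val[improved] <- val[improved]
    g <- which.min(pbest_val)
    if (pbest_val[g] < gbest_val) {
      gbest <- pbest[g, ]
      gbest_val <- pbest_val[g]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (swarm_size > 1 && is.finite(restart_stall) && stall >= restart_stall) {
      keep <- which.min(pbest_val)
      redo <- setdiff(seq_len(swarm_size), keep)
      pos[redo, ] <- matrix(stats::runif(length(redo) * d,
        rep(lower, each = length(redo)), rep(upper, each = length(redo))),
      nrow = length(redo))
      vel[redo, ] <- 0
      pbest[redo, ] <- pos[redo, , drop = FALSE]
      pbest_val[redo] <- Inf
      stall <- 0L
    }
    history <- c(history, gbest_val)
  }
  list(par = gbest, value = gbest_val, history = history, evaluations = evals)
}

#' Build an endpoint-mortality simulator for calibration
#'
#' Returns a function `(c1, c2, lambda, dose1, dose2, pair)` that sets the
#' doses and apoptosis parameters in the pair's configuration template and
#' returns the replicate-averaged endpoint mortality. A fixed base seed is
#' reused for every evaluation (common random numbers), so the stochastic
#' objective is quasi-deterministic for the swarm.
#'
#' @param pair_configs Named list of `abm_config` templates, one per pair,
#'   with the pair's half-lives and fitted `theta` already set.
#' @param endpoint_h Readout time (hours).
#' @param replicates Replicate seeds per evaluation.
#' @param seed Base seed shared by all evaluations.
#' @return A simulator function.
#' @export
make_endpoint_simulator <- function(pair_configs, endpoint_h = 48,
                                    replicates = 3, seed = 1) {
  function(c1, c2, lambda, dose1, dose2, pair) {
    cfg <- pair_configs[[pair]]
    if (is.null(cfg)) {
      rlang::abort(paste0("no configuration template for pair '", pair, "'."),
        class = "synergyabm_invalid_argument"
      )
    }
    cfg$c1 <- c1
    cfg$c2 <- c2
    cfg$lambda <- lambda
    cfg$drugs$initial_uM <- c(dose1, dose2)
    as.numeric(endpoint_msrate(cfg,
      endpoint_h = endpoint_h,
      replicates = replicates, seed = seed
    ))
  }
}

# weighted objective: sum over pairs of (1/max merate)^2 * sum of squared
# Msrate - Merate over that pair's rows
global_objective <- function(tables, simulator) {
  tabs <- dplyr::bind_rows(tables)
  stopifnot(all(c("pair", "dose1_uM", "dose2_uM", "merate") %in% names(tabs)))
  wts <- tabs |>
    dplyr::summarise(w = 1 / max(.data$merate)^2, .by = "pair")
  tabs <- dplyr::left_join(tabs, wts, by = "pair")
  function(par) {
    ms <- purrr::pmap_dbl(
      list(tabs$dose1_uM, tabs$dose2_uM, tabs$pair),
      function(d1, d2, p) simulator(par[1], par[2], par[3], d1, d2, p)
    )
    sum(tabs$w * (ms - tabs$merate)^2)
  }
}

#' Global fit of the apoptosis parameters by particle swarm
#'
#' Fits `(c1, c2, lambda)` by minimising the weighted squared gap between
#' simulated endpoint mortality and experimental mortality over every dose
#' combination, with per-pair weights `(1 / max merate)^2`.
#'
#' @param tables A prepared dose table or list of tables, each with
#'   columns `pair`, `dose1_uM`, `dose2_uM`, `merate`.
#' @param simulator A function `(c1, c2, lambda, dose1, dose2, pair)`
#'   returning the simulated endpoint mortality; see
#'   [make_endpoint_simulator()].
#' @param bounds Named list with elements `c1`, `c2`, `lambda`, each a
#'   `(lower, upper)` pair. Defaults `c1, c2` in `[0, 1]`, `lambda` in
#'   `[0, 2]` per hour.
#' @param swarm_size,iters,seed Swarm settings, see [pso_optimize()].
#' @return An object of class `abm_global_fit` with elements `par`
#'   (named `c1`, `c2`, `lambda`), `objective`, `history`, `predictions`
#'   (per-row simulated mortality at the optimum) and `seed`.
#' @export
fit_global <- function(tables, simulator,
                       bounds = list(c1 = c(0, 1), c2 = c(0, 1), lambda = c(0, 2)),
                       swarm_size = 16, iters = 30, seed = 1) {
  if (!all(c("c1", "c2", "lambda") %in% names(bounds))) {
    rlang::abort("`bounds` needs elements c1, c2, lambda.",
      class = "synergyabm_invalid_argument"
    )
  }
  obj <- global_objective(tables, simulator)
  res <- pso_optimize(obj,
    lower = vapply(bounds[c("c1", "c2", "lambda")], `[`, numeric(1), 1),
    upper = vapply(bounds[c("c1", "c2", "lambda")], `[`, numeric(1), 2),
    swarm_size = swarm_size, iters = iters, seed = seed
  )
  tabs <- dplyr::bind_rows(tables)
  preds <- purrr::pmap_dbl(
    list(tabs$dose1_uM, tabs$dose2_uM, tabs$pair),
    function(d1, d2, p) simulator(res$par[1], res$par[2], res$par[3], d1, d2, p)
  )
  structure(
    list(
      par = stats::setNames(res$par, c("c1", "c2", "lambda")),
      objective = res$value, history = res$history,
      predictions = dplyr::mutate(tabs, msrate = preds), seed = seed
    ),
    class = "abm_global_fit"
  )
}

#' @export
print.abm_global_fit <- function(x, ...) {
  cat("<abm_global_fit>  c1 =", signif(x$par["c1"], 4),
      " c2 =", signif(x$par["c2"], 4),
      " lambda =", signif(x$par["lambda"], 4),
      "\n  weighted objective =", signif(x$objective, 5), "\n")
  invisible(x)
}

#' @export
tidy.abm_global_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @export
glance.abm_global_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective, nobs = nrow(x$predictions),
    iterations = length(x$history) - 1, seed = x$seed
  )
}

#' Relative error of simulated against experimental mortality
#'
#' `(msrate - merate) / merate`, with rows at zero experimental mortality
#' excluded (with a warning) to guard the division.
#'
#' @param msrate Simulated mortality fractions.
#' @param merate Experimental mortality fractions.
#' @return Numeric vector of relative errors (`NA` where excluded).
#' @export
relative_error <- function(msrate, merate) {
  bad <- merate == 0
  if (any(bad)) {
    rlang::warn(paste(sum(bad), "row(s) with zero experimental mortality excluded."))
  }
  out <- (msrate - merate) / merate
  out[bad] <- NA_real_
  out
}

#' Cross-validated relative error of the global fit
#'
#' Default protocol: per pair, the rows are split into thirds (seeded);
#' the designated third trains the global fit and the held-out rows score
#' the mean absolute relative error. `protocol = "loocv"` instead trains
#' on all rows but one and scores the left-out row, cycling over rows.
#'
#' @param tables Prepared dose table(s) with `pair`, doses and `merate`.
#' @param simulator As in [fit_global()].
#' @param protocol `"thirds"` (default) or `"loocv"`.
#' @param train_fold Which third trains (1-3), thirds protocol only.
#' @param bounds,swarm_size,iters,seed Passed to [fit_global()].
#' @return A tibble with one row per pair: `pair`, `n_train`, `n_test`,
#'   `mean_abs_re`, and the fitted `c1`, `c2`, `lambda`.
#' @export
crossvalidate <- function(tables, simulator, protocol = c("thirds", "loocv"),
                          train_fold = 1,
                          bounds = list(c1 = c(0, 1), c2 = c(0, 1), lambda = c(0, 2)),
                          swarm_size = 16, iters = 30, seed = 1) {
  protocol <- match.arg(protocol)
  tabs <- dplyr::bind_rows(tables)
  pairs <- unique(tabs$pair)
  purrr::map_dfr(pairs, function(p) {
    tab <- dplyr::filter(tabs, .data$pair == p)
    if (protocol == "thirds") {
      old <- globalenv()$.Random.seed
      on.exit(restore_rng(old), add = TRUE)
      set.seed(seed)
      fold <- sample(rep_len(1:3, nrow(tab)))
      train <- tab[fold == train_fold, , drop = FALSE]
      test <- tab[fold != train_fold, , drop = FALSE]
      fit <- fit_global(train, simulator,
        bounds = bounds,
        swarm_size = swarm_size, iters = iters, seed = seed
      )
      ms <- purrr::pmap_dbl(
        list(test$dose1_uM, test$dose2_uM, test$pair),
        function(d1, d2, pp) {
          simulator(fit$par["c1"], fit$par["c2"], fit$par["lambda"], d1, d2, pp)
        }
      )
      re <- relative_error(ms, test$merate)
      tibble::tibble(
        pair = p, n_train = nrow(train), n_test = sum(!is.na(re)),
        mean_abs_re = mean(abs(re), na.rm = TRUE),
        c1 = unname(fit$par["c1"]), c2 = unname(fit$par["c2"]),
        lambda = unname(fit$par["lambda"])
      )
    } else {
      res <- purrr::map_dbl(seq_len(nrow(tab)), function(i) {
        fit <- fit_global(tab[-i, , drop = FALSE], simulator,
          bounds = bounds,
          swarm_size = swarm_size, iters = iters, seed = seed
        )
        ms <- simulator(
          fit$par["c1"], fit$par["c2"], fit$par["lambda"],
          tab$dose1_uM[i], tab$dose2_uM[i], p
        )
        if (tab$merate[i] == 0) NA_real_ else abs((ms - tab$merate[i]) / tab$merate[i])
      })
      tibble::tibble(
        pair = p, n_train = nrow(tab) - 1, n_test = sum(!is.na(res)),
        mean_abs_re = mean(res, na.rm = TRUE),
        c1 = NA_real_, c2 = NA_real_, lambda = NA_real_
      )
    }
  })
}

#' Paired test of simulated against experimental mortality
#'
#' Two-sided paired comparison of equal-length mortality series; Wilcoxon
#' signed-rank by default, paired t-test optionally. A p-value above 0.1
#' is read as no significant simulated-experimental difference.
#'
#' @param simulated,experimental Equal-length numeric series.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return The p-value, with the full `htest` in attribute `test`.
#' @export
significance_test <- function(simulated, experimental,
                              method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  if (length(simulated) != length(experimental)) {
    rlang::abort("series must have equal length.", class = "synergyabm_invalid_argument")
  }
  d <- simulated - experimental
  if (all(d == 0)) {
    out <- 1
    attr(out, "test") <- NULL
    return(out)
  }
  ht <- if (method == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(simulated, experimental,
      paired = TRUE, exact = FALSE
    ))
  } else {
    stats::t.test(simulated, experimental, paired = TRUE)
  }
  out <- unname(ht$p.value)
  attr(out, "test") <- ht
  out
}
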