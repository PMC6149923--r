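test_that("crowding preference maps neighbour counts to the four weights", {
  expect_equal(neighbor_preference(c(0, 1, 2, 3, 4, 5, 6)),
    c(1 / 16, 1, 1, 1 / 4, 1 / 4, 1 / 8, 1 / 8))
  expect_error(neighbor_preference(7), class = "synergyabm_invalid_argument")
  expect_error(neighbor_preference(-1), class = "synergyabm_invalid_argument")
})

test_that("move kernel is a decaying exponential of squared distance", {
  D <- 10
  dt <- 0.72
  expect_equal(move_kernel(0, D, dt), 1 / (4 * pi * D * dt))
  # frozen from an independent log-space evaluation
  s <- 4 * pi * D * dt
  expect_equal(move_kernel(5, D, dt), exp(-log(s) - 25 / s), tolerance = 1e-12)
  r <- seq(0, 30, length.out = 100)
  expect_true(all(diff(move_kernel(r, D, dt)) < 0))
  expect_error(move_kernel(1, 0, 1), class = "synergyabm_invalid_argument")
  expect_error(move_kernel(-1, 1, 1), class = "synergyabm_invalid_argument")
})

test_that("candidate ranking normalises to one and follows the weights", {
  one <- rank_candidates(tibble::tibble(r_um = 5, n_neighbors = 2))
  expect_equal(one$rank_norm, 1)

  six <- rank_candidates(tibble::tibble(r_um = rep(5, 6), n_neighbors = rep(3, 6)))
  expect_equal(six$rank_norm, rep(1 / 6, 6))

  # equal distances cancel the kernel: V = (1, 1/4) -> ranks (0.8, 0.2)
  two <- rank_candidates(tibble::tibble(r_um = c(5, 5), n_neighbors = c(1, 3)))
  expect_equal(two$rank_norm, c(0.8, 0.2))

  expect_error(rank_candidates(tibble::tibble(r_um = numeric(), n_neighbors = integer())),
    class = "synergyabm_no_free_site"
  )
})

test_that("ranking always sums to one over random candidate sets", {
  set.seed(77)
  for (k in 1:100) {
    n <- sample(1:12, 1)
    cand <- tibble::tibble(
      r_um = runif(n, 1, 15),
      n_neighbors = sample(0:6, n, replace = TRUE)
    )
    rk <- rank_candidates(cand, D = runif(1, 1, 50), dt = runif(1, 0.1, 2))
    expect_equal(sum(rk$rank_norm), 1, tolerance = 1e-12)
    expect_true(all(rk$rank_norm >= 0))
  }
})

test_that("ranking agrees with brute-force enumeration over all 2^6 neighbourhoods", {
  # a mover at the centre of a 7^3 lattice; each pattern occupies the
  # distance-2 axial site beyond one of the six free face-neighbour
  # candidates, giving that candidate exactly one occupied neighbour
  axes <- rbind(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)
  )
  centre <- c(3, 3, 3)
  v_table <- c(1 / 16, 1, 1, 1 / 4, 1 / 4, 1 / 8, 1 / 8) # independent copy
  for (pattern in 0:63) {
    bits <- as.integer(intToBits(pattern))[1:6]
    occ <- matrix(FALSE, 7 * 7 * 7, 1)
    idx <- function(p) ((p[1]) * 7 + p[2]) * 7 + p[3] + 1
    occ[idx(centre)] <- TRUE
    for (l in which(bits == 1L)) occ[idx(centre + 2 * axes[l, ])] <- TRUE

    # count each free candidate's occupied face neighbours directly on the
    # lattice, excluding the mover's own site
    n_nb <- vapply(1:6, function(l) {
      cand <- centre + axes[l, ]
      nb <- t(apply(axes, 1, function(a) cand + a))
      nb <- nb[!(nb[, 1] == centre[1] & nb[, 2] == centre[2] & nb[, 3] == centre[3]), ]
      sum(apply(nb, 1, function(p) occ[idx(p)]))
    }, integer(1))

    expected <- v_table[n_nb + 1] / sum(v_table[n_nb + 1])
    got <- rank_candidates(tibble::tibble(r_um = rep(5, 6), n_neighbors = n_nb))
    expect_equal(got$rank_norm, expected, tolerance = 1e-12)
  }
})

test_that("roulette selection returns the interval containing the draw", {
  wheel <- selection_wheel(c(0.8, 0.2))
  expect_equal(select_site(wheel, 0.5), 1)
  expect_equal(select_site(wheel, 0.9), 2)
  expect_equal(select_site(wheel, 1), 2) # final interval closed at 1
  single <- selection_wheel(1)
  expect_equal(select_site(single, 0.123), 1)
  expect_error(select_site(wheel, 1.5), class = "synergyabm_invalid_argument")
  expect_error(selection_wheel(c(0.5, 0.2)), class = "synergyabm_invalid_argument")
})

test_that("empirical selection frequencies match the normalised ranks", {
  set.seed(5)
  rk <- rank_candidates(tibble::tibble(
    r_um = rep(5, 4),
    n_neighbors = c(0, 1, 4, 6)
  ))
  wheel <- selection_wheel(rk$rank_norm)
  n <- 1e5
  draws <- vapply(runif(n), function(d) select_site(wheel, d), numeric(1))
  freq <- tabulate(draws, nbins = 4) / n
  se <- sqrt(rk$rank_norm * (1 - rk$rank_norm) / n)
  expect_true(all(abs(freq - rk$rank_norm) <= 3 * se + 1e-9))
})

test_that("crowded clusters conserve cells and isolated cells move or divide", {
  # dense central cluster with inert dynamics: migration under crowding
  # must neither lose cells nor stack two on a site
  cfg <- quiet_config(n_per_axis = 11, n_cells = 27, horizon_steps = 5, p_pro = 0)
  tr <- run_simulation(cfg, seed = 2)
  fin <- attr(tr, "final_cells")
  expect_equal(nrow(fin), 27)
  expect_equal(anyDuplicated(fin[c("x", "y", "z")]), 0)

  # isolated migrating cell: still exactly one cell, displaced by at most
  # one site per step, never out of bounds
  cfg1 <- quiet_config(n_cells = 1, horizon_steps = 10)
  tr1 <- run_simulation(cfg1, seed = 3, snapshot_steps = 0:10)
  snaps <- attr(tr1, "snapshots")
  expect_equal(nrow(snaps), 11)
  pos <- snaps[order(snaps$step), c("x", "y", "z")]
  step_dist <- rowSums(abs(apply(pos, 2, diff)))
  expect_true(all(step_dist == 1)) # face-neighbour moves only
  expect_true(all(as.matrix(pos) >= 0 & as.matrix(pos) < 21))

  # isolated dividing cell: population grows by one at the division step
  cfg2 <- quiet_config(n_cells = 1, p_pro = 1, horizon_steps = 26)
  tr2 <- run_simulation(cfg2, seed = 4)
  expect_equal(tr2$n_cells[26], 2)
  fin2 <- attr(tr2, "final_cells")
  expect_equal(anyDuplicated(fin2[c("x", "y", "z")]), 0)
})
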