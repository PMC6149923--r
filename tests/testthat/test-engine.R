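test_that("simulated mortality follows its defining ratio", {
  expect_equal(msrate(100, 50), 0.5)
  expect_equal(msrate(100, 100), 0)
  expect_equal(msrate(100, 120), -0.2) # net growth convention
  expect_error(msrate(0, 10), class = "synergyabm_invalid_argument")
})

test_that("inert dynamics leave the population constant", {
  tr <- run_simulation(quiet_config(n_cells = 50, horizon_steps = 40), seed = 1)
  expect_true(all(tr$n_alive == 50))
  expect_true(all(tr$msrate == 0))
})

test_that("with no death channels the population never shrinks", {
  cfg <- quiet_config(n_cells = 20, p_pro = 1, horizon_steps = 60)
  tr <- run_simulation(cfg, seed = 9)
  expect_true(all(diff(tr$n_alive) >= 0))
  expect_gt(tr$n_alive[61], 20)
})

test_that("identical seeds give bit-identical trajectories", {
  cfg <- simulation_config(
    drugs = two_drugs(), n_per_axis = 31, n_cells = 60, horizon_steps = 40
  )
  a <- run_simulation(cfg, seed = 11)
  b <- run_simulation(cfg, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "final_cells"), attr(b, "final_cells"))
  c <- run_simulation(cfg, seed = 12)
  expect_false(identical(a$n_alive, c$n_alive))
})

test_that("per-step drug concentrations equal the closed-form decay", {
  cfg <- simulation_config(
    drugs = two_drugs(half_life_h = c(48, 3.5), initial_uM = c(20, 80)),
    n_per_axis = 21, n_cells = 10, horizon_steps = 50
  )
  tr <- run_simulation(cfg, seed = 1)
  expect_equal(tr$drug1_uM, decay_drug(20, 48, tr$time_h), tolerance = 1e-12)
  expect_equal(tr$drug2_uM, decay_drug(80, 3.5, tr$time_h), tolerance = 1e-12)
  expect_true(all(diff(tr$drug1_uM) <= 0))
})

test_that("cell-count bookkeeping balances births against removals", {
  cfg <- simulation_config(
    drugs = two_drugs(), n_per_axis = 31, n_cells = 80,
    horizon_steps = 60, c1 = 0.02, c2 = 0.06
  )
  tr <- run_simulation(cfg, seed = 21)
  lhs <- diff(tr$n_cells)
  rhs <- tr$births[-1] - tr$removals[-1]
  expect_equal(lhs, rhs)
})

test_that("occupancy exclusion and bounds hold at every recorded step", {
  cfg <- simulation_config(
    drugs = two_drugs(), n_per_axis = 25, n_cells = 60,
    horizon_steps = 30, c1 = 0.01, c2 = 0.05, p_pro = 0.9
  )
  tr <- run_simulation(cfg, seed = 31, snapshot_steps = 0:30)
  snaps <- attr(tr, "snapshots")
  audit <- split(snaps, snaps$step)
  for (st in audit) {
    expect_equal(anyDuplicated(st[c("x", "y", "z")]), 0)
    expect_true(all(st$x >= 0 & st$x < 25 & st$y >= 0 & st$y < 25 &
      st$z >= 0 & st$z < 25))
  }
  # snapshot totals agree with the trajectory counts
  n_by_step <- vapply(audit, nrow, integer(1))
  expect_equal(unname(n_by_step), tr$n_cells)
})

test_that("endpoint mortality is a stable replicate average", {
  cfg <- simulation_config(
    drugs = two_drugs(initial_uM = c(40, 20)),
    n_per_axis = 41, horizon_steps = 67
  )
  e <- endpoint_msrate(cfg, endpoint_h = 48, replicates = 6, seed = 5)
  reps <- attr(e, "replicates")
  expect_length(reps, 6)
  expect_equal(as.numeric(e), mean(reps))
  # deterministic given the seed set
  e2 <- endpoint_msrate(cfg, endpoint_h = 48, replicates = 6, seed = 5)
  expect_identical(as.numeric(e), as.numeric(e2))
  # replicate scatter at N0 = 100 is binomial-scale
  expect_lt(stats::sd(reps) / sqrt(6), 0.05)
  expect_error(endpoint_msrate(cfg, endpoint_h = 200),
    class = "synergyabm_invalid_argument"
  )
})

test_that("endpoint mortality hits the degenerate extremes", {
  # no dynamics at all: zero mortality at any endpoint
  e0 <- endpoint_msrate(quiet_config(horizon_steps = 30),
    endpoint_h = 20, replicates = 2, seed = 1
  )
  expect_equal(as.numeric(e0), 0)
  # certain immediate apoptosis: full mortality
  cfg <- quiet_config(c2 = 1, theta = c(2, 0, 0), horizon_steps = 30)
  e1 <- endpoint_msrate(cfg, endpoint_h = 20, replicates = 2, seed = 1)
  expect_equal(as.numeric(e1), 1)
})

test_that("snapshot export writes the documented columns", {
  cfg <- quiet_config(n_cells = 5, horizon_steps = 4)
  tr <- run_simulation(cfg, seed = 1, snapshot_steps = c(0, 2, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_snapshots(tr, path)
  back <- utils::read.csv(path)
  expect_equal(
    names(back),
    c("time_step", "cell_id", "x", "y", "z", "phase", "phenotype", "age_steps")
  )
  expect_equal(nrow(back), 15)
  expect_true(all(back$phenotype %in% c("proliferative", "quiescent", "apoptotic")))
  expect_error(write_snapshots(run_simulation(cfg, seed = 1), path),
    class = "synergyabm_invalid_argument"
  )
})

test_that("a YAML configuration round-trips into the simulator", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "lattice: {n_per_axis: 30, spacing_um: 5}",
    "init: {n_cells: 40, age_max_h: 24}",
    "drugs:",
    "  - {name: gefitinib, half_life_h: 48, initial_uM: 20}",
    "  - {name: rosiglitazone, half_life_h: 3.5, initial_uM: 80}",
    "phenotype: {lambda: 1, c1: 0.02, c2: 0.05, theta: [0.1686, 0.0067, 0.0019], p_pro: 0.8}",
    "motility: {D: 10, division_radius: 1}",
    "time: {step_h: 0.72, horizon_steps: 25}"
  ), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "abm_config")
  expect_equal(cfg$n_per_axis, 30L)
  expect_equal(cfg$drugs$name, c("gefitinib", "rosiglitazone"))
  expect_equal(cfg$theta, c(0.1686, 0.0067, 0.0019))
  tr <- run_simulation(cfg, seed = 1)
  expect_equal(nrow(tr), 26)
})
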