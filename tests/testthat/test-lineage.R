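test_that("phase classification follows the MPF thresholds with an M latch", {
  thr <- phase_thresholds(theta_S = 0.2, theta_M = 0.6)
  expect_equal(as.character(phase_of(0, thr)), "G1")
  expect_equal(as.character(phase_of(0.3, thr)), "S/G2")
  expect_equal(as.character(phase_of(0.7, thr)), "M")
  ## latched cells stay in M below theta_M
  expect_equal(as.character(phase_of(0.3, thr, in_M_latch = TRUE)), "M")
  expect_equal(as.character(phase_of(c(0, 0.3, 0.9), thr,
                                     in_M_latch = c(TRUE, FALSE, FALSE))),
               c("M", "S/G2", "M"))
  expect_error(phase_thresholds(theta_S = 0.7, theta_M = 0.6))
  expect_error(phase_thresholds(theta_S = 0.2, theta_M = 0.6,
                                theta_div = 0.9), "below theta_M")
})

test_that("deterministic uncoupled lineages cycle once per autonomous period", {
  m <- build_model(2, C1 = 0, C2 = 0, autonomous_TCC = 20)
  run <- run_lineage(m, noise_spec("none"), n_ancestors = 1,
                     stop = list(max_time = 80), seed = 3)
  cells <- lineage_cells(run)
  expect_true(validate_lineage(cells))
  div <- cells[!cells$censored & cells$generation > 0, ]
  expect_true(all(abs(div$imt - 20) < 0.5))
  ## phase order G1 -> S/G2 -> M within each divided cell
  expect_true(all(div$birth_time < div$t_enter_s &
                    div$t_enter_s < div$t_enter_m &
                    div$t_enter_m < div$division_time))
  ## limit-cycle convergence: consecutive IMTs down a lineage differ < 1%
  kids <- div[div$generation > 1, ]
  mother_imt <- cells$imt[match(kids$parent_id, cells$cell_id)]
  expect_true(all(abs(kids$imt - mother_imt) / mother_imt < 0.01))
})

test_that("population cap stops after exactly the needed divisions", {
  m <- model2_default()
  run <- run_lineage(m, noise_spec("none"), n_ancestors = 1,
                     stop = list(max_population = 16), seed = 7)
  cells <- lineage_cells(run)
  expect_equal(sum(!cells$censored), 15)
  expect_gte(sum(cells$censored), 16)
  expect_true(validate_lineage(cells))
})

test_that("daughters inherit the mother's division state verbatim", {
  m <- model2_default()
  run <- run_lineage(m, noise_spec("constant", sigma = 0.03),
                     n_ancestors = 1, stop = list(max_population = 8),
                     seed = 21, keep_trajectories = TRUE)
  cells <- lineage_cells(run)
  mothers <- cells$cell_id[!cells$censored]
  for (mo in mothers) {
    kids <- cells$cell_id[!is.na(cells$parent_id) & cells$parent_id == mo]
    if (length(kids) != 2) next
    tk <- lapply(as.character(kids), function(k) run$trajectories[[k]])
    if (any(vapply(tk, is.null, logical(1)))) next
    ## both daughters start from the identical inherited state ...
    expect_identical(tk[[1]][1, ], tk[[2]][1, ])
    ## ... which is the mother's state at division (her last recorded state
    ## is at most one thinned step earlier)
    mo_traj <- run$trajectories[[as.character(mo)]]
    expect_lt(max(abs(tk[[1]][1, ] - mo_traj[nrow(mo_traj), ])), 0.2)
    expect_equal(cells$generation[match(kids, cells$cell_id)],
                 rep(cells$generation[match(mo, cells$cell_id)] + 1L, 2))
  }
})

test_that("population bookkeeping conserves ancestors plus divisions", {
  m <- model2_default()
  run <- run_lineage(m, noise_spec("constant", sigma = 0.03),
                     n_ancestors = 3, stop = list(max_population = 48),
                     seed = 13)
  cells <- lineage_cells(run)
  for (t in seq(5, run$stop_time, length.out = 7)) {
    alive <- sum(cells$birth_time <= t &
                   (is.na(cells$division_time) | cells$division_time > t))
    divs <- sum(!is.na(cells$division_time) & cells$division_time <= t)
    expect_equal(alive, 3 + divs)
  }
})

test_that("runs are reproducible by seed and the trees stay valid", {
  m <- model2_default()
  ns <- noise_spec("constant", sigma = 0.04)
  for (seed in c(101, 202)) {
    a <- run_lineage(m, ns, n_ancestors = 2,
                     stop = list(max_population = 32), seed = seed)
    b <- run_lineage(m, ns, n_ancestors = 2,
                     stop = list(max_population = 32), seed = seed)
    expect_equal(a$cells, b$cells)
    expect_true(validate_lineage(a$cells))
  }
  c <- run_lineage(m, ns, n_ancestors = 2,
                   stop = list(max_population = 32), seed = 303)
  expect_false(isTRUE(all.equal(a$cells$imt, c$cells$imt)))
})

test_that("arrested cells are censored with a warning", {
  m <- model2_default()
  thr <- phase_thresholds(theta_S = 0.2, theta_M = 5)  # unreachable M
  expect_warning(
    run <- run_lineage(m, noise_spec("none"), thresholds = thr,
                       n_ancestors = 1, stop = list(max_time = 300),
                       seed = 1, guard_factor = 10),
    "arrested")
  expect_true(all(run$cells$censored))
})

test_that("snapshot phase counts sum to the alive population", {
  m <- model2_default()
  set.seed(1)
  run <- run_lineage(m, noise_spec("constant", sigma = 0.03),
                     n_ancestors = 10, stop = list(max_time = 30), seed = 17)
  counts <- snapshot_phase_counts(run, c(0, 10, 20, 30))
  sums <- counts |>
    dplyr::group_by(time) |>
    dplyr::summarise(total = sum(count), alive = alive[1])
  expect_equal(sums$total, sums$alive)
  expect_equal(sums$total[sums$time == 0], 10)
  expect_error(snapshot_phase_counts(run, 1e4), "beyond the run horizon")
})

test_that("seed chain stays in 31-bit range and separates runs", {
  seeds <- vapply(1:50, function(i) run_seed(1, i), integer(1))
  expect_true(all(seeds > 0 & seeds < 2^31))
  expect_equal(anyDuplicated(seeds), 0)
  expect_false(run_seed(1, 1) == run_seed(2, 1))
})
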