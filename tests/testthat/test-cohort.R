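test_that("one propagation step matches hand arithmetic on the case-study matrices", {
  expect_equal(unname(step_distribution(cs_initial, cs_comparator_tm)),
               c(0.678, 0.226, 0.088, 0.008))
  expect_equal(unname(step_distribution(cs_initial, cs_intervention_tm)),
               c(0.219, 0.289, 0.310, 0.182))
  # identity leaves any distribution unchanged
  expect_equal(step_distribution(c(0.2, 0.3, 0.5), diag(3)), c(0.2, 0.3, 0.5))
  expect_error(step_distribution(c(0.5, 0.5), diag(3)), "length 2")
})

test_that("the cohort trace reproduces repeated propagation", {
  m <- build_case_study()
  tr <- run_cohort(m, "intervention")
  occ <- attr(tr, "matrix")
  expect_equal(dim(occ), c(6, 4))
  expect_equal(unname(occ[1, ]), cs_initial)
  expect_equal(unname(round(occ[6, ], 3)), c(0.089, 0.189, 0.310, 0.412))
  expect_equal(unname(occ),
               unname(oracle_trace(cs_initial, cs_intervention_tm, 5)))
  # tidy long format agrees with the matrix
  wide <- tidyr::pivot_wider(tr[, c("cycle", "state", "occupancy")],
                             names_from = "state", values_from = "occupancy")
  expect_equal(as.matrix(wide[, -1]), occ, ignore_attr = TRUE)
  # identity transition: all rows equal the initial distribution
  ident <- generate_fixture_model(3)
  raw <- unclass(ident)
  raw$comparator$transition[] <- diag(4)
  ident <- validate_model(structure(raw, class = "ce_model"))
  occ_i <- attr(run_cohort(ident, "comparator"), "matrix")
  for (t in seq_len(nrow(occ_i))) {
    expect_equal(unname(occ_i[t, ]), unname(ident$initial))
  }
})

test_that("cohort mass is conserved over long horizons for random models", {
  for (seed in c(1, 2, 3, 11, 42)) {
    m <- generate_fixture_model(seed, n_states = 2 + seed %% 5,
                                horizon = 1000)
    occ <- attr(run_cohort(m, "intervention"), "matrix")
    expect_true(all(abs(rowSums(occ) - 1) <= 1e-9))
    expect_true(all(occ >= 0))
  }
})

test_that("trace matches a unit-level microsimulation within binomial 3-sigma", {
  m <- build_case_study()
  N <- 1e5
  for (arm in c("intervention", "comparator")) {
    exact <- attr(run_cohort(m, arm), "matrix")
    set.seed(20260921)
    sim <- oracle_microsim(cs_initial, unclass(m[[arm]]$transition), 5, N)
    tol <- 3 * sqrt(exact * (1 - exact) / N)
    expect_true(all(abs(sim - exact) <= tol + 1e-12))
  }
})

test_that("expected cycle value is the occupancy-weighted per-state value", {
  expect_equal(expected_cycle_value(c(0.3, 0.4, 0.2, 0.1), c(30, 25, 20, 15)),
               24.5)
  expect_equal(expected_cycle_value(c(0.3, 0.4, 0.2, 0.1), cs_effects), 0.71)
  expect_equal(expected_cycle_value(c(1, 0, 0, 0), c(7, 1, 2, 3)), 7)
  expect_error(expected_cycle_value(c(1, 0), c(1, 2, 3)), "differ in length")
})

test_that("accrual reproduces the case-study cumulative costs", {
  m <- build_case_study()
  acc_c <- accrue(m, "comparator")
  acc_i <- accrue(m, "intervention")
  expect_equal(acc_c$cum_cost[1], 56.45)
  expect_equal(round(acc_c$cum_cost[6], 3), 349.396)
  expect_equal(round(acc_i$cum_cost[6], 3), 750.276)
  # full agreement with the loop oracle
  orc <- oracle_accrue(cs_initial, cs_comparator_tm, 5, 30 + cs_indirect,
                       cs_effects, 0)
  expect_equal(acc_c$cum_cost, orc$cum_cost)
  expect_equal(acc_c$cum_effect, orc$cum_effect)
  ori <- oracle_accrue(cs_initial, cs_intervention_tm, 5, 20 + cs_indirect,
                       cs_effects, 500)
  expect_equal(acc_i$cum_cost, ori$cum_cost)
  # cumulative series are prefix sums of the per-cycle series
  expect_equal(acc_i$cum_cost, cumsum(acc_i$cost))
  expect_equal(acc_i$cum_effect, cumsum(acc_i$effect))
})

test_that("a zero-cost zero-effect arm accrues only its single cost", {
  m <- generate_fixture_model(5)
  raw <- unclass(m)
  raw$intervention$costs <- ce_costs(42, 0, numeric(4))
  raw$intervention$effects <- numeric(4)
  m <- validate_model(structure(raw, class = "ce_model"))
  acc <- accrue(m, "intervention")
  expect_equal(acc$cum_cost, rep(42, 6))
  expect_equal(acc$cum_effect, rep(0, 6))
})

test_that("cycle-zero accrual can be switched off, still charging the single cost", {
  m <- build_case_study()
  acc <- accrue(m, "intervention", accrue_cycle_zero = FALSE)
  expect_equal(acc$cum_cost[1], 500)
  expect_equal(acc$cum_effect[1], 0)
  orc <- oracle_accrue(cs_initial, cs_intervention_tm, 5, 20 + cs_indirect,
                       cs_effects, 500, cycle_zero = FALSE)
  expect_equal(acc$cum_cost, orc$cum_cost)
})

test_that("discounting shrinks later cycles by (1+r)^-t", {
  m <- build_case_study()
  r <- 0.03
  plain <- accrue(m, "comparator")
  disc <- accrue(m, "comparator", discount_rate = r)
  expect_equal(disc$cost, plain$cost * (1 + r)^(-(0:5)))
  expect_equal(disc$effect, plain$effect * (1 + r)^(-(0:5)))
})

test_that("accrual is linear in the per-state cost vectors", {
  base <- generate_fixture_model(9)
  split_costs <- function(m, w) {
    raw <- unclass(m)
    raw$intervention$costs <- ce_costs(w * raw$intervention$costs$single,
                                       w * raw$intervention$costs$periodic,
                                       w * raw$intervention$costs$indirect)
    validate_model(structure(raw, class = "ce_model"))
  }
  full <- accrue(base, "intervention")
  half <- accrue(split_costs(base, 0.5), "intervention")
  expect_equal(full$cum_cost, 2 * half$cum_cost)
})

test_that("an absorbing chain converges and accrues the absorbed state's effect linearly", {
  tm <- rbind(c(0.5, 0.5), c(0, 1))  # state 2 absorbing
  m <- ce_model(
    states = data.frame(label = c("U", "V")),
    intervention = ce_arm("intervention", tm, ce_costs(0, 1, c(2, 3)),
                          c(0.2, 0.8)),
    comparator = ce_arm("comparator", diag(2), ce_costs(0, 1, c(2, 3)),
                        c(0.2, 0.8)),
    initial = c(1, 0), horizon = 200)
  occ <- attr(run_cohort(m, "intervention"), "matrix")
  expect_equal(unname(occ[201, ]), c(0, 1), tolerance = 1e-12)
  acc <- accrue(m, "intervention")
  # once absorbed, each extra cycle adds exactly the absorbed state's effect
  late <- diff(acc$cum_effect[150:201])
  expect_equal(late, rep(0.8, 51), tolerance = 1e-9)
})
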