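case_incremental <- function(single = 500, cycle_zero = TRUE) {
  m <- build_case_study()
  if (single != 500) {
    m <- apply_overrides(m, list("intervention.costs.single" = single))
  }
  incremental(accrue(m, "intervention", accrue_cycle_zero = cycle_zero),
              accrue(m, "comparator", accrue_cycle_zero = cycle_zero))
}

test_that("the case-study incremental result matches the loop oracle", {
  res <- case_incremental()
  oi <- oracle_accrue(cs_initial, cs_intervention_tm, 5, 20 + cs_indirect,
                      cs_effects, 500)
  oc <- oracle_accrue(cs_initial, cs_comparator_tm, 5, 30 + cs_indirect,
                      cs_effects, 0)
  expect_equal(res$delta_cost, oi$cum_cost[6] - oc$cum_cost[6])
  expect_equal(res$delta_effect, oi$cum_effect[6] - oc$cum_effect[6])
  expect_equal(round(res$delta_cost, 1), 400.9)
  expect_equal(round(res$delta_effect, 3), 0.782)
  expect_equal(round(res$icer), 512)
  expect_equal(tidy(res)$delta_cost, oi$cum_cost - oc$cum_cost)
  g <- glance(res)
  expect_equal(g$quadrant, "NE")
  expect_equal(g$dominance, "none")
})

test_that("identical accruals give a zero point with undefined ICER on the axis", {
  m <- build_case_study()
  acc <- accrue(m, "comparator")
  res <- incremental(acc, acc)
  expect_equal(res$delta_cost, 0)
  expect_equal(res$delta_effect, 0)
  expect_true(is.na(res$icer))
  expect_equal(classify(res)$quadrant, "axis")
  expect_error(
    incremental(acc, accrue(build_case_study(horizon = 3), "comparator")),
    "horizons differ")
})

test_that("quadrant classification follows the cost-effectiveness plane signs", {
  fake <- function(dc, de) {
    structure(list(series = tibble::tibble(cycle = 0:1,
                                           delta_cost = c(0, dc),
                                           delta_effect = c(0, de)),
                   delta_cost = dc, delta_effect = de,
                   icer = if (de != 0) dc / de else NA_real_,
                   horizon = 1L),
              class = "ce_incremental")
  }
  expect_equal(classify(fake(10, 0.5)),
               list(quadrant = "NE", dominance = "none"))
  expect_equal(classify(fake(-10, 0.5)),
               list(quadrant = "SE", dominance = "intervention_dominant"))
  expect_equal(classify(fake(10, -0.5)),
               list(quadrant = "NW", dominance = "intervention_dominated"))
  expect_equal(classify(fake(-10, -0.5)),
               list(quadrant = "SW", dominance = "none"))
  # cost-saving, effect-neutral counts as dominant; the reverse as dominated
  expect_equal(classify(fake(-5, 0)),
               list(quadrant = "axis", dominance = "intervention_dominant"))
  expect_equal(classify(fake(5, 0)),
               list(quadrant = "axis", dominance = "intervention_dominated"))
  # decisions on the axes
  expect_equal(decide(fake(-5, 0), 100)$decision, "accept")
  expect_equal(decide(fake(5, 0), 100)$decision, "reject")
  expect_equal(decide(fake(0, 0.5), 100)$decision, "accept")
  expect_equal(decide(fake(0, -0.5), 100)$decision, "reject")
})

test_that("the case study is accepted at WTP 700 and rejected at WTP 400", {
  res <- case_incremental()
  d700 <- decide(res, 700)
  d400 <- decide(res, 400)
  expect_equal(d700$decision, "accept")
  expect_equal(d400$decision, "reject")
  expect_equal(d700$quadrant, "NE")
  # the bracket holds under both cycle-zero accrual conventions
  res_excl <- case_incremental(cycle_zero = FALSE)
  expect_equal(decide(res_excl, 700)$decision, "accept")
  expect_equal(decide(res_excl, 400)$decision, "reject")
  expect_true(res$icer >= 400 && res$icer <= 700)
  expect_true(res_excl$icer >= 400 && res_excl$icer <= 700)
})

test_that("net monetary benefit matches hand arithmetic and the decisions", {
  res <- case_incremental()
  expect_equal(net_monetary_benefit(res, 700),
               700 * res$delta_effect - res$delta_cost)
  expect_equal(round(net_monetary_benefit(res, 700), 1), 146.8)
  expect_equal(round(net_monetary_benefit(res, 400), 1), -87.9)
  zero <- incremental(accrue(build_case_study(), "comparator"),
                      accrue(build_case_study(), "comparator"))
  expect_equal(net_monetary_benefit(zero, 123), 0)
})

test_that("decide agrees with the sign of NMB off-axis for random models", {
  wtps <- c(0, 10, 100, 1000)
  for (seed in 1:60) {
    m <- generate_fixture_model(seed, n_states = 2 + seed %% 4)
    res <- incremental(accrue(m, "intervention"), accrue(m, "comparator"))
    cls <- classify(res)
    if (cls$quadrant == "axis") next
    for (w in wtps) {
      nmb <- net_monetary_benefit(res, w)
      expect_equal(decide(res, w)$decision,
                   if (nmb >= 0) "accept" else "reject",
                   info = sprintf("seed %d wtp %g", seed, w))
    }
  }
})

test_that("swapping the arms negates the deltas and mirrors the quadrants", {
  mirror <- c(NE = "SW", SW = "NE", SE = "NW", NW = "SE", axis = "axis")
  for (seed in 1:25) {
    m <- generate_fixture_model(seed)
    ai <- accrue(m, "intervention")
    ac <- accrue(m, "comparator")
    res <- incremental(ai, ac)
    swapped <- incremental(ac, ai)
    expect_equal(swapped$delta_cost, -res$delta_cost)
    expect_equal(swapped$delta_effect, -res$delta_effect)
    expect_equal(classify(swapped)$quadrant,
                 unname(mirror[classify(res)$quadrant]))
  }
})

test_that("scaling all costs by k scales delta cost and ICER by k and preserves the decision at k*WTP", {
  k <- 3.7
  res <- case_incremental()
  m <- build_case_study()
  scaled <- apply_overrides(m, list(
    "intervention.costs.single" = 500 * k,
    "intervention.costs.periodic" = 20 * k,
    "intervention.costs.indirect" = cs_indirect * k,
    "comparator.costs.periodic" = 30 * k,
    "comparator.costs.indirect" = cs_indirect * k))
  res_k <- incremental(accrue(scaled, "intervention"),
                       accrue(scaled, "comparator"))
  expect_equal(res_k$delta_cost, k * res$delta_cost)
  expect_equal(res_k$delta_effect, res$delta_effect)
  expect_equal(res_k$icer, k * res$icer)
  for (w in c(400, 700)) {
    expect_equal(decide(res_k, k * w)$decision, decide(res, w)$decision)
  }
})

test_that("acceptance is monotone in WTP in the north-east quadrant", {
  res <- case_incremental()
  wtps <- seq(0, 1500, by = 50)
  accepted <- vapply(wtps, function(w) decide(res, w)$decision == "accept",
                     logical(1))
  expect_true(all(diff(accepted) >= 0))
  expect_equal(min(wtps[accepted]) > res$icer - 50, TRUE)
})
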