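# Independent oracle: naive element-by-element arithmetic, no matrix
# products, kept deliberately separate from the engine's code paths.

oracle_step <- function(dist, m) {
  n <- length(dist)
  out <- numeric(n)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) out[j] <- out[j] + dist[i] * m[i, j]
  }
  out
}

oracle_trace <- function(init, m, horizon) {
  occ <- matrix(NA_real_, horizon + 1, length(init))
  occ[1, ] <- init
  d <- init
  for (t in seq_len(horizon)) {
    d <- oracle_step(d, m)
    occ[t + 1, ] <- d
  }
  occ
}

oracle_accrue <- function(init, m, horizon, state_cost, effects, single,
                          cycle_zero = TRUE) {
  occ <- oracle_trace(init, m, horizon)
  per_cost <- numeric(horizon + 1)
  per_eff <- numeric(horizon + 1)
  for (t in 0:horizon) {
    for (i in seq_along(init)) {
      per_cost[t + 1] <- per_cost[t + 1] + occ[t + 1, i] * state_cost[i]
      per_eff[t + 1] <- per_eff[t + 1] + occ[t + 1, i] * effects[i]
    }
  }
  if (!cycle_zero) {
    per_cost[1] <- 0
    per_eff[1] <- 0
  }
  per_cost[1] <- per_cost[1] + single
  list(cum_cost = cumsum(per_cost), cum_effect = cumsum(per_eff))
}

# unit-level microsimulation of the same chain (multinomial draws)
oracle_microsim <- function(init, m, horizon, N) {
  n <- length(init)
  counts <- as.vector(stats::rmultinom(1, N, init))
  occ <- matrix(0, horizon + 1, n)
  occ[1, ] <- counts / N
  for (t in seq_len(horizon)) {
    nxt <- numeric(n)
    for (i in seq_len(n)) {
      if (counts[i] > 0) {
        nxt <- nxt + as.vector(stats::rmultinom(1, counts[i], m[i, ]))
      }
    }
    counts <- nxt
    occ[t + 1, ] <- counts / N
  }
  occ
}

# case-study inputs, spelled out independently of the packaged fixture
cs_comparator_tm <- rbind(
  A = c(0.9, 0.1, 0.0, 0.0),
  B = c(0.6, 0.3, 0.1, 0.0),
  C = c(0.2, 0.4, 0.4, 0.0),
  D = c(0.0, 0.0, 0.2, 0.8))
cs_intervention_tm <- rbind(
  A = c(0.4, 0.3, 0.2, 0.1),
  B = c(0.1, 0.3, 0.4, 0.2),
  C = c(0.1, 0.2, 0.3, 0.4),
  D = c(0.0, 0.1, 0.3, 0.6))
colnames(cs_comparator_tm) <- colnames(cs_intervention_tm) <- c("A", "B", "C", "D")
cs_initial <- c(0.40, 0.50, 0.09, 0.01)
cs_effects <- c(0.6, 0.7, 0.8, 0.9)
cs_indirect <- c(30, 25, 20, 15)

build_case_study <- function(horizon = 5) {
  ce_model(
    states = data.frame(label = c("A", "B", "C", "D"),
                        exposure = c(40, 30, 20, 10)),
    intervention = ce_arm("intervention", cs_intervention_tm,
                          ce_costs(500, 20, cs_indirect), cs_effects),
    comparator = ce_arm("non-intervention", cs_comparator_tm,
                        ce_costs(0, 30, cs_indirect), cs_effects),
    initial = cs_initial, horizon = horizon,
    cycle_length = "1 year", unit_label = "neighborhood")
}
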