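#' Advance a cohort distribution by one cycle
#'
#' Left-multiplies the occupancy row vector by the transition matrix:
#' entry j of the result is the probability mass arriving in state j from
#' all origin states. The output stays on the probability simplex because
#' the matrix is row-stochastic.
#'
#' @param dist Numeric occupancy vector (proportions summing to 1).
#' @param transition Row-stochastic matrix of matching dimension.
#' @return A numeric occupancy vector of the same length.
#' @examples
#' tm <- rbind(c(0.9, 0.1), c(0.2, 0.8))
#' step_distribution(c(1, 0), tm)
#' @export
step_distribution <- function(dist, transition) {
  dist <- as.numeric(dist)
  if (length(dist) != nrow(transition)) {
    stop("distribution has length ", length(dist),
         " but the transition matrix is ", nrow(transition), "x",
         ncol(transition), call. = FALSE)
  }
  out <- as.vector(dist %*% unclass(transition))
  names(out) <- colnames(transition)
  out
}

#' Run the cohort simulation for one arm
#'
#' Propagates the model's initial distribution through `horizon` cycles of
#' the chosen arm's transition matrix, producing the cohort trace: the
#' state-occupancy distribution after 0, 1, ..., horizon cycles.
#'
#' @param model A validated `ce_model`.
#' @param arm `"intervention"` or `"comparator"`.
#' @return A tibble of class `ce_trace` in long format with columns
#'   `cycle` (0..horizon), `state` (factor in declaration order),
#'   `occupancy`, and `arm`. The `(horizon+1) x n` occupancy matrix is
#'   attached as attribute `"matrix"` (row `t+1` = distribution after `t`
#'   cycles).
#' @examples
#' run_cohort(case_study_model(), "comparator")
#' @export
run_cohort <- function(model, arm = c("intervention", "comparator")) {
  stopifnot(inherits(model, "ce_model"))
  arm <- match.arg(arm)
  a <- model[[arm]]
  n <- nrow(model$states)
  h <- model$horizon
  occ <- matrix(NA_real_, h + 1, n,
                dimnames = list(cycle = 0:h, state = model$states$label))
  occ[1, ] <- model$initial
  for (t in seq_len(h)) {
    occ[t + 1, ] <- step_distribution(occ[t, ], a$transition)
  }
  out <- tibble::as_tibble(as.data.frame.table(occ, responseName = "occupancy",
                                               stringsAsFactors = FALSE))
  out <- tibble::tibble(
    cycle = as.integer(out$cycle),
    state = factor(out$state, levels = model$states$label),
    occupancy = out$occupancy,
    arm = arm
  )
  out <- dplyr::arrange(out, .data$cycle, .data$state)
  structure(out, class = c("ce_trace", class(tibble::tibble())),
            matrix = occ, arm = arm)
}

#' Expected per-unit value of a distribution
#'
#' Dot product of a state-occupancy distribution with a per-state value
#' vector: the expected cost or effect a cohort unit accrues in one cycle
#' spent under that distribution.
#'
#' @param dist Numeric occupancy vector.
#' @param values Numeric per-state values of the same length.
#' @return A scalar.
#' @examples
#' expected_cycle_value(c(0.3, 0.4, 0.2, 0.1), c(30, 25, 20, 15))  # 24.5
#' @export
expected_cycle_value <- function(dist, values) {
  if (length(dist) != length(values)) {
    stop("distribution (", length(dist), ") and values (", length(values),
         ") differ in length", call. = FALSE)
  }
  sum(as.numeric(dist) * as.numeric(values))
}

#' Accrue expected costs and effects along a cohort trace
#'
#' For each cycle t, the per-cycle cost is the expected per-state running
#' cost ([per_state_cycle_cost()]) under the trace's distribution at t,
#' and the per-cycle effect is the expected per-state effect. Cumulative
#' series are left-to-right prefix sums, with the arm's one-off single
#' cost charged at cycle 0. By default cycle 0 accrues the initial
#' distribution's running costs and effects (`accrue_cycle_zero = TRUE`);
#' setting it `FALSE` starts accrual at cycle 1 while still charging the
#' single cost at 0. An optional discount rate r applies the factor
#' (1+r)^-t to cycle-t costs and effects.
#'
#' @param model A validated `ce_model`.
#' @param arm `"intervention"` or `"comparator"`.
#' @param trace Optional `ce_trace` computed from the same model and arm;
#'   computed on the fly when `NULL`.
#' @param discount_rate Per-cycle discount rate r >= 0 (default 0).
#' @param accrue_cycle_zero Whether cycle 0 accrues running costs/effects
#'   (default `TRUE`).
#' @return A tibble of class `ce_accrual` with columns `cycle`, `cost`,
#'   `effect` (per-cycle, discounted if r > 0; the single cost appears in
#'   `cost` at cycle 0), `cum_cost`, `cum_effect`, `arm`.
#' @examples
#' accrue(case_study_model(), "comparator")
#' @export
accrue <- function(model, arm = c("intervention", "comparator"),
                   trace = NULL, discount_rate = 0,
                   accrue_cycle_zero = TRUE) {
  stopifnot(inherits(model, "ce_model"))
  arm <- match.arg(arm)
  if (is.null(trace)) trace <- run_cohort(model, arm)
  if (!identical(attr(trace, "arm"), arm)) {
    stop("trace was computed for arm '", attr(trace, "arm"),
         "', not '", arm, "'", call. = FALSE)
  }
  occ <- attr(trace, "matrix")
  h <- model$horizon
  if (nrow(occ) != h + 1 || ncol(occ) != nrow(model$states)) {
    stop("trace dimensions do not match the model", call. = FALSE)
  }
  a <- model[[arm]]
  state_cost <- per_state_cycle_cost(a)
  cycles <- 0:h
  per_cost <- as.vector(occ %*% state_cost)
  per_eff <- as.vector(occ %*% a$effects)
  if (!accrue_cycle_zero) {
    per_cost[1] <- 0
    per_eff[1] <- 0
  }
  if (discount_rate != 0) {
    disc <- (1 + discount_rate)^(-cycles)
    per_cost <- per_cost * disc
    per_eff <- per_eff * disc
  }
  per_cost[1] <- per_cost[1] + a$costs$single
  out <- tibble::tibble(
    cycle = as.integer(cycles),
    cost = per_cost,
    effect = per_eff,
    cum_cost = cumsum(per_cost),
    cum_effect = cumsum(per_eff),
    arm = arm
  )
  structure(out, class = c("ce_accrual", class(tibble::tibble())),
            arm = arm, single_cost = a$costs$single,
            discount_rate = discount_rate,
            accrue_cycle_zero = accrue_cycle_zero)
}
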