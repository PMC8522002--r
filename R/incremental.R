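#' Incremental cost-effectiveness of intervention versus comparator
#'
#' Subtracts the comparator's cumulative costs and effects from the
#' intervention's, cycle by cycle, and forms the incremental
#' cost-effectiveness ratio (ICER) at the horizon:
#' ICER = delta_cost / delta_effect, in MU per effect unit. When the
#' incremental effect at the horizon is exactly zero the ICER is
#' undefined and reported as `NA` (never as +/-Inf); the axis rules in
#' [decide()] still yield a decision.
#'
#' @param intervention_accrual,comparator_accrual `ce_accrual` tibbles for
#'   the two arms over the same horizon.
#' @return An object of class `ce_incremental`: a list with `series` (a
#'   tibble of cumulative `delta_cost`, `delta_effect` per cycle),
#'   `delta_cost`, `delta_effect` (values at the horizon), `icer`, and
#'   `horizon`. Use [tidy()] for the series and [glance()] for the
#'   horizon summary.
#' @examples
#' m <- case_study_model()
#' incremental(accrue(m, "intervention"), accrue(m, "comparator"))
#' @export
incremental <- function(intervention_accrual, comparator_accrual) {
  stopifnot(inherits(intervention_accrual, "ce_accrual"),
            inherits(comparator_accrual, "ce_accrual"))
  if (nrow(intervention_accrual) != nrow(comparator_accrual)) {
    stop("accrual horizons differ: ", nrow(intervention_accrual) - 1,
         " vs ", nrow(comparator_accrual) - 1, call. = FALSE)
  }
  series <- tibble::tibble(
    cycle = intervention_accrual$cycle,
    delta_cost = intervention_accrual$cum_cost - comparator_accrual$cum_cost,
    delta_effect = intervention_accrual$cum_effect - comparator_accrual$cum_effect
  )
  h <- nrow(series)
  dc <- series$delta_cost[h]
  de <- series$delta_effect[h]
  structure(
    list(series = series,
         delta_cost = dc,
         delta_effect = de,
         icer = if (de != 0) dc / de else NA_real_,
         horizon = h - 1L),
    class = "ce_incremental")
}

#' Classify an incremental result on the cost-effectiveness plane
#'
#' The plane has incremental effect on the x axis and incremental cost on
#' the y axis. Quadrants: NE (more effective, more costly — the trade-off
#' region governed by willingness to pay), SE (more effective, cheaper —
#' the intervention *dominates*), NW (less effective, more costly — the
#' intervention is *dominated*), SW (less effective, cheaper — trade-off
#' again). Differences within `tol` times the series scale of zero map to
#' `"axis"`; an axis point with negative cost (cost-saving,
#' effect-neutral) is treated as dominant.
#'
#' @param res A `ce_incremental` object.
#' @param tol Relative zero tolerance (default `1e-12`).
#' @return A list with elements `quadrant` (`"NE"`, `"NW"`, `"SE"`,
#'   `"SW"`, or `"axis"`) and `dominance` (`"intervention_dominant"`,
#'   `"intervention_dominated"`, or `"none"`).
#' @export
classify <- function(res, tol = 1e-12) {
  stopifnot(inherits(res, "ce_incremental"))
  cost_scale <- max(1, abs(res$series$delta_cost))
  eff_scale <- max(1, abs(res$series$delta_effect))
  dc <- if (abs(res$delta_cost) <= tol * cost_scale) 0 else res$delta_cost
  de <- if (abs(res$delta_effect) <= tol * eff_scale) 0 else res$delta_effect
  quadrant <- if (dc == 0 || de == 0) {
    "axis"
  } else if (de > 0 && dc > 0) {
    "NE"
  } else if (de > 0 && dc < 0) {
    "SE"
  } else if (de < 0 && dc > 0) {
    "NW"
  } else {
    "SW"
  }
  dominance <- if (quadrant == "SE" || (quadrant == "axis" && dc < 0) ||
                   (quadrant == "axis" && dc == 0 && de > 0)) {
    "intervention_dominant"
  } else if (quadrant == "NW" || (quadrant == "axis" && dc > 0 && de == 0) ||
             (quadrant == "axis" && dc == 0 && de < 0)) {
    "intervention_dominated"
  } else {
    "none"
  }
  list(quadrant = quadrant, dominance = dominance)
}

#' Apply the willingness-to-pay decision rule
#'
#' The decision logic of the cost-effectiveness plane: a dominant
#' intervention (SE quadrant — cheaper and more effective) is accepted
#' regardless of WTP; a dominated one (NW) is rejected regardless of WTP.
#' In the NE quadrant the intervention is accepted iff its ICER does not
#' exceed the WTP (each effect unit is bought at or below the acceptable
#' price); in the SW quadrant iff the ICER is at least the WTP (each
#' forgone effect unit saves more than its acceptable price). On the
#' axes: effect-neutral points are accepted iff cost-saving; cost-neutral
#' points iff not effect-losing.
#'
#' @param res A `ce_incremental` object.
#' @param wtp Willingness to pay, a nonnegative scalar in MU per effect
#'   unit; defaults to the model WTP recorded on `res` if any.
#' @param tol Relative zero tolerance passed to [classify()].
#' @return A one-row tibble of class `ce_decision` with columns
#'   `delta_cost`, `delta_effect`, `icer`, `quadrant`, `dominance`,
#'   `decision` (`"accept"`/`"reject"`), `wtp`, `nmb` (net monetary
#'   benefit), and `rationale`.
#' @examples
#' m <- case_study_model()
#' res <- incremental(accrue(m, "intervention"), accrue(m, "comparator"))
#' decide(res, wtp = 700)  # accept
#' decide(res, wtp = 400)  # reject
#' @export
decide <- function(res, wtp, tol = 1e-12) {
  stopifnot(inherits(res, "ce_incremental"))
  if (length(wtp) != 1 || is.na(wtp) || wtp < 0) {
    stop("`wtp` must be a single nonnegative number", call. = FALSE)
  }
  cls <- classify(res, tol = tol)
  dc <- res$delta_cost
  de <- res$delta_effect
  icer <- res$icer
  out <- switch(
    cls$quadrant,
    SE = list("accept", "dominant: cheaper and more effective at the horizon"),
    NW = list("reject", "dominated: more costly and less effective at the horizon"),
    NE = if (icer <= wtp) {
      list("accept", sprintf("ICER %.6g <= WTP %.6g MU per effect unit", icer, wtp))
    } else {
      list("reject", sprintf("ICER %.6g > WTP %.6g MU per effect unit", icer, wtp))
    },
    SW = if (icer >= wtp) {
      list("accept", sprintf(
        "cost saved per forgone effect unit (%.6g) >= WTP %.6g", icer, wtp))
    } else {
      list("reject", sprintf(
        "cost saved per forgone effect unit (%.6g) < WTP %.6g", icer, wtp))
    },
    axis = {
      near0 <- function(x, scale) abs(x) <= tol * max(1, scale)
      de0 <- near0(de, max(abs(res$series$delta_effect)))
      if (de0) {
        if (dc <= 0) {
          list("accept", "effect-neutral and not more costly")
        } else {
          list("reject", "effect-neutral but more costly")
        }
      } else if (de >= 0) {
        list("accept", "cost-neutral and not less effective")
      } else {
        list("reject", "cost-neutral but less effective")
      }
    })
  dec <- tibble::tibble(
    delta_cost = dc,
    delta_effect = de,
    icer = icer,
    quadrant = cls$quadrant,
    dominance = cls$dominance,
    decision = out[[1]],
    wtp = as.numeric(wtp),
    nmb = net_monetary_benefit(res, wtp),
    rationale = out[[2]]
  )
  structure(dec, class = c("ce_decision", class(tibble::tibble())))
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' NMB = WTP * delta_effect - delta_cost, in MU. Off the axes,
#' NMB >= 0 is equivalent to the accept decision of [decide()] in the NE
#' and SW quadrants, and NMB is always positive under dominance (SE) and
#' negative when dominated (NW).
#'
#' @param res A `ce_incremental` object.
#' @param wtp Nonnegative willingness to pay in MU per effect unit.
#' @return A scalar in MU.
#' @export
net_monetary_benefit <- function(res, wtp) {
  stopifnot(inherits(res, "ce_incremental"))
  wtp * res$delta_effect - res$delta_cost
}

#' @export
print.ce_incremental <- function(x, ...) {
  cat("<ce_incremental> horizon ", x$horizon, " cycles\n", sep = "")
  cat("  delta cost:   ", format(x$delta_cost), " MU per unit\n", sep = "")
  cat("  delta effect: ", format(x$delta_effect), " effect units per unit\n",
      sep = "")
  cat("  ICER:         ",
      if (is.na(x$icer)) "undefined (delta effect = 0)"
      else paste0(format(x$icer), " MU per effect unit"), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-cycle incremental series of a `ce_incremental` object
#'
#' @param x A `ce_incremental` object.
#' @param ... Unused.
#' @return A tibble with columns `cycle`, `delta_cost`, `delta_effect`
#'   (cumulative, intervention minus comparator).
#' @method tidy ce_incremental
#' @export
tidy.ce_incremental <- function(x, ...) {
  x$series
}

#' One-row horizon summary of a `ce_incremental` object
#'
#' @param x A `ce_incremental` object.
#' @param ... Unused.
#' @return A one-row tibble with `delta_cost`, `delta_effect`, `icer`,
#'   `quadrant`, `dominance`, `horizon`.
#' @method glance ce_incremental
#' @export
glance.ce_incremental <- function(x, ...) {
  cls <- classify(x)
  tibble::tibble(
    delta_cost = x$delta_cost,
    delta_effect = x$delta_effect,
    icer = x$icer,
    quadrant = cls$quadrant,
    dominance = cls$dominance,
    horizon = x$horizon
  )
}

#' Run the full cost-effectiveness analysis of a model
#'
#' Convenience wrapper: simulates both arms, accrues costs and effects,
#' computes the incremental result, and (when a WTP is supplied or stored
#' on the model) applies the decision rule.
#'
#' @param model A validated `ce_model`.
#' @param wtp Willingness to pay in MU per effect unit; defaults to the
#'   model's stored `wtp`, if any.
#' @param discount_rate,accrue_cycle_zero Passed to [accrue()].
#' @return A list of class `ce_analysis` with elements `model`, `traces`
#'   (named list of `ce_trace`), `accruals` (named list of `ce_accrual`),
#'   `incremental` (`ce_incremental`), and `decision` (`ce_decision`, or
#'   `NULL` when no WTP is available).
#' @examples
#' ana <- run_analysis(case_study_model(), wtp = 700)
#' ana$decision
#' @export
run_analysis <- function(model, wtp = NULL, discount_rate = 0,
                         accrue_cycle_zero = TRUE) {
  stopifnot(inherits(model, "ce_model"))
  wtp <- wtp %||% model$wtp
  traces <- list(intervention = run_cohort(model, "intervention"),
                 comparator = run_cohort(model, "comparator"))
  accruals <- list(
    intervention = accrue(model, "intervention", traces$intervention,
                          discount_rate, accrue_cycle_zero),
    comparator = accrue(model, "comparator", traces$comparator,
                        discount_rate, accrue_cycle_zero))
  inc <- incremental(accruals$intervention, accruals$comparator)
  structure(
    list(model = model, traces = traces, accruals = accruals,
         incremental = inc,
         decision = if (!is.null(wtp)) decide(inc, wtp) else NULL),
    class = "ce_analysis")
}

#' @export
print.ce_analysis <- function(x, ...) {
  print(x$incremental)
  if (!is.null(x$decision)) {
    cat("  decision at WTP ", x$decision$wtp, ": ", x$decision$decision,
        " (", x$decision$rationale, ")\n", sep = "")
  }
  invisible(x)
}
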