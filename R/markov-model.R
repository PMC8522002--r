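#' Define the state space of a Markov cohort model
#'
#' States are the mutually exclusive conditions a cohort unit can occupy
#' (e.g. pollution bands of a neighbourhood). Their declaration order is
#' semantic: it fixes the index convention for every matrix and vector in
#' the model, and is never re-sorted.
#'
#' @param states A data frame with one row per state and columns:
#'   * `label` (character, unique): short identifier, e.g. `"A"`.
#'   * `description` (character, optional): free text.
#'   * `exposure` (numeric, optional): nonnegative exposure level attached
#'     to the state (e.g. a pollution reading in sensor units), usable by
#'     [effect_from_exposure()].
#' @return A tibble of class `ce_states` with columns `label`,
#'   `description`, `exposure`.
#' @examples
#' ce_states(data.frame(label = c("well", "ill"), exposure = c(0, 50)))
#' @export
ce_states <- function(states) {
  stopifnot(is.data.frame(states))
  if (!"label" %in% names(states)) {
    stop("`states` needs a `label` column", call. = FALSE)
  }
  out <- tibble::tibble(
    label = as.character(states$label),
    description = if ("description" %in% names(states)) {
      as.character(states$description)
    } else {
      NA_character_
    },
    exposure = if ("exposure" %in% names(states)) {
      as.numeric(states$exposure)
    } else {
      NA_real_
    }
  )
  if (nrow(out) < 2) stop("a state space needs at least 2 states", call. = FALSE)
  if (anyDuplicated(out$label)) {
    stop("state labels must be unique: ",
         paste(unique(out$label[duplicated(out$label)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.na(out$exposure) & out$exposure < 0
  if (any(bad)) {
    stop("exposure must be >= 0 (state ", paste(out$label[bad], collapse = ", "),
         ")", call. = FALSE)
  }
  class(out) <- c("ce_states", class(out))
  out
}

#' Per-cycle transition matrix for one model arm
#'
#' @param probs A numeric n x n matrix (or data frame coercible to one) of
#'   per-cycle transition probabilities; row = origin state, column =
#'   destination state. Every entry must lie in \[0, 1\] and every row must
#'   sum to 1 within `tolerance`. Rows within tolerance are renormalized
#'   exactly (divided by their sum) so downstream algebra conserves mass —
#'   this absorbs decimal round-off from CSV round-tripping.
#' @param arm_label Identifier for the arm the matrix belongs to.
#' @param state_labels Optional character vector of state labels; defaults
#'   to the matrix dimnames or `S1..Sn`.
#' @param tolerance Absolute row-sum tolerance (default `1e-9`).
#' @return A numeric matrix of class `ce_transition` with state labels as
#'   dimnames and the arm label as an attribute.
#' @examples
#' ce_transition(rbind(c(0.9, 0.1), c(0.2, 0.8)),
#'               arm_label = "comparator", state_labels = c("A", "B"))
#' @export
ce_transition <- function(probs, arm_label = "arm", state_labels = NULL,
                          tolerance = 1e-9) {
  m <- as.matrix(probs)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) {
    stop("transition matrix must be square, got ", nrow(m), "x", ncol(m),
         call. = FALSE)
  }
  if (is.null(state_labels)) {
    state_labels <- rownames(m)
    if (is.null(state_labels)) state_labels <- paste0("S", seq_len(nrow(m)))
  }
  dimnames(m) <- list(state_labels, state_labels)
  problems <- check_transition(m, tolerance)
  if (length(problems)) {
    stop("invalid transition matrix (", arm_label, "):\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  m <- m / rowSums(m)
  structure(m, class = c("ce_transition", "matrix", "array"),
            arm_label = arm_label)
}

check_transition <- function(m, tolerance = 1e-9) {
  problems <- character()
  labs <- rownames(m)
  if (anyNA(m)) problems <- c(problems, "matrix contains missing values")
  neg <- which(m < 0, arr.ind = TRUE)
  for (k in seq_len(nrow(neg))) {
    problems <- c(problems, sprintf(
      "negative probability %g at row %s, column %s",
      m[neg[k, 1], neg[k, 2]], labs[neg[k, 1]], labs[neg[k, 2]]))
  }
  over <- which(m > 1, arr.ind = TRUE)
  for (k in seq_len(nrow(over))) {
    problems <- c(problems, sprintf(
      "probability %g > 1 at row %s, column %s",
      m[over[k, 1], over[k, 2]], labs[over[k, 1]], labs[over[k, 2]]))
  }
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > tolerance)
  for (i in bad) {
    problems <- c(problems, sprintf(
      "row %s sums to %.12g, not 1", labs[i], rs[i]))
  }
  problems
}

#' Cost model for one arm
#'
#' Three cost components, all in the model's monetary unit (MU) per cohort
#' unit: a one-off `single` cost charged at intervention start (cycle 0), a
#' state-independent `periodic` service cost per cycle, and per-state
#' `indirect` consequence costs per cycle (e.g. pollution-related illness
#' care).
#'
#' @param single Nonnegative scalar, charged once at cycle 0.
#' @param periodic Nonnegative scalar per unit per cycle.
#' @param indirect Nonnegative numeric vector, one entry per state, per
#'   unit per cycle.
#' @return A list of class `ce_costs`.
#' @examples
#' ce_costs(single = 500, periodic = 20, indirect = c(30, 25, 20, 15))
#' @export
ce_costs <- function(single = 0, periodic = 0, indirect) {
  stopifnot(length(single) == 1, length(periodic) == 1,
            is.numeric(indirect), length(indirect) >= 1)
  comp <- c(single = single, periodic = periodic)
  if (anyNA(c(comp, indirect))) stop("costs contain missing values", call. = FALSE)
  if (any(comp < 0)) {
    stop("negative cost: ", paste(names(comp)[comp < 0], collapse = ", "),
         call. = FALSE)
  }
  if (any(indirect < 0)) {
    stop("negative indirect cost at state index ",
         paste(which(indirect < 0), collapse = ", "), call. = FALSE)
  }
  structure(list(single = as.numeric(single), periodic = as.numeric(periodic),
                 indirect = as.numeric(indirect)),
            class = "ce_costs")
}

#' Assemble one arm of a cost-effectiveness model
#'
#' An arm bundles the transition matrix, cost model, and per-state effect
#' vector for one of the two compared situations (with or without the
#' intervention). Effects are per-cycle values in a declared effect unit
#' (here a dimensionless "usefulness"); they may differ between arms even
#' when states are shared.
#'
#' @param label Arm identifier, e.g. `"intervention"`.
#' @param transition A `ce_transition` matrix (or plain matrix, coerced).
#' @param costs A `ce_costs` object.
#' @param effects Numeric vector of per-state per-cycle effects (finite).
#' @return A list of class `ce_arm`.
#' @export
ce_arm <- function(label, transition, costs, effects) {
  if (!inherits(transition, "ce_transition")) {
    transition <- ce_transition(transition, arm_label = label)
  }
  if (!inherits(costs, "ce_costs")) {
    costs <- ce_costs(single = costs$single %||% 0,
                      periodic = costs$periodic %||% 0,
                      indirect = costs$indirect)
  }
  effects <- as.numeric(effects)
  if (any(!is.finite(effects))) stop("effects must be finite", call. = FALSE)
  structure(list(label = label, transition = transition, costs = costs,
                 effects = effects),
            class = "ce_arm")
}

#' Assemble a two-arm Markov cohort cost-effectiveness model
#'
#' The central model object: a shared state space, an intervention arm and
#' a comparator (non-intervention) arm, an initial cohort distribution,
#' and the simulation frame (cycle length and horizon). Costs and effects
#' are modelled per cohort unit (e.g. per neighbourhood) per cycle;
#' population scaling is a reporting-time multiplier, keeping the engine
#' scale-free.
#'
#' @param states A `ce_states` tibble (or data frame coerced by
#'   [ce_states()]).
#' @param intervention,comparator `ce_arm` objects of matching dimension.
#' @param initial Numeric vector of initial state-occupancy proportions
#'   (entries in \[0, 1\], summing to 1 within `1e-9`; renormalized exactly).
#' @param horizon Positive integer number of cycles to simulate.
#' @param cycle_length Human-readable cycle duration label (default
#'   `"1 year"`); informational, the engine works in cycles.
#' @param unit_label What one cohort member is (default `"unit"`).
#' @param wtp Optional default willingness-to-pay threshold in MU per
#'   effect unit, carried as model metadata.
#' @return A list of class `ce_model`, validated by [validate_model()].
#' @seealso [case_study_model()] for a complete worked example.
#' @export
ce_model <- function(states, intervention, comparator, initial, horizon,
                     cycle_length = "1 year", unit_label = "unit",
                     wtp = NULL) {
  if (!inherits(states, "ce_states")) states <- ce_states(states)
  model <- structure(
    list(states = states,
         intervention = intervention,
         comparator = comparator,
         initial = as.numeric(initial),
         horizon = horizon,
         cycle_length = cycle_length,
         unit_label = unit_label,
         wtp = if (is.null(wtp)) NULL else as.numeric(wtp)),
    class = "ce_model")
  validate_model(model)
}

#' Validate a Markov cohort cost-effectiveness model
#'
#' Checks every structural invariant and reports *all* violations at once,
#' not just the first: square row-stochastic transition matrices (each row
#' sum within `tolerance` of 1, named in the error if not), entries in
#' \[0, 1\], nonnegative costs, finite effects, an initial distribution on
#' the probability simplex, consistent dimensions, and a horizon of at
#' least 1. Rows and the initial distribution that pass within tolerance
#' are renormalized exactly so cohort mass is conserved bit-for-bit
#' downstream.
#'
#' @param model A `ce_model` object.
#' @param tolerance Absolute tolerance for simplex checks (default `1e-9`).
#' @return The validated (possibly renormalized) model, invisibly
#'   identical in structure to the input.
#' @export
validate_model <- function(model, tolerance = 1e-9) {
  stopifnot(inherits(model, "ce_model"))
  problems <- character()
  n <- nrow(model$states)
  labs <- model$states$label

  for (arm_name in c("intervention", "comparator")) {
    arm <- model[[arm_name]]
    if (!inherits(arm, "ce_arm")) {
      problems <- c(problems, paste0(arm_name, " is not a ce_arm"))
      next
    }
    tm <- arm$transition
    if (nrow(tm) != n) {
      problems <- c(problems, sprintf(
        "%s transition matrix is %dx%d but there are %d states",
        arm_name, nrow(tm), ncol(tm), n))
    } else {
      tm_problems <- check_transition(tm, tolerance)
      if (length(tm_problems)) {
        problems <- c(problems, paste0(arm_name, ": ", tm_problems))
      }
    }
    if (length(arm$costs$indirect) != n) {
      problems <- c(problems, sprintf(
        "%s indirect costs have length %d, expected %d",
        arm_name, length(arm$costs$indirect), n))
    }
    if (any(c(arm$costs$single, arm$costs$periodic, arm$costs$indirect) < 0)) {
      problems <- c(problems, paste0(arm_name, ": negative cost component"))
    }
    if (length(arm$effects) != n) {
      problems <- c(problems, sprintf(
        "%s effects have length %d, expected %d",
        arm_name, length(arm$effects), n))
    } else if (any(!is.finite(arm$effects))) {
      problems <- c(problems, paste0(arm_name, ": non-finite effect"))
    }
  }

  init <- model$initial
  if (length(init) != n) {
    problems <- c(problems, sprintf(
      "initial distribution has length %d, expected %d", length(init), n))
  } else {
    if (any(init < 0) || any(init > 1)) {
      problems <- c(problems, "initial distribution has entries outside [0, 1]")
    }
    s <- sum(init)
    if (abs(s - 1) > tolerance) {
      problems <- c(problems, sprintf(
        "initial distribution sums to %.12g, not 1", s))
    }
  }

  h <- model$horizon
  if (length(h) != 1 || is.na(h) || h < 1 || h != round(h)) {
    problems <- c(problems, "horizon must be a positive integer")
  }
  bad_exp <- !is.na(model$states$exposure) & model$states$exposure < 0
  if (any(bad_exp)) {
    problems <- c(problems, paste0("negative exposure at state ",
                                   paste(labs[bad_exp], collapse = ", ")))
  }

  if (length(problems)) {
    stop("model validation failed:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }

  # exact renormalization within tolerance
  for (arm_name in c("intervention", "comparator")) {
    tm <- model[[arm_name]]$transition
    tm[] <- tm / rowSums(tm)
    dimnames(tm) <- list(labs, labs)
    model[[arm_name]]$transition <- tm
  }
  model$initial <- init / sum(init)
  names(model$initial) <- labs
  model$horizon <- as.integer(h)
  model
}

#' Per-state running cost of an arm
#'
#' The cost a unit in each state accrues per cycle: the arm's periodic
#' (state-independent) cost plus the state's indirect cost. The single
#' one-off cost is *not* included here — it is charged once at accrual
#' time, in cycle 0.
#'
#' @param arm A `ce_arm` object.
#' @return A named numeric vector, MU per unit per cycle, one entry per
#'   state.
#' @examples
#' arm <- ce_arm("intervention",
#'               transition = diag(4),
#'               costs = ce_costs(500, 20, c(30, 25, 20, 15)),
#'               effects = c(0.6, 0.7, 0.8, 0.9))
#' per_state_cycle_cost(arm)  # 50 45 40 35
#' @export
per_state_cycle_cost <- function(arm) {
  stopifnot(inherits(arm, "ce_arm"))
  v <- arm$costs$periodic + arm$costs$indirect
  names(v) <- rownames(arm$transition)
  v
}

#' @export
print.ce_model <- function(x, ...) {
  n <- nrow(x$states)
  cat("<ce_model> ", n, " states (", paste(x$states$label, collapse = ", "),
      "), horizon ", x$horizon, " cycles of ", x$cycle_length,
      ", unit: ", x$unit_label, "\n", sep = "")
  cat("  intervention: single ", x$intervention$costs$single,
      " MU, periodic ", x$intervention$costs$periodic, " MU/cycle\n", sep = "")
  cat("  comparator:   single ", x$comparator$costs$single,
      " MU, periodic ", x$comparator$costs$periodic, " MU/cycle\n", sep = "")
  cat("  initial: ", paste(signif(x$initial, 4), collapse = " "), "\n", sep = "")
  if (!is.null(x$wtp)) cat("  default WTP: ", x$wtp, " MU per effect unit\n", sep = "")
  invisible(x)
}
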