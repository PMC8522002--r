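#' Estimate transition probabilities from a count table
#'
#' Maximum-likelihood (row-proportion) estimation: the probability of
#' moving from state i to state j over one cycle is the observed count
#' divided by the row total. Zero counts give exact zero probabilities —
#' structural zeros in the data stay structural. For sparse tables an
#' optional add-alpha (Laplace) smoothing is available; it is off by
#' default so printed count tables reproduce their printed probabilities
#' exactly.
#'
#' @param counts An n x n matrix or data frame of nonnegative integer
#'   counts; `counts[i, j]` = units observed moving from state i to state
#'   j over one cycle. Row/column names are taken as state labels.
#' @param arm_label Label for the resulting transition matrix.
#' @param smooth Add-alpha smoothing constant (default 0 = none).
#' @return A `ce_transition` matrix whose rows sum to 1.
#' @examples
#' counts <- rbind(c(45, 5), c(30, 15))
#' estimate_transitions(counts)
#' @export
estimate_transitions <- function(counts, arm_label = "estimated",
                                 smooth = 0) {
  m <- as.matrix(counts)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) {
    stop("count table must be square, got ", nrow(m), "x", ncol(m),
         call. = FALSE)
  }
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("S", seq_len(nrow(m)))
  if (anyNA(m) || any(m < 0)) {
    stop("counts must be nonnegative and complete", call. = FALSE)
  }
  if (any(m != round(m))) {
    stop("counts must be integers", call. = FALSE)
  }
  stopifnot(length(smooth) == 1, smooth >= 0)
  m <- m + smooth
  rs <- rowSums(m)
  zero <- rs == 0
  if (any(zero)) {
    stop("no observations for state ", paste(labs[zero], collapse = ", "),
         ": cannot estimate its transition row", call. = FALSE)
  }
  ce_transition(m / rs, arm_label = arm_label, state_labels = labs)
}

#' Map an exposure level to a per-cycle effect
#'
#' The case study's usefulness mapping: a state whose exposure (pollution)
#' level is P contributes an effect of (100 - P)/100 per cycle — less
#' pollution is more useful to society, on a 0-1 scale. This is one
#' pluggable mapping among any the user may define; the engine itself
#' accepts arbitrary per-state effect vectors.
#'
#' @param exposure Numeric vector of exposure levels, each in \[0, 100\].
#' @return Effects in \[0, 1\], strictly decreasing in exposure.
#' @examples
#' effect_from_exposure(c(40, 30, 20, 10))  # 0.6 0.7 0.8 0.9
#' @export
effect_from_exposure <- function(exposure) {
  exposure <- as.numeric(exposure)
  bad <- is.na(exposure) | exposure < 0 | exposure > 100
  if (any(bad)) {
    stop("exposure must lie in [0, 100]; got ",
         paste(exposure[bad], collapse = ", "), call. = FALSE)
  }
  (100 - exposure) / 100
}

#' Compose per-state running costs from components
#'
#' Elementwise sum of a state-independent periodic cost and per-state
#' indirect costs: the total cost a unit in each state accrues per cycle.
#'
#' @param periodic Nonnegative scalar, MU per unit per cycle.
#' @param indirect Nonnegative per-state vector, MU per unit per cycle.
#' @return A numeric vector of the same length as `indirect`.
#' @examples
#' compose_state_costs(20, c(30, 25, 20, 15))  # 50 45 40 35
#' @export
compose_state_costs <- function(periodic, indirect) {
  stopifnot(length(periodic) == 1, periodic >= 0,
            is.numeric(indirect), all(indirect >= 0))
  periodic + indirect
}
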