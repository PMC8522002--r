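#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cohort trace
#'
#' State occupancy over cycles for one arm, one line per state.
#'
#' @param object A `ce_trace` tibble from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ce_trace
#' @export
autoplot.ce_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$cycle, .data$occupancy,
                                       colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "cycle", y = "occupancy proportion",
                  colour = "state",
                  title = paste("Cohort trace:", attr(object, "arm"))) +
    ggplot2::theme_minimal()
}

#' Plot an accrual series
#'
#' Cumulative cost and cumulative effect over cycles, facetted.
#'
#' @param object A `ce_accrual` tibble from [accrue()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ce_accrual
#' @export
autoplot.ce_accrual <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("cycle", "cum_cost", "cum_effect")],
    cols = c("cum_cost", "cum_effect"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "cycle", y = NULL,
                  title = paste("Accrual:", attr(object, "arm"))) +
    ggplot2::theme_minimal()
}

#' Plot incremental series
#'
#' Cumulative incremental cost and effect over cycles.
#'
#' @param object A `ce_incremental` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ce_incremental
#' @export
autoplot.ce_incremental <- function(object, ...) {
  long <- tidyr::pivot_longer(object$series, cols = c("delta_cost", "delta_effect"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "cycle", y = "intervention - comparator (cumulative)") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane
#'
#' Plots incremental results as points at (delta effect, delta cost) with
#' the quadrant axes and, for each WTP, the threshold line through the
#' origin with slope WTP. Points below a WTP line in the east half-plane
#' are acceptable at that threshold; the south-east quadrant (cheaper,
#' more effective) is dominant regardless of WTP.
#'
#' @param x A `ce_incremental` object, a `ce_decision` row, or a scenario
#'   report tibble with `delta_effect` and `delta_cost` columns (as from
#'   [run_scenarios()] or [sweep_parameter()]).
#' @param wtp Numeric vector of WTP thresholds to draw (MU per effect
#'   unit); defaults to the `wtp` column when present.
#' @return A ggplot.
#' @examples
#' ana <- run_analysis(case_study_model())
#' plot_ce_plane(ana$incremental, wtp = c(400, 700))
#' @export
plot_ce_plane <- function(x, wtp = NULL) {
  if (inherits(x, "ce_incremental")) {
    pts <- tibble::tibble(label = "result", delta_effect = x$delta_effect,
                          delta_cost = x$delta_cost)
  } else if (is.data.frame(x)) {
    pts <- tibble::tibble(
      label = if ("scenario" %in% names(x)) x$scenario else
        as.character(seq_len(nrow(x))),
      delta_effect = x$delta_effect,
      delta_cost = x$delta_cost)
    if (is.null(wtp) && "wtp" %in% names(x)) {
      wtp <- unique(stats::na.omit(x$wtp))
    }
  } else {
    stop("cannot plot object of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$delta_effect, .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40")
  for (w in wtp) {
    p <- p + ggplot2::geom_abline(slope = w, intercept = 0, linetype = 2,
                                  colour = "steelblue")
  }
  p +
    ggplot2::geom_point(size = 2, colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "incremental effect (effect units per unit)",
                  y = "incremental cost (MU per unit)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
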