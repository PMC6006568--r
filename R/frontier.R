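#' Incremental cost-effectiveness frontier
#'
#' Orders strategies by expected cost, removes strictly dominated
#' strategies (weakly less effective than a cheaper or equally costly
#' alternative), removes extendedly dominated strategies (those whose
#' incremental cost-effectiveness ratio exceeds that of the next, more
#' effective option, so a mix of their neighbours is more efficient), and
#' computes the ICER \eqn{\Delta C / \Delta E} of each remaining strategy
#' against the one directly preceding it on the frontier.
#'
#' @param expectations A data frame with columns `strategy`,
#'   `expected_cost` and `expected_effect` (or `cost` / `effect`); one row
#'   per strategy. A `cea_expectations` object may be passed together with
#'   `scale` to select one outcome scale.
#' @param scale Optional scale filter when `expectations` has a `scale`
#'   column.
#' @return A tibble of class `cea_frontier`, ordered by expected cost:
#'   `strategy`, `cost`, `effect`, `status` (`"on-frontier"`,
#'   `"dominated"`, `"extendedly-dominated"`), `comparator`, `delta_cost`,
#'   `delta_effect`, `icer`. ICERs along the frontier are non-decreasing
#'   in effectiveness; the cheapest frontier strategy has no comparator.
#' @examples
#' x <- data.frame(strategy = c("control", "mi", "mi_pst"),
#'                 cost = c(11.44, 15.57, 33.48),
#'                 effect = c(0.88, 0.92, 1.06))
#' icer_frontier(x)
#' @export
icer_frontier <- function(expectations, scale = NULL) {
  x <- tibble::as_tibble(expectations)
  if (!is.null(scale) && "scale" %in% names(x)) {
    x <- x[x$scale == scale, ]
  }
  if ("expected_cost" %in% names(x)) x$cost <- x$expected_cost
  if ("expected_effect" %in% names(x)) x$effect <- x$expected_effect
  if (nrow(x) < 2) {
    abort("Need at least two strategies to compare.",
          class = "bicea_frontier_error")
  }
  if (anyDuplicated(x$strategy)) {
    abort("Duplicate strategy names.", class = "bicea_frontier_error")
  }
  x <- x[order(x$cost, -x$effect), c("strategy", "cost", "effect")]
  x$status <- "on-frontier"

  # Strict dominance: some other strategy is no costlier and no less
  # effective, and better on at least one margin.
  for (i in seq_len(nrow(x))) {
    others <- x[-i, ]
    dominated <- any(
      others$cost <= x$cost[i] & others$effect >= x$effect[i] &
        (others$cost < x$cost[i] | others$effect > x$effect[i]))
    if (dominated) x$status[i] <- "dominated"
  }

  # Extended dominance: drop frontier members until pairwise ICERs are
  # non-decreasing in effectiveness.
  repeat {
    idx <- which(x$status == "on-frontier")
    if (length(idx) < 3) break
    eff <- x$effect[idx]
    cost <- x$cost[idx]
    icers <- diff(cost) / diff(eff)
    bad <- which(diff(icers) < 0)
    if (!length(bad)) break
    # the middle strategy of the first offending triple leaves the frontier
    x$status[idx[bad[1] + 1]] <- "extendedly-dominated"
  }

  idx <- which(x$status == "on-frontier")
  x$comparator <- NA_character_
  x$delta_cost <- NA_real_
  x$delta_effect <- NA_real_
  x$icer <- NA_real_
  if (length(idx) >= 2) {
    for (k in 2:length(idx)) {
      i <- idx[k]; j <- idx[k - 1]
      x$comparator[i] <- x$strategy[j]
      x$delta_cost[i] <- x$cost[i] - x$cost[j]
      x$delta_effect[i] <- x$effect[i] - x$effect[j]
      x$icer[i] <- if (x$delta_effect[i] == 0) NA_real_ else
        x$delta_cost[i] / x$delta_effect[i]
    }
  }
  class(x) <- c("cea_frontier", class(x))
  x
}

#' @export
print.cea_frontier <- function(x, ...) {
  cat("<cea_frontier> strategies ordered by expected cost\n")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @rdname icer_frontier
#' @param x A `cea_frontier` object.
#' @param ... Unused.
#' @export
tidy.cea_frontier <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname icer_frontier
#' @export
glance.cea_frontier <- function(x, ...) {
  on <- x[x$status == "on-frontier", ]
  tibble::tibble(
    n_strategies = nrow(x),
    n_on_frontier = nrow(on),
    n_dominated = sum(x$status == "dominated"),
    n_extendedly_dominated = sum(x$status == "extendedly-dominated"),
    max_icer = suppressWarnings(max(x$icer, na.rm = TRUE))
  )
}

#' Cost-effectiveness plane for a frontier
#'
#' Plots each strategy on the (effect, cost) plane, draws the efficient
#' frontier, and labels dominance status.
#'
#' @param object A `cea_frontier`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_frontier <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  on <- df[df$status == "on-frontier", ]
  on <- on[order(on$effect), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$cost)) +
    ggplot2::geom_line(data = on, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$status), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$strategy),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "Expected effect per screened patient",
                  y = "Expected cost per screened patient (US$)",
                  shape = "Status") +
    ggplot2::theme_minimal()
}
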