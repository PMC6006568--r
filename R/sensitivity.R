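#' Rescale fixed cost pools for a different level of excess capacity
#'
#' The fixed cost base (counsellor salaries, supplies, capital) is spread
#' over whatever patient contact actually happens; if counsellors are
#' busier (less excess capacity) each patient carries a smaller slice.
#' This rescales the fixed portion of the time-shared pools by
#' \eqn{(1 - e_0) / (1 - e)} where \eqn{e_0} is the base excess capacity
#' and \eqn{e} the scenario target. Variable and directly allocated items
#' are unchanged per patient, and total fixed spend is conserved — only
#' its per-patient apportionment changes.
#'
#' @param pools A `cea_cost_pools` object (see [build_cost_pools()]).
#' @param allocation The `cea_time_allocation` the pools were built with.
#' @param capacity Capacity parameters: a list with `available_hours` (or
#'   the output of [capacity_utilization()]).
#' @param excess_target Scenario excess capacity, a fraction in [0, 1).
#'   `excess_target = 1` would mean no throughput at all and is rejected.
#' @return The pools with the fixed share of each time-shared component
#'   rescaled; attribute `capacity_factor` records the multiplier.
#' @export
apply_capacity_scenario <- function(pools, allocation, capacity,
                                    excess_target) {
  if (!is.finite(excess_target) || excess_target < 0 || excess_target >= 1) {
    abort("`excess_target` must be in [0, 1); 1 means zero throughput.",
          class = "bicea_parameter_error")
  }
  util <- if (is.data.frame(capacity) && "excess_capacity" %in%
                names(capacity)) {
    capacity
  } else {
    capacity_utilization(allocation, capacity$available_hours)
  }
  factor <- (1 - util$excess_capacity) / (1 - excess_target)
  fixed_rate <- attr(pools, "fixed_rate_per_minute")
  fixed_c <- fixed_rate * pools$time_shared /
    attr(pools, "rate_per_minute")  # fixed slice of each time-shared pool
  pools$time_shared <- pools$time_shared - fixed_c + fixed_c * factor
  pools$total <- pools$time_shared + pools$direct
  attr(pools, "grand_total") <- sum(pools$total)
  attr(pools, "time_shared_fixed") <-
    attr(pools, "time_shared_fixed") * factor
  attr(pools, "time_shared_total") <-
    attr(pools, "time_shared_variable") + attr(pools, "time_shared_fixed")
  attr(pools, "rate_per_minute") <- attr(pools, "time_shared_total") /
    attr(allocation, "grand_total_minutes")
  attr(pools, "fixed_rate_per_minute") <- fixed_rate * factor
  attr(pools, "capacity_factor") <- factor
  pools
}

#' Evaluate one sensitivity scenario
#'
#' Re-derives the whole model — patient flow, counsellor time allocation,
#' cost pools, decision trees and rollback — under modified parameters,
#' and reports each intervention against the control strategy, the
#' convention of the one-way analyses. Throughput changes (positivity,
#' acceptance, completion) scale the cohort counts from the base counts,
#' keep the fixed cost base constant (so per-patient fixed costs dilute as
#' counsellors get busier) and hold variable costs constant per patient.
#' Capacity changes rescale fixed pools via [apply_capacity_scenario()]
#' without touching flow.
#'
#' @param config A `cea_config`.
#' @param pos_mult Multiplier on the base screening-positivity rate.
#' @param accept_mult Multiplier on the base acceptance rate.
#' @param accept_target Absolute acceptance probability overriding
#'   `accept_mult` (e.g. `1` for the universal-acceptance scenario).
#' @param completion If `TRUE`, every MI-PST participant attends all four
#'   PST sessions.
#' @param excess_target Absolute excess-capacity target in [0, 1), or
#'   `NULL` to leave capacity at base.
#' @param label Scenario label carried into the result.
#' @param flow_mode Flow convention; defaults to the config's.
#' @return A tibble of class `cea_scenario`: one row per strategy and
#'   scale with `scenario`, `strategy`, `scale`, `expected_cost`,
#'   `expected_effect`, `delta_cost`, `delta_effect`, `icer` (all versus
#'   control) and `cost_per_participant` (average cost per enrolled
#'   participant in that arm, including screening and patient costs).
#' @examples
#' base <- run_scenario(strive_config(), label = "base")
#' low_pos <- run_scenario(strive_config(), pos_mult = 0.75)
#' @export
run_scenario <- function(config, pos_mult = 1, accept_mult = 1,
                         accept_target = NULL, completion = FALSE,
                         excess_target = NULL, label = "scenario",
                         flow_mode = NULL) {
  flow_mode <- flow_mode %||% config$flow_mode
  if (!is.finite(pos_mult) || pos_mult < 0 ||
      (!is.null(accept_target) &&
         (accept_target < 0 || accept_target > 1))) {
    abort("Scenario multipliers must be non-negative and targets in [0, 1].",
          class = "bicea_parameter_error")
  }
  counts <- config$counts
  flow <- flow_proportions(counts)

  # Base cost structure: fixed spend, variable spend, per-minute rates.
  base_alloc <- compute_time_allocation(config$sessions)
  base_pools <- build_cost_pools(config$ledger, base_alloc, counts)
  base_minutes <- attr(base_alloc, "grand_total_minutes")
  fixed_total <- attr(base_pools, "time_shared_fixed")
  variable_total <- attr(base_pools, "time_shared_variable")

  # Scaled cohort counts (continuous; the model is an expectation).
  p_pos_base <- flow_value(flow, "p_positive", flow_mode)
  p_acc_base <- flow_value(flow, "p_accept", flow_mode)
  p_pos <- min(1, p_pos_base * pos_mult)
  if (p_pos_base * pos_mult > 1) {
    warn("Positivity multiplier pushes the rate above 1; clipped.")
  }
  p_acc <- if (!is.null(accept_target)) accept_target else
    min(1, p_acc_base * accept_mult)
  if (is.null(accept_target) && p_acc_base * accept_mult > 1) {
    warn("Acceptance multiplier pushes the rate above 1; clipped.")
  }
  eff_pos_mult <- p_pos / p_pos_base
  eff_acc_mult <- p_acc / p_acc_base
  new_counts <- counts
  new_counts$positive <- counts$positive * eff_pos_mult
  new_counts$accepted <- counts$accepted * eff_pos_mult * eff_acc_mult
  arm_ratio <- new_counts$accepted / counts$accepted
  for (a in .strategies) {
    new_counts[[paste0("n_", a)]] <- counts[[paste0("n_", a)]] * arm_ratio
  }
  attendance <- if (completion) {
    rep(new_counts$n_mi_pst, 5)
  } else {
    config$pst_attendance * arm_ratio
  }

  # Scenario session profile and time allocation.
  sessions <- config$sessions
  sessions$n_sessions <- dplyr::case_when(
    sessions$component == "screening" ~ counts$screened,
    sessions$component == "mi" ~ new_counts$n_mi,
    sessions$session_type == "mi" ~ attendance[1],
    TRUE ~ attendance[match(sessions$session_type,
                            paste0("pst", 1:4)) + 1]
  )
  alloc <- compute_time_allocation(sessions)
  minutes_new <- attr(alloc, "grand_total_minutes")

  # Pools: fixed spend constant, variable spend scales with throughput.
  variable_new <- variable_total * (minutes_new / base_minutes)
  shared_new <- fixed_total + variable_new
  pools <- build_cost_pools(config$ledger, alloc, new_counts)
  pools$time_shared <- shared_new * alloc$share[
    match(pools$component, alloc$component)]
  pools$time_shared[is.na(pools$time_shared)] <- 0
  pools$total <- pools$time_shared + pools$direct
  attr(pools, "time_shared_total") <- shared_new
  attr(pools, "time_shared_fixed") <- fixed_total
  attr(pools, "time_shared_variable") <- variable_new
  attr(pools, "rate_per_minute") <- shared_new / minutes_new
  attr(pools, "fixed_rate_per_minute") <- fixed_total / minutes_new
  attr(pools, "grand_total") <- sum(pools$total)

  if (!is.null(excess_target)) {
    pools <- apply_capacity_scenario(pools, alloc, config$capacity,
                                     excess_target)
  }

  costing <- costing_parameters(
    utils::modifyList(config, list(counts = new_counts)), alloc, pools)
  tree_flow <- list(p_positive = p_pos, p_accept = p_acc)
  trees <- purrr::map(
    setNames(.strategies, .strategies),
    function(s) build_strategy_tree(
      s, tree_flow, costing, config$effects,
      attendance = attendance, flow_mode = flow_mode))
  expectations <- purrr::map(trees, rollback) |> dplyr::bind_rows()

  per_participant <- average_cost_per_participant(
    pools, new_counts,
    patient_cost_per_course = scenario_patient_course_cost(
      config, attendance))

  ctrl <- expectations[expectations$strategy == "control", ]
  out <- expectations |>
    dplyr::left_join(
      ctrl |> dplyr::select("scale", control_cost = "expected_cost",
                            control_effect = "expected_effect"),
      by = "scale") |>
    dplyr::mutate(
      scenario = label,
      delta_cost = .data$expected_cost - .data$control_cost,
      delta_effect = .data$expected_effect - .data$control_effect,
      icer = ifelse(.data$delta_effect == 0, NA_real_,
                    .data$delta_cost / .data$delta_effect),
      cost_per_participant = per_participant$total[
        match(.data$strategy, per_participant$arm)]) |>
    dplyr::select("scenario", "strategy", "scale", "expected_cost",
                  "expected_effect", "delta_cost", "delta_effect", "icer",
                  "cost_per_participant")
  attr(out, "pools") <- pools
  attr(out, "allocation") <- alloc
  attr(out, "counts") <- new_counts
  class(out) <- c("cea_scenario", class(out))
  out
}

scenario_patient_course_cost <- function(config, attendance) {
  if (attendance[1] <= 0) return(0)
  (config$patient_costs$mean_cost_per_visit %||% 0) *
    sum(attendance[-1]) / attendance[1]
}

#' One-way sensitivity series over a parameter grid
#'
#' Evaluates [run_scenario()] over a grid of relative multipliers for one
#' parameter and stacks the results, base case included, in grid order —
#' ready for tornado or line plotting. Grid points that are infeasible
#' (an excess-capacity multiplier that implies excess \eqn{\ge} 1, i.e.
#' no throughput) are returned as rows of `NA` with a warning.
#'
#' @param config A `cea_config`.
#' @param parameter `"p_positive"`, `"p_accept"` or `"excess_capacity"`.
#' @param grid Relative multipliers on the base value (default
#'   `c(0.75, 1, 1.25)`, the conventional quarter swing each way).
#' @return A `cea_scenario` tibble with an extra `multiplier` column.
#' @export
one_way_series <- function(config, parameter = c("p_positive", "p_accept",
                                                 "excess_capacity"),
                           grid = c(0.75, 1, 1.25)) {
  parameter <- match.arg(parameter)
  if (!length(grid)) {
    abort("`grid` must be non-empty.", class = "bicea_parameter_error")
  }
  base_excess <- base_excess_capacity(config)
  purrr::map(grid, function(m) {
    label <- sprintf("%s x %.2f", parameter, m)
    res <- switch(parameter,
      p_positive = run_scenario(config, pos_mult = m, label = label),
      p_accept = run_scenario(config, accept_mult = m, label = label),
      excess_capacity = {
        target <- base_excess * m
        if (target >= 1) {
          warn(sprintf(
            "excess capacity %.3f is infeasible (>= 1); returning NA.",
            target))
          NULL
        } else {
          run_scenario(config, excess_target = target, label = label)
        }
      })
    if (is.null(res)) {
      res <- tidyr::expand_grid(strategy = .strategies, scale = .scales) |>
        dplyr::mutate(scenario = label, expected_cost = NA_real_,
                      expected_effect = NA_real_, delta_cost = NA_real_,
                      delta_effect = NA_real_, icer = NA_real_,
                      cost_per_participant = NA_real_) |>
        dplyr::relocate("scenario")
    }
    dplyr::mutate(res, multiplier = m)
  }) |>
    dplyr::bind_rows() |>
    structure(class = c("cea_scenario", class(tibble::tibble())))
}

base_excess_capacity <- function(config) {
  alloc <- compute_time_allocation(config$sessions)
  capacity_utilization(alloc, config$capacity$available_hours)$excess_capacity
}

#' The standard scenario suite
#'
#' Runs the full set of one-way and extreme scenarios: the base case,
#' screening positivity and acceptance swung a quarter down and up,
#' universal acceptance with full PST completion, excess capacity reduced
#' by a quarter, and the zero-excess-capacity extreme. The upward
#' excess-capacity swing is omitted because it implies excess \eqn{\ge} 1
#' (no throughput at all).
#'
#' @param config A `cea_config`.
#' @return A `cea_scenario` tibble stacking all scenarios.
#' @export
sensitivity_suite <- function(config) {
  base_excess <- base_excess_capacity(config)
  dplyr::bind_rows(
    run_scenario(config, label = "base"),
    run_scenario(config, pos_mult = 0.75, label = "positivity -25%"),
    run_scenario(config, pos_mult = 1.25, label = "positivity +25%"),
    run_scenario(config, accept_mult = 0.75, label = "acceptance -25%"),
    run_scenario(config, accept_mult = 1.25, label = "acceptance +25%"),
    run_scenario(config, accept_target = 1, completion = TRUE,
                 label = "acceptance 100% + full completion"),
    run_scenario(config, excess_target = base_excess * 0.75,
                 label = "excess capacity -25%"),
    run_scenario(config, excess_target = 0, label = "zero excess capacity")
  ) |>
    structure(class = c("cea_scenario", class(tibble::tibble())))
}

#' Tornado-style plot of a scenario table
#'
#' Incremental cost and incremental effect of each intervention versus
#' control across scenarios.
#'
#' @param object A `cea_scenario` tibble.
#' @param scale Outcome scale to display (default `"assist"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_scenario <- function(object, scale = "assist", ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$scale == scale & df$strategy != "control", ]
  long <- tidyr::pivot_longer(
    df, cols = c("delta_cost", "delta_effect", "icer"),
    names_to = "measure", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$value, y = .data$scenario,
                               fill = .data$strategy)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~measure, scales = "free_x") +
    ggplot2::labs(x = "Value (vs control, per screened patient)",
                  y = NULL, fill = "Strategy") +
    ggplot2::theme_minimal()
}
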