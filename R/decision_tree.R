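#' Build the decision tree for one strategy
#'
#' Encodes the chance structure a screened patient moves through under a
#' given strategy: screening result (positive with probability
#' `p_positive`), acceptance of the offered intervention (`p_accept`),
#' and — for MI-PST — how many weekly problem-solving-therapy sessions
#' are attended before dropout. Screening costs are charged on the
#' per-enrolled-participant basis (the whole screening pool is spread over
#' enrolled participants), so screen-negative and refusing patients carry
#' zero additional cost and zero intervention effect at their leaves.
#'
#' Dropout handling: MI-PST dropouts incur the cost of the sessions they
#' actually attended (counsellor time at the pooled time-share rate plus
#' per-visit patient cost) but are assigned the arm's completer mean
#' reduction — the strongest assumption of the reconstruction, since no
#' dropout-specific effect is observed.
#'
#' @param strategy `"control"`, `"mi"` or `"mi_pst"`.
#' @param flow A `cea_flow` table ([flow_proportions()]) or a list with
#'   `p_positive` and `p_accept`.
#' @param costing A list with per-patient cost ingredients:
#'   `screening_per_enrolled`, `direct_per_patient` (named by arm),
#'   `rate_per_minute` (pooled time-share cost per contact minute),
#'   `session_minutes` (named: `mi`, `pst1`..`pst4`) and
#'   `patient_cost_per_visit`.
#' @param effects A tibble with `scale`, `arm`, `mean_reduction` (see
#'   [mean_reductions()]).
#' @param attendance For `"mi_pst"`: numbers still attending at the MI
#'   session and each PST session (length 5, non-increasing), used to
#'   derive per-branch attendance probabilities. Ignored otherwise.
#' @param flow_mode `"rounded"` or `"exact"`: which flow convention to
#'   read off a `cea_flow` table.
#' @return A tibble of class `cea_tree`, one row per root-to-leaf path:
#'   `strategy`, `leaf`, `probability`, `cost`, `effect_assist`,
#'   `effect_cesd`. Probabilities sum to one.
#' @examples
#' config <- strive_config()
#' model <- evaluate_strategies(config)
#' attr(model, "trees")[["mi"]]
#' @export
build_strategy_tree <- function(strategy, flow, costing, effects,
                                attendance = NULL,
                                flow_mode = c("rounded", "exact")) {
  flow_mode <- match.arg(flow_mode)
  strategy <- match.arg(strategy, .strategies)
  if (inherits(flow, "cea_flow") || is.data.frame(flow)) {
    p_pos <- flow_value(flow, "p_positive", flow_mode)
    p_acc <- flow_value(flow, "p_accept", flow_mode)
  } else {
    p_pos <- flow$p_positive
    p_acc <- flow$p_accept
  }
  if (length(p_pos) != 1 || length(p_acc) != 1 ||
      any(c(p_pos, p_acc) < 0) || any(c(p_pos, p_acc) > 1)) {
    abort("Flow probabilities must be single values in [0, 1].",
          class = "bicea_tree_error")
  }
  eff <- mean_reductions(effects)
  eff_for <- function(scale) {
    v <- eff$mean_reduction[eff$scale == scale & eff$arm == strategy]
    if (length(v) != 1) {
      abort(paste0("Missing effect for strategy '", strategy,
                   "' on scale '", scale, "'."),
            class = "bicea_tree_error")
    }
    v
  }
  needed <- c("screening_per_enrolled", "direct_per_patient",
              "rate_per_minute", "session_minutes",
              "patient_cost_per_visit")
  miss <- setdiff(needed, names(costing))
  if (length(miss)) {
    abort(paste0("Costing parameters missing: ",
                 paste(miss, collapse = ", ")),
          class = "bicea_tree_error")
  }

  base <- costing$screening_per_enrolled +
    costing$direct_per_patient[[strategy]]
  common <- tibble::tibble(
    leaf = c("screen_negative", "positive_refuse"),
    probability = c(1 - p_pos, p_pos * (1 - p_acc)),
    cost = c(0, 0), effect_assist = 0, effect_cesd = 0)

  accept <- if (strategy == "mi_pst") {
    if (is.null(attendance) || length(attendance) != 5) {
      abort("MI-PST needs `attendance`: numbers at MI and PST sessions 1-4.",
            class = "bicea_tree_error")
    }
    # P(attended exactly k PST sessions), k = 0..4, among those enrolled.
    still <- attendance / attendance[1]
    p_k <- c(-diff(still), still[5])
    pst_min <- costing$session_minutes[c("pst1", "pst2", "pst3", "pst4")]
    cum_min <- cumsum(c(0, pst_min))
    tibble::tibble(
      leaf = paste0("accept_pst", 0:4),
      probability = p_pos * p_acc * p_k,
      cost = base + costing$rate_per_minute *
        (costing$session_minutes[["mi"]] + cum_min) +
        costing$patient_cost_per_visit * (0:4),
      effect_assist = eff_for("assist"), effect_cesd = eff_for("cesd"))
  } else {
    mi_minutes <- if (strategy == "mi") costing$session_minutes[["mi"]] else 0
    tibble::tibble(
      leaf = "accept_treated",
      probability = p_pos * p_acc,
      cost = base + costing$rate_per_minute * mi_minutes,
      effect_assist = eff_for("assist"), effect_cesd = eff_for("cesd"))
  }

  tree <- dplyr::bind_rows(common, accept) |>
    dplyr::mutate(strategy = strategy, .before = 1)
  if (any(tree$cost < 0)) {
    abort("Leaf costs must be non-negative.", class = "bicea_tree_error")
  }
  class(tree) <- c("cea_tree", class(tree))
  tree
}

#' Roll back a decision tree to expected cost and effect
#'
#' Probability-weights every root-to-leaf path: the expected cost and
#' expected effect per screened patient are
#' \eqn{\sum_{\ell} P(\ell)\,(c_\ell, e_\ell)}.
#'
#' @param tree A `cea_tree` (see [build_strategy_tree()]).
#' @return A one-row-per-scale tibble: `strategy`, `scale`,
#'   `expected_cost`, `expected_effect`.
#' @export
rollback <- function(tree) {
  p <- sum(tree$probability)
  if (abs(p - 1) > 1e-9) {
    abort(sprintf("Leaf probabilities sum to %.12f, not 1.", p),
          class = "bicea_tree_error")
  }
  if (any(tree$probability < -1e-12)) {
    abort("Leaf probabilities must be non-negative.",
          class = "bicea_tree_error")
  }
  tibble::tibble(
    strategy = tree$strategy[1],
    scale = .scales,
    expected_cost = sum(tree$probability * tree$cost),
    expected_effect = c(sum(tree$probability * tree$effect_assist),
                        sum(tree$probability * tree$effect_cesd))
  )
}

#' Expected cost and effect per screened patient for every strategy
#'
#' Runs the full base-case model for a configuration: time allocation,
#' cost pools, per-patient cost ingredients, one decision tree per
#' strategy, and rollback. This is the engine behind both the base-case
#' tables and the sensitivity scenarios.
#'
#' @param config A `cea_config` (see [strive_config()]).
#' @param flow_mode Overrides the config's flow convention if given.
#' @return A tibble of class `cea_expectations`: `strategy`, `scale`,
#'   `expected_cost`, `expected_effect`, with attributes `trees` (named
#'   list of `cea_tree`s), `pools`, `allocation`, `avg_costs`
#'   (per-participant averages) and `flow`.
#' @export
evaluate_strategies <- function(config, flow_mode = NULL) {
  flow_mode <- flow_mode %||% config$flow_mode
  allocation <- compute_time_allocation(config$sessions)
  pools <- build_cost_pools(config$ledger, allocation, config$counts)
  flow <- flow_proportions(config$counts)
  costing <- costing_parameters(config, allocation, pools)
  trees <- purrr::map(
    setNames(.strategies, .strategies),
    function(s) build_strategy_tree(
      s, flow, costing, config$effects,
      attendance = config$pst_attendance, flow_mode = flow_mode))
  out <- purrr::map(trees, rollback) |> dplyr::bind_rows()
  attr(out, "trees") <- trees
  attr(out, "pools") <- pools
  attr(out, "allocation") <- allocation
  attr(out, "flow") <- flow
  attr(out, "avg_costs") <- average_cost_per_participant(
    pools, config$counts,
    patient_cost_per_course = patient_cost_per_course(config))
  attr(out, "flow_mode") <- flow_mode
  class(out) <- c("cea_expectations", class(out))
  out
}

# Per-patient cost ingredients for the tree leaves, derived from the
# pooled costing so that rollback conserves the pool totals.
costing_parameters <- function(config, allocation, pools) {
  counts <- config$counts
  session_minutes <- setNames(config$sessions$minutes_per_patient,
                              config$sessions$session_type)
  # direct non-screening items per patient, by arm
  direct_pp <- vapply(.strategies, function(a) {
    pools$direct[pools$component == a] / counts[[paste0("n_", a)]]
  }, numeric(1))
  list(
    screening_per_enrolled =
      pools$total[pools$component == "screening"] / counts$accepted,
    direct_per_patient = as.list(direct_pp),
    rate_per_minute = attr(pools, "rate_per_minute"),
    fixed_rate_per_minute = attr(pools, "fixed_rate_per_minute"),
    session_minutes = session_minutes[c("mi", "pst1", "pst2", "pst3",
                                        "pst4")],
    patient_cost_per_visit = config$patient_costs$mean_cost_per_visit %||% 0
  )
}

patient_cost_per_course <- function(config) {
  att <- config$pst_attendance
  if (is.null(att) || length(att) < 2) return(0)
  mean_visits <- sum(att[-1]) / att[1]
  (config$patient_costs$mean_cost_per_visit %||% 0) * mean_visits
}

#' @export
print.cea_expectations <- function(x, ...) {
  cat("<cea_expectations> expected cost and effect per screened patient\n")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
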