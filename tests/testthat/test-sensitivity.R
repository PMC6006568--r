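test_that("the identity scenario reproduces the base case exactly", {
  for (mode in c("rounded", "exact")) {
    config <- strive_config(flow_mode = mode)
    base <- evaluate_strategies(config)
    sc <- run_scenario(config, label = "base")
    joined <- dplyr::left_join(
      tibble::as_tibble(sc), tibble::as_tibble(base),
      by = c("strategy", "scale"), suffix = c("_sc", "_base"))
    expect_equal(joined$expected_cost_sc, joined$expected_cost_base,
                 tolerance = 1e-12)
    expect_equal(joined$expected_effect_sc, joined$expected_effect_base,
                 tolerance = 1e-12)
  }
})

test_that("capacity rescaling dilutes fixed costs and conserves their base", {
  config <- strive_config()
  alloc <- compute_time_allocation(config$sessions)
  pools <- build_cost_pools(config$ledger, alloc, config$counts)
  cap <- capacity_utilization(alloc, config$capacity$available_hours)
  fixed0 <- attr(pools, "time_shared_fixed")

  # identity: targeting the base excess leaves every pool unchanged
  same <- apply_capacity_scenario(pools, alloc, config$capacity,
                                  cap$excess_capacity)
  expect_equal(same$total, pools$total, tolerance = 1e-12)
  expect_equal(attr(same, "capacity_factor"), 1, tolerance = 1e-12)

  # zero excess: fixed slices shrink by the base utilization (~0.16)
  busy <- apply_capacity_scenario(pools, alloc, config$capacity, 0)
  expect_equal(attr(busy, "capacity_factor"), cap$utilization)
  expect_equal(attr(busy, "time_shared_fixed"),
               fixed0 * cap$utilization)
  # variable spend untouched
  expect_equal(attr(busy, "time_shared_variable"),
               attr(pools, "time_shared_variable"))
  # implied fixed spend at the implied throughput is conserved: the
  # per-patient slice times the 1/factor patient load recovers the base
  expect_equal(attr(busy, "time_shared_fixed") /
                 attr(busy, "capacity_factor"), fixed0)

  # less excess -> strictly lower per-patient fixed cost
  lower <- apply_capacity_scenario(pools, alloc, config$capacity,
                                   cap$excess_capacity * 0.75)
  expect_true(all(lower$time_shared <= pools$time_shared + 1e-12))
  expect_lt(attr(lower, "capacity_factor"), 1)

  expect_error(apply_capacity_scenario(pools, alloc, config$capacity, 1),
               class = "bicea_parameter_error")
})

test_that("throughput scenarios conserve total fixed spend in the pools", {
  config <- strive_config()
  base <- run_scenario(config, label = "base")
  for (sc in list(run_scenario(config, pos_mult = 0.75),
                  run_scenario(config, accept_mult = 1.25),
                  run_scenario(config, accept_target = 1,
                               completion = TRUE))) {
    expect_equal(attr(attr(sc, "pools"), "time_shared_fixed"),
                 attr(attr(base, "pools"), "time_shared_fixed"))
  }
})

test_that("scenario directions match the qualitative sensitivity findings", {
  config <- strive_config()
  suite <- sensitivity_suite(config)
  base <- suite[suite$scenario == "base", ]
  zero <- suite[suite$scenario == "zero excess capacity", ]
  extreme <- suite[suite$scenario == "acceptance 100% + full completion", ]
  low_pos <- suite[suite$scenario == "positivity -25%", ]

  for (s in c("mi", "mi_pst")) {
    pick <- function(d) d[d$strategy == s & d$scale == "assist", ]
    # zero excess capacity generates the largest cost savings in the suite
    others <- suite[suite$strategy == s & suite$scale == "assist" &
                      suite$scenario != "zero excess capacity", ]
    expect_true(pick(zero)$delta_cost < min(others$delta_cost))
    # universal acceptance with full completion: cheaper per patient,
    # larger expected outcomes
    expect_lt(pick(extreme)$cost_per_participant,
              pick(base)$cost_per_participant)
    expect_gt(pick(extreme)$expected_effect, pick(base)$expected_effect)
    # fewer positives: both incremental cost and incremental effect shrink,
    # and cost-effectiveness worsens
    expect_lt(pick(low_pos)$delta_cost, pick(base)$delta_cost)
    expect_lt(pick(low_pos)$delta_effect, pick(base)$delta_effect)
    expect_gt(pick(low_pos)$icer, pick(base)$icer)
  }
})

test_that("one-way series cover the grid, keep the base, and flag infeasible", {
  config <- strive_config()
  series <- one_way_series(config, "p_positive")
  expect_equal(unique(series$multiplier), c(0.75, 1, 1.25))
  base_rows <- series[series$multiplier == 1, ]
  direct <- run_scenario(config, label = unique(base_rows$scenario))
  expect_equal(base_rows$expected_cost, direct$expected_cost)

  acc <- one_way_series(config, "p_accept", grid = c(0.5, 0.75, 1, 1.25))
  mi_eff <- acc$delta_effect[acc$strategy == "mi" & acc$scale == "assist"]
  expect_true(all(diff(mi_eff) > 0))

  expect_warning(
    inf <- one_way_series(config, "excess_capacity", grid = c(1, 1.25)),
    "infeasible")
  expect_true(all(is.na(inf$expected_cost[inf$multiplier == 1.25])))
  expect_error(one_way_series(config, "p_accept", grid = numeric(0)),
               class = "bicea_parameter_error")
})

test_that("probabilities clip to one with a warning at extreme multipliers", {
  config <- strive_config()
  expect_warning(sc <- run_scenario(config, pos_mult = 10), "clipped")
  expect_lte(max(sc$expected_effect), max(
    mean_reductions(config$effects)$mean_reduction))
})

test_that("scenario tables plot", {
  suite <- sensitivity_suite(strive_config())
  expect_s3_class(autoplot(suite), "ggplot")
})
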