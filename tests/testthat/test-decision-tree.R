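# Minimal costing parameter set for hand-checkable trees.
toy_costing <- function(screening = 10, rate = 1, patient = 0.5) {
  list(
    screening_per_enrolled = screening,
    direct_per_patient = list(control = 0.1, mi = 0.5, mi_pst = 2.5),
    rate_per_minute = rate,
    session_minutes = c(mi = 30, pst1 = 60, pst2 = 40, pst3 = 40,
                        pst4 = 40),
    patient_cost_per_visit = patient)
}

toy_effects <- function() {
  tidyr::expand_grid(scale = c("assist", "cesd"),
                     arm = c("control", "mi", "mi_pst")) |>
    dplyr::mutate(baseline_mean = c(10, 11, 12, 20, 21, 22),
                  followup_mean = c(5, 4, 3, 16, 14, 10))
}

test_that("tree structure follows the chance nodes of the patient flow", {
  # nobody screens positive: the only reachable leaf is screen-negative
  tr <- build_strategy_tree("control", list(p_positive = 0, p_accept = 0.5),
                            toy_costing(), toy_effects())
  expect_equal(tr$probability[tr$leaf == "screen_negative"], 1)
  expect_equal(sum(tr$probability), 1)

  # universal acceptance: the refusal branch carries no probability
  tr2 <- build_strategy_tree("mi", list(p_positive = 0.2, p_accept = 1),
                             toy_costing(), toy_effects())
  expect_equal(tr2$probability[tr2$leaf == "positive_refuse"], 0)
  expect_equal(sum(tr2$probability > 0), 2)

  # the MI-PST tree enumerates negative / refuse / accept x attendance
  tr3 <- build_strategy_tree("mi_pst", list(p_positive = 0.2, p_accept = 0.6),
                             toy_costing(), toy_effects(),
                             attendance = c(109, 87, 77, 69, 65))
  expect_setequal(tr3$leaf, c("screen_negative", "positive_refuse",
                              paste0("accept_pst", 0:4)))
  expect_equal(sum(tr3$probability), 1)
  # attendance sub-branch probabilities follow the retention counts
  expect_equal(tr3$probability[tr3$leaf == "accept_pst4"],
               0.2 * 0.6 * 65 / 109)
  # dropouts pay only for sessions attended
  expect_lt(tr3$cost[tr3$leaf == "accept_pst0"],
            tr3$cost[tr3$leaf == "accept_pst4"])

  expect_error(build_strategy_tree("mi_pst", list(p_positive = .2,
                                                  p_accept = .6),
                                   toy_costing(), toy_effects()),
               class = "bicea_tree_error")
  expect_error(build_strategy_tree("mi", list(p_positive = 2, p_accept = .5),
                                   toy_costing(), toy_effects()),
               class = "bicea_tree_error")
})

test_that("rollback equals brute-force enumeration on random trees", {
  set.seed(11)
  for (i in 1:25) {
    p_pos <- runif(1); p_acc <- runif(1)
    cost <- toy_costing(screening = runif(1, 1, 50),
                        rate = runif(1, 0.1, 3),
                        patient = runif(1, 0, 2))
    att <- sort(sample(50:150, 5), decreasing = TRUE)
    eff <- toy_effects() |>
      dplyr::mutate(followup_mean = baseline_mean - runif(6, 0, 5))
    for (s in c("control", "mi", "mi_pst")) {
      tr <- build_strategy_tree(s, list(p_positive = p_pos,
                                        p_accept = p_acc),
                                cost, eff, attendance = att)
      rb <- rollback(tr)
      # independent enumeration: explicit probability-weighted path sums
      exp_cost <- sum(tr$probability * tr$cost)
      exp_eff_as <- sum(tr$probability * tr$effect_assist)
      red <- dplyr::mutate(eff, r = baseline_mean - followup_mean)
      # closed-form check for the accept branch expectations
      expect_equal(rb$expected_effect[rb$scale == "assist"],
                   p_pos * p_acc * red$r[red$scale == "assist" &
                                           red$arm == s])
      expect_equal(rb$expected_cost[1], exp_cost)
      expect_equal(rb$expected_effect[rb$scale == "assist"], exp_eff_as)
    }
  }
})

test_that("rollback is monotone in flow probabilities and leaf effects", {
  base <- rollback(build_strategy_tree(
    "mi", list(p_positive = 0.2, p_accept = 0.5),
    toy_costing(), toy_effects()))
  higher_pos <- rollback(build_strategy_tree(
    "mi", list(p_positive = 0.3, p_accept = 0.5),
    toy_costing(), toy_effects()))
  higher_acc <- rollback(build_strategy_tree(
    "mi", list(p_positive = 0.2, p_accept = 0.7),
    toy_costing(), toy_effects()))
  bigger_eff <- rollback(build_strategy_tree(
    "mi", list(p_positive = 0.2, p_accept = 0.5), toy_costing(),
    dplyr::mutate(toy_effects(), followup_mean = followup_mean - 1)))
  expect_true(all(higher_pos$expected_effect >= base$expected_effect))
  expect_true(all(higher_acc$expected_effect >= base$expected_effect))
  expect_true(all(bigger_eff$expected_effect >= base$expected_effect))
})

test_that("a certain pathway collapses expectation to the arm values", {
  # everyone screens positive, accepts, and completes all sessions
  att <- rep(100, 5)
  tr <- build_strategy_tree("mi_pst", list(p_positive = 1, p_accept = 1),
                            toy_costing(), toy_effects(), attendance = att)
  rb <- rollback(tr)
  full_cost <- 10 + 2.5 + 1 * (30 + 60 + 40 + 40 + 40) + 0.5 * 4
  expect_equal(rb$expected_cost[1], full_cost)
  expect_equal(rb$expected_effect[rb$scale == "assist"], 12 - 3)
  expect_equal(rb$expected_effect[rb$scale == "cesd"], 22 - 10)
})

test_that("rollback validates the probability distribution", {
  tr <- build_strategy_tree("control", list(p_positive = .2, p_accept = .5),
                            toy_costing(), toy_effects())
  broken <- tr
  broken$probability[1] <- broken$probability[1] + 0.05
  expect_error(rollback(broken), class = "bicea_tree_error")
})

test_that("study expectations reproduce the published per-patient table", {
  e <- evaluate_strategies(strive_config())
  as_eff <- e$expected_effect[e$scale == "assist"]
  dp_eff <- e$expected_effect[e$scale == "cesd"]
  # outcome cells: arm mean reduction x 0.19 x 0.63
  expect_equal(as_eff, c(0.88, 0.92, 1.06), tolerance = 0.01)
  expect_equal(dp_eff, c(0.53, 0.74, 1.27), tolerance = 0.01)
  expect_equal(8.82 * 0.19 * 0.63, 1.0558, tolerance = 1e-4)
  # cost column, from the reconstructed ledger
  cost <- unique(round(e$expected_cost, 4))
  expect_equal(cost, c(11.44, 15.57, 33.48), tolerance = 0.03)
  # hand-enumerated control tree: two effective leaves
  ctrl_leaf <- attr(e, "trees")$control
  s_pp <- ctrl_leaf$cost[ctrl_leaf$leaf == "accept_treated"]
  expect_equal(e$expected_cost[e$strategy == "control"][1],
               0.19 * 0.63 * s_pp)
  expect_equal(s_pp, 95.6, tolerance = 0.02)
})
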