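test_that("annuitization matches the annuity equation and its limits", {
  # zero-rate limit is straight-line depreciation
  expect_equal(annuitize(1000, 5, 0), 200)
  # a one-year annuity repays cost plus one year of interest
  expect_equal(annuitize(1000, 1, 0.03), 1030)
  # frozen from the first-principles oracle: solve sum P (1.03)^-t = 1000
  expect_equal(oracle_annuity(1000, 5, 0.03), 218.3546, tolerance = 1e-6)
  expect_equal(annuitize(1000, 5, 0.03), oracle_annuity(1000, 5, 0.03))

  expect_error(annuitize(1000, 0, 0.03), class = "bicea_parameter_error")
  expect_error(annuitize(1000, 5, -0.01), class = "bicea_parameter_error")
  expect_error(annuitize(-5, 5, 0.03), class = "bicea_parameter_error")
})

test_that("present value of the annuitized stream recovers the capital cost", {
  set.seed(7)
  for (i in 1:50) {
    K <- runif(1, 1, 1e6)
    n <- sample(1:40, 1)
    r <- runif(1, 0.001, 0.3)
    pay <- annuitize(K, n, r)
    pv <- sum(pay * (1 + r)^-(seq_len(n)))
    expect_equal(pv, K, tolerance = 1e-9)
    # annualized value between K/n (undiscounted) and K (one-year limit)
    expect_gte(pay * n, K)
    expect_lte(pay, K * (1 + r))
  }
})

test_that("currency conversion is linear, tagged, and one-way", {
  expect_equal(convert_currency(10.3952, 10.3952), 1)
  expect_equal(convert_currency(0, 10.3952), 0)
  expect_equal(convert_currency(1039.52, 10.3952), 100)
  expect_error(convert_currency(5, 0), class = "bicea_parameter_error")
  expect_error(convert_currency(5, 10.3952, currency = "USD"),
               class = "bicea_currency_error")

  ledger <- cost_ledger(tibble::tibble(
    item = c("a", "b"), cost_class = "fixed", basis = "lump",
    unit_cost = c(103.952, 10), currency = c("ZAR", "USD"),
    allocation = "time_share"))
  conv <- convert_ledger_currency(ledger, 10.3952)
  expect_equal(conv$unit_cost, c(10, 10))
  expect_true(all(conv$currency == "USD"))
})

test_that("time allocation reproduces the study's minute totals and shares", {
  alloc <- compute_time_allocation(strive_sessions())
  expect_equal(attr(alloc, "grand_total_minutes"), 47680)
  expect_equal(alloc$minutes[alloc$component == "screening"], 27360)
  expect_equal(alloc$minutes[alloc$component == "mi"], 3390)
  expect_equal(alloc$minutes[alloc$component == "mi_pst"], 16930)
  expect_equal(round(100 * alloc$share), c(57, 7, 36),
               ignore_attr = TRUE)
  expect_equal(sum(alloc$share), 1, tolerance = 1e-12)
})

test_that("time shares normalise, scale-invariantly, and reject empty input", {
  single <- compute_time_allocation(tibble::tibble(
    component = "screening", session_type = "screening",
    minutes_per_patient = 10, n_sessions = 1))
  expect_equal(single$share, 1)

  pair <- compute_time_allocation(tibble::tibble(
    component = c("screening", "mi"), session_type = c("screening", "mi"),
    minutes_per_patient = 10, n_sessions = 100))
  expect_equal(pair$share, c(0.5, 0.5))

  base <- compute_time_allocation(strive_sessions())
  scaled_sessions <- strive_sessions()
  scaled_sessions$n_sessions <- scaled_sessions$n_sessions * 7
  scaled <- compute_time_allocation(scaled_sessions)
  expect_equal(scaled$share, base$share)

  expect_error(compute_time_allocation(tibble::tibble(
    component = "mi", session_type = "mi",
    minutes_per_patient = 30, n_sessions = 0)),
    class = "bicea_parameter_error")

  bad_pst <- strive_sessions()
  bad_pst$n_sessions[bad_pst$session_type == "pst3"] <- 200
  expect_warning(compute_time_allocation(bad_pst), "non-increasing")
})

test_that("cost pools allocate direct items and conserve the ledger total", {
  alloc <- compute_time_allocation(strive_sessions())
  pools <- build_cost_pools(toy_ledger(), alloc, toy_counts())
  # screening tools: 0.10 x 2736 charged straight to the screening pool
  expect_equal(pools$direct[pools$component == "screening"], 273.60)
  # the shared 100-unit item splits proportionally to time shares
  expect_equal(pools$time_shared[pools$component != "control"],
               100 * alloc$share, ignore_attr = TRUE)
  expect_equal(attr(pools, "grand_total"), 100 + 273.60)

  # full study ledger conserves its total through the allocation
  config <- strive_config()
  full <- build_cost_pools(config$ledger, alloc, config$counts)
  ledger_total <- with(config$ledger, sum(unit_cost * vapply(
    seq_along(item),
    function(i) bicea:::resolve_quantity(basis[i], qty_per_basis[i],
                                         config$counts, item[i]),
    numeric(1))))
  expect_equal(attr(full, "grand_total"), ledger_total, tolerance = 1e-12)
  expect_true(all(full$total >= 0))

  bad <- toy_ledger()
  bad$basis[1] <- "per_llama"
  expect_error(build_cost_pools(bad, alloc, toy_counts()),
               "per_llama", class = "bicea_quantity_error")
})

test_that("raising any unit cost weakly raises pools and per-patient averages", {
  config <- strive_config()
  alloc <- compute_time_allocation(config$sessions)
  base_pools <- build_cost_pools(config$ledger, alloc, config$counts)
  base_avg <- average_cost_per_participant(base_pools, config$counts)
  for (i in c(1, 3, 7, 14)) {
    bumped <- config$ledger
    bumped$unit_cost[i] <- bumped$unit_cost[i] * 1.5
    pools <- build_cost_pools(bumped, alloc, config$counts)
    avg <- average_cost_per_participant(pools, config$counts)
    expect_true(all(pools$total >= base_pools$total - 1e-9))
    expect_true(all(avg$total >= base_avg$total - 1e-9))
  }
})

test_that("per-participant averages reproduce the published cost table", {
  config <- strive_config()
  alloc <- compute_time_allocation(config$sessions)
  pools <- build_cost_pools(config$ledger, alloc, config$counts)
  avg <- average_cost_per_participant(pools, config$counts)
  # control arm carries (almost) only the screening component
  expect_equal(avg$cost_screening, rep(avg$cost_screening[1], 3))
  expect_equal(avg$total[avg$arm == "control"], 95, tolerance = 0.03)
  expect_lt(avg$cost_intervention[avg$arm == "control"], 0.1)
  expect_equal(avg$cost_intervention[avg$arm == "mi"], 34, tolerance = 0.03)

  zero <- pools
  zero$time_shared <- zero$direct <- zero$total <- rep(0, nrow(zero))
  expect_equal(average_cost_per_participant(zero, config$counts)$total,
               rep(0, 3))

  broke <- config$counts
  broke$accepted <- 0
  expect_error(average_cost_per_participant(pools, broke),
               class = "bicea_parameter_error")
})

test_that("capacity utilization compares delivered with available hours", {
  alloc <- compute_time_allocation(strive_sessions())
  cap <- capacity_utilization(alloc, 4905)
  expect_equal(cap$utilized_hours, 47680 / 60)
  expect_equal(cap$utilization, 0.162, tolerance = 0.005)

  full <- capacity_utilization(alloc, 47680 / 60)
  expect_equal(full$utilization, 1)

  day <- compute_time_allocation(tibble::tibble(
    component = "screening", session_type = "screening",
    minutes_per_patient = 10, n_sessions = 240))
  expect_equal(capacity_utilization(
    day, list(n_counsellors = 5, hours_per_day = 8,
              working_days = 1))$utilization, 1)

  expect_error(capacity_utilization(alloc, 0),
               class = "bicea_parameter_error")
})

test_that("patient-cost summaries aggregate transport and productivity", {
  one <- tibble::tibble(visits = 2, transport_total = 10,
                        took_time_off = FALSE, lost_income = FALSE)
  s <- summarize_patient_costs(one)
  expect_equal(s$mean_cost_per_visit, 5)
  expect_equal(s$mean_cost_per_course, 10)

  zero <- tibble::tibble(visits = c(3, 2), transport_total = 0,
                         took_time_off = FALSE, lost_income = FALSE)
  sz <- summarize_patient_costs(zero)
  expect_equal(sz$mean_cost_per_visit, 0)
  expect_equal(sz$prop_zero_cost, 1)

  expect_error(summarize_patient_costs(tibble::tibble()),
               class = "bicea_parameter_error")
})
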