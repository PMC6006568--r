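#' Annuitize a capital outlay
#'
#' Converts a one-off capital purchase into the equivalent constant annual
#' cost over the asset's useful life, using the standard annuity factor
#' \eqn{AF = (1 - (1+r)^{-n}) / r}. At \eqn{r = 0} the factor is the
#' continuity limit \eqn{n} (straight-line depreciation). The present value
#' of the resulting annual stream, discounted at \eqn{r}, equals the
#' purchase cost exactly.
#'
#' @param purchase_cost Capital outlay (money, any currency). Vectorised.
#' @param useful_life_years Useful life of the asset in years; must be > 0.
#' @param discount_rate Annual discount rate as a fraction (default 0.03,
#'   the conventional rate for comparability across economic evaluations).
#' @return Annual equivalent cost (money per year), same length as the
#'   longest input.
#' @examples
#' annuitize(1000, 5)           # 218.35 / yr at 3%
#' annuitize(1000, 5, 0)        # straight line: 200 / yr
#' @export
annuitize <- function(purchase_cost, useful_life_years, discount_rate = 0.03) {
  if (any(!is.finite(useful_life_years)) || any(useful_life_years <= 0)) {
    abort("`useful_life_years` must be positive and finite.",
          class = "bicea_parameter_error")
  }
  if (any(!is.finite(discount_rate)) || any(discount_rate < 0) ||
      any(discount_rate >= 1)) {
    abort("`discount_rate` must be a fraction in [0, 1).",
          class = "bicea_parameter_error")
  }
  if (any(purchase_cost < 0)) {
    abort("`purchase_cost` must be non-negative.",
          class = "bicea_parameter_error")
  }
  af <- ifelse(discount_rate == 0,
               useful_life_years,
               (1 - (1 + discount_rate)^(-useful_life_years)) / discount_rate)
  purchase_cost / af
}

#' Convert an amount from local currency to US dollars
#'
#' Division by the period exchange rate (local currency units per US$1).
#' Amounts already tagged as USD are rejected so a ledger cannot be
#' converted twice.
#'
#' @param amount Money amount(s) in the source currency.
#' @param zar_per_usd Exchange rate: source-currency units per US dollar
#'   (must be > 0).
#' @param currency Currency tag of `amount`; converting `"USD"` is an error.
#' @return Amount in US dollars.
#' @examples
#' convert_currency(10.3952, 10.3952)  # 1 USD
#' @export
convert_currency <- function(amount, zar_per_usd, currency = "ZAR") {
  if (!is.numeric(zar_per_usd) || any(zar_per_usd <= 0)) {
    abort("`zar_per_usd` must be positive.", class = "bicea_parameter_error")
  }
  if (any(currency == "USD")) {
    abort("Amount is already in USD; refusing to convert twice.",
          class = "bicea_currency_error")
  }
  amount / zar_per_usd
}

#' Convert the local-currency rows of a cost ledger to USD
#'
#' Rows tagged `"ZAR"` are divided by the exchange rate and re-tagged
#' `"USD"`; rows already in USD are left untouched, so the operation is
#' idempotent at the ledger level while [convert_currency()] guards the
#' row level.
#'
#' @param ledger A cost ledger tibble (see [cost_ledger()]).
#' @param zar_per_usd Exchange rate, local units per US$1.
#' @return The ledger with all `unit_cost` values in USD.
#' @export
convert_ledger_currency <- function(ledger, zar_per_usd) {
  zar <- ledger$currency == "ZAR"
  ledger$unit_cost[zar] <- convert_currency(ledger$unit_cost[zar], zar_per_usd)
  ledger$currency[zar] <- "USD"
  ledger
}

#' Construct a validated cost ledger
#'
#' An ingredients-costing ledger: one row per resource with its unit cost,
#' the rule resolving its quantity against cohort counts, its
#' variable/fixed class, how it is allocated to intervention components,
#' and (for capital items) how the printed cost is to be read.
#'
#' @param items A data frame with columns
#'   \describe{
#'     \item{item}{resource label (unique).}
#'     \item{cost_class}{`"variable"` or `"fixed"`.}
#'     \item{basis}{quantity basis: one of `"lump"`, `"screened"`,
#'       `"positive"`, `"accepted"`, `"mi_recipients"` (both arms receiving
#'       a motivational-interviewing session), `"mi_pst"`, `"counsellor"`.}
#'     \item{qty_per_basis}{units consumed per basis unit (default 1).}
#'     \item{unit_cost}{money per unit.}
#'     \item{currency}{`"USD"` or `"ZAR"`.}
#'     \item{cost_form}{`"unit-price"`, `"lump-sum"`, `"pre-annuitized"`
#'       (an annual capital figure as printed) or `"raw-capital"` (a
#'       purchase price still to be annuitized via `useful_life_years`).}
#'     \item{useful_life_years}{years, required for `"raw-capital"` rows.}
#'     \item{allocation}{`"time_share"`, `"screening"`, `"mi"`, `"mi_pst"`,
#'       `"arms"` (split over the three arms by size) or `"mi_arms"`
#'       (split over the MI and MI-PST arms by size).}
#'   }
#' @param discount_rate Annual discount rate used to annuitize
#'   `"raw-capital"` rows.
#' @return A tibble of class `cea_ledger`.
#' @export
cost_ledger <- function(items, discount_rate = 0.03) {
  items <- tibble::as_tibble(items)
  if (!"qty_per_basis" %in% names(items)) items$qty_per_basis <- 1
  if (!"currency" %in% names(items)) items$currency <- "USD"
  if (!"cost_form" %in% names(items)) items$cost_form <- "unit-price"
  if (!"useful_life_years" %in% names(items)) items$useful_life_years <- NA_real_
  required <- c("item", "cost_class", "basis", "unit_cost", "allocation")
  missing <- setdiff(required, names(items))
  if (length(missing)) {
    abort(paste0("Ledger is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "bicea_ledger_error")
  }
  if (anyDuplicated(items$item)) {
    abort("Ledger item names must be unique.", class = "bicea_ledger_error")
  }
  if (any(items$unit_cost < 0)) {
    abort("Ledger unit costs must be non-negative.",
          class = "bicea_ledger_error")
  }
  bad_class <- setdiff(items$cost_class, c("variable", "fixed"))
  if (length(bad_class)) {
    abort(paste0("Unknown cost_class: ", paste(bad_class, collapse = ", ")),
          class = "bicea_ledger_error")
  }
  bad_alloc <- setdiff(items$allocation,
                       c("time_share", "screening", "mi", "mi_pst",
                         "arms", "mi_arms"))
  if (length(bad_alloc)) {
    abort(paste0("Unknown allocation mode: ",
                 paste(bad_alloc, collapse = ", ")),
          class = "bicea_ledger_error")
  }
  raw <- items$cost_form == "raw-capital"
  if (any(raw & !is.finite(items$useful_life_years))) {
    abort("raw-capital rows need a finite `useful_life_years`.",
          class = "bicea_ledger_error")
  }
  # Annuitize purchase prices up front; every downstream cost is annual.
  items$unit_cost[raw] <- annuitize(items$unit_cost[raw],
                                    items$useful_life_years[raw],
                                    discount_rate)
  items$cost_form[raw] <- "pre-annuitized"
  class(items) <- c("cea_ledger", class(items))
  items
}

# Resolve a quantity basis to a count of units.
resolve_quantity <- function(basis, qty_per_basis, counts, item = basis) {
  n <- switch(basis,
    lump          = 1,
    screened      = counts$screened,
    positive      = counts$positive,
    accepted      = counts$accepted,
    mi_recipients = counts$n_mi + counts$n_mi_pst,
    mi_pst        = counts$n_mi_pst,
    counsellor    = counts$n_counsellors,
    abort(paste0("Cannot resolve quantity rule '", basis,
                 "' for ledger item '", item, "'."),
          class = "bicea_quantity_error")
  )
  if (is.null(n) || !is.finite(n) || n < 0) {
    abort(paste0("Quantity for ledger item '", item,
                 "' resolved to a non-finite or negative count."),
          class = "bicea_quantity_error")
  }
  n * qty_per_basis
}

#' Counsellor time allocation across intervention components
#'
#' Sums patient-contact minutes per component (minutes per session times
#' number of sessions) and converts them to shares of total counsellor
#' contact time. These shares drive the allocation of all non-direct
#' provider costs to screening, the MI arm, and the MI-PST arm.
#'
#' @param profiles A data frame with columns `component` (one of
#'   `"screening"`, `"mi"`, `"mi_pst"`), `session_type` (free label),
#'   `minutes_per_patient` (> 0) and `n_sessions` (>= 0).
#' @return A tibble of class `cea_time_allocation` with one row per
#'   component: `minutes` and `share`, plus a `grand_total_minutes`
#'   attribute. Shares sum to one.
#' @examples
#' profiles <- data.frame(
#'   component = c("screening", "mi"),
#'   session_type = c("screen", "mi"),
#'   minutes_per_patient = c(10, 10),
#'   n_sessions = c(100, 100)
#' )
#' compute_time_allocation(profiles)  # 50% / 50%
#' @export
compute_time_allocation <- function(profiles) {
  profiles <- tibble::as_tibble(profiles)
  if (nrow(profiles) == 0) {
    abort("At least one session profile is required.",
          class = "bicea_parameter_error")
  }
  if (any(profiles$minutes_per_patient <= 0)) {
    abort("`minutes_per_patient` must be positive.",
          class = "bicea_parameter_error")
  }
  if (any(profiles$n_sessions < 0)) {
    abort("`n_sessions` must be non-negative.",
          class = "bicea_parameter_error")
  }
  pst <- profiles[grepl("^pst", profiles$session_type), ]
  if (nrow(pst) > 1 && is.unsorted(rev(pst$n_sessions), strictly = FALSE)) {
    warn("PST session counts are not non-increasing across sessions.")
  }
  out <- profiles |>
    dplyr::mutate(minutes = .data$minutes_per_patient * .data$n_sessions) |>
    dplyr::group_by(component = .data$component) |>
    dplyr::summarise(minutes = sum(.data$minutes), .groups = "drop")
  grand <- sum(out$minutes)
  if (grand <= 0) {
    abort("All session counts are zero; time shares are undefined.",
          class = "bicea_parameter_error")
  }
  out$share <- out$minutes / grand
  out <- out[order(match(out$component, .components)), ]
  attr(out, "grand_total_minutes") <- grand
  class(out) <- c("cea_time_allocation", class(out))
  out
}

#' Allocate the cost ledger to component cost pools
#'
#' Direct items (screeners, manuals, flyers) are charged to the component
#' or arm that consumes them; every other item — staffing, supplies and
#' annuitized capital — is split across screening, MI and MI-PST in
#' proportion to counsellor contact time. The pools conserve the ledger
#' total exactly.
#'
#' @param ledger A `cea_ledger` (see [cost_ledger()]).
#' @param allocation A `cea_time_allocation` (see
#'   [compute_time_allocation()]).
#' @param counts Cohort counts: a list or one-row data frame with
#'   `screened`, `positive`, `accepted`, `n_control`, `n_mi`, `n_mi_pst`,
#'   `n_counsellors`.
#' @return A tibble of class `cea_cost_pools` with one row per component
#'   (`screening`, `control`, `mi`, `mi_pst`): `time_shared`, `direct` and
#'   `total` money columns; attributes `grand_total`, `time_shared_total`,
#'   `time_shared_fixed`, `time_shared_variable` and `rate_per_minute`.
#' @export
build_cost_pools <- function(ledger, allocation, counts) {
  counts <- as.list(counts)
  amounts <- ledger |>
    dplyr::mutate(
      quantity = purrr::pmap_dbl(
        list(.data$basis, .data$qty_per_basis, .data$item),
        function(b, q, it) resolve_quantity(b, q, counts, it)),
      total = .data$unit_cost * .data$quantity)

  shared <- amounts[amounts$allocation == "time_share", ]
  direct <- amounts[amounts$allocation != "time_share", ]

  shared_total <- sum(shared$total)
  shared_fixed <- sum(shared$total[shared$cost_class == "fixed"])

  shares <- setNames(allocation$share, allocation$component)
  comp_levels <- intersect(.components, c("screening", .strategies))
  pool <- tibble::tibble(
    component = comp_levels,
    time_shared = shared_total *
      unname(dplyr::coalesce(shares[comp_levels], 0)),
    direct = 0
  )

  arm_n <- c(control = counts$n_control, mi = counts$n_mi,
             mi_pst = counts$n_mi_pst)
  add_direct <- function(pool, component, amount) {
    pool$direct[pool$component == component] <-
      pool$direct[pool$component == component] + amount
    pool
  }
  for (i in seq_len(nrow(direct))) {
    row <- direct[i, ]
    pool <- switch(row$allocation,
      screening = add_direct(pool, "screening", row$total),
      mi        = add_direct(pool, "mi", row$total),
      mi_pst    = add_direct(pool, "mi_pst", row$total),
      arms      = {
        w <- arm_n / sum(arm_n)
        for (a in names(w)) pool <- add_direct(pool, a, row$total * w[[a]])
        pool
      },
      mi_arms   = {
        w <- arm_n[c("mi", "mi_pst")] / sum(arm_n[c("mi", "mi_pst")])
        for (a in names(w)) pool <- add_direct(pool, a, row$total * w[[a]])
        pool
      }
    )
  }
  pool$total <- pool$time_shared + pool$direct
  attr(pool, "grand_total") <- sum(pool$total)
  attr(pool, "time_shared_total") <- shared_total
  attr(pool, "time_shared_fixed") <- shared_fixed
  attr(pool, "time_shared_variable") <- shared_total - shared_fixed
  attr(pool, "rate_per_minute") <-
    shared_total / attr(allocation, "grand_total_minutes")
  attr(pool, "fixed_rate_per_minute") <-
    shared_fixed / attr(allocation, "grand_total_minutes")
  class(pool) <- c("cea_cost_pools", class(pool))
  pool
}

#' Average provider cost per participant, by arm
#'
#' Screening costs (the screening pool, including screening tools) are
#' spread over all enrolled participants and charged equally to the three
#' arms; each arm's own intervention pool is spread over that arm's
#' participants. Patient-borne costs, incurred only by participants who
#' travel back for problem-solving-therapy sessions, are added to the
#' MI-PST arm when supplied.
#'
#' @param pools A `cea_cost_pools` object.
#' @param counts Cohort counts (see [build_cost_pools()]).
#' @param patient_cost_per_course Mean patient-borne cost per treated
#'   MI-PST participant (money), or `NULL` to omit.
#' @return A tibble with one row per arm: `cost_screening`,
#'   `cost_intervention`, `cost_patient` and `total` per participant.
#' @export
average_cost_per_participant <- function(pools, counts,
                                         patient_cost_per_course = NULL) {
  counts <- as.list(counts)
  arm_n <- c(control = counts$n_control, mi = counts$n_mi,
             mi_pst = counts$n_mi_pst)
  if (counts$accepted <= 0 || any(arm_n <= 0)) {
    abort("Participant counts must be positive to average costs.",
          class = "bicea_parameter_error")
  }
  screening_pp <- pools$total[pools$component == "screening"] / counts$accepted
  intervention_pp <- vapply(
    names(arm_n),
    function(a) pools$total[pools$component == a] / arm_n[[a]],
    numeric(1))
  patient_pp <- c(control = 0, mi = 0,
                  mi_pst = patient_cost_per_course %||% 0)
  tibble::tibble(
    arm = names(arm_n),
    cost_screening = unname(screening_pp),
    cost_intervention = unname(intervention_pp),
    cost_patient = unname(patient_pp),
    total = .data$cost_screening + .data$cost_intervention +
      .data$cost_patient
  )
}

#' Counsellor capacity utilization
#'
#' Compares patient-contact time actually delivered with the contact time
#' available from the employed counsellors, expressed as hours.
#'
#' @param allocation A `cea_time_allocation`.
#' @param available_hours Total counsellor contact hours available over
#'   the delivery period (> 0). May instead be supplied as a list with
#'   `n_counsellors`, `hours_per_day` and `working_days`, in which case it
#'   is their product.
#' @return A one-row tibble: `utilized_hours`, `available_hours`,
#'   `utilization` (fraction in [0, 1]) and `excess_capacity`
#'   (= 1 - utilization).
#' @export
capacity_utilization <- function(allocation, available_hours) {
  if (is.list(available_hours)) {
    available_hours <- available_hours$n_counsellors *
      available_hours$hours_per_day * available_hours$working_days
  }
  if (!is.finite(available_hours) || available_hours <= 0) {
    abort("`available_hours` must be positive.",
          class = "bicea_parameter_error")
  }
  utilized <- attr(allocation, "grand_total_minutes") / 60
  utilization <- utilized / available_hours
  tibble::tibble(
    utilized_hours = utilized,
    available_hours = available_hours,
    utilization = utilization,
    excess_capacity = 1 - utilization
  )
}

#' Summarize patient-borne costs from visit records
#'
#' Means and proportions of out-of-pocket and productivity costs incurred
#' by participants returning to the facility for counselling sessions.
#'
#' @param records A data frame with one row per interviewed participant:
#'   `visits` (number of attended visits), `transport_total` (money spent
#'   on transport across those visits), and logical `took_time_off` and
#'   `lost_income`.
#' @return A one-row tibble: `n`, `mean_cost_per_visit` (total transport
#'   over total visits), `mean_visits`, `mean_cost_per_course`,
#'   `prop_zero_cost` (walked), `prop_time_off`, `prop_income_loss`.
#' @export
summarize_patient_costs <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    abort("No patient-cost records supplied.", class = "bicea_parameter_error")
  }
  total_visits <- sum(records$visits)
  per_visit <- if (total_visits > 0) {
    sum(records$transport_total) / total_visits
  } else {
    0
  }
  tibble::tibble(
    n = nrow(records),
    mean_cost_per_visit = per_visit,
    mean_visits = mean(records$visits),
    mean_cost_per_course = per_visit * mean(records$visits),
    prop_zero_cost = mean(records$transport_total == 0),
    prop_time_off = mean(records$took_time_off),
    prop_income_loss = mean(records$lost_income)
  )
}
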