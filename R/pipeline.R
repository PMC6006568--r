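#' Run the full cost-effectiveness pipeline
#'
#' Orchestrates every stage for one configuration: counsellor time
#' allocation and capacity, effect summaries and flow proportions, cost
#' pools and per-participant averages, the per-strategy decision trees
#' and their rollback, and the incremental cost-effectiveness frontier on
#' each outcome scale. When patient-level `records` are supplied the
#' effect summaries, flow counts, attendance and patient costs are
#' estimated from them; otherwise the configuration's summary inputs are
#' used as printed.
#'
#' @param config A `cea_config` (see [strive_config()]).
#' @param records Optional patient-record tibble (see
#'   [generate_cohort()], [strive_fixture()]).
#' @param flow_mode Overrides the config's flow convention
#'   (`"rounded"` reproduces report-rounded probabilities; `"exact"`
#'   uses the count ratios).
#' @return A list of class `cea_report` with tibbles `time_allocation`,
#'   `capacity`, `effects`, `flow`, `cost_pools`, `avg_costs`,
#'   `patient_costs`, `expectations`, `frontier_assist`, `frontier_cesd`,
#'   and a `log` of the parameters used.
#' @examples
#' report <- run_pipeline(strive_config())
#' report$frontier_assist
#' @export
run_pipeline <- function(config, records = NULL, flow_mode = NULL) {
  flow_mode <- flow_mode %||% config$flow_mode
  if (!is.null(records)) {
    if (nrow(records) == 0 ||
        !any(records$arm %in% .strategies & records$followed_up)) {
      abort("effectiveness stage: no follow-up completers in `records`.",
            class = "bicea_pipeline_error")
    }
    est <- effect_summaries(records)
    config$effects <- est
    config$counts <- utils::modifyList(
      config$counts, cohort_counts(records,
                                   config$counts$n_counsellors %||% 5))
    config$pst_attendance <- pst_attendance_counts(records)
    att <- records[records$arm == "mi_pst" & records$visits > 0, ]
    patient_costs <- if (nrow(att)) summarize_patient_costs(att) else NULL
    if (!is.null(patient_costs)) {
      config$patient_costs$mean_cost_per_visit <-
        patient_costs$mean_cost_per_visit
    }
    # session counts follow the cohort
    config$sessions$n_sessions <- dplyr::case_when(
      config$sessions$component == "screening" ~
        as.numeric(config$counts$screened),
      config$sessions$component == "mi" ~
        as.numeric(config$counts$n_mi),
      config$sessions$session_type == "mi" ~
        as.numeric(config$pst_attendance[1]),
      TRUE ~ as.numeric(config$pst_attendance[
        match(config$sessions$session_type, paste0("pst", 1:4)) + 1])
    )
  } else {
    patient_costs <- tibble::as_tibble(config$patient_costs)
  }
  config <- validate_cea_config(unclass(config))

  expectations <- evaluate_strategies(config, flow_mode = flow_mode)
  allocation <- attr(expectations, "allocation")
  capacity <- capacity_utilization(allocation,
                                   config$capacity$available_hours)
  out <- list(
    time_allocation = tibble::as_tibble(allocation) |>
      dplyr::mutate(grand_total_minutes =
                      attr(allocation, "grand_total_minutes")),
    capacity = capacity,
    effects = mean_reductions(config$effects),
    flow = tibble::as_tibble(attr(expectations, "flow")),
    cost_pools = tibble::as_tibble(attr(expectations, "pools")),
    avg_costs = attr(expectations, "avg_costs"),
    patient_costs = patient_costs,
    expectations = tibble::as_tibble(expectations),
    frontier_assist = icer_frontier(expectations, scale = "assist"),
    frontier_cesd = icer_frontier(expectations, scale = "cesd"),
    log = tibble::tibble(
      parameter = c("study", "flow_mode", "records_supplied",
                    "screened", "positive", "accepted"),
      value = as.character(c(config$study, flow_mode, !is.null(records),
                             config$counts$screened,
                             config$counts$positive,
                             config$counts$accepted)))
  )
  class(out) <- "cea_report"
  out
}

#' @export
print.cea_report <- function(x, digits = 2, ...) {
  cat("== Cost-effectiveness report ==\n\n")
  cat("Counsellor time (minutes and share):\n")
  ta <- x$time_allocation
  ta$share <- round(100 * ta$share)
  print(ta, ...)
  cat(sprintf("\nCapacity: %.0f of %.0f available hours (%.0f%%)\n",
              x$capacity$utilized_hours, x$capacity$available_hours,
              100 * x$capacity$utilization))
  cat("\nAverage cost per participant (US$):\n")
  print(dplyr::mutate(x$avg_costs,
                      dplyr::across(dplyr::where(is.numeric),
                                    ~ round(.x, digits))), ...)
  cat("\nExpected cost / effect per screened patient and ICERs:\n")
  for (s in .scales) {
    cat("  scale:", s, "\n")
    fr <- tidy(x[[paste0("frontier_", s)]])
    print(dplyr::mutate(fr, dplyr::across(dplyr::where(is.numeric),
                                          ~ round(.x, digits))), ...)
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `cea_report`.
#' @param ... Unused.
#' @export
tidy.cea_report <- function(x, ...) {
  dplyr::bind_rows(
    assist = tidy(x$frontier_assist),
    cesd = tidy(x$frontier_cesd),
    .id = "scale")
}

#' @rdname run_pipeline
#' @export
glance.cea_report <- function(x, ...) {
  tibble::tibble(
    grand_total_cost = sum(x$cost_pools$total),
    utilization = x$capacity$utilization,
    n_strategies = length(unique(x$expectations$strategy)),
    max_icer_assist = suppressWarnings(
      max(x$frontier_assist$icer, na.rm = TRUE)),
    max_icer_cesd = suppressWarnings(
      max(x$frontier_cesd$icer, na.rm = TRUE)))
}

#' Write the report tables to delimiter-separated files
#'
#' Emits each table of a [run_pipeline()] report as a TSV file mirroring
#' the published table layouts (time shares, effect summaries, per-arm
#' average costs, cost-effectiveness comparisons), plus the run log.
#'
#' @param report A `cea_report`.
#' @param dir Output directory (created if needed).
#' @param money_digits Decimal places for money columns (default 2).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, money_digits = 2) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    time_allocation = report$time_allocation,
    capacity = report$capacity,
    effects = report$effects,
    flow = report$flow,
    cost_pools = report$cost_pools,
    avg_costs = report$avg_costs,
    expectations = report$expectations,
    frontier_assist = tidy(report$frontier_assist),
    frontier_cesd = tidy(report$frontier_cesd),
    log = report$log)
  paths <- purrr::imap_chr(tables, function(tb, nm) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    tb <- dplyr::mutate(tibble::as_tibble(tb),
                        dplyr::across(dplyr::where(is.numeric),
                                      ~ round(.x, money_digits + 2)))
    utils::write.table(tb, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    path
  })
  invisible(paths)
}
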