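#' Read an analysis configuration file
#'
#' Loads a YAML configuration describing one screening-plus-intervention
#' study: the ingredients cost ledger, session time profiles, cohort
#' counts, counsellor capacity, patient-cost summaries and per-arm outcome
#' summaries. The packaged `"strive"` configuration encodes a South
#' African emergency-department brief-intervention study and reproduces
#' its published cost and effect tables.
#'
#' @param path Path to a YAML file (see the packaged
#'   `inst/extdata/strive.yaml` for the schema).
#' @return A list of class `cea_config` with elements `ledger`
#'   (a [cost_ledger()]), `sessions`, `counts`, `pst_attendance`,
#'   `capacity`, `patient_costs`, `effects`, `flow_mode`, `zar_per_usd`
#'   and `discount_rate`.
#' @export
read_cea_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Configuration file not found: ", path),
          class = "bicea_config_error")
  }
  raw <- yaml::read_yaml(path)
  config <- list(
    study = raw$study %||% "unnamed",
    zar_per_usd = raw$zar_per_usd %||% NA_real_,
    discount_rate = raw$discount_rate %||% 0.03,
    ledger = cost_ledger(dplyr::bind_rows(raw$ledger),
                         discount_rate = raw$discount_rate %||% 0.03),
    sessions = dplyr::bind_rows(raw$sessions),
    counts = raw$counts,
    pst_attendance = as.numeric(raw$pst_attendance),
    capacity = raw$capacity,
    patient_costs = raw$patient_costs,
    effects = tibble::as_tibble(dplyr::bind_rows(raw$effects)),
    flow_mode = match.arg(raw$flow_mode %||% "rounded",
                          c("rounded", "exact"))
  )
  validate_cea_config(config)
}

#' The packaged emergency-department brief-intervention configuration
#'
#' Loads the shipped configuration whose ledger, session profile, cohort
#' counts and outcome summaries describe a three-facility South African
#' emergency-department study of motivational interviewing (MI) and MI
#' plus problem solving therapy (MI-PST) delivered by lay counsellors.
#'
#' @param flow_mode `"rounded"` (default; decision-tree probabilities use
#'   the report-rounded 19% positivity and 63% acceptance) or `"exact"`
#'   (count ratios 531/2736 and 332/531).
#' @return A `cea_config` list; see [read_cea_config()].
#' @examples
#' config <- strive_config()
#' config$counts$screened
#' @export
strive_config <- function(flow_mode = c("rounded", "exact")) {
  flow_mode <- match.arg(flow_mode)
  config <- read_cea_config(
    system.file("extdata", "strive.yaml", package = "bicea", mustWork = TRUE))
  config$flow_mode <- flow_mode
  config
}

validate_cea_config <- function(config) {
  counts <- config$counts
  needed <- c("screened", "positive", "accepted", "n_control", "n_mi",
              "n_mi_pst", "n_counsellors")
  missing <- setdiff(needed, names(counts))
  if (length(missing)) {
    abort(paste0("Config counts are missing: ",
                 paste(missing, collapse = ", ")),
          class = "bicea_config_error")
  }
  if (counts$positive > counts$screened || counts$accepted > counts$positive) {
    abort("Cohort counts must satisfy screened >= positive >= accepted.",
          class = "bicea_config_error")
  }
  if (length(config$pst_attendance) &&
      is.unsorted(rev(config$pst_attendance))) {
    warn("PST attendance counts are not non-increasing.")
  }
  if (!all(c("scale", "arm", "baseline_mean", "followup_mean") %in%
             names(config$effects))) {
    abort("Config effects need scale, arm, baseline_mean, followup_mean.",
          class = "bicea_config_error")
  }
  class(config) <- "cea_config"
  config
}

#' @export
print.cea_config <- function(x, ...) {
  cat("<cea_config> study:", x$study, "\n")
  cat("  ledger items:", nrow(x$ledger),
      "| session profiles:", nrow(x$sessions), "\n")
  cat("  cohort: screened", x$counts$screened,
      "| positive", x$counts$positive,
      "| enrolled", x$counts$accepted, "\n")
  cat("  flow mode:", x$flow_mode, "\n")
  invisible(x)
}
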