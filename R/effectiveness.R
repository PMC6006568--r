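#' ASSIST risk classification
#'
#' Classifies a substance-specific involvement score into low, moderate or
#' high risk. Alcohol uses the 0–10 / 11–26 / 27+ bands; all other
#' substances use 0–3 / 4–26 / 27+.
#'
#' @param score Numeric involvement score(s).
#' @param substance Substance label(s); `"alcohol"` or anything else.
#' @return Character vector: `"low"`, `"moderate"` or `"high"`.
#' @export
classify_assist <- function(score, substance) {
  lower <- ifelse(substance == "alcohol", 11, 4)
  dplyr::case_when(
    score > 26 ~ "high",
    score >= lower ~ "moderate",
    .default = "low"
  )
}

#' Per-arm effect summaries from patient records
#'
#' Computes baseline and follow-up means and standard deviations, and the
#' mean reduction (baseline minus follow-up), over follow-up completers
#' only — an available-case analysis. For patients reporting several
#' substances the involvement score of the primary substance is used;
#' records are expected to already carry that score.
#'
#' @param records Patient records: a data frame with columns `arm`,
#'   `followed_up` and per-scale score columns `assist_baseline`,
#'   `assist_followup`, `cesd_baseline`, `cesd_followup`.
#' @param scales Which scales to summarise (default both).
#' @param arms Which arms (default the three trial arms present).
#' @return A tibble with one row per scale and arm: `n_completers`,
#'   `baseline_mean`, `baseline_sd`, `followup_mean`, `followup_sd`,
#'   `mean_reduction`.
#' @examples
#' records <- strive_fixture()
#' effect_summaries(records)
#' @export
effect_summaries <- function(records, scales = c("assist", "cesd"),
                             arms = NULL) {
  records <- tibble::as_tibble(records)
  arms <- arms %||% intersect(.strategies, unique(records$arm))
  completers <- records[records$arm %in% arms & records$followed_up, ]
  if (nrow(completers) == 0) {
    abort("No follow-up completers in the requested arms.",
          class = "bicea_no_completers_error")
  }
  out <- tidyr::expand_grid(scale = scales, arm = arms) |>
    purrr::pmap(function(scale, arm) {
      x <- completers[completers$arm == arm, ]
      if (nrow(x) == 0) {
        abort(paste0("No completers in arm '", arm, "'."),
              class = "bicea_no_completers_error")
      }
      base <- x[[paste0(scale, "_baseline")]]
      follow <- x[[paste0(scale, "_followup")]]
      tibble::tibble(
        scale = scale, arm = arm, n_completers = nrow(x),
        baseline_mean = mean(base), baseline_sd = stats::sd(base),
        followup_mean = mean(follow), followup_sd = stats::sd(follow),
        mean_reduction = mean(base) - mean(follow))
    }) |>
    dplyr::bind_rows()
  out[order(match(out$scale, .scales), match(out$arm, .strategies)), ]
}

#' Mean reductions from printed summary means
#'
#' Completes a per-arm effect-summary table (as carried by a
#' [read_cea_config()] object) with the mean reduction, defined as the
#' baseline mean minus the follow-up mean among completers.
#'
#' @param effects A data frame with `scale`, `arm`, `baseline_mean`,
#'   `followup_mean` (and optionally the SDs).
#' @return The same tibble with a `mean_reduction` column.
#' @export
mean_reductions <- function(effects) {
  effects |>
    tibble::as_tibble() |>
    dplyr::mutate(mean_reduction = .data$baseline_mean - .data$followup_mean)
}

#' Patient-flow proportions
#'
#' Derives the probabilities that drive the decision tree — screening
#' positivity, acceptance of the intervention and follow-up — from cohort
#' counts, together with their report-rounded versions (whole percent,
#' i.e. two decimals as a fraction).
#'
#' @param counts Cohort counts: a data frame or list with `screened`,
#'   `positive`, `accepted`, and optionally per-arm sizes `n_control`,
#'   `n_mi`, `n_mi_pst` and completer counts `completers_control`,
#'   `completers_mi`, `completers_mi_pst`.
#' @return A tibble of class `cea_flow` with columns `quantity`
#'   (`"p_positive"`, `"p_accept"`, `"p_followup"`, `"p_followup_<arm>"`),
#'   `numerator`, `denominator`, `exact` and `rounded`.
#' @examples
#' flow_proportions(list(screened = 2736, positive = 531, accepted = 332))
#' @export
flow_proportions <- function(counts) {
  counts <- as.list(counts)
  with(counts, {
    if (positive > screened || accepted > positive) {
      abort("Counts must satisfy screened >= positive >= accepted.",
            class = "bicea_parameter_error")
    }
  })
  rows <- list(
    tibble::tibble(quantity = "p_positive", numerator = counts$positive,
                   denominator = counts$screened),
    tibble::tibble(quantity = "p_accept", numerator = counts$accepted,
                   denominator = counts$positive)
  )
  arms <- c("control", "mi", "mi_pst")
  comp <- paste0("completers_", arms)
  n_arm <- paste0("n_", arms)
  if (all(c(comp, n_arm) %in% names(counts))) {
    total_completers <- sum(unlist(counts[comp]))
    total_n <- sum(unlist(counts[n_arm]))
    if (any(unlist(counts[comp]) > unlist(counts[n_arm]))) {
      abort("Completer counts cannot exceed arm sizes.",
            class = "bicea_parameter_error")
    }
    rows <- c(rows, list(
      tibble::tibble(quantity = "p_followup", numerator = total_completers,
                     denominator = total_n),
      tibble::tibble(quantity = paste0("p_followup_", arms),
                     numerator = unlist(counts[comp]),
                     denominator = unlist(counts[n_arm]))
    ))
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(numerator = unname(.data$numerator),
                  denominator = unname(.data$denominator),
                  exact = .data$numerator / .data$denominator,
                  rounded = round(.data$exact, 2))
  class(out) <- c("cea_flow", class(out))
  out
}

flow_value <- function(flow, quantity, mode = c("rounded", "exact")) {
  mode <- match.arg(mode)
  unname(flow[[mode]][flow$quantity == quantity])
}
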