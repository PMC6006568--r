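# Truncated-normal utilities used by the cohort generator. Latent means
# are calibrated so the *realized* (truncated) means equal the targets.

rtnorm <- function(n, mean, sd, lower, upper) {
  lo <- pnorm((lower - mean) / sd)
  hi <- pnorm((upper - mean) / sd)
  qnorm(runif(n, lo, hi)) * sd + mean
}

tnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  z <- pnorm(b) - pnorm(a)
  out <- mu + sd * (dnorm(a) - dnorm(b)) / z
  # Mills-ratio asymptotes keep the calibration root-finder finite when
  # the latent mean sits far outside the truncation window.
  hi <- a > 6
  lo <- b < -6
  out[hi] <- lower + sd / a[hi]
  out[lo] <- upper + sd / b[lo]
  out
}

# Latent mu such that the truncated mean equals `target`.
calibrate_tnorm_mu <- function(target, sd, lower, upper) {
  if (target <= lower || target >= upper) {
    abort(sprintf("Target mean %.2f outside truncation bounds [%g, %g].",
                  target, lower, upper),
          class = "bicea_parameter_error")
  }
  uniroot(function(mu) tnorm_mean(mu, sd, lower, upper) - target,
          interval = c(lower - 10 * sd, upper + 10 * sd),
          tol = 1e-10)$root
}

tnorm_density <- function(x, mu, sd, lower, upper) {
  z <- pnorm((upper - mu) / sd) - pnorm((lower - mu) / sd)
  dnorm((x - mu) / sd) / (sd * z)
}

# Latent intercept mu2 for the conditional follow-up draw
#   follow | base = x ~ TN(mu2 + k (x - mu1), s_c, a2, b2)
# such that the marginal mean of the (doubly truncated) follow-up equals
# `target2`, integrating over the truncated baseline distribution.
calibrate_followup_mu <- function(target2, mu1, sd1, a1, b1,
                                  sd2, rho, a2, b2) {
  k <- rho * sd2 / sd1
  s_c <- sd2 * sqrt(1 - rho^2)
  marginal_mean <- function(mu2) {
    integrate(function(x) {
      tnorm_mean(mu2 + k * (x - mu1), s_c, a2, b2) *
        tnorm_density(x, mu1, sd1, a1, b1)
    }, lower = a1, upper = b1, rel.tol = 1e-8)$value
  }
  uniroot(function(mu2) marginal_mean(mu2) - target2,
          interval = c(a2 - 10 * sd2, b2 + 10 * sd2), tol = 1e-8)$root
}

assist_lower_positive <- function(substance) {
  ifelse(substance == "alcohol", 11, 4)
}
.assist_max <- 39
.cesd_max <- 60

#' Parameters for the synthetic cohort generator
#'
#' Collects the statistical structure the generator emulates: screening
#' positivity, acceptance, arm allocation, per-arm truncated-normal score
#' distributions at baseline and follow-up, arm-specific loss to
#' follow-up, sequential PST-session retention, and the patient
#' transport-cost mixture. Defaults reproduce the packaged
#' emergency-department study: 19.4% positivity, 62.5% acceptance, the
#' published per-arm score means and SDs, follow-up of 60/62/42% for
#' control/MI/MI-PST, attendance decaying 109 to 87/77/69/65, and an 85%
#' zero / mean US$0.96-per-visit transport cost mixture.
#'
#' @param n_screened Number of patients screened.
#' @param p_positive,p_accept Screening positivity and acceptance
#'   probabilities.
#' @param arm_shares Named allocation shares for `control`, `mi`,
#'   `mi_pst` (normalised internally).
#' @param effects Per-arm score summary table (`scale`, `arm`,
#'   `baseline_mean`, `baseline_sd`, `followup_mean`, `followup_sd`).
#' @param p_followup Named per-arm follow-up probabilities.
#' @param pst_retention Probabilities of returning for each successive
#'   PST session (length 4).
#' @param substance_probs Named primary-substance mixture.
#' @param refused_mean,refused_sd Baseline involvement score distribution
#'   of patients who refuse participation.
#' @param baseline_followup_cor Correlation between baseline and
#'   follow-up scores (assumed, not observed; default 0.5).
#' @param transport_prop_zero Proportion of participants who walk (zero
#'   transport cost).
#' @param transport_mean_per_visit Overall mean transport cost per visit,
#'   zeros included.
#' @param p_time_off,p_income_loss Probabilities of taking time off work
#'   and of losing income, among attending participants.
#' @param followup_score_shift Optional missing-not-at-random knob: added
#'   to the follow-up logit per point of follow-up score above the arm
#'   mean (default 0, missing completely at random).
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(
    n_screened = 2736,
    p_positive = 531 / 2736,
    p_accept = 332 / 531,
    arm_shares = c(control = 110, mi = 113, mi_pst = 109) / 332,
    effects = strive_config()$effects,
    p_followup = c(control = 66 / 110, mi = 70 / 113, mi_pst = 46 / 109),
    pst_retention = c(87, 77, 69, 65) / c(109, 87, 77, 69),
    substance_probs = c(alcohol = 286, cannabis = 24,
                        methamphetamine = 20, other = 2) / 332,
    refused_mean = 15.68, refused_sd = 7.60,
    baseline_followup_cor = 0.5,
    transport_prop_zero = 0.85,
    transport_mean_per_visit = 0.96,
    p_time_off = 0.08, p_income_loss = 0.02,
    followup_score_shift = 0) {
  stopifnot(p_positive >= 0, p_positive <= 1, p_accept >= 0, p_accept <= 1,
            all(pst_retention >= 0), all(pst_retention <= 1),
            abs(baseline_followup_cor) < 1)
  if (any(effects$baseline_sd <= 0) || any(effects$followup_sd <= 0)) {
    abort("Score SDs must be positive.", class = "bicea_parameter_error")
  }
  params <- list(
    n_screened = n_screened, p_positive = p_positive, p_accept = p_accept,
    arm_shares = arm_shares / sum(arm_shares),
    effects = tibble::as_tibble(effects),
    p_followup = p_followup, pst_retention = pst_retention,
    substance_probs = substance_probs / sum(substance_probs),
    refused_mean = refused_mean, refused_sd = refused_sd,
    baseline_followup_cor = baseline_followup_cor,
    transport_prop_zero = transport_prop_zero,
    transport_mean_per_visit = transport_mean_per_visit,
    p_time_off = p_time_off, p_income_loss = p_income_loss,
    followup_score_shift = followup_score_shift)
  class(params) <- "cohort_params"
  params
}

#' Generate a synthetic patient-level cohort
#'
#' Simulates the screening-to-follow-up flow of an emergency-department
#' brief-intervention study: screening scores drawn so that moderate/high
#' risk classification matches the positivity rate, acceptance and 1:1:1
#' arm allocation, truncated-normal baseline and follow-up scores whose
#' realized means match the target summaries (latent means are calibrated
#' for the truncation), arm-specific loss to follow-up, sequential PST
#' attendance, and per-visit transport costs. Reproducible given `seed`.
#'
#' @param params A [cohort_params()] list.
#' @param seed Integer seed; every source of randomness flows from it.
#' @return A tibble with one row per screened patient: `id`, `arm`
#'   (`control`, `mi`, `mi_pst`, `refused`, `excluded`),
#'   `primary_substance`, `assist_baseline`, `assist_followup`,
#'   `cesd_baseline`, `cesd_followup`, `followed_up`,
#'   `pst_sessions_attended`, `visits`, `transport_total`,
#'   `took_time_off`, `lost_income`.
#' @examples
#' cohort <- generate_cohort(cohort_params(n_screened = 500), seed = 1)
#' effect_summaries(cohort)
#' @export
generate_cohort <- function(params, seed) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(as.integer(seed))
  n <- params$n_screened
  substance <- sample(names(params$substance_probs), n, replace = TRUE,
                      prob = params$substance_probs)
  positive <- rbinom(n, 1, params$p_positive) == 1
  accept <- positive & rbinom(n, 1, params$p_accept) == 1
  arm <- rep("excluded", n)
  arm[positive & !accept] <- "refused"
  arm[accept] <- sample(names(params$arm_shares), sum(accept),
                        replace = TRUE, prob = params$arm_shares)

  lower_pos <- assist_lower_positive(substance)
  assist_baseline <- numeric(n)
  cesd_baseline <- rep(NA_real_, n)
  assist_followup <- rep(NA_real_, n)
  cesd_followup <- rep(NA_real_, n)
  followed_up <- rep(FALSE, n)

  # Screen-negative: low-risk band.
  neg <- which(!positive)
  assist_baseline[neg] <- runif(length(neg), 0, pmax(lower_pos[neg] - 1, 0))
  # Refusers: positive band, lower involvement than participants.
  ref <- which(positive & !accept)
  assist_baseline[ref] <- rtnorm(length(ref), params$refused_mean,
                                 params$refused_sd, lower_pos[ref],
                                 .assist_max)

  eff <- params$effects
  rho <- params$baseline_followup_cor
  for (a in intersect(.strategies, unique(arm))) {
    idx <- which(arm == a)
    e_as <- eff[eff$scale == "assist" & eff$arm == a, ]
    e_dp <- eff[eff$scale == "cesd" & eff$arm == a, ]
    p_fu <- params$p_followup[[a]]
    followed_up[idx] <- rbinom(length(idx), 1, p_fu) == 1

    # ASSIST scores respect the positive band of the primary substance;
    # latent means are calibrated per band so each subgroup hits the
    # targets, hence so does the mixture.
    k_a <- rho * e_as$followup_sd / e_as$baseline_sd
    for (lp in unique(lower_pos[idx])) {
      sub <- idx[lower_pos[idx] == lp]
      mu1 <- calibrate_tnorm_mu(e_as$baseline_mean, e_as$baseline_sd,
                                lp, .assist_max)
      assist_baseline[sub] <- rtnorm(length(sub), mu1, e_as$baseline_sd,
                                     lp, .assist_max)
      comp <- sub[followed_up[sub]]
      if (length(comp)) {
        mu2 <- calibrate_followup_mu(
          e_as$followup_mean, mu1, e_as$baseline_sd, lp, .assist_max,
          e_as$followup_sd, rho, 0, .assist_max)
        assist_followup[comp] <- rtnorm(
          length(comp), mu2 + k_a * (assist_baseline[comp] - mu1),
          e_as$followup_sd * sqrt(1 - rho^2), 0, .assist_max)
      }
    }

    cesd_mu1 <- calibrate_tnorm_mu(e_dp$baseline_mean, e_dp$baseline_sd,
                                   0, .cesd_max)
    cesd_baseline[idx] <- rtnorm(length(idx), cesd_mu1, e_dp$baseline_sd,
                                 0, .cesd_max)
    comp <- idx[followed_up[idx]]
    if (length(comp)) {
      mu2_d <- calibrate_followup_mu(
        e_dp$followup_mean, cesd_mu1, e_dp$baseline_sd, 0, .cesd_max,
        e_dp$followup_sd, rho, 0, .cesd_max)
      k_d <- rho * e_dp$followup_sd / e_dp$baseline_sd
      cesd_followup[comp] <- rtnorm(
        length(comp), mu2_d + k_d * (cesd_baseline[comp] - cesd_mu1),
        e_dp$followup_sd * sqrt(1 - rho^2), 0, .cesd_max)
    }
  }

  # Optional missing-not-at-random adjustment (default off): re-draw
  # follow-up status with the logit shifted by the follow-up score.
  if (params$followup_score_shift != 0) {
    for (a in intersect(.strategies, unique(arm))) {
      idx <- which(arm == a & !is.na(assist_followup))
      dev <- assist_followup[idx] - mean(assist_followup[idx])
      p <- stats::plogis(stats::qlogis(params$p_followup[[a]]) +
                           params$followup_score_shift * dev)
      followed_up[idx] <- rbinom(length(idx), 1, p) == 1
    }
    assist_followup[!followed_up] <- NA_real_
    cesd_followup[!followed_up] <- NA_real_
  }

  # PST attendance: sequential retention after the MI session.
  pst <- rep(0L, n)
  mipst <- which(arm == "mi_pst")
  still <- rep(TRUE, length(mipst))
  for (s in seq_along(params$pst_retention)) {
    still <- still & rbinom(length(mipst), 1, params$pst_retention[s]) == 1
    pst[mipst[still]] <- s
  }

  # Transport costs attach to attended PST visits.
  visits <- pst
  transport_total <- numeric(n)
  walker <- rbinom(n, 1, params$transport_prop_zero) == 1
  payers <- which(visits > 0 & !walker)
  mean_paid <- params$transport_mean_per_visit /
    (1 - params$transport_prop_zero)
  transport_total[payers] <- vapply(
    visits[payers],
    function(v) sum(rgamma(v, shape = 2, scale = mean_paid / 2)),
    numeric(1))
  attends <- visits > 0
  took_time_off <- attends & rbinom(n, 1, params$p_time_off) == 1
  lost_income <- took_time_off & rbinom(n, 1, pmin(
    1, params$p_income_loss / params$p_time_off)) == 1

  tibble::tibble(
    id = seq_len(n), arm = arm, primary_substance = substance,
    assist_baseline = assist_baseline, assist_followup = assist_followup,
    cesd_baseline = cesd_baseline, cesd_followup = cesd_followup,
    followed_up = followed_up, pst_sessions_attended = pst,
    visits = visits, transport_total = transport_total,
    took_time_off = took_time_off, lost_income = lost_income)
}

#' Aggregate cohort counts from patient records
#'
#' Tallies the flow counts the costing and decision-tree stages need from
#' a patient-record table.
#'
#' @param records A patient-record tibble (see [generate_cohort()]).
#' @param n_counsellors Number of counsellors delivering the programme.
#' @return A named list: `screened`, `positive`, `accepted`, per-arm
#'   sizes, completer counts and `n_counsellors`.
#' @export
cohort_counts <- function(records, n_counsellors = 5) {
  arm <- records$arm
  counts <- list(
    screened = nrow(records),
    positive = sum(arm != "excluded"),
    accepted = sum(arm %in% .strategies),
    n_counsellors = n_counsellors)
  for (a in .strategies) {
    counts[[paste0("n_", a)]] <- sum(arm == a)
    counts[[paste0("completers_", a)]] <- sum(arm == a & records$followed_up)
  }
  counts
}

#' PST attendance counts from patient records
#'
#' Numbers still attending at the MI session and at each PST session,
#' among MI-PST participants.
#'
#' @param records A patient-record tibble.
#' @return Integer vector of length 5.
#' @export
pst_attendance_counts <- function(records) {
  k <- records$pst_sessions_attended[records$arm == "mi_pst"]
  vapply(0:4, function(s) sum(k >= s), integer(1))
}

# Deterministic score vector with exact sample mean and SD, kept within
# +/- one SD of the mean so scale/band bounds are respected.
two_point_scores <- function(n, mean, sd) {
  if (n == 1) return(mean)
  if (n %% 2 == 0) {
    d <- sd * sqrt((n - 1) / n)
    rep(c(mean - d, mean + d), n / 2)
  } else {
    d <- sd
    c(mean, rep(c(mean - d, mean + d), (n - 1) / 2))
  }
}

#' Deterministic packaged cohort reproducing the study flow
#'
#' A fully deterministic patient-level table whose aggregate counts equal
#' the published flow exactly — 2736 screened, 531 positive, 332 enrolled
#' (110/113/109 in control/MI/MI-PST), 66/70/46 completers, PST
#' attendance 109/87/77/69/65 — and whose completer score summaries match
#' the published per-arm means and SDs exactly (two-point moment
#' matching; the scores are synthetic, not the trial's). Transport costs
#' are placed so the mean cost per visit is exactly US$0.96 with 85% of
#' attendees paying nothing.
#'
#' @return A patient-record tibble (see [generate_cohort()]).
#' @examples
#' records <- strive_fixture()
#' effect_summaries(records)
#' @export
strive_fixture <- function() {
  arms <- c(control = 110, mi = 113, mi_pst = 109)
  completers <- c(control = 66, mi = 70, mi_pst = 46)
  eff <- strive_config()$effects

  make_arm <- function(a) {
    n <- arms[[a]]
    nc <- completers[[a]]
    e_as <- eff[eff$scale == "assist" & eff$arm == a, ]
    e_dp <- eff[eff$scale == "cesd" & eff$arm == a, ]
    base_as <- c(two_point_scores(nc, e_as$baseline_mean, e_as$baseline_sd),
                 rep(e_as$baseline_mean, n - nc))
    fol_as <- c(two_point_scores(nc, e_as$followup_mean, e_as$followup_sd),
                rep(NA_real_, n - nc))
    base_dp <- c(two_point_scores(nc, e_dp$baseline_mean, e_dp$baseline_sd),
                 rep(e_dp$baseline_mean, n - nc))
    fol_dp <- c(two_point_scores(nc, e_dp$followup_mean, e_dp$followup_sd),
                rep(NA_real_, n - nc))
    tibble::tibble(
      arm = a, primary_substance = "alcohol",
      assist_baseline = base_as, assist_followup = fol_as,
      cesd_baseline = base_dp, cesd_followup = fol_dp,
      followed_up = c(rep(TRUE, nc), rep(FALSE, n - nc)))
  }
  accepted <- dplyr::bind_rows(purrr::map(names(arms), make_arm))

  # Attendance: exactly 22/10/8/4 drop after 0-3 PST sessions, 65 complete.
  drop_after <- c(109 - 87, 87 - 77, 77 - 69, 69 - 65, 65)
  pst_k <- rep(0:4, times = drop_after)
  accepted$pst_sessions_attended <- 0L
  accepted$pst_sessions_attended[accepted$arm == "mi_pst"] <- pst_k

  refused <- tibble::tibble(
    arm = "refused", primary_substance = "alcohol",
    assist_baseline = two_point_scores(199, 15.68, 4.6),
    assist_followup = NA_real_,
    cesd_baseline = 20, cesd_followup = NA_real_,
    followed_up = FALSE, pst_sessions_attended = 0L)
  excluded <- tibble::tibble(
    arm = "excluded", primary_substance = "alcohol",
    assist_baseline = 5, assist_followup = NA_real_,
    cesd_baseline = 15, cesd_followup = NA_real_,
    followed_up = FALSE, pst_sessions_attended = 0L)[rep(1, 2205), ]

  records <- dplyr::bind_rows(accepted, refused, excluded)
  records$visits <- records$pst_sessions_attended
  # 13 of the 87 attendees pay (74 walk, 85.1%); payers are
  # four-session completers paying a flat rate per visit chosen so the
  # overall mean per visit is exactly 0.96.
  attendee <- which(records$visits > 0)
  total_visits <- sum(records$visits)
  payers <- attendee[records$visits[attendee] == 4][1:13]
  rate <- 0.96 * total_visits / sum(records$visits[payers])
  records$transport_total <- 0
  records$transport_total[payers] <- rate * records$visits[payers]
  records$took_time_off <- FALSE
  records$took_time_off[attendee[1:7]] <- TRUE
  records$lost_income <- FALSE
  records$lost_income[attendee[1:2]] <- TRUE
  records$id <- seq_len(nrow(records))
  dplyr::relocate(records, "id")
}
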