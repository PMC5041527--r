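# Synthetic matched case-control questionnaire studies with known ground
# truth: the statistical structure the matched and propensity analyses
# assume, generated so every pipeline stage is testable without patient
# data.

#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline targets: a multi-center
#' case-control study where each case's family recruits up to two friends or
#' schoolmates as controls (so controls share the case's reference age and,
#' partially, its environment), a mixed binary/ordinal questionnaire, and
#' covariate-driven confounding. The control pattern defaults to the
#' observed 1077:451:241 mix of cases with 0/1/2 controls; SES weights to
#' the observed 837:725:278 split; the reference-age distribution is a Beta
#' shape on the 0.5-15.5 year window matching the observed median of about
#' 7.5 years; delays are lognormal around 3 years, truncated at the
#' exclusion ceiling so that the default world is the post-exclusion regime.
#' Missingness is mildly differential (cases 5 %, controls 4 %), mirroring
#' the observed asymmetry.
#'
#' @param n_cases Number of cases.
#' @param control_pattern Proportions of cases with 0, 1, 2 controls
#'   (normalized internally).
#' @param n_variables Total questionnaire variables (default 200 for test
#'   speed; set 845 for full-scale runs).
#' @param prop_binary Fraction of binary variables; ordinal variables cycle
#'   through 3, 4, 5 levels.
#' @param reversed_fraction Fraction of questions declared with reversed
#'   orientation (exercises the encoding path; no statistical effect).
#' @param effects Named numeric vector: per-variable log-odds effect of case
#'   status per unit of encoded exposure (extreme-response log odds ratio).
#'   Names must be variable ids (`"v001"`, ...). Unnamed variables are null.
#' @param confounding Named list: per variable id, a numeric vector
#'   `c(age = , ses = , urban = , pct_farmers = )` of coefficients linking
#'   the (standardized) covariate to the exposure's linear predictor. NULL
#'   for no confounding.
#' @param miss_case,miss_control Per-variable missingness rates.
#' @param matching_fidelity Probability that a control copies its case's
#'   categorical covariates (and mixing weight for continuous ones);
#'   friends/schoolmates share environment.
#' @param orphan_control_rate Fraction of additional controls whose case
#'   never returned a questionnaire (they are dropped when building the
#'   matched sample), relative to the number of matched controls.
#' @param control_tilt_ses,control_tilt_urban Log-odds tilts applied to the
#'   SES and urban-unit-index distributions of freshly drawn *control*
#'   covariates (defaults 0 = controls exchangeable with cases). Nonzero
#'   values emulate participation bias -- e.g. more affluent or more urban
#'   families volunteering as controls -- which turns covariates into
#'   genuine confounders of any covariate-driven exposure: the regime the
#'   propensity analysis exists to correct.
#' @param n_centers Number of recruitment centers (sizes roughly Zipf).
#' @param ses_weights,age_shape1,age_shape2 Covariate model knobs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 1769L,
                       control_pattern = c(1077, 451, 241),
                       n_variables = 200L,
                       prop_binary = 0.5,
                       reversed_fraction = 0.1,
                       effects = NULL,
                       confounding = NULL,
                       miss_case = 0.05,
                       miss_control = 0.04,
                       matching_fidelity = 0.7,
                       orphan_control_rate = 152 / 933,
                       control_tilt_ses = 0,
                       control_tilt_urban = 0,
                       n_centers = 25L,
                       ses_weights = c(837, 725, 278),
                       age_shape1 = 1.5, age_shape2 = 1.7) {
  stopifnot(n_cases >= 1L, n_variables >= 1L, length(control_pattern) == 3L,
            all(control_pattern >= 0), sum(control_pattern) > 0,
            miss_case >= 0, miss_case <= 1, miss_control >= 0,
            miss_control <= 1, matching_fidelity >= 0, matching_fidelity <= 1)
  if (!is.null(effects)) {
    stopifnot(!is.null(names(effects)), all(is.finite(effects)))
  }
  structure(list(
    n_cases = as.integer(n_cases),
    control_pattern = control_pattern / sum(control_pattern),
    n_variables = as.integer(n_variables), prop_binary = prop_binary,
    reversed_fraction = reversed_fraction, effects = effects,
    confounding = confounding, miss_case = miss_case,
    miss_control = miss_control, matching_fidelity = matching_fidelity,
    orphan_control_rate = orphan_control_rate,
    control_tilt_ses = control_tilt_ses,
    control_tilt_urban = control_tilt_urban,
    n_centers = as.integer(n_centers),
    ses_weights = ses_weights / sum(ses_weights),
    age_shape1 = age_shape1, age_shape2 = age_shape2
  ), class = "sim_config")
}

# Variable ids are zero-padded so lexicographic order equals definition
# order, keeping screens deterministic.
sim_variable_ids <- function(n) sprintf("v%03d", seq_len(n))

# Build the questionnaire spec implied by a config (deterministic given the
# RNG state: reversed flags are drawn).
sim_questionnaire <- function(config) {
  n <- config$n_variables
  ids <- sim_variable_ids(n)
  n_bin <- round(n * config$prop_binary)
  kinds <- rep(c("binary", "ordinal"), c(n_bin, n - n_bin))
  lev_counts <- ifelse(kinds == "binary", 2L,
                       3L + (seq_len(n) %% 3L))
  reversed <- stats::runif(n) < config$reversed_fraction
  qs <- lapply(seq_len(n), function(i) {
    L <- lev_counts[i]
    labels <- if (L == 2L) c("no", "yes") else paste0("lvl", seq_len(L))
    question_def(ids[i], labels,
                 orientation = if (reversed[i]) "reversed" else "as_is")
  })
  questionnaire_spec(qs)
}

# Draw one commune profile per participant: urban-unit index 0 (rural) to 8
# (largest urban area) with a bimodal rural/metropolitan weighting, and a
# percent-farmers fraction that shrinks with urbanization. `tilt` applies a
# log-odds gradient over the index (participation bias for controls).
sim_commune <- function(n, tilt = 0) {
  prob <- c(4, 2, 2, 1.5, 1.5, 1.5, 1, 1, 4) * exp(tilt * (0:8) / 8)
  uui <- sample(0:8, n, replace = TRUE, prob = prob)
  pf <- stats::rbeta(n, 1, 1 + 2 * uui) * 0.3
  list(urban_unit_index = uui, pct_farmers = pf)
}

sim_ses <- function(n, weights, tilt = 0) {
  sample(0:2, n, replace = TRUE, prob = weights * exp(tilt * (0:2)))
}

rtrunc_lnorm <- function(n, meanlog, sdlog, upper) {
  pmax_u <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, 0, pmax_u), meanlog, sdlog)
}

#' Simulate a matched case-control questionnaire study
#'
#' Generative order: per case, draw center, commune, SES and reference age;
#' attach 0-2 controls that inherit the case's reference age exactly and its
#' other covariates with probability `matching_fidelity` (fresh draws
#' otherwise; continuous covariates are convex mixtures); draw each
#' exposure from a logistic (binary) or proportional-odds (ordinal) model
#' with the configured confounding terms; tilt the exposure distribution of
#' cases by `exp(effect x encoded value)` -- retrospective sampling, so the
#' configured effect *is* the extreme-response log odds ratio; apply
#' missingness; emit response labels. Identical config + seed give identical
#' output.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `dataset` (a [study_dataset()]) and `truth`, a list of
#'   class `sim_truth`: `effects` (full named log-OR vector, zeros for null
#'   variables), `confounding`, `config`, `seed`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  nc <- config$n_cases
  spec <- sim_questionnaire(config)
  ids <- names(spec)

  # --- cases ---------------------------------------------------------------
  center <- sprintf("C%02d", sample(seq_len(config$n_centers), nc,
                                    replace = TRUE,
                                    prob = 1 / seq_len(config$n_centers)))
  comm <- sim_commune(nc)
  ses <- sample(0:2, nc, replace = TRUE, prob = config$ses_weights)
  age <- 0.5 + 15 * stats::rbeta(nc, config$age_shape1, config$age_shape2)
  delay <- rtrunc_lnorm(nc, log(3), 1, upper = 10)
  n_controls <- sample(0:2, nc, replace = TRUE, prob = config$control_pattern)

  cases <- data.frame(
    participant_id = sprintf("case%04d", seq_len(nc)),
    status = "case",
    matched_set_id = sprintf("set%04d", seq_len(nc)),
    reference_age = age, delay = delay, ses = ses,
    urban_unit_index = comm$urban_unit_index, pct_farmers = comm$pct_farmers,
    center_id = center, stringsAsFactors = FALSE
  )

  # --- matched controls ----------------------------------------------------
  case_idx <- rep(seq_len(nc), n_controls)
  ncm <- length(case_idx)
  w <- config$matching_fidelity
  copy <- function(case_vals, fresh_vals) {
    keep <- stats::runif(ncm) < w
    ifelse(keep, case_vals[case_idx], fresh_vals)
  }
  comm_f <- sim_commune(ncm, config$control_tilt_urban)
  controls <- data.frame(
    participant_id = sprintf("ctrl%04d", seq_len(ncm)),
    status = "control",
    matched_set_id = cases$matched_set_id[case_idx],
    reference_age = cases$reference_age[case_idx],  # same age by design
    delay = NA_real_,                               # inherited at exclusion
    ses = as.integer(copy(cases$ses,
                          sim_ses(ncm, config$ses_weights,
                                  config$control_tilt_ses))),
    urban_unit_index = as.integer(copy(cases$urban_unit_index,
                                       comm_f$urban_unit_index)),
    pct_farmers = w * cases$pct_farmers[case_idx] +
      (1 - w) * comm_f$pct_farmers,
    center_id = copy(cases$center_id,
                     sprintf("C%02d", sample(seq_len(config$n_centers), ncm,
                                             replace = TRUE,
                                             prob = 1 / seq_len(config$n_centers)))),
    stringsAsFactors = FALSE
  )

  # --- orphan controls (their case never returned a questionnaire) --------
  no <- round(config$orphan_control_rate * ncm)
  if (no > 0) {
    comm_o <- sim_commune(no, config$control_tilt_urban)
    orphans <- data.frame(
      participant_id = sprintf("orph%04d", seq_len(no)),
      status = "control",
      matched_set_id = sprintf("oset%04d", seq_len(no)),
      reference_age = 0.5 + 15 * stats::rbeta(no, config$age_shape1,
                                              config$age_shape2),
      delay = NA_real_,
      ses = sim_ses(no, config$ses_weights, config$control_tilt_ses),
      urban_unit_index = comm_o$urban_unit_index,
      pct_farmers = comm_o$pct_farmers,
      center_id = sprintf("C%02d", sample(seq_len(config$n_centers), no,
                                          replace = TRUE,
                                          prob = 1 / seq_len(config$n_centers))),
      stringsAsFactors = FALSE
    )
    participants <- rbind(cases, controls, orphans)
  } else {
    participants <- rbind(cases, controls)
  }
  n <- nrow(participants)
  # reported primary-school attendance, consistent with age
  participants$attended_primary_school <-
    stats::runif(n) < stats::plogis(2 * (participants$reference_age - 6))

  # --- exposures -----------------------------------------------------------
  effects <- stats::setNames(rep(0, length(ids)), ids)
  if (!is.null(config$effects)) {
    unknown <- setdiff(names(config$effects), ids)
    if (length(unknown)) {
      stop("effects name unknown variables: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    effects[names(config$effects)] <- config$effects
  }
  # standardized covariates entering the exposure models
  zage <- as.numeric(scale(participants$reference_age))
  zses <- participants$ses - 1
  zurb <- as.numeric(scale(participants$urban_unit_index))
  zpf <- as.numeric(scale(participants$pct_farmers))
  is_case <- participants$status == "case"

  responses <- matrix(NA_character_, n, length(ids),
                      dimnames = list(participants$participant_id, ids))
  miss_rate <- ifelse(is_case, config$miss_case, config$miss_control)

  for (v in ids) {
    q <- spec[[v]]
    L <- length(q$levels)
    enc <- seq_len(L) - 1
    if (q$orientation == "reversed") enc <- rev(enc)
    enc <- enc / (L - 1)                     # encoded value of each level

    conf <- config$confounding[[v]]
    eta <- if (is.null(conf)) {
      numeric(n)
    } else {
      conf <- conf[c("age", "ses", "urban", "pct_farmers")]
      conf[is.na(conf)] <- 0
      conf[["age"]] * zage + conf[["ses"]] * zses +
        conf[["urban"]] * zurb + conf[["pct_farmers"]] * zpf
    }
    # population level probabilities (n x L)
    if (L == 2L) {
      # columns follow the declared level order; confounding and tilt act on
      # the encoded values, so orientation needs no special casing
      alpha <- stats::qlogis(stats::runif(1, 0.15, 0.85))
      p1 <- stats::plogis(alpha + eta)
      pr <- cbind(1 - p1, p1)
    } else {
      base <- stats::rgamma(L, 2)
      base <- base / sum(base)
      theta <- stats::qlogis(cumsum(base)[-L])  # proportional-odds cutpoints
      cum <- stats::plogis(outer(-eta, theta, `+`))  # P(level <= k)
      pr <- cbind(cum, 1)
      pr <- pr - cbind(0, cum)
    }
    # retrospective tilt: cases' level odds multiplied by exp(beta * enc)
    b <- effects[[v]]
    if (b != 0) {
      tilt <- exp(b * enc)
      pr[is_case, ] <- pr[is_case, , drop = FALSE] *
        matrix(tilt, sum(is_case), L, byrow = TRUE)
      pr[is_case, ] <- pr[is_case, , drop = FALSE] /
        rowSums(pr[is_case, , drop = FALSE])
    }
    # vectorized categorical draw by inverse CDF (cumsum across <= 5 cols)
    u <- stats::runif(n)
    for (k in seq_len(L - 1) + 1L) pr[, k] <- pr[, k] + pr[, k - 1L]
    pr[, L] <- 1  # guard against floating-point undershoot
    lev <- rowSums(u > pr) + 1L
    lab <- q$levels[lev]
    lab[stats::runif(n) < miss_rate] <- NA_character_
    responses[, v] <- lab
  }

  truth <- structure(list(effects = effects,
                          confounding = config$confounding,
                          config = config, seed = seed),
                     class = "sim_truth")
  list(dataset = study_dataset(participants, responses, spec), truth = truth)
}

#' Score a screen against simulation ground truth
#'
#' @param results Screen output ([run_matched_screen()] or
#'   [run_propensity_screen()]).
#' @param truth `sim_truth` from [simulate_study()] of the same run.
#' @param reject Optional logical vector aligned with `results` rows (e.g.
#'   from [bonferroni_holm()] or [benjamini_hochberg()]); defaults to the
#'   uncorrected rule `p < alpha`.
#' @param alpha Level for the default rejection rule.
#' @return List of class `screen_metrics`: `n_tests`, `type1` (rejection
#'   rate among null variables), `any_false_rejection` (the per-replicate
#'   FWER contribution), `fdp` (false-discovery proportion; 0 when nothing
#'   is rejected), `power` (rejection rate among non-null variables; NA if
#'   none), `bias_log_or`, `rmse_log_or`, `ci_coverage` (share of ok-status
#'   non-null variables whose CI covers the true OR).
#' @export
evaluate_screen <- function(results, truth, reject = NULL, alpha = 0.05) {
  stopifnot(inherits(truth, "sim_truth"))
  unknown <- setdiff(results$variable_id, names(truth$effects))
  if (length(unknown)) {
    stop("results contain variables absent from truth: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  beta <- truth$effects[results$variable_id]
  is_null <- beta == 0
  ok <- results$status == "ok" & !is.na(results$p_value)
  if (is.null(reject)) reject <- ok & results$p_value < alpha
  reject <- reject & ok

  n_rej <- sum(reject)
  fdp <- if (n_rej > 0) sum(reject & is_null) / n_rej else 0
  log_or <- suppressWarnings(log(results$effect_size))
  err <- log_or[ok & !is_null] - beta[ok & !is_null]
  cover <- results$ci_low <= exp(beta) & exp(beta) <= results$ci_high
  structure(list(
    n_tests = sum(ok),
    type1 = if (any(ok & is_null)) mean(reject[ok & is_null]) else NA_real_,
    any_false_rejection = any(reject & is_null),
    fdp = fdp,
    power = if (any(ok & !is_null)) mean(reject[ok & !is_null]) else NA_real_,
    bias_log_or = if (length(err)) mean(err) else NA_real_,
    rmse_log_or = if (length(err)) sqrt(mean(err^2)) else NA_real_,
    ci_coverage = if (any(ok & !is_null)) mean(cover[ok & !is_null]) else NA_real_
  ), class = "screen_metrics")
}
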