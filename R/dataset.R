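#' Bundle participants, responses and questionnaire into a study dataset
#'
#' The container every pipeline stage operates on: a participant table with
#' covariates and matching structure, the raw response table, and the
#' questionnaire specification. Encoding is done lazily by
#' [encode_variables()]; `study_dataset()` only validates structure.
#'
#' @param participants data.frame with columns `participant_id`, `status`
#'   (`"case"`/`"control"`), `matched_set_id` (NA when unmatched),
#'   `reference_age` (years, continuous), `delay` (years between diagnosis
#'   and questionnaire reception; NA for unmatched controls), `ses` (0/1/2),
#'   `urban_unit_index`, `pct_farmers`, `center_id`,
#'   `attended_primary_school` (logical, NA allowed).
#' @param responses Response table as accepted by [encode_variables()].
#' @param spec A [questionnaire_spec()].
#' @return An object of class `study_dataset`: a list with elements
#'   `participants`, `responses`, `spec`.
#' @export
study_dataset <- function(participants, responses, spec) {
  stopifnot(is.data.frame(participants), inherits(spec, "questionnaire_spec"))
  required <- c("participant_id", "status", "matched_set_id", "reference_age",
                "delay", "ses", "urban_unit_index", "pct_farmers", "center_id",
                "attended_primary_school")
  miss <- setdiff(required, names(participants))
  if (length(miss)) {
    stop("participants table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  participants$participant_id <- as.character(participants$participant_id)
  if (anyDuplicated(participants$participant_id)) {
    stop("duplicated participant_id", call. = FALSE)
  }
  if (!all(participants$status %in% c("case", "control"))) {
    stop("status must be 'case' or 'control'", call. = FALSE)
  }
  responses <- as_response_table(responses)
  unknown <- setdiff(participants$participant_id, rownames(responses))
  if (length(unknown)) {
    stop("participants without response rows: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  # a control's matched_set_id must point at exactly one case when present
  ms <- participants$matched_set_id
  case_sets <- ms[participants$status == "case" & !is.na(ms)]
  if (anyDuplicated(case_sets)) {
    stop("a matched_set_id is shared by several cases", call. = FALSE)
  }
  responses <- responses[participants$participant_id, , drop = FALSE]
  structure(list(participants = participants, responses = responses, spec = spec),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  p <- x$participants
  cat("study_dataset:", nrow(p), "participants (",
      sum(p$status == "case"), "cases,", sum(p$status == "control"),
      "controls ),", length(x$spec), "variables\n")
  invisible(x)
}

#' Default exclusion-cascade configuration
#'
#' Thresholds of the staged exclusions: questionnaires more than half empty,
#' reference age outside the childhood window, diagnosis-to-questionnaire
#' delay over 10 years (a recall-quality guard), and the primary-school
#' consistency check (reporting primary-school attendance below age 5.5
#' flags unreliable recall).
#'
#' @param missingness_max Maximum tolerated fraction of unanswered questions.
#' @param age_min,age_max Reference-age window in years.
#' @param delay_max Maximum delay in years.
#' @param school_age_cut Age below which reported primary-school attendance
#'   is inconsistent.
#' @param sd_min Minimum per-variable standard deviation for [sd_filter()].
#' @return A named list of thresholds.
#' @export
exclusion_config <- function(missingness_max = 0.5, age_min = 0.5,
                             age_max = 15.5, delay_max = 10,
                             school_age_cut = 5.5, sd_min = 0.1) {
  list(missingness_max = missingness_max, age_min = age_min, age_max = age_max,
       delay_max = delay_max, school_age_cut = school_age_cut, sd_min = sd_min)
}

#' Apply the participant exclusion cascade
#'
#' Rules are conjunctive and applied in a fixed, documented order --
#' missingness, age window, delay, school consistency -- so the retained set
#' does not depend on the order but the log (which records the *first*
#' triggering rule per participant) is stable. A control without its own
#' delay inherits the delay of its matched case; unmatched controls with no
#' delay are exempt from the delay rule. Participants with a missing
#' reference age are removed with the distinct rule code
#' `"unusable_missing_age"`.
#'
#' @param dataset A [study_dataset()].
#' @param rules An [exclusion_config()].
#' @return A list with `dataset` (the filtered `study_dataset`) and `log`, a
#'   data.frame with columns `participant_id`, `excluded` (logical) and
#'   `rule` (NA for retained participants).
#' @export
apply_exclusions <- function(dataset, rules = exclusion_config()) {
  stopifnot(inherits(dataset, "study_dataset"))
  p <- dataset$participants
  n_items <- length(dataset$spec)
  resp <- dataset$responses[, names(dataset$spec), drop = FALSE]
  missfrac <- rowSums(is.na(resp)) / n_items

  # effective delay: controls take their matched case's delay
  delay <- p$delay
  case_delay <- stats::setNames(
    p$delay[p$status == "case"],
    p$matched_set_id[p$status == "case"]
  )
  is_ctrl <- p$status == "control"
  has_set <- !is.na(p$matched_set_id)
  idx <- is_ctrl & has_set & (p$matched_set_id %in% names(case_delay))
  delay[idx] <- unname(case_delay[as.character(p$matched_set_id[idx])])

  rule <- rep(NA_character_, nrow(p))
  hit <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    rule[is.na(rule) & cond] <<- code
  }
  hit(missfrac > rules$missingness_max, "missingness")
  hit(is.na(p$reference_age), "unusable_missing_age")
  hit(p$reference_age < rules$age_min | p$reference_age > rules$age_max,
      "age_window")
  hit(!is.na(delay) & delay > rules$delay_max, "delay")
  hit(!is.na(p$attended_primary_school) & p$attended_primary_school &
        p$reference_age < rules$school_age_cut, "school_consistency")

  keep <- is.na(rule)
  log <- data.frame(participant_id = p$participant_id, excluded = !keep,
                    rule = rule, stringsAsFactors = FALSE)
  filtered <- dataset
  filtered$participants <- p[keep, , drop = FALSE]
  filtered$responses <- dataset$responses[p$participant_id[keep], , drop = FALSE]
  list(dataset = filtered, log = log)
}

#' Build the matched analysis sample
#'
#' After exclusions, keeps only complete matched sets: each stratum is one
#' case and the one or two of its controls that survived. Cases whose
#' controls were all removed, and controls whose case was removed (or never
#' returned a questionnaire), are dropped and logged.
#'
#' @param dataset A post-exclusion [study_dataset()].
#' @return A list with `sample` -- a data.frame (`participant_id`,
#'   `stratum_id`, `status`) defining the matched strata -- and `dropped`, a
#'   data.frame (`participant_id`, `reason`) for participants excluded as
#'   unmatched.
#' @export
build_matched_sample <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  p <- dataset$participants
  has_set <- !is.na(p$matched_set_id)
  case_sets <- unique(p$matched_set_id[p$status == "case" & has_set])
  ctrl_sets <- unique(p$matched_set_id[p$status == "control" & has_set])
  complete <- intersect(case_sets, ctrl_sets)
  in_sample <- has_set & p$matched_set_id %in% complete
  sample <- data.frame(participant_id = p$participant_id[in_sample],
                       stratum_id = as.character(p$matched_set_id[in_sample]),
                       status = p$status[in_sample], stringsAsFactors = FALSE)
  dropped <- data.frame(
    participant_id = p$participant_id[!in_sample],
    reason = ifelse(p$status[!in_sample] == "case",
                    "case_without_control", "control_without_case"),
    stringsAsFactors = FALSE
  )
  dropped$reason[!has_set[!in_sample]] <- ifelse(
    p$status[!in_sample][!has_set[!in_sample]] == "case",
    "case_without_control", "control_without_case")
  list(sample = sample, dropped = dropped)
}

#' Build the propensity analysis sample
#'
#' The propensity analysis ignores matching; it only requires the covariates
#' used for bias control. Retains every participant (matched or not) with
#' non-missing commune covariates (urban unit index and percent farmers,
#' both derived from the postal code), parental-profession SES, recruitment
#' center and reference age.
#'
#' @param dataset A post-exclusion [study_dataset()].
#' @return A list with `sample` -- data.frame (`participant_id`, `status`) --
#'   and `dropped` (participants lacking covariates, with reasons).
#' @export
build_propensity_sample <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  p <- dataset$participants
  lack_commune <- is.na(p$urban_unit_index) | is.na(p$pct_farmers)
  lack_ses <- is.na(p$ses)
  lack_center <- is.na(p$center_id)
  lack_age <- is.na(p$reference_age)
  keep <- !(lack_commune | lack_ses | lack_center | lack_age)
  reason <- rep(NA_character_, nrow(p))
  reason[lack_age] <- "missing_reference_age"
  reason[lack_center] <- "missing_center"
  reason[lack_ses] <- "missing_profession"
  reason[lack_commune] <- "missing_postal_code"
  list(
    sample = data.frame(participant_id = p$participant_id[keep],
                        status = p$status[keep], stringsAsFactors = FALSE),
    dropped = data.frame(participant_id = p$participant_id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  )
}

#' Filter near-constant variables
#'
#' Variables with tiny variance make stratified tests and conditional
#' logistic fits unstable, so any variable whose standard deviation
#' (population formula, divisor n, over non-missing values of the analysis
#' sample -- cases and controls pooled) falls below the threshold is removed
#' before testing. A variable entirely missing in the sample is dropped with
#' a distinct flag.
#'
#' @param matrix Encoded matrix from [encode_variables()].
#' @param sample_ids Participant ids defining the analysis sample.
#' @param threshold Minimum standard deviation (default 0.1).
#' @return data.frame with columns `variable_id`, `sd`, `kept` (logical) and
#'   `reason` (`NA`, `"low_sd"` or `"all_missing"`).
#' @export
sd_filter <- function(matrix, sample_ids, threshold = 0.1) {
  stopifnot(threshold >= 0, length(sample_ids) > 0)
  m <- matrix[as.character(sample_ids), , drop = FALSE]
  n <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  sqdev <- sweep(m, 2L, mu)^2
  sdv <- sqrt(colSums(sqdev, na.rm = TRUE) / n)   # population sd, divisor n
  sdv[n == 0L] <- NA_real_
  kept <- !is.na(sdv) & sdv >= threshold
  reason <- rep(NA_character_, ncol(m))
  reason[!kept] <- "low_sd"
  reason[n == 0L] <- "all_missing"
  data.frame(variable_id = colnames(m), sd = unname(sdv), kept = kept,
             reason = reason, stringsAsFactors = FALSE)
}
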