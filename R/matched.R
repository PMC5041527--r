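# Per-variable association screen over matched strata: CMH for binary
# variables, conditional logistic regression for ordinal ones.

# Template row so every variable yields a record even when filtered or
# degenerate.
result_row <- function(variable_id, analysis, p_value = NA_real_,
                       effect_size = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, n_cases_used = NA_integer_,
                       n_controls_used = NA_integer_,
                       missing_pct_cases = NA_real_,
                       missing_pct_controls = NA_real_, status = "ok") {
  data.frame(variable_id = variable_id, analysis = analysis,
             p_value = p_value, effect_size = effect_size, ci_low = ci_low,
             ci_high = ci_high, n_cases_used = n_cases_used,
             n_controls_used = n_controls_used,
             missing_pct_cases = missing_pct_cases,
             missing_pct_controls = missing_pct_controls, status = status,
             stringsAsFactors = FALSE)
}

# Vectorized per-stratum 2x2 cell counts for a block of binary variables.
# Returns G x V matrices a, b, c, d (exposed case / exposed control /
# unexposed case / unexposed control).
stratified_counts <- function(X, y, s) {
  M <- !is.na(X)
  Xz <- X
  Xz[!M] <- 0
  a <- rowsum(Xz * y, s)
  n1 <- rowsum(Xz, s)
  m1 <- rowsum(M * y, s)
  Tn <- rowsum(M * 1, s)
  list(a = a, b = n1 - a, c = m1 - a, d = Tn - n1 - m1 + a)
}

#' Run the matched association screen
#'
#' For every questionnaire variable, tests its association with case-control
#' status across the matched strata: binary variables with the
#' Cochran-Mantel-Haenszel test ([cmh_test()]), ordinal variables with
#' conditional logistic regression on the \[0, 1\] encoding
#' ([conditional_logit()]). Near-constant variables are removed first by
#' [sd_filter()] (standard deviation below `sd_min` over the pooled matched
#' sample) and reported with status `filtered`. Each test uses per-variable
#' complete cases; strata rendered single-status by missingness carry no
#' information and are dropped for that variable.
#'
#' @param sample Matched sample data.frame (`participant_id`, `stratum_id`,
#'   `status`) from [build_matched_sample()].
#' @param matrix Encoded matrix from [encode_variables()].
#' @param spec The [questionnaire_spec()].
#' @param sd_min Standard-deviation filter threshold (default 0.1).
#' @return data.frame with one row per variable, ordered by `variable_id`:
#'   columns `variable_id`, `analysis` (= `"matched"`), `p_value`,
#'   `effect_size` (odds-ratio scale; for ordinal variables the odds ratio
#'   between the two extreme responses), `ci_low`, `ci_high`,
#'   `n_cases_used`, `n_controls_used`, `missing_pct_cases`,
#'   `missing_pct_controls`, `status` (`ok`, `filtered`, `degenerate`,
#'   `nonconverged`).
#' @export
run_matched_screen <- function(sample, matrix, spec, sd_min = 0.1) {
  stopifnot(inherits(spec, "questionnaire_spec"))
  screen_over_strata(sample$participant_id, sample$status, sample$stratum_id,
                     matrix, spec, sd_min = sd_min, analysis = "matched")
}

# Shared engine for the matched and propensity screens: both are "test each
# variable against status within strata"; they differ only in how strata are
# defined (matched sets vs propensity deciles) and, for the propensity
# screen, in that strata are recomputed per variable. Columns are filled
# into preallocated vectors: one data.frame allocation per screen, not per
# variable.
screen_over_strata <- function(ids, status, strata, matrix, spec, sd_min,
                               analysis) {
  ids <- as.character(ids)
  vs <- names(spec)
  X <- matrix[ids, vs, drop = FALSE]
  y <- as.integer(status == "case")
  is_case <- y == 1L
  filt <- sd_filter(matrix, ids, threshold = sd_min)
  kinds <- vapply(spec, `[[`, character(1), "kind")

  miss_case <- 100 * colMeans(is.na(X[is_case, , drop = FALSE]))
  miss_ctrl <- 100 * colMeans(is.na(X[!is_case, , drop = FALSE]))
  n_case <- colSums(!is.na(X[is_case, , drop = FALSE]))
  n_ctrl <- colSums(!is.na(X[!is_case, , drop = FALSE]))

  nv <- length(vs)
  p_value <- effect <- ci_lo <- ci_hi <- rep(NA_real_, nv)
  status_out <- rep("filtered", nv)
  names(p_value) <- names(effect) <- names(ci_lo) <- names(ci_hi) <-
    names(status_out) <- vs

  kept_bin <- vs[filt$kept & kinds == "binary"]
  if (length(kept_bin)) {
    cnt <- stratified_counts(X[, kept_bin, drop = FALSE], y,
                             as.character(strata))
    for (v in kept_bin) {
      r <- cmh_from_counts(cnt$a[, v], cnt$b[, v], cnt$c[, v], cnt$d[, v])
      p_value[[v]] <- r$p_value
      effect[[v]] <- r$or
      ci_lo[[v]] <- r$ci_low
      ci_hi[[v]] <- r$ci_high
      status_out[[v]] <- r$status
    }
  }
  for (v in vs[filt$kept & kinds == "ordinal"]) {
    fit <- conditional_logit(X[, v], status, strata)
    if (fit$status == "ok") {
      p_value[[v]] <- fit$p_value
      effect[[v]] <- unname(fit$or)
      ci_lo[[v]] <- unname(fit$ci_low)
      ci_hi[[v]] <- unname(fit$ci_high)
    }
    status_out[[v]] <- fit$status
  }
  o <- order(vs)
  out <- data.frame(
    variable_id = vs[o], analysis = analysis, p_value = unname(p_value[o]),
    effect_size = unname(effect[o]), ci_low = unname(ci_lo[o]),
    ci_high = unname(ci_hi[o]), n_cases_used = unname(n_case[o]),
    n_controls_used = unname(n_ctrl[o]),
    missing_pct_cases = unname(miss_case[o]),
    missing_pct_controls = unname(miss_ctrl[o]),
    status = unname(status_out[o]), stringsAsFactors = FALSE
  )
  out
}
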