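#' Build the covariate matrix for propensity estimation
#'
#' Assembles the bias-control covariates: non-rounded reference age (a
#' matched control carries its case's age by design), parental-profession
#' SES (0/1/2), the commune's urban-unit index and percentage of farmers in
#' the active population, and one binary indicator per recruitment center
#' with more than 30 participants in the sample (smaller centers are left
#' all-zero). Column order is deterministic.
#'
#' @param participants Participant table restricted to the propensity sample
#'   (see [build_propensity_sample()]); no covariate may be missing.
#' @param center_min Minimum center size for a dedicated indicator column.
#' @return Numeric matrix, one row per participant (rownames =
#'   `participant_id`).
#' @export
build_covariate_matrix <- function(participants, center_min = 30L) {
  p <- participants
  if (nrow(p) == 0L) {
    return(matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("reference_age", "ses",
                                          "urban_unit_index", "pct_farmers"))))
  }
  base <- c("reference_age", "ses", "urban_unit_index", "pct_farmers")
  bad <- vapply(c(base, "center_id"), function(col) anyNA(p[[col]]), logical(1))
  if (any(bad)) {
    stop("missing covariates (", paste(names(bad)[bad], collapse = ", "),
         "); participants lacking covariates must be excluded upstream",
         call. = FALSE)
  }
  m <- cbind(reference_age = as.numeric(p$reference_age),
             ses = as.numeric(p$ses),
             urban_unit_index = as.numeric(p$urban_unit_index),
             pct_farmers = as.numeric(p$pct_farmers))
  sizes <- table(as.character(p$center_id))
  big <- sort(names(sizes)[sizes > center_min])
  for (cid in big) {
    m <- cbind(m, as.numeric(p$center_id == cid))
    colnames(m)[ncol(m)] <- paste0("center_", cid)
  }
  rownames(m) <- p$participant_id
  m
}

#' Fit a regression random forest
#'
#' Bagged CART regression trees with `mtry` candidate features per split and
#' out-of-bag (OOB) predictions: each participant is predicted only by trees
#' whose bootstrap resample did not contain it, giving an internally
#' cross-validated score that does not overfit the training sample.
#' Hyperparameters follow the reference regression-forest defaults: 500
#' trees, `mtry = max(1, floor(p/3))`, terminal nodes of at most 5
#' observations, no depth limit.
#'
#' @param x Numeric covariate matrix (no missing values).
#' @param y Numeric response.
#' @param ntree Number of trees.
#' @param mtry Candidate features per split.
#' @param min_node Maximum size of an unsplit node.
#' @param seed Integer seed; fixed seed implies identical fits.
#' @return Object of class `rf_fit` with elements `trees`, `oob` (OOB
#'   predictions; participants never out-of-bag -- vanishingly rare at 500
#'   trees -- fall back to the sample mean and are counted in
#'   `n_never_oob`), `oob_n`, `mtry`, `ntree`.
#' @export
rf_fit <- function(x, y, ntree = 500L, mtry = max(1L, floor(ncol(x) / 3)),
                   min_node = 5L, seed = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), !anyNA(x), !anyNA(y))
  if (!is.null(seed)) set.seed(seed)
  fit <- .rf_fit_cpp(x, as.numeric(y), as.integer(ntree), as.integer(mtry),
                     as.integer(min_node))
  oob <- fit$oob_sum / fit$oob_n
  never <- fit$oob_n == 0L
  oob[never] <- mean(y)
  structure(list(trees = fit$trees, oob = oob, oob_n = fit$oob_n,
                 n_never_oob = sum(never), mtry = mtry, ntree = ntree),
            class = "rf_fit")
}

#' @rdname rf_fit
#' @param object An `rf_fit`.
#' @param newdata Covariate matrix with the same columns as the training
#'   matrix.
#' @param ... Unused.
#' @export
predict.rf_fit <- function(object, newdata, ...) {
  .rf_predict_cpp(object$trees, as.matrix(newdata))
}

#' Estimate per-participant propensity scores
#'
#' Trains a random-forest *regression* of the encoded exposure on the
#' covariates (regression even for binary exposures) and defines the
#' propensity score as the out-of-bag prediction. Scores are clipped to
#' \[0, 1\]: ordinal exposures can yield OOB averages marginally outside the
#' encoding range.
#'
#' @param covariates Matrix from [build_covariate_matrix()].
#' @param exposure Encoded exposure values (no missing entries; reduce to
#'   complete cases first).
#' @param seed Integer seed for reproducibility.
#' @param min_n Minimum sample size accepted (default 50).
#' @param ... Passed to [rf_fit()] (e.g. `ntree`).
#' @return Numeric vector of scores in \[0, 1\], named by participant.
#' @export
fit_propensity <- function(covariates, exposure, seed = NULL, min_n = 50L,
                           ...) {
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == length(exposure))
  if (anyNA(exposure)) {
    stop("exposure has missing values; reduce to complete cases first",
         call. = FALSE)
  }
  if (nrow(covariates) < min_n) {
    stop("propensity fit needs at least ", min_n, " participants",
         call. = FALSE)
  }
  if (max(exposure) == min(exposure)) {
    stop("exposure is constant; sd_filter should have removed it",
         call. = FALSE)
  }
  fit <- rf_fit(covariates, exposure, seed = seed, ...)
  scores <- pmin(1, pmax(0, fit$oob))
  names(scores) <- rownames(covariates)
  scores
}

#' Stratify scores into quantile bins
#'
#' Cuts the score distribution at its k-quantiles (deciles for the default
#' k = 10). Duplicate cut points -- common when many participants share a
#' score -- are merged, so fewer than k strata can result; the effective
#' number is reported by the caller. Every participant receives a label and
#' labels are ordered by score interval.
#'
#' @param scores Numeric vector, no missing values.
#' @param k Target number of strata.
#' @return Integer vector of stratum labels in `1:effective_k`.
#' @export
quantile_stratify <- function(scores, k = 10L) {
  stopifnot(!anyNA(scores), k >= 1L)
  qs <- stats::quantile(scores, probs = seq(0, 1, length.out = k + 1),
                        names = FALSE, type = 7)
  edges <- unique(qs)
  if (length(edges) < 2L) {
    warning("all scores identical; single stratum")
    return(rep(1L, length(scores)))
  }
  lab <- findInterval(scores, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  as.integer(lab)
}

# Stable per-variable seed from the master seed and the variable id, so
# results do not depend on variable iteration order. Plain polynomial string
# hash folded into [0, 2^31).
derive_seed <- function(master_seed, variable_id) {
  h <- as.double(master_seed %% 2147483647L)
  for (code in utf8ToInt(as.character(variable_id))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Run the propensity-score stratified screen
#'
#' The unmatched, bias-controlled analysis: for each questionnaire variable,
#' (1) estimate a propensity score for that exposure by random-forest
#' regression on the covariates ([fit_propensity()]), (2) stratify the
#' sample into deciles of the score ([quantile_stratify()]), and (3) test
#' exposure against case-control status within strata -- CMH for binary
#' variables, conditional logistic regression (propensity strata as
#' conditioning sets) for ordinal ones. Per-variable forest seeds are
#' derived deterministically from `seed` and the variable id.
#'
#' @param sample Propensity sample data.frame (`participant_id`, `status`)
#'   from [build_propensity_sample()].
#' @param matrix Encoded matrix from [encode_variables()].
#' @param spec The [questionnaire_spec()].
#' @param participants Full participant table (covariate source).
#' @param seed Master integer seed.
#' @param k Number of propensity strata (default 10).
#' @param sd_min Standard-deviation filter threshold.
#' @param ntree Trees per forest.
#' @return data.frame as in [run_matched_screen()] (with
#'   `analysis = "propensity"`) plus columns `effective_k` and `rf_seed`.
#' @export
run_propensity_screen <- function(sample, matrix, spec, participants,
                                  seed = 1L, k = 10L, sd_min = 0.1,
                                  ntree = 500L) {
  stopifnot(inherits(spec, "questionnaire_spec"))
  ids <- as.character(sample$participant_id)
  p <- participants[match(ids, participants$participant_id), , drop = FALSE]
  covm <- build_covariate_matrix(p)
  X <- matrix[ids, names(spec), drop = FALSE]
  status <- sample$status
  is_case <- status == "case"
  filt <- sd_filter(matrix, ids, threshold = sd_min)
  kinds <- vapply(spec, `[[`, character(1), "kind")

  rows <- vector("list", length(spec))
  names(rows) <- names(spec)
  for (v in names(spec)) {
    miss_case <- 100 * mean(is.na(X[is_case, v]))
    miss_ctrl <- 100 * mean(is.na(X[!is_case, v]))
    if (!filt$kept[filt$variable_id == v]) {
      r <- result_row(v, "propensity", missing_pct_cases = miss_case,
                      missing_pct_controls = miss_ctrl, status = "filtered")
      r$effective_k <- NA_integer_
      r$rf_seed <- NA_integer_
      rows[[v]] <- r
      next
    }
    cc <- !is.na(X[, v])
    x <- X[cc, v]
    rf_seed <- derive_seed(seed, v)
    res <- tryCatch({
      scores <- fit_propensity(covm[cc, , drop = FALSE], x, seed = rf_seed,
                               ntree = ntree)
      strat <- quantile_stratify(scores, k = k)
      eff_k <- length(unique(strat))
      if (kinds[[v]] == "binary") {
        r <- cmh_from_counts_from(x, status[cc], strat)
        list(p = r$p_value, or = r$or, lo = r$ci_low, hi = r$ci_high,
             st = r$status, eff_k = eff_k)
      } else {
        fit <- conditional_logit(x, status[cc], strat)
        list(p = if (fit$status == "ok") fit$p_value else NA_real_,
             or = unname(fit$or), lo = unname(fit$ci_low),
             hi = unname(fit$ci_high), st = fit$status, eff_k = eff_k)
      }
    }, error = function(e) list(p = NA_real_, or = NA_real_, lo = NA_real_,
                                hi = NA_real_, st = "degenerate",
                                eff_k = NA_integer_))
    r <- result_row(v, "propensity", p_value = res$p,
                    effect_size = res$or, ci_low = res$lo, ci_high = res$hi,
                    n_cases_used = sum(cc & is_case),
                    n_controls_used = sum(cc & !is_case),
                    missing_pct_cases = miss_case,
                    missing_pct_controls = miss_ctrl, status = res$st)
    r$effective_k <- res$eff_k
    r$rf_seed <- rf_seed
    rows[[v]] <- r
  }
  out <- do.call(rbind, rows[order(names(rows))])
  rownames(out) <- NULL
  out
}

# CMH on raw vectors (binary exposure, status, strata) without building the
# 2x2xK array explicitly.
cmh_from_counts_from <- function(exposure, status, strata) {
  cnt <- stratified_counts(cbind(v = exposure),
                           as.integer(status == "case"),
                           as.character(strata))
  cmh_from_counts(cnt$a[, 1], cnt$b[, 1], cnt$c[, 1], cnt$d[, 1])
}
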