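# End-to-end orchestration: encode -> exclude -> sample build -> filter ->
# matched and/or propensity screens -> dual discovery, with a reconciled
# run manifest.

#' Run the full screening pipeline
#'
#' Executes every stage on a [study_dataset()]: encoding, the exclusion
#' cascade, matched- and propensity-sample construction, both per-variable
#' screens, and the dual-discovery rule. All randomness (the propensity
#' forests) derives from `seed`, so reruns are reproducible. When `out_dir`
#' is given, the standard artifact files are written there
#' (`exclusions.tsv`, `encoded_matrix.tsv`, `matched_results.tsv`,
#' `propensity_results.tsv`, `discovery_report.tsv`, `volcano_*.tsv`,
#' `comparison.tsv`, `manifest.yaml`).
#'
#' @param dataset A [study_dataset()].
#' @param config An [exclusion_config()].
#' @param seed Master integer seed.
#' @param matched,propensity Logical switches for the two analyses.
#' @param alpha Level for the discovery rule.
#' @param k Propensity strata count.
#' @param ntree Trees per propensity forest.
#' @param out_dir Optional output directory (created if needed).
#' @return List of class `ewas_run`: `matched_results`,
#'   `propensity_results` (NULL when switched off), `discovery`
#'   ([dual_discovery()] report; NULL unless both analyses ran),
#'   `exclusion_log`, `matched_sample`, `propensity_sample`, `manifest`.
#' @export
run_all <- function(dataset, config = exclusion_config(), seed = 1L,
                    matched = TRUE, propensity = TRUE, alpha = 0.05,
                    k = 10L, ntree = 500L, out_dir = NULL) {
  stopifnot(inherits(dataset, "study_dataset"), matched || propensity)
  encoded <- encode_variables(dataset$responses, dataset$spec)
  excl <- apply_exclusions(dataset, config)
  kept <- excl$dataset

  matched_results <- propensity_results <- NULL
  msample <- psample <- NULL
  if (matched) {
    msample <- build_matched_sample(kept)
    matched_results <- run_matched_screen(msample$sample, encoded,
                                          dataset$spec,
                                          sd_min = config$sd_min)
  }
  if (propensity) {
    psample <- build_propensity_sample(kept)
    propensity_results <- run_propensity_screen(
      psample$sample, encoded, dataset$spec, kept$participants,
      seed = seed, k = k, sd_min = config$sd_min, ntree = ntree)
  }
  discovery <- if (matched && propensity) {
    dual_discovery(matched_results, propensity_results, alpha)
  }

  manifest <- build_manifest(dataset, excl, msample, psample,
                             matched_results, propensity_results, seed,
                             config)
  res <- structure(list(
    matched_results = matched_results,
    propensity_results = propensity_results,
    discovery = discovery, exclusion_log = excl$log,
    matched_sample = msample, propensity_sample = psample,
    manifest = manifest
  ), class = "ewas_run")
  if (!is.null(out_dir)) write_run(res, encoded, out_dir, alpha)
  res
}

count_by_status <- function(results) {
  if (is.null(results)) return(NULL)
  as.list(table(results$status))
}

build_manifest <- function(dataset, excl, msample, psample, matched_results,
                           propensity_results, seed, config) {
  n_in <- nrow(dataset$participants)
  by_rule <- as.list(table(excl$log$rule[excl$log$excluded]))
  n_retained <- sum(!excl$log$excluded)
  manifest <- list(
    software = paste0("ewascreen ",
                      as.character(utils::packageVersion("ewascreen"))),
    seed = seed,
    config = config,
    n_participants_in = n_in,
    n_retained_after_exclusions = n_retained,
    excluded_by_rule = by_rule,
    n_variables = length(dataset$spec),
    matched = if (!is.null(msample)) list(
      n_in_sample = nrow(msample$sample),
      n_strata = length(unique(msample$sample$stratum_id)),
      n_dropped_unmatched = nrow(msample$dropped),
      tests_by_status = count_by_status(matched_results)
    ),
    propensity = if (!is.null(psample)) list(
      n_in_sample = nrow(psample$sample),
      n_dropped_missing_covariates = nrow(psample$dropped),
      tests_by_status = count_by_status(propensity_results)
    )
  )
  stopifnot(n_in == n_retained + sum(unlist(by_rule)))
  manifest
}

write_run <- function(res, encoded, out_dir, alpha) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(out_dir, written)), add = TRUE)
  written <- character(0)
  put <- function(df, name) {
    write_tsv(df, file.path(out_dir, name))
    written <<- c(written, name)
  }
  put(res$exclusion_log, "exclusions.tsv")
  put(data.frame(participant_id = rownames(encoded), encoded,
                 check.names = FALSE), "encoded_matrix.tsv")
  if (!is.null(res$matched_results)) {
    put(res$matched_results, "matched_results.tsv")
    put(volcano_table(res$matched_results, alpha), "volcano_matched.tsv")
  }
  if (!is.null(res$propensity_results)) {
    put(res$propensity_results, "propensity_results.tsv")
    put(volcano_table(res$propensity_results, alpha),
        "volcano_propensity.tsv")
  }
  if (!is.null(res$discovery)) {
    put(res$discovery$table, "discovery_report.tsv")
    put(comparison_table(res$matched_results, res$propensity_results, alpha),
        "comparison.tsv")
  }
  writeLines(yaml::as.yaml(res$manifest), file.path(out_dir, "manifest.yaml"))
  written <- c(written, "manifest.yaml")
  ok <- TRUE
  invisible(out_dir)
}

#' @export
print.ewas_run <- function(x, ...) {
  m <- x$manifest
  cat("ewas_run:", m$n_participants_in, "participants ->",
      m$n_retained_after_exclusions, "after exclusions;",
      m$n_variables, "variables\n")
  if (!is.null(x$discovery)) print(x$discovery)
  invisible(x)
}
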