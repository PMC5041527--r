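# Multiple-testing thresholds and the dual-analysis discovery rule.

#' Holm step-down FWER control (with the plain Bonferroni display line)
#'
#' Controls the family-wise error rate at `alpha` by Holm's step-down
#' procedure, which rejects at least as much as plain Bonferroni at the same
#' FWER. The plain Bonferroni cut `alpha/m` is returned as well because
#' volcano plots draw it as a horizontal line.
#'
#' @param pvals Numeric p-values in \[0, 1\] (NA allowed; never rejected).
#' @param alpha Target FWER.
#' @return List with `reject` (logical, same order as input),
#'   `bonferroni_threshold` (= alpha/m), `m` (number of non-missing
#'   p-values), `alpha`.
#' @export
bonferroni_holm <- function(pvals, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  reject <- rep(FALSE, length(pvals))
  ok <- !is.na(pvals)
  m <- sum(ok)
  if (m == 0L) {
    return(list(reject = reject, bonferroni_threshold = NA_real_, m = 0L,
                alpha = alpha))
  }
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values outside [0, 1]")
  p <- pvals[ok]
  o <- order(p)
  # Holm: reject the i-th smallest while p_(i) <= alpha / (m - i + 1)
  thresh <- alpha / (m - seq_len(m) + 1)
  pass <- p[o] <= thresh
  cut <- if (all(pass)) m else which(!pass)[1L] - 1L
  rej <- rep(FALSE, m)
  if (cut > 0L) rej[o[seq_len(cut)]] <- TRUE
  reject[ok] <- rej
  list(reject = reject, bonferroni_threshold = alpha / m, m = m,
       alpha = alpha)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure: with ordered p-values p(1) <= ... <= p(m), find the
#' largest i with p(i) <= i * alpha / m and reject ranks 1..i. The display
#' threshold is p(i*) when any rejection occurs (the FDR line on a volcano
#' plot) and alpha/m otherwise.
#'
#' @inheritParams bonferroni_holm
#' @param alpha Target false discovery rate.
#' @return List with `reject`, `fdr_threshold`, `m`, `alpha`.
#' @export
benjamini_hochberg <- function(pvals, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  reject <- rep(FALSE, length(pvals))
  ok <- !is.na(pvals)
  m <- sum(ok)
  if (m == 0L) {
    return(list(reject = reject, fdr_threshold = NA_real_, m = 0L,
                alpha = alpha))
  }
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values outside [0, 1]")
  p <- pvals[ok]
  o <- order(p)
  pass <- p[o] <= seq_len(m) * alpha / m
  istar <- if (any(pass)) max(which(pass)) else 0L
  rej <- rep(FALSE, m)
  if (istar > 0L) rej[o[seq_len(istar)]] <- TRUE
  reject[ok] <- rej
  list(reject = reject,
       fdr_threshold = if (istar > 0L) p[o][istar] else alpha / m,
       m = m, alpha = alpha)
}

#' Dual-analysis discovery rule
#'
#' A variable is *discovered* when it passes the (lenient) FDR threshold in
#' the matched analysis -- the higher-quality design -- AND the (strict)
#' Bonferroni-Holm threshold in the propensity analysis. Requiring both
#' gives better false-positive control than either alone. Variables tested
#' in only one analysis are reported but can never be discovered. The number
#' of tests m for each correction counts only that analysis's `ok`-status
#' results.
#'
#' @param matched_results,propensity_results Screen outputs
#'   ([run_matched_screen()], [run_propensity_screen()]).
#' @param alpha Level for both corrections.
#' @return Object of class `discovery_report`: a list with `table` (one row
#'   per variable seen in either analysis: p-values, effect sizes, CIs,
#'   flags `passed_fdr_matched`, `passed_bonferroni_matched`,
#'   `passed_bonferroni_propensity`, `discovered`), `thresholds`, `m_matched`,
#'   `m_propensity`, `alpha`.
#' @export
dual_discovery <- function(matched_results, propensity_results, alpha = 0.05) {
  vm <- matched_results
  vp <- propensity_results
  pm <- ifelse(vm$status == "ok", vm$p_value, NA_real_)
  pp <- ifelse(vp$status == "ok", vp$p_value, NA_real_)
  bh_m <- benjamini_hochberg(pm, alpha)
  holm_m <- bonferroni_holm(pm, alpha)
  holm_p <- bonferroni_holm(pp, alpha)

  all_ids <- sort(union(vm$variable_id, vp$variable_id))
  im <- match(all_ids, vm$variable_id)
  ip <- match(all_ids, vp$variable_id)
  pick <- function(df, idx, col) {
    out <- rep(NA_real_, length(idx))
    has <- !is.na(idx)
    out[has] <- df[[col]][idx[has]]
    out
  }
  flag <- function(res, idx) {
    out <- rep(FALSE, length(idx))
    has <- !is.na(idx)
    out[has] <- res$reject[idx[has]]
    out
  }
  tab <- data.frame(
    variable_id = all_ids,
    p_matched = pick(vm, im, "p_value"),
    p_propensity = pick(vp, ip, "p_value"),
    effect_matched = pick(vm, im, "effect_size"),
    ci_low_matched = pick(vm, im, "ci_low"),
    ci_high_matched = pick(vm, im, "ci_high"),
    effect_propensity = pick(vp, ip, "effect_size"),
    ci_low_propensity = pick(vp, ip, "ci_low"),
    ci_high_propensity = pick(vp, ip, "ci_high"),
    passed_fdr_matched = flag(bh_m, im),
    passed_bonferroni_matched = flag(holm_m, im),
    passed_bonferroni_propensity = flag(holm_p, ip),
    stringsAsFactors = FALSE
  )
  tab$discovered <- tab$passed_fdr_matched & tab$passed_bonferroni_propensity
  structure(list(
    table = tab,
    thresholds = c(fdr_matched = bh_m$fdr_threshold,
                   bonferroni_matched = holm_m$bonferroni_threshold,
                   bonferroni_propensity = holm_p$bonferroni_threshold),
    m_matched = bh_m$m, m_propensity = holm_p$m, alpha = alpha
  ), class = "discovery_report")
}

#' @export
print.discovery_report <- function(x, ...) {
  cat("discovery_report:", nrow(x$table), "variables;",
      sum(x$table$discovered), "discovered (matched FDR + propensity",
      "Bonferroni at", x$alpha, ")\n")
  cat("  m_matched =", x$m_matched, " m_propensity =", x$m_propensity, "\n")
  invisible(x)
}

#' Volcano-plot table
#'
#' Plot-ready coordinates for one analysis: x = log effect size (protective
#' factors negative, to the left), y = -log10(p). Variables past the FDR
#' threshold get labels. Zero p-values are capped at a display ceiling and
#' flagged.
#'
#' @param results A screen output; only `status == "ok"` rows are used.
#' @param alpha Level for the threshold lines.
#' @param p_ceiling Display cap for -log10(p) when p = 0.
#' @return data.frame (`variable_id`, `log_effect`, `neg_log10_p`, `label`,
#'   `capped`) with attributes `fdr_threshold` and `bonferroni_threshold`
#'   (on the -log10 scale).
#' @export
volcano_table <- function(results, alpha = 0.05, p_ceiling = 300) {
  ok <- results[results$status == "ok" & !is.na(results$p_value) &
                  !is.na(results$effect_size), , drop = FALSE]
  bh <- benjamini_hochberg(ok$p_value, alpha)
  holm <- bonferroni_holm(ok$p_value, alpha)
  y <- -log10(ok$p_value)
  capped <- !is.finite(y)
  y[capped] <- p_ceiling
  out <- data.frame(variable_id = ok$variable_id,
                    log_effect = log(ok$effect_size),
                    neg_log10_p = y,
                    label = ifelse(bh$reject, ok$variable_id, ""),
                    capped = capped, stringsAsFactors = FALSE)
  attr(out, "fdr_threshold") <- -log10(bh$fdr_threshold)
  attr(out, "bonferroni_threshold") <- -log10(holm$bonferroni_threshold)
  out
}

#' Matched-vs-propensity comparison table
#'
#' Per-variable (-log10 p_matched, -log10 p_propensity) pairs for variables
#' with an `ok` result in both analyses; dual-discovered variables are
#' labeled (they sit in the upper right). Threshold lines (matched FDR,
#' propensity Bonferroni) are attached as attributes; variables present in
#' only one analysis are omitted and counted in attribute `n_omitted`.
#'
#' @inheritParams dual_discovery
#' @return data.frame (`variable_id`, `neg_log10_p_matched`,
#'   `neg_log10_p_propensity`, `label`).
#' @export
comparison_table <- function(matched_results, propensity_results,
                             alpha = 0.05) {
  rep <- dual_discovery(matched_results, propensity_results, alpha)
  tab <- rep$table
  both <- !is.na(tab$p_matched) & !is.na(tab$p_propensity)
  out <- data.frame(
    variable_id = tab$variable_id[both],
    neg_log10_p_matched = -log10(tab$p_matched[both]),
    neg_log10_p_propensity = -log10(tab$p_propensity[both]),
    label = ifelse(tab$discovered[both], tab$variable_id[both], ""),
    stringsAsFactors = FALSE
  )
  attr(out, "fdr_threshold_matched") <- -log10(rep$thresholds[["fdr_matched"]])
  attr(out, "bonferroni_threshold_propensity") <-
    -log10(rep$thresholds[["bonferroni_propensity"]])
  attr(out, "n_omitted") <- sum(!both)
  out
}
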