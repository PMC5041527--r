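#' Build a stratified 2x2 table for a binary exposure
#'
#' Cross-tabulates exposure (encoded 0/1) against case-control status within
#' each stratum, on per-variable complete cases. Strata reduced to a single
#' status (e.g. the case's response missing) stay in the array but carry no
#' information: they contribute zero to the Cochran-Mantel-Haenszel
#' statistic.
#'
#' @param exposure Numeric vector of encoded values in \{0, 1\} (NA = missing).
#' @param status Character vector, `"case"`/`"control"`.
#' @param strata Stratum identifiers (matched-set ids or propensity deciles).
#' @return A 2x2xK array with dimensions exposure (`1`, `0`) x status
#'   (`case`, `control`) x stratum, as accepted by [cmh_test()].
#' @export
build_stratified_table <- function(exposure, status, strata) {
  stopifnot(length(exposure) == length(status),
            length(exposure) == length(strata))
  ok <- !is.na(exposure)
  if (!all(exposure[ok] %in% c(0, 1))) {
    stop("exposure must be binary (encoded 0/1)", call. = FALSE)
  }
  x <- factor(ifelse(exposure[ok] == 1, "1", "0"), levels = c("1", "0"))
  y <- factor(status[ok], levels = c("case", "control"))
  s <- factor(as.character(strata[ok]))
  table(exposure = x, status = y, stratum = s)
}

# Vectorized CMH machinery over per-stratum 2x2 cell counts.
# a = exposed cases, b = exposed controls, c = unexposed cases,
# d = unexposed controls; each a vector over strata.
cmh_from_counts <- function(a, b, c, d, conf_level = 0.95) {
  Tn <- a + b + c + d
  n1 <- a + b; n0 <- c + d          # exposure margins
  m1 <- a + c; m0 <- b + d          # status margins
  use <- Tn >= 2
  Ea <- ifelse(use, n1 * m1 / Tn, 0)
  Va <- ifelse(use, n1 * n0 * m1 * m0 / (Tn^2 * (Tn - 1)), 0)
  dev <- sum(ifelse(use, a - Ea, 0))
  V <- sum(Va)
  stat <- if (V > 0) dev^2 / V else 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)

  # Mantel-Haenszel common odds ratio + Robins-Breslow-Greenland variance
  R <- ifelse(Tn > 0, a * d / Tn, 0)
  S <- ifelse(Tn > 0, b * c / Tn, 0)
  sR <- sum(R); sS <- sum(S)
  if (sR > 0 && sS > 0) {
    or <- sR / sS
    P <- ifelse(Tn > 0, (a + d) / Tn, 0)
    Q <- ifelse(Tn > 0, (b + c) / Tn, 0)
    v <- sum(P * R) / (2 * sR^2) +
      sum(P * S + Q * R) / (2 * sR * sS) +
      sum(Q * S) / (2 * sS^2)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- exp(log(or) + c(-1, 1) * z * sqrt(v))
  } else {
    or <- NA_real_; ci <- c(NA_real_, NA_real_)
  }
  list(statistic = stat, p_value = p, or = or, ci_low = ci[1], ci_high = ci[2],
       n_informative = sum(Va > 0),
       status = if (V > 0 && !is.na(or)) "ok" else "degenerate")
}

#' Cochran-Mantel-Haenszel test on a stratified 2x2 table
#'
#' One-degree-of-freedom CMH chi-square test of conditional association
#' between a binary exposure and case-control status across strata, without
#' continuity correction (so that on 1:1 matched pairs the statistic equals
#' McNemar's (b-c)^2/(b+c) exactly). The common odds ratio is the
#' Mantel-Haenszel estimate, with a 95 % confidence interval from the
#' Robins-Breslow-Greenland variance, which remains valid in the sparse-data
#' regime of many small strata typical of matched designs.
#'
#' Fully concordant strata contribute zero to the statistic. With no
#' informative stratum the statistic is 0 and p = 1; when all cross-products
#' fall on one side the MH estimate is undefined and the result is flagged
#' `degenerate`.
#'
#' @param table 2x2xK array from [build_stratified_table()] (exposure x
#'   status x stratum).
#' @param conf_level Confidence level of the odds-ratio interval.
#' @return A list of class `cmh_test` with elements `statistic`, `p_value`,
#'   `or`, `ci_low`, `ci_high`, `n_informative`, `status`.
#' @examples
#' # 15 discordant pairs one way, 5 the other: statistic (15-5)^2/20 = 5
#' tab <- array(0, c(2, 2, 20))
#' tab[1, 1, 1:15] <- 1; tab[2, 2, 1:15] <- 1   # case exposed, control not
#' tab[2, 1, 16:20] <- 1; tab[1, 2, 16:20] <- 1 # control exposed, case not
#' cmh_test(tab)$statistic
#' @export
cmh_test <- function(table, conf_level = 0.95) {
  stopifnot(is.array(table), length(dim(table)) == 3L,
            all(dim(table)[1:2] == 2L))
  res <- cmh_from_counts(a = table[1, 1, ], b = table[1, 2, ],
                         c = table[2, 1, ], d = table[2, 2, ],
                         conf_level = conf_level)
  class(res) <- "cmh_test"
  res
}

#' @export
print.cmh_test <- function(x, ...) {
  cat("Cochran-Mantel-Haenszel test (1 df, no continuity correction)\n")
  cat(sprintf("  statistic = %.4f, p = %.4g [%s]\n", x$statistic, x$p_value,
              x$status))
  if (!is.na(x$or)) {
    cat(sprintf("  MH odds ratio = %.4f (%.4f, %.4f)\n", x$or, x$ci_low,
                x$ci_high))
  }
  invisible(x)
}
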