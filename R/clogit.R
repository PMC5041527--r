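#' Conditional logistic regression over strata
#'
#' Maximizes the conditional likelihood of case status given each stratum's
#' case count, eliminating per-stratum nuisance intercepts -- the standard
#' model for matched sets of one case and one or two controls, and for
#' propensity-decile strata. For strata with a single case the likelihood is
#' the exact conditional one (the case's linear predictor against all
#' stratum members'); strata holding several cases use the Breslow
#' approximation to the conditional likelihood, which coincides with the
#' exact form in the single-case situation.
#'
#' Because exposures are encoded on \[0, 1\], `exp(coefficient)` is the odds
#' ratio between the two extreme responses. Inference is Wald-based;
#' optimization is Newton-Raphson with relative tolerance `1e-8` and at most
#' 100 iterations, started at zero.
#'
#' Strata with no case or no control after complete-case reduction (complete
#' jointly on exposure and covariates) are uninformative and dropped; their
#' count is reported. If the exposure varies within no remaining stratum the
#' result is `degenerate`; divergence of the exposure coefficient
#' (separation) yields `nonconverged`.
#'
#' @param exposure Numeric vector of encoded exposure values in \[0, 1\]
#'   (NA = missing).
#' @param status `"case"`/`"control"` per participant.
#' @param strata Stratum identifiers.
#' @param covariates Optional numeric matrix/data.frame of additional
#'   adjustment variables (e.g. a second questionnaire item), one row per
#'   participant.
#' @param conf_level Confidence level for the Wald interval.
#' @param max_iter,tol Newton-Raphson controls.
#' @return A list of class `clogit_fit`: `coef` (named vector, exposure
#'   first), `se`, `or`, `ci_low`, `ci_high`, `p_value` (all for the
#'   exposure), `loglik`, `n_used`, `n_strata_used`, `n_strata_dropped`,
#'   `iterations`, `status` (`ok`, `degenerate`, `nonconverged`).
#' @examples
#' # 15 pairs discordant one way, 5 the other: conditional MLE of OR is 15/5
#' x <- c(rbind(rep(1, 15), rep(0, 15)), rbind(rep(0, 5), rep(1, 5)))
#' y <- rep(c("case", "control"), 20)
#' s <- rep(1:20, each = 2)
#' conditional_logit(x, y, s)$or
#' @export
conditional_logit <- function(exposure, status, strata, covariates = NULL,
                              conf_level = 0.95, max_iter = 100L, tol = 1e-8) {
  stopifnot(length(exposure) == length(status),
            length(exposure) == length(strata))
  X <- cbind(exposure = as.numeric(exposure))
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)
    if (nrow(Z) != length(exposure)) {
      stop("covariates must have one row per participant", call. = FALSE)
    }
    if (is.null(colnames(Z))) {
      colnames(Z) <- paste0("covariate", seq_len(ncol(Z)))
    }
    X <- cbind(X, Z)
  }
  y <- as.integer(status == "case")
  cc <- stats::complete.cases(X)
  X <- X[cc, , drop = FALSE]
  y <- y[cc]
  s <- strata[cc]

  empty <- function(status, n_dropped = 0L) {
    structure(list(coef = NULL, se = NULL, or = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, p_value = NA_real_, loglik = NA_real_,
                   n_used = 0L, n_strata_used = 0L,
                   n_strata_dropped = n_dropped, iterations = 0L,
                   status = status),
              class = "clogit_fit")
  }
  if (length(y) == 0L) return(empty("degenerate"))

  # integer stratum codes (match/tabulate: much cheaper than factor)
  su <- unique(s)
  g <- match(s, su)
  G <- length(su)

  # drop uninformative strata: all cases or all controls
  d_g <- rowsum(y, g)[, 1]
  n_g <- tabulate(g, G)
  keep_g <- d_g > 0 & d_g < n_g
  n_dropped <- sum(!keep_g)
  keep <- keep_g[g]
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  gk <- g[keep]
  gu <- unique(gk)
  g <- match(gk, gu)
  G <- length(gu)
  if (length(y) == 0L) return(empty("degenerate", n_dropped))

  # exposure must vary within at least one stratum (sum-of-squares test)
  sx <- rowsum(X[, 1], g)[, 1]
  sx2 <- rowsum(X[, 1]^2, g)[, 1]
  n_g <- tabulate(g, G)
  if (all(n_g * sx2 - sx^2 <= 1e-12)) return(empty("degenerate", n_dropped))

  d_g <- rowsum(y, g)[, 1]
  p <- ncol(X)
  beta <- numeric(p)
  ll_old <- -Inf
  status_flag <- "nonconverged"
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    if (max(abs(eta)) > 30) {                # stabilize within stratum
      mx <- as.vector(tapply(eta, g, max))
      w <- exp(eta - mx[g])
    } else {
      mx <- 0
      w <- exp(eta)
    }
    denom <- rowsum(w, g)[, 1]
    pw <- w / denom[g]                       # within-stratum softmax weights
    ll <- sum(eta[y == 1]) - sum(d_g * (log(denom) + mx))
    Ex <- rowsum(X * pw, g)                  # E_g[x] per stratum (rows)
    grad <- colSums(X[y == 1, , drop = FALSE]) - colSums(d_g * Ex)
    H <- matrix(0, p, p)
    for (j in seq_len(p)) {
      Exx_j <- rowsum(X * (X[, j] * pw), g)  # E_g[x x_j]
      H[, j] <- colSums(d_g * (Exx_j - Ex * Ex[, j]))
    }
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (abs(beta[1]) > 15) { status_flag <- "nonconverged"; iter <- iter; break }
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + tol) &&
        max(abs(grad)) < 1e-4) {
      status_flag <- "ok"
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (status_flag != "ok") {
    out <- empty("nonconverged", n_dropped)
    out$n_used <- length(y)
    out$n_strata_used <- G
    out$iterations <- iter
    return(out)
  }

  Hinv <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(Hinv) || any(diag(Hinv) <= 0)) {
    out <- empty("nonconverged", n_dropped)
    out$n_used <- length(y)
    return(out)
  }
  se <- sqrt(diag(Hinv))
  names(beta) <- names(se) <- colnames(X)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    coef = beta, se = se,
    or = unname(exp(beta[1])),
    ci_low = unname(exp(beta[1] - z * se[1])),
    ci_high = unname(exp(beta[1] + z * se[1])),
    p_value = unname(2 * stats::pnorm(-abs(beta[1] / se[1]))),
    loglik = ll_old, n_used = length(y), n_strata_used = G,
    n_strata_dropped = n_dropped, iterations = iter, status = "ok"
  ), class = "clogit_fit")
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat("Conditional logistic regression [", x$status, "]\n", sep = "")
  if (x$status == "ok") {
    cat(sprintf("  OR (extreme responses) = %.4f (%.4f, %.4f), p = %.4g\n",
                x$or, x$ci_low, x$ci_high, x$p_value))
    cat(sprintf("  n = %d over %d strata (%d dropped), loglik = %.4f\n",
                x$n_used, x$n_strata_used, x$n_strata_dropped, x$loglik))
  }
  invisible(x)
}
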