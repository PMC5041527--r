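test_that("Holm step-down behaves like Bonferroni at the first step", {
  # with m = 845, any rejection requires min p < 0.05/845
  p <- c(6e-5, rep(0.5, 844))
  h <- bonferroni_holm(p)
  expect_false(any(h$reject))                    # 6e-5 > 0.05/845 ~ 5.92e-5
  expect_equal(h$bonferroni_threshold, 0.05 / 845)
  p[1] <- 5.5e-5
  expect_true(bonferroni_holm(p)$reject[1])
  # m = 1 reduces to plain alpha
  expect_true(bonferroni_holm(0.04)$reject)
  expect_false(bonferroni_holm(0.06)$reject)
  # all p = 1 -> nothing
  expect_false(any(bonferroni_holm(rep(1, 10))$reject))
  # empty input -> empty output
  expect_length(bonferroni_holm(numeric(0))$reject, 0)
})

test_that("Benjamini-Hochberg step-up matches its definition", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.8)
  b <- benjamini_hochberg(p, 0.05)
  expect_equal(b$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(b$fdr_threshold, 0.04)            # p_(4) = 0.04 <= 4*0.05/5
  expect_false(any(benjamini_hochberg(rep(1, 20))$reject))
  expect_true(all(benjamini_hochberg(rep(0, 20))$reject))
  # NA p-values (degenerate tests) are never rejected and don't count in m
  p2 <- c(0.001, NA, 0.04)
  b2 <- benjamini_hochberg(p2)
  expect_equal(b2$m, 2L)
  expect_false(b2$reject[2])
})

test_that("rejection sets nest: bonferroni <= holm <= BH", {
  set.seed(55)
  for (i in 1:20) {
    m <- sample(5:300, 1)
    p <- c(stats::runif(m) ^ sample(1:3, 1))    # skew some towards 0
    h <- bonferroni_holm(p)
    b <- benjamini_hochberg(p)
    bonf <- p <= 0.05 / m
    expect_true(all(bonf <= h$reject))           # Holm rejects a superset
    expect_true(all(h$reject <= b$reject))       # BH rejects a superset
  }
})

test_that("dual discovery requires both thresholds", {
  mk <- function(ids, p, status = "ok") {
    n <- length(ids)
    data.frame(variable_id = ids, analysis = rep("x", n), p_value = p,
               effect_size = rep(0.5, n), ci_low = rep(0.4, n),
               ci_high = rep(0.7, n), n_cases_used = rep(100L, n),
               n_controls_used = rep(100L, n),
               missing_pct_cases = rep(0, n),
               missing_pct_controls = rep(0, n),
               status = rep_len(status, n), stringsAsFactors = FALSE)
  }
  ids <- sprintf("v%02d", 1:20)
  pm <- rep(0.5, 20); pm[1] <- 1e-8; pm[2] <- 0.003
  pp <- rep(0.5, 20); pp[1] <- 1e-8; pp[3] <- 1e-8
  rep <- dual_discovery(mk(ids, pm), mk(ids, pp))
  tab <- rep$table
  expect_true(tab$discovered[tab$variable_id == "v01"])    # passes both
  expect_false(tab$discovered[tab$variable_id == "v02"])   # matched FDR only
  expect_false(tab$discovered[tab$variable_id == "v03"])   # propensity only
  # discovered set is a subset of each constituent rejected set
  expect_true(all(tab$discovered <= tab$passed_fdr_matched))
  expect_true(all(tab$discovered <= tab$passed_bonferroni_propensity))
  # m counts only ok-status tests
  m2 <- mk(ids, pm, status = c(rep("ok", 15), rep("degenerate", 5)))
  rep2 <- dual_discovery(m2, mk(ids, pp))
  expect_equal(rep2$m_matched, 15L)
  # a variable present in only one analysis is reported, never discovered
  rep3 <- dual_discovery(mk(ids[1:10], pm[1:10]), mk(ids, pp))
  expect_equal(nrow(rep3$table), 20)
  expect_false(any(rep3$table$discovered[11:20]))
  # empty inputs
  rep4 <- dual_discovery(mk(character(0), numeric(0)),
                         mk(character(0), numeric(0)))
  expect_equal(nrow(rep4$table), 0)
})

test_that("volcano table: protective left, significance up, p=0 capped", {
  res <- data.frame(
    variable_id = c("a", "b", "c", "d"),
    analysis = "matched",
    p_value = c(0.05, 1e-10, 0, 0.5),
    effect_size = c(0.5, 2, 1, 1.2),
    ci_low = 0.1, ci_high = 3, n_cases_used = 10L, n_controls_used = 10L,
    missing_pct_cases = 0, missing_pct_controls = 0, status = "ok",
    stringsAsFactors = FALSE
  )
  v <- volcano_table(res)
  expect_equal(v$log_effect[v$variable_id == "a"], log(0.5))
  expect_lt(v$log_effect[v$variable_id == "a"], 0)   # protective -> left
  expect_equal(v$log_effect[v$variable_id == "c"], 0)
  expect_equal(v$neg_log10_p[v$variable_id == "a"], -log10(0.05))
  expect_true(v$capped[v$variable_id == "c"])
  expect_equal(v$neg_log10_p[v$variable_id == "c"], 300)
  expect_true(all(c("fdr_threshold", "bonferroni_threshold") %in%
                    names(attributes(v))))
})

test_that("comparison table pairs analyses and counts omissions", {
  mk <- function(ids, p) {
    n <- length(ids)
    data.frame(variable_id = ids, analysis = rep("x", n), p_value = p,
               effect_size = rep(1, n), ci_low = rep(0.5, n),
               ci_high = rep(2, n), n_cases_used = rep(10L, n),
               n_controls_used = rep(10L, n), missing_pct_cases = rep(0, n),
               missing_pct_controls = rep(0, n), status = rep_len("ok", n),
               stringsAsFactors = FALSE)
  }
  cm <- comparison_table(mk(c("a", "b", "c"), c(1e-9, 0.2, 0.3)),
                         mk(c("a", "b"), c(1e-9, 0.4)))
  expect_equal(nrow(cm), 2)
  expect_equal(attr(cm, "n_omitted"), 1)
  expect_equal(cm$label[cm$variable_id == "a"], "a")  # dual-discovered
  expect_equal(cm$label[cm$variable_id == "b"], "")
  empty <- comparison_table(mk(character(0), numeric(0)),
                            mk(character(0), numeric(0)))
  expect_equal(nrow(empty), 0)
})
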