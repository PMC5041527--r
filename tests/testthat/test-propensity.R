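test_that("covariate matrix has indicators only for centers > 30", {
  parts <- do.call(rbind, lapply(seq_len(85), function(i) {
    participant(sprintf("p%02d", i),
                center = c(rep("A", 40), rep("B", 35), rep("C", 10))[i])
  }))
  m <- build_covariate_matrix(parts)
  expect_setequal(colnames(m),
                  c("reference_age", "ses", "urban_unit_index", "pct_farmers",
                    "center_A", "center_B"))
  expect_equal(sum(m[, "center_A"]), 40)
  # small-center participants are all-zero on the indicators
  small <- parts$center_id == "C"
  expect_true(all(m[small, c("center_A", "center_B")] == 0))
  # indicators are mutually exclusive
  expect_true(all(rowSums(m[, c("center_A", "center_B")]) <= 1))
  # empty sample -> empty matrix
  expect_equal(nrow(build_covariate_matrix(parts[0, ])), 0)
  # missing covariates rejected
  bad <- parts; bad$ses[3] <- NA
  expect_error(build_covariate_matrix(bad), "missing covariates")
})

test_that("a matched control carries its case's reference age", {
  sim <- simulate_study(sim_config(n_cases = 50, n_variables = 4), seed = 2)
  p <- sim$dataset$participants
  ctrl <- p[p$status == "control" & !is.na(p$matched_set_id) &
              p$matched_set_id %in% p$matched_set_id[p$status == "case"], ]
  case_age <- setNames(p$reference_age[p$status == "case"],
                       p$matched_set_id[p$status == "case"])
  expect_equal(ctrl$reference_age, unname(case_age[ctrl$matched_set_id]))
})

test_that("propensity scores: determinism, no-signal, strong-signal", {
  set.seed(3)
  n <- 300
  covm <- cbind(reference_age = runif(n, 0.5, 15.5),
                ses = sample(0:2, n, TRUE),
                urban_unit_index = sample(0:8, n, TRUE),
                pct_farmers = runif(n, 0, 0.3))
  rownames(covm) <- sprintf("p%03d", 1:n)
  # no signal: exposure independent of covariates
  x0 <- rbinom(n, 1, 0.4)
  s1 <- fit_propensity(covm, x0, seed = 42, ntree = 150)
  s2 <- fit_propensity(covm, x0, seed = 42, ntree = 150)
  expect_identical(s1, s2)                       # same seed, same scores
  expect_equal(mean(s1), mean(x0), tolerance = 0.05)
  expect_lt(abs(cor(s1, covm[, "reference_age"], method = "spearman")), 0.2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  # strong age-driven exposure: scores track age
  x1 <- rbinom(n, 1, plogis(1.5 * scale(covm[, "reference_age"])))
  s3 <- fit_propensity(covm, x1, seed = 42, ntree = 150)
  expect_gt(cor(s3, covm[, "reference_age"], method = "spearman"), 0.7)
  # guards
  expect_error(fit_propensity(covm, rep(1, n), seed = 1), "constant")
  expect_error(fit_propensity(covm[1:10, ], x0[1:10], seed = 1), "at least")
  expect_error(fit_propensity(covm, replace(x0, 3, NA), seed = 1), "missing")
})

test_that("out-of-bag predictions approximate leave-one-out refits", {
  set.seed(8)
  n <- 200
  covm <- cbind(a = runif(n), b = runif(n))
  y <- covm[, "a"] * 2 + rnorm(n, 0, 0.2)
  fit <- rf_fit(covm, y, ntree = 400, seed = 5)
  # spot-check: drop one point, refit, compare its fresh prediction with OOB
  i <- 17
  refit <- rf_fit(covm[-i, ], y[-i], ntree = 400, seed = 6)
  pred <- predict(refit, covm[i, , drop = FALSE])
  expect_lt(abs(pred - fit$oob[i]), 0.35)        # loose tolerance by design
  expect_equal(fit$n_never_oob, 0L)
})

test_that("quantile stratification: deciles, ties, exhaustiveness", {
  set.seed(4)
  scores <- runif(1000)
  strat <- quantile_stratify(scores, 10)
  expect_equal(sort(unique(strat)), 1:10)
  expect_true(all(table(strat) == 100))
  expect_equal(length(strat), 1000)              # exhausts the sample
  # labels ordered by score interval
  expect_true(all(tapply(scores, strat, max)[-10] <=
                    tapply(scores, strat, min)[-1] + 1e-12))
  # all identical -> single stratum with a warning
  expect_warning(one <- quantile_stratify(rep(0.3, 50), 10), "identical")
  expect_equal(unique(one), 1L)
  # massive ties at the minimum merge duplicate edges
  tied <- c(rep(0, 550), runif(450, 0.5, 1))
  st <- quantile_stratify(tied, 10)
  expect_lt(length(unique(st)), 10)
  expect_equal(length(st), 1000)
})

test_that("k = 1 propensity screen reduces to the unstratified test", {
  sim <- simulate_study(sim_config(n_cases = 150, n_variables = 6,
                                   prop_binary = 1, orphan_control_rate = 0,
                                   control_pattern = c(0, 1, 0),
                                   miss_case = 0, miss_control = 0),
                        seed = 12)
  enc <- encode_variables(sim$dataset$responses, sim$dataset$spec)
  ps <- build_propensity_sample(sim$dataset)
  res <- run_propensity_screen(ps$sample, enc, sim$dataset$spec,
                               sim$dataset$participants, seed = 1, k = 1,
                               ntree = 50)
  ids <- ps$sample$participant_id
  for (v in res$variable_id[res$status == "ok"]) {
    tab <- array(table(factor(enc[ids, v], levels = c(1, 0)),
                       factor(ps$sample$status,
                              levels = c("case", "control"))),
                 c(2, 2, 1))
    expect_equal(res$p_value[res$variable_id == v], cmh_test(tab)$p_value,
                 tolerance = 1e-12)
  }
  expect_true(all(res$effective_k[res$status == "ok"] == 1))
})

test_that("propensity screen output is reproducible and well-formed", {
  sim <- simulate_study(sim_config(n_cases = 100, n_variables = 8,
                                   control_pattern = c(0.3, 0.5, 0.2)),
                        seed = 6)
  enc <- encode_variables(sim$dataset$responses, sim$dataset$spec)
  ps <- build_propensity_sample(sim$dataset)
  r1 <- run_propensity_screen(ps$sample, enc, sim$dataset$spec,
                              sim$dataset$participants, seed = 9, ntree = 60)
  r2 <- run_propensity_screen(ps$sample, enc, sim$dataset$spec,
                              sim$dataset$participants, seed = 9, ntree = 60)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 8)
  expect_true(all(r1$effective_k[r1$status == "ok"] <= 10))
  # per-variable seeds differ across variables but are seed-stable
  expect_gt(length(unique(r1$rf_seed[!is.na(r1$rf_seed)])), 1)
})
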