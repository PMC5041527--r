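make_ds <- function(parts, resp = NULL, spec = tiny_spec()) {
  if (is.null(resp)) resp <- tiny_responses(parts$participant_id, spec)
  study_dataset(parts, resp, spec)
}

test_that("exclusion cascade applies each rule and logs the first hit", {
  parts <- rbind(
    participant("keep", age = 7),
    participant("young", age = 0.3),
    participant("old", age = 15.8),
    participant("late", delay = 12),
    participant("school", age = 5.0, school = TRUE),
    participant("school_ok", age = 6.0, school = TRUE),
    participant("noage", age = NA),
    participant("empty")
  )
  spec <- tiny_spec()
  resp <- tiny_responses(parts$participant_id, spec)
  resp["empty", ] <- NA   # 100 % missing
  out <- apply_exclusions(make_ds(parts, resp))
  log <- out$log
  rule_of <- function(id) log$rule[log$participant_id == id]
  expect_equal(rule_of("young"), "age_window")
  expect_equal(rule_of("old"), "age_window")
  expect_equal(rule_of("late"), "delay")
  expect_equal(rule_of("school"), "school_consistency")
  expect_equal(rule_of("noage"), "unusable_missing_age")
  expect_equal(rule_of("empty"), "missingness")
  expect_setdiff <- setdiff(out$dataset$participants$participant_id,
                            c("keep", "school_ok"))
  expect_length(expect_setdiff, 0)
  # boundary values are retained (window is inclusive, delay cut strict)
  parts2 <- rbind(participant("lo", age = 0.5), participant("hi", age = 15.5),
                  participant("d10", delay = 10))
  out2 <- apply_exclusions(make_ds(parts2))
  expect_false(any(out2$log$excluded))
})

test_that("a control inherits its case's delay; unmatched controls exempt", {
  parts <- rbind(
    participant("c1", "case", set = "s1", delay = 12),
    participant("k1", "control", set = "s1", delay = NA),
    participant("c2", "case", set = "s2", delay = 3),
    participant("k2", "control", set = "s2", delay = NA),
    participant("lone", "control", delay = NA)
  )
  out <- apply_exclusions(make_ds(parts))
  log <- out$log
  expect_true(log$excluded[log$participant_id == "c1"])
  expect_true(log$excluded[log$participant_id == "k1"])  # via case's delay
  expect_false(log$excluded[log$participant_id == "k2"])
  expect_false(log$excluded[log$participant_id == "lone"])
})

test_that("exclusion cascade is monotone in its thresholds", {
  set.seed(21)
  sim <- simulate_study(sim_config(n_cases = 60, n_variables = 10,
                                   orphan_control_rate = 0), seed = 3)
  loose <- apply_exclusions(sim$dataset,
                            exclusion_config(missingness_max = 1, delay_max = Inf,
                                             age_min = 0, age_max = 100))
  tight <- apply_exclusions(sim$dataset, exclusion_config())
  tighter <- apply_exclusions(sim$dataset,
                              exclusion_config(age_min = 3, age_max = 12,
                                               delay_max = 4))
  n <- function(o) nrow(o$dataset$participants)
  expect_true(n(loose) >= n(tight))
  expect_true(n(tight) >= n(tighter))
  # retained + excluded-by-rule reconciles
  expect_equal(n(tight) + sum(tight$log$excluded), nrow(sim$dataset$participants))
  # tighter's retained set is a subset of tight's
  expect_true(all(tighter$dataset$participants$participant_id %in%
                    tight$dataset$participants$participant_id))
})

test_that("matched sample keeps only complete sets, sizes 2 or 3", {
  parts <- rbind(
    participant("c1", "case", set = "s1"),
    participant("k1a", "control", set = "s1"),
    participant("k1b", "control", set = "s1"),
    participant("c2", "case", set = "s2"),
    participant("k2", "control", set = "s2"),
    participant("c3", "case", set = "s3"),              # no control
    participant("k4", "control", set = "s4"),           # orphan control
    participant("c5", "case")                            # unmatched case
  )
  ms <- build_matched_sample(make_ds(parts))
  sizes <- table(ms$sample$stratum_id)
  expect_setequal(names(sizes), c("s1", "s2"))
  expect_true(all(sizes %in% c(2, 3)))
  expect_setequal(ms$dropped$participant_id, c("c3", "k4", "c5"))
  expect_equal(ms$dropped$reason[ms$dropped$participant_id == "k4"],
               "control_without_case")
  expect_equal(ms$dropped$reason[ms$dropped$participant_id == "c3"],
               "case_without_control")
})

test_that("matched sample after exclusions has stratum sizes only {2,3}", {
  sim <- simulate_study(sim_config(n_cases = 80, n_variables = 6), seed = 9)
  out <- apply_exclusions(sim$dataset)
  ms <- build_matched_sample(out$dataset)
  expect_true(all(table(ms$sample$stratum_id) %in% c(2, 3)))
  # every stratum has exactly one case
  by_status <- table(ms$sample$stratum_id, ms$sample$status)
  expect_true(all(by_status[, "case"] == 1))
  expect_true(all(by_status[, "control"] >= 1))
})

test_that("propensity sample needs covariates, ignores matching", {
  parts <- rbind(
    participant("a", "case"),                      # unmatched, full covariates
    participant("b", "control", pf = NA),          # no postal-code covariates
    participant("c", "control", ses = NA),         # no profession
    participant("d", "control", set = "s9")
  )
  ps <- build_propensity_sample(make_ds(parts))
  expect_setequal(ps$sample$participant_id, c("a", "d"))
  expect_setequal(ps$dropped$participant_id, c("b", "c"))
  expect_equal(ps$dropped$reason[ps$dropped$participant_id == "b"],
               "missing_postal_code")
  expect_equal(ps$dropped$reason[ps$dropped$participant_id == "c"],
               "missing_profession")
  # empty dataset -> empty sample
  empty <- make_ds(participant("x"))
  empty$participants <- empty$participants[0, ]
  empty$responses <- empty$responses[0, , drop = FALSE]
  expect_equal(nrow(build_propensity_sample(empty)$sample), 0)
})

test_that("sd_filter drops near-constant and all-missing variables", {
  n <- 1000
  m <- cbind(
    rare = c(rep(1, 10), rep(0, n - 10)),      # prevalence 0.01
    constant = rep(1, n),
    balanced = rep(c(0, 1), n / 2),
    gone = rep(NA_real_, n)
  )
  rownames(m) <- sprintf("p%04d", seq_len(n))
  f <- sd_filter(m, rownames(m), threshold = 0.1)
  expect_equal(f$kept, c(FALSE, FALSE, TRUE, FALSE))
  # population sd of a 1 % binary variable is sqrt(p(1-p)) ~ 0.0995
  expect_equal(f$sd[f$variable_id == "rare"], sqrt(0.01 * 0.99))
  expect_equal(f$sd[f$variable_id == "balanced"], 0.5)
  expect_equal(f$reason[f$variable_id == "gone"], "all_missing")
  expect_equal(f$reason[f$variable_id == "constant"], "low_sd")
})
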