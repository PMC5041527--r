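# Small handcrafted fixtures shared across test files. Everything is built
# in code; no files on disk.

# A 4-question spec covering binary, 3-, and 5-level ordinals plus a
# reversed-orientation item.
tiny_spec <- function() {
  questionnaire_spec(list(
    question_def("qbin", c("no", "yes")),
    question_def("qmid", paste0("l", 1:3)),
    question_def("qfreq", c("never", "monthly", "weekly", "daily", "several_daily")),
    question_def("qrev", paste0("r", 1:3), orientation = "reversed")
  ))
}

# One participant row with sensible defaults, overridable per test.
participant <- function(id, status = "case", set = NA, age = 7, delay = 2,
                        ses = 1, uui = 3, pf = 0.05, center = "C1",
                        school = FALSE) {
  data.frame(participant_id = id, status = status, matched_set_id = set,
             reference_age = age, delay = delay, ses = ses,
             urban_unit_index = uui, pct_farmers = pf, center_id = center,
             attended_primary_school = school, stringsAsFactors = FALSE)
}

# Full-response matrix for the tiny spec (first level everywhere).
tiny_responses <- function(ids, spec = tiny_spec()) {
  m <- matrix(NA_character_, length(ids), length(spec),
              dimnames = list(ids, names(spec)))
  for (v in names(spec)) m[, v] <- spec[[v]]$levels[1]
  m
}

# Matched pairs with a binary exposure given by discordance counts:
# b pairs (case exposed, control not), c pairs (control exposed, case not),
# conc concordant-exposed pairs. Returns exposure, status, strata vectors.
paired_binary <- function(b, c, conc = 0) {
  n_pairs <- b + c + conc
  x <- c(rbind(c(rep(1, b), rep(0, c), rep(1, conc)),
               c(rep(0, b), rep(1, c), rep(1, conc))))
  y <- rep(c("case", "control"), n_pairs)
  s <- rep(seq_len(n_pairs), each = 2)
  list(x = x, y = y, s = s)
}

# Brute-force conditional log-likelihood for 1-case strata: enumerates each
# stratum's denominator directly from the definition. Independent oracle for
# conditional_logit on small data.
brute_cloglik <- function(beta, x, y, s) {
  ll <- 0
  for (g in unique(s)) {
    xi <- x[s == g]
    yi <- y[s == g]
    if (length(unique(yi)) < 2) next
    ll <- ll + beta * xi[yi == "case"] - log(sum(exp(beta * xi)))
  }
  ll
}
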