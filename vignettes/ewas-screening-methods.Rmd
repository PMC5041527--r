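---
title: "Environment-wide association screening for matched case-control questionnaires: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Environment-wide association screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewascreen)
```

## The problem

An environment-wide association study (EWAS) screens hundreds of candidate
exposures against a single outcome with no prior hypothesis, the way a GWAS
screens genetic variants. `ewascreen` implements such a screen for the
design in which cases of a childhood disease are matched to friend or
schoolmate controls of the same reference age, and the exposures come from a
large retrospective questionnaire of mixed binary and ordinal items filled
by parents. Two independent analyses of the same question bank are run — a
matched stratified analysis and an unmatched propensity-score analysis — and
a variable counts as *discovered* only when it clears a multiple-testing
threshold in both.

## Encoding

Every questionnaire item is declared (`question_def()`) with its kind,
ordered response levels (2–5) and an orientation flag. An item with $L$
levels maps its $k$-th level (after orientation) to $k/(L-1)$, so all
variables live on $[0,1]$ with endpoints exactly 0 and 1. Two consequences:

* effect sizes are comparable across items — for any variable,
  $\exp(\hat\beta)$ is the odds ratio between the two *extreme* responses;
* equal spacing of interior levels is an explicit modelling choice. Only the
  endpoints are identified by the extreme-response interpretation; we take
  the simplest interior interpolation and treat departures from it as part
  of model error.

The attainable value set is fixed by the declaration, never by the observed
data, so encodings are comparable between samples. Missing responses stay
missing — each test uses per-variable complete cases; no imputation.

## Exclusion cascade

Participants are removed, in a fixed order that stabilizes the log without
changing the retained set (the rules are conjunctive):

| rule | default | rationale |
|---|---|---|
| missingness | > 50 % of items unanswered | questionnaire unusable |
| age window | reference age outside [0.5, 15.5] y | instrument targets childhood |
| delay | diagnosis-to-questionnaire > 10 y | recall quality |
| school consistency | primary school reported before age 5.5 | recall quality marker |

A control has no diagnosis, hence no delay of its own: it inherits its
matched case's delay; unmatched controls with no delay are exempt. A
missing reference age is a distinct "unusable" code. Participants whose
school answer is missing are not excluded by the school rule.

The matched sample then keeps only complete sets (one case plus one or two
surviving controls → strata of size 2 or 3); the propensity sample keeps
every participant with complete bias-control covariates, matched or not.

## Matched analysis

Within matched strata, binary items are tested by the
Cochran–Mantel–Haenszel statistic (1 df, no continuity correction, so on
1:1 pairs it equals McNemar's $(b-c)^2/(b+c)$ exactly), with the
Mantel–Haenszel common odds ratio and a Robins–Breslow–Greenland confidence
interval — the variance estimate that remains valid with many sparse
strata, the matched design's regime. Ordinal items enter a conditional
logistic regression linearly on the $[0,1]$ encoding: one coefficient,
Wald inference, Newton–Raphson with relative tolerance $10^{-8}$ and at
most 100 iterations. The same routine accepts additional covariates, which
is how a two-variable adjusted model (e.g. checking that one exposure's
association survives adjustment for another) is fitted.

For strata holding a single case the likelihood is the exact conditional
one. Strata holding several cases (they arise in the propensity analysis,
where a decile is one stratum) use the Breslow approximation; exact
enumeration over $\binom{180}{90}$ case assignments is not a real option,
and the two coincide in the single-case situation. Variables with standard
deviation below 0.1 (population formula, pooled analysis sample) are
filtered before testing — near-constant exposures make these fits
unstable — and reported with status `filtered` rather than silently
dropped.

Both engines are validated against independent oracles in the test suite:
`stats::mantelhaen.test`, `survival::clogit`, closed forms on discordant
pairs, and brute-force enumeration of the conditional likelihood on tiny
strata.

## Propensity analysis

The unmatched analysis controls bias by stratifying on an estimated
propensity score. Per exposure:

1. a *regression* random forest (500 trees, mtry $= \lfloor p/3\rfloor$,
   terminal nodes ≤ 5) predicts the encoded exposure from reference age,
   SES (0/1/2), the commune's urban-unit index and percent farmers, and one
   indicator per recruitment center with more than 30 participants;
2. the propensity score is the *out-of-bag* prediction — each participant
   is predicted only by trees whose bootstrap resample excluded it, an
   internally cross-validated score that does not overfit; scores are
   clipped to $[0,1]$;
3. the sample is cut at score deciles (duplicate quantile edges merged;
   the effective number of strata is reported), and the exposure is tested
   against case-control status within strata: CMH for binary items,
   conditional logistic regression with deciles as conditioning sets for
   ordinal ones.

Per-variable forest seeds derive deterministically from the master seed and
the variable id, so results do not depend on iteration order. The forest
itself is implemented in C++ inside the package because no random-forest
package is available in the target environment; it is deliberately plain
bagged CART regression with the reference defaults, and its out-of-bag
contract is tested against leave-one-out refits.

## Multiple testing and discovery

With $m$ tests per analysis ($m$ = variables with an `ok` result, not the
nominal questionnaire size — tests never performed cannot be corrected
for):

* the matched analysis, considered the higher-quality design, uses the
  lenient Benjamini–Hochberg FDR at 5 %;
* the propensity analysis uses the strict family-wise criterion. The
  procedure is Holm's step-down (same FWER guarantee as plain Bonferroni,
  uniformly more rejections); the plain $\alpha/m$ Bonferroni line is also
  emitted because volcano plots draw it.

`dual_discovery()` flags a variable as discovered when it passes the
matched FDR threshold *and* the propensity Bonferroni threshold — requiring
agreement between two analyses with different bias structures gives better
false-positive control than either alone. `volcano_table()` and
`comparison_table()` emit plot-ready coordinates ($\log$ effect size with
protective factors negative, $-\log_{10} p$), with zero p-values capped at
a display ceiling of 300 and flagged.

## Synthetic data: the stated world

`simulate_study()` generates the structure the two analyses assume, with
known ground truth, so every operating characteristic in the test suite is
measured rather than asserted. Defaults encode the target study design:

* cases with 0/1/2 controls in proportions 1077:451:241; an additional
  152:933 ratio of "orphan" controls whose case never returned a
  questionnaire;
* SES weights 837:725:278; reference age Beta(1.5, 1.7) scaled to
  [0.5, 15.5] years (median ≈ 7.4 y); delay lognormal with median 3 y,
  truncated at the 10-year exclusion ceiling — the default world is the
  post-exclusion regime, and exclusion-rule behaviour is tested on
  handcrafted participants instead;
* matched controls inherit the case's reference age exactly and copy its
  categorical covariates with probability 0.7 (the "matching fidelity" of
  friends sharing an environment), mixing continuous ones convexly;
* per-variable missingness 5 % in cases vs 4 % in controls, mirroring the
  mild differential seen in practice;
* exposures follow logistic (binary) or proportional-odds (ordinal) models
  with optional covariate confounding; case status acts by *tilting* the
  exposure distribution of cases by $\exp(\beta \cdot \text{encoding})$ —
  retrospective sampling, so a configured $\beta$ *is* the
  extreme-response log odds ratio the matched analysis estimates;
* 200 variables by default (845 available) to keep the suite fast.

What the generator does **not** emulate: recall-bias content, item-level
correlation structure within questionnaire themes, real commune/center
joint distributions (stylized Zipf centers and a synthetic urban gradient),
or participation bias beyond the covariate-tilt knob. A green test
therefore establishes calibration and recovery under the assumed
statistical structure, not robustness to violations of it.

### The confounded-null design

The headline validity simulation drives exposure and status through shared
covariates with no direct effect: control covariates are drawn with a
participation-bias tilt (more urban, higher SES), and the exposure model
loads on percent farmers, the urban index and SES. The naive unstratified
chi-square test then rejects far above nominal while the propensity screen
stays near 5 %. Two design notes, decided before the confirmatory runs and
frozen:

* reference age cannot confound this design — a matched control carries
  its case's age by construction — so the confounding runs through the
  socio-geographic covariates instead;
* pilot runs showed that a confounder observed only through a 3-level SES
  variable leaves visible residual confounding after decile stratification
  (strata stay internally heterogeneous); that is a known property of
  coarse stratification, not an implementation artifact. The frozen design
  therefore includes the continuous percent-farmers channel, where decile
  stratification is effective.

## Numerical choices

* CMH: strata with total < 2 contribute nothing; a zero hypergeometric
  variance sum gives statistic 0, p = 1, status `degenerate`; an MH
  estimate with all cross-products on one side is undefined (`degenerate`,
  p kept).
* Conditional logit: complete separation is declared when the exposure
  coefficient passes ±15 (odds ratios beyond e¹⁵ between extreme
  responses are not estimable from these designs) → `nonconverged`, no
  estimate. Within-stratum linear predictors are max-shifted before
  exponentiation only when they exceed ±30, keeping the common case fast.
* Quantile stratification uses type-7 quantiles; duplicate edges are
  merged and every participant labeled via `findInterval`.
* Per-variable forest seeds: a 31-bit polynomial hash of the variable id
  folded with the master seed.

## Limitations

* Wald p-values and the chi-square CMH tail are asymptotic; at a few
  hundred strata their far tail ($p \sim 10^{-4}$) is measurably, mildly
  anticonservative. The acceptance criteria absorb this within
  Monte-Carlo slack, but exact conditional tests would be preferable for
  borderline discoveries near a Bonferroni threshold.
* Decile stratification removes most, not all, measured confounding; with
  coarse categorical confounders residual bias persists (see above).
* The Breslow approximation slightly attenuates estimates in strata where
  cases are a large fraction of the stratum, as in propensity deciles of a
  case-heavy sample.
* No dependence-adjusted FDR: the BH guarantee is exact under
  independence; questionnaire items are correlated in real data.
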