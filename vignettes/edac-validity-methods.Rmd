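---
title: "Methods: the avoidability classification and its criterion-validity analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the avoidability classification and its criterion-validity analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edacr)
```

## The problem and the classifier

Emergency departments see a substantial volume of visits that could have been
managed safely in subacute primary care (walk-in clinics, urgent care).
Quantifying that volume from routinely collected administrative data requires
a deterministic, auditable rule. The Emergency Department Avoidability
Classification (EDAC) is such a rule: it labels a retrospective ED visit

* **avoidable** when *all* of: age 18–70 (inclusive at both ends), triage
  acuity CTAS 4 or 5, no specialist consultation in the ED, a main physician
  intervention on a registry of subacute-manageable procedure codes, and
  discharge from the ED;
* **potentially avoidable** when the same conjunction holds with CTAS 3;
* **not avoidable** otherwise.

The three classes are ordered (not avoidable < potentially avoidable <
avoidable) and that ordering is what the association analyses exploit.
`classify_visit()` and `classify_cohort()` implement the rule; visits missing
any criterion variable raise an error rather than defaulting to
not-avoidable, mirroring the chart-exclusion practice of validation studies
(a silent default would bias prevalence estimates downward invisibly). The
registry of subacute-manageable intervention codes is site configuration:
`default_registry()` ships clearly synthetic CCI-style codes so the package
runs self-contained, and `read_code_registry()` loads a real site list. Codes
are canonicalized (trim, uppercase) before matching.

## The criterion standard: paired physician judgement

Validity is assessed against blinded judgements by practising ED physicians:
every sampled visit is reviewed independently by two physicians, each judging
whether the visit could have been managed appropriately and safely in
subacute primary care (and rating their confidence 1–5). The package
represents the data at two levels:

* **judgement pairs** — one row per visit with two anonymous rating slots;
* the **concordance table** — a 3×3 cross-classification of avoidability
  class against the ordinal pair outcome *both-ED < discordant <
  both-subacute* (`concordance_table()`).

`fixture_concordance()` freezes the reconstructed table of the published
160-visit validation study (per class, both-ED/discordant/both-subacute:
avoidable 1/1/52, potentially avoidable 3/13/37, not avoidable 33/7/13). The
potentially-avoidable split is fixed by that class's 40 concordant pairs;
the same split independently reproduces the published correlation, odds
ratios, concordance index and every precision cell, which is why the package
treats it as the authoritative reconstruction even though one narrative
sentence in the source transposes the 13 and the 3.

## Agreement statistics

`percent_agreement()` is the concordant fraction. `pooled_kappa()` is
chance-corrected agreement in which the chance term uses a single marginal
pooled over both rating slots, `p = (total subacute ratings)/(2n)`,
`pe = p² + (1−p)²`, `κ = (po − pe)/(1 − pe)`. The pooled marginal is a
deliberate design choice: after randomized assignment the two slots of an
anonymized pair do not identify raters, so any statistic that depends on slot
labels is not estimable from the data as archived. The pooled estimator is
exactly slot-symmetric and coincides with classical two-rater Cohen's kappa
whenever the per-rater marginals are symmetric.

What anonymization costs can be quantified: `kappa_attribution_range()`
enumerates every possible attribution of the discordant pairs to raters and
returns the classical Cohen's kappa each implies. On the fixture the overall
(0.69), avoidable-and-not-avoidable (0.84) and avoidable-class (0.66)
estimates are stable at two decimals across the entire envelope. The
not-avoidable class is the one place the envelope straddles a rounding
boundary: the pooled estimator gives 0.692 (prints as 0.69) while the
asymmetric end of the envelope reaches 0.698 (prints as 0.70, the published
figure). The potentially-avoidable class is more extreme still — pooled
≈ 0.17 against a published 0.25 that is attained only under a maximally
asymmetric attribution of its 13 discordant pairs — which is why that value
is documented but not treated as a reproducible target.

The default confidence interval is the asymptotic large-sample
(Fleiss–Cohen–Everitt) interval evaluated on the slot-symmetrized 2×2 table;
the original report does not state its interval method, so intervals are not
treated as reproduction targets, and `bootstrap_ci()` (percentile, visit-level
resampling, seed-reproducible) is offered as a distribution-free alternative.
Kappa is reported with Landis–Koch bands (`kappa_interpretation()`); the
band edges 0.20/0.40/0.60/0.80 belong to the lower band and 0 to "slight",
so a kappa of exactly 0 is slight, not poor. Confidence scores are summarised
as mean and SD with the sample (n−1) denominator.

Degenerate inputs signal classed conditions rather than returning silent
`NA`s: a subset in which every rating is identical has `pe = 1` and raises
`edacr_kappa_undefined`, distinct from any computational failure.

## Association analyses

`spearman_ordinal()` is the tie-corrected Spearman correlation between the
class ordinal and the concordance ordinal: Pearson correlation of midranks,
computed from the 3×3 counts by weighted formulas (the expansion to 160 rows
is never materialized). It is invariant to strictly monotone relabeling of
either scale, and is undefined (classed error) when a margin is concentrated
in a single level.

`fit_cumulative_logit()` fits the proportional-odds model
`logit P(Y ≤ j | class) = ζ_j − β_class` (referent: not avoidable) by damped
Newton iteration on the multinomial likelihood: analytic gradient, numeric
Hessian, full Newton steps halved until the log-likelihood does not decrease,
convergence when the gradient max-norm falls below 1e−8 (default cap 100
iterations, which the fixture reaches in 7). Thresholds start at the pooled
cumulative logits and coefficients at zero. Separated tables (a class row
entirely at one extreme level) are flagged with an inflated-variance warning
before fitting. The fit agrees with `MASS::polr` to six decimals on the
fixture, and the tests keep `polr` as an independent oracle only.

Two odds-ratio routes are exposed deliberately. The published headline ORs
(80.0 with 17.1–374.9; 7.1 with 3.0–16.8) match, to every printed digit, the
closed-form cross-product ratios of the dichotomy *both-subacute vs rest*
with Wald intervals `exp(ln OR ± 1.96·√Σ1/cell)` — not the proportional-odds
coefficients, whose avoidable-class OR is 109.5. `reported_or()` therefore
implements the dichotomized closed form (with an optional 0.5 continuity
correction for zero cells), while the genuinely ordinal estimates live in
`fit_cumulative_logit()`. The model "AUC" of 0.84 is Harrell's C over ordinal
outcome pairs (`ordinal_cindex()`): among all pairs of visits with different
concordance levels, the fraction in which the higher level carries the higher
class score, ties counting one half. C is antisymmetric under score reversal
and equals the published 0.84 with any scores respecting the class order.

## Precision under regrouping of the middle class

`rating_table()` scores each individual judgement (two per visit; 320 in the
study, 214 when the middle class is excluded) against the classifier group
under three scenarios: potentially-avoidable excluded, merged into avoidable,
merged into not-avoidable. `precision_stats()` reports accuracy, sensitivity
and specificity with exact Clopper–Pearson intervals (`stats::binom.test`).
The study's orientation convention — recovered by matching all nine printed
cells — conditions "sensitivity" on the classifier-negative group (fraction
judged ED-appropriate) and "specificity" on the positive group (fraction
judged subacute-suitable), the reverse of the textbook labeling; both
orientations are therefore returned, labeled, so no new dataset inherits the
ambiguity silently. Structurally, excluding the middle class or merging it
downward leaves specificity identical, and merging it upward leaves
sensitivity identical; `scenario_compare()` reports the scenario table plus
percentage-point deltas against the exclusion baseline (−21.6 accuracy and
−25.5 sensitivity points when the middle class is called not-avoidable).
Accuracy is always the prevalence-weighted mix of the two conditional rates,
asserted numerically in the tests.

## Study design tools

`stratified_sample()` draws equal cluster quantities (remainder, when the
total is not divisible by 3, allocated avoidable-first, so 160 gives
54/53/53), uniformly without replacement, seed-reproducible.
`build_assignment()` produces the blinded dual-rater plan: first-round
batches of 20 with per-cluster composition 7/7/6, the light cluster rotating
across raters so aggregate workloads balance (the source does not state how
the 6 was allocated; rotation is this package's choice); second-round batches
absorb the remaining demand as evenly as possible. Within a cluster, visit
slots are placed by a randomized largest-remaining-capacity rule with
whole-cluster retries as backtracking — for the study's dimensions the greedy
step essentially never sticks, and the retry bound makes termination
explicit. The emitted plan deliberately contains no class column (blinding);
the class map stays with the sampling output. A rater appearing in both
rounds is one rater for the distinct-raters-per-visit constraint.

`simulate_power()` estimates the power of the two-sided asymptotic kappa
z-test against a null value, generating paired binary ratings from the
common-correlation 2×2 construction (both-subacute probability
`p² + κp(1−p)`, discordance `2p(1−p)(1−κ)`). It uses the same pooled
estimator and SE as the agreement module, so the power statement is about
the test actually used. The original protocol's closed-form 126-visit
calculation is out of scope; this simulator is the mechanism, not that
formula. At the study-like point (κ₀ = 0.4, κ₁ = 0.69, prevalence 0.7,
n = 160, α = 0.05) an independent 50,000-replicate run gives power 0.983,
which the test suite checks at 2,000 replicates; at κ₁ = κ₀ the rejection
rate sits at α up to the mild anticonservatism of a Wald test at n = 160.

## The synthetic cohort and judgement generator

The generator defines the study conditions the tests run under.
`generate_visits()` draws 54/53/53 visits per class by default, with
per-class marginals for sex, age band, arrival mode, CTAS, day of week,
time-in-ED band, provider and outcome fixed at the validation cohort's
descriptive frequencies (`default_marginals()`). Attributes are independent
within class — the source publishes marginals only — except where the class
definition constrains them: avoidable/potentially-avoidable visits are
forced to age ≤ 70, no consult, registry code and discharge; not-avoidable
visits drawn into the avoidable conjunction are repaired with an
off-registry code. Age and ED minutes are uniform within their band (the
over-241-minute band capped at 1440; the published mean 429/SD 547 implies a
heavy tail no banded model reproduces, and no parametric duration model is
claimed). The consult probability for not-avoidable visits (0.5) is a free
choice; the source reports no consult marginal. Every generated visit is
asserted, on every run, to classify to its intended class.

`generate_judgements()` gives each visit a latent suitability state
(per-class probability `p_subacute`, defaults 0.97/0.82/0.31 — the fixture's
per-class subacute rating margins) and flips it independently in each rating
with probability `rater_error`. The default 0.07 was calibrated once to the
fixture's overall discordance via `2e(1−e) = 21/160` and left alone; it
implies a constant per-class discordance rate, a simplification the fixture
itself violates (its discordance varies 2%–25% by class), so per-class
agreement patterns of real data are *not* emulated — only the overall level.
Confidence scores are normal draws (per-class means 4.2/3.9/4.4, SD 0.9)
rounded and clipped to 1–5, which pulls the realized mean slightly toward
the middle; confidence means are descriptive only and never targets.
`recover_parameters()` inverts the model by method of moments (pooled
discordance identifies the error rate, each class's both-subacute fraction
then identifies its latent probability) and recovers the defaults to ±0.02 /
±0.01 at n = 50,000 in the tests.

What passing tests therefore show: the pipeline's statistics are correct on
data with the study's margins and a single shared error rate. What they do
not show: robustness to rater heterogeneity, class-dependent error,
attribute correlation (e.g. age × acuity) or true clinical case-mix — none
of which the published marginals constrain.

## Problem sizes and numerical choices

The test suite runs the fixture analyses (instant), bootstrap checks at a
few hundred replicates, power calibration at 2,000–3,000 replicates,
generator-moment checks at cohorts of ~5,000 and parameter recovery at
50,000 — sizes chosen so each check's Monte-Carlo error is comfortably below
the tolerance it asserts. All stochastic tests fix seeds. Tolerances on
frozen Monte-Carlo values are three combined standard errors; tolerances on
deterministic reproductions are the printed precision of the quantity (two
decimals for kappa and correlation, one for percentages and ORs).

## Known limitations

* The pooled-marginal kappa cannot reproduce a published per-class value
  that depended on the unpublished rater attribution (the not-avoidable
  0.70 vs 0.692 rounding difference, and the potentially-avoidable 0.25);
  the attribution envelope quantifies exactly how far attribution can move
  the estimate.
* Asymptotic kappa intervals differ from the source's (method unstated);
  intervals are not reproduction targets.
* The generator models judgement with one shared error rate and
  class-independent attributes; it is a test harness, not a clinical
  simulator.
* The shipped registry is synthetic. Real avoidability estimates require the
  local consensus code list.
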