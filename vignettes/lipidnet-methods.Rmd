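---
title: "Coupling lipid networks to time-to-event endpoints: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling lipid networks to time-to-event endpoints: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidnet)
library(dplyr)
```

# The scientific problem

Circulating ceramides and dihydroceramides form a tightly co-regulated panel:
elongation and desaturation reactions make neighbouring species strongly
correlated, so a single species' association with disease risk is easily an
echo of its biochemical neighbours. lipidnet implements an analysis chain
that separates direct from network-confounded disease associations in a
case-cohort study, and then asks two follow-up questions: do diet exposures
act *through* the disease-related lipids (mediation), and does genetic
variation support a causal role for a lipid (Mendelian randomization)?

The chain is: log/z preprocessing → conditional-independence network →
single-lipid screen → iterative neighbour-adjusted direct-effect
classification → mediation ("proportion explainable") → Wald-ratio MR.
Because the motivating cohort data cannot be public, every stage is
exercised against a synthetic generator whose ground truth is known, so the
package's guarantees are parameter-recovery guarantees.

# The models, stage by stage

## Preprocessing

Raw concentrations (nM, right-tailed) are natural-log transformed and
z-scaled with the sample SD (denominator $n-1$); all regression estimates
downstream are per 1 SD of the log concentration. Subjects with a missing
or non-positive value in a selected column are excluded from analyses using
that column only.

One subtlety matters in a case-cohort sample: cases are oversampled, so
means and SDs computed on the analysis sample are not representative of the
cohort and inflate the scale (we measured a 4–5% upward bias on the log
hazard ratio with ~25% cases). `log_z_transform()` therefore accepts a
`params` argument: derive the transform on the random subcohort, apply it to
the analysis sample. `run_pipeline()` does this automatically.

Measurement reliability is summarized by the one-way random-effects
intraclass correlation on the log scale,
$\mathrm{ICC} = (MS_B - MS_W) / (MS_B + MS_W)$ for paired measurements,
classed at the conventional cutoffs 0.40 and 0.75 (poor / fair-to-good /
excellent). The two-way estimator would additionally model a systematic
occasion effect, which the generator does not produce; one-way is the
documented choice.

## The conditional-independence skeleton

`pc_skeleton()` implements the stable variant of the PC algorithm: starting
from the complete graph, for conditioning sizes $\ell = 0, 1, 2, \dots$ each
adjacent pair is tested against every size-$\ell$ subset of its neighbours,
with neighbour sets frozen at the start of each level and deletions applied
at level end. Freezing plus deferred deletion makes the edge set invariant
to the input column order, which we assert over 20 random permutations.

Conditional independence is tested by the Fisher-z transform of the partial
correlation, $z = \tfrac12\log\{(1+r)/(1-r)\}$, with statistic
$\sqrt{n - |S| - 3}\,|z|$ against the standard normal, two-sided, at
$\alpha = 0.05$. Partial correlations come from the precision matrix of the
relevant submatrix; $|r| = 1$ is declared dependent with $p = 0$ rather than
overflowing the transform. Only the undirected skeleton is produced: the
downstream classification consumes adjacency only, and edge orientation
cannot be read reliably from observational lipid panels. The maximum
conditioning size is configurable and unlimited by default; lipid panels
are small (tens of species).

## Prentice-weighted case-cohort Cox models

Age is the time scale: subjects enter the risk set at their baseline age
(left truncation) and exit at event or censoring age. The case-cohort
design is handled by the Prentice pseudolikelihood through risk-set
construction: subcohort members are at risk over their whole observed
interval, cases outside the subcohort enter only immediately before their
own event age. With a sampling fraction of 1 this reduces *exactly* to the
ordinary partial likelihood (asserted to 1e-8). Variance is always the
robust sandwich estimator — the pseudolikelihood invalidates the
model-based one — and ties use Efron's approximation (ages are continuous,
so ties are rare anyway). An optional flag additionally stratifies the
baseline hazard by 5-year baseline-age bands, reconciling "age as time
scale" with the reporting convention of an age strata variable; it is off
by default because the time scale already is age.

The single-lipid screen fits one model per metabolite per adjustment set
and controls the false discovery rate by Benjamini–Hochberg within each
(endpoint × model) family at 0.05.

## Direct-effect classification

For each metabolite $g$, one Cox model is fitted per subset of its skeleton
neighbours (all $2^d$ subsets, capped at $2^{10}$ submodels per node), each
adjusted for the base confounders, the current fixed set, and the subset.
$g$ is classified **direct** when every submodel is significant at
$\alpha = 0.05$ with a single coefficient sign; **none** when no submodel is
significant; **ambiguous** otherwise (the three-way split is our reporting
extension; only "direct" feeds selection); a non-convergent submodel makes
the decision **unresolved** rather than silently negative.

Rounds repeat with all newly selected effectors joining the fixed
adjustment set *together at round end* (batch update — this is what makes
the selection invariant to metabolite ordering; a greedy mid-round update
would not be). Selected effectors can only confound, not mediate, the
remaining candidates, which justifies conditioning on them. The fixed set
grows monotonically, so at most $p$ rounds occur. Finally all selected
metabolites enter one mutually adjusted Cox model, guarded by a
model-matrix condition-number check.

Sign consistency is sign-only (no magnitude or CI-overlap requirement) —
the weakest defensible reading of "directionally consistent".

Class totals (`total_Cer`, `total_dhCer`, summed on the raw nM scale and
then log-z transformed) can join the base adjustment. With very small
panels this is near-collinear: in a 3-species class the total carries
almost the same information as the species plus its neighbours, and the
conditional effect of one species is barely identifiable. `run_pipeline()`
therefore enables totals adjustment only for panels of ten or more species,
where a single species is a small share of its class; the cutoff is
configurable (`adjust_totals`).

## Mediation: proportion explainable

Candidate mediators of a diet exposure are screened by confounder-adjusted
linear regression of the (standardized) metabolite on the exposure, with a
*one-sided* p < 0.05 in the direction consistent with mediation: the sign
of exposure→metabolite times metabolite→disease must match the sign of the
exposure's total disease association. The metabolite→disease signs come
from the mutually adjusted joint model, so selection is reproducible from
pipeline state alone.

The proportion explainable is the difference method on the log-HR scale,

$$\mathrm{PE} = 100 \left(1 - \beta_{\text{adjusted}} / \beta_{\text{total}}\right),$$

with $|\beta_{\text{total}}| \ge 0.01$ required (below that, mediation is
undefined and the function refuses). The point estimate is never truncated
(it may be negative under amplification or exceed 100); only the reported
interval's upper bound is capped at 100%. A delta-method SE is available,
with the covariance of the two nested fits supplied by the caller (default
0); the primary uncertainty statement is the bootstrap interval.

The 95% interval is bias-corrected and accelerated: subjects are resampled
with replacement at a two-thirds sampling fraction, B = 1000 replicates by
default; $z_0$ comes from the bootstrap distribution's position relative to
the point estimate, and the acceleration from a grouped jackknife (20
delete-one-group estimates), the same construction as `bcajack`. The seed
fully determines the interval. Replicates in which a Cox fit fails to
converge count as failures and more than 5% of them aborts the interval;
replicates whose resampled total effect happens to be near zero are *not*
failures — they fatten the bootstrap tails, which the percentile mapping
absorbs. Bootstrap resampling ignores the case-cohort strata (simple
subject resampling at the stated fraction); a stratified variant would
resample subcohort and cases separately and is a known limitation.

Hazard ratios for diet exposures are reported per interpretable unit —
2 SD of intake for food quantities, or a fixed `exposure_unit` such as two
cups for coffee-like exposures; PE itself is invariant to this scaling (and
to any affine rescaling of the exposure).

## Mendelian randomization

Single-instrument two-sample MR via the Wald ratio. The instrument is the
discovery SNP with the smallest p below the suggestive threshold $10^{-5}$
*among those available in the external datasets* (ties broken lexically) —
availability, not raw strength, is binding, which is why the bundled worked
example selects rs680379 over the nominally stronger rs686548. Exposure and
outcome rows are harmonized by effect allele (outcome beta negated when its
effect allele is the exposure's other allele; palindromic A/T and C/G pairs
are flagged, not dropped, since strand cannot be resolved from alleles
alone). Then

$$\mathrm{WR} = \beta_{\text{outcome}} / \beta_{\text{exposure}}, \qquad
\mathrm{SE} = \mathrm{SE}_{\text{outcome}} / |\beta_{\text{exposure}}|,$$

the first-order SE that ignores exposure uncertainty — this is the
convention that reproduces the published SEs from published betas; a
second-order SE is available behind a flag. Because one SNP–outcome effect
is shared, the z statistic (and p-value) is identical across exposure
cohorts, a useful internal consistency check. The bundled summary tables
carry synthetic allele labels (the source tables print none) chosen to
encode the published effect directions; betas, SEs and p-values are the
published numbers. Multi-instrument estimators and pleiotropy diagnostics
are out of scope in a single-SNP setting.

# The synthetic generator: what it emulates, and what it does not

`generate_ground_truth()` + `simulate_cohort()` produce:

* **Metabolites** from a linear-Gaussian structural model on the log scale,
  exponentiated to strictly positive right-tailed nM concentrations. The
  default `elongation_chain` topology links consecutive chain lengths
  within class and same-chain dhCer→Cer pairs, mimicking elongation and
  desaturation; `random_sparse` draws forward edges at a configurable
  density. Edge weights default to Uniform(0.3, 0.6) — bounded away from
  zero, so the generated models are faithful and skeleton recovery is
  well-posed. The model-implied covariance is available in closed form
  (`implied_covariance()`) and the empirical log-scale covariance matches
  it at n = 20000 within Monte-Carlo error, which is the generator's own
  acceptance test.
* **Confounders** (binary sex, continuous waist by default) loading on both
  metabolites and hazard, so that tests can verify adjustment removes their
  bias.
* **Events** from a proportional-hazards model with a Weibull baseline
  hazard on the age axis (shape 5 by default — incidence rising steeply
  with age), baseline age Uniform(35, 65), left truncation at entry and
  administrative censoring after a fixed horizon. The Weibull scale is
  calibrated by root-finding so the expected observed-event fraction hits a
  configurable target (5–40% are reasonable; defaults 15%). The hazard's
  linear predictor uses metabolites standardized by their implied SD, so
  true log hazard ratios are per 1 SD, matching the analysis scale. Two
  endpoints are two independent event processes; competing risks are not
  modelled, mirroring analyses that treat endpoints separately.
* **Diet exposures** as standard normal variables that shift their
  designated mediator metabolites and carry a direct (non-mediated) log-HR;
  **a genetic instrument** as a binomial(2, MAF) dosage shifting one
  metabolite, MAF restricted to [0.05, 0.5].
* **Repeat measurements** for a configurable subset of subjects, with
  within-person log-scale noise calibrated so the one-way ANOVA ICC equals
  the target exactly in expectation.

What it does *not* emulate: laboratory batch effects, assay
quantification error structure, genotyping error, FFQ measurement
properties, informative censoring, competing risks, or non-linear
metabolite–hazard relationships. Passing recovery tests therefore shows the
inference machinery is correct under its stated assumptions — not that
those assumptions hold in any particular cohort.

# Numerical choices

* Cases outside the subcohort enter risk sets at their event age minus
  $10^{-6}$ of the observed exit-age range — small enough never to cross
  another subject's event time in continuous age data.
* Confidence intervals use the conventional 1.96 multiplier.
* Wald 95% CIs are $\exp(\hat\beta \pm 1.96\,\mathrm{SE})$ with the robust
  SE.
* The Fisher-z test clamps $|r| \ge 1$ to a hard dependence verdict rather
  than transforming it.
* Rank deficiency of a Cox model matrix is detected by pivoted QR before
  fitting and reported with the offending columns; near-collinearity among
  jointly modelled effectors is screened by a condition-number cap of
  $10^6$.
* Subset enumeration is capped at $2^{10}$ submodels per node; denser nodes
  are refused with the degree reported rather than silently truncated.
* All randomness is routed through explicit seeds; seeded functions restore
  the caller's RNG state.

# Simulation designs used by the recovery tests

The test suite's recovery designs (sizes chosen to make the suite complete
in minutes on one core, stated here as the package's own choices):

* **Case-cohort unbiasedness**: 200 replicates of n = 10000 cohorts with a
  5% case fraction and a 15% subcohort (~500 cases, ~1900 sampled
  subjects), true logHR 0.5 per SD; the case-cohort mean is required to
  match the full-cohort oracle mean and the truth within 3 Monte-Carlo SEs.
* **Direct-effector selection**: 100 replicates at n = 4000 with ~600 cases,
  effectors at ±0.4 per SD inside a 6-node elongation network; power ≥ 0.8
  for true effectors, ≤ 10% selection of their network-confounded null
  neighbours.
* **Proportion explainable**: an elongation network in which the diet
  exposure's indirect (through the mediator) and direct log-HR shares are
  equal by construction, so the true PE is 50%; 60 experiments at n = 3000
  with B = 150 bootstrap replicates, requiring ≥ 85% BCa coverage.
  (Estimated PE at these sizes is 50 ± 12, so intervals are wide but
  centred.)
* **Two-sample MR**: a 0.25 log-odds-per-SD effect with a 0.5-SD-per-allele
  instrument at MAF 0.3, two independent samples of n = 20000. For this
  design the baseline hazard is constant over age (Weibull shape 1) and
  confounders are silenced, so "log-odds per SD" is a well-defined
  estimand for the logistic outcome regression; with the default
  age-steep hazard, conditioning the logistic model on the strongly
  prognostic entry age inflates the conditional log-odds well above the
  generating log-HR — ordinary non-collapsibility, worth remembering when
  comparing MR estimates across outcome-model specifications.

# Known limitations

* The difference-method PE on the log-HR scale is a descriptive attenuation
  measure, not a counterfactual effect decomposition; with hazard ratios
  noticeably far from 1 or strong unmeasured mediator–outcome confounding
  it diverges from the natural indirect effect share.
* Cox non-collapsibility means marginal and conditional hazard ratios
  differ slightly even without confounding; recovery tests use moderate
  effect sizes where this is negligible relative to Monte-Carlo error.
* The skeleton's correctness relies on approximate multivariate normality
  of the log panel and faithfulness of the generating structure.
* Classification at $\alpha = 0.05$ per submodel family is deliberately
  uncorrected across metabolites, trading specificity for sensitivity in
  the selection step; the joint model and its intervals are the effect
  estimates of record.
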