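---
title: "Qualifying urinary miRNA diagnostic biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualifying urinary miRNA diagnostic biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uromir)
library(dplyr)
```

# The problem

Esophageal cancer is usually detected late; a noninvasive early-detection
biomarker would change its prognosis materially. Urinary microRNAs are
attractive candidates: urine is abundant and collected without any
intervention, and circulating miRNAs are stable because they travel bound
to proteins or inside extracellular vesicles. The catch is that urine
concentration fluctuates with collection time, so raw qPCR signal is
meaningless until it is normalized against internal-control assays, and a
candidate marker is only credible after a disciplined qualification chain:
a case–control cohort balanced on demographics, an unbiased discovery
screen, and a cross-validated estimate of out-of-sample discrimination.

`uromir` implements that chain end to end, together with a synthetic
cohort generator whose ground truth is known exactly. Every statistical
claim the pipeline makes can therefore be checked against closed-form or
brute-force oracles, which is how the package's test suite is built.

# The data model

Two tables flow through the pipeline:

* **subjects** — one row per participant: `subject_id`, `group`
  (control/case), `age` (years), `sex`, `serum_creatinine` (mg/dl), and
  for cases the tumor descriptors `tnm_stage` (I–IV), `t_stage` (T1–T4)
  and `histology`.
* **ct** — long-format qPCR threshold cycles: `sample_id`, `assay_id`,
  `assay_role` (candidate marker vs internal-control candidate),
  `replicate`, `ct` in cycles, with `NA` for undetermined reactions.

All functions take these tibbles first and return tibbles (or small S3
result objects with `tidy()`/`glance()` methods), so the pipeline
composes with the usual dplyr verbs.

# The synthetic cohort generator

`simulation_config()` + `simulate_cohort()` emulate a two-group urinary
qPCR study. Design choices, in the cycle (Ct) domain:

* **Noise model.** Ct values are Gaussian per assay;
  since relative expression is \(2^{-\Delta Ct}\), this makes expression
  log2-normal, the standard qPCR noise model. A case–control shift of
  \(\delta\) cycles on a marker with per-group noise SD \(\sigma\) gives
  the closed-form discrimination
  \[\mathrm{AUC} = \Phi\!\left(\frac{\delta}{\sigma\sqrt{2}}\right),\]
  which the tests use as an oracle (verified at n = 2000 per group to
  0.01).
* **Default panel.** Eight candidate markers with shifts derived from
  target AUCs between 0.5 and ~0.79 via
  \(\delta = \sqrt{2}\,\sigma\,\Phi^{-1}(\mathrm{AUC})\) and a common
  noise SD of 1.5 cycles — the regime of a realistic discovery panel in
  which some candidates qualify and others fail. Two internal-control
  assays vary with SD 0.15 cycles.
* **Demographics.** Ages are drawn from one truncated normal
  (mean 69, SD 8, range 20–90 years) shared by both groups, matching the
  enrollment criteria and the post-matching balance of the emulated
  study; `age_shift_case` deliberately unbalances them to exercise the
  matching stage. Sex is ~10% female in both groups; creatinine is
  log-normal around 0.84 mg/dl. The stage mix defaults to 16/4/12/11
  over stages I–IV (37.2% stage I). Where the emulated study reports
  only medians and IQRs, the distributional forms (truncated normal,
  log-normal) and spreads are the package's own choices, exposed as
  parameters.
* **Stage correlation.** When requested, one marker's case-group Ct noise
  is coupled to the latent stage variable through a Gaussian copula with
  latent correlation \(2\sin(\pi\rho_s/6)\), targeting a Spearman
  correlation \(\rho_s\) between expression and stage while preserving
  the Ct marginal. Discretizing stage into four categories attenuates the
  realized coefficient (large-sample runs at the default
  \(\rho_s=-0.435\) realize about \(-0.39\) on average), inside the ±0.1
  tolerance asserted in the tests.
* **Technical structure.** Reactions are duplicated by default; replicate
  2 is replicate 1 plus N(0, 0.15) cycles of technical jitter. A
  configurable fraction of samples (default 9.4%, the rate that removes
  ~20 of 213 samples) is flagged poor-quality and excluded by
  `apply_quality_failures()`. Undetermined Ct is missing data; it is
  never imputed as cycle 40.

What the generator does **not** emulate: amplification-efficiency
differences between assays, plate/batch effects, per-assay dropout in
otherwise good samples (off by default), or microarray intensity data —
the discovery screen operates on the Ct/expression domain throughout.
Passing tests therefore demonstrate correctness of the statistical
machinery under this idealized model, not robustness to every artifact of
real qPCR data.

# Propensity-score matching

`fit_propensity()` fits a maximum-likelihood logistic regression of case
status on age and sex. Two edge cases are handled explicitly: constant
covariates are dropped with a warning, and complete or quasi-complete
separation (which makes the MLE diverge — it genuinely happens when, say,
no case is female) triggers a Firth bias-reduced refit, flagged in the
result. The model's C-statistic is the rank-based AUC of the propensity
score against the group label, so it is invariant under monotone
transforms of the score.

`match_nearest_neighbor()` performs greedy 1:`ratio` nearest-neighbor
matching on the logit of the propensity score within a caliper of
`caliper_multiplier` (default 0.2) times the SD of the logit. Choices
where the convention was open:

* Cases are visited in seeded random order, each taking its nearest
  remaining in-caliper controls; matching is without replacement by
  default, since a matched-cohort design implies each control is used
  once.
* The logit SD is computed over the pooled sample by default
  (`sd_scope = "within"` gives the within-group average alternative).
* Distance ties are broken by subject id, making the whole procedure a
  pure function of the seed.
* Balance is reported as absolute standardized differences,
  \(d = |\bar x_a - \bar x_b| / \sqrt{(s_a^2+s_b^2)/2}\) (continuous) or
  its proportion analogue (binary), before and after matching.

Whether a study should refit the propensity model after matching is a
known ambiguity; the package reports the pre-matching C-statistic and
leaves post-matching refits to the user, asserting neither against any
external value.

# qPCR normalization

`aggregate_replicates()` collapses replicates to their arithmetic mean,
flagging cells whose replicate range exceeds `discordance_limit`
(default 1.0 cycle — a documented convention for duplicate reactions,
not an assertion about any particular laboratory's protocol).

`select_internal_controls()` operationalizes global-mean normalization
for reference-gene selection: compute each sample's global mean Ct over
all assays, score each assay by the SD across samples of its deviation
from that mean, and keep the `n_controls` lowest-scoring assays (exact
ties broken by assay id). An assay sitting exactly at the global mean in
every sample scores 0, and the score is invariant to constant per-assay
offsets — stability, not absolute level, is what qualifies a reference.

`delta_ct()` computes, per sample, the reference Ct as the arithmetic
mean over the selected internal controls (equivalently the geometric
mean of their expression — the standard choice with two references),
then \(\Delta Ct = Ct_{marker} - Ct_{ref}\) and
\(2^{-\Delta Ct}\). Two identities pin the implementation down: adding a
constant to every Ct of a sample leaves its relative expression unchanged
(to 1e−9), and lower marker Ct strictly increases expression. Samples
missing a finite reference Ct are excluded and listed rather than
imputed. Table-style outputs display medians ×10⁻²; stored values are
never scaled.

# Discovery screening

`differential_screen()` reproduces microarray-style candidate selection
on the expression domain: fold change of group means (medians available
via `center = "median"`, more robust under log-normal tails), a
two-sided Mann–Whitney p-value, and per-group detection rates. A marker
is selected when |fold change| exceeds 2 in either direction and
p < 0.05. No multiple-testing correction is applied at this stage — by
design, mirroring conventional discovery screening; the cost is a ~5%
per-marker false-positive rate that the downstream training/test stage
must absorb, which is exactly why qualification requires surviving both
stages. `stability_filter()` then keeps markers detected in at least 80%
of samples per group (the threshold is a package convention; "stably
expressed" is rarely given a number).

A consequence worth knowing: at discovery sizes of 6 controls vs 3
cases the exact Mann–Whitney test is so discrete that only near-perfect
rank separation can reach p < 0.05. An 0.9-AUC marker passes such a
screen only ~60% of the time. The package faithfully reproduces this
under-powering; tests that need a reliably powered screen simply use a
larger discovery split.

# Diagnostic evaluation

* **Mann–Whitney** (`mann_whitney()`): U with midranks. For pooled
  sample sizes up to 12 the two-sided p is exact, computed by
  enumerating all \(\binom{n_1+n_2}{n_1}\) assignments and doubling the
  smaller tail (capped at 1); enumeration with midranks remains exact
  under ties. Larger samples use the normal approximation with tie
  correction and a 0.5 continuity correction.
* **ROC/AUC** (`roc_auc()`): the rank formula
  \(U/(n_1 n_2)\) — ties count one half. The AUC–U identity, monotone
  invariance and label-swap complementarity are property-tested to
  1e−12. The 95% CI is a stratified percentile bootstrap (2000
  resamples) everywhere, with the analytic Hanley–McNeil interval as an
  option — the package computes both because which one a given report
  used is often unstated, and asserts neither against external values.
* **Optimal cutoff** (`optimal_cutoff()`): Youden's
  J = sensitivity + specificity − 1 maximized over the smallest observed
  score and all midpoints between adjacent distinct pooled scores, with
  the rule score ≥ cutoff ⇒ case (higher expression indicates cancer).
  Ties in J break toward higher sensitivity, then lower cutoff; all-equal
  scores degenerate to sensitivity 1, specificity 0.
* **Cross-validation** (`kfold_cross_validate()`): subjects are split
  into k = 5 label-stratified, seeded folds — stratification matters
  because with 40 cases an unstratified 5-fold split risks single-class
  test sets. Within each fold the marker score itself is evaluated by
  ROC on the training portion and the held-out portion; no classifier is
  fitted, because a single-marker score needs none. The reported train
  and test AUCs are arithmetic means over folds. Their confidence
  intervals resample subjects within class B = 1000 times and re-run the
  entire k-fold procedure per resample (the resampling unit is the
  subject — the natural choice when the procedure itself is the
  statistic).
* **Bootstrap** (`bootstrap_ci()`): seeded, group-stratified percentile
  intervals; resamples on which the statistic is undefined are redrawn
  and counted. Coverage for a Gaussian mean is verified at 93–97% over
  500 replications.
* **Spearman** (`spearman_cor()`): Pearson correlation of midranks with
  a t-approximation p-value (documented; exact small-sample Spearman
  null distributions are not used).
* **Categorical tests** (`categorical_test()`): Pearson chi-square
  without continuity correction when every expected cell count exceeds
  5, Fisher's exact test otherwise. Treating expected counts of exactly
  5 as too small for the chi-square is this package's convention; it
  keeps the classical "expected counts above five" validity rule strict.

# The pipeline

`run_pipeline(study_config(...))` executes the full design: simulate (or
read) an enrollment-scale cohort (default 299 controls / 44 cases) →
fit the propensity model and match 1:4 within the caliper → exclude
poor-quality samples (~9.4%) → randomly split into a 6-control/3-case
discovery cohort and the training/test remainder → aggregate replicates,
select internal controls, compute \(2^{-\Delta Ct}\) → screen in the
discovery cohort → evaluate every screened candidate in the
training/test cohort: Mann–Whitney p, medians, full-cohort ROC with
Youden cutoff, 5-fold cross-validated AUCs with bootstrap CIs for the
all-stage stratum and for the stage-I stratum (full control group vs
stage-I cases only), and Spearman correlation of expression with TNM
stage among cases. A marker is *qualified* when it passes the discovery
screen and stays significant in the training/test cohort.

Matching precedes splitting, and quality exclusion sits between them,
mirroring the consort order of the emulated design. All randomness flows
from one root seed with fixed per-stage offsets (+1 simulation, +2
matching order, +3 quality, +4 split, +5 evaluation), so identical
configurations produce byte-identical result documents and each stage is
independently reproducible. `write_study()` emits the screen, evaluation,
balance and characteristics tables as CSV plus a JSON results document;
a thin command-line wrapper (`inst/cli/uromir.R`, subcommands `simulate`
and `run`) drives the same functions from a shell.

# Numerical choices and degenerate inputs

* Undetermined Ct propagates as `NA`, never as zero expression.
* A screen marker with fewer than 2 usable values in a group is skipped
  with a warning, not silently dropped.
* `bootstrap_ci()` refuses B < 100; `kfold_cross_validate()` refuses
  class counts below k.
* Zero pooled variance with unequal means yields an infinite
  standardized difference, flagged by a warning.
* All tie-breaks (assay id in reference selection, subject id in
  matching, higher-sensitivity-then-lower-cutoff in Youden) are
  deterministic so that every result is a pure function of configuration
  and seed.

# Problem sizes used in the checks

The packaged test-suite and the acceptance script run at deliberately
moderate sizes chosen to keep Monte-Carlo error well inside the asserted
tolerances: 1000 random instances for the AUC–U identity, 100–200
instances for brute-force matching and cutoff sweeps, 60–100 simulated
cohorts of 144 controls / 40 cases for cross-validated AUC recovery at
the 0.79 regime, 1000 null markers at 50 vs 50 for the type-I error
band, 500 replications at B = 200 for bootstrap coverage, and 50-seed
pipeline runs for end-to-end ground-truth recovery.

# Known limitations

* The generator's idealizations listed above; in particular, reference
  assays are genuinely stable by construction, so internal-control
  selection is easier than on real plates with batch structure.
* Cross-validation evaluates single-marker scores only; multi-marker
  panel combination (and AUC-difference testing between markers) is out
  of scope.
* The exact Mann–Whitney p is enumerated only up to pooled n = 12;
  beyond that the tie-corrected normal approximation is used even when
  an exact network algorithm would be feasible.
* Stage-I sensitivity/specificity can be read either at the all-stage
  cutoff or at a stratum-specific cutoff; the evaluation table reports
  the stratum-specific cross-validated AUCs, and both cutoff modes are
  available through `optimal_cutoff()` on the corresponding subsets.
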