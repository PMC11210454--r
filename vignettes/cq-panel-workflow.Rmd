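---
title: "From Cq values to dysregulated miRNAs: the cqdiff workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From Cq values to dysregulated miRNAs: the cqdiff workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cqdiff)
```

## The problem

Hemorrhagic transformation (HT) is bleeding into infarcted brain tissue
after ischemic stroke, and the main feared complication of intravenous
thrombolysis. A natural pilot design asks whether circulating miRNA
profiles measured in plasma *before* treatment differ between patients who
later develop HT and matched patients who do not. The data are a qPCR
panel: one quantification cycle (Cq) per miRNA assay per sample, with
lower Cq meaning more template, plus spike-in control channels and a pair
of hemolysis-indicator miRNAs. Cohorts are tiny (10 vs 10), values are
noisy and heavy-tailed on the expression scale, and many low-abundance
miRNAs drop out below the limit of detection — which is exactly the regime
where a robust, permutation-based analysis with explicit QC gates matters.

cqdiff implements that decision chain end to end, plus a synthetic Cq
generator with known ground truth so that every stage can be validated
without patient data.

## Quality gates

**Spike-ins.** UniSp2/4/5 monitor RNA isolation and UniSp6 cDNA synthesis;
each is added at a known concentration (successive channels differ by
roughly 100-fold, i.e. about 6.6 cycles). Their Cq should be tight across
samples, so `spike_in_report()` flags any sample deviating from the cohort
median by more than a window (default ±2 cycles). The window is a warning
device, not an exclusion rule.

**Hemolysis.** Red-cell lysis floods plasma with miR-451a while miR-23a is
stable in blood, so `dCq = Cq(miR-23a) − Cq(miR-451a)` grows with
contamination; samples with dCq strictly above 7 cycles are flagged
(`compute_hemolysis_dcq()`). The sign convention matters and is chosen so
that contamination (lower miR-451a Cq) *raises* dCq; the flag is therefore
monotone in contamination. Flagged samples are retained by default —
mild hemolysis is near-unavoidable in clinical plasma, and dropping
samples from a 10-vs-10 cohort is costly — but `drop_hemolyzed = TRUE`
excludes them, and the flag always propagates to the QC report.

**Reference-signal outliers.** A sample whose mean reference Cq sits far
above the cohort has globally degraded or under-loaded template, and its
normalized values would be dominated by censoring artifacts. "Looked like
an outlier" is not reproducible, so `detect_reference_outlier_samples()`
offers two explicit parameterized rules: a robust z-score on the
median/MAD scale (default, cutoff 3.5) and a gap rule (mean reference Cq
more than 3 cycles above every other sample). With the default rule a
cohort whose per-sample reference means are 29.0, 29.5, 30.0 and 34.7
flags exactly the last sample. When the MAD is zero and all means are
equal, nothing is flagged.

**Assay missingness.** "Not detected" here means the template was too
dilute to amplify, so it is informative but unusable: a target assay
missing in strictly more than 50% of retained samples is excluded.
The inequality is strict — an assay missing in exactly half the samples
survives — and the denominator is the currently retained sample set, since
outlier samples are removed first. Reference, hemolysis-marker and
spike-in assays are exempt (they are QC infrastructure, not hypotheses)
but their missingness is reported.

**Manual exclusions.** Calls that cannot be recomputed from the Cq table
(e.g. an assay discarded after inspection of non-specific amplification on
the instrument) enter as an explicit `(id, kind, reason)` list and are
ledgered in the run manifest rather than silently applied.

## Normalization and fold change

Relative expression is
`expr(s, a) = 2^−(Cq(s,a) − mean reference Cq(s))`,
with the per-sample arithmetic mean over the three reference miRNAs
(miR-30c-5p, miR-103a-3p, miR-23a-3p by default). Two properties anchor
the implementation and its tests:

* a target at its sample's reference mean has expression exactly 1, and
  each cycle below doubles it;
* any global per-sample Cq offset cancels exactly through the reference
  mean (shift invariance, assertable to machine precision).

Missing Cq stays missing — no imputation. The per-assay fold change is the
quotient of arithmetic group means of normalized expression (case over
control), computed on complete cases per assay. Arithmetic rather than
geometric means follow the convention of reporting "mean normalized
expression" for this assay family; a geometric alternative is available
via `geometric = TRUE`. Swapping the group labels maps FC to 1/FC exactly.
If partial reference dropout occurs, the reference mean uses the present
references and records how many were used, rather than failing the
sample.

## The robust testing core

Expression-scale values from small cohorts are skewed and outlier-prone,
so group comparison uses trimmed means. With trim proportion γ (default
0.10) and `g = floor(γ n)` removed from each tail:

* `trimmed_mean()` averages the central `n − 2g` order statistics;
* `winsorized_variance()` is the `n − 1` sample variance after clamping
  each tail to its nearest retained order statistic;
* the Yuen–Welch statistic is
  `T = (tmean(x) − tmean(y)) / sqrt(d_x + d_y)` with
  `d_j = (n_j − 1) s²w_j / (h_j (h_j − 1))`, `h_j = n_j − 2 g_j`.

At γ = 0 this reduces *exactly* to the Welch unequal-variance t statistic,
which the test suite verifies to 1e-12 against `t.test()` on a thousand
random instances; the trimmed case is verified against a second,
independently coded evaluation of the formula.

Significance comes from a permutation null: pool both groups, redraw the
labels B times preserving group sizes (true permutations, without
replacement), recompute T, and report the two-sided add-one estimate
`p = (1 + #{|T*| ≥ |T_obs|}) / (B + 1)`. The add-one form guarantees
p > 0 and p ≥ 1/(B+1). Defaults are B = 1000 and root seed 123. For small
groups `exhaustive_permutation_test()` enumerates all relabelings and
serves as the exact oracle; Monte-Carlo p-values agree with it to well
under 0.02 at B = 20000.

Numerical conventions worth stating:

* the tie comparison `|T*| ≥ |T_obs|` uses a 1e-12 absolute slack so that
  the identity relabeling always counts;
* a relabeling with zero Yuen standard error contributes T = 0 when the
  trimmed means agree and ±∞ when they differ (the public
  `yuen_welch_statistic()` raises an error in the latter case instead,
  because a user calling it directly should see the degeneracy);
* an all-constant pooled sample short-circuits to p = 1.

Each assay gets its own RNG stream: per-assay seeds are spawned once from
the root seed in assay order, so a given assay's p-value does not depend
on how many other assays were tested before it (for a fixed retained
assay list), and reruns are bit-identical. The permutation inner loop is
implemented in C++ (hooked into R's own RNG) because the validation suite
alone recomputes several million statistics.

Multiplicity is handled by Benjamini–Hochberg adjustment across all tested
assays. Classification into `up` / `down`, however, uses the *raw*
permutation p-value against α = 0.10 together with fold-change bounds
(down: FC < 0.67; up: FC > 1.5; all three boundaries strict). In a pilot
screen of this size the BH-adjusted values are reported alongside as an
honesty device but are deliberately not the selection criterion — at
n = 10 per group nothing survives FDR control, and the screen's purpose is
to shortlist candidates for a powered follow-up. α = 0.10 rather than 0.05
reflects the same pilot logic.

## Propensity-score matching

Case–control selection uses a main-effects logistic propensity model on
the matching covariates (age, sex, NIHSS, stroke subtype in the motivating
design), then greedy 1:1 nearest-neighbour matching without replacement on
the probability scale (`--logit-distance` switches the metric). Greedy
matching is order-dependent, so the order is fixed and documented: cases
in descending propensity, ties broken by input order. Perfect separation —
likely with categorical covariates and 10 cases — falls back to a
ridge-penalized fit (fixed small penalty, λ = 0.1) so scores stay strictly
inside (0, 1) and matching remains well defined. Samples with missing
covariates are dropped from matching with a logged reason; no imputation.
Balance is diagnosed with standardized mean differences
(`(mean_case − mean_control) / sqrt((var_case + var_control)/2)`) before
matching (all samples) and after (paired samples only); a zero-variance
covariate with equal means reports SMD 0, with unequal means it is
non-evaluable.

## What the synthetic generator does and does not emulate

`simulate_cq_dataset()` draws
`Cq(s, a) = baseline_a − case(s)·δ_a − sample_effect(s) + noise`, then
injects hemolysis and applies limit-of-detection censoring. Defaults
mirror the motivating panel: 84 miRNA assays of which 3 are references and
one is the RBC marker, 4 spike-in channels at ~100-fold concentration
steps, 10 cases vs 10 controls, target baselines Normal(28, 3) cycles,
technical noise 0.5 cycles, per-sample global offsets 0.5 cycles, LOD
ceiling 37 cycles. Effects are injected on the Cq scale (−δ cycles ≡ +δ
log2 expression), so in the noiseless limit the normalization identity
makes injected fold changes exact, which gives the tests sharp anchors.
Missingness arises mechanistically from censoring — a dim assay drifts
over the ceiling and is then removed by the missingness filter — rather
than from a missing-at-random mask, matching how dropout actually occurs
in dilute plasma.

What it does **not** model: amplification-efficiency differences between
assays, plate position effects, inter-miRNA biological correlation (the
only induced correlation is the shared per-sample offset and the shared
reference noise), and heavy-tailed contamination beyond what trimming is
designed for. Passing recovery tests on this generator therefore shows the
pipeline machinery is correct and calibrated, not that real plasma data
meet the generator's assumptions.

One calibration subtlety is worth spelling out. Within a simulated panel,
all assays of a sample share that sample's reference-mean measurement
noise, so the per-assay tests are positively correlated *within* a panel
and the count of null assays below p = 0.10 is overdispersed relative to a
binomial. The package's null-calibration checks therefore take one assay
per independently simulated panel, where the binomial reference is exact.
The marginal calibration is clean: across panels the null fraction below
p = 0.10 sits at 0.10.

## Validation problem sizes

The shipped checks use: 1000 random instances for the Welch reduction;
exhaustive-vs-Monte-Carlo comparison at 5 vs 5 with B = 20000; 2000 null
simulations of 10 vs 10 for the type-I rate at α = 0.05; 200 panels for
fold-change recovery (median estimated log2 FC within 0.15 of injected
effects −2, −1, 0, +1); 100 panels for the detection rate of a true
log2 FC of −2 (classified down in ≥95%); 400 one-assay panels for null
calibration; 100 datasets for hemolysis-flag operating characteristics
(near-noiseless dCq, one-cycle calibration margin, 100% sensitivity and
specificity expected of the deterministic rule); and 200 confounded
cohorts of 10 cases in a pool of 50 for the balance-improvement rate.
These sizes were chosen so each estimate's Monte-Carlo error is small
against the property being asserted.

## Known limitations

* The hemolysis rule is a threshold on one marker pair; it cannot grade
  the *degree* of contamination, and low-level hemolysis passes silently.
* Complete-case group means can bias fold changes for assays near the LOD
  (censoring is not at random with respect to abundance); such assays are
  better treated as screening candidates only, and assays with fewer than
  two complete cases per group are excluded outright.
* Greedy matching is not optimal matching; with very small pools the
  descending-order convention can leave late cases with distant controls.
* Permutation p-values at B = 1000 have a resolution of about 0.001 and
  Monte-Carlo noise near the α = 0.10 boundary can move borderline assays
  in or out of the classified set between RNG streams.
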