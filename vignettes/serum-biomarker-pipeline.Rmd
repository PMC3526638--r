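---
title: "From spectral counts to absolute serum concentrations: the seroquant methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From spectral counts to absolute serum concentrations: the seroquant methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seroquant)
```

seroquant implements the computational chain of a two-phase serum biomarker
study: a *discovery* phase in which a cancer and a control cohort are
profiled by shotgun proteomics and compared by spectral counting, and a
*verification* phase in which selected candidates are re-measured by
immunoassays (tissue microarrays, western blots) and by targeted mass
spectrometry (stable-isotope-dilution MRM) in a larger cohort. This
vignette explains each model, its assumptions, the tunable parameters, and
the limits of what the synthetic-data simulations can show.

## 1. Identification: target-decoy filtering of PSMs

Peptide-spectrum matches arrive as a table of SEQUEST-style scores. The
package searches spectra against nothing — identification is assumed done —
but it decides which PSMs to trust. Two filters apply jointly:

* **deltaCn ≥ 0.1** for every PSM regardless of charge state. This gap to
  the second-best candidate guards against ambiguous assignments.
* **a per-charge Xcorr threshold**, chosen by `select_thresholds()` as the
  smallest observed score at which the target-decoy estimate
  FDR = (#decoy passers)/(#target passers) falls below the requested level
  (1% by default). The search ranges over observed scores only, so it is
  finite and reproducible; raising the FDR target can only lower the
  thresholds.

The decoy estimate rests on the equal-chance assumption: a reversed-database
match is as likely as an incorrect forward match. The synthetic PSM
generator enforces this by drawing decoy and incorrect-target scores from
the same per-charge Gaussian; the correct population sits higher. Gaussians
are a modeling choice — any location-scale family preserving the
decoy/incorrect symmetry would serve — and the per-charge means/SDs are
configurable in `psm_sim_config()`.

Accepted PSMs are collapsed by `group_proteins()` with greedy parsimony:
the accession explaining the most still-unexplained peptides claims them as
a group; accessions with identical peptide sets are co-listed;
accessions whose peptides are fully explained elsewhere are absorbed. Ties
break lexicographically, so grouping is deterministic. Protein-level
confidence is then the naive decoy count ratio,
`estimate_protein_fdr() = decoy groups / target groups` — deliberately the
simple estimator, not 2d/(t+d), and callers filter at 5%.

Two discreteness caveats are worth knowing. The pooled FDR across charge
states can *rise* as one charge's threshold passes beyond its decoy range
(the other charge then dominates the numerator), and even within a charge a
single removed target can nudge the ratio up by ~1/#targets. The package
treats the per-charge ratio as monotone only up to this granularity, and
the tests check exactly that.

## 2. Discovery quantification: Re, permutation tests, normalization

Spectral counts — PSMs per protein group per sample — are the quantitative
currency. For protein *f* in sample *s* the **relative enrichment factor**
is

$$ R_e(f,s) = \frac{n_{f}/n_s}{N_f/N}, $$

with \(n_f\) the protein's count in the sample, \(n_s\) the sample total,
\(N_f\) the protein's grand total and \(N\) the grand total. It compares a
protein's within-sample share to its cohort-wide share; values above 1 mean
enrichment. The identity \(\sum_f (N_f/N)\,R_e(f,s) = 1\) holds exactly per
sample and is used as an invariant test. Proteins never observed are
dropped; zero cells give \(R_e = 0\).

Differences between cohorts are tested by `permutation_test()`: sample
labels are permuted jointly across proteins, and per protein
\(p = (1 + \#\{|\text{stat}_{perm}| \ge |\text{stat}_{obs}|\})/(B + 1)\)
with a pooled-variance t (two groups) or one-way F (three). The add-one
correction keeps p strictly positive; a p-value can therefore never be
smaller than \(1/(B+1)\), which matters when choosing B relative to the
significance level (B = 10,000 at α = 0.01 leaves ample resolution).
Constant rows are defined to p = 1. `filter_significant()` flags a protein
at raw p < α (default 0.01) when the ANOVA **or** any pairwise t fires —
reproducing a "differential in at least one contrast" list — with an AND
rule available. No multiple-testing correction is applied, matching
discovery-phase practice of screening on raw p; this is a screening
decision, not an error-control guarantee, and is deliberately left visible
to the caller.

For clustering and PCA the counts are transformed to
\(\log_2(\text{count}+1)\) and quantile normalized: each column is forced
onto the reference distribution of per-rank row means. Ties receive the
mean of the reference values over their rank range — a policy under which
a tied group maps to one value, so columns with different tie patterns
need not match the reference multiset exactly. The normalization is
implemented in-package because this tie policy is part of the contract;
on tie-free input it agrees with limma's `normalizeQuantiles` to 1e-10
(checked in the tests). Clustering is Euclidean/average-linkage by default
(configurable; no claim is made that these match any particular historical
analysis), and `pca_biplot()` returns sample scores plus protein loadings
with a deterministic sign convention (largest-magnitude loading per
component made positive).

ROC analysis delegates to pROC — AUC, DeLong asymptotic confidence
interval, curve coordinates — and `logistic_panel()` enters all features
as one block into a maximum-likelihood logistic fit, scoring the in-sample
predicted probabilities by ROC. Complete separation is flagged but still
scored, since the AUC depends only on the ordering of the linear
predictor. In-sample panel AUC is optimistically biased; the package makes
no cross-validation claim.

## 3. Verification: TMA quick score and WB calibration

Tissue sections are read by multiple pathologists as a percentage of
positive cells (0–100) and a staining intensity (0–3). The percentage is
binned into a **P score** 0–9 over ten bins — 0–5, 5–15, 15–25, …, 75–85,
85–100 — and the **quick score** is Q = P × I, spanning 0 to 27. Two
choices the scoring rule as usually stated leaves open are fixed here:
bins are
half-open on the left with the top bin closed at 100 (so shared endpoints
resolve upward), and rater readings are averaged on the *raw* scales
before binning/multiplying (losing the least information); averaging
per-rater Q values instead is available via `combine = "average_q"`.
Averaged intensities make Q possibly non-integer; the 0–27 bounds still
hold. The bins between 35% and 85% follow the evident decade pattern.
Paired tumor/normal comparison uses a Wilcoxon signed-rank test on the Q
differences by default (a paired t test is available), dropping incomplete
pairs.

Western-blot densitometry is made comparable across runs by a pooled
calibration sample loaded on every membrane: each band's integrated
optical density is divided by its own membrane's calibration IOD, which
cancels multiplicative between-run factors exactly (an invariant test
doubles a whole membrane and checks that nothing changes). Groups are then
compared by a two-sample t test.

## 4. Targeted verification: SID-MRM calibration and absolute amounts

Each peptide's transitions are measured in light (endogenous) and heavy
(spiked, constant) channels; `compute_ratios()` forms light/heavy area
ratios after an optional QC gate. Assay linearity is characterized on a
base-3 dilution series: `fit_calibration()` regresses log3(observed ratio)
on log3(nominal ratio) by OLS over the per-point replicate means — the
space in which such response curves are conventionally drawn (fitting in
linear space is available via `space = "linear"`). The point whose observed
ratio is closest to 1 is reported as the anchor at which the endogenous
amount is assigned during assay characterization; downstream conversion
uses the whole fitted line, not the single anchor point.

* **LOQ** (`determine_loq()`): scanning from the most dilute point upward,
  the lowest concentration whose replicate CV is below 20% *and* for which
  the Pearson correlation of the curve restricted to that point and above
  exceeds 0.99. Only the candidate point's own CV enters the rule, per the
  standard empirical definition.
* **LOD** (`determine_lod()`): the concentration at which interpolated
  signal-to-noise reaches 3, interpolating in log-log space where a
  proportional response is linear.
* **Best transition** (`select_best_transition()`): highest Pearson R,
  ties broken by lower LOQ, then stronger heavy signal; one transition per
  protein is fixed for the whole cohort.

`absolute_concentration()` inverts the fitted line: observed ratio →
nominal ratio → fmol on column (× heavy spike), then to a serum
concentration via the serum-equivalent volume on column (0.1 µL default)
and the protein molar mass:
µg/mL = fmol × M(g/mol) / V(µL) × 10⁻⁶. Sequence molar masses of A1BG
(54,254 Da) and LRG1 (38,178 Da) ship as defaults in
`protein_molar_masses`; both volume and mass are explicit arguments because
the conversion constants belong to the assay design, not the algorithm.
Ratios outside the calibrated range are converted but flagged
`extrapolated`. `cohort_stats()` then reuses the ROC/panel machinery and
screens demographics (binary variables by t test on concentration,
continuous ones by Pearson correlation).

## 5. The synthetic cohorts: what they emulate, and what they do not

Every stage is exercised by seeded generators whose defaults *are* the
study conditions:

* `count_sim_config()`: 18 discovery sera — 13 cancer (8 adenocarcinoma +
  5 squamous) vs 5 controls — over 600 proteins whose base abundances are
  log-uniform across 6 decades, counts negative binomial (dispersion 0.15)
  with ~35,000 counts/sample and 10% depth variation; 15% of proteins carry
  a planted 1.5 log2-fold shift (half up, half down) in the cancer cohorts.
  The negative binomial is a choice (spectral counts are overdispersed);
  no claim is made about the true generative law.
* `psm_sim_config()`: 10,000 targets, 60% correct, over a pool of 647
  proteins × 7 peptides (the shape of a deep serum proteome), 4,000 decoys
  mirroring the incorrect-target score law per charge.
* `mrm_sim_config()`: an 8-point base-3 series (3⁷-fold span) anchored so
  the middle point has nominal ratio 1, 5 replicates/point at 5% channel
  CV, with light-channel CV inflated to 100% below the 3rd point — the
  signal-at-noise-floor regime — so a true LOQ exists at a known
  concentration; a 70/30 cancer/control cohort with a 2-fold shift.
* `tma_sim_config()`: 89 valid tumor/adjacent-normal pairs, two
  pathologists, tumor staining at 60 ± 20% with intensities skewed to 2–3
  against 20 ± 15% and 0–1 in normal tissue.

Noise is multiplicative lognormal (mean exactly 1) and independent between
MRM channels. All randomness flows through explicit `seed` arguments; no
global state is consulted.

**Limitations the simulations do not hide.** The MRM cohort model has
measurement noise only — no between-subject biological variance — so
synthetic cancer/control cohorts separate almost perfectly (AUC ≈ 1).
Passing tests therefore demonstrate that the estimators recover planted
parameters (fold changes within [1.8, 2.2] at n = 70/30, calibration
slopes within 3%, the planted LOQ knee in ≥ 90% of series), *not* that any
particular clinical discrimination would be achieved; real serum cohorts
overlap substantially. Likewise the count generator plants clean
multiplicative shifts, whereas real differential proteins mix abundance
regimes, and the PSM generator's Gaussian scores only stylize empirical
Xcorr histograms. Simulation sizes in the test suite (600-protein null
matrices at 10,000 permutations, 10,000-PSM tables, 100–200 replicate
series for recovery rates) were chosen as the smallest designs at which
the Monte-Carlo error of each check is comfortably below its tolerance.

## 6. Numerical conventions and degenerate inputs

* Permutation p-values are never 0 (add-one) and constant rows give p = 1.
* `estimate_psm_fdr()` returns 0 when nothing passes; a protein FDR with
  zero target groups is 0 with a warning.
* Parsimony grouping breaks all ties deterministically (coverage, then
  lexicographic accession).
* An all-zero count matrix, a sample with zero totals, single-class ROC
  labels, membranes without a calibration lane, dilution series of fewer
  than 3 points, and non-positive ratios are rejected with informative
  errors rather than propagated.
* `determine_loq()` returns NA (not quantifiable) with a warning when no
  point satisfies both rules; `determine_lod()` errors when S/N never
  reaches 3.
* Quick-score percentages outside [0, 100] and intensities outside
  {0, 1, 2, 3} are rejected.

## 7. A compact end-to-end run

```{r pipeline, eval = FALSE}
library(seroquant)

## discovery: identification + quantification
psms <- generate_psm_table(psm_sim_config(seed = 42))
id <- filter_psms(psms, psm_fdr_target = 0.01)
sim <- generate_count_matrix(count_sim_config(seed = 42))
stats <- lfq_stats(sim$counts, sim$group, n_perm = 10000, seed = 42)

## verification: TMA, then MRM absolute quantification
tma <- quick_score(generate_tma_cohort(tma_sim_config(seed = 42)))
paired_compare(tma, alternative = "greater")

mrm <- generate_mrm_dataset(mrm_sim_config(seed = 42))
cal <- fit_calibration(mrm$dilution)
cal$loq_fmol <- determine_loq(cal)
conc <- absolute_concentration(mrm$cohort$light_area / mrm$cohort$heavy_area,
                               cal, molar_mass_da = protein_molar_masses["A1BG"])
```

The README shows this run with the numbers it prints.
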