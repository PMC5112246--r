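---
title: "Methods: co-twin methylation association and bump-hunting DMR detection"
author: "twindmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-twin methylation association and bump-hunting DMR detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twindmr)
```

## The design and the model

`twindmr` analyses methylation-array data from disease-discordant
monozygotic (MZ) twin pairs. Because co-twins share genotype, cohort and
early environment, the within-pair difference in methylation cancels those
factors by construction; what remains is disease, individual exposures and
noise. The package works on beta values, the methylation fraction at a CpG
computed from methylated (M) and unmethylated (U) array intensities as

$$\beta = \frac{M}{M + U + 100},$$

with the +100 offset stabilising low-intensity probes.

For pair $j$ at probe $p$ the response is the within-pair difference
$\Delta_{pj} = \beta^{case}_{pj} - \beta^{ctrl}_{pj}$, and the per-CpG
model is ordinary least squares

$$\Delta_{pj} = \alpha_p + \sum_k \beta_{pk} x_{kj} + \varepsilon_{pj},$$

where $x_{kj}$ are pair-level covariates: ever-smoking, anti-CCP antibody
positivity and current DMARD treatment of the affected twin (each 0/1),
plus age and sex. $\alpha_p > 0$ means hypermethylation in the affected
twin; a positive exposure slope means exposure-linked hypermethylation.
Each coefficient gets a two-sided t test on
$n_{pairs} - (1 + \text{covariates})$ degrees of freedom. Probes are
called genome-wide significant at Benjamini–Hochberg FDR < 0.05 and
suggestive at uncorrected $p < 5\times10^{-5}$. Ratio-scale fold changes
(mean case beta / mean control beta, below one = relative hypomethylation)
are reported alongside, but the model itself operates on the difference
scale: a ratio response with a null at zero would be internally
inconsistent, while the delta scale keeps the sign semantics of
$\alpha$ exact. A `response` on the log-ratio scale was considered and
rejected for the same reason; the difference scale is also where the
synthetic generator defines effect sizes.

### Covariate coding: the one genuinely open choice

Whether binary exposures enter centered or as raw 0/1 changes what
$\alpha$ means, and the two options trade power against attribution:

* **Uncentered (default, `center = c("age", "sex")`).** $\alpha$ is the
  disease effect in unexposed pairs, and the intercept functional is
  exactly orthogonal to every exposure column: a purely smoking-driven
  regional effect cannot surface as a disease effect. The price is
  precision — the minimum-norm unbiased functional orthogonal to three
  exposures of ~60–70% prevalence has norm several times $1/\sqrt{n}$, so
  intercept estimates are noisier and the permutation null at strongly
  affected probes is wide.
* **Fully centered (`center` = all covariates).** $\alpha$ is the disease
  effect at cohort-average exposures, estimated with near-$1/\sqrt{n}$
  precision — the right estimator when the question is "is there a
  uniform disease effect here?" — but it absorbs a fraction (the exposure
  prevalence) of any exposure-driven signal.

Both are exposed; the default favours attribution because the package's
central output is the set of per-surface DMR tables, whose interpretation
depends on signal landing on the correct surface. The power study of a
uniform disease spike in the acceptance material uses the centered
estimator, whose question it answers.

Pairs with missing smoking status (the generator defaults inject 14%) are
excluded from any fit that includes smoking — no imputation. Probes with
fewer than `min_pairs` (default 10) complete pairs are skipped: with six
parameters a smaller fit is numerically legal but statistically
meaningless. Covariate columns constant or collinear across the pairs in
use are dropped with a warning and reported as `NA` rather than silently
renormalised.

## Quality control

Three steps, mirroring standard array practice:

1. beta computation from non-negative intensities (`compute_beta`);
2. masking of entries whose detection p-value is **strictly** above 0.01
   (`mask_by_detection`) — a value at exactly the threshold is kept;
3. dropping probes with **strictly** more than 5% missing entries
   (`filter_high_missing`) — exactly 5% is retained.

Both rules are deliberately strict inequalities; both operations are
idempotent, and masking is monotone in the threshold. Before any
ratio-scale summary, betas are clipped to $[10^{-6}, 1-10^{-6}]$ so fold
changes are finite and positive.

## Cell-type composition

Whole blood is a mixture of leukocyte populations with distinct
methylation signatures, and co-twins can differ in composition; left
unadjusted this masquerades as disease signal. `estimate_proportions`
solves, per sample, the reference-based deconvolution problem

$$\min_w \lVert R w - b \rVert^2 \quad \text{s.t. } w \ge 0,\; \textstyle\sum_k w_k = 1,$$

with $R$ the reference profile matrix at distinguishing probes. The
solver is exact for panel-sized problems: it enumerates candidate active
sets (all $2^K - 1$ supports), solves each equality-constrained system by
its KKT equations, and keeps the best feasible solution, preferring the
larger support on ties so symmetric inputs yield symmetric weights. This
is a deliberate choice over iterative NNLS: at $K \le 12$ cell types
enumeration costs microseconds and removes both convergence and
tie-breaking ambiguity.

`adjust_for_celltype` then removes composition linearly: per CpG, betas
are replaced by the residuals of an OLS fit on the proportion covariates
(one column dropped — proportions sum to one) plus the CpG's grand mean,
clipped back to $[0,1]$. Residualisation was chosen over carrying
proportions as covariates into the pair model because composition is a
sample-level, not pair-level, quantity; the pair model's design matrix
has one row per pair and cannot represent it without first collapsing to
differences. Re-adjusting adjusted data changes nothing (to $10^{-8}$),
so the step is safe to place once in any pipeline.

## Bump hunting and permutation inference

Regional analysis runs on a chosen coefficient surface — the disease
intercept or one exposure slope — never on raw betas, since only the
coefficients carry the disease/exposure contrast:

1. **Clustering.** Maximal runs of probes with inter-probe gaps
   ≤ `maxgap` (default 500 bp, boundary inclusive), per chromosome.
2. **Smoothing.** Within clusters of ≥ 7 probes, a local linear fit with
   tricube weights over a ±1000 bp window, evaluated at each probe;
   clusters of 3–6 probes get a running mean of window 3; clusters of
   ≤ 2 pass through. The smoother reproduces constants everywhere and
   linear trends at interior probes. Because its weights depend only on
   probe positions, it is precomputed once as a sparse linear operator —
   this is what makes 1000-permutation inference affordable, since each
   permutation then costs two matrix products and a run scan.
3. **Thresholds.** Upper threshold = 99th percentile
   (linear-interpolation quantile) of the absolute smoothed values,
   lower = its negative. The signed-quantile alternative (99th/1st of the
   signed values) is available via `signed_thresholds`; the symmetric
   absolute rule is the default because hyper- and hypomethylation are
   exchangeable under the within-pair null.
4. **Detection.** Maximal runs of probes strictly beyond a threshold on
   one side become candidate DMRs; a sign change splits a run. Each
   bump's **area** is the sum of absolute smoothed values over its
   probes; bumps are ranked by area, ties broken by genomic position.
5. **Permutation.** Case/control labels are swapped independently per
   pair with probability 1/2 — within an MZ pair that is the only
   exchangeable relabelling — which flips the sign of that pair's delta
   column while covariates stay attached to the pair. The full
   fit → smooth → detect chain is re-run per permutation with thresholds
   **held fixed at the observed ones**, making the null areas directly
   comparable with the observed areas; recomputing thresholds per
   permutation is a defensible alternative but breaks that
   exchangeability, and is not offered.

Per observed bump, with strict ">" tail counts throughout and no add-one
correction (an exact zero is flagged `at_boundary` and reads "<
1/n_perm"):

* `fwer_p` — fraction of per-permutation **maximum** areas larger than
  the observed area (a permutation with no bumps contributes 0);
* `suggestive` — observed area larger than the smallest of the
  per-permutation maximum areas;
* `emp_p` — fraction of **all** null bump areas larger than the observed
  area (note `emp_p` ≤ `fwer_p` is not guaranteed: the two denominators
  differ);
* `fdr` — expected null bump count at or above the observed area
  (averaged over permutations) divided by the observed count at or above
  it, monotonised by a running minimum from the smallest area upward and
  capped at 1. BH on `emp_p` is a reasonable alternative; the
  count-ratio estimator is reported because it needs no per-bump p-value
  resolution floor.

## The synthetic cohort generator

The generator produces what the analysis assumes, with ground truth for
recovery testing. Fixed design choices (stated here once; they are the
package's study conditions, not tuning knobs):

* **Cohort**: 28 pairs; ever-smoking 69% with 14% missing, anti-CCP 61%,
  DMARD 68%, 78% female, age ~ N(56, 10²).
* **Genome**: 1 chromosome, 500 clusters of 5–15 probes (~5,000 probes),
  intra-cluster gaps 20–400 bp, inter-cluster gaps 2–10 kb — scaled so a
  full fit + 200-permutation scan runs in about a second.
* **Baseline**: bimodal mixture — 45% Beta(2,18) (low mode ≈ 0.10), 45%
  Beta(18,2) (high mode ≈ 0.90), 10% Beta(5,5) — the canonical
  two-horned beta-value distribution.
* **Correlation**: per probe and pair a shared latent deviation
  (`pair_sd` = 0.05) plus independent twin noise (`noise_sd` = 0.05), so
  within-pair correlation exceeds between-pair correlation.
* **Spikes**: added to the affected twin only; on a covariate surface
  only in exposed pairs — which is exactly what makes an exposure-linked
  region detectable on its own slope surface and not on the disease
  surface. Spiked probes draw their baseline from Beta(8,8)
  (intermediate methylation): regions of genuine differential
  methylation live where methylation is variable, and this keeps a
  configured delta-scale effect from being truncated at the [0,1]
  boundary.
* **Artifacts**: optional detection-p failures at a configured rate, and
  optional cell-type mixture structure (reference-weighted betas with
  per-sample simplex weights).

What the generator does **not** emulate: probe-type chemistry
differences, chip/batch effects (the design it mimics processed co-twins
on the same chip), genomic dependence beyond cluster-level smoothness,
and non-Gaussian heavy-tailed noise. Tests passing on this generator
therefore demonstrate correctness of the machinery and calibration under
the stated model, not robustness to every artifact of real arrays.

## Numerical choices and degenerate inputs

* Quantiles are type-7 (linear interpolation), R's default.
* The per-probe OLS engine groups probes by missingness pattern and
  factorises each design matrix once; permutations reuse the
  factorisation through per-surface hat vectors.
* Rank-deficient designs drop offending covariate columns (never the
  intercept), with a warning.
* A constant smoothed surface triggers a degenerate-threshold warning;
  an all-missing probe row is excluded from every stage.
* All RNG is explicit: every generator and the permutation engine take a
  seed, and the pipeline refuses to run without one.

## Problem sizes used in the packaged checks

The test-suite and acceptance experiments use the default ~5,000-probe
genome with 200 permutations, 100 null datasets for calibration, 20
replicates for power/specificity, and a 50,000-probe single fit for the
p-value uniformity check — sizes chosen so the entire suite completes in
a few minutes while leaving each experiment enough resolution (200
permutations bound FWER p-values at 1/200; 20 replicates resolve an 80%
power criterion) to be informative.

## Known limitations

* Empirical FWER resolution is 1/`n_perm`; with the default 1000
  permutations the smallest reportable non-zero p is 0.001.
* The permutation keeps covariates attached to pairs; it tests the
  within-pair exchangeability null, not covariate effects themselves.
* Reference-based deconvolution is only as good as the reference panel;
  residual composition confounding cannot be excluded.
* Fold changes near-zero control methylation are clipped, not modelled.
* The region-to-gene annotation is overlap-then-nearest with a 100 kb
  cutoff; it does not model regulatory domains, and enrichment against
  an ontology corpus is out of scope (regions are exported as BED for
  external tools, and `probes_per_gene_bias` checks the returned tables
  for probe-density-driven significance).
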