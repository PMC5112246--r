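# twindmr

Epigenome-wide association analysis for **disease-discordant monozygotic
twin pairs** measured on methylation arrays, with region-level detection
of differentially methylated regions (DMRs) by bump hunting and
permutation inference.

Monozygotic co-twins share genotype, cohort and early environment, so the
within-pair difference in methylation beta values
(Δ = β<sub>case</sub> − β<sub>control</sub>) cancels those factors by
construction. `twindmr` is aimed at analysts of such co-twin cohorts —
e.g. pairs discordant for an autoimmune disease, where exposures like
smoking and treatment are themselves strong methylation modifiers and
must be modelled, not just noted.

## The model

Per CpG *p* and pair *j*, ordinary least squares on the difference scale:

    Δ_pj = α_p + Σ_k β_pk · x_kj + ε_pj

with pair-level covariates x: ever-smoking, anti-CCP antibody status and
current DMARD treatment of the affected twin (0/1), plus age and sex
(centered). α<sub>p</sub> > 0 indicates hypermethylation in the affected
twin; each exposure gets its own slope surface. CpGs are genome-wide
significant at Benjamini–Hochberg FDR < 0.05 and suggestive at
uncorrected p < 5×10⁻⁵.

Region detection then runs per coefficient surface: probes are clustered
(gaps ≤ 500 bp), the surface is smoothed within clusters (tricube local
linear, ±1000 bp), symmetric thresholds are set at the 99th percentile of
the absolute smoothed values, and maximal runs beyond a threshold become
candidate DMRs scored by the **area statistic** — the sum of absolute
smoothed values over the run. Significance comes from permutations that
swap case/control labels independently per pair (sign-flipping each
pair's Δ column): FWER p (fraction of per-permutation maximum areas
exceeding the observed area), a suggestive flag, an empirical
per-bump p, and an FDR estimate. Supporting stages: beta-value QC
(strict detection-p > 0.01 masking, strict > 5% probe missingness drop),
reference-based cell-type deconvolution (exact simplex-constrained least
squares) with linear composition adjustment, region-to-gene annotation,
and a synthetic paired-cohort generator with spike-in ground truth.

## Worked example

Simulate a 28-pair cohort (~2,000 probes here) with one smoking-linked
hypomethylated region spiked into the affected twins of smoking pairs,
then scan the disease and smoking surfaces:

```r
library(twindmr)

manifest <- generate_manifest(n_clusters = 200, seed = 7)
design   <- generate_pairs(n_pairs = 28, seed = 8)
spike    <- spike_regions(manifest, surface = "smoking", effect = -0.15,
                          n_probes = 10, seed = 9)
data     <- generate_dataset(manifest, design, spikes = spike, seed = 10)

dmrs <- find_dmrs(data$betas, design, manifest,
                  surfaces = c("alpha", "smoking"),
                  n_perm = 200, seed = 11)
head(dmrs$smoking[, c("chrom", "start", "end", "n_probes", "direction",
                      "area", "fold_change", "fwer_p", "suggestive",
                      "emp_p", "fdr")], 3)
```

```
  chrom  start    end n_probes direction   area fold_change fwer_p suggestive
1  chr1 811196 812733       10      hypo 1.3745       0.790  0.000       TRUE
2  chr1 300082 300082        1     hyper 0.0903       0.941  0.610       TRUE
3  chr1 558818 558818        1     hyper 0.0705       0.984  0.965       TRUE
   emp_p   fdr
1 0.0000 0.000
2 0.0916 0.445
3 0.3364 0.715
```

The spiked region (chr1:811196–812733, exactly the simulated truth) is
the top-ranked smoking-surface DMR: hypomethylated, fold change 0.79
(affected twins of smoking pairs ~21% less methylated than their
co-twins), FWER p reported as 0 — i.e. below the 1/200 permutation
resolution. The same data scanned on the disease surface yield
18 putative DMRs of which none reaches FWER p < 0.05: the exposure-linked
signal is attributed to its own surface, not to disease. The
corresponding per-CpG table ranks the spiked probes first on the smoking
slope (`smoking_slope ≈ -0.2`, p ~ 10⁻⁵) while their disease intercepts
stay null:

```r
dmps <- call_dmps(fit_pair_model(data$betas, design))
head(dmps[order(dmps$smoking_p),
          c("probe_id", "alpha", "alpha_p", "smoking_slope", "smoking_p",
            "fold_change", "fdr")], 3)
```

```
      probe_id  alpha alpha_p smoking_slope smoking_p fold_change   fdr
1072 cg0001072 0.0702  0.0746        -0.208  1.18e-05       0.874 0.971
1074 cg0001074 0.0292  0.4218        -0.187  2.31e-05       0.759 1.000
1069 cg0001069 0.0566  0.1536        -0.174  1.23e-04       0.896 0.971
```

`run_pipeline()` wires the full chain (QC → cell-type adjustment → DMP
table → per-surface DMR tables → BED export) from a single seeded config
and writes reproducible, hash-stamped outputs.

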