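# MycStratify

Stratification of pancreatic cancer expression cohorts by c-MYC
transcriptional activity, and characterization of the resulting strata.

A substantial minority of pancreatic ductal adenocarcinomas (PDAC) run an
exacerbated c-MYC transcriptional program. These MYC-high tumors
proliferate faster, are less differentiated, have shorter survival, and
are markedly more sensitive to BET bromodomain inhibitors (JQ1) than
MYC-low tumors — so calling the stratum from a handful of transcripts is
directly actionable. MycStratify is aimed at computational biologists who
want that full analysis chain as tested, scriptable R.

## The method

The core is a compact ratio-based classifier over a 16-gene panel —
K = 10 up-markers (CDC20, KPNA2, PLK1, SRM, RFC4, MCM2, RUVBL2, MAD2L1,
CCT4, CAD) and L = 6 down-markers (VSIG2, BCL2L15, RAB25, TXNIP, CTSE,
ERN2). With linear-scale expression u_iα (up-marker i, sample α) and
d_jα (down-marker j), each marker row is mean-center normalized over the
cohort,

    Ũ_iα = 100 · u_iα / Σ_α u_iα        D̃_jα = 100 · d_jα / Σ_α d_jα,

all K·L = 60 ratios r̃_ijα = Ũ_iα / D̃_jα are formed per sample, and the
score is their median m̃_α. Samples with m̃_α > 1 are MYC-high, m̃_α < 1
MYC-low (a score of exactly 1 is flagged as a boundary case). The
normalization cancels per-gene calibration, so the same panel scores RMA
microarray intensities and ΔΔCt qPCR quantities.

Around the classifier the package provides:

- **Discovery**: complete-linkage Euclidean clustering of samples over a
  MYC-target gene panel, 2-cluster cut, Welch-t differential ranking with
  BH q-values, and data-driven derivation of the 10 + 6 marker panel.
- **Enrichment**: GSEA from its definition — weighted running-sum ES,
  phenotype-permutation null (1,000 permutations default), NES, nominal p
  and pooled-NES FDR, 15–500 set-size filter.
- **Outcomes**: Kaplan–Meier curves and medians, Mantel–Haenszel log-rank
  test, observed/expected hazard ratios with 95% CIs, Welch and
  Mann–Whitney group comparisons.
- **Pharmacology**: four-parameter logistic (4PL) fits of dose–viability
  chemograms with multi-start Levenberg–Marquardt, IC50 group summaries,
  spheroid/tumor volume formulas.
- **Synthetic cohorts**: a seeded generator planting the whole structure
  (17/55 MYC-high prevalence, a 239-gene elevated target block, reciprocal
  down-markers, exponential survival with 9.2/18.8-month medians, 4PL
  chemograms at 2.3/39.22 µM group IC50s, ordinal Ki67/differentiation
  scores, marker qPCR Ct tables), so every stage is testable end to end
  without any download.

## Worked example

```r
library(MycStratify)

cohort <- simulateCohort(cohortConfig(seed = 1))   # 55 samples, 17 high
cl     <- clusterMycActivity(cohort, mycTargetGenes())
panel  <- selectMarkerPanel(rankGenes(cohort, cl$labels), mycTargetGenes())
scores <- scoreSignature(cohort, panel)
table(signature = sigLabel(scores), truth = trueLabels(cohort))
```

```
          truth
signature  high low
  MYC-high   17   0
  MYC-low     0  38
```

Unsupervised clustering finds the planted 17/38 split, the derived panel
recovers the designated 10 up- and 6 down-markers, and the ratio
signature calls every sample correctly (scores ranged 0.24–11.6 here; the
decision threshold is 1).

```r
survivalSummary(survivalData(cohort))
#> KM medians: high 15.7 / low 18.1 months; log-rank p = 0.437; HR = 1.25 [0.7-2.3]

ic50GroupSummary(fitChemograms(chemograms(cohort)))$table
#>   group n  mean    sem
#> 1  high 4  2.29 0.0498
#> 2   low 4 33.77 3.8765
```

At n = 55 the survival medians are noisy (the generating medians are
9.2/18.8 months; the log-rank test is underpowered at this size for a
rate ratio of 2), while the chemogram fits cleanly separate the groups:
MYC-high lines average 2.3 µM against 34 µM for MYC-low (Welch
p = 0.004).

`runPipeline()` chains these stages from a single config and writes
per-stage tables plus a reproducible `summary.json`;
`inst/scripts/mycstratify.R` wraps simulate/score/run for the shell.

## Vignette

`vignettes/myc-stratification-methods.Rmd` documents the model, the
formulas, every tunable parameter with its default and rationale, the
generator's scope (what it emulates and what it deliberately does not),
and the numerical conventions.
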