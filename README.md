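# mibcSubtyper

Molecular subclassification of muscle-invasive bladder cancer (MIBC) into
**luminal**, **basal** and **infiltrated** (p53-like) tumors from targeted
gene-expression panels, with survival stratification and drug-target
screening.

MIBC carries transcriptomic subtypes analogous to the breast-cancer
subclasses, and the subtype carries prognosis: luminal tumors treated with
radical cystectomy alone do markedly worse than infiltrated tumors. A
cost-effective route to the clinic is a small digital-counting panel
(NanoString nCounter) rather than full transcriptomes. This package
implements that analysis end to end for panel-scale data:

- **nCounter normalization** — per-sample scaling by the positive-control
  geometric mean, background subtraction from the negative controls, scaling
  by the geometric mean of the 6 reference genes (CALM2, RPL37A, B2M, TUBB,
  GAPDH, G6PD), then log2. Microarray cohorts are log2 + quantile normalized.
- **Consensus gene panel** — per cohort, the panel genes are clustered with
  Ward agglomeration on correlation distance d = 1 − r and the three clusters
  are labeled basal / luminal / p53-like by optimal seed-marker overlap; the
  consensus keeps only genes whose label agrees in *every* cohort (Venn
  intersection), reducing 64 subtyping genes to a stable core (16 basal,
  8 luminal, 12 p53-like in the bundled design).
- **Subtype calling** — unsupervised Ward/Pearson clustering of samples on
  the z-scored consensus genes, clusters named by their highest mean
  signature z-score; cross-cohort prediction by Pearson nearest centroid.
- **Survival** — Kaplan–Meier curves, log-rank tests, and Cox proportional
  hazards with Efron ties and score-test forward selection (entry p < 0.05),
  with the subtype dichotomized as luminal vs non-luminal.
- **Association and target tests** — exact r×c Fisher tests
  (Freeman–Halton probability ordering, full lattice enumeration with a
  seeded Monte-Carlo fallback), Kruskal–Wallis tests, a clustering-independent
  drug-target screen, and a minimal phenotype-permutation GSEA
  (weighted Kolmogorov–Smirnov enrichment score, NES, FDR).
- **Synthetic cohorts** — a generator planting all of the above structure
  (negative-binomial counts, control-probe ladders, subtype-dependent
  exponential survival, censoring, weakly associated clinical covariates), so
  every stage is testable without access to patient data.

## Worked example

Four synthetic cohorts (one nCounter, three microarray) sharing a 64-gene
signature structure, with 28 genes planted as cohort-unstable:

```r
library(mibcSubtyper)

cfgs <- lapply(1:4, function(i) simulation_config(
  n_samples = if (i == 1) 150 else 80, seed = i,
  platform = if (i == 1) "ncounter-raw" else "log2-array"))
cohorts <- generate_multicohort(cfgs, n_unstable = 28)
mats <- lapply(cohorts, function(co) normalize_cohort(co$expression)$matrix)

consensus <- derive_consensus(mats, default_panel())
#> consensus_panel: 36 genes (basal 16, luminal 8, p53-like/infiltrated 12),
#>                  4 cohorts, 28 unstable
```

The Venn intersection strips exactly the 28 unstable genes and keeps the
planted 36-gene core. Subtype the index cohort and stratify survival:

```r
calls <- call_subtypes(mats[[1]], consensus)
table(calls$subtype)
#>     luminal       basal infiltrated
#>          24          45          81

cov <- encode_covariates(cohorts[[1]]$clinical, calls)
cox_fit(cov, c("luminal", "stage_t34", "node_pos", "ac"),
        endpoint = "dss", selection = "forward")
#> cox_result (efron ties): n = 150, events = 55
#>     term coef   hr ci_lo ci_hi    se        p
#>  luminal 1.42 4.14  2.35   7.3 0.289 8.57e-07
```

Forward selection keeps only the luminal/non-luminal covariate: luminal
tumors carry a roughly four-fold disease-specific death hazard here (the
generator plants a hazard ratio of 5). The Kaplan–Meier 8-year
disease-specific survival in this run is 18% for luminal vs 76% for
infiltrated tumors. Drug targets, tested independently of the clustering
genes:

```r
drug_target_screen(mats[[1]], calls, c("ERBB2", "FGFR1", "AR"), consensus)
#>    gene         H df            p   direction
#> 1 ERBB2  60.10127  2 8.895602e-14     luminal
#> 2 FGFR1 110.46810  2 1.028386e-24 infiltrated
#> 3    AR  89.22943  2 4.208001e-20     luminal
```

`run_pipeline()` chains all stages from one config and writes TSV artifacts
plus a JSON report; see the methods vignette
(`vignettes/mibc-subtyping.Rmd`) for the model, parameter and design
discussion.

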