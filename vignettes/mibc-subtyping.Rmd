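---
title: "Methods: MIBC subtyping, survival stratification and target screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MIBC subtyping, survival stratification and target screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements: the
models, the tunable parameters, the numerical conventions, and the design
choices made where the underlying analysis protocol leaves room. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The subtyping model

Muscle-invasive bladder cancer (MIBC) separates transcriptomically into a
**basal** compartment (cytokeratins KRT5/KRT14, CD44), a **luminal**
compartment (KRT20, UPK2, PPARG, FGFR3, CD24) and a third compartment
historically called **p53-like**, in which — after reduction to
cross-cohort-stable genes — mostly immune/inflammation genes remain (FAS,
NCAM1, CCL2, CD14). Because of that composition, and the favorable prognosis
of these tumors, the package renders the third label as **"infiltrated"**
everywhere, keeping `p53-like` as the internal alias. Late-cell-cycle genes
(AURKA, AURKB, CCNB1, CCNA2, MAD2L1) sit on the axis shared by basal and
luminal tumors: they are elevated in both and low in infiltrated tumors, so
in gene clustering they ride with the basal/luminal blocks rather than
forming a fourth stable cluster.

The pipeline makes three modeling assumptions worth stating:

1. *Three clusters* — k is fixed at 3 for both gene and sample clustering;
   no model selection over k is attempted.
2. *Cohorts are analyzed separately* — normalization and clustering never
   pool cohorts into one matrix; only cluster *labels* cross cohorts (via
   the consensus intersection) and *centroids* cross cohorts (via
   prediction). This sidesteps cross-platform batch effects by design.
3. *Signature structure is block-like* — a subtyping gene belongs to exactly
   one signature; the consensus construction treats any gene whose label
   moves between cohorts as unusable.

## nCounter normalization

For raw nCounter counts the chain is, in order:

1. **Positive controls** — each sample is scaled by
   (cohort geometric mean of positive-control geometric means) /
   (sample positive-control geometric mean). This removes hybridization/lane
   efficiency differences.
2. **Background** — the per-sample mean of the negative-control probes is
   subtracted, flooring at 0. The policy is a switch
   (`mean`, `mean_2sd`, `max`) because the original protocol states only
   that negative-control background subtraction was performed; `mean` is the
   default and the assumption is recorded in the report header.
3. **Reference genes** — each sample is scaled to the cohort geometric mean
   of reference-gene geometric means, computed *after* steps 1–2. After this
   step the reference geometric mean is identical across samples (the test
   suite checks relative agreement to 1e-9).
4. **log2(x + 1)** — the pseudocount keeps zeros (which survive background
   flooring) finite.

The order positive → background → reference follows standard nCounter
practice; the protocol itself does not state one. A property worth knowing:
multiplying one sample's counts by a constant c cancels from that sample's
own factors, but the *cohort* targets (geometric means over samples) move by
c^(1/n), so the whole cohort's pre-log values shift by exactly that
constant. The idealized claim "rescaling a sample leaves its output
unchanged" therefore holds only up to a cohort-global factor that vanishes
as 1/n; the test suite asserts the exact form.

Microarray cohorts are log2-transformed and quantile normalized (every
sample receives the mean order-statistic distribution; ties within a sample
receive the mean of the quantile values they span — the dominant microarray
convention, deterministic, implemented via `limma::normalizeQuantiles`).
Missing values are a hard error: imputation is out of scope.

## Consensus panel

Per cohort, the 64 subtyping genes are z-scored across samples and clustered
with Ward agglomeration on correlation distance d = 1 − Pearson. Two
conventions are switches because the original description pins neither:

- `ward_on = "distance"` (default) applies the Ward update to d itself
  (`hclust` method `ward.D`), the common usage in this literature;
  `"squared"` uses squared dissimilarities (`ward.D2`).
- Genes are z-scored before clustering by default: correlation distance is
  scale-free but Ward merge *heights* are not, and standardization makes the
  merge structure comparable across cohorts and platforms.

The three clusters are labeled semi-supervised: over all 3! permutations of
(basal, luminal, p53-like), the one maximizing the total count of seed
markers landing in their matching cluster wins. The assignment is optimal,
not greedy, and a tie between permutations is a hard error asking for more
seed markers — a deterministic, auditable reading of "semi-supervised". The
same machinery (with mean signature z-scores instead of seed counts) names
the patient clusters.

The consensus panel is the strict Venn intersection: a gene is kept under a
label only if it carried that label in *every* cohort. Consequences tested
as invariants: the result is invariant to cohort order, and adding a cohort
can only shrink (never grow) a consensus set.

## Subtype calling and prediction

Samples are clustered on z-scored consensus genes (1 − Pearson between
sample profiles, Ward, cut at k = 3); each cluster gets the subtype whose
signature mean z-score is highest, via the optimal assignment above. For
cross-cohort prediction the protocol's mechanism is unstated, so the package
uses the minimal defensible choice, isolated behind its own interface:
per-subtype centroids (mean z-scored consensus profile) and Pearson
nearest-centroid assignment, reporting the margin between best and
second-best correlation per sample; an exact tie is a hard error naming the
sample.

## Survival analysis

Kaplan–Meier estimation and the log-rank test follow the standard
conventions (censorings at an event time stay in the at-risk set). The Cox
model maximizes the Efron-tie partial likelihood (`ties = "breslow"`
available as a switch; Efron is the more accurate default even though some
legacy software defaults to Breslow). Forward selection mirrors the
classical procedure: at each step the candidate with the smallest 1-df
score-test p enters while p < 0.05. The score test is computed by evaluating
the global score statistic at the restricted maximum (current coefficients,
0 for the candidate), where it reduces exactly to the 1-df test for the
added term. There is no removal step. Wald intervals are
exp(coef ± 1.96·SE). Monotone likelihood (complete separation) is detected —
by the fitter's own diagnostics plus coefficient/SE divergence guards — and
raised as an error advising penalized regression rather than returning a
silently diverged fit. The subtype covariate enters dichotomized as luminal
vs non-luminal; 8-year survival means the step value at 96 months. No
multiple-testing adjustment is applied anywhere, matching the analysis
convention this package reproduces (p < 0.05 judged significant);
that choice is deliberate and documented rather than hidden.

## Exact association tests

The r×c Fisher test uses Freeman–Halton probability ordering: the two-sided
p is the total multivariate-hypergeometric probability of all tables with
the observed margins whose probability does not exceed the observed table's.
Two numerical conventions matter:

- probabilities are computed in log space (log-factorials), so n ≈ 50-scale
  tables cannot overflow;
- the "≤" comparison carries a relative tolerance of 1e-7, because
  mathematically equal table probabilities differ in their last floating
  bits, and dropping a tied table would bias p downward. Under this rule the
  published association table reproduces at printed precision
  (the acceptance suite checks all four printed p-values).

The lattice is enumerated exactly (vectorized row-by-row expansion with
feasibility pruning) up to a cap of 5×10⁶ tables, beyond which a
margin-preserving Monte-Carlo estimate (`r2dtable`, fixed seed, add-one
smoothing) is reported with its rep count and seed. Kruskal–Wallis uses
midranks with tie correction; the all-values-tied degenerate case returns
H = 0, p = 1 by convention.

## GSEA

Gene ranking uses the signal-to-noise ratio with the customary floor of each
class standard deviation at 20% of the absolute class mean (which is why
classes need ≥ 3 samples), ties broken deterministically by gene symbol. The
enrichment score is the signed extremum of the weighted Kolmogorov–Smirnov
running sum with hit weight |score|^1. When the gene set spans the entire
list there are no misses and the running sum climbs monotonically to exactly
1 — the package takes that limit as the defined behavior of the statistic
rather than treating it as an error. The null comes from phenotype-label
permutations (not gene permutations); the nominal p is add-one-smoothed on
the matching sign side, so it has resolution 1/(n_perm + 1) and is never 0.
NES divides by the mean magnitude of same-sign permuted scores; for a single
set the FDR q reduces to the same-sign NES-ratio capped at 1. When the label
space is smaller than the requested permutations, it is enumerated
exhaustively with a warning.

## The synthetic-cohort generator

The generator exists so that every downstream stage has a ground truth. Its
defaults are the study conditions the analysis was built around:

| parameter | default | meaning |
|---|---|---|
| `subtype_proportions` | 9/47, 13/47, 25/47 | luminal / basal / infiltrated mixture |
| `marker_effect` | 2.0 log2 | elevation of a subtype's own markers |
| `infiltration_effect` | 1.0 log2 | extra immune-gene elevation in infiltrated tumors |
| `dispersion` | 0.1 | negative-binomial overdispersion of counts |
| `library_size_range` | 0.7–1.4 | multiplicative per-sample library factor |
| `baseline_hazard` | 0.0033 / month | infiltrated disease-specific hazard (≈ 73% 8-year DSS) |
| `subtype_hazard_ratios` | luminal 5, basal 2.5, infiltrated 1 | planted prognosis, luminal-vs-rest HR at the published effect scale |
| `other_cause_hazard` | 0.002 / month | competing mortality (enters OS, censors DSS) |
| `censoring_rate`, `followup_cap` | 0.004 / month, 120 months | loss to follow-up and administrative censoring |

Counts are negative-binomial (nCounter counts are overdispersed; Poisson
would understate the noise), reference genes are subtype-independent,
positive controls follow the fixed geometric spike-in ladder
(128…0.125 fM) times the library factor so positive-control scaling is
exercised non-trivially, negatives are low-level Poisson. Survival is
exponential per subtype — the simplest model in which the Cox hazard ratio
has a known truth for parameter-recovery tests. Clinical covariates are
sampled with deliberately weak subtype association (a mild nodal-positivity
tilt for luminal tumors only), because the published association table shows
no significant covariate–subtype association and the generator should
reproduce that regime. Effect sizes in the real cohorts are unknown (no
per-patient data is printed), so these defaults are chosen for testability,
not fidelity, and are fixed once here.

`generate_multicohort` plants "unstable" genes to exercise the Venn
reduction: each selected non-core gene receives independently shuffled
signature labels per cohort, with the guarantee that at least one cohort
disagrees (if the draws happen to coincide, the last cohort is forced to a
different label — without this, roughly 1 gene in 27 would stay concordant
by chance and the planted 64 → 36 reduction would not be exact). The
"null" condition used in recovery tests sets both `marker_effect` and
`infiltration_effect` to 0: the latter is part of the planted subtype
signal, so a true no-signal null must switch both off.

What the generator does *not* emulate: scanner-level microarray artifacts,
probe-sequence effects, treatment-response mechanisms, cohort-specific
clinical covariate distributions, or the inter-cohort heterogeneity of real
platforms. Passing recovery tests therefore demonstrates correctness of the
pipeline's machinery under its own model, not clinical validity on real
cohorts.

## Problem sizes and determinism

The test and acceptance runs use desk-scale sizes chosen to make the checks
sharp but quick: cohorts of 80–150 samples (20 seeds for recovery
properties), n = 1000 for Cox parameter recovery, 500 replicates for type-I
error calibration, 10⁵ Monte-Carlo reps for the Fisher cross-check, and
100 random instances for each oracle-equivalence sweep (Ward linkage vs a
naive O(n³) agglomerator, enrichment scores vs a brute-force running sum).
Every stochastic component takes an explicit seed; `run_pipeline` derives
per-stage seeds by hashing (global seed, stage name), so inserting a stage
never perturbs the streams of the others, and re-running a config reproduces
all artifacts byte-for-byte.

## Known limitations

- The bundled 64-gene panel is a synthetic stand-in with the documented
  seed markers and group sizes; the original assay's exact probe list is not
  public, so real analyses should supply their own panel.
- Nearest-centroid prediction is one defensible choice among several; the
  interface isolates it so alternatives (e.g. correlation-to-signature
  scores) can be added.
- No TCGA five-subtype mapping, no time-dependent covariates, no
  competing-risks model, no batch correction across cohorts.
- The Cox proportionality assumption is not formally tested; the generator's
  exponential model satisfies it by construction, real data may not.
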