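---
title: "Methods: the GD2 expression signature, equal-error-rate MCC, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the GD2 expression signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gd2sig)
```

## The biological model

Surface GD2 is the product of a short enzymatic cascade:
lactosylceramide (via *B4GALT6*) → GM3 (*ST3GAL5*) → GD3 (*ST8SIA1*) →
GD2 (*B4GALNT1*), with *ST8SIA5* and *B3GALT4* catalyzing downstream
reactions that consume GD2. The working hypothesis is that the functional
balance of these six transcripts predicts the surface phenotype. The
package operationalizes this as an additive score in decimal-log space:
for a signature with terms $(g, s_g)$, $s_g \in \{+1, -1\}$,

$$S_j = \sum_g s_g \cdot \log_{10}(e_{gj} + c),$$

where $e_{gj}$ is the median-of-ratios-normalized expression of gene $g$
in sample $j$ and $c$ is a pseudocount. When all 15 two-gene signatures
over the panel are enumerated, genes on the GD2-consuming side
(*ST8SIA5*, *B3GALT4*) always enter with $s_g = -1$; the flagship
signature is *ST8SIA1* + *B4GALNT1*, both $+1$.

## Normalization

Size factors follow the median-of-ratios estimator: genes with strictly
positive counts in every sample form the reference set; $m_g$ is the
geometric mean of gene $g$ across samples; $s_j = \mathrm{median}_g\,
c_{gj}/m_g$. Two conventions deserve explicit statement:

* **Exact equivariance.** Scaling one sample's counts by $k$ does *not*
  multiply its size factor by $k$ in isolation: the shared geometric
  means absorb $k^{1/n}$, so the scaled sample's factor gains exactly
  $k^{(n-1)/n}$ and all others $k^{-1/n}$. What holds exactly is the
  ratio form — every $s_j/s_i$ gains a factor $k$ — and that is what the
  test suite asserts. Likewise, renormalizing an already-normalized
  matrix yields *constant* size factors equal to the geometric mean of
  the original factors (unity only when that geometric mean is 1). At
  consortium scale ($n$ in the thousands) the $k^{1/n}$ drift vanishes,
  which is why the idealized statements are common shorthand.
* **Median convention.** The per-sample median is taken in ratio space.
  DESeq2 takes it in log space; the two coincide whenever the reference
  set has odd size (the median is then an order statistic) and differ by
  the arithmetic-vs-geometric mean of the two middle ratios when it is
  even. The test suite pins the cross-check to an odd-sized reference
  set.

The matrix is normalized jointly as supplied by the caller; joint
normalization of ever-larger cohort unions is a scale choice, not an
algorithmic one.

### Pseudocount

$\log_{10} 0$ is undefined and upstream practice is silent on the matter,
so the default is $c = 1$ **on normalized counts**: it maps zero
expression to a zero log value, preserves ordering, and leaves
well-expressed genes essentially untouched. It is configurable
(`pseudocount` everywhere); scores from different pseudocounts are not
comparable.

## Equal-error-rate MCC evaluation

A continuous score is turned into a binary call by the rule *positive iff
score ≥ threshold*. Candidate thresholds are the midpoints between
consecutive distinct sorted scores plus $\pm\infty$; the chosen threshold
minimizes $|FPR - FNR|$ — the empirical equal-error-rate point, our
reading of "equal type I and type II errors". Ties are broken by maximal
MCC, then by the smaller threshold; both tie-breaks are deterministic and
oracle-tested against exhaustive search. The orientation is fixed:
anti-predictive predictors yield negative MCC and are *not* flipped, which
prevents inflating |MCC| post hoc.

MCC is computed from the confusion matrix at that threshold; when a
marginal factor of the denominator is zero the MCC is defined as 0 (the
continuity convention — a degenerate margin carries no correlation). A
score vector with all values identical is flagged `degenerate`, evaluated
as all-positive, and given MCC 0 rather than an error.

Two p-value conventions coexist deliberately:

* `evaluate_predictor()` uses the **add-one permutation estimator**
  $p = (1 + \#\{MCC_{perm} \ge MCC_{obs}\}) / (1 + n_{perm})$, which is
  never exactly zero and is the statistically safe default for a
  label-shuffling test.
* `random_pair_null()` uses the **literal strictly-greater frequency**
  $p = \#\{MCC_{null} > MCC_{obs}\} / n_{pairs}$, because that frequency
  *defines* the random-pair null: the score of the observed signature is
  compared against 2-gene signatures of randomly chosen pool genes (both
  signs $+1$, genes distinct within a pair, pairs drawn independently
  with repeats allowed, the observed genes not excluded). A reported
  $p = 0$ from this route means "no random pair beat the signature", not
  an impossibility claim.

## Congruence screening

A signature is *congruent* with known phenotypes when every GD2-positive
sample scores strictly higher than every GD2-negative sample; the
three-level version additionally requires every GD2++ score to exceed
every GD2+ score. Comparisons are strict — ties fail — matching the
"higher than" semantics; the weaker mean-difference reading was rejected
because strict separation is what makes a signature usable as a
single-threshold classifier. Boundary RFI values (exactly 1.5 or 10) are
assigned to the middle GD2+ class: the published cut-offs are strict
inequalities that leave the boundaries unassigned, and the conservative
choice is the intermediate class (configurable via `boundaries`).
Replicate RFIs aggregate as the mean of per-replicate stained/unstained
ratios, not the ratio of means: the per-replicate ratio is the measured
quantity and replicates are exchangeable measurements of it.

## The synthetic cohort generator

`simulation_config()` states a world and `simulate_counts()` draws from
it: counts for gene $g$ in sample $j$ are negative binomial with mean
$L_j \,\mu_g\, 2^{\beta_g [j\,\text{positive}]}$ and variance
$\mu + \phi\mu^2$, with $L_j = \exp N(0, \sigma_L^2)$.

Defaults (chosen once, reported in every output, and not estimates of any
real cohort):

| parameter | default | rationale |
|---|---|---|
| `n_pos`, `n_neg` | 200, 200 | a mid-sized two-arm cohort; large enough that MCC noise is ~0.1 |
| `panel_means` | 2000 / 150 / 50 / 400 / 100 / 800 | spans the baseline range of moderately expressed transferase genes in bulk RNA-seq |
| `log2_effects` | +1 on *ST8SIA1*, *B4GALNT1* | a twofold shift per component — strong but not trivially separable at $\phi = 0.1$ |
| `dispersion` | 0.1 | a typical bulk RNA-seq NB dispersion; the generative model a DESeq2-style workflow presumes |
| `n_background` | 520 | the size of the GO lipid-metabolism pool the null is drawn from |
| `background_mean_range` | [10, 1000] | uninformative genes across three orders of magnitude |
| `libsize_log_sd` | 0.3 | ±35% typical library-size spread, so size-factor estimation is non-trivially exercised |

Counts are drawn directly from the NB sampler (no rounding of continuous
draws); background genes are i.i.d. and carry no group effect unless
effects are injected by name through `log2_effects` (for null-robustness
experiments). The generator does **not** emulate: gene–gene correlation
beyond shared library size, batch structure, GC/length bias, isoform
structure, or zero inflation. A green pipeline test on synthetic data
therefore establishes the *statistical machinery* — normalization,
scoring, thresholding, calibration of the permutation and random-pair
nulls — and not the biological validity of the signature on real tumors,
which only labelled real cohorts can establish.

Flow records are simulated per replicate as an unstained MFI around 100
with the stained MFI equal to unstained × target RFI × log-normal noise
of coefficient of variation `noise_cv` and mean exactly 1, so the
expected ratio is the target RFI.

## Determinism and reporting

Every stochastic routine takes a seed and is a pure function of its
arguments including that seed; `run_pipeline()` produces byte-identical
report bundles for identical configurations (the provenance record
deliberately excludes the output directory and any timestamp). The
sample-type ranking aggregates per-sample scores by the **median** per
type — robust to outlier samples — with lexicographic tie-breaks; the
published material does not state its aggregation rule, so this is a
package design choice. Heatmaps and dendrograms are not rendered: the
sorted score matrix and ranking tables carry the same information and the
clustering is presentational.

## Known limitations

* The headline published MCCs (0.32 / 0.88 / 0.98 across the three
  consortium comparisons) are properties of multi-thousand-sample
  cohorts; the package reproduces the *method*, and its tests assert the
  desk-scale analogues (signature ≥ each individual gene; random-pair
  p < 0.05) on the stated synthetic world.
* The 5-of-15 congruent-pair count on the six profiled cell lines
  requires the deposited cell-line counts; with a user-supplied matrix
  the congruence screen reproduces the computation
  (`run_pipeline()`'s `congruence.tsv`).
* Per-predictor p-values from external utilities are not reproduced
  exactly; the permutation machinery here is self-contained and its
  calibration is tested.
* The equal-error threshold is an in-sample quantity; no train/test split
  is performed, matching the descriptive use of MCC upstream.
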