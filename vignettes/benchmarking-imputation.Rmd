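---
title: "Benchmarking missing-value imputation: models, indices and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking missing-value imputation: models, indices and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mvibench` compares missing-value imputation algorithms on gene-expression
matrices by a mask–impute–score simulation. This vignette explains the
procedure and its assumptions, the built-in algorithms and their tunable
parameters, what the synthetic data generator does and does not emulate,
and the numerical and design decisions taken where the method left them
open.

## The simulation model

The framework's premise is that an imputation algorithm should be judged by
how well it restores a matrix whose truth is known. Starting from a
*complete* matrix (no missing entries, finite log-scale expression values),
cells are held out **completely at random** (MCAR) at five percentages of
all cells — 1%, 3%, 5%, 8%, 10% — re-imputed, and compared to the original.
One *run* comprises the five percentages; `B` runs are averaged, so a final
score is the mean of `5·B` per-run scores. MCAR is an idealization: real
missingness in microarray data is partly intensity-dependent (MNAR), and
results obtained under MCAR are optimistic for methods that exploit
low-intensity structure. Simulating MNAR is deliberately out of scope.

Masks are drawn uniformly without replacement over cells, with exactly
`round(p · cells)` cells per mask, and are redrawn (up to 1000 times) until
every gene keeps at least two observed values and every sample at least
one. The retention constraint exists because distance- and regression-based
imputers are undefined on fully missing rows; it slightly truncates the
mask distribution at extreme shapes, which is irrelevant at the matrix
sizes the framework targets. The percentage is interpreted as a fraction of
*all cells* (not of genes), the convention of the imputation literature,
and rounding is half-away-from-zero. The five percentages are drawn
independently rather than nested; nothing downstream assumes nesting.

Within one (dataset, run, percentage) triple, every algorithm receives the
*identical* mask (a paired design), which removes mask-to-mask variance
from between-algorithm contrasts; `paired = FALSE` restores fully
independent masks for sensitivity analysis. Each imputed matrix is scored
once per selected index — imputation is never repeated per index — so the
work is `datasets × algorithms × 5 × B` imputations.

All randomness (masks, imputation seeds, clustering seeds) derives from one
`master_seed` through a deterministic integer mix keyed by dataset *name*,
run, percentage index and algorithm id. Consequences: two studies with the
same configuration and master seed agree bit-exactly; removing an algorithm
or dataset from the roster does not change anyone else's scores; and a
single cell evaluated in isolation (`evaluate_cell()`) reproduces its value
inside the full study.

## The three indices

**1/NRMSE** measures numerical fidelity at the masked cells only:
`NRMSE = RMSE(masked) / sd(true masked values)` with the population SD. The
SD normalization is the convention of the local-least-squares literature;
normalizing by the mean of the data (the early KNN-imputation convention)
is available via `nrmse_normalization = "mean"`. A perfect reconstruction
has NRMSE 0; the score 1/NRMSE is capped at `1e12` so downstream rank and
normalization arithmetic never meets an infinity. A mask whose true values
are constant makes the ratio undefined and raises an error rather than a
sentinel value.

**CPP** measures preservation of gene-clustering structure. Both matrices
are clustered with k-means (`k` default 10, 10 restarts, 100 iterations)
under the *same* seed, and the score is the fraction of unordered gene
pairs co-clustered in the complete matrix's clustering that remain
co-clustered in the imputed one. The shared fixed seed makes the index a
deterministic function of its inputs; the complete matrix's clustering is
computed once per dataset and reused across algorithms and runs. The
denominator is the complete clustering's pair set, so CPP is directed:
it asks how much of the original structure survives, not whether new
structure appeared.

**BLCI** measures concordance of differential-expression calls. Genes are
tested with a per-gene Welch t-test between the two sample groups at
`alpha = 0.05`, uncorrected — the simplest published biomarker rule; the
index is `|D_o∩D_i|/|D_o| + |D_o^c∩D_i^c|/|D_o^c| − 1`, symmetric in the
two error directions and 1 for perfect agreement. Multiple-testing
correction is deliberately not applied: BLCI compares two *lists produced
by the same rule*, so the rule's calibration cancels. Matrices without
group labels (time courses) default to first-half vs second-half of the
columns, with a warning — a deterministic stand-in users should override
with a label file when a real design exists. If the complete matrix yields
zero DE genes (or all genes DE), the index is undefined and errors with
guidance, rather than silently returning 0.

## The algorithm roster

Two baselines and twelve established algorithms run behind one contract:
matrix with missing cells in, complete matrix out, observed cells then
*overwritten from the source* so observed-cell preservation holds
bit-exactly regardless of what the algorithm did.

| id | family | sketch |
|----|--------|--------|
| `zero`, `row_average` | baselines | constant fill / observed row mean |
| `svd` | global | EM: iterate rank-`r` truncated SVD over the filled matrix |
| `bpca` | global | variational Bayesian PCA, ARD priors per factor |
| `knn`, `sknn`, `iknn` | local | inverse-distance-weighted k nearest genes; sequential / iterative refits |
| `ls` | local | per-neighbour simple regression, weights `(r²/(1−r²+ε))²` |
| `lls`, `slls`, `ills` | local | minimum-norm least squares on k nearest complete genes; sequential / iterative |
| `shrink_*` | local | LLS variants with positive-part James–Stein coefficient shrinkage |

Distances are root-mean-square differences over jointly observed columns
(plain Euclidean where the candidate pool is fully observed); neighbour
ties break by ascending row index, making every local method deterministic.
A cell with no eligible neighbour falls back to the gene's observed row
average and is counted in the result's diagnostics.

Defaults, all overridable per algorithm: `k = 10` for the KNN family and
`ls`; `rank = max(1, round(0.2 · samples))` for `svd`;
`n_factors = samples − 1` for `bpca`; `k = max(5, min(round(0.1 · genes),
150))` for the LLS family; `tol = 1e-4` relative change and
`max_iter = 100` for the iterative methods; `ε = 1e-6` in the `ls` weights.
The sources of the twelve algorithms specify no universal settings, so the
defaults follow the respective original papers' conventions and are
exposed in the configuration rather than hidden. The shrinkage factor is
`c = max(0, 1 − (k−2)·σ̂²/‖β‖²)` with `σ̂²` the residual variance of the
local fit (`df = max(1, |observed| − k)`), applied multiplicatively to the
coefficient vector when `k > 2`; it is the positive-part James–Stein form,
and an exact fit (σ̂² = 0) leaves the coefficients untouched, so the
shrinkage variants coincide with their parents in the noiseless limit.

`bpca` deserves a note: it is a variational EM over loadings, per-gene
factor scores, a shared noise precision and per-factor ARD precisions,
with genes grouped by missingness pattern so the posterior factor
covariance is solved once per pattern. Initialization is the SVD of the
row-average fill, making the method deterministic; the ARD precisions
prune unneeded factors, which is what lets the default
`n_factors = samples − 1` work without choosing a rank.

User algorithms join through the plugin contract: an executable called with
an input TSV (missing cells as `NA`) and an output path; the output must
keep shape and identifiers, contain no missing cells, and move no observed
cell by more than `1e-9`. Violations are hard errors carrying the captured
stderr. Inside a study, a plugin failure marks only that plugin's cells
failed; failed cells are excluded from both ORS and ONS symmetrically, with
per-algorithm evaluated-cell counts printed, because zero-filling a failed
cell would corrupt the rankings.

## Aggregation

Within each (index, dataset) cell algorithms are ranked by descending final
score, fractional ranks on ties (preserving the rank-sum invariant
`Σ ranks = m(m+1)/2`); ORS is the rank sum, smaller better. ONS divides
each final score by the cell's best and sums, larger better, maximum =
number of cells. BLCI can be negative while the normalized-score bound
`0 ≤ N ≤ 1` presumes nonnegative scores, so for ONS only, BLCI values are
affinely mapped through `(value + 1)/2` first; the mapping is recorded in
the report metadata and can be disabled. ORS and ONS can disagree — rank
information discards magnitudes — and both are reported without
reconciliation.

## The synthetic generator

`generate_complete()` plants everything the three indices need to have
recoverable truth: gene `g` in cluster `c`, sample `s` in group `r` gets
`profile(c, s) + shift(g, r) + N(0, noise_sd)`. In the two-group design the
cluster profile is a *constant* baseline expression level (`2c`). Two
considerations force this, and they are worth spelling out. First, log-scale
expression sits at gene-specific baseline levels; without a baseline term,
zero-fill and row-average would be artificially indistinguishable. Second,
biological replicates within a condition are exchangeable: any
deterministic within-group profile variation would enter the per-gene
t-test as apparent biological variance and destroy its power, making the
planted DE genes unrecoverable at any realistic effect size — an early
design with sample-varying sign-pattern profiles capped recovery near 15%
where the group-constant design achieves the nominal power of the test.
The DE shift (`effect_size · noise_sd`, applied to group-2 samples of the
first `round(de_fraction · n_genes)` genes, spread evenly over clusters by
the cyclic cluster assignment) decouples the clustering truth from the DE
truth, and with constant profiles the planted DE genes are *exactly* the
genes whose group means differ — the truth is uncontaminated.

Sample-varying structure belongs to `generate_timecourse()`: profiles are
cluster-specific baselines plus phase-shifted half-cosines with
cluster-specific amplitudes, so adjacent time points are positively
correlated and neighbour- and regression-based imputers see exploitable
temporal structure. The zero-noise time-course matrix has low controlled
rank (at most the number of distinct profiles, all within the span of the
constant, cosine and sine directions), which the exact-recovery tests of
the low-rank imputers use. Note the power caveat above applies to
time-course BLCI as well: its first-half vs second-half grouping sees the
profile variation as within-group variance, which is one more reason the
halves default is a convention rather than a design.

The default spec — 300 genes × 6 samples, 3 clusters, 10% DE genes at
effect size 2.5, noise SD 0.5 — mirrors the small-sample shape of public
microarray benchmark sets while keeping a single imputation sub-second;
the test suite and the acceptance script run full studies at this size
(two datasets × 14 algorithms × 3 indices × 5 percentages × B = 2).

What the generator does **not** emulate: intensity-dependent variance,
spatial artifacts, heavy-tailed noise, correlated samples beyond the
planted profiles, MNAR missingness, and realistic gene counts (thousands).
Passing tests therefore demonstrate the framework's *contracts* —
determinism, pairing, conservation laws, oracle equivalence, correct
ordering of baselines vs advanced methods — not that any algorithm ranking
transfers to a particular real dataset. For real comparisons, load your
own complete matrices with `read_expr_matrix()`.

## Numerical choices and degenerate inputs

- Masked counts use round-half-away-from-zero; a percentage too small to
  mask one cell errors rather than silently masking none.
- All seed derivation uses exact integer arithmetic below 2^31; children
  are keyed by names, not positions, so rosters can change without
  cascading.
- Least-squares systems use the Moore–Penrose pseudoinverse (minimum-norm
  solution); rank-deficient neighbour blocks are therefore handled without
  special-casing and flagged in diagnostics.
- `ls` excludes candidate neighbours sharing fewer than 3 observed columns
  with the target, or with zero variance on the shared columns; with no
  candidate left it falls back to the row average (counted).
- Iterative methods (`svd`, `iknn`, `ills`, `bpca`) stop at relative
  Frobenius change `< 1e-4` over the imputed cells or 100 iterations.
  `iknn` and `ills` additionally stop once the change has failed to improve
  its running minimum for three consecutive iterations: their neighbour
  reselection makes the iteration oscillate at the noise floor on weakly
  structured data, and iterating further neither converges nor helps
  accuracy. Non-convergence and stalls are reported in diagnostics, never
  as errors.
- k-means for CPP runs under a fixed derived seed with 10 restarts; both
  clusterings share the seed, so CPP of a perfect imputation is exactly 1.
- A weighted mean over a single KNN neighbour returns that neighbour's
  value exactly (no `w·v/w` round-trip), preserving the duplicated-row
  identity bit-exactly.

## Known limitations

Auto-tuning of `k` (e.g. by cross-validation, as some LLS implementations
do) is not the default anywhere; the framework compares algorithms at
stated settings. CPP is k-means-specific by design; hierarchical or
model-based clusterings would define a different index. BLCI's first-half /
second-half fallback for unlabeled time courses is a convention, not a
design. And the MCAR masking model, shared with the literature this
framework implements, remains the central idealization to keep in mind when
reading any ranking it produces.
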