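---
title: "Rank-based gene-pair signatures: model, tuning and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based gene-pair signatures: model, tuning and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Quantitative transcriptional classifiers — rules thresholding normalised
expression values — are fragile against batch effects, varying tumor-cell
content, partial RNA degradation and cross-platform scale differences. A
*qualitative* alternative uses only the relative expression ordering (REO) of
two genes **within one sample**: whether `E_i > E_j`. Any per-sample strictly
increasing transform (normalisation, affine rescaling, rank replacement)
leaves every such ordering unchanged, so an REO-based rule transfers across
laboratories without renormalisation. The motivating application is calling
the CpG-island methylator phenotype (CIMP+) of right-sided colon cancers from
expression alone, where the wet-lab methylation assays disagree and no gold
standard exists; the method itself is generic to any two-group phenotype.

For a gene pair `(i, j)` and group `c ∈ {1, 2}` (group 1 is the positive
class), define

* `p_ij(c) = P(E_i > E_j | c)` — the ordering frequency in group `c`,
* `FD_ij = p_ij(1) − p_ij(2)` — the frequency difference.

A useful pair has the ordering almost always present in one group and almost
always reversed in the other (|FD| near 1). Classification is by majority
vote: a sample is called positive when at least `k` of the signature's pairs
show their positive-class ordering.

## The training procedure

1. **Differential gate.** A per-gene two-sample test with
   Benjamini–Hochberg control (threshold `de_fdr`, default 0.01) selects the
   genes anchoring the pair space. This is purely a search-space reduction —
   a local-optimisation compromise; exhaustively pairing all genes would be
   quadratic in the transcriptome and prone to overfitting.
2. **Pair screen** (`screen_pairs()`). Candidate pairs (default: at least one
   differential member, `pair_space = "de_by_all"`) are tested with a
   two-sided Fisher's exact test on the 2×2 group-by-ordering table;
   Benjamini–Hochberg adjustment runs across **all tested pairs** (the
   multiplicity universe must equal the test universe), and pairs with FDR
   below `pair_fdr` (default 0.01) are kept, oriented so `fd = p1 − p2 > 0`.
3. **Panel scan** (`fd_cutoff_scan()`). For each FD cutoff on a grid of
   multiples of `spacing` (default 0.01) spanning the candidates' FD range:
   keep pairs with `fd ≥ cutoff`, remove gene-sharing redundancy greedily
   (per gene only the largest-FD pair survives), then pick the vote threshold
   `k ∈ 1..panel size` maximising the training F-score — here the harmonic
   mean of sensitivity and specificity, `2·sens·spec/(sens+spec)`, not the
   precision/recall F1. The panel with the largest F-score becomes the
   signature.

`classify_samples()` then applies `votes ≥ k`. Because every ingredient is an
ordering count, the trained classifier is invariant — bit-identically, not
approximately — to per-sample monotone distortions; the test suite verifies
this on full-size cohorts with affine, exponential and rank distortions.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `de_fdr` | 0.01 | BH threshold of the differential gate; controls pair-space size, not validity |
| `pair_fdr` | 0.01 | BH threshold over all tested pairs |
| `spacing` | 0.01 | FD-cutoff grid step; grid points are multiples of `spacing`, so cutoffs are platform-independent |
| `de_method` | `welch_t` | `welch_t` or `moderated_t` (pooled variance shrunk toward the mean variance, prior weight `d0 = 4`) |
| `log2` | `TRUE` | log-transform before the differential test only; never affects ordering statistics. No autodetection: data already on log scale must pass `log2 = FALSE` |
| `pair_space` | `de_by_all` | `de_by_de` restricts to differential×differential for tractability on large gene sets |
| `removal_stage` | `per_panel` | redundancy removal inside each cutoff panel; `global` removes once before the scan. Both orders are defensible readings of the procedure; per-panel is the default and the alternative is one switch away |

## Numerical and tie conventions

* **Ties count against the pattern.** `E_i = E_j` never supports `E_i > E_j`
  (events are defined by strict inequality) and casts no vote. A
  deterministic rule beats random tie-breaking for reproducibility;
  continuous data make ties measure-zero anyway.
* **Two-sided exact test, orientation post hoc.** Both ordering directions
  are covered by one two-sided test; the retained pair is then oriented by
  the sign of `p1 − p2`. Fisher's tail summation can exceed 1 by a few ulp;
  p-values are clamped at 1.
* **Vote-threshold ties go to the larger `k`** (the stricter rule), and
  **panel ties to the larger cutoff** (the smaller, higher-FD panel). The
  scan grid is anchored at multiples of `spacing` rather than at the maximum
  FD itself. Degenerate grid (all FD between two multiples) falls back to a
  single cutoff at the minimum FD.
* **Deterministic global sort** (fd descending, p ascending, lexicographic
  pair ids) fixes the greedy sweep order, so screening output and panels are
  invariant to gene/sample ordering of the input.
* **Degenerate tests.** Zero-variance genes with zero group difference get
  p = 1 (never selected); AUC uses the rank/Mann–Whitney identity with
  half-credit ties, which matters because vote counts are small integers.
* Loaders reject missing values by default; per-row median imputation is the
  only offered fallback, because silent imputation can flip orderings.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the method assumes: a
log-scale Gaussian background (baseline means `N(8, 2²)` on a log2-like
scale, within-gene noise sd 0.4) with `n_planted_pairs` gene-disjoint pairs.
Within a planted pair both genes share a baseline, and a per-sample Bernoulli
draw (`pi_pos` or `pi_neg` by group) decides the ordering, realised by a
±2·`noise_sd` offset; where residual noise contradicts the draw, the pair's
two values are swapped within that sample. The swap preserves both genes'
marginal distributions and makes the planted frequency **exactly** `pi`, so
ground truth is exact per sample and empirical frequencies concentrate at the
binomial rate. Planted-pair identities and baselines derive from the config
seed alone; sample-level randomness from the draw seed — so training and
held-out cohorts share structure but are independent. The reference design
used throughout the tests is the study's: 2000 genes, 30 planted pairs,
`pi_pos = 0.95`, `pi_neg = 0.05`, 60+120 training and 40+80 held-out samples.

Companion generators produce probe-level replicates with decoy
unmapped/multimapped probes (`to_probe_level()`), per-sample monotone
corruptions (`corrupt_monotone()`), and methylation intensities
(`generate_methylation()`), where beta values near a 0.1/0.9 bimodal
background are back-solved into methylated/unmethylated intensities via
`M = beta·(T + 100)`, `U = T − M`, so `M/(U + M + 100)` reproduces the target
beta exactly.

What the generator does **not** emulate: hybridisation saturation and other
microarray physics beyond monotone distortion, correlated co-expression
modules, mixed tumor/stroma composition, or realistic methylation–expression
coupling. Passing tests therefore demonstrate the statistical machinery and
its invariances, not performance on any particular clinical cohort.

### A composition caveat

Planted pairs are gene-disjoint, but nothing prevents the screen from pairing
the up-gene of one planted pair with the down-gene of another. When two
planted pairs have nearby baselines, such a cross-pair has the same expected
ordering frequencies as a true planted pair and is statistically
indistinguishable from it — and there are ~30× more cross-pairs than planted
pairs. The winning panel therefore freely recombines planted *genes* into
pairs that need not match the planted *pairing*: in practice every signature
gene is a planted gene while only a minority of signature pairs are literal
planted pairs. The recovery tests check composition at the gene level, pair
recovery at the screen stage (where all planted pairs pass), and performance
on held-out cohorts — which is unaffected, since cross-pairs are genuinely
discriminative. Real cohorts have the same property: many gene pairings carry
equivalent ordering information, and the specific pairs a greedy sweep keeps
are not uniquely determined by the biology.

## Null behaviour and validation design

With `pi_pos = pi_neg` the generator produces a null cohort (the
configuration validator deliberately allows equality). Screening anchored on
the planted genes then retains essentially nothing at FDR 0.01, which the
tests assert over ten seeds. Differential-methylation screening at raw
`P < 0.05` fires at its nominal rate on null sites — raw p is the convention
for hypermethylation screens; an FDR variant is one `bh_adjust()` away.

Problem sizes in the test suite were chosen so the whole suite exercises the
full reference design where the claim depends on it (monotone invariance,
end-to-end recovery, null control — ten seeds each) and small crafted
fixtures everywhere else; the complete suite runs in about a minute and a
half on one core.

## Platform adaptation

A signature trained on one platform may reference genes a validation platform
lacks. `adapt_to_platform()` drops the affected pairs and re-optimises only
`k` on the **original training cohort** restricted to the surviving pairs —
the validation data are never touched, so the adapted rule is still an
honestly pre-specified classifier.

## Known limitations

* The differential gate makes the discovered pair set depend on the DE
  method and threshold; the signature is a local, not global, optimum (the
  global pairing problem is quadratic and overfits).
* The F-score optimum is frequently non-unique on separable training data;
  the tie rules make the choice deterministic but the selected panel size is
  then the smallest panel achieving the maximum, which can be much smaller
  than a hand-curated signature.
* `optimize_vote_rule()` optimises on training labels only; no internal
  cross-validation is performed. Held-out evaluation is the caller's
  responsibility (`classify_samples()` + `metrics_from_confusion()` /
  `roc_auc()`).
* The moderated differential test is a fixed-prior (`d0 = 4`) pooled-variance
  shrinkage, not a full empirical-Bayes fit; it gates the search space and is
  cross-checked against an established implementation in the test suite.
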