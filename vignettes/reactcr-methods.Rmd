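---
title: "reacTCR: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{reacTCR: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reacTCR)
```

This vignette is the package's own account of the science it implements:
what is modeled, which knobs matter, what the synthetic cohorts do and do
not emulate, and where the design was genuinely open.

## The prediction problem

Tumor-infiltrating lymphocytes (TILs) are a mixture of bystander T cells
and T cells whose TCR recognizes the tumor. The unit of decision is the
**clonotype** — the set of cells sharing one TCR rearrangement — because a
clonotype, not a cell, is what gets cloned into a therapeutic product.
Reactivity leaves a transcriptional imprint (activation/exhaustion
programs, canonically including *CXCL13*), but the imprint is expressed in
only part of a clonotype's cells: the same TCR is found in naive, memory
and exhausted phenotypes. The classifier therefore scores cells and
averages within clonotypes, recovering a clean bimodal clonotype score
distribution even when single cells are ambiguous.

## Reactivity labels from flow cytometry

Each tested TCR is transfected into donor T cells and cocultured with the
patient's tumor line; CD107a marks degranulation. The corrected signal

$$(\%\mathrm{CD107a}_{TCR\,vs\,line} - \%\mathrm{CD107a}_{TCR,unstim}) -
  (\%\mathrm{CD107a}_{mock\,vs\,line} - \%\mathrm{CD107a}_{mock,unstim})$$

removes both the transfected cells' spontaneous degranulation and the
mock-electroporation response; it can legitimately be negative. A TCR is
reactive when the corrected signal strictly exceeds twice the standard
deviation of the unstimulated signal. `sd_unstim` is an input with
default 0.34 (percentage points), the value measured on the plates this
rule was calibrated with; it is a property of the assay, not of the data
being scored. TCRs with mTCRβ ≤ 2% never expressed the transgenic TCR well
enough to be interpretable and are excluded. Where a clonotype carries two
productive α chains, the chain pair that elicits the response (the
functional pair) defines the clonotype label. Whether the s.d. should be
plate-wise or global is under-determined; a single global value is used
because the per-plate breakdown is not an input of this pipeline.

## Quality filtering and normalization

Cells with total counts below 1,200 **or** fewer than 500 detected genes
are dropped (strict inequalities: a cell exactly at a threshold stays).
The criterion could also be read as a conjunction; the stricter
disjunction is the default and `rule = "and"` is available. Ambient-RNA
and mitochondrial-fraction cleaning are upstream concerns of the read
processor and are deliberately out of scope.

Counts are normalized to Pearson residuals under a depth-offset
negative-binomial model: gene $g$ has mean fraction $p_g$ (its share of
all counts) and dispersion $\theta_g$, a cell $c$ of depth $n_c$ has
$\mu_{gc} = n_c p_g$, and

$$r_{gc} = \frac{x_{gc} - \mu_{gc}}
                {\sqrt{\mu_{gc} + \mu_{gc}^2/\theta_g}},$$

clipped to $\pm\sqrt{n_{cells}}$. Dispersions are method-of-moments
estimates on depth-scaled counts, floored at $10^{-4}$ and set to
$+\infty$ (the Poisson limit) when the moment estimate is non-positive.
This keeps every quantity in closed form, so an independent per-entry
recomputation can verify the implementation exactly — the reason
kernel-regularized dispersion smoothing across genes was *not* adopted:
it buys smoothness on tiny genes at the cost of a determinate, testable
contract, and the classifier's tree ensemble is insensitive to monotone
rescalings of individual features. Genes present in the model but absent
from a scored sample get residual 0, the model-neutral value — this is the
imputation contract that lets one trained model score samples from other
platforms with partial gene overlap.

## The two-stage classifier

Training data are labeled cells: TIL cells of tested clonotypes plus a
large healthy-donor background pool labeled nonreactive (donors carry
pseudo-clonotypes so they can be split like clonotypes). The pool is
heavily imbalanced toward nonreactive cells, which mirrors real training
cohorts and is why `scale_pos_weight` sits inside the search space,
anchored at the class ratio (box: 0.1–10 × neg/pos, log scale).

Splits are clonotype-wise, stratified by label, 70/30 by default: cells of
one clonotype are transcriptionally correlated, so a cell-wise split would
leak identity and inflate test AUC. Hyperparameters (learning rate, depth,
tree count, subsampling, regularization, class weight, etc.) are tuned by
sequential model-based optimization: a maximin Latin hypercube initial
design over the unit cube, then a random-forest surrogate with an
upper-confidence-bound acquisition over random candidates. The objective
is mean stratified k-fold **cell-level** CV AUC — tuning happens before
clonotype aggregation, matching the training granularity. The surrogate
choice is deliberately unconstrained: what is asserted (and tested) is the
achieved CV AUC, not optimizer internals. Search boxes are declared
defaults (standard effective ranges for gradient boosting), not empirical
facts.

The intermediate full-feature model is then explained with exact TreeSHAP
(per-cell, per-gene Shapley values of the ensemble margin); genes are
ranked by mean |Shapley value| with ties broken by feature order, and the
final model is re-tuned and re-fit on the top 100 genes. The restriction
is the overfitting control: a 100-gene model cannot memorize
cohort-specific noise spread over thousands of genes. On ≤3-feature
depth-1 ensembles the TreeSHAP attributions are verified against exact
subset enumeration of the Shapley value; depth-1 is where the
path-dependent and interventional formulations of the value function
coincide, which is what makes an exact oracle possible.

All randomness funnels through one integer seed; XGBoost runs
single-threaded histogram construction so refits are bit-reproducible.

## Clonotype calls

Per-cell probabilities are averaged per clonotype (singletons are scored;
`min_cells` can exclude them, since the mean of one cell is noisy). The
decision threshold is computed per sample by **Fisher–Jenks natural-break
optimization**: the exact dynamic-programming partition of the sorted
scores into two contiguous classes minimizing total within-class squared
deviation. The threshold is defined as the minimum score of the upper
class — the minimum score required to be called reactive — so the call
rule is `score >= threshold` and boundary ties land in the reactive class.
A sample whose scores are all identical has no natural break; this is
surfaced as an error with the guidance to report no calls rather than
fabricating a threshold. For manufacturing prioritization, a percentile
filter (default 95th, linear-interpolation quantile, strict `>`) trades
recall for a lower false-positive rate.

## Signature baselines

Four published per-cell scoring schemes are implemented behind one
interface, sharing the clonotype aggregation and Fisher–Jenks layer so
that method comparisons differ only in the per-cell score:

* **ssGSEA-style** running sum: rank-weighted hit curve (weight exponent
  0.25, the single-sample convention) minus uniform miss curve, averaged
  over list positions. Rank-based, hence computed on raw counts.
* **Additive**: Σ expression of positive genes − Σ negative genes on
  log-normalized expression; positive score ⇒ signature-positive cell.
* **Module score**: signature mean minus the mean of control genes drawn
  from expression-decile-like bins (24 bins, 100 controls per gene),
  seeded for determinism; undersized bins fall back to replacement
  sampling with a warning.
* **Rank-U**: per-cell Mann–Whitney statistic of the signature ranks,
  capped at rank 1500; score $1 - U/(n_{sig}\cdot cap)$ clamped to
  [0, 1]. With every signature gene at or beyond the cap the score
  collapses to $(n_{sig}+1)/(2\,cap)$ — numerically near zero but not
  exactly zero; the formula is kept as stated rather than renormalized.

The weight exponent and rank cap follow the source methods' published
defaults. Signature gene lists belong to their source studies and are
runtime inputs; the package ships only a synthetic example list
(`inst/extdata/`) documenting the format (one symbol per line, leading
`-` for negative genes). The cluster-based scheme additionally flags all
cells of clusters whose mean score reaches the 0.95 quantile of cluster
means (ties flagged); clustering itself is an input, not re-implemented,
because cluster structure depends on upstream choices the baseline does
not control.

Which normalization each baseline "should" receive is not fully
determined by the source descriptions; the defaults here follow each
method's own convention (rank-based scores on raw counts, additive and
module scores on log-normalized counts) and are configurable.

## Metrics

Confusion counts at the clonotype level; accuracy; G-mean
$\sqrt{TPR \times TNR}$, the headline metric because validation sets are
small and imbalanced; AUC as the normalized Mann–Whitney statistic with
half-credit for ties. When a truth class is absent, G-mean and AUC are
reported as `NA`, never silently 0. Display rounding is half-up to two
decimals. Published per-sample tables of this kind occasionally print a
metric inconsistent with their own confusion counts (e.g. an accuracy of
0.82 alongside counts giving 0.77); this package always reports the value
implied by the formula.

## The synthetic cohort generator

`sim_config()` defaults describe a desk-scale TIL cohort that preserves
the statistical structure that matters to the pipeline:

| parameter | default | what it emulates |
|---|---|---|
| `n_genes` | 500 | harmonized feature space |
| `n_background_cells` / `n_til_cells` | 3000 / 1000 | the strong control-vs-TIL imbalance of real training pools |
| `n_clonotypes` | 50 | a 50-TCR screening campaign |
| `frac_reactive_clonotypes` | 0.68 | 34/50 reactive, as in a real screen |
| `n_program_genes`, `program_log2fc` | 10, 2 | a compact reactive program, ~4-fold up |
| `program_cell_fraction` | 0.6 | state mixing: only part of a reactive clonotype's cells express the program |
| `nb_dispersion` | 2 | strongly overdispersed UMI counts |
| `depth_meanlog`, `depth_sdlog` | log(3000), 0.3 | log-normal library sizes |
| `clonotype_size_power`, `reactive_expansion_factor` | 1.5, 3 | power-law repertoire; reactive clonotypes more expanded |
| `n_donors` | 10 | healthy-donor pseudo-clonotypes |

Counts are NB(μ = depth × p<sub>g</sub> × fold, θ) with fold =
2^log2fc for program genes in program-active cells; baseline gene
fractions are log-normal. The generator intentionally shares its NB
parameterization with the normalizer, so `fit_nb_params()` is a
consistent estimator on simulator output and parameter-recovery tests are
meaningful. What it does **not** emulate: batch effects, ambient RNA,
doublets, dropout beyond NB sampling, gene–gene correlation outside the
program, or realistic gene symbols. Passing end-to-end tests therefore
demonstrates that the machinery recovers planted structure under the
stated noise model — not that any particular real cohort would reach the
same AUC.

The flow-readout simulator gives reactive TCRs a +5 percentage-point
CD107a elevation over a 1% baseline with Gaussian well noise (default
s.d. 0.34); at that effect size the 2 s.d. rule recovers truth exactly in
the noiseless limit and at ≥ 95% accuracy under default noise.

## Problem sizes and numerical choices

End-to-end validation runs use the default cohort (≈ 4,000 cells ×
500 genes), 5 CV folds and 15 optimization evaluations per stage — sizes
chosen so a full simulate–train–call cycle completes in a few minutes on
one CPU while leaving the recovery contrast (held-out clonotype AUC
≥ 0.90 at default effect vs. ≈ 0.5 at zero effect) far from its decision
boundaries. Unit tests use smaller cohorts. Other numerical choices worth
knowing: dispersion floor $10^{-4}$; residual clipping at
$\pm\sqrt{n_{cells}}$; Fisher–Jenks split ties resolved toward the later
split (boundary values join the upper class); quantiles use R's default
type-7 linear interpolation; stratified CV folds are redrawn once if a
fold degenerates to a single class, then error.

## Known limitations

* Clonotype identity trusts the upstream caller's `raw_clonotype_id`
  when present; otherwise identity is synthesized at the nucleotide level
  per barcode. Amino-acid-level convergence is not collapsed.
* The optimizer's budget and boxes are pragmatic defaults; with budget 15
  the tuner reliably finds good, not optimal, configurations.
* Probabilities are not calibrated; only their ranking and the
  natural-break threshold are used.
* Healthy-donor controls enter the clonotype split like any clonotype
  (grouped by donor); holding them entirely inside training is a
  defensible alternative the package does not default to, because
  held-out controls keep the test-side score distribution honest.
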