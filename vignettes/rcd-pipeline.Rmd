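---
title: "Regulated cell death scoring, signature screening and survival modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulated cell death scoring, signature screening and survival modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcdsig)
```

`rcdsig` chains five analyses: single-sample gene-set enrichment, a
composite regulated-cell-death (RCD) score, a cross-dataset gene screen, a
prognostic survival model, and CRISPR screen hit ranking. This vignette is
the package's account of the underlying models, the parameters that
matter, the numerical conventions, and what the synthetic benchmarks do
and do not establish.

## Single-sample enrichment

Both enrichment statistics compare, walking down a per-sample gene
ranking, the cumulative distribution of a gene set's members against the
cumulative distribution of non-members.

**Bulk (`ssgsea_scores`).** Genes are ranked by decreasing expression
within each sample; the gene at position $i$ of $G$ carries weight
$(G - i + 1)^\alpha$, so highly expressed genes dominate. The enrichment
score is the sum over all positions of (weighted in-set ECDF − uniform
out-set ECDF). Two tunables:

* `alpha` (default **0.25**, dimensionless): the usual default of this
  statistic; `alpha = 0` degenerates to the unweighted Kolmogorov–Smirnov
  running sum, larger values emphasise the top of the ranking.
* `normalize` (default **TRUE**): divides the whole score matrix by its
  range (max − min), the statistic's customary normalization. Because the
  divisor is matrix-wide, adding samples rescales all scores jointly but
  never reorders them.

**Single cell (`gsva_scores`).** Sparse profiles make within-sample
rankings unstable, so each gene is first placed on its *cross-sample*
distribution: a Gaussian-kernel cumulative density with bandwidth
per-gene sd / 4 (the method's convention for continuous log-scale data; a
count kernel is not implemented because the pipeline consumes
log-normalized input). Genes are then ranked per sample by that statistic,
with the symmetric weight $|i - (G+1)/2|$ so both extremes count, and a
KS-like running sum is summarised either as the signed maximum deviation
(`"max-deviation"`) or as the sum of the largest positive and negative
deviations (`"diff-of-extremes"`, the default, which is also the common
default of the method this mirrors).

Numerical conventions, chosen for bit-reproducibility and pinned by
brute-force oracle tests (50 random matrices to 1e-9):

* all rank ties break by gene identifier;
* zero-variance genes are dropped from kernel scoring with a warning
  (they carry no cross-sample information);
* in `"max-deviation"` mode a tie in magnitude between the positive and
  negative extremes — exactly symmetric walks do occur — resolves to the
  positive extreme (tolerance 1e-12), so the score cannot depend on
  floating-point accumulation order;
* a set must keep ≥ 2 measured members and ≥ 1 non-member after
  intersection with the matrix, otherwise scoring stops with an error.

## The composite RCD score

`rcd_score` is the per-sample sum of the enrichment scores of the 18
cell-death gene sets (`n_sets` guards against accidental subsetting; other
collections can be scored by overriding it). Samples split into high/low
groups at the median (`stratify_median`; scores exactly at the median go
to "low" — the convention had to be fixed somewhere and is configurable in
spirit by flipping labels) or into top/bottom quantile bands
(`stratify_quantile`, floor rule). Whether the median is taken per cancer
type or across a pan-cancer cohort is the caller's choice: pass the
subgroup's scores. Two small derived scores: `cnv_score` (per-sample sum
of squared copy-number values) and `cyt_score` (mean of GZMA and PRF1
expression).

## The four-step screen

Per dataset: (1) Spearman correlation of every gene with the RCD score,
passing at p < `p_threshold` (default 0.05) and |ρ| > 0; (2) differential
expression — bulk: Wilcoxon rank sum between median-split high/low groups;
single cell: natural-log fold change of malignant vs other cells above
`sc_logfc_threshold` (default 0.25) with Wilcoxon p below threshold;
(3) genes passing both steps form the per-dataset set Gₙ; (4) per gene,
the geometric mean of ρ over the datasets where it entered Gₙ must exceed
`geo_mean_threshold_bulk` (0.35) or `geo_mean_threshold_sc` (0.2), with at
least `min_datasets` contributions. The signature is the intersection of
bulk and single-cell candidates.

Decisions taken where the procedure was genuinely open:

* **Geometric mean over contributing datasets only.** The mean runs over
  the datasets where the gene passed steps 1–2, not over all datasets —
  this is the reading consistent with taking the mean "for each gene
  across the datasets" *after* the Gₙ step, and it lets genes missing from
  some datasets contribute only where measured.
* **Sign policy.** How negative correlations enter a geometric mean is
  undefined; the default `"consistent-sign"` policy disqualifies genes
  with mixed signs (a gene must point the same way in every contributing
  dataset), `"signed-abs"` instead applies the majority sign to the
  geometric mean of magnitudes.
* **`min_datasets` = 3.** A geometric mean over one or two datasets is
  fragile; three is the smallest count that makes cross-dataset
  consistency meaningful. Exposed in `screen_config`.
* **Raw p-values per dataset.** The per-dataset filters use raw p < 0.05;
  Benjamini–Hochberg adjustment is available (`adjust_p = TRUE`) but off
  by default, matching the per-test phrasing of the procedure.
* **Single-cell fold change** is computed on the `expm1` scale with a
  pseudocount of 1 — `log(mean(expm1(x_mal)) + 1) −
  log(mean(expm1(x_rest)) + 1)` — the convention of the single-cell
  ecosystem for log-normalized data.
* Constant genes are flagged `degenerate` and excluded rather than
  silently producing NaN correlations.

## The survival model

**Log-rank scores.** Subjects are ordered by time, events before
censorings at ties. With $\gamma_k$ = number of subjects with
$T_l \le T_k$, subject $l$'s score is
$a_l = \delta_l - \sum_{k=1}^{\gamma_l} \delta_k / (N - \gamma_k + 1)$.
With no censoring and distinct times the scores sum to zero exactly (a
telescoping identity the tests check on 200 random instances). All
censored is a valid degenerate case: all scores zero, flagged.

**Split rule.** A split $x \le b$ with $R_1$ left-hand subjects is scored
by $M(x,b) = (\sum_{x_j \le b} a_j - R_1\bar a) /
\sqrt{R_1(1 - R_1/N)S_a^2}$, where $\bar a$ and $S_a^2$ are the mean and
the divisor-$N$ variance of the scores. The numerator is the sum of
left-hand scores minus $R_1$ times the mean — the standard standardized
linear rank statistic; written any other way the statistic loses its
approximately standard-normal null scale (the tests verify the empirical
95th percentile of |M| sits near 1.96 over 2000 null simulations, and that
group sums of $a_l$ equal the log-rank O − E exactly). `best_split` scans
the midpoints between consecutive distinct values of every candidate
feature and maximizes |M|; ties break toward the lowest feature index,
then the lowest threshold.

**Forest (`rsf_fit`).** Per tree: a bootstrap sample, recursive
`best_split` over a random `mtry`-subset of features with the log-rank
scores *recomputed within each node*, stopping when a node has fewer than
`2 * min_terminal_events` events or no admissible split leaves
`min_terminal_events` events per child. Terminal nodes store the
Nelson–Aalen cumulative hazard on the tree's own event-time grid; a
sample's ensemble mortality is the mean over trees of its terminal
cumulative hazard summed over that grid. Defaults: `ntree = 500`,
`mtry = ceiling(sqrt(p))`, `min_terminal_events = 3`, bootstrap with
replacement, out-of-bag predictions retained — conventional forest
settings, all configurable. Forests are bit-reproducible from their seed.

**Cox and stepwise selection.** `cox_fit` maximizes the Breslow-ties
partial likelihood by Newton–Raphson with step halving (convergence: max
|score| < 1e-8 or relative log-likelihood change < 1e-10); standard errors
come from the inverse observed information; monotone likelihoods are
reported, not silently returned. Breslow tie handling was chosen for its
closed-form risk-set prefix sums; the tests pin the fit against a generic
optimizer of the same likelihood (absolute 1e-6 on coefficients) and
against an independent implementation. `stepwise_cox` starts from the full
model and alternates drop/add moves by largest AIC reduction, evaluating
moves in feature order with first-minimum tie-breaks, so selection is
deterministic given the input column order. Candidate fits that fail to
converge are skipped; an unfit full model falls back to forward selection
from the null model with a warning.

**Evaluation.** `c_index` is Harrell's concordance (risk ties 1/2; pairs
tied on time with two events not comparable). `meta_pool` pools
per-cohort log hazard ratios by DerSimonian–Laird random effects (or
equal-effects fixed mode) through `metafor`. `logrank_test` wraps
`survival::survdiff`. The model-selection harness implied by a
cross-validated model zoo is deliberately reduced to its winning member:
the stepwise-Cox + forest combination is implemented and the concordance
machinery to rank alternatives is exposed, but the other model families
are out of scope.

## CRISPR ranking

`mean_rank_scores` averages raw scores over the datasets where a gene was
measured (mean-of-ranks is available as an option), orientation lower =
stronger effect; `top_fraction` takes the floor of the requested fraction
(default 10% — the fraction, not a fixed gene count, is what reproduces
realistic hit-set sizes); `intersect_hits` intersects cell-fitness hits,
immune-screen hits and the signature. Per-dataset orientation is the
caller's responsibility (flip signs before ranking if a cohort is scored
the other way).

## Synthetic data: what it emulates, and what it does not

`generate_bulk` draws a latent per-sample activity $u_s \sim N(0,1)$ and
gives every planted gene expression
$\text{baseline} + \text{effect} \cdot u_s \cdot \beta_g + \varepsilon$,
with lognormal loadings $\beta_g$ (mean 1, sdlog 0.25) and Gaussian noise.
The defaults `effect = 0.75`, `noise_sd = 1` put the Spearman correlation
between a planted gene and the activity near 0.6 — a moderately strong,
realistic coupling; the calibration is asserted in the tests.
`generate_sc` adds Bernoulli dropout (default rate 0.3), a malignant cell
fraction (0.5) with elevated latent activity (+0.5) and an additive
planted-gene shift (+0.3 natural-log units, sized to exercise the
logFC > 0.25 filter). `generate_survival` draws exponential event times
with rate $\lambda_0 e^{X\beta}$ under uniform censoring;
`baseline_rate = 0.5` with `censor_horizon = 10` yields ≈ 30% censoring
for a linear predictor of unit-scale features with three unit
coefficients. `generate_ici` links binary response to a score through a
logistic model, with an optional target responder rate (e.g. 0.28) for
imbalanced cohorts.

Deliberate simplifications: expression is Gaussian on the log scale, not
negative-binomial counts — every statistic downstream is rank- or
mean-based, so count-level noise would add complexity without changing
what is tested; dropout is independent Bernoulli rather than
expression-dependent; there is no batch structure, no cell-type mixture
beyond the malignant flag, and no copy-number segments. Consequently the
passing benchmarks establish *correctness of the machinery and its
behaviour under the assumed generative structure* — recovery of planted
signals, calibration under null permutations — not performance on real
cohorts, where batch effects, expression-dependent dropout and weaker,
collinear signals will reduce recall.

## Problem sizes and benchmark conditions

The test suite validates the screen end to end on 5 bulk datasets
(200 samples × 500 genes) plus 5 single-cell datasets (1000 cells ×
500 genes) with 50 planted genes, requiring ≥ 90% recall with ≤ 5% false
inclusions, and the survival pipeline on n = 500 (3 true of 20 features,
≈ 30% censoring, 250/250 train/test, 200 trees) across 5 seeds, requiring
held-out concordance ≥ 0.70 and permuted-outcome concordance in
[0.45, 0.55]. These sizes were chosen as the smallest at which the planted
effects are comfortably identifiable, keeping the suite quick while still
exercising every code path; forest and tree counts are model choices, not
statistical necessities, and scale up unchanged.

## Known limitations

* The enrichment scorers are dense-matrix implementations; extremely large
  single-cell matrices (≫ 10⁴ cells) will want chunking.
* Exact Wilcoxon enumeration is used only up to a combined n of 12; beyond
  that the continuity-corrected normal approximation is standard but can
  deviate from exact p-values by a few hundredths under severe group
  imbalance.
* The Cox fitter targets the modest feature counts that survive stepwise
  selection; it is not a sparse/regularized solver.
* Gene identifiers are matched case-sensitively as strings — symbol
  harmonization across datasets must happen upstream.
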