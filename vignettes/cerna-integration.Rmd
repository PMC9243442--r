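---
title: "Methods: multi-omics ceRNA integration with a planted-truth simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics ceRNA integration with a planted-truth simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernaflow)
```

# The analysis problem

Case/control multi-omics cohorts of brain tissue often cannot sample the
same anatomical site in both groups: diseased hippocampus is compared
against surgically accessible healthy cortex. Any per-feature two-group
comparison then mixes two signals — disease and tissue site. This package
implements the full analysis chain for such a design: per-layer
differential screening, removal of tissue-confounded signatures against a
paired reference of the two healthy tissues, cross-layer correlation
networks intersected with miRNA target predictions, assembly of competing
endogenous RNA (ceRNA) triads, nine-quadrant integration of differential
methylation with differential expression, and enrichment analysis
(over-representation, GSEA, guilt-by-association).

Everything runs on tibbles: matrices travel as `omics_tbl` (feature id
column plus one numeric column per sample, with the molecular layer as an
attribute), every stage returns a tibble, and `run_cerna_pipeline()` chains
the stages with a manifest of per-stage counts.

# Statistical model, stage by stage

## Differential screening

For feature $g$ with case values $x$ ($n_1 \ge 2$) and control values $y$
($n_2 \ge 2$) on the log2 scale, the screen uses the pooled-variance
Student $t$:

$$ t_g = \frac{\bar x - \bar y}{\sqrt{s_p^2 (1/n_1 + 1/n_2)}},
   \qquad s_p^2 = \frac{(n_1-1)s_x^2 + (n_2-1)s_y^2}{n_1+n_2-2}, $$

with a two-sided $p$ from the $t$ distribution on $n_1+n_2-2$ df. A
moderated option shrinks $s_p^2$ toward the across-feature mean variance
with a fixed prior df (default 4), the empirical-Bayes stabilization
microarray frameworks apply; the plain test is the default because it is
the test the screen is defined by. Degenerate rows are handled explicitly:
identical constant groups give $t=0$, $p=1$; otherwise a variance floor of
$10^{-12}$ prevents division by zero (a constant-but-different row is then
maximally significant, which is the right answer).

Multiplicity is controlled by Benjamini–Hochberg step-up adjustment
(`bh_adjust()`, a validating wrapper over the standard implementation,
verified in the tests against a direct hand computation of
$q_{(i)} = \min_{j \ge i} p_{(j)} m / j$). Calls use strict
`adj_p < 0.05` and non-strict `|log2FC| >= 1` (fold change 2); the strict/
non-strict split is stated explicitly because informal descriptions of
such thresholds mix "greater than" and "at least". Methylation rows are
beta values in $[0,1]$, analyzed with the same machinery on the natural
scale (never log-transformed or quantile-normalized); the effect is
delta-beta with a default call threshold $|\Delta\beta| \ge 0.2$ — a
convention, since array methylation studies rarely state one.

## Preprocessing

`filter_probes()` removes features annotated on chrX/chrY (features with
unknown annotation are kept: the filter removes only what is provably on a
sex chromosome) and features detected in strictly less than 60% of samples
when a detection matrix is available. `quantile_normalize()` maps every
sample onto the vector of row-wise means of the sorted columns; tied values
receive the mean of the reference values over their tied positions (the
common convention; verified against a hand-computed oracle and against
limma on tie-free input). `log2_transform()` applies
$\log_2(x + \text{offset})$ with an `already_log2` escape hatch.

The pipeline default is `normalize = FALSE`: the simulator emulates arrays
that the vendor software has already normalized and log2-scaled, which is
the form in which such data reaches the downstream statistics.
Quantile normalization assumes most rows are non-differential; at the
planted-signal density of the default simulation (about a quarter of rows
carry real shifts), re-normalizing visibly compresses the planted effects.
For raw intensities, `normalize = TRUE` restores the full preprocessing
contract.

## Reference tissue filter

For every feature of the paired reference cohort the within-pair
differences $d_i$ are tested for location zero: Shapiro–Wilk at
$\alpha = 0.05$ decides between the paired $t$-test (normal-looking
differences) and the two-sided Wilcoxon signed-rank test (zero differences
dropped; exact $p$ up to 25 non-zero pairs, normal approximation with
continuity correction above). Cohort-differential features whose reference
test is significant at raw $p < 0.05$ are removed. Raw rather than adjusted
$p$ is deliberate: the filter should be aggressive about flagging
tissue differences, i.e. conservative about what it lets through. Features
the reference never measured are kept but flagged `unmeasured`
(configurable), since silently dropping them would shrink the result set
for reasons unrelated to biology. With 10 pairs and a between-tissue offset
of 2.0 log2 units against residual noise of SD 0.5, the per-pair
standardized effect is $2.0 / (0.5\sqrt{2}) \approx 2.8$, so the paired $t$
flags a confounded feature with power essentially 1 — and a clean feature
is falsely flagged at the 5% test level, which is exactly the collateral
loss the recovery figures below show.

## Correlation network and triads

Pearson correlations are computed across all samples, cases and controls
pooled, matching how co-expression is screened in such cohorts (per-group
correlation is out of scope). $p$ comes from the exact transform
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df; the BH-adjusted column is always
reported, and significance can be switched from raw $p$ (default, the
published convention for these pair screens) to the FDR column. Thresholds
are strict: miRNA–mRNA keeps $r < -0.5$, miRNA–lncRNA keeps $|r| > 0.5$,
lncRNA–mRNA confirmation keeps $r > 0.5$, all at $p < 0.05$; a pair at
exactly $\pm 0.5$ is excluded. After intersection with the prediction
table (which logs the correlated-only / predicted-only / both Venn),
`assemble_cerna_triads()` takes, per miRNA, the cross product of its
negative predicted sponge lncRNAs and negative predicted target mRNAs.
Positive miRNA–lncRNA edges survive thresholding (they are reported as
network edges) but never enter triads — a sponge must sequester its miRNA.
The positive lncRNA–mRNA confirmation edge is optional and off by default:
the sponge logic implies it, but filtering on it is an additional modelling
commitment the screen itself does not require.

Note one property of pooled-sample correlation screens that the simulator
reproduces faithfully: any two features with real case/control shifts are
correlated through the group structure alone, so the network contains
prediction-supported pairs (and hence triads) beyond the mechanistically
coupled ones. The planted triads are recovered; they are not the only
edges, just as in real cohorts.

## Nine-quadrant integration

Genes present in both the methylation and the expression results are
cross-classified by the *significance calls* (not raw effect signs):
methylation hypo/none/hyper crossed with expression down/none/up, quadrant
$= 3\,\text{row} + \text{column} + 1$ on the fixed grid. Quadrant 3 —
hypomethylated and upregulated — flags candidate epigenetically activated
genes, returned most-hypomethylated first.

## Enrichment

Over-representation is the upper-tail hypergeometric test with BH across
the collection (equivalent to enumerating all draws, which the tests do for
small universes). GSEA walks the ranked list with the weighted
Kolmogorov–Smirnov running sum: hits add $|s_i|^p / \sum |s|^p$ (weight
$p = 1$ by default, $p = 0$ giving the classic KS statistic), misses
subtract $1/(N - n_{hits})$; the enrichment score is the extremum of the
running sum, and the leading edge contains the members at or before it
(after it, for negative scores). The null is gene-label permutation at
matched set size — membership is resampled while scores stay attached to
their positions. This single null serves both phenotype-free rankings
(guilt-by-association has no phenotype to permute) and the standard case,
keeping one code path. NES divides the observed score by the mean absolute
value of same-sign null scores; $p$ uses the add-one correction
$(b+1)/(m+1)$; sets with fewer than 2 in-list members are skipped, and a
set with no same-sign null draws gets an undefined NES and a flag rather
than a division by zero. Ties in ranked lists are broken lexicographically
by id so every ranking is deterministic.

Guilt-by-association ranks all mRNAs by Pearson correlation with a hub
feature (the hub excluded from its own ranking, constant rows dropped) and
runs the permutation GSEA on that ranking, reporting sets by $|NES|$. For a
miRNA hub, repressed targets anticorrelate and surface with negative NES.

# The synthetic cohort and what it does (not) emulate

`sim_config()` defaults define the study conditions: 20 cases vs 20
controls, 200 features per layer, residual noise SD 0.5 on the log2 scale,
background level 8. Planted signals:

* 20 ordinary DE features per layer (half up, half down) at
  $\pm 1.5$ log2 units;
* 5 ceRNA triads driven by a latent per-sample miRNA activity
  $a \sim N(-2 \cdot \text{is case},\ 1)$: miRNA $= 8 + a + \varepsilon$,
  sponge lncRNA and target mRNA $= 8 - 0.8\,a + \varepsilon$. The coupling
  0.8 gives pairwise correlations near $-0.76$ before the group shift adds
  to them, comfortably past the $-0.5$ threshold at $n = 40$, while the
  activity shift makes all three members differential (miRNA down, lncRNA
  and mRNA up). A `targets_per_triad` extension couples one miRNA to
  several mRNAs, used to give a hub a multi-gene target set for the
  guilt-by-association checks;
* 6 hypomethylated genes ($\Delta\beta = -0.25$), exactly one of which is
  also upregulated — the hypo-up candidate the quadrant selector must find.
  Methylation baselines are drawn in $(0.2, 0.8)$, for planted genes in
  $(0.4, 0.75)$ so the planted shift is realized away from the $[0.01,
  0.99]$ clipping boundary; beta noise SD is 0.05, typical of gene-level
  array summaries;
* 18 tissue-confounded decoys (6 per layer) shifted $+2.0$ in cases only
  because of tissue site; the paired reference cohort (10 hippocampus/
  cortex pairs, shared per-pair effect SD 1.0) carries the same offset, so
  the reference filter can — and does — remove them;
* a prediction table containing every planted triad edge plus decoy
  predictions over 30% of all (miRNA, target) pairs among never-planted
  features.

The generator is deterministic under its seed and restores the caller's
RNG state. What it does *not* emulate: probe-level noise models, batch and
hybridization effects, correlated backgrounds, probe-to-gene multimapping,
and sequence-based target plausibility. Passing recovery tests therefore
show that the inference chain is correct under its stated model — not that
real arrays meet that model.

# Numerical choices and edge cases

* Detection-rate comparison is strict (`< 0.60`): a feature detected in
  exactly 60% of samples stays.
* Fold-change comparison is non-strict (`>= log2(2)`), the adjusted-p
  comparison strict (`< 0.05`).
* Zero-variance features: identical constant groups short-circuit to
  $t = 0, p = 1$; otherwise the $10^{-12}$ variance floor applies.
* Constant rows are skipped (with a log line) wherever a correlation is
  undefined; a constant guilt-by-association hub is an error.
* Edge lists are written ordered by $|r|$ descending with lexicographic
  tie-breaks, and all stage outputs are byte-identical across reruns of the
  same config — the golden-manifest regression test freezes one fixture
  run (seed 7) to catch unintended behavioural drift.
* The pipeline derives per-stage seeds from the single config seed by fixed
  offsets, so each stage is individually reproducible.

# Problem sizes used by the test suite

The suite exercises oracle equivalence on hand-computable cases (vectors of
3–6 values, universes of 9–12 genes), calibration on 50 signal-free
cohorts of 40 features (12 samples each) and 50 random gene sets
(60-gene rankings, 200 permutations), and recovery on 20 full-default
cohorts (200 features per layer, 40 samples). These sizes were chosen so
the planted effects sit well inside the detectable regime while each
property check completes in seconds; the acceptance script
(`scripts/acceptance.R`) recomputes the same quantities from scratch at the
same sizes.

# Known limitations

* The reference filter tests each feature at raw $\alpha = 0.05$ without
  multiplicity correction; with many features, roughly 5% of genuinely
  disease-driven signatures are lost. That trade-off is visible in the
  collateral-loss figure the acceptance script reports.
* Pooled-sample correlations conflate group-driven and mechanistic
  co-expression (above); partial-correlation or per-group ceRNA scores are
  out of scope.
* Multi-probe-to-gene collapsing is upstream of this package; feature ids
  are opaque strings.
* GSEA uses gene-label permutation only; phenotype permutation is not
  implemented.
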