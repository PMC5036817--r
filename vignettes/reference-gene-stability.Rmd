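---
title: "Selecting stable reference genes from replicate-level Cq panels"
author: "qpcrStability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting stable reference genes from replicate-level Cq panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrStability)
```

## The problem

Quantitative PCR reports, for every reaction, a quantification cycle Cq:
the (fractional) cycle at which fluorescence crosses a threshold.  Cq is a
negative log2 abundance — one cycle earlier means roughly twice the
starting template.  Because Cq absorbs every upstream source of variation
(RNA input, reverse transcription, loading), expression is reported
relative to *reference genes* (RG) assumed stable across samples and
conditions.  On large panels the RG themselves must be chosen from the
data, by ranking candidates with stability statistics and checking that
the choice is robust across algorithms and across cohorts.  This package
implements that workflow end to end on replicate-level Cq data with
explicit missing reactions, plus the downstream check that matters in
practice: whether a well-chosen versus a poorly-chosen RG pair changes the
statistical significance of target-gene group differences.

## Data model and QC

A `CqPanel` holds genes × samples × replicates with `NA` for reactions
that never amplified, and one group label per sample.  Replicates are
aggregated by arithmetic mean on the Cq scale over the available
replicates — no outlier rejection, matching common qPCR-analysis software.
A gene × sample cell whose replicates *all* failed is non-amplified;
because the stability algorithms need complete matrices, any gene with at
least one such cell is excluded (`excludeIncompleteGenes()`, mode
`"cell"`).  We interpret "no amplification in a sample" at the cell level
rather than the replicate level because a single failed replicate still
leaves a usable Cq for the cell; the stricter `"replicate"` mode is
available for panels where any failure is disqualifying.  Missing
reactions are always *counted* at the replicate level in the `QcReport`,
so the bookkeeping (total, missing, fraction) is independent of the
exclusion mode.  No Cq ceiling is applied by default; `cqCeiling` can
censor late cells (e.g. Cq > 35) where the platform's late calls are not
trusted.

## Expression scale

All log-ratio statistics work on log2 relative quantities,
`log2rq(g,s) = log2(base) · (anchorCq(g) − Cq(g,s))`, with a single
amplification factor `base = 2` for every assay — appropriate for
platforms whose Cq calls are already efficiency-corrected per curve, and
configurable otherwise.  The anchor (per-gene mean Cq by default, minimum
optionally) shifts each gene by a constant only; every pairwise log-ratio,
and hence every geNorm/ΔCt/NormFinder statistic, is invariant to it.  The
mean anchor makes each gene's RQ geometric-mean-centred, which in turn
centres the normalization factors (below) at geometric mean 1 — a useful
internal consistency check.

## The four stability algorithms

**geNorm.** Pairwise variation between genes *j* and *k* is the sample sd
over samples of their log2 ratio; M_j is the mean over partners.  The gene
with the largest M is eliminated and M is recomputed until two genes
remain (these two are formally unrankable; we order them by final-round M,
then input order, because rank aggregation needs a total order — the
tied-rank alternative is available as `genormTieAverage`).  Ties during
elimination remove the gene later in input order, for determinism.  Since
the pairwise sd between two genes does not depend on which other genes are
in play, the implementation computes the pairwise-variation matrix once
and subsets it per round; a naive per-round recomputation is kept in the
test suite as an independent oracle.  The V-curve uses normalization
factors defined on the log scale as the arithmetic mean of the top-n
genes' log2rq (equivalently the geometric mean of RQ), with the top-n sets
taken from the final ranking.  Thresholds M < 0.5 and V(n/n+1) < 0.15 are
reported conventions, not hard filters.

**NormFinder.** Each gene's log2 values are first centred within each
sample (which removes loading offsets exactly), then decomposed into a
group effect and residual noise.  The within-group variances are
bias-corrected for the centring step — subtracting a 1/(k−1) share of the
group's mean variance and rescaling by k/(k−2), with a floor of 1e-12 to
keep near-degenerate panels finite — and a between-group variance γ² is
estimated from the excess spread of the group differences.  The group
differences are shrunk by γ²/(γ² + σ̂²/n) before entering the stability
value ρ = mean over groups of |d̃| + sqrt(σ̂²/n).  With one group (or
`useGroups = FALSE`) ρ reduces to the corrected intragroup sd.  The
across-group gene mean is sample-size-weighted by default so the weighted
group differences sum to zero exactly under unbalanced cohorts (23 vs 24
here); `weighted = FALSE` gives the unweighted variant.  The original
method's exact variance algebra is not uniquely pinned by published
descriptions, so this reconstruction is validated by its *properties*
(loading invariance, zero-sum differences, single-group reduction,
monotonicity in planted noise, rank agreement with designed instability at
large n) rather than by bit-level agreement with any particular tool.

**BestKeeper.** Deliberately works on raw Cq: per-gene sd (cycles) and CV
(% of mean Cq), plus the Pearson correlation of each gene with the
per-sample geometric-mean index.  Ranking is by sd ascending with CV as
tie-break; the classical sd ≤ 1 acceptability flag is reported but never
removes genes, since the aggregation wants all candidates ranked.  The
correlation is undefined (reported `NA`) for a constant gene.  Its
sensitivity to per-sample loading offsets — unlike every log-ratio method —
is asserted in the tests as a feature, not a bug: it is the one method
that sees loading quality.

**Comparative ΔCt.** The mean over partner genes of the sd of pairwise Cq
differences.  At base-2 efficiency this is algebraically identical to the
full-panel geNorm M, and the test suite holds the two implementations to
1e-12 of each other — a cross-module consistency check that exercises both
code paths.

**Aggregation.** The comprehensive ranking is the geometric mean of the
four ranks, ordered ascending with ties broken by best single-method rank
then input order.  `consensusTop()` intersects top-n lists across
algorithms or cohorts.  BestKeeper and ΔCt consume raw Cq while
geNorm/NormFinder consume log2rq; since Cq is itself a log2 scale, both
conventions are accepted by every function and converted internally.

## Normalization evaluation

`normalizeToReference()` computes per-sample normalization factors as the
geometric mean of the chosen RGs' RQs and divides target RQs by them;
`compareGroups()` runs a two-sided Mann-Whitney test per target on the NRQ
values and summarizes the effect as the ratio of group medians (medians
matching the nonparametric test; means by flag).  The Mann-Whitney wrapper
reports U = min(U_A, U_B), exact by enumeration-equivalent computation for
combined n ≤ 16 without ties, otherwise the normal approximation with tie
and continuity corrections; an exhaustive-enumeration oracle in the tests
checks the exact branch.  Significance is annotated at 0.05 and 0.01 with
no multiple-testing adjustment by default (a Bonferroni flag exists),
since typical usage compares a handful of pre-chosen targets.

## The synthetic generator

`simulateCqPanel()` draws Cq values from the additive model on the cycle
scale

> Cq(g,s,r) = B_g + L_s + Δ_g·[group(s) ≠ reference] + ε_gs + τ_gsr

with gene baselines B (uniform 18–32 cycles by default), sample loading
L ~ N(0, 0.5 cycles), per-gene biological noise ε (designed-stable genes
0.1–0.25 cycles, unstable 0.5–2.0), group shifts Δ in cycles (one cycle =
a 2-fold change at base-2 efficiency; negative = up-regulated in the
second group) and technical replicate noise τ ~ N(0, 0.1).  These defaults
are typical of high-throughput TaqMan panels on well-handled tissue RNA.
Dropout is planted with exact replicate-level counts; in the default
detection-limit mode it concentrates in the highest-Cq (lowest-expression)
genes and cells, and every affected gene is guaranteed at least one fully
missing cell so that cell-mode QC excludes exactly the affected genes.
The ground-truth record (all parameter draws) makes the noise-free limit
exactly recomputable and lets recovery tests compare rankings against
designed instability.

What the generator does *not* emulate: PCR inhibition, gene-specific
efficiencies, correlated biological regulation between genes (every gene's
ε is independent), batch/plate effects beyond a scalar loading offset, and
stochastic dropout at the detection boundary (planted counts are exact).
Passing recovery tests therefore demonstrate that the statistics identify
designed stability under the assumed additive model, not that any
particular biological panel will behave as cleanly.

`studyScalePanel()` is the deterministic fixture used throughout: 112
assays × 47 samples (23 control + 24 infected) × 3 replicates = 15792
reactions; 1516 missing reactions spread over 41 filler genes (each with a
fully-missing cell), leaving 71 complete genes; a 10-gene designed-stable
block including *Il2rg* and *Itgb2*; six classical RG candidates with
mixed stability — *Hprt* deliberately decent (it typically performs well
in mouse spleen), *B2m*/*Polr2a*/*Tbp* deliberately poor; and cytokine
targets *Cxcl10*, *Ifng*, *Tnf* up-shifted in the infected group by 2.5, 2
and 1.5 cycles.  All of its values are synthetic.

```{r fixture}
fx <- studyScalePanel()
qc <- excludeIncompleteGenes(fx$panel)
qc$report
```

```{r ranking}
mat <- qc$matrix
cr <- comprehensiveRanking(geNorm(mat), normFinder(mat),
                           bestKeeper(mat), deltaCt(mat))
head(geneRanking(cr), 10)
```

```{r evaluation}
evaluateNormalization(mat, rgSet = c("Il2rg", "Itgb2"),
                      targets = c("Cxcl10", "Ifng", "Tnf"))@comparison
```

## Pipeline and design choices

`runStabilityPipeline()` runs QC, the four algorithms, aggregation and
consensus per cohort (each group label plus all samples combined by
default), then the NRQ evaluation for each configured RG set, writing
TSV/JSON reports and a manifest (package version, config hash, seed) that
suffices to reproduce a run.  QC is applied within each cohort's own
samples, so a single cohort can retain a gene that the combined analysis
excludes (its missing cells may all lie in the other cohort); the combined
cohort always sees the full exclusion.  Plots are deliberately not part of
the pipeline output so headless runs never depend on a graphics device;
all results are returned as objects and plain-text reports.

Numerical choices worth knowing: pairwise sds are computed through the
covariance identity var(x−y) = var x + var y − 2 cov(x,y) (fast, and
guarded against tiny negative values before the square root); all sds use
the n−1 denominator; geNorm tie-breaks remove the later gene in input
order; NormFinder's variance floor is 1e-12; rank aggregation breaks
geometric-mean ties by best single rank then input order.  Test and
vignette simulations use panels of up to 30 genes × 400 samples and 100 to
200 replicate runs — sizes at which every statistic here is
well-conditioned and the whole suite runs in well under a minute per
property.

Recovery-simulation ground truths use sign-balanced group shifts (the
across-gene mean shift is exactly zero).  This is not a convenience: the
per-sample centring that removes loading also removes the *mean* group
shift across genes, so a panel whose regulated genes all move the same way
would make every gene appear group-shifted relative to the panel mean.
That is a real limitation of loading-normalized stability analysis —
global shifts are unidentifiable from Cq data alone — and the generator's
balanced design states the regime in which the designed-instability oracle
is meaningful.

## Limitations

- A single amplification efficiency is assumed for all assays; per-assay
  efficiencies (standard-curve calibration) are out of scope.
- The NormFinder reconstruction targets the published model's structure,
  validated by properties and rank behaviour, not bit-level agreement with
  any specific implementation.
- The missing-amplification rule discards genes, never imputes; panels
  with widespread dropout lose power accordingly.
- Exact gene rankings on any real data set depend on that data; the
  fixture reproduces a study design's bookkeeping and qualitative
  behaviour, not measured rankings.
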