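---
title: "Methods: genotype-associated DNA methylation across development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-associated DNA methylation across development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdev)
```

This vignette is the package's own account of its statistical methods: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where more than one
reasonable reading existed.

## The study design the package assumes

The pipeline targets bulk-tissue DNA methylation measured on a beadchip
array in a two-genotype mouse model (wild type vs heterozygous mutant)
across five developmental stages: E14.5, E18.5, P7, P35 and P70, with a
handful of animals per genotype per stage. Methylation is carried as beta
values — proportions in [0, 1] — and analysed on that scale throughout.
Where age must enter a model continuously (per-day slopes), stages are
encoded as days since E14.5: E14.5 → 0, E18.5 → 4, P7 → 26, P35 → 54,
P70 → 89 (birth at gestational day 19). All differential models treat age
as categorical, so this encoding only matters for the pseudo-age and
cell-composition trend tests.

## Quality control and the analysis background

Sample gates operate on precomputed signal summaries (median
methylated/unmethylated intensity ≥ 2000 a.u., fraction of probes failing
detection ≤ 1%, bisulfite conversion ≥ 90%, the 90 inclusive); computing
detection P values from raw intensities is deliberately out of scope, so
the pipeline consumes per-probe counts of detection failures rather than
recomputing them. Probe removal applies four reasons in a fixed priority
order (manifest technical flag, manufacturer change flag, chromosome "0",
detection failure in more than one sample); the retained set is invariant
to the order, but each removed probe is reported with exactly one reason.

Quantile normalisation forces all samples onto the across-sample mean of
sorted values, ties sharing the average rank (delegated to
`limma::normalizeQuantiles(ties = TRUE)`, which implements exactly this).

The analysis background is the set of *variable* probes: those whose beta
range across the inner 80% of samples exceeds 0.05, strictly. "Inner 80%"
is read as the linear-interpolation (type-7) quantiles at 0.1 and 0.9 of
the sorted sample betas, so the range is q₀.₉ − q₀.₁. An alternative
reading — trim 10% of samples per tail and take the remaining min–max —
differs only by interpolation at the cut points; the quantile reading is
the default and `inner_fraction` is configurable. The strict `>` matters
at the boundary: a probe with an inner range of exactly 0.05 is not
variable.

## Cell-type deconvolution

A reference panel is trained from labelled, nuclei-sorted neuronal
(NeuN+) and non-neuronal (NeuN−) methylation profiles. After restricting
to autosomal sites, a per-site one-way ANOVA across cell types ranks
sites; among those with P < 1e-8, each cell type contributes its top 50
sites where its mean is below all other types (hypo) and top 50 where it
is above (hyper). With two cell types the directions mirror each other —
"hypo in NeuN+" is "hyper in NeuN−" — so the deduplicated union is
exactly 100 sites when both directions are saturated; this is how the
package resolves the 100-site arithmetic for two types, and for more
types it selects 2 × 50 per type before deduplication. A depleted
direction contributes what it has, with a warning; zero qualifying sites
is an error.

Bulk proportions solve min ‖b − Mw‖² subject to w ≥ 0 per sample
(`pracma::lsqnonneg`), with **no sum-to-one constraint**: weights may sum
below 1 for profiles unlike any reference mixture, and the reported
neuronal proportion is the raw NeuN+ weight. The per-sample error score
is the root-mean-square residual over panel sites — a reconstruction
error in beta units that flags samples poorly described by the reference
(on simulated data it sits close to the observation noise sd, and it
grows with added noise). Projection requires at least 80% of panel sites
to survive the bulk dataset's QC.

## Pseudo-age

The score is the literal weighted sum over clock sites, Σᵢ sᵢ·βᵢ, with sᵢ
the OLS slope of beta on age in days. There is no intercept and no
rescaling to days, so the score is unitless and only its association with
age (and genotype) is interpreted; `fit_clock()` builds synthetic clocks
and real clocks are supplied as a site/slope table. Scoring is linear in
the beta vector and zero-slope sites never change a score.

## Probe-level models

Each probe gets an ordinary least-squares fit of

```
beta ~ genotype + age (categorical, E14.5 reference) + chip + neuronal_prop
```

with genotype coded WT = 0 / HET = 1, so a negative coefficient means
hypomethylated in the mutant. All probes share one design matrix, so the
fits run through a single QR decomposition. The genotype-by-age
interaction is a nested-model F contrast against the model with
`genotype·age`, numerator df = (number of ages − 1); the F statistic is
invariant to the age reference level (verified against per-probe `lm`
fits). Degenerate probes with zero residual variance take P = 1 when the
fitted effect is also zero (keeping downstream aggregation total) and
P → 0 when a non-zero effect is fitted exactly. A design with aliased
columns (e.g. chip confounded with genotype) errors naming the columns
rather than silently dropping them.

DMP calling is strict Bonferroni: threshold α/m, a probe qualifies only
with P strictly below it. The denominator defaults to the number of
probes actually tested (the variable probes), which is the statistically
defensible choice; passing `n_tests` explicitly reproduces the convention
of correcting over the full post-QC site count — with m = 262,086 the
threshold is 1.91 × 10⁻⁷ to three significant figures. Litter is recorded
in the sample sheet but not modelled; designs are assumed balanced across
litters.

## Empirical Brown's method

Gene- and region-level P values combine dependent probe-level tests. For
each probe's data row (the normalised betas across samples, not
residuals — the residual option exists as an argument of interest but raw
rows are the default, matching how the method is used on expression
data), the row is standardised and transformed through its empirical CDF:
wᵢ(s) = −2 ln(Fᵢ(xᵢ(s))) with Fᵢ right-continuous and valued in (0, 1]
via rank/n — the rank convention avoids log(0) and is the choice that
shifts small-sample covariance, hence documented. The Fisher statistic
Ψ = −2Σ ln pᵢ has nominal mean 2k; its variance is estimated as
4k + 2Σᵢ<ⱼ cov(wᵢ, wⱼ) and Ψ/c is referred to χ²_f with
f = 2(2k)²/var and c = var/(4k). When the estimated variance falls at or
below the independence value 4k the method degrades to Fisher exactly;
k = 1 returns the input P unchanged. In the fully dependent limit
(identical rows) the pairwise covariances equal var(w) and the combined P
of k identical tests returns approximately the shared single-test P. The
empirical covariance is used as-is (the Kost–McDermott analytic
approximation is a non-goal).

The motivating property, verified by simulation in the test suite: under
positive dependence (shared-factor rows, correlation 0.7, k = 8, n = 50)
Brown's rejection rate at α = 0.05 stays near nominal while Fisher's
roughly triples.

Gene aggregation groups tested probes by annotated gene (a probe
annotated to several genes contributes to each; the secondary
promoter-only mode keeps only promoter-class probes, using the manifest's
feature column), and adjusts by Bonferroni over genes with at least one
contributing probe.

## DMR calling

Candidate regions are maximal runs of two or more *qualifying* probes —
raw genotype P < 0.05, non-zero effect, common sign — in which every
adjacent pair is spaced strictly less than 1500 bp. "Consecutive" is read
as consecutive among tested probes, so by default an intervening tested
probe that fails to qualify terminates the run: this prevents regions
spanning contradictory evidence. The permissive reading (ignore
non-qualifying probes, measure gaps between qualifying ones) is available
as `skip_nonsignificant = TRUE`. The gap is strict: probes exactly
1500 bp apart break the run. Region P values are Brown-combined over
member probes and Bonferroni-adjusted over the number of candidate
regions found genome-wide — a data-dependent denominator, the literal
reading of adjusting for the regions considered. Region boundaries are
the outermost member-probe positions (1-based inclusive internally,
converted to 0-based half-open on BED export); boundaries are not
extended beyond the probes. Annotation attaches every gene whose body
± 1500 bp overlaps the region (closed-interval arithmetic), so nested
genes (a snoRNA inside its host) each receive the annotation. The caller
is validated against an exhaustive enumeration oracle on randomized toy
manifests.

## Enrichment

The gene universe is the set of genes annotated to at least one variable
probe. Term enrichment fits a logistic regression of DM status on term
membership plus log10 probe density over the whole universe — probe
density spans orders of magnitude, so the log is the natural scale for a
"covarying for probe density" adjustment — and reports the membership
coefficient's exponent as the odds ratio with a two-sided Wald P,
Bonferroni over tested terms; the raw 2×2 odds ratio is always reported
alongside since figures conventionally size points by it. Terms with
fewer than 10 universe genes are excluded. Perfect separation (or an
aliased predictor) does not crash: a small-ridge IRLS refit (λ = 1e-3) is
used and flagged, and a predictor perfectly collinear with a conditioning
covariate reports NA.

Conditional selection of independent terms is greedy: the significant
term with the largest marginal odds ratio (ties by smaller P, then term
id — a deterministic ordering) enters the model as a covariate, remaining
significant terms are refitted conditioning on all entered terms, and a
term is retained while its conditional coefficient stays at unadjusted
P < 0.05 (the conditional criterion is not pinned down by convention, so
it is documented and configurable). Biotype enrichment uses the same
model with the biotype indicator as predictor; conditioning on host-gene
pathways implements the shared-signal adjustment that asks whether, e.g.,
a snoRNA enrichment survives the differential methylation of overlapping
host pathways. Array coverage of a pathway is the proportion of its genes
annotated to at least one variable probe.

Overlap tests between externally derived sets use Fisher's exact test
(conditional-MLE odds ratio, two-sided P). The threshold sweep calls DMPs
at a ladder of P cut-offs and tests overlap with target regions at each,
with Woolf-logit 95% CIs (Haldane 0.5 correction only when a cell is
empty); a threshold yielding no DMPs is skipped with a warning, and a
degenerate background (targets covering all or no probes) reports odds
ratio 1.

## The assay module

The standard curve regresses known concentration on absorbance (≥ 3
standards) and inverts readings through the fitted line. The kinetic rate
ΔC/Δt is the OLS slope of concentration on time over the kinetic window
(34 s grid up to 374 s) — the slope is the standard kinetic-assay
estimator and is robust to single-read noise; `method = "first_last"`
reproduces the two-point version. Net activity is
(rate₋rot − rate₊rot)·D / (protein concentration × loaded volume), which
resolves to mU/μg with the default 0.66 μg/μL × 2 μL loading; the
typeset source formula is ambiguous about the denominator grouping, and
this is the algebra under which the units resolve. The quantity is
antisymmetric in the two series and invariant to a shared absorbance
offset; negative values are allowed (inhibitor-insensitive signal) and
flagged. Group comparisons use a standard two-way ANOVA with pairwise
genotype contrasts per level Šidák-adjusted, 1 − (1 − p)^m.

## The synthetic-data generator

`simulate_dataset()` builds betas as

```
clip[0,1]( w·m_neuron + (1−w)·m_glia + age_effect(age) + δ·[HET]·[planted]
           + clock_slope·age_days + chip_effect + ε )
```

Effects are additive on the beta scale and then clipped — not
logit-scale — because the analysis models normalised betas directly, so
planted effect sizes are interpretable as the model's coefficients. The
defaults are a desk-scale version of the assumed study: 5,000 probes,
2 × 5 × 5 = 50 samples, 8 planted region blocks of 3–8 probes (internal
gaps < 1500 bp; background probes ≥ 1600 bp apart), 50 isolated planted
positions with |δ| = 0.15, two chips with sd 0.01 shifts, categorical age
effects sd 0.02, Gaussian noise sd 0.02 (optionally probe-specific for
stress tests), a 105-site clock with slopes within ±0.002 beta/day, 500
cell-type-discriminatory probes (|Δ| 0.2–0.5), and a true neuronal
proportion of 0.40 + 9 × 10⁻⁴ per day ± 0.03 — a slow compositional
drift of the order reported for cortical development. Roughly 5% of
genes are "hosts" carrying a nested snoRNA gene on shared probes, so
biotype enrichment and its host-pathway conditioning have structure to
find. The generator emits the planted truth (positions, region blocks,
true proportions, clip fraction — under defaults well below 1%) so every
downstream test computes recovery rather than trusting the stages.

What it does **not** emulate: the bimodal marginal distribution of real
array betas, probe-type chemistry differences, spatial correlation of
noise along the chip, litter structure, sex chromosomes beyond a token
fraction, and raw two-channel intensities (detection failures are planted
as counts). Passing tests therefore demonstrate correctness of the
statistics on data satisfying the model's assumptions — calibration,
power and oracle equivalence — not robustness to every artefact of real
beadchip data.

## Problem sizes and determinism

Test and example runs use 500–5,000 probes and 50 samples; a full default
pipeline run completes in a few seconds, and the whole suite (including
twenty seeded null-pipeline runs and the Monte-Carlo calibration checks)
in about a minute. These sizes were chosen so that planted effects at
δ = 0.15 over n = 50 give essentially complete power at the Bonferroni
threshold, while null runs have an expected false-positive count well
below one — the regimes in which the acceptance properties are sharp.
Every stochastic step derives from an explicit integer seed, and pipeline
runs are bit-reproducible under a fixed design.

## Known limitations

- Detection P values and signal intensities are consumed as summaries;
  there is no IDAT-level processing, background correction or dye-bias
  adjustment.
- The deconvolution reference supports any number of cell types, but the
  directional top-k arithmetic is only canonical for two; for more types
  the pre-deduplication selection is 2 × k per type.
- Mixed models (litter, animal) and robust/heteroscedastic standard
  errors are not implemented; the models assume exchangeable residuals.
- Gene sets are flat; no ontology-graph propagation.
- M-value analysis is not provided; everything is on the beta scale.
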