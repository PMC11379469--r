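---
title: "cfdecon: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cfdecon: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfdecon)
```

## The problem

Plasma cell-free DNA (cfDNA) is a pool of fragments released by dying
cells from many tissues, dominated by hematopoietic lineages. Because CpG
methylation is laid down in a cell-type-specific way, the methylation
state of a cfDNA fragment carries the signature of the tissue that shed
it. Given a *reference atlas* — region-level methylated/total CpG counts
for a panel of cell and tissue types — the composition of a cfDNA sample
can be estimated by deconvolution: find non-negative proportions, summing
to one, whose combination of atlas methylation profiles best explains the
sample. Applications include estimating the tumor-derived fraction and
assigning a tissue of origin (TOO) to a cancer signal found in blood.

Whole-genome methylation sequencing of plasma is shallow (a few reads per
CpG), so region-level methylation ratios are noisy in a way that varies
strongly across marker regions, and any practical atlas is incomplete:
real cfDNA contains contributors that are not in the reference. The model
here addresses both.

## The model

Let `D` and `M` be total and methylated CpG-count matrices over `K`
marker regions (a CpG spanned by several reads contributes once per read,
so these are CpG counts, not genomic coverage). Methylation ratios are
`R = M / D`, undefined (masked) where `D = 0`. With `N` cfDNA samples and
`J` atlas entities, the factorization model is

    R_cfdna  ≈  A G,

where `A` (`N x (J + h)`) holds per-sample proportions constrained to the
probability simplex row-wise, and `G` (`(J + h) x K`) holds per-entity
region methylation ratios in `[0, 1]`. The fit minimizes

    L(A, G) = Σ_ik w_ik |R_ik − (AG)_ik|  +  λ Σ_jk v_jk |G_jk − Ratlas_jk|

* `w_ik = D_ik / Σ_k D_ik` are per-sample coverage weights: regions whose
  ratio is estimated from more CpG counts carry proportionally more of
  the objective, so low-coverage (noisy) regions are down-weighted.
  Masked cells get weight zero and cannot influence the fit.
* The second term tethers `G` to the observed atlas ratios: `G` may
  deviate to absorb atlas imperfections (conversion chemistry, tumor
  purity, replicate biases), but deviations are penalized, more strongly
  where the atlas itself is well covered (`v_jk` is the per-row-normalized
  atlas coverage). The L1 form matches the MAE data term, so a constant
  fraction of atlas bias is absorbed without distorting the rest of the
  profile. `λ` defaults to 1.0. The `h` learned unknown rows carry no
  tether, as there is nothing to tether them to; likewise cells where the
  atlas has zero coverage.

### Unknown contributors

With `h > 0`, the atlas is extended by `h` rows learned from the samples
before the joint fit. Each round deconvolves the samples against the
current atlas by non-negative least squares (NNLS), forms residuals
`R − A0 Ratlas`, and initializes the unknown profile per region as the
clipped sum of the coverage-weighted mean reconstruction and the
coverage-weighted mean residual across samples (weights column-normalized
over samples). Because reconstruction plus residual equals the
observation cell-wise, this is the coverage-weighted column mean of
`R_cfdna` — a neutral starting profile that the gradient fit then refines
freely (no tether). The appended row receives pseudo-counts with
per-region total equal to the median across atlas rows (a per-region
median is used rather than a single scalar because a count row needs one
value per region): neutral confidence for a learned row. A small seeded
jitter (±0.01) is added so that the configuration seed is the single
source of randomness in the whole algorithm.

After fitting, entities are re-identified by Pearson correlation between
rows of `G` and of `Ratlas`, solved as an optimal one-to-one bipartite
assignment (a Hungarian/shortest-augmenting-path solver implemented in
the package); unmatched `G` rows become `unknown_1`, `unknown_2`, ….
Constant rows have undefined correlation and are assigned similarity 0.

### Optimization

`A` is parameterized through a row-wise normalized exponential (softmax)
and `G` through a logistic map, making the problem unconstrained — the
simplex and `[0,1]` constraints hold exactly at every iterate with no
projection. Subgradients of the L1 terms are propagated analytically and
the free parameters are updated with Adam (learning rate 0.01, standard
moment constants 0.9/0.999, at most 5000 iterations). `A` starts at the
NNLS solution (the softmax of its logarithm reproduces it exactly) and
`G` at the observed atlas ratios, so the start is already the classical
reference-based estimate; the fit stops early when the objective improves
by less than `1e-6` over a 100-iteration window, and the returned
parameters are the best iterate seen, so the final objective never
exceeds the initial one. On noiseless, exactly representable mixtures the
initial residual is zero, its subgradient vanishes, and the optimizer
correctly stays at the exact solution.

### Numerical choices and degenerate inputs

* Zero-coverage atlas cells are imputed with the cross-entity region mean
  (0.5 if no entity covers the region) for initialization and NNLS; their
  tether weight is zero.
* An all-zero NNLS solution yields uniform proportions — defined behavior
  on degenerate samples.
* A sample with zero coverage at every region is an error naming the
  sample.
* Softmax initialization uses `log(A0 + 1e-8)`; the logistic map clips
  ratios to `[1e-6, 1 − 1e-6]` before the logit.

## Atlas construction

Marker regions are selected one-versus-all: a CpG is a differentially
methylated site (DMS) for an entity when its methylation ratio differs by
at least 30% (margin 0.30) from **each** other entity — not the pooled
rest, which would let a single aberrant entity hide behind the average (a
pooled-rest switch is provided). Direction is hyper- or hypomethylated
according to whether the target sits above or below all others. Sites are
chained downstream into regions: consecutive same-entity, same-direction
sites at most 500 bp apart form one maximal region, kept when it has at
least 4 CpGs and spans at least a configurable minimum length (50, 100 or
250 bp; default 100). The gap rule is applied between consecutive sites
rather than over the whole window, which keeps regions contiguous. When
counting, all CpGs inside the final interval contribute, including
non-DMS CpGs lying between chained sites — region-level validity is then
re-established statistically.

Each candidate region is scored with a two-sided Fisher exact test on the
2x2 table of methylated/unmethylated region-summed counts in the target
entity versus all remaining entities pooled; all-zero tables score 1 by
convention. The p-value is computed directly from the conditional
hypergeometric distribution over the fixed margins (vectorized, with the
same `1 + 1e-7` relative tolerance as `stats::fisher.test`, against which
it is cross-checked in the tests); this keeps exhaustive scans over
hundreds of thousands of tables fast. Sidedness is configurable;
two-sided is the default. Marker lists come in three modes: *all*
candidates, *significant* (Bonferroni-corrected p ≤ 0.001, divisor =
number of candidates entering the test), and *balanced* (the 23 most
significant regions per entity, ties broken by longer region then by
coordinate, for deterministic output).

Replicates of one entity are aggregated by summing per-CpG counts after
removing highly variant CpGs — those whose ratio range across replicates
(among replicates with total ≥ 5) exceeds 0.25. The 0.25/5 values are
exposed in `atlas_config()`; they are a package choice of what "highly
variant" means. A "full" atlas keeps one row per replicate with the
replicate-to-tissue mapping retained; the "condensed" atlas has one row
per tissue.

## The simulator

Synthetic studies use `make_synthetic_atlas()`: each entity owns a block
of discriminative regions (ratio ≈ 0.9 for the owner, ≈ 0.1 elsewhere,
each with s.d. 0.03) plus shared background regions, with counts drawn
binomially at Poisson depth. Mixtures draw proportions from a symmetric
Dirichlet(1) by default (configurable), totals from Poisson at a mean
depth, and methylated counts binomially given the expected mixed ratio —
so count noise scales correctly with coverage. Heteroscedastic coverage
(log-normal per-region multipliers, sdlog 1.2, giving order-of-magnitude
spread) exercises the coverage weighting. An unknown contributor is
injected as an extra entity with Uniform(0,1) ratios per region mixed in
at 5–30% per sample. Dilution series mix a tumor profile into a healthy
background at 12 fractions from 50% down to 0.1% (the grid is a
reconstruction: only the endpoints and the count are conventionally
fixed), 10 replicates each, at a mean depth of 6 — the shallow regime in
which detection limits are meaningful.

A `noise = "none"` mode returns exact expected counts `M = rD`
(real-valued) for oracle constructions: integer rounding at moderate
depth would itself inject ratio noise of order `1/(2D)` and confound
exact-recovery checks at tolerance `1e-3`.

What the simulator does *not* emulate: fragment-level effects
(fragmentomics, read-length coupling), conversion chemistry biases,
copy-number-driven coverage structure, correlated noise between nearby
regions, and real atlas misspecification beyond binomial sampling.
Passing the synthetic checks therefore demonstrates correctness of the
algorithm under its own statistical assumptions, not clinical
performance.

## Evaluation

Pearson correlation (constant input flagged as 0), MSE, accuracy and
Cohen's kappa follow their standard definitions. TOO calling normalizes
each cancer entity's estimated proportion by its maximum across healthy
controls, calls the argmax over cancer entities (ties: raw value, then
lexicographic), returns `"normal"` iff every raw cancer contribution is
zero, and groups subtypes (cervical adeno/squamous → CERCA, colon/rectum
→ COLCA) *after* the argmax, so a subtype-level win still counts for its
group. A zero control maximum with a positive case value maps to `Inf` —
detected above any finite competitor. The limit of detection scans a
dilution series from the highest fraction down: detection holds while the
true entity's estimate is positive and it is the top cancer contributor;
the LOD of a replicate is the smallest fraction of the unbroken run from
the top, and the summary is the mean over replicates (which is how
off-grid values arise from a discrete grid). Blood proportions can be
collapsed to complete-blood-count classes (lymphocytes = B + CD4+ T +
CD8+ T + NK; erythroblasts excluded from the three-class
renormalization, as a CBC differential does not report them).

## Problem sizes used in the checks

The packaged tests and the acceptance script run at desk scale, chosen to
make each property measurable with margin: exact recovery on a
13-entity, 500-region, 100-sample noiseless design; the weighting
comparison over 20 seeded repeats of 100 samples on 299 regions at mean
depth 30 with ≥10x coverage spread; leave-one-out unknown recovery at
depth 200 on 500 regions with the held-out entity at 20–40%; dilution
series of 12 fractions x 10 replicates at 6X against a 6-entity atlas.
The Fisher implementation is verified against full hypergeometric
enumeration on every 2x2 table with row margins up to 30.

## Known limitations

* The unknown-row estimate absorbs part of the signal of entities
  correlated with it, so proportions of unknowns are upward-biased even
  when their profile is recovered well; this is intrinsic to learning a
  free row and mirrors the sensitivity/typing trade-off seen when
  modeling unknowns.
* The L1 objective is piecewise linear; Adam oscillates near optima
  rather than converging monotonically, which is why the best iterate is
  returned and descent is asserted, not proven.
* One-versus-all marker selection becomes more conservative as entities
  are added — the number of markers can only shrink.
* Count matrices are dense in memory; genome-scale per-CpG inputs are
  streamed through `read_bedgraph()` per entity, but region counts for
  very large atlases (> ~10^6 regions) would need chunking.
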