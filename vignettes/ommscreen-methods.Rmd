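---
title: "ommscreen: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ommscreen: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ommscreen` implements the quantitative core of an eye-based genetic
modifier screen: an image-derived score of ommatidial lattice disorder, a
two-way-ANOVA classifier of two-hit epistasis, parametric gene-set
enrichment with a cross-model overlap test, and connector-gene analysis on
functional networks. This vignette records the models, the parameters that
matter, the numerical choices, and what the synthetic validation does and
does not establish.

## The phenotypic score

The compound eye packs ommatidia on a hexagonal lattice; developmental
insults disorder it. Scoring proceeds in three steps.

**Detection.** The image is band-pass filtered with a difference of
Gaussians at scales 0.2 and 0.6 times the expected facet spacing. The
narrow scale suppresses pixel noise; the wide scale removes illumination
gradients, so detection needs no global threshold tuning. Candidate centres
are local maxima of the band-passed image above an intensity quantile
(default 0.95), thinned so that no two survivors lie within 0.6 spacings
(stronger peaks win), then refined to sub-pixel positions by three-point
Gaussian interpolation of the narrow-scale profile along each axis — exact
for a Gaussian peak, and in practice accurate to a few hundredths of a
pixel on clean synthetic facets. A constant image returns zero centres
rather than an error, since an empty field is a legitimate detection
result. The minimum supported spacing is 3 px; below that the two filter
scales collapse onto each other.

**Local geometry.** Each facet's k = min(6, N−1) nearest neighbours define
vector lengths l_j and azimuths; ties in distance (exact in square-lattice
test fixtures) are broken by smaller azimuth, then by point index, after
rounding distances to 9 decimals so floating-point noise cannot hide a
geometric tie. Angular gaps Δθ_j between azimuth-sorted neighbours always
sum to 360°. Facets on the convex hull of the centre set — or within 0.6 of
the median nearest-neighbour spacing of it — are flagged non-interior. The
margin matters: a convex-hull *vertex* test alone misses facets on straight
boundary rows (collinear points are on the hull polygon but are not its
vertices) and the half-spacing zig-zag columns of an offset lattice, and
those truncated neighbourhoods would dominate the score of a small image.
0.6 median spacings excludes both while keeping true interior facets, whose
hull distance is at least ~0.87 spacings on a hexagonal lattice.

**Aggregation.** Each interior facet with at least two neighbours
contributes

$$d_i = w_L\,\frac{\mathrm{sd}(l_j)}{\mathrm{mean}(l_j)}
      + w_A\,\frac{1}{k_i}\sum_j \frac{|\Delta\theta_j - 60|}{60},
\qquad S = 100\,\overline{d_i}.$$

Both components are dimensionless, so S is invariant under rigid motion and
uniform scaling of the centre set, and S = 0 exactly on any perfect
hexagonal lattice — two properties the tests verify directly. The default
weights w_L = w_A = 1 treat length and angular disorder equally; no claim
of numerical parity with any particular scoring software is made, and the
score is validated instead by its zero-lattice, invariance, and
jitter-monotonicity properties. The detected facet count enters only
through the interior-mean normalisation; missing or fused facets raise S
through the distorted neighbour geometry they leave behind, a deliberate
simplification.

## The epistasis classifier

A two-hit experiment measures replicate severity scores (image score S or
manual rank; higher = more severe) for four genotypes: control, A one-hit,
B one-hit, A+B two-hit. This is a 2×2 factorial in "A knocked down" ×
"B knocked down", each effect with one degree of freedom. Balanced designs
use the classical cell-mean decomposition in closed form; unbalanced
designs use type-II sums of squares (via `car::Anova`), chosen because the
two factors have no a-priori ordering. Zero residual variance (all
replicates identical) flags F as undefined rather than dividing by zero.

With Δ1 = mean(AB) − mean(A) and Δ2 = mean(B) − mean(control), the
interaction contrast Δ1 − Δ2 is symmetric in the two genes. The decision
tree at level α (default 0.05 per pair):

1. interaction significant → **suppressor** if the contrast is negative,
   **enhancer** if positive;
2. otherwise B main effect significant → **additive**;
3. otherwise → **none**.

Keying additive-vs-none to the B main effect reads the additive case as "B
shifts the phenotype equally in both backgrounds". A suppressor is
additionally flagged **full rescue** when the two-hit scores are
indistinguishable from control (two-sided Mann–Whitney, p ≥ rescue_alpha)
while the A one-hit differs from control. Mann–Whitney comparisons are
two-sided by default with a one-sided option, since screen designs differ
in whether the rescue direction is pre-specified. No cross-pair correction
is applied by default (screens are typically validated per pair with
independent RNAi lines); Benjamini–Hochberg across interaction p-values is
available, and can only move calls toward none/additive. The classifier is
invariant to adding a constant to all scores and to positive rescaling, and
suppressor/enhancer labels flip when scores are negated — the
severity-direction contract.

The reported F and p are per-pair at the stated df; no fixed F cutoff is
hard-coded, because a critical value is meaningless without the residual
degrees of freedom, which vary by design.

## Enrichment and overlap

**DE filter.** A gene is differentially expressed when |log2FC| > 1 and
FDR < 0.05, both strict; a gene exactly at either boundary is excluded.
DE model fitting itself is out of scope — the pipeline consumes the tabular
output of upstream tools.

**PAGE.** For a gene set with m measured members, mean member log2FC S_m,
and background mean μ and sample SD δ over all measured genes,

$$Z = \frac{(S_m - \mu)\sqrt{m}}{\delta}.$$

The √m factor is the central-limit standardisation of a mean of m values
and is on by default; `sqrt_m = FALSE` gives the plain standardised set
mean for the literal-prose variant of the procedure. δ uses the n−1
denominator, matching reference implementations of the parametric method.
Sets with m ≥ 500 are excluded as too general, sets with m < 2 as
unstable. Two-sided normal p-values are BH-corrected across the retained
terms; the significance flag defaults to adjusted p < 0.01. Under a null
table the Z-scores are standard normal up to a finite-population factor
√((N−m)/(N−1)), negligible for m ≪ N; the test suite checks normality by
Kolmogorov–Smirnov at N = 5000, 1000 random terms of 20–100 genes.

**Cross-model overlap.** Given per-model DE sets restricted to an
annotation universe (e.g. cell-proliferation genes), the statistic is the
number of universe genes DE in at least k models (k = 2, 3 by default).
The null redraws each model's set uniformly without replacement from the
universe at its observed size — set sizes are preserved, coordination is
destroyed; the universe is the resampling pool because the statistic counts
universe genes. The estimator p = (1 + #{null ≥ observed})/(n_perm + 1)
never returns zero. Two consequences are worth recording. First, when the
sets *are* the full universe every permutation reproduces the maximum, so p
is 1, not 1/(n_perm+1); the maximal-statistic property (p = 1/(n_perm+1))
holds for identical sets that are proper subsets, at k equal to the number
of models. Second, the ≥2 count rewards *pairwise* spread: coordinated
sharing across all models concentrates membership mass into high
multiplicities, so planted sharing only exceeds the size-preserving null
when sets are sparse in the universe (roughly U > 15(2s − c) for set size
s and shared count c at six models). The packaged study conditions — six
models, 40 DE genes per model, shared fraction 0.4, a measured universe of
4000 genes — satisfy this comfortably, and the planted-overlap check then
rejects at p < 0.001 with 9999 permutations. Null uniformity of the
empirical p is checked by KS over 500 replications at conditions where the
statistic has wide support (six sets of 400 in a universe of 4000,
399 permutations); with ties the add-one estimator is conservative, which
is the standard and safe direction.

**Homolog mapping** resolves many-to-many fly→human tables either by
keeping all pairs (default) or best score per fly gene; unmapped genes are
dropped and counted, never silently lost. The optional
`set_score_ttest` compares a user-supplied per-gene score between set
members and non-members (one-sided Welch); which score to use is left to
the caller because set-level enrichment of this kind is only meaningful for
an explicitly chosen quantity.

## Connector genes

Seed genes are mapped onto an undirected network read from a weighted edge
list. Edges below an optional weight cutoff are removed; the surviving
graph is then treated as **unweighted**, which makes "number of shortest
paths through an edge" well-defined and tie-free. For each seed pair, a
breadth-first search from both ends gives distances and geodesic counts
(Brandes-style predecessor counting); a node v lies on an s–t geodesic iff
d(s,v) + d(v,t) = d(s,t) and then carries σ_s(v)·σ_t(v) of the pair's
σ_s(t) geodesics, and an edge (u,v) carries σ_s(u)·σ_t(v) when
d(s,u) + 1 + d(t,v) = d(s,t). Connectors are the non-seed nodes on at
least one geodesic of at least one pair; per-edge criticality c_e sums the
(pair, geodesic) memberships, and Σ_e c_e equals Σ_pairs length × count,
an identity the tests assert. Explicit path enumeration appears only in
the test oracle, which must agree exactly with the dynamic program on
random graphs up to 30 nodes. Disconnected seed pairs are reported, not
fatal; fewer than two mapped seeds is an error.

Connector enrichment uses a one-sided (greater) Fisher's exact test with
the non-seed network nodes as default background — the sampling frame
connectors are drawn from, not the whole genome — and connectors excluded
from the background margin. `random_seed_control` re-runs the whole
procedure for random seed sets drawn from a stated pool, giving the null
enrichment distribution against which a real seed set is judged; with
uniformly placed annotations its median odds ratio is near 1.

## Synthetic data: what it emulates, and what it does not

The generators produce every input with known ground truth and one RNG
stream per object (a child seed derived from the master seed and a tag), so
adding one generated object never perturbs another, and identical seeds
give byte-identical outputs.

* **Eye images**: offset-row hexagonal packing (odd rows shifted by half a
  spacing, row pitch spacing·√3/2 — true ommatidial geometry), isotropic
  Gaussian jitter of SD σ per axis, independent dropout, pairwise fusion
  (a sampled site merges with its nearest surviving neighbour into one blob
  at the midpoint; a site whose partner is already consumed is skipped),
  Gaussian facet profiles of SD radius/2 truncated at 3 SD, additive
  Gaussian background noise, intensities clipped to [0, 1]. Defaults:
  spacing 10 px, radius 3 px, 12×12 facets for score calibration.
* **Score tables**: Gaussian replicates around the 2×2 cell means
  control, +effect_a, +effect_b, +effect_a+effect_b+interaction_shift;
  full-rescue truths pin the two-hit mean at control. Planted screens use
  one-hit effects of 3–4.5 within-SDs and interaction contrasts of 3
  within-SDs at 12 replicates — effect sizes where a competent assay should
  essentially always call the right class, so recovery failures indicate
  implementation faults, not power limits.
* **Expression studies**: null genes N(0, 0.5²) log2FC with FDR above
  0.05; planted DE genes |log2FC| in 1.2–3 with FDR below 0.05; a shared
  DE pool across models at the stated fraction; each model's own target
  gene at log2FC −1.05 — the ~50% transcript reduction RNAi typically
  achieves, placed just past the strict two-fold cut so the knockdown is
  itself called DE. FDR values are assigned, not fitted: DE model fitting
  is upstream of this pipeline.
* **Networks**: Erdős–Rényi or small-world graphs with Uniform(0,1] edge
  weights, giant component taken (and flagged) if disconnected, seeds
  sampled without replacement, annotations sampled per node.

What the generators do **not** emulate: necrotic patches, glossy eyes,
pigment loss, and overall eye size (features outside lattice disorder);
realistic optics or illumination; correlated biological replicates;
count-level expression noise and its FDR estimation; the degree structure
of real functional networks. Passing tests therefore establish the
*correctness and calibration* of the algorithms under their stated models,
not their field performance on microscope images or published networks.

## Validation strategy and problem sizes

The suite checks, with fixed seeds throughout: S < 1 on detected perfect
lattices and strict monotone mean S over σ ∈ {0, 0.05, 0.15, 0.30}×spacing
(50 images per level, 12×12 facets); detection recall and precision ≥ 0.98
at 5% dropout with background noise SD 0.05; ≥ 90% class recovery on 40
planted pairs and interaction-test size within [0.035, 0.065] over 2000
additive-null simulations at α = 0.05; ANOVA agreement with a brute-force
least-squares oracle to 10⁻⁶ relative on 500 random balanced and unbalanced
tables; the PAGE worked example Z = 0.54772 to five decimals, the exact
all-genes zero, and null KS calibration; BH equality with the step-up
definition on 1000 random vectors; the overlap test's extremes and null
uniformity; exact connector/criticality agreement with exhaustive
enumeration on 100 random graphs (n ≤ 30) and the hypergeometric point
mass 1/C(20,5); and a full pipeline run from the bundled YAML config that
reproduces its tables byte-for-byte under a fixed master seed. These sizes
keep the whole suite around a minute on one CPU while leaving the
statistical checks comfortable margins. `scripts/acceptance.R` recomputes
the same quantities from scratch and writes them as JSON.

## Known limitations

* Detection assumes roughly uniform facet spacing; strongly curved eye
  surfaces (perspective foreshortening at the image rim) would need a
  spatially varying expected spacing.
* The score weights length and angular disorder equally; other weightings
  are exposed but not calibrated against human severity ranking.
* Very high jitter (σ ≳ 0.3 spacing) makes neighbouring facets collide;
  detection then under-counts and S saturates — the score orders moderate
  disorder well but compresses extreme phenotypes.
* The overlap test's power depends on set sparsity in the universe (see
  above); with dense sets, coordinated sharing is better probed at k equal
  to the model count.
* `full_rescue` uses a non-significance criterion and therefore inherits
  the usual caveat that absence of evidence at small n is weak evidence of
  absence.
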