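---
title: "Retinal microvascular parameters and cognitive-risk modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal microvascular parameters and cognitive-risk modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retmorph)
```

`retmorph` measures retinal microvascular parameters (RMPs) from
artery/vein-labelled segmentation masks and models their association with
cognitive impairment. This vignette is the package's account of the
science: the estimators, their assumptions, the tunable parameters, what
the synthetic generators do and do not emulate, and the numerical choices
behind the implementation.

## Coordinate and unit conventions

Images are integer matrices indexed `(row, col)`, 1-based, origin top-left.
All distances are in pixels between pixel centres; `pixel_scale` (units per
pixel, default 1) converts calibres to physical units when the acquisition
geometry is known. A `labeled_vessel_mask` assigns each pixel exactly one
label: 0 background, 1 artery, 2 vein.

## The measurement zone

Vessel calibres are summarized in *zone B*, the standard annulus for
caliber protocols: from 0.5 to 1.0 disc diameters away from the optic-disc
**margin**, i.e. radii `D/2 + 0.5·D` to `D/2 + D` from the disc centre for
disc diameter `D`. The phrase "0.5-to-1 disc diameter surrounding the
disc" is ambiguous between the margin and centre conventions; we adopt the
margin convention because it is the established one behind CRAE/CRVE, and
expose the bounds (`inner_dd`, `outer_dd` of `zone_b()`) so the centre
convention is one argument away.

## Skeletonization and vessel width

Each class is thinned to a one-pixel-wide centreline by Zhang–Suen
morphological thinning (8-connected), implemented in C++. Zhang–Suen can
leave 2×2 foreground blocks at staircase joints and crossings; a cleanup
pass removes block pixels that are *simple points* — their 8-neighbours
remain one 8-connected component without them. We test geometric
properties of the skeleton (subset of the source class, strict thinness,
idempotence on curves, midline position on rectangles) rather than any
byte-exact reference skeleton, since all topology-preserving thinnings are
acceptable here.

Skeleton length is geodesic: each 8-adjacency between skeleton pixels
counts once, 1 for orthogonal and √2 for diagonal steps; an isolated pixel
counts 1. Raw pixel counting would under-measure oblique curves by up to
29%.

Local vessel width at a centreline pixel is read from the Euclidean
distance transform (EDT) of the class foreground (EBImage's `distmap`).
Three corrections make this estimator accurate to well under half a pixel
on ideal ribbons and within 10% on synthetic trees:

* **Boundary correction.** The EDT returns the distance to the nearest
  *background pixel centre*; the distance to the vessel *boundary* is half
  a pixel less, so width = `2·EDT − 1`. Without this, a width-7 ribbon
  reads 8.
* **Ridge correction.** Thinning can place the centreline up to ~1 px off
  the true medial ridge on oblique vessels, under-reading the EDT; each
  skeleton pixel therefore takes the maximum EDT over its 3×3
  neighbourhood.
* **Junction trimming.** Adjacent to a bifurcation the EDT reflects the
  junction blob, not the branch; width readings at a path's ends exceeding
  1.15× the path median are dropped from the width profile.

The zone-restricted skeleton is split into maximal branch-point-free paths
(a branch point has ≥ 3 skeleton neighbours); paths shorter than
`min_path_length` (default 10 px) are discarded as thinning spurs. Output
ordering is deterministic: descending mean width, then centroid.

**Global width** is simpler and deliberately un-corrected: whole-image
class area divided by skeleton length. Thinning retracts roughly half a
vessel width from each free end, so on short thick segments the quotient
overestimates width; on realistic trees (total length ≫ calibre) the
effect is negligible, and on test ribbons we keep length ≫ width².

## Caliber summaries

CRAE and CRVE use the revised Knudtson–Hubbard reduction with branching
coefficients 0.88 (arterioles) and 0.95 (venules): take the six largest
zone-B calibres, then repeatedly combine the current largest and smallest
via `c·√(w₁² + w₂²)`, reinserting the result, until one value remains. The
coefficients are arguments, not hard-wired literals. A `use_all` switch
admits every zone-B vessel instead of the big six — the two readings of
"all arterioles and venules" — with the big six as the default because it
is how the named formula is defined. The reduction is permutation
invariant, homogeneous of degree 1, and monotone in each input; the test
suite checks all three plus exact agreement with an independently written
brute-force pairing. AVR = CRAE/CRVE; a degenerate CRAE of zero yields AVR
0 with a warning rather than an error.

## Fractal dimension

FD is plain box counting on the **centreline tracings** (union of artery
and vein skeletons), not the filled mask — calibre would otherwise leak
into the complexity estimate; a flag recovers the filled-mask variant for
sensitivity analysis. The lattice is anchored at the image origin with no
grid-offset averaging, partial edge boxes count, and the default size
ladder is powers of 2 from 2 to a quarter of the smaller image dimension
(7 ladder points at 1024²). FD is the OLS slope of `log N` against
`log(1/s)`, so space-filling patterns score higher; `r²` of the fit is
reported as a quality flag. Calibration on analytic fixtures: a straight
line fits 1.0 and a filled square 2.0 essentially exactly; the Sierpinski
gasket at full resolution (`size = 2^depth`) fits log 3/log 2 to machine
precision, and the Koch curve at depth 5 lands within 0.04 of log 4/log 3.
Absolute FD values depend on resolution and ladder — comparisons are only
meaningful within a fixed imaging protocol.

## Synthetic vascular trees

`generate_vessel_tree()` emulates *segmented* fundus vasculature — the
input of this pipeline — not fundus photographs. Artery/vein root pairs
sprout from the disc margin at interleaved angles and bifurcate outward;
at each bifurcation child widths satisfy Murray's law
`w_parent^m = w₁^m + w₂^m` exactly (default exponent m = 3), with the
split fraction drawn from `branch_asymmetry` (default 0.40–0.60; set
`c(0.5, 0.5)` for symmetric branching). Widths are constant within a
segment, giving piecewise-constant ground truth; rasterization is binary
(a pixel is foreground iff its centre lies within width/2 of the
centreline), so width recovery is analytically checkable. Veins are drawn
after arteries, so the vein label wins at crossings while ground truth
records both — mirroring real AV crossings under a one-label-per-pixel
raster. A spec whose worst-case radial extent (disc radius + (depth+1) ×
max segment length) exceeds the disc's clearance fails loudly rather than
truncating branches.

Defaults: 1024² image, 150 px disc left-of-centre at (512, 420), four
root pairs (the four arcades), root calibres 14 px (artery) / 18 px
(vein), four bifurcation levels, segments 30–60 px. These were fixed once
as a plausible disc-centred geometry; the source study does not describe
its image geometry, so fixture geometry is a free choice.

What the generator does **not** emulate: photometric texture, pathology,
tortuosity, calibre taper within segments, and vessel crossings with
preserved continuity. Consequently, passing width-recovery tests shows the
estimator is correct on clean geometry; it does not certify performance on
noisy clinical segmentations.

## Cohort simulation

`simulate_cohort()` draws the class label first (fixed class sizes,
default 491 impaired / 417 unimpaired), then continuous variables from
class-conditional Gaussians truncated at physical bounds (age ∈ [23, 83],
BMI > 10, calibres > 0) and binary variables from class prevalences. MoCA
is integer-valued on 0–30 and resampled (bounded retries) until consistent
with its class (impaired < 26 ≤ unimpaired), so `ci_label ⇔ moca < 26`
holds on every row; an infeasible specification errors rather than loops.
Variables are independent *within class* because only marginal summaries
are available to parameterize them; between-class mean gaps induce the
marginal correlation structure. The analytic point-biserial correlation
implied by the spec, `r = Δμ·√(pq) / σ_total` with
`σ_total² = p·σ₁² + q·σ₀² + pq·Δμ²`, is exposed
(`point_biserial_check()`) as a closed-form oracle for the correlation
stage. One deliberate consequence of the MoCA class-consistency rule: the
truncation shifts the impaired-class MoCA mean ~2.6% below its nominal
value; all other class-conditional means converge to their targets within
1% at large n.

Non-model columns (smoking, alcohol, CSVD score) are simulated by the
same mechanism but never enter the classifiers, mirroring the defined
model-input list. The simulator cannot, by construction, reproduce
within-class dependence (e.g. age–hypertension correlation), so classifier
performance on it reflects marginal separations only.

## Statistics

Continuous two-group comparisons use Student's t (equal variances) when
both groups pass a Shapiro–Wilk screen at α = 0.05 (on the first 5000
values; Shapiro–Wilk is undefined beyond that), Mann–Whitney U otherwise;
both are always reported side by side so the selection rule is auditable.
Binary variables use chi-squared without continuity correction (a
proportional table then scores exactly 0). Pearson correlations against
cognition default to coding 1 = *unimpaired*, under which variables that
are higher in healthy subjects (FD, CRAE) correlate positively — the
coding is an explicit argument (`"healthy"`, `"impaired"`, `"moca"`)
because published sign conventions for such screens are often ambiguous.
Raw p-values are the primary report (matching the P < 0.05 convention of
the application field); Benjamini–Hochberg adjusted values are emitted
alongside for transparency.

ROC curves place thresholds midway between consecutive distinct scores
with ±∞ sentinels. AUC is the trapezoid over the (FPR, TPR) polyline and
is cross-checked internally against the tie-corrected rank statistic
U/(n₁n₀) (they agree to 1e-12 by construction; the suite verifies this on
random tied instances). The Youden cut-off maximizes sens + spec − 1;
ties break toward higher sensitivity, then the lower threshold. One
property worth stating precisely: flipping the `direction` argument alone
complements the AUC but does *not* preserve the optimal Youden index —
a marker that discriminates in one direction is a poor classifier in the
other. J is preserved when direction and labels are flipped together
(the complementary, equivalent problem), and that is the invariant the
tests assert.

## The random forest

The classifier is implemented from its defining mechanism: each of
`n_trees` (default 500) trees grows on a bootstrap resample; each node
searches a fresh random subset of `mtry = ⌈√p⌉` features for the
Gini-optimal axis-aligned split, with thresholds at midpoints between
consecutive distinct values, at least `min_leaf = 5` samples per child,
and unlimited depth; impurity ties break toward the lower feature index,
then the lower threshold, making training deterministic given the seed
(all randomness flows through R's RNG). Prediction is the majority of
tree votes, with the vote fraction as a score; a 0.5 tie is called
positive, documented. Importances are cumulative weighted impurity
decreases, normalized to sum to 1. Setting `bootstrap = FALSE` makes a
one-tree forest an exhaustive-search CART, which the suite matches
against an independently written oracle; the default honours the
bootstrap contract (verified via the recorded in-bag multiplicities). The
hyperparameters are conventional defaults — the application names only
the algorithm family — and all are arguments.

`split_cohort()` is stratified ~4:1 with optional majority-class
undersampling of the *training fold only* to ~1:1 (the test fold keeps
cohort prevalence). `compare_models()` trains the combined (12-feature)
and physiological-only (6-feature) forests on identical folds per seed
and reports paired test AUCs. On the default simulated cohort the
combined model wins in essentially every replicate, with mean AUCs around
0.78 vs 0.70 — the qualitative ordering is the transportable finding; the
absolute values depend on the simulator's marginal-only structure.

## Problem sizes and runtimes

The shipped checks use sizes chosen to exercise each property at
convincing scale on a single CPU: 512²–729² fractal fixtures; 100 random
64² masks for the box-count oracle; 1000 random sextets for the caliber
oracle; 600 px test ribbons; 200 random ROC instances and n = 2000 for
the binormal check; 400-row planted-signal datasets with 20 permutation
seeds; 10⁵ subjects per class for simulator fidelity and 50 seeds at
n = 908 for the point-biserial comparison; 25 paired replicates for the
model comparison; and a 50-eye demo at the full 1024² default geometry,
run twice to confirm byte-for-byte reproducibility of every artefact.

## Known limitations

* Widths below ~3 px are quantization-dominated; the generator stops
  branches below 1 px calibre, and sub-pixel centreline fitting is out of
  scope.
* Vessels are not tracked across crossings; a crossing can split a
  skeleton path, and crossing-distorted stubs are filtered only by the
  minimum path length.
* FD values are resolution- and ladder-dependent; only within-protocol
  comparisons are meaningful.
* The cohort simulator reproduces marginals, not joint structure; it
  validates machinery, not clinical effect sizes.
* The annulus convention (margin vs centre) materially changes CRAE/CRVE;
  it is configurable and must be reported alongside any measurement.
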