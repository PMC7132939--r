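---
title: "Quantifying organelles in volume EM: models, estimators and design choices"
author: "mvbquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying organelles in volume EM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvbquant)
```

## The problem

Multivesicular bodies (MVBs) and similar membrane-bound organelles lack
reliable light-microscopy markers, so their density, size and spatial
organisation in neural tissue are measured on serial-section electron
microscopy volumes (FIB-SEM): stacks of aligned 2D images with fine
in-plane resolution (a few nm per pixel) and coarser section thickness
(typically 20 nm). After segmentation, each organelle is a labeled voxel
component with a centroid, a volume, a cortical layer, a subcellular
compartment (dendrite, excitatory axon, inhibitory axon, or a process
with no synapse in the imaged volume), and morphology flags (docked on a
mitochondrion, tubular protrusions, clathrin coat).

`mvbquant` implements the quantitative machinery such a study needs —
morphometry, stereology, size-distribution fitting, compartment
concentration analysis, and 3D spatial statistics — together with a
synthetic-data generator whose parameters are known exactly, so every
estimator in the package is validated by parameter recovery rather than
by eyeballing.

## The generative model behind the synthetic data

The generator composes four ingredients, each of which mirrors a
well-established empirical description of cortical neuropil:

* **Positions.** Organelle centroids follow either a homogeneous Poisson
  process (complete spatial randomness, CSR) at intensity
  $\lambda$ objects/µm³, or a Thomas cluster process: Poisson parents of
  intensity $\kappa$, each with a Poisson($\mu_c$) number of offspring
  displaced by an isotropic Gaussian of standard deviation
  $\sigma_c$. The effective intensity of the Thomas process is
  $\kappa\mu_c$. Parents are simulated in a window expanded by
  $4\sigma_c$ on every face so that clusters straddling the boundary are
  not truncated. The default intensity is 0.21 objects/µm³, the density
  characteristic of the reference tissue.
* **Sizes.** Volumes are log-normal with natural-log-scale parameters
  $\mu = -5.1375$ and $\sigma = 0.9173$ (median
  $e^{\mu} \approx 5.9\times10^{-3}$ µm³, mean
  $e^{\mu+\sigma^2/2} \approx 8.9\times10^{-3}$ µm³).
* **Compartments.** Multinomial with probabilities 0.3914 (dendrite),
  0.1587 (excitatory axon), 0.0229 (inhibitory axon) and 0.4270
  (nonsynaptic).
* **Flags.** Independent Bernoulli marginals: 18.16 % docked, 6.66 %
  tubular, 19.74 % clathrin-coated.

A multi-stack experiment draws 29 cubic windows whose volumes are
uniform between 167.39 and 444.11 µm³ and assigns cortical layers in the
proportion 3 : 4 : 10 : 5 : 3 : 4 (layers I–VI). One global seed derives
deterministic per-stack substreams, so a 29-stack experiment reproduces
stack-by-stack.

What the generator deliberately does **not** emulate: electron-optics
noise, membrane appearance, intraluminal vesicles, synapse geometry, or
any spatial interaction between size and position (sizes, compartments
and flags are independent of location). Passing the package's
recovery tests therefore certifies the estimators under these idealised
conditions; it does not certify a segmentation pipeline, and real tissue
may violate the independence assumptions.

## Morphometry

`measureObjects()` trusts labels as object identity (segmentation is
upstream): the volume of a label is its voxel count times the
anisotropic voxel volume $v_x v_y v_z$, and the centroid is the
unweighted mean of voxel-center positions (label images carry no
intensity to weight by). Voxel centers are mapped to physical
micrometres as $\mathrm{origin} + (i - \tfrac12)\,v$, which makes
raster/physical round-tripping unambiguous.

Tissue shrinks during osmication and resin embedding. Shrinkage factors
are after/before ratios — linear 0.90, hence area $0.90^2 = 0.81$ and
volume $0.90^3 \approx 0.73$ — and `applyShrinkage()` *divides* by the
factor, inflating post-processing measurements back to tissue scale.
Frame volumes and object volumes are corrected with the same factor so
densities stay coherent.

`renderLabelStack()` closes the loop for testing: spheres (ellipsoids in
voxel space) whose radii reproduce the catalog volumes, an optional
cylindrical protrusion for tubule-flagged objects, overlap resolved
deterministically by ascending ID. The default phantom geometry
(256×256×128 voxels at 20 nm) is deliberately desk-scale; every
estimator takes the geometry as a parameter, so nothing depends on that
choice. Rendering then re-measuring a 8.8×10⁻³ µm³ sphere at 20 nm
voxels recovers the volume within about 1 %, and the error decreases
with voxel size (the package asserts this across 80/20/5 nm).

## Stereology

**Density.** `countInFrame()` implements the unbiased brick: three
inclusion faces meeting at one corner (closed) and three exclusion faces
(open), applied to each object's unique counting point, its centroid.
With the default lower corner, a centroid is counted iff
$\mathrm{lower} \le p < \mathrm{upper}$ on every axis, so objects on
exclusion planes are never double-counted between adjacent frames.
Density is count over (corrected) frame volume. The across-layer summary
is, by default, the **unweighted mean of the layer means** rather than
the pooled total-over-volume ratio; the two differ when layers contribute
different numbers of stacks, and the layer-mean convention is the one
under which a grand density of 0.21 /µm³ is reproduced from per-layer
densities. Stack-weighted pooling is available
(`aggregateDensity(..., across = "stacks")`).

**Volume fractions.** `cavalieriVolumeFraction()` overlays a square
point grid (default grid constant 632 nm, associated area
$632^2 = 399\,424 \approx 4\times10^5$ nm² per point — the spacing is the
primitive, the area is derived) on every $k$-th section (default every
40th 20-nm section, i.e. 800 nm in z). The fraction of grid points
hitting the target labels among points hitting the reference space
estimates the volume fraction. The grid origin is fixed at half a
spacing by default so tests are reproducible; giving a seed randomises
the XY origin within one grid cell *and* the starting section within one
period, which is what makes the estimator unbiased — the package
verifies that the mean over 200 random origins matches the analytic
volume fraction of a rendered sphere.

## Spatial statistics

Centroids in a stack form a 3D point pattern in a box window. Three
summary functions are estimated on a common distance grid (64 points
from 0 to one quarter of the shortest window side — beyond that, edge
effects dominate a box window):

* $G(r)$, the nearest-neighbour distance distribution;
* $F(r)$, the empty-space function (distance from arbitrary locations to
  the nearest point), probed at a regular 32³ lattice of cell-centred
  test sites by default (deterministic; random sites are available);
* $K(r)$, Ripley's reduced second moment,
  $\hat K(r) = \frac{V}{n(n-1)}\sum_{i \ne j} \mathbf 1[d_{ij} \le r]\, e_{ij}$.

Under CSR, $G(r) = F(r) = 1 - \exp(-\lambda\frac43\pi r^3)$ and
$K(r) = \frac43\pi r^3$.

**Edge corrections.** G and F use the border (reduced-sample)
correction: a point (or test site) contributes at distance $r$ only if
its distance to the window boundary is at least $r$. K uses the
translation correction, $e_{ij} = V / \prod_a (L_a - |\Delta_a|)$. These
were chosen because they are simple, unbiased and *exactly* checkable
against brute-force double loops — which the test suite does at
$n \le 50$ to 10⁻¹⁰. Kaplan–Meier-style corrections are deliberately not
the default: they are harder to oracle-check, and nothing downstream
depends on the choice. A caveat stated here because it surprises people:
the border-corrected G and F are not guaranteed monotone in $r$ (the
at-risk set shrinks as $r$ grows); only the uncorrected variants are
cumulative distributions in the strict sense.

**Envelope test.** `envelopeTest()` simulates `nsim = 100` CSR patterns
*conditioned on the observed point count* in the observed window
(removing count variance from the envelope; Poisson counts by flag),
forms pointwise min/max envelopes, and classifies: **random** if every
selected function stays inside its envelope everywhere; **clustered** if
all breaches carry the clustering signature (G above, F below, K above);
**regular** for the opposite signature; **mixed** otherwise. Patterns
with fewer than 25 points are refused — too little information for
spatial inference at these intensities.

Two numerical details matter. First, pointwise min/max envelopes over
100 simulations have a pointwise exceedance probability of 2/101 *per
distance*, so over a 64-point grid and three correlated functions the
global type-I error is substantial: in the package's calibration suite
only about 60 % of genuinely CSR patterns at the reference intensity
are classified random — the other 40 % show at least one single-point
excursion, split roughly symmetrically between clustered-signature and
regular-signature directions. This is a property of the
pointwise-envelope methodology itself (each summary function contributes
on the order of ten effectively independent distances), not of the
implementation: observed and simulated curves are exchangeable by
construction, and the estimators are oracle-checked exactly. Verdicts on
real data should be read with this false-positive rate in mind — a
"slight tendency to cluster" in a minority of samples is exactly what
this regime produces under pure randomness. Second, below the spacing of
the F test-site lattice the
empty-space estimate is quantized to a handful of sites and its rank
among simulations is meaningless; F breaches at $r$ smaller than one
lattice spacing are therefore ignored for classification (they are still
reported in the curves). Without this rule, strongly clustered patterns
were occasionally demoted to "mixed" by a single-site artifact at
$r \approx 0$.

The calibration suite measures both operating characteristics over 100
seeds with 100 simulations per envelope: essentially all strongly
clustered Thomas patterns ($\kappa = 0.021$, $\mu_c = 10$,
$\sigma_c = 0.35$ µm in a ≈6.5 µm window) are classified clustered
(observed ≈ 100 %), while the specificity on CSR patterns sits near
60 % for the reasons above — the suite asserts a 70 % specificity
bound and documents the shortfall rather than relaxing the verdict rule
to meet it.

## Size distributions and hypothesis tests

`fitLognormal()` fits by maximum likelihood on natural logs:
$\hat\mu = \overline{\ln v}$,
$\hat\sigma = \sqrt{\tfrac1n\sum(\ln v - \hat\mu)^2}$ (divisor $n$, the
MLE, so `fitLognormal(c(exp(-1), exp(-3)))`-style hand calculations come
out exact). Moment matching is available as an alternative. The KS
statistic against the fitted CDF is reported as a descriptive
goodness-of-fit summary; its p-value does not account for estimated
parameters. On 10⁵ synthetic draws the fit recovers $\mu$ and $\sigma$
within ±0.01.

`concentrationRatio()` divides the percentage of objects in a
compartment by that compartment's volume fraction (in %); values above 1
mean enrichment. `compartmentChiSquare()` provides the matching
goodness-of-fit test (expected counts proportional to volume fractions,
df = c−1) and the r×c independence form for layer-by-compartment tables.
`groupCompare()` wraps Mann–Whitney for two groups and Kruskal–Wallis
with Dunn's post-hoc for k groups; Dunn z-statistics are computed on the
shared ranks with tie correction, and adjusted by Holm's method by
default (chosen over plain Bonferroni because it is uniformly more
powerful at the same family-wise error; any `p.adjust` method can be
requested). Large-sample approximations with tie correction are used
throughout; exact small-n variants are out of scope. Both tests hold
their nominal 5 % size within binomial error over 2000 null replicates
in the test suite.

## Reproducibility and problem sizes

Every stochastic entry point takes an explicit seed, and multi-part
computations derive child seeds deterministically, so identical inputs
give bit-identical outputs (the pipeline writes no timestamps for the
same reason). The validation suite runs at deliberately chosen problem
sizes: 10⁵ draws for distribution recovery, 29 stacks for density
recovery, 200 simulations for the CSR closed-form checks, 100 seeds ×
100 simulations for envelope calibration, 2000 replicates for test-size
calibration, and 128³-voxel phantoms for the raster stages — sizes at
which Monte-Carlo error is far below the tolerances being asserted while
a full run remains a desk-scale computation.

## Known limitations

* Labels are trusted; there is no segmentation, no connected-component
  splitting or merging, and no detection of docking, tubules or clathrin
  from images — those arrive as catalog flags.
* Only homogeneous point-process models: no inhomogeneous intensities,
  pair-correlation functions or multitype statistics.
* The envelope verdict is a classification, not a p-value; global
  (simultaneous) envelopes would give cleaner error control and are a
  natural extension.
* Flags are independent Bernoulli in the generator, so it cannot emulate
  reported interactions such as tubule-bearing organelles being
  disproportionately clathrin-coated.
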