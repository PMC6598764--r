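---
title: "Quantifying biaxial nematic order in liver lobules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biaxial nematic order in liver lobules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepnematic)
```

## The problem

Hepatocytes are not polarized like sheet epithelial cells, which carry a
single apical surface and hence a polarity *vector*. A hepatocyte's apical
membrane is distributed over its surface in several patches and belts, its
basal membrane faces the sinusoidal capillary network on multiple sides,
and the tissue as a whole shows no crystalline packing. `hepnematic`
implements a quantitative framework for this situation: each cell's
membrane-marker distribution is summarized by a *nematic tensor* whose
eigen-system defines two sign-free axes — a bipolar axis and a ring axis —
and tissue-level organization is measured by how those axes align with a
lobule-wide reference field spanning from the portal vein (PV) to the
central vein (CV). Layered (smectic-like) positional order of hepatocytes
and sinusoids is detected separately by a projected cross-correlation
analysis. A synthetic-lobule generator with known ground truth makes every
stage testable without microscopy data.

## Per-cell biaxial polarity

The cell surface is a closed triangulated mesh with per-vertex membrane
labels (apical, basal, lateral, unlabeled). A triangle belongs to a
membrane domain when at least two of its vertices carry the label. To
remove the influence of cell shape, triangles are first projected radially
onto a unit sphere centered at the cell's volumetric center (the
divergence-theorem centroid; the vertex centroid is used, with a warning,
for meshes that are not closed). The projection assumes the surface is
star-convex about that center; violations are counted and reported. For a
closed star-convex mesh the projected solid angles sum to $4\pi$, which is
asserted to 0.5% in the tests.

The nematic tensor of a membrane domain $I$ is the solid-angle-weighted
second moment of the projected triangle directions $\mathbf{n}_i$:

$$
N_{\alpha\beta} \;=\; \frac{3}{2}\,
\frac{\sum_{i \in I} A_i \left( n^{(i)}_\alpha n^{(i)}_\beta -
\tfrac{1}{3}\delta_{\alpha\beta} \right)}{\sum_{i \in I} A_i},
$$

a symmetric traceless $3\times3$ matrix. Two normalization conventions are
conceivable — dividing by the total projected area or by the marker
domain's own area. The package divides by the *marker* area, so that an
ideal bipolar pattern (two antipodal point-like caps) yields weight
$\sigma_1 = 1$ regardless of how small the apical surface fraction is, and
an ideal ring yields $\sigma_2 = -1/2$; these are exactly the two extreme
morphologies the weights are meant to interpolate between.

With eigenvalues ordered $\sigma_2 \le \sigma_3 \le \sigma_1$ (they sum to
zero), the **bipolar axis** $\mathbf{a}_1$ is the eigenvector of
$\sigma_1$, the **ring axis** $\mathbf{a}_2$ that of $\sigma_2$, and
$\mathbf{a}_3 = \mathbf{a}_1 \times \mathbf{a}_2$. Axes are nematic
(defined up to sign); the stored representative has a non-negative third
component, but all downstream statistics are sign-free. An axis is flagged
*degenerate* when its eigenvalue gap to the middle eigenvalue is below a
tolerance (default 0.05): a pure bipolar pattern leaves the ring axis
undetermined in the normal plane, a pure ring leaves the bipolar axis
undetermined. Degenerate axes are excluded from alignment averages, since
their direction is noise. The same construction applied to basal labels
yields $\mathbf{b}_1, \mathbf{b}_2$.

For visualization, the apical domain can be mapped to equal-area Mollweide
coordinates in a cell-intrinsic frame: $\mathbf{b}_1$ is the pole axis and
the zero meridian passes through $\mathbf{a}_1$, so the largest basal
patches sit at the map poles and the dominant apical patch at the map
center. The Mollweide parameter equation $2\theta + \sin 2\theta = \pi
\sin\varphi$ is solved by Newton iteration to $10^{-13}$; the equal-area
property is verified in the tests by Monte-Carlo uniformity.

## Network anisotropy

Sinusoid and bile-canaliculi skeletons are segment lists. Their anisotropy
tensor is the length-weighted analogue of the polarity tensor, with
segment orientations $\mathbf{e}_i$ and lengths $l_i$ as weights. The
*local* preferred axis around a cell restricts the skeleton to segments
whose midpoint falls within a neighborhood ball (default radius 20 µm,
approximately one hepatocyte diameter — the source analysis does not state
a radius, so it is a configurable default here), clips crossing segments
to the ball so the length weighting approximates a true restriction, and
returns the largest-eigenvalue axis with its eigenvalue as a local order
weight.

## The lobule-level reference field

The CV–PV axis varies across a lobule, so alignment must be measured
against a position-dependent reference. Each vein's triangulated surface
is converted to point charges at the triangle centroids, with strength
proportional to relative triangle area — positive on the CV, negative on
the PV, net charge $\pm 1$ per vein, i.e. a uniform surface charge
density. The scalar field

$$ \chi(\mathbf{r}) = \sum_i \frac{q_i}{|\mathbf{r} - \mathbf{r}_i|} $$

is the Green's-function superposition (equivalently, the steady state of
diffusion between sources and sinks); its analytic gradient, normalized to
unit length, is the reference direction $\mathbf{J} = \nabla\chi$.
Negative $\chi$ means portal-side, positive central-side. No homogeneous
offset is added, as only the gradient and the sign structure are used.
Points within an exclusion radius (default 2 µm) of any charge are
rejected as singular — evaluation positions that close to a vein surface
are segmentation artifacts in practice; stagnation points
($|\nabla\chi| < 10^{-14}$) return a flagged absent direction. Both the
potential and the gradient are checked in the tests against a brute-force
pairwise sum, central finite differences, a discrete Laplacian
(harmonicity), and rotation equivariance.

## Alignment statistics

The nematic alignment parameter between paired axes $\mathbf{e}_i$ and
references $\mathbf{g}_i$ is

$$ S = \frac{1}{N} \sum_{i=1}^{N}
\left[ \frac{3}{2} (\mathbf{e}_i \cdot \mathbf{g}_i)^2 - \frac{1}{2} \right], $$

equal to 1 for parallel, 0 for isotropic, $-1/2$ for perpendicular
alignment. Applied per cell against $\mathbf{J}$ it measures tissue-scale
liquid-crystal order; applied between apical and basal axes it quantifies
the repulsion between the two membrane domains (same-type axes
perpendicular, different-type parallel, for complementary patterns).

For biaxial objects with $S_1 + S_2 + S_3 = 0$, a uniaxial ensemble (ring
axis uniform in the plane normal to the bipolar axis) satisfies the
maximum-likelihood baseline $S_2^{\mathrm{ML}} = -S_1/2$. The *biaxiality
excess* $S_2 - (-S_1/2)$ therefore isolates genuine secondary-axis order.
Because the statistical test behind that comparison is not pinned down by
the source analysis, the package defaults to a paired one-sided t-test
across replicates (animals) and provides a sign-flip permutation test as a
cross-check; the tests exercise both. Group-level contrasts (e.g. control
versus knockdown) use the two-sided Welch t-test with unequal variances.
Alignment statistics are aggregated per replicate first, then averaged
across replicates (mean ± s.d.), never pooled across animals.

Spatial maps use Gaussian local averaging of axes: at each position the
weighted nematic tensor with kernel standard deviation 20 µm
(approximately one hepatocyte diameter) is diagonalized and its principal
axis displayed. Weights are normalized by their sum — this does not change
the principal axis but makes the leading eigenvalue an interpretable local
order weight in $[0, 1]$. Quantitative $S$ values are always computed from
raw per-cell axes; the averaged field is for display only.

## Layered order

Voxelized density grids of hepatocytes and sinusoids (0.3 µm isotropic
voxels by default) are mean-projected along $z$, and the two images are
compared by the normalized cross-correlation

$$
C_{SH}[k, l] = \frac{1}{N_S + N_H} \sum_{n,m}
\frac{(S[n,m] - \mu_S)(H[n+k, m+l] - \mu_H)}{\sigma_S \sigma_H},
$$

with the mean-subtracted second image zero-padded outside its range, and
means and standard deviations computed with the full-image pixel count.
The $1/(N_S + N_H)$ prefactor is implemented exactly as defined, under
which the zero-lag autocorrelation of an image with itself is $1/2$, not
1; a conventionally normalized per-overlap variant is available behind the
`normalization = "overlap"` flag for comparison. The 2D correlation array
is then mean-projected onto a line through the origin along the layer
normal, with 1.5 µm bins (5 pixels at 0.3 µm) — a mean projection rather
than a 1D cut, which suppresses noise and tolerates random phase shifts
between neighboring layers.

Period estimation needs two refinements beyond "first local maximum":

* **Extremum type.** Anticorrelated pairs (sinusoid against hepatocyte,
  which are complementary) repeat a correlation *minimum* at the layer
  spacing, positively correlated pairs (bile canaliculi inside hepatocyte
  layers) a maximum. The sign of the profile at zero lag selects which
  extremum type continues the periodicity.
* **Half-period gate.** A genuine repeat must be preceded by an anti-phase
  half-period, so candidate extrema are required to follow a zero crossing
  of the signed profile; this rejects noise wiggles on the broad zero-lag
  plateau produced by the finite slab widths.

The selected extremum (first beyond a 5 µm minimum lag) is refined by
quadratic interpolation over its three bins. Significance is assessed
against a null band from 200 random circular shifts of the second image.
A single global shift would preserve global periodicity — the null would
be as strong as the signal — so each image line parallel to the projection
direction is shifted by an *independent* random circular offset instead.
This phase-scrambling surrogate preserves every line's own structure while
destroying the inter-layer phase coherence that defines layered order. The
extremum must exceed the 95% quantile of the strongest same-type null
extrema; otherwise the analysis reports no period, which is the expected
outcome for the control direction along the CV–PV axis.

## The synthetic lobule generator

The generator emulates the statistical structure the analysis assumes,
with known ground truth:

* **Cell meshes** are icospheres (1280 triangles by default) with gentle
  random radial modulation (8% amplitude, guaranteed star-convex). Apical
  patterns span the bipolar-to-ring range: two antipodal caps, an
  equatorial band, or their union ("mixed", the hepatocyte-like default,
  with an apical surface fraction in the 10–25% range). Patch boundaries
  are perturbed by a smooth low-order Fourier wobble of total amplitude
  $1/\kappa$ radians (default $\kappa = 20$) — a coherent-boundary noise
  model, since membrane domains are contiguous regions, not independent
  per-vertex speckle. The basal domain is the complement of the apical
  one, separated by a 15° lateral margin ring as in real hepatocytes;
  this complementarity is what produces the apical–basal repulsion
  signature.
* **Geometry**: CV and PV are parallel triangulated cylinders (radii 20
  and 15 µm) at opposite ends of the lobule block (default
  250 × 250 × 60 µm), so $\mathbf{J}$ runs between them; cell centers are
  Poisson-disk sampled with minimum separation 0.9 cell diameters
  (confluent but non-overlapping).
* **Axis dispersion** uses the Watson distribution, the natural axial
  (sign-free) analogue of the von-Mises–Fisher distribution; this is a
  generator choice, not a claim about tissue data. True bipolar axes are
  Watson-distributed about $\mathbf{J}(\mathbf{x})$ with concentration
  `kappa_align` (default 5); with `ring_coupling` the true ring axis is
  biased toward the in-plane component of $\mathbf{J}$ (wrapped-normal
  jitter, s.d. 0.35 rad), which produces a positive biaxiality excess,
  while the uniform in-plane choice reproduces the uniaxial baseline
  exactly. Sinusoid skeletons are chains of 5 µm segments with
  Watson-distributed orientations about $\mathbf{J}$ (default
  concentration 10).
* **Layered grids**: alternating slabs along an in-plane layer normal,
  hepatocyte slabs of 20 µm and sinusoid slabs of 4 µm (spacing 24 µm,
  the sum of one hepatocyte and one sinusoid diameter), each layer's
  phase jittered independently and uniformly by ±10% of the spacing by
  default. Hepatocyte and sinusoid grids are exact complements; the
  bile-canaliculi band (2 µm) is centered in each hepatocyte slab. The
  pattern is constant along $z$.
* The disordered ("knockdown-like") preset reduces `kappa_align` and
  `sinusoid_kappa` and disables ring coupling while leaving the per-cell
  apical patterns untouched — tissue-level order drops while the
  $(\sigma_1, \sigma_2)$ distributions are statistically unchanged, the
  dissociation the analysis is designed to resolve.

What the generator does *not* emulate: real network topology (loops,
anastomoses, branching hierarchies — only orientation statistics),
mechanical cell packing and shape anisotropy, segmentation noise in the
meshes, intensity-level imaging artifacts, and any mechanistic coupling
between cells and sinusoids. Passing tests therefore demonstrate that the
estimators recover known ground truth under the stated statistical
structure, not that real tissue satisfies that structure.

## Numerical choices

* Solid angles via the van Oosterom–Strackee formula (signed, orientation
  aware); the test suite cross-checks it per triangle against l'Huilier's
  spherical-excess formula. Note that a midpoint-subdivided icosphere's
  face solid angles spread by −7%/+20% around the mean, so per-face
  uniformity is not assumed anywhere.
* Eigen-decompositions use base `eigen(symmetric = TRUE)`; tensors are
  symmetrized before decomposition to suppress rounding drift.
* Cross-correlations run through FFTs padded to highly composite sizes;
  the direct-sum oracle is asserted to $10^{-10}$ on 32 × 32 images.
* Watson sampling is by rejection from the uniform axis distribution,
  exact for any $\kappa \ge 0$; its order parameter is cross-checked by
  numerical quadrature of the Watson moments.
* Poisson-disk packing uses dart throwing with a bounded retry budget and
  fails loudly on infeasible configurations.
* Degenerate inputs are errors, not silent results: empty marker sets,
  zero-length segments, flat images, points inside the singular exclusion
  zone, parallel Mollweide frame axes.

Test problem sizes are chosen to exercise each property at the smallest
scale that resolves it: 1280–5120-face spheres for projection and tensor
properties, 50–100-cell lobules for pipeline statistics, $10^4$–$10^5$
samples for Monte-Carlo baselines, and 0.6 µm voxels on 150 × 150 µm
grids for layered-order recovery (0.3 µm is the analysis default). Because
the synthetic layer pattern is constant along $z$, grids are generated
with a thin z extent; the z-mean projection is unchanged.

## Known limitations

* The star-convexity assumption is checked but not repaired; strongly
  non-convex segmented cells would need a different projection.
* The spherical projection weights membrane by solid angle, so a marker
  patch hidden in a deep fold contributes less than its metric area.
* The reference field treats veins as the only organizers; lobules with
  several vein branches produce stagnation regions where $\mathbf{J}$ is
  undefined and cells are excluded.
* The layered-order null is a surrogate-data test; its 95% band at 200
  shifts has Monte-Carlo resolution of about 2%, so marginal periodicity
  near the band should be interpreted cautiously.
* Period estimation assumes at least two repeats of the layer spacing
  inside the region of interest.
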