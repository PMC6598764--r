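# hepnematic

Biaxial nematic cell polarity and liquid-crystal order in liver lobules.

Hepatocytes do not fit the textbook picture of epithelial polarity: their
apical membrane is distributed over several patches and belts rather than
a single surface, so a polarity *vector* cannot describe them.
`hepnematic` quantifies this organization at three scales, for anyone
analyzing 3D reconstructions of liver tissue (segmented cell-surface
meshes, vessel meshes, network skeletons and density grids) or studying
liquid-crystal-like order in tissues more generally:

* **Cell scale** — each cell's labeled surface mesh is radially projected
  onto a unit sphere about its volumetric center, and the membrane
  distribution is summarized by the nematic tensor

  N = (3/2) Σᵢ Aᵢ (nᵢ ⊗ nᵢ − I/3) / Σᵢ Aᵢ,

  summed over projected triangles of the marker domain (solid angles Aᵢ,
  directions nᵢ). Its eigen-system (σ₂ ≤ σ₃ ≤ σ₁, σ₁+σ₂+σ₃ = 0) defines
  the **bipolar axis a₁** (weight σ₁) and the **ring axis a₂** (weight
  σ₂): a pure two-pole pattern has σ₁ = 1, a pure belt has σ₂ = −1/2.
* **Lobule scale** — a reference direction **J** = ∇χ, where
  χ(r) = Σᵢ qᵢ/|r − rᵢ| superposes point charges placed on the central-
  (+1 net) and portal-vein (−1 net) meshes. The nematic alignment
  parameter S = ⟨(3/2)(e·g)² − 1/2⟩ (1 parallel, 0 isotropic, −1/2
  perpendicular) measures order of polarity axes and of local sinusoid
  axes against J, with the uniaxial baseline S₂ᴹᴸ = −S₁/2 separating
  genuine biaxial order from the trivial consequence of primary-axis
  alignment.
* **Layered order** — projected hepatocyte/sinusoid density images are
  compared by a normalized cross-correlation, mean-projected onto the
  layer normal (1.5 µm bins) and scanned for the first significant
  off-origin extremum; the layer period of healthy tissue equals one
  hepatocyte plus one sinusoid diameter (24 µm by default).

A synthetic-lobule generator with known ground truth (Watson-dispersed
axes about J, complementary apical/basal patterns, jittered layer grids)
makes the full pipeline runnable and testable without any imaging data.

## Worked example

```r
library(hepnematic)

cfg <- lobule_config(n_cells = 80, seed = 7)   # defaults: 24 um layers,
lob <- generate_lobule(cfg)                    # kappa_align = 5, cells 20 um

print(lob$meshes[[1]])
#> labeled_mesh 'cell_001': 642 vertices, 1280 triangles (closed)
#>   labels: lateral=109, apical=157, basal=376, unlabeled=0
#>   center: (26.042, 66.062, 41.680) um

cell_polarity(lob$meshes[[1]])
#> polarity_axes: sigma1 = 0.374, sigma2 = -0.454
#>   a1 = (-0.613, 0.574, 0.542)  a2 = (-0.628, -0.771, 0.106)

report <- run_full_analysis(lob, cfg, layered = FALSE)
report$alignment
#> S(a1, J) = 0.639
#> S(a2, J) = -0.199 (uniaxial baseline -0.320, excess +0.120)
#> S(sinusoid, J) = 0.907
round(report$axis_correlations, 3)
#>  a1-b1  a1-b2  a2-b1  a2-b2
#> -0.500  0.987  0.999 -0.500

g <- generate_layered_grid(cfg, extent = c(150, 150, 6), seed = 7)
res <- layered_order_analysis(g$sinusoid, g$hepatocyte,
                              direction = g$layer_normal)
res$period
#> layer period: 23.1 um (minimum, significant: TRUE)
```

Reading the numbers: the first cell's apical pattern sits between the
bipolar (σ₁ = 1) and ring (σ₂ = −1/2) extremes, as typical hepatocytes
do. Bipolar axes align with the CV–PV field (S(a1,J) = 0.64 for Watson
concentration 5), ring axes are preferentially perpendicular to it
(S(a2,J) < 0) yet *less* perpendicular than the uniaxial baseline
predicts — the positive excess is the signature of biaxial order. The
apical–basal table shows same-type axes perpendicular (≈ −1/2) and
different-type axes parallel (≈ +1), i.e. mutual repulsion of the two
membrane domains. The sinusoid–hepatocyte cross-correlation repeats its
zero-lag minimum at 23.1 µm ≈ one hepatocyte plus one sinusoid diameter,
while the control direction along the CV–PV axis yields no significant
period.

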