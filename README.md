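# mvbquant

Quantitative analysis of membrane-bound organelles — multivesicular
bodies (MVBs) and their kin — reconstructed from volume electron
microscopy (FIB-SEM) stacks of neural tissue. The package is aimed at
anyone turning a segmented label volume or an object catalog into the
numbers such studies report: densities, compartment distributions, size
distributions, and spatial-organisation verdicts.

## What it computes

* **Morphometry** — object volumes and centroids from 3D label rasters
  with anisotropic voxel geometry (`measureObjects()`), and tissue
  shrinkage correction by division with the after/before factors
  (linear 0.90 → area 0.81, volume 0.73; `applyShrinkage()`).
* **Stereology** — unbiased density estimation with a 3D counting frame
  (brick rule on centroids: count iff lower ≤ p < upper per axis;
  `countInFrame()`, `estimateDensity()`), and Cavalieri point-grid
  volume fractions on every k-th section
  (`cavalieriVolumeFraction()`).
* **Size distributions** — maximum-likelihood log-normal fits on natural
  logs, μ̂ = mean(ln v), σ̂ = RMS deviation (divisor n)
  (`fitLognormal()`).
* **Compartment analysis** — concentration ratios (% of objects in a
  compartment ÷ its volume fraction; > 1 means enrichment) and
  chi-squared occupancy tests (`concentrationRatio()`,
  `compartmentChiSquare()`), plus Mann–Whitney / Kruskal–Wallis with
  Dunn's post-hoc (`groupCompare()`).
* **3D spatial statistics** — nearest-neighbour G, empty-space F and
  Ripley K functions with border / translation edge corrections, and a
  Monte-Carlo envelope test against complete spatial randomness
  (CSR): 100 conditional simulations, pointwise envelopes, and a
  random / clustered / regular / mixed verdict
  (`gFunction()`, `fFunction()`, `kFunction()`, `envelopeTest()`).
  Under CSR, G(r) = F(r) = 1 − exp(−λ·(4/3)πr³) and K(r) = (4/3)πr³.
* **Synthetic ground truth** — a generator for CSR or Thomas-clustered
  catalogs with log-normal sizes, multinomial compartments and Bernoulli
  morphology flags (`generateCatalog()`), plus voxel-phantom rendering
  (`renderLabelStack()`), so every estimator is testable by parameter
  recovery. Defaults are the reference study conditions: 29 stacks over
  cortical layers I–VI, frame volumes 167.39–444.11 μm³, intensity
  0.21 μm⁻³, log-normal(μ = −5.1375, σ = 0.9173) volumes.

See the vignette in `vignettes/mvb-quantification-methods.Rmd` for the
models, estimator definitions and design rationale.

## Worked example

```r
library(mvbquant)

# a 29-stack synthetic experiment at the reference conditions
cat29 <- generateCatalog(catalogSpec(), csrProcess(0.21), seed = 1)
cat29
#> MVBCatalog: 1698 objects in 29 stack(s)
#>   compartments: dendrite=676, excitatory_axon=276, inhibitory_axon=37, nonsynaptic=709
#>   volumes: median 0.00594 um^3 (range 0.000261-0.184)
#>   synthetic catalog with recorded ground truth

agg <- aggregateDensity(estimateDensity(cat29))
sprintf("grand mean density: %.3f +/- %.3f per um^3", agg$mean, agg$sem)
#> "grand mean density: 0.202 +/- 0.006 per um^3"

fitLognormal(mvbTable(cat29)$volume_um3)
#> Log-normal fit: mu = -5.1341, sigma = 0.9264 (n = 1698)
#>   logLik = 6438.18, KS D = 0.0111 (p ~ 0.985)

envelopeTest(catalogPattern(cat29, "stack_03"), nsim = 100, seed = 2)
#> EnvelopeResult: verdict 'random' (n = 39, 100 CSR simulations)
#>   G: 0 high / 0 low breach points
#>   F: 0 high / 0 low breach points
#>   K: 0 high / 0 low breach points

concentrationRatio(c(39.14, 18.16, 42.70), c(38.50, 22.81, 38.69),
                   c("dendrites", "axons", "nonsynaptic"))
#>   compartment pct_mvbs volume_fraction    ratio
#> 1   dendrites    39.14           38.50 1.016623
#> 2       axons    18.16           22.81 0.796142
#> 3 nonsynaptic    42.70           38.69 1.103644
```

The density estimate recovers the generator's 0.21 μm⁻³ intensity
within sampling error; the log-normal fit recovers (−5.1375, 0.9173);
the CSR-generated stack is classified random; and the concentration
ratios say MVBs are slightly enriched in dendrites and nonsynaptic
processes and depleted in axons relative to the tissue volume those
compartments occupy.

`runPipeline()` chains the stages (catalog → density → compartment
tables → size fit → per-stack envelopes) from a JSON configuration and
writes a reproducible result bundle; identical configuration and seed
give byte-identical outputs.

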