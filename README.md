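# colonyevo

Tools for studying how bacterial colonies evolve when selection acts on
surface spreading. Colonies of spore-forming bacteria such as *Bacillus
subtilis* develop strong internal gradients: cells at the expanding edge
grow on fresh nutrient while cells in the depleted center sporulate. Under
a passaging regime that repeatedly transfers only the outermost colony edge
to a fresh plate, selection favors genotypes that spread faster and
sporulate less — and mutations in global regulators that shift this
growth/dormancy balance reshape the expression of a large fraction of the
genome in a coordinated way.

`colonyevo` implements the computational machinery for this kind of study
as one tested R package:

* **Surface growth and competition simulator** — a radial
  reaction–diffusion model per genotype $g$:
  $\partial_t V_g = D_b \nabla_r^2 V_g + \mu\,\tfrac{N}{K_g+N}V_g -
  \sigma\,\tfrac{K_s^m}{K_s^m+N^m}V_g$, with spores accumulating from the
  sporulation term and a shared nutrient field consumed in proportion to
  growth; weekly edge-transfer passaging (`run_serial_passages()`) and
  mutant-vs-wild-type parameter sweeps (`selection_sweep()`).
* **Regulator activity analysis** — median-of-ratios normalization,
  activity of a regulator as the (sign-corrected) mean z-score of its
  regulon's targets, Pearson coactivation matrices, and activity-module
  detection by average-linkage clustering with silhouette-selected k.
* **Expression analysis** — Mann–Whitney + Benjamini–Hochberg
  differential-expression screen with a 2-fold filter, two-sided Fisher
  exact overlap and regulon-enrichment tests, PCA of expression profiles,
  and a batch self-organizing map with operon-coherence statistics
  (relative Shannon diversity, start-codon distances vs permutation).
* **Colony outline pipeline** — Petri-dish detection, colony segmentation,
  and subpixel boundary refinement that moves each outline point to the
  inflection of a sigmoid fitted to the intensity profile along the local
  normal, making radii robust to shading.
* **Synthetic data generators** — regulon-structured negative-binomial
  transcriptomes driven by a latent growth→dormancy axis, cell-type
  composition tables, and shaded/blurred/noisy plate images, all seeded and
  with ground truth, so every pipeline stage is testable end to end.

## Worked example

Simulate a default colony for one weekly cycle and read off its spatial
structure:

```r
library(colonyevo)
domain   <- radial_domain()
wt       <- genotype_params("wt")
protocol <- passage_protocol()
state    <- make_state(domain, list(wt = list(mass = 0.05, radius = 2)))
snaps    <- simulate_colony(state, list(wt), domain, 168, dt = 0.1,
                            record_times = c(24, 48, 96, 168))
```

Running `analysis/01_colony_growth.R`, which does exactly this, prints:

```
 time_h radius_mm edge_spore_fraction center_spore_fraction nutrient_center
     24       3.0        0.0009906165           0.001461207    8.213405e-01
     48       4.9        0.0009878206           0.212344627    2.698318e-03
     96       8.6        0.0011380220           0.688790969    4.727457e-07
    168      14.2        0.0012483428           0.920433738    2.056641e-08
```

The colony expands at a near-constant front speed to 14.2 mm, nutrient at
the center collapses within two days, and by day 7 the center is 92 %
spores while the edge stays vegetative (0.1 %) — the edge/center asymmetry
that edge-transfer selection acts on.

The transcriptome workflow (`analysis/03_transcriptome_modules.R`)
generates a synthetic colony expression dataset and recovers its planted
structure:

```
DE screen (edge, days 1-2 vs 4-7): 172/400 genes >= 2-fold and significant (43%)
regulon enrichment: 8/17 regulons enriched among DE genes
PCA: PC1 81%, PC2 1% of expression variance
module detection: k = 2 (mean silhouette 0.98); planted split recovered: TRUE
activity recovery: inferred vs true correlation 0.95-1.00 per regulator
activity ~ spore fraction: R^2 = 0.89 +/- 0.01 (mean +/- s.e. over regulators)
```

That is the package's central scientific claim in miniature: a single
latent growth→dormancy axis dominates the transcriptome (PC1), regulator
activities inferred from target expression recover the truth, and their
coactivation splits into exactly two modules — one vegetative, one
dormancy-associated.

The remaining scripts exercise the other modules: `02_serial_passaging.R`
(selection sweeps over diffusion, growth, and sporulation rates),
`04_expression_map.R` (SOM and operon coherence), and
`05_image_analysis.R` (simulated radii rendered as shaded plate images and
re-measured to within 0.01 px).

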