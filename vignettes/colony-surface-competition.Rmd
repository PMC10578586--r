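---
title: "Modeling colony surface competition and regulon activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling colony surface competition and regulon activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyevo)
```

`colonyevo` studies how bacterial colonies evolve under selection for surface
spreading. Its pieces mirror one experimental program: colonies grow on a
plate for a week, cells from the outermost edge are transferred to a fresh
plate, and the cycle repeats. Over cycles this regime favors genotypes that
spread faster and sporulate less. The package provides (i) a mechanistic
simulator of that regime, (ii) an expression workflow that infers regulator
activities from colony transcriptomes and groups them into activity modules,
(iii) an expression-map and differential-expression toolkit, (iv) a colony
outline measurement pipeline for plate images, and (v) seeded synthetic-data
generators so that every step can be validated against a known ground truth.

## The surface growth and competition model

The simulator describes a colony in 1-D radial geometry. For each genotype
$g$ there is a vegetative biomass density $V_g(r, t)$ and a spore density
$S_g(r, t)$; a single shared nutrient field $N(r, t)$ couples the genotypes:

$$\partial_t V_g = D_{b,g}\, \nabla_r^2 V_g
  + \mu_g \frac{N}{K_g + N} V_g
  - \sigma_g \frac{K_s^m}{K_s^m + N^m} V_g$$
$$\partial_t S_g = \sigma_g \frac{K_s^m}{K_s^m + N^m} V_g, \qquad
  \partial_t N = D_N \nabla_r^2 N
  - \sum_g \frac{\mu_g}{Y_g} \frac{N}{K_g + N} V_g$$

with $\nabla_r^2 f = \frac{1}{r}\partial_r(r\, \partial_r f)$, the symmetric
limit $2\,\partial_r^2 f$ at $r = 0$, and zero-flux boundaries. The three
ingredients are deliberately minimal:

* **Diffusive spreading.** Colony expansion is modeled as biomass diffusion
  with coefficient $D_b$; combined with Monod growth this produces a
  traveling expansion front with the classical Fisher speed
  $v = 2\sqrt{D_b\,\mu_{\mathrm{eff}}}$, which the test suite verifies to
  within 20 % on a fine grid. $D_b$ is a phenomenological stand-in for
  sliding motility, filamentation, and reduced cell-cell adhesion — the
  traits that mutations actually modify.
* **Monod growth** $\mu_{\max} N/(K_g + N)$: growth stops where nutrient is
  exhausted, which happens first at the colony center.
* **Nutrient-repressed sporulation.** Sporulation is induced where nutrient
  is depleted, via the Hill term $h(N) = K_s^m/(K_s^m + N^m)$, so $h \to 1$
  as $N \to 0$ and $h \approx 0$ at fresh-medium levels. $\sigma_{\max}$ is
  the maximal per-capita sporulation rate, the continuous-time analog of a
  per-division sporulation probability. Spores are inert: they do not grow,
  consume, or revert within a growth cycle.

### Assumptions and non-goals

Spores germinate instantly when transferred to a fresh plate (transferred
spore mass seeds the next cycle as vegetative biomass) but never within a
cycle. Cell death and lysis are not modeled; total biomass $V + S$ can only
grow, and the tests hold the model to that ledger. There is no 2-D
morphology, no branching, no mechanical interaction, and no demographic
noise — the model is meant to reproduce the qualitative spatial structure
(growing edge, sporulating center) and the direction of selection under edge
transfer, not colony shapes.

### Default parameters

All defaults are package choices on a nominal scale (mm, hours, nutrient
units); they are not measured quantities. They were fixed once so that a
default colony behaves like the experimental ones qualitatively: visible
radial expansion over 7 days, nutrient exhaustion at the center within the
first days, and a spore-dominated center by day 7.

| parameter | default | meaning |
|---|---|---|
| `D_b` | 0.01 mm²/h | biomass diffusion; with `mu_max` gives a front speed of ≈ 0.08 mm/h, i.e. ≈ 14 mm in a week |
| `mu_max` | 0.25 /h | maximal growth rate (≈ 2.8 h doubling time at saturation) |
| `sigma_max` | 0.02 /h | sporulation rate; ≈ 90 % spores in the center after a week of starvation |
| `K_g` | 0.5 | Monod constant (half of `N0`) |
| `K_s`, `m` | 0.3, 4 | sporulation induced sharply once N falls below ≈ 30 % of fresh medium |
| `Y` | 1 | biomass yield per nutrient |
| `R_max`, `n_r` | 20 mm, 201 | domain and grid (dr = 0.1 mm) |
| `D_N` | 0.02 mm²/h | slow nutrient diffusion in the substrate |
| protocol | 168 h, 1 mm edge annulus, 0.05 inoculum mass, 2 mm seed disk, θ = 0.01 | weekly edge transfer |

### Numerics

The scheme is explicit Euler in time with a conservative (finite-volume)
discretization of the radial Laplacian. Mass bookkeeping uses the quadrature
matched to that discretization, `radial_integral()`
($2\pi\,\mathrm{dr}\sum_i w_i f_i$), under which pure diffusion conserves
total mass to round-off — so the conservation test at 1e-6 measures the
scheme, not the quadrature. The time step must satisfy
$\mathrm{dt} \le 0.4\,\mathrm{dr}^2/\max(D_b, D_N)$; `step_pde()` refuses
larger steps. Negative values smaller than 1e-12 in magnitude (round-off)
are clipped to zero; anything more negative is treated as a bug and raises
an error naming the field and time. With all diffusion off the scheme
reduces to independent per-node ODEs; the suite checks node trajectories
against `deSolve::lsoda` at 1e-4 relative, using a small Euler step (dt =
0.001 h over 5 h) because the comparison measures the right-hand side, not
the first-order integrator's global error.

The colony radius is read off as the largest radius where total density
exceeds an absolute threshold θ. An absolute rather than relative threshold
keeps the readout comparable across genotypes with different carrying
densities.

### What the competition runs show

`run_serial_passages()` alternates growth and edge transfer. Identical
genotypes are a fixed point (the code path is symmetric, so 50/50 stays
exactly 50/50). In mutant-vs-wild-type competitions started at 50/50,
`selection_sweep()` tabulates the final edge share: it increases with `D_b`
and `mu_max` and decreases with `sigma_max`, while the edge spore percentage
increases with `sigma_max`. Only these selection directions are asserted —
effect sizes depend on the artifact-chosen parameters.

## Regulator activity and coactivation

The expression workflow starts from a raw gene × sample count matrix.
Normalization is median-of-ratios: per-gene geometric means over samples
form a reference (genes with any zero are excluded), the per-sample factor
is the median count/reference ratio, and factors are rescaled to geometric
mean 1; expression values are `log2(count/factor + 1)`.

A regulator's *activity* in a sample is inferred from its targets, not from
its own transcript: each target is z-scored across the reference samples,
and the activity is the mean target z-score, sign-flipped for repressors —
a repressor is considered active when its targets are low. The aggregation
statistic (mean of z-scores) is the simplest one consistent with that rule;
targets missing from the matrix or with zero variance are dropped with a
message, and a regulon that loses all its targets yields an explicitly
undefined (NA) activity rather than zero. Because z-scores are standardized
per gene, activities are invariant to rescaling all counts by a common
factor up to the pseudocount, whose effect at realistic depths is of order
1e-3 z-units; the test suite asserts invariance at 0.01.

*Coactivation* is the Pearson correlation of two regulators' activities
across a named sample set. Modules are found by average-linkage hierarchical
clustering on the distance $1 - r$; when the number of modules is not fixed,
k is chosen in 2..6 by maximal mean silhouette width, with ties broken
toward smaller k. A best silhouette below 0.25 is flagged as degenerate —
an all-alike correlation matrix has no module structure, and the flag (plus
a warning) is the honest answer there. On default synthetic data the choice
is unambiguous: the mean silhouette at k = 2 is ≈ 0.94 against ≤ 0.85 for
k > 2.

`activity_fits()` regresses activities on a covariate by OLS — either the
regulator's own expression or an external composition readout such as the
fraction of sporulating cells — and reports per-regulator R² with mean ±
s.e. across regulators.

## Differential expression, enrichment, PCA, expression maps

* `de_screen()` is a two-sided exact Mann-Whitney U test per gene with
  Benjamini-Hochberg correction across genes, plus a 2-fold-change filter.
  The log2 fold change is the difference of group means of log-normalized
  values (so a uniform shift of +2 log2 units gives lfc = 2 exactly). Note
  the test's granularity: with 2 vs 2 samples the smallest attainable
  two-sided p is 1/3, so small designs can never reach significance — the
  analysis scripts therefore compare pooled early vs late groups.
* `overlap_fisher()` computes the two-sided Fisher exact p by direct
  hypergeometric enumeration (sum of table probabilities not exceeding the
  observed one, with the conventional 1e-7 relative tie tolerance) and
  reports the sample odds ratio ad/bc, so a disjoint pair gives an odds
  ratio of exactly 0. Because the overlap denominator is ambiguous in
  general use, both |A∩B|/|A∪B| and |A∩B|/min(|A|,|B|) are reported,
  labeled.
* `regulon_enrichment()` tests the k largest regulons (default 40) and
  flags a regulon as enriched only when the BH-adjusted p is below α *and*
  the odds ratio exceeds 1 — the two-sided p is also small under depletion,
  which is not enrichment.
* `pca_profiles()` treats samples as observations with genes centered; on
  the synthetic data a single latent axis dominates and PC1 carries ≈ 80 %
  of the variance.
* `train_som()` is batch Kohonen training on a hexagonal grid (default
  10×10, 50 epochs): every epoch assigns each gene to its nearest codebook
  and replaces each codebook by the neighborhood-weighted mean of all genes,
  with a Gaussian neighborhood whose radius shrinks linearly from half the
  grid diameter to 0.5. Codebooks are initialized from seeded sampled gene
  profiles (plus tiny jitter), so training is exactly reproducible given the
  seed. The quantization error is recorded after every epoch; it is highest
  after the first, heavily smoothed epoch and decreases as the neighborhood
  narrows.
* `operon_coherence()` scores whether co-mapped genes share operons: the
  relative Shannon index $(-\sum_k p_k \ln p_k)/\ln n$ per unit (0 = one
  operon, 1 = all distinct; values clamped against float round-off at the
  anchors), the converse index per operon, same-strand start-coordinate
  distances within units against a label-permutation null, and a permutation
  test of same-operon co-assignment (add-one p-value, seeded).

## Colony outline measurement

Plate images are grayscale matrices in [0, 1]. The pipeline is deterministic:

1. **Dish detection**: Otsu threshold, morphological closing, largest
   connected component, circularity gate ($4\pi A/P^2 \ge 0.8$), and an
   algebraic (Kasa) least-squares circle fit to the component boundary. If
   the first Otsu split is dominated by a bright colony rather than the
   dish, the darker pixels are re-thresholded once — a second Otsu level —
   to separate dish from background. A boundary touching the frame raises a
   `truncated` flag instead of failing.
2. **Colony segmentation**: Otsu threshold restricted to the dish interior
   minus a rim margin, largest component (a message reports when several
   candidates exist), marching-squares contour at the threshold level,
   resampled to 360 equally spaced points. An interior with no contrast
   (< 0.02 intensity range) means there is no colony.
3. **Sigmoid refinement**: at each outline point, intensities are sampled by
   bilinear interpolation along the outward normal (half-length 10 px, step
   0.5 px) and fitted with $I(x) = a + b/(1 + e^{-(x - x_0)/s})$
   (`minpack.lm::nlsLM`; $x_0$ initialized at the steepest gradient, $b$
   with the gradient's sign so decreasing profiles fit with $b < 0$). The
   point moves to the fitted inflection $x_0$ when the fit converged and
   $|x_0| \le$ `max_shift`; shifts are smoothed by a circular moving median
   (window 5), and points whose shift would make the polygon
   self-intersecting are reverted. Fits never throw — failure is a flag.
4. **Radius**: the equivalent-area radius $\sqrt{A/\pi}$ from the shoelace
   area (the mean centroid distance is also reported), per image in a series
   with per-image failures isolated, plus a CSV hook for manual point
   corrections in place of an interactive editor.

The point of refinement is robustness to uneven illumination: a global
threshold biases the contour under a shading gradient, while the local
inflection does not. On generated images with 0–40 % linear shading the
refined radius error is at most the threshold-segmentation error everywhere
and below 0.01 px at 40 % shading.

## Synthetic data: what it emulates and what it does not

The generators produce the three study-shaped inputs with known truth:

* **Transcriptomes.** Genes are organized into operons (geometric sizes,
  mean 3, capped at 8; one strand and sequential coordinates per operon).
  Each operon belongs to one primary regulon; 15 % of operons also join a
  second, coherently acting regulon (same product of regulator mode and
  module sign). This gives overlapping regulons without systematic sign
  cancellation — the overlap structure of coherent co-regulation, chosen so
  that target-averaged activities remain identifiable. 17 regulators split
  alternately into a vegetative and a dormancy module. Every sample carries
  a latent dormancy value $d \in [0, 1]$ increasing with day, higher at the
  colony center, suppressed by a factor $(1 - \delta)$ in evolved genotypes,
  with a small seeded jitter; dormancy-module regulators have true activity
  $2d - 1$ and vegetative ones $-(2d - 1)$. Gene log2 means are baseline
  (N(5, 1.5²)) plus β (= 1) times the summed signed regulatory input, scaled
  to a common depth (5·10⁵), and counts are negative-binomial with
  dispersion φ = 0.05 (variance μ + φμ²). The default design is days
  {1, 2, 4, 7} × {edge, center} × 2 replicates of an ancestor-like genotype.
* **Composition tables** map $d$ to (filamentous, vegetative, sporulating,
  spores) fractions on the simplex, with sporulating cells peaking at
  intermediate $d$ and spores rising monotonically to dominance at $d = 1$.
  Only these anchors and the simplex constraint are asserted; the map is a
  smooth package choice, and because sporulating cells are deliberately
  non-monotone in $d$, linear activity-on-sporulating-fraction fits are
  weaker than fits on the spore fraction.
* **Images** are rendered analytically: dark background, brighter dish
  disk, colony disk whose edge is an exact Gaussian-blurred step
  ($\Phi((R - \rho)/\sigma)$), multiplied by a linear shading field and
  degraded with seeded Gaussian noise — so the true subpixel radius is known
  exactly.

What passing tests on these data do **not** show: real RNA-seq has
gene-specific dispersions, batch effects, and regulon annotations that are
wrong in sign or membership for some regulators; real plate images have
vignetting, reflections, condensation, and texture inside the colony. The
synthetic generators span none of that, so recovery rates here are upper
bounds on real-data performance.

## Problem sizes

The shipped configurations are sized for a laptop-scale run: 400 genes × 16
samples for the transcriptome workflow, a 201-node radial grid with dt =
0.1 h (1 680 steps per weekly cycle), 2–5 passaging cycles per competition,
512×512 px images with 360 outline points. The full test suite runs in
about two minutes; the analysis scripts in about one.

## Known limitations

* The PDE instantiation is one concrete choice among those consistent with
  the qualitative model description; coefficients are nominal, so only
  directions, orderings, and scalings are meaningful.
* Activity inference assumes regulon annotations with correct modes; the
  negative expression-activity correlations reported for some real
  regulators indicate exactly the annotation caveats the synthetic data do
  not model.
* The silhouette criterion can only return k ≥ 2; a truly module-free
  matrix is reported via the degeneracy flag, not as k = 1.
* The outline pipeline assumes one colony per dish and grayscale input.
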