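---
title: "Quantifying perivascular cells in cleared nerve volumes: models, parameters and design choices"
author: "perivquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perivascular cells in cleared nerve volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perivquant)
```

This vignette is the package's own account of its science: the measurement
model, what the synthetic data emulate, the parameters that matter, the
numerical conventions, and the places where the design was genuinely open and
a choice had to be made.

## 1. The measurement model

A cleared sciatic nerve from a Pdgfrb-lineage reporter mouse is imaged as a
three-channel confocal z-stack: FITC-albumin fills vessel lumens, tdTomato
marks Pdgfrb+ cells (mural cells and fibroblasts alike), DAPI marks nuclei.
The quantification is deliberately simple and per-plane, mirroring how such
stacks are analysed interactively:

* **Vessel mask.** The FITC channel is thresholded; the vessel mask is the
  strict superlevel set, and vessel area per plane is voxel count × in-plane
  voxel area. Thresholds come in three flavours: `auto` (IsoData iterative
  intermeans — the common software default), `manual`, and `cross`
  (copy a threshold computed on another channel verbatim; applying the FITC
  threshold to tdTomato avoids condition-dependent drift of automatic
  tdTomato thresholds).
* **Broadening.** The vessel mask is dilated in-plane by a Euclidean disk of
  radius ⌈r/voxel⌉ pixels. This "artificial broadening" converts the vessel
  mask into a *vessel-proximity* mask; a nucleus overlapping
  tdTomato ∩ broadened-FITC is a putative mural cell.
* **Nuclei.** DAPI is segmented per plane: Gaussian smoothing (default
  0.7 µm), a single IsoData threshold computed over the whole stack, then a
  distance-transform watershed to split touching nuclei. ROIs under
  10 µm² are discarded *before any counting*. The segmenter is a classical,
  deterministic stand-in behind a method-agnostic contract (the original
  analyses used a trained star-convex-polygon network; any segmenter
  returning labelled per-plane ROIs can be slotted in).
* **Counting and averaging.** Per plane: `n_nuclei` ≥ `n_tdtomato` ≥
  `n_mural` by construction. Default overlap rule: at least one shared pixel
  (`overlap_frac = 0`); a minimum overlap fraction is available. Counts are
  averaged over five planes 8 µm apart, and when one nerve region was imaged
  twice, the per-image averages are averaged again — mean over planes first,
  then mean over images. That order matters for derived ratios and is fixed.

Two conventions deserve emphasis. First, the mural criterion tests the
*nucleus pixels* against the co-expression mask, not the whole soma; this is
the stricter reading and is stated in the function documentation. Second, the
broadening radius is not a published value; it defaults to 5 µm (the scale of
a mural soma's offset from the lumen) and is always echoed into the output
parameter log, because results are not interpretable without it.

## 2. What the synthetic volumes emulate — and what they do not

`build_scene()` + `render_volume()` generate scenes with exact ground truth:

* **Vessels** are tubes around polyline centerlines, rendered as FITC-filled
  lumens (the perfusion fills the lumen; walls are not outlined).
* **Mural cells** sit on the vessel surface: soma centre `wall_offset_um`
  (default 2 µm) outside the lumen, soma and nucleus spheroids elongated
  along the vessel axis. Counts are Poisson with mean
  density × centerline length × effect multiplier (default 20 cells /
  100 µm). Surface positions whose nucleus would leave the volume are
  resampled — only the imaged part of the wall carries cells — so a vessel
  wider than the stack is deep carries cells only on its imaged belt.
* **Fibroblasts** are Poisson in the non-vessel tissue volume (default
  8 cells / 10⁵ µm³), rejection-sampled to stay at least `exclusion_margin_um`
  (default 10 µm) from every vessel surface. Together with the 2 µm wall
  offset this guarantees an unambiguous ground-truth class boundary.
* **Rendering**: uniform-intensity rasterization (overlaps take the max),
  per-channel background, separable Gaussian PSF (defaults 0.6 µm in-plane,
  2 µm axial), Poisson shot noise at `photon_gain` (default 100 photons per
  intensity unit) and Gaussian read noise (default sd 0.01). Blur and noise
  are independently switchable, and rendering is linear in amplitude when
  noise is off.
* **Study design**: `simulate_group()` emits labelled (volume, truth) pairs
  per (condition, region) group with per-sample seeds derived from one master
  seed by a counter-based scheme, so any single sample can be regenerated.
  Effect multipliers scale densities per (condition, region); contralateral
  and sham groups default to 1.0.

**Default geometry.** The default scene is a single straight arteriole-scale
vessel (radius 24 µm) spanning the analysed z-range, with near-confluent
mural coverage. This mirrors the vessels actually selected in cleared-nerve
imaging — clearly visible vessels whose whole thickness the stack captures —
and it matters methodologically: with a thin capillary crossing only one
analysed plane, a mural cell whose nucleus surfaces on a neighbouring plane
can never overlap the broadened vessel mask there, i.e. the per-plane method
itself cannot see it. Stacks are 5 planes × 8 µm × 160 × 160 pixels at
0.62 µm (a typical 20×/0.8 NA field); pixel calibration and stack depth are
declared defaults, not values inferred from any source.

**Not emulated**: vascular branching and flow, photobleaching, depth-dependent
attenuation, clearing artefacts, non-uniform fluorophore expression, nuclear
texture. Passing recovery tests on these volumes therefore demonstrates that
the *measurement chain* is correct and unbiased under its own assumptions —
not that segmentation would survive every pathology of real tissue.

**Countability and evaluation.** With planes 8 µm apart and nucleus z
semi-axes of 2.5–3.5 µm, a cell between planes intersects none of them. The
ground-truth reference for recovery and precision/recall is therefore the set
of cells whose *rasterized* nucleus cross-section on an analysed plane reaches
the area filter (the rasterizer is shared with the renderer). On noise-free,
blur-free volumes with non-overlapping nuclei the per-plane counts equal this
reference exactly; on default-noise volumes, matching predicted to true cells
one-to-one within 5 µm gives F1 ≥ 0.90 for both classes. Those two properties
are asserted in the test suite.

## 3. Nonparametric statistics

`mann_whitney()` computes the exact two-sided test by the null U distribution
(full enumeration of rank assignments when ties are present) for small
samples, and the tie-corrected normal approximation (continuity correction on
by default, as in common statistical software) otherwise; `auto` switches at
n₁+n₂ ≤ 16 without ties. `kruskal_wallis()` is the tie-corrected H with a
χ² reference; all observations identical gives H = 0, p = 1 by definition.
`dunn_posthoc()` uses pooled mean ranks with tie correction and a
Bonferroni-style family adjustment (adjusted p = min(1, m·p) over the m
*requested* comparisons) — conservative, reproducible, and switchable to no
adjustment. All of these are cross-checked in the tests against independent
oracles (full enumeration, direct rank formulas) and against base R.

**Sensitivity analysis.** `minimum_detectable_effect()` simulates two normal
samples shifted by d·σ, applies the two-sided Mann–Whitney test at α to each
replicate, and returns the smallest grid d (step 0.02) whose estimated power
reaches the target, bracketing coarsely first and reporting a Monte-Carlo
confidence interval for the crossing. One choice here was genuinely open: the
simulated test uses the tie-corrected normal approximation *without*
continuity correction. That is the power-planning convention — the same
convention embodied by the closed-form comparator `mde_t_are()` (the t-test's
detectable d inflated by 1/√0.955, the asymptotic relative efficiency of the
rank test under normal alternatives) — and the two routes agree to within
0.02 at n = 10. The exact (or continuity-corrected) test is slightly
conservative at these sizes (actual size 0.043 rather than 0.05) and shifts
the detectable effect up by about 0.05; analysts planning with the exact test
should expect that shift. For data analysis, `mann_whitney()` keeps the
continuity correction.

## 4. Ligand–receptor communication scores

The DE table is consumed, never recomputed: `select_regulated_genes()` keeps
genes at adjusted p < α (default 0.05) with the requested sign, optionally
above a fold-change magnitude (a log2FC cutoff of 3 keeps only >8-fold
genes — the volcano-plot convention). Matching requires *every* receptor
subunit strictly above the expression threshold (default 0: any positive
expression), because a multi-chain receptor without one chain does not
signal; Il6, Lif and Clcf1 all require the gp130 chain Il6st.

The scoring formula is a documented stand-in (the analysis it emulates
delegates scoring to an external package without restating the formula):
per-pair contribution = scaled sender ligand expression × the minimum scaled
receiver expression over the subunits; family score = sum of its pairs. With
`minmax_0_10` scaling, each gene is rescaled to [0, 10] across the supplied
population panel, making scores invariant to global rescaling of expression
units. A gene absent from a population is expression 0 throughout the module
(matching the matching rule), so any expressed gene has a non-degenerate
range. The pre/post comparison of enabled-interaction counts is a two-sided
Fisher exact test on the 2×2 (matched/unmatched × pre/post) table with the
direction reported — an explicit interpretation, since the original analysis
does not state its test.

The synthetic tables mirror the biology being modelled: eight
injury-upregulated ligands (Il6, Lif, Clcf1, Ccl2, Ngf, Tnc, Spp1, Mmp9) over
a mostly-null background, a small curated pair database with families and
multi-subunit receptors spelled out, and three receiver profiles (NF neurons,
nociceptors, cLTMRs) with subtype structure (nociceptors rich in
Ntrk1/Ngfr/Ccr2; NF neurons in Ntrk2/Ncam1 and lacking Ntrk1).

## 5. Numerical conventions and degenerate inputs

* IsoData iterates t ← (mean below + mean above)/2 on a 256-bin histogram
  from the global mean to its fixed point; a constant image is a degeneracy
  error (callers that can face blank planes check first and return no ROIs).
* The stack-wide DAPI threshold exists because a sparsely populated single
  plane has no reliable bimodal histogram; per-plane IsoData on such planes
  shatters background noise into countable ROIs.
* Watershed tolerance is 1 distance-map pixel; smoothing is skipped when the
  Gaussian brush would not fit the plane.
* Dilation uses the exact Euclidean disk {(dy,dx): dy²+dx² ≤ r²}; radius 0 is
  the identity; mural counts are non-decreasing in the radius.
* TIFF volumes are stored as 32-bit integer samples n = round(intensity·2^k)
  with the exponent k in the YAML sidecar (written at 15-digit precision);
  the roundtrip is bitwise for intensities on that dyadic grid and within
  2⁻³⁰ relative error otherwise.
* Mann–Whitney exact mode with ties enumerates subsets only up to
  choose(n₁+n₂, n₁) ≤ 2×10⁵ and directs larger problems to the asymptotic
  mode. Degenerate Dunn variances (all observations equal) give z = 0, p = 1.
* Seeds: every stochastic entry point takes one; per-sample seeds derive from
  the master seed by an affine counter hash below 2³¹.

## 6. Problem sizes used in the shipped checks

The test suite and acceptance script size their simulations for a desk-scale
run: Poisson-placement checks use 1000 scene draws against the analytic mean;
the effect-multiplier ratio uses 200 draws per arm; recovery and F1 checks
pool four default volumes; the end-to-end power check repeats a 12-animal
experiment 50 times (observed rejection rate well above the 80% bound); and
the sensitivity analysis uses 10⁴ replicates per fine-grid point, which pins
the detectable effect to ±0.01–0.02 across seeds. These sizes are the
package's declared defaults for its own validation and can all be scaled up
through the same function arguments.

## 7. Known limitations

* Per-plane 2D segmentation (as in the emulated workflow): a cell is counted
  on each analysed plane its nucleus crosses; with 8 µm spacing and ~3 µm
  nuclei that is at most one plane, but denser sampling would double-count
  without additional linking.
* The classical watershed stand-in merges heavily overlapping nuclei more
  readily than a trained segmenter would; the F1 bound is evaluated under the
  default densities.
* Mural/fibroblast separation in truth is enforced by construction
  (wall offset ≪ exclusion margin); the package does not model ambiguous
  intermediate positions, so classification error rates on real tissue are
  not predicted by these simulations.
* The communication score is a transparent stand-in, not a reimplementation
  of any published scoring package; absolute score values are only comparable
  within one panel and scaling choice.
* Arteriole/venule/capillary typing is out of scope; vessel `type` labels
  pass through untouched.
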