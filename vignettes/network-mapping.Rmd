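---
title: "Coordinate-based functional connectivity network mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate-based functional connectivity network mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcnm)
```

## The problem

Neuroimaging studies of focal brain stimulation (the motivating case is
acupuncture at the ST36 and GB34 acupoints) report their findings as peak
activation coordinates — a handful of x/y/z triplets in MNI or Talairach
space per experiment. Coordinates scatter across studies, so asking "which
brain network does this stimulation site engage?" needs more than plotting
peaks. Functional connectivity network mapping answers it by passing every
study's coordinates through a *normative connectome*: resting-state fMRI
from a large healthy cohort that serves as a reference wiring diagram. Even
when two studies report different peaks, the network those peaks belong to
can agree — and that agreement is what the method quantifies.

## The mapping procedure

For each study (or contrast) the pipeline:

1. **Seeds.** Builds spheres of radius 4 mm around each reported
   coordinate and merges them into one seed mask per study. A voxel joins
   a sphere when its centre lies within the radius of the focus; the voxel
   containing the focus is always kept, so a 1 mm sphere on a 3 mm grid is
   still a well-defined single-voxel seed. Talairach-space coordinates are
   first mapped to MNI (see *Coordinate handling* below).
2. **Subject-level connectivity.** For every connectome subject, Pearson
   correlation between the seed's mean time series and every brain voxel,
   Fisher z-transformed (`atanh`) to stabilise variance:
   `z = atanh(r)`, with `r` clipped to `±(1 − 1e−7)` so maps stay finite.
3. **Group inference.** A voxel-wise one-sample t-test across subjects,
   `t = mean(z) / (sd(z)/√n)`, `df = n − 1`.
4. **Thresholding.** Benjamini–Hochberg FDR at `q = 0.01` over brain-mask
   voxels, keeping only positively connected voxels (`t > 0`); the
   surviving set is the study's binary network. Negative connectivity is
   excluded because its biological reading is contentious.
5. **Consensus.** Binary networks are overlaid into a probability map
   (per-voxel fraction of studies containing the voxel) and thresholded at
   60% agreement: over 14 studies a voxel must appear in at least 9
   (9/14 ≈ 0.643), over 4 studies in at least 3.

Downstream, the consensus network is decomposed against the seven
canonical cortical systems plus an aggregated subcortical label
(composition: network∩label voxels divided by network voxels, so the
shares plus the unassigned fraction sum to one), correlated with
receptor/transporter density maps over a ~119-region parcellation
(rank-based partial correlation with a gray-matter covariate, permutation
p-values, BH-FDR at 0.05 across the catalogue), and validated by Dice
overlap across seed radii (1/4/7 mm), across connectomes, and between
acupoints.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `radius_mm` | 4 | seed sphere radius (mm); 1 and 7 used for sensitivity |
| `fdr_q` | 0.01 | voxel-wise FDR for the group test |
| `probability_threshold` | 0.60 | consensus agreement level (inclusive) |
| `positive_only` | TRUE | restrict networks to positive connectivity |
| `n_permutations` | 10000 | permutations for the receptor screen |
| `nt_fdr_alpha` | 0.05 | FDR level across the receptor catalogue |

All of them live in one `fcnm_config()` object, read from YAML by
`read_config()`, and are recorded in every run manifest.

## Design choices where the procedure was genuinely open

* **Sidedness of the group test.** We default to a two-sided t-test with a
  post-hoc positive restriction (`t > 0`), because a stated significance
  level and a separate positive-connectivity rule compose naturally that
  way; a one-sided `"greater"` mode is available in the config for users
  who prefer the directional test. The two typically agree at `q = 0.01`
  apart from the halved p-values.
* **Inclusive consensus threshold.** `≥ 60%`, not `> 60%`: with 4 studies
  both rules keep the same voxels (3/4), and inclusivity keeps a
  threshold of 1.0 attainable.
* **Aggregation unit.** One seed per *study* by default, pooling its
  contrasts' coordinates, so each experiment contributes exactly one map
  to the probability overlay and the study counts (e.g. 14 and 4) are the
  consensus denominators. Per-contrast mode (`unit = "contrast"`) is
  retained for analyses phrased contrast-wise.
* **Talairach conversion.** The Lancaster `icbm_spm` affine (inverted at
  run time from the published matrix) is the default, being the current
  standard in coordinate-based meta-analysis; Brett's piecewise transform
  is selectable (`tal_method = "brett"`). The method used is recorded on
  the converted foci table.
* **Receptor-screen unit.** Two modes are implemented because the
  literature is ambiguous about what enters the group test: `single-map`
  (default) correlates the final consensus network once per receptor map
  with a permutation p; `subject-level` gives each subject's connectivity
  map its own Fisher-z rho and tests their mean against zero with a
  permuted-map null. Both share the same partial-Spearman core.
* **Permutation null.** Receptor-map values are permuted uniformly across
  parcels — an exchangeability null that ignores spatial autocorrelation.
  Spatial-autocorrelation-preserving nulls are out of scope here, but the
  permutation engine is isolated in `permutation_pvalue()` and easy to
  swap.
* **Voxel indexing.** The R API is 1-based (matching R arrays); the NIfTI
  affine maps 0-based indices to RAS mm as the format defines, and
  `mm_to_voxel()` / `voxel_to_mm()` absorb the offset. Rounding is
  half-away-from-zero so seed membership is platform-stable.

## Numerical conventions and degenerate inputs

* Correlations are clipped to `|r| ≤ 1 − 1e−7` before `atanh`; clipped or
  zero-variance voxels are flagged and the latter are excluded from the
  FDR family (they carry no test).
* Zero across-subject variance with nonzero mean gives `p = 0` (flagged
  degenerate); with zero mean, `t = 0, p = 1` and exclusion from the
  family.
* BH-FDR is computed through `stats::p.adjust(method = "BH")`; ties at the
  step-up threshold are all rejected, as the rule depends only on values.
* Permutation p-values use the add-one estimator
  `(1 + #{|rho_null| ≥ |rho_obs|}) / (B + 1)`, so the smallest attainable
  p is `1/(B + 1)` and p is never 0.
* Composition ties in reports break alphabetically by label name;
  Spearman ranks use average ranks for ties.
* An empty per-study network is allowed (logged) and still counts in the
  consensus denominator; an empty *seed* is an error naming the study.

## What the synthetic generator emulates — and what it does not

`gen_scene()` plants, per acupoint, a seed region nested inside a larger
ground-truth network on a small 3 mm grid (default 20×24×20 voxels with an
interior-box brain mask). `gen_connectome()` drives all voxels of a
planted system with a shared latent AR(1) signal `u(t)`:

```
x_v(t) = λ·u(t) + ε_v(t),   ε ~ N(0, σ²) iid,  Var(u) = 1
```

so any two driven voxels correlate at `λ²/(λ² + σ²)` in expectation — the
default `λ = √(2/3), σ = 1` plants 0.4, a realistic seed-based
resting-state effect size. `gen_foci()` scatters study coordinates over
the seed region with 1 mm jitter and draws study sample sizes ≥ 10;
the default scenario sizes are 14 studies for one acupoint and 4 for the
other, the canonical two-acupoint literature. `gen_atlas_and_parcellation()`
builds space-filling Voronoi labels (8 canonical, 119 parcels), optionally
forcing a known fraction of a planted network into a designated canonical
label; `gen_nt_catalogue()` plants Spearman correlations between receptor
maps and a target pattern through a Gaussian copula
(`ρ̃ = 2 sin(π ρ_s / 6)`).

The generator deliberately omits motion, physiological noise, spatial
smoothing, hemodynamics, and spatial autocorrelation of receptor maps:
the pipeline consumes *preprocessed* data, and the tests establish that
the statistics do what they claim on data satisfying their assumptions —
not that any particular empirical dataset satisfies them. Passing tests
therefore validate the machinery, not the neurobiology.

Every generator derives independent sub-streams from one base seed
(subject, unit, and map indices enter a fixed integer recurrence), so
regeneration is bit-identical under the same seed while subjects differ
from one another.

## Problem sizes used by the test suite

The packaged checks run the full pipeline at 40 subjects × 120 timepoints
with 6 planted-scene studies for recovery (Dice ≥ 0.8 against the planted
network), 20 subjects × 50 noise-only seeds for false-positive control
(< 0.5% of mask voxels surviving), 200 replicates × 999 permutations for
p-value calibration, and 500 replicates for copula calibration — sizes we
chose so the whole suite exercises every stage end-to-end in about a
minute on a laptop while keeping Monte-Carlo error well inside the stated
bounds.

## Known limitations

* No cluster-extent or mixed-effects inference; the group model is the
  voxel-wise one-sample t-test the mapping procedure specifies.
* The permutation null assumes parcel exchangeability (see above).
* Hard parcellations only; probabilistic atlases must be argmax-reduced
  upstream.
* Volumes must share one session grid; resampling is deliberately outside
  the package (a mismatched affine is an error, never a silent resample).
* The t-test against the 0.5 Dice benchmark is honest but fragile for the
  two-or-three comparisons it typically receives; `dice_below_half_test()`
  always reports the raw values and a degeneracy flag alongside p.

## A worked miniature

```{r example, eval = FALSE}
scene <- gen_scene(seed = 1)
foci <- gen_foci(scene, n_units = c(ST36 = 14, GB34 = 4))
connectome <- gen_connectome(scene)
res <- run_fcnm(foci, connectome, scene$grid, fcnm_config(seed = 1))
tidy(res)
dice_overlap(res$networks$ST36, scene_truth(scene, "ST36"))

maps <- gen_atlas_and_parcellation(scene, network_label = c(ST36 = "somatomotor"))
autoplot(overlap_profile(res$networks$ST36, maps$atlas))
```
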