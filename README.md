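# fcnm — functional connectivity network mapping from activation coordinates

Neuroimaging experiments on focal brain stimulation — the motivating case
is acupuncture at the ST36 (*Zusanli*) and GB34 (*Yanglingquan*)
acupoints — report their findings as peak activation coordinates that
scatter widely across studies. `fcnm` maps those scattered coordinates to
a *consensus brain network* by passing each study's coordinates through a
normative resting-state connectome, the logic of lesion/coordinate network
mapping applied to stimulation sites.

For each study, spheres of radius 4 mm around its reported foci form a
seed mask; for every connectome subject the seed's mean time series is
correlated with every brain voxel and Fisher z-transformed,
`z = atanh(r)`; a voxel-wise one-sample t-test
(`t = mean(z) / (sd(z)/√n)`, `df = n − 1`) under Benjamini–Hochberg FDR at
`q = 0.01` with a positive-connectivity restriction gives the study's
binary network; the per-study networks are overlaid into a probability
map and thresholded at **60% agreement** (≥ 9 of 14 studies, ≥ 3 of 4) to
define the consensus network. Downstream tools decompose that network
against the seven canonical cortical systems plus subcortex, correlate it
with receptor/transporter density maps by partial Spearman correlation
(gray-matter covariate, permutation p-values, FDR 0.05 across the
catalogue), and validate robustness via Dice overlap,
`D = 2|A∩B| / (|A| + |B|)`, across seed radii (1/4/7 mm), connectomes, and
acupoints.

Everything is testable without downloads: a synthetic-data module plants
ground-truth networks in a small connectome (latent AR(1) factor model
with driven-pair correlation `λ²/(λ²+σ²)`), generates foci tables,
atlases, parcellations, and receptor catalogues with calibrated planted
correlations.

## Worked example

```r
library(fcnm)

scene      <- gen_scene(seed = 1)                      # planted two-acupoint scene
foci       <- gen_foci(scene, n_units = c(ST36 = 14, GB34 = 4))
connectome <- gen_connectome(scene)                    # 40 subjects x 120 timepoints
res        <- run_fcnm(foci, connectome, scene$grid, fcnm_config(seed = 1))
res
#> <fcnm_result>
#>   ST36: 226 voxels from 14 unit maps at >= 60% agreement
#>   GB34: 225 voxels from 4 unit maps at >= 60% agreement

tidy(res)
#> # A tibble: 2 × 6
#>   acupoint n_unit_maps threshold min_agreeing_units network_voxels nonzero_probability_voxels
#> 1 ST36              14       0.6                  9            226        ...
#> 2 GB34               4       0.6                  3            225        ...

dice_overlap(res$networks$ST36, scene_truth(scene, "ST36"))
#> # A tibble: 1 × 6
#>   id_a  id_b  size_a size_b intersection  dice
#> 1 ST36  ST36     226    225          225 0.998

maps <- gen_atlas_and_parcellation(scene, network_label = c(ST36 = "somatomotor"))
head(overlap_profile(res$networks$ST36, maps$atlas), 3)
#> # A tibble: 3 × 4
#>   network label            n_voxels proportion
#> 1 ST36    somatomotor           180     0.796
#> 2 ST36    dorsal attention       34     0.150
#> 3 ST36    visual                 11     0.0487
```

Reading: 14 simulated studies were mapped through a 40-subject synthetic
connectome; the consensus ST36 network (226 voxels, requiring agreement of
at least 9 of 14 studies) recovers the planted ground-truth network at
Dice 0.998, and ~80% of its voxels fall in the canonical label the
generator assigned to it. `autoplot()` methods draw the composition polar
plot and the receptor-screen lollipop; `molecular_screen()`,
`radius_sensitivity()`, `dice_below_half_test()`, and
`acupoint_contrast()` cover the downstream analyses. `run_all()` chains
every stage on one config and writes NIfTI/CSV/JSON outputs with a hashed
manifest; `inst/cli/fcnm.R` is a thin shell wrapper over the same
functions.

See the vignette (`vignettes/network-mapping.Rmd`) for the model,
parameter meanings, design decisions, and limitations.

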