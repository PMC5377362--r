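# llmseg

Patch-based segmentation of compact brain structures (the hippocampus) from
T1-weighted MR volumes by **local linear mapping (LLM)** of image patches to
signed distance-field (DF) patches.

For each binary training label the package computes an exact signed
Euclidean distance field — positive inside the structure, negative outside,
magnitude the distance to the nearest opposite-class voxel. Aligned MR/DF
patch pairs sampled around the structure are compressed by k-means into a
*paired dictionary*: cluster centers as MR atoms `d_i^MR`, per-cluster DF
means as DF atoms `d_i^DF`. A test patch `x` is coded over its `k` nearest
MR atoms by locality-constrained linear coding (LLC),

    min_w || x - sum_j w_j d_j^MR ||^2   s.t.  sum_j w_j = 1,

(or by local anchor embedding, which adds `w >= 0`), and the weights are
transferred verbatim to the DF atoms to predict the patch's distance field —
the locally linear MR-to-DF map is the modelling assumption that licenses
the transfer. Overlapping patch predictions are fused per voxel by a
confidence-based weighted average (CWA) with weights
`exp(-r_u^2 / sigma^2(p))`, where `r_u` is the patch's coding residual and
`sigma^2(p) = min_u r_u^2 + epsilon` adapts to the most confident patch
covering the voxel. Thresholding the fused field at zero yields the label.
A synthetic phantom module (bent ellipsoids, partial-volume blur, textured
background, additive noise) makes the whole pipeline testable without any
MRI download, and Dice-overlap utilities evaluate it.

Intended users: researchers in medical image analysis who want a compact,
fully deterministic reference implementation of distance-field patch fusion
with a classic R modelling interface, plus the controlled synthetic
benchmark around it. Volumes are expected already preprocessed (skull
stripping, bias correction, registration are out of scope).

## Worked example

Train on four synthetic subjects, segment two held-out ones:

```r
library(llmseg)

base   <- phantom_params(grid_size = 32L, semi_axis_range = c(3, 7), noise_sd = 0.05)
cohort <- generate_cohort(6L, base, seed = 42L)

cfg <- llm_config(patch_edge = 5L, stride = 2L, n_atoms = 512L, k = 10L,
                  sample_stride = 2L, seed = 42L)
fit <- llm_train(lapply(cohort[1:4], `[[`, "mr"),
                 lapply(cohort[1:4], `[[`, "label"), config = cfg)
print(fit)
#> Local linear mapping segmentation model
#>   dictionary: 512 paired atoms, patch 5^3
#>   trained on 4 subject(s), 4236 patch pairs
#>   coding: LLC, k=10; fusion: cwa, stride 2

seg <- predict(fit, cohort[[5]]$mr)
print(seg)
#> <llm_segmentation> 32x32x32 voxels, 1080 patches (LLC, cwa), foreground 784 voxels
#>   residuals: median 4.501 [3.153, 9.983]; 0.65s code, 0.05s fuse

dsc(seg$label, cohort[[5]]$label)
#> [1] 0.9223
```

`fit` is an ordinary S3 model object (`print`, `summary`, `plot`,
`predict`); `seg` carries the fused distance field (`seg$df`), the binary
label (`seg$label`), per-patch coding residuals, and a per-voxel coverage
map. The held-out Dice overlap of 0.92 says that 92% agreement (by the
`2|A∩B|/(|A|+|B|)` measure) was reached on a subject whose shape and noise
the model never saw; the residual range in the printout is the confidence
signal the CWA fusion feeds on. On real data, replace the phantom lists
with `read_volume()` NIfTI volumes (plus optional ROI masks) — the
interface is identical, and `inst/cli/llm` exposes the same pipeline as
`llm train | segment | evaluate | simulate | experiment` for shell use.

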