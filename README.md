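# hsiseg — unsupervised spatio-spectral segmentation of hyperspectral images

`hsiseg` segments biomedical Raman / infrared hyperspectral images (HSIs)
without any labelled training data.  It is built for the situation where
tissue regions share the same molecular constituents — so pixel-spectrum
clustering cannot tell them apart — but differ in how those constituents
are arranged in space.

## The method

An HSI cube (height × width × bands) is decomposed into overlapping
`p × p` patches on a raster grid of step `s`.  A convolutional
autoencoder (CAE) compresses each patch `x_i` into a latent vector
`l̄_i` (length 100 by default) that encodes the patch's joint
spatio-spectral content.  Patches are then grouped in latent space, two
ways:

* **CAE+k-means** — k-means on the latents of a reconstruction-only
  pretrained CAE;
* **end-to-end clustering** — a clustering head computes Student's-t
  soft assignments
  `q_ij ∝ (1 + ‖l̄_i − μ_j‖²/α)^(−(α+1)/2)` around `k` learnable
  centres, and the CAE and centres are trained jointly under
  `L = L_rec + γ·KL(P‖Q)`, where `P` is the sharpened target
  distribution `p_ij ∝ q_ij²/f_j` (`f_j` the soft cluster frequencies).
  Feature extraction is thereby optimised *for the clustering task*,
  not just for reconstruction.

Per-patch labels are rasterised back into a pixel label map (overlapping
footprints, later patches overwriting earlier ones), edge artefacts are
cropped, and segmentations are scored against ground truth with
normalised mutual information (NMI) and the adjusted Rand score (ARS).
A spectral k-means baseline (k-means on raw pixel spectra) is included
as the purely spectral point of comparison.

Three CAE architectures are provided: a branched 2D network (`uwu2d`,
default) whose activation maps are each processed by their own encoder
branch, a parameter-matched generic 2D CAE, and a generic 3D CAE.
A synthetic tissue-phantom simulator regenerates the standard test bed:
240 × 240 cubes of muscle carrying one solid, one striped and one
globular fat section (exactly two distinct pixel spectra), with the
pattern kind as ground truth.

## A worked example

```r
library(hsiseg)

# a small phantom: 120 x 120 pixels, 60 spectral points, three fat patterns
cube <- phantom_hsi(height = 120, width = 120, bands = 60, seed = 1)
cube
#> <hsi_cube> 120 x 120 pixels, 60 bands (444.2-2026 cm^-1), with ground truth

# spectral k-means separates fat from muscle but not the three patterns
sk <- spectral_kmeans(cube, k = 3, seed = 1)
#> Warning: only 2 distinct points for k = 3; 1 cluster(s) left empty
nmi(sk$label_map, truth_label_map(cube))
#> [1] 0.2609764

# spatio-spectral route: patches -> pretrained CAE -> joint clustering
# (a few minutes on one CPU core at these sizes)
ps  <- normalize_patches(extract_patches(cube, p = 20, s = 4))
cfg <- cae_config("uwu2d", patch_size = 20, bands = 60, seed = 1)
tc  <- train_config(max_pretrain_epochs = 20, max_joint_epochs = 10, seed = 1)
pre <- pretrain_cae(build_cae(cfg), ps, tc)
fit <- train_end_to_end(pre$cae, ps, k = 3, tc)

map   <- crop_edge_artifacts(reconstruct_label_map(fit$labels, ps), 20, 4)
truth <- crop_edge_artifacts(truth_label_map(cube), 20, 4)
nmi(map, truth)
#> [1] 0.4657668
ars(map, truth)
#> [1] 0.3683893
```

The spectral baseline's NMI against the three-pattern ground truth is
0.26: spectra alone only reveal the fat/muscle split, which cuts across
all three sections.  The spatio-spectral segmentation nearly doubles
that (0.47 on this deliberately small demo; the full-scale 240 × 240
study below averages around 0.56), because the latent vectors see each
patch's texture.  `plot(map)` displays the label map;
`write_label_map()` exports it as PNG + CSV.

The same pipeline applies to real cubes: `read_hsi()` reads ENVI
(BSQ/BIL/BIP) or band-stacked TIFF, `resample_band()` truncates and
re-grids the spectral axis (e.g. to the 1000–1800 cm⁻¹ fingerprint
region at 1 cm⁻¹), and `segment_cube()` applies a trained model.  A thin
command-line interface (`inst/cli/hsiseg`) wraps `simulate`, `train`,
`segment` and `evaluate` for shell use.

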