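#' Run the full phantom segmentation study for one seed
#'
#' End-to-end driver for the canonical synthetic experiment: generate a
#' 240 x 240 phantom with one solid, one striped and one globular fat
#' section; extract 20 x 20 patches at step 4 and normalise them; pretrain
#' the chosen CAE; segment both ways — CAE+k-means (no joint training) and
#' end-to-end clustering — reconstruct the pixel label maps, crop the edge
#' artefacts, and score both maps against the pattern ground truth with NMI
#' and ARS.  A spectral k-means map can be scored alongside as the purely
#' spectral reference.
#'
#' @param seed master seed; phantom, initialisation, batching and k-means
#'   all draw named sub-streams from it.
#' @param bands spectral points of the phantom (default 100, the desk-scale
#'   axis spanning the full wavenumber range).
#' @param k number of clusters (default 3, one per fat pattern kind).
#' @param arch CAE architecture, see [cae_config()].
#' @param patch_size,step patch geometry in pixels.
#' @param height,width phantom size in pixels.
#' @param tc a [train_config()]; its seed is overridden by `seed`.  The
#'   default caps pretraining at 25 epochs and joint training at 12 — the
#'   desk-scale study size (the assignment-stability rule typically fires
#'   before the joint cap anyway).
#' @param include_spectral also run [spectral_kmeans()] with the same `k`.
#' @param verbose print training progress.
#' @return a list with `scores` (one-row data frame: `nmi_end_to_end`,
#'   `ars_end_to_end`, `nmi_cae_kmeans`, `ars_cae_kmeans`, and spectral
#'   columns when requested), `maps` (cropped [label_map]s plus the cropped
#'   truth), `fit` (the [train_end_to_end()] result) and `pretrain_history`.
#' @export
phantom_benchmark <- function(seed = 1L, bands = 100L, k = 3L,
                              arch = "uwu2d", patch_size = 20L, step = 4L,
                              height = 240L, width = 240L,
                              tc = train_config(max_pretrain_epochs = 25L,
                                                max_joint_epochs = 12L),
                              include_spectral = FALSE, verbose = FALSE) {
  cube <- phantom_hsi(height = height, width = width, bands = bands,
                      seed = substream_seed(seed, "phantom"))
  ps <- normalize_patches(extract_patches(cube, patch_size, step))
  cfg <- cae_config(arch, patch_size = patch_size, bands = bands,
                    seed = substream_seed(seed, "weights"))
  tc$seed <- substream_seed(seed, "train")
  pre <- pretrain_cae(build_cae(cfg), ps, tc, verbose = verbose)

  km_labels <- cae_kmeans(pre$cae, ps, k, seed = substream_seed(seed, "kmeans"))
  fit <- train_end_to_end(pre$cae, ps, k, tc, verbose = verbose)

  crop <- function(m) crop_edge_artifacts(m, patch_size, step)
  truth_c <- crop(truth_label_map(cube))
  map_km <- crop(reconstruct_label_map(km_labels, ps,
                                       provenance = "cae_kmeans"))
  map_e2e <- crop(reconstruct_label_map(fit$labels, ps,
                                        provenance = "end_to_end"))
  scores <- data.frame(
    seed = seed,
    nmi_end_to_end = nmi(map_e2e, truth_c),
    ars_end_to_end = ars(map_e2e, truth_c),
    nmi_cae_kmeans = nmi(map_km, truth_c),
    ars_cae_kmeans = ars(map_km, truth_c))
  maps <- list(end_to_end = map_e2e, cae_kmeans = map_km, truth = truth_c)
  if (include_spectral) {
    sk <- spectral_kmeans(cube, k, seed = substream_seed(seed, "spectral"))
    map_sk <- crop(sk$label_map)
    scores$nmi_spectral_kmeans <- nmi(map_sk, truth_c)
    scores$ars_spectral_kmeans <- ars(map_sk, truth_c)
    maps$spectral_kmeans <- map_sk
  }
  list(scores = scores, maps = maps, fit = fit,
       pretrain_history = pre$history)
}

#' Segment a cube with a trained model
#'
#' Applies a pretrained (or jointly trained) CAE plus a cluster state to a
#' cube: extract and normalise patches, encode, soft-assign to the centres,
#' and reconstruct the pixel label map.
#'
#' @param cube an [hsi_cube].
#' @param cae a trained [build_cae()] model.
#' @param cs an [init_centers()] cluster state (e.g. `fit$centers` from
#'   [train_end_to_end()]).
#' @param patch_size,step patch geometry.
#' @param mode reconstruction mode, see [reconstruct_label_map()].
#' @return a [label_map] (uncropped; apply [crop_edge_artifacts()] before
#'   scoring).
#' @export
segment_cube <- function(cube, cae, cs, patch_size = 20L, step = 4L,
                         mode = "raster_overwrite") {
  ps <- normalize_patches(extract_patches(cube, patch_size, step))
  q <- soft_assign(encode(cae, ps), cs)
  reconstruct_label_map(max.col(q, ties.method = "first"), ps, mode = mode,
                        provenance = "end_to_end")
}
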