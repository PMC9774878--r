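#' Decompose a cube into overlapping patches
#'
#' Slides a `p x p` window over the cube in raster order (rows outer,
#' columns inner) with step `s` pixels, yielding
#' `(floor((H - p) / s) + 1) * (floor((W - p) / s) + 1)` patches.  Patch
#' coordinates are the 0-based (row, col) of each top-left pixel.
#'
#' Patches are stored column-wise in a `(p * p * B) x N` matrix whose rows
#' follow the band-fastest `(band, row, col)` layout, the format consumed
#' by the autoencoders (their first layer mixes spectra per pixel, so the
#' spectrum of each pixel is kept contiguous); [get_patch()] returns the
#' conventional `p x p x B` array view.
#'
#' @param cube an [hsi_cube].
#' @param p patch side in pixels.
#' @param s step (stride) in pixels.
#' @return an object of class `patch_set` with fields `patches`, `coords`,
#'   `patch_size`, `step`, `source_shape`, `norm`.
#' @export
#' @examples
#' cube <- phantom_hsi(height = 60, width = 60, bands = 20, seed = 1)
#' ps <- extract_patches(cube, p = 20, s = 4)
#' nrow(ps$coords)  # 11 * 11 patches
extract_patches <- function(cube, p, s) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$data); H <- d[1L]; W <- d[2L]; B <- d[3L]
  if (p > H || p > W)
    stop("patch size p = ", p, " exceeds the cube's spatial extent",
         call. = FALSE)
  if (s < 1) stop("step s must be >= 1", call. = FALSE)
  p <- as.integer(p); s <- as.integer(s)
  r0 <- seq.int(0L, H - p, by = s)   # 0-based top-left rows
  c0 <- seq.int(0L, W - p, by = s)
  coords <- cbind(row = rep(r0, each = length(c0)),
                  col = rep(c0, times = length(r0)))
  N <- nrow(coords)
  v <- as.numeric(cube$data)
  # linear offsets of one patch anchored at (0, 0), (band, row, col) order
  off <- as.vector(outer((seq_len(B) - 1L) * H * W,
                         outer(seq_len(p), (seq_len(p) - 1L) * H, "+"),
                         "+"))
  X <- matrix(0, length(off), N)
  shift <- coords[, 1L] + coords[, 2L] * H
  for (i in seq_len(N)) X[, i] <- v[off + shift[i]]
  structure(
    list(patches = X, coords = coords, patch_size = p, step = s,
         source_shape = d,
         norm = list(global_max = max(max(v), 0), negatives_zeroed = FALSE)),
    class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf(
    "<patch_set> %d patches of %d x %d x %d (step %d) from a %d x %d cube%s\n",
    ncol(x$patches), x$patch_size, x$patch_size, x$source_shape[3L], x$step,
    x$source_shape[1L], x$source_shape[2L],
    if (isTRUE(x$norm$negatives_zeroed)) ", normalized" else ""))
  invisible(x)
}

#' Retrieve one patch as an array
#'
#' @param ps a [extract_patches()] patch set.
#' @param i patch index (1-based, raster order).
#' @return a `p x p x B` array.
#' @export
get_patch <- function(ps, i) {
  stopifnot(inherits(ps, "patch_set"), i >= 1, i <= ncol(ps$patches))
  aperm(array(ps$patches[, i],
              c(ps$source_shape[3L], ps$patch_size, ps$patch_size)),
        c(2L, 3L, 1L))
}

#' Zero negatives and scale patches by the global maximum
#'
#' Negative intensities are clipped to zero, then every patch is divided by
#' the single maximum over all extracted data (with the standard full-cover
#' patch grid this is the maximum pixel amplitude of the whole cube), so
#' all values end up in `[0, 1]`.  The operation is idempotent.
#'
#' @param ps a [extract_patches()] patch set.
#' @return the patch set with normalised values and a filled normalisation
#'   record (`norm$global_max`, `norm$negatives_zeroed`).
#' @export
normalize_patches <- function(ps) {
  stopifnot(inherits(ps, "patch_set"))
  X <- ps$patches
  X[X < 0] <- 0
  gm <- max(X)
  if (gm <= 0)
    stop("cannot normalise: no strictly positive value in the cube",
         call. = FALSE)
  ps$patches <- X / gm
  ps$norm <- list(global_max = gm, negatives_zeroed = TRUE)
  ps
}

#' 2D class-label image
#'
#' @param labels integer matrix of class ids (>= 1; `NA` marks pixels not
#'   covered by any patch).
#' @param n_classes number of classes; defaults to the largest label.
#' @param provenance one of `"end_to_end"`, `"cae_kmeans"`,
#'   `"spectral_kmeans"`, `"truth"`.
#' @return an object of class `label_map`.
#' @export
label_map <- function(labels, n_classes = NULL,
                      provenance = c("end_to_end", "cae_kmeans",
                                     "spectral_kmeans", "truth")) {
  provenance <- match.arg(provenance)
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (is.null(n_classes)) n_classes <- max(labels, 0L, na.rm = TRUE)
  structure(list(labels = labels, n_classes = as.integer(n_classes),
                 provenance = provenance, crop = NULL),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d, %d classes, provenance '%s'%s\n",
              nrow(x$labels), ncol(x$labels), x$n_classes, x$provenance,
              if (is.null(x$crop)) "" else
                sprintf(", cropped by %d px", x$crop$margin)))
  invisible(x)
}

#' @export
plot.label_map <- function(x, palette_seed = 1L, ...) {
  k <- max(x$n_classes, 1L)
  pal <- label_palette(k, palette_seed)
  graphics::image(t(x$labels)[, nrow(x$labels):1, drop = FALSE],
                  col = pal, zlim = c(1, k), axes = FALSE, asp = 1, ...)
  invisible(x)
}

#' Rebuild a 2D label map from per-patch cluster assignments
#'
#' Mirrors the segmentation-image reconstruction used with overlapping
#' tiles: in `"raster_overwrite"` mode each patch paints its label over its
#' `p x p` footprint in raster order, later patches overwriting earlier
#' ones (this is what produces the characteristic bottom/right edge bands
#' and the small diagonal offset; see [crop_edge_artifacts()]).  In
#' `"majority"` mode each pixel takes the modal label over all covering
#' patches, ties going to the lowest label id.
#'
#' @param labels integer vector, one cluster label per patch (raster order).
#' @param ps the [extract_patches()] patch set the labels refer to.
#' @param mode `"raster_overwrite"` (default) or `"majority"`.
#' @param provenance recorded in the output map.
#' @return a [label_map]; pixels not covered by any patch (possible when
#'   `(H - p)` is not a multiple of `s`) are `NA`.
#' @export
reconstruct_label_map <- function(labels, ps,
                                  mode = c("raster_overwrite", "majority"),
                                  provenance = "end_to_end") {
  stopifnot(inherits(ps, "patch_set"))
  mode <- match.arg(mode)
  N <- nrow(ps$coords)
  if (length(labels) != N)
    stop("got ", length(labels), " labels for ", N, " patches", call. = FALSE)
  labels <- as.integer(labels)
  H <- ps$source_shape[1L]; W <- ps$source_shape[2L]; p <- ps$patch_size
  k <- max(labels)
  if (mode == "raster_overwrite") {
    m <- matrix(NA_integer_, H, W)
    for (i in seq_len(N)) {
      r <- ps$coords[i, 1L]; c <- ps$coords[i, 2L]
      m[(r + 1L):(r + p), (c + 1L):(c + p)] <- labels[i]
    }
  } else {
    cnt <- matrix(0L, H * W, k)
    pix0 <- as.vector(outer(seq_len(p), (seq_len(p) - 1L) * H, "+"))
    for (i in seq_len(N)) {
      ix <- pix0 + ps$coords[i, 1L] + ps$coords[i, 2L] * H +
        (labels[i] - 1L) * H * W
      cnt[ix] <- cnt[ix] + 1L
    }
    m <- matrix(max.col(cnt, ties.method = "first"), H, W)
    m[matrix(rowSums(cnt) == 0L, H, W)] <- NA_integer_
  }
  label_map(m, n_classes = k, provenance = provenance)
}

#' Crop reconstruction artefacts from a label map
#'
#' Overlap-reconstructed maps carry block/smear artefacts in a band of
#' thickness equal to the patch size along the bottom and right edges
#' (patches there are overwritten by fewer neighbours), plus a subtle
#' diagonal translation related to the step size.  This removes a `p`-wide
#' band from the bottom and right (plus an optional extra alignment
#' margin), and can optionally shift the map by `(s, s)` towards the top
#' left first to undo the translation.
#'
#' @param m a [label_map].
#' @param p patch size in pixels.
#' @param s step size in pixels (used only when `shift = TRUE`).
#' @param align_margin extra margin (pixels) cropped from all four edges.
#' @param shift if `TRUE`, translate by `(s, s)` before cropping.
#' @return the cropped [label_map]; the crop is recorded in `$crop`.
#' @export
crop_edge_artifacts <- function(m, p, s = NULL, align_margin = 0L,
                                shift = FALSE) {
  stopifnot(inherits(m, "label_map"))
  lab <- m$labels
  if (shift) {
    if (is.null(s)) stop("`s` is required when shift = TRUE", call. = FALSE)
    lab <- lab[(s + 1L):nrow(lab), (s + 1L):ncol(lab), drop = FALSE]
  }
  a <- as.integer(align_margin)
  H <- nrow(lab); W <- ncol(lab)
  if (H - p - 2L * a < 1L || W - p - 2L * a < 1L)
    stop("crop exceeds the map size", call. = FALSE)
  lab <- lab[(1L + a):(H - p - a), (1L + a):(W - p - a), drop = FALSE]
  out <- label_map(lab, n_classes = m$n_classes, provenance = m$provenance)
  out$crop <- list(margin = p + a, align_margin = a, shifted = shift,
                   previous = m$crop)
  out
}
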