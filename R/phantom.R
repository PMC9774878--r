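#' Divide an image into rectangular tissue sections
#'
#' A section map partitions the image into rectangles, each carrying one fat
#' pattern kind (`"solid"`, `"stripes"` or `"globules"`).  The rectangles
#' must tile the image exactly (no gaps, no overlap).
#'
#' @param height,width image dimensions in pixels.
#' @param layout list of sections, each a list with fields `row`, `col`
#'   (top-left corner, 1-based), `height`, `width`, `pattern`.  Defaults to
#'   [default_section_layout()].
#' @param seed optional integer seed (the default layouts are deterministic;
#'   kept so randomised layouts stay reproducible).
#' @return an object of class `section_map` with fields `labels`
#'   (`height x width` integer matrix of section ids) and `patterns`
#'   (character vector, one pattern kind per section).
#' @export
#' @examples
#' sm <- make_section_layout(240, 240)
#' table(sm$patterns)
make_section_layout <- function(height, width,
                                layout = default_section_layout(height, width),
                                seed = NULL) {
  stopifnot(height >= 1, width >= 1, length(layout) >= 1)
  .local_seed(seed)
  kinds <- c("solid", "stripes", "globules")
  labels <- matrix(0L, height, width)
  cover <- matrix(0L, height, width)
  patterns <- character(length(layout))
  for (i in seq_along(layout)) {
    sec <- layout[[i]]
    stopifnot(all(c("row", "col", "height", "width", "pattern") %in% names(sec)))
    if (!sec$pattern %in% kinds)
      stop("unknown pattern kind: ", sec$pattern, call. = FALSE)
    r <- sec$row + seq_len(sec$height) - 1L
    c <- sec$col + seq_len(sec$width) - 1L
    if (min(r) < 1L || max(r) > height || min(c) < 1L || max(c) > width)
      stop("section ", i, " exceeds the image bounds", call. = FALSE)
    labels[r, c] <- i
    cover[r, c] <- cover[r, c] + 1L
    patterns[i] <- sec$pattern
  }
  if (any(cover > 1L))
    stop("layout rectangles overlap", call. = FALSE)
  if (any(cover == 0L))
    stop("layout rectangles do not cover the image", call. = FALSE)
  structure(list(labels = labels, patterns = patterns, layout = layout),
            class = "section_map")
}

#' Default three-section phantom layout
#'
#' Three equal horizontal bands: solid fat on top, striped fat in the
#' middle, fat globules at the bottom — one section of each pattern kind,
#' matching the canonical phantom geometry.
#'
#' @param height,width image dimensions in pixels (height must be
#'   divisible by 3).
#' @return a layout list for [make_section_layout()].
#' @export
default_section_layout <- function(height = 240, width = 240) {
  if (height %% 3L != 0L)
    stop("default layout needs a height divisible by 3", call. = FALSE)
  h <- height %/% 3L
  list(
    list(row = 1L,         col = 1L, height = h, width = width, pattern = "solid"),
    list(row = h + 1L,     col = 1L, height = h, width = width, pattern = "stripes"),
    list(row = 2L * h + 1L, col = 1L, height = h, width = width, pattern = "globules"))
}

#' @export
print.section_map <- function(x, ...) {
  cat(sprintf("<section_map> %d x %d, %d sections (%s)\n",
              nrow(x$labels), ncol(x$labels), length(x$patterns),
              paste(x$patterns, collapse = ", ")))
  invisible(x)
}

#' Render the binary fat mask over a section map
#'
#' Fills each section according to its pattern kind: solid sections are
#' entirely fat; striped sections alternate fat/muscle bands of the given
#' width and period (measured from the section's own top edge); globule
#' sections receive randomly placed fat disks until the requested fill
#' fraction is reached.
#'
#' @param sections a [make_section_layout()] object.
#' @param stripe_width,stripe_period stripe geometry in pixels
#'   (`stripe_width` fat rows out of every `stripe_period`).
#' @param globule_radius numeric pair, min/max disk radius in pixels; radii
#'   are drawn uniformly from this range.
#' @param globule_fill target fat area fraction in globule sections,
#'   in (0, 1); disks may overlap, so the achieved fraction overshoots by at
#'   most one disk.
#' @param orientation `"horizontal"` (default) or `"vertical"` stripes.
#' @param seed integer seed controlling globule placement.
#' @return an object of class `fat_mask` with fields `mask` (binary matrix,
#'   1 = fat) and `sections` (the input section map).
#' @export
#' @examples
#' sm <- make_section_layout(120, 120, list(
#'   list(row = 1, col = 1, height = 120, width = 120, pattern = "globules")))
#' fm <- render_fat_mask(sm, seed = 1)
#' mean(fm$mask)
render_fat_mask <- function(sections, stripe_width = 8, stripe_period = 16,
                            globule_radius = c(3, 6), globule_fill = 0.3,
                            orientation = c("horizontal", "vertical"),
                            seed = 1L) {
  stopifnot(inherits(sections, "section_map"))
  orientation <- match.arg(orientation)
  if (stripe_width <= 0 || stripe_period <= 0 || stripe_width > stripe_period)
    stop("need 0 < stripe_width <= stripe_period", call. = FALSE)
  if (length(globule_radius) != 2L || any(globule_radius <= 0) ||
      globule_radius[1L] > globule_radius[2L])
    stop("`globule_radius` must be an increasing positive pair", call. = FALSE)
  if (globule_fill <= 0 || globule_fill >= 1)
    stop("`globule_fill` must lie in (0, 1)", call. = FALSE)
  .local_seed(seed)

  lab <- sections$labels
  H <- nrow(lab); W <- ncol(lab)
  mask <- matrix(0L, H, W)
  for (i in seq_along(sections$patterns)) {
    inside <- lab == i
    idx <- which(inside, arr.ind = TRUE)
    r0 <- min(idx[, 1L]); c0 <- min(idx[, 2L])
    bb_h <- max(idx[, 1L]) - r0 + 1L; bb_w <- max(idx[, 2L]) - c0 + 1L
    kind <- sections$patterns[i]
    if (kind == "solid") {
      mask[inside] <- 1L
    } else if (kind == "stripes") {
      pos <- if (orientation == "horizontal") idx[, 1L] - r0 else idx[, 2L] - c0
      sel <- (pos %% stripe_period) < stripe_width
      mask[idx[sel, , drop = FALSE]] <- 1L
    } else { # globules
      if (2 * globule_radius[2L] >= min(bb_h, bb_w))
        stop("globule radius too large for section ", i, call. = FALSE)
      area <- nrow(idx)
      filled <- inside & FALSE
      guard <- 0L
      while (sum(mask[inside]) / area < globule_fill) {
        guard <- guard + 1L
        if (guard > 100000L) stop("globule placement failed to converge")
        ctr <- idx[sample.int(nrow(idx), 1L), ]
        rad <- runif(1L, globule_radius[1L], globule_radius[2L])
        rr <- max(1L, floor(ctr[1L] - rad)):min(H, ceiling(ctr[1L] + rad))
        cc <- max(1L, floor(ctr[2L] - rad)):min(W, ceiling(ctr[2L] + rad))
        d2 <- outer((rr - ctr[1L])^2, (cc - ctr[2L])^2, "+")
        disk <- d2 <= rad^2 & inside[rr, cc, drop = FALSE]
        sub <- mask[rr, cc, drop = FALSE]
        sub[disk] <- 1L
        mask[rr, cc] <- sub
      }
    }
  }
  structure(list(mask = mask, sections = sections), class = "fat_mask")
}

#' @export
print.fat_mask <- function(x, ...) {
  cat(sprintf("<fat_mask> %d x %d, fat fraction %.3f\n",
              nrow(x$mask), ncol(x$mask), mean(x$mask)))
  invisible(x)
}

#' Assemble a two-endmember hyperspectral cube from a fat mask
#'
#' Every fat pixel receives the fat endmember spectrum and every muscle
#' pixel the muscle spectrum, giving an idealised cube with exactly two
#' distinct pixel spectra.  The ground-truth image is either the pattern
#' kind of each pixel's section (default; solid = 1, stripes = 2,
#' globules = 3) or the raw section id.
#'
#' @param fat a [render_fat_mask()] object.
#' @param fat_spec,muscle_spec [synth_endmember()] objects sharing one axis.
#' @param truth_mode `"pattern"` (default) or `"section"`.
#' @param noise_sd standard deviation of optional additive Gaussian noise
#'   (default 0, i.e. the idealised noiseless phantom); negative intensities
#'   created by noise are kept (they are zeroed during patch normalisation).
#' @param seed seed for the noise draw.
#' @return an [hsi_cube] with a `truth` image attached.
#' @export
assemble_hsi <- function(fat, fat_spec, muscle_spec,
                         truth_mode = c("pattern", "section"),
                         noise_sd = 0, seed = NULL) {
  stopifnot(inherits(fat, "fat_mask"), inherits(fat_spec, "endmember"),
            inherits(muscle_spec, "endmember"))
  truth_mode <- match.arg(truth_mode)
  if (!isTRUE(all.equal(fat_spec$axis$values, muscle_spec$axis$values)))
    stop("endmembers do not share a wavenumber axis", call. = FALSE)
  mask <- fat$mask
  H <- nrow(mask); W <- ncol(mask); B <- fat_spec$axis$count
  m <- as.numeric(mask)
  dat <- tcrossprod(m, fat_spec$intensity) +
    tcrossprod(1 - m, muscle_spec$intensity)   # (H*W) x B
  if (noise_sd > 0) {
    .local_seed(seed)
    dat <- dat + rnorm(length(dat), sd = noise_sd)
  }
  dim(dat) <- c(H, W, B)
  sm <- fat$sections
  truth <- if (truth_mode == "pattern") {
    kind_id <- match(sm$patterns, c("solid", "stripes", "globules"))
    matrix(kind_id[sm$labels], H, W)
  } else sm$labels
  hsi_cube(dat, fat_spec$axis, truth = truth)
}

#' Generate a complete synthetic fat/muscle phantom cube
#'
#' One-call builder for the standard phantom: a 240 x 240 muscle image with
#' one solid, one striped and one globular fat section, two endmember
#' spectra (fat assigned to every fat pixel, muscle to every muscle pixel)
#' and a pattern-kind ground truth.  The spectral axis spans the full
#' 444.2-2026.2 cm^-1 range at any band count: 800 bands reproduce the
#' native 1.98 cm^-1 grid, while the default 100 bands keep desk-scale
#' training runs affordable without changing the experiment's logic.
#'
#' @param height,width spatial size in pixels.
#' @param bands number of spectral points.
#' @param layout section layout, see [make_section_layout()].
#' @param stripe_width,stripe_period,globule_radius,globule_fill,orientation
#'   pattern parameters, see [render_fat_mask()].
#' @param truth_mode,noise_sd see [assemble_hsi()].
#' @param seed master seed; globule placement and noise draw from named
#'   sub-streams of it.
#' @return an [hsi_cube] with ground truth.
#' @export
#' @examples
#' cube <- phantom_hsi(height = 60, width = 60, bands = 40, seed = 1)
#' dim(cube$data)
phantom_hsi <- function(height = 240, width = 240, bands = 100,
                        layout = default_section_layout(height, width),
                        stripe_width = 8, stripe_period = 16,
                        globule_radius = c(3, 6), globule_fill = 0.3,
                        orientation = "horizontal",
                        truth_mode = "pattern", noise_sd = 0, seed = 1L) {
  axis <- make_wavenumber_axis(444.2, 1.98 * 799 / (bands - 1), bands)
  sm <- make_section_layout(height, width, layout)
  fm <- render_fat_mask(sm, stripe_width, stripe_period, globule_radius,
                        globule_fill, orientation,
                        seed = substream_seed(seed, "mask"))
  assemble_hsi(fm, endmember_preset("fat", axis),
               endmember_preset("muscle", axis),
               truth_mode = truth_mode, noise_sd = noise_sd,
               seed = substream_seed(seed, "noise"))
}
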