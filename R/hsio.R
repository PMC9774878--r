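# Cube and label-map I/O.
#
# The canonical on-disk container is ENVI (a plain-text .hdr beside a flat
# binary file), the de-facto interchange format of spectroscopy tooling;
# the wavenumber axis travels in the header's `wavelength` block and the
# ground truth (if any) in a CSV sidecar.  Band-stacked TIFF (32-bit float,
# one directory per band, axis in a CSV sidecar) is provided for image
# tooling interoperability.

#' Write a hyperspectral cube to disk
#'
#' @param cube an [hsi_cube].
#' @param path output path without extension; `write_hsi` creates
#'   `path.raw` + `path.hdr` (ENVI) or `path.tif` (+ `path.axis.csv`), plus
#'   `path.truth.csv` when ground truth is present.
#' @param format `"envi"` (default) or `"tiff"`.
#' @param interleave ENVI band order: `"bsq"` (band sequential, default),
#'   `"bil"` or `"bip"`.
#' @param data_type ENVI data type code: 5 = 64-bit float (default,
#'   lossless round trip) or 4 = 32-bit float.
#' @return the paths written, invisibly.
#' @export
write_hsi <- function(cube, path, format = c("envi", "tiff"),
                      interleave = c("bsq", "bil", "bip"), data_type = 5L) {
  stopifnot(inherits(cube, "hsi_cube"))
  format <- match.arg(format)
  interleave <- match.arg(interleave)
  d <- dim(cube$data)
  paths <- character()
  if (format == "envi") {
    if (!data_type %in% c(4L, 5L)) stop("data_type must be 4 or 5")
    perm <- switch(interleave,                 # stream order, fastest first
                   bsq = c(2L, 1L, 3L),        # sample, line, band
                   bil = c(2L, 3L, 1L),        # sample, band, line
                   bip = c(3L, 2L, 1L))        # band, sample, line
    raw_path <- paste0(path, ".raw"); hdr_path <- paste0(path, ".hdr")
    con <- file(raw_path, "wb")
    writeBin(as.numeric(aperm(cube$data, perm)), con,
             size = if (data_type == 5L) 8L else 4L, endian = "little")
    close(con)
    hdr <- c(
      "ENVI",
      "description = { hsiseg hyperspectral cube }",
      paste0("samples = ", d[2L]),
      paste0("lines = ", d[1L]),
      paste0("bands = ", d[3L]),
      "header offset = 0",
      "file type = ENVI Standard",
      paste0("data type = ", data_type),
      paste0("interleave = ", interleave),
      "byte order = 0",
      "wavelength units = cm-1",
      paste0("wavelength = { ",
             paste(format(cube$axis$values, digits = 12), collapse = ", "),
             " }"))
    writeLines(hdr, hdr_path)
    paths <- c(raw_path, hdr_path)
  } else {
    tif_path <- paste0(path, ".tif")
    slices <- lapply(seq_len(d[3L]), function(b) cube$data[, , b])
    tiff::writeTIFF(slices, tif_path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
    axis_path <- paste0(path, ".axis.csv")
    write.csv(data.frame(wavenumber = cube$axis$values), axis_path,
              row.names = FALSE)
    paths <- c(tif_path, axis_path)
  }
  if (!is.null(cube$truth)) {
    tp <- paste0(path, ".truth.csv")
    utils::write.table(cube$truth, tp, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

.parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  kv <- list()
  # collapse brace blocks, then parse key = value lines
  txt <- gsub("\\{([^}]*)\\}", "{\\1}", txt)
  pat <- gregexpr("([a-zA-Z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)", txt)[[1]]
  starts <- pat; lens <- attr(pat, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    eq <- regexpr("=", piece)
    key <- tolower(trimws(substr(piece, 1L, eq - 1L)))
    val <- trimws(substr(piece, eq + 1L, nchar(piece)))
    kv[[key]] <- val
  }
  kv
}

#' Read a hyperspectral cube from disk
#'
#' Counterpart of [write_hsi()]; the interleave, data type and axis are
#' recovered from the ENVI header (or the TIFF's CSV sidecar), and a
#' truncated binary file raises an error rather than returning garbage.
#'
#' @param path path without extension, as given to [write_hsi()].
#' @param format `"envi"` or `"tiff"`.
#' @return an [hsi_cube]; ground truth is re-attached when a
#'   `path.truth.csv` sidecar exists.
#' @export
read_hsi <- function(path, format = c("envi", "tiff")) {
  format <- match.arg(format)
  if (format == "envi") {
    hdr_path <- paste0(path, ".hdr"); raw_path <- paste0(path, ".raw")
    if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path,
                                     call. = FALSE)
    kv <- .parse_envi_header(hdr_path)
    H <- as.integer(kv$lines); W <- as.integer(kv$samples)
    B <- as.integer(kv$bands)
    dt <- as.integer(kv[["data type"]])
    interleave <- tolower(kv$interleave)
    if (is.null(kv$wavelength))
      stop("ENVI header lacks a wavelength block; add `wavelength = {...}` ",
           "with one value per band", call. = FALSE)
    wl <- as.numeric(strsplit(gsub("[{}]", "", kv$wavelength), ",")[[1]])
    if (length(wl) != B)
      stop("header declares ", B, " bands but ", length(wl), " wavelengths",
           call. = FALSE)
    size <- if (dt == 5L) 8L else 4L
    want <- as.numeric(H) * W * B
    got <- file.size(raw_path) / size
    if (!isTRUE(got == want))
      stop("ENVI binary has ", got, " values but the header promises ", want,
           " (truncated or corrupt file?)", call. = FALSE)
    con <- file(raw_path, "rb")
    v <- readBin(con, "numeric", n = want, size = size, endian = "little")
    close(con)
    perm <- switch(interleave,
                   bsq = list(d = c(W, H, B), p = c(2L, 1L, 3L)),
                   bil = list(d = c(W, B, H), p = c(3L, 1L, 2L)),
                   bip = list(d = c(B, W, H), p = c(3L, 2L, 1L)),
                   stop("unknown interleave: ", interleave, call. = FALSE))
    dat <- aperm(array(v, perm$d), perm$p)
    step <- if (B > 1L) (wl[B] - wl[1L]) / (B - 1L) else 1
    axis <- make_wavenumber_axis(wl[1L], step, B)
  } else {
    tif_path <- paste0(path, ".tif")
    slices <- tiff::readTIFF(tif_path, all = TRUE, as.is = FALSE)
    if (!is.list(slices)) slices <- list(slices)
    dat <- array(unlist(slices), c(dim(slices[[1L]]), length(slices)))
    axis_path <- paste0(path, ".axis.csv")
    if (!file.exists(axis_path))
      stop("missing axis sidecar: ", axis_path, "; write the wavenumber ",
           "axis as a one-column CSV named <path>.axis.csv", call. = FALSE)
    wl <- read.csv(axis_path)[[1L]]
    B <- length(wl)
    if (B != dim(dat)[3L])
      stop("axis sidecar has ", B, " points but the TIFF has ",
           dim(dat)[3L], " bands", call. = FALSE)
    step <- if (B > 1L) (wl[B] - wl[1L]) / (B - 1L) else 1
    axis <- make_wavenumber_axis(wl[1L], step, B)
  }
  truth <- NULL
  tp <- paste0(path, ".truth.csv")
  if (file.exists(tp))
    truth <- as.matrix(read.csv(tp, header = FALSE))
  hsi_cube(dat, axis, truth = truth)
}

#' Truncate and resample the spectral axis
#'
#' Restricts the band axis to `[lo, hi]` cm^-1 and linearly interpolates
#' every pixel spectrum onto the arithmetic grid of spacing `step`, the
#' standard preprocessing for mid-IR cubes (e.g. truncation to the
#' 1000-1800 cm^-1 fingerprint region at 1 cm^-1 spacing).
#'
#' @param cube an [hsi_cube].
#' @param lo,hi target range (cm^-1), must lie within the cube's axis.
#' @param step target spacing (cm^-1).
#' @return an [hsi_cube] on the new axis (truth carried over).
#' @export
resample_band <- function(cube, lo, hi, step) {
  stopifnot(inherits(cube, "hsi_cube"), step > 0, hi > lo)
  v <- cube$axis$values
  if (lo < v[1L] || hi > v[length(v)])
    stop("requested range [", lo, ", ", hi, "] exceeds the axis range [",
         v[1L], ", ", v[length(v)], "]", call. = FALSE)
  count <- floor((hi - lo) / step + 1e-9) + 1L
  new_v <- lo + step * (seq_len(count) - 1)
  # linear interpolation as a sparse-in-structure B x count weight matrix
  j <- findInterval(new_v, v, rightmost.closed = TRUE)
  j <- pmin(j, length(v) - 1L)
  wR <- (new_v - v[j]) / (v[j + 1L] - v[j])
  Wt <- matrix(0, length(v), count)
  Wt[cbind(j, seq_len(count))] <- 1 - wR
  Wt[cbind(j + 1L, seq_len(count))] <- Wt[cbind(j + 1L, seq_len(count))] + wR
  d <- dim(cube$data)
  dat <- matrix(cube$data, d[1L] * d[2L], d[3L]) %*% Wt
  dim(dat) <- c(d[1L], d[2L], count)
  hsi_cube(dat, make_wavenumber_axis(lo, step, count), truth = cube$truth)
}

#' Deterministic class palette
#'
#' @param k number of classes.
#' @param seed palette seed (the colour scale is random but reproducible).
#' @return character vector of `k` hex colours.
#' @export
label_palette <- function(k, seed = 1L) {
  .local_seed(seed)
  grDevices::hsv(h = sample(seq(0, 1, length.out = max(k, 2L) + 1L)[seq_len(max(k, 1L))]),
                 s = 0.75, v = 0.95)
}

#' Write a label map as indexed PNG and CSV
#'
#' The PNG uses a deterministic random colour scale (seeded palette; the
#' seed and class count are recorded in the PNG text metadata) and is meant
#' for viewing; the CSV of integers is the lossless representation that
#' [read_label_map()] reads back.
#'
#' @param m a [label_map].
#' @param path output path without extension (`path.png`, `path.csv`).
#' @param palette_seed seed of the colour scale.
#' @return the paths written, invisibly.
#' @export
write_label_map <- function(m, path, palette_seed = 1L) {
  stopifnot(inherits(m, "label_map"))
  k <- max(m$n_classes, 1L)
  pal <- grDevices::col2rgb(label_palette(k, palette_seed)) / 255
  lab <- m$labels
  img <- array(0, c(nrow(lab), ncol(lab), 3L))
  ok <- !is.na(lab)
  for (ch in 1:3) {
    plane <- matrix(0, nrow(lab), ncol(lab))
    plane[ok] <- pal[ch, lab[ok]]
    img[, , ch] <- plane
  }
  png_path <- paste0(path, ".png"); csv_path <- paste0(path, ".csv")
  png::writePNG(img, png_path,
                text = c(n_classes = as.character(m$n_classes),
                         palette_seed = as.character(palette_seed),
                         provenance = m$provenance))
  utils::write.table(lab, csv_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(c(png_path, csv_path))
}

#' Read a label map from its CSV representation
#'
#' @param path path without extension, as given to [write_label_map()].
#' @param provenance provenance tag for the restored map.
#' @return a [label_map].
#' @export
read_label_map <- function(path, provenance = "end_to_end") {
  lab <- as.matrix(read.csv(paste0(path, ".csv"), header = FALSE))
  dimnames(lab) <- NULL
  label_map(lab, provenance = provenance)
}
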