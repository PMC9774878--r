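#' Hyperspectral image cube
#'
#' Container for a rank-3 intensity cube (`height x width x bands`,
#' arbitrary units) with its wavenumber axis and an optional ground-truth
#' label image.
#'
#' @param data numeric `H x W x B` array.
#' @param axis a [make_wavenumber_axis()] object with `B` points.
#' @param truth optional `H x W` integer matrix of ground-truth classes.
#' @return an object of class `hsi_cube` with fields `data`, `axis`,
#'   `truth`.
#' @export
hsi_cube <- function(data, axis, truth = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, inherits(axis, "wn_axis"))
  if (dim(data)[3L] != axis$count)
    stop("band dimension (", dim(data)[3L], ") does not match the axis (",
         axis$count, " points)", call. = FALSE)
  if (!is.null(truth)) {
    truth <- matrix(as.integer(truth), nrow(truth), ncol(truth))
    if (!all(dim(truth) == dim(data)[1:2]))
      stop("`truth` must match the cube's spatial dimensions", call. = FALSE)
  }
  structure(list(data = data, axis = axis, truth = truth), class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands (%.4g-%.4g cm^-1)%s\n",
              d[1L], d[2L], d[3L], x$axis$values[1L],
              x$axis$values[x$axis$count],
              if (is.null(x$truth)) "" else ", with ground truth"))
  invisible(x)
}

#' @export
dim.hsi_cube <- function(x) dim(x$data)

#' Ground truth of a cube as a label map
#'
#' @param cube an [hsi_cube] carrying a `truth` image.
#' @return a [label_map] with provenance `"truth"`.
#' @export
truth_label_map <- function(cube) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (is.null(cube$truth)) stop("cube has no ground truth", call. = FALSE)
  label_map(cube$truth, provenance = "truth")
}
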