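#' Spectral k-means pixel clustering
#'
#' The purely spectral comparison method: every pixel's spectrum is a point
#' in `B`-dimensional space and pixels are grouped by k-means (multiple
#' restarts, best inertia kept), ignoring all spatial arrangement.  On a
#' two-endmember phantom this trivially separates fat from muscle but
#' cannot distinguish tissue sections that differ only in how those two
#' spectra are arranged in space.
#'
#' Pixel spectra are used raw apart from the cube-level preprocessing also
#' applied before patching (negatives zeroed, division by the global
#' maximum); no per-spectrum scaling is applied.
#'
#' @param cube an [hsi_cube].
#' @param k number of clusters (>= 2).
#' @param seed integer seed for the restarts.
#' @param nstart number of k-means restarts.
#' @return an object of class `spectral_kmeans_result`: list with
#'   `label_map` (an `H x W` [label_map], provenance `"spectral_kmeans"`),
#'   `centers` (`k x B` matrix of cluster-mean spectra) and `inertia`
#'   (total within-cluster sum of squares).  If the cube holds fewer
#'   distinct spectra than `k`, the surplus clusters are left empty with a
#'   warning.
#' @export
#' @examples
#' cube <- phantom_hsi(height = 60, width = 60, bands = 30, seed = 1)
#' res <- spectral_kmeans(cube, k = 2, seed = 1)
#' table(res$label_map$labels)
spectral_kmeans <- function(cube, k, seed = 1L, nstart = 30L) {
  stopifnot(inherits(cube, "hsi_cube"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  d <- dim(cube$data)
  if (d[1L] * d[2L] < k) stop("fewer pixels than clusters", call. = FALSE)
  X <- matrix(as.numeric(cube$data), d[1L] * d[2L], d[3L])
  X[X < 0] <- 0
  gm <- max(X)
  if (gm > 0) X <- X / gm
  .local_seed(seed)
  fit <- .robust_kmeans(X, k, nstart = nstart)
  structure(
    list(label_map = label_map(matrix(as.integer(fit$cluster), d[1L], d[2L]),
                               n_classes = k, provenance = "spectral_kmeans"),
         centers = fit$centers * gm, inertia = fit$tot.withinss),
    class = "spectral_kmeans_result")
}

#' @export
print.spectral_kmeans_result <- function(x, ...) {
  cat(sprintf("<spectral_kmeans_result> k = %d, inertia %.4g\n",
              x$label_map$n_classes, x$inertia))
  invisible(x)
}
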