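#' Initialise cluster centres by k-means on the latents
#'
#' The clustering head's centres are initialised with k-means (multiple
#' restarts, best within-cluster sum of squares kept), the standard warm
#' start for Student's-t embedded clustering; segmentation accuracy is
#' known to depend strongly on this initialisation.
#'
#' @param latents `D x N` matrix of concatenated latent vectors (or a
#'   [encode()] latent set).
#' @param k number of clusters (a user choice; >= 1).
#' @param seed integer seed for the restarts.
#' @param nstart number of k-means restarts.
#' @return an object of class `cluster_state`: list with `centers`
#'   (`D x k`), `k`, `alpha` (Student's-t degrees of freedom, fixed at 1).
#' @export
init_centers <- function(latents, k, seed = 1L, nstart = 30L) {
  Z <- if (inherits(latents, "latent_set")) latents$concat else as.matrix(latents)
  N <- ncol(Z)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (N < k) stop("cannot place ", k, " centres with only ", N, " points",
                  call. = FALSE)
  .local_seed(seed)
  centers <- if (k == 1L) {
    matrix(rowMeans(Z), ncol = 1L)
  } else if (N == k) {
    Z
  } else {
    fit <- .robust_kmeans(t(Z), k, nstart = nstart)
    t(fit$centers)
  }
  structure(list(centers = centers, k = k, alpha = 1), class = "cluster_state")
}

# kmeans that tolerates data with fewer distinct points than k: falls back
# to clustering the distinct points and reports empty clusters.
.robust_kmeans <- function(X, k, nstart = 30L) {
  tryCatch(
    stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100L),
    error = function(e) {
      keys <- do.call(paste, c(as.data.frame(X), sep = "\r"))
      uk <- !duplicated(keys)
      u <- sum(uk)
      if (u >= k) stop(e)
      warning("only ", u, " distinct points for k = ", k, "; ",
              k - u, " cluster(s) left empty", call. = FALSE)
      fit <- if (u == 1L) {
        list(cluster = rep(1L, nrow(X)), centers = X[uk, , drop = FALSE],
             tot.withinss = 0)
      } else stats::kmeans(X, centers = X[uk, , drop = FALSE], iter.max = 100L)
      fit$centers <- rbind(fit$centers,
                           fit$centers[rep(1L, k - nrow(fit$centers)), ,
                                       drop = FALSE])
      fit
    })
}

#' @export
print.cluster_state <- function(x, ...) {
  cat(sprintf("<cluster_state> k = %d centres in %d dims (alpha = %g)\n",
              x$k, nrow(x$centers), x$alpha))
  invisible(x)
}

# squared distances, N x k
.sqdist <- function(Z, centers) {
  d2 <- outer(colSums(Z^2), colSums(centers^2), "+") - 2 * crossprod(Z, centers)
  d2[d2 < 0] <- 0
  d2
}

#' Student's-t soft cluster assignments
#'
#' Membership of patch `i` in cluster `j` under a Student's-t kernel around
#' the centres:
#' `q_ij = (1 + |z_i - mu_j|^2 / a)^(-(a+1)/2) / sum_j' (...)`,
#' with `a` the degrees of freedom (1 by default).  Rows sum to one.
#'
#' @param latents `D x N` matrix (or [encode()] latent set).
#' @param cs an [init_centers()] cluster state.
#' @return `N x k` matrix of soft assignments.
#' @export
soft_assign <- function(latents, cs) {
  Z <- if (inherits(latents, "latent_set")) latents$concat else as.matrix(latents)
  stopifnot(inherits(cs, "cluster_state"))
  if (nrow(Z) != nrow(cs$centers))
    stop("latent dimension does not match the centres", call. = FALSE)
  a <- cs$alpha
  w <- (1 + .sqdist(Z, cs$centers) / a)^(-(a + 1) / 2)
  w / rowSums(w)
}

#' Sharpened target distribution for end-to-end clustering
#'
#' The auxiliary distribution toward which the soft assignments are pulled:
#' `p_ij = (q_ij^2 / f_j) / sum_j' (q_ij'^2 / f_j')` with cluster
#' frequencies `f_j = sum_i q_ij`.  Squaring sharpens confident assignments
#' while the `1/f_j` factor counteracts large clusters.
#'
#' @param q `N x k` soft-assignment matrix (rows sum to 1).
#' @return `N x k` matrix with unit row sums; empty clusters
#'   (`f_j = 0`) trigger a warning and are excluded from the normalisation.
#' @export
target_distribution <- function(q) {
  q <- as.matrix(q)
  f <- colSums(q)
  dead <- f <= 0
  if (any(dead)) {
    warning(sum(dead), " degenerate cluster(s) with zero total membership")
    f[dead] <- 1  # column is all-zero anyway, keep the arithmetic finite
  }
  p <- sweep(q^2, 2L, f, "/")
  p / rowSums(p)
}

#' Kullback-Leibler clustering loss
#'
#' `KL(p || q)` between the target distribution and the soft assignments,
#' averaged over patches.  Zero iff `p == q`; non-negative by Gibbs'
#' inequality.  `q` entries are floored at `1e-12` before taking logs.
#'
#' @param q soft assignments (`N x k`).
#' @param p target distribution (`N x k`).
#' @return non-negative scalar.
#' @export
clustering_loss <- function(q, p) {
  q <- as.matrix(q); p <- as.matrix(p)
  if (!all(dim(q) == dim(p))) stop("shape mismatch", call. = FALSE)
  q <- pmax(q, 1e-12)
  term <- p * (log(pmax(p, 1e-300)) - log(q))
  term[p == 0] <- 0
  mean(rowSums(term))
}

# gradients of gamma * clustering_loss wrt latents (D x N) and centres
# (D x k); a = Student's-t dof
.cluster_grads <- function(Z, centers, q, p, alpha, scale) {
  wt <- 1 / (1 + .sqdist(Z, centers) / alpha)     # N x k
  a <- (p - q) * wt
  cc <- scale * (alpha + 1) / alpha
  dz <- cc * (Z * rep(rowSums(a), each = nrow(Z)) - centers %*% t(a))
  dmu <- -cc * (Z %*% a - centers * rep(colSums(a), each = nrow(centers)))
  list(dz = dz, dmu = dmu)
}
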