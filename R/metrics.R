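# Partition-agreement metrics.  Both scores are permutation invariant and
# are computed from the contingency table of the two labelings; label maps
# are compared pixel-wise with NA positions (uncovered pixels) dropped.

.as_labels <- function(x) {
  if (inherits(x, "label_map")) x <- x$labels
  if (inherits(x, "spectral_kmeans_result")) x <- x$label_map$labels
  as.vector(x)
}

.paired_labels <- function(a, b) {
  a <- .as_labels(a); b <- .as_labels(b)
  if (length(a) != length(b))
    stop("labelings differ in length (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  if (length(a) == 0L) stop("empty labelings", call. = FALSE)
  keep <- !(is.na(a) | is.na(b))
  list(a = a[keep], b = b[keep])
}

#' Contingency table of two labelings
#'
#' `counts[u, v]` is the number of positions carrying label `u` in `a` and
#' label `v` in `b`; the row/column marginals sum to the total `n`.
#'
#' @param a,b equal-length integer labelings (vectors, matrices or
#'   [label_map]s).
#' @return an object of class `contingency`: list with `counts`,
#'   `row_marginals`, `col_marginals`, `n`.
#' @export
contingency <- function(a, b) {
  pr <- .paired_labels(a, b)
  counts <- unclass(table(pr$a, pr$b))
  structure(list(counts = counts,
                 row_marginals = as.integer(rowSums(counts)),
                 col_marginals = as.integer(colSums(counts)),
                 n = length(pr$a)),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  cat(sprintf("<contingency> %d x %d classes, n = %d\n",
              nrow(x$counts), ncol(x$counts), x$n))
  print(x$counts)
  invisible(x)
}

.entropy <- function(marg, n) {
  p <- marg[marg > 0] / n
  -sum(p * log(p))
}

#' Normalised mutual information between two labelings
#'
#' Mutual information of the contingency distribution normalised by a mean
#' of the two marginal entropies (arithmetic by default, the most common
#' convention; `min`, `geometric` and `max` are available for sensitivity
#' checks).  Returns 0 when either labeling is constant, 1 for identical
#' partitions (up to relabeling).
#'
#' @param a,b equal-length labelings (vectors, matrices or [label_map]s).
#' @param variant normalisation: `"arithmetic"` (default), `"min"`,
#'   `"geometric"` or `"max"`.
#' @return a number in `[0, 1]`.
#' @export
#' @examples
#' nmi(c(0, 0, 1, 1), c(1, 1, 0, 0))  # permutation invariant: 1
nmi <- function(a, b, variant = c("arithmetic", "min", "geometric", "max")) {
  variant <- match.arg(variant)
  ct <- contingency(a, b)
  n <- ct$n
  ha <- .entropy(ct$row_marginals, n)
  hb <- .entropy(ct$col_marginals, n)
  if (ha == 0 || hb == 0) return(0)
  nz <- which(ct$counts > 0, arr.ind = TRUE)
  nij <- ct$counts[nz]
  mi <- sum(nij / n * log(nij * n /
                            (ct$row_marginals[nz[, 1L]] *
                               ct$col_marginals[nz[, 2L]])))
  mi <- max(mi, 0)
  denom <- switch(variant,
                  arithmetic = (ha + hb) / 2,
                  min = min(ha, hb),
                  geometric = sqrt(ha * hb),
                  max = max(ha, hb))
  min(mi / denom, 1)
}

#' Adjusted Rand score between two labelings
#'
#' Pair-counting Rand index corrected for chance agreement under the
#' hypergeometric model: 1 for identical partitions, about 0 for random
#' ones, negative for worse-than-chance agreement.
#'
#' @param a,b equal-length labelings (vectors, matrices or [label_map]s).
#' @return a number `<= 1`.  For degenerate pairs where the chance
#'   correction is undefined (both partitions constant, or both all
#'   singletons), returns 1 if the partitions are identical and 0
#'   otherwise.
#' @export
#' @examples
#' ars(c(0, 0, 1, 1), c(0, 1, 0, 1))  # -0.5
ars <- function(a, b) {
  ct <- contingency(a, b)
  n <- ct$n
  sij <- sum(choose(ct$counts, 2))
  sa <- sum(choose(ct$row_marginals, 2))
  sb <- sum(choose(ct$col_marginals, 2))
  tot <- choose(n, 2)
  expected <- sa * sb / tot
  maximum <- (sa + sb) / 2
  if (maximum == expected) {
    pr <- .paired_labels(a, b)
    identical_partition <- all(as.integer(factor(pr$a)) ==
                                 as.integer(factor(pr$b)))
    return(as.numeric(identical_partition))
  }
  (sij - expected) / (maximum - expected)
}

#' Relabel a predicted map to best match a reference
#'
#' Solves the one-to-one assignment between predicted and reference classes
#' that maximises pixel agreement (exhaustively for up to 8 classes, greedy
#' beyond), then rewrites the predicted labels accordingly.  Surplus
#' predicted classes keep fresh ids above the reference range.  Intended
#' for confusion matrices and colour-consistent overlays only — [nmi()] and
#' [ars()] are permutation invariant and never need it.
#'
#' @param pred,truth labelings of identical shape (vectors, matrices or
#'   [label_map]s).
#' @return `pred` with rewritten labels, same type as the input.
#' @export
align_labels <- function(pred, truth) {
  pv <- .as_labels(pred); tv <- .as_labels(truth)
  if (length(pv) != length(tv)) stop("shape mismatch", call. = FALSE)
  ct <- contingency(pred, truth)
  pc <- as.integer(rownames(ct$counts))
  tcls <- as.integer(colnames(ct$counts))
  r <- length(pc); s <- length(tcls)
  m <- max(r, s)
  sq <- matrix(0, m, m)
  sq[seq_len(r), seq_len(s)] <- ct$counts
  assign_to <- if (m <= 8L) {
    perms <- .permutations(m)
    scores <- apply(perms, 1L, function(pm) sum(sq[cbind(seq_len(m), pm)]))
    perms[which.max(scores), ]
  } else {
    .greedy_assign(sq)
  }
  mapping <- integer(r)
  fresh <- max(tcls) + 1L
  for (i in seq_len(r)) {
    j <- assign_to[i]
    if (j <= s) mapping[i] <- tcls[j]
    else { mapping[i] <- fresh; fresh <- fresh + 1L }
  }
  new <- mapping[match(pv, pc)]
  if (inherits(pred, "label_map")) {
    out <- pred
    out$labels <- matrix(as.integer(new), nrow(pred$labels), ncol(pred$labels))
    out$n_classes <- max(new, na.rm = TRUE)
    out
  } else if (is.matrix(pred)) {
    matrix(new, nrow(pred), ncol(pred))
  } else new
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

.greedy_assign <- function(sq) {
  m <- nrow(sq)
  assign_to <- integer(m)
  free <- rep(TRUE, m)
  ord <- order(apply(sq, 1L, max), decreasing = TRUE)
  for (i in ord) {
    j <- which.max(ifelse(free, sq[i, ], -Inf))
    assign_to[i] <- j
    free[j] <- FALSE
  }
  assign_to
}

#' Segmentation evaluation report
#'
#' Bundles the agreement scores and the (aligned) confusion matrix of a
#' predicted map against a reference map.
#'
#' @param pred,truth labelings of identical shape.
#' @param nmi_variant passed to [nmi()].
#' @return an object of class `eval_report`: list with `nmi`, `ars`,
#'   `contingency`, `aligned_confusion`.
#' @export
eval_report <- function(pred, truth, nmi_variant = "arithmetic") {
  structure(list(nmi = nmi(pred, truth, nmi_variant),
                 ars = ars(pred, truth),
                 contingency = contingency(pred, truth),
                 aligned_confusion = contingency(align_labels(pred, truth),
                                                 truth)$counts),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> NMI %.4f, ARS %.4f\n", x$nmi, x$ars))
  invisible(x)
}
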