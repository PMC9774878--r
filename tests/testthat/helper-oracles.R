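# Independent brute-force oracles used to pin expected values.  These stay
# deliberately naive (direct sums, pair enumeration) and never share code
# with the package implementations they check.

# mutual-information score by direct summation over the joint distribution
oracle_nmi <- function(a, b, variant = "arithmetic") {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  joint <- matrix(0, length(ua), length(ub))
  for (i in seq_len(n))
    joint[match(a[i], ua), match(b[i], ub)] <-
      joint[match(a[i], ua), match(b[i], ub)] + 1 / n
  pa <- rowSums(joint); pb <- colSums(joint)
  mi <- 0
  for (u in seq_along(ua)) for (v in seq_along(ub))
    if (joint[u, v] > 0)
      mi <- mi + joint[u, v] * log(joint[u, v] / (pa[u] * pb[v]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 || hb == 0) return(0)
  denom <- switch(variant, arithmetic = (ha + hb) / 2, min = min(ha, hb),
                  geometric = sqrt(ha * hb), max = max(ha, hb))
  mi / denom
}

# adjusted Rand score by exhaustive enumeration of all unordered pairs
oracle_ars <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- s11 + s00 + s10 + s01
  expected <- (s11 + s10) * (s11 + s01) / tot
  maximum <- ((s11 + s10) + (s11 + s01)) / 2
  if (maximum == expected)
    return(as.numeric(all((a[1] == a) == (b[1] == b))))
  (s11 - expected) / (maximum - expected)
}

# KL(p || q) summed element by element, averaged over rows
oracle_kl <- function(q, p) {
  tot <- 0
  for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q)))
    if (p[i, j] > 0) tot <- tot + p[i, j] * log(p[i, j] / q[i, j])
  unname(tot / nrow(q))
}

# brute-force overlapping-patch count: enumerate admissible start positions
oracle_patch_count <- function(H, W, p, s) {
  n <- 0
  for (r in seq(0, H - p)) if (r %% s == 0)
    for (c in seq(0, W - p)) if (c %% s == 0) n <- n + 1
  n
}

# small two-class patch matrix: constant "bright" and "dark" patches
toy_two_class_patches <- function(p = 4, B = 3, n_each = 12,
                                  levels = c(0.2, 0.8), jitter = 0.01,
                                  seed = 1) {
  withr::with_seed(seed, {
    S <- p * p * B
    X <- cbind(matrix(levels[1], S, n_each), matrix(levels[2], S, n_each))
    X <- X + matrix(rnorm(length(X), sd = jitter), nrow = S)
    list(X = pmin(pmax(X, 0), 1), classes = rep(1:2, each = n_each))
  })
}

tiny_cae <- function(arch = "uwu2d", p = 4, B = 3, D = 4,
                     M = if (arch == "uwu2d") 2 else 1, seed = 1) {
  build_cae(cae_config(arch, patch_size = p, bands = B, latent_total = D,
                       branches = M, seed = seed))
}

fast_tc <- function(...) train_config(batch_size = 8L, seed = 7L, ...)
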