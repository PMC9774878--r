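test_that("centre initialisation reduces to means and recovers blobs", {
  withr::with_seed(1, {
    Z <- matrix(rnorm(5 * 20), 5, 20)
    cs <- init_centers(Z, 1)
    expect_equal(as.vector(cs$centers), rowMeans(Z), tolerance = 1e-12)
    # N == k: the points themselves (inertia zero)
    Zk <- matrix(c(0, 0, 1, 1, 5, 5), 2, 3)
    csk <- init_centers(Zk, 3)
    expect_equal(sort(colSums(csk$centers)), sort(colSums(Zk)))
    expect_error(init_centers(Zk, 4), "only 3 points")
    # two well-separated Gaussian blobs
    n2 <- 100
    blobs <- cbind(matrix(rnorm(2 * n2, 0, 0.5), 2),
                   matrix(rnorm(2 * n2, 8, 0.5), 2))
    cs2 <- init_centers(blobs, 2, seed = 3)
    mus <- cs2$centers[, order(cs2$centers[1, ])]
    expect_lt(sqrt(sum((mus[, 1] - rowMeans(blobs[, 1:n2]))^2)),
              3 * 0.5 / sqrt(n2) * 2)
    expect_lt(sqrt(sum((mus[, 2] - rowMeans(blobs[, -(1:n2)]))^2)),
              3 * 0.5 / sqrt(n2) * 2)
  })
})

test_that("soft assignments follow the Student's-t kernel and are row stochastic", {
  Z <- matrix(c(0, 1, 4), 1)
  cs1 <- init_centers(Z, 1)
  expect_equal(as.vector(soft_assign(Z, cs1)), rep(1, 3))
  # symmetric two-centre case: the midpoint gets (1/2, 1/2)
  cs2 <- structure(list(centers = matrix(c(0, 1), 1), k = 2L, alpha = 1),
                   class = "cluster_state")
  expect_equal(as.vector(soft_assign(matrix(0.5, 1, 1), cs2)), c(0.5, 0.5))
  # 1-D worked example: z = 0, centres {0, 1}, alpha = 1 ->
  # unnormalised (1, 1/2) -> (2/3, 1/3)
  expect_equal(as.vector(soft_assign(matrix(0, 1, 1), cs2)), c(2 / 3, 1 / 3))
  withr::with_seed(4, {
    Zr <- matrix(rnorm(3 * 50), 3)
    csr <- init_centers(Zr, 4, seed = 1)
    q <- soft_assign(Zr, csr)
    expect_equal(rowSums(q), rep(1, 50), tolerance = 1e-9)
    expect_true(all(q >= 0 & q <= 1))
  })
})

test_that("the target distribution sharpens q and keeps rows stochastic", {
  q <- matrix(c(0.8, 0.6, 0.2, 0.4), 2)
  p <- target_distribution(q)
  # hand evaluation with f = (1.4, 0.6)
  expect_equal(p[1, ], c(0.64 / 1.4, 0.04 / 0.6) / (0.64 / 1.4 + 0.04 / 0.6),
               tolerance = 1e-12)
  expect_equal(round(p[1, ], 3), c(0.873, 0.127))
  expect_equal(round(p[2, ], 3), c(0.491, 0.509))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-12)
  # one-hot rows are a fixed point
  onehot <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(target_distribution(onehot), onehot)
  # uniform q with equal frequencies stays uniform
  u <- matrix(1 / 3, 6, 3)
  expect_equal(target_distribution(u), u)
  # sharpening: row entropies do not increase
  withr::with_seed(9, {
    qr <- matrix(rexp(40 * 4), 40); qr <- qr / rowSums(qr)
    pr <- target_distribution(qr)
    ent <- function(m) -rowSums(ifelse(m > 0, m * log(m), 0))
    expect_true(mean(ent(pr)) <= mean(ent(qr)) + 1e-12)
  })
  expect_warning(target_distribution(matrix(c(1, 1, 0, 0), 2)), "degenerate")
})

test_that("the KL clustering loss matches a brute-force double sum", {
  q <- matrix(c(0.7, 0.2, 0.1, 0.3, 0.3, 0.4), 2, 3, byrow = TRUE)
  expect_equal(clustering_loss(q, q), 0, tolerance = 1e-12)
  # one-hot target vs uniform q over 2: per-row loss ln 2
  expect_equal(clustering_loss(matrix(0.5, 3, 2), diag(2)[c(1, 2, 1), ]),
               log(2), tolerance = 1e-12)
  withr::with_seed(10, {
    for (rep in 1:50) {
      qr <- matrix(rexp(15), 5, 3); qr <- qr / rowSums(qr)
      pr <- matrix(rexp(15), 5, 3); pr <- pr / rowSums(pr)
      expect_gte(clustering_loss(qr, pr), 0)
      expect_equal(clustering_loss(qr, pr), oracle_kl(qr, pr),
                   tolerance = 1e-10)
    }
  })
  expect_error(clustering_loss(matrix(0.5, 2, 2), matrix(0.5, 2, 3)), "shape")
})

test_that("clustering gradients match finite differences", {
  withr::with_seed(12, {
    D <- 6; n <- 9; k <- 3; eps <- 1e-6
    Z <- matrix(rnorm(D * n), D, n)
    mu <- matrix(rnorm(D * k), D, k)
    cs <- structure(list(centers = mu, k = k, alpha = 1),
                    class = "cluster_state")
    p <- target_distribution(soft_assign(Z, cs))
    q <- soft_assign(Z, cs)
    cg <- hsiseg:::.cluster_grads(Z, mu, q, p, 1, scale = 1 / n)
    lf <- function(Z, mu) {
      cs$centers <- mu
      clustering_loss(soft_assign(Z, cs), p)
    }
    for (trial in 1:10) {
      i <- sample(length(Z), 1)
      Zp <- Z; Zp[i] <- Z[i] + eps; Zm <- Z; Zm[i] <- Z[i] - eps
      expect_equal(cg$dz[i], (lf(Zp, mu) - lf(Zm, mu)) / (2 * eps),
                   tolerance = 1e-4)
      j <- sample(length(mu), 1)
      mp <- mu; mp[j] <- mu[j] + eps; mm <- mu; mm[j] <- mu[j] - eps
      expect_equal(cg$dmu[j], (lf(Z, mp) - lf(Z, mm)) / (2 * eps),
                   tolerance = 1e-4)
    }
  })
})
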