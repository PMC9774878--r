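test_that("configs validate their invariants", {
  expect_error(cae_config("uwu2d", 8, 6, latent_total = 10, branches = 3),
               "divisible")
  expect_error(cae_config("uwu2d", 8, 3, latent_total = 8, branches = 4),
               "fewer branches")
  expect_error(cae_config("generic2d", 8, 6, latent_total = 0), "positive")
  cfg <- cae_config("uwu2d", 20, 100)
  expect_equal(cfg$latent_total, 100L)
  expect_equal(cfg$branches, 4L)
})

test_that("encoder and decoder are exact shape inverses for all architectures", {
  withr::with_seed(1, {
    grid <- list(c(p = 8, B = 6), c(p = 12, B = 10), c(p = 5, B = 9))
    for (arch in c("uwu2d", "generic2d", "generic3d")) {
      for (g in grid) {
        D <- 8L
        cae <- build_cae(cae_config(arch, g["p"], g["B"], latent_total = D,
                                    branches = if (arch == "uwu2d") 2L else 1L,
                                    seed = 9))
        X <- matrix(runif(g["p"]^2 * g["B"] * 3), ncol = 3)
        ls <- encode(cae, X)
        expect_equal(dim(ls$concat), c(D, 3L))
        expect_equal(length(ls$per_branch), cae$cfg$branches)
        xhat <- decode(cae, ls)
        expect_equal(dim(xhat), dim(X))
        expect_true(all(is.finite(xhat)))
      }
    }
  })
})

test_that("uwu2d splits the latent across branches; generic2d does not branch", {
  cae <- build_cae(cae_config("uwu2d", 20, 100))
  ls <- encode(cae, matrix(0, 20 * 20 * 100, 1))
  expect_equal(length(ls$per_branch), 4L)
  expect_equal(vapply(ls$per_branch, nrow, integer(1)), rep(25L, 4))
  expect_equal(nrow(concat_latents(ls)), 100L)
  expect_true(all(is.finite(ls$concat)))
  g <- build_cae(cae_config("generic2d", 20, 100))
  lg <- encode(g, matrix(0, 20 * 20 * 100, 1))
  expect_equal(length(lg$per_branch), 1L)
  expect_equal(nrow(lg$concat), 100L)
})

test_that("uwu2d and generic2d default parameter counts agree within 20%", {
  a <- n_parameters(build_cae(cae_config("uwu2d", 20, 100)))
  b <- n_parameters(build_cae(cae_config("generic2d", 20, 100)))
  expect_gte(a / b, 0.8)
  expect_lte(a / b, 1.25)
})

test_that("encoding is deterministic and decode handles bad latent lengths", {
  cae <- tiny_cae()
  X <- matrix(runif(4 * 4 * 3 * 2), ncol = 2)
  expect_identical(encode(cae, X)$concat, encode(cae, X)$concat)
  expect_identical(encode(cae, X[, 1, drop = FALSE])$concat,
                   encode(cae, X[, 1, drop = FALSE])$concat)
  expect_error(encode(cae, X[-1, ]), "expects")
  expect_error(decode(cae, matrix(0, 7, 2)), "latent length")
})

test_that("concat_latents preserves branch order", {
  ls <- structure(list(per_branch = list(matrix(1:2, 2), matrix(3:4, 2)),
                       concat = matrix(1:4, 4), branches = 2L,
                       latent_total = 4L), class = "latent_set")
  expect_equal(as.vector(concat_latents(ls)), 1:4)
  ls$per_branch <- ls$per_branch[1]
  expect_error(concat_latents(ls), "missing")
})

test_that("reconstruction loss is the elementwise mean square", {
  x <- array(0, c(3, 3, 2)); y <- array(1, c(3, 3, 2))
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(x, y), 1)
  withr::with_seed(2, {
    a <- array(rnorm(18), c(3, 3, 2)); b <- array(rnorm(18), c(3, 3, 2))
    brute <- sum((a - b)^2) / 18
    expect_equal(reconstruction_loss(a, b), brute, tolerance = 1e-12)
    expect_equal(reconstruction_loss(a, b), reconstruction_loss(b, a))
  })
  expect_error(reconstruction_loss(array(0, c(2, 2, 2)), array(0, c(2, 2, 3))),
               "shape")
})

test_that("backpropagated gradients match finite differences", {
  withr::with_seed(6, {
    cae <- build_cae(cae_config("uwu2d", 6, 4, latent_total = 6,
                                branches = 2, seed = 11))
    # evaluate at a generic point: freshly built nets have all-zero biases,
    # which parks some ReLU pre-activations exactly on their kink where
    # two-sided differences and the subgradient legitimately disagree
    for (id in names(cae$layers)) if (!is.null(cae$layers[[id]]$b))
      cae$layers[[id]]$b <- rnorm(length(cae$layers[[id]]$b), sd = 0.05)
    X <- matrix(runif(6 * 6 * 4 * 3), ncol = 3)
    loss_fn <- function(cae) {
      fw <- hsiseg:::.cae_forward(cae, X)
      mean((fw$xhat - X)^2)
    }
    fw <- hsiseg:::.cae_forward(cae, X)
    grads <- hsiseg:::.cae_backward(cae, fw, 2 * (fw$xhat - X) / length(X))
    eps <- 1e-6
    for (id in names(cae$layers)) {
      if (is.null(cae$layers[[id]]$W)) next
      for (trial in 1:2) {
        i <- sample(length(cae$layers[[id]]$W), 1)
        up <- cae; up$layers[[id]]$W[i] <- up$layers[[id]]$W[i] + eps
        dn <- cae; dn$layers[[id]]$W[i] <- dn$layers[[id]]$W[i] - eps
        num <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
        expect_equal(grads[[id]]$W[i], num, tolerance = 1e-4,
                     info = paste("layer", id))
      }
      i <- sample(length(cae$layers[[id]]$b), 1)
      up <- cae; up$layers[[id]]$b[i] <- up$layers[[id]]$b[i] + eps
      dn <- cae; dn$layers[[id]]$b[i] <- dn$layers[[id]]$b[i] - eps
      num <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
      expect_equal(grads[[id]]$b[i], num, tolerance = 1e-4,
                   info = paste("layer", id, "bias"))
    }
  })
})

test_that("a tiny CAE memorises a constant patch set", {
  X <- matrix(0.6, 4 * 4 * 3, 10)
  cae <- tiny_cae(seed = 4)
  tc <- train_config(learning_rate = 0.01, batch_size = 10,
                     pretrain_patience = 50, pretrain_min_delta = 0,
                     max_pretrain_epochs = 300, validation_fraction = 0.2,
                     seed = 1)
  pre <- pretrain_cae(cae, X, tc)
  err <- reconstruction_loss(X, decode(pre$cae, encode(pre$cae, X)))
  expect_lt(err, 1e-3)
})

test_that("pretraining reduces the loss and logs its configuration", {
  toy <- toy_two_class_patches(n_each = 16, seed = 3)
  cae <- tiny_cae(seed = 2)
  pre <- pretrain_cae(cae, toy$X, fast_tc(max_pretrain_epochs = 12))
  h <- pre$history
  expect_lte(h$val_loss[nrow(h)], h$val_loss[1])
  # moving-average of the training loss decreases from start to end
  ma <- stats::filter(h$train_loss, rep(1 / 3, 3), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(tail(ma, 1), head(ma, 1))
  expect_equal(attr(h, "config")$batch_size, 8L)
  expect_equal(attr(h, "config")$learning_rate, 0.001)
  expect_true(pre$cae$pretrained)
})

test_that("trained latents separate distinct patch classes; branches stay live", {
  toy <- toy_two_class_patches(n_each = 16, seed = 5)
  cae <- tiny_cae(seed = 8)
  pre <- pretrain_cae(cae, toy$X, fast_tc(max_pretrain_epochs = 20))
  Z <- encode(pre$cae, toy$X)$concat
  za <- rowMeans(Z[, toy$classes == 1]); zb <- rowMeans(Z[, toy$classes == 2])
  expect_gt(sqrt(sum((za - zb)^2)), 0)
})

test_that("no branch goes dead after pretraining on heterogeneous patches", {
  withr::with_seed(31, {
    X <- matrix(runif(6 * 6 * 4 * 24), ncol = 24)  # richly varied patches
    cae <- build_cae(cae_config("uwu2d", 6, 4, latent_total = 8,
                                branches = 2, seed = 5))
    pre <- pretrain_cae(cae, X, fast_tc(max_pretrain_epochs = 30))
    ls <- encode(pre$cae, X[, 1:4])
    full <- decode(pre$cae, ls)
    for (m in 1:2) {
      zk <- ls$concat
      rows <- if (m == 1) 1:4 else 5:8
      zk[rows, ] <- 0
      expect_gt(mean((decode(pre$cae, zk) - full)^2), 0,
                label = sprintf("effect of zeroing branch %d", m))
    }
  })
})
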