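make_cube <- function(H, W, B, seed = 1) {
  withr::with_seed(seed, {
    ax <- make_wavenumber_axis(1000, 2, B)
    hsi_cube(array(runif(H * W * B), c(H, W, B)), ax)
  })
}

test_that("patch counts follow the closed form", {
  cube <- make_cube(240, 240, 3)
  ps <- extract_patches(cube, 20, 4)
  expect_equal(nrow(ps$coords), 3136L)       # (floor(220/4)+1)^2 = 56^2
  expect_equal(ncol(ps$patches), 3136L)
  cube <- make_cube(128, 128, 2)
  expect_equal(nrow(extract_patches(cube, 10, 2)$coords), 3600L)  # 60 * 60
  cube <- make_cube(12, 12, 2)
  ps1 <- extract_patches(cube, 12, 3)
  expect_equal(nrow(ps1$coords), 1L)
  expect_equal(unname(ps1$coords[1, ]), c(0L, 0L))
  expect_error(extract_patches(cube, 13, 1), "exceeds")
})

test_that("patch counts match brute-force start enumeration over random geometries", {
  withr::with_seed(13, {
    for (rep in 1:25) {
      H <- sample(6:30, 1); W <- sample(6:30, 1)
      p <- sample(2:min(H, W), 1); s <- sample(1:6, 1)
      cube <- make_cube(H, W, 2, seed = rep)
      ps <- extract_patches(cube, p, s)
      expect_equal(nrow(ps$coords), oracle_patch_count(H, W, p, s),
                   info = sprintf("H=%d W=%d p=%d s=%d", H, W, p, s))
      # closed form from the invariant
      expect_equal(nrow(ps$coords),
                   (floor((H - p) / s) + 1) * (floor((W - p) / s) + 1))
    }
  })
})

test_that("patches are raster-ordered raw intensity views", {
  cube <- make_cube(10, 10, 4)
  ps <- extract_patches(cube, 4, 3)
  # rows outer, cols inner
  expect_equal(unname(ps$coords[1:3, 2]), c(0L, 3L, 6L))
  expect_equal(unname(ps$coords[c(1, 4), 1]), c(0L, 3L))
  i <- 5  # coord (3, 3)
  expect_equal(get_patch(ps, i), cube$data[4:7, 4:7, ], tolerance = 0)
})

test_that("normalisation zeroes negatives and divides by the global max", {
  ax <- make_wavenumber_axis(1000, 1, 2)
  cube <- hsi_cube(array(rep(c(-1, 0, 2, 4), 2), c(2, 2, 2)), ax)
  ps <- normalize_patches(extract_patches(cube, 1, 1))
  expect_equal(sort(unique(as.vector(ps$patches))), c(0, 0.5, 1))
  expect_equal(ps$norm$global_max, 4)
  expect_true(ps$norm$negatives_zeroed)
  # idempotence
  ps2 <- normalize_patches(ps)
  expect_equal(ps2$patches, ps$patches)
  expect_equal(ps2$norm$global_max, 1)
  # one shared divisor across patches of one cube
  cube <- make_cube(8, 8, 3)
  psn <- normalize_patches(extract_patches(cube, 4, 4))
  expect_equal(max(psn$patches), 1)
  expect_equal(psn$patches,
               pmax(extract_patches(cube, 4, 4)$patches, 0) / max(cube$data))
  zero <- hsi_cube(array(-1, c(2, 2, 2)), ax)
  expect_error(normalize_patches(extract_patches(zero, 1, 1)), "positive")
})

test_that("raster_overwrite reconstruction paints later patches over earlier", {
  cube <- make_cube(6, 9, 2)
  ps <- extract_patches(cube, 6, 3)  # 1 x 2 grid of patches
  m <- reconstruct_label_map(c(3L, 1L), ps)
  expect_true(all(m$labels[, 1:3] == 3L))
  expect_true(all(m$labels[, 4:9] == 1L))  # overlap columns 4-6 overwritten
  single <- reconstruct_label_map(7L, extract_patches(make_cube(5, 5, 2), 5, 5))
  expect_true(all(single$labels == 7L))
  expect_error(reconstruct_label_map(1:3, ps), "labels")
})

test_that("modes agree on non-overlapping tilings and majority takes the mode", {
  cube <- make_cube(9, 9, 2)
  ps <- extract_patches(cube, 3, 3)  # 3 x 3 partition
  withr::with_seed(2, labs <- sample.int(4, 9, replace = TRUE))
  m1 <- reconstruct_label_map(labs, ps, mode = "raster_overwrite")
  m2 <- reconstruct_label_map(labs, ps, mode = "majority")
  expect_equal(m1$labels, m2$labels)
  # every pixel painted exactly once in a partition
  expect_false(anyNA(m1$labels))
  # overlapping case: centre pixel of a 2x2 overlapping grid takes the
  # modal label, ties to the lowest id
  ps2 <- extract_patches(make_cube(4, 4, 2), 3, 1)  # 4 patches
  mm <- reconstruct_label_map(c(2L, 2L, 1L, 1L), ps2, mode = "majority")
  expect_equal(mm$labels[2, 2], 1L)  # 2-2 tie among covering patches -> 1
})

test_that("constant truth round-trips exactly through patch labels", {
  cube <- make_cube(20, 20, 2)
  for (s in c(2, 4)) {
    ps <- extract_patches(cube, 4, s)
    m <- reconstruct_label_map(rep(5L, nrow(ps$coords)), ps)
    expect_true(all(m$labels == 5L))
  }
})

test_that("overwrite reconstruction has a translation ceiling; majority is exact", {
  # paint each patch with its true dominant class: majority-vote
  # reconstruction recovers the ground truth exactly, while the raster
  # overwrite scheme's diagonal offset leaves a systematic error band
  cube <- phantom_hsi(height = 72, width = 72, bands = 10, seed = 6)
  ps <- extract_patches(cube, 12, 4)
  oracle <- apply(ps$coords, 1, function(rc) {
    blk <- cube$truth[(rc[1] + 1):(rc[1] + 12), (rc[2] + 1):(rc[2] + 12)]
    as.integer(names(which.max(table(blk))))
  })
  crop <- function(m) crop_edge_artifacts(m, 12, 4)
  truth_c <- crop(truth_label_map(cube))
  over <- crop(reconstruct_label_map(oracle, ps, mode = "raster_overwrite"))
  major <- crop(reconstruct_label_map(oracle, ps, mode = "majority"))
  expect_equal(nmi(major, truth_c), 1)
  expect_lt(nmi(over, truth_c), 1)
  expect_gt(nmi(over, truth_c), 0.5)  # offset hurts but does not destroy
})

test_that("edge cropping removes the patch-size band and records itself", {
  m <- label_map(matrix(1L, 240, 240), provenance = "truth")
  mc <- crop_edge_artifacts(m, p = 20)
  expect_equal(dim(mc$labels), c(220L, 220L))
  expect_equal(mc$crop$margin, 20)
  # labels in the retained region unchanged
  m2 <- label_map(matrix(sample.int(3, 100, TRUE), 10, 10),
                  provenance = "end_to_end")
  mc2 <- crop_edge_artifacts(m2, p = 4)
  expect_equal(mc2$labels, m2$labels[1:6, 1:6])
  # cropping twice reduces further and keeps the history chain
  mc3 <- crop_edge_artifacts(mc2, p = 2)
  expect_equal(dim(mc3$labels), c(4L, 4L))
  expect_false(is.null(mc3$crop$previous))
  expect_error(crop_edge_artifacts(mc3, p = 5), "exceeds")
  # shift correction moves the map by (s, s) before cropping
  m3 <- label_map(matrix(1:100, 10, 10), provenance = "end_to_end")
  ms <- crop_edge_artifacts(m3, p = 2, s = 1, shift = TRUE)
  expect_equal(ms$labels[1, 1], m3$labels[2, 2])
})
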