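test_that("wavenumber axis is the arithmetic grid start + i*step", {
  ax <- make_wavenumber_axis(444.2, 1.98, 800)
  expect_equal(ax$count, 800L)
  expect_equal(ax$values[1], 444.2)
  expect_equal(ax$values[800], 444.2 + 799 * 1.98)  # = 2026.22
  expect_equal(diff(ax$values), rep(1.98, 799))
  expect_equal(make_wavenumber_axis(0, 1, 2)$values, c(0, 1))
  expect_error(make_wavenumber_axis(0, -1, 10), "positive")
  expect_error(make_wavenumber_axis(0, 1, 1), ">= 2")
})

test_that("section layouts partition the image and are deterministic", {
  sm <- make_section_layout(240, 240)
  expect_equal(sort(unique(sm$patterns)), c("globules", "solid", "stripes"))
  expect_true(all(sm$labels %in% 1:3))
  one <- make_section_layout(10, 10, list(
    list(row = 1, col = 1, height = 10, width = 10, pattern = "solid")))
  expect_true(all(one$labels == 1L))
  a <- make_section_layout(60, 60, seed = 5)
  b <- make_section_layout(60, 60, seed = 5)
  expect_identical(a$labels, b$labels)
  expect_error(make_section_layout(10, 10, list(
    list(row = 1, col = 1, height = 5, width = 10, pattern = "solid"))),
    "cover")
  expect_error(make_section_layout(10, 10, list(
    list(row = 1, col = 1, height = 10, width = 10, pattern = "solid"),
    list(row = 1, col = 1, height = 2, width = 2, pattern = "stripes"))),
    "overlap")
})

test_that("fat patterns render as specified", {
  # solid: every pixel fat
  solid <- render_fat_mask(make_section_layout(16, 16, list(
    list(row = 1, col = 1, height = 16, width = 16, pattern = "solid"))))
  expect_equal(sum(solid$mask), 256L)
  # stripes width 4 period 8 over a 16-row section: fat rows 0-3 and 8-11
  # (0-based from the section top)
  st <- render_fat_mask(make_section_layout(16, 8, list(
    list(row = 1, col = 1, height = 16, width = 8, pattern = "stripes"))),
    stripe_width = 4, stripe_period = 8)
  fat_rows <- which(rowSums(st$mask) == 8) - 1L
  expect_equal(fat_rows, c(0:3, 8:11))
  muscle_rows <- which(rowSums(st$mask) == 0) - 1L
  expect_equal(muscle_rows, c(4:7, 12:15))
  # globules: fill fraction achieved within +-0.05 over 10 seeds
  gsec <- make_section_layout(100, 100, list(
    list(row = 1, col = 1, height = 100, width = 100, pattern = "globules")))
  fr <- vapply(1:10, function(s)
    mean(render_fat_mask(gsec, globule_fill = 0.3, seed = s)$mask),
    numeric(1))
  expect_true(all(abs(fr - 0.3) <= 0.05))
  # bit-reproducible per seed
  expect_identical(render_fat_mask(gsec, seed = 3)$mask,
                   render_fat_mask(gsec, seed = 3)$mask)
  expect_false(identical(render_fat_mask(gsec, seed = 3)$mask,
                         render_fat_mask(gsec, seed = 4)$mask))
  expect_error(render_fat_mask(gsec, globule_radius = c(60, 80)), "radius")
})

test_that("synthetic endmembers behave like spectra", {
  ax <- make_wavenumber_axis(444.2, 15.98, 100)
  flat <- synth_endmember(list(), baseline = c(1, 0), axis = ax)
  expect_equal(flat$intensity, rep(1, 100))
  one <- synth_endmember(list(c(1440, 12, 1)), c(0, 0), ax)
  expect_equal(which.max(one$intensity), which.min(abs(ax$values - 1440)))
  fat <- endmember_preset("fat", ax)
  muscle <- endmember_preset("muscle", ax)
  expect_true(all(fat$intensity >= 0), all(muscle$intensity >= 0))
  expect_lt(cor(fat$intensity, muscle$intensity), 0.95)
  expect_warning(synth_endmember(list(c(9000, 5, 1)), c(0, 0), ax), "outside")
})

test_that("assembled cubes substitute one spectrum per pixel", {
  # a short 8-point axis keeps the cube tiny; some canonical peaks fall
  # outside it, which rightly warns and is not the subject here
  ax <- make_wavenumber_axis(1000, 10, 8)
  fat <- suppressWarnings(endmember_preset("fat", ax))
  mus <- suppressWarnings(endmember_preset("muscle", ax))
  sm <- make_section_layout(2, 2, list(
    list(row = 1, col = 1, height = 2, width = 2, pattern = "solid")))
  fm <- structure(list(mask = matrix(c(1L, 0L, 0L, 1L), 2, 2), sections = sm),
                  class = "fat_mask")
  cube <- assemble_hsi(fm, fat, mus)
  expect_equal(cube$data[1, 1, ], fat$intensity)
  expect_equal(cube$data[2, 2, ], fat$intensity)
  expect_equal(cube$data[1, 2, ], mus$intensity)
  fm$mask[] <- 0L
  allm <- assemble_hsi(fm, fat, mus)
  expect_true(all(apply(allm$data, c(1, 2), function(s)
    isTRUE(all.equal(s, mus$intensity)))))
  ax2 <- make_wavenumber_axis(1000, 10, 9)
  mus2 <- suppressWarnings(endmember_preset("muscle", ax2))
  expect_error(assemble_hsi(fm, fat, mus2), "axis")
})

test_that("the default phantom has the native 240 x 240 x 800 geometry", {
  cube <- phantom_hsi(bands = 800, seed = 1)
  expect_equal(dim(cube$data), c(240L, 240L, 800L))
  expect_equal(cube$axis$step, 1.98, tolerance = 1e-12)
  expect_equal(sort(unique(as.vector(cube$truth))), 1:3)
  rm(cube); gc(verbose = FALSE)
})

test_that("a phantom contains exactly two distinct pixel spectra", {
  cube <- phantom_hsi(height = 48, width = 48, bands = 25, seed = 2)
  spectra <- matrix(cube$data, 48 * 48, 25)
  expect_equal(nrow(unique(round(spectra, 12))), 2L)
})
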