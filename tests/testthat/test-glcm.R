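# Image loading, gray-level quantization, GLCM and texture features.

const_img <- function(v, h = 8, w = 8) array(as.integer(v), c(h, w, 3))

test_that("load_image round-trips PNGs and promotes grayscale", {
  dir <- withr::local_tempdir()
  rgb <- array(stats::runif(64 * 64 * 3), c(64, 64, 3))
  png::writePNG(rgb, file.path(dir, "rgb.png"))
  got <- load_image(file.path(dir, "rgb.png"))
  expect_identical(dim(got), c(64L, 64L, 3L))
  expect_true(all(got >= 0 & got <= 255))
  gray <- matrix(stats::runif(16 * 16), 16, 16)
  png::writePNG(gray, file.path(dir, "gray.png"))
  gotg <- load_image(file.path(dir, "gray.png"))
  expect_identical(dim(gotg), c(16L, 16L, 3L))
  expect_identical(gotg[, , 1], gotg[, , 3])
  expect_error(load_image(file.path(dir, "nope.png")), "not found")
})

test_that("quantize bins luminance into equal-width levels", {
  expect_true(all(quantize(const_img(0)) == 0L))
  expect_true(all(quantize(const_img(255)) == 7L))
  # linear horizontal gradient over 8 columns -> one column per level,
  # verified against direct bin arithmetic
  vals <- round(seq(0, 255, length.out = 8))
  img <- array(0L, c(8, 8, 3))
  for (j in 1:8) img[, j, ] <- vals[j]
  q <- quantize(img, 8)
  oracle <- pmin(floor(vals * 8 / 256), 7)
  for (j in 1:8) expect_true(all(q[, j] == oracle[j]))
  expect_identical(sort(unique(as.vector(q))), 0:7)
  expect_error(quantize(const_img(0), levels = 1), "levels")
})

test_that("GLCM of a constant image has one cell equal to 1", {
  q <- quantize(const_img(100))
  g <- glcm(q, offsets = list(c(0L, 1L)))
  expect_equal(sum(g), 1)
  expect_equal(sum(unclass(g) > 0), 1L)
  lev <- quantize(const_img(100))[1, 1] + 1L
  expect_equal(unclass(g)[lev, lev], 1)
})

test_that("GLCM equals exhaustive pair enumeration on random grids", {
  set.seed(21)
  offs_sets <- list(list(c(0L, 1L)), list(c(1L, 0L), c(1L, -1L)),
                    list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L)))
  for (i in 1:12) {
    q <- rand_grid(sample(4:7, 1), sample(4:7, 1))
    offs <- offs_sets[[(i %% 3) + 1]]
    for (symmetric in c(TRUE, FALSE)) {
      got <- glcm(q, offsets = offs, symmetric = symmetric)
      want <- glcm_bruteforce(q, offs, symmetric = symmetric)
      expect_equal(unclass(got), want, ignore_attr = TRUE)
    }
  }
})

test_that("GLCM invariants: normalization, symmetry, coordinate convention", {
  set.seed(22)
  for (i in 1:8) {
    q <- rand_grid(6, 9)
    g <- glcm(q)
    expect_equal(sum(g), 1, tolerance = 1e-9)
    expect_equal(unclass(g), t(unclass(g)))
    # transposing the grid and the offsets gives the same matrix
    qt <- t(q); attr(qt, "levels") <- attr(q, "levels")
    g1 <- glcm(q, offsets = list(c(0L, 1L)), symmetric = FALSE,
               normalize = FALSE)
    g2 <- glcm(qt, offsets = list(c(1L, 0L)), symmetric = FALSE,
               normalize = FALSE)
    expect_equal(unclass(g1), unclass(g2), ignore_attr = TRUE)
  }
})

test_that("GLCM rejects bad offsets and empty grids", {
  q <- rand_grid(4, 4)
  expect_error(glcm(q, offsets = list(c(0L, 0L))), "not allowed")
  expect_error(glcm(q, offsets = list(c(4L, 0L))), "extent")
  expect_error(glcm(matrix(integer(0), 0, 0)), "empty")
})

test_that("background masking drops white-white pairs only", {
  q <- matrix(c(7L, 7L, 7L, 0L), 2, 2)
  attr(q, "levels") <- 8L
  g_all <- glcm(q, offsets = list(c(0L, 1L)), symmetric = FALSE,
                normalize = FALSE)
  g_mask <- glcm(q, offsets = list(c(0L, 1L)), symmetric = FALSE,
                 normalize = FALSE, mask_background = TRUE)
  expect_equal(unclass(g_all)[8, 8], 1)
  expect_equal(unclass(g_mask)[8, 8], 0)
  expect_equal(sum(g_all) - sum(g_mask), 1)
})

test_that("glcm_feature flattens row-major, sums to 1, and is a bijection", {
  set.seed(23)
  q <- rand_grid(10, 10)
  g <- glcm(q)
  v <- glcm_feature(g)
  expect_length(v, 64L)
  expect_equal(sum(v), 1, tolerance = 1e-9)
  expect_true(all(v >= 0))
  expect_equal(matrix(v, 8, 8, byrow = TRUE), unclass(g), ignore_attr = TRUE)
  # identity-like: all mass in cell (1,1) -> v[1] = 1
  qc <- quantize(const_img(0))
  vc <- glcm_feature(glcm(qc, offsets = list(c(0L, 1L))))
  expect_equal(vc[1], 1)
  expect_equal(sum(vc[-1]), 0)
  g_raw <- glcm(q, normalize = FALSE)
  expect_error(glcm_feature(g_raw), "normalize")
})
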