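# Otsu thresholding, binarization, labelling, moment ellipses

test_that("otsu threshold handles bimodal and degenerate images", {
  img <- matrix(c(rep(0, 60), rep(1, 40)), 10, 10)
  t <- otsu_threshold(img)
  expect_lt(t, 0.01) # smallest-tie rule: bin of 0.0
  expect_true(all(binarize(img, t) == (img == 1)))
  expect_error(otsu_threshold(matrix(0.5, 5, 5)),
               class = "mfod_degenerate_error")
})

test_that("otsu threshold equals brute-force maximization on a toy histogram", {
  vals <- rep(0:7, times = c(8, 8, 8, 8, 2, 2, 2, 2))
  img <- matrix(vals, 8, 5)
  expect_equal(otsu_threshold(img, n_levels = 8L),
               oracle_otsu(img, n_levels = 8L))
})

test_that("otsu threshold matches the exhaustive oracle on random images", {
  withr::with_seed(42, {
    for (i in 1:25) {
      img <- matrix(runif(64, 0, sample(c(1, 10, 255), 1)), 8, 8)
      if (i %% 3 == 0) img <- round(img) # heavy ties
      if (diff(range(img)) == 0) next
      expect_equal(otsu_threshold(img), oracle_otsu(img))
    }
  })
})

test_that("binarize is strict and shape-preserving", {
  img <- matrix(0.3, 3, 3)
  img[2, 3] <- 0.9
  expect_identical(sum(binarize(img, 0.5)), 1L)
  expect_true(binarize(img, 0.5)[2, 3])
  expect_false(any(binarize(img, 0.9)))
  expect_true(all(binarize(img, -1)))
  expect_identical(sum(binarize(img, 0.3)), 1L) # strict: equal is background
})

test_that("labelling follows 8-connectivity and raster-order labels", {
  m <- matrix(FALSE, 6, 6)
  expect_identical(nrow(label_regions(m)), 0L)

  m[2, 2] <- TRUE
  m[3, 3] <- TRUE # touching only diagonally
  expect_identical(nrow(label_regions(m)), 1L)
  expect_identical(nrow(label_regions(m, connectivity = 4L)), 2L)

  two <- matrix(FALSE, 9, 12)
  two[2, 2:11] <- TRUE
  two[7, 2:11] <- TRUE # separated by >= 2 background rows
  regs <- label_regions(two)
  expect_identical(regs$label, 1:2)
  expect_identical(regs$area, c(10L, 10L))
  expect_identical(nrow(unique(rbind(regs$pixels[[1]], regs$pixels[[2]]))),
                   20L)
  expect_true(all(regs$pixels[[1]][, "row"] == 1)) # 0-based, raster order
})

test_that("labelling partitions match a flood-fill oracle on random masks", {
  withr::with_seed(7, {
    for (i in 1:15) {
      m <- matrix(runif(20 * 24) < 0.35, 20, 24)
      regs <- label_regions(m)
      lab <- oracle_label(m)
      expect_identical(sum(regs$area), sum(m)) # conservation
      expect_identical(nrow(regs), max(lab))
      for (k in seq_len(nrow(regs))) {
        px <- regs$pixels[[k]]
        expect_identical(unname(unique(lab[px + 1L])), k)
      }
    }
  })
})

test_that("moment ellipse of canonical pixel sets has closed-form values", {
  one <- region_shape(tibble::tibble(pixels = list(cbind(5, 7))))
  expect_equal(one$L, 4 * sqrt(1 / 12), tolerance = 1e-12)
  expect_equal(one$omega, one$L, tolerance = 1e-12)
  expect_equal(one$Ar, 1)
  expect_identical(one$phi_deg, 0) # isotropic tie-break

  row100 <- region_shape(tibble::tibble(
    pixels = list(cbind(row = rep(3, 100), col = 0:99))
  ))
  expect_equal(row100$Ar, 100, tolerance = 1e-12)
  expect_equal(row100$L, 4 * sqrt(10000 / 12), tolerance = 1e-12)
  expect_identical(row100$phi_deg, 90)
})

test_that("axis-aligned rectangles have aspect ratio l/w exactly", {
  for (dims in list(c(40, 4), c(25, 5), c(60, 12), c(7, 7))) {
    px <- as.matrix(expand.grid(row = 0:(dims[2] - 1), col = 0:(dims[1] - 1)))
    sh <- region_shape(tibble::tibble(pixels = list(px)))
    expect_equal(sh$Ar, dims[1] / dims[2], tolerance = 1e-12)
  }
})

test_that("moment descriptors match the covariance-eigen oracle on random blobs", {
  withr::with_seed(11, {
    for (i in 1:30) {
      px <- random_blob()
      if (nrow(px) < 3) next
      sh <- region_shape(tibble::tibble(pixels = list(px)))
      or <- oracle_shape(px)
      expect_equal(sh$L, or$L, tolerance = 1e-9)
      expect_equal(sh$omega, or$omega, tolerance = 1e-9)
      expect_equal(sh$phi_deg, or$phi, tolerance = 1e-9)
    }
  })
})

test_that("moment descriptors are translation-invariant; transposition maps phi to 90 - phi", {
  withr::with_seed(23, {
    for (i in 1:10) {
      px <- random_blob()
      sh <- region_shape(tibble::tibble(pixels = list(px)))
      moved <- region_shape(tibble::tibble(pixels = list(px + 100)))
      expect_equal(moved$L, sh$L, tolerance = 1e-9)
      expect_equal(moved$phi_deg, sh$phi_deg, tolerance = 1e-9)
      flipped <- region_shape(tibble::tibble(pixels = list(px[, 2:1])))
      expect_equal(flipped$L, sh$L, tolerance = 1e-9)
      expect_equal(flipped$omega, sh$omega, tolerance = 1e-9)
      expect_equal(flipped$phi_deg %% 180, (90 - sh$phi_deg) %% 180,
                   tolerance = 1e-9)
    }
  })
})
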