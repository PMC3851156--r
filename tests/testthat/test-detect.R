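# Region classification, Hough voting, angle conventions, removal, loop

test_that("classification is strict on both shape thresholds", {
  cfg <- detector_config() # T1 = 5, T2 = 30
  expect_identical(classify_region(6, 20, cfg), "ellipse")
  expect_identical(classify_region(5, 20, cfg), "hough") # Ar boundary
  expect_identical(classify_region(6, 30, cfg), "hough") # omega boundary
  expect_identical(classify_region(12, 35, cfg), "hough") # too wide
  expect_identical(classify_region(c(6, 2), c(10, 10), cfg),
                   c("ellipse", "hough"))
})

test_that("hough voting recovers axis-aligned pixel lines", {
  horiz <- cbind(row = rep(10, 50), col = 0:49)
  hl <- hough_line(horiz, image_diag = 80)
  expect_equal(hl$theta_deg, 90)
  expect_equal(hl$rho, 10, tolerance = 0.5)
  expect_identical(hl$votes, 50L)

  vert <- cbind(row = 0:29, col = rep(5, 30))
  hl <- hough_line(vert, image_diag = 40)
  expect_equal(hl$theta_deg, 0)
  expect_equal(hl$rho, 5, tolerance = 0.5)
  expect_identical(hl$votes, 30L)

  single <- hough_line(cbind(3, 4), image_diag = 10)
  expect_identical(single$votes, 1L)
  expect_equal(single$theta_deg, 0) # all thetas tie; smallest wins

  expect_error(hough_line(cbind(numeric(0), numeric(0))),
               class = "mfod_contract_error")
})

test_that("hough argmax equals the dense-accumulator oracle on random pixel sets", {
  withr::with_seed(31, {
    for (i in 1:12) {
      n <- sample(10:40, 1)
      px <- cbind(row = sample(0:30, n, TRUE), col = sample(0:30, n, TRUE))
      px <- unique(px)
      hl <- hough_line(px, image_diag = 45)
      or <- oracle_hough(px, image_diag = 45)
      expect_equal(hl$theta_deg, or$theta_deg)
      expect_equal(hl$rho, or$rho)
      expect_identical(hl$votes, as.integer(or$votes))
    }
  })
})

test_that("hough theta maps to the NIH angle convention as the identity", {
  expect_equal(line_angle_from_theta(90), 90) # horizontal line
  expect_equal(line_angle_from_theta(0), 0)   # vertical line
  expect_equal(line_angle_from_theta(45), 45)
  expect_equal(line_angle_from_theta(137.25), 137.25, tolerance = 1e-9)
  expect_error(line_angle_from_theta(180), class = "mfod_contract_error")
  expect_error(line_angle_from_theta(-1), class = "mfod_contract_error")
  expect_identical(ellipse_angle_to_mfo(137.2), 137.2)
})

test_that("hough and ellipse paths agree on the same pixel line", {
  # down-left diagonal (r = c): both paths must call it the same angle
  px <- cbind(row = 0:40, col = 0:40)
  sh <- region_shape(tibble::tibble(pixels = list(px)))
  hl <- hough_line(px, image_diag = 60)
  expect_equal(line_angle_from_theta(hl$theta_deg), sh$phi_deg,
               tolerance = 1)
})

test_that("removal clears a strip of the stated half-width, map-wide", {
  m <- matrix(TRUE, 5, 30)
  ln <- list(angle_deg = 0, anchor_row = 2, anchor_col = 10) # vertical line
  out <- remove_line_pixels(m, ln, removal_width = 17L)
  kept_cols <- which(apply(out, 2, any)) - 1L # 0-based
  expect_identical(kept_cols, c(0L, 1L, 19L:29L)) # |c - 10| <= 8 removed
  expect_identical(m, matrix(TRUE, 5, 30)) # input untouched

  # all pixels on the line -> all removed
  mm <- matrix(FALSE, 20, 20)
  mm[5, ] <- TRUE
  ln2 <- list(angle_deg = 90, anchor_row = 4, anchor_col = 3) # 0-based row 4
  expect_false(any(remove_line_pixels(mm, ln2, 1L)))

  # line far from any pixel -> unchanged
  ln3 <- list(angle_deg = 90, anchor_row = 100, anchor_col = 0)
  expect_identical(remove_line_pixels(mm, ln3, 17L), mm)
})

test_that("removal never adds pixels and is idempotent", {
  withr::with_seed(5, {
    m <- matrix(runif(40 * 40) < 0.3, 40, 40)
    ln <- list(angle_deg = 63, anchor_row = 20, anchor_col = 17)
    once <- remove_line_pixels(m, ln, 17L)
    expect_lte(sum(once), sum(m))
    expect_identical(remove_line_pixels(once, ln, 17L), once)
  })
})

test_that("detect_lines walks regions longest-first and respects N and T3", {
  expect_identical(nrow(detect_lines(matrix(FALSE, 30, 30))), 0L)

  # three bars of decreasing length, well separated
  m <- matrix(FALSE, 40, 120)
  m[5, 1:100] <- TRUE
  m[20, 1:60] <- TRUE
  m[35, 1:30] <- TRUE
  out <- detect_lines(m, detector_config(N = 5L))
  expect_identical(out$order, 1:3)
  expect_equal(out$angle_deg, rep(90, 3), tolerance = 1e-9)
  expect_true(all(out$method == "ellipse"))
  expect_true(all(diff(out$L) < 0)) # longest first here (no splitting)
  expect_gte(out$L[1], max(region_shape(label_regions(m))$L) - 1e-9)

  # T3 stop: terminal short line kept by default, dropped on request
  m2 <- matrix(FALSE, 40, 120)
  m2[5, 1:100] <- TRUE
  m2[20, 1:5] <- TRUE # shorter than 10% of the first
  kept <- detect_lines(m2, detector_config())
  expect_identical(nrow(kept), 2L)
  expect_lt(kept$L[2], kept$L[1] * 0.1)
  dropped <- detect_lines(m2, detector_config(drop_terminal_short_line = TRUE))
  expect_identical(nrow(dropped), 1L)
})

test_that("detect_lines routes a branched X-component through hough", {
  m <- matrix(FALSE, 61, 61)
  for (i in 0:60) {
    m[i + 1, i + 1] <- TRUE # r = c, angle 135
    m[i + 1, 61 - i] <- TRUE # r = 60 - c, angle 45
  }
  m[30:32, 30:32] <- TRUE # thicken the junction
  regs <- region_shape(label_regions(m))
  expect_identical(nrow(regs), 1L)
  out <- detect_lines(m, detector_config())
  expect_identical(out$method[1], "hough")
  expect_equal(sort(out$angle_deg[1:2]), c(45, 135), tolerance = 1.5)
})

test_that("detector_config validates invariants", {
  expect_error(detector_config(T3 = 0), class = "mfod_param_error")
  expect_error(detector_config(T3 = 1.2), class = "mfod_param_error")
  expect_error(detector_config(removal_width = 16), class = "mfod_param_error")
  expect_error(detector_config(N = 0), class = "mfod_param_error")
  expect_error(detector_config(connectivity = 6), class = "mfod_param_error")
})
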