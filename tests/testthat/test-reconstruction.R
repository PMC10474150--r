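test_that("decodeImage inverts the bit expansion in the fixed variable order", {
  expect_equal(imageValues(decodeImage(c(0, 0, 1, 0, 0, 1, 1, 1), 2, 1)),
               matrix(c(0, 1, 2, 3), 2, 2, byrow = TRUE))
  expect_equal(imageValues(decodeImage(c(1, 1), 1, 1)), matrix(3, 1, 1))
  expect_error(decodeImage(c(0, 1), 2, 1), "length")
  set.seed(71)
  for (rep in 1:10) {
    bits <- randomBits(3 * 3 * 3)
    img <- decodeImage(bits, n = 3, m = 2)
    expect_identical(encodeImage(img, m = 2), as.integer(bits))
  }
})

test_that("calibrateXray zeroes the empty region mean and clamps", {
  flat <- matrix(5, 4, 4)
  expect_equal(calibrateXray(flat, matrix(TRUE, 4, 4)), matrix(0, 4, 4))
  img <- matrix(2, 5, 5)
  img[2:4, 2:4] <- 7
  mask <- matrix(TRUE, 5, 5); mask[2:4, 2:4] <- FALSE
  cal <- calibrateXray(img, mask)
  expect_equal(cal[3, 3], 5)
  expect_equal(cal[1, 1], 0)
  # pre-clamp empty mean is exactly zero
  raw <- matrix(runif(25, 1, 3), 5, 5)
  expect_lt(abs(mean((raw - mean(raw[mask]))[mask])), 1e-12)
  expect_error(calibrateXray(img, matrix(FALSE, 5, 5)), "mask")
})

test_that("compareImages counts exact mismatches and returns the signed map", {
  a <- ImageGrid(matrix(c(0, 1, 2, 3), 2, 2, byrow = TRUE), bitDepth = 2L)
  expect_equal(compareImages(a, a),
               list(mismatchedPixels = 0L, relativeError = 0,
                    diffImage = matrix(0, 2, 2)))
  b <- ImageGrid(matrix(c(0, 1, 2, 2), 2, 2, byrow = TRUE), bitDepth = 2L)
  cmp <- compareImages(a, b)
  expect_equal(cmp$mismatchedPixels, 1L)
  expect_equal(cmp$relativeError, 0.25)
  expect_equal(sum(cmp$diffImage), 1)
  expect_equal(cmp$diffImage[2, 2], 1)
  # independent per-pixel loop oracle
  set.seed(73)
  va <- matrix(sample(0:3, 36, TRUE), 6, 6)
  vb <- matrix(sample(0:3, 36, TRUE), 6, 6)
  loop <- 0L
  for (i in 1:6) for (j in 1:6) if (va[i, j] != vb[i, j]) loop <- loop + 1L
  expect_equal(compareImages(va, vb)$mismatchedPixels, loop)
  expect_error(compareImages(va, matrix(0, 5, 5)), "size")
})

test_that("the toy pipeline reconstructs the sample exactly with a certificate", {
  sm <- systemMatrix(makeGeometry(2, 2))
  sino <- project(toySample2x2(), sm)
  rep <- reconstruct(sino, m = 1, solver = "exhaustive",
                     reference = toySample2x2())
  expect_equal(rep@achievedEnergy, -46)
  expect_equal(rep@expectedEnergy, -46)
  expect_equal(rep@energyGap, 0)
  expect_identical(rep@mismatchedPixels, 0L)
  expect_equal(rep@relativeError, 0)
  expect_equal(imageValues(rep@image), imageValues(toySample2x2()))
})

test_that("a zero sinogram reconstructs the zero image at zero energy", {
  geom <- makeGeometry(3, 2)
  rep <- reconstruct(Sinogram(matrix(0, 2, 3), geom), m = 0,
                     solver = "exhaustive")
  expect_equal(imageValues(rep@image), matrix(0, 3, 3))
  expect_equal(rep@achievedEnergy, 0)
  expect_equal(rep@expectedEnergy, 0)
  expect_true(is.na(rep@mismatchedPixels))
})

test_that("exhaustive reconstruction recovers random binary 3x3 images when unique", {
  set.seed(79)
  sm <- systemMatrix(makeGeometry(3, 3))
  for (rep in 1:5) {
    vals <- matrix(sample(0:1, 9, TRUE), 3, 3)
    img <- ImageGrid(vals, bitDepth = 1L)
    sino <- project(img, sm)
    qm <- buildQubo(sm, sino, m = 0)
    best <- solveExhaustive(qm)
    # enumerate all 512 images to check the minimizer is unique
    unique_min <- best@occurrencesBest == 1L
    out <- reconstruct(sino, m = 0, solver = "exhaustive", reference = img,
                       sm = sm)
    expect_lt(out@energyGap, 1e-9)
    if (unique_min) expect_identical(out@mismatchedPixels, 0L)
  }
})

test_that("a zero energy gap certifies sinogram reproduction", {
  set.seed(83)
  inst <- randomInstance(n = 3, m = 1, numProjections = 3)
  out <- reconstruct(inst$sino, m = 1, solver = "sa", numReads = 16,
                     seed = 7, reference = inst$img, sm = inst$sm)
  if (abs(out@energyGap) < 1e-6) {
    reproj <- sinogramValues(project(out@image, inst$sm))
    expect_lt(max(abs(reproj - sinogramValues(inst$sino))), 1e-6)
  }
  expect_gte(out@energyGap, -1e-6)
})

test_that("diff images render symmetrically about mid-gray", {
  d <- matrix(c(-2, 0, 1, 2), 2, 2)
  r <- renderDiffImage(d)
  expect_equal(r[1, 1], 1)      # reconstruction short -> bright
  expect_equal(r[2, 2], 0)      # reconstruction high -> dark
  expect_equal(r[2, 1], 0.5)    # equal -> mid-gray
})
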