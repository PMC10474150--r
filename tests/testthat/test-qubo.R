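test_that("bitsNeeded returns the smallest sufficient bit count", {
  expect_identical(bitsNeeded(1023), 10L)
  expect_identical(bitsNeeded(1), 1L)
  expect_identical(bitsNeeded(3), 2L)
  expect_identical(bitsNeeded(0), 1L)
  expect_identical(bitsNeeded(4), 3L)
  expect_identical(bitsNeeded(1024), 11L)
})

test_that("the 2x2 QUBO reproduces the printed coefficient matrix", {
  qm <- toyQubo()
  expect_equal(qm@linear, c(-4, -4, -8, -12, -12, -20, -16, -28))
  Q <- as.matrix(qm@quadratic)
  expect_equal(Q[1, 2], 8)    # same-pixel bit pair of pixel (1,1)
  expect_equal(Q[1, 5], 2)    # (q0^11, q0^21): shared angle-0 ray
  expect_equal(qm@offset, 46)
  expect_true(all(Q[lower.tri(Q, diag = TRUE)] == 0))
})

test_that("a zero sinogram yields a purely positive-diagonal model", {
  geom <- makeGeometry(3, 3)
  sm <- systemMatrix(geom)
  qm <- buildQubo(sm, Sinogram(matrix(0, 3, 3), geom), m = 1)
  expect_true(all(qm@linear > 0))
  expect_equal(energy(qm, rep(0, qm@numVars)), 0)
  expect_equal(solveExhaustive(qm)@energy, 0)
})

test_that("QUBO energy plus offset equals the squared sinogram residual", {
  set.seed(41)
  inst <- randomInstance(n = 3, m = 2, numProjections = 3)
  qm <- buildQubo(inst$sm, inst$sino, m = 2)
  for (rep in seq_len(200)) {
    q <- randomBits(qm@numVars)
    pixels <- as.vector(t(imageValues(decodeImage(q, 3, 2))))
    expect_lt(abs(energy(qm, q) + qm@offset -
                    oracleResidual(inst$sm, inst$sino, pixels)), 1e-9)
  }
})

test_that("expectedMinEnergy is the negated model offset", {
  set.seed(43)
  for (k in 1:5) {
    inst <- randomInstance(n = sample(2:4, 1), m = sample(0:2, 1),
                           numProjections = sample(1:4, 1))
    qm <- buildQubo(inst$sm, inst$sino, m = bitDepth(inst$img) - 1)
    expect_equal(expectedMinEnergy(inst$sino), -qm@offset)
  }
  geom <- makeGeometry(3, 2)
  expect_equal(expectedMinEnergy(Sinogram(matrix(0, 2, 3), geom)), 0)
})

test_that("the Ising conversion matches the printed example and the energy identity", {
  qm <- toyQubo()
  im <- quboToIsing(qm)
  expect_equal(im@h[1], 3)                       # leading field value
  expect_equal(as.matrix(im@J)[1, 2], 2)
  ri <- solveExhaustive(im)
  expect_equal(ri@energy, -20)                   # brute-force Ising minimum
  expect_equal(im@offset, -26)                   # QUBO min - Ising min
  set.seed(47)
  for (rep in seq_len(100)) {
    q <- randomBits(8)
    expect_lt(abs(energy(qm, q) - (energy(im, 2 * q - 1) + im@offset)), 1e-9)
  }
  # all-zero QUBO converts to an all-zero Ising model
  z <- quboToIsing(QuboModel(numeric(3)))
  expect_true(all(z@h == 0) && all(as.matrix(z@J) == 0) && z@offset == 0)
})

test_that("energy validates assignment length and alphabet", {
  qm <- toyQubo()
  expect_error(energy(qm, c(0, 1)), "length")
  expect_error(energy(qm, rep(2, 8)), "entries")
  expect_error(energy(quboToIsing(qm), rep(0, 8)), "entries")
  expect_equal(energy(qm, c(0, 0, 1, 0, 0, 1, 1, 1)), -46)
  expect_equal(energy(qm, rep(0, 8)), 0)
})

test_that("upper-triangular evaluation equals symmetrized-matrix evaluation", {
  set.seed(53)
  inst <- randomInstance(n = 3, m = 1, numProjections = 2)
  qm <- buildQubo(inst$sm, inst$sino, m = 1)
  Q <- as.matrix(qm@quadratic)
  S <- (Q + t(Q)) / 2
  for (rep in seq_len(20)) {
    q <- randomBits(qm@numVars)
    expect_lt(abs(energy(qm, q) -
                    (sum(qm@linear * q) + as.numeric(t(q) %*% S %*% q))), 1e-9)
  }
})

test_that("every model energy is bounded below by the negated offset", {
  set.seed(59)
  for (k in 1:4) {
    inst <- randomInstance(n = 2, m = sample(0:1, 1),
                           numProjections = sample(1:3, 1))
    qm <- buildQubo(inst$sm, inst$sino, m = bitDepth(inst$img) - 1)
    best <- solveExhaustive(qm)
    expect_gte(best@energy, -qm@offset - 1e-9)
    # equality certifies exact sinogram reproduction
    pix <- as.vector(t(imageValues(decodeImage(best@assignment, 2,
                                               bitDepth(inst$img) - 1))))
    expect_lt(oracleResidual(inst$sm, inst$sino, pix), 1e-9)
  }
})

test_that("buildQubo rejects mismatched geometries", {
  sm <- systemMatrix(makeGeometry(2, 2))
  other <- Sinogram(matrix(0, 3, 2), makeGeometry(2, 3))
  expect_error(buildQubo(sm, other, m = 0), "geometry")
})
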