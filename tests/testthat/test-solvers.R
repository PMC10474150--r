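test_that("exhaustive search finds the printed 2x2 ground states", {
  qm <- toyQubo()
  res <- solveExhaustive(qm)
  expect_equal(res@energy, -46)
  expect_equal(res@assignment, c(0L, 0L, 1L, 0L, 0L, 1L, 1L, 1L))
  ri <- solveExhaustive(quboToIsing(qm))
  expect_equal(ri@energy, -20)
  expect_equal(ri@assignment, 2L * res@assignment - 1L)
})

test_that("exhaustive search handles trivial and oversized models", {
  res <- solveExhaustive(QuboModel(5))
  expect_equal(res@energy, 0)
  expect_equal(res@assignment, 0L)
  expect_error(solveExhaustive(QuboModel(numeric(30))), "refuses")
  # lexicographic tie-break: all-zero model has 2^k degenerate minima
  tie <- solveExhaustive(QuboModel(numeric(3)))
  expect_equal(tie@assignment, c(0L, 0L, 0L))
  expect_equal(tie@occurrencesBest, 8L)
})

test_that("simulated annealing solves the 2x2 model and is seed-reproducible", {
  qm <- toyQubo()
  res <- solveSA(qm, numReads = 100, seed = 99)
  expect_equal(res@energy, -46)
  expect_lte(res@occurrencesBest, res@numReads)
  res2 <- solveSA(qm, numReads = 100, seed = 99)
  expect_identical(res@assignment, res2@assignment)
  expect_identical(res@energy, res2@energy)
  expect_identical(res@occurrencesBest, res2@occurrencesBest)
  # zero model: any assignment, energy 0
  expect_equal(solveSA(QuboModel(numeric(4)), numReads = 2, seed = 1)@energy, 0)
})

test_that("tabu search solves the 2x2 model and flips an isolated negative bias", {
  qm <- toyQubo()
  res <- solveTabu(qm, seed = 99)
  expect_equal(res@energy, -46)
  res2 <- solveTabu(qm, seed = 99)
  expect_identical(res@assignment, res2@assignment)
  lone <- solveTabu(QuboModel(c(-3, 2, 1)), numRestarts = 1, maxIters = 5,
                    seed = 3)
  expect_equal(lone@energy, -3)
  expect_equal(lone@assignment, c(1L, 0L, 0L))
})

test_that("heuristic solvers never beat the exhaustive optimum", {
  set.seed(61)
  for (k in 1:5) {
    inst <- randomInstance(n = sample(2:3, 1), m = sample(0:1, 1),
                           numProjections = sample(1:3, 1))
    qm <- buildQubo(inst$sm, inst$sino, m = bitDepth(inst$img) - 1)
    if (qm@numVars > 18) next
    opt <- solveExhaustive(qm)@energy
    expect_gte(solveSA(qm, numReads = 8, seed = k)@energy, opt - 1e-9)
    expect_gte(solveTabu(qm, numRestarts = 2, seed = k)@energy, opt - 1e-9)
  }
})

test_that("reported solver energies survive independent re-evaluation", {
  qm <- toyQubo()
  for (res in list(solveExhaustive(qm), solveSA(qm, numReads = 4, seed = 5),
                   solveTabu(qm, numRestarts = 2, seed = 5))) {
    expect_lt(abs(energy(qm, res@assignment) - res@energy), 1e-9)
  }
})

test_that("the external-sampler file contract round-trips and is verified", {
  qm <- toyQubo()
  dir <- withr::local_tempdir()

  # dependency-free exhaustive stub honoring the contract
  stub <- file.path(dir, "stub.R")
  writeLines(c(
    'args <- commandArgs(trailingOnly = TRUE)',
    'lines <- readLines(args[1])',
    'f <- do.call(rbind, lapply(strsplit(lines, " "), as.numeric))',
    'nv <- max(f[, 1:2])',
    'best <- Inf; bestq <- NULL',
    'for (v in 0:(2^nv - 1)) {',
    '  q <- (v %/% 2^((nv - 1):0)) %% 2',
    '  e <- sum(ifelse(f[, 1] == f[, 2], f[, 3] * q[f[, 1]],',
    '                  f[, 3] * q[f[, 1]] * q[f[, 2]]))',
    '  if (e < best) { best <- e; bestq <- q }',
    '}',
    'writeLines(sprintf("{\\"assignment\\": \\"%s\\", \\"energy\\": %.17g}",',
    '                   paste(bestq, collapse = ""), best), args[2])'
  ), stub)
  res <- solveExternal(qm, file.path(R.home("bin"), "Rscript"), args = stub,
                       workDir = dir)
  expect_equal(res@energy, -46)
  expect_equal(res@assignment, c(0L, 0L, 1L, 0L, 0L, 1L, 1L, 1L))
  expect_identical(res@solverName, "external")

  # a stub reporting a wrong energy for its assignment is rejected
  bad <- file.path(dir, "bad.R")
  writeLines(c(
    'args <- commandArgs(trailingOnly = TRUE)',
    'writeLines("{\\"assignment\\": \\"00000000\\", \\"energy\\": -999}", args[2])'
  ), bad)
  expect_error(solveExternal(qm, file.path(R.home("bin"), "Rscript"),
                             args = bad, workDir = dir),
               "direct evaluation")
})

test_that("model serialization preserves variables, coefficients and header", {
  qm <- toyQubo()
  dir <- withr::local_tempdir()
  p <- file.path(dir, "toy.coo")
  writeModel(qm, p)
  back <- readModel(p)
  expect_s4_class(back, "QuboModel")
  expect_identical(back@numVars, qm@numVars)
  expect_equal(back@linear, qm@linear)
  expect_equal(as.matrix(back@quadratic), as.matrix(qm@quadratic))
  expect_equal(back@offset, qm@offset)
  expect_identical(back@n, qm@n)
  expect_identical(back@m, qm@m)
})
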