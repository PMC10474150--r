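## Classical solvers for QUBO / Ising models: exact enumeration, simulated
## annealing, tabu search, and a file contract for external samplers.

.modelParts <- function(model) {
  if (is(model, "QuboModel"))
    list(linear = model@linear, Q = model@quadratic, spin = FALSE,
         alphabet = c(0, 1))
  else if (is(model, "IsingModel"))
    list(linear = model@h, Q = model@J, spin = TRUE, alphabet = c(-1, 1))
  else stop("model must be a QuboModel or IsingModel")
}

.tripletsOf <- function(Q) {
  T <- as(Q, "TsparseMatrix")
  list(i = T@i + 1L, j = T@j + 1L, x = T@x)
}

.verifyEnergy <- function(model, assignment, reported) {
  e <- energy(model, assignment)
  if (abs(e - reported) > 1e-9 * max(1, abs(e)))
    stop(sprintf("solver reported energy %.12g but direct evaluation gives %.12g",
                 reported, e))
  e
}

.solveResult <- function(assignment, energy, numReads, occ, name, seed, wt) {
  new("SolveResult", assignment = as.integer(assignment),
      energy = as.numeric(energy), numReads = as.integer(numReads),
      occurrencesBest = as.integer(occ), solverName = name,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      wallTime = as.numeric(wt))
}

#' Exact solver by exhaustive enumeration
#'
#' Enumerates all \code{2^numVars} assignments (in chunks) and returns the
#' global minimum; ties are broken by the lexicographically smallest
#' assignment (0 before 1, -1 before +1). Deterministic; refuses models
#' with more than \code{maxVars} variables.
#'
#' @param model a [QuboModel-class] or [IsingModel-class].
#' @param maxVars refusal threshold, default 24.
#' @return a [SolveResult-class]; \code{numReads} is the number of
#'   assignments enumerated and \code{occurrencesBest} the number attaining
#'   the minimum.
#' @export
solveExhaustive <- function(model, maxVars = 24) {
  t0 <- proc.time()[["elapsed"]]
  parts <- .modelParts(model)
  nv <- length(parts$linear)
  if (nv > maxVars)
    stop(sprintf("model has %d variables; exhaustive search refuses more than %d",
                 nv, maxVars))
  total <- 2^nv
  chunk <- min(total, 2^14)
  bestE <- Inf; bestX <- NULL; occ <- 0
  pow <- 2^((nv - 1):0)                 # variable 1 = most significant bit
  for (start in seq(0, total - 1, by = chunk)) {
    v <- start + seq_len(min(chunk, total - start)) - 1
    X <- vapply(pow, function(p) (v %/% p) %% 2, numeric(length(v)))
    X <- t(X)                           # nvars x B, bits in {0,1}
    if (parts$spin) X <- 2 * X - 1
    E <- .energiesMatrix(parts$linear, parts$Q, X)
    mE <- min(E)
    if (mE < bestE - 1e-9) {            # strictly better chunk minimum
      bestE <- mE
      bestX <- X[, which.min(E)]        # first hit = lexicographically smallest
      occ <- sum(E <= mE + 1e-9)
    } else if (mE <= bestE + 1e-9) {    # ties with the running best
      occ <- occ + sum(E <= bestE + 1e-9)
    }
  }
  e <- .verifyEnergy(model, bestX, bestE)
  .solveResult(bestX, e, min(total, .Machine$integer.max), min(occ, total),
               "exhaustive", NULL, proc.time()[["elapsed"]] - t0)
}

# spec-stated schedule heuristic: beta0 = 0.1 / mean |coeff|,
# beta1 = 10 / min nonzero |coeff|
.defaultBetaRange <- function(parts) {
  co <- c(parts$linear[parts$linear != 0], parts$Q@x[parts$Q@x != 0])
  co <- abs(co)
  if (!length(co)) return(c(0.1, 10))
  c(0.1 / mean(co), 10 / min(co))
}

#' Simulated-annealing solver
#'
#' Best-of-\code{numReads} single-spin-flip Metropolis annealing over a
#' geometric inverse-temperature ladder, with O(degree) incremental energy
#' updates. Reproducible for a fixed \code{seed}. May return a local
#' optimum; the reported energy is always re-verified by direct evaluation.
#'
#' @param model a [QuboModel-class] or [IsingModel-class].
#' @param numReads independent restarts (default 32).
#' @param sweeps Metropolis sweeps per read (default \code{10 * numVars}).
#' @param betaSchedule length-2 numeric \code{c(beta0, beta1)}; default is
#'   \code{0.1 / mean(|coeff|)} to \code{10 / min(nonzero |coeff|)}.
#' @param seed integer seed, or \code{NULL} to leave the RNG state alone.
#' @return a [SolveResult-class].
#' @export
solveSA <- function(model, numReads = 32, sweeps = NULL, betaSchedule = NULL,
                    seed = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stopifnot(numReads >= 1)
  parts <- .modelParts(model)
  nv <- length(parts$linear)
  if (is.null(sweeps)) sweeps <- 10L * nv
  stopifnot(sweeps >= 1)
  if (is.null(betaSchedule)) betaSchedule <- .defaultBetaRange(parts)
  if (!is.null(seed)) set.seed(seed)
  tr <- .tripletsOf(parts$Q)
  res <- .saCpp(nv, parts$linear, tr$i, tr$j, tr$x,
                as.integer(numReads), as.integer(sweeps),
                betaSchedule[1], betaSchedule[2], parts$spin)
  e <- .verifyEnergy(model, res$assignment, res$energy)
  .solveResult(res$assignment, e, numReads, res$occurrencesBest, "sa",
               seed, proc.time()[["elapsed"]] - t0)
}

#' Tabu-search solver
#'
#' Multistart single-flip tabu search: each iteration flips the
#' best-improving non-tabu variable (a tabu move is admitted by aspiration
#' when it improves on the best energy seen), with a fixed tabu tenure.
#' Heuristic; the reported energy is re-verified by direct evaluation.
#'
#' @param model a [QuboModel-class] or [IsingModel-class].
#' @param numRestarts independent restarts (default 8).
#' @param tenure iterations a flipped variable stays tabu (default
#'   \code{max(10, numVars \%/\% 10)}).
#' @param maxIters iterations per restart (default \code{50 * numVars}).
#' @param seed integer seed, or \code{NULL}.
#' @return a [SolveResult-class].
#' @export
solveTabu <- function(model, numRestarts = 8, tenure = NULL, maxIters = NULL,
                      seed = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stopifnot(numRestarts >= 1)
  parts <- .modelParts(model)
  nv <- length(parts$linear)
  if (is.null(tenure)) tenure <- max(10L, nv %/% 10L)
  if (is.null(maxIters)) maxIters <- 50L * nv
  stopifnot(tenure >= 1, maxIters >= 1)
  if (!is.null(seed)) set.seed(seed)
  tr <- .tripletsOf(parts$Q)
  res <- .tabuCpp(nv, parts$linear, tr$i, tr$j, tr$x,
                  as.integer(numRestarts), as.integer(tenure),
                  as.integer(maxIters), parts$spin)
  e <- .verifyEnergy(model, res$assignment, res$energy)
  .solveResult(res$assignment, e, numRestarts, res$occurrencesBest, "tabu",
               seed, proc.time()[["elapsed"]] - t0)
}

#' Run an external sampler through the file contract
#'
#' Serializes the model to a coordinate-list file (see [writeModel()]),
#' invokes \code{command} with the model path and an output path appended
#' to \code{args}, and parses the JSON result the executable writes
#' (fields \code{assignment} -- a 0/1 or -1/+1 vector or compact string --
#' and \code{energy}). The returned energy is recomputed against the model
#' and the run is rejected if the executable's bookkeeping disagrees.
#'
#' Any executable honoring this contract (read a coordinate-list model,
#' emit assignment + energy as JSON) can stand in for an external annealing
#' service.
#'
#' @param model a [QuboModel-class] or [IsingModel-class].
#' @param command path to the executable.
#' @param args character vector of leading arguments (e.g. a script path
#'   when \code{command} is an interpreter).
#' @param workDir directory for the temporary model/result files.
#' @return a [SolveResult-class] with \code{solverName = "external"}.
#' @export
solveExternal <- function(model, command, args = character(),
                          workDir = tempdir()) {
  t0 <- proc.time()[["elapsed"]]
  modelFile <- file.path(workDir, "model.coo")
  resultFile <- file.path(workDir, "result.json")
  writeModel(model, modelFile)
  status <- system2(command, c(args, modelFile, resultFile),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0)
    stop(sprintf("external solver '%s' exited with status %d", command, status))
  if (!file.exists(resultFile))
    stop("external solver produced no result file")
  out <- tryCatch(jsonlite::read_json(resultFile, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed external result JSON: ", conditionMessage(e)))
  if (is.null(out$assignment) || is.null(out$energy))
    stop("external result must contain 'assignment' and 'energy' fields")
  a <- out$assignment
  if (is.character(a))
    a <- as.integer(strsplit(a, "")[[1]]) * (if (is(model, "IsingModel")) 2 else 1) -
      (if (is(model, "IsingModel")) 1 else 0)
  a <- as.numeric(a)
  e <- .verifyEnergy(model, a, as.numeric(out$energy))
  .solveResult(a, e,
               if (is.null(out$numReads)) 1L else out$numReads,
               if (is.null(out$occurrencesBest)) 1L else out$occurrencesBest,
               "external", NULL, proc.time()[["elapsed"]] - t0)
}

#' Resolve a solver specification to a solver function
#'
#' @param solver `"exhaustive"`, `"sa"`, `"tabu"`, or a function taking a
#'   model and returning a [SolveResult-class].
#' @param ... fixed arguments passed through to the named solver.
#' @return a function of one argument (the model).
#' @export
getSolver <- function(solver, ...) {
  if (is.function(solver)) return(solver)
  fixed <- list(...)
  fn <- switch(match.arg(solver, c("exhaustive", "sa", "tabu")),
               exhaustive = solveExhaustive, sa = solveSA, tabu = solveTabu)
  function(model) do.call(fn, c(list(model), fixed))
}
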