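# Replicate-consensus assignment: R-side orchestration of the compiled
# engine (candidate windows, weighted stochastic initialization, simulated
# annealing, greedy polish), plus the majority-consensus step.

#' Assignment engine parameters
#'
#' @param k hard-window multiplier: a measured peak is a candidate for an
#'   expected peak only if every coordinate lies within k * width of the
#'   atom's search-space center.
#' @param lambda penalty weight on the unmatched expected-peak fraction.
#' @param initGreed softmax greed of the stochastic initialization
#'   (candidate weight exp(-initGreed * deviation); 0 = uniform sampling).
#' @param itersPerPeak annealing iterations per expected peak.
#' @param t0,tEnd initial/final annealing temperature (geometric cooling).
#' @param moveProbs probabilities of the reassign / swap / unassign moves.
#' @param polishSweeps maximum best-improvement sweeps after annealing.
#' @param replicates number of optimization replicates for the consensus.
#' @param sMin strong-assignment support threshold.
#' @param tol per-nucleus matching tolerance for shared-atom consistency
#'   (and for consensus clustering).
#' @return list with class "EngineParams".
#' @export
engineParams <- function(k = 3, lambda = 1, initGreed = 50,
                         itersPerPeak = 10, t0 = 0.3, tEnd = 0.005,
                         moveProbs = c(0.8, 0.15, 0.05), polishSweeps = 4,
                         replicates = 20L, sMin = 0.8,
                         tol = cstFloors("random")) {
  stopifnot(length(moveProbs) == 3L, all(moveProbs >= 0),
            abs(sum(moveProbs) - 1) < 1e-9)
  structure(list(k = k, lambda = lambda, initGreed = initGreed,
                 itersPerPeak = itersPerPeak, t0 = t0, tEnd = tEnd,
                 moveProbs = moveProbs, polishSweeps = polishSweeps,
                 replicates = as.integer(replicates), sMin = sMin,
                 tol = asNucleusVector(tol, "tol")),
            class = "EngineParams")
}

#' Prepare an assignment problem
#'
#' Builds the expected-peak list for every supplied spectrum, checks that
#' the search spaces cover all expected-peak atoms, stacks the measured
#' peaks in canonical order (sorted by spectrum and coordinates, so results
#' are invariant to the input peak order) and precomputes the candidate
#' windows.
#'
#' @param sequence target protein sequence.
#' @param peakLists named list of PeakList objects (names = spectrum types,
#'   or taken from the objects).
#' @param spaces a SearchSpaceSet covering the expected-atom set.
#' @param params an [engineParams()].
#' @param cfg a [simConfig()] (contact rule for NOESY templates).
#' @param structure optional StructureCoords for the structure contact rule.
#' @return an opaque problem object for [initializeAssignment()] /
#'   [optimizeAssignment()] / [assignShifts()].
#' @export
prepareAssignment <- function(sequence, peakLists, spaces,
                              params = engineParams(), cfg = simConfig(),
                              structure = NULL) {
  atoms <- spaceTable(spaces)
  atomKey <- paste(atoms$residue_index, atoms$atom_name, sep = ".")
  types <- unname(vapply(peakLists, spectrumType, character(1)))

  expAtoms <- NULL; expSpec <- integer(0)
  coords <- NULL; measSpec <- integer(0)
  for (i in seq_along(peakLists)) {
    ep <- expectedPeaks(sequence, types[i], cfg, structure)
    if (nrow(ep)) {
      am <- matrix(-1L, nrow(ep), 3L)
      for (d in 1:3) {
        key <- paste(ep[[paste0("res", d)]], ep[[paste0("atom", d)]],
                     sep = ".")
        id <- match(key, atomKey)
        used <- !is.na(ep[[paste0("res", d)]])
        if (any(used & is.na(id)))
          stop("search spaces do not cover expected-peak atom(s): ",
               paste(utils::head(key[used & is.na(id)], 3), collapse = ", "))
        am[used, d] <- id[used] - 1L
      }
      expAtoms <- rbind(expAtoms, am)
      expSpec <- c(expSpec, rep(i - 1L, nrow(ep)))
    }
    co <- peakCoords(peakLists[[i]])
    if (nrow(co)) {
      cm <- matrix(0, nrow(co), 3L)
      cm[, seq_len(ncol(co))] <- co
      ord <- do.call(order, as.data.frame(cm))
      coords <- rbind(coords, cm[ord, , drop = FALSE])
      measSpec <- c(measSpec, rep(i - 1L, nrow(co)))
    }
  }
  if (is.null(expAtoms)) expAtoms <- matrix(integer(0), 0L, 3L)
  if (is.null(coords)) coords <- matrix(numeric(0), 0L, 3L)
  storage.mode(expAtoms) <- "integer"

  halfw <- params$k * atoms$width
  tol <- unname(params$tol[atoms$nucleus])
  cand <- if (nrow(expAtoms)) {
    .cstCandidates(expAtoms, as.integer(expSpec), coords,
                   as.integer(measSpec), atoms$center, halfw)
  } else list()
  structure(list(sequence = sequence, atoms = atoms, expAtoms = expAtoms,
                 expSpec = as.integer(expSpec), coords = coords,
                 measSpec = as.integer(measSpec), halfw = halfw, tol = tol,
                 cand = cand, params = params),
            class = "AssignmentProblem")
}

.runReplicate <- function(problem, seed, initMatch = NULL, iters = NULL,
                          polishSweeps = NULL) {
  p <- problem$params
  nE <- nrow(problem$expAtoms)
  if (nE == 0L)
    return(list(match = integer(0),
                atomShift = rep(NA_real_, nrow(problem$atoms)), score = 0))
  if (is.null(iters)) iters <- as.integer(p$itersPerPeak * nE)
  if (is.null(polishSweeps)) polishSweeps <- p$polishSweeps
  coolRate <- if (iters > 0) (p$tEnd / p$t0)^(1 / iters) else 1
  doInit <- is.null(initMatch)
  im <- if (doInit) rep(-1L, nE) else {
    v <- initMatch; v[is.na(v)] <- 0L; as.integer(v - 1L)
  }
  .cstRun(problem$expAtoms, problem$expSpec, problem$coords,
          problem$measSpec, problem$atoms$center, problem$halfw,
          problem$tol, problem$cand, im, doInit, p$initGreed,
          as.integer(iters), p$t0, coolRate, p$moveProbs,
          as.integer(polishSweeps), p$lambda, as.integer(seed))
}

#' Stochastic initialization of an assignment state
#'
#' Expected peaks are visited in random order; each is matched to a
#' candidate measured peak sampled with weight exp(-initGreed * deviation)
#' among those consistent with already-committed shifts of shared atoms, or
#' left unmatched if none qualifies.  Deterministic under the seed.
#'
#' @param problem from [prepareAssignment()].
#' @param seed integer seed.
#' @return state: list(match (1-based measured index or NA per expected
#'   peak), atomShift (committed shift per atom, NA if unsupported), score).
#' @export
initializeAssignment <- function(problem, seed) {
  .runReplicate(problem, seed, initMatch = NULL, iters = 0L,
                polishSweeps = 0L)
}

#' Score an assignment state
#'
#' score = sum over matched peaks of (1 - mean squared normalized deviation
#' of the coordinates from the search-space centers) minus
#' lambda * (unmatched expected fraction).
#'
#' @param problem from [prepareAssignment()].
#' @param state a state from [initializeAssignment()] or
#'   [optimizeAssignment()].
#' @return numeric score (higher is better).
#' @export
scoreAssignment <- function(problem, state) {
  nE <- nrow(problem$expAtoms)
  if (nE == 0L) return(0)
  m <- state$match; m[is.na(m)] <- 0L
  .cstScore(problem$expAtoms, problem$expSpec, problem$coords,
            problem$measSpec, problem$atoms$center, problem$halfw,
            problem$tol, problem$params$lambda, as.integer(m - 1L))
}

#' Optimize an assignment state
#'
#' Simulated annealing over reassign/swap/unassign moves with geometric
#' cooling, followed by best-improvement polish sweeps.  The returned score
#' is never below the input score when run with the default zero-temperature
#' polish; every intermediate state respects the hard candidate windows.
#'
#' @param problem from [prepareAssignment()].
#' @param state initial state.
#' @param seed integer seed.
#' @param iters annealing iterations (default itersPerPeak * number of
#'   expected peaks; 0 leaves the state unchanged).
#' @return optimized state (same shape as [initializeAssignment()]).
#' @export
optimizeAssignment <- function(problem, state, seed, iters = NULL) {
  if (!is.null(iters) && iters == 0L)
    return(.runReplicate(problem, seed, initMatch = state$match, iters = 0L,
                         polishSweeps = 0L))
  .runReplicate(problem, seed, initMatch = state$match, iters = iters)
}

#' Majority consensus over replicate assignments
#'
#' Per atom, the replicate shift values are clustered by single linkage at
#' the atom's matching tolerance; the largest cluster's mean is the
#' consensus shift and its size / replicates the support.  Ties prefer the
#' cluster with smaller mean absolute deviation, then lower ppm.
#'
#' @param shiftsByReplicate list of per-atom shift vectors (one per
#'   replicate, NA = unassigned in that replicate).
#' @param atoms atom table (residue_index, residue_type, atom_name, nucleus).
#' @param tol per-atom numeric tolerance vector.
#' @param sMin strong-assignment support threshold.
#' @return A \code{ConsensusResult}.
#' @export
consensusAssignment <- function(shiftsByReplicate, atoms, tol, sMin = 0.8) {
  R <- length(shiftsByReplicate)
  if (R < 1L) stop("at least one replicate is required")
  nA <- nrow(atoms)
  mat <- do.call(cbind, shiftsByReplicate)
  shift <- rep(NA_real_, nA); support <- rep(0, nA)
  for (a in seq_len(nA)) {
    v <- mat[a, ]
    v <- v[!is.na(v)]
    if (!length(v)) next
    v <- sort(v)
    brk <- which(diff(v) > tol[a])
    starts <- c(1L, brk + 1L); ends <- c(brk, length(v))
    size <- ends - starts + 1L
    mu <- vapply(seq_along(starts), function(i)
      mean(v[starts[i]:ends[i]]), numeric(1))
    dev <- vapply(seq_along(starts), function(i)
      mean(abs(v[starts[i]:ends[i]] - mu[i])), numeric(1))
    best <- order(-size, dev, mu)[1L]
    shift[a] <- mu[best]
    support[a] <- size[best] / R
  }
  ConsensusResult(data.frame(
    residue_index = atoms$residue_index, residue_type = atoms$residue_type,
    atom_name = atoms$atom_name, nucleus = atoms$nucleus,
    shift = shift, support = support, strong = support >= sMin,
    stringsAsFactors = FALSE), replicates = R, sMin = sMin)
}

#' Assign chemical shifts by replicate consensus
#'
#' Full engine pipeline: expected-peak construction for every supplied
#' spectrum, R seeded replicates of stochastic initialization + annealing +
#' polish, and majority consensus.  Deterministic under the seed
#' (per-replicate sub-seeds are derived from it).
#'
#' @param sequence target protein sequence.
#' @param peakLists named list of PeakList objects.
#' @param spaces a SearchSpaceSet.
#' @param seed integer master seed.
#' @param params an [engineParams()].
#' @param cfg a [simConfig()] (NOESY contact rule).
#' @param structure optional StructureCoords.
#' @return A \code{ConsensusResult}; the per-replicate states are attached
#'   as attribute "replicates".
#' @export
assignShifts <- function(sequence, peakLists, spaces, seed = 1L,
                         params = engineParams(), cfg = simConfig(),
                         structure = NULL) {
  problem <- prepareAssignment(sequence, peakLists, spaces, params, cfg,
                               structure)
  reps <- lapply(seq_len(params$replicates), function(r)
    .runReplicate(problem, deriveSeed(seed, 200L + r)))
  cons <- consensusAssignment(lapply(reps, `[[`, "atomShift"),
                              problem$atoms, problem$tol, params$sMin)
  attr(cons, "replicateStates") <- reps
  attr(cons, "problem") <- problem
  cons
}

#' Count hard-window violations of a state
#'
#' Diagnostic for the engine invariant: every matched pair must have all
#' coordinates within k * width of the search-space centers.
#'
#' @param problem from [prepareAssignment()].
#' @param state an engine state.
#' @return integer count (0 when the invariant holds).
#' @export
windowViolations <- function(problem, state) {
  n <- 0L
  for (e in seq_len(nrow(problem$expAtoms))) {
    m <- state$match[e]
    if (is.na(m)) next
    for (d in 1:3) {
      a <- problem$expAtoms[e, d] + 1L
      if (a <= 0L) next
      if (abs(problem$coords[m, d] - problem$atoms$center[a]) >
          problem$halfw[a] + 1e-9) n <- n + 1L
    }
  }
  n
}

#' Atoms appearing in at least one simulatable expected peak
#'
#' @param problem from [prepareAssignment()], or a ConsensusResult returned
#'   by [assignShifts()].
#' @return character vector of "residue_index.atom_name" keys.
#' @export
simulatableAtoms <- function(problem) {
  if (is(problem, "ConsensusResult")) problem <- attr(problem, "problem")
  ids <- unique(as.vector(problem$expAtoms))
  ids <- ids[ids >= 0L] + 1L
  paste(problem$atoms$residue_index[ids], problem$atoms$atom_name[ids],
        sep = ".")
}
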