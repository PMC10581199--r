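# Accuracy metrics and the synthetic benchmark driver.

#' Default accuracy tolerances
#' @param convention "idealized" (0.04 ppm 1H / 0.4 ppm 13C,15N) or
#'   "alignment" (0.03 ppm 1H / 0.4 ppm 13C,15N).
#' @return named numeric vector per nucleus.
#' @export
accuracyTol <- function(convention = c("idealized", "alignment")) {
  convention <- match.arg(convention)
  if (convention == "idealized") FLOORS_RANDOM else FLOORS_STRUCT
}

#' Assignment accuracy against a reference shift list
#'
#' An atom is correct iff it is assigned and its shift lies within the
#' per-nucleus tolerance of the reference shift.  The denominator is the
#' number of reference atoms considered (unassigned counts as incorrect);
#' the "of assigned" variant is reported alongside.  Atoms without a
#' reference shift are excluded from the denominator.
#'
#' @param assigned a ConsensusResult or ShiftList.
#' @param reference reference ShiftList (non-empty).
#' @param tol per-nucleus tolerances (ppm), all > 0.
#' @param strongOnly count only strong consensus assignments as assigned
#'   (denominator unchanged).
#' @param atomSubset optional character vector of "residue_index.atom_name"
#'   keys restricting the reference atoms considered (e.g.
#'   [simulatableAtoms()]).
#' @return list with class "AccuracyReport": overall / backbone / sidechain
#'   / amide accuracies, counts, the of-assigned variant, and the per-atom
#'   correctness table.
#' @export
accuracy <- function(assigned, reference, tol = accuracyTol("idealized"),
                     strongOnly = FALSE, atomSubset = NULL) {
  tol <- asNucleusVector(tol, "tol")
  if (any(tol <= 0)) stop("tolerances must be > 0")
  ref <- shiftTable(reference)
  if (!nrow(ref)) stop("reference shift list is empty")
  if (is(assigned, "ConsensusResult")) {
    a <- consensusTable(assigned)
    if (strongOnly) a$shift[!a$strong] <- NA_real_
  } else {
    a <- shiftTable(assigned)
  }
  key <- paste(ref$residue_index, ref$atom_name, sep = ".")
  if (!is.null(atomSubset)) {
    keep <- key %in% atomSubset
    ref <- ref[keep, , drop = FALSE]; key <- key[keep]
  }
  av <- a$shift[match(key, paste(a$residue_index, a$atom_name, sep = "."))]
  correct <- !is.na(av) & abs(av - ref$shift) <= tol[ref$nucleus]
  perAtom <- data.frame(residue_index = ref$residue_index,
                        residue_type = ref$residue_type,
                        atom_name = ref$atom_name, nucleus = ref$nucleus,
                        reference = ref$shift, assigned = av,
                        correct = correct, stringsAsFactors = FALSE)
  frac <- function(sel) {
    n <- sum(sel)
    if (n == 0) NA_real_ else sum(correct[sel]) / n
  }
  isBackbone <- ref$atom_name %in% backboneAtoms()
  isAmide <- ref$atom_name %in% amideAtoms()
  nAssigned <- sum(!is.na(av))
  structure(list(
    overall = frac(rep(TRUE, nrow(ref))),
    backbone = frac(isBackbone),
    sidechain = frac(!isBackbone),
    amide = frac(isAmide),
    ofAssigned = if (nAssigned) sum(correct) / nAssigned else NA_real_,
    nReference = nrow(ref), nAssigned = nAssigned, nCorrect = sum(correct),
    perAtom = perAtom), class = "AccuracyReport")
}

#' @export
print.AccuracyReport <- function(x, ...) {
  cat(sprintf(paste0("AccuracyReport: overall %.3f (backbone %.3f, ",
                     "sidechain %.3f, amide NH %.3f)\n"),
              x$overall, x$backbone, x$sidechain, x$amide))
  cat(sprintf("  %d correct / %d assigned / %d reference atoms\n",
              x$nCorrect, x$nAssigned, x$nReference))
  invisible(x)
}

#' Fraction of correct aligned shifts
#'
#' For an aligned (already reindexed) source shift list: the fraction of
#' its entries within tolerance of the corresponding target reference
#' shift (entries without a target counterpart count as incorrect).  Used
#' with [selectHomologPairs()] to qualify source/target pairs.
#'
#' @param alignedSource ShiftList in target numbering.
#' @param targetReference target reference ShiftList.
#' @param tol per-nucleus tolerances (alignment convention by default).
#' @return fraction in [0, 1].
#' @export
fractionCorrectAligned <- function(alignedSource, targetReference,
                                   tol = accuracyTol("alignment")) {
  tol <- asNucleusVector(tol, "tol")
  s <- shiftTable(alignedSource)
  if (!nrow(s)) stop("aligned shift list is empty; fraction undefined")
  r <- shiftTable(targetReference)
  rv <- r$shift[match(paste(s$residue_index, s$atom_name, sep = "."),
                      paste(r$residue_index, r$atom_name, sep = "."))]
  sum(!is.na(rv) & abs(s$shift - rv) <= tol[s$nucleus]) / nrow(s)
}

#' Transfer / de-novo improvement ratio
#'
#' Ratio of the transfer-based accuracy to the de-novo accuracy; 1.0 is a
#' neutral effect.  A zero de-novo accuracy is signalled and reported as
#' +Inf.
#'
#' @param cstReport,denovoReport AccuracyReport objects (or numeric
#'   accuracies).
#' @param component which accuracy component to compare.
#' @return numeric ratio.
#' @export
improvementRatio <- function(cstReport, denovoReport, component = "overall") {
  num <- if (inherits(cstReport, "AccuracyReport"))
    cstReport[[component]] else cstReport
  den <- if (inherits(denovoReport, "AccuracyReport"))
    denovoReport[[component]] else denovoReport
  if (is.na(num) || is.na(den)) return(NA_real_)
  if (den == 0) {
    warning("de-novo accuracy is zero; ratio reported as Inf")
    return(Inf)
  }
  num / den
}

#' Run one paired transfer / de-novo assignment experiment
#'
#' Shared peak lists and seeds for both arms: simulate peaks from the
#' protein's reference shifts, assign once with the supplied search spaces
#' and once with statistics-only spaces, and report both accuracies and
#' their ratio (accuracy restricted to simulatable atoms).
#'
#' @param protein a [syntheticProtein()] fixture.
#' @param spaces transfer-arm SearchSpaceSet.
#' @param stats a StatTable.
#' @param cfg a [simConfig()].
#' @param params an [engineParams()].
#' @param seed integer seed (peak simulation and both assignment arms
#'   derive sub-seeds from it; the arms share the peak lists).
#' @param tol accuracy tolerances.
#' @param denovo also run the de-novo arm (skip to save time when only the
#'   transfer arm is needed).
#' @return list(cst, denovo (AccuracyReport or NULL), ratio).
#' @export
runPairedExperiment <- function(protein, spaces, stats, cfg = simConfig(),
                                params = engineParams(), seed = 1L,
                                tol = accuracyTol("idealized"),
                                denovo = TRUE) {
  peaks <- simulatePeakLists(protein$shifts, protein$sequence, cfg,
                             seed = deriveSeed(seed, 1L))
  consCst <- assignShifts(protein$sequence, peaks, spaces,
                          seed = deriveSeed(seed, 2L), params = params,
                          cfg = cfg)
  sim <- simulatableAtoms(consCst)
  accCst <- accuracy(consCst, protein$shifts, tol = tol, atomSubset = sim)
  accDen <- NULL; ratio <- NA_real_
  if (denovo) {
    consDen <- assignShifts(protein$sequence, peaks,
                            denovoSpaces(protein$sequence, stats),
                            seed = deriveSeed(seed, 3L), params = params,
                            cfg = cfg)
    accDen <- accuracy(consDen, protein$shifts, tol = tol, atomSubset = sim)
    ratio <- improvementRatio(accCst, accDen)
  }
  list(cst = accCst, denovo = accDen, ratio = ratio)
}

#' Synthetic perturbation benchmark over a (c, p) grid
#'
#' For every protein and every (c, p) cell: perturb the reference shifts
#' (random mode), build transfer search spaces with the known per-atom
#' sigmas, assign, and compare with a de-novo arm sharing the same peak
#' lists and simulation seed.  The de-novo arm is run once per protein and
#' seed (it does not depend on the perturbation).
#'
#' @param proteins list of [syntheticProtein()] fixtures.
#' @param stats a StatTable.
#' @param cGrid,pGrid perturbation scaling constants and fractions
#'   (reference grid: c, p in {0.2, 0.5, 1.0}).
#' @param cfg a [simConfig()].
#' @param params an [engineParams()].
#' @param seed integer master seed.
#' @return long-format data.frame: protein, c, p, arm, overall, backbone,
#'   sidechain, amide, ratio (NA for the de-novo rows).
#' @export
benchmarkGrid <- function(proteins, stats, cGrid = c(0.2, 0.5, 1.0),
                          pGrid = c(0.2, 0.5, 1.0), cfg = simConfig(),
                          params = engineParams(), seed = 1L) {
  rows <- list()
  for (ip in seq_along(proteins)) {
    prot <- proteins[[ip]]
    simSeed <- deriveSeed(seed, 10L * ip)
    peaks <- simulatePeakLists(prot$shifts, prot$sequence, cfg,
                               seed = simSeed)
    consDen <- assignShifts(prot$sequence, peaks,
                            denovoSpaces(prot$sequence, stats),
                            seed = deriveSeed(seed, 10L * ip + 1L),
                            params = params, cfg = cfg)
    sim <- simulatableAtoms(consDen)
    accDen <- accuracy(consDen, prot$shifts, atomSubset = sim)
    rows[[length(rows) + 1L]] <- data.frame(
      protein = prot$id, c = NA_real_, p = NA_real_, arm = "denovo",
      overall = accDen$overall, backbone = accDen$backbone,
      sidechain = accDen$sidechain, amide = accDen$amide,
      ratio = NA_real_, stringsAsFactors = FALSE)
    cell <- 0L
    for (cc in cGrid) for (pp in pGrid) {
      cell <- cell + 1L
      pert <- randomPerturb(prot$shifts, stats, c = cc, p = pp,
                            seed = deriveSeed(seed, 100L * ip + cell))
      spaces <- buildSearchSpaces(prot$sequence, pert$perturbed, stats,
                                  cstConfig(cCst = 1),
                                  perAtomSigma = pert$sigmaPerAtom)
      consCst <- assignShifts(prot$sequence, peaks, spaces,
                              seed = deriveSeed(seed, 10L * ip + 2L),
                              params = params, cfg = cfg)
      accCst <- accuracy(consCst, prot$shifts, atomSubset = sim)
      rows[[length(rows) + 1L]] <- data.frame(
        protein = prot$id, c = cc, p = pp, arm = "cst",
        overall = accCst$overall, backbone = accCst$backbone,
        sidechain = accCst$sidechain, amide = accCst$amide,
        ratio = improvementRatio(accCst, accDen),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
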