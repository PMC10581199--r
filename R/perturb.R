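# Synthetic transfer-test generators: random Gaussian perturbation of a
# shift list (a chosen fraction p of atoms, noise sd = c * reference std)
# and structure-based perturbation (noise sd scaled by a normalized count
# of perturbation centers within a distance cutoff of each residue's
# backbone amide nitrogen).

.atomKeys <- function(s) paste(s$residue_index, s$atom_name, sep = ".")

.perturbResult <- function(perturbed, sigma, widths, decay = NULL) {
  structure(list(perturbed = perturbed, sigmaPerAtom = sigma,
                 widthPerAtom = widths, decayPerResidue = decay),
            class = "PerturbationResult")
}

#' @export
print.PerturbationResult <- function(x, ...) {
  cat("PerturbationResult:", sum(x$sigmaPerAtom > 0), "of",
      length(x$sigmaPerAtom), "atoms perturbed\n")
  invisible(x)
}

#' Randomly perturb a chemical-shift list
#'
#' A uniformly random subset of exactly \code{round(p * N)} atoms (round
#' half up) receives additive Gaussian noise with standard deviation
#' \code{c} times the atom's reference standard deviation; all other atoms
#' are unchanged.  The reported per-atom search-space width is
#' \code{max(sigma_i, floor)}.
#'
#' @param shifts a ShiftList.
#' @param stats a StatTable covering the perturbed atoms.
#' @param c noise scaling constant (>= 0); reference settings use
#'   c in {0.2, 0.5, 1.0}.
#' @param p fraction of atoms perturbed, in [0, 1]; reference settings use
#'   p in {0.2, 0.5, 1.0}.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param floors per-nucleus width floors (0.04/0.4/0.4 ppm convention).
#' @return A PerturbationResult: \code{$perturbed} (ShiftList),
#'   \code{$sigmaPerAtom} (named by "residue_index.atom_name"; the noise sd,
#'   0 for unperturbed atoms), \code{$widthPerAtom}.
#' @export
randomPerturb <- function(shifts, stats, c, p, seed,
                          floors = cstFloors("random")) {
  stopifnot_scalar_number(c, "c")
  stopifnot_scalar_number(p, "p")
  if (c < 0) stop("'c' must be >= 0")
  if (p < 0 || p > 1) stop("'p' must lie in [0, 1]")
  s <- shiftTable(shifts)
  n <- nrow(s)
  keys <- .atomKeys(s)
  st <- .statLookupMulti(stats, s$residue_type, s$atom_name)
  nPick <- roundHalfUp(p * n)
  sigma <- setNames(rep(0, n), keys)
  withSeed(seed, {
    pick <- if (nPick > 0) sample.int(n, nPick) else integer(0)
    sigma[pick] <- c * st$std[pick]
    noise <- rep(0, n)
    if (length(pick)) noise[pick] <- rnorm(length(pick), 0, sigma[pick])
  })
  out <- s
  out$shift <- s$shift + noise
  widths <- setNames(pmax(unname(sigma), floors[s$nucleus]), keys)
  .perturbResult(ShiftList(out), sigma, widths)
}

#' Decay factors from perturbation centers
#'
#' For each residue i, counts the perturbation centers whose backbone amide
#' nitrogen lies within \code{x0} Angstrom of residue i's amide nitrogen
#' (Euclidean distance, step function), then normalizes by the maximum
#' count so the decay factors lie in [0, 1].  Residues without an amide-N
#' coordinate get decay 0 (with a warning).
#'
#' @param structure a StructureCoords with amide-N coordinates.
#' @param centers integer vector of perturbation-center residue indices.
#' @param x0 distance cutoff in Angstrom (> 0).
#' @return named numeric vector, one entry per residue with coordinates.
#' @export
decayFactors <- function(structure, centers, x0) {
  stopifnot_scalar_number(x0, "x0", positive = TRUE)
  if (!length(centers)) stop("at least one perturbation center is required")
  nc <- amideNCoords(structure)
  resIdx <- as.integer(rownames(nc))
  miss <- setdiff(as.integer(centers), resIdx)
  if (length(miss))
    stop("perturbation center(s) without amide-N coordinates: ",
         paste(miss, collapse = ", "))
  cm <- nc[match(as.integer(centers), resIdx), , drop = FALSE]
  e <- rep(0, nrow(nc))
  for (j in seq_len(nrow(cm))) {
    d <- sqrt(rowSums((nc - matrix(cm[j, ], nrow(nc), 3, byrow = TRUE))^2))
    e <- e + as.numeric(d <= x0)
  }
  emax <- max(e)
  ep <- if (emax > 0) e / emax else e
  setNames(ep, resIdx)
}

#' Structure-based perturbation of a chemical-shift list
#'
#' Every atom i receives additive Gaussian noise with
#' \code{sigma_i = e'_i * c * std_i}, where \code{e'_i} is the decay factor
#' of the atom's residue (see [decayFactors()]) and \code{std_i} its
#' reference standard deviation.  Atoms in residues with decay 0 (or
#' without coordinates) are unchanged.  Reported widths are
#' \code{max(sigma_i, floor)} with the 0.03 ppm 1H floor convention.
#'
#' @inheritParams randomPerturb
#' @param structure a StructureCoords.
#' @param centers perturbation-center residue indices.
#' @param x0 distance cutoff in Angstrom.
#' @param floors per-nucleus width floors (0.03/0.4/0.4 ppm convention).
#' @return A PerturbationResult with \code{$decayPerResidue} populated.
#' @export
structurePerturb <- function(shifts, stats, structure, centers, x0, c, seed,
                             floors = cstFloors("structure")) {
  stopifnot_scalar_number(c, "c")
  if (c < 0) stop("'c' must be >= 0")
  ep <- decayFactors(structure, centers, x0)
  s <- shiftTable(shifts)
  keys <- .atomKeys(s)
  st <- .statLookupMulti(stats, s$residue_type, s$atom_name)
  dres <- ep[as.character(s$residue_index)]
  noCoord <- is.na(dres)
  if (any(noCoord)) {
    warning("residue(s) without amide-N coordinates inherit decay 0: ",
            paste(unique(s$residue_index[noCoord]), collapse = ", "))
    dres[noCoord] <- 0
  }
  sigma <- setNames(unname(dres) * c * st$std, keys)
  withSeed(seed, {
    noise <- ifelse(sigma > 0, rnorm(length(sigma), 0, pmax(sigma, 1e-300)), 0)
  })
  out <- s
  out$shift <- s$shift + noise
  widths <- setNames(pmax(sigma, floors[s$nucleus]), keys)
  .perturbResult(ShiftList(out), sigma, widths, decay = ep)
}

#' Sample structure-based perturbation specifications
#'
#' Draws \code{nExamples} specifications: cutoff \code{x0} uniform on
#' [5, 25] Angstrom, number of centers uniform over the integers 1..10
#' (capped at the protein length; a configurable weight vector replaces
#' the uniform choice if supplied), center positions sampled without
#' replacement from the residue indices.
#'
#' @param structure a StructureCoords (defines the residue indices).
#' @param nExamples number of specifications (>= 1).
#' @param seed integer seed.
#' @param centerWeights optional length-10 weight vector for the number of
#'   centers.
#' @return list of specs, each list(mode = "structure", centers, x0, seed).
#' @export
sampleStructureSpecs <- function(structure, nExamples, seed,
                                 centerWeights = NULL) {
  if (nExamples < 1) stop("nExamples must be >= 1")
  resIdx <- as.integer(rownames(amideNCoords(structure)))
  withSeed(seed, {
    lapply(seq_len(nExamples), function(i) {
      x0 <- runif(1, 5, 25)
      nG <- sample.int(10L, 1L, prob = centerWeights)
      nG <- min(nG, length(resIdx))
      centers <- sort(sample(resIdx, nG))
      list(mode = "structure", centers = centers, x0 = x0,
           seed = deriveSeed(seed, i))
    })
  })
}
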