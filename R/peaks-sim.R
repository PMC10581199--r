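# Expected-peak templates and measured-peak simulation.  These stand in for
# experimental spectra at desk scale: expected peaks are enumerated from the
# sequence (HSQC: one peak per amide / bonded H-C pair; NOESY: proton pairs
# under a contact rule), and measured peaks are the true shifts plus
# Gaussian jitter, with random omissions and uniform spurious peaks.

#' Simulation configuration
#'
#' @param jitter per-nucleus coordinate jitter sd (ppm).  The defaults
#'   (0.01 ppm 1H, 0.1 ppm 13C/15N) sit well inside the search-space
#'   floors, so matching tolerances dominate the jitter.
#' @param missingProb probability that a true peak is omitted, in [0, 1].
#' @param artifactRate expected number of spurious peaks per true peak
#'   (Poisson), >= 0.
#' @param contactRule "sequential" (intra-residue plus adjacent-residue
#'   proton pairs) or "structure" (residues whose amide nitrogens lie
#'   within \code{dmax} Angstrom).
#' @param dmax contact cutoff for the structure rule (Angstrom).
#' @return list with class "SimConfig".
#' @export
simConfig <- function(jitter = c("1H" = 0.01, "13C" = 0.1, "15N" = 0.1),
                      missingProb = 0, artifactRate = 0,
                      contactRule = c("sequential", "structure"), dmax = 5) {
  jitter <- asNucleusVector(jitter, "jitter")
  if (any(jitter < 0)) stop("jitter must be >= 0")
  if (missingProb < 0 || missingProb > 1)
    stop("missingProb must lie in [0, 1]")
  if (artifactRate < 0) stop("artifactRate must be >= 0")
  structure(list(jitter = jitter, missingProb = missingProb,
                 artifactRate = artifactRate,
                 contactRule = match.arg(contactRule), dmax = dmax),
            class = "SimConfig")
}

# residue-level contact sets: list residue -> integer vector of residues in
# contact (including itself)
.contactSets <- function(nRes, rule, structure = NULL, dmax = 5) {
  if (rule == "sequential") {
    lapply(seq_len(nRes), function(i)
      intersect(c(i - 1L, i, i + 1L), seq_len(nRes)))
  } else {
    if (is.null(structure))
      stop("contactRule 'structure' requires structure coordinates")
    nc <- amideNCoords(structure)
    idx <- as.integer(rownames(nc))
    d <- as.matrix(stats::dist(nc))
    lapply(seq_len(nRes), function(i) {
      k <- match(i, idx)
      if (is.na(k)) return(i)
      sort(unique(c(i, idx[d[k, ] <= dmax])))
    })
  }
}

#' Expected peaks of one spectrum type
#'
#' Enumerates the atom tuples observed in each experiment: N15_HSQC gives
#' one (H, N) peak per non-proline residue from position 2 on; C13_HSQC one
#' (H, C) peak per bonded proton-carbon pair; the 3D NOESY types pair each
#' anchor proton with every other proton of residues under the contact rule
#' (diagonal self-pairs excluded).
#'
#' @param sequence target protein sequence (1-letter codes).
#' @param spectrumType one of N15_HSQC, C13_HSQC, N15_NOESY, C13_NOESY.
#' @param cfg a [simConfig()] (contact rule for the NOESY types).
#' @param structure optional StructureCoords for the structure contact rule.
#' @return data.frame with columns spectrum_type and res1/atom1 .. res3/atom3
#'   (NA for unused dimensions); one row per expected peak.
#' @export
expectedPeaks <- function(sequence, spectrumType, cfg = simConfig(),
                          structure = NULL) {
  atoms <- expectedAtoms(sequence)
  nRes <- nchar(sequence)
  amide <- atoms[atoms$atom_name == "H", , drop = FALSE]
  hc <- atoms[atoms$nucleus == "1H" & !is.na(atoms$partner) &
                substr(atoms$partner, 1, 1) == "C", , drop = FALSE]
  protons <- atoms[atoms$nucleus == "1H", , drop = FALSE]
  protonsByRes <- split(protons$atom_name, protons$residue_index)

  emit <- function(r1, a1, r2, a2, r3 = NA_integer_, a3 = NA_character_) {
    data.frame(spectrum_type = unname(spectrumType), res1 = unname(r1),
               atom1 = unname(a1), res2 = unname(r2), atom2 = unname(a2),
               res3 = unname(r3), atom3 = unname(a3),
               stringsAsFactors = FALSE)
  }

  if (spectrumType == "N15_HSQC") {
    keep <- amide$residue_index >= 2L
    return(emit(amide$residue_index[keep], "H",
                amide$residue_index[keep], "N"))
  }
  if (spectrumType == "C13_HSQC") {
    return(emit(hc$residue_index, hc$atom_name, hc$residue_index, hc$partner))
  }

  contacts <- .contactSets(nRes, cfg$contactRule, structure, cfg$dmax)
  anchors <- if (spectrumType == "N15_NOESY") {
    data.frame(res = amide$residue_index, hAtom = "H", heavy = "N",
               stringsAsFactors = FALSE)
  } else if (spectrumType == "C13_NOESY") {
    data.frame(res = hc$residue_index, hAtom = hc$atom_name,
               heavy = hc$partner, stringsAsFactors = FALSE)
  } else stop("unknown spectrum_type: ", spectrumType)

  out <- vector("list", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    ri <- anchors$res[i]
    cres <- contacts[[ri]]
    qres <- rep(cres, lengths(protonsByRes[as.character(cres)]))
    qatom <- unlist(protonsByRes[as.character(cres)], use.names = FALSE)
    self <- qres == ri & qatom == anchors$hAtom[i]
    if (any(self)) { qres <- qres[!self]; qatom <- qatom[!self] }
    if (!length(qres)) next
    out[[i]] <- emit(qres, qatom, rep(ri, length(qres)), anchors$hAtom[i],
                     rep(ri, length(qres)), anchors$heavy[i])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- emit(integer(0), character(0), integer(0),
                                character(0))
  rownames(res) <- NULL
  res
}

.peakTag <- function(ep) {
  nd <- if (all(is.na(ep$res3))) 2L else 3L
  tag <- paste0(ep$res1, ".", ep$atom1, "|", ep$res2, ".", ep$atom2)
  if (nd == 3L) tag <- paste0(tag, "|", ep$res3, ".", ep$atom3)
  tag
}

#' Simulate a measured peak list from true shifts
#'
#' Expected peaks whose atoms all carry a shift in \code{shifts} are
#' emitted at the true coordinates plus independent Gaussian jitter; each
#' is omitted with probability \code{missingProb}.  Spurious peaks
#' (Poisson with mean artifactRate * number of retained true peaks) are
#' drawn uniformly over the occupied bounding box of each dimension.
#' True peaks carry their generating atom tuple as a tag.
#'
#' @param shifts a ShiftList of true shifts.
#' @param expected expected-peak table from [expectedPeaks()].
#' @param cfg a [simConfig()].
#' @param seed integer seed; simulation is deterministic given the seed.
#' @return A \code{PeakList} with true-assignment tags (NA for artifacts).
#' @export
simulateMeasured <- function(shifts, expected, cfg, seed) {
  spectrumType <- unique(expected$spectrum_type)
  if (length(spectrumType) != 1L)
    stop("expected-peak table must cover exactly one spectrum type")
  dims <- spectrumDims(spectrumType)
  nd <- length(dims)
  s <- shiftTable(shifts)
  skey <- paste(s$residue_index, s$atom_name, sep = ".")
  co <- matrix(NA_real_, nrow(expected), nd)
  for (d in seq_len(nd)) {
    key <- paste(expected[[paste0("res", d)]], expected[[paste0("atom", d)]],
                 sep = ".")
    co[, d] <- s$shift[match(key, skey)]
  }
  keep <- rowSums(is.na(co)) == 0L
  co <- co[keep, , drop = FALSE]
  tags <- .peakTag(expected[keep, , drop = FALSE])

  withSeed(seed, {
    nTrue <- nrow(co)
    lo <- hi <- NULL
    if (nTrue) {
      jit <- cfg$jitter[dims]
      co <- co + matrix(rnorm(length(co), 0, rep(jit, each = nrow(co))),
                        nrow(co), nd)
      lo <- apply(co, 2, min); hi <- apply(co, 2, max)
      omit <- runif(nrow(co)) < cfg$missingProb
      co <- co[!omit, , drop = FALSE]
      tags <- tags[!omit]
    }
    nArt <- if (nTrue && cfg$artifactRate > 0)
      rpois(1L, cfg$artifactRate * nTrue) else 0L
    if (nArt > 0L) {
      art <- sapply(seq_len(nd), function(d) runif(nArt, lo[d], hi[d]))
      art <- matrix(art, nArt, nd)
      co <- rbind(co, art)
      tags <- c(tags, rep(NA_character_, nArt))
    }
  })
  PeakList(spectrumType, co, tags)
}

#' Simulate the standard four-spectrum peak-list set
#'
#' @param shifts true ShiftList.
#' @param sequence protein sequence.
#' @param cfg a [simConfig()].
#' @param seed master seed (per-spectrum sub-seeds are derived from it).
#' @param spectra spectrum types to simulate.
#' @param structure optional StructureCoords for the structure contact rule.
#' @return named list of \code{PeakList} objects.
#' @export
simulatePeakLists <- function(shifts, sequence, cfg = simConfig(), seed = 1L,
                              spectra = SPECTRUM_TYPES, structure = NULL) {
  out <- lapply(seq_along(spectra), function(i) {
    ep <- expectedPeaks(sequence, spectra[i], cfg, structure)
    simulateMeasured(shifts, ep, cfg, deriveSeed(seed, 100L + i))
  })
  setNames(out, spectra)
}

#' Generate a synthetic protein fixture
#'
#' Random sequence plus a reference shift list drawn per atom from the
#' statistics table (shift ~ Normal(mean, std)).  Synthetic in every
#' respect: no covariance between atoms, no secondary-structure effects,
#' and methyl protons get independent values.
#'
#' @param nRes number of residues.
#' @param seed integer seed.
#' @param stats a StatTable (packaged default if NULL).
#' @param id fixture identifier.
#' @return list(id, sequence, shifts (ShiftList), structure
#'   (StructureCoords; idealized helical backbone trace)).
#' @export
syntheticProtein <- function(nRes = 60L, seed = 1L, stats = NULL,
                             id = paste0("synth", seed)) {
  if (is.null(stats)) stats <- loadStatTable()
  withSeed(seed, {
    sequence <- paste(sample(AA1, nRes, replace = TRUE), collapse = "")
    atoms <- expectedAtoms(sequence)
    st <- .statLookupMulti(stats, atoms$residue_type, atoms$atom_name)
    atoms$shift <- rnorm(nrow(atoms), st$mean, st$std)
  })
  shifts <- ShiftList(atoms[, c("residue_index", "residue_type",
                                "atom_name", "nucleus", "shift")])
  list(id = id, sequence = sequence, shifts = shifts,
       structure = syntheticHelixCoords(nRes))
}

#' Idealized helical backbone-nitrogen coordinates
#'
#' Places one amide nitrogen per residue on an alpha-helix-like spiral
#' (2.3 Angstrom radius, 1.5 Angstrom rise and 100 degrees turn per
#' residue), giving realistic ~3.8 Angstrom consecutive spacing.  Used as a
#' stand-in structure for the structure-based perturbation generator.
#'
#' @param nRes number of residues.
#' @return A \code{StructureCoords} with one "N" atom per residue.
#' @export
syntheticHelixCoords <- function(nRes) {
  i <- seq_len(nRes)
  theta <- (i - 1L) * 100 * pi / 180
  StructureCoords(data.frame(
    residue_index = i, atom_name = "N",
    x = 2.3 * cos(theta), y = 2.3 * sin(theta), z = 1.5 * (i - 1L),
    stringsAsFactors = FALSE))
}

#' Packaged synthetic benchmark proteins
#'
#' Three ~60-residue synthetic proteins with fixed seeds, used throughout
#' the package's tests and benchmarks.
#'
#' @param nRes residues per protein.
#' @return list of three [syntheticProtein()] fixtures.
#' @export
packagedProteins <- function(nRes = 60L) {
  lapply(c(101L, 102L, 103L), function(s)
    syntheticProtein(nRes = nRes, seed = s, id = paste0("bench", s)))
}
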