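# Chemical shift transfer proper: construction of per-atom search spaces
# from a transferred (reindexed) shift list, with database-statistics
# fallback for atoms the transfer does not cover.

#' Search-space width configuration
#'
#' Exactly one of \code{cCst} and \code{fixedWidths} is active.  In
#' \code{cCst} mode a transferred atom's width is cCst times its reference
#' standard deviation; in fixed-width mode it is a per-nucleus constant
#' (the reference setting is 0.09 ppm for 1H and 1.2 ppm for 13C/15N).
#' Widths never fall below the per-nucleus floors: 0.04 ppm (1H) and
#' 0.4 ppm (13C/15N) in the random-perturbation and idealized-transfer
#' convention; the structure-perturbation and homolog-selection convention
#' uses a 0.03 ppm 1H floor (\code{floors = cstFloors("structure")}).
#'
#' @param cCst expected-perturbation scaling constant (> 0), or NULL.
#' @param fixedWidths per-nucleus widths c("1H"=,"13C"=,"15N"=), or NULL.
#' @param floors per-nucleus minimum widths.
#' @return list with class "CstConfig".
#' @export
#' @examples
#' cstConfig(cCst = 1.0)
#' cstConfig(fixedWidths = c("1H" = 0.09, "13C" = 1.2, "15N" = 1.2))
cstConfig <- function(cCst = NULL, fixedWidths = NULL,
                      floors = cstFloors("random")) {
  if (is.null(cCst) == is.null(fixedWidths))
    stop("exactly one of 'cCst' and 'fixedWidths' must be given")
  if (!is.null(cCst)) stopifnot_scalar_number(cCst, "cCst", positive = TRUE)
  if (!is.null(fixedWidths)) {
    fixedWidths <- asNucleusVector(fixedWidths, "fixedWidths")
    if (any(fixedWidths <= 0)) stop("fixedWidths must be > 0")
  }
  floors <- asNucleusVector(floors, "floors")
  if (any(floors <= 0)) stop("floors must be > 0")
  structure(list(cCst = cCst, fixedWidths = fixedWidths, floors = floors),
            class = "CstConfig")
}

#' Per-nucleus search-space floors
#' @param convention "random" (0.04/0.4/0.4 ppm) or "structure"
#'   (0.03/0.4/0.4 ppm).
#' @return named numeric vector.
#' @export
cstFloors <- function(convention = c("random", "structure")) {
  convention <- match.arg(convention)
  if (convention == "random") FLOORS_RANDOM else FLOORS_STRUCT
}

#' Build per-atom search spaces for a target protein
#'
#' For every expected atom of the target sequence: if the (already
#' reindexed) transferred shift list covers the atom, the search space is
#' centered on the transferred shift with width
#' \code{max(floor, w)} where \code{w} is the per-atom sigma from a
#' perturbation experiment when supplied, else \code{cCst * std} from the
#' statistics table (cCst mode), else the fixed per-nucleus width.  Atoms
#' without a transferred shift fall back to the statistics mean/std
#' (provenance "stats").
#'
#' @param targetSeq target protein sequence (1-letter codes).
#' @param transferred a ShiftList in target numbering (possibly empty).
#' @param stats a StatTable.
#' @param cfg a [cstConfig()].
#' @param perAtomSigma optional named numeric vector of per-atom sigmas, with
#'   names "residue_index.atom_name" (as produced by the perturbation
#'   generators); takes precedence over cCst for the atoms it covers.
#' @return A \code{SearchSpaceSet} covering the full expected-atom set.
#' @export
buildSearchSpaces <- function(targetSeq, transferred, stats, cfg,
                              perAtomSigma = NULL) {
  stopifnot(inherits(cfg, "CstConfig"))
  atoms <- expectedAtoms(targetSeq)
  tr <- shiftTable(transferred)
  key <- paste(atoms$residue_index, atoms$atom_name, sep = ".")
  trIdx <- match(key, paste(tr$residue_index, tr$atom_name, sep = "."))
  hasTr <- !is.na(trIdx)
  st <- .statLookupMulti(stats, atoms$residue_type, atoms$atom_name)
  floors <- cfg$floors[atoms$nucleus]

  center <- ifelse(hasTr, tr$shift[trIdx], st$mean)
  width <- st$std                               # stats fallback width
  if (any(hasTr)) {
    if (!is.null(cfg$cCst)) {
      w <- cfg$cCst * st$std[hasTr]
    } else {
      w <- cfg$fixedWidths[atoms$nucleus[hasTr]]
    }
    if (!is.null(perAtomSigma)) {
      ps <- perAtomSigma[key[hasTr]]
      w <- ifelse(is.na(ps), w, ps)
    }
    width[hasTr] <- pmax(floors[hasTr], w)
  }
  if (anyNA(center))
    stop("atom with neither transferred shift nor statistics entry")
  SearchSpaceSet(data.frame(
    residue_index = atoms$residue_index, residue_type = atoms$residue_type,
    atom_name = atoms$atom_name, nucleus = atoms$nucleus,
    center = center, width = width,
    provenance = ifelse(hasTr, "transferred", "stats"),
    stringsAsFactors = FALSE))
}

#' Idealized search spaces from the target's own shifts
#'
#' Reference setting in which the target's own chemical-shift list serves
#' as the transfer source: centers at the true shifts, widths at the
#' per-nucleus floors (0.04 ppm 1H, 0.4 ppm 13C/15N by default).  Upper
#' bound for transfer accuracy.
#'
#' @param targetSeq target protein sequence.
#' @param targetReference the target's own ShiftList.
#' @param stats a StatTable (fallback for unlisted atoms).
#' @param floors per-nucleus widths used for the covered atoms.
#' @return A \code{SearchSpaceSet}.
#' @export
idealizedSpaces <- function(targetSeq, targetReference, stats,
                            floors = cstFloors("random")) {
  cfg <- cstConfig(cCst = 1, floors = floors)
  n <- length(targetReference)
  sigma <- setNames(rep(0, n),
                    paste(shiftTable(targetReference)$residue_index,
                          shiftTable(targetReference)$atom_name, sep = "."))
  buildSearchSpaces(targetSeq, targetReference, stats, cfg,
                    perAtomSigma = sigma)
}

#' De-novo (statistics-only) search spaces
#'
#' Every atom uses the database-statistics mean and standard deviation; no
#' transfer information.
#'
#' @param targetSeq target protein sequence.
#' @param stats a StatTable.
#' @return A \code{SearchSpaceSet} with provenance "stats" throughout.
#' @export
denovoSpaces <- function(targetSeq, stats) {
  buildSearchSpaces(targetSeq, ShiftList(), stats, cstConfig(cCst = 1))
}
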