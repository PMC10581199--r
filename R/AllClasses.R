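#' @title Core classes
#' @description S4 containers for assigned chemical shifts, reference shift
#'   statistics, per-atom assignment search spaces, peak lists, structure
#'   coordinates, residue mappings, local alignments and consensus
#'   assignment results.
#' @name cstransfer-classes
NULL

setClass("ShiftList", representation(shifts = "data.frame"))

setValidity("ShiftList", function(object) {
  s <- object@shifts
  need <- c("residue_index","residue_type","atom_name","nucleus","shift")
  if (!all(need %in% names(s)))
    return(paste("shifts must have columns", paste(need, collapse = ", ")))
  if (nrow(s) == 0L) return(TRUE)
  if (any(s$residue_index < 1L) || any(s$residue_index != floor(s$residue_index)))
    return("residue_index must be a positive integer")
  key <- paste(s$residue_index, s$atom_name)
  if (anyDuplicated(key))
    return(paste("duplicate (residue_index, atom_name):",
                 key[duplicated(key)][1L]))
  if (!all(is.finite(s$shift))) return("shifts must be finite")
  inferred <- tryCatch(inferNucleus(s$atom_name), error = function(e) NULL)
  if (is.null(inferred)) return("atom_name with uninferrable nucleus")
  if (!all(s$nucleus == inferred))
    return("nucleus inconsistent with atom_name leading element")
  TRUE
})

#' Assigned chemical-shift list
#'
#' One row per assigned atom: 1-based residue index, 1-letter residue type,
#' IUPAC-style atom name, nucleus and chemical shift in ppm.  The nucleus is
#' inferred from the atom name when omitted.
#'
#' @param shifts data.frame with columns residue_index, residue_type,
#'   atom_name, shift (ppm) and optionally nucleus.
#' @return A \code{ShiftList} object.
#' @export
#' @examples
#' ShiftList(data.frame(residue_index = 5, residue_type = "A",
#'                      atom_name = "CA", shift = 52.4))
ShiftList <- function(shifts = data.frame()) {
  if (nrow(shifts) > 0L) {
    if (is.null(shifts$nucleus)) shifts$nucleus <- inferNucleus(shifts$atom_name)
    shifts$residue_index <- as.integer(shifts$residue_index)
    shifts <- shifts[, c("residue_index","residue_type","atom_name",
                         "nucleus","shift")]
    shifts <- shifts[order(shifts$residue_index, shifts$atom_name), ,
                     drop = FALSE]
    rownames(shifts) <- NULL
  } else {
    shifts <- data.frame(residue_index = integer(), residue_type = character(),
                         atom_name = character(), nucleus = character(),
                         shift = numeric())
  }
  new("ShiftList", shifts = shifts)
}

#' @describeIn ShiftList underlying shift table (data.frame).
#' @param x a ShiftList.
#' @export
shiftTable <- function(x) {
  stopifnot(is(x, "ShiftList"))
  x@shifts
}

setMethod("length", "ShiftList", function(x) nrow(x@shifts))

setMethod("show", "ShiftList", function(object) {
  s <- object@shifts
  cat("ShiftList with", nrow(s), "assigned atoms")
  if (nrow(s)) cat(" over", length(unique(s$residue_index)), "residues")
  cat("\n")
  if (nrow(s)) print(utils::head(s, 4L))
})

setClass("StatTable", representation(records = "data.frame"))

setValidity("StatTable", function(object) {
  r <- object@records
  need <- c("residue_type","atom_name","mean","std")
  if (!all(need %in% names(r)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  if (any(r$std <= 0)) return("std must be > 0")
  if (anyDuplicated(paste(r$residue_type, r$atom_name)))
    return("duplicate (residue_type, atom_name) record")
  TRUE
})

#' Reference chemical-shift statistics table
#'
#' Per-(residue type, atom name) mean and standard deviation of chemical
#' shifts, as used to build default (database-statistics) search spaces.
#'
#' @param records data.frame with columns residue_type, atom_name, mean, std.
#' @return A \code{StatTable}.
#' @seealso [loadStatTable()] for the packaged synthetic table.
#' @export
StatTable <- function(records) {
  records <- records[, c("residue_type","atom_name","mean","std")]
  rownames(records) <- NULL
  new("StatTable", records = records)
}

#' @describeIn StatTable underlying records (data.frame).
#' @param x a StatTable.
#' @export
statRecords <- function(x) {
  stopifnot(is(x, "StatTable"))
  x@records
}

setMethod("length", "StatTable", function(x) nrow(x@records))

setMethod("show", "StatTable", function(object) {
  cat("StatTable with", nrow(object@records), "(residue, atom) records\n")
})

setClass("SearchSpaceSet", representation(spaces = "data.frame"))

setValidity("SearchSpaceSet", function(object) {
  s <- object@spaces
  need <- c("residue_index","residue_type","atom_name","nucleus",
            "center","width","provenance")
  if (!all(need %in% names(s)))
    return(paste("spaces must have columns", paste(need, collapse = ", ")))
  if (nrow(s) == 0L) return(TRUE)
  if (any(s$width <= 0)) return("width must be > 0")
  if (!all(s$provenance %in% c("transferred","stats")))
    return("provenance must be 'transferred' or 'stats'")
  if (anyDuplicated(paste(s$residue_index, s$atom_name)))
    return("duplicate atom in search-space set")
  TRUE
})

#' Per-atom assignment search spaces
#'
#' One row per expected atom of the target: the center (ppm) and width (ppm,
#' the standard-deviation parameter of the initialization distribution) of
#' its search space, with provenance 'transferred' (from the source shift
#' list) or 'stats' (database-statistics fallback).
#'
#' @param spaces data.frame with columns residue_index, residue_type,
#'   atom_name, nucleus, center, width, provenance.
#' @return A \code{SearchSpaceSet}.
#' @export
SearchSpaceSet <- function(spaces) {
  if (is.null(spaces$nucleus)) spaces$nucleus <- inferNucleus(spaces$atom_name)
  spaces$residue_index <- as.integer(spaces$residue_index)
  spaces <- spaces[, c("residue_index","residue_type","atom_name","nucleus",
                       "center","width","provenance")]
  spaces <- spaces[order(spaces$residue_index, spaces$atom_name), , drop = FALSE]
  rownames(spaces) <- NULL
  new("SearchSpaceSet", spaces = spaces)
}

#' @describeIn SearchSpaceSet underlying table (data.frame).
#' @param x a SearchSpaceSet.
#' @export
spaceTable <- function(x) {
  stopifnot(is(x, "SearchSpaceSet"))
  x@spaces
}

setMethod("length", "SearchSpaceSet", function(x) nrow(x@spaces))

setMethod("show", "SearchSpaceSet", function(object) {
  s <- object@spaces
  cat("SearchSpaceSet:", nrow(s), "atoms (",
      sum(s$provenance == "transferred"), "transferred,",
      sum(s$provenance == "stats"), "stats fallback )\n")
})

SPECTRUM_TYPES <- c("N15_HSQC", "C13_HSQC", "N15_NOESY", "C13_NOESY")

spectrumDims <- function(spectrumType) {
  switch(spectrumType,
         N15_HSQC = c("1H", "15N"),
         C13_HSQC = c("1H", "13C"),
         N15_NOESY = c("1H", "1H", "15N"),
         C13_NOESY = c("1H", "1H", "13C"),
         stop("unknown spectrum_type: ", spectrumType))
}

setClass("PeakList", representation(spectrumType = "character",
                                    dims = "character",
                                    peaks = "matrix",
                                    tags = "character"))

setValidity("PeakList", function(object) {
  if (!object@spectrumType %in% SPECTRUM_TYPES)
    return(paste("spectrum_type must be one of",
                 paste(SPECTRUM_TYPES, collapse = ", ")))
  want <- spectrumDims(object@spectrumType)
  if (!identical(object@dims, want))
    return("dims inconsistent with spectrum_type")
  if (ncol(object@peaks) != length(want))
    return("each peak must have exactly length(dims) coordinates")
  if (length(object@tags) && length(object@tags) != nrow(object@peaks))
    return("tags must be empty or one per peak")
  TRUE
})

#' Peak list for one spectrum
#'
#' Cross-peak coordinates (ppm) of a 2D HSQC or 3D NOESY spectrum.  Peaks may
#' carry a true-assignment tag (fixtures only): a string of
#' residue.atom tokens, one per dimension, e.g. "5.H|5.N".
#'
#' @param spectrumType one of N15_HSQC, C13_HSQC, N15_NOESY, C13_NOESY.
#' @param peaks numeric matrix, one row per peak, ncol = number of dimensions.
#' @param tags optional character vector of assignment tags (NA for unknown).
#' @return A \code{PeakList}.
#' @export
PeakList <- function(spectrumType, peaks, tags = character()) {
  dims <- spectrumDims(spectrumType)
  peaks <- as.matrix(peaks)
  if (nrow(peaks) && ncol(peaks) != length(dims))
    stop("peaks for ", spectrumType, " need ", length(dims),
         " coordinates, got ", ncol(peaks))
  if (!nrow(peaks)) peaks <- matrix(numeric(), 0L, length(dims))
  colnames(peaks) <- dims
  new("PeakList", spectrumType = spectrumType, dims = dims,
      peaks = peaks, tags = as.character(tags))
}

#' @describeIn PeakList coordinate matrix (one row per peak).
#' @param x a PeakList.
#' @export
peakCoords <- function(x) {
  stopifnot(is(x, "PeakList"))
  x@peaks
}

#' @describeIn PeakList spectrum type string.
#' @export
spectrumType <- function(x) {
  stopifnot(is(x, "PeakList"))
  x@spectrumType
}

#' @describeIn PeakList true-assignment tags (may be empty).
#' @export
peakTags <- function(x) {
  stopifnot(is(x, "PeakList"))
  x@tags
}

setMethod("length", "PeakList", function(x) nrow(x@peaks))

setMethod("show", "PeakList", function(object) {
  cat("PeakList", object@spectrumType, "with", nrow(object@peaks), "peaks (",
      paste(object@dims, collapse = " x "), ")\n")
})

setClass("StructureCoords", representation(coords = "data.frame"))

setValidity("StructureCoords", function(object) {
  d <- object@coords
  need <- c("residue_index","atom_name","x","y","z")
  if (!all(need %in% names(d)))
    return(paste("coords must have columns", paste(need, collapse = ", ")))
  if (!all(is.finite(as.matrix(d[, c("x","y","z")]))))
    return("coordinates must be finite")
  TRUE
})

#' Protein structure coordinates
#'
#' Cartesian coordinates (Angstrom) of named atoms per residue; at minimum
#' the backbone amide nitrogen "N" of each residue, which drives the
#' structure-based perturbation generator.
#'
#' @param coords data.frame with columns residue_index, atom_name, x, y, z.
#' @return A \code{StructureCoords}.
#' @export
StructureCoords <- function(coords) {
  coords$residue_index <- as.integer(coords$residue_index)
  coords <- coords[, c("residue_index","atom_name","x","y","z")]
  rownames(coords) <- NULL
  new("StructureCoords", coords = coords)
}

#' @describeIn StructureCoords underlying coordinate table.
#' @param x a StructureCoords.
#' @export
coordTable <- function(x) {
  stopifnot(is(x, "StructureCoords"))
  x@coords
}

#' @describeIn StructureCoords amide-N coordinate matrix, rownames = residue
#'   index.
#' @export
amideNCoords <- function(x) {
  d <- coordTable(x)
  d <- d[d$atom_name == "N", , drop = FALSE]
  m <- as.matrix(d[, c("x","y","z")])
  rownames(m) <- d$residue_index
  m
}

setMethod("show", "StructureCoords", function(object) {
  d <- object@coords
  cat("StructureCoords:", nrow(d), "atoms,",
      length(unique(d$residue_index)), "residues\n")
})

setClass("ResidueMapping", representation(pairs = "data.frame"))

setValidity("ResidueMapping", function(object) {
  p <- object@pairs
  if (!all(c("source_index","target_index") %in% names(p)))
    return("pairs must have columns source_index, target_index")
  if (anyDuplicated(p$source_index) || anyDuplicated(p$target_index))
    return("mapping must be one-to-one")
  TRUE
})

#' Source-to-target residue mapping
#'
#' Alignment-derived residue correspondences restricted to columns where the
#' source and target residue types are identical; the only positions usable
#' for shift transfer.
#'
#' @param pairs data.frame with integer columns source_index, target_index.
#' @return A \code{ResidueMapping}.
#' @export
ResidueMapping <- function(pairs) {
  pairs <- data.frame(source_index = as.integer(pairs$source_index),
                      target_index = as.integer(pairs$target_index))
  pairs <- pairs[order(pairs$source_index), , drop = FALSE]
  rownames(pairs) <- NULL
  new("ResidueMapping", pairs = pairs)
}

#' @describeIn ResidueMapping underlying pair table.
#' @param x a ResidueMapping.
#' @export
mappingPairs <- function(x) {
  stopifnot(is(x, "ResidueMapping"))
  x@pairs
}

setMethod("length", "ResidueMapping", function(x) nrow(x@pairs))

setMethod("show", "ResidueMapping", function(object) {
  cat("ResidueMapping with", nrow(object@pairs), "identical-residue pairs\n")
})

setClass("Alignment", representation(pairs = "data.frame",
                                     rawScore = "numeric",
                                     params = "list"))

setValidity("Alignment", function(object) {
  p <- object@pairs
  if (!all(c("source_index","target_index") %in% names(p)))
    return("pairs must have columns source_index, target_index")
  if (any(is.na(p$source_index) & is.na(p$target_index)))
    return("no column may be (gap, gap)")
  si <- p$source_index[!is.na(p$source_index)]
  ti <- p$target_index[!is.na(p$target_index)]
  if (is.unsorted(si, strictly = TRUE) || is.unsorted(ti, strictly = TRUE))
    return("indices must be strictly increasing along each sequence")
  TRUE
})

#' Local pairwise alignment
#'
#' Aligned column list (NA marks a gap on one side), the raw
#' Smith-Waterman score and the scoring parameters used.
#'
#' @param pairs data.frame with columns source_index, target_index (NA = gap).
#' @param rawScore numeric alignment score.
#' @param params list(matrix, gapOpening, gapExtension).
#' @return An \code{Alignment}.
#' @export
Alignment <- function(pairs, rawScore, params = list()) {
  new("Alignment", pairs = pairs, rawScore = rawScore, params = params)
}

#' @describeIn Alignment aligned column table.
#' @param x an Alignment.
#' @export
alignmentPairs <- function(x) {
  stopifnot(is(x, "Alignment"))
  x@pairs
}

#' @describeIn Alignment raw alignment score.
#' @export
rawScore <- function(x) {
  stopifnot(is(x, "Alignment"))
  x@rawScore
}

setMethod("show", "Alignment", function(object) {
  p <- object@pairs
  m <- sum(!is.na(p$source_index) & !is.na(p$target_index))
  cat("Local Alignment:", nrow(p), "columns,", m, "matched, score",
      object@rawScore, "\n")
})

setClass("ConsensusResult", representation(atoms = "data.frame",
                                           replicates = "integer",
                                           sMin = "numeric"))

setValidity("ConsensusResult", function(object) {
  a <- object@atoms
  need <- c("residue_index","residue_type","atom_name","nucleus",
            "shift","support","strong")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  ok <- !is.na(a$support)
  if (any(a$support[ok] < 0 | a$support[ok] > 1))
    return("support must lie in [0, 1]")
  if (any(a$strong[ok] & a$support[ok] < object@sMin))
    return("strong implies support >= sMin")
  TRUE
})

#' Replicate-consensus assignment result
#'
#' Per expected atom: the consensus chemical shift over optimization
#' replicates, the support fraction (size of the majority cluster / number
#' of replicates) and the strong flag (support >= sMin).
#'
#' @param atoms data.frame with columns residue_index, residue_type,
#'   atom_name, nucleus, shift, support, strong.
#' @param replicates number of replicates the consensus was taken over.
#' @param sMin strong-assignment support threshold.
#' @return A \code{ConsensusResult}.
#' @export
ConsensusResult <- function(atoms, replicates, sMin) {
  new("ConsensusResult", atoms = atoms, replicates = as.integer(replicates),
      sMin = sMin)
}

#' @describeIn ConsensusResult per-atom consensus table.
#' @param x a ConsensusResult.
#' @export
consensusTable <- function(x) {
  stopifnot(is(x, "ConsensusResult"))
  x@atoms
}

#' @describeIn ConsensusResult consensus shifts as a ShiftList (assigned
#'   atoms only; optionally strong assignments only).
#' @param strongOnly drop atoms below the strong-support threshold.
#' @export
consensusShiftList <- function(x, strongOnly = FALSE) {
  a <- consensusTable(x)
  a <- a[!is.na(a$shift), , drop = FALSE]
  if (strongOnly) a <- a[a$strong, , drop = FALSE]
  ShiftList(a[, c("residue_index","residue_type","atom_name","nucleus","shift")])
}

setMethod("show", "ConsensusResult", function(object) {
  a <- object@atoms
  cat("ConsensusResult over", object@replicates, "replicates:",
      sum(!is.na(a$shift)), "of", nrow(a), "atoms assigned,",
      sum(a$strong, na.rm = TRUE), "strong (sMin =", object@sMin, ")\n")
})
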