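# Local pairwise alignment, normalized scoring, residue mapping and shift
# reindexing.  The alignment itself is delegated to Biostrings'
# Smith-Waterman implementation; defaults (BLOSUM62, gap open 10, gap
# extend 0.5) penalize opening a gap heavily and extending it cheaply, so
# optima have few, wide gaps between large aligned sub-sequences.  A gap of
# length L costs gapOpening + L * gapExtension.

#' Alignment parameters
#'
#' @param matrix substitution matrix name (a matrix shipped with
#'   Biostrings, e.g. "BLOSUM62"), or an explicit numeric matrix.
#' @param gapOpening cost for opening a gap.
#' @param gapExtension cost per gapped position.
#' @return list of parameters for [localAlign()].
#' @export
alignParams <- function(matrix = "BLOSUM62", gapOpening = 10,
                        gapExtension = 0.5) {
  list(matrix = matrix, gapOpening = gapOpening, gapExtension = gapExtension)
}

.substMatrix <- function(params) {
  if (is.matrix(params$matrix)) return(params$matrix)
  get(data(list = params$matrix, package = "Biostrings",
           envir = environment()), envir = environment())
}

#' Optimal local pairwise sequence alignment
#'
#' Smith-Waterman local alignment with affine gap penalties.  Ties between
#' equal-scoring optima are broken deterministically by the dynamic
#' program's fixed traceback order, so repeated runs are identical.
#'
#' @param sourceSeq,targetSeq 1-letter amino-acid strings.
#' @param params see [alignParams()].
#' @return An \code{Alignment}; column indices are 1-based positions in the
#'   source and target (NA marks a gap on that side).
#' @export
#' @examples
#' localAlign("ACDE", "ACDE")
localAlign <- function(sourceSeq, targetSeq, params = alignParams()) {
  if (!nzchar(sourceSeq) || !nzchar(targetSeq))
    stop("sequences must be non-empty")
  sm <- .substMatrix(params)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sourceSeq), Biostrings::AAString(targetSeq),
    substitutionMatrix = sm, gapOpening = params$gapOpening,
    gapExtension = params$gapExtension, type = "local")
  pat <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  si <- Biostrings::start(Biostrings::pattern(aln))
  ti <- Biostrings::start(Biostrings::subject(aln))
  n <- length(pat)
  srcIdx <- integer(n); tgtIdx <- integer(n)
  s <- si; t <- ti
  for (k in seq_len(n)) {
    srcIdx[k] <- if (pat[k] == "-") NA_integer_ else { v <- s; s <- s + 1L; v }
    tgtIdx[k] <- if (sub[k] == "-") NA_integer_ else { v <- t; t <- t + 1L; v }
  }
  Alignment(data.frame(source_index = srcIdx, target_index = tgtIdx),
            rawScore = Biostrings::score(aln),
            params = list(matrix = if (is.matrix(params$matrix)) "custom"
                          else params$matrix,
                          gapOpening = params$gapOpening,
                          gapExtension = params$gapExtension))
}

#' Normalized local-alignment score
#'
#' Raw local-alignment score of source against target divided by the score
#' of aligning the target to itself, clipped to [0, 1].  Used to rank
#' candidate homolog pairs (selection threshold > 0.8).
#'
#' @inheritParams localAlign
#' @return numeric in [0, 1].
#' @export
normalizedScore <- function(sourceSeq, targetSeq, params = alignParams()) {
  self <- rawScore(localAlign(targetSeq, targetSeq, params))
  if (self <= 0) stop("self-alignment score of the target must be > 0")
  raw <- rawScore(localAlign(sourceSeq, targetSeq, params))
  min(1, max(0, raw / self))
}

#' Identical-residue mapping from an alignment
#'
#' Keeps only matched alignment columns where the source and target residue
#' types are identical; mismatched pairs and gapped columns are disregarded
#' (those target atoms fall back to database-statistics search spaces).
#'
#' @param alignment an Alignment of these two sequences.
#' @param sourceSeq,targetSeq the aligned sequences.
#' @return A \code{ResidueMapping}.
#' @export
buildMapping <- function(alignment, sourceSeq, targetSeq) {
  p <- alignmentPairs(alignment)
  keep <- !is.na(p$source_index) & !is.na(p$target_index)
  p <- p[keep, , drop = FALSE]
  src <- strsplit(sourceSeq, "")[[1]]
  tgt <- strsplit(targetSeq, "")[[1]]
  if (nrow(p) && (max(p$source_index) > length(src) ||
                  max(p$target_index) > length(tgt)))
    stop("alignment does not refer to these sequences")
  same <- src[p$source_index] == tgt[p$target_index]
  ResidueMapping(p[same, , drop = FALSE])
}

#' Reindex a source shift list onto target numbering
#'
#' Each shift of a mapped source residue is re-labelled with its target
#' residue index; atoms of unmapped residues are dropped.  Residue types are
#' preserved (identical by construction of the mapping).
#'
#' @param source a ShiftList in source numbering.
#' @param mapping a ResidueMapping.
#' @return A \code{ShiftList} in target numbering.
#' @export
reindexShifts <- function(source, mapping) {
  s <- shiftTable(source)
  p <- mappingPairs(mapping)
  idx <- match(s$residue_index, p$source_index)
  keep <- !is.na(idx)
  s <- s[keep, , drop = FALSE]
  s$residue_index <- p$target_index[idx[keep]]
  ShiftList(s)
}

#' Identity mapping for a sequence
#' @param sequence 1-letter amino-acid string.
#' @return A \code{ResidueMapping} mapping every residue onto itself.
#' @export
identityMapping <- function(sequence) {
  n <- nchar(sequence)
  ResidueMapping(data.frame(source_index = seq_len(n),
                            target_index = seq_len(n)))
}

#' Homolog-pair selection predicate
#'
#' A candidate source/target pair qualifies for shift transfer when the
#' normalized alignment score exceeds \code{scoreMin} and the fraction of
#' correct aligned shifts is at least \code{fractionMin}.
#'
#' @param normScore normalized alignment score(s).
#' @param fractionCorrect fraction(s) of correct aligned shifts.
#' @param scoreMin normalized-score threshold (default 0.8, exclusive).
#' @param fractionMin fraction-correct threshold (default 0.5, inclusive).
#' @return logical vector.
#' @export
selectHomologPairs <- function(normScore, fractionCorrect,
                               scoreMin = 0.8, fractionMin = 0.5) {
  normScore > scoreMin & fractionCorrect >= fractionMin
}
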