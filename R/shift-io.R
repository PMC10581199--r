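# Readers and writers: shift lists (TSV, NMR-STAR), peak lists (TSV),
# search-space "chemical shift statistics" files, FASTA sequences and PDB
# coordinates.  The TSV dialect throughout is whitespace-separated with '#'
# comments and an optional header line.

.readTsvLines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  lineno <- seq_along(raw)
  raw <- sub("#.*$", "", raw)
  keep <- grepl("\\S", raw)
  list(lines = raw[keep], lineno = lineno[keep])
}

.splitFields <- function(line) strsplit(trimws(line), "\\s+")[[1]]

#' Read an assigned chemical-shift list
#'
#' TSV dialect: whitespace-separated columns residue_index, residue_type,
#' atom_name, shift (optional header, '#' comments).  NMR-STAR dialect:
#' every \code{_Atom_chem_shift} loop of the file is read (assigned
#' chemical-shift saveframes only; read-only support).
#'
#' @param path input file.
#' @param format "tsv" or "nmrstar".
#' @return A \code{ShiftList}.  Unknown atom names are preserved verbatim;
#'   the nucleus is inferred from the first alphabetic character of the atom
#'   name.
#' @export
readShiftList <- function(path, format = c("tsv", "nmrstar")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") .readShiftTsv(path) else .readShiftStar(path)
}

.readShiftTsv <- function(path) {
  tl <- .readTsvLines(path)
  rows <- vector("list", length(tl$lines))
  for (i in seq_along(tl$lines)) {
    f <- .splitFields(tl$lines[i])
    if (i == 1L && identical(tolower(f[1]), "residue_index")) next
    if (length(f) < 4L)
      stop("parse error in ", path, " line ", tl$lineno[i],
           ": expected >= 4 fields, got ", length(f))
    val <- suppressWarnings(as.numeric(f[4]))
    idx <- suppressWarnings(as.integer(f[1]))
    if (is.na(val) || is.na(idx))
      stop("parse error in ", path, " line ", tl$lineno[i],
           ": non-numeric residue_index or shift")
    rows[[i]] <- data.frame(residue_index = idx, residue_type = f[2],
                            atom_name = f[3], shift = val,
                            stringsAsFactors = FALSE)
  }
  ShiftList(do.call(rbind, rows))
}

.readShiftStar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  rows <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (identical(lines[i], "loop_")) {
      j <- i + 1L
      tags <- character(0)
      while (j <= n && startsWith(lines[j], "_")) {
        tags <- c(tags, lines[j]); j <- j + 1L
      }
      if (any(grepl("^_Atom_chem_shift\\.", tags))) {
        cols <- sub("^_Atom_chem_shift\\.", "", tags)
        pick <- function(alts) {
          k <- which(cols %in% alts)
          if (!length(k)) stop("NMR-STAR loop lacks tag(s) ",
                               paste(alts, collapse = "/"), " in ", path)
          k[1L]
        }
        iSeq <- pick(c("Seq_ID", "Comp_index_ID"))
        iCmp <- pick("Comp_ID"); iAtm <- pick("Atom_ID"); iVal <- pick("Val")
        while (j <= n && !lines[j] %in% c("stop_", "loop_") &&
               !startsWith(lines[j], "save_")) {
          if (nzchar(lines[j]) && !startsWith(lines[j], "#")) {
            f <- .splitFields(lines[j])
            if (length(f) >= length(cols)) {
              aa3 <- toupper(f[iCmp])
              aa1 <- if (aa3 %in% names(AA3TO1)) AA3TO1[[aa3]] else
                       if (nchar(aa3) == 1L) aa3 else "X"
              rows[[length(rows) + 1L]] <- data.frame(
                residue_index = as.integer(f[iSeq]), residue_type = aa1,
                atom_name = f[iAtm], shift = as.numeric(f[iVal]),
                stringsAsFactors = FALSE)
            }
          }
          j <- j + 1L
        }
      }
      i <- j
    }
    i <- i + 1L
  }
  if (!length(rows))
    stop("no _Atom_chem_shift loop found in ", path)
  ShiftList(do.call(rbind, rows))
}

#' Write a chemical-shift list as TSV
#' @param shifts a ShiftList.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeShiftList <- function(shifts, path) {
  s <- shiftTable(shifts)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# residue_index residue_type atom_name shift", con)
  writeLines(sprintf("%d\t%s\t%s\t%.4f", s$residue_index, s$residue_type,
                     s$atom_name, s$shift), con)
  invisible(path)
}

#' Write search spaces as a chemical-shift-statistics file
#'
#' One record per target atom: residue_index, residue_type, atom_name,
#' center (ppm), width (ppm) and the provenance flag ("transferred" or
#' "stats").  This is the file handed to the assignment stage; numeric
#' fields round-trip at 4 decimal places.
#'
#' @param spaces a SearchSpaceSet.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeShiftStatistics <- function(spaces, path) {
  s <- spaceTable(spaces)
  if (!nrow(s)) stop("empty SearchSpaceSet")
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# residue_index residue_type atom_name center width provenance",
             con)
  writeLines(sprintf("%d\t%s\t%s\t%.4f\t%.4f\t%s", s$residue_index,
                     s$residue_type, s$atom_name, s$center, s$width,
                     s$provenance), con)
  invisible(path)
}

#' Read a chemical-shift-statistics (search-space) file
#' @param path file written by [writeShiftStatistics()].
#' @return A \code{SearchSpaceSet}.
#' @export
readShiftStatistics <- function(path) {
  tl <- .readTsvLines(path)
  f <- lapply(tl$lines, .splitFields)
  bad <- which(vapply(f, length, 1L) < 6L)
  if (length(bad))
    stop("parse error in ", path, " line ", tl$lineno[bad[1L]],
         ": expected 6 fields")
  m <- do.call(rbind, f)
  SearchSpaceSet(data.frame(
    residue_index = as.integer(m[, 1]), residue_type = m[, 2],
    atom_name = m[, 3], center = as.numeric(m[, 4]),
    width = as.numeric(m[, 5]), provenance = m[, 6],
    stringsAsFactors = FALSE))
}

#' Read a peak list from TSV
#'
#' One peak per line: the ppm coordinates (as many columns as the spectrum
#' type has dimensions) followed by an optional assignment tag.
#'
#' @param path input file.
#' @param spectrumType one of N15_HSQC, C13_HSQC, N15_NOESY, C13_NOESY.
#' @return A \code{PeakList}.
#' @export
readPeakList <- function(path, spectrumType) {
  nd <- length(spectrumDims(spectrumType))
  tl <- .readTsvLines(path)
  coords <- matrix(numeric(), 0L, nd)
  tags <- character(0)
  if (length(tl$lines)) {
    f <- lapply(tl$lines, .splitFields)
    nf <- vapply(f, length, 1L)
    bad <- which(nf < nd | nf > nd + 1L)
    if (length(bad))
      stop("peak list ", path, " line ", tl$lineno[bad[1L]], ": expected ",
           nd, " coordinates (+ optional tag), got ", nf[bad[1L]])
    coords <- t(vapply(f, function(x) as.numeric(x[seq_len(nd)]),
                       numeric(nd)))
    if (any(!is.finite(coords)))
      stop("peak list ", path, ": non-numeric coordinate")
    tags <- vapply(f, function(x)
      if (length(x) > nd) x[nd + 1L] else NA_character_, character(1))
    if (all(is.na(tags))) tags <- character(0)
  }
  PeakList(spectrumType, coords, tags)
}

#' Write a peak list as TSV
#' @param peaks a PeakList.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writePeakList <- function(peaks, path) {
  co <- peakCoords(peaks)
  tg <- peakTags(peaks)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# ", spectrumType(peaks), " dims: ",
                    paste(peaks@dims, collapse = " ")), con)
  for (i in seq_len(nrow(co))) {
    line <- paste(sprintf("%.4f", co[i, ]), collapse = "\t")
    if (length(tg) && !is.na(tg[i])) line <- paste(line, tg[i], sep = "\t")
    writeLines(line, con)
  }
  invisible(path)
}

#' Read protein sequences from FASTA
#' @param path FASTA file.
#' @return named character vector of 1-letter sequences.
#' @export
readFastaSequences <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write protein sequences to FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeFastaSequences <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Read structure coordinates from a PDB file
#'
#' Standard ATOM coordinate records (first model, first chain by default),
#' read with bio3d.
#'
#' @param path PDB file.
#' @param chain optional chain identifier; default: first chain present.
#' @return A \code{StructureCoords}.
#' @export
readPdbCoords <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain == chain, , drop = FALSE]
  StructureCoords(data.frame(
    residue_index = at$resno, atom_name = at$elety,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE))
}

#' Export a residue mapping as TSV
#' @param mapping a ResidueMapping.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeMapping <- function(mapping, path) {
  p <- mappingPairs(mapping)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# source_index target_index", con)
  writeLines(sprintf("%d\t%d", p$source_index, p$target_index), con)
  invisible(path)
}

#' Write a consensus assignment as TSV
#'
#' Emits the assigned shift list with support and strength columns.
#' @param consensus a ConsensusResult.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeConsensus <- function(consensus, path) {
  a <- consensusTable(consensus)
  a <- a[!is.na(a$shift), , drop = FALSE]
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# residue_index residue_type atom_name shift support strong", con)
  writeLines(sprintf("%d\t%s\t%s\t%.4f\t%.4f\t%s", a$residue_index,
                     a$residue_type, a$atom_name, a$shift, a$support,
                     ifelse(a$strong, "strong", "weak")), con)
  invisible(path)
}
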