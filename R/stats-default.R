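# Packaged reference chemical-shift statistics.
#
# The table shipped with the package is SYNTHETIC: per-atom means are
# field-typical values (random-coil-like) and standard deviations are
# category-typical, chosen to be internally consistent (every expected atom
# of every standard residue is covered, all values inside the physically
# plausible range of its nucleus).  It does not reproduce any particular
# BMRB release; a real database-derived table in the same TSV schema
# (residue_type, atom_name, mean, std) can be supplied wherever a StatTable
# is accepted.

.caMeans <- c(A=53.2,R=56.8,N=53.5,D=54.7,C=58.2,E=57.4,Q=56.6,G=45.4,
              H=56.5,I=61.6,L=55.6,K=56.9,M=56.1,F=58.1,P=63.3,S=58.7,
              T=62.2,W=57.7,Y=58.1,V=62.5)

.nMeans <- c(A=123.2,R=120.8,N=118.9,D=120.4,C=119.0,E=120.7,Q=119.9,
             G=109.5,H=119.1,I=121.4,L=121.8,K=121.3,M=120.1,F=120.3,
             P=132.0,S=116.3,T=114.6,W=121.7,Y=120.5,V=121.1)

# sidechain means per residue (CB included); keyed residue -> atom -> ppm
.scMeans <- list(
  A = c(CB=19.0, HB1=1.39, HB2=1.39, HB3=1.39),
  R = c(CB=30.7, CG=27.2, CD=43.2, CZ=159.5, NE=84.6, NH1=72.6, NH2=72.4,
        HB2=1.82, HB3=1.78, HG2=1.62, HG3=1.58, HD2=3.17, HD3=3.13, HE=7.35),
  N = c(CB=38.7, CG=176.8, ND2=112.8,
        HB2=2.83, HB3=2.76, HD21=7.35, HD22=7.15),
  D = c(CB=40.9, CG=179.5, HB2=2.73, HB3=2.66),
  C = c(CB=32.8, HB2=2.98, HB3=2.92),
  E = c(CB=30.0, CG=36.1, CD=183.5,
        HB2=2.05, HB3=2.01, HG2=2.30, HG3=2.27),
  Q = c(CB=29.2, CG=33.7, CD=179.7, NE2=111.9,
        HB2=2.10, HB3=2.05, HG2=2.34, HG3=2.31, HE21=7.30, HE22=7.00),
  G = c(),
  H = c(CB=30.2, CG=131.0, CD2=119.5, CE1=136.5, ND1=195.0, NE2=180.0,
        HB2=3.14, HB3=3.07, HD2=7.08, HE1=8.10),
  I = c(CB=38.6, CG1=27.7, CG2=17.5, CD1=13.4,
        HB=1.78, HG12=1.28, HG13=1.20,
        HG21=0.86, HG22=0.86, HG23=0.86,
        HD11=0.80, HD12=0.80, HD13=0.80),
  L = c(CB=42.3, CG=26.8, CD1=24.7, CD2=24.1,
        HB2=1.64, HB3=1.55, HG=1.60,
        HD11=0.85, HD12=0.85, HD13=0.85,
        HD21=0.82, HD22=0.82, HD23=0.82),
  K = c(CB=32.8, CG=24.9, CD=29.0, CE=41.9, NZ=33.2,
        HB2=1.80, HB3=1.75, HG2=1.43, HG3=1.39,
        HD2=1.68, HD3=1.66, HE2=2.99, HE3=2.97),
  M = c(CB=32.9, CG=32.0, CE=17.1,
        HB2=2.06, HB3=2.00, HG2=2.58, HG3=2.52,
        HE1=2.02, HE2=2.02, HE3=2.02),
  F = c(CB=39.9, CG=138.5, CD1=131.5, CD2=131.4, CE1=130.7, CE2=130.7,
        CZ=129.2,
        HB2=3.04, HB3=2.97, HD1=7.22, HD2=7.22, HE1=7.34, HE2=7.34, HZ=7.28),
  P = c(CB=31.8, CG=27.2, CD=50.3,
        HB2=2.08, HB3=2.01, HG2=1.96, HG3=1.92, HD2=3.65, HD3=3.60),
  S = c(CB=63.8, HB2=3.89, HB3=3.85),
  T = c(CB=69.7, CG2=21.4, HB=4.17, HG21=1.20, HG22=1.20, HG23=1.20),
  W = c(CB=29.9, CG=110.5, CD1=126.5, CD2=127.5, CE2=138.0, CE3=120.5,
        CZ2=114.3, CZ3=121.5, CH2=123.8, NE1=129.3,
        HB2=3.24, HB3=3.17, HD1=7.22, HE1=10.10, HE3=7.55, HZ2=7.45,
        HZ3=7.10, HH2=7.15),
  Y = c(CB=39.0, CG=129.8, CD1=132.8, CD2=132.8, CE1=118.0, CE2=118.0,
        CZ=156.7,
        HB2=2.98, HB3=2.90, HD1=7.05, HD2=7.05, HE1=6.75, HE2=6.75),
  V = c(CB=32.6, CG1=21.5, CG2=21.3,
        HB=2.06,
        HG11=0.92, HG12=0.92, HG13=0.92,
        HG21=0.90, HG22=0.90, HG23=0.90)
)

.stdFor <- function(residue, atom, nucleus, mean) {
  if (nucleus == "1H") {
    if (atom == "H") return(0.60)
    if (mean > 6) return(0.50)           # ring / amide-like protons
    return(0.32)
  }
  if (nucleus == "13C") {
    if (mean > 165) return(1.8)          # carbonyl-like
    if (mean > 100) return(2.2)          # aromatic ring
    return(1.9)
  }
  # 15N
  if (atom == "N") return(4.2)
  if (residue == "H" && atom %in% c("ND1","NE2")) return(12.0)
  2.0
}

#' Synthetic default shift-statistics records
#'
#' Builds the packaged per-(residue, atom) mean/std table covering every
#' expected atom of the 20 standard residues.  The values are synthetic
#' (field-typical, not tied to any database release); see the package
#' vignette.
#'
#' @return data.frame with columns residue_type, atom_name, mean, std.
#' @export
defaultStatRecords <- function() {
  defs <- atomDefs()
  n <- nrow(defs)
  mean <- numeric(n); std <- numeric(n)
  for (i in seq_len(n)) {
    aa <- defs$residue_type[i]; at <- defs$atom_name[i]
    nuc <- defs$nucleus[i]
    m <- switch(at,
                N  = .nMeans[[aa]],
                H  = 8.30,
                CA = .caMeans[[aa]],
                HA = 4.35, HA2 = 3.95, HA3 = 3.90,
                C  = if (aa == "G") 174.0 else 176.4,
                { v <- .scMeans[[aa]][at]
                  if (is.na(v)) stop("no mean for ", aa, " ", at)
                  unname(v) })
    mean[i] <- m
    std[i]  <- .stdFor(aa, at, nuc, m)
  }
  data.frame(residue_type = defs$residue_type, atom_name = defs$atom_name,
             mean = mean, std = std, stringsAsFactors = FALSE)
}

.checkStatRanges <- function(records) {
  nuc <- inferNucleus(records$atom_name)
  bad <- (nuc == "1H"  & (records$mean < -2  | records$mean > 13)) |
         (nuc == "13C" & (records$mean < 0   | records$mean > 220)) |
         (nuc == "15N" & records$atom_name == "N" &
            (records$mean < 90 | records$mean > 140)) |
         (nuc == "15N" & (records$mean < 0 | records$mean > 260))
  if (any(bad))
    stop("statistics mean out of plausible range for: ",
         paste(paste(records$residue_type[bad], records$atom_name[bad]),
               collapse = ", "))
  invisible(TRUE)
}

#' Load a chemical-shift statistics table
#'
#' With \code{path = NULL} loads the packaged synthetic default (TSV under
#' \code{inst/extdata}); otherwise reads a user table in the same schema
#' (whitespace-separated columns residue_type, atom_name, mean, std, '#'
#' comments, optional header).  User records override packaged ones when
#' \code{merge = TRUE}.
#'
#' @param path TSV file, or NULL for the packaged default.
#' @param merge if TRUE and \code{path} is given, user records override the
#'   packaged defaults instead of replacing the whole table.
#' @param checkRanges validate means against per-nucleus plausible ranges.
#' @return A \code{StatTable}.
#' @export
#' @examples
#' tab <- loadStatTable()
#' statLookup(tab, "A", "CA")
loadStatTable <- function(path = NULL, merge = FALSE, checkRanges = TRUE) {
  if (is.null(path)) {
    file <- system.file("extdata", "shift_stats_synthetic.tsv",
                        package = "cstransfer", mustWork = TRUE)
    rec <- .readStatsTsv(file)
  } else {
    if (!file.exists(path)) stop("statistics file not found: ", path)
    rec <- .readStatsTsv(path)
    if (merge) {
      base <- statRecords(loadStatTable())
      key <- paste(base$residue_type, base$atom_name)
      ukey <- paste(rec$residue_type, rec$atom_name)
      rec <- rbind(rec, base[!key %in% ukey, , drop = FALSE])
    }
  }
  if (any(!is.finite(rec$std)) || any(rec$std <= 0))
    stop("statistics std must be > 0 (validation error at load time)")
  if (checkRanges) .checkStatRanges(rec)
  StatTable(rec)
}

.readStatsTsv <- function(path) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("residue_type","atom_name","mean","std"),
                    colClasses = c("character","character","numeric","numeric"),
                    stringsAsFactors = FALSE)
  if (identical(tolower(tab$residue_type[1]), "residue_type"))
    tab <- tab[-1L, , drop = FALSE]
  tab$mean <- as.numeric(tab$mean); tab$std <- as.numeric(tab$std)
  tab
}

#' Write a statistics table to TSV
#' @param table a StatTable.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeStatTable <- function(table, path) {
  rec <- statRecords(table)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# residue_type atom_name mean std", con)
  writeLines(sprintf("%s\t%s\t%.4f\t%.4f", rec$residue_type, rec$atom_name,
                     rec$mean, rec$std), con)
  invisible(path)
}

#' Look up reference statistics for one atom
#'
#' @param table a StatTable.
#' @param residueType 1-letter residue code.
#' @param atomName atom name.
#' @param fallback if TRUE, an absent key resolves to the nucleus-wide
#'   default (mean of all means/stds of that nucleus in the table) instead
#'   of erroring.
#' @return named numeric c(mean=, std=).
#' @export
statLookup <- function(table, residueType, atomName, fallback = FALSE) {
  rec <- statRecords(table)
  i <- which(rec$residue_type == residueType & rec$atom_name == atomName)
  if (length(i) == 1L)
    return(c(mean = rec$mean[i], std = rec$std[i]))
  if (!fallback)
    stop("no statistics record for (", residueType, ", ", atomName, ")")
  nuc <- inferNucleus(atomName)
  sel <- inferNucleus(rec$atom_name) == nuc
  if (!any(sel)) stop("no records for nucleus ", nuc)
  c(mean = mean(rec$mean[sel]), std = mean(rec$std[sel]))
}

# vectorized internal lookup; returns data.frame(mean, std) aligned to input
.statLookupMulti <- function(table, residueType, atomName, fallback = FALSE) {
  rec <- statRecords(table)
  idx <- match(paste(residueType, atomName), paste(rec$residue_type, rec$atom_name))
  out <- data.frame(mean = rec$mean[idx], std = rec$std[idx])
  if (anyNA(idx)) {
    if (!fallback) {
      bad <- which(is.na(idx))[1L]
      stop("no statistics record for (", residueType[bad], ", ",
           atomName[bad], ")")
    }
    miss <- which(is.na(idx))
    for (j in miss) {
      p <- statLookup(table, residueType[j], atomName[j], fallback = TRUE)
      out$mean[j] <- p[["mean"]]; out$std[j] <- p[["std"]]
    }
  }
  out
}
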