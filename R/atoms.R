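# Expected-atom sets per residue type.
#
# For every standard residue this table lists the 1H/13C/15N atoms an
# assignment run is expected to resolve: backbone N, H(N), CA, HA(, HA2/HA3),
# C plus the sidechain carbons/nitrogens and their bonded protons.
# Exchangeable OH/SH protons (Ser/Thr/Tyr HG/HH, Cys HG), fast-exchanging
# terminal amine/guanidinium protons (Lys HZ*, Arg HH*) and the His ring
# protons HD1/HE2 are excluded, as they are rarely observed in the four
# experiment types handled here.  Each proton records its bonded heavy-atom
# partner, which drives the C13-HSQC / NOESY peak templates.

.sidechainDefs <- list(
  A = list(C = c("CB"), H = c(HB1 = "CB", HB2 = "CB", HB3 = "CB")),
  R = list(C = c("CB","CG","CD","CZ"), N = c("NE","NH1","NH2"),
           H = c(HB2="CB",HB3="CB",HG2="CG",HG3="CG",HD2="CD",HD3="CD",HE="NE")),
  N = list(C = c("CB","CG"), N = c("ND2"),
           H = c(HB2="CB",HB3="CB",HD21="ND2",HD22="ND2")),
  D = list(C = c("CB","CG"), H = c(HB2="CB",HB3="CB")),
  C = list(C = c("CB"), H = c(HB2="CB",HB3="CB")),
  E = list(C = c("CB","CG","CD"), H = c(HB2="CB",HB3="CB",HG2="CG",HG3="CG")),
  Q = list(C = c("CB","CG","CD"), N = c("NE2"),
           H = c(HB2="CB",HB3="CB",HG2="CG",HG3="CG",HE21="NE2",HE22="NE2")),
  G = list(),
  H = list(C = c("CB","CG","CD2","CE1"), N = c("ND1","NE2"),
           H = c(HB2="CB",HB3="CB",HD2="CD2",HE1="CE1")),
  I = list(C = c("CB","CG1","CG2","CD1"),
           H = c(HB="CB",HG12="CG1",HG13="CG1",
                 HG21="CG2",HG22="CG2",HG23="CG2",
                 HD11="CD1",HD12="CD1",HD13="CD1")),
  L = list(C = c("CB","CG","CD1","CD2"),
           H = c(HB2="CB",HB3="CB",HG="CG",
                 HD11="CD1",HD12="CD1",HD13="CD1",
                 HD21="CD2",HD22="CD2",HD23="CD2")),
  K = list(C = c("CB","CG","CD","CE"), N = c("NZ"),
           H = c(HB2="CB",HB3="CB",HG2="CG",HG3="CG",
                 HD2="CD",HD3="CD",HE2="CE",HE3="CE")),
  M = list(C = c("CB","CG","CE"),
           H = c(HB2="CB",HB3="CB",HG2="CG",HG3="CG",
                 HE1="CE",HE2="CE",HE3="CE")),
  F = list(C = c("CB","CG","CD1","CD2","CE1","CE2","CZ"),
           H = c(HB2="CB",HB3="CB",HD1="CD1",HD2="CD2",
                 HE1="CE1",HE2="CE2",HZ="CZ")),
  P = list(C = c("CB","CG","CD"),
           H = c(HB2="CB",HB3="CB",HG2="CG",HG3="CG",HD2="CD",HD3="CD")),
  S = list(C = c("CB"), H = c(HB2="CB",HB3="CB")),
  T = list(C = c("CB","CG2"),
           H = c(HB="CB",HG21="CG2",HG22="CG2",HG23="CG2")),
  W = list(C = c("CB","CG","CD1","CD2","CE2","CE3","CZ2","CZ3","CH2"),
           N = c("NE1"),
           H = c(HB2="CB",HB3="CB",HD1="CD1",HE1="NE1",
                 HE3="CE3",HZ2="CZ2",HZ3="CZ3",HH2="CH2")),
  Y = list(C = c("CB","CG","CD1","CD2","CE1","CE2","CZ"),
           H = c(HB2="CB",HB3="CB",HD1="CD1",HD2="CD2",
                 HE1="CE1",HE2="CE2")),
  V = list(C = c("CB","CG1","CG2"),
           H = c(HB="CB",
                 HG11="CG1",HG12="CG1",HG13="CG1",
                 HG21="CG2",HG22="CG2",HG23="CG2"))
)

.buildAtomDefs <- function() {
  rows <- lapply(AA1, function(aa) {
    sc <- .sidechainDefs[[aa]]
    nm <- character(0); nuc <- character(0); partner <- character(0)
    add <- function(n, u, p) {
      nm <<- c(nm, n); nuc <<- c(nuc, u); partner <<- c(partner, p)
    }
    add("N", "15N", NA_character_)
    if (aa != "P") add("H", "1H", "N")
    add("CA", "13C", NA_character_)
    if (aa == "G") {
      add("HA2", "1H", "CA"); add("HA3", "1H", "CA")
    } else {
      add("HA", "1H", "CA")
    }
    add("C", "13C", NA_character_)
    for (cn in sc$C) add(cn, "13C", NA_character_)
    for (nn in sc$N) add(nn, "15N", NA_character_)
    if (!is.null(sc$H))
      for (i in seq_along(sc$H))
        add(names(sc$H)[i], "1H", unname(sc$H[i]))
    data.frame(residue_type = aa, atom_name = nm, nucleus = nuc,
               partner = partner, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.atomDefsCache <- new.env(parent = emptyenv())

#' Expected-atom table
#'
#' Returns the packaged table of assignable atoms per residue type, with the
#' bonded heavy-atom partner for every proton (used by the C13-HSQC and
#' NOESY peak templates).
#'
#' @return data.frame with columns residue_type, atom_name, nucleus, partner.
#' @export
#' @examples
#' head(atomDefs())
atomDefs <- function() {
  if (is.null(.atomDefsCache$defs)) .atomDefsCache$defs <- .buildAtomDefs()
  .atomDefsCache$defs
}

#' Expected atoms of a protein sequence
#'
#' Enumerates every assignable atom of a protein: the cross product of the
#' sequence with the per-residue expected-atom set.
#'
#' @param sequence character scalar of 1-letter residue codes.
#' @return data.frame with columns residue_index, residue_type, atom_name,
#'   nucleus, partner.
#' @export
#' @examples
#' nrow(expectedAtoms("GAV"))
expectedAtoms <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  if (length(res) == 0L) stop("empty sequence")
  unknown <- setdiff(res, c(AA1, "X"))
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "))
  defs <- atomDefs()
  out <- lapply(seq_along(res), function(i) {
    if (res[i] == "X") return(NULL)
    d <- defs[defs$residue_type == res[i], , drop = FALSE]
    rownames(d) <- NULL
    cbind(residue_index = i, d)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("residue_index", "residue_type", "atom_name", "nucleus", "partner")]
}

#' Backbone atom names
#'
#' The fixed backbone partition used for accuracy breakdowns:
#' N, H, CA, HA (HA2/HA3 for glycine), C and CB.
#' @return character vector.
#' @export
backboneAtoms <- function() c("N","H","CA","HA","HA2","HA3","C","CB")

#' Amide NH atom names
#' @return character vector.
#' @export
amideAtoms <- function() c("N", "H")
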