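#' @useDynLib cstransfer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif rpois setNames
#' @importFrom utils read.table write.table
NULL

NUCLEI <- c("1H", "13C", "15N")

# matching-tolerance / search-space floor presets (ppm), keyed by nucleus.
# 0.04/0.4 is the random-perturbation & idealized-transfer convention,
# 0.03/0.4 the structure-perturbation & homolog-selection convention.
FLOORS_RANDOM <- c("1H" = 0.04, "13C" = 0.4, "15N" = 0.4)
FLOORS_STRUCT <- c("1H" = 0.03, "13C" = 0.4, "15N" = 0.4)

AA1 <- c("A","R","N","D","C","E","Q","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

AA3TO1 <- c(ALA="A", ARG="R", ASN="N", ASP="D", CYS="C", GLU="E", GLN="Q",
            GLY="G", HIS="H", ILE="I", LEU="L", LYS="K", MET="M", PHE="F",
            PRO="P", SER="S", THR="T", TRP="W", TYR="Y", VAL="V")

#' Infer the nucleus of an atom from its name
#'
#' The nucleus is taken from the first alphabetic character of the atom name
#' (H -> 1H, C -> 13C, N -> 15N).  Pseudo-atom prefixes Q and M are treated
#' as proton groups (1H).
#'
#' @param atomName character vector of atom names (e.g. "CA", "HB2", "N").
#' @return character vector of nucleus labels ("1H", "13C", "15N").
#' @export
#' @examples
#' inferNucleus(c("CA", "HB2", "N", "QB"))
inferNucleus <- function(atomName) {
  first <- substr(gsub("[^A-Za-z].*$", "", atomName), 1L, 1L)
  out <- character(length(atomName))
  out[first %in% c("H", "Q", "M")] <- "1H"
  out[first == "C"] <- "13C"
  out[first == "N"] <- "15N"
  bad <- out == ""
  if (any(bad))
    stop("cannot infer nucleus for atom name(s): ",
         paste(unique(atomName[bad]), collapse = ", "))
  out
}

#' Is an atom name a pseudo-atom (Q/M proton group)?
#' @param atomName character vector of atom names.
#' @return logical vector.
#' @export
isPseudoAtom <- function(atomName) {
  grepl("^[QM]", atomName) & !grepl("^MET|^M$", atomName)
}

# round-half-up (the perturbed-atom count round(p*N) must not use banker's
# rounding so that counts are exactly reproducible)
roundHalfUp <- function(x) floor(x + 0.5)

# derive a stage-specific sub-seed from a master seed; stays below 2^31
deriveSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1103L + 7919 * stage) %% 2147483647)
}

# evaluate `expr` under a temporary RNG seed, restoring RNG state afterwards
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a finite numeric scalar")
  if (positive && x <= 0)
    stop("'", name, "' must be > 0")
  invisible(x)
}

# normalize a per-nucleus named vector (tolerances, floors, jitter ...)
asNucleusVector <- function(x, name) {
  if (is.null(names(x)) && length(x) == 3L) names(x) <- NUCLEI
  if (!all(NUCLEI %in% names(x)))
    stop("'", name, "' must be named with ", paste(NUCLEI, collapse = ", "))
  x[NUCLEI]
}
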