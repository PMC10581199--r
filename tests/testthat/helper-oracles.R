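# Independent oracles and fixture builders shared across the test files.

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Independent affine-gap local-alignment oracle (three-state recurrence,
# written against the textbook definition: a gap of length L costs
# open + L * ext, local score floored at zero).  Kept separate from the
# package's alignment path, which goes through Biostrings.
oracleLocalScore <- function(s, t, mat = blosum62(), open = 10, ext = 0.5) {
  a <- strsplit(s, "")[[1]]; b <- strsplit(t, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in s (consumes t)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in t (consumes s)
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, E[i + 1, j] - ext)
    F[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, F[i, j + 1] - ext)
    H[i + 1, j + 1] <- max(0, H[i, j] + mat[a[i], b[j]],
                           E[i + 1, j + 1], F[i + 1, j + 1])
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# Exhaustive enumeration of every local alignment (start anywhere, any
# interleaving of match / insert / delete steps, affine gap costs); used on
# very short sequences to validate both the package and the recurrence
# oracle above.
enumLocalScore <- function(s, t, mat = blosum62(), open = 10, ext = 0.5) {
  a <- strsplit(s, "")[[1]]; b <- strsplit(t, "")[[1]]
  n <- length(a); m <- length(b)
  best <- 0
  rec <- function(i, j, sc, lastOp) {
    # candidate alignments end on a match column
    if (lastOp == "M") best <<- max(best, sc)
    if (i <= n && j <= m)
      rec(i + 1L, j + 1L, sc + mat[a[i], b[j]], "M")
    if (lastOp != "S") {   # gaps only inside an alignment
      if (j <= m) rec(i, j + 1L, sc - ext - if (lastOp == "I") 0 else open, "I")
      if (i <= n) rec(i + 1L, j, sc - ext - if (lastOp == "D") 0 else open, "D")
    }
  }
  for (i0 in seq_len(n)) for (j0 in seq_len(m)) rec(i0, j0, 0, "S")
  best
}

# tiny deterministic shift-list builder
makeShiftList <- function(idx, type, atom, shift) {
  ShiftList(data.frame(residue_index = idx, residue_type = type,
                       atom_name = atom, shift = shift,
                       stringsAsFactors = FALSE))
}

# small random shift list over real residue types/atoms
randomShiftList <- function(nRes = 10, seed = 1) {
  prot <- syntheticProtein(nRes, seed = seed)
  prot$shifts
}

testStats <- function() loadStatTable()

# fast engine parameters for unit-scale problems
fastParams <- function(replicates = 3L, ...) {
  engineParams(replicates = replicates, ...)
}
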