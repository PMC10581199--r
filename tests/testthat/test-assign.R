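# Engine-level tests run on small synthetic proteins with idealized search
# spaces so the generating truth is the known optimum.

mkProblem <- function(nRes = 10, seed = 20, cfg = simConfig(),
                      spaces = NULL, params = fastParams()) {
  prot <- syntheticProtein(nRes, seed = seed)
  peaks <- simulatePeakLists(prot$shifts, prot$sequence, cfg,
                             seed = seed + 1)
  if (is.null(spaces))
    spaces <- idealizedSpaces(prot$sequence, prot$shifts, testStats())
  list(prot = prot, peaks = peaks,
       problem = prepareAssignment(prot$sequence, peaks, spaces, params,
                                   cfg))
}

test_that("initialization matches compatible peaks and is seed-deterministic", {
  fx <- mkProblem()
  st <- initializeAssignment(fx$problem, seed = 1)
  expect_gt(sum(!is.na(st$match)), 0.9 * nrow(fx$problem$expAtoms))
  st2 <- initializeAssignment(fx$problem, seed = 1)
  expect_identical(st, st2)
  st3 <- initializeAssignment(fx$problem, seed = 2)
  expect_false(identical(st$match, st3$match))
  # zero measured peaks -> everything unmatched
  empty <- lapply(fx$peaks, function(p)
    PeakList(spectrumType(p), matrix(numeric(), 0, ncol(peakCoords(p)))))
  pe <- prepareAssignment(fx$prot$sequence, empty,
                          idealizedSpaces(fx$prot$sequence, fx$prot$shifts,
                                          testStats()), fastParams())
  stE <- initializeAssignment(pe, seed = 1)
  expect_true(all(is.na(stE$match)))
})

test_that("one compatible measured peak is matched to its expected peak", {
  prot <- syntheticProtein(4, seed = 30)
  s <- shiftTable(prot$shifts)
  h2 <- s$shift[s$residue_index == 2 & s$atom_name == "H"]
  n2 <- s$shift[s$residue_index == 2 & s$atom_name == "N"]
  pl <- list(N15_HSQC = PeakList("N15_HSQC", matrix(c(h2, n2), 1)))
  pr <- prepareAssignment(prot$sequence, pl,
                          idealizedSpaces(prot$sequence, prot$shifts,
                                          testStats()), fastParams())
  st <- initializeAssignment(pr, seed = 1)
  matched <- which(!is.na(st$match))
  a <- pr$expAtoms[matched, ] + 1L
  expect_equal(length(matched), 1L)
  expect_equal(pr$atoms$residue_index[a[1]], 2L)
})

test_that("the score rewards exact center matches and penalizes empties", {
  fx <- mkProblem(nRes = 6, cfg = local({
    cfg <- simConfig(); cfg$jitter[] <- 0; cfg
  }))
  st <- optimizeAssignment(fx$problem, initializeAssignment(fx$problem, 7),
                           seed = 8)
  # noiseless: every matched peak sits exactly at its search-space center
  expect_true(all(!is.na(st$match)))
  expect_equal(st$score, sum(!is.na(st$match)), tolerance = 1e-9)
  emptyState <- list(match = rep(NA_integer_, nrow(fx$problem$expAtoms)))
  expect_equal(scoreAssignment(fx$problem, emptyState),
               -fx$problem$params$lambda)
})

test_that("swaps that reduce deviation strictly increase the score", {
  # two amide expected peaks, two measured peaks at the true positions;
  # crossed assignment is within windows but off-center
  sl <- makeShiftList(c(2L, 2L, 3L, 3L), c("A", "A", "A", "A"),
                      c("H", "N", "H", "N"),
                      c(8.30, 119.0, 8.35, 119.2))
  pl <- list(N15_HSQC = PeakList("N15_HSQC",
                                 matrix(c(8.30, 119.0, 8.35, 119.2), 2,
                                        byrow = TRUE)))
  spaces <- idealizedSpaces("GAAG", sl, testStats())
  pr <- prepareAssignment("GAAG", pl, spaces, fastParams())
  expect_equal(nrow(pr$expAtoms), 3L)  # amides 2..4; residue 4 unassigned
  iPk <- order(pr$atoms$residue_index[pr$expAtoms[, 1] + 1L])[1:2]
  co <- pr$coords
  straight <- rep(NA_integer_, 3L)
  crossed <- rep(NA_integer_, 3L)
  # identify which measured row is which by first coordinate
  m1 <- which(abs(co[, 1] - 8.30) < 1e-9)
  m2 <- which(abs(co[, 1] - 8.35) < 1e-9)
  straight[iPk] <- c(m1, m2); crossed[iPk] <- c(m2, m1)
  sStraight <- scoreAssignment(pr, list(match = straight))
  sCrossed <- scoreAssignment(pr, list(match = crossed))
  expect_gt(sStraight, sCrossed)
})

test_that("optimization never lowers the score and respects hard windows", {
  fx <- mkProblem(nRes = 12, cfg = simConfig(missingProb = 0.1,
                                             artifactRate = 0.3))
  st0 <- initializeAssignment(fx$problem, seed = 3)
  stO <- optimizeAssignment(fx$problem, st0, seed = 4)
  expect_gte(stO$score, st0$score)
  expect_equal(windowViolations(fx$problem, st0), 0L)
  expect_equal(windowViolations(fx$problem, stO), 0L)
  # zero iterations leave the state unchanged
  stZ <- optimizeAssignment(fx$problem, st0, seed = 4, iters = 0L)
  expect_equal(stZ$match, st0$match)
})

test_that("results are invariant to measured-peak input order", {
  prot <- syntheticProtein(8, seed = 33)
  cfg <- simConfig(missingProb = 0.1, artifactRate = 0.2)
  peaks <- simulatePeakLists(prot$shifts, prot$sequence, cfg, seed = 2)
  shuffled <- lapply(peaks, function(p) {
    co <- peakCoords(p)
    set.seed(99)
    PeakList(spectrumType(p), co[sample(nrow(co)), , drop = FALSE])
  })
  spaces <- idealizedSpaces(prot$sequence, prot$shifts, testStats())
  a <- assignShifts(prot$sequence, peaks, spaces, seed = 5,
                    params = fastParams())
  b <- assignShifts(prot$sequence, shuffled, spaces, seed = 5,
                    params = fastParams())
  expect_equal(consensusTable(a), consensusTable(b))
})

test_that("consensus clusters replicate values and flags strong support", {
  atoms <- data.frame(residue_index = 1L, residue_type = "A",
                      atom_name = "HA", nucleus = "1H")
  identical10 <- replicate(10, 4.2, simplify = FALSE)
  c1 <- consensusAssignment(identical10, atoms, tol = 0.04, sMin = 0.8)
  expect_equal(consensusTable(c1)$support, 1.0)
  expect_true(consensusTable(c1)$strong)
  # two replicates disagreeing beyond tolerance: support 0.5, not strong
  c2 <- consensusAssignment(list(4.2, 5.0), atoms, tol = 0.04, sMin = 0.8)
  expect_equal(consensusTable(c2)$support, 0.5)
  expect_false(consensusTable(c2)$strong)
  # 7 at 4.20 +- 0.005, 3 at 3.1 -> consensus near 4.20, support 0.7
  vals <- c(4.195, 4.198, 4.200, 4.201, 4.202, 4.204, 4.205, 3.1, 3.1, 3.1)
  c3 <- consensusAssignment(as.list(vals), atoms, tol = 0.04, sMin = 0.8)
  expect_equal(consensusTable(c3)$shift, mean(vals[1:7]), tolerance = 1e-9)
  expect_equal(consensusTable(c3)$support, 0.7)
  # support is always a multiple of 1/R
  expect_true(consensusTable(c3)$support * 10 == round(
    consensusTable(c3)$support * 10))
  # a single replicate is its own consensus
  c4 <- consensusAssignment(list(2.5), atoms, tol = 0.04, sMin = 0.8)
  expect_equal(consensusTable(c4)$shift, 2.5)
  expect_equal(consensusTable(c4)$support, 1.0)
})

test_that("full assignment is deterministic under the master seed", {
  fx <- mkProblem(nRes = 8, seed = 40,
                  cfg = simConfig(missingProb = 0.1, artifactRate = 0.2))
  a <- assignShifts(fx$prot$sequence, fx$peaks,
                    idealizedSpaces(fx$prot$sequence, fx$prot$shifts,
                                    testStats()),
                    seed = 11, params = fastParams())
  b <- assignShifts(fx$prot$sequence, fx$peaks,
                    idealizedSpaces(fx$prot$sequence, fx$prot$shifts,
                                    testStats()),
                    seed = 11, params = fastParams())
  expect_identical(consensusTable(a), consensusTable(b))
  # replicate states respect the hard windows throughout
  pr <- attr(a, "problem")
  for (st in attr(a, "replicateStates"))
    expect_equal(windowViolations(pr, st), 0L)
})

test_that("shrinking search spaces toward the floors never hurts noiseless recovery", {
  stats <- testStats()
  cfg <- simConfig(); cfg$jitter[] <- 0
  for (seed in 1:3) {
    prot <- syntheticProtein(20, seed = 90 + seed)
    peaks <- simulatePeakLists(prot$shifts, prot$sequence, cfg, seed = seed)
    spNarrow <- idealizedSpaces(prot$sequence, prot$shifts, stats)
    wide <- spaceTable(spNarrow); wide$width <- wide$width * 10
    spWide <- SearchSpaceSet(wide)
    accN <- accuracy(assignShifts(prot$sequence, peaks, spNarrow,
                                  seed = 7, params = fastParams(),
                                  cfg = cfg),
                     prot$shifts)
    accW <- accuracy(assignShifts(prot$sequence, peaks, spWide,
                                  seed = 7, params = fastParams(),
                                  cfg = cfg),
                     prot$shifts)
    expect_gte(accN$overall, accW$overall)
  }
})
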