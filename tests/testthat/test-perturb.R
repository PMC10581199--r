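test_that("zero fraction or zero scale leaves the list unchanged", {
  stats <- testStats()
  sl <- randomShiftList(10, seed = 6)
  r0 <- randomPerturb(sl, stats, c = 0.5, p = 0, seed = 1)
  expect_equal(shiftTable(r0$perturbed), shiftTable(sl))
  expect_true(all(r0$sigmaPerAtom == 0))
  rc <- randomPerturb(sl, stats, c = 0, p = 1, seed = 1)
  expect_equal(shiftTable(rc$perturbed), shiftTable(sl))
})

test_that("exactly round(p*N) entries change, deterministically under the seed", {
  stats <- testStats()
  sl <- randomShiftList(10, seed = 6)
  n <- length(sl)
  for (p in c(0.2, 0.5, 1.0)) {
    r <- randomPerturb(sl, stats, c = 0.5, p = p, seed = 42)
    changed <- sum(shiftTable(r$perturbed)$shift != shiftTable(sl)$shift)
    expect_equal(changed, floor(p * n + 0.5))
    expect_equal(sum(r$sigmaPerAtom > 0), floor(p * n + 0.5))
    r2 <- randomPerturb(sl, stats, c = 0.5, p = p, seed = 42)
    expect_identical(shiftTable(r2$perturbed), shiftTable(r$perturbed))
  }
  # reported widths honor the floors
  r <- randomPerturb(sl, stats, c = 0.01, p = 1, seed = 1)
  s <- shiftTable(sl)
  expect_true(all(r$widthPerAtom >= cstFloors("random")[s$nucleus] - 1e-12))
})

test_that("a missing statistics entry for a selected atom is a key error", {
  rec <- statRecords(testStats())
  rec <- rec[!(rec$residue_type == "A" & rec$atom_name == "CA"), ]
  sl <- makeShiftList(1L, "A", "CA", 52.4)
  expect_error(randomPerturb(sl, StatTable(rec), c = 1, p = 1, seed = 1),
               "\\(A, CA\\)")
})

test_that("decay factors are normalized step-function counts", {
  # one center, residue within cutoff
  st <- StructureCoords(data.frame(residue_index = 1:2, atom_name = "N",
                                   x = c(0, 3), y = 0, z = 0))
  e <- decayFactors(st, centers = 1L, x0 = 5)
  expect_equal(unname(e), c(1, 1))  # both within 5 A; center itself d = 0
  # residue beyond the cutoff decays to zero
  st2 <- StructureCoords(data.frame(residue_index = 1:2, atom_name = "N",
                                    x = c(0, 30), y = 0, z = 0))
  e2 <- decayFactors(st2, centers = 1L, x0 = 5)
  expect_equal(unname(e2), c(1, 0))
  expect_true(all(e2 >= 0 & e2 <= 1))
  expect_error(decayFactors(st2, centers = 99L, x0 = 5), "99")
})

test_that("structure perturbation reports floored widths and zero-sigma identity", {
  stats <- testStats()
  prot <- syntheticProtein(10, seed = 8)
  st <- prot$structure
  # centers far away from every residue: nothing perturbed
  far <- StructureCoords(rbind(coordTable(st),
                               data.frame(residue_index = 99L,
                                          atom_name = "N", x = 1e4,
                                          y = 1e4, z = 1e4)))
  res <- structurePerturb(prot$shifts, stats, far, centers = 99L, x0 = 5,
                          c = 1, seed = 3)
  expect_equal(shiftTable(res$perturbed), shiftTable(prot$shifts))
  expect_true(all(res$sigmaPerAtom == 0))
  # widths fall back to the 0.03 / 0.4 floors for unperturbed atoms
  s <- shiftTable(prot$shifts)
  expect_equal(unname(res$widthPerAtom),
               unname(cstFloors("structure")[s$nucleus]))
  # a 1H atom with tiny sigma still reports the 0.03 ppm floor
  resN <- structurePerturb(prot$shifts, stats, st, centers = 1L, x0 = 1e-3,
                           c = 1e-4, seed = 3)
  hAtoms <- s$nucleus == "1H"
  expect_true(all(resN$widthPerAtom[hAtoms] >= 0.03))
})

test_that("maximum-decay residues match the random-mode sigma", {
  stats <- testStats()
  prot <- syntheticProtein(10, seed = 8)
  # x0 large enough that every residue is within cutoff of the center
  res <- structurePerturb(prot$shifts, stats, prot$structure, centers = 5L,
                          x0 = 1e6, c = 0.5, seed = 11)
  expect_true(all(res$decayPerResidue == 1))
  rnd <- randomPerturb(prot$shifts, stats, c = 0.5, p = 1, seed = 11)
  expect_equal(res$sigmaPerAtom, rnd$sigmaPerAtom)
})

test_that("sampled structure specs stay in the published ranges and repeat under a seed", {
  st <- syntheticHelixCoords(40)
  specs <- sampleStructureSpecs(st, 50, seed = 19)
  x0 <- vapply(specs, `[[`, numeric(1), "x0")
  nG <- vapply(specs, function(s) length(s$centers), integer(1))
  expect_true(all(x0 >= 5 & x0 <= 25))
  expect_true(all(nG >= 1 & nG <= 10))
  expect_true(all(vapply(specs, function(s)
    !anyDuplicated(s$centers), logical(1))))
  specs2 <- sampleStructureSpecs(st, 50, seed = 19)
  expect_identical(specs, specs2)
  # short protein caps the number of centers
  tiny <- syntheticHelixCoords(3)
  specsT <- sampleStructureSpecs(tiny, 30, seed = 2)
  expect_true(all(vapply(specsT, function(s) length(s$centers),
                         integer(1)) <= 3))
})

test_that("residues lacking amide-N coordinates inherit zero decay with a warning", {
  stats <- testStats()
  prot <- syntheticProtein(6, seed = 12)
  co <- coordTable(prot$structure)
  st <- StructureCoords(co[co$residue_index != 3L, ])
  expect_warning(
    res <- structurePerturb(prot$shifts, stats, st, centers = 1L, x0 = 1e6,
                            c = 1, seed = 5),
    "decay 0")
  s <- shiftTable(res$perturbed)
  orig <- shiftTable(prot$shifts)
  expect_equal(s$shift[s$residue_index == 3L],
               orig$shift[orig$residue_index == 3L])
})
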