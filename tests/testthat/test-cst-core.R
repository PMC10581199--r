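test_that("transferred width is the floor when the perturbation sigma is tiny", {
  stats <- testStats()
  seqT <- "AG"
  ref <- makeShiftList(1L, "A", "HA", 4.21)
  sigma <- c("1.HA" = 0.01)
  sp <- buildSearchSpaces(seqT, ref, stats, cstConfig(cCst = 1),
                          perAtomSigma = sigma)
  row <- spaceTable(sp)
  ha <- row[row$residue_index == 1 & row$atom_name == "HA", ]
  expect_equal(ha$center, 4.21)
  expect_equal(ha$width, 0.04)       # 1H floor binds
  expect_equal(ha$provenance, "transferred")
})

test_that("fixed-width mode applies 0.09 / 1.2 ppm uniformly to transferred atoms", {
  stats <- testStats()
  prot <- syntheticProtein(8, seed = 2)
  cfg <- cstConfig(fixedWidths = c("1H" = 0.09, "13C" = 1.2, "15N" = 1.2))
  sp <- spaceTable(buildSearchSpaces(prot$sequence, prot$shifts, stats, cfg))
  tr <- sp[sp$provenance == "transferred", ]
  expect_true(all(tr$width[tr$nucleus == "1H"] == 0.09))
  expect_true(all(tr$width[tr$nucleus != "1H"] == 1.2))
})

test_that("atoms absent from the transfer fall back to statistics", {
  stats <- testStats()
  ref <- makeShiftList(1L, "A", "HA", 4.21)
  sp <- spaceTable(buildSearchSpaces("AG", ref, stats, cstConfig(cCst = 1)))
  ca <- sp[sp$residue_index == 1 & sp$atom_name == "CA", ]
  want <- statLookup(stats, "A", "CA")
  expect_equal(ca$center, unname(want["mean"]))
  expect_equal(ca$width, unname(want["std"]))
  expect_equal(ca$provenance, "stats")
})

test_that("cCst widths compose with the floors", {
  # 13C atom with std 0.3 at cCst = 1 -> width max(0.4, 0.3) = 0.4
  stats <- StatTable(rbind(statRecords(testStats()),
                           data.frame(residue_type = "A", atom_name = "CQ9",
                                      mean = 55, std = 0.3)))
  # use a real atom name so the expected-atom set picks it up: override CA
  rec <- statRecords(testStats())
  rec$std[rec$residue_type == "A" & rec$atom_name == "CA"] <- 0.3
  stats <- StatTable(rec)
  ref <- makeShiftList(1L, "A", "CA", 52.0)
  sp <- spaceTable(buildSearchSpaces("AG", ref, stats, cstConfig(cCst = 1)))
  ca <- sp[sp$residue_index == 1 & sp$atom_name == "CA", ]
  expect_equal(ca$width, 0.4)
  # and with a larger std the scaled width wins
  rec$std[rec$residue_type == "A" & rec$atom_name == "CA"] <- 2.5
  sp2 <- spaceTable(buildSearchSpaces("AG", ref, StatTable(rec),
                                      cstConfig(cCst = 0.5)))
  expect_equal(sp2[sp2$residue_index == 1 & sp2$atom_name == "CA", "width"],
               1.25)
})

test_that("search spaces always cover the expected-atom set with width >= floor", {
  stats <- testStats()
  for (seed in 1:3) {
    prot <- syntheticProtein(12, seed = seed)
    nAtoms <- nrow(expectedAtoms(prot$sequence))
    # partial transfer: drop half the shifts
    s <- shiftTable(prot$shifts)
    part <- ShiftList(s[seq(1, nrow(s), by = 2), ])
    for (cfg in list(cstConfig(cCst = 0.2), cstConfig(cCst = 1),
                     cstConfig(fixedWidths = c("1H" = .09, "13C" = 1.2,
                                               "15N" = 1.2)))) {
      sp <- spaceTable(buildSearchSpaces(prot$sequence, part, stats, cfg))
      expect_equal(nrow(sp), nAtoms)
      tr <- sp$provenance == "transferred"
      expect_true(all(sp$width[tr] >= cfg$floors[sp$nucleus[tr]] - 1e-12))
      expect_true(all(sp$width > 0))
    }
  }
})

test_that("idealized spaces equal a zero-sigma transfer of the reference", {
  stats <- testStats()
  prot <- syntheticProtein(10, seed = 4)
  a <- idealizedSpaces(prot$sequence, prot$shifts, stats)
  sigma <- setNames(rep(0, length(prot$shifts)),
                    paste(shiftTable(prot$shifts)$residue_index,
                          shiftTable(prot$shifts)$atom_name, sep = "."))
  b <- buildSearchSpaces(prot$sequence, prot$shifts, stats,
                         cstConfig(cCst = 1), perAtomSigma = sigma)
  expect_equal(spaceTable(a), spaceTable(b))
  tr <- spaceTable(a)$provenance == "transferred"
  expect_true(all(spaceTable(a)$width[tr] %in% c(0.04, 0.4)))
  # reference CA center at its true shift with the 0.4 ppm floor width
  s <- shiftTable(prot$shifts)
  caKey <- which(s$atom_name == "CA")[1]
  row <- spaceTable(a)
  got <- row[row$residue_index == s$residue_index[caKey] &
               row$atom_name == "CA", ]
  expect_equal(got$center, s$shift[caKey])
  expect_equal(got$width, 0.4)
  # an empty reference collapses to the all-statistics set
  empty <- idealizedSpaces(prot$sequence, ShiftList(), stats)
  expect_true(all(spaceTable(empty)$provenance == "stats"))
})

test_that("config validation enforces the one-active-mode rule", {
  expect_error(cstConfig(), "exactly one")
  expect_error(cstConfig(cCst = 1, fixedWidths = c("1H" = .1, "13C" = 1,
                                                   "15N" = 1)),
               "exactly one")
  expect_error(cstConfig(cCst = -1), "> 0")
  expect_error(cstConfig(cCst = 1, floors = c("1H" = 0, "13C" = .4,
                                              "15N" = .4)), "> 0")
})
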