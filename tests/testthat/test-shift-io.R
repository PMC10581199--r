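test_that("a one-row TSV maps directly onto ShiftList fields", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("5 A CA 52.4", f)
  sl <- readShiftList(f)
  s <- shiftTable(sl)
  expect_equal(nrow(s), 1L)
  expect_equal(s$residue_index, 5L)
  expect_equal(s$atom_name, "CA")
  expect_equal(s$nucleus, "13C")
  expect_equal(s$shift, 52.4)
})

test_that("shift lists round-trip through TSV", {
  sl <- randomShiftList(8, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeShiftList(sl, f)
  back <- readShiftList(f)
  expect_equal(shiftTable(back)$atom_name, shiftTable(sl)$atom_name)
  expect_equal(shiftTable(back)$shift, shiftTable(sl)$shift,
               tolerance = 1e-4)
})

test_that("NMR-STAR shift loops across saveframes match the equivalent TSV", {
  fixture <- data.frame(
    residue_index = c(1L, 1L, 2L, 2L),
    residue_type = c("M", "M", "K", "K"),
    atom_name = c("CA", "HA", "CA", "N"),
    shift = c(55.21, 4.18, 56.33, 120.42))
  star <- c(
    "data_test",
    "save_shifts_part1",
    "loop_",
    "  _Atom_chem_shift.ID",
    "  _Atom_chem_shift.Seq_ID",
    "  _Atom_chem_shift.Comp_ID",
    "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Val",
    "  1 1 MET CA 55.21",
    "  2 1 MET HA 4.18",
    "stop_",
    "save_",
    "save_shifts_part2",
    "loop_",
    "  _Atom_chem_shift.ID",
    "  _Atom_chem_shift.Seq_ID",
    "  _Atom_chem_shift.Comp_ID",
    "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Val",
    "  3 2 LYS CA 56.33",
    "  4 2 LYS N 120.42",
    "stop_",
    "save_")
  fStar <- withr::local_tempfile(fileext = ".str")
  writeLines(star, fStar)
  fTsv <- withr::local_tempfile(fileext = ".tsv")
  writeShiftList(ShiftList(fixture), fTsv)
  expect_equal(shiftTable(readShiftList(fStar, "nmrstar")),
               shiftTable(readShiftList(fTsv)), tolerance = 1e-6)
})

test_that("malformed and duplicate shift rows are rejected with context", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1 A CA 52.4", "2 G xx"), f)
  expect_error(readShiftList(f), "line 2")
  writeLines(c("1 A CA 52.4", "1 A CA 52.9"), f)
  expect_error(readShiftList(f), "duplicate")
})

test_that("search-space statistics files round-trip at 4 decimals", {
  set.seed(42)
  n <- 1000L
  atoms <- expectedAtoms(paste(rep("AKVLSE", 30), collapse = ""))[1:n, ]
  spaces <- SearchSpaceSet(data.frame(
    residue_index = atoms$residue_index, residue_type = atoms$residue_type,
    atom_name = atoms$atom_name, center = runif(n, 0, 150),
    width = runif(n, 1e-4, 5),
    provenance = sample(c("transferred", "stats"), n, replace = TRUE)))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeShiftStatistics(spaces, f)
  back <- readShiftStatistics(f)
  expect_equal(spaceTable(back)$provenance, spaceTable(spaces)$provenance)
  expect_true(all(abs(spaceTable(back)$width - spaceTable(spaces)$width)
                  < 1e-4))
  expect_true(all(abs(spaceTable(back)$center - spaceTable(spaces)$center)
                  < 1e-4))
  expect_error(writeShiftStatistics(SearchSpaceSet(
    data.frame(residue_index = integer(), residue_type = character(),
               atom_name = character(), center = numeric(),
               width = numeric(), provenance = character())), f),
    "empty")
})

test_that("peak lists round-trip and enforce the dimension contract", {
  co <- matrix(runif(1000 * 3, 0, 10), ncol = 3)
  pl <- PeakList("N15_NOESY", co,
                 tags = c(rep("1.H|2.H|2.N", 500), rep(NA_character_, 500)))
  f <- withr::local_tempfile(fileext = ".tsv")
  writePeakList(pl, f)
  back <- readPeakList(f, "N15_NOESY")
  expect_equal(peakCoords(back), peakCoords(pl), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(peakTags(back), peakTags(pl))
  # a 3-dim file read as a 2-dim spectrum is a contract violation
  expect_error(readPeakList(f, "N15_HSQC"), "expected 2 coordinates")
  # 2-column file under N15_HSQC gives 2-dim peaks
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("8.1 120.2", "7.9 118.4"), f2)
  expect_equal(dim(peakCoords(readPeakList(f2, "N15_HSQC"))), c(2L, 2L))
  expect_error(PeakList("N15_HSQC", co), "coordinates")
})

test_that("nucleus inference covers every packaged atom name and flags pseudo-atoms", {
  defs <- atomDefs()
  expect_equal(inferNucleus(defs$atom_name), defs$nucleus)
  expect_true(all(isPseudoAtom(c("QB", "QD1", "MB"))))
  expect_false(any(isPseudoAtom(c("CA", "HB2", "N"))))
  expect_error(inferNucleus("XX"), "cannot infer")
})
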