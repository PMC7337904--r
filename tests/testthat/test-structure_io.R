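test_that("PDB round-trip preserves atoms, categories and coordinates", {
  m <- build_fiber_duplex(CRYSTAL_SEQ, fiber_spec("A"))
  f <- tempfile(fileext = ".pdb")
  write_structure(m, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(m2$atoms$atom, m$atoms$atom)
  expect_equal(m2$atoms$resid, m$atoms$resid)
  expect_equal(m2$atoms$category, m$atoms$category)
  expect_equal(as.matrix(m2$atoms[, c("x", "y", "z")]),
               as.matrix(m$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  unlink(f)
})

test_that("mmCIF round-trip preserves the model", {
  m <- build_fiber_duplex("GGACC", fiber_spec("B"), hybrid = "strand2_rna")
  f <- tempfile(fileext = ".cif")
  write_structure(m, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(m2$atoms$atom, m$atoms$atom)
  expect_equal(m2$atoms$category, m$atoms$category)
  expect_equal(as.matrix(m2$atoms[, c("x", "y", "z")]),
               as.matrix(m$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  unlink(f)
})

test_that("CRYST1 cell parameters and space group are captured", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
            37.1, 116.2, 56.8, 90, 102.9, 90, "P 1 21 1"),
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_equal(m$cell, c(37.1, 116.2, 56.8, 90, 102.9, 90))
  expect_equal(m$space_group, "P 1 21 1")
  expect_equal(nrow(m$atoms), 1L)
  unlink(f)
})

test_that("one-atom model writes one ATOM record and re-reads identically", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1      12.345  -6.789   0.001  1.00 10.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 1L)
  f2 <- tempfile(fileext = ".pdb")
  write_structure(m, f2)
  m2 <- read_structure(f2)
  expect_equal(as.numeric(m2$atoms[1, c("x", "y", "z")]),
               c(12.345, -6.789, 0.001), tolerance = 1e-3)
  expect_equal(sum(grepl("^ATOM", readLines(f2))), 1L)
  unlink(c(f, f2))
})

test_that("unreadable and empty inputs give informative errors", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(read_structure(f), "empty structure")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
  m <- build_fiber_duplex("GT", fiber_spec("B"))
  m$atoms <- m$atoms[0, ]
  expect_error(write_structure(m, tempfile(fileext = ".pdb")), "empty")
  unlink(f)
})

test_that("residue classification covers RNA, DNA, protein, water, metal", {
  res <- function(atoms, resid, elems = substr(atoms, 1, 1)) {
    data.frame(chain = "A", resno = 1, insert = "", resid = resid,
               atom = atoms, elem = elems, stringsAsFactors = FALSE)
  }
  expect_equal(classify_residue(res(c("O2'", "C1'", "N1"), "C")), "RNA")
  expect_equal(classify_residue(res(c("C1'", "O4'", "N9", "C8"), "DA")), "DNA")
  expect_equal(classify_residue(res(c("N", "CA", "C", "O"), "ALA")), "protein")
  expect_equal(classify_residue(res("O", "HOH")), "water")
  expect_equal(classify_residue(res("CA", "CA", elems = "CA")), "metal")
  expect_equal(classify_residue(res("C1", "LIG")), "other")
  empty <- res("C1", "LIG")[0, , drop = FALSE]
  expect_error(classify_residue(empty), "no atoms")
})

test_that("classification is total: category counts sum to residue count", {
  m <- build_fiber_duplex(CRYSTAL_SEQ, fiber_spec("A"), hybrid = "strand1_rna")
  m <- place_probes(m, data.frame(chain = "B", resno = 3, clash = 0))
  per_res <- m$atoms$category[!duplicated(m$atoms$res_uid)]
  expect_equal(length(per_res), length(unique(m$atoms$res_uid)))
  expect_true(all(per_res %in% c("DNA", "RNA", "protein", "water", "metal",
                                 "other")))
  expect_equal(sum(table(per_res)), length(per_res))
})

test_that("Bondi radii are assigned with a warned default for unknowns", {
  m <- build_fiber_duplex("GTAG", fiber_spec("B"))
  m$atoms$elem[1] <- "XX"
  expect_warning(m2 <- assign_radii(m), "unknown element")
  a <- m2$atoms
  expect_equal(unique(a$vdw[a$elem == "C"]), 1.70)
  expect_equal(unique(a$vdw[a$elem == "O"]), 1.52)
  expect_equal(unique(a$vdw[a$elem == "P"]), 1.80)
  expect_equal(a$vdw[1], 1.70)  # default
})

test_that("highest-occupancy altloc conformer is kept, ties by identifier", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       5.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AGLY A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BGLY A   1       6.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$x[m$atoms$atom == "CA"], 5.0)  # occupancy 0.6 wins
  expect_equal(m$atoms$x[m$atoms$atom == "CB"], 1.0)  # tie: altloc A wins
  m_b <- read_structure(f, altloc = "B")
  expect_equal(m_b$atoms$x, c(5, 6))
  unlink(f)
})
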