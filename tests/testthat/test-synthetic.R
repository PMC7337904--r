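test_that("fiber builds validate their sequence input", {
  expect_error(build_fiber_duplex("G", fiber_spec("B")), "sequence error")
  expect_error(build_fiber_duplex("GXT", fiber_spec("B")), "sequence error")
  expect_error(build_fiber_duplex("GUT", fiber_spec("B")), "sequence error")
  expect_silent(build_fiber_duplex("GUU", fiber_spec("A"),
                                   hybrid = "strand1_rna"))
  expect_error(fiber_spec("B", rise = -1), "rise")
  expect_error(fiber_spec("B", twist = 75), "twist")
})

test_that("identical inputs give bit-identical coordinates", {
  m1 <- build_fiber_duplex(CRYSTAL_SEQ, fiber_spec("A"))
  m2 <- build_fiber_duplex(CRYSTAL_SEQ, fiber_spec("A"))
  expect_identical(m1$atoms, m2$atoms)
  p1 <- place_probes(m1, data.frame(chain = "A", resno = 5, clash = 0.4),
                     seed = 9)
  p2 <- place_probes(m2, data.frame(chain = "A", resno = 5, clash = 0.4),
                     seed = 9)
  expect_identical(p1$atoms, p2$atoms)
})

test_that("RNA strands carry O2' and U, DNA strands do not", {
  m <- build_fiber_duplex("GUAGGACCAUG", fiber_spec("A"),
                          hybrid = "strand1_rna")
  a <- m$atoms
  expect_true(all(a$category[a$chain == "A"] == "RNA"))
  expect_true(all(a$category[a$chain == "B"] == "DNA"))
  expect_true(any(a$atom[a$chain == "A"] == "O2'"))
  expect_false(any(a$atom[a$chain == "B"] == "O2'"))
  expect_true(any(a$resid[a$chain == "A"] == "U"))
  expect_false(any(a$resid[a$chain == "B"] == "DU"))
})

test_that("5'-terminal residues lack the phosphate group", {
  m <- build_fiber_duplex("GTAG", fiber_spec("B"))
  a <- m$atoms
  expect_false(any(a$atom[a$chain == "A" & a$resno == 1] %in%
                     c("P", "OP1", "OP2")))
  expect_true("P" %in% a$atom[a$chain == "A" & a$resno == 2])
  expect_false(any(a$atom[a$chain == "B" & a$resno == 1] %in%
                     c("P", "OP1", "OP2")))
})

test_that("strand-1 backbone is covalently continuous under the helix", {
  for (form in c("A", "B")) {
    m <- build_fiber_duplex("GTAGGA", fiber_spec(form))
    a <- m$atoms
    for (i in 1:5) {
      o3 <- as.numeric(a[a$chain == "A" & a$resno == i & a$atom == "O3'",
                         c("x", "y", "z")])
      p <- as.numeric(a[a$chain == "A" & a$resno == i + 1 & a$atom == "P",
                        c("x", "y", "z")])
      expect_equal(sqrt(sum((o3 - p)^2)), 1.60, tolerance = 0.05 / 1.6)
    }
  }
})

test_that("interpolation endpoints reproduce the pure forms exactly", {
  sa <- fiber_spec("A"); sb <- fiber_spec("B")
  m0 <- interpolate_conformation(sa, sb, 0, "GTAGGA")
  mB <- build_fiber_duplex("GTAGGA", sb)
  expect_identical(as.matrix(m0$atoms[, c("x", "y", "z")]),
                   as.matrix(mB$atoms[, c("x", "y", "z")]))
  m1 <- interpolate_conformation(sa, sb, 1, "GTAGGA")
  mA <- build_fiber_duplex("GTAGGA", sa)
  expect_equal(as.matrix(m1$atoms[, c("x", "y", "z")]),
               as.matrix(mA$atoms[, c("x", "y", "z")]), tolerance = 1e-12)
  expect_error(interpolate_conformation(sa, sb, 1.2, "GTAGGA"), "\\[0, 1\\]")
})

test_that("mid-interpolation Zp lies strictly between the endpoints", {
  sa <- fiber_spec("A"); sb <- fiber_spec("B")
  zp <- sapply(c(0, 0.5, 1), function(t) {
    mean(duplex_geometry(pair_bases(
      interpolate_conformation(sa, sb, t, "GTAGGACCA")))$steps$zp)
  })
  expect_gt(zp[2], zp[1])
  expect_lt(zp[2], zp[3])
})

test_that("generator output survives the io round-trip and re-pairs", {
  m <- build_fiber_duplex("GGACCA", fiber_spec("A"), hybrid = "strand2_rna")
  f <- tempfile(fileext = ".pdb")
  write_structure(m, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  d2 <- pair_bases(m2)
  expect_equal(nrow(d2$pairs), 6L)
  unlink(f)
})

test_that("probes are placed at the constructed clash distance", {
  m <- build_fiber_duplex(CRYSTAL_SEQ, fiber_spec("A"))
  pm <- place_probes(m, data.frame(chain = "A", resno = 6, clash = 0.7,
                                   element = "C"), seed = 2)
  tr <- attr(pm, "probes")
  expect_equal(tr$intended_clash, 0.7)
  ## by construction: |probe - O2'| = r_O2' + r_probe - clash
  res <- model_residue(pm, "A", 6)
  g <- graft_o2prime(res)
  pa <- pm$atoms[pm$atoms$chain == tr$chain & pm$atoms$resno == tr$resno, ]
  d <- sqrt(sum((g$o2prime_position - as.numeric(pa[, c("x", "y", "z")]))^2))
  expect_equal(d, 1.52 + 1.70 - 0.7, tolerance = 1e-9)
  expect_error(place_probes(m, data.frame(chain = "A", resno = 99, clash = 0)),
               "not found")
  expect_error(place_probes(m, data.frame(chain = "A", resno = 6, clash = -1)),
               ">= 0")
})
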