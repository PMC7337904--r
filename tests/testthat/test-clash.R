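test_that("pairwise clash is max(0, r_a + r_b - d)", {
  at <- function(x, r) list(x = x, y = 0, z = 0, vdw = r)
  expect_equal(pair_clash(at(0, 1.52), at(2.5, 1.70)), 0.72)
  expect_equal(pair_clash(at(0, 1.52), at(3.3, 1.70)), 0)
  expect_equal(pair_clash(at(0, 1.52), at(0, 1.52)), 3.04)
})

test_that("probe-oracle clashes are recovered to 1e-6", {
  m <- build_fiber_duplex(CRYSTAL_SEQ, fiber_spec("A"))
  pm <- assign_radii(place_probes(
    m, data.frame(chain = "A", resno = c(4, 6, 8), clash = c(0.7, 0.0, 1.2))))
  d <- pair_bases(pm)
  tab <- score_duplex(d, pm)
  expect_equal(tab$max_prot_1[tab$pos == 4], 0.7, tolerance = 1e-6)
  expect_equal(tab$max_prot_1[tab$pos == 6], 0.0, tolerance = 1e-6)
  expect_equal(tab$max_prot_1[tab$pos == 8], 1.2, tolerance = 1e-6)
  expect_true(tab$above_threshold[tab$pos == 8])
  expect_false(tab$above_threshold[tab$pos == 4])
})

test_that("a naked duplex has zero protein clash components", {
  d <- fixture_duplex("A")
  tab <- score_duplex(d)
  expect_true(all(tab$max_prot_1 == 0))
  expect_true(all(tab$max_prot_2 == 0))
  expect_true(all(tab$mean_cum_protein == 0))
  ## and the A-form accommodates 2'-OH: all clashes compensable
  expect_true(all(tab$max_1 <= 1.1))
  expect_true(all(tab$max_2 <= 1.1))
})

test_that("window neighbor search equals the exhaustive scan exactly", {
  set.seed(17)
  for (rep in 1:3) {
    n <- 5000
    atoms <- data.frame(
      chain = "Z", resno = seq_len(n), insert = "", resid = "LIG",
      atom = "C1", elem = sample(c("C", "N", "O", "P"), n, replace = TRUE),
      alt = "", x = runif(n, -20, 20), y = runif(n, -20, 20),
      z = runif(n, -20, 20), occ = 1, b = 0)
    model <- assign_radii(agraft:::new_structure_model(atoms))
    graft <- structure(list(chain = "A", resno = 0, insert = "",
                            res_uid = 0L,
                            o2prime_position = runif(3, -20, 20),
                            chirality_ok = TRUE, status = "ok"),
                       class = "graft_result")
    fast <- score_graft(graft, model, method = "window")
    slow <- score_graft(graft, model, method = "exhaustive")
    expect_identical(fast[c("max_clash", "cumulative_clash",
                            "max_clash_protein", "max_clash_nucleic",
                            "cumulative_protein", "cumulative_nucleic",
                            "worst_partner", "above_threshold")],
                     slow[c("max_clash", "cumulative_clash",
                            "max_clash_protein", "max_clash_nucleic",
                            "cumulative_protein", "cumulative_nucleic",
                            "worst_partner", "above_threshold")])
  }
})

test_that("clash values are invariant under rigid motion", {
  m <- build_fiber_duplex(CRYSTAL_SEQ, fiber_spec("A"))
  pm <- assign_radii(place_probes(
    m, data.frame(chain = "A", resno = 6, clash = 0.9)))
  t1 <- score_duplex(pair_bases(pm), pm)
  rig <- random_rigid(8)
  pm2 <- transform_model(pm, rig$R, rig$t)
  t2 <- score_duplex(pair_bases(pm2), pm2)
  expect_equal(t2$max_1, t1$max_1, tolerance = 1e-6)
  expect_equal(t2$cum_1, t1$cum_1, tolerance = 1e-6)
})

test_that("moving a probe closer along its ray never decreases max clash", {
  m <- build_fiber_duplex(CRYSTAL_SEQ, fiber_spec("A"))
  clashes <- seq(0, 1.2, 0.2)
  mx <- sapply(clashes, function(cl) {
    pm <- assign_radii(place_probes(
      m, data.frame(chain = "A", resno = 6, clash = cl)))
    tab <- score_duplex(pair_bases(pm), pm)
    tab$max_prot_1[tab$pos == 6]
  })
  expect_true(all(diff(mx) >= -1e-12))
})

test_that("strand means equal the mean of the per-strand values", {
  d <- fixture_duplex("B")
  tab <- score_duplex(d)
  expect_equal(tab$mean_max, (tab$max_1 + tab$max_2) / 2)
  expect_equal(tab$mean_cum, (tab$cum_1 + tab$cum_2) / 2)
  ## a palindromic ideal duplex has identical per-strand profiles
  dp <- fixture_duplex("B", "AGGACCGGTCCT")
  tp <- score_duplex(dp)
  expect_equal(tp$max_1, rev(tp$max_2), tolerance = 1e-6)
})

test_that("graft exclusion rules drop bonded atoms, hydrogens and solvent", {
  d <- fixture_duplex("B")
  uid <- d$pairs$i_uid[5]
  mask <- agraft:::clash_partner_mask(d$model, uid)
  a <- d$model$atoms
  own <- a$res_uid == uid
  expect_false(any(mask[own & a$atom %in% c("C1'", "C2'", "C3'")]))
  expect_true(all(mask[own & a$atom %in% c("O4'", "O3'", "C4'")]))
})
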