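test_that("superposition recovers known rigid transforms and stays proper", {
  pts <- standard_base("G")[, 1:3]
  fit0 <- superpose(pts, pts)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  for (seed in 1:5) {
    rig <- random_rigid(seed)
    mob <- t(rig$R %*% t(pts)) + matrix(rig$t, nrow(pts), 3, byrow = TRUE)
    fit <- superpose(pts, mob)
    expect_equal(fit$rotation, rig$R, tolerance = 1e-6)
    expect_equal(fit$translation, rig$t, tolerance = 1e-6)
    expect_lt(fit$rmsd, 1e-8)
  }
  ## mirror image of a chiral 3D set: proper rotation still returned,
  ## rmsd > 0 (no reflection allowed)
  set.seed(77)
  chiral <- matrix(rnorm(15, sd = 2), 5, 3)
  mir <- chiral %*% diag(c(-1, 1, 1))
  fitm <- superpose(chiral, mir)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-9)
  expect_gt(fitm$rmsd, 0.1)
  ## degenerate inputs
  expect_error(superpose(pts[1:2, ], pts[1:2, ]), "degenerate")
  lin <- cbind(1:5, 2 * (1:5), -1:3 * 0)
  expect_error(superpose(lin, lin), "collinear")
})

test_that("base frames are recovered exactly for templated bases", {
  for (b in c("A", "C", "G", "T", "U")) {
    rig <- random_rigid(match(b, c("A", "C", "G", "T", "U")))
    tmpl <- standard_base(b)
    xyz <- t(rig$R %*% t(tmpl)) + matrix(rig$t, nrow(tmpl), 3, byrow = TRUE)
    res <- data.frame(chain = "A", resno = 1, insert = "",
                      resid = if (b == "U") "U" else paste0("D", b),
                      atom = rownames(tmpl), elem = substr(rownames(tmpl), 1, 1),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    fr <- fit_base_frame(res)
    expect_equal(fr$axes, rig$R, tolerance = 1e-6)
    expect_equal(fr$origin, rig$t, tolerance = 1e-6)
    expect_lt(fr$rmsd, 1e-8)
  }
})

test_that("a purine with deleted ring atoms raises an incomplete-base error", {
  d <- fixture_duplex("B")
  res <- agraft:::residue_atoms(d$model, d$pairs$i_uid[4])
  res <- res[!(res$atom %in% c("N9", "C8")), ]
  expect_error(fit_base_frame(res), "incomplete base.*N9")
})

test_that("paired base frames have anti-aligned normals", {
  d <- fixture_duplex("B")
  for (k in c(1, 6, 11)) {
    fi <- fit_base_frame(agraft:::residue_atoms(d$model, d$pairs$i_uid[k]))
    fj <- fit_base_frame(agraft:::residue_atoms(d$model, d$pairs$j_uid[k]))
    expect_lt(sum(fi$axes[, 3] * fj$axes[, 3]), 0)
  }
})

test_that("step analysis round-trips the generator's helical parameters", {
  ## fixed forms at the printed values
  gB <- fixture_geometry("B")
  expect_equal(mean(gB$steps$helical_twist), 36.0, tolerance = 0.01 / 36)
  expect_equal(mean(gB$steps$helical_rise), 3.375, tolerance = 0.001 / 3.375)
  gA <- fixture_geometry("A")
  expect_equal(mean(gA$steps$helical_twist), 32.7, tolerance = 0.01 / 32.7)
  expect_equal(mean(gA$steps$helical_rise), 2.548, tolerance = 0.001 / 2.548)
  ## randomized fiber specifications across the physical range
  set.seed(3)
  for (rep in 1:4) {
    tw <- runif(1, 25, 40); ri <- runif(1, 2.6, 3.6)
    sp <- fiber_spec("custom", twist = tw, rise = ri,
                     x_disp = runif(1, -4, 1), inclination = runif(1, -7, 20),
                     templates = agraft:::load_form_templates("B"))
    g <- duplex_geometry(pair_bases(build_fiber_duplex("GATTACAGC", sp)))
    expect_equal(mean(g$steps$helical_twist), tw, tolerance = 0.1 / tw)
    expect_equal(mean(g$steps$helical_rise), ri, tolerance = 0.05 / ri)
    expect_equal(mean(g$steps$inclination), sp$inclination, tolerance = 0.05)
  }
})

test_that("strand reversal flips shift/tilt and preserves the rest", {
  ## jitter an ideal duplex so the step parameters are non-trivial
  m <- build_fiber_duplex("GTAGGAC", fiber_spec("B"))
  set.seed(21)
  m$atoms$x <- m$atoms$x + rnorm(nrow(m$atoms), sd = 0.05)
  m$atoms$y <- m$atoms$y + rnorm(nrow(m$atoms), sd = 0.05)
  m$atoms$z <- m$atoms$z + rnorm(nrow(m$atoms), sd = 0.05)
  d <- pair_bases(m)
  g <- duplex_geometry(d)
  g_rev <- duplex_geometry(agraft:::reverse_duplex(d))
  n <- nrow(g$steps)
  for (s in seq_len(n)) {
    fw <- g$steps[s, ]; bw <- g_rev$steps[n - s + 1, ]
    expect_equal(bw$shift, -fw$shift, tolerance = 1e-6)
    expect_equal(bw$tilt, -fw$tilt, tolerance = 1e-6)
    expect_equal(bw$slide, fw$slide, tolerance = 1e-6)
    expect_equal(bw$rise, fw$rise, tolerance = 1e-6)
    expect_equal(bw$roll, fw$roll, tolerance = 1e-6)
    expect_equal(bw$twist, fw$twist, tolerance = 1e-6)
  }
})

test_that("coincident frames give a degenerate-step error", {
  f <- list(origin = c(0, 0, 0), axes = diag(3))
  expect_error(step_parameters(f, f), "degenerate step")
})

test_that("Zp classifies every dinucleotide step of the ideal forms", {
  seq_all <- "AATACAGAGCCGCCA"  # covers all 10 distinct step types
  gA <- fixture_geometry("A", seq_all)
  gB <- fixture_geometry("B", seq_all)
  expect_gte(length(unique(c(gA$steps$dinucleotide))), 10L)
  expect_true(all(gA$steps$classification == "A"))
  expect_true(all(gB$steps$classification == "B"))
  expect_gt(mean(gA$steps$zp), 1.5)
  expect_lt(mean(gB$steps$zp), 0.5)
  ## thresholds are configurable
  expect_equal(classify_step(1.0), "intermediate")
  expect_equal(classify_step(1.0, zp_A = 0.9), "A")
})

test_that("Zp increases monotonically along the B-to-A interpolation", {
  sa <- fiber_spec("A"); sb <- fiber_spec("B")
  zp <- sapply(seq(0, 1, 0.2), function(t) {
    g <- duplex_geometry(pair_bases(
      interpolate_conformation(sa, sb, t, "GTAGGACCA")))
    mean(g$steps$zp)
  })
  expect_true(all(diff(zp) > 0))
})

test_that("pseudorotation identifies the form-defining sugar puckers", {
  gA <- fixture_geometry("A")
  expect_true(all(gA$bp$pucker_phase_1 >= 0 & gA$bp$pucker_phase_1 < 36))
  expect_true(all(gA$bp$pucker_conf_1 == "C3'-endo"))
  gB <- fixture_geometry("B")
  expect_true(all(gB$bp$pucker_phase_1 >= 144 & gB$bp$pucker_phase_1 < 180))
  expect_true(all(gB$bp$pucker_conf_1 == "C2'-endo"))
  expect_error(pseudorotation(c(0, 0, 0, 0, 0)), "planar")
  ## direct evaluation of a synthetic torsion set:
  ## nu_j = 38 cos(100 + 144 (j - 2)) must give P = 100, amplitude 38
  nus <- 38 * cos((100 + 144 * ((0:4) - 2)) * pi / 180)
  pk <- pseudorotation(nus)
  expect_equal(pk$phase, 100, tolerance = 1e-8)
  expect_equal(pk$amplitude, 38, tolerance = 1e-8)
  expect_equal(pk$conformer, "O4'-endo")
})

test_that("displacement definitions reproduce the ideal-form values", {
  gA <- fixture_geometry("A"); gB <- fixture_geometry("B")
  expect_equal(duplex_displacement(gA, "c1mid"), 6.9, tolerance = 0.01)
  expect_equal(duplex_displacement(gB, "c1mid"), 1.9, tolerance = 0.02)
  ## the alternative definitions recover the generator x-displacement instead
  expect_equal(duplex_displacement(gA, "origin"), 4.42, tolerance = 0.01)
  expect_equal(duplex_displacement(gB, "origin"), 0.56, tolerance = 0.01)
})
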