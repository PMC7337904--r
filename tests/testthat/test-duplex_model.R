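test_that("generator duplexes pair completely and match the ground truth", {
  for (form in c("A", "B")) {
    m <- build_fiber_duplex(CRYSTAL_SEQ, fiber_spec(form))
    d <- pair_bases(m)
    expect_equal(nrow(d$pairs), 11L)
    expect_equal(paste(d$pairs$base_i, collapse = ""), CRYSTAL_SEQ)
    expect_true(all(d$pairs$pair_type == "WC"))
    truth <- attr(m, "fiber")$pairing
    got_i <- m$atoms$resno[match(d$pairs$i_uid, m$atoms$res_uid)]
    got_j <- m$atoms$resno[match(d$pairs$j_uid, m$atoms$res_uid)]
    expect_equal(got_i, truth$resno_i)
    expect_equal(got_j, truth$resno_j)
  }
})

test_that("hybrid duplex pairs with one RNA strand", {
  d <- fixture_duplex("A", "GUAGGACCAUG", hybrid = "strand1_rna")
  expect_equal(nrow(d$pairs), 11L)
  cat_i <- d$model$atoms$category[match(d$pairs$i_uid, d$model$atoms$res_uid)]
  cat_j <- d$model$atoms$category[match(d$pairs$j_uid, d$model$atoms$res_uid)]
  expect_true(all(cat_i == "RNA"))
  expect_true(all(cat_j == "DNA"))
})

test_that("nucleotides too far apart give an empty-duplex error", {
  m <- build_fiber_duplex("GT", fiber_spec("B"))
  shift <- m$atoms$chain == "B"
  m$atoms$x[shift] <- m$atoms$x[shift] + 50
  m2 <- agraft:::new_structure_model(m$atoms[, !(names(m$atoms) %in%
                                                   c("vdw", "category",
                                                     "res_uid"))])
  expect_error(pair_bases(m2), "empty duplex")
})

test_that("IUPAC site annotation matches degenerate patterns", {
  d <- fixture_duplex("B")
  d2 <- annotate_site(d, "GGWCC")   # GGACC matches, W = A
  expect_equal(d2$site_span, c(4L, 8L))
  expect_warning(annotate_site(d, "GGSCC"), "not found")  # C is not W's mate
  d3 <- annotate_site(fixture_duplex("B", "TAGGACCTG"), "RGGNCCY")
  expect_equal(d3$site_span, c(2L, 8L))
  expect_error(annotate_site(d, "GG!CC"), "IUPAC")
})

test_that("site search re-chooses the reference strand when needed", {
  # GGTCC (the complement of GGACC) only matches reading the other strand
  d <- fixture_duplex("B", "CATGGTCCTAC")
  d2 <- annotate_site(d, "GGACC")
  expect_false(is.null(d2$site_span))
  site <- d2$pairs$base_i[d2$site_span[1]:d2$site_span[2]]
  expect_equal(paste(site, collapse = ""), "GGACC")
})

test_that("IUPAC matching equals a brute-force scan over all windows", {
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D",
             "H", "V", "N")
  brute <- function(seq_l, pat_l) {
    hits <- integer()
    n <- length(seq_l); m <- length(pat_l)
    if (m > n) return(hits)
    tab <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
    for (s in 1:(n - m + 1)) {
      if (all(mapply(function(p, b) b %in% tab[[p]], pat_l,
                     seq_l[s:(s + m - 1)]))) hits <- c(hits, s)
    }
    hits
  }
  set.seed(11)
  for (rep in 1:25) {
    seq_l <- sample(c("A", "C", "G", "T"), 20, replace = TRUE)
    pat_l <- sample(codes, sample(2:5, 1), replace = TRUE)
    expect_equal(agraft:::iupac_find(seq_l, paste(pat_l, collapse = "")),
                 brute(seq_l, pat_l))
  }
})
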