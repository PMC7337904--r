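## Standard reference-frame geometry of the five nucleobases.  Each base is
## given as heavy-atom coordinates in the standard base frame: the base lies
## in the xy plane, x points into the major groove, y runs along the
## pseudo-dyad toward the glycosidic bond side, z completes a right-handed
## triad along helix advance.  In this frame the Watson-Crick partner of a
## base is obtained by the proper rotation diag(1, -1, -1) (a 180 degree flip
## about x).  C1' is included for convenience; frame fitting uses ring atoms
## only.

.base_coords <- function(base) {
  m <- switch(base,
    A = rbind(
      `C1'` = c(-2.479, 5.346), N9 = c(-1.291, 4.498), C8 = c(0.024, 4.897),
      N7 = c(0.877, 3.902), C5 = c(0.071, 2.771), C6 = c(0.369, 1.398),
      N6 = c(1.611, 0.909), N1 = c(-0.668, 0.532), C2 = c(-1.912, 1.023),
      N3 = c(-2.320, 2.290), C4 = c(-1.267, 3.124)),
    G = rbind(
      `C1'` = c(-2.477, 5.399), N9 = c(-1.289, 4.551), C8 = c(0.023, 4.962),
      N7 = c(0.870, 3.969), C5 = c(0.071, 2.833), C6 = c(0.424, 1.460),
      O6 = c(1.554, 0.955), N1 = c(-0.700, 0.641), C2 = c(-1.999, 1.087),
      N2 = c(-2.949, 0.139), N3 = c(-2.342, 2.364), C4 = c(-1.265, 3.177)),
    C = rbind(
      `C1'` = c(-2.477, 5.402), N1 = c(-1.285, 4.542), C2 = c(-1.472, 3.158),
      O2 = c(-2.628, 2.709), N3 = c(-0.391, 2.344), C4 = c(0.837, 2.868),
      N4 = c(1.875, 2.027), C5 = c(1.056, 4.275), C6 = c(-0.023, 5.068)),
    T = rbind(
      `C1'` = c(-2.481, 5.354), N1 = c(-1.284, 4.500), C2 = c(-1.462, 3.135),
      O2 = c(-2.562, 2.608), N3 = c(-0.298, 2.407), C4 = c(0.994, 2.897),
      O4 = c(1.944, 2.119), C5 = c(1.106, 4.338), C7 = c(2.466, 4.961),
      C6 = c(-0.024, 5.057)),
    U = rbind(
      `C1'` = c(-2.481, 5.354), N1 = c(-1.284, 4.500), C2 = c(-1.462, 3.131),
      O2 = c(-2.563, 2.608), N3 = c(-0.302, 2.397), C4 = c(0.989, 2.884),
      O4 = c(1.935, 2.094), C5 = c(1.089, 4.311), C6 = c(-0.024, 5.053)),
    stop("unknown base: ", base))
  cbind(m, z = 0)
}

#' Standard base template
#'
#' Heavy-atom coordinates of an idealized base in the standard reference
#' frame (origin at the base-pair center, base in the xy plane).
#'
#' @param base one of `"A"`, `"C"`, `"G"`, `"T"`, `"U"`.
#' @return n x 3 coordinate matrix with atom-name rownames.
#' @export
standard_base <- function(base) {
  .base_coords(toupper(base))
}

## ring atoms used for least-squares frame fitting
base_ring_atoms <- function(base) {
  if (toupper(base) %in% c("A", "G")) {
    c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  } else {
    c("N1", "C2", "N3", "C4", "C5", "C6")
  }
}

## glycosidic nitrogen and the chi-defining base carbon
glycosidic_atoms <- function(base) {
  if (toupper(base) %in% c("A", "G")) c(N = "N9", C = "C4") else c(N = "N1", C = "C2")
}

is_purine <- function(base) toupper(base) %in% c("A", "G")

#' Watson-Crick complement of a base letter
#' @param base character vector of base letters.
#' @param rna logical; if `TRUE` the complement of A is U.
#' @return complementary base letters.
#' @export
wc_complement <- function(base, rna = FALSE) {
  up <- toupper(base)
  out <- chartr("ACGTU", "TGCAA", up)
  if (rna) out[up == "A"] <- "U"
  out
}

## canonical Watson-Crick hydrogen-bond donor/acceptor atom pairs, listed as
## (atom on base1, atom on base2) for base1:base2
wc_hbond_atoms <- function(b1, b2) {
  key <- paste0(toupper(b1), toupper(b2))
  switch(key,
    AT = , AU = list(c("N6", "O4"), c("N1", "N3")),
    TA = , UA = list(c("O4", "N6"), c("N3", "N1")),
    GC = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")),
    CG = list(c("N4", "O6"), c("N3", "N1"), c("O2", "N2")),
    NULL)
}

## one-letter base code from a residue component name, or NA
base_letter <- function(resid) {
  up <- toupper(trimws(resid))
  map <- c(DA = "A", DC = "C", DG = "G", DT = "T", DU = "U",
           A = "A", C = "C", G = "G", T = "T", U = "U",
           ADE = "A", CYT = "C", GUA = "G", THY = "T", URA = "U",
           RA = "A", RC = "C", RG = "G", RU = "U")
  unname(map[up])
}
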