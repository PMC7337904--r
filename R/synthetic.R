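## synthetic_structures: fiber-model generator for idealized A-form, B-form,
## interpolated and RNA/DNA-hybrid duplexes, plus controlled "probe" atom
## environments with clash magnitudes known by construction.
##
## A duplex is built by placing a per-form nucleotide template (base in the
## standard reference frame plus sugar/phosphate backbone solved for helical
## continuity) at every base-pair level n with the rigid motion
##   R_n = Rz(n * twist) %*% Rx(inclination),
##   o_n = Rz(n * twist) %*% c(x_disp, 0, 0) + c(0, 0, n * rise);
## the complementary strand uses the additional proper rotation
## diag(1, -1, -1) (180 degrees about the pair x axis).  Propeller, buckle
## and all other intra-pair degrees of freedom are zero: these are fiber
## models, not sequence-dependent structures.

.template_cache <- new.env(parent = emptyenv())

load_form_templates <- function(form) {
  form <- toupper(form)
  key <- paste0("form_", form)
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  path <- system.file("extdata", "templates",
                      paste0("nucleotide_", form, ".csv"), package = "agraft")
  if (!nzchar(path)) stop("no nucleotide template table for form ", form)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  tmpl <- lapply(split(tab, tab$base), function(d) {
    m <- as.matrix(d[, c("x", "y", "z")])
    rownames(m) <- d$atom
    m
  })
  .template_cache[[key]] <- tmpl
  tmpl
}

#' Fiber-model specification
#'
#' Helical parameters and nucleotide templates of an idealized duplex form.
#' Defaults are standard fiber values: A-form twist 32.7 deg, rise 2.548 A,
#' x-displacement -4.42 A, inclination +19 deg, C3'-endo sugars; B-form
#' twist 36.0 deg, rise 3.375 A, x-displacement +0.56 A, inclination -6 deg,
#' C2'-endo sugars.
#'
#' @param form `"A"`, `"B"` or `"custom"`.
#' @param twist,rise,x_disp,inclination helical parameters (deg / Angstrom);
#'   defaults by form.
#' @param templates optional named list of nucleotide template matrices
#'   (bases A, C, G, T, U) overriding the built-in form templates.
#' @return a `fiber_spec` list.
#' @export
fiber_spec <- function(form = c("B", "A", "custom"), twist = NULL,
                       rise = NULL, x_disp = NULL, inclination = NULL,
                       templates = NULL) {
  form <- match.arg(toupper(form[1L]), c("B", "A", "CUSTOM"))
  dft <- switch(form,
                A = list(twist = 32.7, rise = 2.548, x_disp = -4.42,
                         inclination = 19.0),
                B = list(twist = 36.0, rise = 3.375, x_disp = 0.56,
                         inclination = -6.0),
                CUSTOM = list(twist = 34, rise = 3.0, x_disp = 0,
                              inclination = 0))
  sp <- list(form = form,
             twist = if (is.null(twist)) dft$twist else twist,
             rise = if (is.null(rise)) dft$rise else rise,
             x_disp = if (is.null(x_disp)) dft$x_disp else x_disp,
             inclination = if (is.null(inclination)) dft$inclination
                           else inclination,
             templates = templates)
  if (sp$rise <= 0) stop("rise must be positive")
  if (sp$twist <= 0 || sp$twist >= 60) stop("twist must be in (0, 60) degrees")
  structure(sp, class = "fiber_spec")
}

spec_templates <- function(spec) {
  if (!is.null(spec$templates)) return(spec$templates)
  if (spec$form %in% c("A", "B")) return(load_form_templates(spec$form))
  stop("custom fiber_spec needs explicit templates")
}

BACKBONE_5P <- c("P", "OP1", "OP2")

elem_from_name <- function(nm) substr(gsub("[^A-Z]", "", toupper(nm)), 1L, 1L)

#' Build an idealized fiber duplex
#'
#' Generates a Watson-Crick duplex of the given sequence under a fiber
#' specification.  Strands marked RNA carry O2' atoms and U in place of T.
#' 5'-terminal residues lack the phosphate group.  Ground truth (the fiber
#' spec, the pairing, and the hybrid flag) is attached as attribute
#' `"fiber"`.
#'
#' @param sequence reference-strand sequence, 5'->3' (A/C/G/T; U only on a
#'   strand marked RNA), length >= 2.
#' @param spec a [fiber_spec()].
#' @param hybrid `"none"`, `"strand1_rna"` or `"strand2_rna"`.
#' @return a `structure_model` with two chains A (reference strand) and B.
#' @export
build_fiber_duplex <- function(sequence, spec = fiber_spec("B"),
                               hybrid = c("none", "strand1_rna",
                                          "strand2_rna")) {
  hybrid <- match.arg(hybrid)
  letters1 <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(letters1)
  if (n < 2L) stop("sequence error: need at least 2 nucleotides")
  ok <- c("A", "C", "G", "T", "U")
  if (!all(letters1 %in% ok)) {
    stop("sequence error: invalid character(s) ",
         paste(setdiff(letters1, ok), collapse = ""))
  }
  rna1 <- hybrid == "strand1_rna"; rna2 <- hybrid == "strand2_rna"
  if (any(letters1 == "U") && !rna1) {
    stop("sequence error: U is only valid on a strand marked RNA")
  }
  if (rna1) letters1[letters1 == "T"] <- "U"
  letters2 <- wc_complement(letters1, rna = rna2)
  tmpl <- spec_templates(spec)
  flip <- diag(c(1, -1, -1))
  res_atoms <- function(base, pos0, strand, rna, terminal5) {
    m <- tmpl[[base]]
    keep <- rownames(m) != "O2'" | rna
    if (terminal5) keep <- keep & !(rownames(m) %in% BACKBONE_5P)
    m <- m[keep, , drop = FALSE]
    Rn <- rot_z(pos0 * spec$twist) %*% rot_x(spec$inclination)
    on <- as.numeric(rot_z(pos0 * spec$twist) %*% c(spec$x_disp, 0, 0)) +
      c(0, 0, pos0 * spec$rise)
    if (strand == 2L) Rn <- Rn %*% flip
    xyz <- t(Rn %*% t(m)) + matrix(on, nrow(m), 3L, byrow = TRUE)
    data.frame(atom = rownames(m), x = xyz[, 1L], y = xyz[, 2L],
               z = xyz[, 3L], stringsAsFactors = FALSE)
  }
  rows <- list()
  for (k in seq_len(n)) {       # strand 1, 5'->3' with increasing level
    b <- letters1[k]
    a <- res_atoms(b, k - 1L, 1L, rna1, terminal5 = (k == 1L))
    a$chain <- "A"; a$resno <- k
    a$resid <- if (rna1) b else paste0("D", b)
    rows[[length(rows) + 1L]] <- a
  }
  for (k in rev(seq_len(n))) {  # strand 2, 5' end at the last level
    b <- letters2[k]
    a <- res_atoms(b, k - 1L, 2L, rna2, terminal5 = (k == n))
    a$chain <- "B"; a$resno <- n - k + 1L
    a$resid <- if (rna2) b else paste0("D", b)
    rows[[length(rows) + 1L]] <- a
  }
  at <- do.call(rbind, rows)
  atoms <- data.frame(chain = at$chain, resno = at$resno, insert = "",
                      resid = at$resid, atom = at$atom,
                      elem = elem_from_name(at$atom), alt = "",
                      x = at$x, y = at$y, z = at$z, occ = 1, b = 0,
                      stringsAsFactors = FALSE)
  model <- new_structure_model(atoms, source_id = sprintf(
    "fiber:%s:%s%s", spec$form, sequence,
    if (hybrid == "none") "" else paste0(":", hybrid)))
  attr(model, "fiber") <- list(
    spec = spec, hybrid = hybrid, sequence = paste(letters1, collapse = ""),
    pairing = data.frame(pos = seq_len(n), chain_i = "A",
                         resno_i = seq_len(n), chain_j = "B",
                         resno_j = n - seq_len(n) + 1L))
  model
}

#' Duplex interpolated between two fiber forms
#'
#' Linearly interpolates helical parameters and nucleotide template
#' coordinates between a B-like endpoint (`t = 0`) and an A-like endpoint
#' (`t = 1`); the endpoints reproduce the corresponding
#' [build_fiber_duplex()] output exactly.
#'
#' @param spec_A,spec_B the endpoint fiber specifications.
#' @param t interpolation fraction in \[0, 1\].
#' @param sequence,hybrid as in [build_fiber_duplex()].
#' @return a `structure_model`.
#' @export
interpolate_conformation <- function(spec_A, spec_B, t, sequence,
                                     hybrid = "none") {
  if (!is.finite(t) || t < 0 || t > 1) stop("t must be in [0, 1]")
  tA <- spec_templates(spec_A); tB <- spec_templates(spec_B)
  mix <- lapply(names(tB), function(b) {
    mB <- tB[[b]]; mA <- tA[[b]][rownames(mB), , drop = FALSE]
    (1 - t) * mB + t * mA
  })
  names(mix) <- names(tB)
  sp <- fiber_spec("custom",
                   twist = (1 - t) * spec_B$twist + t * spec_A$twist,
                   rise = (1 - t) * spec_B$rise + t * spec_A$rise,
                   x_disp = (1 - t) * spec_B$x_disp + t * spec_A$x_disp,
                   inclination = (1 - t) * spec_B$inclination +
                     t * spec_A$inclination,
                   templates = mix)
  m <- build_fiber_duplex(sequence, sp, hybrid)
  attr(m, "fiber")$t <- t
  m
}

#' Place probe atoms at controlled clash distances from graftable O2' sites
#'
#' For each probe, one pseudo-protein atom (a single-atom glycine residue on
#' its own chain, so that it is categorized as protein) is placed on the
#' outward ray from the would-be grafted O2' position of the target
#' 2'-deoxyribose, at distance `r_O2' + r_probe - intended_clash`.  The
#' clash later reported for the grafted O2' against this probe therefore
#' equals `intended_clash` by construction.  Placement is deterministic;
#' `seed` is accepted for interface stability and seeds no randomness in the
#' default placement rule.
#'
#' @param model a `structure_model`.
#' @param probes data.frame with columns `chain`, `resno`, `clash`
#'   (Angstrom, >= 0) and optionally `element` (default C).
#' @param seed integer.
#' @param radius_set radii used for the placement arithmetic.
#' @return the model with probe atoms appended; ground truth in attribute
#'   `"probes"`.
#' @export
place_probes <- function(model, probes, seed = 1L,
                         radius_set = bondi_radii()) {
  set.seed(seed)
  probes <- as.data.frame(probes)
  if (is.null(probes$element)) probes$element <- "C"
  if (any(probes$clash < 0)) stop("intended_clash must be >= 0")
  names(radius_set) <- sub("\\.$", "", toupper(names(radius_set)))
  r_o2 <- unname(radius_set[["O"]])
  pchain <- setdiff(LETTERS, unique(model$atoms$chain))[1L]
  new_rows <- list(); truth <- list()
  for (k in seq_len(nrow(probes))) {
    sel <- model$atoms$chain == probes$chain[k] &
      model$atoms$resno == probes$resno[k]
    if (!any(sel)) {
      stop("probe target ", probes$chain[k], "/", probes$resno[k],
           " not found")
    }
    res <- model$atoms[sel, , drop = FALSE]
    g <- compute_o2prime(res)
    r_p <- radius_set[[toupper(probes$element[k])]]
    if (is.null(r_p)) r_p <- 1.70
    pos <- g$position + g$direction * (r_o2 + r_p - probes$clash[k])
    ## the probe must not clash with existing atoms beyond the intended clash
    d <- sqrt((model$atoms$x - pos[1L])^2 + (model$atoms$y - pos[2L])^2 +
                (model$atoms$z - pos[3L])^2)
    rr <- radius_set[toupper(model$atoms$elem)]
    rr[is.na(rr)] <- 1.70
    over <- r_p + rr - d
    if (any(over > probes$clash[k] + 1e-6)) {
      stop("placement error: probe ", k, " collides with existing atoms ",
           "beyond the intended clash")
    }
    new_rows[[k]] <- data.frame(
      chain = pchain, resno = k, insert = "", resid = "GLY",
      atom = toupper(probes$element[k]), elem = toupper(probes$element[k]),
      alt = "", x = pos[1L], y = pos[2L], z = pos[3L], occ = 1, b = 0,
      stringsAsFactors = FALSE)
    truth[[k]] <- data.frame(chain = pchain, resno = k,
                             target_chain = probes$chain[k],
                             target_resno = probes$resno[k],
                             intended_clash = probes$clash[k],
                             element = toupper(probes$element[k]),
                             stringsAsFactors = FALSE)
  }
  atoms <- rbind(model$atoms[, c("chain", "resno", "insert", "resid", "atom",
                                 "elem", "alt", "x", "y", "z", "occ", "b")],
                 do.call(rbind, new_rows))
  out <- new_structure_model(atoms, cell = model$cell,
                             space_group = model$space_group,
                             source_id = model$source_id)
  ## single-atom glycines are protein by component name; keep the fiber
  ## ground truth and record the probe truth table
  attr(out, "fiber") <- attr(model, "fiber")
  attr(out, "probes") <- do.call(rbind, truth)
  out
}
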