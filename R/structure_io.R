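## structure_io: read/write macromolecular structures, residue classification,
## van-der-Waals radius assignment.
##
## A `structure_model` is a list with
##   atoms       data.frame: chain, resno, insert, resid, atom, elem, alt,
##               x, y, z, occ, b, vdw, category, res_uid
##   cell        numeric(6) (a, b, c, alpha, beta, gamma) or NULL
##   space_group character or NA
##   source_id   free-text provenance
## Atom names are normalized to the prime convention (C1', O2', ...).
## Author numbering (chain/resno/insert) is preserved verbatim; res_uid is a
## positional residue index in file order.

METAL_ELEMENTS <- c("LI", "NA", "MG", "K", "CA", "MN", "FE", "CO", "NI",
                    "CU", "ZN", "RB", "SR", "CD", "CS", "BA", "AG", "HG",
                    "TL", "PB")

WATER_COMPS <- c("HOH", "WAT", "DOD", "H2O", "SOL")

AMINO_COMPS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL", "MSE")

#' Bondi van-der-Waals radii
#'
#' Default radius set used for clash scoring and surface areas.  Values in
#' Angstrom; any element absent from the table falls back to the configured
#' default in [assign_radii()].
#'
#' @return named numeric vector of radii, names are uppercase element symbols.
#' @export
bondi_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    NA. = 2.27, MG = 1.73, K = 2.75, ZN = 1.39, SE = 1.90)
}

normalize_atom_name <- function(x) {
  x <- gsub("*", "'", trimws(x), fixed = TRUE)
  x
}

guess_element <- function(name, resid = "") {
  name <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(name, 1L, 2L)
  one <- substr(name, 1L, 1L)
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "SE", "NA", "CA") &
           nchar(resid) <= 2 & toupper(resid) == two,
         two, one)
}

new_structure_model <- function(atoms, cell = NULL, space_group = NA_character_,
                                source_id = "") {
  need <- c("chain", "resno", "insert", "resid", "atom", "elem", "alt",
            "x", "y", "z", "occ", "b")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("empty structure: no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  atoms$occ[!is.finite(atoms$occ)] <- 1
  atoms$occ <- pmin(pmax(atoms$occ, 0), 1)
  if (is.null(atoms$vdw)) atoms$vdw <- NA_real_
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  atoms$res_uid <- as.integer(factor(key, levels = unique(key)))
  m <- structure(list(atoms = atoms, cell = cell, space_group = space_group,
                      source_id = source_id),
                 class = "structure_model")
  m$atoms$category <- classify_model_residues(m)
  m
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("<structure_model> ", nrow(a), " atoms, ",
      length(unique(a$res_uid)), " residues, ",
      length(unique(a$chain)), " chain(s)\n", sep = "")
  tb <- table(a$category[!duplicated(a$res_uid)])
  cat("  residues by category:",
      paste(names(tb), as.integer(tb), sep = "=", collapse = ", "), "\n")
  if (!is.null(x$cell)) {
    cat("  cell:", paste(sprintf("%.1f", x$cell), collapse = " "),
        " space group:", x$space_group, "\n")
  }
  invisible(x)
}

residue_split <- function(model) {
  split(seq_len(nrow(model$atoms)), model$atoms$res_uid)
}

#' Classify a residue
#'
#' Decides the category of one residue from its atom content: `RNA` if it is
#' a nucleotide carrying a ribose O2' atom, `DNA` if a nucleotide without
#' O2', `protein` if the peptide backbone (N, CA, C) is present, `water` for
#' solvent components, `metal` for single-atom ions of a configured metal
#' element, and `other` otherwise.  Always returns a category.
#'
#' @param residue data.frame of one residue's atoms (columns `atom`, `resid`,
#'   `elem` as in a `structure_model`).
#' @param metals uppercase element symbols treated as metals.
#' @return one of `"DNA"`, `"RNA"`, `"protein"`, `"water"`, `"metal"`,
#'   `"other"`.
#' @export
classify_residue <- function(residue, metals = METAL_ELEMENTS) {
  if (!nrow(residue)) stop("residue has no atoms")
  nm <- normalize_atom_name(residue$atom)
  comp <- toupper(trimws(residue$resid[1L]))
  if (comp %in% WATER_COMPS) return("water")
  is_nt <- "C1'" %in% nm && any(c("O4'", "N9", "N1") %in% nm)
  if (is_nt) {
    return(if ("O2'" %in% nm) "RNA" else "DNA")
  }
  if (all(c("N", "CA", "C") %in% nm)) return("protein")
  if (comp %in% AMINO_COMPS) return("protein")
  if (nrow(residue) == 1L && toupper(residue$elem[1L]) %in% metals) {
    return("metal")
  }
  "other"
}

classify_model_residues <- function(model) {
  idx <- residue_split(model)
  out <- character(nrow(model$atoms))
  for (ii in idx) out[ii] <- classify_residue(model$atoms[ii, , drop = FALSE])
  out
}

#' Assign van-der-Waals radii to every atom
#'
#' @param model a `structure_model`.
#' @param radius_set named numeric vector (element symbol -> radius in
#'   Angstrom); defaults to [bondi_radii()].
#' @param default radius used (with one warning) for elements absent from the
#'   table.
#' @return the model with `atoms$vdw` filled.
#' @export
assign_radii <- function(model, radius_set = bondi_radii(), default = 1.70) {
  names(radius_set) <- sub("\\.$", "", toupper(names(radius_set)))
  el <- toupper(model$atoms$elem)
  r <- unname(radius_set[el])
  unknown <- unique(el[is.na(r)])
  if (length(unknown)) {
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            ": using default radius ", default, " A")
    r[is.na(r)] <- default
  }
  model$atoms$vdw <- r
  model
}

## keep the highest-occupancy conformer per (residue, atom); ties broken by
## altloc identifier order
filter_altloc <- function(atoms, altloc = "highest") {
  if (!any(nzchar(atoms$alt))) return(atoms)
  if (!identical(altloc, "highest")) {
    keep <- atoms$alt == "" | atoms$alt == altloc
    return(atoms[keep, , drop = FALSE])
  }
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$atom, sep = "|")
  ord <- order(key, -atoms$occ, atoms$alt)
  a <- atoms[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$atom, sep = "|")), ,
         drop = FALSE]
  a[order(as.integer(rownames(a))), , drop = FALSE]
}

#' Read a macromolecular structure
#'
#' Loads all ATOM/HETATM records of a PDB or mmCIF file into a
#' `structure_model`, captures unit-cell and space-group information when
#' present, and classifies every residue (DNA/RNA/protein/water/metal/other).
#' Alternate conformations are reduced to the highest-occupancy conformer per
#' atom by default (ties broken by altloc identifier order); pass a specific
#' altloc letter to select one conformer-resolved model.
#'
#' @param path file path.
#' @param format `"pdb"`, `"cif"` or `"auto"` (by file extension).
#' @param altloc `"highest"`, `"all"`, or a single altloc letter.
#' @return a `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           altloc = "highest") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  if (format == "pdb") read_structure_pdb(path, altloc)
  else read_structure_cif(path, altloc)
}

read_structure_pdb <- function(path, altloc = "highest") {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE,
                                  multi = FALSE),
                  error = function(e) {
                    stop("cannot parse PDB file ", path, ": ",
                         conditionMessage(e))
                  })
  a <- pdb$atom
  if (is.null(a) || !nrow(a)) stop("empty structure: no ATOM/HETATM records in ", path)
  elem <- toupper(trimws(a$elesy))
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- guess_element(a$elety[bad], a$resid[bad])
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = trimws(a$resid),
    atom = normalize_atom_name(a$elety),
    elem = elem,
    alt = ifelse(is.na(a$alt), "", a$alt),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    stringsAsFactors = FALSE)
  if (!identical(altloc, "all")) atoms <- filter_altloc(atoms, altloc)
  cell <- NULL; sg <- NA_character_
  hdr <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(hdr)) {
    h <- hdr[1L]
    cl <- suppressWarnings(as.numeric(c(substr(h, 7, 15), substr(h, 16, 24),
                                        substr(h, 25, 33), substr(h, 34, 40),
                                        substr(h, 41, 47), substr(h, 48, 54))))
    if (all(is.finite(cl)) && all(cl[1:3] > 0)) {
      cell <- cl
      sg <- trimws(substr(h, 56, 66))
    }
  }
  new_structure_model(atoms, cell = cell, space_group = sg, source_id = path)
}

## --- minimal mmCIF support (atom_site, cell, symmetry) ---------------------

cif_tokenize <- function(line) {
  scan(text = line, what = character(), quiet = TRUE,
       quote = "\"'", strip.white = TRUE)
}

read_structure_cif <- function(path, altloc = "highest") {
  lines <- readLines(path, warn = FALSE)
  kv <- function(tag) {
    i <- grep(paste0("^", tag, "\\s"), lines)
    if (!length(i)) return(NA_character_)
    tok <- cif_tokenize(lines[i[1L]])
    if (length(tok) >= 2L) tok[2L] else NA_character_
  }
  ## locate the atom_site loop
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  atoms <- NULL
  for (ls in loop_starts) {
    j <- ls + 1L
    fields <- character()
    while (j <= length(lines) && grepl("^_", trimws(lines[j]))) {
      fields <- c(fields, trimws(lines[j])); j <- j + 1L
    }
    if (!length(fields) || !all(grepl("^_atom_site\\.", fields))) next
    fields <- sub("^_atom_site\\.", "", fields)
    rows <- list()
    while (j <= length(lines)) {
      ln <- lines[j]
      if (grepl("^\\s*(loop_|_|#|data_)", ln) || !nzchar(trimws(ln))) break
      tok <- cif_tokenize(ln)
      if (length(tok) != length(fields)) {
        stop("cannot parse mmCIF file ", path, ": atom_site row at line ", j,
             " has ", length(tok), " fields, expected ", length(fields))
      }
      rows[[length(rows) + 1L]] <- tok
      j <- j + 1L
    }
    tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(tab) <- fields
    atoms <- tab
    break
  }
  if (is.null(atoms) || !nrow(atoms)) {
    stop("empty structure: no _atom_site loop in ", path)
  }
  get <- function(nmv, default = "") {
    for (nm in nmv) if (nm %in% names(atoms)) return(atoms[[nm]])
    rep(default, nrow(atoms))
  }
  q <- function(x, default = "") {
    x[x %in% c(".", "?")] <- default; x
  }
  num <- function(x, default = NA_real_) {
    suppressWarnings(as.numeric(q(x, NA))) -> v
    v[!is.finite(v)] <- default; v
  }
  out <- data.frame(
    chain = q(get(c("auth_asym_id", "label_asym_id"))),
    resno = as.integer(num(get(c("auth_seq_id", "label_seq_id")), 0)),
    insert = q(get("pdbx_PDB_ins_code")),
    resid = q(get(c("auth_comp_id", "label_comp_id"))),
    atom = normalize_atom_name(q(get(c("auth_atom_id", "label_atom_id")))),
    elem = toupper(q(get("type_symbol"))),
    alt = q(get("label_alt_id")),
    x = num(get("Cartn_x")), y = num(get("Cartn_y")), z = num(get("Cartn_z")),
    occ = num(get("occupancy"), 1),
    b = num(get("B_iso_or_equiv"), 0),
    stringsAsFactors = FALSE)
  bad <- out$elem == ""
  if (any(bad)) out$elem[bad] <- guess_element(out$atom[bad], out$resid[bad])
  if (!identical(altloc, "all")) out <- filter_altloc(out, altloc)
  cell <- suppressWarnings(as.numeric(c(kv("_cell.length_a"), kv("_cell.length_b"),
                                        kv("_cell.length_c"), kv("_cell.angle_alpha"),
                                        kv("_cell.angle_beta"), kv("_cell.angle_gamma"))))
  if (!all(is.finite(cell))) cell <- NULL
  sg <- kv("_symmetry.space_group_name_H-M")
  new_structure_model(out, cell = cell, space_group = sg, source_id = path)
}

#' Write a structure to PDB or mmCIF
#'
#' The emitted file re-reads with [read_structure()] to an equivalent model
#' (atom names, residues, coordinates to format precision).
#'
#' @param model a `structure_model` (non-empty).
#' @param path output file path.
#' @param format `"pdb"`, `"cif"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  a <- model$atoms
  if (is.null(a) || !nrow(a)) stop("cannot write an empty structure")
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  if (format == "pdb") {
    het <- a$category %in% c("water", "metal", "other")
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = ifelse(het, "HETATM", "ATOM"),
                     resno = a$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$atom,
                     chain = a$chain, insert = ifelse(a$insert == "", NA, a$insert),
                     alt = ifelse(a$alt == "", NA, a$alt),
                     o = a$occ, b = a$b, elesy = a$elem)
    if (!is.null(model$cell)) {
      cl <- model$cell
      sg <- if (is.na(model$space_group)) "P 1" else model$space_group
      cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                       cl[1], cl[2], cl[3], cl[4], cl[5], cl[6], sg)
      body <- readLines(path, warn = FALSE)
      writeLines(c(cryst, body), path)
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("data_agraft", con)
    if (!is.null(model$cell)) {
      cl <- model$cell
      writeLines(sprintf(c("_cell.length_a %.3f", "_cell.length_b %.3f",
                           "_cell.length_c %.3f", "_cell.angle_alpha %.2f",
                           "_cell.angle_beta %.2f", "_cell.angle_gamma %.2f"),
                         cl), con)
      if (!is.na(model$space_group)) {
        writeLines(sprintf("_symmetry.space_group_name_H-M '%s'",
                           model$space_group), con)
      }
    }
    writeLines(c("loop_", "_atom_site.group_PDB", "_atom_site.id",
                 "_atom_site.auth_atom_id", "_atom_site.label_alt_id",
                 "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
                 "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
                 "_atom_site.Cartn_x", "_atom_site.Cartn_y",
                 "_atom_site.Cartn_z", "_atom_site.occupancy",
                 "_atom_site.B_iso_or_equiv", "_atom_site.type_symbol"), con)
    het <- a$category %in% c("water", "metal", "other")
    qs <- function(x, blank = ".") ifelse(nzchar(x), sprintf("\"%s\"", x), blank)
    writeLines(sprintf("%s %d %s %s %s %s %d %s %.3f %.3f %.3f %.2f %.2f %s",
                       ifelse(het, "HETATM", "ATOM"), seq_len(nrow(a)),
                       qs(a$atom), qs(a$alt), a$resid,
                       qs(a$chain), a$resno, qs(a$insert),
                       a$x, a$y, a$z, a$occ, a$b, a$elem), con)
  }
  invisible(path)
}
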