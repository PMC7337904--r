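## hydroxyl_grafting: place an O2' oxygen on a 2'-deoxyribose with ideal
## tetrahedral geometry at C2', correct ribo (trans-to-base) face, and no
## movement of any existing atom.

O2P_BOND_LENGTH <- 1.413     # C2'-O2' bond, Angstrom
TETRAHEDRAL_ANGLE <- 109.47  # target O2'-C2'-C1' / O2'-C2'-C3' angle, deg

## Handedness of the canonical D-(deoxy)ribofuranose, measured at the C3'
## stereocenter as the signed volume det[C2'-C3', C4'-C3', O3'-C3'].
## The sign is a true chirality marker: invariant under conformational
## change (pucker), flipped by mirror inversion.  Negative for the natural
## D-sugar (about -2.7 A^3 for ideal nucleotide geometry).
RING_CHIRALITY_SIGN <- -1

ring_chirality <- function(xyz) {
  det(cbind(xyz[["C2'"]] - xyz[["C3'"]],
            xyz[["C4'"]] - xyz[["C3'"]],
            xyz[["O3'"]] - xyz[["C3'"]]))
}

## core placement shared by grafting and probe construction
compute_o2prime <- function(residue, bond_length = O2P_BOND_LENGTH) {
  nm <- normalize_atom_name(residue$atom)
  if ("O2'" %in% nm) stop("already a ribose: O2' present")
  need <- c("C1'", "C2'", "C3'")
  miss <- setdiff(need, nm)
  if (length(miss)) {
    stop("incomplete sugar: missing ", paste(miss, collapse = ", "))
  }
  get <- function(a) as.numeric(residue[match(a, nm), c("x", "y", "z")])
  c1 <- get("C1'"); c2 <- get("C2'"); c3 <- get("C3'")
  b1 <- unitv(c1 - c2); b2 <- unitv(c3 - c2)
  u <- unitv(b1 + b2); v <- unitv(cross3(b1, b2))
  ## direction d with angle(d, b1) = angle(d, b2) = 109.47 deg:
  ## d = alpha * u + beta * v, alpha fixed by the angle target
  alpha <- cos(TETRAHEDRAL_ANGLE * DEG) / sum(u * b1)
  if (abs(alpha) >= 1) stop("degenerate sugar geometry at C2'")
  beta_mag <- sqrt(1 - alpha^2)
  ## ribo configuration: O2' sits on the sugar face opposite the base
  ## (trans to the glycosidic nitrogen)
  gn <- intersect(c("N9", "N1"), nm)
  if (!length(gn)) stop("incomplete sugar: no glycosidic nitrogen")
  side_base <- sign(sum((get(gn[1L]) - c2) * v))
  beta <- -side_base * beta_mag
  d <- alpha * u + beta * v
  ## intrinsic handedness check at the C3' stereocenter; a mirror-imaged
  ## sugar is rejected here (skipped when O3'/C4' are absent)
  chir <- NA_real_
  if (all(c("C4'", "O3'") %in% nm)) {
    chir <- ring_chirality(list(`C2'` = c2, `C3'` = c3,
                                `C4'` = get("C4'"), `O3'` = get("O3'")))
    if (sign(chir) != RING_CHIRALITY_SIGN) {
      stop("chirality error: sugar has inverted handedness")
    }
  }
  list(position = c2 + bond_length * d, direction = d,
       chirality = chir)
}

#' Graft an O2' hydroxyl oxygen onto a 2'-deoxyribose
#'
#' Places the O2' atom at the configured C2'-O2' bond length, completing
#' ideal tetrahedral geometry at C2' on the ribose face (trans to the
#' base), without moving any existing atom: the sugar pucker before and
#' after grafting is identical by construction.  A mirror-imaged sugar
#' fails the signed-volume handedness check.  The hydroxyl hydrogen is not
#' placed; downstream clash scoring uses the oxygen only.
#'
#' @param residue data.frame of one DNA nucleotide's atoms.
#' @param bond_length C2'-O2' distance in Angstrom.
#' @return list of class `graft_result`: `chain`, `resno`, `insert`,
#'   `res_uid`, `o2prime_position`, `chirality_ok`, `pucker_before`,
#'   `pucker_after`, `status` (`"ok"`).
#' @export
graft_o2prime <- function(residue, bond_length = O2P_BOND_LENGTH) {
  pk <- tryCatch(sugar_pucker(residue), error = function(e) NULL)
  g <- compute_o2prime(residue, bond_length)
  structure(list(chain = residue$chain[1L], resno = residue$resno[1L],
                 insert = residue$insert[1L],
                 res_uid = if (!is.null(residue$res_uid)) residue$res_uid[1L]
                           else NA_integer_,
                 o2prime_position = g$position,
                 chirality_ok = TRUE,
                 pucker_before = pk, pucker_after = pk,
                 status = "ok"),
            class = "graft_result")
}

#' Graft O2' groups across a duplex, one at a time
#'
#' Produces one graft per eligible 2'-deoxyribose.  Grafts are independent:
#' each graft's clash context contains no other grafted hydroxyl.  RNA
#' residues are skipped with an `already-ribose` note; per-residue failures
#' are collected, not fatal.
#'
#' @param duplex a `duplex`.
#' @param which `"both_strands"`, `"strand1"`, `"strand2"`, `"site_only"`
#'   (both strands of the annotated site), or `"all"` (every DNA residue in
#'   the model, paired or not).
#' @param model structure model (defaults to the duplex's).
#' @return list of `graft_result` objects; failed residues appear with
#'   `status` describing the error.
#' @export
graft_duplex <- function(duplex, which = c("both_strands", "strand1",
                                           "strand2", "site_only", "all"),
                         model = duplex$model) {
  which <- match.arg(which)
  pr <- duplex$pairs
  uids <- switch(which,
    both_strands = c(rbind(pr$i_uid, pr$j_uid)),
    strand1 = pr$i_uid,
    strand2 = pr$j_uid,
    site_only = {
      if (is.null(duplex$site_span)) stop("no site annotated on duplex")
      sel <- pr$pos >= duplex$site_span[1L] & pr$pos <= duplex$site_span[2L]
      c(rbind(pr$i_uid[sel], pr$j_uid[sel]))
    },
    all = unique(model$atoms$res_uid[model$atoms$category == "DNA"]))
  out <- lapply(uids, function(u) {
    res <- residue_atoms(model, u)
    if (res$category[1L] == "RNA") {
      return(structure(list(chain = res$chain[1L], resno = res$resno[1L],
                            insert = res$insert[1L], res_uid = u,
                            o2prime_position = NULL, chirality_ok = NA,
                            pucker_before = NULL, pucker_after = NULL,
                            status = "already-ribose"),
                       class = "graft_result"))
    }
    tryCatch(graft_o2prime(res), error = function(e) {
      structure(list(chain = res$chain[1L], resno = res$resno[1L],
                     insert = res$insert[1L], res_uid = u,
                     o2prime_position = NULL, chirality_ok = FALSE,
                     pucker_before = NULL, pucker_after = NULL,
                     status = conditionMessage(e)),
                class = "graft_result")
    })
  })
  out
}

#' Write a graft report as TSV
#' @param grafts list of `graft_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graft_table <- function(grafts, path) {
  tab <- do.call(rbind, lapply(grafts, function(g) {
    pos <- if (is.null(g$o2prime_position)) c(NA_real_, NA_real_, NA_real_)
           else g$o2prime_position
    data.frame(chain = g$chain, resno = g$resno, status = g$status,
               chirality_ok = g$chirality_ok,
               x = pos[1L], y = pos[2L], z = pos[3L])
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
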