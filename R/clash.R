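## clash_scoring: van-der-Waals overlap of grafted O2' atoms against
## protein and nucleic-acid atoms; per-nucleotide maximal and cumulative
## clashes, split by partner category, strand-averaged per position.

#' Pairwise van-der-Waals clash
#'
#' `clash = max(0, r_a + r_b - d)`.
#'
#' @param atom_a,atom_b lists or one-row data.frames with `x`, `y`, `z` and
#'   `vdw`.
#' @return clash in Angstrom (>= 0).
#' @examples
#' a <- list(x = 0, y = 0, z = 0, vdw = 1.52)
#' b <- list(x = 2.5, y = 0, z = 0, vdw = 1.70)
#' pair_clash(a, b)  # 0.72
#' @export
pair_clash <- function(atom_a, atom_b) {
  d <- sqrt((atom_a$x - atom_b$x)^2 + (atom_a$y - atom_b$y)^2 +
              (atom_a$z - atom_b$z)^2)
  max(0, atom_a$vdw + atom_b$vdw - d)
}

## candidate partner atoms for a graft: everything except hydrogens,
## waters, metals, and same-nucleotide atoms within two covalent bonds of
## the grafted O2' (C2', C1', C3' and their hydrogens)
clash_partner_mask <- function(model, res_uid) {
  a <- model$atoms
  nm <- normalize_atom_name(a$atom)
  excl <- toupper(a$elem) == "H" |
    a$category %in% c("water", "metal") |
    (a$res_uid == res_uid & nm %in% c("C1'", "C2'", "C3'"))
  !excl
}

#' Score a grafted O2' against a structure
#'
#' Computes the van-der-Waals overlap of the grafted oxygen with every
#' non-excluded atom (exclusions: same-nucleotide atoms within two covalent
#' bonds of O2', all hydrogens, waters, monoatomic ions), records the
#' maximum and the per-partner-atom cumulative clash, overall and split
#' into protein and nucleic-acid partners.  A coordinate-window neighbor
#' search restricts the candidate set; it is exact because the window is
#' wider than any possible contact distance (verified against the
#' exhaustive scan in the test suite).
#'
#' @param graft a `graft_result` with `status == "ok"`.
#' @param model a `structure_model` with radii assigned.
#' @param threshold flag threshold in Angstrom (default 1.1: overlaps up to
#'   1.1 A are treated as compensable by local adaptation).
#' @param o2_radius radius of the grafted oxygen.
#' @param cutoff neighbor-window half-width in Angstrom (speed only).
#' @param method `"window"` or `"exhaustive"` (identical results).
#' @return list of class `clash_record`: max_clash, cumulative_clash,
#'   max_clash_protein, max_clash_nucleic, cumulative_protein,
#'   cumulative_nucleic, worst_partner, above_threshold.
#' @export
score_graft <- function(graft, model, threshold = 1.1, o2_radius = 1.52,
                        cutoff = 4.8, method = c("window", "exhaustive")) {
  method <- match.arg(method)
  if (!identical(graft$status, "ok")) stop("graft was not accepted: ",
                                           graft$status)
  if (anyNA(model$atoms$vdw)) stop("assign_radii must be run first")
  p <- graft$o2prime_position
  mask <- clash_partner_mask(model, graft$res_uid)
  a <- model$atoms
  if (method == "window") {
    mask <- mask & abs(a$x - p[1L]) <= cutoff & abs(a$y - p[2L]) <= cutoff &
      abs(a$z - p[3L]) <= cutoff
  }
  idx <- which(mask)
  if (!length(idx)) {
    rec <- list(chain = graft$chain, resno = graft$resno,
                res_uid = graft$res_uid,
                max_clash = 0, cumulative_clash = 0,
                max_clash_protein = 0, max_clash_nucleic = 0,
                cumulative_protein = 0, cumulative_nucleic = 0,
                worst_partner = NA_character_, above_threshold = FALSE,
                threshold = threshold)
    return(structure(rec, class = "clash_record"))
  }
  d <- sqrt((a$x[idx] - p[1L])^2 + (a$y[idx] - p[2L])^2 +
              (a$z[idx] - p[3L])^2)
  ov <- pmax(0, o2_radius + a$vdw[idx] - d)
  cat_i <- a$category[idx]
  is_prot <- cat_i == "protein"
  is_nuc <- cat_i %in% c("DNA", "RNA")
  mx <- if (length(ov)) max(ov) else 0
  worst <- NA_character_
  if (mx > 0) {
    w <- idx[which.max(ov)]
    worst <- paste0(a$chain[w], "/", a$resno[w], "/", a$atom[w])
  }
  rec <- list(chain = graft$chain, resno = graft$resno,
              res_uid = graft$res_uid,
              max_clash = mx, cumulative_clash = sum(ov),
              max_clash_protein = if (any(is_prot)) max(ov[is_prot]) else 0,
              max_clash_nucleic = if (any(is_nuc)) max(ov[is_nuc]) else 0,
              cumulative_protein = sum(ov[is_prot]),
              cumulative_nucleic = sum(ov[is_nuc]),
              worst_partner = worst,
              above_threshold = mx > threshold,
              threshold = threshold)
  structure(rec, class = "clash_record")
}

#' @export
print.clash_record <- function(x, ...) {
  cat(sprintf("clash %s/%s: max %.3f (prot %.3f, nuc %.3f) cum %.3f%s\n",
              x$chain, x$resno, x$max_clash, x$max_clash_protein,
              x$max_clash_nucleic, x$cumulative_clash,
              if (x$above_threshold) " [above threshold]" else ""))
  invisible(x)
}

#' Per-position clash table of a duplex
#'
#' Grafts O2' one at a time on the requested strands and scores each graft
#' against the unmodified model, then tabulates per base-pair position the
#' two strands' records and their arithmetic mean (maximal and cumulative,
#' each split into protein and nucleic partners).  Positions whose graft
#' failed are reported as NA, not zero.
#'
#' @param duplex a `duplex`.
#' @param model structure model with radii assigned (defaults to the
#'   duplex's model, radii auto-assigned if absent).
#' @param which strands to graft (see [graft_duplex()]).
#' @param threshold clash flag threshold (Angstrom).
#' @param ... passed to [score_graft()].
#' @return data.frame of class `clash_table`: per position max/cum (overall,
#'   protein, nucleic) for strand 1, strand 2 and their mean, plus
#'   above-threshold flags.
#' @export
score_duplex <- function(duplex, model = duplex$model,
                         which = "both_strands", threshold = 1.1, ...) {
  if (anyNA(model$atoms$vdw)) model <- assign_radii(model)
  grafts <- graft_duplex(duplex, which = which, model = model)
  recs <- lapply(grafts, function(g) {
    if (!identical(g$status, "ok")) return(NULL)
    score_graft(g, model, threshold = threshold, ...)
  })
  names(recs) <- vapply(grafts, function(g) as.character(g$res_uid),
                        character(1L))
  pr <- duplex$pairs
  val <- function(uid, field) {
    r <- recs[[as.character(uid)]]
    if (is.null(r)) NA_real_ else r[[field]]
  }
  out <- do.call(rbind, lapply(seq_len(nrow(pr)), function(k) {
    m1 <- val(pr$i_uid[k], "max_clash"); m2 <- val(pr$j_uid[k], "max_clash")
    data.frame(
      pos = pr$pos[k], base_i = pr$base_i[k], base_j = pr$base_j[k],
      max_1 = m1, cum_1 = val(pr$i_uid[k], "cumulative_clash"),
      max_prot_1 = val(pr$i_uid[k], "max_clash_protein"),
      max_nuc_1 = val(pr$i_uid[k], "max_clash_nucleic"),
      max_2 = m2, cum_2 = val(pr$j_uid[k], "cumulative_clash"),
      max_prot_2 = val(pr$j_uid[k], "max_clash_protein"),
      max_nuc_2 = val(pr$j_uid[k], "max_clash_nucleic"),
      mean_max = mean(c(m1, m2)),
      mean_cum = mean(c(val(pr$i_uid[k], "cumulative_clash"),
                        val(pr$j_uid[k], "cumulative_clash"))),
      mean_max_protein = mean(c(val(pr$i_uid[k], "max_clash_protein"),
                                val(pr$j_uid[k], "max_clash_protein"))),
      mean_max_nucleic = mean(c(val(pr$i_uid[k], "max_clash_nucleic"),
                                val(pr$j_uid[k], "max_clash_nucleic"))),
      mean_cum_protein = mean(c(val(pr$i_uid[k], "cumulative_protein"),
                                val(pr$j_uid[k], "cumulative_protein"))),
      mean_cum_nucleic = mean(c(val(pr$i_uid[k], "cumulative_nucleic"),
                                val(pr$j_uid[k], "cumulative_nucleic"))),
      above_threshold = !is.na(m1) && !is.na(m2) &&
        max(m1, m2) > threshold,
      stringsAsFactors = FALSE)
  }))
  attr(out, "threshold") <- threshold
  attr(out, "site_span") <- duplex$site_span
  class(out) <- c("clash_table", "data.frame")
  out
}

#' Write a per-position clash table as TSV
#' @param tab a `clash_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clash_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
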