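## surface_metrics: Shrake-Rupley solvent-accessible surface area with a
## deterministic golden-spiral point set, buried interface area, and metal
## coordination shells.

## deterministic quasi-uniform points on the unit sphere
golden_spiral_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area
#'
#' Shrake-Rupley sampling: for every atom, `n_points` deterministic
#' golden-spiral points on the sphere of radius `vdw + probe_radius`; the
#' exposed fraction times the sphere area sums to the SASA.  Hydrogens are
#' excluded.
#'
#' @param model a `structure_model` with radii assigned.
#' @param selection optional logical or integer index into the atom table;
#'   default all atoms.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param n_points sample points per atom (default 960).
#' @return total SASA in Angstrom^2, with per-atom values in attribute
#'   `"per_atom"`.
#' @export
sasa <- function(model, selection = NULL, probe_radius = 1.4,
                 n_points = 960L) {
  a <- model$atoms
  if (anyNA(a$vdw)) stop("assign_radii must be run first")
  idx <- if (is.null(selection)) seq_len(nrow(a))
         else if (is.logical(selection)) which(selection)
         else as.integer(selection)
  idx <- idx[toupper(a$elem[idx]) != "H"]
  if (!length(idx)) stop("empty selection")
  xyz <- as.matrix(a[idx, c("x", "y", "z")])
  rr <- a$vdw[idx] + probe_radius
  sph <- golden_spiral_points(n_points)
  n <- length(idx)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    ri <- rr[i]
    ## neighbors that can occlude points on sphere i
    d2 <- rowSums(sweep(xyz, 2L, xyz[i, ])^2)
    nb <- which(d2 < (ri + rr)^2 & d2 > 1e-12)
    if (!length(nb)) {
      per_atom[i] <- 4 * pi * ri^2
      next
    }
    pts <- sph * ri
    pts <- sweep(pts, 2L, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- (pts[exposed, 1L] - xyz[j, 1L])^2 +
        (pts[exposed, 2L] - xyz[j, 2L])^2 +
        (pts[exposed, 3L] - xyz[j, 3L])^2
      exposed[exposed] <- dj2 >= rr[j]^2
    }
    per_atom[i] <- 4 * pi * ri^2 * sum(exposed) / n_points
  }
  out <- sum(per_atom)
  attr(out, "per_atom") <- per_atom
  out
}

#' Buried solvent-accessible interface area between two chain groups
#'
#' `buried_total = sasa(A) + sasa(B) - sasa(AB)`, computed on heavy atoms
#' with hydrogens and waters excluded.  The total over both sides is the
#' headline number; the per-side value is half of it.
#'
#' @param model a `structure_model` with radii assigned.
#' @param group_A,group_B character vectors of chain identifiers; must be
#'   disjoint and non-empty.
#' @param ... passed to [sasa()].
#' @return list of class `interface_area`: `sasa_A`, `sasa_B`, `sasa_AB`,
#'   `buried_total`, `buried_per_side`.
#' @export
interface_area <- function(model, group_A, group_B, ...) {
  if (!length(group_A) || !length(group_B)) stop("empty chain group")
  if (length(intersect(group_A, group_B))) {
    stop("grouping error: chain groups overlap")
  }
  a <- model$atoms
  usable <- !(a$category %in% "water")
  inA <- a$chain %in% group_A & usable
  inB <- a$chain %in% group_B & usable
  if (!any(inA) || !any(inB)) stop("grouping error: empty group selection")
  ## isolated-group SASA: compute on a model containing only that group
  sub_model <- function(sel) {
    m <- model
    m$atoms <- a[sel, , drop = FALSE]
    m
  }
  sA <- as.numeric(sasa(sub_model(inA), ...))
  sB <- as.numeric(sasa(sub_model(inB), ...))
  sAB <- as.numeric(sasa(sub_model(inA | inB), ...))
  structure(list(group_A = group_A, group_B = group_B,
                 sasa_A = sA, sasa_B = sB, sasa_AB = sAB,
                 buried_total = max(0, sA + sB - sAB),
                 buried_per_side = max(0, sA + sB - sAB) / 2),
            class = "interface_area")
}

#' @export
print.interface_area <- function(x, ...) {
  cat(sprintf(paste0("interface %s | %s: SASA A %.0f, B %.0f, AB %.0f A^2;",
                     " buried %.0f A^2 total (%.0f per side)\n"),
              paste(x$group_A, collapse = ","),
              paste(x$group_B, collapse = ","),
              x$sasa_A, x$sasa_B, x$sasa_AB, x$buried_total,
              x$buried_per_side))
  invisible(x)
}

#' Coordination shell of an atom
#'
#' All non-hydrogen atoms (excluding the center's own residue) within the
#' cutoff of a uniquely selected center atom, sorted by distance.
#'
#' @param model a `structure_model`.
#' @param center list with `chain`, `resno` and optionally `atom` selecting
#'   exactly one atom.
#' @param cutoff shell radius in Angstrom (default 3.0).
#' @return list of class `coordination_shell`: `center` (atom row),
#'   `ligands` (data.frame with distances, ascending), `n` (coordination
#'   number).
#' @export
coordination_shell <- function(model, center, cutoff = 3.0) {
  a <- model$atoms
  sel <- a$chain == center$chain & a$resno == center$resno
  if (!is.null(center$atom)) {
    sel <- sel & normalize_atom_name(a$atom) == normalize_atom_name(center$atom)
  }
  if (sum(sel) != 1L) {
    stop("selection error: center matches ", sum(sel), " atoms")
  }
  ci <- which(sel)
  p <- as.numeric(a[ci, c("x", "y", "z")])
  d <- sqrt((a$x - p[1L])^2 + (a$y - p[2L])^2 + (a$z - p[3L])^2)
  keep <- d <= cutoff & toupper(a$elem) != "H" &
    a$res_uid != a$res_uid[ci]
  lig <- a[keep, c("chain", "resno", "resid", "atom", "elem")]
  lig$distance <- d[keep]
  lig <- lig[order(lig$distance), , drop = FALSE]
  rownames(lig) <- NULL
  structure(list(center = a[ci, ], ligands = lig, n = nrow(lig),
                 cutoff = cutoff),
            class = "coordination_shell")
}

#' @export
print.coordination_shell <- function(x, ...) {
  cat(sprintf("coordination shell of %s/%s %s (%s): %d ligand(s) <= %.1f A\n",
              x$center$chain, x$center$resno, x$center$atom, x$center$elem,
              x$n, x$cutoff))
  if (x$n) {
    cat(sprintf("  mean distance %.2f A\n", mean(x$ligands$distance)))
  }
  invisible(x)
}
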