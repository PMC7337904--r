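## base_geometry: base reference frames, base-pair and step parameters
## (CEHS mid-step convention), local helical parameters, Zp, sugar
## pseudorotation and per-step A/B classification.

#' Fit the standard reference frame of a base
#'
#' Least-squares superposes the idealized base ring onto the observed ring
#' atoms; the recovered rigid transform is the base frame (origin at the
#' standard-frame origin, axes x into the major groove, y along the pair,
#' z along helix advance).
#'
#' @param residue data.frame of one nucleotide's atoms (columns `atom`,
#'   `resid`, `x`, `y`, `z`).
#' @return list with `origin`, `axes` (3x3, columns x/y/z), `rmsd`, `base`.
#' @export
fit_base_frame <- function(residue) {
  b <- base_letter(residue$resid[1L])
  if (is.na(b)) stop("not a standard nucleotide: ", residue$resid[1L])
  ring <- base_ring_atoms(b)
  nm <- normalize_atom_name(residue$atom)
  miss <- setdiff(ring, nm)
  if (length(miss)) {
    stop("incomplete base ", residue$resid[1L], ": missing ring atoms ",
         paste(miss, collapse = ", "))
  }
  idx <- match(ring, nm)
  obs <- as.matrix(residue[idx, c("x", "y", "z")])
  tmpl <- standard_base(b)[ring, , drop = FALSE]
  fit <- superpose(tmpl, obs)
  list(origin = as.numeric(fit$translation), axes = fit$rotation,
       rmsd = fit$rmsd, base = b)
}

## orientation average of two frames (nearest rotation to the matrix mean)
mean_rotation <- function(R1, R2) nearest_rotation((R1 + R2) / 2)

#' Base-pair reference frame
#'
#' The complementary base frame is flipped about its x axis (y and z
#' negated), then the two frames are averaged; origin is the midpoint of the
#' base origins.
#'
#' @param frame_i,frame_j base frames from [fit_base_frame()]; `frame_j` is
#'   the complementary strand base.
#' @return list with `origin` and `axes`.
#' @export
base_pair_frame <- function(frame_i, frame_j) {
  flip <- diag(c(1, -1, -1))
  Rj <- frame_j$axes %*% flip
  list(origin = (frame_i$origin + frame_j$origin) / 2,
       axes = mean_rotation(frame_i$axes, Rj))
}

#' Base-pair step and local helical parameters
#'
#' Computes shift/slide/rise and tilt/roll/twist in the mid-step frame (CEHS
#' convention), the local helical parameters (x- and y-displacement,
#' inclination, tip, helical rise/twist), and, when the two step phosphorus
#' positions are supplied, Zp: the mean z coordinate of those phosphorus
#' atoms in the mid-step helical frame.  High Zp marks A-form steps.
#'
#' @param pair_frame_1,pair_frame_2 consecutive base-pair frames
#'   (lists with `origin` and `axes`).
#' @param p_atoms optional 2 x 3 matrix with the step phosphorus coordinates
#'   (strand 1 and strand 2).
#' @return object of class `step_parameters`: shift, slide, rise (Angstrom),
#'   tilt, roll, twist (degrees), x_displacement, y_displacement (Angstrom),
#'   inclination, tip, helical_twist, helical_rise, zp, plus the local
#'   helical `axis`/`axis_point` and `classification` (filled by
#'   [classify_step()]).
#' @export
step_parameters <- function(pair_frame_1, pair_frame_2, p_atoms = NULL) {
  R1 <- pair_frame_1$axes; R2 <- pair_frame_2$axes
  o1 <- pair_frame_1$origin; o2 <- pair_frame_2$origin
  if (vnorm(o2 - o1) < 1e-6 && vnorm(R2 - R1) < 1e-8) {
    stop("degenerate step: coincident base-pair frames")
  }
  z1 <- R1[, 3L]; z2 <- R2[, 3L]
  cr <- cross3(z1, z2)
  gamma <- vec_angle(z1, z2)
  if (vnorm(cr) > 1e-9) {
    hinge <- unitv(cr)
    R1p <- rot_axis(hinge, +gamma / 2) %*% R1
    R2p <- rot_axis(hinge, -gamma / 2) %*% R2
  } else {
    hinge <- NULL
    R1p <- R1; R2p <- R2
  }
  zm <- unitv((R1p[, 3L] + R2p[, 3L]) / 2)
  twist <- signed_angle(R1p[, 1L], R2p[, 1L], zm)
  Rm <- nearest_rotation((R1p + R2p) / 2)
  disp <- as.numeric(t(Rm) %*% (o2 - o1))
  if (!is.null(hinge)) {
    phi <- signed_angle(Rm[, 2L], hinge, zm)
    roll <- gamma * cos(phi * DEG)
    tilt <- gamma * sin(phi * DEG)
  } else {
    roll <- 0; tilt <- 0
  }
  ## local helical axis: screw axis of the frame-1 -> frame-2 rigid motion
  Rstep <- R2 %*% t(R1)
  aa <- rotation_axis_angle(Rstep)
  h_axis <- aa$axis
  if (sum(h_axis * zm) < 0) {
    h_axis <- -h_axis
    aa$angle <- -aa$angle
  }
  helical_twist <- aa$angle
  d <- o2 - o1
  helical_rise <- sum(d * h_axis)
  if (abs(aa$angle) > 1e-6) {
    ## point p on the axis: (I - R) p = d_perp  (solved in the plane normal
    ## to the axis), anchored at o1
    d_perp <- d - helical_rise * h_axis
    M <- diag(3L) - Rstep
    ## least-squares with the axis-direction null space removed
    A <- rbind(M, h_axis)
    bvec <- c(d_perp + as.numeric(M %*% o1), sum(h_axis * o1))
    p <- qr.solve(A, bvec)
  } else {
    p <- o1
  }
  ## helical frame at the step: z along the axis, x from the projected
  ## mid-frame x axis
  xh <- Rm[, 1L] - sum(Rm[, 1L] * h_axis) * h_axis
  xh <- unitv(xh)
  yh <- cross3(h_axis, xh)
  o1_on <- p + sum((o1 - p) * h_axis) * h_axis
  xdisp <- sum((o1 - o1_on) * xh)
  ydisp <- sum((o1 - o1_on) * yh)
  incl <- asin(max(-1, min(1, sum(R1[, 2L] * h_axis)))) / DEG
  tip <- asin(max(-1, min(1, sum(R1[, 1L] * h_axis)))) / DEG
  ## Zp: mean z of the step phosphates in the CEHS middle frame, each
  ## phosphate measured in its own strand's frame (z negated for the
  ## complementary strand).  A-form inclination lifts Zp above ~2; B-form
  ## steps sit slightly below zero.
  zp <- NA_real_
  if (!is.null(p_atoms)) {
    om <- (o1 + o2) / 2
    zm2 <- Rm[, 3L]
    pm <- as.matrix(p_atoms)
    zs <- vapply(seq_len(nrow(pm)), function(i) {
      s <- if (i == 1L) 1 else -1
      s * sum((pm[i, ] - om) * zm2)
    }, numeric(1L))
    zp <- mean(zs, na.rm = TRUE)
    if (!is.finite(zp)) zp <- NA_real_
  }
  structure(list(shift = disp[1L], slide = disp[2L], rise = disp[3L],
                 tilt = tilt, roll = roll, twist = twist,
                 x_displacement = xdisp, y_displacement = ydisp,
                 inclination = incl, tip = tip,
                 helical_twist = helical_twist, helical_rise = helical_rise,
                 zp = zp, axis = h_axis, axis_point = as.numeric(p),
                 mid_frame = Rm, classification = NA_character_),
            class = "step_parameters")
}

#' @export
print.step_parameters <- function(x, ...) {
  cat(sprintf(paste0("step: shift %.2f slide %.2f rise %.2f | tilt %.1f ",
                     "roll %.1f twist %.1f | xdisp %.2f incl %.1f | Zp %s",
                     " | %s\n"),
              x$shift, x$slide, x$rise, x$tilt, x$roll, x$twist,
              x$x_displacement, x$inclination,
              if (is.na(x$zp)) "NA" else sprintf("%.2f", x$zp),
              if (is.na(x$classification)) "-" else x$classification))
  invisible(x)
}

#' Classify a step as A, B or intermediate
#'
#' Uses the Zp criterion: A if `zp >= zp_A`, B if `zp <= zp_B`, otherwise
#' intermediate.  Default thresholds (1.5 / 0.5 Angstrom) are calibrated so
#' that every step of an ideal A-form fiber duplex classifies A and every
#' ideal B-form step classifies B.
#'
#' @param step a `step_parameters` object (or a number taken as Zp).
#' @param zp_A,zp_B thresholds in Angstrom.
#' @return `"A"`, `"B"` or `"intermediate"`.
#' @export
classify_step <- function(step, zp_A = 1.5, zp_B = 0.5) {
  zp <- if (inherits(step, "step_parameters")) step$zp else as.numeric(step)
  if (is.na(zp)) return(NA_character_)
  if (zp >= zp_A) "A" else if (zp <= zp_B) "B" else "intermediate"
}

PUCKER_WEDGES <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
                   "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo")

#' Sugar pseudorotation phase and amplitude
#'
#' Altona-Sundaralingam analysis of the five endocyclic torsions
#' nu0..nu4 of a (deoxy)ribose.  The phase P parameterizes the pucker:
#' C3'-endo (A-form sugars) for P in \[0, 36) degrees, C2'-endo (B-form) for
#' P in \[144, 180).
#'
#' @param nu numeric(5): endocyclic torsions nu0..nu4 in degrees
#'   (nu0 = C4'-O4'-C1'-C2', ..., nu4 = C3'-C4'-O4'-C1').
#' @return list with `phase` (degrees in \[0, 360)), `amplitude` (degrees)
#'   and `conformer` label.
#' @export
pseudorotation <- function(nu) {
  nu <- as.numeric(nu)
  if (length(nu) != 5L || any(!is.finite(nu))) {
    stop("pseudorotation needs five finite torsions nu0..nu4")
  }
  denom <- 2 * nu[3L] * (sin(36 * DEG) + sin(72 * DEG))
  numer <- (nu[5L] + nu[2L]) - (nu[4L] + nu[1L])
  if (max(abs(nu)) < 0.5) stop("undefined pucker: ring is planar")
  P <- atan2(numer, denom) / DEG
  ## atan2 form: amplitude from nu2 and P
  amp <- nu[3L] / cos(P * DEG)
  if (!is.finite(amp) || abs(amp) < 0.5) {
    stop("undefined pucker: amplitude is (near) zero")
  }
  if (amp < 0) { amp <- -amp; P <- P + 180 }
  P <- P %% 360
  conf <- PUCKER_WEDGES[floor(P / 36) + 1L]
  list(phase = P, amplitude = amp, conformer = conf)
}

## endocyclic torsions of a nucleotide's sugar ring
sugar_torsions <- function(residue) {
  nm <- normalize_atom_name(residue$atom)
  ring <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  miss <- setdiff(ring, nm)
  if (length(miss)) {
    stop("incomplete sugar: missing ", paste(miss, collapse = ", "))
  }
  xyz <- as.matrix(residue[match(ring, nm), c("x", "y", "z")])
  rownames(xyz) <- ring
  tor <- function(a, b, c, d) torsion4(xyz[a, ], xyz[b, ], xyz[c, ], xyz[d, ])
  c(nu0 = tor("C4'", "O4'", "C1'", "C2'"),
    nu1 = tor("O4'", "C1'", "C2'", "C3'"),
    nu2 = tor("C1'", "C2'", "C3'", "C4'"),
    nu3 = tor("C2'", "C3'", "C4'", "O4'"),
    nu4 = tor("C3'", "C4'", "O4'", "C1'"))
}

#' Sugar pucker of a nucleotide residue
#'
#' Convenience wrapper computing the endocyclic torsions from atom
#' coordinates and passing them to [pseudorotation()].
#'
#' @param residue data.frame of one nucleotide's atoms.
#' @return as [pseudorotation()].
#' @export
sugar_pucker <- function(residue) {
  pseudorotation(sugar_torsions(residue))
}
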