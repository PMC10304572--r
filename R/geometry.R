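# Vector helpers -------------------------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Folded angle in [0, 90] degrees between two directionless axes.
fold_angle <- function(u, v) {
  d <- abs(sum(unit(u) * unit(v)))
  acos(min(1, d)) * 180 / pi
}

# Minimum-image displacement for an orthorhombic box (NULL box = open space).
min_image <- function(d, box = NULL) {
  if (is.null(box)) return(d)
  d - box * round(d / box)
}

#' Local reference frame of a dye's xanthene plane
#'
#' Builds the molecular frame used as a proxy for the transition dipole: the
#' centroid of the xanthene atoms, the best-fit plane normal (smallest
#' singular direction of the centered xanthene coordinates), and the long
#' axis defined by `long_axis_atoms`, projected into the plane. The in-plane
#' short axis completes a right-handed triad (`x cross y = z`).
#'
#' @param dye_atoms Data frame of one dye molecule's atoms with columns
#'   `atom_name`, `x`, `y`, `z`.
#' @param topology A [system_topology()].
#' @return An object of class `molecule_frame`: a list with `center`,
#'   `x_axis`, `y_axis`, `z_axis` (unit 3-vectors) and `probe_coords`
#'   (4 x 3 matrix of the stack-probe atom coordinates).
#' @export
compute_frame <- function(dye_atoms, topology) {
  dye_atoms <- as.data.frame(dye_atoms)
  sel <- match(topology$xanthene_atoms, dye_atoms$atom_name)
  if (anyNA(sel)) {
    stop("dye molecule is missing xanthene atom(s): ",
         paste(topology$xanthene_atoms[is.na(sel)], collapse = ", "),
         call. = FALSE)
  }
  xm <- as.matrix(dye_atoms[sel, c("x", "y", "z")])
  center <- unname(colMeans(xm))
  centered <- sweep(xm, 2, center)
  sv <- svd(centered)
  if (abs(sv$d[2] - sv$d[3]) < 1e-10) {
    stop("degenerate xanthene geometry: atoms are collinear ",
         "(plane normal undefined)", call. = FALSE)
  }
  z_axis <- sv$v[, 3]
  la <- match(topology$long_axis_atoms, dye_atoms$atom_name)
  if (anyNA(la)) {
    stop("dye molecule is missing long-axis atom(s): ",
         paste(topology$long_axis_atoms[is.na(la)], collapse = ", "),
         call. = FALSE)
  }
  raw <- as.numeric(dye_atoms[la[2], c("x", "y", "z")]) -
    as.numeric(dye_atoms[la[1], c("x", "y", "z")])
  in_plane <- raw - sum(raw * z_axis) * z_axis
  if (vnorm(in_plane) < 1e-10) {
    stop("long axis is perpendicular to the xanthene plane", call. = FALSE)
  }
  x_axis <- unit(in_plane)
  y_axis <- cross3(z_axis, x_axis)
  pr <- match(topology$stack_probe_atoms, dye_atoms$atom_name)
  if (anyNA(pr)) {
    stop("dye molecule is missing stack probe atom(s): ",
         paste(topology$stack_probe_atoms[is.na(pr)], collapse = ", "),
         call. = FALSE)
  }
  probe_coords <- as.matrix(dye_atoms[pr, c("x", "y", "z")])
  rownames(probe_coords) <- topology$stack_probe_atoms
  structure(
    list(center = center, x_axis = x_axis, y_axis = y_axis, z_axis = z_axis,
         probe_coords = probe_coords),
    class = "molecule_frame"
  )
}

#' Pairwise dimer geometry between two molecular frames
#'
#' Computes the center-center vector `rcc_vec` (minimum image when `box` is
#' given), its modulus `rcc`, the folded angle `theta` between the two long
#' axes, the folded angle `alpha` between `rcc_vec` and the sign-aligned mean
#' long axis, the in-frame components `rx`, `ry`, `rz` of `rcc_vec` evaluated
#' in each molecule's own frame, and the perpendicular distances of each
#' molecule's four probe atoms from the partner's best-fit plane. Angles are
#' folded into [0, 90] degrees because molecular axes are directionless.
#'
#' @param frameA,frameB [compute_frame()] results.
#' @param box Optional length-3 box sides (angstrom) for minimum image.
#' @return An object of class `dimer_geometry`: a list with elements
#'   `rcc_vec`, `rcc`, `theta`, `alpha`, `rx`, `ry`, `rz` (each of the last
#'   three a named vector with entries `A` and `B`, one per frame ordering)
#'   and `probe_plane_dists` (2 x 4 matrix, row `A` = A's probes against B's
#'   plane and vice versa).
#' @export
dimer_geometry <- function(frameA, frameB, box = NULL) {
  stopifnot(inherits(frameA, "molecule_frame"), inherits(frameB, "molecule_frame"))
  d_raw <- frameB$center - frameA$center
  d <- min_image(d_raw, box)
  shift <- d - d_raw          # lattice shift applied to all of molecule B
  rcc <- vnorm(d)
  if (rcc < 1e-9) {
    stop("coincident molecule centers: alpha is undefined", call. = FALSE)
  }
  xA <- frameA$x_axis; xB <- frameB$x_axis
  theta <- fold_angle(xA, xB)
  s <- sum(xA * xB)
  mean_axis <- xA + (if (s >= 0) 1 else -1) * xB
  if (vnorm(mean_axis) < 1e-9) {
    # axes exactly perpendicular after sign alignment cannot happen for the
    # folded range; exactly antiparallel is handled by the sign flip, so this
    # only triggers for numerically null axes
    stop("mean long axis undefined", call. = FALSE)
  }
  alpha <- fold_angle(d, mean_axis)
  rx <- c(A = abs(sum(d * frameA$x_axis)), B = abs(sum(d * frameB$x_axis)))
  ry <- c(A = abs(sum(d * frameA$y_axis)), B = abs(sum(d * frameB$y_axis)))
  rz <- c(A = abs(sum(d * frameA$z_axis)), B = abs(sum(d * frameB$z_axis)))
  centerB <- frameB$center + shift
  probesB <- sweep(frameB$probe_coords, 2, shift, `+`)
  dist_A_to_Bplane <- abs(as.numeric(
    sweep(frameA$probe_coords, 2, centerB) %*% frameB$z_axis))
  dist_B_to_Aplane <- abs(as.numeric(
    sweep(probesB, 2, frameA$center) %*% frameA$z_axis))
  probe_plane_dists <- rbind(A = dist_A_to_Bplane, B = dist_B_to_Aplane)
  structure(
    list(rcc_vec = d, rcc = rcc, theta = theta, alpha = alpha,
         rx = rx, ry = ry, rz = rz, probe_plane_dists = probe_plane_dists),
    class = "dimer_geometry"
  )
}

#' @export
print.dimer_geometry <- function(x, ...) {
  cat(sprintf("<dimer_geometry> rcc = %.3f A, theta = %.2f deg, alpha = %.2f deg\n",
              x$rcc, x$theta, x$alpha))
  cat(sprintf("  rx = (%.3f, %.3f), ry = (%.3f, %.3f) A\n",
              x$rx["A"], x$rx["B"], x$ry["A"], x$ry["B"]))
  cat(sprintf("  probe-plane distances: A->B [%s], B->A [%s] A\n",
              paste(sprintf("%.2f", x$probe_plane_dists["A", ]), collapse = ", "),
              paste(sprintf("%.2f", x$probe_plane_dists["B", ]), collapse = ", ")))
  invisible(x)
}

# Molecular frames for every dye molecule in a single-frame trajectory table.
dye_frames <- function(frame_df, topology) {
  role <- residue_role(frame_df$residue_name, topology)
  dye_ids <- unique(frame_df$molecule_id[role == "dye"])
  frames <- lapply(dye_ids, function(mid) {
    compute_frame(frame_df[frame_df$molecule_id == mid, ], topology)
  })
  names(frames) <- as.character(dye_ids)
  list(ids = dye_ids, frames = frames)
}
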