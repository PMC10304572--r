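# Shared fixtures and independent brute-force oracles. The oracles recompute
# every quantity from raw coordinates with plain loops and eigen-decomposition
# (not the package's svd path) so that agreement is a genuine cross-check.

TOPO <- template_topology()
DYE_TPL <- rigid_dye_template()

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
}

random_rot <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Single frame with one dye per (center, rotation)
make_dye_frame <- function(centers, rotations = NULL, box = NULL,
                           template = DYE_TPL) {
  centers <- matrix(centers, ncol = 3)
  n <- nrow(centers)
  if (is.null(rotations)) rotations <- replicate(n, diag(3), simplify = FALSE)
  rows <- lapply(seq_len(n), function(i) {
    xyz <- as.matrix(template[, c("x", "y", "z")]) %*% t(rotations[[i]])
    tibble::tibble(
      frame = 1L, time = 0, molecule_id = i,
      residue_name = "RBE", residue_id = i,
      atom_name = template$atom_name, element = template$element,
      x = xyz[, 1] + centers[i, 1], y = xyz[, 2] + centers[i, 2],
      z = xyz[, 3] + centers[i, 3])
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "box") <- box
  out
}

# ---- brute-force geometry/classification oracle -----------------------------

bf_min_image <- function(d, box) if (is.null(box)) d else d - box * round(d / box)

bf_frame_axes <- function(mol, topo) {
  xm <- as.matrix(mol[match(topo$xanthene_atoms, mol$atom_name), c("x", "y", "z")])
  ctr <- colMeans(xm)
  cen <- sweep(xm, 2, ctr)
  ev <- eigen(t(cen) %*% cen, symmetric = TRUE)
  zax <- ev$vectors[, 3]
  la <- as.numeric(mol[match(topo$long_axis_atoms[2], mol$atom_name), c("x", "y", "z")]) -
    as.numeric(mol[match(topo$long_axis_atoms[1], mol$atom_name), c("x", "y", "z")])
  la <- la - sum(la * zax) * zax
  xax <- la / sqrt(sum(la^2))
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])
  probes <- as.matrix(mol[match(topo$stack_probe_atoms, mol$atom_name),
                          c("x", "y", "z")])
  list(center = ctr, x = xax, y = yax, z = zax, probes = probes)
}

bf_fold <- function(u, v) {
  acos(min(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)))) * 180 / pi
}

# One dye pair, classified from raw coordinates
bf_classify_pair <- function(molA, molB, topo, thr, box = NULL) {
  fa <- bf_frame_axes(molA, topo)
  fb <- bf_frame_axes(molB, topo)
  d0 <- fb$center - fa$center
  d <- bf_min_image(d0, box)
  shift <- d - d0
  rcc <- sqrt(sum(d^2))
  theta <- bf_fold(fa$x, fb$x)
  sgn <- if (sum(fa$x * fb$x) >= 0) 1 else -1
  m <- fa$x + sgn * fb$x
  alpha <- bf_fold(d, m)
  interacting <- rcc < thr$rcc_cut
  cls <- if (!interacting) "none"
    else if (theta >= thr$theta_cut) "crossed_J"
    else if (alpha > thr$alpha_magic) "H" else "J"
  # base molecule's lateral offsets paired with the PARTNER's probe atoms
  # against the base plane
  stack_side <- function(x_ax, y_ax, partner_probes, base_center, base_z) {
    rx <- abs(sum(d * x_ax)); ry <- abs(sum(d * y_ax))
    dists <- apply(partner_probes, 1,
                   function(p) abs(sum((p - base_center) * base_z)))
    rx < thr$stack_rx_cut && ry < thr$stack_ry_cut &&
      all(dists < thr$stack_plane_cut)
  }
  cb <- fa$center + d
  pb <- sweep(fb$probes, 2, shift, `+`)
  stacked <- interacting &&
    (stack_side(fa$x, fa$y, pb, fa$center, fa$z) ||
     stack_side(fb$x, fb$y, fa$probes, cb, fb$z))
  list(rcc = rcc, theta = theta, alpha = alpha,
       interacting = interacting, class = cls, stacked = stacked)
}

bf_classify_frame <- function(frame_df, topo, thr, box = NULL) {
  ids <- sort(unique(frame_df$molecule_id[
    frame_df$residue_name %in% names(topo$role_map)[topo$role_map == "dye"]]))
  out <- list()
  k <- 0
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    k <- k + 1
    res <- bf_classify_pair(frame_df[frame_df$molecule_id == ids[i], ],
                            frame_df[frame_df$molecule_id == ids[j], ],
                            topo, thr, box)
    out[[k]] <- tibble::tibble(mol_a = ids[i], mol_b = ids[j],
                               interacting = res$interacting,
                               geometry_class = res$class,
                               stacked = res$stacked)
  }
  dplyr::bind_rows(out)
}

# ---- brute-force nonbonded energy oracle ------------------------------------

bf_pair_energy <- function(molA, molB, scale_factor = 1) {
  e <- 0
  for (i in seq_len(nrow(molA))) for (j in seq_len(nrow(molB))) {
    r <- sqrt((molA$x[i] - molB$x[j])^2 + (molA$y[i] - molB$y[j])^2 +
              (molA$z[i] - molB$z[j])^2)
    s <- if (molA$scaled_subset[i] && molB$scaled_subset[j]) scale_factor else 1
    eps <- s * sqrt(molA$epsilon[i] * molB$epsilon[j])
    rmin <- molA$rmin_half[i] + molB$rmin_half[j]
    e <- e + 332.0636 * molA$charge[i] * molB$charge[j] / r +
      eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }
  e
}

random_molecule <- function(n_atoms = 20, origin = c(0, 0, 0)) {
  nonbonded_params(tibble::tibble(
    x = origin[1] + runif(n_atoms, -3, 3),
    y = origin[2] + runif(n_atoms, -3, 3),
    z = origin[3] + runif(n_atoms, -3, 3),
    charge = runif(n_atoms, -0.5, 0.5),
    epsilon = runif(n_atoms, 0, 0.3),
    rmin_half = runif(n_atoms, 1, 2.5),
    scaled_subset = runif(n_atoms) < 0.5
  ))
}

torsion_fixture_path <- function() {
  system.file("extdata", "torsion_scan_3well_synthetic.csv",
              package = "dyeaggr", mustWork = TRUE)
}
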