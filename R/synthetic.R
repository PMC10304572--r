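# Synthetic test systems: a rigid planar dye stand-in with the topology roles
# of a xanthene dye (plane atoms, long-axis pair, four stack probes), planted
# dimer geometries, dispersed frames, and a seeded rigid-body Monte Carlo
# aggregation generator with a counterion-attraction toggle. The dye template
# is a geometric stand-in with toy nonbonded parameters, not a claim about
# the real molecule's geometry or charges.

#' Rigid planar dye template
#'
#' A planar tricyclic scaffold built from three fused idealized hexagons
#' (bond length 1.4 angstrom) with a bridging oxygen at the central-ring
#' apex, two nitrogen atoms extending the long axis (net +1 e overall), and a
#' short planar tail. The four ring-junction carbons `C1`-`C4` serve as the
#' stack-probe atoms; the xanthene subset (ring carbons plus the oxygen)
#' carries the `scaled_subset` flag used by the epsilon-scaling machinery.
#'
#' @return A tibble of atoms (`atom_name`, `element`, `x`, `y`, `z`,
#'   `charge`, `epsilon`, `rmin_half`, `scaled_subset`) with attribute
#'   `residue_name = "RBE"`. The xanthene centroid sits at the local origin
#'   and the long axis along local x.
#' @export
rigid_dye_template <- function() {
  h <- 1.4 * sqrt(3) / 2   # 1.2124, half the hex width
  cx <- 1.4 * sqrt(3)      # fused-ring center spacing
  ring <- rbind(
    # ring-junction carbons (stack probes)
    C1 = c(h, 0.7), C2 = c(-h, 0.7), C3 = c(-h, -0.7), C4 = c(h, -0.7),
    # remaining ring carbons
    C5 = c(0, -1.4),
    C6 = c(cx, 1.4), C7 = c(-cx, 1.4), C8 = c(-cx, -1.4), C9 = c(cx, -1.4),
    C10 = c(cx + h, 0.7), C11 = c(-cx - h, 0.7),
    C12 = c(-cx - h, -0.7), C13 = c(cx + h, -0.7)
  )
  atoms <- tibble::tibble(
    atom_name = c(rownames(ring), "O1", "N1", "N2", "C14"),
    element = c(rep("C", 13), "O", "N", "N", "C"),
    x = c(ring[, 1], 0, -5.04, 5.04, 0),
    y = c(ring[, 2], 1.4, 0, 0, -2.8),
    z = 0,
    charge = c(rep(0.5 / 13, 13), -0.25, 0.30, 0.30, 0.15),
    epsilon = c(rep(0.086, 13), 0.21, 0.17, 0.17, 0.086),
    rmin_half = c(rep(1.908, 13), 1.6612, 1.824, 1.824, 1.908),
    scaled_subset = c(rep(TRUE, 13), TRUE, FALSE, FALSE, FALSE)
  )
  xan <- atoms$scaled_subset
  ctr <- c(mean(atoms$x[xan]), mean(atoms$y[xan]), mean(atoms$z[xan]))
  atoms$x <- atoms$x - ctr[1]; atoms$y <- atoms$y - ctr[2]; atoms$z <- atoms$z - ctr[3]
  attr(atoms, "residue_name") <- "RBE"
  atoms
}

#' Toy nonbonded parameter table for the dye template
#'
#' The [rigid_dye_template()] atoms as a [nonbonded_params()] table, with an
#' optional uniform charge scaling. With the full +1 e net charge the vacuum
#' dimer approach curve of this 17-atom stand-in is purely repulsive (its toy
#' dispersion cannot offset the Coulomb repulsion the way a full-size dye
#' can); `charge_scale = 0.25` yields the characteristic shape of the real
#' system - a Coulomb approach barrier followed by a van der Waals well near
#' 3.5 angstrom - and is the recommended setting for demonstration scans.
#'
#' @param charge_scale Uniform factor applied to all charges.
#' @return A [nonbonded_params()] tibble (with `atom_name`).
#' @export
dye_nonbonded_table <- function(charge_scale = 1) {
  tpl <- rigid_dye_template()
  tpl$charge <- tpl$charge * charge_scale
  nonbonded_params(tpl[, c("atom_name", "x", "y", "z", "charge", "epsilon",
                           "rmin_half", "scaled_subset")])
}

#' Counterion templates for the two aggregation regimes
#'
#' `bulky_hydrophobic` emulates a tetraarylborate-like anion: a central boron
#' with eight stylized aryl-arm atoms at 3.5 angstrom (two interleaved
#' tetrahedra), net charge -1 e. `small_ionic` is a single iodide-like atom.
#'
#' @param mode `"bulky_hydrophobic"` or `"small_ionic"`.
#' @return An atom tibble like [rigid_dye_template()], with attribute
#'   `residue_name` (`"F5T"` or `"IOD"`).
#' @export
counterion_template <- function(mode = c("bulky_hydrophobic", "small_ionic")) {
  mode <- match.arg(mode)
  if (mode == "small_ionic") {
    atoms <- tibble::tibble(
      atom_name = "I1", element = "I", x = 0, y = 0, z = 0,
      charge = -1, epsilon = 0.4, rmin_half = 2.35, scaled_subset = FALSE
    )
    attr(atoms, "residue_name") <- "IOD"
    return(atoms)
  }
  s <- 3.5 / sqrt(3)
  dirs <- rbind(
    c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1),
    c(-1, -1, -1), c(-1, 1, 1), c(1, -1, 1), c(1, 1, -1)
  ) * s
  atoms <- tibble::tibble(
    atom_name = c("B1", paste0("A", 1:8)),
    element = c("B", rep("C", 8)),
    x = c(0, dirs[, 1]), y = c(0, dirs[, 2]), z = c(0, dirs[, 3]),
    charge = c(-0.2, rep(-0.1, 8)),
    epsilon = c(0.1, rep(0.25, 8)),
    rmin_half = c(2.0, rep(2.0, 8)),
    scaled_subset = FALSE
  )
  attr(atoms, "residue_name") <- "F5T"
  atoms
}

#' Topology matching the synthetic templates
#'
#' @param counterion_mode Which counterion residue to register.
#' @return A [system_topology()] for frames built from
#'   [rigid_dye_template()] and [counterion_template()].
#' @export
template_topology <- function(counterion_mode = c("bulky_hydrophobic", "small_ionic")) {
  counterion_mode <- match.arg(counterion_mode)
  ci_res <- attr(counterion_template(counterion_mode), "residue_name")
  roles <- c("dye", "counterion", "solvent")
  names(roles) <- c("RBE", ci_res, "HOH")
  tpl <- rigid_dye_template()
  system_topology(
    role_map = roles,
    xanthene_atoms = tpl$atom_name[tpl$scaled_subset],
    long_axis_atoms = c("N1", "N2"),
    stack_probe_atoms = c("C1", "C2", "C3", "C4")
  )
}

#' Configuration of the synthetic aggregation generator
#'
#' Defaults mirror the study conditions of the reference systems: 10 dyes and
#' 10 counterions in a cubic box of side 85 angstrom, initially dispersed
#' with all dye-dye center distances above 6 angstrom. The Monte Carlo moves
#' are rigid single-molecule translations (max 0.5 angstrom per axis) and
#' rotations (max 10 degrees) at 300 K, supplemented by rigid whole-cluster
#' translations so that formed clusters keep diffusing; electrostatics are
#' Debye-screened with dielectric 78.5 as an implicit-water stand-in.
#' `attraction_scale` sets the epsilon boost on dye-counterion site pairs
#' that models the hydrophobic dye/counterion affinity: it defaults to 25 for
#' `bulky_hydrophobic` and 0 for `small_ionic`.
#'
#' @param n_dye,n_counterion Molecule counts.
#' @param box_side Cubic box side (angstrom).
#' @param seed Integer seed; identical configs give identical trajectories.
#' @param counterion_mode `"bulky_hydrophobic"` or `"small_ionic"`.
#' @param attraction_scale Nonnegative dye-counterion epsilon boost.
#' @param n_steps Number of Monte Carlo moves.
#' @param frame_stride Emit a frame every this many moves.
#' @param timestep_label Nominal ns per emitted frame (labeling only).
#' @param temperature Metropolis temperature (K).
#' @param max_translation,max_rotation Single-molecule move sizes (angstrom,
#'   degrees).
#' @param cluster_move_prob Probability of a whole-cluster translation move.
#' @param cluster_translation Cluster move size (angstrom per axis).
#' @param cluster_cut Center-center distance defining move-time clusters.
#' @param dye_site_epsilon Lennard-Jones well depth (kcal/mol) of the dye
#'   coarse sites, controlling direct dye-dye stickiness (transient stacked
#'   dimers in both regimes).
#' @param dielectric,debye_length Implicit-solvent screening (unitless,
#'   angstrom).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_dye = 10, n_counterion = 10, box_side = 85,
                             seed = 1,
                             counterion_mode = c("bulky_hydrophobic", "small_ionic"),
                             attraction_scale = NULL,
                             n_steps = 80000, frame_stride = 800,
                             timestep_label = 0.02,
                             temperature = 300,
                             max_translation = 0.5, max_rotation = 10,
                             cluster_move_prob = 0.25,
                             cluster_translation = 1.5,
                             cluster_cut = 9.0,
                             dye_site_epsilon = 0.2,
                             dielectric = 78.5, debye_length = 10) {
  counterion_mode <- match.arg(counterion_mode)
  if (is.null(attraction_scale)) {
    attraction_scale <- if (counterion_mode == "bulky_hydrophobic") 25 else 0
  }
  stopifnot(n_dye >= 0, n_counterion >= 0, box_side > 0,
            attraction_scale >= 0, n_steps >= 0, frame_stride >= 1,
            timestep_label > 0, temperature > 0,
            max_translation > 0, max_rotation > 0,
            cluster_move_prob >= 0, cluster_move_prob <= 1,
            cluster_translation > 0, cluster_cut > 0, dye_site_epsilon > 0,
            dielectric > 0, debye_length > 0)
  structure(
    list(n_dye = as.integer(n_dye), n_counterion = as.integer(n_counterion),
         box_side = box_side, seed = as.integer(seed),
         counterion_mode = counterion_mode,
         attraction_scale = attraction_scale,
         n_steps = as.integer(n_steps), frame_stride = as.integer(frame_stride),
         timestep_label = timestep_label, temperature = temperature,
         max_translation = max_translation, max_rotation = max_rotation,
         cluster_move_prob = cluster_move_prob,
         cluster_translation = cluster_translation, cluster_cut = cluster_cut,
         dye_site_epsilon = dye_site_epsilon,
         dielectric = dielectric, debye_length = debye_length),
    class = "synthetic_config"
  )
}

rotation_about_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# Rotation by `deg` degrees about an arbitrary unit axis (Rodrigues).
rotation_about_axis <- function(axis, deg) {
  u <- unit(axis)
  th <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Atom rows of one template placed at `center` with rotation `rot`.
place_template <- function(template, center, rot, residue_id, frame, time) {
  xyz <- as.matrix(template[, c("x", "y", "z")]) %*% t(rot)
  tibble::tibble(
    frame = frame, time = time, molecule_id = 0L,
    residue_name = attr(template, "residue_name"),
    residue_id = as.integer(residue_id),
    atom_name = template$atom_name, element = template$element,
    x = xyz[, 1] + center[1], y = xyz[, 2] + center[2], z = xyz[, 3] + center[3]
  )
}

# Build a full-atom single-frame table from per-molecule centers/rotations.
build_frame <- function(centers, rotations, kinds, dye_tpl, ci_tpl,
                        frame, time, box) {
  rows <- vector("list", nrow(centers))
  dye_i <- 0L; ci_i <- 0L
  for (i in seq_len(nrow(centers))) {
    if (kinds[i] == "dye") {
      dye_i <- dye_i + 1L
      rows[[i]] <- place_template(dye_tpl, centers[i, ], rotations[[i]],
                                  dye_i, frame, time)
    } else {
      ci_i <- ci_i + 1L
      rows[[i]] <- place_template(ci_tpl, centers[i, ], rotations[[i]],
                                  ci_i, frame, time)
    }
  }
  df <- dplyr::bind_rows(rows)
  df$molecule_id <- assign_molecule_ids(df$residue_name, df$residue_id)
  new_trajectory(df, box)
}

#' Plant a dimer with prescribed geometry
#'
#' Places two copies of the dye template so that [dimer_geometry()] recovers
#' the requested `(theta, alpha, rcc)` exactly (to numerical precision).
#' Molecule A sits at the origin in its local frame; molecule B is rotated by
#' `theta` about the shared plane normal and displaced by a center-center
#' vector with component `rcc cos(alpha)` along the mean long axis,
#' `plane_sep` along the plane normal, and the in-plane remainder
#' perpendicular to both. By default all of the perpendicular displacement is
#' out-of-plane (`plane_sep = rcc sin(alpha)`), giving the planted plane
#' separation directly.
#'
#' @param theta Angle between the two long axes (degrees, in \[0, 90\]).
#' @param alpha Angle between the center-center vector and the mean long axis
#'   (degrees, in \[0, 90\]).
#' @param rcc Center-center distance (angstrom, > 0).
#' @param plane_sep Out-of-plane component of the center-center vector
#'   (angstrom); must not exceed `rcc sin(alpha)` within rounding. `NULL`
#'   (default) uses `rcc sin(alpha)`.
#' @param template Dye template tibble ([rigid_dye_template()]).
#' @return A single-frame, non-periodic trajectory tibble of two dye
#'   molecules.
#' @export
make_planted_dimer <- function(theta, alpha, rcc, plane_sep = NULL,
                               template = rigid_dye_template()) {
  if (theta < 0 || theta > 90) stop("`theta` must be in [0, 90]", call. = FALSE)
  if (alpha < 0 || alpha > 90) stop("`alpha` must be in [0, 90]", call. = FALSE)
  if (rcc <= 0) stop("`rcc` must be positive", call. = FALSE)
  a <- rcc * cos(alpha * pi / 180)
  perp <- sqrt(max(0, rcc^2 - a^2))
  if (is.null(plane_sep)) plane_sep <- perp
  if (plane_sep > rcc * (1 + 1e-12)) {
    stop("infeasible geometry: `plane_sep` exceeds `rcc`", call. = FALSE)
  }
  if (a^2 + plane_sep^2 > rcc^2 * (1 + 1e-9)) {
    stop("infeasible geometry: rcc cos(alpha) and plane_sep leave no ",
         "in-plane component (plane_sep > rcc sin(alpha))", call. = FALSE)
  }
  b <- sqrt(max(0, rcc^2 - a^2 - plane_sep^2))
  half <- theta / 2 * pi / 180
  m <- c(cos(half), sin(half), 0)           # mean long axis direction
  p <- c(-sin(half), cos(half), 0)          # in-plane normal to m
  rvec <- a * m + b * p + plane_sep * c(0, 0, 1)
  # A's long axis lies along x and B's at theta, so m is their exact bisector
  rotA <- rotation_about_z(0)
  rotB <- rotation_about_z(theta)
  df <- dplyr::bind_rows(
    place_template(template, c(0, 0, 0), rotA, 1L, 1L, 0),
    place_template(template, rvec, rotB, 2L, 1L, 0)
  )
  df$molecule_id <- assign_molecule_ids(df$residue_name, df$residue_id)
  new_trajectory(df, box = NULL)
}

# Rejection-sampled molecule placement: dye-dye centers > dye_min_sep, any
# pair > any_min_sep (minimum image). Returns centers, rotations, kinds.
place_molecules <- function(config, dye_min_sep = 6, any_min_sep = 5,
                            max_attempts = 5000) {
  n <- config$n_dye + config$n_counterion
  box <- rep(config$box_side, 3)
  if (n * 4 / 3 * pi * (any_min_sep / 2)^3 > 0.5 * prod(box)) {
    stop("packing infeasible: molecule exclusion volume exceeds half the box",
         call. = FALSE)
  }
  kinds <- c(rep("dye", config$n_dye), rep("counterion", config$n_counterion))
  centers <- matrix(NA_real_, n, 3)
  rotations <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      cand <- stats::runif(3, 0, config$box_side)
      ok <- TRUE
      if (i > 1) {
        d <- sweep(centers[seq_len(i - 1), , drop = FALSE], 2, cand)
        d <- d - sweep(round(sweep(d, 2, box, `/`)), 2, box, `*`)
        dist <- sqrt(rowSums(d * d))
        lim <- ifelse(kinds[seq_len(i - 1)] == "dye" & kinds[i] == "dye",
                      dye_min_sep, any_min_sep)
        ok <- all(dist > lim)
      }
      if (ok) {
        centers[i, ] <- cand
        rotations[[i]] <- random_rotation()
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("failed to place molecule ", i, " after ", max_attempts,
           " attempts (box too dense)", call. = FALSE)
    }
  }
  list(centers = centers, rotations = rotations, kinds = kinds)
}

#' Generate a dispersed frame
#'
#' Random seeded placement of `n_dye` dyes and `n_counterion` counterions in
#' the periodic box with all dye-dye center distances above 6 angstrom
#' (minimum image), each molecule in a uniformly random orientation.
#'
#' @param config A [synthetic_config()].
#' @return A single-frame trajectory tibble with the box attribute set.
#' @export
make_dispersed_frame <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    pl <- place_molecules(config)
    build_frame(pl$centers, pl$rotations, pl$kinds,
                rigid_dye_template(), counterion_template(config$counterion_mode),
                frame = 1L, time = 0, box = rep(config$box_side, 3))
  })
}

# Coarse interaction sites used by the Monte Carlo energy model: three
# collinear sites along the dye long axis, one site per counterion.
coarse_sites <- function(config) {
  dye_local <- rbind(c(-3, 0, 0), c(0, 0, 0), c(3, 0, 0))
  ci <- counterion_template(config$counterion_mode)
  ci_rmin <- if (config$counterion_mode == "bulky_hydrophobic") 4.5 else 2.35
  ci_eps <- if (config$counterion_mode == "bulky_hydrophobic") 0.5 else 0.4
  list(
    dye_local = dye_local,
    dye_charge = rep(1 / 3, 3),
    dye_eps = rep(config$dye_site_epsilon, 3), dye_rmin = rep(2.4, 3),
    ci_charge = sum(ci$charge), ci_eps = ci_eps, ci_rmin = ci_rmin
  )
}

#' Synthetic aggregation trajectory (rigid-body Metropolis Monte Carlo)
#'
#' Evolves the dispersed initial frame of [make_dispersed_frame()] by
#' Metropolis Monte Carlo over coarse interaction sites (three collinear
#' sites per dye, one per counterion) with Debye-screened Coulomb plus
#' Lennard-Jones energies, in the same functional form as [pair_energy()].
#' In `bulky_hydrophobic` mode the dye-counterion epsilon is multiplied by
#' `1 + attraction_scale`, modelling the hydrophobic affinity that lets the
#' bulky anion glue dyes into aggregates while sitting between them; with
#' `attraction_scale = 0` (the `small_ionic` default) interactions stay
#' within a thermal energy and the system remains dispersed. Moves are
#' single-molecule rigid translations/rotations plus whole-cluster
#' translations; frames are emitted every `frame_stride` moves with
#' monotonically increasing nominal times. Identical configs (including the
#' seed) produce identical trajectories.
#'
#' @param config A [synthetic_config()].
#' @return A trajectory tibble (full-atom frames built from the templates),
#'   with attributes `box` and `config`.
#' @export
run_aggregation <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  box <- rep(config$box_side, 3)
  dye_tpl <- rigid_dye_template()
  ci_tpl <- counterion_template(config$counterion_mode)
  cs <- coarse_sites(config)
  kT <- 0.0019872041 * config$temperature
  n <- config$n_dye + config$n_counterion

  withr::with_seed(config$seed, {
    pl <- place_molecules(config)
    centers <- pl$centers
    rotations <- pl$rotations
    kinds <- pl$kinds
    is_dye <- kinds == "dye"

    # flat site arrays
    sites_of <- function(i) {
      if (is_dye[i]) {
        sweep(cs$dye_local %*% t(rotations[[i]]), 2, centers[i, ], `+`)
      } else {
        matrix(centers[i, ], 1, 3)
      }
    }
    n_sites_mol <- ifelse(is_dye, 3L, 1L)
    site_mol <- rep(seq_len(n), n_sites_mol)
    site_dye <- is_dye[site_mol]
    site_charge <- ifelse(site_dye, 1 / 3, cs$ci_charge)
    site_eps <- ifelse(site_dye, cs$dye_eps[1], cs$ci_eps)
    site_rmin <- ifelse(site_dye, cs$dye_rmin[1], cs$ci_rmin)
    site_xyz <- do.call(rbind, lapply(seq_len(n), sites_of))

    kappa <- 1 / config$debye_length
    boost <- 1 + config$attraction_scale

    # Metropolis energy change for replacing the sites in `sel` (old
    # positions from site_xyz) by new_xyz; interactions within `sel` cancel
    delta_energy <- function(new_xyz, sel) {
      oth <- which(!sel)
      if (length(oth) == 0) return(0)
      mine <- which(sel)
      both <- rbind(new_xyz, site_xyz[mine, , drop = FALSE])
      m <- nrow(new_xyz)
      dx <- outer(both[, 1], site_xyz[oth, 1], `-`)
      dy <- outer(both[, 2], site_xyz[oth, 2], `-`)
      dz <- outer(both[, 3], site_xyz[oth, 3], `-`)
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
      dz <- dz - box[3] * round(dz / box[3])
      r <- sqrt(dx * dx + dy * dy + dz * dz)
      qs <- c(site_charge[mine], site_charge[mine])
      coul <- KCOULOMB * outer(qs, site_charge[oth]) /
        (config$dielectric * r) * exp(-kappa * r)
      eps <- sqrt(outer(c(site_eps[mine], site_eps[mine]), site_eps[oth]))
      cross <- outer(c(site_dye[mine], site_dye[mine]), site_dye[oth], `!=`)
      eps[cross] <- eps[cross] * boost
      rmin <- outer(c(site_rmin[mine], site_rmin[mine]), site_rmin[oth], `+`)
      f6 <- (rmin / r)^6
      e <- coul + eps * (f6 * f6 - 2 * f6)
      sum(e[seq_len(m), ]) - sum(e[m + seq_len(m), ])
    }

    # connected components of the center-distance contact graph by label
    # propagation (cheap at these molecule counts; called every cluster move)
    mol_clusters <- function() {
      dx <- outer(centers[, 1], centers[, 1], `-`)
      dy <- outer(centers[, 2], centers[, 2], `-`)
      dz <- outer(centers[, 3], centers[, 3], `-`)
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
      dz <- dz - box[3] * round(dz / box[3])
      adj <- (dx * dx + dy * dy + dz * dz) < config$cluster_cut^2
      labels <- seq_len(n)
      repeat {
        new_labels <- vapply(seq_len(n),
                             function(i) min(labels[adj[i, ]]), numeric(1))
        if (identical(new_labels, labels)) break
        labels <- new_labels
      }
      match(labels, unique(labels))
    }

    frames <- list()
    frame_i <- 0L
    emit <- function(step) {
      frame_i <<- frame_i + 1L
      frames[[frame_i]] <<- build_frame(
        centers, rotations, kinds, dye_tpl, ci_tpl,
        frame = frame_i, time = (frame_i - 1L) * config$timestep_label, box)
    }
    emit(0L)

    if (config$n_steps > 0) {
      for (step in seq_len(config$n_steps)) {
        if (n > 1 && stats::runif(1) < config$cluster_move_prob) {
          memb <- mol_clusters()
          target <- memb[sample.int(n, 1)]
          mols <- which(memb == target)
          sel <- site_mol %in% mols
          if (length(mols) < n) {
            shift <- stats::runif(3, -config$cluster_translation,
                                  config$cluster_translation)
            new_xyz <- sweep(site_xyz[sel, , drop = FALSE], 2, shift, `+`)
            de <- delta_energy(new_xyz, sel)
            if (de <= 0 || stats::runif(1) < exp(-de / kT)) {
              site_xyz[sel, ] <- new_xyz
              centers[mols, ] <- sweep(centers[mols, , drop = FALSE], 2, shift, `+`)
            }
          }
        } else {
          i <- sample.int(n, 1)
          sel <- site_mol == i
          shift <- stats::runif(3, -config$max_translation, config$max_translation)
          new_center <- centers[i, ] + shift
          new_rot <- rotations[[i]]
          if (is_dye[i]) {
            ang <- stats::runif(1, -config$max_rotation, config$max_rotation)
            axis <- stats::rnorm(3)
            new_rot <- rotation_about_axis(axis, ang) %*% rotations[[i]]
            new_xyz <- sweep(cs$dye_local %*% t(new_rot), 2, new_center, `+`)
          } else {
            new_xyz <- matrix(new_center, 1, 3)
          }
          de <- delta_energy(new_xyz, sel)
          if (de <= 0 || stats::runif(1) < exp(-de / kT)) {
            centers[i, ] <- new_center
            rotations[[i]] <- new_rot
            site_xyz[sel, ] <- new_xyz
          }
        }
        if (step %% config$frame_stride == 0L) emit(step)
      }
    }

    out <- dplyr::bind_rows(frames)
    out <- new_trajectory(out, box)
    attr(out, "config") <- config
    out
  })
}
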