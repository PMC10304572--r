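# Coulomb constant in kcal*angstrom/(mol*e^2)
KCOULOMB <- 332.0636

#' Per-atom nonbonded parameter table
#'
#' Validates (and optionally converts) a nonbonded parameter table in the
#' AMBER Rmin/epsilon convention: geometric-mean epsilon combining, additive
#' Rmin/2. Tables in the sigma convention are converted via
#' `Rmin = 2^(1/6) sigma`.
#'
#' @param df Data frame with columns `x`, `y`, `z` (angstrom), `charge` (e),
#'   `epsilon` (kcal/mol), and either `rmin_half` (angstrom) or `sigma`
#'   (angstrom, with `convention = "sigma"`), plus logical `scaled_subset`
#'   marking membership in the epsilon-scaled (xanthene) set. An `atom_name`
#'   column is carried through if present.
#' @param convention `"rmin"` (default) or `"sigma"`.
#' @return A validated tibble in the rmin convention.
#' @export
nonbonded_params <- function(df, convention = c("rmin", "sigma")) {
  convention <- match.arg(convention)
  df <- tibble::as_tibble(df)
  if (convention == "sigma") {
    if (!"sigma" %in% names(df)) stop("`sigma` column required", call. = FALSE)
    df$rmin_half <- 2^(1 / 6) * df$sigma / 2
    df$sigma <- NULL
  }
  need <- c("x", "y", "z", "charge", "epsilon", "rmin_half", "scaled_subset")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("nonbonded table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$epsilon < 0)) stop("`epsilon` must be >= 0", call. = FALSE)
  if (any(df$rmin_half <= 0)) stop("`rmin_half` must be > 0", call. = FALSE)
  df$scaled_subset <- as.logical(df$scaled_subset)
  df
}

#' Read a per-atom nonbonded parameter table from CSV
#'
#' Expected columns: `atom_name`, `charge_e`, `epsilon_kcal`, `rmin_half_A`
#' (or `sigma_A`), `scaled_subset`, and coordinates `x`, `y`, `z`.
#'
#' @param path CSV file path.
#' @param convention `"rmin"` or `"sigma"`.
#' @return A [nonbonded_params()] tibble.
#' @export
read_nonbonded_csv <- function(path, convention = c("rmin", "sigma")) {
  convention <- match.arg(convention)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ren <- c(charge_e = "charge", epsilon_kcal = "epsilon",
           rmin_half_A = "rmin_half", sigma_A = "sigma")
  for (old in names(ren)) {
    if (old %in% names(df)) names(df)[names(df) == old] <- ren[[old]]
  }
  nonbonded_params(df, convention)
}

# Pairwise epsilon scaling matrix. scaling = "pair": s where both atoms are
# in the subset, 1 otherwise. scaling = "atom": sqrt(s) contributed per
# subset atom in the pair.
epsilon_scale_matrix <- function(subA, subB, scale_factor, scaling) {
  if (scaling == "pair") {
    ifelse(outer(subA, subB, `&`), scale_factor, 1)
  } else {
    outer(ifelse(subA, sqrt(scale_factor), 1),
          ifelse(subB, sqrt(scale_factor), 1))
  }
}

#' Rigid intermolecular Coulomb + Lennard-Jones energy
#'
#' Sums, over all intermolecular atom pairs,
#' `k_C q_i q_j / (D r_ij) exp(-kappa r_ij) +
#'  eps_ij ((Rmin_ij/r_ij)^12 - 2 (Rmin_ij/r_ij)^6)`
#' with `k_C = 332.0636` kcal A/(mol e^2), `eps_ij = s sqrt(eps_i eps_j)`,
#' `Rmin_ij = rmin_half_i + rmin_half_j`. The epsilon scale `s` equals
#' `scale_factor` when both atoms belong to the scaled (xanthene) subset and
#' 1 otherwise (`scaling = "pair"`, the default); `scaling = "atom"` applies
#' `sqrt(scale_factor)` per subset atom instead. The defaults `dielectric =
#' 1`, `kappa = 0` give plain vacuum electrostatics; the screening options
#' exist for the implicit-solvent Monte Carlo generator.
#'
#' @param molA,molB [nonbonded_params()] tables (coordinates included).
#' @param scale_factor Epsilon scale applied to subset pairs (> 0).
#' @param scaling `"pair"` or `"atom"`.
#' @param dielectric Relative dielectric constant.
#' @param kappa Inverse Debye screening length (1/angstrom); 0 disables.
#' @return Energy in kcal/mol.
#' @export
pair_energy <- function(molA, molB, scale_factor = 1,
                        scaling = c("pair", "atom"),
                        dielectric = 1, kappa = 0) {
  scaling <- match.arg(scaling)
  if (scale_factor <= 0) stop("`scale_factor` must be positive", call. = FALSE)
  a <- as.matrix(molA[, c("x", "y", "z")])
  b <- as.matrix(molB[, c("x", "y", "z")])
  dx <- outer(a[, 1], b[, 1], `-`)
  dy <- outer(a[, 2], b[, 2], `-`)
  dz <- outer(a[, 3], b[, 3], `-`)
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  if (any(r < 1e-9)) stop("coincident atoms: zero interatomic distance", call. = FALSE)
  qq <- outer(molA$charge, molB$charge)
  coul <- KCOULOMB * qq / (dielectric * r)
  if (kappa > 0) coul <- coul * exp(-kappa * r)
  eps <- sqrt(outer(molA$epsilon, molB$epsilon)) *
    epsilon_scale_matrix(molA$scaled_subset, molB$scaled_subset,
                         scale_factor, scaling)
  rmin <- outer(molA$rmin_half, molB$rmin_half, `+`)
  frac6 <- (rmin / r)^6
  sum(coul) + sum(eps * (frac6 * frac6 - 2 * frac6))
}

# Centroid of the scaled (xanthene) subset, falling back to all atoms.
scan_center <- function(mol) {
  sub <- mol[mol$scaled_subset, c("x", "y", "z")]
  if (nrow(sub) == 0) sub <- mol[, c("x", "y", "z")]
  colMeans(as.matrix(sub))
}

#' Rigid-dimer approach potential energy scan
#'
#' Rigidly translates `molB` along `approach_axis` so that the separation of
#' the two xanthene centers equals each entry of `distances`, evaluates the
#' intermolecular energy there, and reports it relative to the same geometry
#' at `reference_distance`: `delta_e(d) = E(d) - E(reference_distance)`.
#' Distances at which any interatomic distance falls below 0.1 angstrom are
#' sterically overlapping; their `delta_e` is set to `NA` with a warning.
#'
#' @inheritParams pair_energy
#' @param approach_axis Direction of approach (3-vector, normalized
#'   internally).
#' @param distances Sorted positive xanthene-center separations (angstrom).
#' @param reference_distance Zero-point separation (default 40 angstrom).
#' @return A `pes_scan` tibble with columns `distance`, `delta_e` and
#'   attributes `reference_distance`, `well_depth`, `barrier_height`,
#'   `r_min_location`, `scale_factor` (see [glance.pes_scan()]).
#' @export
scan_pes <- function(molA, molB, approach_axis, distances,
                     scale_factor = 1, reference_distance = 40,
                     scaling = c("pair", "atom"),
                     dielectric = 1, kappa = 0) {
  scaling <- match.arg(scaling)
  distances <- as.numeric(distances)
  if (any(distances <= 0)) stop("`distances` must be positive", call. = FALSE)
  if (is.unsorted(distances, strictly = TRUE)) {
    stop("`distances` must be strictly increasing", call. = FALSE)
  }
  u <- unit(as.numeric(approach_axis))
  cA <- scan_center(molA)
  cB <- scan_center(molB)
  place_b <- function(d) {
    shift <- cA + d * u - cB
    molB2 <- molB
    molB2$x <- molB$x + shift[1]
    molB2$y <- molB$y + shift[2]
    molB2$z <- molB$z + shift[3]
    molB2
  }
  energy_at <- function(d) {
    molB2 <- place_b(d)
    rmin_sep <- min_pair_set_dist(as.matrix(molA[, c("x", "y", "z")]),
                                  as.matrix(molB2[, c("x", "y", "z")]))
    if (rmin_sep < 0.1) return(NA_real_)
    pair_energy(molA, molB2, scale_factor = scale_factor, scaling = scaling,
                dielectric = dielectric, kappa = kappa)
  }
  e_ref <- energy_at(reference_distance)
  if (is.na(e_ref)) stop("steric overlap at the reference distance", call. = FALSE)
  e <- vapply(distances, energy_at, numeric(1))
  if (anyNA(e)) {
    warning("steric overlap (interatomic distance < 0.1 A) at distance(s): ",
            paste(signif(distances[is.na(e)], 4), collapse = ", "),
            "; delta_e set to NA", call. = FALSE)
  }
  delta_e <- e - e_ref
  out <- tibble::tibble(distance = distances, delta_e = delta_e)
  ok <- !is.na(delta_e)
  if (!any(ok)) stop("all scan points sterically overlap", call. = FALSE)
  i_min <- which(ok)[which.min(delta_e[ok])]
  r_min_location <- distances[i_min]
  beyond <- ok & distances >= r_min_location
  attr(out, "reference_distance") <- reference_distance
  attr(out, "well_depth") <- delta_e[i_min]
  attr(out, "barrier_height") <- max(delta_e[beyond])
  attr(out, "r_min_location") <- r_min_location
  attr(out, "scale_factor") <- scale_factor
  class(out) <- unique(c("pes_scan", class(out)))
  out
}

#' Fit the xanthene epsilon scale factor against a reference scan
#'
#' Finds the epsilon scale `s` for which [scan_pes()] best reproduces a
#' reference approach curve (e.g. a quantum-mechanical scan), by bounded 1-D
#' minimization of the summed squared `delta_e` deviation over the reference
#' grid on `s` in `[0.5, 5]` (tolerance 1e-3).
#'
#' @param reference_pes A `pes_scan` (or data frame with `distance`,
#'   `delta_e`) that exhibits a well (minimum below zero).
#' @inheritParams scan_pes
#' @return The fitted scale factor (numeric scalar).
#' @export
fit_scale_factor <- function(reference_pes, molA, molB, approach_axis,
                             reference_distance = 40,
                             scaling = c("pair", "atom"),
                             dielectric = 1, kappa = 0,
                             bounds = c(0.5, 5)) {
  scaling <- match.arg(scaling)
  ref <- tibble::as_tibble(reference_pes)[, c("distance", "delta_e")]
  ref <- ref[!is.na(ref$delta_e), ]
  if (nrow(ref) < 3) stop("reference scan too short", call. = FALSE)
  if (min(ref$delta_e) >= 0) {
    stop("reference scan has no well (no negative delta_e)", call. = FALSE)
  }
  objective <- function(s) {
    scan <- scan_pes(molA, molB, approach_axis, ref$distance,
                     scale_factor = s, reference_distance = reference_distance,
                     scaling = scaling, dielectric = dielectric, kappa = kappa)
    sum((scan$delta_e - ref$delta_e)^2, na.rm = TRUE)
  }
  opt <- stats::optimize(objective, interval = bounds, tol = 1e-3)
  opt$minimum
}

#' Write a PES scan as a two-column CSV
#'
#' @param scan A `pes_scan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pes_csv <- function(scan, path) {
  utils::write.csv(
    data.frame(distance_A = scan$distance, delta_e_kcal = scan$delta_e),
    path, row.names = FALSE)
  invisible(path)
}
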