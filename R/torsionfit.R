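#' Torsional energy profile
#'
#' A tabulated dihedral scan: a strictly increasing angle grid (degrees,
#' spanning at least 180) and energies (kcal/mol) shifted so the minimum is
#' zero. A profile whose grid covers the full period (e.g. 0 to 350 in 10
#' degree steps) is treated as periodic over 360 degrees.
#'
#' @param angles Angles in degrees, strictly increasing.
#' @param energies Energies in kcal/mol (any additive offset; min-shifted).
#' @return A `torsion_profile` tibble with columns `angle`, `energy` and a
#'   logical attribute `periodic`.
#' @export
torsion_profile <- function(angles, energies) {
  angles <- as.numeric(angles)
  energies <- as.numeric(energies)
  if (length(angles) != length(energies) || length(angles) < 4) {
    stop("`angles` and `energies` must have equal length >= 4", call. = FALSE)
  }
  if (is.unsorted(angles, strictly = TRUE)) {
    stop("`angles` must be strictly increasing", call. = FALSE)
  }
  span <- max(angles) - min(angles)
  if (span < 180) stop("angle grid must span at least 180 degrees", call. = FALSE)
  if (!all(is.finite(energies))) stop("energies must be finite", call. = FALSE)
  step <- stats::median(diff(angles))
  out <- tibble::tibble(angle = angles, energy = energies - min(energies))
  attr(out, "periodic") <- span + step >= 360 - 1e-6
  class(out) <- unique(c("torsion_profile", class(out)))
  out
}

#' Read a torsional profile from a two-column CSV
#'
#' Columns: `angle_deg`, `energy_kcal` (header optional; first two columns
#' used).
#'
#' @param path CSV file path.
#' @return A [torsion_profile()].
#' @export
read_torsion_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  torsion_profile(df[[1]], df[[2]])
}

#' Locate the minima regions of a torsional profile
#'
#' Detects local minima on the (periodic, if full-circle) grid and grows each
#' into its maximal contiguous interval of points lying within `depth_window`
#' kcal/mol of that minimum; overlapping intervals are merged. A flat profile
#' (energy range below 1e-6) yields a single region covering all angles. A
#' non-periodic profile with no interior minimum (monotone segment) is an
#' error.
#'
#' @param profile A [torsion_profile()].
#' @param depth_window Energy window above each local minimum (kcal/mol,
#'   default 1.0).
#' @return A tibble with columns `start`, `end` (degrees; `end < start`
#'   indicates a region wrapping through the grid boundary), `min_angle` and
#'   `min_energy`.
#' @export
find_minima_regions <- function(profile, depth_window = 1.0) {
  stopifnot(inherits(profile, "torsion_profile"))
  e <- profile$energy
  a <- profile$angle
  n <- length(e)
  periodic <- isTRUE(attr(profile, "periodic"))
  if (diff(range(e)) < 1e-6) {
    return(tibble::tibble(start = a[1], end = a[n],
                          min_angle = a[which.min(e)], min_energy = min(e)))
  }
  nb <- function(i, k) if (periodic) ((i - 1 + k) %% n) + 1 else i + k
  is_min <- logical(n)
  rng <- if (periodic) seq_len(n) else 2:(n - 1)
  for (i in rng) {
    lo <- nb(i, -1L); hi <- nb(i, 1L)
    is_min[i] <- e[i] <= e[lo] && e[i] <= e[hi] && (e[i] < e[lo] || e[i] < e[hi])
  }
  mins <- which(is_min)
  if (length(mins) == 0) {
    stop("profile has no interior local minimum (monotone non-periodic span)",
         call. = FALSE)
  }
  member <- logical(n)
  for (i in mins) {
    thresh <- e[i] + depth_window
    member[i] <- TRUE
    lo <- i
    repeat {
      nxt <- nb(lo, -1L)
      if (is.null(nxt) || nxt < 1 || nxt == i || e[nxt] > thresh) break
      lo <- nxt
      if (periodic && lo == i) break
    }
    hi <- i
    repeat {
      nxt <- nb(hi, 1L)
      if (is.null(nxt) || nxt > n || nxt == i || e[nxt] > thresh) break
      hi <- nxt
      if (periodic && hi == i) break
    }
    idx <- if (periodic && hi < lo) c(lo:n, 1:hi) else lo:hi
    member[idx] <- TRUE
  }
  # contiguous runs of member points -> merged regions
  runs <- split(seq_len(n)[member], cumsum(!member)[member])
  runs <- lapply(runs, as.integer)
  if (periodic && length(runs) > 1) {
    first <- runs[[1]]; last <- runs[[length(runs)]]
    if (first[1] == 1 && last[length(last)] == n) {
      runs[[1]] <- c(last, first)
      runs[[length(runs)]] <- NULL
    }
  }
  out <- lapply(runs, function(idx) {
    tibble::tibble(start = a[idx[1]], end = a[idx[length(idx)]],
                   min_angle = a[idx[which.min(e[idx])]],
                   min_energy = min(e[idx]))
  })
  regions <- dplyr::bind_rows(out)
  attr(regions, "member_mask") <- member
  regions
}

# Evaluate a cosine series offset + sum (V_n/2)(1 + cos(n phi - gamma_n))
# on angles in degrees.
eval_cosine_series <- function(terms, offset, angles) {
  phi <- angles * pi / 180
  v <- rep(offset, length(angles))
  for (k in seq_len(nrow(terms))) {
    v <- v + terms$v_n[k] / 2 *
      (1 + cos(terms$n[k] * phi - terms$gamma[k] * pi / 180))
  }
  v
}

#' Fit cosine-series dihedral terms against a reference profile
#'
#' Fits the residual `reference - mm_without_torsion` with the AMBER dihedral
#' functional form `sum_n (V_n/2)(1 + cos(n phi - gamma_n))` plus a constant,
#' with phases restricted to 0 or 180 degrees so the problem is linear: the
#' basis is `{1, cos(n phi)}` for `n = 1..max_n`, solved by least squares,
#' and a negative cosine coefficient becomes a positive `V_n` with
#' `gamma_n = 180`. Convergence is judged on the maximum absolute deviation
#' inside the minima regions of the reference ([find_minima_regions()]),
#' against `tolerance` (0.2 kcal/mol by default).
#'
#' @param reference Reference (e.g. quantum-mechanical) [torsion_profile()].
#' @param mm_without_torsion MM profile with the fitted torsion zeroed, on
#'   the same angle grid.
#' @param max_n Highest cosine multiplicity (default 4).
#' @param tolerance Convergence tolerance on the minima-region deviation
#'   (kcal/mol, default 0.2).
#' @param depth_window Minima-region energy window (kcal/mol, default 1.0).
#' @return A `torsion_fit` object; see [tidy.torsion_fit()] and
#'   [glance.torsion_fit()]. Fields include `terms` (tibble of `n`, `v_n`,
#'   `gamma`), `offset`, `profile` (angle, reference, baseline, fitted,
#'   deviation), `minima_regions`, `max_dev_minima`, `max_dev_global`,
#'   `converged`.
#' @export
fit_torsion <- function(reference, mm_without_torsion, max_n = 4,
                        tolerance = 0.2, depth_window = 1.0) {
  stopifnot(inherits(reference, "torsion_profile"),
            inherits(mm_without_torsion, "torsion_profile"))
  if (nrow(reference) != nrow(mm_without_torsion) ||
      max(abs(reference$angle - mm_without_torsion$angle)) > 1e-9) {
    stop("reference and MM profiles must share the same angle grid",
         call. = FALSE)
  }
  if (max_n < 1) stop("`max_n` must be >= 1", call. = FALSE)
  phi <- reference$angle * pi / 180
  basis <- cbind(1, sapply(seq_len(max_n), function(n) cos(n * phi)))
  if (nrow(basis) < ncol(basis) || qr(basis)$rank < ncol(basis)) {
    stop("rank-deficient cosine basis: too few grid points for max_n = ",
         max_n, call. = FALSE)
  }
  target <- reference$energy - mm_without_torsion$energy
  coef <- qr.solve(basis, target)
  cn <- coef[-1]
  terms <- tibble::tibble(
    n = seq_len(max_n),
    v_n = 2 * abs(cn),
    gamma = ifelse(cn >= 0, 0, 180)
  )
  terms <- terms[terms$v_n > 0, , drop = FALSE]
  offset <- coef[1] - sum(terms$v_n) / 2
  fitted <- mm_without_torsion$energy +
    eval_cosine_series(terms, offset, reference$angle)
  deviation <- reference$energy - fitted
  regions <- find_minima_regions(reference, depth_window = depth_window)
  mask <- attr(regions, "member_mask")
  if (is.null(mask)) mask <- rep(TRUE, nrow(reference))  # flat reference
  structure(
    list(
      terms = terms,
      offset = offset,
      profile = tibble::tibble(
        angle = reference$angle,
        reference = reference$energy,
        baseline = mm_without_torsion$energy,
        fitted = fitted,
        deviation = deviation
      ),
      minima_regions = regions,
      max_dev_minima = max(abs(deviation[mask])),
      max_dev_global = max(abs(deviation)),
      tolerance = tolerance,
      max_n = max_n,
      converged = max(abs(deviation[mask])) <= tolerance
    ),
    class = "torsion_fit"
  )
}

#' @export
print.torsion_fit <- function(x, ...) {
  cat("<torsion_fit>", nrow(x$terms), "cosine term(s), offset",
      sprintf("%.4f", x$offset), "kcal/mol\n")
  for (k in seq_len(nrow(x$terms))) {
    cat(sprintf("  n = %d: V = %.4f kcal/mol, gamma = %g deg\n",
                x$terms$n[k], x$terms$v_n[k], x$terms$gamma[k]))
  }
  cat(sprintf("  max deviation: %.4f (minima regions), %.4f (global) kcal/mol\n",
              x$max_dev_minima, x$max_dev_global))
  cat("  converged (<=", x$tolerance, "kcal/mol in minima):", x$converged, "\n")
  invisible(x)
}

#' Export fitted torsion terms as an frcmod-style text block
#'
#' Writes a DIHE-like section (one line per multiplicity) in the layout of
#' AMBER frcmod files; intended for human transfer into a force-field file,
#' not byte-exact AMBER input.
#'
#' @param fit A `torsion_fit`.
#' @param path Output path.
#' @param atom_types Four dash-joined atom types for the dihedral label.
#' @return `path`, invisibly.
#' @export
write_torsion_frcmod <- function(fit, path, atom_types = "X -c -c -X") {
  stopifnot(inherits(fit, "torsion_fit"))
  lines <- c("DIHE")
  nterm <- nrow(fit$terms)
  for (k in seq_len(nterm)) {
    # negative periodicity signals continuation lines, as in frcmod files
    per <- if (k < nterm) -fit$terms$n[k] else fit$terms$n[k]
    lines <- c(lines, sprintf("%-14s 1 %10.5f %8.2f %6.1f",
                              atom_types, fit$terms$v_n[k],
                              fit$terms$gamma[k], per))
  }
  writeLines(lines, path)
  invisible(path)
}
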