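#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PES scan
#'
#' @param x A `pes_scan` from [scan_pes()].
#' @param ... Unused.
#' @return A tibble with columns `distance` (angstrom) and `delta_e`
#'   (kcal/mol).
#' @method tidy pes_scan
#' @export
tidy.pes_scan <- function(x, ...) {
  tibble::tibble(distance = x$distance, delta_e = x$delta_e)
}

#' One-row summary of a PES scan
#'
#' @inheritParams tidy.pes_scan
#' @return A tibble with `well_depth`, `barrier_height`, `r_min_location`,
#'   `reference_distance` and `scale_factor`.
#' @method glance pes_scan
#' @export
glance.pes_scan <- function(x, ...) {
  tibble::tibble(
    well_depth = attr(x, "well_depth"),
    barrier_height = attr(x, "barrier_height"),
    r_min_location = attr(x, "r_min_location"),
    reference_distance = attr(x, "reference_distance"),
    scale_factor = attr(x, "scale_factor")
  )
}

#' Tidy a torsion fit: one row per cosine term
#'
#' @param x A `torsion_fit` from [fit_torsion()].
#' @param ... Unused.
#' @return A tibble with columns `n` (multiplicity), `v_n` (barrier height,
#'   kcal/mol) and `gamma` (phase, degrees, 0 or 180).
#' @method tidy torsion_fit
#' @export
tidy.torsion_fit <- function(x, ...) x$terms

#' One-row summary of a torsion fit
#'
#' @inheritParams tidy.torsion_fit
#' @return A tibble with `n_terms`, `offset`, `max_dev_minima`,
#'   `max_dev_global`, `tolerance` and `converged`.
#' @method glance torsion_fit
#' @export
glance.torsion_fit <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x$terms),
    offset = x$offset,
    max_dev_minima = x$max_dev_minima,
    max_dev_global = x$max_dev_global,
    tolerance = x$tolerance,
    converged = x$converged
  )
}
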