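#' Define the system topology: residue roles and xanthene frame atoms
#'
#' The analysis needs to know which residues are dyes, counterions or
#' solvent, which atoms span the xanthene plane, which atom pair defines the
#' long axis (the direction of the transition dipole), and which four atoms
#' are used as probes for the plane-distance stacking criterion.
#'
#' @param role_map Named character vector or list mapping residue names to a
#'   role, one of `"dye"`, `"counterion"`, `"solvent"`, `"other"`.
#' @param xanthene_atoms Character vector of atom names spanning the xanthene
#'   plane of each dye residue.
#' @param long_axis_atoms Character vector of exactly two distinct atom names;
#'   the vector from the first to the second defines the long (transition
#'   dipole) axis before projection into the plane.
#' @param stack_probe_atoms Character vector of exactly four atom names, a
#'   subset of `xanthene_atoms`, whose distances to the partner plane feed the
#'   stacking test.
#' @return An object of class `system_topology`.
#' @seealso [load_topology()] to read the same structure from a YAML file.
#' @export
system_topology <- function(role_map, xanthene_atoms, long_axis_atoms,
                            stack_probe_atoms) {
  role_map <- unlist(role_map)
  roles <- c("dye", "counterion", "solvent", "other")
  if (is.null(names(role_map)) || any(!nzchar(names(role_map)))) {
    stop("`role_map` must be named by residue name", call. = FALSE)
  }
  bad <- setdiff(unique(role_map), roles)
  if (length(bad) > 0) {
    stop("unknown role(s): ", paste(bad, collapse = ", "),
         " (must be dye/counterion/solvent/other)", call. = FALSE)
  }
  xanthene_atoms <- as.character(xanthene_atoms)
  long_axis_atoms <- as.character(long_axis_atoms)
  stack_probe_atoms <- as.character(stack_probe_atoms)
  if (length(xanthene_atoms) < 3) {
    stop("`xanthene_atoms` must name at least 3 atoms", call. = FALSE)
  }
  if (length(long_axis_atoms) != 2 || long_axis_atoms[1] == long_axis_atoms[2]) {
    stop("`long_axis_atoms` must be two distinct atom names", call. = FALSE)
  }
  if (length(stack_probe_atoms) != 4) {
    stop("`stack_probe_atoms` must name exactly 4 atoms, got ",
         length(stack_probe_atoms), call. = FALSE)
  }
  if (anyDuplicated(stack_probe_atoms)) {
    stop("`stack_probe_atoms` must be distinct", call. = FALSE)
  }
  missing_probe <- setdiff(stack_probe_atoms, xanthene_atoms)
  if (length(missing_probe) > 0) {
    stop("stack probe atom(s) not in `xanthene_atoms`: ",
         paste(missing_probe, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      role_map = role_map,
      xanthene_atoms = xanthene_atoms,
      long_axis_atoms = long_axis_atoms,
      stack_probe_atoms = stack_probe_atoms
    ),
    class = "system_topology"
  )
}

#' @export
print.system_topology <- function(x, ...) {
  cat("<system_topology>\n")
  for (role in unique(x$role_map)) {
    cat(sprintf("  %-10s: %s\n", role,
                paste(names(x$role_map)[x$role_map == role], collapse = ", ")))
  }
  cat("  xanthene plane atoms:", length(x$xanthene_atoms), "\n")
  cat("  long axis:", paste(x$long_axis_atoms, collapse = " -> "), "\n")
  cat("  stack probes:", paste(x$stack_probe_atoms, collapse = ", "), "\n")
  invisible(x)
}

#' Read a system topology from a YAML file
#'
#' Schema: a mapping with keys `roles` (residue name to role), and the three
#' atom lists `xanthene_atoms`, `long_axis_atoms`, `stack_probe_atoms`.
#'
#' @param path Path to a YAML file.
#' @return A [system_topology()] object.
#' @export
load_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  need <- c("roles", "xanthene_atoms", "long_axis_atoms", "stack_probe_atoms")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0) {
    stop("topology file missing key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  system_topology(
    role_map = cfg$roles,
    xanthene_atoms = cfg$xanthene_atoms,
    long_axis_atoms = cfg$long_axis_atoms,
    stack_probe_atoms = cfg$stack_probe_atoms
  )
}

#' Write a system topology to a YAML file
#'
#' @param topology A [system_topology()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "system_topology"))
  yaml::write_yaml(
    list(
      roles = as.list(topology$role_map),
      xanthene_atoms = topology$xanthene_atoms,
      long_axis_atoms = topology$long_axis_atoms,
      stack_probe_atoms = topology$stack_probe_atoms
    ),
    path
  )
  invisible(path)
}

# Role of a residue name under a topology; unknown residues are "other".
residue_role <- function(residue_name, topology) {
  role <- unname(topology$role_map[residue_name])
  role[is.na(role)] <- "other"
  role
}
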