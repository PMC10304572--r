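#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

# A trajectory is a tibble with one row per atom per frame and columns
#   frame, time, molecule_id, residue_name, residue_id, atom_name, element,
#   x, y, z
# plus an attribute "box" (numeric length-3 side lengths in angstrom, or
# NULL for a non-periodic system). Times are in ns, coordinates in angstrom.

new_trajectory <- function(df, box = NULL) {
  df <- as_tibble(df)
  need <- c("frame", "time", "molecule_id", "residue_name", "residue_id",
            "atom_name", "element", "x", "y", "z")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("trajectory table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    stopifnot(length(box) == 3, all(box > 0))
  }
  attr(df, "box") <- box
  class(df) <- unique(c("dye_trajectory", class(df)))
  df
}

#' Periodic box of a trajectory or frame
#'
#' @param traj A trajectory tibble as returned by [read_trajectory()] or the
#'   synthetic generators.
#' @return Numeric length-3 vector of box side lengths (angstrom), or `NULL`
#'   for a non-periodic system.
#' @export
trajectory_box <- function(traj) attr(traj, "box")

# Keep the box attribute across dplyr operations that drop attributes.
with_box <- function(df, box) {
  attr(df, "box") <- box
  class(df) <- unique(c("dye_trajectory", class(df)))
  df
}

# Assign molecule ids as contiguous runs of identical (residue_name,
# residue_id) within one frame's atom ordering.
assign_molecule_ids <- function(residue_name, residue_id) {
  key <- paste(residue_name, residue_id, sep = "\r")
  n <- length(key)
  if (n == 0) return(integer(0))
  new_run <- c(TRUE, key[-1] != key[-n])
  cumsum(new_run)
}

guess_element <- function(atom_name) {
  two <- c("CL", "BR", "NA", "MG", "FE", "ZN", "SE")
  up <- toupper(gsub("[^A-Za-z].*$", "", atom_name))
  first2 <- substr(up, 1, 2)
  ifelse(first2 %in% two, paste0(substr(first2, 1, 1), tolower(substr(first2, 2, 2))),
         substr(up, 1, 1))
}

#' Read a multi-frame trajectory
#'
#' Supports multi-frame PDB (MODEL/ENDMDL records, CRYST1 box) and extended
#' XYZ (atom count line, comment line carrying `Lattice=` and optionally
#' `time=`, then one atom per line). The XYZ dialect written by
#' [write_trajectory()] appends `atom_name residue_name residue_id` after the
#' coordinates so that round trips preserve residue structure; plain
#' 4-column XYZ is accepted, with atom names set to the element and all atoms
#' assigned to a single `UNK` residue.
#'
#' Molecule ids are assigned as contiguous runs of identical
#' `(residue_name, residue_id)` in file order; chain identifiers are ignored.
#' Residues whose name has no role in `topology` trigger a warning and are
#' treated as role `"other"`.
#'
#' @param path Input file path.
#' @param topology A [system_topology()] used to validate residue roles.
#' @param format `"pdb"` or `"xyz"`; by default guessed from the extension.
#' @return A trajectory tibble (see [trajectory_box()]); frames appear in
#'   file order with a constant atom ordering.
#' @export
read_trajectory <- function(path, topology,
                            format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("trajectory file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xyz", "exyz")) "xyz" else "pdb"
  }
  traj <- switch(format,
    pdb = read_pdb_frames(path),
    xyz = read_xyz_frames(path)
  )
  check_frame_consistency(traj, path)
  unknown <- setdiff(unique(traj$residue_name), names(topology$role_map))
  if (length(unknown) > 0) {
    warning("residue(s) with no role in topology treated as 'other': ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  traj
}

check_frame_consistency <- function(traj, path) {
  counts <- table(traj$frame)
  if (length(unique(as.integer(counts))) > 1) {
    stop("inconsistent atom count across frames in ", path, ": ",
         paste(unique(as.integer(counts)), collapse = " vs "), call. = FALSE)
  }
  first <- traj[traj$frame == traj$frame[1],
                c("atom_name", "residue_name", "residue_id")]
  for (f in unique(traj$frame)) {
    cur <- traj[traj$frame == f, c("atom_name", "residue_name", "residue_id")]
    if (!identical(as.data.frame(cur), as.data.frame(first))) {
      stop("atom ordering differs between frames in ", path,
           " (frame ", f, ")", call. = FALSE)
    }
  }
  if (!all(is.finite(c(traj$x, traj$y, traj$z)))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  invisible(traj)
}

read_pdb_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  box <- NULL
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (length(cryst) > 0) {
    a <- as.numeric(substr(cryst[1], 7, 15))
    b <- as.numeric(substr(cryst[1], 16, 24))
    c3 <- as.numeric(substr(cryst[1], 25, 33))
    if (all(is.finite(c(a, b, c3))) && all(c(a, b, c3) > 0)) box <- c(a, b, c3)
  }
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) {
    frame_of_line <- rep(1L, length(lines))
    times <- NA_real_
    n_frames <- 1L
  } else {
    frame_of_line <- cumsum(grepl("^MODEL", lines))
    frame_of_line[frame_of_line == 0L] <- 1L
    n_frames <- max(frame_of_line)
    times <- rep(NA_real_, n_frames)
  }
  time_lines <- grep("^REMARK   6 TIME_NS=", lines)
  for (i in time_lines) {
    f <- frame_of_line[i]
    times[f] <- as.numeric(sub("^REMARK   6 TIME_NS=\\s*", "", lines[i]))
  }
  atom_idx <- grep("^(ATOM  |HETATM)", lines)
  if (length(atom_idx) == 0) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  al <- lines[atom_idx]
  frame <- frame_of_line[atom_idx]
  atom_name <- trimws(substr(al, 13, 16))
  residue_name <- trimws(substr(al, 18, 20))
  residue_id <- as.integer(substr(al, 23, 26))
  x <- as.numeric(substr(al, 31, 38))
  y <- as.numeric(substr(al, 39, 46))
  z <- as.numeric(substr(al, 47, 54))
  element <- trimws(substr(al, 77, 78))
  element[!nzchar(element)] <- guess_element(atom_name[!nzchar(element)])
  if (anyNA(residue_id) || any(residue_id < 0)) {
    stop("invalid residue ids in ", path, call. = FALSE)
  }
  df <- tibble(
    frame = frame, time = NA_real_,
    molecule_id = 0L,
    residue_name = residue_name, residue_id = residue_id,
    atom_name = atom_name, element = element,
    x = x, y = y, z = z
  )
  finalize_frames(df, times, box)
}

read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  frames <- list()
  times <- numeric(0)
  box <- NULL
  f <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0) stop("malformed XYZ count line at line ", i, call. = FALSE)
    if (i + 1L + nat > length(lines) + 1L) {
      stop("truncated XYZ frame at line ", i, call. = FALSE)
    }
    comment <- lines[i + 1L]
    f <- f + 1L
    lat <- parse_xyz_lattice(comment)
    if (!is.null(lat)) box <- lat
    tm <- regmatches(comment, regexpr("time=[-0-9.eE+]+", comment))
    times[f] <- if (length(tm) == 1) as.numeric(sub("time=", "", tm)) else NA_real_
    body <- lines[(i + 2L):(i + 1L + nat)]
    tok <- strsplit(trimws(body), "\\s+")
    ncol <- lengths(tok)
    if (any(ncol < 4)) stop("malformed XYZ atom line in frame ", f, call. = FALSE)
    element <- vapply(tok, `[`, "", 1L)
    x <- as.numeric(vapply(tok, `[`, "", 2L))
    y <- as.numeric(vapply(tok, `[`, "", 3L))
    z <- as.numeric(vapply(tok, `[`, "", 4L))
    extended <- all(ncol >= 7)
    atom_name <- if (extended) vapply(tok, `[`, "", 5L) else element
    residue_name <- if (extended) vapply(tok, `[`, "", 6L) else rep("UNK", nat)
    residue_id <- if (extended) as.integer(vapply(tok, `[`, "", 7L)) else rep(1L, nat)
    frames[[f]] <- tibble(
      frame = f, time = NA_real_, molecule_id = 0L,
      residue_name = residue_name, residue_id = residue_id,
      atom_name = atom_name, element = element, x = x, y = y, z = z
    )
    i <- i + 2L + nat
  }
  if (length(frames) == 0) stop("no frames found in ", path, call. = FALSE)
  finalize_frames(dplyr::bind_rows(frames), times, box)
}

parse_xyz_lattice <- function(comment) {
  m <- regmatches(comment,
                  regexpr('Lattice="?[-0-9.eE+ ]+"?', comment))
  if (length(m) != 1) return(NULL)
  vals <- as.numeric(strsplit(trimws(gsub('Lattice=|"', "", m)), "\\s+")[[1]])
  vals <- vals[is.finite(vals)]
  if (length(vals) == 3) return(vals)
  if (length(vals) == 9) return(vals[c(1, 5, 9)])
  NULL
}

finalize_frames <- function(df, times, box) {
  frames <- sort(unique(df$frame))
  df$frame <- match(df$frame, frames)
  if (length(times) < length(frames)) times <- c(times, rep(NA_real_, length(frames) - length(times)))
  times <- times[seq_along(frames)]
  # unlabeled frames get a nominal 0-based index time (ns)
  times[is.na(times)] <- (seq_along(frames) - 1)[is.na(times)]
  df$time <- times[df$frame]
  per_frame <- split(seq_len(nrow(df)), df$frame)
  for (idx in per_frame) {
    df$molecule_id[idx] <- assign_molecule_ids(df$residue_name[idx], df$residue_id[idx])
  }
  new_trajectory(df, box)
}

#' Write a trajectory to multi-frame PDB or extended XYZ
#'
#' PDB output uses MODEL/ENDMDL records, a CRYST1 record when a box is
#' present, and a `REMARK   6 TIME_NS=` line per frame; coordinates are
#' written at the PDB fixed precision of 1e-3 angstrom. XYZ output writes
#' `Lattice="a b c"` and `time=` on the comment line and the extended atom
#' columns described in [read_trajectory()].
#'
#' @param traj Trajectory tibble.
#' @param path Output path.
#' @param format `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (nrow(traj) == 0) stop("cannot write an empty trajectory", call. = FALSE)
  box <- trajectory_box(traj)
  frames <- sort(unique(traj$frame))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    if (!is.null(box)) {
      writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                         box[1], box[2], box[3], 90, 90, 90), con)
    }
    for (f in frames) {
      fr <- traj[traj$frame == f, ]
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(sprintf("REMARK   6 TIME_NS= %.6f", fr$time[1]), con)
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        seq_len(nrow(fr)) %% 100000L, substr(fr$atom_name, 1, 4),
        substr(fr$residue_name, 1, 3), "A", fr$residue_id %% 10000L,
        fr$x, fr$y, fr$z, 1, 0, substr(fr$element, 1, 2)), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    for (f in frames) {
      fr <- traj[traj$frame == f, ]
      writeLines(as.character(nrow(fr)), con)
      lat <- if (is.null(box)) "" else
        sprintf(' Lattice="%.6f %.6f %.6f"', box[1], box[2], box[3])
      writeLines(sprintf("time=%.6f%s", fr$time[1], lat), con)
      writeLines(sprintf("%-2s %14.6f %14.6f %14.6f %-4s %-3s %d",
                         fr$element, fr$x, fr$y, fr$z,
                         fr$atom_name, fr$residue_name, fr$residue_id), con)
    }
  }
  invisible(path)
}

#' Extract one frame of a trajectory
#'
#' @param traj Trajectory tibble.
#' @param frame Frame index (1-based, as stored in the `frame` column).
#' @return A single-frame trajectory tibble retaining the box attribute.
#' @export
trajectory_frame <- function(traj, frame) {
  out <- traj[traj$frame == frame, , drop = FALSE]
  if (nrow(out) == 0) stop("no such frame: ", frame, call. = FALSE)
  with_box(out, trajectory_box(traj))
}
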