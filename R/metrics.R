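# Xanthene centroid of each dye molecule and plain centroid of each
# counterion in one frame; returns a tibble (molecule_id, role, x, y, z).
molecule_centers <- function(frame_df, topology) {
  role <- residue_role(frame_df$residue_name, topology)
  keep <- role %in% c("dye", "counterion")
  df <- frame_df[keep, ]
  role <- role[keep]
  is_dye <- role == "dye"
  df_x <- df[!is_dye | df$atom_name %in% topology$xanthene_atoms, ]
  agg <- dplyr::summarise(
    dplyr::group_by(df_x, .data$molecule_id),
    role = residue_role(.data$residue_name[1], topology),
    x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
    .groups = "drop"
  )
  dplyr::arrange(agg, .data$molecule_id)
}

# All unordered pairwise minimum-image distances between rows of a coordinate
# matrix; returns a vector of length n(n-1)/2 in combn order.
pairwise_min_image_dist <- function(coords, box = NULL) {
  n <- nrow(coords)
  if (n < 2) return(numeric(0))
  idx <- utils::combn(n, 2)
  d <- coords[idx[2, ], , drop = FALSE] - coords[idx[1, ], , drop = FALSE]
  if (!is.null(box)) {
    d <- d - sweep(round(sweep(d, 2, box, `/`)), 2, box, `*`)
  }
  sqrt(rowSums(d * d))
}

#' Per-frame aggregation statistics
#'
#' Summarizes one frame: the number of interacting dye pairs, the number of
#' pi-stacked pairs broken down by geometry class (so the three class counts
#' sum to the stacked count), the sum of all dye-dye center distances
#' (minimum image; the aggregation order parameter that decreases when large
#' aggregates form), and contact-graph cluster sizes.
#'
#' @param labels Output of [classify_frame()] for this frame.
#' @param frame_df The single-frame trajectory tibble.
#' @param topology A [system_topology()].
#' @param contact_cut Contact distance (angstrom) for [find_clusters()].
#' @return A one-row tibble: `time`, `n_interacting`, `n_H`, `n_J`,
#'   `n_crossedJ`, `n_stacked`, `sum_rcc`, `n_clusters`, `largest_cluster`,
#'   `full_aggregate`, and a list column `cluster_sizes`.
#' @export
frame_stats <- function(labels, frame_df, topology, contact_cut = 4.5) {
  centers <- molecule_centers(frame_df, topology)
  dye_centers <- as.matrix(centers[centers$role == "dye", c("x", "y", "z")])
  box <- trajectory_box(frame_df)
  sum_rcc <- sum(pairwise_min_image_dist(dye_centers, box))
  cl <- find_clusters(frame_df, topology, contact_cut = contact_cut)
  sizes <- sort(as.integer(table(cl$cluster)))
  n_dyes <- nrow(dye_centers)
  dye_clusters <- unique(cl$cluster[cl$role == "dye"])
  stacked <- labels[labels$stacked, ]
  tibble::tibble(
    time = if (nrow(frame_df) > 0) frame_df$time[1] else NA_real_,
    n_interacting = sum(labels$interacting),
    n_H = sum(stacked$geometry_class == "H"),
    n_J = sum(stacked$geometry_class == "J"),
    n_crossedJ = sum(stacked$geometry_class == "crossed_J"),
    n_stacked = nrow(stacked),
    sum_rcc = sum_rcc,
    n_clusters = length(sizes),
    largest_cluster = if (length(sizes)) max(sizes) else 0L,
    full_aggregate = n_dyes > 0 && length(dye_clusters) == 1 &&
      sum(cl$role == "dye" & cl$cluster == dye_clusters[1]) == n_dyes,
    cluster_sizes = list(sizes)
  )
}

#' Aggregation statistics for every frame of a trajectory
#'
#' Runs [classify_frame()] and [frame_stats()] over all frames.
#'
#' @inheritParams classify_dimers
#' @param contact_cut Contact distance (angstrom) for cluster detection.
#' @return A tibble with one row per frame (columns of [frame_stats()] plus
#'   `frame`).
#' @export
aggregate_stats <- function(traj, topology,
                            thresholds = classification_thresholds(),
                            contact_cut = 4.5) {
  box <- trajectory_box(traj)
  frames <- sort(unique(traj$frame))
  out <- lapply(frames, function(f) {
    fr <- with_box(traj[traj$frame == f, ], box)
    labels <- classify_frame(fr, topology, thresholds, box = box)
    dplyr::mutate(frame_stats(labels, fr, topology, contact_cut = contact_cut),
                  frame = f, .before = 1)
  })
  dplyr::bind_rows(out)
}

#' Non-overlapping block averages of a time series
#'
#' Averages each numeric column over consecutive windows of fixed width
#' starting at the first time point. The trailing window is kept even if the
#' data do not span it fully, and flagged in the `partial` column.
#'
#' @param series Data frame with a `time` column (ns) sorted increasing and
#'   one or more numeric value columns.
#' @param window Window width in ns (default 0.1).
#' @return A tibble with `time` (window midpoints), the averaged value
#'   columns, `n` (points per window) and `partial` (logical).
#' @export
block_average <- function(series, window = 0.1) {
  series <- as.data.frame(series)
  if (nrow(series) == 0) {
    return(tibble::tibble(time = numeric(0), n = integer(0), partial = logical(0)))
  }
  if (!"time" %in% names(series)) stop("`series` needs a `time` column", call. = FALSE)
  if (is.unsorted(series$time)) stop("`time` must be sorted increasing", call. = FALSE)
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  t0 <- series$time[1]
  k <- floor((series$time - t0) / window + 1e-12)
  value_cols <- setdiff(names(series)[vapply(series, is.numeric, TRUE)], "time")
  ks <- sort(unique(k))
  out <- lapply(ks, function(kk) {
    sub <- series[k == kk, value_cols, drop = FALSE]
    row <- as.data.frame(lapply(sub, mean))
    row$time <- t0 + (kk + 0.5) * window
    row$n <- nrow(sub)
    row
  })
  out <- tibble::as_tibble(dplyr::bind_rows(out))
  span <- max(series$time) - t0
  out$partial <- FALSE
  out$partial[nrow(out)] <- span < (ks[length(ks)] + 1) * window - 1e-12
  dplyr::relocate(out, "time")
}

#' Contact clusters of dye and counterion molecules
#'
#' Builds the graph whose nodes are the dye and counterion molecules of one
#' frame and whose edges join molecules with minimum heavy-atom (non-H)
#' distance below `contact_cut` (minimum image), and returns its connected
#' components. This is the package's operational aggregate definition; a
#' "full aggregate" is a component containing every dye.
#'
#' @param frame_df Single-frame trajectory tibble.
#' @param topology A [system_topology()].
#' @param contact_cut Contact distance in angstrom (default 4.5).
#' @return A tibble with columns `molecule_id`, `residue_name`, `role` and
#'   `cluster` (integer component label).
#' @export
find_clusters <- function(frame_df, topology, contact_cut = 4.5) {
  if (contact_cut <= 0) stop("`contact_cut` must be positive", call. = FALSE)
  role <- residue_role(frame_df$residue_name, topology)
  keep <- role %in% c("dye", "counterion") & frame_df$element != "H"
  df <- frame_df[keep, ]
  mols <- unique(df$molecule_id)
  n <- length(mols)
  info <- dplyr::summarise(
    dplyr::group_by(df, .data$molecule_id),
    residue_name = .data$residue_name[1], .groups = "drop"
  )
  info$role <- residue_role(info$residue_name, topology)
  if (n == 0) {
    return(tibble::tibble(molecule_id = integer(0), residue_name = character(0),
                          role = character(0), cluster = integer(0)))
  }
  box <- trajectory_box(frame_df)
  coords <- as.matrix(df[, c("x", "y", "z")])
  midx <- match(df$molecule_id, mols)
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    pairs <- utils::combn(n, 2)
    hit <- logical(ncol(pairs))
    for (kk in seq_len(ncol(pairs))) {
      i <- pairs[1, kk]; j <- pairs[2, kk]
      a <- coords[midx == i, , drop = FALSE]
      b <- coords[midx == j, , drop = FALSE]
      dmin <- min_pair_set_dist(a, b, box)
      hit[kk] <- dmin < contact_cut
    }
    edges <- t(pairs[, hit, drop = FALSE])
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  tibble::tibble(
    molecule_id = info$molecule_id[match(mols, info$molecule_id)],
    residue_name = info$residue_name[match(mols, info$molecule_id)],
    role = info$role[match(mols, info$molecule_id)],
    cluster = as.integer(comp)
  )
}

# Minimum distance between two coordinate sets under minimum image.
min_pair_set_dist <- function(a, b, box = NULL) {
  dx <- outer(a[, 1], b[, 1], `-`)
  dy <- outer(a[, 2], b[, 2], `-`)
  dz <- outer(a[, 3], b[, 3], `-`)
  if (!is.null(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  sqrt(min(dx * dx + dy * dy + dz * dz))
}

#' Radial pair distribution function over the trajectory tail
#'
#' Center-to-center g(r) between dye-dye or dye-counterion molecule pairs
#' (xanthene centroid for dyes, molecular centroid for counterions),
#' averaged over the frames in the last `tail` ns and normalized by the
#' ideal-gas shell expectation for the periodic box.
#'
#' @param traj Trajectory tibble with a periodic box.
#' @param topology A [system_topology()].
#' @param pair_kind `"dye_dye"` or `"dye_counterion"`.
#' @param r_max Histogram range (angstrom); must not exceed half the smallest
#'   box side. Defaults to that bound.
#' @param bin_width Bin width in angstrom (default 0.1).
#' @param tail Averaging window: frames with `time >= max(time) - tail` are
#'   used (default 1.0 ns).
#' @return An `rdf_result` tibble with columns `r` (bin centers) and `g`,
#'   and attributes `pair_kind` and `n_frames_averaged`.
#' @export
compute_rdf <- function(traj, topology,
                        pair_kind = c("dye_dye", "dye_counterion"),
                        r_max = NULL, bin_width = 0.1, tail = 1.0) {
  pair_kind <- match.arg(pair_kind)
  box <- trajectory_box(traj)
  if (is.null(box)) stop("RDF requires a periodic box", call. = FALSE)
  half <- min(box) / 2
  if (is.null(r_max)) r_max <- half
  if (r_max > half + 1e-9) {
    stop("`r_max` must not exceed half the smallest box side (",
         signif(half, 4), " A)", call. = FALSE)
  }
  frames <- sort(unique(traj$frame))
  tmax <- max(traj$time)
  keep_frames <- frames[vapply(frames, function(f) {
    traj$time[traj$frame == f][1] >= tmax - tail - 1e-9
  }, TRUE)]
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max - 1e-9) breaks <- c(breaks, r_max)
  counts <- numeric(length(breaks) - 1)
  n_pairs <- NULL
  for (f in keep_frames) {
    fr <- with_box(traj[traj$frame == f, ], box)
    centers <- molecule_centers(fr, topology)
    dye <- as.matrix(centers[centers$role == "dye", c("x", "y", "z")])
    if (pair_kind == "dye_dye") {
      dists <- pairwise_min_image_dist(dye, box)
      n_pairs <- nrow(dye) * (nrow(dye) - 1) / 2
    } else {
      ci <- as.matrix(centers[centers$role == "counterion", c("x", "y", "z")])
      dx <- outer(dye[, 1], ci[, 1], `-`); dx <- dx - box[1] * round(dx / box[1])
      dy <- outer(dye[, 2], ci[, 2], `-`); dy <- dy - box[2] * round(dy / box[2])
      dz <- outer(dye[, 3], ci[, 3], `-`); dz <- dz - box[3] * round(dz / box[3])
      dists <- sqrt(as.numeric(dx^2 + dy^2 + dz^2))
      n_pairs <- nrow(dye) * nrow(ci)
    }
    counts <- counts + graphics::hist(dists[dists < r_max], breaks = breaks,
                                      plot = FALSE)$counts
  }
  if (is.null(n_pairs) || n_pairs == 0) stop("no molecule pairs of kind ", pair_kind, call. = FALSE)
  vol <- prod(box)
  shell <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-length(breaks)]^3)
  expected <- length(keep_frames) * n_pairs * shell / vol
  g <- ifelse(expected > 0, counts / expected, 0)
  out <- tibble::tibble(r = (breaks[-1] + breaks[-length(breaks)]) / 2, g = g)
  attr(out, "pair_kind") <- pair_kind
  attr(out, "n_frames_averaged") <- length(keep_frames)
  class(out) <- unique(c("rdf_result", class(out)))
  out
}
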