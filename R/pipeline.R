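# End-to-end pipeline verbs behind the command-line wrapper
# (inst/scripts/dyeaggr.R): simulate -> analyze -> report, plus the
# standalone PES-scan and torsion-fit commands.

#' Run the full trajectory analysis and write its outputs
#'
#' Classifies every dye pair in every frame, accumulates per-frame
#' aggregation statistics, computes the tail-averaged radial distribution
#' functions when a periodic box is present, and writes: `stats.csv` (one row
#' per frame), `rdf_dye_dye.csv` and `rdf_dye_counterion.csv`, and
#' `summary.json` (frame count, whether and when a full aggregate first
#' appears, mean stacked-dimer counts and occupancy fractions by class).
#'
#' @param trajectory Trajectory tibble, or path to a PDB/XYZ file.
#' @param topology A [system_topology()], or path to a topology YAML.
#' @param out_dir Output directory (created if missing).
#' @param thresholds A [classification_thresholds()].
#' @param window Block-average window (ns) stored in the summary.
#' @param tail RDF averaging window (ns).
#' @param bin_width RDF bin width (angstrom).
#' @param contact_cut Cluster contact distance (angstrom).
#' @return Invisibly, a list with the `stats` tibble, the `summary` list and
#'   the written file paths.
#' @export
run_analysis <- function(trajectory, topology, out_dir = ".",
                         thresholds = classification_thresholds(),
                         window = 0.1, tail = 1.0, bin_width = 0.1,
                         contact_cut = 4.5) {
  if (is.character(topology)) topology <- load_topology(topology)
  if (is.character(trajectory)) trajectory <- read_trajectory(trajectory, topology)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stats <- aggregate_stats(trajectory, topology, thresholds,
                           contact_cut = contact_cut)
  stats_path <- file.path(out_dir, "stats.csv")
  utils::write.csv(
    stats[, c("time", "n_interacting", "n_H", "n_J", "n_crossedJ",
              "n_stacked", "sum_rcc", "n_clusters", "largest_cluster")],
    stats_path, row.names = FALSE)
  paths <- stats_path
  box <- trajectory_box(trajectory)
  if (!is.null(box)) {
    for (kind in c("dye_dye", "dye_counterion")) {
      rdf <- tryCatch(
        compute_rdf(trajectory, topology, kind, bin_width = bin_width, tail = tail),
        error = function(e) NULL)
      if (!is.null(rdf)) {
        p <- file.path(out_dir, paste0("rdf_", kind, ".csv"))
        utils::write.csv(data.frame(r_A = rdf$r, g = rdf$g), p, row.names = FALSE)
        paths <- c(paths, p)
      }
    }
  } else {
    message("no periodic box: RDFs skipped, distances unwrapped")
  }
  first_full <- stats$time[stats$full_aggregate]
  occupancy <- function(col) mean(stats[[col]] > 0)
  summary <- list(
    n_frames = nrow(stats),
    time_span_ns = max(stats$time) - min(stats$time),
    block_window_ns = window,
    full_aggregate_reached = any(stats$full_aggregate),
    first_full_aggregate_ns = if (length(first_full)) min(first_full) else NULL,
    mean_interacting = mean(stats$n_interacting),
    mean_stacked = mean(stats$n_stacked),
    occupancy_fraction = list(
      H = occupancy("n_H"), J = occupancy("n_J"),
      crossed_J = occupancy("n_crossedJ"), stacked = occupancy("n_stacked")
    ),
    final_sum_rcc = stats$sum_rcc[nrow(stats)]
  )
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  message(sprintf("analyzed %d frames; full aggregate: %s", nrow(stats),
                  if (summary$full_aggregate_reached)
                    sprintf("first at %.3f ns", summary$first_full_aggregate_ns)
                  else "never"))
  invisible(list(stats = stats, summary = summary,
                 paths = c(paths, summary_path)))
}

#' Run the synthetic aggregation generator and write its outputs
#'
#' Writes `trajectory.pdb` (or `.xyz`) and the matching `topology.yaml`,
#' directly consumable by [run_analysis()].
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory.
#' @param format `"pdb"` or `"xyz"`.
#' @return Invisibly, a list with the trajectory, the topology and the
#'   written paths.
#' @export
run_simulation <- function(config = synthetic_config(), out_dir = ".",
                           format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  message(sprintf(
    "simulate: %d dyes + %d %s counterions, box %.1f A, %d steps, seed %d",
    config$n_dye, config$n_counterion, config$counterion_mode,
    config$box_side, config$n_steps, config$seed))
  traj <- run_aggregation(config)
  topo <- template_topology(config$counterion_mode)
  traj_path <- file.path(out_dir, paste0("trajectory.", format))
  topo_path <- file.path(out_dir, "topology.yaml")
  write_trajectory(traj, traj_path, format)
  write_topology(topo, topo_path)
  invisible(list(trajectory = traj, topology = topo,
                 paths = c(traj_path, topo_path)))
}

#' Render the report figure from a stats CSV
#'
#' Reads a per-frame statistics CSV (schema of [run_analysis()]), drops rows
#' with missing values with a warning, and writes the two-panel aggregation
#' figure plus a small text summary table of block means.
#'
#' @param stats_csv Path to a stats CSV.
#' @param out_dir Output directory.
#' @param window Block-average window in ns.
#' @return Invisibly, the paths written.
#' @export
run_report <- function(stats_csv, out_dir = ".", window = 0.1) {
  stats <- tibble::as_tibble(utils::read.csv(stats_csv))
  need <- c("time", "n_interacting", "n_H", "n_J", "n_crossedJ", "sum_rcc")
  missing <- setdiff(need, names(stats))
  if (length(missing) > 0) {
    stop("stats CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(stats) == 0) stop("stats CSV is empty", call. = FALSE)
  bad <- !stats::complete.cases(stats[, need])
  if (any(bad)) {
    warning("dropping ", sum(bad), " row(s) with missing values", call. = FALSE)
    stats <- stats[!bad, ]
  }
  if (nrow(stats) == 0) stop("no complete rows in stats CSV", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fig_path <- file.path(out_dir, "aggregation.png")
  ggplot2::ggsave(fig_path, plot_aggregation(stats, window = window),
                  width = 7, height = 5, dpi = 150)
  bl <- block_average(stats[, need], window = window)
  table_path <- file.path(out_dir, "block_means.txt")
  utils::write.table(format(as.data.frame(bl), digits = 4), table_path,
                     quote = FALSE, row.names = FALSE)
  invisible(c(fig_path, table_path))
}
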