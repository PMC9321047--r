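## Strain presets for the simulator. The presets encode the contrast the
## pipeline is designed to resolve: wildtype cells carry one small, mobile
## early focus each (per-10 s step scale ~0.75 um), while the actin
## patch-polarisation mutant act1-122 carries several foci per cell with a
## slower step scale (~0.55 um) and a size mixture in which large foci are
## nearly static. Per-axis innovation scales are chosen so the free-space
## mean 3D step length (2*sqrt(2/pi) * sigma for a chi_3 step) matches the
## target step scale.

.CHI3_MEAN <- 2 * sqrt(2 / pi)

.preset_foci <- function(preset) {
  switch(preset,
    "wildtype" = data.frame(
      cell = 1:5, foci_in_cell = 1,
      sigma = 0.75 / .CHI3_MEAN,
      initial_volume = 0.03, size_class = "wildtype"),
    "act1-122" = {
      ## 11 foci across 6 cells: 4 small mobile, 3 large static, 4 "other"
      cls <- c("small", "small", "small", "small", "large", "large",
               "large", "other", "other", "other", "other")
      data.frame(
        cell = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 6, 6), foci_in_cell = NA,
        sigma = c(small = 0.55 / .CHI3_MEAN, large = 0.08,
                  other = 0.25)[cls],
        initial_volume = c(small = 0.03, large = 0.50, other = 0.15)[cls],
        size_class = cls)
    },
    stop("unknown preset: ", preset))
}

#' Simulate a full strain dataset
#'
#' Generates everything the pipeline ingests for one strain preset:
#' confined correlated-random-walk trajectories of early foci (one per
#' wildtype cell, several per mutant cell, with per-frame focus extents),
#' noisy membrane edge sets for each cell, peripherally biased mature
#' aggregate positions, per-cell aggregate counts, and binomial plate
#' counts around the strain's typical induction frequency.
#'
#' @param preset `"wildtype"` or `"act1-122"`.
#' @param seed integer RNG seed; all per-object seeds derive from it.
#' @param n_frames frames per trajectory (default 100, i.e. 16.5 min of
#'   10 s sampling).
#' @param cell_radius cell radius in um (default 2.6).
#' @param gamma_true directional correlation of the generating walks
#'   (default 0.1: random movement).
#' @param n_count_cells cells scored for aggregate counts (default 100).
#' @param peripheral_bias bias exponent for mature aggregate positions
#'   (default 2).
#' @param true_induction_frequency per-cell induction probability; default
#'   0.006 for wildtype and 0.006/1.7 for act1-122.
#' @return list of class `strain_dataset` with elements `trajectories`,
#'   `cells` (edge sets), `aggregate_positions` (per-cell matrices),
#'   `counts`, `platings` (list of `induction_count`), `preset`.
#' @export
simulate_preset <- function(preset = c("wildtype", "act1-122"), seed = 1,
                            n_frames = 100, cell_radius = 2.6,
                            gamma_true = 0.1, n_count_cells = 100,
                            peripheral_bias = 2,
                            true_induction_frequency = NULL) {
  preset <- match.arg(preset)
  if (is.null(true_induction_frequency))
    true_induction_frequency <-
      if (preset == "wildtype") 0.006 else 0.006 / 1.7
  spec <- .preset_foci(preset)
  trajs <- lapply(seq_len(nrow(spec)), function(i) {
    p <- simulation_params(
      gamma_true = gamma_true, sigma_true = spec$sigma[i],
      n_steps = n_frames, cell_radius = cell_radius,
      boundary = "reflecting", start = "random",
      focus_growth = 1e-4, initial_volume = spec$initial_volume[i],
      seed = seed * 101 + i)
    simulate_trajectory(
      p, focus_id = sprintf("%s_f%02d", preset, i),
      cell_id = sprintf("%s_c%02d", preset, spec$cell[i]),
      label = paste(preset, spec$size_class[i], sep = ":"))
  })
  names(trajs) <- vapply(trajs, `[[`, "", "focus_id")
  cell_ids <- unique(vapply(trajs, `[[`, "", "cell_id"))
  cells <- lapply(seq_along(cell_ids), function(j)
    simulate_cell(cell_radius, edge_noise = 0.05, n_edges = 8,
                  seed = seed * 211 + j, cell_id = cell_ids[j]))
  names(cells) <- cell_ids
  agg <- lapply(seq_along(cell_ids), function(j) {
    sph <- fit_sphere(cells[[j]])
    simulate_aggregate_positions(sph, n = 3,
                                 peripheral_bias = peripheral_bias,
                                 seed = seed * 307 + j)
  })
  names(agg) <- cell_ids
  counts <- simulate_aggregate_counts(n_count_cells, preset,
                                      seed = seed * 401 + 1)
  platings <- lapply(1:3, function(k)
    simulate_induction_counts(true_induction_frequency, cfu_total = 100,
                              density_factor = 100, seed = seed * 503 + k,
                              group = preset))
  structure(list(preset = preset, trajectories = trajs, cells = cells,
                 aggregate_positions = agg, counts = counts,
                 platings = platings),
            class = "strain_dataset")
}

#' @export
print.strain_dataset <- function(x, ...) {
  cat(sprintf("<strain_dataset> %s: %d foci in %d cells, %d scored cells, %d platings\n",
              x$preset, length(x$trajectories), length(x$cells),
              nrow(x$counts), length(x$platings)))
  invisible(x)
}

#' Write a simulated strain dataset to CSV files
#'
#' Emits the standard pipeline input files into a directory:
#' `trajectories.csv`, `edges.csv`, `counts.csv`, `plates.csv`, and
#' `aggregates.csv` (mature aggregate coordinates per cell).
#'
#' @param dataset a [simulate_preset()] result (or list of several; files
#'   are concatenated).
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_strain_dataset <- function(dataset, dir) {
  if (inherits(dataset, "strain_dataset")) dataset <- list(dataset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trajectories(do.call(c, lapply(dataset, `[[`, "trajectories")),
                     file.path(dir, "trajectories.csv"))
  edges <- do.call(rbind, lapply(dataset, function(ds)
    do.call(rbind, lapply(ds$cells, function(ce)
      data.frame(cell_id = ce$cell_id, x_um = ce$edge_points[, 1],
                 y_um = ce$edge_points[, 2], z_um = ce$edge_points[, 3],
                 diameter_um = c(ce$diameters,
                                 rep(NA, nrow(ce$edge_points) -
                                       length(ce$diameters))))))))
  write_results(edges, file.path(dir, "edges.csv"))
  write_results(do.call(rbind, lapply(dataset, function(ds)
    as.data.frame(ds$counts))), file.path(dir, "counts.csv"))
  write_results(do.call(rbind, lapply(dataset, function(ds)
    do.call(rbind, lapply(ds$platings, as.data.frame)))),
    file.path(dir, "plates.csv"))
  aggs <- do.call(rbind, lapply(dataset, function(ds) {
    do.call(rbind, lapply(names(ds$aggregate_positions), function(cid) {
      m <- ds$aggregate_positions[[cid]]
      data.frame(cell_id = cid, group = ds$preset,
                 x_um = m[, 1], y_um = m[, 2], z_um = m[, 3])
    }))
  }))
  write_results(aggs, file.path(dir, "aggregates.csv"))
  invisible(dir)
}
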