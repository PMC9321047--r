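#' Median ellipsoid volume of a tracked focus
#'
#' Per-frame ellipsoid volumes from the trajectory's measured extents,
#' summarised by the median (robust to occasional mis-measured frames).
#'
#' @param traj a [trajectory] carrying `extents`.
#' @return volume in um^3.
#' @export
focus_volume <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$extents)) stop("trajectory carries no extents")
  stats::median(ellipsoid_volume(traj$extents[, 1], traj$extents[, 2],
                                 traj$extents[, 3]))
}

#' Run the full focus-dynamics pipeline on simulated strain data
#'
#' End-to-end driver: simulates the requested strain presets, writes their
#' CSV inputs to `dir`, re-ingests them from disk, and runs kinematics,
#' movement-model fitting, cell geometry / periphery mapping, and the
#' result-level statistics, writing one CSV per stage plus a plain-text
#' summary. Deterministic for a fixed seed.
#'
#' @param dir working directory for the CSV artefacts.
#' @param seed integer master seed.
#' @param presets strain presets to simulate and contrast.
#' @param n_frames frames per trajectory (default 100).
#' @return invisibly, a list with `profiles`, `fits` (data frames),
#'   `histograms` (per group), `count_summary`, `regressions` (gamma and
#'   sigma vs focus:cell volume ratio), `periphery` (per-aggregate
#'   positions), `periphery_test` (KS across groups, when 2 presets),
#'   `induction` (per-plating frequencies and per-group means),
#'   `fold_change`.
#' @export
run_focus_pipeline <- function(dir = tempfile("foci_"), seed = 1,
                               presets = c("wildtype", "act1-122"),
                               n_frames = 100) {
  datasets <- lapply(seq_along(presets), function(i)
    simulate_preset(presets[i], seed = seed + (i - 1), n_frames = n_frames))
  write_strain_dataset(datasets, dir)

  ## ingest from disk so the pipeline exercises the I/O layer
  trajs <- read_trajectories(file.path(dir, "trajectories.csv"))
  cells <- read_cell_edges(file.path(dir, "edges.csv"))
  counts <- read_counts(file.path(dir, "counts.csv"))
  plates <- read_plate_counts(file.path(dir, "plates.csv"))
  aggs <- utils::read.csv(file.path(dir, "aggregates.csv"))

  ## kinematics
  profiles <- lapply(trajs, speed_profile)
  write_results(profiles, file.path(dir, "speed_profiles.csv"))
  group_of <- function(tr) sub(":.*", "", tr$label)
  groups <- vapply(trajs, group_of, "")
  histograms <- lapply(split(trajs, groups), run_length_histogram)
  write_results(do.call(rbind, lapply(names(histograms), function(g)
    cbind(group = g, as.data.frame(histograms[[g]])))),
    file.path(dir, "run_lengths.csv"))

  ## movement model
  fits <- lapply(trajs, fit_markov_model)
  fit_df <- do.call(rbind, lapply(fits, as.data.frame))
  fit_df$classification <- vapply(fits, classify_randomness, "")
  write_results(fit_df, file.path(dir, "movement_fits.csv"))

  ## geometry: conceptual spheres, volume ratios, periphery mapping
  spheres <- lapply(cells, fit_sphere)
  cell_vol <- vapply(spheres, function(s)
    ellipsoid_volume(2 * s$radius, 2 * s$radius, 2 * s$radius), 0)
  fit_df$volume_um3 <- vapply(trajs[fit_df$focus_id], focus_volume, 0)
  fit_df$volume_ratio <- fit_df$volume_um3 /
    cell_vol[vapply(trajs[fit_df$focus_id], `[[`, "", "cell_id")]
  periph <- do.call(rbind, lapply(split(aggs, aggs$cell_id), function(d) {
    pp <- relative_periphery_distance(
      cbind(d$x_um, d$y_um, d$z_um), spheres[[d$cell_id[1]]])
    cbind(cell_id = d$cell_id, group = d$group, pp)
  }))
  write_results(periph, file.path(dir, "periphery.csv"))

  ## result-level statistics
  regressions <- list(
    gamma_vs_ratio = volume_movement_regression(fit_df$volume_ratio,
                                                fit_df$gamma),
    sigma_vs_ratio = volume_movement_regression(fit_df$volume_ratio,
                                                fit_df$sigma))
  count_summary <- aggregate_count_summary(counts)
  periphery_test <- if (length(presets) == 2) {
    sp <- split(periph$relative_distance, periph$group)
    group_comparison(sp[[presets[1]]], sp[[presets[2]]], "ks")
  }
  speed_test <- if (length(presets) == 2) {
    sp <- split(vapply(profiles, function(p) mean(p$steps$speed), 0),
                groups)
    group_comparison(sp[[presets[1]]], sp[[presets[2]]], "welch_t")
  }
  induction <- do.call(rbind, lapply(seq_len(nrow(plates)), function(i)
    as.data.frame(induction_frequency(plates$colonies_selective[i],
                                      plates$cfu_total[i],
                                      plates$density_factor[i],
                                      group = plates$group[i]))))
  mean_freq <- tapply(induction$frequency, induction$group, mean)
  fold_change <- if (length(presets) == 2)
    induction_fold_change(mean_freq[[presets[1]]], mean_freq[[presets[2]]])

  write_results(count_summary, file.path(dir, "count_summary.csv"))
  write_results(induction, file.path(dir, "induction.csv"))

  summary_lines <- c(
    sprintf("foci pipeline report (seed %d)", seed),
    sprintf("presets: %s", paste(presets, collapse = ", ")),
    sprintf("foci tracked: %d; mean speed %.1f nm/s",
            nrow(fit_df), 1000 * mean(do.call(rbind, lapply(
              profiles, as.data.frame))$mean_speed)),
    sprintf("max directional correlation: %.3f (all %s)",
            max(fit_df$gamma),
            if (all(fit_df$classification == "random")) "random"
            else "not all random"),
    sprintf("gamma vs volume ratio: slope %.3g (p = %.3g, r2 = %.3f)",
            regressions$gamma_vs_ratio$slope,
            regressions$gamma_vs_ratio$p_value,
            regressions$gamma_vs_ratio$r_squared),
    sprintf("sigma vs volume ratio: slope %.3g (p = %.3g, r2 = %.3f)",
            regressions$sigma_vs_ratio$slope,
            regressions$sigma_vs_ratio$p_value,
            regressions$sigma_vs_ratio$r_squared),
    sprintf("percent single-aggregate cells: %s",
            paste(sprintf("%s %.0f%%", count_summary$group,
                          count_summary$percent_single), collapse = ", ")),
    sprintf("mean induction frequency: %s",
            paste(sprintf("%s %.4f", names(mean_freq), mean_freq),
                  collapse = ", ")))
  if (!is.null(fold_change))
    summary_lines <- c(summary_lines,
                       sprintf("induction fold change (%s / %s): %.2f",
                               presets[1], presets[2], fold_change))
  writeLines(summary_lines, file.path(dir, "summary.txt"))

  invisible(list(dir = dir, profiles = profiles, fits = fit_df,
                 histograms = histograms, count_summary = count_summary,
                 regressions = regressions, periphery = periph,
                 periphery_test = periphery_test, speed_test = speed_test,
                 induction = induction, mean_frequency = mean_freq,
                 fold_change = fold_change, summary = summary_lines))
}
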