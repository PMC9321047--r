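## Plain-CSV readers/writers for the pipeline's tabular inputs: trajectory
## tables (one row per focus x frame), membrane edge tables, per-cell
## aggregate counts, and plate counts. Comma-separated UTF-8 with a header
## row, matching manual-tracking spreadsheet exports.

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("format error in '%s': missing column(s) %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
}

#' Read tracked-focus trajectories from a CSV table
#'
#' Expects one row per (focus, frame) with columns `focus_id`, `cell_id`,
#' `frame`, `x_um`, `y_um`, `z_um`, and optionally `len_x`, `len_y`, `len_z`
#' (focus extents, micrometres) and `label`. Missing frames are encoded as
#' absent rows and reconstructed as gaps from the 0-based frame index. When
#' the z coordinate comes from a stack index, pass the per-movie z step size
#' as `z_scale` (axial steps vary per acquisition, typically 0.28-0.6 um).
#'
#' @param path CSV file path.
#' @param frame_interval seconds per frame (default 10).
#' @param z_scale multiplicative factor applied to the z column (default 1).
#' @param column_map optional named character vector mapping the expected
#'   column names to the names actually present in the file, e.g.
#'   `c(x_um = "X", y_um = "Y")`.
#' @return named list of [trajectory] objects, one per `focus_id`.
#' @export
read_trajectories <- function(path, frame_interval = 10, z_scale = 1,
                              column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      if (!column_map[[std]] %in% names(df))
        stop(sprintf("format error in '%s': mapped column '%s' absent",
                     path, column_map[[std]]), call. = FALSE)
      names(df)[names(df) == column_map[[std]]] <- std
    }
  }
  .require_columns(df, c("focus_id", "cell_id", "frame", "x_um", "y_um",
                         "z_um"), path)
  if (anyDuplicated(df[c("focus_id", "frame")]))
    stop("validation error: duplicate (focus_id, frame) rows in ", path)
  has_ext <- all(c("len_x", "len_y", "len_z") %in% names(df))
  out <- lapply(split(df, df$focus_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    trajectory(
      focus_id = d$focus_id[1], cell_id = d$cell_id[1],
      positions = cbind(d$x_um, d$y_um, d$z_um * z_scale),
      frames = d$frame, frame_interval = frame_interval,
      extents = if (has_ext) cbind(d$len_x, d$len_y, d$len_z),
      label = if ("label" %in% names(d)) d$label[1] else NA_character_)
  })
  out[order(names(out))]
}

#' Write trajectories back to the CSV trajectory format
#'
#' Inverse of [read_trajectories()]: values round-trip at full precision and
#' gaps are preserved through the frame indices.
#'
#' @param trajectories list of [trajectory] objects.
#' @param path output CSV path (directory must exist).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  rows <- lapply(trajectories, function(tr) {
    d <- data.frame(focus_id = tr$focus_id, cell_id = tr$cell_id,
                    frame = tr$frames,
                    x_um = tr$positions[, 1], y_um = tr$positions[, 2],
                    z_um = tr$positions[, 3])
    if (!is.null(tr$extents)) {
      d$len_x <- tr$extents[, 1]; d$len_y <- tr$extents[, 2]
      d$len_z <- tr$extents[, 3]
    }
    d$label <- tr$label
    d
  })
  has_ext <- vapply(rows, function(d) "len_x" %in% names(d), logical(1))
  if (any(has_ext) && !all(has_ext))
    rows <- lapply(rows, function(d) {
      if (!"len_x" %in% names(d)) d$len_x <- d$len_y <- d$len_z <- NA_real_
      d[c("focus_id", "cell_id", "frame", "x_um", "y_um", "z_um",
          "len_x", "len_y", "len_z", "label")]
    })
  write_results(do.call(rbind, rows), path)
}

#' Read cell membrane measurements
#'
#' Accepts either an edge-point table (`cell_id`, `x_um`, `y_um`, `z_um`) or
#' a diameter table (`cell_id`, `diameter_um`); files may carry both column
#' sets.
#'
#' @param path CSV file path.
#' @return named list of [cell_edge_set] objects, one per cell.
#' @export
read_cell_edges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, "cell_id", path)
  has_pts <- all(c("x_um", "y_um", "z_um") %in% names(df))
  has_dia <- "diameter_um" %in% names(df)
  if (!has_pts && !has_dia)
    stop(sprintf("format error in '%s': need x_um/y_um/z_um or diameter_um",
                 path), call. = FALSE)
  out <- lapply(split(df, df$cell_id), function(d) {
    pts <- if (has_pts) {
      m <- cbind(d$x_um, d$y_um, d$z_um)
      m <- m[stats::complete.cases(m), , drop = FALSE]
      if (nrow(m)) m
    }
    dia <- if (has_dia) d$diameter_um[!is.na(d$diameter_um)]
    if (!is.null(dia) && !length(dia)) dia <- NULL
    cell_edge_set(d$cell_id[1], edge_points = pts, diameters = dia)
  })
  out[order(names(out))]
}

#' Read per-cell aggregate counts
#'
#' Expects columns `cell_id`, `group`, `n_aggregates` (nonnegative
#' integers).
#'
#' @param path CSV file path.
#' @return data frame of class `count_table`.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("cell_id", "group", "n_aggregates"), path)
  if (any(df$n_aggregates < 0) || any(df$n_aggregates != round(df$n_aggregates)))
    stop("validation error: aggregate counts must be nonnegative integers")
  df$n_aggregates <- as.integer(df$n_aggregates)
  class(df) <- c("count_table", "data.frame")
  df
}

#' Read plate counts for induction-frequency estimation
#'
#' Expects columns `group`, `colonies_selective`, `cfu_total`, and
#' optionally `density_factor` (default 100: the selective plate receives a
#' 100-fold higher cell density than the CFU plate).
#'
#' @param path CSV file path.
#' @return data frame with one row per plating.
#' @export
read_plate_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("group", "colonies_selective", "cfu_total"), path)
  if (!"density_factor" %in% names(df)) df$density_factor <- 100
  if (any(df$colonies_selective < 0) || any(df$cfu_total <= 0))
    stop("validation error: counts must be nonnegative with positive CFU")
  df
}

#' Write a results table to CSV
#'
#' Accepts a data frame, or a list of per-focus fit/profile objects that
#' have an `as.data.frame` method (e.g. [fit_markov_model()] results), and
#' writes a header-row CSV that round-trips numeric values at full
#' precision.
#'
#' @param records data frame or list of records.
#' @param path output CSV path (directory must exist).
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  if (!dir.exists(dirname(path)))
    stop("I/O error: directory does not exist: ", dirname(path))
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, lapply(records, as.data.frame))
  if (is.null(records) || nrow(records) == 0) {
    warning("writing header-only file: no records")
    if (is.null(records)) records <- data.frame()
  }
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
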