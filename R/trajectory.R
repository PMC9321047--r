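#' Construct a focus trajectory
#'
#' A `trajectory` holds the time-ordered 3D positions (in micrometres) of one
#' tracked focus inside one cell. Frames are 0-based indices into the movie;
#' missing frames (gaps) are encoded as absent entries, never as zero
#' coordinates, so a focus that first appears mid-movie carries its leading
#' gaps implicitly in its frame indices.
#'
#' @param focus_id identifier of the tracked focus.
#' @param cell_id identifier of the cell containing it.
#' @param positions numeric matrix with one row per observed frame and three
#'   columns (x, y, z), micrometres.
#' @param frames integer vector of 0-based frame indices, strictly increasing.
#'   Defaults to `0:(n-1)` (no gaps).
#' @param frame_interval seconds between consecutive frames (default 10 s,
#'   the acquisition interval of the time-lapse protocol this package
#'   targets).
#' @param times optional explicit time stamps in seconds, strictly
#'   increasing; derived as `frames * frame_interval` when omitted.
#' @param extents optional matrix (same rows as `positions`, three columns)
#'   of measured full axis lengths of the focus in micrometres, used for
#'   ellipsoid volumes.
#' @param label free-text group tag (strain, size class, ...).
#'
#' @return An object of class `trajectory`: a list with elements `focus_id`,
#'   `cell_id`, `frames`, `times`, `positions`, `extents`, `label`.
#' @export
trajectory <- function(focus_id, cell_id, positions, frames = NULL,
                       frame_interval = 10, times = NULL, extents = NULL,
                       label = NA_character_) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop("`positions` must have three columns (x, y, z)")
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  if (n < 1L) stop("trajectory needs at least one observed frame")
  if (!all(is.finite(positions)))
    stop("positions must be finite; encode missing frames as absent rows, ",
         "not as NA or zero coordinates")
  if (is.null(frames)) frames <- seq_len(n) - 1L
  frames <- as.integer(frames)
  if (length(frames) != n) stop("`frames` must match rows of `positions`")
  if (any(frames < 0L)) stop("frame indices are 0-based and nonnegative")
  if (any(diff(frames) <= 0L)) stop("frames must be strictly increasing")
  if (is.null(times)) times <- frames * frame_interval
  times <- as.numeric(times)
  if (length(times) != n) stop("`times` must match rows of `positions`")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(extents)) {
    extents <- as.matrix(extents)
    if (nrow(extents) != n || ncol(extents) != 3L)
      stop("`extents` must be an n x 3 matrix of axis lengths")
    if (any(extents[is.finite(extents)] <= 0))
      stop("extents must be positive")
  }
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  structure(
    list(focus_id = as.character(focus_id), cell_id = as.character(cell_id),
         frames = frames, times = times, positions = positions,
         extents = extents, label = as.character(label)),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> focus %s in cell %s: %d frames (%d gaps), %.0f-%.0f s%s\n",
              x$focus_id, x$cell_id, length(x$frames), n_gaps(x),
              min(x$times), max(x$times),
              if (is.na(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

#' Number of missing frames (gaps) in a trajectory
#'
#' Gaps are counted relative to the start of the movie (frame 0), so a focus
#' first tracked at frame 30 has 30 leading gaps even before any internal
#' dropout.
#'
#' @param traj a [trajectory].
#' @return integer count of missing frames in `0:max(frames)`.
#' @export
n_gaps <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  max(traj$frames) + 1L - length(traj$frames)
}

#' Split a trajectory into gap-free segments
#'
#' Returns index runs of consecutive frames (frame difference exactly 1).
#' Displacements, rolling averages and model fits never span a gap.
#'
#' @param traj a [trajectory].
#' @return list of integer index vectors into the trajectory's rows.
#' @export
trajectory_segments <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  brk <- c(0L, which(diff(traj$frames) != 1L), length(traj$frames))
  lapply(seq_len(length(brk) - 1L),
         function(i) (brk[i] + 1L):brk[i + 1L])
}

#' Construct a cell-edge measurement set
#'
#' Membrane measurements for one cell: 3D coordinates of points on the
#' membrane (at least four, not all coplanar, for sphere fitting) and/or
#' measured cell diameters.
#'
#' @param cell_id identifier.
#' @param edge_points optional numeric matrix (>= 4 rows, 3 columns) of
#'   membrane points in micrometres.
#' @param diameters optional positive lengths in micrometres.
#' @return An object of class `cell_edge_set`.
#' @export
cell_edge_set <- function(cell_id, edge_points = NULL, diameters = NULL) {
  if (is.null(edge_points) && is.null(diameters))
    stop("need edge points and/or diameters")
  if (!is.null(edge_points)) {
    edge_points <- as.matrix(edge_points)
    if (ncol(edge_points) != 3L) stop("edge points must be 3D")
    if (nrow(edge_points) < 4L)
      stop("need at least 4 edge points (the protocol records >= 6)")
    if (!all(is.finite(edge_points))) stop("edge points must be finite")
    storage.mode(edge_points) <- "double"
  }
  if (!is.null(diameters)) {
    diameters <- as.numeric(diameters)
    if (any(!is.finite(diameters)) || any(diameters <= 0))
      stop("diameters must be positive and finite")
  }
  structure(list(cell_id = as.character(cell_id),
                 edge_points = edge_points, diameters = diameters),
            class = "cell_edge_set")
}

#' @export
print.cell_edge_set <- function(x, ...) {
  cat(sprintf("<cell_edge_set> cell %s: %d edge points, %d diameters\n",
              x$cell_id,
              if (is.null(x$edge_points)) 0L else nrow(x$edge_points),
              length(x$diameters)))
  invisible(x)
}
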