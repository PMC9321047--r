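#' Ellipsoid volume from measured axis lengths
#'
#' Computes the volume of an ellipsoid, `V = 4/3 * pi * a * b * c`, from
#' the three measured full lengths of a focus or cell along x, y and z.
#' The measured lengths are full extents, so they are halved to the
#' semi-axes a, b, c before applying the formula.
#'
#' @param len_x,len_y,len_z measured full axis lengths in micrometres
#'   (vectorised).
#' @return volume(s) in cubic micrometres.
#' @export
ellipsoid_volume <- function(len_x, len_y, len_z) {
  if (any(!is.finite(c(len_x, len_y, len_z))) ||
      any(c(len_x, len_y, len_z) <= 0))
    stop("axis lengths must be positive and finite")
  (4 / 3) * pi * (len_x / 2) * (len_y / 2) * (len_z / 2)
}

#' Ratio of focus volume to cell volume
#'
#' @param focus_volume,cell_volume volumes in cubic micrometres (either
#'   bare numbers or the `volume` elements of ellipsoid measurements).
#' @return dimensionless ratio; a warning is raised when it exceeds 1
#'   (focus apparently larger than its cell implies a measurement error).
#' @export
volume_ratio <- function(focus_volume, cell_volume) {
  if (any(!is.finite(cell_volume)) || any(cell_volume <= 0))
    stop("cell volume must be positive")
  if (any(!is.finite(focus_volume)) || any(focus_volume <= 0))
    stop("focus volume must be positive")
  r <- focus_volume / cell_volume
  if (any(r > 1))
    warning("volume ratio > 1: focus measured larger than its cell")
  r
}

#' Fit the conceptual cell sphere
#'
#' Reduces a cell's membrane measurements to a sphere (centre + radius R).
#' Two methods: `"least_squares_edges"` fits an algebraic least-squares
#' sphere through the recorded membrane edge points; `"mean_diameter"`
#' takes R as half the mean of the measured diameters, with the centre at
#' the centroid of any edge points (or a supplied `center`). The default
#' `"auto"` uses the edge-point fit when at least 6 edge points exist,
#' falling back to the diameter method.
#'
#' @param edges a [cell_edge_set].
#' @param method `"auto"`, `"least_squares_edges"` or `"mean_diameter"`.
#' @param center optional 3-vector: sphere centre for the diameter method
#'   when no edge points are available.
#' @return object of class `fitted_sphere`: list with `cell_id`, `center`,
#'   `radius` (um), `method`, `rms_residual` (um; radial misfit of the edge
#'   points, `NA` without edge points).
#' @export
fit_sphere <- function(edges, method = c("auto", "least_squares_edges",
                                         "mean_diameter"), center = NULL) {
  stopifnot(inherits(edges, "cell_edge_set"))
  method <- match.arg(method)
  n_pts <- if (is.null(edges$edge_points)) 0L else nrow(edges$edge_points)
  if (method == "auto")
    method <- if (n_pts >= 6L) "least_squares_edges" else "mean_diameter"

  if (method == "least_squares_edges") {
    if (n_pts < 4L)
      stop("least_squares_edges needs >= 4 edge points; ",
           "fall back to method = 'mean_diameter'")
    p <- edges$edge_points
    ## coplanarity: centred points must span 3 dimensions
    sv <- svd(scale(p, scale = FALSE))$d
    if (sv[3] < 1e-8 * max(sv[1], 1))
      stop("edge points are (nearly) coplanar; ",
           "fall back to method = 'mean_diameter'")
    ## |p - c|^2 = R^2  <=>  2 p.c + (R^2 - |c|^2) = |p|^2, linear in (c, k)
    A <- cbind(2 * p, 1)
    b <- rowSums(p^2)
    sol <- unname(qr.solve(A, b))
    ctr <- sol[1:3]
    radius <- sqrt(sol[4] + sum(ctr^2))
    rms <- sqrt(mean((sqrt(rowSums(sweep(p, 2, ctr)^2)) - radius)^2))
  } else {
    if (is.null(edges$diameters))
      stop("mean_diameter needs >= 1 recorded diameter; ",
           "fall back to method = 'least_squares_edges'")
    radius <- mean(edges$diameters) / 2
    if (n_pts > 0) {
      ctr <- colMeans(edges$edge_points)
      rms <- sqrt(mean((sqrt(rowSums(sweep(edges$edge_points, 2,
                                           ctr)^2)) - radius)^2))
    } else {
      if (is.null(center))
        stop("mean_diameter without edge points requires a `center`")
      ctr <- as.numeric(center)
      rms <- NA_real_
    }
  }
  if (!is.finite(radius) || radius <= 0) stop("fitted radius not positive")
  structure(list(cell_id = edges$cell_id, center = unname(ctr),
                 radius = radius, method = method, rms_residual = rms),
            class = "fitted_sphere")
}

#' @export
print.fitted_sphere <- function(x, ...) {
  cat(sprintf(
    "<fitted_sphere> cell %s: R = %.3f um at (%.2f, %.2f, %.2f), %s (rms %.3g um)\n",
    x$cell_id, x$radius, x$center[1], x$center[2], x$center[3], x$method,
    x$rms_residual))
  invisible(x)
}

#' @export
as.data.frame.fitted_sphere <- function(x, ...) {
  data.frame(cell_id = x$cell_id, center_x = x$center[1],
             center_y = x$center[2], center_z = x$center[3],
             radius_um = x$radius, method = x$method,
             rms_residual_um = x$rms_residual)
}

#' Relative distance of an aggregate from the cell periphery
#'
#' Places an aggregate inside the conceptual cell sphere and expresses its
#' position as a relative distance from the periphery: 0.0 is the cell
#' periphery (on the membrane, radial distance r = R) and 0.5 is the middle
#' of the cell (r = 0), linearly via `(R - r) / (2R)`. Aggregates measured
#' slightly outside the fitted sphere (r > R, inevitable with manual
#' membrane coordinates) are clipped to 0 with a warning.
#'
#' @param aggregate_xyz 3-vector or n x 3 matrix of aggregate coordinates
#'   (um).
#' @param sphere a [fit_sphere()] result.
#' @return data frame of class `periphery_position` with columns `x`, `y`,
#'   `z`, `radial_distance` (um), `relative_distance` (in `[0, 0.5]`).
#' @export
relative_periphery_distance <- function(aggregate_xyz, sphere) {
  stopifnot(inherits(sphere, "fitted_sphere"))
  if (sphere$radius <= 0) stop("sphere radius must be positive")
  p <- if (is.matrix(aggregate_xyz)) aggregate_xyz else
    matrix(as.numeric(aggregate_xyz), ncol = 3)
  r <- sqrt(rowSums(sweep(p, 2, sphere$center)^2))
  rel <- (sphere$radius - r) / (2 * sphere$radius)
  if (any(rel < 0))
    warning(sprintf(
      "%d aggregate(s) outside the fitted sphere; clipped to periphery (0)",
      sum(rel < 0)))
  out <- data.frame(x = p[, 1], y = p[, 2], z = p[, 3],
                    radial_distance = r,
                    relative_distance = pmin(0.5, pmax(0, rel)))
  class(out) <- c("periphery_position", "data.frame")
  out
}
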