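## Synthetic-data generators. These produce every input the pipeline
## consumes -- confined correlated-random-walk trajectories, noisy membrane
## edge points, peripherally biased aggregate positions, per-cell aggregate
## counts, and binomial colony counts -- with known ground truth, so that
## estimator recovery can be tested end to end. All generators are
## deterministic for a fixed seed.

#' Parameters for the trajectory simulator
#'
#' @param gamma_true directional correlation of the generating walk, in
#'   `[0, 1)`; 0 is a pure random walk, values near 1 are nearly ballistic
#'   (exactly 1 is nonstationary and rejected).
#' @param sigma_true per-axis standard deviation of the random step
#'   component, um per frame interval.
#' @param n_steps number of frames to simulate (>= 4).
#' @param frame_interval seconds between frames (default 10).
#' @param cell_radius confining cell radius in um (default 2.5, a typical
#'   haploid yeast cell).
#' @param boundary `"reflecting"` (radial fold at the cell sphere) or
#'   `"none"` (unconfined).
#' @param start `"center"` or `"random"` (uniform in the cell volume).
#' @param focus_growth volume increase per frame, um^3/step (default 0);
#'   linear growth emulating early-focus maturation.
#' @param initial_volume starting focus volume, um^3 (default 0.035,
#'   a ~0.4 um spherical focus).
#' @param sigma_fun optional function(volume) -> sigma, overriding
#'   `sigma_true` per frame to emulate size-dependent mobility (small
#'   mobile vs large static foci); default `NULL` (constant sigma).
#' @param seed integer RNG seed.
#' @return list of class `simulation_params`.
#' @export
simulation_params <- function(gamma_true = 0, sigma_true = 0.25,
                              n_steps = 100, frame_interval = 10,
                              cell_radius = 2.5,
                              boundary = c("reflecting", "none"),
                              start = c("center", "random"),
                              focus_growth = 0, initial_volume = 0.035,
                              sigma_fun = NULL, seed = 1) {
  boundary <- match.arg(boundary)
  start <- match.arg(start)
  if (gamma_true >= 1)
    stop("gamma_true >= 1 is nonstationary; use a ballistic fixture instead")
  if (gamma_true < 0) stop("gamma_true must be in [0, 1)")
  if (sigma_true < 0) stop("sigma_true must be >= 0")
  if (n_steps < 4) stop("n_steps must be >= 4")
  if (cell_radius <= 0) stop("cell_radius must be positive")
  if (focus_growth < 0) stop("focus_growth must be >= 0")
  structure(list(gamma_true = gamma_true, sigma_true = sigma_true,
                 n_steps = as.integer(n_steps),
                 frame_interval = frame_interval,
                 cell_radius = cell_radius, boundary = boundary,
                 start = start, focus_growth = focus_growth,
                 initial_volume = initial_volume, sigma_fun = sigma_fun,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

## radial fold back into the sphere of radius R (repeat for rare large
## overshoots); preserves the step direction, folds only the radius
.reflect_into_sphere <- function(p, R) {
  nrm <- sqrt(sum(p^2))
  while (nrm > R) {
    p <- p * (2 * R - nrm) / nrm
    nrm <- abs(2 * R - nrm)
  }
  p
}

#' Simulate a confined correlated-random-walk trajectory
#'
#' Generates displacements `d_t = gamma_true * d_{t-1} + eps_t` with
#' isotropic Gaussian innovations of per-axis scale `sigma_true`, the
#' generative form of the movement model fitted by [fit_markov_model()]
#' (rotation term set to the identity). The first displacement is drawn
#' from the stationary distribution (per-axis sd
#' `sigma_true / sqrt(1 - gamma_true^2)`). With a reflecting boundary,
#' positions are folded radially back inside the cell sphere, and the
#' realised (post-fold) displacement feeds the next step's correlation.
#' When `focus_growth > 0` (or `sigma_fun` is given), per-frame extents of
#' a sphere-equivalent focus are attached to the trajectory.
#'
#' @param params a [simulation_params()] list.
#' @param focus_id,cell_id,label identifiers for the output trajectory.
#' @return a [trajectory] with `n_steps` frames.
#' @export
simulate_trajectory <- function(params, focus_id = "sim1", cell_id = "cell1",
                                label = NA_character_) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n <- params$n_steps
  R <- params$cell_radius
  pos <- matrix(0, n, 3)
  pos[1, ] <- if (params$start == "random") {
    repeat {
      cand <- stats::runif(3, -R, R)
      if (sum(cand^2) <= R^2) break
    }
    cand
  } else c(0, 0, 0)
  vol <- params$initial_volume + params$focus_growth * (seq_len(n) - 1)
  sig_at <- function(i) {
    if (is.null(params$sigma_fun)) params$sigma_true
    else params$sigma_fun(vol[i])
  }
  g <- params$gamma_true
  d_prev <- stats::rnorm(3, 0, sig_at(1) / sqrt(max(1 - g^2, .Machine$double.eps)))
  for (t in seq_len(n - 1)) {
    d <- g * d_prev + stats::rnorm(3, 0, sig_at(t + 1))
    cand <- pos[t, ] + d
    if (params$boundary == "reflecting")
      cand <- .reflect_into_sphere(cand, R)
    pos[t + 1, ] <- cand
    d_prev <- cand - pos[t, ]
  }
  extents <- if (params$focus_growth > 0 || !is.null(params$sigma_fun)) {
    diam <- 2 * (vol / (4 / 3 * pi))^(1 / 3)
    cbind(diam, diam, diam)
  }
  trajectory(focus_id, cell_id, pos, frames = seq_len(n) - 1L,
             frame_interval = params$frame_interval, extents = extents,
             label = label)
}

#' Simulate membrane edge points of a spherical cell
#'
#' Places `n_edges` points at quasi-uniform directions on the sphere
#' (Fibonacci lattice) at radius `cell_radius` plus Gaussian radial noise.
#'
#' @param cell_radius true cell radius, um.
#' @param edge_noise standard deviation of radial measurement noise, um.
#' @param n_edges number of edge points (>= 4; the tracking protocol
#'   records at least 6).
#' @param seed integer RNG seed.
#' @param cell_id identifier.
#' @param center true cell centre (default origin).
#' @return a [cell_edge_set]; its `diameters` are filled with the four
#'   axis-aligned diameters implied by `cell_radius` plus noise, so both
#'   sphere-fitting methods can be exercised.
#' @export
simulate_cell <- function(cell_radius, edge_noise = 0.05, n_edges = 6,
                          seed = 1, cell_id = "cell1", center = c(0, 0, 0)) {
  if (edge_noise < 0) stop("edge_noise must be >= 0")
  if (n_edges < 4) stop("n_edges must be >= 4")
  if (cell_radius <= 0) stop("cell_radius must be positive")
  set.seed(seed)
  i <- seq_len(n_edges) - 0.5
  phi <- pi * (1 + sqrt(5)) * i           # golden-angle longitude
  costh <- 1 - 2 * i / n_edges            # uniform latitude
  sinth <- sqrt(pmax(0, 1 - costh^2))
  dirs <- cbind(sinth * cos(phi), sinth * sin(phi), costh)
  radii <- cell_radius + stats::rnorm(n_edges, 0, edge_noise)
  pts <- unname(sweep(dirs * radii, 2, center, "+"))
  dia <- 2 * cell_radius + stats::rnorm(4, 0, edge_noise)
  cell_edge_set(cell_id, edge_points = pts, diameters = dia)
}

#' Simulate aggregate positions with peripheral bias
#'
#' Draws `n` positions inside the fitted cell sphere with radial density
#' proportional to `r^(2 + peripheral_bias)` on `[0, R]`: bias 0 is uniform
#' in the cell volume, larger bias pushes mass toward the membrane
#' (emulating the peripherally biased aggregate localisation the pipeline
#' quantifies). Directions are uniform on the sphere.
#'
#' @param sphere a [fit_sphere()] result (or any list with `center` and
#'   `radius`).
#' @param n number of aggregates.
#' @param peripheral_bias nonnegative bias exponent (default 0).
#' @param seed integer RNG seed.
#' @return n x 3 matrix of coordinates, um.
#' @export
simulate_aggregate_positions <- function(sphere, n, peripheral_bias = 0,
                                         seed = 1) {
  if (peripheral_bias < 0) stop("peripheral_bias must be >= 0")
  if (sphere$radius <= 0) stop("sphere radius must be positive")
  set.seed(seed)
  ## density ~ r^(2+b) on [0,R]  =>  r = R * U^(1/(3+b))
  r <- sphere$radius * stats::runif(n)^(1 / (3 + peripheral_bias))
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  sweep(r * cbind(s * cos(phi), s * sin(phi), z), 2, sphere$center, "+")
}

#' Simulate per-cell aggregate counts for a strain preset
#'
#' Draws aggregate counts per cell from a strain-specific distribution:
#' wildtype cells overwhelmingly carry a single aggregate, while actin
#' patch-polarisation mutants frequently carry one large plus several
#' smaller aggregates.
#'
#' @param n_cells number of cells.
#' @param preset `"wildtype"` or `"act1-122"`.
#' @param seed integer RNG seed.
#' @return `count_table` data frame (`cell_id`, `group`, `n_aggregates`).
#' @export
simulate_aggregate_counts <- function(n_cells = 100,
                                      preset = c("wildtype", "act1-122"),
                                      seed = 1) {
  preset <- match.arg(preset)
  set.seed(seed)
  probs <- switch(preset,
    ## wildtype: ~88% single-aggregate cells
    "wildtype" = c(`1` = 0.88, `2` = 0.09, `3` = 0.03),
    ## patch-polarisation mutant: <50% single, long tail of multiples
    "act1-122" = c(`1` = 0.45, `2` = 0.20, `3` = 0.15, `4` = 0.10,
                   `5` = 0.06, `6` = 0.04))
  counts <- sample(as.integer(names(probs)), n_cells, replace = TRUE,
                   prob = probs)
  df <- data.frame(cell_id = sprintf("%s_cell%03d", preset, seq_len(n_cells)),
                   group = preset, n_aggregates = counts)
  class(df) <- c("count_table", "data.frame")
  df
}

#' Simulate colony counts from a plating experiment
#'
#' Emulates the induction-frequency protocol: roughly `cfu_total` cells are
#' plated on the permissive plate and a `density_factor`-fold higher
#' density on the selective plate, where each plated cell forms a colony
#' independently with probability `true_frequency`.
#'
#' @param true_frequency per-cell probability of giving rise to a colony on
#'   the selective plate, in `[0, 1]`.
#' @param cfu_total colony-forming units counted on the permissive plate.
#' @param density_factor fold excess of cells on the selective plate
#'   (default 100).
#' @param seed integer RNG seed.
#' @param group label.
#' @return an `induction_count` (see [induction_frequency()]) with the
#'   observed `frequency` estimate.
#' @export
simulate_induction_counts <- function(true_frequency, cfu_total = 100,
                                      density_factor = 100, seed = 1,
                                      group = "sim") {
  if (!is.finite(true_frequency) || true_frequency < 0 || true_frequency > 1)
    stop("true_frequency must be in [0, 1]")
  set.seed(seed)
  colonies <- stats::rbinom(1, size = round(cfu_total * density_factor),
                            prob = true_frequency)
  induction_frequency(colonies, cfu_total, density_factor, group = group)
}
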