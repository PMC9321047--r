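## Per-trajectory kinematics: step displacements, speeds, rolling (SMA)
## speeds over 30 s windows, linear speed trends, and pooled run-length
## histograms. All quantities respect gaps: no displacement, window or fit
## ever spans a missing frame.

## internal: per-interval table over gap-free segments
.step_table <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  segs <- trajectory_segments(traj)
  rows <- lapply(seq_along(segs), function(s) {
    idx <- segs[[s]]
    if (length(idx) < 2L) return(NULL)
    i0 <- idx[-length(idx)]; i1 <- idx[-1]
    dt <- traj$times[i1] - traj$times[i0]
    if (any(dt <= 0)) stop("validation error: nonpositive time difference")
    dvec <- traj$positions[i1, , drop = FALSE] -
      traj$positions[i0, , drop = FALSE]
    data.frame(segment = s, frame_from = traj$frames[i0],
               frame_to = traj$frames[i1],
               t_from = traj$times[i0], t_to = traj$times[i1], dt = dt,
               dx = dvec[, 1], dy = dvec[, 2], dz = dvec[, 3],
               displacement = sqrt(rowSums(dvec^2)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    stop("empty-result error: trajectory has no consecutive frame pair")
  st <- do.call(rbind, rows)
  st$speed <- st$displacement / st$dt
  rownames(st) <- NULL
  st
}

#' Per-interval 3D displacements of a focus
#'
#' Euclidean distance moved between each pair of consecutive frames, in
#' micrometres. Pairs spanning a gap are omitted.
#'
#' @param traj a [trajectory] with at least 2 consecutive non-gap frames.
#' @return numeric vector of displacements (um per frame interval).
#' @export
step_displacements <- function(traj) .step_table(traj)$displacement

#' Per-interval speeds of a focus
#'
#' Displacement divided by the time difference for each consecutive frame
#' pair, in micrometres per second.
#'
#' @inheritParams step_displacements
#' @return numeric vector of speeds (um/s).
#' @export
speeds <- function(traj) .step_table(traj)$speed

#' Rolling (simple moving average) of a speed series
#'
#' Smooths per-interval speeds by averaging `window` successive recordings
#' (default 3, i.e. a 30 s window at 10 s sampling), rolling with stride 1.
#'
#' @param x numeric speed series.
#' @param window integer window length in intervals (default 3).
#' @return numeric vector of length `length(x) - window + 1`.
#' @export
sma_speed <- function(x, window = 3) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (length(x) < window)
    stop(sprintf("series of length %d shorter than window %d",
                 length(x), window))
  as.numeric(stats::filter(x, rep(1 / window, window),
                           sides = 1))[window:length(x)]
}

#' Linear trend of a (rolling) speed series
#'
#' Ordinary least-squares fit of speed against time. A negative slope
#' classifies a focus as "slowing", a near-zero slope as "static".
#'
#' @param x numeric speed series (typically SMA speeds), um/s.
#' @param times time stamps in seconds, same length as `x`.
#' @return list with `slope` (um/s per s), `intercept` (um/s), `r_squared`,
#'   `p_value`, `n`.
#' @export
speed_trend <- function(x, times) {
  if (length(x) != length(times)) stop("x and times must have equal length")
  if (length(x) < 3L) stop("need at least 3 points for a trend")
  if (diff(range(times)) == 0) stop("constant time vector")
  fit <- stats::lm(x ~ times)
  ## exact lines are legitimate fixtures; silence summary.lm's perfect-fit note
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  co <- stats::coef(sm)
  list(slope = unname(co["times", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r_squared = sm$r.squared,
       p_value = if (nrow(co) > 1) unname(co["times", "Pr(>|t|)"]) else NA_real_,
       n = length(x))
}

#' Full speed profile of one trajectory
#'
#' Convenience wrapper bundling the per-interval step table, the rolling
#' SMA speeds (window centres carry the mid-window time stamp), and the OLS
#' trend of SMA speed against time. Windows never span a gap: each gap-free
#' segment is smoothed separately and segments shorter than the window
#' contribute no SMA values.
#'
#' @inheritParams step_displacements
#' @param window SMA window in intervals (default 3).
#' @return object of class `speed_profile`: list with `focus_id`, `steps`
#'   (data frame), `sma` (data frame with `time`, `sma_speed`), `trend`.
#' @export
speed_profile <- function(traj, window = 3) {
  st <- .step_table(traj)
  sma <- do.call(rbind, lapply(split(st, st$segment), function(d) {
    if (nrow(d) < window) return(NULL)
    data.frame(
      time = as.numeric(stats::filter((d$t_from + d$t_to) / 2,
                                      rep(1 / window, window),
                                      sides = 1))[window:nrow(d)],
      sma_speed = sma_speed(d$speed, window))
  }))
  trend <- if (!is.null(sma) && nrow(sma) >= 3L && diff(range(sma$time)) > 0)
    speed_trend(sma$sma_speed, sma$time)
  structure(list(focus_id = traj$focus_id, label = traj$label, steps = st,
                 sma = sma, trend = trend, window = window),
            class = "speed_profile")
}

#' @export
print.speed_profile <- function(x, ...) {
  cat(sprintf("<speed_profile> focus %s: %d intervals, mean speed %.3f um/s",
              x$focus_id, nrow(x$steps), mean(x$steps$speed)))
  if (!is.null(x$trend))
    cat(sprintf(", SMA trend slope %.2e um/s^2", x$trend$slope))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.speed_profile <- function(x, ...) {
  data.frame(focus_id = x$focus_id, label = x$label,
             n_intervals = nrow(x$steps),
             mean_speed = mean(x$steps$speed),
             mean_step_um = mean(x$steps$displacement),
             trend_slope = if (is.null(x$trend)) NA_real_ else x$trend$slope,
             trend_intercept = if (is.null(x$trend)) NA_real_ else
               x$trend$intercept,
             trend_r_squared = if (is.null(x$trend)) NA_real_ else
               x$trend$r_squared)
}

#' Pooled run-length histogram
#'
#' Tallies the net distances travelled per frame interval (run lengths, in
#' nm per 10 s at the default sampling) across trajectories, in contiguous
#' bins from 0.
#'
#' @param trajectories a [trajectory] or list of them.
#' @param bin_width_nm bin width in nanometres (default 200).
#' @return object of class `run_length_histogram`: list with `bin_edges`
#'   (nm, length bins + 1), `counts`, `fractions`.
#' @export
run_length_histogram <- function(trajectories, bin_width_nm = 200) {
  if (bin_width_nm <= 0) stop("bin width must be positive")
  if (inherits(trajectories, "trajectory"))
    trajectories <- list(trajectories)
  d_nm <- unlist(lapply(trajectories, step_displacements)) * 1000
  if (!length(d_nm)) stop("empty-result error: no displacements to bin")
  n_bins <- max(1L, ceiling(max(d_nm) / bin_width_nm))
  if (max(d_nm) == n_bins * bin_width_nm) n_bins <- n_bins + 1L
  edges <- seq(0, by = bin_width_nm, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(d_nm, edges, left.open = FALSE),
                     nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts,
                 fractions = counts / sum(counts)),
            class = "run_length_histogram")
}

#' @export
print.run_length_histogram <- function(x, ...) {
  cat(sprintf("<run_length_histogram> %d runs in %d bins of %g nm\n",
              sum(x$counts), length(x$counts), diff(x$bin_edges[1:2])))
  invisible(x)
}

#' @export
as.data.frame.run_length_histogram <- function(x, ...) {
  nb <- length(x$counts)
  data.frame(bin_lo_nm = x$bin_edges[seq_len(nb)],
             bin_hi_nm = x$bin_edges[seq_len(nb) + 1L],
             count = x$counts, fraction = x$fractions)
}
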