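test_that("step displacements are 3D Euclidean distances that never span gaps", {
  tr <- make_traj(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(step_displacements(tr), 5)
  tr0 <- make_traj(rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(step_displacements(tr0), 0)
  gappy <- make_traj(rbind(c(0, 0, 0), c(1, 0, 0), c(9, 9, 9)),
                     frames = c(0L, 1L, 3L))
  expect_equal(step_displacements(gappy), 1)  # nothing across the gap
  lonely <- make_traj(rbind(c(0, 0, 0), c(1, 0, 0)), frames = c(0L, 5L))
  expect_error(step_displacements(lonely), "no consecutive")
})

test_that("speeds divide displacement by the frame interval", {
  tr <- make_traj(rbind(c(0, 0, 0), c(0.75, 0, 0)))  # 0.75 um in 10 s
  expect_equal(speeds(tr), 0.075)                     # 75 nm/s
  expect_equal(speeds(make_traj(rbind(c(0, 0, 0), c(0, 0, 0)))), 0)
  expect_error(make_traj(rbind(c(0, 0, 0), c(1, 0, 0)), frames = 0:1,
                         times = c(0, 0)),
               "strictly increasing")
})

test_that("SMA is a stride-1 rolling mean with strict length checks", {
  expect_equal(sma_speed(1:5, 3), c(2, 3, 4))
  expect_equal(sma_speed(rep(0.7, 6), 3), rep(0.7, 4))
  expect_error(sma_speed(1:2, 3), "shorter than window")
})

test_that("SMA is bounded by its window and fixed on constants (property)", {
  set.seed(5)
  for (i in 1:20) {
    x <- runif(sample(4:30, 1), 0, 2)
    w <- sample(2:3, 1)
    s <- sma_speed(x, w)
    for (j in seq_along(s)) {
      win <- x[j:(j + w - 1)]
      expect_lte(s[j], max(win) + 1e-12)
      expect_gte(s[j], min(win) - 1e-12)
    }
    expect_equal(sma_speed(rep(x[1], 5), w), rep(x[1], 5 - w + 1))
  }
})

test_that("speed_trend recovers exact lines and rejects degenerate input", {
  t <- seq(0, 90, by = 10)
  tr <- speed_trend(2 * t + 1, t)
  expect_equal(tr$slope, 2)
  expect_equal(tr$intercept, 1)
  expect_equal(tr$r_squared, 1)
  expect_equal(speed_trend(rep(3, 10), t)$slope, 0)
  expect_error(speed_trend(c(1, 2, 3), rep(5, 3)), "constant time")
})

test_that("speed_trend matches the normal-equations OLS oracle (property)", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    x <- sort(runif(n, 0, 100))
    y <- runif(1, -1, 1) * x + rnorm(n)
    got <- speed_trend(y, x)
    ora <- ols_oracle(x, y)
    expect_equal(got$slope, ora$slope, tolerance = 1e-9)
    expect_equal(got$intercept, ora$intercept, tolerance = 1e-9)
    expect_equal(got$r_squared, ora$r_squared, tolerance = 1e-9)
  }
})

test_that("a decelerating simulated focus has a negative SMA speed trend", {
  ## mobility decays as the focus grows: sigma drops 10-fold over the movie
  p <- simulation_params(gamma_true = 0, sigma_true = 0.5, n_steps = 100,
                         boundary = "none", focus_growth = 0.002,
                         initial_volume = 0.03,
                         sigma_fun = function(v) 0.5 * exp(-15 * v),
                         seed = 21)
  prof <- speed_profile(simulate_trajectory(p))
  expect_lt(prof$trend$slope, 0)
  ## trend agrees with the closed-form OLS oracle on the same series
  ora <- ols_oracle(prof$sma$time, prof$sma$sma_speed)
  expect_equal(prof$trend$slope, ora$slope, tolerance = 1e-9)
})

test_that("speed_profile windows never span a gap", {
  set.seed(3)
  tr <- make_traj(matrix(rnorm(36), 12, 3), frames = c(0:5, 8:13))
  prof <- speed_profile(tr, window = 3)
  ## two segments of 6 frames -> 5 speeds each -> 3 SMA values each
  expect_equal(nrow(prof$steps), 10)
  expect_equal(nrow(prof$sma), 6)
})

test_that("run-length histograms bin displacements in nm from zero", {
  tr <- make_traj(rbind(c(0, 0, 0), c(0.25, 0, 0), c(0.7, 0, 0),
                        c(1.55, 0, 0)))
  h <- run_length_histogram(tr, bin_width_nm = 200)
  expect_equal(h$counts, c(0, 1, 1, 0, 1))
  expect_equal(h$bin_edges, seq(0, 1000, by = 200))
  expect_equal(sum(h$fractions), 1)
  still <- make_traj(matrix(0, 5, 3))
  expect_equal(run_length_histogram(still)$counts[1], 4)
  expect_error(run_length_histogram(tr, bin_width_nm = 0), "positive")
})

test_that("histogram totals equal the number of displacements (property)", {
  set.seed(9)
  for (i in 1:10) {
    trs <- lapply(1:3, function(j) random_traj(sample(5:20, 1)))
    h <- run_length_histogram(trs, bin_width_nm = 150)
    expect_equal(sum(h$counts),
                 length(unlist(lapply(trs, step_displacements))))
    expect_equal(sum(h$fractions), 1, tolerance = 1e-9)
  }
})
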