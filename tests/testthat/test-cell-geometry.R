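test_that("ellipsoid volume halves measured lengths to semi-axes", {
  expect_equal(ellipsoid_volume(2, 2, 2), 4 * pi / 3)
  expect_equal(ellipsoid_volume(2, 4, 6), 8 * pi)
  expect_error(ellipsoid_volume(0, 2, 2), "positive")
})

test_that("ellipsoid volume is monotone and permutation invariant (property)", {
  set.seed(31)
  for (i in 1:15) {
    l <- runif(3, 0.1, 5)
    v <- ellipsoid_volume(l[1], l[2], l[3])
    expect_equal(v, ellipsoid_volume(l[3], l[1], l[2]))
    expect_gt(ellipsoid_volume(l[1] * 1.1, l[2], l[3]), v)
  }
})

test_that("volume ratios behave and flag foci larger than their cell", {
  expect_equal(volume_ratio(5, 5), 1)
  expect_equal(volume_ratio(4.18879, 41.8879), 0.1)
  expect_warning(volume_ratio(10, 5), "larger")
  expect_error(volume_ratio(1, 0), "positive")
})

test_that("least-squares sphere fit is exact on noiseless edge points", {
  pts <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0),
               c(0, 0, 2), c(0, 0, -2))
  s <- fit_sphere(cell_edge_set("c1", edge_points = pts))
  expect_equal(s$center, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(s$radius, 2, tolerance = 1e-9)
  expect_equal(s$rms_residual, 0, tolerance = 1e-9)
  expect_equal(s$method, "least_squares_edges")
  ## off-centre exact sphere
  off <- sweep(pts, 2, c(1, -2, 0.5), "+")
  s2 <- fit_sphere(cell_edge_set("c2", edge_points = off))
  expect_equal(s2$center, c(1, -2, 0.5), tolerance = 1e-9)
  expect_equal(s2$radius, 2, tolerance = 1e-9)
})

test_that("the diameter method averages and halves", {
  s <- fit_sphere(cell_edge_set("c1", diameters = c(4.0, 4.2, 3.8, 4.0)),
                  method = "mean_diameter", center = c(0, 0, 0))
  expect_equal(s$radius, 2)
  expect_error(
    fit_sphere(cell_edge_set("c1", diameters = 4), method = "mean_diameter"),
    "center")
})

test_that("noisy sphere fits recover the radius and match the oracle", {
  ce <- simulate_cell(2, edge_noise = 0.05, n_edges = 12, seed = 42)
  s <- fit_sphere(ce)
  expect_lt(abs(s$radius - 2) / 2, 0.03)
  ora <- sphere_oracle(ce$edge_points)
  expect_equal(s$radius, ora$radius, tolerance = 0.05)
  expect_equal(s$center, ora$center, tolerance = 0.05)
})

test_that("coplanar edge points are rejected with a fallback hint", {
  flat <- cbind(rnorm(6), rnorm(6), 0)
  expect_error(fit_sphere(cell_edge_set("c1", edge_points = flat)),
               "coplanar")
})

test_that("auto method prefers edges when six or more points exist", {
  ce_rich <- simulate_cell(2, 0.01, n_edges = 8, seed = 1)
  expect_equal(fit_sphere(ce_rich)$method, "least_squares_edges")
  ce_poor <- cell_edge_set("c1", edge_points = rbind(
    c(2, 0, 0), c(0, 2, 0), c(0, 0, 2), c(-2, 0, 0)), diameters = 4)
  expect_equal(fit_sphere(ce_poor)$method, "mean_diameter")
})

test_that("periphery mapping hits the defined anchors exactly", {
  s <- fit_sphere(cell_edge_set("c1", edge_points = rbind(
    c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0), c(0, 0, 2),
    c(0, 0, -2))))
  expect_equal(relative_periphery_distance(c(0, 0, 0), s)$relative_distance,
               0.5)   # middle of the cell
  expect_equal(relative_periphery_distance(c(2, 0, 0), s)$relative_distance,
               0)     # on the membrane
  expect_equal(relative_periphery_distance(c(1, 0, 0), s)$relative_distance,
               0.25)  # r = R/2
})

test_that("aggregates outside the fitted sphere clip to the periphery", {
  s <- fit_sphere(cell_edge_set("c1", edge_points = rbind(
    c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0), c(0, 0, 2),
    c(0, 0, -2))))
  expect_warning(pp <- relative_periphery_distance(c(2.3, 0, 0), s),
                 "outside")
  expect_equal(pp$relative_distance, 0)
})

test_that("relative distance decreases monotonically with radius (property)", {
  s <- structure(list(cell_id = "c", center = c(0, 0, 0), radius = 3,
                      method = "mean_diameter", rms_residual = 0),
                 class = "fitted_sphere")
  r <- seq(0, 3, length.out = 50)
  rel <- relative_periphery_distance(cbind(r, 0, 0), s)$relative_distance
  expect_true(all(diff(rel) < 0))
  expect_equal(rel[1], 0.5)
  expect_equal(rel[50], 0)
})

test_that("simulated peripheral bias lowers the median relative distance", {
  s <- fit_sphere(simulate_cell(2.5, 0, n_edges = 10, seed = 2))
  uni <- relative_periphery_distance(
    simulate_aggregate_positions(s, 400, peripheral_bias = 0, seed = 3),
    s)$relative_distance
  bia <- relative_periphery_distance(
    simulate_aggregate_positions(s, 400, peripheral_bias = 4, seed = 4),
    s)$relative_distance
  expect_lt(median(bia), median(uni))
})
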