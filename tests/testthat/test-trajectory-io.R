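test_that("frame indices become time stamps at the frame interval", {
  path <- write_traj_csv(data.frame(
    focus_id = "f1", cell_id = "c1", frame = 0:2,
    x_um = c(0, 1, 2), y_um = 0, z_um = 0))
  trajs <- read_trajectories(path, frame_interval = 10)
  expect_length(trajs, 1)
  expect_equal(trajs$f1$times, c(0, 10, 20))
  expect_equal(trajs$f1$positions[, "x"], c(0, 1, 2))
})

test_that("a focus appearing mid-movie carries its leading frames as gaps", {
  path <- write_traj_csv(data.frame(
    focus_id = "late", cell_id = "c1", frame = 30:99,
    x_um = rnorm(70), y_um = rnorm(70), z_um = rnorm(70)))
  tr <- read_trajectories(path)$late
  expect_equal(n_gaps(tr), 30L)
  expect_equal(tr$times[1], 300)
})

test_that("format and validation errors name the problem", {
  bad <- write_traj_csv(data.frame(
    focus_id = "f1", cell_id = "c1", frame = 0:2, y_um = 0, z_um = 0))
  expect_error(read_trajectories(bad), "x_um")
  dup <- write_traj_csv(data.frame(
    focus_id = "f1", cell_id = "c1", frame = c(0, 0, 1),
    x_um = 0, y_um = 0, z_um = 0))
  expect_error(read_trajectories(dup), "duplicate")
  expect_error(read_trajectories(tempfile()), "not found")
})

test_that("column_map renames nonstandard headers and z_scale rescales z", {
  path <- write_traj_csv(data.frame(
    spot = "f1", cell_id = "c1", frame = 0:2,
    X = c(0, 1, 2), y_um = 0, z_um = c(0, 1, 2)))
  trajs <- read_trajectories(path, z_scale = 0.5,
                             column_map = c(focus_id = "spot", x_um = "X"))
  expect_equal(trajs$f1$positions[, "z"], c(0, 0.5, 1))
  expect_error(
    read_trajectories(path, column_map = c(x_um = "nope")), "nope")
})

test_that("trajectories round-trip through write/read, preserving gaps", {
  set.seed(7)
  trs <- list(
    make_traj(matrix(rnorm(30), 10, 3), frames = c(0:3, 6:11),
              extents = matrix(runif(30, 0.3, 0.6), 10, 3)),
    trajectory("f2", "c2", matrix(rnorm(15), 5, 3), frames = 10:14,
               label = "wt"))
  path <- tempfile(fileext = ".csv")
  write_trajectories(trs, path)
  back <- read_trajectories(path)
  expect_equal(back$f1$positions, trs[[1]]$positions)
  expect_equal(back$f1$extents, trs[[1]]$extents,
               ignore_attr = TRUE)
  expect_equal(n_gaps(back$f1), n_gaps(trs[[1]]))
  expect_equal(n_gaps(back$f2), n_gaps(trs[[2]]))
  expect_equal(back$f2$label, "wt")
})

test_that("movement fits round-trip through write_results at full precision", {
  set.seed(11)
  fits <- lapply(1:3, function(i) fit_markov_model(random_traj(40)))
  path <- tempfile(fileext = ".csv")
  write_results(fits, path)
  back <- read.csv(path)
  expect_equal(back$gamma, vapply(fits, `[[`, 0, "gamma"),
               tolerance = 1e-6)
  expect_equal(back$sigma, vapply(fits, `[[`, 0, "sigma"),
               tolerance = 1e-6)
})

test_that("degenerate writes warn or fail as appropriate", {
  expect_warning(write_results(list(), tempfile(fileext = ".csv")),
                 "header-only")
  expect_error(
    write_results(data.frame(a = 1),
                  file.path(tempfile(), "nodir", "x.csv")),
    "directory")
})

test_that("cell-edge files accept edge points, diameters, or both", {
  pts <- write_traj_csv(data.frame(
    cell_id = "c1", x_um = c(2, -2, 0, 0, 0, 0),
    y_um = c(0, 0, 2, -2, 0, 0), z_um = c(0, 0, 0, 0, 2, -2)))
  ce <- read_cell_edges(pts)$c1
  expect_equal(nrow(ce$edge_points), 6)
  dia <- write_traj_csv(data.frame(cell_id = "c1",
                                   diameter_um = c(4, 4.2, 3.8, 4)))
  ce2 <- read_cell_edges(dia)$c1
  expect_equal(ce2$diameters, c(4, 4.2, 3.8, 4))
  expect_error(read_cell_edges(write_traj_csv(data.frame(cell_id = "c1"))),
               "format error")
})

test_that("count and plate tables are validated on read", {
  ok <- write_traj_csv(data.frame(cell_id = c("a", "b"), group = "wt",
                                  n_aggregates = c(1, 2)))
  expect_s3_class(read_counts(ok), "count_table")
  bad <- write_traj_csv(data.frame(cell_id = "a", group = "wt",
                                   n_aggregates = -1))
  expect_error(read_counts(bad), "nonnegative")
  plates <- write_traj_csv(data.frame(group = "wt", colonies_selective = 60,
                                      cfu_total = 100))
  expect_equal(read_plate_counts(plates)$density_factor, 100)
})
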