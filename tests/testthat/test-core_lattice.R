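test_that("grid descriptor derives spacing and rejects bad sizes", {
  g <- make_grid(sim_config(grid_n = 200, domain_edge = 0.01, total_days = 0))
  expect_identical(g$shape, rep(200L, 3L))
  expect_equal(g$spacing, 5e-5)
  g8 <- make_grid(sim_config(grid_n = 8, domain_edge = 0.008, total_days = 0))
  expect_equal(g8$spacing, 1e-3)
  expect_error(sim_config(grid_n = 0), "grid_n")
})

test_that("neighborhoods have the right sizes and truncate at boundaries", {
  shape <- c(10L, 10L, 10L)
  expect_equal(nrow(neighborhood(c(5, 5, 5), shape, "moore26")), 26)
  expect_equal(nrow(neighborhood(c(5, 5, 5), shape, "faces6")), 6)
  expect_equal(nrow(neighborhood(c(1, 1, 1), shape, "faces6")), 3)
  expect_equal(nrow(neighborhood(c(1, 1, 1), shape, "moore26")), 7)
  # cube(K = 1) is exactly the Moore shell
  c1 <- neighborhood(c(5, 5, 5), shape, "cube", K = 1)
  m <- neighborhood(c(5, 5, 5), shape, "moore26")
  expect_equal(c1[order(c1[,1], c1[,2], c1[,3]), ],
               m[order(m[,1], m[,2], m[,3]), ])
  expect_equal(nrow(neighborhood(c(5, 5, 5), shape, "cube", K = 2)), 124)
  expect_error(neighborhood(c(0, 5, 5), shape, "faces6"), "bounds")
})

test_that("cell density fraction counts the K-cube with nominal denominator", {
  cfg <- tiny_config()
  st <- init_state(cfg)
  # empty region
  expect_equal(cell_density_theta(st, c(2, 2, 2), K = 1), 0)
  # 5-cell seed at the centre, K = 1
  ctr <- ceiling(cfg$grid_n / 2)
  expect_equal(cell_density_theta(st, c(ctr, ctr, ctr), K = 1), 5 / 27)
  # full cube
  st$phen[] <- 1L
  expect_equal(cell_density_theta(st, c(ctr, ctr, ctr), K = 2), 1)
  # boundary point keeps the nominal (2K+1)^3 denominator
  expect_equal(cell_density_theta(st, c(1, 1, 1), K = 1), 8 / 27)
})

test_that("initial state holds the five-cell seed and homogeneous fields", {
  cfg <- tiny_config()
  st <- init_state(cfg)
  cnt <- cell_counts(st)
  expect_equal(cnt[["total"]], 5)
  expect_equal(cnt[["active"]], 5)
  expect_true(all(st$fields$drug == 0))
  expect_true(all(st$fields$oxygen == 1))
  expect_true(all(st$fields$taf == 1))
  # bitwise determinism of initialisation
  st2 <- init_state(cfg)
  expect_identical(st$phen, st2$phen)
  expect_identical(st$cve, st2$cve)
  expect_identical(st$fields, st2$fields)
})

test_that("one cell per voxel holds through simulated steps", {
  cfg <- tiny_config(total_days = 2)
  st <- init_state(cfg)
  for (i in 1:40) {
    st <- step_simulation(st, pin_fields = TRUE)
    expect_true(all(st$phen %in% 0:3))
  }
  expect_gt(cell_counts(st)[["total"]], 5)
})

test_that("vessel files round-trip and malformed input is rejected", {
  cfg <- tiny_config(parent_vessel = "single_axis")
  net <- generate_parent_vessels(cfg, "single_axis")
  f <- withr::local_tempfile(fileext = ".csv")
  write_vessel_file(net, f)
  back <- load_vessel_file(f)
  cols <- c("id", "parent_id", "x", "y", "z", "radius", "age")
  expect_equal(back[cols], net[cols])
  # write(load(f)) reproduces the file
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_vessel_file(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # two-segment file: one root, one child, leaf marked as tip
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# units: grid", "id,parent_id,x,y,z,radius,age",
               "1,-1,1,1,1,1e-6,10", "2,1,2,1,1,1e-6,10"), f3)
  two <- load_vessel_file(f3)
  expect_equal(sum(two$parent_id == -1), 1)
  expect_equal(two$tip, c(FALSE, TRUE))
  # orphan parent reference names the line
  writeLines(c("# units: grid", "id,parent_id,x,y,z,radius,age",
               "1,-1,1,1,1,1e-6,10", "2,9,2,1,1,1e-6,10"), f3)
  expect_error(load_vessel_file(f3), "line 4.*parent")
  # duplicate id
  writeLines(c("# units: grid", "id,parent_id,x,y,z,radius,age",
               "1,-1,1,1,1,1e-6,10", "1,-1,2,1,1,1e-6,10"), f3)
  expect_error(load_vessel_file(f3), "duplicate")
})

test_that("vessel file round-trip is lossless on random forests", {
  set.seed(42)
  for (rep in 1:5) {
    net <- random_vessel_forest(40)
    f <- withr::local_tempfile(fileext = ".csv")
    write_vessel_file(net, f)
    back <- load_vessel_file(f)
    cols <- c("id", "parent_id", "x", "y", "z", "radius", "age")
    expect_equal(back[cols], net[cols])
  }
})

test_that("parent vessel fixtures are deterministic with the declared shape", {
  cfg <- sim_config(grid_n = 50, total_days = 0, parent_vessel = "single_axis")
  v1 <- generate_parent_vessels(cfg, "single_axis")
  expect_equal(nrow(v1), 50)
  expect_true(all(diff(v1$x) == 1))   # monotone along the axis
  expect_equal(length(unique(v1$y)), 1)
  expect_identical(v1, generate_parent_vessels(cfg, "single_axis"))
  vg <- generate_parent_vessels(sim_config(grid_n = 50, total_days = 0,
                                           parent_n_vessels = 5), "face_grid")
  expect_equal(sum(vg$parent_id == -1), 5)
})

test_that("configs survive a YAML round trip and reject unknown keys", {
  cfg <- desk_config(grid_n = 20, total_days = 2)
  f <- withr::local_tempfile(fileext = ".yml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(unclass(back), unclass(cfg))
  writeLines("not_a_real_knob: 3", f)
  expect_error(read_config(f), "unknown configuration keys")
})
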