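test_that("an empty domain is a fixed point of the coupled step", {
  cfg <- tiny_config(parent_vessel = "none")
  st <- init_state(cfg)
  st$phen[] <- 0L
  st$cve[] <- 0
  st$activity[] <- 0
  st <- oncovasc:::refresh_pressure(st)
  st1 <- step_simulation(st)
  expect_equal(st1$fields$oxygen, st$fields$oxygen, tolerance = 1e-12)
  expect_equal(st1$fields$taf, st$fields$taf, tolerance = 1e-12)
  expect_true(all(st1$fields$pressure == 0))
  expect_equal(cell_counts(st1)[["total"]], 0)
})

test_that("runs are bitwise deterministic and cell counts never decrease", {
  cfg <- tiny_config(parent_vessel = "single_axis", total_days = 2)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$record, r2$record)
  expect_identical(r1$state$phen, r2$state$phen)
  expect_true(all(diff(r1$record$total) >= 0))
})

test_that("zero-day runs record only the initial row", {
  r <- run_simulation(tiny_config(total_days = 0))
  expect_equal(nrow(r$record), 1)
  expect_equal(r$record$total, 5)
})

test_that("the five-cell seed doubles on the day-one division clock", {
  cfg <- tiny_config(total_days = 1.1)
  r <- run_simulation(cfg, pin_fields = TRUE)
  rec <- r$record
  expect_equal(rec$total[rec$step == 30], 5)
  expect_equal(rec$total[rec$step == 36], 10)
})

test_that("growth stages are recovered from synthetic count curves", {
  mk <- function(N) data.frame(day = seq_along(N) - 1, total = N)
  # strictly exponential: T1 from day 0, no later stages
  s <- detect_growth_stages(mk(5 * 2^(0:12)))
  expect_equal(s$start_day[s$stage == "T1"], 0)
  expect_true(is.na(s$start_day[s$stage == "T3"]))
  # constant: a single stasis stage
  s2 <- detect_growth_stages(mk(rep(100, 13)))
  expect_true(is.na(s2$start_day[s2$stage == "T1"]))
  expect_equal(s2$start_day[s2$stage == "T3"], 0)
  # piecewise exp / linear / flat / renewed growth with known change points:
  # the linear slope sits between the stasis band (1%/day of ~7000) and the
  # exponential threshold (5% per 2-day window)
  n9 <- 5 * exp(0.8 * 9)
  N <- c(5 * exp(0.8 * 0:9),          # days 0-9: exponential
         n9 + 120 * (1:5),            # days 10-14: linear expansion
         rep(n9 + 600, 5),            # days 15-19: stasis
         n9 + 600 + 120 * (1:5))      # days 20-24: secondary growth
  s3 <- detect_growth_stages(mk(round(N)))
  expect_equal(s3$start_day[s3$stage == "T1"], 0)
  expect_lt(abs(s3$start_day[s3$stage == "T2"] - 9.5), 2.5)
  expect_lt(abs(s3$start_day[s3$stage == "T3"] - 14.5), 2.5)
  expect_lt(abs(s3$start_day[s3$stage == "T4"] - 19.5), 2.5)
  expect_error(detect_growth_stages(mk(c(1, 2))), "3 days")
})

test_that("sphericity ranks balls above rods and grows with ball radius", {
  # single voxel: 6^(2/3) pi^(1/3) / 6, pinned by hand
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_equal(sphericity_metric(one), pi^(1/3) * 6^(2/3) / 6,
               tolerance = 1e-12)
  ball <- function(r) {
    n <- 2 * r + 5
    g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
    c0 <- (n + 1) / 2
    array((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2 <= r^2, rep(n, 3))
  }
  s <- vapply(c(5, 10, 15), function(r) sphericity_metric(ball(r)), numeric(1))
  expect_true(all(diff(s) > 0))   # approaches the continuum value from below
  expect_true(all(s < 1))
  rod <- function(L) {
    a <- array(FALSE, c(L + 2, 5, 5)); a[2:(L + 1), 3, 3] <- TRUE; a
  }
  rods <- vapply(c(4, 10, 25), function(L) sphericity_metric(rod(L)), numeric(1))
  expect_true(all(diff(rods) < 0))   # longer rods are less spherical
  expect_lt(rods[3], s[1])
  expect_error(sphericity_metric(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("outputs round-trip and the manifest reproduces the run", {
  cfg <- tiny_config(parent_vessel = "single_axis", total_days = 1)
  r <- run_simulation(cfg)
  out <- withr::local_tempdir()
  paths <- write_outputs(r, out)
  expect_true(all(file.exists(paths)))
  ts <- utils::read.csv(paths[["timeseries"]])
  expect_equal(nrow(ts), nrow(r$record))
  expect_equal(ts$total, r$record$total)
  net <- load_vessel_file(paths[["vessels"]])
  expect_equal(nrow(net), nrow(r$state$vessels))
  # VTK header conformance
  head <- readLines(paths[["field_oxygen"]], n = 10)
  expect_equal(head[1], "# vtk DataFile Version 3.0")
  expect_equal(head[3], "ASCII")
  expect_equal(head[4], "DATASET STRUCTURED_POINTS")
  expect_match(head[5], "^DIMENSIONS 12 12 12$")
  expect_match(head[8], sprintf("^POINT_DATA %d$", 12^3))
  vals <- as.numeric(readLines(paths[["field_oxygen"]])[-(1:10)])
  expect_equal(vals, as.vector(r$state$fields$oxygen), tolerance = 1e-8)
  # manifest-driven reproduction
  r2 <- run_from_manifest(paths[["manifest"]])
  expect_identical(r2$record, r$record)
})

test_that("checkpointing resumes to the same trajectory as an unbroken run", {
  cfg <- tiny_config(parent_vessel = "single_axis", total_days = 2)
  whole <- run_simulation(cfg)
  half_cfg <- tiny_config(parent_vessel = "single_axis", total_days = 1)
  half <- run_simulation(half_cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(half$state, f)
  st <- load_checkpoint(f)
  st$config$total_days <- 1
  resumed <- run_simulation(st$config, resume_state = st)
  expect_equal(resumed$state$phen, whole$state$phen)
  expect_equal(resumed$state$fields, whole$state$fields)
})
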