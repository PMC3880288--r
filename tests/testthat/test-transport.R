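test_that("stability sub-step count follows the CFL bound", {
  expect_equal(stability_substeps(0, 0, 1), 1L)
  # 6 D dt / h^2 = 3 -> 6 sub-steps
  expect_equal(stability_substeps(0.5, 0, 1), 6L)
  expect_equal(stability_substeps(1.0, 0, 1), 12L)  # doubling D doubles m
  expect_error(stability_substeps(0.1, 0, 1, spacing = 0), "spacing")
})

test_that("uniform field at the boundary value is a fixed point", {
  phi <- array(0.7, c(8, 8, 8))
  out <- phi
  for (i in 1:20) out <- advance_scalar(out, D = 0.05, dt = 1, bc = 0.7)
  attr(out, "clipped") <- NULL
  expect_equal(out, phi, tolerance = 1e-12)
  expect_identical(dim(out), dim(phi))
})

test_that("a single-voxel source deposits source * dt in one step", {
  phi <- array(0, c(8, 8, 8))
  src <- array(0, c(8, 8, 8))
  src[4, 4, 4] <- 0.25
  out <- advance_scalar(phi, D = 0, dt = 1, source = src)
  expect_equal(out[4, 4, 4], 0.25)
  expect_equal(sum(out), 0.25)
})

test_that("the null operator leaves any field unchanged", {
  set.seed(1)
  phi <- array(runif(6^3), c(6, 6, 6))
  out <- advance_scalar(phi, D = 0, dt = 1)
  attr(out, "clipped") <- NULL
  expect_equal(out, phi)
})

test_that("production stepper matches the naive reference with all terms on", {
  set.seed(11)
  d <- c(8, 8, 8)
  phi <- array(runif(prod(d)), d)
  vel <- list(ux = array(runif(prod(d), -0.05, 0.05), d),
              uy = array(runif(prod(d), -0.05, 0.05), d),
              uz = array(runif(prod(d), -0.05, 0.05), d))
  src <- array(runif(prod(d), 0, 0.01), d)
  snk <- array(runif(prod(d), 0, 0.01), d)
  a <- phi; b <- phi
  for (i in 1:25) {
    a <- advance_scalar(a, D = 0.05, dt = 1, velocity = vel,
                        source = src, sink = snk, bc = 0.5)
    attr(a, "clipped") <- NULL
    b <- naive_fd_step(b, D = 0.05, vel = vel, src = src, snk = snk,
                       dt = 1, bc = 0.5)
  }
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-10)
})

test_that("steady 1D diffusion converges to the linear Dirichlet profile", {
  n <- 16
  phi <- array(0, c(n, 4, 4))
  pin <- function(p) { p[1, , ] <- 0; p[n, , ] <- 1; p }
  phi <- pin(phi)
  repeat {
    nxt <- pin(advance_scalar(phi, D = 0.08, dt = 1))
    attr(nxt, "clipped") <- NULL
    if (max(abs(nxt - phi)) < 1e-12) break
    phi <- nxt
  }
  target <- array(rep(seq(0, 1, length.out = n), times = 16), c(n, 4, 4))
  expect_lt(max(abs(phi - target)), 1e-6)
})

test_that("oxygen exchange terms respect their indicators and clamps", {
  cfg <- tiny_config(parent_vessel = "single_axis")
  st <- init_state(cfg)
  # supply stops at the plasma saturation level
  expect_true(all(oxygen_source(st) == 0))
  st$fields$oxygen[] <- 0.5
  src <- oxygen_source(st)
  v <- st$vessels
  vmask <- oncovasc:::vessel_occupancy(v, dim(src))
  expect_true(all(src[!vmask] == 0))
  expect_true(any(src[vmask] > 0))
  # no supply against an adverse transmural gradient
  st$fields$pressure[] <- cfg$p_v + 10
  expect_true(all(oxygen_source(st) == 0))
  # consumption only at cells, scaled by activity
  st2 <- init_state(tiny_config())
  snk <- oxygen_sink(st2)
  expect_true(all(snk[st2$phen == 0L] == 0))
  st2$activity[] <- 0
  expect_true(all(oxygen_sink(st2) == 0))
})

test_that("CO2 terms mirror the oxygen structure", {
  cfg <- tiny_config(parent_vessel = "single_axis")
  st <- init_state(cfg)
  full <- co2_source(st)
  st$activity <- st$activity / 2
  expect_equal(co2_source(st), full / 2)   # proportional to activity
  st$vessels <- oncovasc:::empty_vessel_network()
  st$vess_occ[] <- FALSE
  expect_true(all(co2_sink(st) == 0))
})

test_that("TAF secretion is hypoxia-weighted and removal follows the config", {
  st <- init_state(tiny_config())
  # fully oxygenated tumor secretes nothing
  st$fields$oxygen[] <- 1
  expect_true(all(taf_source(st) == 0))
  # secretion is gated at the hypoxia threshold and larger for deeper hypoxia
  ctr <- ceiling(st$config$grid_n / 2)
  st$fields$oxygen[] <- 0.8
  st$fields$oxygen[ctr, ctr, ctr] <- 0.1
  st$fields$oxygen[ctr + 1, ctr, ctr] <- 0.4
  src <- taf_source(st)
  expect_gt(src[ctr, ctr, ctr], src[ctr + 1, ctr, ctr])
  expect_gt(src[ctr + 1, ctr, ctr], 0)
  expect_equal(src[ctr - 1, ctr, ctr], 0)   # above threshold: no secretion
  # published default removal rate is zero
  expect_true(all(taf_removal(st) == 0))
  st2 <- init_state(tiny_config(lambda_c0 = 1e-5))
  expect_true(any(taf_removal(st2) > 0))
})

test_that("concentration fields stay non-negative through simulated steps", {
  cfg <- tiny_config(parent_vessel = "single_axis", total_days = 1,
                     drug_start_day = 0, drug_dose = 10)
  st <- init_state(cfg)
  for (i in 1:33) {
    st <- step_simulation(st)
    for (sp in c("oxygen", "co2", "taf", "drug"))
      expect_true(all(st$fields[[sp]] >= 0))
  }
  expect_true(any(st$fields$drug > 0))   # dosing is delivering
})
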