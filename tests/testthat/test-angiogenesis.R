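test_that("tip proliferation rate floors at baseline and grows with pressure", {
  cfg <- sim_config(total_days = 0)
  expect_equal(vessel_growth_rate(0, cfg), cfg$g1)
  expect_equal(vessel_growth_rate(-15, cfg), cfg$g1)
  expect_lt(vessel_growth_rate(5, cfg), vessel_growth_rate(20, cfg))
  # regression fixture: rate at a full transmural drop, from direct evaluation
  expect_equal(vessel_growth_rate(cfg$p_v, cfg), 2.0)
})

test_that("branching probability is the published power law in TAF", {
  cfg <- sim_config(total_days = 0)
  expect_equal(branching_probability(0, cfg), 0)
  expect_equal(branching_probability(1, cfg), 0.3e-3)
  taf <- seq(0, 3, by = 0.5)
  expect_true(all(diff(branching_probability(taf, cfg)) >= 0))
  expect_true(all(branching_probability(c(0, 1, 1e6), cfg) <= 1))
  expect_error(branching_probability(-1, cfg), "non-negative")
})

test_that("tips chase the TAF gradient and avoid necrotic tissue", {
  cfg <- tiny_config(parent_vessel = "none",
                     tip_rate_normal = 1, tip_rate_tumor = 1)  # move every step
  st <- init_state(cfg)
  # clear the tumor seed: this exercises migration in cell-free tissue
  st$phen[] <- 0L; st$cve[] <- 0; st$activity[] <- 0
  st <- oncovasc:::refresh_pressure(st)
  st$vessels <- oncovasc:::new_segments(1L, -1L, 6L, 6L, 6L,
                                        age = 100, radius = 1e-6, tip = TRUE)
  st$vess_occ <- oncovasc:::vessel_occupancy(st$vessels, dim(st$phen))
  # TAF strictly increasing in +x only: deterministic move to (7,6,6)
  st$fields$taf <- array(rep(seq_len(12), times = 144), rep(12, 3))
  st2 <- tip_migration_step(st, 1L)
  expect_true(attr(st2, "moved"))
  tip <- st2$vessels[st2$vessels$tip, ]
  expect_equal(c(tip$x, tip$y, tip$z), c(7, 6, 6))
  expect_equal(tip$parent_id, 1L)
  # uniform TAF: samples some admissible face neighbour
  st$fields$taf[] <- 1
  set.seed(3)
  st3 <- tip_migration_step(st, 1L)
  expect_true(attr(st3, "moved"))
  # fully enclosed by necrotic voxels: permanent stall
  st$phen[5:7, 5:7, 5:7] <- 3L
  st$phen[6, 6, 6] <- 0L
  st4 <- tip_migration_step(st, 1L)
  expect_false(attr(st4, "moved"))
  expect_equal(st4$vessels$stall[st4$vessels$tip], 1L)
})

test_that("hotpoint sampling is TAF-gated, seeded, and spawns single branches", {
  cfg <- tiny_config(parent_vessel = "single_axis")
  st <- init_state(cfg)
  # no TAF, no hotpoints
  st$fields$taf[] <- 0
  expect_equal(nrow(sample_branching_hotpoints(st)), 0)
  # determinism under the same seed
  st$fields$taf[] <- 5
  set.seed(10); h1 <- sample_branching_hotpoints(st)
  set.seed(10); h2 <- sample_branching_hotpoints(st)
  expect_identical(h1, h2)
  # probability forced to 1 near one segment: exactly one new tip per segment
  cfg1 <- tiny_config(parent_vessel = "none", k_BH = 1, alpha_BH = 1e-9)
  st1 <- init_state(cfg1)
  st1$vessels <- oncovasc:::new_segments(1L, -1L, 6L, 6L, 6L,
                                         age = 100, radius = 1e-6, tip = FALSE)
  st1$vess_occ <- oncovasc:::vessel_occupancy(st1$vessels, dim(st1$phen))
  st1$fields$taf[] <- 1
  set.seed(2)
  hp <- sample_branching_hotpoints(st1)
  expect_equal(nrow(hp), 6)   # all six face neighbours fire at p = 1
  st1b <- apply_branching(st1, hp)
  expect_equal(nrow(st1b$vessels), 2)   # but only one branch per segment
  expect_true(st1b$vessels$tip[2])
})

test_that("maturation is monotone and saturating; age zero marks pruning", {
  cfg <- sim_config(total_days = 0)
  ages <- c(0, 1, 10, 100, 500, 5000, 1e6)
  r <- vessel_radius(ages, cfg)
  expect_true(all(diff(r) > 0))
  expect_true(all(r[-1] > 0))
  expect_equal(r[1], 0)
  expect_equal(vessel_radius(1e12, cfg), cfg$R_max * cfg$k_AR1, tolerance = 1e-6)
  # stalled tips age backwards, perfused segments forwards
  v <- oncovasc:::new_segments(1:2, c(-1L, 1L), c(3L, 4L), 3L, 3L,
                               age = c(5, 5), radius = 1e-6,
                               tip = c(FALSE, TRUE),
                               stall = c(0L, cfg$stall_steps))
  v2 <- age_and_radius_update(v, cfg)
  expect_equal(v2$age, c(6, 4))
})

test_that("pruning removes exactly the unreachable distal subtree", {
  set.seed(21)
  for (rep in 1:10) {
    v <- random_vessel_forest(60)
    # kill a few random segments
    v$age[sample.int(60, 4)] <- 0
    kept <- prune_vessels(v)
    alive <- v[v$age > 0, , drop = FALSE]
    expect_setequal(kept$id, reachable_segments(alive))
    # survivors keep valid parents (forest invariant)
    nonroot <- kept$parent_id != -1L
    expect_true(all(kept$parent_id[nonroot] %in% kept$id))
  }
  # no zero-age segment: identity
  v <- random_vessel_forest(30)
  expect_identical(prune_vessels(v), v)
  # pruned root removes the whole tree
  chain <- oncovasc:::new_segments(1:5, c(-1L, 1:4), 1:5, 1L, 1L,
                                   age = c(0, rep(10, 4)), radius = 1e-6,
                                   tip = FALSE)
  expect_equal(nrow(prune_vessels(chain)), 0)
})

test_that("the network stays a forest through simulated angiogenesis", {
  cfg <- tiny_config(parent_vessel = "single_axis", total_days = 1,
                     k_BH = 0.05)   # branch-rich setting to exercise topology
  st <- init_state(cfg)
  for (i in 1:33) {
    st <- step_simulation(st)
    v <- st$vessels
    if (!nrow(v)) break
    nonroot <- v$parent_id != -1L
    expect_true(all(v$parent_id[nonroot] %in% v$id))
    expect_false(any(v$id[nonroot] == v$parent_id[nonroot]))
    # acyclic: walking parents always terminates at a root
    depth_ok <- vapply(v$id, function(id) {
      seen <- 0L
      while (id != -1L && seen <= nrow(v)) {
        id <- v$parent_id[match(id, v$id)]
        seen <- seen + 1L
      }
      seen <= nrow(v)
    }, logical(1))
    expect_true(all(depth_ok))
  }
})

test_that("tips drift toward a TAF point source on average", {
  cfg <- tiny_config(parent_vessel = "none", tip_rate_normal = 1)
  st0 <- init_state(cfg)
  # radial TAF hill centred at (10, 10, 10)
  g <- expand.grid(x = 1:12, y = 1:12, z = 1:12)
  st0$fields$taf <- array(10 / (1 + sqrt((g$x - 10)^2 + (g$y - 10)^2 +
                                         (g$z - 10)^2)), rep(12, 3))
  set.seed(17)
  disp <- replicate(40, {
    st <- st0
    st$vessels <- oncovasc:::new_segments(1L, -1L, 3L, 3L, 3L,
                                          age = 100, radius = 1e-6, tip = TRUE)
    st$vess_occ <- oncovasc:::vessel_occupancy(st$vessels, dim(st$phen))
    st$next_vessel_id <- 2L
    for (i in 1:8) {
      tid <- st$vessels$id[st$vessels$tip]
      st <- tip_migration_step(st, tid)
    }
    tip <- st$vessels[st$vessels$tip, ]
    start_d <- sqrt(3 * 7^2)
    start_d - sqrt((tip$x - 10)^2 + (tip$y - 10)^2 + (tip$z - 10)^2)
  })
  expect_gt(mean(disp), 0)
})
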