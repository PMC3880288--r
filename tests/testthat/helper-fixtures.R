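# Small configurations and a cross-file cache for the heavier desk-scale
# runs, so each scenario is simulated once per test session.

tiny_config <- function(...) {
  sim_config(grid_n = 12, total_days = 1, ...)
}

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, maker) {
  if (!exists(key, envir = .run_cache))
    assign(key, maker(), envir = .run_cache)
  get(key, envir = .run_cache)
}

desk_run_vascular <- function() {
  cached_run("desk_vascular", function()
    run_simulation(desk_config(angiogenesis = TRUE)))
}

desk_run_avascular <- function() {
  cached_run("desk_avascular", function()
    run_simulation(desk_config(angiogenesis = FALSE)))
}

# random vessel forest builder for property tests
random_vessel_forest <- function(n_seg, grid = 30L, n_roots = 3L) {
  ids <- seq_len(n_seg)
  parent <- integer(n_seg)
  pos <- matrix(0L, n_seg, 3)
  for (i in ids) {
    if (i <= n_roots) {
      parent[i] <- -1L
      pos[i, ] <- sample.int(grid, 3, replace = TRUE)
    } else {
      p <- sample.int(i - 1L, 1L)
      parent[i] <- p
      step <- sample(c(-1L, 0L, 1L), 3, replace = TRUE)
      pos[i, ] <- pmin(pmax(pos[p, ] + step, 1L), grid)
    }
  }
  oncovasc:::new_segments(ids, parent, pos[, 1], pos[, 2], pos[, 3],
                          age = sample(1:400, n_seg, replace = TRUE),
                          radius = 1e-6, tip = FALSE)
}
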