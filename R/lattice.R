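#' Grid descriptor
#'
#' @param cfg a [sim_config()].
#' @return a list with `shape` (three lattice extents), `spacing` (m) and the
#'   coordinate convention: 1-based integer lattice indices in R, physical
#'   position `(index - 1) * spacing`.
#' @export
make_grid <- function(cfg) {
  validate_config(cfg)
  list(shape = rep(cfg$grid_n, 3L), spacing = cfg$spacing_m,
       coordinates = "1-based lattice indices; position = (index - 1) * spacing")
}

# direction tables ------------------------------------------------------------

faces6_offsets <- function() {
  matrix(c(-1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1),
         ncol = 3, byrow = TRUE)
}

cube_offsets <- function(K) {
  d <- seq(-K, K)
  g <- as.matrix(expand.grid(dx = d, dy = d, dz = d))
  g[rowSums(g != 0) > 0, , drop = FALSE]
}

#' Lattice neighborhoods
#'
#' In-bounds neighbours of a lattice point: the 6 face neighbours
#' (`"faces6"`), the full 26-point Moore shell (`"moore26"`), or the
#' `(2K+1)^3 - 1` points of the K-cube (`"cube"`). Points at the domain
#' boundary return truncated lists.
#'
#' @param point integer vector of length 3 (1-based indices).
#' @param shape lattice extents (length-3 integer vector).
#' @param mode one of `"faces6"`, `"moore26"`, `"cube"`.
#' @param K cube half-width (only for `mode = "cube"`).
#' @return an integer matrix, one neighbour per row.
#' @export
neighborhood <- function(point, shape, mode = c("faces6", "moore26", "cube"), K = 1L) {
  mode <- match.arg(mode)
  point <- as.integer(point)
  if (length(point) != 3L || any(point < 1L) || any(point > shape))
    stop("point out of lattice bounds", call. = FALSE)
  off <- switch(mode,
    faces6 = faces6_offsets(),
    moore26 = cube_offsets(1L),
    cube = cube_offsets(as.integer(K)))
  nb <- sweep(off, 2L, point, `+`)
  keep <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
          nb[, 2] >= 1 & nb[, 2] <= shape[2] &
          nb[, 3] >= 1 & nb[, 3] <= shape[3]
  storage.mode(nb) <- "integer"
  nb[keep, , drop = FALSE]
}

#' Local tumor-cell density fraction
#'
#' The occupancy fraction theta of the `(2K+1)^3` lattice points in the K-cube
#' centred on `point` (centre included). The denominator is always the nominal
#' cube size: points beyond the domain boundary cannot hold cells and count as
#' empty, keeping theta in `[0, 1]`.
#'
#' @param state a simulation state.
#' @param point lattice point (1-based).
#' @param K cube half-width; defaults to the configured neighbourhood.
#' @return a fraction in `[0, 1]`.
#' @export
cell_density_theta <- function(state, point, K = state$config$K_neighborhood) {
  shape <- rep(state$config$grid_n, 3L)
  point <- as.integer(point)
  if (any(point < 1L) || any(point > shape))
    stop("point out of lattice bounds", call. = FALSE)
  K <- as.integer(K)
  lo <- pmax(point - K, 1L)
  hi <- pmin(point + K, shape)
  occ <- state$phen[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  sum(occ > 0L) / (2 * K + 1)^3
}

# theta fields over the whole lattice (shared by pressure and analytics)
theta_field <- function(occ_logical, K) {
  dims <- dim(occ_logical)
  box_sum_cpp(as.numeric(occ_logical), as.integer(dims), as.integer(K)) /
    (2 * K + 1)^3
}

# five-cell seed: centre of the lattice plus its four in-plane face neighbours
seed_positions <- function(n) {
  c0 <- as.integer(ceiling(n / 2))
  rbind(c(c0, c0, c0),
        c(c0 - 1L, c0, c0), c(c0 + 1L, c0, c0),
        c(c0, c0 - 1L, c0), c(c0, c0 + 1L, c0))
}

#' Initialise a simulation state
#'
#' Places the five-cell tumor seed at the lattice centre (centre point plus
#' its four face neighbours in the central plane), sets all continuum fields
#' to their homogeneous initial values (oxygen, carbon dioxide and TAF at
#' their normalised standards, drug at zero), builds the configured parent
#' vasculature, calibrates the derived constants (kernel amplitude, division
#' threshold, drug-damage coefficient) and seeds the central RNG.
#'
#' @param cfg a [sim_config()].
#' @param vessels optional pre-built vessel network (as returned by
#'   [generate_parent_vessels()] or [load_vessel_file()]); overrides the
#'   configured fixture.
#' @return a `sim_state` object.
#' @export
init_state <- function(cfg, vessels = NULL) {
  validate_config(cfg)
  set.seed(cfg$rng_seed)
  n <- cfg$grid_n
  dims <- rep(n, 3L)
  zero <- array(0, dims)

  state <- structure(list(config = cfg), class = "sim_state")
  state$scales <- derive_scales(cfg)
  state$rho_max_t <- calibrate_rho_max(cfg)
  state$rho_max_v <- state$rho_max_t * cfg$rho_max_v_frac
  state$cve_threshold <- calibrate_division_threshold(cfg)
  state$k_drug <- calibrate_k_drug(cfg, state$cve_threshold)

  state$step <- 0L
  state$phen <- array(0L, dims)   # 0 empty, 1 active, 2 quiescent, 3 necrotic
  state$activity <- zero
  state$cve <- zero
  state$cell_age <- array(0L, dims)

  seeds <- seed_positions(n)
  state$phen[seeds] <- 1L
  state$cve[seeds] <- state$cve_threshold / 2
  a0 <- cell_activity(cfg$oxygen_init, cfg$co2_init, cfg)
  state$activity[seeds] <- a0

  state$fields <- list(
    oxygen = array(cfg$oxygen_init, dims),
    co2    = array(cfg$co2_init, dims),
    taf    = array(cfg$taf_init, dims),
    drug   = array(cfg$drug_init, dims),
    pressure = zero)
  state$velocity <- list(ux = zero, uy = zero, uz = zero)

  if (is.null(vessels)) {
    vessels <- if (cfg$parent_vessel == "none") empty_vessel_network()
               else generate_parent_vessels(cfg, cfg$parent_vessel)
  }
  state$vessels <- vessels
  state$vess_occ <- vessel_occupancy(vessels, dims)
  state$next_vessel_id <- if (nrow(vessels)) max(vessels$id) + 1L else 1L

  state$diagnostics <- list(clipped_mass = c(oxygen = 0, co2 = 0, taf = 0, drug = 0))
  refresh_pressure(state)
}

#' @export
print.sim_state <- function(x, ...) {
  cnt <- cell_counts(x)
  cat("<sim_state> step ", x$step, " (day ",
      signif(x$step / x$config$steps_per_day, 4), ")\n", sep = "")
  cat("  cells: ", cnt["total"], " (", cnt["active"], " active, ",
      cnt["quiescent"], " quiescent, ", cnt["necrotic"], " necrotic); vessels: ",
      nrow(x$vessels), " segments\n", sep = "")
  invisible(x)
}

#' Cell counts by phenotype
#'
#' @param state a `sim_state`.
#' @return named integer vector: active, quiescent, necrotic, viable, total.
#' @export
cell_counts <- function(state) {
  tab <- tabulate(state$phen[state$phen > 0L], nbins = 3L)
  c(active = tab[1], quiescent = tab[2], necrotic = tab[3],
    viable = tab[1] + tab[2], total = sum(tab))
}

# occupied lattice positions (m x 3 matrix of 1-based indices)
cell_positions <- function(state, which_phen = 1:3) {
  which(array(state$phen %in% which_phen & state$phen > 0L,
              dim(state$phen)), arr.ind = TRUE)
}
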