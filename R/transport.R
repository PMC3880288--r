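# Explicit finite-difference transport of the continuum species on the unit
# lattice. Normalised per-step units: concentrations in standard-concentration
# units, lengths in lattice spacings, time in iterations.

#' Stability sub-steps for the explicit scheme
#'
#' Smallest integer m such that one sub-step of length `dt/m` satisfies
#' `(dt/m) * (6 D / spacing^2 + sum|u|_max / spacing) <= 0.5`, where
#' `sum|u|_max` is the maximum over the lattice of `|ux| + |uy| + |uz|`.
#'
#' @param D diffusion coefficient.
#' @param u_max_sum maximum of `|ux|+|uy|+|uz|` over the lattice (same units).
#' @param dt step length.
#' @param spacing lattice spacing.
#' @return an integer number of sub-steps, at least 1.
#' @export
stability_substeps <- function(D, u_max_sum, dt, spacing = 1) {
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  load <- dt * (6 * D / spacing^2 + u_max_sum / spacing)
  max(1L, as.integer(ceiling(load / 0.5)))
}

#' Advance a scalar field by one explicit step
#'
#' One step of `d(phi)/dt = D lap(phi) - div(u phi) + source - sink` with a
#' 7-point Laplacian, conservative first-order upwind convection and Dirichlet
#' faces reset to `bc` after each sub-step. The step is split into
#' [stability_substeps()] equal sub-steps; sources and sinks are rates (per
#' unit time) applied at each sub-step. Negative values produced by the
#' scheme are clipped to zero and the removed mass is reported in the
#' `"clipped"` attribute.
#'
#' @param phi 3D array.
#' @param D diffusion coefficient (units of spacing^2 / time; the lattice
#'   spacing is 1 in the internal normalisation).
#' @param dt step length.
#' @param velocity optional list of 3D arrays `ux`, `uy`, `uz`.
#' @param source,sink optional 3D rate arrays (applied as `+source - sink`).
#' @param bc Dirichlet value for all six faces, or `NULL` to leave the
#'   boundary free (zero-flux stencil closure only).
#' @param clip clip negatives to zero (default `TRUE`).
#' @return the advanced 3D array with attribute `clipped`.
#' @export
advance_scalar <- function(phi, D, dt, velocity = NULL, source = NULL,
                           sink = NULL, bc = NULL, clip = TRUE) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  dims <- dim(phi)
  u_sum <- if (is.null(velocity)) 0 else
    max(abs(velocity$ux) + abs(velocity$uy) + abs(velocity$uz))
  m <- stability_substeps(D, u_sum, dt, 1)
  sub <- dt / m
  ux <- velocity$ux; uy <- velocity$uy; uz <- velocity$uz
  clipped <- 0
  for (s in seq_len(m)) {
    res <- fd_step_cpp(phi, as.integer(dims), D, ux, uy, uz, source, sink,
                       sub, if (is.null(bc)) 0 else bc, !is.null(bc), clip)
    phi <- res$field
    clipped <- clipped + res$clipped
  }
  if (any(!is.finite(phi))) stop("transport step produced non-finite values",
                                 call. = FALSE)
  attr(phi, "clipped") <- clipped
  phi
}

# vessel exchange weights ------------------------------------------------------

# radius weight g(R) = R / R_max, clamped to [0, 1]
radius_weight <- function(radius, cfg) pmin(pmax(radius / cfg$R_max, 0), 1)

# transmural pressure weight h(p_v - p_i) = max(p_v - p_i, 0) / p_v
pressure_weight <- function(p_i, cfg) pmax(cfg$p_v - p_i, 0) / cfg$p_v

# scatter per-segment values onto a zero lattice (segments occupy one voxel
# each; coincident segments accumulate)
vessel_scatter <- function(state, values) {
  out <- array(0, dim(state$phen))
  v <- state$vessels
  if (nrow(v)) {
    idx <- cbind(v$x, v$y, v$z)
    lin <- idx[, 1] + dim(out)[1] * ((idx[, 2] - 1) + dim(out)[2] * (idx[, 3] - 1))
    acc <- rowsum(values, lin)
    out[as.integer(rownames(acc))] <- acc[, 1]
  }
  out
}

#' Transport source and sink fields
#'
#' Per-step normalised rate fields for the four species, evaluated on the
#' current state:
#' * `oxygen_source()`: supply at vessel voxels, proportional to the radius
#'   weight `R/R_max`, the transmural pressure weight
#'   `max(p_v - p_i, 0)/p_v` (no supply against an adverse gradient), and the
#'   saturation headroom `max(1 - n, 0)` (exchange stops at the plasma
#'   level).
#' * `oxygen_sink()`: consumption at live-cell voxels, proportional to cell
#'   activity and local oxygen.
#' * `co2_source()` / `co2_sink()`: activity-proportional secretion at
#'   live-cell voxels; vascular clearance with the same radius and pressure
#'   weights as oxygen supply, proportional to local CO2.
#' * `taf_source()` / `taf_removal()`: hypoxia-weighted secretion
#'   `s(n) = max(0, 1 - n)` at live (non-necrotic) cell voxels; removal at
#'   the configured rate, damped in high-pressure regions by
#'   `r(p) = p_v / (p_v + p)`.
#'
#' @param state a `sim_state`.
#' @return a 3D rate array (per iteration, normalised concentration units).
#' @name transport_sources
NULL

#' @rdname transport_sources
#' @export
oxygen_source <- function(state) {
  cfg <- state$config
  v <- state$vessels
  if (!nrow(v)) return(array(0, dim(state$phen)))
  p_i <- state$fields$pressure[cbind(v$x, v$y, v$z)]
  per_seg <- state$scales$src_n * radius_weight(v$radius, cfg) *
    pressure_weight(p_i, cfg)
  vessel_scatter(state, per_seg) * pmax(1 - state$fields$oxygen, 0)
}

#' @rdname transport_sources
#' @export
oxygen_sink <- function(state) {
  live <- state$phen == 1L | state$phen == 2L
  (state$scales$snk_n * state$activity * live + state$scales$snk_n_bg) *
    state$fields$oxygen
}

#' @rdname transport_sources
#' @export
co2_source <- function(state) {
  live <- state$phen == 1L | state$phen == 2L
  state$scales$src_w * state$activity * live
}

#' @rdname transport_sources
#' @export
co2_sink <- function(state) {
  cfg <- state$config
  v <- state$vessels
  if (!nrow(v)) return(array(0, dim(state$phen)))
  p_i <- state$fields$pressure[cbind(v$x, v$y, v$z)]
  per_seg <- state$scales$snk_w * radius_weight(v$radius, cfg) *
    pressure_weight(p_i, cfg)
  vessel_scatter(state, per_seg) * state$fields$co2
}

#' @rdname transport_sources
#' @export
taf_source <- function(state) {
  live <- state$phen == 1L | state$phen == 2L
  hypoxia <- pmax(0, 1 - state$fields$oxygen / state$config$taf_n_threshold)
  headroom <- pmax(0, 1 - state$fields$taf / state$config$taf_saturation)
  state$scales$src_c * live * hypoxia * headroom
}

#' @rdname transport_sources
#' @export
taf_removal <- function(state) {
  cfg <- state$config
  if (state$scales$snk_c == 0) return(array(0, dim(state$phen)))
  damp <- cfg$p_v / (cfg$p_v + pmax(state$fields$pressure, 0))
  state$scales$snk_c * damp * state$fields$taf
}

# advance all four species on a state (one iteration)
transport_step <- function(state) {
  cfg <- state$config
  sc <- state$scales
  f <- state$fields
  vel <- state$velocity
  adv <- function(field, D, src, snk, bc, tag) {
    if (!is.null(bc) && is.na(bc)) bc <- NULL   # NA = zero-flux boundary
    out <- advance_scalar(f[[field]], D, 1, velocity = vel,
                          source = src, sink = snk, bc = bc)
    state$diagnostics$clipped_mass[tag] <<-
      state$diagnostics$clipped_mass[tag] + attr(out, "clipped")
    attr(out, "clipped") <- NULL
    out
  }
  f$oxygen <- adv("oxygen", sc$Dn, oxygen_source(state), oxygen_sink(state),
                  cfg$oxygen_bc, "oxygen")
  f$co2 <- adv("co2", sc$Dw, co2_source(state), co2_sink(state),
               cfg$co2_bc, "co2")
  f$taf <- adv("taf", sc$Dc, taf_source(state), taf_removal(state),
               cfg$taf_bc, "taf")
  day <- state$step / cfg$steps_per_day
  d_plasma <- dosing_schedule(cfg, day) / cfg$d0
  f$drug <- adv("drug", sc$Dd, drug_source(state, d_plasma),
                drug_sink(state), cfg$drug_bc, "drug")
  state$fields <- f
  state
}
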