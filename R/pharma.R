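# Drug delivery and pharmacodynamics: Starling transvascular fluid flux,
# Peclet-number partitioning of convective vs diffusive wall transport
# (Patlak form), interstitial transport, cellular uptake and decay, and the
# dosing schedule.

#' Transvascular fluid flux (Starling)
#'
#' Volumetric fluid flow out of the vasculature per unit tissue volume:
#' `J_v = L_p * (S/V) * (p_v - p_i - sigma_avg * (pi_v - pi_e))`.
#' The sign is preserved: negative values mean reabsorption. The surface
#' area per unit volume `S/V` of a segment occupying one voxel is the
#' cylinder lateral surface over the voxel volume, `2 pi R / spacing^2`.
#'
#' @param p_i local interstitial pressure, mmHg.
#' @param radius vessel radius, m.
#' @param cfg a [sim_config()].
#' @return list with `J_v` (1/s) and `S_V` (1/m).
#' @export
transvascular_fluid_flux <- function(p_i, radius, cfg = sim_config()) {
  S_V <- 2 * pi * radius / cfg$spacing_m^2
  J_v <- cfg$L_p * S_V * (cfg$p_v - p_i - cfg$sigma_avg * (cfg$pi_v - cfg$pi_e))
  list(J_v = J_v, S_V = S_V)
}

#' Transcapillary Peclet number
#'
#' Ratio of convective to diffusive drug transport across the capillary
#' wall: `Pe = J_v * (1 - sigma_f) / (P_perm * S/V)`; its sign follows the
#' fluid flux.
#'
#' @param J_v transvascular fluid flux, 1/s.
#' @param S_V surface area per unit volume, 1/m.
#' @param cfg a [sim_config()].
#' @return Peclet numbers.
#' @export
peclet_number <- function(J_v, S_V, cfg = sim_config()) {
  if (cfg$P_perm <= 0) stop("vascular permeability must be > 0", call. = FALSE)
  if (any(S_V <= 0)) stop("surface area per unit volume must be > 0", call. = FALSE)
  J_v * (1 - cfg$sigma_f) / (cfg$P_perm * S_V)
}

#' Patlak wall-transport factor
#'
#' `f(Pe) = Pe / (exp(Pe) - 1)`, continuous through `Pe = 0` where its limit
#' is 1 (evaluated by series for tiny `|Pe|`).
#'
#' @param Pe Peclet numbers.
#' @return factors in `(0, Inf)`.
#' @export
patlak_factor <- function(Pe) {
  out <- numeric(length(Pe))
  tiny <- abs(Pe) < 1e-8
  out[tiny] <- 1 - Pe[tiny] / 2 + Pe[tiny]^2 / 12
  big <- !tiny
  out[big] <- Pe[big] / expm1(Pe[big])
  out
}

#' Dosing schedule
#'
#' Plasma drug concentration as a function of simulated day: zero before
#' `drug_start_day`, constant `drug_dose` thereafter (an intravenous-infusion
#' approximation; a time-varying plasma course can be supplied by overriding
#' this function in a custom driver).
#'
#' @param cfg a [sim_config()].
#' @param day simulation day (non-negative).
#' @return plasma concentration, mol/m^3.
#' @export
dosing_schedule <- function(cfg, day) {
  if (any(day < 0)) stop("day must be >= 0", call. = FALSE)
  if (cfg$drug_dose < 0) stop("negative dose", call. = FALSE)
  ifelse(day >= cfg$drug_start_day, cfg$drug_dose, 0)
}

#' Drug source and sink fields
#'
#' `drug_source()` is the transvascular supply at vessel voxels, per step and
#' in normalised concentration units: the convective extravasation
#' `(1 - sigma_f) * J_v * d_plasma` plus the Patlak diffusive exchange
#' `P_perm * (S/V) * (d_plasma - d_local) * f(Pe)`. Negative net exchange
#' (tissue-to-blood washout) is clipped to zero unless `washout_enabled`.
#' `drug_sink()` combines activity-linear cellular uptake at live-cell voxels
#' with first-order natural decay everywhere.
#'
#' @param state a `sim_state`.
#' @param d_plasma normalised plasma drug concentration.
#' @return a 3D rate array (per iteration).
#' @export
drug_source <- function(state, d_plasma) {
  cfg <- state$config
  v <- state$vessels
  if (!nrow(v)) return(array(0, dim(state$phen)))
  if (d_plasma <= 0 && !cfg$washout_enabled) return(array(0, dim(state$phen)))
  idx <- cbind(v$x, v$y, v$z)
  p_i <- state$fields$pressure[idx]
  d_loc <- state$fields$drug[idx]
  fl <- transvascular_fluid_flux(p_i, v$radius, cfg)
  Pe <- peclet_number(fl$J_v, pmax(fl$S_V, .Machine$double.xmin), cfg)
  phi <- (1 - cfg$sigma_f) * fl$J_v * d_plasma +
    cfg$P_perm * fl$S_V * (d_plasma - d_loc) * patlak_factor(Pe)
  if (!cfg$washout_enabled) phi <- pmax(phi, 0)
  vessel_scatter(state, phi * state$scales$dt)
}

#' @rdname drug_source
#' @export
drug_sink <- function(state) {
  live <- state$phen == 1L | state$phen == 2L
  uptake <- state$scales$snk_d0 * state$activity * live
  (uptake + state$scales$snk_d2) * state$fields$drug
}
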