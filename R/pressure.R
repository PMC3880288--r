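# Growth pressurization model: interstitial pressure as the sum of
# Gaussian-like kernels centred on tumor cells (cell-induced tumor pressure,
# CTP) and on endothelial segments (vasculature-induced tumor pressure, VTP),
# with density-dependent amplitude and width, plus Darcy interstitial flow.

# amplitude and width maps; theta is the local occupancy fraction at the
# *evaluation* point X0 (not at each source), see the methods vignette.
rho_map <- function(theta, rho_max) rho_max * theta
lambda_map <- function(theta, cfg) {
  cfg$lambda_min + (cfg$lambda_max - cfg$lambda_min) * theta
}

# The occupancy fraction takes (2K+1)^3 + 1 discrete levels and squared
# kernel distances are bounded by 3K^2, so the weight
# rho(theta) * exp(-d^2 / (2 lambda(theta)^2)) is precomputed as a
# (level x distance) table once per field evaluation.
kernel_weight_table <- function(cfg, rho_max) {
  K <- cfg$K_neighborhood
  ncube <- (2 * K + 1)^3
  theta <- (0:ncube) / ncube
  rho <- rho_map(theta, rho_max)
  lam <- lambda_map(theta, cfg)
  d2 <- 0:(3 * K^2)
  outer(seq_along(theta), seq_along(d2), function(i, j)
    rho[i] * exp(-d2[j] / (2 * lam[i]^2)))
}

kernel_field <- function(occ, pos, cfg, rho_max) {
  dims <- dim(occ)
  counts <- box_sum_cpp(as.numeric(occ), as.integer(dims), cfg$K_neighborhood)
  level <- as.integer(round(counts))
  W <- kernel_weight_table(cfg, rho_max)
  kernel_scatter_tab_cpp(pos, level, W, cfg$K_neighborhood, as.integer(dims))
}

#' Cell-induced tumor pressure field
#'
#' At every lattice point X0,
#' `CTP(X0) = sum_i rho(theta(X0)) * exp(-d(X_i, X0)^2 / (2 lambda(theta(X0))^2))`
#' over the tumor cells X_i within the K-cube of X0, where `theta` is the
#' local tumor-cell occupancy fraction, `rho(theta) = rho_max * theta` and
#' `lambda(theta)` interpolates linearly between the configured kernel
#' widths. `rho_max` is calibrated at initialisation so a fully dense core
#' reaches the configured tumor pressure.
#'
#' @param state a `sim_state`.
#' @return a 3D array, mmHg.
#' @export
ctp_field <- function(state) {
  cfg <- state$config
  dims <- dim(state$phen)
  pos <- cell_positions(state)
  if (!nrow(pos)) return(array(0, dims))
  kernel_field(state$phen > 0L, pos, cfg, state$rho_max_t)
}

#' Vasculature-induced tumor pressure field
#'
#' Same kernel structure as [ctp_field()], summing over endothelial-segment
#' positions with the vascular amplitude (a configured fraction of the tumor
#' one) and the endothelial occupancy fraction.
#'
#' @param state a `sim_state`.
#' @return a 3D array, mmHg.
#' @export
vtp_field <- function(state) {
  cfg <- state$config
  dims <- dim(state$phen)
  if (!nrow(state$vessels)) return(array(0, dims))
  pos <- cbind(state$vessels$x, state$vessels$y, state$vessels$z)
  storage.mode(pos) <- "integer"
  kernel_field(state$vess_occ, pos, cfg, state$rho_max_v)
}

#' Combined interstitial pressure
#'
#' Pointwise sum of the cell- and vasculature-induced components; in the
#' avascular state the combined pressure equals the cell-induced one.
#'
#' @param ctp,vtp 3D pressure arrays on the same lattice.
#' @return a 3D array, mmHg.
#' @export
combined_pressure <- function(ctp, vtp) {
  if (!identical(dim(ctp), dim(vtp)))
    stop("pressure fields live on different grids", call. = FALSE)
  ctp + vtp
}

#' Darcy interstitial fluid velocity
#'
#' `u = -k grad(p)` with central differences in the interior and one-sided
#' differences at the domain faces. A uniform pressure field gives zero
#' velocity everywhere.
#'
#' @param pressure 3D pressure array (mmHg).
#' @param k_hydraulic hydraulic conductivity in cm^2/(mmHg s).
#' @param spacing lattice spacing in m.
#' @return list of 3D arrays `ux`, `uy`, `uz` in m/s.
#' @export
darcy_velocity <- function(pressure, k_hydraulic, spacing) {
  if (any(!is.finite(pressure))) stop("pressure field is not finite", call. = FALSE)
  k <- k_hydraulic * 1e-4  # cm^2 -> m^2
  p <- pressure
  n <- dim(p)
  gx <- array(0, n); gy <- array(0, n); gz <- array(0, n)
  h2 <- 2 * spacing
  gx[2:(n[1] - 1), , ] <- (p[3:n[1], , ] - p[1:(n[1] - 2), , ]) / h2
  gx[1, , ] <- (p[2, , ] - p[1, , ]) / spacing
  gx[n[1], , ] <- (p[n[1], , ] - p[n[1] - 1, , ]) / spacing
  gy[, 2:(n[2] - 1), ] <- (p[, 3:n[2], ] - p[, 1:(n[2] - 2), ]) / h2
  gy[, 1, ] <- (p[, 2, ] - p[, 1, ]) / spacing
  gy[, n[2], ] <- (p[, n[2], ] - p[, n[2] - 1, ]) / spacing
  gz[, , 2:(n[3] - 1)] <- (p[, , 3:n[3]] - p[, , 1:(n[3] - 2)]) / h2
  gz[, , 1] <- (p[, , 2] - p[, , 1]) / spacing
  gz[, , n[3]] <- (p[, , n[3]] - p[, , n[3] - 1]) / spacing
  list(ux = -k * gx, uy = -k * gy, uz = -k * gz)
}

# Recompute pressure and Darcy velocity on a state (honouring k_press thinning
# is the driver's job; this always recomputes).
refresh_pressure <- function(state) {
  cfg <- state$config
  ctp <- ctp_field(state)
  vtp <- vtp_field(state)
  state$fields$pressure <- combined_pressure(ctp, vtp)
  u <- darcy_velocity(state$fields$pressure, cfg$k_hydraulic, cfg$spacing_m)
  # normalised to grid steps per iteration for the transport stepper
  f <- state$scales$dt / state$scales$h
  state$velocity <- list(ux = u$ux * f, uy = u$uy * f, uz = u$uz * f)
  state
}
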