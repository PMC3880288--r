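#' Simulation configuration
#'
#' Builds the full parameter set for a coupled tumor-growth / angiogenesis /
#' chemotherapy run. Defaults reproduce the reference scenario: a 1 cm cube
#' discretised as a 200^3 lattice, 60 simulated days at 33 iterations per day,
#' five seed cells at the domain centre, and the published physical constants
#' (diffusivities, supply/consumption rates, Starling-flux parameters,
#' branching and vessel-maturation constants).
#'
#' Concentrations are normalised internally by the standard concentrations
#' `n0`, `w0`, `c0`, `d0`; pressures are carried in mmHg; diffusivities are in
#' m^2/s, supply/secretion rates in mol/(m^3 s) and consumption/decay rates in
#' 1/s (an ml/(cm^3 s) rate is a volume fraction per second).
#'
#' @param ... named overrides of any default listed below.
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(grid_n = 16, total_days = 1)
#' cfg$spacing_m
#' @export
sim_config <- function(...) {
  defaults <- list(
    # grid / time
    grid_n         = 200L,     # lattice points per axis
    domain_edge    = 0.01,     # m
    steps_per_day  = 33L,
    total_days     = 60,
    rng_seed       = 1L,
    K_neighborhood = 3L,       # half-width of the pressure / density cube

    # transport (Table-1 physical constants)
    D_n       = 8e-14,   # oxygen diffusion, m^2/s
    rho_n0    = 6.8e-4,  # oxygen supply rate, mol/(m^3 s)
    lambda_n0 = 3e-5,    # oxygen consumption rate, 1/s
    background_oxygen_consumption = 0, # host-tissue respiration rate, 1/s
    D_w       = 4e-14,   # CO2 diffusion
    rho_w0    = 1e-5,    # CO2 secretion rate
    lambda_w0 = 2.5e-5,  # CO2 consumption rate (by vessels)
    D_c       = 1.2e-13, # TAF diffusion
    rho_c0    = 2e-9,    # TAF secretion rate, mol/(m^3 s)
    lambda_c0 = 0,       # TAF consumption rate (published default: off)
    taf_molar_mass = 45, # kg/mol; converts the mass standard c0 to molar
    taf_n_threshold = 0.5, # oxygen level below which cells secrete TAF
    taf_saturation = 3,  # secretion shuts off as TAF saturates (normalised)
    D_d       = 1.5e-14, # drug diffusion
    lambda_d0 = 2.5e-7,  # drug consumption rate by cells
    lambda_d2 = 1e-8,    # drug natural decay rate

    # angiogenesis
    k_BH      = 0.3e-3,  # branching-hotpoint constant
    alpha_BH  = 1.3,     # branching-hotpoint exponent
    k_AR1     = 1.0,     # vessel radius constant (amplitude)
    k_AR2     = 500.0,   # vessel radius constant (half-saturation age, steps)
    R_max     = 1e-5,    # saturating vessel radius scale, m
    g1        = 1.0,     # tip proliferation: baseline factor
    g2        = 1.0,     # tip proliferation: pressure gain
    tip_rate_normal = 0.1,       # grid steps advanced per iteration, normal tissue
    tip_rate_tumor  = 1 / 3,     # grid steps per iteration inside tumor tissue
    stall_steps     = 10L,       # stalled iterations before a tip ages backwards
    taf_sprout_threshold = 0.2,  # TAF level at a vessel that selects a tip cell
                                 # when the network has no active tip
    angiogenesis_enabled = TRUE,

    # cell dynamics
    k_active     = 1.0,   # CVE addition rate, per step (active cells)
    k_quiescent  = 0.1,   # CVE housekeeping drain, per step (quiescent cells)
    activity_Kn  = 0.25,  # oxygen half-saturation of activity (normalised)
    activity_n_hill = 3,  # Hill exponent of the oxygen dependence
    activity_Kw  = 1.8,   # CO2 inhibition constant of activity (normalised)
    activity_w_hill = 4,  # Hill exponent of the CO2 inhibition
    activity_threshold = 0.5,
    hill_coef    = 2,     # CVE consumption Hill coefficient
    hill_halfmax = 0.35,  # CVE consumption Hill half-max (activity units)
    hill_scale   = 0.716, # hill(1) = hill_scale * k_active; net CVE gain
                          # positive only above A ~ 0.6: division needs
                          # genuinely well-supplied cells
    cve_division_threshold = NULL,  # NULL = calibrate to a 24 h cycle
    k_drug       = NULL,            # NULL = calibrate to the dose-response ladder
    division_softness = 1,          # mmHg; softmax scale of daughter placement
                                    # (0 = strict steepest-drop placement)

    # pressure (growth pressurization)
    k_hydraulic = 4.5e-15, # interstitial hydraulic conductivity, cm^2/(mmHg s)
    p_v         = 30,      # capillary/vascular pressure, mmHg
    p_tumor     = 60,      # calibrated dense-core pressure, mmHg
    rho_max_t   = NULL,    # NULL = calibrate so a dense core reaches p_tumor
    rho_max_v_frac = 0.5,  # vascular kernel amplitude as fraction of tumor one
    lambda_min  = 1.0,     # kernel width at theta = 0, index units
    lambda_max  = 3.0,     # kernel width at theta = 1, index units
    k_press     = 1L,      # recompute pressure every k_press steps

    # drug / Starling exchange
    L_p       = 2.8e-9,  # microvascular hydraulic conductivity, m/(mmHg s)
    P_perm    = 1.49e-9, # vascular permeability, m/s
    sigma_avg = 0.82,    # average osmotic reflection coefficient
    sigma_f   = 0.1,     # filtration reflection coefficient
    pi_v      = 0.3546,  # plasma osmotic pressure, mmHg
    pi_e      = 0.2667,  # interstitial osmotic pressure, mmHg
    drug_start_day = 40,
    drug_dose      = 0,   # plasma drug concentration while dosing, mol/m^3
    washout_enabled = FALSE,

    # standard concentrations used for normalisation
    n0 = 8.4,     # mol/m^3
    w0 = 10.5,    # mol/m^3
    c0 = 4.3e-4,  # kg/m^3
    d0 = 2.13,    # mol/m^3
    d_i = 1.0,    # reference interstitial drug concentration, mol/m^3

    # initial / boundary values (normalised)
    oxygen_init = 1, co2_init = 1, taf_init = 1, drug_init = 0,
    oxygen_bc   = 1, co2_bc   = 1, taf_bc   = 1, drug_bc   = 0,

    # parent vasculature fixture
    parent_vessel      = "none",  # "none", "single_axis" or "face_grid"
    parent_offset_frac = 0.24,    # lateral offset of single_axis from centre
    parent_n_vessels   = 5L,      # comb size for face_grid
    parent_age         = 500     # initial age of pre-existing segments, steps
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("all configuration overrides must be named", call. = FALSE)
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    defaults[names(overrides)] <- overrides
  }
  cfg <- defaults
  cfg$grid_n <- as.integer(cfg$grid_n)
  cfg$steps_per_day <- as.integer(cfg$steps_per_day)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  cfg$K_neighborhood <- as.integer(cfg$K_neighborhood)
  cfg$spacing_m <- cfg$domain_edge / cfg$grid_n
  cfg$dt_s <- 86400 / cfg$steps_per_day
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  err <- function(msg) stop("invalid configuration: ", msg, call. = FALSE)
  if (cfg$grid_n < 8L) err("grid_n must be >= 8")
  if (cfg$steps_per_day < 1L) err("steps_per_day must be >= 1")
  if (cfg$total_days < 0) err("total_days must be >= 0")
  if (cfg$domain_edge <= 0) err("domain_edge must be > 0")
  if (cfg$K_neighborhood < 1L) err("K_neighborhood must be >= 1")
  for (nm in c("D_n", "D_w", "D_c", "D_d"))
    if (cfg[[nm]] < 0) err(paste(nm, "must be >= 0"))
  for (nm in c("n0", "w0", "c0", "d0"))
    if (cfg[[nm]] <= 0) err(paste(nm, "must be > 0"))
  for (nm in c("sigma_avg", "sigma_f"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) err(paste(nm, "must lie in [0, 1]"))
  for (nm in c("k_BH", "alpha_BH", "k_AR1", "k_AR2", "k_hydraulic", "R_max"))
    if (cfg[[nm]] <= 0) err(paste(nm, "must be > 0"))
  if (cfg$drug_dose < 0) err("drug_dose must be >= 0")
  if (cfg$lambda_min <= 0 || cfg$lambda_max <= 0) err("kernel widths must be > 0")
  if (cfg$activity_threshold <= 0 || cfg$activity_threshold >= 1)
    err("activity_threshold must lie in (0, 1)")
  if (!cfg$parent_vessel %in% c("none", "single_axis", "face_grid"))
    err("parent_vessel must be one of none, single_axis, face_grid")
  invisible(cfg)
}

#' Desk-scale reference configuration
#'
#' A reduced scenario for development, tests and the bundled analyses: a 50^3
#' lattice over the same 1 cm domain, 20 simulated days, a single pre-existing
#' vessel offset from the tumor seed, and two resolution adjustments described
#' in the methods vignette: diffusivities are scaled by `(h/h_ref)^2` so the
#' per-voxel diffusion number matches the fine reference lattice
#' (`h_ref = 5e-5` m), and the interstitial hydraulic conductivity is raised
#' so the pressure-driven convection it models is resolvable on the coarse
#' grid. The dosing window is rescaled to the shortened horizon (start day 13
#' of 20, mirroring day 40 of 60).
#'
#' @param grid_n lattice points per axis (default 50).
#' @param total_days simulated days (default 20).
#' @param angiogenesis logical; `FALSE` gives the avascular comparator
#'   scenario (endothelial dynamics off and no parent vasculature).
#' @param ... further `sim_config()` overrides applied on top.
#' @return a `sim_config`.
#' @export
desk_config <- function(grid_n = 50L, total_days = 20, angiogenesis = TRUE, ...) {
  h_ref <- 5e-5
  h <- 0.01 / grid_n
  dscale <- (h / h_ref)^2
  # time compression: the slow arms (waste accumulation, TAF build-up,
  # vessel maturation) are sped up threefold, mapping the 60-day reference
  # course onto the 20-day desk horizon; oxygen metabolism and the cell
  # cycle stay on the calendar. The factor is fixed so that runs longer
  # than 20 days continue the same compressed scenario.
  tscale <- 3
  base <- list(
    grid_n = as.integer(grid_n),
    total_days = total_days,
    D_n = 8e-14 * dscale, D_w = 4e-14 * dscale,
    D_c = 1.2e-13 * dscale, D_d = 1.5e-14 * dscale,
    rho_w0 = 1e-5 * tscale, lambda_w0 = 2.5e-5 * tscale,
    rho_c0 = 2e-9 * tscale, D_c = 1.2e-13 * dscale * tscale,
    taf_saturation = 5,
    k_AR2 = 500 / tscale,   # vessel maturation keeps pace with the horizon
    # zero-flux metabolite boundaries: the reference domain's faces are many
    # diffusion lengths from the tumor, so the desk box behaves as a finite
    # tissue reservoir supplied only by vasculature; the host tissue itself
    # respires, so the unvascularised reservoir drains over ~2 weeks
    oxygen_bc = NA, co2_bc = NA,
    background_oxygen_consumption = 7e-7,
    taf_init = 0, taf_bc = 0,  # angiogenic factor only where tumor secretes it
    drug_start_day = round(40 * total_days / 60 * 2) / 2,  # day 40 of 60, rescaled
    parent_vessel = if (angiogenesis) "single_axis" else "none",
    angiogenesis_enabled = angiogenesis
  )
  extra <- list(...)
  base[names(extra)] <- extra
  do.call(sim_config, base)
}

#' Read / write a configuration file
#'
#' Configurations are stored as flat YAML key-value maps mirroring
#' [sim_config()] arguments. Unknown keys are an error, so a stale file fails
#' loudly rather than silently running defaults.
#'
#' @param path file path.
#' @param cfg a `sim_config`.
#' @return `read_config()` returns a `sim_config`; `write_config()` its path,
#'   invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("configuration file must be a YAML mapping", call. = FALSE)
  raw$spacing_m <- NULL
  raw$dt_s <- NULL
  if (!is.null(raw$parent_vessel)) raw$parent_vessel <- as.character(raw$parent_vessel)
  do.call(sim_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- unclass(cfg)
  out$spacing_m <- NULL
  out$dt_s <- NULL
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$grid_n, "^3 lattice, ", x$total_days, " days @ ",
      x$steps_per_day, " steps/day, seed ", x$rng_seed, "\n", sep = "")
  cat("  spacing ", signif(x$spacing_m, 3), " m; dt ", signif(x$dt_s, 4),
      " s; angiogenesis ", x$angiogenesis_enabled,
      "; parent vessels: ", x$parent_vessel, "\n", sep = "")
  cat("  drug: dose ", x$drug_dose, " mol/m^3 from day ", x$drug_start_day,
      "\n", sep = "")
  invisible(x)
}

# Per-step normalised rates and scales derived from a config. Concentrations
# are measured in units of the standard concentrations, lengths in lattice
# spacings and time in iterations; the derivation is a single documented pass
# (see the methods vignette).
derive_scales <- function(cfg) {
  h <- cfg$spacing_m
  dt <- cfg$dt_s
  list(
    h = h, dt = dt,
    # diffusion numbers, per step on the unit lattice
    Dn = cfg$D_n * dt / h^2,
    Dw = cfg$D_w * dt / h^2,
    Dc = cfg$D_c * dt / h^2,
    Dd = cfg$D_d * dt / h^2,
    # sources: supply/secretion rate over standard concentration, per step
    src_n = cfg$rho_n0 / cfg$n0 * dt,
    src_w = cfg$rho_w0 / cfg$w0 * dt,
    # TAF standard c0 is a mass concentration; its molar equivalent
    # c0 / taf_molar_mass normalises the molar secretion rate
    src_c = cfg$rho_c0 / (cfg$c0 / cfg$taf_molar_mass) * dt,
    # sinks: first-order rates per step
    snk_n = cfg$lambda_n0 * dt,
    snk_n_bg = cfg$background_oxygen_consumption * dt,
    snk_w = cfg$lambda_w0 * dt,
    snk_c = cfg$lambda_c0 * dt,
    snk_d0 = cfg$lambda_d0 * dt,
    snk_d2 = cfg$lambda_d2 * dt,
    # Darcy factor: (grid steps / iteration) per (mmHg / grid step)
    k_darcy = (cfg$k_hydraulic * 1e-4) * dt / h^2
  )
}

# Calibrated tumor-kernel amplitude: a fully dense core (theta = 1) reaches
# p_tumor at its centre.
calibrate_rho_max <- function(cfg) {
  if (!is.null(cfg$rho_max_t)) return(cfg$rho_max_t)
  K <- cfg$K_neighborhood
  d <- seq(-K, K)
  d2 <- outer(outer(d^2, d^2, `+`), d^2, `+`)
  s_full <- sum(exp(-d2 / (2 * cfg$lambda_max^2)))
  cfg$p_tumor / s_full
}

# Division threshold giving a 24 h birth-to-division interval under abundant
# oxygen: daughters start at half threshold and regain the other half in
# steps_per_day iterations at the pinned net accumulation rate.
calibrate_division_threshold <- function(cfg) {
  if (!is.null(cfg$cve_division_threshold)) return(cfg$cve_division_threshold)
  a_star <- cell_activity(1, 1, cfg)
  net <- cfg$k_active * a_star - hill_consumption(a_star, cfg)
  if (net <= 0)
    stop("activity parameters give no net CVE gain at n = w = 1; ",
         "cannot calibrate the division threshold", call. = FALSE)
  2 * cfg$steps_per_day * net
}

# Drug-damage coefficient: calibrated so that at the highest reference dose
# (10 mol/m^3, interstitial level taken as half the normalised plasma level)
# an active cell's full CVE reserve is destroyed within ~5 days, while the
# lowest reference dose (0.1) cannot overcome the net CVE gain.
calibrate_k_drug <- function(cfg, threshold) {
  if (!is.null(cfg$k_drug)) return(cfg$k_drug)
  a_star <- cell_activity(1, 1, cfg)
  net <- cfg$k_active * a_star - hill_consumption(a_star, cfg)
  d_ref <- 0.5 * 10 / cfg$d0
  (threshold / (5 * cfg$steps_per_day) + net) / (a_star * d_ref)
}
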