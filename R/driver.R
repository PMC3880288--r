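# Orchestration: the per-iteration operator splitting, full runs with
# time-series recording, and checkpoint/manifest plumbing.

record_row <- function(state) {
  cnt <- cell_counts(state)
  f <- state$fields
  data.frame(
    step = state$step,
    day = state$step / state$config$steps_per_day,
    active = cnt[["active"]], quiescent = cnt[["quiescent"]],
    necrotic = cnt[["necrotic"]], viable = cnt[["viable"]],
    total = cnt[["total"]],
    vessel_segments = nrow(state$vessels),
    tumor_volume = cnt[["total"]],
    necrotic_volume = cnt[["necrotic"]],
    mean_oxygen = mean(f$oxygen), max_oxygen = max(f$oxygen),
    mean_co2 = mean(f$co2), max_co2 = max(f$co2),
    mean_taf = mean(f$taf), max_taf = max(f$taf),
    mean_drug = mean(f$drug), max_drug = max(f$drug),
    mean_pressure = mean(f$pressure), max_pressure = max(f$pressure))
}

#' Advance the simulation by one iteration
#'
#' Fixed operator-splitting order: (1) interstitial pressure (cell- plus
#' vasculature-induced kernels, recomputed every `k_press` steps) and the
#' Darcy velocity; (2) explicit transport of oxygen, carbon dioxide, TAF and
#' drug with stability sub-stepping; (3) cell activity, vital energy,
#' phenotype transitions and pressure-directed divisions; (4) angiogenesis
#' (tip advance, hotpoint branching, maturation, necrotic exclusion,
#' pruning); (5) clock advance. Cells see end-of-transport field values
#' within the step.
#'
#' @param state a `sim_state`.
#' @param pin_fields debugging hook: skip transport and hold all continuum
#'   fields at their current values (used to pin abundant-oxygen conditions
#'   in calibration checks).
#' @return the advanced state.
#' @export
step_simulation <- function(state, pin_fields = FALSE) {
  step_err <- function(e)
    stop("step ", state$step + 1L, ": ", conditionMessage(e), call. = FALSE)
  tryCatch({
    if (state$step %% state$config$k_press == 0L)
      state <- refresh_pressure(state)
    if (!pin_fields) state <- transport_step(state)
    state <- cell_step(state)
    state <- angio_step(state)
    state$step <- state$step + 1L
    state
  }, error = step_err)
}

#' Run a full simulation
#'
#' Initialises a state from `cfg` (or resumes a checkpointed one), advances
#' it `total_days * steps_per_day` iterations and records the per-step time
#' series (phenotype counts, vessel segment count, field means/maxima,
#' tumor and necrotic-core volumes). Identical config and seed give
#' bitwise-identical results.
#'
#' @param cfg a [sim_config()].
#' @param resume_state optional `sim_state` to continue instead of a fresh
#'   initialisation (its accumulated record is extended).
#' @param snapshot_days days at which to keep full field/lattice snapshots.
#' @param pin_fields see [step_simulation()].
#' @param progress print a line per simulated day.
#' @return a `sim_result`: list with `record` (data frame), `state` (final),
#'   `config`, and `snapshots`.
#' @export
run_simulation <- function(cfg, resume_state = NULL, snapshot_days = numeric(),
                           pin_fields = FALSE, progress = FALSE) {
  state <- if (is.null(resume_state)) init_state(cfg) else resume_state
  cfg <- state$config
  total_steps <- as.integer(round(cfg$total_days * cfg$steps_per_day))
  rows <- vector("list", total_steps + 1L)
  rows[[1L]] <- record_row(state)
  snapshots <- list()
  snap_steps <- as.integer(round(snapshot_days * cfg$steps_per_day))
  start <- state$step
  while (state$step < start + total_steps) {
    state <- step_simulation(state, pin_fields = pin_fields)
    rows[[state$step - start + 1L]] <- record_row(state)
    if (state$step %in% snap_steps)
      snapshots[[sprintf("day_%g", state$step / cfg$steps_per_day)]] <-
        list(fields = state$fields, phen = state$phen, vessels = state$vessels)
    if (progress && state$step %% cfg$steps_per_day == 0L) {
      cnt <- cell_counts(state)
      message("day ", state$step / cfg$steps_per_day, ": ", cnt[["total"]],
              " cells (", cnt[["viable"]], " viable), ",
              nrow(state$vessels), " vessel segments")
    }
  }
  structure(list(record = do.call(rbind, rows), state = state, config = cfg,
                 snapshots = snapshots),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  last <- x$record[nrow(x$record), ]
  cat("<sim_result> ", nrow(x$record) - 1L, " steps (",
      signif(last$day, 4), " days)\n", sep = "")
  cat("  final: ", last$total, " cells (", last$viable, " viable, ",
      last$necrotic, " necrotic), ", last$vessel_segments,
      " vessel segments\n", sep = "")
  invisible(x)
}

#' Classify growth stages from a cell-count time series
#'
#' Sliding-window classification of the total-cell-count curve into the four
#' canonical stages: exponential growth (T1), linear expansion (T2), stasis
#' (T3) and secondary (post-angiogenic) growth (T4). Each window of
#' `window_days` is labelled stasis when its absolute growth is within
#' `stasis_tol` of the current count per day, exponential when it grows
#' relatively faster than `r_exp` *and* its absolute growth accelerates by
#' at least `accel` over the previous window, and linear when the absolute
#' rate is positive and roughly constant (the defining property of the
#' expansion stage). T4 is renewed growth after a stasis phase.
#'
#' @param record a run record (needs `day` and `total` columns) spanning at
#'   least 3 days.
#' @param r_exp minimum relative growth per window for the exponential label.
#' @param stasis_tol relative absolute growth per day labelling stasis.
#' @param accel window-over-window absolute-growth ratio separating
#'   accelerating (exponential) from constant-rate (linear) growth.
#' @param window_days window length in days.
#' @return data frame with columns `stage` ("T1".."T4") and `start_day`
#'   (`NA` for absent stages).
#' @export
detect_growth_stages <- function(record, r_exp = 0.05, stasis_tol = 0.01,
                                 accel = 1.4, window_days = 2) {
  days <- floor(max(record$day))
  if (days < 3) stop("record must span at least 3 days", call. = FALSE)
  # daily totals at integer days
  N <- vapply(0:days, function(d)
    record$total[which.min(abs(record$day - d))], numeric(1))
  w <- window_days
  starts <- 0:(days - w)
  growth <- vapply(starts, function(d) N[d + w + 1L] - N[d + 1L], numeric(1))
  labels <- vapply(seq_along(starts), function(i) {
    d <- starts[i]
    g <- growth[i]
    rel <- g / max(N[d + 1L], 1)
    g_prev <- if (i > 1L) growth[i - 1L] else NA_real_
    if (abs(g) <= stasis_tol * max(N[d + 1L], 1) * w) "stasis"
    else if (g > 0 && rel >= r_exp &&
             (is.na(g_prev) || g >= accel * max(g_prev, 0))) "exp"
    else if (g > 0) "linear"
    else "decline"
  }, character(1))
  first_at <- function(lab, from) {
    hit <- which(labels == lab & starts >= from)
    if (length(hit)) starts[hit[1]] else NA_real_
  }
  t1 <- first_at("exp", 0)
  t2 <- first_at("linear", if (is.na(t1)) 0 else t1)
  t3 <- first_at("stasis", max(0, t1, t2, na.rm = TRUE))
  t4 <- NA_real_
  if (!is.na(t3)) {
    hit <- which(labels %in% c("exp", "linear") & starts > t3)
    if (length(hit)) t4 <- starts[hit[1]]
  }
  data.frame(stage = c("T1", "T2", "T3", "T4"),
             start_day = c(t1, t2, t3, t4))
}

#' Tumor sphericity
#'
#' Discrete surface-to-volume shape index
#' `pi^(1/3) * (6 V)^(2/3) / A`, with `V` the occupied-voxel count and `A`
#' the number of exposed voxel faces. Rounded tumors score higher, dendritic
#' ones lower; the digitised surface overestimates the continuum area, so
#' even a perfect discrete ball stays below 1.
#'
#' @param state a `sim_state`, or a logical/integer occupancy array.
#' @return a value in `(0, 1]`.
#' @export
sphericity_metric <- function(state) {
  occ <- if (inherits(state, "sim_state")) state$phen > 0L else state > 0L
  V <- sum(occ)
  if (V == 0) stop("empty tumor has no shape", call. = FALSE)
  d <- dim(occ)
  n1 <- d[1]; n2 <- d[2]; n3 <- d[3]
  # interior faces between an occupied voxel and an empty neighbour, plus
  # occupied voxels flush against the domain boundary
  exposed <-
    sum(occ[1:(n1 - 1), , ] & !occ[2:n1, , ]) +
    sum(occ[2:n1, , ] & !occ[1:(n1 - 1), , ]) +
    sum(occ[, 1:(n2 - 1), ] & !occ[, 2:n2, ]) +
    sum(occ[, 2:n2, ] & !occ[, 1:(n2 - 1), ]) +
    sum(occ[, , 1:(n3 - 1)] & !occ[, , 2:n3]) +
    sum(occ[, , 2:n3] & !occ[, , 1:(n3 - 1)]) +
    sum(occ[1, , ]) + sum(occ[n1, , ]) +
    sum(occ[, 1, ]) + sum(occ[, n2, ]) +
    sum(occ[, , 1]) + sum(occ[, , n3])
  pi^(1 / 3) * (6 * V)^(2 / 3) / exposed
}

#' Parameter sensitivity scan
#'
#' Re-runs the simulation with one parameter perturbed at a time and reports
#' the percent change of the end-of-run whole-grid mean of each continuum
#' species (nutrient, waste, TAF, drug) against the unperturbed baseline.
#' All runs share the configured seed.
#'
#' @param cfg a [sim_config()].
#' @param parameters parameter names to vary (default: the seven transport
#'   supply/consumption rates of the published scan).
#' @param perturbations relative perturbations (default
#'   `c(-0.10, -0.01, -0.001, 0.001, 0.01, 0.10)`).
#' @return a data frame with columns `parameter`, `perturbation`, `species`,
#'   `pct_change`.
#' @export
sensitivity_scan <- function(cfg,
    parameters = c("rho_n0", "lambda_n0", "rho_w0", "lambda_w0",
                   "rho_c0", "lambda_d0", "lambda_d2"),
    perturbations = c(-0.10, -0.01, -0.001, 0.001, 0.01, 0.10)) {
  species <- c(nutrient = "mean_oxygen", waste = "mean_co2",
               taf = "mean_taf", drug = "mean_drug")
  final_means <- function(cc) {
    rec <- run_simulation(cc)$record
    vapply(species, function(col) rec[[col]][nrow(rec)], numeric(1))
  }
  base <- final_means(cfg)
  out <- list()
  for (p in parameters) {
    if (is.null(cfg[[p]])) stop("unknown parameter: ", p, call. = FALSE)
    for (eps in perturbations) {
      if (eps == 0) {
        pct <- stats::setNames(numeric(length(species)), names(species))
      } else {
        cc <- cfg
        cc[[p]] <- cfg[[p]] * (1 + eps)
        m <- final_means(cc)
        pct <- ifelse(base == 0, 0, abs(m - base) / abs(base) * 100)
      }
      out[[length(out) + 1L]] <- data.frame(
        parameter = p, perturbation = eps, species = names(species),
        pct_change = as.numeric(pct), row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Dose-response sweep
#'
#' Runs the configured scenario once per plasma dose level (same seed) and
#' reports end-of-run phenotype counts and mean interstitial drug.
#'
#' @param cfg a [sim_config()]; `drug_start_day` applies to every run.
#' @param doses plasma concentrations in mol/m^3.
#' @return data frame: dose, active, quiescent, necrotic, viable, total,
#'   mean_drug.
#' @export
dose_response <- function(cfg, doses = c(0, 0.1, 1, 10)) {
  rows <- lapply(doses, function(d) {
    cc <- cfg
    cc$drug_dose <- d
    rec <- run_simulation(cc)$record
    last <- rec[nrow(rec), ]
    data.frame(dose = d, active = last$active, quiescent = last$quiescent,
               necrotic = last$necrotic, viable = last$viable,
               total = last$total, mean_drug = last$mean_drug)
  })
  do.call(rbind, rows)
}
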