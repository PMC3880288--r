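# Cellular bookkeeping: activity from the local metabolite levels, the cell
# vital energy (CVE) store, phenotype transitions, and pressure-directed
# division on the 26-neighbour shell.

#' Tumor cell activity
#'
#' Activity from local normalised oxygen `n` and carbon dioxide `w`:
#' `A = (n^hn / (n^hn + Kn^hn)) * (Kw^hw / (w^hw + Kw^hw))`, increasing in
#' oxygen, decreasing in waste, zero without oxygen and bounded in `[0, 1]`.
#' With the default constants `A(1, 1) ~ 0.80` sits above the 0.5 activity
#' threshold; both responses are switch-like (Hill exponents 3 and 4), so
#' proliferation collapses once local oxygen falls below roughly half the
#' standard level or accumulated waste exceeds roughly 1.4 times it. The
#' waste arm is what arrests a large avascular tumor — carbon dioxide
#' builds up tumor-wide because only vessels clear it — and its clearance
#' by new vasculature is what reactivates growth.
#'
#' @param n,w normalised oxygen and carbon dioxide (vectors recycle).
#' @param cfg a [sim_config()].
#' @return activities in `[0, 1]`.
#' @export
cell_activity <- function(n, w, cfg = sim_config()) {
  if (any(n < 0) || any(w < 0))
    stop("metabolite concentrations must be non-negative", call. = FALSE)
  hn <- cfg$activity_n_hill
  hw <- cfg$activity_w_hill
  (n^hn / (n^hn + cfg$activity_Kn^hn)) *
    (cfg$activity_Kw^hw / (w^hw + cfg$activity_Kw^hw))
}

# CVE consumption Hill term, scaled so hill(1) = hill_scale * k_active
hill_consumption <- function(A, cfg) {
  h <- cfg$hill_coef
  base <- A^h / (A^h + cfg$hill_halfmax^h)
  base1 <- 1 / (1 + cfg$hill_halfmax^h)
  cfg$hill_scale * cfg$k_active * base / base1
}

#' Cell vital energy update
#'
#' One step of the CVE balance. Active cells (`A > activity_threshold`) add
#' energy at `k_active * A`, pay a Hill-shaped synthesis cost, and lose
#' `k_drug * A * drug` to cytotoxic damage. Quiescent cells pay the
#' housekeeping drain `k_quiescent` plus the same drug damage and add
#' nothing. CVE may become negative, which triggers necrosis in
#' [classify_phenotype()].
#'
#' @param cve current CVE values.
#' @param A cell activities.
#' @param drug local normalised drug concentrations.
#' @param cfg a [sim_config()].
#' @param k_drug drug-damage coefficient (the calibrated value lives on the
#'   state; the default here reruns the calibration).
#' @param dt step length in iterations (default 1).
#' @return updated CVE values.
#' @export
cve_update <- function(cve, A, drug, cfg = sim_config(),
                       k_drug = calibrate_k_drug(cfg, calibrate_division_threshold(cfg)),
                       dt = 1) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  damage <- k_drug * A * drug
  active <- A > cfg$activity_threshold
  gain <- cfg$k_active * A - hill_consumption(A, cfg) - damage
  loss <- -(cfg$k_quiescent + damage)
  cve + dt * ifelse(active, gain, loss)
}

#' Phenotype classification
#'
#' Necrosis is terminal: once a cell's CVE has depleted (`CVE <= 0`) it stays
#' necrotic. Otherwise the activity threshold separates active
#' (`A > threshold`) from quiescent cells, and that transition is reversible.
#'
#' @param phen current phenotype codes (0 empty, 1 active, 2 quiescent,
#'   3 necrotic).
#' @param A activities.
#' @param cve CVE values.
#' @param cfg a [sim_config()].
#' @return updated phenotype codes.
#' @export
classify_phenotype <- function(phen, A, cve, cfg = sim_config()) {
  occupied <- phen > 0L
  necrotic <- phen == 3L | (occupied & cve <= 0)
  out <- phen
  out[occupied & !necrotic] <-
    ifelse(A[occupied & !necrotic] > cfg$activity_threshold, 1L, 2L)
  out[necrotic] <- 3L
  out
}

#' Attempt a cell division
#'
#' Places a daughter cell on the 26-neighbour shell of an active parent whose
#' CVE has reached the division threshold. Among the unoccupied in-bounds
#' neighbours the placement probability is a softmax of the pressure drop
#' (parent pressure minus neighbour pressure) on the `division_softness`
#' scale: where pressure differences dwarf that scale the daughter goes to
#' the steepest drop, where they are comparable to it placement is
#' density-weighted-random, and with `division_softness = 0` the rule is the
#' strict steepest-drop argmax (exact ties broken by a seeded draw). Parent
#' and daughter each keep half the parent's pre-division CVE. With no free
#' neighbour the division is deferred and the parent's CVE capped at the
#' threshold.
#'
#' @param state a `sim_state`.
#' @param point parent position (1-based indices).
#' @return the updated state, with attribute `"divided"` (logical) and, when
#'   a division happened, `"daughter"` (the daughter position).
#' @export
attempt_division <- function(state, point) {
  point <- as.integer(point)
  shape <- rep(state$config$grid_n, 3L)
  nb <- neighborhood(point, shape, "moore26")
  free <- state$phen[nb] == 0L
  if (!any(free)) {
    state$cve[matrix(point, 1)] <- min(state$cve[matrix(point, 1)],
                                       state$cve_threshold)
    attr(state, "divided") <- FALSE
    return(state)
  }
  nb <- nb[free, , drop = FALSE]
  p0 <- state$fields$pressure[matrix(point, 1)]
  drop <- p0 - state$fields$pressure[nb]
  temp <- state$config$division_softness
  if (temp > 0) {
    w <- exp((drop - max(drop)) / temp)
    pick <- sample.int(nrow(nb), 1L, prob = w)
  } else {
    best <- which(drop == max(drop))
    pick <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
  }
  daughter <- nb[pick, , drop = FALSE]
  half <- state$cve[matrix(point, 1)] / 2
  state$cve[matrix(point, 1)] <- half
  state$cve[daughter] <- half
  state$phen[daughter] <- 1L
  state$activity[daughter] <- state$activity[matrix(point, 1)]
  state$cell_age[daughter] <- 0L
  attr(state, "divided") <- TRUE
  attr(state, "daughter") <- as.integer(daughter)
  state
}

# one iteration of the cellular module: activity, CVE, phenotype, divisions
cell_step <- function(state) {
  cfg <- state$config
  occ <- which(state$phen > 0L)
  if (!length(occ)) return(state)
  live <- occ[state$phen[occ] != 3L]
  if (length(live)) {
    A <- cell_activity(pmax(state$fields$oxygen[live], 0),
                       pmax(state$fields$co2[live], 0), cfg)
    state$activity[live] <- A
    state$cve[live] <- cve_update(state$cve[live], A,
                                  state$fields$drug[live], cfg,
                                  k_drug = state$k_drug)
    newphen <- classify_phenotype(state$phen[live], A, state$cve[live], cfg)
    state$phen[live] <- newphen
    state$activity[live[newphen == 3L]] <- 0
    state$cell_age[live] <- state$cell_age[live] + 1L
  }
  # divisions: active cells at or above the threshold, visited in seeded
  # random order so crowding is resolved reproducibly
  cand <- which(state$phen == 1L & state$cve >= state$cve_threshold)
  if (length(cand)) {
    ord <- if (length(cand) > 1L) sample(cand) else cand
    dims <- dim(state$phen)
    for (lin in ord) {
      pt <- arrayInd(lin, dims)[1, ]
      state <- attempt_division(state, pt)
    }
  }
  state
}
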