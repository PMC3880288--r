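# Sprouting angiogenesis: TAF-directed tip migration with pressure-modulated
# advance, hotpoint-sampled branching, maturation and pruning.

#' Endothelial tip proliferation rate factor
#'
#' Pressure dependence of the tip advance rate:
#' `rate = g1 + g2 * max(dp, 0) / p_v`, where `dp = p_v - p_i` is the
#' transmural pressure difference at the tip. The rate floors at the baseline
#' `g1` for adverse gradients and grows linearly with favourable ones.
#'
#' @param delta_p_wall transmural pressure difference `p_v - p_i`, mmHg.
#' @param cfg a [sim_config()].
#' @return a non-negative rate factor.
#' @export
vessel_growth_rate <- function(delta_p_wall, cfg = sim_config()) {
  cfg$g1 + cfg$g2 * pmax(delta_p_wall, 0) / cfg$p_v
}

#' Branching probability from local TAF
#'
#' `p = min(1, k_BH * taf^alpha_BH)`: zero without TAF and monotone
#' increasing in it.
#'
#' @param taf_local normalised TAF concentration (non-negative).
#' @param cfg a [sim_config()].
#' @return probabilities in `[0, 1]`.
#' @export
branching_probability <- function(taf_local, cfg = sim_config()) {
  if (any(taf_local < 0)) stop("TAF concentration must be non-negative",
                               call. = FALSE)
  pmin(1, cfg$k_BH * taf_local^cfg$alpha_BH)
}

# admissible voxel for endothelial growth: in-bounds, not vessel-occupied,
# not a necrotic-cell voxel
admissible_mask <- function(state, nb) {
  state$phen[nb] != 3L & !state$vess_occ[nb]
}

#' One migration attempt for a vessel tip
#'
#' The tip accumulates advance at `tip_rate * (g1 + g2 max(dp,0)/p_v)` grid
#' steps per iteration (`tip_rate_tumor` when any Moore neighbour holds a
#' tumor cell, else `tip_rate_normal`). Once the accumulator reaches one grid
#' step, the next voxel is sampled among the six face neighbours with weights
#' proportional to the positive directional TAF derivative; necrotic and
#' vessel-occupied voxels are excluded. If no direction has a positive
#' derivative the tip samples uniformly among the admissible voxels, and it
#' stalls only when none is admissible.
#'
#' @param state a `sim_state`.
#' @param tip_id id of an active tip segment.
#' @return the updated state; attribute `"moved"` reports whether the tip
#'   advanced.
#' @export
tip_migration_step <- function(state, tip_id) {
  v <- state$vessels
  i <- match(tip_id, v$id)
  if (is.na(i) || !v$tip[i]) stop("not an active tip segment", call. = FALSE)
  cfg <- state$config
  pos <- c(v$x[i], v$y[i], v$z[i])
  shape <- rep(cfg$grid_n, 3L)
  p_i <- state$fields$pressure[matrix(pos, 1)]
  moore <- neighborhood(pos, shape, "moore26")
  in_tumor <- any(state$phen[moore] > 0L)
  base <- if (in_tumor) cfg$tip_rate_tumor else cfg$tip_rate_normal
  v$acc[i] <- v$acc[i] + base * vessel_growth_rate(cfg$p_v - p_i, cfg)
  moved <- FALSE
  if (v$acc[i] >= 1) {
    nb <- neighborhood(pos, shape, "faces6")
    ok <- admissible_mask(state, nb)
    if (any(ok)) {
      nb <- nb[ok, , drop = FALSE]
      taf0 <- state$fields$taf[matrix(pos, 1)]
      w <- pmax(state$fields$taf[nb] - taf0, 0)
      if (sum(w) <= 0) w <- rep(1, nrow(nb))
      pick <- sample.int(nrow(nb), 1L, prob = w)
      newpos <- nb[pick, ]
      nid <- state$next_vessel_id
      state$next_vessel_id <- nid + 1L
      v$tip[i] <- FALSE
      v$stall[i] <- 0L
      acc_carry <- v$acc[i] - 1
      v$acc[i] <- 0
      v <- rbind(v, new_segments(nid, v$id[i], newpos[1], newpos[2], newpos[3],
                                 age = 1, radius = vessel_radius(1, cfg),
                                 tip = TRUE, acc = acc_carry))
      state$vess_occ[matrix(newpos, 1)] <- TRUE
      moved <- TRUE
    } else {
      v$stall[i] <- v$stall[i] + 1L
      v$acc[i] <- 1  # retains readiness to move once space opens
    }
  }
  state$vessels <- v
  attr(state, "moved") <- moved
  state
}

#' Sample branching hotpoints
#'
#' Every non-vessel lattice point face-adjacent to a vessel segment is
#' flagged as a branching hotpoint with probability
#' [branching_probability()] evaluated at its TAF level, one seeded
#' Bernoulli draw per point in lattice order.
#'
#' @param state a `sim_state`.
#' @return an integer matrix of hotpoint positions (possibly 0 rows).
#' @export
sample_branching_hotpoints <- function(state) {
  v <- state$vessels
  if (!nrow(v)) return(matrix(integer(), 0, 3))
  shape <- rep(state$config$grid_n, 3L)
  off <- faces6_offsets()
  cand <- do.call(rbind, lapply(seq_len(6), function(d)
    cbind(v$x + off[d, 1], v$y + off[d, 2], v$z + off[d, 3])))
  keep <- cand[, 1] >= 1 & cand[, 1] <= shape[1] &
          cand[, 2] >= 1 & cand[, 2] <= shape[2] &
          cand[, 3] >= 1 & cand[, 3] <= shape[3]
  cand <- cand[keep, , drop = FALSE]
  lin <- cand[, 1] + shape[1] * ((cand[, 2] - 1) + shape[2] * (cand[, 3] - 1))
  o <- order(lin)
  cand <- cand[o, , drop = FALSE]
  lin <- lin[o]
  dupes <- duplicated(lin)
  cand <- cand[!dupes, , drop = FALSE]
  lin <- lin[!dupes]
  open <- !state$vess_occ[lin] & state$phen[lin] != 3L
  cand <- cand[open, , drop = FALSE]
  if (!nrow(cand)) return(matrix(integer(), 0, 3))
  p <- branching_probability(pmax(state$fields$taf[cand], 0), state$config)
  hit <- stats::runif(nrow(cand)) < p
  storage.mode(cand) <- "integer"
  cand[hit, , drop = FALSE]
}

#' Apply branching at sampled hotpoints
#'
#' For each hotpoint (in lattice order) the face-adjacent vessel segment with
#' the lowest id that has not yet branched this step spawns a new tip into
#' the hotpoint voxel; each segment branches at most once per step.
#'
#' @param state a `sim_state`.
#' @param hotpoints integer matrix of hotpoint positions.
#' @return the updated state.
#' @export
apply_branching <- function(state, hotpoints) {
  if (!nrow(hotpoints)) return(state)
  v <- state$vessels
  shape <- rep(state$config$grid_n, 3L)
  branched <- integer(0)
  vlin <- v$x + shape[1] * ((v$y - 1) + shape[2] * (v$z - 1))
  off <- faces6_offsets()
  for (r in seq_len(nrow(hotpoints))) {
    hp <- hotpoints[r, ]
    if (state$vess_occ[matrix(hp, 1)] || state$phen[matrix(hp, 1)] == 3L) next
    nb <- sweep(off, 2L, hp, `+`)
    keep <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
            nb[, 2] >= 1 & nb[, 2] <= shape[2] &
            nb[, 3] >= 1 & nb[, 3] <= shape[3]
    nb <- nb[keep, , drop = FALSE]
    nlin <- nb[, 1] + shape[1] * ((nb[, 2] - 1) + shape[2] * (nb[, 3] - 1))
    src <- which(vlin %in% nlin & !(v$id %in% branched))
    if (!length(src)) next
    src <- src[which.min(v$id[src])]
    nid <- state$next_vessel_id
    state$next_vessel_id <- nid + 1L
    seg <- new_segments(nid, v$id[src], hp[1], hp[2], hp[3],
                        age = 1, radius = vessel_radius(1, state$config),
                        tip = TRUE)
    v <- rbind(v, seg)
    vlin <- c(vlin, hp[1] + shape[1] * ((hp[2] - 1) + shape[2] * (hp[3] - 1)))
    branched <- c(branched, v$id[src])
    state$vess_occ[matrix(hp, 1)] <- TRUE
  }
  state$vessels <- v
  state
}

# one iteration of the angiogenesis module
angio_step <- function(state) {
  cfg <- state$config
  if (!cfg$angiogenesis_enabled || !nrow(state$vessels)) return(state)
  # tips advance in id order
  tip_ids <- state$vessels$id[state$vessels$tip]
  for (tid in tip_ids) state <- tip_migration_step(state, tid)
  # branching
  hp <- sample_branching_hotpoints(state)
  state <- apply_branching(state, hp)
  # tip-cell selection: an activated vessel with no growing tip sprouts
  # deterministically at its strongest admissible TAF contact
  if (!any(state$vessels$tip)) {
    v <- state$vessels
    shape <- rep(cfg$grid_n, 3L)
    off <- faces6_offsets()
    cand <- do.call(rbind, lapply(seq_len(6), function(d)
      cbind(v$x + off[d, 1], v$y + off[d, 2], v$z + off[d, 3],
            seq_len(nrow(v)))))
    keep <- cand[, 1] >= 1 & cand[, 1] <= shape[1] &
            cand[, 2] >= 1 & cand[, 2] <= shape[2] &
            cand[, 3] >= 1 & cand[, 3] <= shape[3]
    cand <- cand[keep, , drop = FALSE]
    pos <- cand[, 1:3, drop = FALSE]
    open <- !state$vess_occ[pos] & state$phen[pos] != 3L
    cand <- cand[open, , drop = FALSE]
    if (nrow(cand)) {
      taf <- state$fields$taf[cand[, 1:3, drop = FALSE]]
      if (max(taf) >= cfg$taf_sprout_threshold) {
        pick <- which.max(taf)
        nid <- state$next_vessel_id
        state$next_vessel_id <- nid + 1L
        seg <- new_segments(nid, v$id[cand[pick, 4]],
                            cand[pick, 1], cand[pick, 2], cand[pick, 3],
                            age = 1, radius = vessel_radius(1, cfg), tip = TRUE)
        state$vessels <- rbind(v, seg)
        state$vess_occ[matrix(cand[pick, 1:3], 1)] <- TRUE
      }
    }
  }
  # necrotic overwrite kills segments (the necrotic core excludes vessels)
  v <- state$vessels
  if (nrow(v)) {
    on_necrotic <- state$phen[cbind(v$x, v$y, v$z)] == 3L
    v$age[on_necrotic] <- 0
    v <- age_and_radius_update(v, cfg)
    v$age[on_necrotic] <- 0
    v <- prune_vessels(v)
    state$vessels <- v
    state$vess_occ <- vessel_occupancy(v, dim(state$phen))
  }
  state
}
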