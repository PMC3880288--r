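# Independent brute-force references used to validate the production
# kernels. Deliberately written as plain nested loops over the documented
# update rules; they share no code with the package internals.

# one explicit step of the diffusion-convection-reaction scheme:
# 7-point Laplacian with reflected boundary closure, conservative
# first-order upwind fluxes with arithmetic-mean face velocities and no
# flux through the domain boundary, Dirichlet reset on all six faces,
# negatives clipped.
naive_fd_step <- function(phi, D, vel = NULL, src = NULL, snk = NULL,
                          dt = 1, bc = NULL, clip = TRUE) {
  d <- dim(phi)
  out <- array(0, d)
  at <- function(a, i, j, k) a[i, j, k]
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    pc <- phi[i, j, k]
    nb <- function(di, dj, dk) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3]) pc
      else phi[ii, jj, kk]
    }
    lap <- nb(-1, 0, 0) + nb(1, 0, 0) + nb(0, -1, 0) + nb(0, 1, 0) +
      nb(0, 0, -1) + nb(0, 0, 1) - 6 * pc
    div <- 0
    if (!is.null(vel)) {
      flux <- function(u, axis, side) {
        # side +1: face between this voxel and its +axis neighbour
        step <- c(0, 0, 0); step[axis] <- side
        ii <- i + step[1]; jj <- j + step[2]; kk <- k + step[3]
        if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3])
          return(0)
        uf <- (u[i, j, k] + u[ii, jj, kk]) / 2
        upwind <- if (side == 1) {
          if (uf > 0) pc else phi[ii, jj, kk]
        } else {
          if (uf > 0) phi[ii, jj, kk] else pc
        }
        uf * upwind
      }
      div <- flux(vel$ux, 1, 1) - flux(vel$ux, 1, -1) +
        flux(vel$uy, 2, 1) - flux(vel$uy, 2, -1) +
        flux(vel$uz, 3, 1) - flux(vel$uz, 3, -1)
    }
    rhs <- D * lap - div
    if (!is.null(src)) rhs <- rhs + src[i, j, k]
    if (!is.null(snk)) rhs <- rhs - snk[i, j, k]
    out[i, j, k] <- pc + dt * rhs
  }
  if (!is.null(bc)) {
    out[1, , ] <- bc; out[d[1], , ] <- bc
    out[, 1, ] <- bc; out[, d[2], ] <- bc
    out[, , 1] <- bc; out[, , d[3]] <- bc
  }
  if (clip) out[out < 0] <- 0
  out
}

# brute-force pairwise Gaussian-kernel pressure: for every lattice point X0,
# sum over sources within the Chebyshev K-ball of
#   rho(theta(X0)) * exp(-||Xi - X0||^2 / (2 lambda(theta(X0))^2)),
# with theta(X0) the occupancy fraction of the K-cube about X0 over the
# nominal (2K+1)^3 denominator.
naive_kernel_pressure <- function(occ, K, rho_max, lambda_min, lambda_max) {
  d <- dim(occ)
  pos <- which(occ, arr.ind = TRUE)
  out <- array(0, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    cnt <- 0
    for (dz in -K:K) for (dy in -K:K) for (dx in -K:K) {
      x <- i + dx; y <- j + dy; z <- k + dz
      if (x >= 1 && y >= 1 && z >= 1 && x <= d[1] && y <= d[2] && z <= d[3] &&
          occ[x, y, z]) cnt <- cnt + 1
    }
    theta <- cnt / (2 * K + 1)^3
    if (theta == 0) next
    rho <- rho_max * theta
    lam <- lambda_min + (lambda_max - lambda_min) * theta
    s <- 0
    if (nrow(pos)) for (r in seq_len(nrow(pos))) {
      dx <- pos[r, 1] - i; dy <- pos[r, 2] - j; dz <- pos[r, 3] - k
      if (max(abs(dx), abs(dy), abs(dz)) <= K)
        s <- s + exp(-(dx^2 + dy^2 + dz^2) / (2 * lam^2))
    }
    out[i, j, k] <- rho * s
  }
  out
}

# reachable set of a vessel forest from its roots, by breadth-first search
# over parent links; used as the pruning oracle.
reachable_segments <- function(vessels) {
  keep <- vessels$parent_id == -1L
  repeat {
    grow <- vessels$parent_id %in% vessels$id[keep] & !keep
    if (!any(grow)) break
    keep <- keep | grow
  }
  vessels$id[keep]
}
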