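# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: closed-form sums, exact enumeration, transfer
# matrices and direct sampling.

# Mean-square end-to-end distance of a discrete freely rotating chain with
# n segments of length ds and per-step tangent correlation c0: the exact
# closed-form double sum. As ds -> 0 with c0 = exp(-ds/Lp) this converges
# to the continuous semiflexible-chain result.
frcSquaredEndToEnd <- function(lp, lc, n = 20000L) {
  ds <- lc / n
  c0 <- exp(-ds / lp)
  k <- seq_len(n - 1L)
  ds^2 * (n + 2 * sum((n - k) * c0^k))
}

# Direct Monte Carlo of the freely rotating chain (fixed polar angle,
# uniform azimuth). Returns per-chain squared end-to-end distances.
frcSample <- function(lp, lc, nseg, nchains) {
  ds <- lc / nseg
  cth <- exp(-ds / lp)
  sth <- sqrt(1 - cth^2)
  tx <- rep(1, nchains); ty <- rep(0, nchains); tz <- rep(0, nchains)
  Rx <- Ry <- Rz <- rep(0, nchains)
  for (i in seq_len(nseg)) {
    Rx <- Rx + ds * tx; Ry <- Ry + ds * ty; Rz <- Rz + ds * tz
    phi <- runif(nchains, 0, 2 * pi)
    pick <- abs(tx) < 0.9
    ax <- ifelse(pick, 1, 0); ay <- ifelse(pick, 0, 1)
    ux <- ay * tz; uy <- -ax * tz; uz <- ax * ty - ay * tx
    un <- sqrt(ux^2 + uy^2 + uz^2)
    ux <- ux / un; uy <- uy / un; uz <- uz / un
    vx <- ty * uz - tz * uy; vy <- tz * ux - tx * uz; vz <- tx * uy - ty * ux
    ntx <- cth * tx + sth * (cos(phi) * ux + sin(phi) * vx)
    nty <- cth * ty + sth * (cos(phi) * uy + sin(phi) * vy)
    ntz <- cth * tz + sth * (cos(phi) * uz + sin(phi) * vz)
    tx <- ntx; ty <- nty; tz <- ntz
  }
  Rx^2 + Ry^2 + Rz^2
}

# Per-vertex <cos theta> of a uniformly stiff phantom cubic-lattice chain:
# 6-state transfer matrix with Boltzmann weights exp(-eps*(1 - cos)).
# Every row of the direction-transfer matrix has the same sum, so vertex
# angles are iid and the marginal is the weighted angle distribution.
latticeCosTheta <- function(eps) {
  (1 - exp(-2 * eps)) / (1 + 4 * exp(-eps) + exp(-2 * eps))
}

# Exact lattice-walk radius of gyration: <Rg^2> for an ideal chain of
# nBeads beads with unit bonds, (nBeads^2 - 1) / (6 nBeads).
idealLatticeRg2 <- function(nBeads) (nBeads^2 - 1) / (6 * nBeads)

# Exhaustive enumeration of all 6^n direction sequences of an n-bond
# lattice walk; returns mean Rg^2 (exact, feasible for n <= 6).
enumerateLatticeRg2 <- function(nBonds) {
  dirs <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1),
                 6, 3, byrow = TRUE)
  idx <- as.matrix(expand.grid(rep(list(1:6), nBonds)))
  mean(apply(idx, 1L, function(ii) {
    xyz <- rbind(0, apply(dirs[ii, , drop = FALSE], 2L, cumsum))
    cen <- colMeans(xyz)
    mean(rowSums(sweep(xyz, 2L, cen)^2))
  }))
}

# Exact Boltzmann distribution of the bending energy of a 3-bond lattice
# chain with vertex energies eps (length 2): enumerate all 6^3 direction
# sequences. Returns a table of energy level -> probability.
enumerate3BondEnergies <- function(eps) {
  dirs <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1),
                 6, 3, byrow = TRUE)
  idx <- as.matrix(expand.grid(1:6, 1:6, 1:6))
  E <- apply(idx, 1L, function(ii) {
    b <- dirs[ii, , drop = FALSE]
    eps[1L] * (1 - sum(b[1L, ] * b[2L, ])) +
      eps[2L] * (1 - sum(b[2L, ] * b[3L, ]))
  })
  w <- exp(-E)
  tapply(w, round(E, 9), sum) / sum(w)
}

# Mean-square distances of a Gaussian spring network by direct sampling:
# bead 1 pinned at the origin, positions drawn via the Cholesky factor of
# the reduced Laplacian (independent of the pseudo-inverse route used by
# the package). Returns mean and standard error of |r_i - r_j|^2 for the
# requested pairs.
sampleGaussianNetwork <- function(topology, pairs, nDraws = 1e5,
                                  bondVariance = 1) {
  n <- nBeads(topology)
  L <- matrix(0, n, n)
  ii <- seq_len(n - 1L)
  L[cbind(ii, ii + 1L)] <- -1
  b <- extraBonds(topology)
  if (nrow(b) > 0L)
    for (r in seq_len(nrow(b)))
      L[b[r, 1L], b[r, 2L]] <- L[b[r, 1L], b[r, 2L]] - 1
  L <- L + t(L)
  diag(L) <- -rowSums(L)
  Lred <- L[-1L, -1L, drop = FALSE]
  R <- chol(Lred)  # t(R) %*% R = Lred
  sdc <- sqrt(bondVariance / 3)
  d2 <- matrix(0, nDraws, nrow(pairs))
  for (k in 1:3) {
    z <- matrix(rnorm((n - 1L) * nDraws), n - 1L, nDraws)
    x <- rbind(0, backsolve(R, z) * sdc)  # coordinates, bead 1 at 0
    for (p in seq_len(nrow(pairs)))
      d2[, p] <- d2[, p] + (x[pairs[p, 2L], ] - x[pairs[p, 1L], ])^2
  }
  list(mean = colMeans(d2),
       se = apply(d2, 2L, sd) / sqrt(nDraws))
}

expect_within_se <- function(observed, expected, se, nSe = 3,
                             label = "value") {
  expect_lt(abs(observed - expected), nSe * se,
            label = sprintf("%s = %g (expected %g +/- %g x %g SE)",
                            label, observed, expected, nSe, se))
}
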