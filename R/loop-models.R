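## Gaussian-chain loop models: random-loop topologies solved exactly via
## the connectivity Laplacian, the random-walk/giant-loop (RW-GL)
## construction, and ensemble-averaged distance profiles.

#' Draw a random-loop topology
#'
#' Decorates a linear backbone with extra harmonic bonds: every bead pair
#' separated by at least \code{minLoopSeparation} along the backbone is
#' included independently with probability \code{p}. At the default
#' granularity of 10 kbp per bead, the default cutoff of 15 beads encodes
#' "loops at all scales above 150 kbp". Cell-to-cell variation is modelled
#' by averaging observables over independent draws of the topology.
#'
#' @param nBeads number of backbone beads (>= 2).
#' @param p per-pair loop probability in [0, 1].
#' @param minLoopSeparation minimum backbone separation of a loop (beads,
#'   default 15).
#' @param bpPerBead base pairs per bead (default 10000).
#' @param seed optional integer seed.
#' @return a \code{\linkS4class{LoopTopology}}. When no pair is eligible
#'   (cutoff >= chain length) an empty topology is returned with a warning.
#' @examples
#' randomLoopTopology(100, 1e-3, seed = 1)
#' @export
randomLoopTopology <- function(nBeads, p, minLoopSeparation = 15L,
                               bpPerBead = 1e4, seed = NULL) {
  nBeads <- as.integer(nBeads)
  if (nBeads < 2L) stop("nBeads must be >= 2", call. = FALSE)
  if (!is.finite(p) || p < 0 || p > 1)
    stop("p must lie in [0, 1]", call. = FALSE)
  minLoopSeparation <- as.integer(minLoopSeparation)
  if (!is.null(seed)) set.seed(seed)

  pairs <- .eligiblePairs(nBeads, minLoopSeparation)
  if (nrow(pairs) == 0L) {
    warning("minimum loop separation >= chain length: no eligible pairs",
            call. = FALSE)
    bonds <- matrix(integer(0), 0L, 2L)
  } else if (p == 0) {
    bonds <- matrix(integer(0), 0L, 2L)
  } else {
    keep <- runif(nrow(pairs)) < p
    bonds <- pairs[keep, , drop = FALSE]
  }
  colnames(bonds) <- c("i", "j")
  new("LoopTopology", nBeads = nBeads, extraBonds = bonds,
      loopProbability = p, minLoopSeparation = minLoopSeparation,
      bpPerBead = as.numeric(bpPerBead))
}

.eligiblePairs <- function(nBeads, minSep) {
  if (minSep >= nBeads) return(matrix(integer(0), 0L, 2L))
  ## enumerate (i, i + d) for d = minSep .. nBeads - 1
  out <- do.call(rbind, lapply(minSep:(nBeads - 1L), function(d) {
    ii <- seq_len(nBeads - d)
    cbind(ii, ii + d)
  }))
  storage.mode(out) <- "integer"
  out
}

#' Exact mean-square distances of a Gaussian loop network
#'
#' For a Gaussian chain with harmonic backbone bonds plus the topology's
#' extra loop bonds, the equilibrium mean-square inter-bead distances
#' follow exactly from the Moore--Penrose pseudo-inverse \eqn{\Gamma^+} of
#' the connectivity Laplacian:
#' \deqn{\langle r_{ij}^2 \rangle = b^2 (\Gamma^+_{ii} + \Gamma^+_{jj}
#'   - 2\Gamma^+_{ij}),}
#' i.e. \eqn{b^2} times the graph resistance distance. With no loops this
#' reduces to the ideal chain, \eqn{\langle r_{ij}^2\rangle = |i - j| b^2}.
#'
#' @param topology a \code{\linkS4class{LoopTopology}}.
#' @param bondVariance \eqn{b^2}, mean-square length of one backbone bond
#'   (default 1).
#' @param loopStrength spring constant of loop bonds relative to backbone
#'   bonds (default 1).
#' @return symmetric \code{nBeads x nBeads} matrix of mean-square distances.
#' @examples
#' topo <- randomLoopTopology(10, 0)
#' gaussianDistanceMatrix(topo)[1, ]   # 0, 1, 2, ..., 9
#' @export
gaussianDistanceMatrix <- function(topology, bondVariance = 1,
                                   loopStrength = 1) {
  stopifnot(is(topology, "LoopTopology"))
  .checkPositive(bondVariance, "bondVariance")
  .checkPositive(loopStrength, "loopStrength")
  n <- topology@nBeads
  gp <- .laplacianPinv(topology, loopStrength)
  d <- diag(gp)
  bondVariance * (outer(d, d, `+`) - 2 * gp)
}

#' Radius of gyration of a Gaussian loop network
#'
#' Exact ensemble-average squared radius of gyration,
#' \eqn{\langle R_g^2\rangle = b^2\,\mathrm{tr}(\Gamma^+)/n}. For looped
#' structures the radius of gyration is the appropriate size measure:
#' intra-chain distances mislead because loops pin distant beads together.
#'
#' @inheritParams gaussianDistanceMatrix
#' @return scalar \eqn{\langle R_g^2\rangle}.
#' @export
gaussianRadiusOfGyration <- function(topology, bondVariance = 1,
                                     loopStrength = 1) {
  stopifnot(is(topology, "LoopTopology"))
  gp <- .laplacianPinv(topology, loopStrength)
  bondVariance * sum(diag(gp)) / topology@nBeads
}

## pseudo-inverse of the weighted connectivity Laplacian via symmetric
## eigendecomposition; the single null mode (uniform translation) is
## dropped. A second near-zero mode means the network is numerically rank
## deficient beyond translation invariance and is reported as an error.
.laplacianPinv <- function(topology, loopStrength = 1) {
  n <- topology@nBeads
  L <- matrix(0, n, n)
  ii <- seq_len(n - 1L)
  L[cbind(ii, ii + 1L)] <- -1
  b <- topology@extraBonds
  if (nrow(b) > 0L)
    for (r in seq_len(nrow(b)))
      L[b[r, 1L], b[r, 2L]] <- L[b[r, 1L], b[r, 2L]] - loopStrength
  L <- L + t(L)
  diag(L) <- -rowSums(L)
  e <- eigen(L, symmetric = TRUE)
  vals <- e$values
  tol <- max(vals) * n * 100 * .Machine$double.eps
  null <- vals < tol
  if (sum(null) != 1L)
    stop("connectivity Laplacian is rank deficient beyond the ",
         "translation mode", call. = FALSE)
  keep <- which(!null)
  e$vectors[, keep] %*% (t(e$vectors[, keep]) / vals[keep])
}

#' Ensemble-averaged distance profile of the random loop model
#'
#' Averages the exact Gaussian mean-square distances over independent draws
#' of the loop topology (modelling cell-to-cell loop variability), and over
#' all bead pairs at each backbone separation. With increasing loop density
#' the profile flattens: mean-square distances become independent of the
#' genomic separation (scaling exponent tending to zero).
#'
#' @inheritParams randomLoopTopology
#' @param nTopologies number of topology draws to average over.
#' @param bondVariance mean-square backbone bond length \eqn{b^2}.
#' @param separations backbone separations to report (default every bead up
#'   to \code{nBeads - 1}).
#' @param seed master seed; per-topology seeds via \code{\link{splitSeed}}.
#' @return data.frame with columns \code{s}, \code{mean_r2}, \code{stderr}
#'   (across topologies), \code{n_samples}.
#' @export
randomLoopProfile <- function(nBeads, p, minLoopSeparation = 15L,
                              nTopologies = 20L, bondVariance = 1,
                              bpPerBead = 1e4, separations = NULL,
                              seed = 1L) {
  nBeads <- as.integer(nBeads)
  if (is.null(separations)) separations <- seq_len(nBeads - 1L)
  separations <- as.integer(separations)
  perTopo <- matrix(NA_real_, nTopologies, length(separations))
  for (t in seq_len(nTopologies)) {
    topo <- randomLoopTopology(nBeads, p, minLoopSeparation, bpPerBead,
                               seed = splitSeed(seed, t))
    m <- gaussianDistanceMatrix(topo, bondVariance)
    perTopo[t, ] <- vapply(separations, function(s)
      mean(m[cbind(seq_len(nBeads - s), seq_len(nBeads - s) + s)]),
      numeric(1))
  }
  data.frame(s = separations,
             mean_r2 = colMeans(perTopo),
             stderr = apply(perTopo, 2L, sd) / sqrt(nTopologies),
             n_samples = nTopologies)
}

#' Random-walk/giant-loop (RW-GL) distance profile
#'
#' Samples conformations in which Mbp-scale closed loops hang consecutively
#' off a randomly oriented backbone: the chain is partitioned into
#' consecutive loops of \code{loopSize} beads, each realised as a Gaussian
#' Brownian bridge returning to its anchor, and consecutive anchors are
#' connected by Gaussian backbone steps. Within one loop of \eqn{m} beads
#' the mean-square distance at separation \eqn{s} follows the closed-loop
#' form \eqn{b^2 s (m - s)/m}; across many loops the profile flattens,
#' reproducing the observed leveling-off of geometric distances at large
#' genomic separations. With \code{loopSize = 0} (or \code{NULL}) the
#' construction degenerates to a plain ideal chain with a linear profile.
#'
#' @param nBeads number of beads.
#' @param loopSize beads per giant loop (>= 2), or 0/NULL for no loops. At
#'   the default granularity of 10 kbp/bead, 200 beads represent a 2-Mbp
#'   loop (mid-range of 1--3 Mbp).
#' @param replicates number of independent conformations.
#' @param bondVariance mean-square length of one intra-loop bond (default 1).
#' @param backboneVariance mean-square length of one anchor-to-anchor
#'   backbone step (default 1).
#' @param separations separations to report (default up to
#'   \code{nBeads - 1}).
#' @param seed master seed.
#' @return data.frame with columns \code{s}, \code{mean_r2}, \code{stderr},
#'   \code{n_samples}, plus attribute \code{"rg2"}: the mean squared radius
#'   of gyration across replicates (with its standard error), the size
#'   measure appropriate for looped structures.
#' @export
rwglProfile <- function(nBeads, loopSize = 200L, replicates = 100L,
                        bondVariance = 1, backboneVariance = 1,
                        separations = NULL, seed = 1L) {
  nBeads <- as.integer(nBeads)
  if (is.null(loopSize) || loopSize == 0L) {
    loopSize <- 0L
  } else {
    loopSize <- as.integer(loopSize)
    if (loopSize < 2L) stop("loopSize must be >= 2 beads", call. = FALSE)
    if (loopSize > nBeads)
      stop("loopSize cannot exceed nBeads", call. = FALSE)
  }
  if (is.null(separations)) separations <- seq_len(nBeads - 1L)
  separations <- as.integer(separations)
  sdBond <- sqrt(bondVariance / 3)

  sampleConf <- function() {
    if (loopSize == 0L)
      return(apply(matrix(rnorm(nBeads * 3, sd = sdBond), nBeads, 3), 2L,
                   cumsum))
    x <- matrix(NA_real_, nBeads, 3L)
    anchor <- c(0, 0, 0)
    filled <- 0L
    while (filled < nBeads) {
      m <- min(loopSize, nBeads - filled)
      if (m >= 2L) {
        ## Brownian bridge of m steps from the anchor back to the anchor
        w <- apply(matrix(rnorm(m * 3, sd = sdBond), m, 3), 2L, cumsum)
        k <- seq_len(m)
        bridge <- w - (k / m) %o% w[m, ]
        x[filled + k, ] <- rep(anchor, each = m) + bridge
      } else {
        x[filled + 1L, ] <- anchor
      }
      filled <- filled + m
      anchor <- anchor + rnorm(3, sd = sqrt(backboneVariance / 3))
    }
    x
  }

  perRep <- matrix(NA_real_, replicates, length(separations))
  rg2s <- numeric(replicates)
  for (r in seq_len(replicates)) {
    set.seed(splitSeed(seed, r))
    x <- sampleConf()
    rg2s[r] <- mean(rowSums(sweep(x, 2L, colMeans(x))^2))
    perRep[r, ] <- vapply(separations, function(s) {
      d <- x[seq_len(nBeads - s) + s, , drop = FALSE] -
           x[seq_len(nBeads - s), , drop = FALSE]
      mean(rowSums(d^2))
    }, numeric(1))
  }
  out <- data.frame(s = separations,
                    mean_r2 = colMeans(perRep),
                    stderr = apply(perRep, 2L, sd) / sqrt(replicates),
                    n_samples = replicates)
  attr(out, "rg2") <- c(mean = mean(rg2s),
                        se = sd(rg2s) / sqrt(replicates))
  out
}
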