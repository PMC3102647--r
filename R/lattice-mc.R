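## Lattice Monte Carlo of phantom semiflexible chains with flexible hinges:
## chain construction, stiffness maps, Metropolis sampling, the hinge
## radius-of-gyration experiment, and tangent-correlation persistence
## length estimation.

#' Build a phantom chain on the cubic lattice
#'
#' @param nBonds number of bonds (>= 2); the chain has \code{nBonds + 1}
#'   beads and \code{nBonds - 1} interior vertices.
#' @param stiffness per-vertex bending energies in kBT, length
#'   \code{nBonds - 1}; default all zero (fully flexible).
#' @param init \code{"rod"} for a collinear chain along x, \code{"random"}
#'   for an unbiased lattice walk.
#' @param seed optional integer seed (used for \code{init = "random"}).
#' @return a \code{\linkS4class{LatticeChain}}.
#' @examples
#' buildChain(16, init = "rod")
#' @export
buildChain <- function(nBonds, stiffness = NULL, init = c("rod", "random"),
                       seed = NULL) {
  init <- match.arg(init)
  nBonds <- as.integer(nBonds)
  if (nBonds < 2L) stop("nBonds must be >= 2", call. = FALSE)
  if (is.null(stiffness)) stiffness <- rep(0, nBonds - 1L)
  if (length(stiffness) != nBonds - 1L)
    stop(sprintf("stiffness must have length nBonds - 1 = %d", nBonds - 1L),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  xyz <- if (init == "rod") {
    cbind(0:nBonds, 0L, 0L)
  } else {
    cpp_lattice_walk(nBonds)
  }
  new("LatticeChain", coords = xyz, stiffness = as.numeric(stiffness))
}

#' Stiffness map with flexible hinges in a stiff background
#'
#' Builds a per-vertex bending-energy map for an overall stiff chain
#' containing \code{nFlexibleRegions} flexible regions ("hinges") of
#' \code{regionWidth} vertices each, modelling local nucleosome depletion.
#' Hinge start positions are the equally spaced interior vertices
#' \eqn{\lfloor j (n_v + 1)/(k + 1) \rfloor}, \eqn{j = 1..k}, where
#' \eqn{n_v} is the vertex count. The default energies differ by the
#' nominal 2 kBT per segment gap between stiff and depleted chromatin.
#'
#' @param nBonds number of bonds of the target chain.
#' @param nFlexibleRegions number of hinges (>= 0).
#' @param stiffEnergy bending energy of the stiff background, kBT
#'   (default 2).
#' @param flexibleEnergy bending energy inside hinges, kBT (default 0).
#' @param regionWidth hinge width in vertices (default 1).
#' @return numeric vector of length \code{nBonds - 1}.
#' @examples
#' hingeStiffnessMap(16, 3)   # hinges at vertices 4, 8, 12
#' @export
hingeStiffnessMap <- function(nBonds, nFlexibleRegions, stiffEnergy = 2,
                              flexibleEnergy = 0, regionWidth = 1L) {
  nBonds <- as.integer(nBonds)
  k <- as.integer(nFlexibleRegions)
  w <- as.integer(regionWidth)
  nv <- nBonds - 1L
  if (nv < 1L) stop("nBonds must be >= 2", call. = FALSE)
  if (k < 0L || w < 1L)
    stop("nFlexibleRegions must be >= 0 and regionWidth >= 1", call. = FALSE)
  if (k * w > nv)
    stop(sprintf("cannot place %d regions of width %d in %d vertices",
                 k, w, nv), call. = FALSE)
  m <- rep(stiffEnergy, nv)
  if (k > 0L) {
    start <- pmin(pmax(floor(seq_len(k) * (nv + 1) / (k + 1)), 1L), nv)
    for (s in start) {
      idx <- s:min(s + w - 1L, nv)
      m[idx] <- flexibleEnergy
    }
  }
  m
}

#' Metropolis sampling of a lattice chain
#'
#' Samples the Boltzmann distribution of the bending energy
#' \eqn{E = \sum_v \epsilon_v (1 - \cos\theta_v)} at temperature 1 kBT with
#' a mix of pivot, corner-flip and end-rotation moves (defaults 0.2 / 0.7 /
#' 0.1). With all energies zero every configuration is equally weighted and
#' the chain is an ideal lattice walk. One sweep is \code{nBonds} attempted
#' moves; by default the chain is equilibrated for \code{10 * nBonds}
#' sweeps and then sampled every 2 sweeps (pivot moves decorrelate the
#' global conformation within a few sweeps).
#'
#' @param chain a \code{\linkS4class{LatticeChain}}.
#' @param nSamples number of samples to record (>= 1).
#' @param equilSweeps equilibration sweeps; default \code{10 * nBonds}.
#' @param sampleInterval sweeps between samples (>= 1, default 2).
#' @param moveMix probabilities for (pivot, corner, end) moves; must sum
#'   to 1.
#' @param seed optional integer seed; identical (chain, config, seed) give
#'   identical series.
#' @param maxSep largest bond separation recorded in the tangent
#'   correlation; default \code{min(nBonds - 1, 32)}.
#' @return an \code{\linkS4class{ObservableSeries}}.
#' @examples
#' ch <- buildChain(32, init = "rod")
#' s <- metropolisSample(ch, nSamples = 50, seed = 1)
#' mean(ree2(s)) / 32  # ~ 1 for the ideal chain
#' @export
metropolisSample <- function(chain, nSamples = 200L, equilSweeps = NULL,
                             sampleInterval = 2L,
                             moveMix = c(pivot = 0.2, corner = 0.7, end = 0.1),
                             seed = NULL, maxSep = NULL) {
  stopifnot(is(chain, "LatticeChain"))
  validObject(chain)
  nSamples <- as.integer(nSamples)
  if (nSamples < 1L)
    stop("nSamples must be >= 1: an empty series has no observables",
         call. = FALSE)
  nb <- nBonds(chain)
  if (is.null(equilSweeps)) equilSweeps <- 10L * nb
  sampleInterval <- as.integer(sampleInterval)
  if (sampleInterval < 1L) stop("sampleInterval must be >= 1", call. = FALSE)
  if (length(moveMix) != 3L || any(moveMix < 0) ||
      abs(sum(moveMix) - 1) > 1e-9)
    stop("moveMix must be 3 non-negative probabilities summing to 1",
         call. = FALSE)
  if (is.null(maxSep)) maxSep <- min(nb - 1L, 32L)
  if (!is.null(seed)) set.seed(seed)

  res <- cpp_lattice_mc(coords(chain), stiffnessMap(chain), nSamples,
                        as.integer(equilSweeps), sampleInterval,
                        as.numeric(moveMix), as.integer(maxSep))
  tc <- cbind(1, res$tcorr)
  colnames(tc) <- paste0("s", 0:(ncol(tc) - 1L))
  new("ObservableSeries", ree2 = res$ree2, rg2 = res$rg2,
      tangentCorrelation = tc, meanCosTheta = res$mean_cos,
      nBonds = nb, acceptance = res$acceptance)
}

#' Hinge-collapse radius-of-gyration experiment
#'
#' For each chain length and hinge count, runs replicate Monte Carlo
#' simulations of (i) a stiff chain carrying that many flexible hinges and
#' (ii) a fully flexible chain, and reports the size ratio
#' \deqn{R(k) = \langle R_g^2\rangle(k \textrm{ hinges, stiff background})
#' / \langle R_g^2\rangle(\textrm{fully flexible}),}
#' with replicate-based standard errors. Introducing hinges softens the
#' stiff chain, so \eqn{R(k)} decreases with \eqn{k} and grows with chain
#' length; this is the qualitative collapse mechanism by which local
#' nucleosome depletion compacts a gene locus.
#'
#' @param nBondsList chain lengths (bonds) to simulate; each >= 4.
#' @param hingeCounts hinge counts, e.g. \code{0:3}.
#' @param replicates independent replicate seeds per condition (default 32).
#' @param stiffEnergy,flexibleEnergy,regionWidth passed to
#'   \code{\link{hingeStiffnessMap}}.
#' @param nSamples samples per replicate (default 150).
#' @param sampleInterval sweeps between samples (default 2).
#' @param seed master seed; replicate seeds are derived with
#'   \code{\link{splitSeed}}.
#' @return data.frame with columns \code{n_bonds}, \code{hinges},
#'   \code{rg2_mean}, \code{rg2_se}, \code{rg2_flexible},
#'   \code{rg2_flexible_se}, \code{ratio}, \code{ratio_se}. The ratio
#'   definition is recorded in the \code{"ratio_definition"} attribute.
#' @export
rgRatioExperiment <- function(nBondsList, hingeCounts = 0:3, replicates = 32L,
                              stiffEnergy = 2, flexibleEnergy = 0,
                              regionWidth = 1L, nSamples = 150L,
                              sampleInterval = 2L, seed = 1L) {
  nBondsList <- as.integer(nBondsList)
  if (any(nBondsList < 4L))
    stop("chains with fewer than 4 bonds are too short to host hinges",
         call. = FALSE)
  hingeCounts <- sort(unique(as.integer(hingeCounts)))
  replicates <- as.integer(replicates)

  runMean <- function(nb, map, seeds) {
    vals <- vapply(seeds, function(s) {
      ch <- buildChain(nb, map, init = "random", seed = s)
      mean(rg2(metropolisSample(ch, nSamples = nSamples,
                                sampleInterval = sampleInterval)))
    }, numeric(1))
    c(mean = mean(vals), se = sd(vals) / sqrt(length(vals)))
  }

  out <- list()
  counter <- 0L
  for (nb in nBondsList) {
    counter <- counter + 1L
    flexSeeds <- vapply(seq_len(replicates),
                        function(r) splitSeed(seed, counter * 100000L + r),
                        integer(1))
    flex <- runMean(nb, rep(flexibleEnergy, nb - 1L), flexSeeds)
    for (k in hingeCounts) {
      counter <- counter + 1L
      seeds <- vapply(seq_len(replicates),
                      function(r) splitSeed(seed, counter * 100000L + r),
                      integer(1))
      map <- hingeStiffnessMap(nb, k, stiffEnergy, flexibleEnergy,
                               regionWidth)
      st <- runMean(nb, map, seeds)
      ratio <- st["mean"] / flex["mean"]
      ratioSe <- ratio * sqrt((st["se"] / st["mean"])^2 +
                              (flex["se"] / flex["mean"])^2)
      out[[length(out) + 1L]] <- data.frame(
        n_bonds = nb, hinges = k,
        rg2_mean = unname(st["mean"]), rg2_se = unname(st["se"]),
        rg2_flexible = unname(flex["mean"]),
        rg2_flexible_se = unname(flex["se"]),
        ratio = unname(ratio), ratio_se = unname(ratioSe))
    }
  }
  res <- do.call(rbind, out)
  attr(res, "ratio_definition") <-
    "R(k) = <Rg2>(k hinges, stiff background) / <Rg2>(fully flexible chain)"
  res
}

#' Persistence length from the tangent-correlation decay
#'
#' Estimates the persistence length (in bond units) from the exponential
#' decay of the tangent autocorrelation,
#' \eqn{\langle t_i \cdot t_{i+s}\rangle \approx e^{-s/L_p}}, by a
#' least-squares fit of \eqn{\ln\langle t_i \cdot t_{i+s}\rangle} against
#' \eqn{s} over the requested separations (slope \eqn{= -1/L_p}).
#'
#' @param series an \code{\linkS4class{ObservableSeries}}.
#' @param fitRange bond separations to fit over (default \code{1:5},
#'   truncated to the recorded range).
#' @return persistence length in bond units, with attributes
#'   \code{"stderr"} (delta-method standard error) and \code{"rodLike"}
#'   (\code{TRUE} when the estimate exceeds the chain length, i.e. the
#'   chain is effectively a rod over the sampled scale).
#' @export
tangentCorrelationLp <- function(series, fitRange = 1:5) {
  stopifnot(is(series, "ObservableSeries"))
  tc <- tangentCorrelation(series)
  smax <- ncol(tc) - 1L
  fitRange <- fitRange[fitRange >= 1 & fitRange <= smax]
  if (length(fitRange) < 2L)
    stop("fitRange must contain at least 2 recorded separations",
         call. = FALSE)
  cbar <- colMeans(tc)[fitRange + 1L]
  if (any(cbar <= 0))
    stop(paste("nonpositive tangent correlations in the fit range;",
               "shorten fitRange to separations with positive correlation"),
         call. = FALSE)
  fit <- lm(log(cbar) ~ fitRange)
  slope <- coef(fit)[[2L]]
  slopeSe <- summary(fit)$coefficients[2L, 2L]
  if (slope >= 0) {
    lp <- Inf
    se <- NA_real_
  } else {
    lp <- -1 / slope
    se <- slopeSe / slope^2
  }
  rodLike <- !is.finite(lp) || lp > nBonds(series)
  if (rodLike)
    warning("estimated persistence length exceeds the chain length; ",
            "the chain is rod-like over the sampled scale", call. = FALSE)
  structure(lp, stderr = se, rodLike = rodLike)
}

#' Derive a replicate seed from a master seed
#'
#' Counter-based seed splitting: each (master seed, counter) pair maps to a
#' fixed derived seed, so adding replicates never reshuffles earlier ones.
#' The map is an affine congruential hash modulo \eqn{2^{31} - 1}.
#'
#' @param master master seed (integer).
#' @param counter non-negative integer stream/replicate counter.
#' @return a positive integer seed below \eqn{2^{31}}.
#' @examples
#' splitSeed(42, 1:3)
#' @export
splitSeed <- function(master, counter) {
  m <- as.numeric(master) %% 2147483647
  v <- (m * 48271 + 1013904223) %% 2147483647
  v <- (v + (as.numeric(counter) %% 2147483647) * 69621) %% 2147483647
  as.integer(v) + 1L
}
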