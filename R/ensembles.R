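## Lattice FJC ensembles (unconfined and density-confined), distance and
## contact profiles, scaling-exponent fits and moment-ratio diagnostics.

#' Generate an ensemble of lattice freely-jointed chains
#'
#' Unconfined chains are unbiased random walks on the cubic lattice (ideal
#' chains, \eqn{\langle R^2(s)\rangle = s}). Confined chains are walks with
#' reflecting walls in a cubic box whose side is fixed by the requested
#' bead density, \eqn{S = \lceil (N/\rho)^{1/3} \rceil}: at fixed density
#' the characteristic chain size grows as \eqn{N^{1/3}} by volume
#' conservation, the space-filling scaling of a fractal-globule-like
#' organization.
#'
#' @param nBeads beads per chain (>= 2).
#' @param mode \code{"unconfined"} or \code{"confined"}.
#' @param nChains number of independent chains.
#' @param density beads per lattice site (confined mode; in (0, 1]).
#' @param boxSize box side in lattice sites (confined mode; alternative to
#'   \code{density}).
#' @param seed master seed; per-chain seeds via \code{\link{splitSeed}}.
#' @return an \code{\linkS4class{FJCEnsemble}}.
#' @examples
#' e <- fjcEnsemble(128, "unconfined", nChains = 8, seed = 1)
#' mean(ensembleRee2(e)) / 127   # ~ 1
#' @export
fjcEnsemble <- function(nBeads, mode = c("unconfined", "confined"),
                        nChains = 64L, density = NULL, boxSize = NULL,
                        seed = 1L) {
  mode <- match.arg(mode)
  nBeads <- as.integer(nBeads)
  nChains <- as.integer(nChains)
  if (nBeads < 2L) stop("nBeads must be >= 2", call. = FALSE)
  if (nChains < 1L) stop("nChains must be >= 1", call. = FALSE)

  if (mode == "confined") {
    if (is.null(boxSize)) {
      if (is.null(density))
        stop("confined mode requires boxSize or density", call. = FALSE)
      if (!is.finite(density) || density <= 0 || density > 1)
        stop("density must lie in (0, 1] beads per site", call. = FALSE)
      boxSize <- max(2L, as.integer(ceiling((nBeads / density)^(1 / 3))))
    }
    boxSize <- as.integer(boxSize)
    density <- nBeads / boxSize^3
    if (density > 1)
      stop("more than one bead per lattice site: enlarge the box",
           call. = FALSE)
  } else {
    boxSize <- NA_real_
    density <- NA_real_
  }

  arr <- array(NA_real_, c(nBeads, 3L, nChains))
  for (cix in seq_len(nChains)) {
    set.seed(splitSeed(seed, cix))
    arr[, , cix] <- if (mode == "unconfined") {
      cpp_lattice_walk(nBeads - 1L)
    } else {
      cpp_confined_walk(nBeads - 1L, as.integer(boxSize))
    }
  }
  new("FJCEnsemble", coords = arr, mode = mode,
      boxSize = as.numeric(boxSize), density = as.numeric(density))
}

#' Squared end-to-end distance and radius of gyration of an ensemble
#'
#' @param ensemble an \code{\linkS4class{FJCEnsemble}}.
#' @return numeric vector, one value per chain.
#' @export
ensembleRee2 <- function(ensemble) {
  stopifnot(is(ensemble, "FJCEnsemble"))
  n <- dim(ensemble@coords)[1L]
  apply(ensemble@coords, 3L, function(x) sum((x[n, ] - x[1L, ])^2))
}

#' @rdname ensembleRee2
#' @export
ensembleRg2 <- function(ensemble) {
  stopifnot(is(ensemble, "FJCEnsemble"))
  apply(ensemble@coords, 3L, function(x)
    mean(rowSums(sweep(x, 2L, colMeans(x))^2)))
}

#' Mean-square distance versus backbone separation for an ensemble
#'
#' Averages \eqn{|r_{i+s} - r_i|^2} over all windows of every chain at each
#' requested separation; the standard error is taken across chains.
#'
#' @param ensemble an \code{\linkS4class{FJCEnsemble}}.
#' @param separations separations to report; default a log-spaced grid.
#' @return data.frame with columns \code{s}, \code{mean_r2}, \code{stderr},
#'   \code{n_samples}.
#' @export
msdProfile <- function(ensemble, separations = NULL) {
  stopifnot(is(ensemble, "FJCEnsemble"))
  n <- dim(ensemble@coords)[1L]
  nc <- dim(ensemble@coords)[3L]
  if (is.null(separations))
    separations <- unique(round(exp(seq(log(1), log(n - 1L),
                                        length.out = 24L))))
  separations <- as.integer(separations[separations >= 1 &
                                          separations <= n - 1L])
  perChain <- matrix(NA_real_, nc, length(separations))
  for (cix in seq_len(nc)) {
    x <- ensemble@coords[, , cix]
    perChain[cix, ] <- vapply(separations, function(s) {
      d <- x[seq_len(n - s) + s, , drop = FALSE] -
           x[seq_len(n - s), , drop = FALSE]
      mean(rowSums(d^2))
    }, numeric(1))
  }
  data.frame(s = separations, mean_r2 = colMeans(perChain),
             stderr = apply(perChain, 2L, sd) / sqrt(nc),
             n_samples = nc)
}

#' Contact probability versus backbone separation
#'
#' Fraction of sampled bead pairs at separation \eqn{s} that lie within the
#' capture radius, pooled over windows and chains -- the quantity measured
#' genome-wide by chromosome conformation capture as a function of loop
#' size. For an unconfined ideal chain the large-\eqn{s} decay follows the
#' Gaussian return probability \eqn{P(s) \sim s^{-3/2}}.
#'
#' @param ensemble an \code{\linkS4class{FJCEnsemble}}.
#' @param captureRadius capture radius in lattice units (default 2 bond
#'   lengths).
#' @param separations separations to report; default a log-spaced grid.
#' @return data.frame with columns \code{s}, \code{contact_probability},
#'   \code{n_pairs}, \code{capture_radius}.
#' @export
contactProbability <- function(ensemble, captureRadius = 2,
                               separations = NULL) {
  stopifnot(is(ensemble, "FJCEnsemble"))
  .checkPositive(captureRadius, "captureRadius")
  n <- dim(ensemble@coords)[1L]
  nc <- dim(ensemble@coords)[3L]
  if (is.null(separations))
    separations <- unique(round(exp(seq(log(1), log(n - 1L),
                                        length.out = 24L))))
  separations <- as.integer(separations[separations >= 1 &
                                          separations <= n - 1L])
  r2 <- captureRadius^2
  prob <- vapply(separations, function(s) {
    hits <- 0
    tot <- 0
    for (cix in seq_len(nc)) {
      x <- ensemble@coords[, , cix]
      d <- x[seq_len(n - s) + s, , drop = FALSE] -
           x[seq_len(n - s), , drop = FALSE]
      hits <- hits + sum(rowSums(d^2) < r2)
      tot <- tot + (n - s)
    }
    c(hits / tot, tot)
  }, numeric(2))
  data.frame(s = separations, contact_probability = prob[1L, ],
             n_pairs = prob[2L, ], capture_radius = captureRadius)
}

#' Moment ratio of the intra-chain distance distribution
#'
#' Computes \eqn{\langle r^4\rangle / \langle r^2\rangle^2} of the
#' inter-bead distance distribution at a given backbone separation. The
#' ratio discriminates chain statistics: 1 for a rod (degenerate
#' distribution), 5/3 for a Gaussian chain; by the Cauchy--Schwarz
#' inequality it is always >= 1.
#'
#' @param x an \code{\linkS4class{FJCEnsemble}}, or a numeric vector of
#'   sampled distances.
#' @param separation backbone separation in beads (required for an
#'   ensemble).
#' @return the moment ratio, with attribute \code{"n"} (sample count). A
#'   warning is emitted below 1000 samples (wide-error regime).
#' @examples
#' momentRatio(rep(3, 2000))   # rod: exactly 1
#' @export
momentRatio <- function(x, separation = NULL) {
  if (is(x, "FJCEnsemble")) {
    if (is.null(separation))
      stop("separation is required for an ensemble", call. = FALSE)
    n <- dim(x@coords)[1L]
    s <- as.integer(separation)
    if (s < 1L || s > n - 1L) stop("separation out of range", call. = FALSE)
    d2 <- unlist(lapply(seq_len(dim(x@coords)[3L]), function(cix) {
      xc <- x@coords[, , cix]
      d <- xc[seq_len(n - s) + s, , drop = FALSE] -
           xc[seq_len(n - s), , drop = FALSE]
      rowSums(d^2)
    }))
  } else {
    if (!is.numeric(x)) stop("x must be an ensemble or distances",
                             call. = FALSE)
    d2 <- x^2
  }
  if (length(d2) < 1000L)
    warning("fewer than 1000 samples: moment ratio has wide error",
            call. = FALSE)
  structure(mean(d2^2) / mean(d2)^2, n = length(d2))
}

#' Fit a size-scaling exponent on log-log axes
#'
#' Least-squares fit of \eqn{\log y} against \eqn{\log x}. When \code{y}
#' holds squared sizes (e.g. a \code{mean_r2} profile), set
#' \code{squared = TRUE} so the reported exponent \eqn{\hat\nu} refers to
#' the RMS size (\eqn{R \sim x^{\nu}} with \eqn{R^2 \sim x^{2\nu}}).
#' Benchmarks: 1/2 for an ideal chain (equilibrium-globule interior), 1/3
#' for a density-confined, space-filling (fractal-globule-like) state.
#'
#' @param x predictor (separations or chain sizes), positive.
#' @param y response (sizes or squared sizes), positive; alternatively pass
#'   a profile data.frame with columns \code{s} and \code{mean_r2} as
#'   \code{x} (then \code{y} is taken from it and \code{squared} defaults
#'   to TRUE).
#' @param fitRange optional numeric length-2 range of \code{x} to fit over.
#' @param squared set TRUE when \code{y} holds squared sizes.
#' @return a \code{\linkS4class{ScalingFit}}.
#' @examples
#' f <- fitScalingExponent(1:100, (1:100)^0.5)
#' scalingExponent(f)   # 0.5
#' @export
fitScalingExponent <- function(x, y = NULL, fitRange = NULL,
                               squared = FALSE) {
  if (is.data.frame(x)) {
    if (!all(c("s", "mean_r2") %in% names(x)))
      stop("profile data.frame needs columns 's' and 'mean_r2'",
           call. = FALSE)
    y <- x$mean_r2
    x <- x$s
    squared <- TRUE
  }
  if (is.null(fitRange)) fitRange <- range(x)
  keep <- x >= fitRange[1L] & x <= fitRange[2L]
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 4L)
    stop("need at least 4 points inside the fit range", call. = FALSE)
  if (any(x <= 0) || any(y <= 0))
    stop("log-log fit requires positive data", call. = FALSE)
  fit <- lm(log(y) ~ log(x))
  slope <- coef(fit)[[2L]]
  se <- summary(fit)$coefficients[2L, 2L]
  intercept <- coef(fit)[[1L]]
  scaleDiv <- if (squared) 2 else 1
  new("ScalingFit", exponent = slope / scaleDiv, stderr = se / scaleDiv,
      fitRange = as.numeric(fitRange),
      prefactor = exp(intercept / scaleDiv), nPoints = length(x))
}
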