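## S4 containers for the package's central objects.

#' LatticeChain: a phantom polymer on the simple cubic lattice
#'
#' Ordered bead coordinates on the cubic lattice (unit bond length) together
#' with a per-vertex bending-energy scale. The chain is a phantom: beads may
#' overlap. A chain of \code{n} beads has \code{n - 1} bonds and \code{n - 2}
#' interior vertices; the stiffness map assigns each vertex the bending
#' energy scale \eqn{\epsilon_v} (units of \eqn{k_B T}) entering the bending
#' energy \eqn{E = \sum_v \epsilon_v (1 - \cos\theta_v)}.
#'
#' @slot coords integer matrix, one row per bead, three columns (lattice
#'   units); consecutive rows differ by exactly one unit step along an axis.
#' @slot stiffness numeric vector of per-vertex bending energies, length
#'   \code{nrow(coords) - 2}, all non-negative.
#'
#' @seealso \code{\link{buildChain}}, \code{\link{metropolisSample}}
#' @exportClass LatticeChain
setClass("LatticeChain",
  representation(coords = "matrix", stiffness = "numeric"))

setValidity("LatticeChain", function(object) {
  x <- object@coords
  if (!is.numeric(x) || ncol(x) != 3L)
    return("coords must be a numeric matrix with 3 columns")
  if (nrow(x) < 3L)
    return("a lattice chain needs at least 3 beads (2 bonds)")
  if (any(x != round(x)))
    return("coords must be integer lattice sites")
  d <- diff(x)
  if (any(rowSums(abs(d)) != 1L))
    return("consecutive beads must differ by exactly one unit lattice step")
  if (length(object@stiffness) != nrow(x) - 2L)
    return(sprintf("stiffness map must have length n_beads - 2 = %d",
                   nrow(x) - 2L))
  if (any(object@stiffness < 0))
    return("bending energies must be non-negative")
  TRUE
})

#' ObservableSeries: Monte Carlo observable time series
#'
#' Per-sample observables from a lattice Monte Carlo run: squared end-to-end
#' distance, squared radius of gyration, the tangent autocorrelation
#' \eqn{\langle t_i \cdot t_{i+s}\rangle} versus bond separation \eqn{s}
#' (including \eqn{s = 0}, identically 1), and the per-sample vertex-average
#' \eqn{\langle\cos\theta\rangle}.
#'
#' @slot ree2 numeric, squared end-to-end distance per sample (lattice units^2).
#' @slot rg2 numeric, squared radius of gyration per sample.
#' @slot tangentCorrelation numeric matrix, samples x separations; column
#'   names \code{s0, s1, ...}.
#' @slot meanCosTheta numeric, vertex-averaged bond-angle cosine per sample.
#' @slot nBonds integer, number of bonds of the sampled chain.
#' @slot acceptance named numeric, per-move-class acceptance rates.
#'
#' @seealso \code{\link{metropolisSample}}, \code{\link{tangentCorrelationLp}}
#' @exportClass ObservableSeries
setClass("ObservableSeries",
  representation(ree2 = "numeric", rg2 = "numeric",
                 tangentCorrelation = "matrix", meanCosTheta = "numeric",
                 nBonds = "integer", acceptance = "numeric"))

setValidity("ObservableSeries", function(object) {
  n <- length(object@ree2)
  if (length(object@rg2) != n || nrow(object@tangentCorrelation) != n)
    return("ree2, rg2 and tangentCorrelation must agree in sample count")
  if (any(object@ree2 < 0) || any(object@rg2 < 0))
    return("squared sizes must be non-negative")
  if (any(abs(object@tangentCorrelation[, 1L] - 1) > 1e-12))
    return("tangent correlation at s = 0 must be 1")
  TRUE
})

#' CompactionResult: locus compaction and Flory amplification
#'
#' Holds the ratio of final to initial mean-square end-to-end distance of a
#' gene locus, the corresponding percent decrease in RMS size, and the
#' fold-change in binary intra-locus interactions implied by the Flory
#' argument (\eqn{n_b \sim c^2}, \eqn{c \sim 1/V}, spherical symmetry
#' \eqn{V \propto \langle R^2\rangle^{3/2}}), i.e. the -3/2... power of the
#' squared-size ratio squared: \code{nbRatio = r2Ratio^(-3)}.
#'
#' @slot r2Ratio final/initial mean-square end-to-end distance (dimensionless).
#' @slot nbRatio final/initial number of binary interactions.
#' @slot percentCompaction percent decrease in RMS end-to-end distance.
#'
#' @seealso \code{\link{floryAmplification}}
#' @exportClass CompactionResult
setClass("CompactionResult",
  representation(r2Ratio = "numeric", nbRatio = "numeric",
                 percentCompaction = "numeric"))

setValidity("CompactionResult", function(object) {
  if (object@r2Ratio <= 0) return("r2Ratio must be positive")
  if (abs(object@nbRatio - object@r2Ratio^(-3)) >
      1e-9 * max(1, object@nbRatio))
    return("nbRatio must equal r2Ratio^(-3)")
  if (abs(object@percentCompaction - 100 * (1 - sqrt(object@r2Ratio))) > 1e-9)
    return("percentCompaction must equal 100*(1 - sqrt(r2Ratio))")
  TRUE
})

#' TwoAngleSpec: two-angle chromatin fiber specification
#'
#' Parameters of the two-angle model of the nucleosome fiber: the linker
#' entry--exit angle \eqn{\alpha} (degrees; 180 means no kink, i.e. a
#' straight fiber), the rotation \eqn{\beta} between consecutive nucleosomes
#' about the incoming linker (degrees; derived from the linker length via the
#' DNA helical repeat unless overridden), and the linker length in base
#' pairs.
#'
#' @slot alpha entry--exit angle in degrees, in (0, 180] (0 allowed but
#'   immediately sterically degenerate).
#' @slot beta inter-nucleosome rotation in degrees, in [0, 360).
#' @slot linkerBp linker DNA length in base pairs.
#' @slot nNucleosomes number of nucleosomes (>= 2).
#' @slot nucleosomeDiameter nucleosome diameter in nm (default 11).
#' @slot dnaRise DNA rise in nm/bp (default 0.34).
#' @slot helicalRepeat DNA helical repeat in bp/turn (default 10.5).
#'
#' @seealso \code{\link{twoAngleSpec}}, \code{\link{buildFiber}}
#' @exportClass TwoAngleSpec
setClass("TwoAngleSpec",
  representation(alpha = "numeric", beta = "numeric", linkerBp = "numeric",
                 nNucleosomes = "integer", nucleosomeDiameter = "numeric",
                 dnaRise = "numeric", helicalRepeat = "numeric"))

setValidity("TwoAngleSpec", function(object) {
  if (object@alpha < 0 || object@alpha > 180)
    return("alpha must lie in [0, 180] degrees")
  if (object@beta < 0 || object@beta >= 360)
    return("beta must lie in [0, 360) degrees")
  if (object@linkerBp < 0) return("linkerBp must be non-negative")
  if (object@nNucleosomes < 2L) return("need at least 2 nucleosomes")
  if (object@nucleosomeDiameter < 0) return("nucleosomeDiameter must be >= 0")
  if (object@dnaRise <= 0 || object@helicalRepeat <= 0)
    return("dnaRise and helicalRepeat must be positive")
  TRUE
})

#' FiberGeometry: a constructed two-angle nucleosome fiber
#'
#' Deterministic output of \code{\link{buildFiber}}: nucleosome centers in nm
#' connected by straight linker segments of identical length.
#'
#' @slot centers numeric matrix of nucleosome centers (nm), one row per
#'   nucleosome.
#' @slot linkerLength linker segment length in nm
#'   (\code{linkerBp * dnaRise}).
#' @slot spec the \code{\linkS4class{TwoAngleSpec}} that generated it.
#'
#' @seealso \code{\link{fiberMetrics}}, \code{\link{detectClashes}}
#' @exportClass FiberGeometry
setClass("FiberGeometry",
  representation(centers = "matrix", linkerLength = "numeric",
                 spec = "TwoAngleSpec"))

setValidity("FiberGeometry", function(object) {
  if (ncol(object@centers) != 3L) return("centers must be n x 3")
  if (nrow(object@centers) != object@spec@nNucleosomes)
    return("center count must match spec nNucleosomes")
  d <- sqrt(rowSums(diff(object@centers)^2))
  if (any(abs(d - object@linkerLength) > 1e-9))
    return("consecutive centers must be one linker length apart (1e-9 nm)")
  TRUE
})

#' LoopTopology: backbone plus random long-range harmonic bonds
#'
#' A linear Gaussian backbone of \code{nBeads} beads decorated with a set of
#' extra harmonic bonds (the loops) between bead pairs separated by at least
#' \code{minLoopSeparation} along the backbone. At a granularity of
#' \code{bpPerBead} base pairs per bead, the default cutoff of 15 beads at
#' 10 kbp/bead encodes loops at all genomic scales above 150 kbp.
#'
#' @slot nBeads number of backbone beads.
#' @slot extraBonds integer matrix with two columns (i < j, 1-based), one row
#'   per loop bond; may have zero rows.
#' @slot loopProbability per-eligible-pair inclusion probability used to draw
#'   the bonds (NA when the topology was built by hand).
#' @slot minLoopSeparation minimum backbone separation of a loop bond (beads).
#' @slot bpPerBead base pairs per bead.
#'
#' @seealso \code{\link{randomLoopTopology}}, \code{\link{gaussianDistanceMatrix}}
#' @exportClass LoopTopology
setClass("LoopTopology",
  representation(nBeads = "integer", extraBonds = "matrix",
                 loopProbability = "numeric", minLoopSeparation = "integer",
                 bpPerBead = "numeric"))

setValidity("LoopTopology", function(object) {
  b <- object@extraBonds
  if (ncol(b) != 2L) return("extraBonds must have two columns")
  if (nrow(b) > 0L) {
    if (any(b < 1L) || any(b > object@nBeads))
      return("bond indices out of range")
    if (any(b[, 2L] - b[, 1L] < object@minLoopSeparation))
      return("loop bonds must respect the minimum separation")
    if (anyDuplicated(paste(b[, 1L], b[, 2L])))
      return("duplicate loop bonds")
  }
  TRUE
})

#' FJCEnsemble: an ensemble of lattice random-walk conformations
#'
#' Freely-jointed (lattice random walk) chains, either unconfined or
#' confined to a cubic box with reflecting walls at a fixed bead density
#' (the confined construction used for fractal-globule-like scaling).
#'
#' @slot coords numeric array \code{nBeads x 3 x nChains} of bead positions
#'   (lattice units).
#' @slot mode \code{"unconfined"} or \code{"confined"}.
#' @slot boxSize box side in lattice units (NA when unconfined).
#' @slot density beads per lattice site (NA when unconfined).
#'
#' @seealso \code{\link{fjcEnsemble}}, \code{\link{contactProbability}}
#' @exportClass FJCEnsemble
setClass("FJCEnsemble",
  representation(coords = "array", mode = "character", boxSize = "numeric",
                 density = "numeric"))

setValidity("FJCEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2L] != 3L)
    return("coords must be an nBeads x 3 x nChains array")
  if (!object@mode %in% c("unconfined", "confined"))
    return("mode must be 'unconfined' or 'confined'")
  if (object@mode == "confined") {
    if (!is.finite(object@boxSize) || object@boxSize < 1)
      return("confined ensembles need a box size >= 1")
    if (any(object@coords < 0) || any(object@coords > object@boxSize - 1))
      return("confined beads must lie inside the box")
  }
  TRUE
})

#' ScalingFit: a fitted size-scaling exponent
#'
#' Result of a least-squares fit of \eqn{\log y} against \eqn{\log x},
#' reporting the scaling exponent \eqn{\hat\nu} with its standard error, the
#' fit range, and the prefactor.
#'
#' @slot exponent fitted exponent.
#' @slot stderr standard error of the exponent.
#' @slot fitRange numeric length-2, range of x used.
#' @slot prefactor fitted prefactor (y at x = 1).
#' @slot nPoints number of points in the fit.
#'
#' @seealso \code{\link{fitScalingExponent}}
#' @exportClass ScalingFit
setClass("ScalingFit",
  representation(exponent = "numeric", stderr = "numeric",
                 fitRange = "numeric", prefactor = "numeric",
                 nPoints = "integer"))

setValidity("ScalingFit", function(object) {
  if (!is.finite(object@exponent)) return("exponent must be finite")
  if (length(object@fitRange) != 2L) return("fitRange must have length 2")
  TRUE
})
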