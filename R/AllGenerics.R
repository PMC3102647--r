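## Generics and accessor/show methods.

#' @name chromfold-accessors
#' @title Accessors for chromfold S4 classes
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots with \code{@}.
#' @param x,object an object of the documented class.
#' @param i chain index (for \code{chainCoords}).
#' @return the corresponding slot value.
NULL

#' @rdname chromfold-accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname chromfold-accessors
#' @export
setGeneric("stiffnessMap", function(x) standardGeneric("stiffnessMap"))
#' @rdname chromfold-accessors
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))
#' @rdname chromfold-accessors
#' @export
setGeneric("nBonds", function(x) standardGeneric("nBonds"))
#' @rdname chromfold-accessors
#' @export
setGeneric("ree2", function(x) standardGeneric("ree2"))
#' @rdname chromfold-accessors
#' @export
setGeneric("rg2", function(x) standardGeneric("rg2"))
#' @rdname chromfold-accessors
#' @export
setGeneric("tangentCorrelation", function(x) standardGeneric("tangentCorrelation"))
#' @rdname chromfold-accessors
#' @export
setGeneric("meanCosTheta", function(x) standardGeneric("meanCosTheta"))
#' @rdname chromfold-accessors
#' @export
setGeneric("r2Ratio", function(x) standardGeneric("r2Ratio"))
#' @rdname chromfold-accessors
#' @export
setGeneric("nbRatio", function(x) standardGeneric("nbRatio"))
#' @rdname chromfold-accessors
#' @export
setGeneric("percentCompaction", function(x) standardGeneric("percentCompaction"))
#' @rdname chromfold-accessors
#' @export
setGeneric("nucleosomeCenters", function(x) standardGeneric("nucleosomeCenters"))
#' @rdname chromfold-accessors
#' @export
setGeneric("linkerSegments", function(x) standardGeneric("linkerSegments"))
#' @rdname chromfold-accessors
#' @export
setGeneric("extraBonds", function(x) standardGeneric("extraBonds"))
#' @rdname chromfold-accessors
#' @export
setGeneric("chainCoords", function(x, i) standardGeneric("chainCoords"))
#' @rdname chromfold-accessors
#' @export
setGeneric("nChains", function(x) standardGeneric("nChains"))
#' @rdname chromfold-accessors
#' @export
setGeneric("scalingExponent", function(x) standardGeneric("scalingExponent"))
#' @rdname chromfold-accessors
#' @export
setGeneric("exponentStderr", function(x) standardGeneric("exponentStderr"))

#' @rdname chromfold-accessors
#' @export
setMethod("coords", "LatticeChain", function(x) x@coords)
#' @rdname chromfold-accessors
#' @export
setMethod("stiffnessMap", "LatticeChain", function(x) x@stiffness)
#' @rdname chromfold-accessors
#' @export
setMethod("nBeads", "LatticeChain", function(x) nrow(x@coords))
#' @rdname chromfold-accessors
#' @export
setMethod("nBonds", "LatticeChain", function(x) nrow(x@coords) - 1L)

#' @rdname chromfold-accessors
#' @export
setMethod("ree2", "ObservableSeries", function(x) x@ree2)
#' @rdname chromfold-accessors
#' @export
setMethod("rg2", "ObservableSeries", function(x) x@rg2)
#' @rdname chromfold-accessors
#' @export
setMethod("tangentCorrelation", "ObservableSeries", function(x) x@tangentCorrelation)
#' @rdname chromfold-accessors
#' @export
setMethod("meanCosTheta", "ObservableSeries", function(x) x@meanCosTheta)
#' @rdname chromfold-accessors
#' @export
setMethod("nBonds", "ObservableSeries", function(x) x@nBonds)

#' @rdname chromfold-accessors
#' @export
setMethod("r2Ratio", "CompactionResult", function(x) x@r2Ratio)
#' @rdname chromfold-accessors
#' @export
setMethod("nbRatio", "CompactionResult", function(x) x@nbRatio)
#' @rdname chromfold-accessors
#' @export
setMethod("percentCompaction", "CompactionResult", function(x) x@percentCompaction)

#' @rdname chromfold-accessors
#' @export
setMethod("nucleosomeCenters", "FiberGeometry", function(x) x@centers)
#' @rdname chromfold-accessors
#' @export
setMethod("linkerSegments", "FiberGeometry", function(x) {
  n <- nrow(x@centers)
  list(from = x@centers[-n, , drop = FALSE], to = x@centers[-1L, , drop = FALSE])
})

#' @rdname chromfold-accessors
#' @export
setMethod("nBeads", "LoopTopology", function(x) x@nBeads)
#' @rdname chromfold-accessors
#' @export
setMethod("extraBonds", "LoopTopology", function(x) x@extraBonds)

#' @rdname chromfold-accessors
#' @export
setMethod("nBeads", "FJCEnsemble", function(x) dim(x@coords)[1L])
#' @rdname chromfold-accessors
#' @export
setMethod("nChains", "FJCEnsemble", function(x) dim(x@coords)[3L])
#' @rdname chromfold-accessors
#' @export
setMethod("chainCoords", "FJCEnsemble", function(x, i) x@coords[, , i])

#' @rdname chromfold-accessors
#' @export
setMethod("scalingExponent", "ScalingFit", function(x) x@exponent)
#' @rdname chromfold-accessors
#' @export
setMethod("exponentStderr", "ScalingFit", function(x) x@stderr)

setMethod("show", "LatticeChain", function(object) {
  cat(sprintf("LatticeChain: %d beads (%d bonds), stiffness in [%g, %g] kBT\n",
              nrow(object@coords), nrow(object@coords) - 1L,
              min(object@stiffness), max(object@stiffness)))
})

setMethod("show", "ObservableSeries", function(object) {
  cat(sprintf(
    "ObservableSeries: %d samples of a %d-bond chain\n  <Ree2> = %.4g  <Rg2> = %.4g  <cos theta> = %.4g\n",
    length(object@ree2), object@nBonds, mean(object@ree2),
    mean(object@rg2), mean(object@meanCosTheta)))
})

setMethod("show", "CompactionResult", function(object) {
  cat(sprintf(
    "CompactionResult: <R2> ratio %.4g -> %.1f%% RMS compaction, %.4g-fold change in binary interactions\n",
    object@r2Ratio, object@percentCompaction, object@nbRatio))
})

setMethod("show", "TwoAngleSpec", function(object) {
  cat(sprintf(
    "TwoAngleSpec: alpha = %g deg, beta = %g deg (linker %g bp), %d nucleosomes\n",
    object@alpha, object@beta, object@linkerBp, object@nNucleosomes))
})

setMethod("show", "FiberGeometry", function(object) {
  cat(sprintf("FiberGeometry: %d nucleosomes, linker %.3g nm (alpha %g, beta %g)\n",
              nrow(object@centers), object@linkerLength,
              object@spec@alpha, object@spec@beta))
})

setMethod("show", "LoopTopology", function(object) {
  cat(sprintf(
    "LoopTopology: %d beads, %d loop bonds (min separation %d beads, %g bp/bead)\n",
    object@nBeads, nrow(object@extraBonds), object@minLoopSeparation,
    object@bpPerBead))
})

setMethod("show", "FJCEnsemble", function(object) {
  cat(sprintf("FJCEnsemble: %d chains of %d beads, %s%s\n",
              dim(object@coords)[3L], dim(object@coords)[1L], object@mode,
              if (object@mode == "confined")
                sprintf(" (box %g, density %.3g)", object@boxSize,
                        object@density) else ""))
})

setMethod("show", "ScalingFit", function(object) {
  cat(sprintf("ScalingFit: exponent %.4f +/- %.4f over [%g, %g] (%d points)\n",
              object@exponent, object@stderr, object@fitRange[1L],
              object@fitRange[2L], object@nPoints))
})
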