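## Freely-jointed-chain folding-index framework: contour length, folded
## size, scaling exponent and persistence length tied together by a
## dimensionless folding index.

#' Freely-jointed-chain summary at a given organization level
#'
#' Describes a chain of contour length \eqn{L_c} as a freely jointed chain
#' of \eqn{N_r = L_c / (2 L_p)} Kuhn segments of length \eqn{l = 2 L_p},
#' with characteristic folded size \eqn{C_s = 2 L_p N_r^{\nu}} where the
#' scaling exponent \eqn{\nu} is the inverse of the fractal dimension
#' (\eqn{\nu = 1/3} for a space-filling, fractal-globule-like organization;
#' \eqn{\nu = 1/2} for an ideal chain; \eqn{\nu = 1} for a rod). The
#' folding index is \eqn{\Phi = L_c / C_s = N_r^{1-\nu}}.
#'
#' For the human genome at the naked-dsDNA level (\eqn{L_p} = 50 nm,
#' \eqn{L_c \approx} 2 m, \eqn{\nu = 1/3}) this gives \eqn{N_r = 2\times
#' 10^7} and a folded size of about 27 um -- the scale of a cell nucleus.
#'
#' @param persistenceLength \eqn{L_p} in nm (> 0).
#' @param nu scaling exponent, in (0, 1].
#' @param contourLength \eqn{L_c} in nm (>= \code{2 * persistenceLength},
#'   i.e. at least one Kuhn segment).
#' @return a named list with elements \code{nRepeat}, \code{kuhnLength}
#'   (nm), \code{nu}, \code{fjcSize} (nm), \code{foldingIndex},
#'   \code{fractalDimension}, \code{contourLength} (nm).
#' @examples
#' fjcSummary(50, 1/3, 2e9)   # human genome worked example (2 m of dsDNA)
#' @export
fjcSummary <- function(persistenceLength, nu, contourLength) {
  .checkPositive(persistenceLength, "persistenceLength")
  .checkPositive(contourLength, "contourLength")
  .checkNu(nu, allowOne = TRUE)
  if (contourLength < 2 * persistenceLength)
    stop("contourLength must be at least one Kuhn segment (2 * Lp)",
         call. = FALSE)
  nr <- contourLength / (2 * persistenceLength)
  cs <- 2 * persistenceLength * nr^nu
  list(nRepeat = nr,
       kuhnLength = 2 * persistenceLength,
       nu = nu,
       fjcSize = cs,
       foldingIndex = nr^(1 - nu),
       fractalDimension = 1 / nu,
       contourLength = contourLength)
}

#' Folding index from contour length and folded size
#'
#' The folding index \eqn{\Phi = L_c / C_s} compares the fully extended
#' contour length to the folded size. The contour length may be given
#' directly in nm, or as a genomic distance in base pairs which is converted
#' via the linear mass density \eqn{c} (bp/nm): \eqn{L_c = d / c}. Since
#' \eqn{L_c = d/c}, the folding index increases as the linear mass density
#' decreases. Two meters of dsDNA folded into a 25-um nucleus give
#' \eqn{\Phi = 8 \times 10^4}.
#'
#' @param size folded size \eqn{C_s} in nm (> 0).
#' @param contourLength contour length in nm; omit if \code{genomicBp} given.
#' @param genomicBp genomic distance in bp (alternative to
#'   \code{contourLength}).
#' @param linearMassDensity linear mass density in bp/nm used to convert
#'   \code{genomicBp}; default 2.94 bp/nm (naked B-DNA).
#' @return dimensionless folding index.
#' @examples
#' foldingIndexFromSizes(25e3, contourLength = 2e9)        # 8e4
#' foldingIndexFromSizes(25e3, genomicBp = 6e9)            # via d / c
#' @export
foldingIndexFromSizes <- function(size, contourLength = NULL,
                                  genomicBp = NULL,
                                  linearMassDensity = 2.94) {
  .checkPositive(size, "size")
  if (is.null(contourLength)) {
    if (is.null(genomicBp))
      stop("supply either contourLength (nm) or genomicBp", call. = FALSE)
    .checkPositive(genomicBp, "genomicBp")
    .checkPositive(linearMassDensity, "linearMassDensity")
    contourLength <- genomicBp / linearMassDensity
  } else {
    .checkPositive(contourLength, "contourLength")
  }
  contourLength / size
}

#' Persistence length as a function of the folding index
#'
#' Inverts the folding-index relation at fixed folded size. With the folded
#' size pinned to the nuclear size \eqn{C_{s,0}} (about 25 um for a human
#' nucleus) the number of Kuhn segments is \eqn{N_r = (C_{s,0}/2L_p)^{1/\nu}}
#' and \eqn{\Phi = N_r^{1-\nu} = (C_{s,0}/2L_p)^{(1-\nu)/\nu}}, so
#' \deqn{L_p = \frac{C_{s,0}}{2}\,\Phi^{-\nu/(1-\nu)},}
#' which for \eqn{\nu = 1/3} is \eqn{L_p = C_{s,0}/(2\sqrt{\Phi})} (i.e.
#' \eqn{\Phi = (C_{s,0}/2L_p)^2}). The folding index acts as a lens of
#' variable resolution: larger \eqn{\Phi} probes finer organization levels
#' with shorter persistence lengths.
#'
#' @param foldingIndex \eqn{\Phi} (>= 1). Vectorized.
#' @param nuclearSize invariant folded size \eqn{C_{s,0}} in nm (default
#'   25000 nm = 25 um).
#' @param nu scaling exponent in (0, 1); \eqn{\nu = 1} is degenerate (a rod
#'   never folds) and is rejected.
#' @return persistence length in nm.
#' @examples
#' persistenceFromFolding(6.25e4)    # 50 nm at the naked-DNA level
#' persistenceFromFolding(1)         # Cs0 / 2: one Kuhn segment spans the nucleus
#' @export
persistenceFromFolding <- function(foldingIndex, nuclearSize = 25e3,
                                   nu = 1 / 3) {
  if (any(!is.finite(foldingIndex)) || any(foldingIndex < 1))
    stop("foldingIndex must be finite and >= 1", call. = FALSE)
  .checkPositive(nuclearSize, "nuclearSize")
  .checkNu(nu, allowOne = FALSE)
  (nuclearSize / 2) * foldingIndex^(-nu / (1 - nu))
}

#' Persistence-length versus folding-index curve
#'
#' Tabulates the persistence length/folding index relation at fixed nuclear
#' size over a range of persistence lengths (log-spaced), the curve that
#' summarizes how the observable correlation length shrinks as the genome
#' is viewed at ever finer folding resolution.
#'
#' @param lpMin,lpMax persistence-length range in nm (> 0).
#' @param n number of points (default 200).
#' @param nuclearSize invariant folded size \eqn{C_{s,0}} in nm.
#' @param nu scaling exponent in (0, 1).
#' @return data.frame with columns \code{lp_nm}, \code{n_repeat},
#'   \code{phi}, \code{cs_nm}.
#' @examples
#' head(foldingCurve(1, 1000, n = 5))
#' @export
foldingCurve <- function(lpMin, lpMax, n = 200L, nuclearSize = 25e3,
                         nu = 1 / 3) {
  .checkPositive(lpMin, "lpMin")
  .checkPositive(lpMax, "lpMax")
  if (lpMax < lpMin) stop("lpMax must be >= lpMin", call. = FALSE)
  .checkNu(nu, allowOne = FALSE)
  lp <- exp(seq(log(lpMin), log(lpMax), length.out = n))
  nr <- (nuclearSize / (2 * lp))^(1 / nu)
  data.frame(lp_nm = lp, n_repeat = nr, phi = nr^(1 - nu),
             cs_nm = rep(nuclearSize, length(lp)))
}

.checkNu <- function(nu, allowOne) {
  ok <- is.numeric(nu) && length(nu) == 1L && is.finite(nu) && nu > 0 &&
    (nu < 1 || (allowOne && nu == 1))
  if (!ok)
    stop(sprintf("nu must lie in (0, 1%s", if (allowOne) "]" else ")"),
         call. = FALSE)
  invisible(TRUE)
}
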