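## Deterministic two-angle geometry of nucleosome fibers: construction by
## local-frame propagation, steric clash detection, packing ratio and
## fiber-size statistics.
##
## Frame convention: nucleosomes are spheres at kink vertices connected by
## straight linkers. alpha is the linker entry-exit angle with the
## supplement convention (alpha = 180 deg means no kink, a straight fiber);
## beta is applied as a right-handed rotation about the incoming linker
## direction before the alpha kink is applied.

#' Inter-nucleosome rotation from the linker length
#'
#' The rotation \eqn{\beta} between consecutive nucleosomes is set by the
#' torsion of the linker DNA: each base pair advances the helix by
#' \eqn{360/\textrm{repeat}} degrees, so
#' \eqn{\beta = 360 (L \bmod \textrm{repeat}) / \textrm{repeat}} mapped to
#' [0, 360). Linkers that are whole multiples of the helical repeat give
#' \eqn{\beta = 0}.
#'
#' @param linkerBp linker length in base pairs (>= 0). Vectorized.
#' @param helicalRepeat DNA helical repeat in bp/turn (default 10.5).
#' @return rotation angle in degrees, in [0, 360).
#' @examples
#' betaFromLinker(21)    # 0: exact two turns
#' betaFromLinker(26)    # 360 * 5 / 10.5 = 171.43
#' @export
betaFromLinker <- function(linkerBp, helicalRepeat = 10.5) {
  if (any(!is.finite(linkerBp)) || any(linkerBp < 0))
    stop("linkerBp must be finite and >= 0", call. = FALSE)
  .checkPositive(helicalRepeat, "helicalRepeat")
  (360 * (linkerBp %% helicalRepeat) / helicalRepeat) %% 360
}

#' Construct a two-angle fiber specification
#'
#' @param alpha linker entry--exit angle in degrees, (0, 180]; 180 is a
#'   straight fiber. \code{alpha = 0} is accepted but immediately clashes.
#' @param nNucleosomes number of nucleosomes (>= 2).
#' @param linkerBp linker length in bp; sets \code{beta} through
#'   \code{\link{betaFromLinker}} unless \code{beta} is given explicitly.
#' @param beta optional explicit rotation in degrees (mapped to [0, 360)).
#' @param nucleosomeDiameter nucleosome diameter in nm (default 11).
#' @param dnaRise DNA rise in nm/bp (default 0.34).
#' @param helicalRepeat DNA helical repeat in bp/turn (default 10.5).
#' @return a \code{\linkS4class{TwoAngleSpec}}.
#' @examples
#' twoAngleSpec(35, nNucleosomes = 50, linkerBp = 44)
#' @export
twoAngleSpec <- function(alpha, nNucleosomes, linkerBp, beta = NULL,
                         nucleosomeDiameter = 11, dnaRise = 0.34,
                         helicalRepeat = 10.5) {
  if (is.null(beta)) beta <- betaFromLinker(linkerBp, helicalRepeat)
  new("TwoAngleSpec", alpha = as.numeric(alpha),
      beta = as.numeric(beta) %% 360, linkerBp = as.numeric(linkerBp),
      nNucleosomes = as.integer(nNucleosomes),
      nucleosomeDiameter = as.numeric(nucleosomeDiameter),
      dnaRise = as.numeric(dnaRise),
      helicalRepeat = as.numeric(helicalRepeat))
}

#' Build the 3D geometry of a two-angle fiber
#'
#' Deterministic construction by propagating an orthonormal local frame
#' (t, n, b) along the fiber. Each step advances one straight linker of
#' length \code{linkerBp * dnaRise} along t; at each interior nucleosome
#' the frame is first rolled by \eqn{\beta} about the incoming linker
#' direction t and then kinked in the (t, n) plane by the deflection
#' \eqn{\delta = 180 - \alpha} degrees. The output is fully reproducible
#' from the specification.
#'
#' @param spec a \code{\linkS4class{TwoAngleSpec}}.
#' @return a \code{\linkS4class{FiberGeometry}} with nucleosome centers in
#'   nm, starting at the origin with the first linker along +x.
#' @examples
#' f <- buildFiber(twoAngleSpec(180, 10, linkerBp = 60, beta = 0))
#' nucleosomeCenters(f)[1:3, ]   # collinear: straight beads-on-a-string
#' @export
buildFiber <- function(spec) {
  stopifnot(is(spec, "TwoAngleSpec"))
  validObject(spec)
  n <- spec@nNucleosomes
  L <- spec@linkerBp * spec@dnaRise
  if (L <= 0)
    stop("linker length must be positive to build a fiber", call. = FALSE)
  delta <- (180 - spec@alpha) * pi / 180
  betar <- spec@beta * pi / 180

  centers <- matrix(0, n, 3)
  tv <- c(1, 0, 0)
  nv <- c(0, 1, 0)
  bv <- c(0, 0, 1)
  for (k in 2:n) {
    centers[k, ] <- centers[k - 1L, ] + L * tv
    if (k < n) {
      ## roll the kink plane about the incoming linker axis
      n2 <- cos(betar) * nv + sin(betar) * bv
      b2 <- cos(betar) * bv - sin(betar) * nv
      ## kink by the deflection angle in the (t, n) plane
      t2 <- cos(delta) * tv + sin(delta) * n2
      nv <- -sin(delta) * tv + cos(delta) * n2
      tv <- t2
      bv <- b2
    }
  }
  fiber <- new("FiberGeometry", centers = centers, linkerLength = L,
               spec = spec)
  if (spec@alpha == 0 && spec@nucleosomeDiameter > 0)
    warning("alpha = 0 folds the fiber back onto itself: ",
            "immediate steric clash; geometry returned as constructed",
            call. = FALSE)
  fiber
}

#' Detect steric clashes between nucleosomes
#'
#' Lists all unordered nucleosome pairs (backbone separation >= 2) whose
#' center distance is below the given diameter. An empty result means the
#' conformation is sterically permissible for spherical nucleosomes of
#' that diameter.
#'
#' @param fiber a \code{\linkS4class{FiberGeometry}}.
#' @param diameter clash distance in nm; defaults to the spec's nucleosome
#'   diameter.
#' @return integer matrix with columns \code{i}, \code{j} (i < j), one row
#'   per clashing pair; zero rows when clash-free.
#' @export
detectClashes <- function(fiber, diameter = NULL) {
  stopifnot(is(fiber, "FiberGeometry"))
  if (is.null(diameter)) diameter <- fiber@spec@nucleosomeDiameter
  .checkPositive(diameter, "diameter")
  d <- as.matrix(dist(fiber@centers))
  n <- nrow(d)
  idx <- which(upper.tri(d) & d < diameter, arr.ind = TRUE)
  if (nrow(idx) > 0L) idx <- idx[idx[, 2L] - idx[, 1L] >= 2L, , drop = FALSE]
  out <- cbind(i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L]))
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

#' Packing ratio, fiber diameter and clash summary
#'
#' Computes standard compaction measures of a constructed fiber. The fiber
#' axis is estimated as the path of sliding-window centroids of the
#' nucleosome centers (window default 5). The packing ratio is the number
#' of nucleosomes per 11 nm of axis arc length, computed as
#' \code{11 * (axis intervals) / (axis arc length)} (one nucleosome per
#' axis interval); for a straight fiber with center spacing \eqn{L} this is
#' exactly \eqn{11 / L}. The fiber diameter is twice the maximal radial
#' distance of any center from the axis polyline plus the nucleosome
#' diameter, so a straight fiber has diameter equal to the nucleosome
#' diameter.
#'
#' @param fiber a \code{\linkS4class{FiberGeometry}} with at least
#'   \code{window + 1} nucleosomes.
#' @param window sliding-window width for the axis estimate (default 5).
#' @return a list with \code{packingRatio} (nucleosomes per 11 nm),
#'   \code{fiberDiameter} (nm), \code{axis} (matrix of axis points),
#'   \code{arcLength} (nm), and \code{clashes} (as
#'   \code{\link{detectClashes}}).
#' @export
fiberMetrics <- function(fiber, window = 5L) {
  stopifnot(is(fiber, "FiberGeometry"))
  x <- fiber@centers
  n <- nrow(x)
  window <- as.integer(window)
  if (n < window + 1L)
    stop(sprintf(
      "axis undefined: need more nucleosomes (%d) than the window (%d)",
      n, window), call. = FALSE)
  nAxis <- n - window + 1L
  axis <- vapply(seq_len(nAxis), function(j)
    colMeans(x[j:(j + window - 1L), , drop = FALSE]), numeric(3))
  axis <- t(axis)
  seg <- diff(axis)
  arcLength <- sum(sqrt(rowSums(seg^2)))
  if (arcLength <= 0)
    stop("degenerate axis: zero arc length", call. = FALSE)
  packingRatio <- 11 * (nAxis - 1L) / arcLength
  radial <- vapply(seq_len(n), function(i)
    .distToPolyline(x[i, ], axis), numeric(1))
  list(packingRatio = packingRatio,
       fiberDiameter = 2 * max(radial) + fiber@spec@nucleosomeDiameter,
       axis = axis, arcLength = arcLength,
       clashes = detectClashes(fiber))
}

## minimum distance from point p to the polyline given by rows of ax;
## the first and last segments are extended to infinity so that points
## beyond the smoothed-axis ends are measured radially, not to the tip
.distToPolyline <- function(p, ax) {
  a <- ax[-nrow(ax), , drop = FALSE]
  b <- ax[-1L, , drop = FALSE]
  ab <- b - a
  ap <- sweep(a, 2L, p, function(x, y) y - x)  # p - a
  tt <- rowSums(ap * ab) / pmax(rowSums(ab^2), .Machine$double.eps)
  lo <- c(-Inf, rep(0, nrow(a) - 1L))
  hi <- c(rep(1, nrow(a) - 1L), Inf)
  tt <- pmin(pmax(tt, lo), hi)
  proj <- a + ab * tt
  sqrt(min(rowSums(sweep(proj, 2L, p)^2)))
}
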