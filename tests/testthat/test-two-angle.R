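# Two-angle fiber geometry: rotation from linker length, construction
# invariants, closed forms for the straight fiber, clash detection and
# rigid-motion invariance of the metrics.

test_that("beta follows the linker length through the helical repeat", {
  expect_equal(betaFromLinker(21), 0)        # exactly two helical turns
  expect_equal(betaFromLinker(0), 0)
  expect_equal(betaFromLinker(26), 360 * 5 / 10.5, tolerance = 1e-12)
  # periodicity in the helical repeat
  expect_equal(betaFromLinker(26 + 10.5), betaFromLinker(26),
               tolerance = 1e-9)
  expect_error(betaFromLinker(-1), ">= 0")
})

test_that("a straight fiber obeys its closed forms exactly", {
  spec <- twoAngleSpec(180, 10, linkerBp = 20, beta = 0)
  fib <- buildFiber(spec)
  x <- nucleosomeCenters(fib)
  L <- 20 * 0.34
  # collinear, evenly spaced
  expect_equal(x[, 2], rep(0, 10))
  expect_equal(x[, 3], rep(0, 10))
  expect_equal(diff(x[, 1]), rep(L, 9), tolerance = 1e-12)
  m <- fiberMetrics(fib)
  expect_equal(m$packingRatio, 11 / L, tolerance = 1e-12)
  expect_equal(m$fiberDiameter, 11, tolerance = 1e-9)
  expect_equal(nrow(m$clashes), 0L)
  # doubling the linker halves the packing ratio
  m2 <- fiberMetrics(buildFiber(twoAngleSpec(180, 10, 40, beta = 0)))
  expect_equal(m2$packingRatio, m$packingRatio / 2, tolerance = 1e-12)
})

test_that("every consecutive-center distance equals the linker length", {
  grid <- expand.grid(alpha = c(30, 60, 90, 120, 179),
                      linker = c(20, 44, 61))
  for (i in seq_len(nrow(grid))) {
    fib <- buildFiber(twoAngleSpec(grid$alpha[i], 25, grid$linker[i]))
    d <- sqrt(rowSums(diff(nucleosomeCenters(fib))^2))
    expect_lt(max(abs(d - grid$linker[i] * 0.34)), 1e-9)
  }
})

test_that("the planar zigzag matches the hand-computed geometry", {
  # alpha = 90, beta = 180: kink plane flips each step -> planar zigzag
  fib <- buildFiber(twoAngleSpec(90, 4, 20, beta = 180))
  x <- nucleosomeCenters(fib)
  L <- 20 * 0.34
  byHand <- rbind(c(0, 0, 0), c(L, 0, 0), c(L, -L, 0), c(2 * L, -L, 0))
  expect_equal(x, byHand, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sqrt(sum((x[4, ] - x[1, ])^2)), L * sqrt(5),
               tolerance = 1e-9)
})

test_that("fibers are deterministic and periodic in beta", {
  a <- nucleosomeCenters(buildFiber(twoAngleSpec(75, 30, 44)))
  b <- nucleosomeCenters(buildFiber(twoAngleSpec(75, 30, 44)))
  expect_identical(a, b)
  # beta and beta + 360 are the same fiber
  c1 <- nucleosomeCenters(buildFiber(twoAngleSpec(75, 30, 44, beta = 95)))
  c2 <- nucleosomeCenters(buildFiber(twoAngleSpec(75, 30, 44,
                                                  beta = 95 + 360)))
  expect_equal(c1, c2, tolerance = 1e-12)
  # linker + one helical repeat gives the same beta
  expect_equal(twoAngleSpec(75, 30, 44)@beta,
               twoAngleSpec(75, 30, 44 + 10.5)@beta, tolerance = 1e-9)
})

test_that("metrics and clash lists are invariant under rigid motions", {
  fib <- buildFiber(twoAngleSpec(50, 40, 30))
  m0 <- fiberMetrics(fib)
  th <- 0.7; ph <- 1.2
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3)
  moved <- nucleosomeCenters(fib) %*% t(Rz %*% Rx)
  moved <- sweep(moved, 2L, c(-11.3, 40, 7.7), `+`)
  fib2 <- new("FiberGeometry", centers = moved,
              linkerLength = fib@linkerLength, spec = fib@spec)
  m1 <- fiberMetrics(fib2)
  expect_equal(m1$packingRatio, m0$packingRatio, tolerance = 1e-9)
  expect_equal(m1$fiberDiameter, m0$fiberDiameter, tolerance = 1e-9)
  expect_identical(detectClashes(fib2), detectClashes(fib))
  expect_equal(m1$arcLength, m0$arcLength, tolerance = 1e-9)
})

test_that("clash detection finds forced overlaps and orders pairs canonically", {
  # wide straight fiber: no clashes
  expect_equal(nrow(detectClashes(
    buildFiber(twoAngleSpec(180, 12, 60, beta = 0)))), 0L)
  # tight hairpins at small alpha must clash for an 11-nm nucleosome
  cl <- detectClashes(buildFiber(twoAngleSpec(5, 20, 20)))
  expect_gt(nrow(cl), 0L)
  expect_true(all(cl[, "j"] - cl[, "i"] >= 2))
  expect_false(anyDuplicated(paste(cl[, 1], cl[, 2])) > 0)
  expect_true(all(diff(order(cl[, 1], cl[, 2])) == 1))
})

test_that("a compact helical fiber packs more densely than a straight one", {
  straight <- fiberMetrics(buildFiber(twoAngleSpec(180, 40, 20, beta = 0)))
  helical <- fiberMetrics(buildFiber(twoAngleSpec(30, 40, 20, beta = 36)))
  expect_gt(helical$packingRatio, straight$packingRatio)
})

test_that("degenerate inputs are handled as documented", {
  expect_warning(buildFiber(twoAngleSpec(0, 6, 20)), "clash")
  expect_error(fiberMetrics(buildFiber(twoAngleSpec(90, 4, 20)))) # < window
  expect_error(twoAngleSpec(200, 10, 20), "alpha")
  expect_error(twoAngleSpec(90, 1, 20), "nucleosomes")
})
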