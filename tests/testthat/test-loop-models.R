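# Gaussian loop models: random-loop topology statistics, exact Laplacian
# distances versus direct Gaussian sampling, the RW-GL construction, and
# the random-loop distance plateau.

test_that("random-loop topologies have binomial bond counts", {
  expect_equal(nrow(extraBonds(randomLoopTopology(200, 0, seed = 1))), 0L)
  full <- randomLoopTopology(30, 1, minLoopSeparation = 1, seed = 1)
  expect_equal(nrow(extraBonds(full)), choose(30, 2))
  # p = 1e-3, n = 1000, min sep 15: count within 4 sqrt(mean) of the
  # binomial mean over the enumerated eligible pairs
  nEligible <- sum(1000 - 15:999)
  topo <- randomLoopTopology(1000, 1e-3, 15, seed = 42)
  mu <- 1e-3 * nEligible
  expect_lt(abs(nrow(extraBonds(topo)) - mu), 4 * sqrt(mu))
  # respect the separation cutoff; reproducible by seed
  b <- extraBonds(topo)
  expect_true(all(b[, 2] - b[, 1] >= 15))
  expect_identical(b, extraBonds(randomLoopTopology(1000, 1e-3, 15,
                                                    seed = 42)))
  expect_warning(randomLoopTopology(10, 0.5, minLoopSeparation = 10),
                 "no eligible pairs")
})

test_that("the loop-free Gaussian network is exactly the ideal chain", {
  topo <- randomLoopTopology(40, 0)
  m <- gaussianDistanceMatrix(topo, bondVariance = 2.5)
  ij <- abs(outer(1:40, 1:40, `-`))
  expect_equal(m, 2.5 * ij, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(gaussianRadiusOfGyration(topo), idealLatticeRg2(40),
               tolerance = 1e-9)
})

test_that("a hand-built looped network matches direct Gaussian sampling", {
  # 3 beads with the (1,3) loop closed: a symmetric 3-spring ring whose
  # resistance distance between any two beads is 2/3
  tri <- new("LoopTopology", nBeads = 3L,
             extraBonds = matrix(c(1L, 3L), 1, dimnames = NULL),
             loopProbability = NA_real_, minLoopSeparation = 2L,
             bpPerBead = 1e4)
  m <- gaussianDistanceMatrix(tri)
  expect_equal(m[1, 2], 2 / 3, tolerance = 1e-9)
  expect_equal(m[1, 3], 2 / 3, tolerance = 1e-9)
  set.seed(8)
  mc <- sampleGaussianNetwork(tri, rbind(c(1L, 2L), c(1L, 3L)),
                              nDraws = 2e5)
  expect_within_se(mc$mean[1], m[1, 2], mc$se[1], label = "r2(1,2)")
  expect_within_se(mc$mean[2], m[1, 3], mc$se[2], label = "r2(1,3)")
})

test_that("pseudo-inverse distances agree with sampling for random topologies", {
  set.seed(99)
  for (rep in 1:3) {
    n <- sample(10:50, 1)
    topo <- randomLoopTopology(n, 0.08, minLoopSeparation = 3,
                               seed = 500 + rep)
    m <- gaussianDistanceMatrix(topo)
    pairs <- cbind(sample(n - 1, 4), n)  # mix of short and long range
    pairs <- rbind(pairs, c(1L, 2L))
    mc <- sampleGaussianNetwork(topo, pairs, nDraws = 5e4)
    z <- (mc$mean - m[pairs]) / mc$se
    expect_lt(abs(mean(z)), 3 / sqrt(nrow(pairs)))
  }
})

test_that("random-loop profiles plateau while loop-free profiles stay linear", {
  sep <- c(1, 2, 4, 8, 16, 32, 64, 120, 180, 250)
  free <- randomLoopProfile(256, 0, nTopologies = 2, separations = sep)
  expect_equal(free$mean_r2, sep, tolerance = 1e-9)  # exact ideal chain
  looped <- randomLoopProfile(256, 3e-3, nTopologies = 15,
                              separations = sep, seed = 3)
  # distances become independent of genomic separation at large s
  fitLarge <- fitScalingExponent(looped[looped$s >= 32, ])
  expect_lt(scalingExponent(fitLarge), 0.1)
  fitSmall <- fitScalingExponent(looped[looped$s <= 8, ])
  expect_gt(scalingExponent(fitSmall), scalingExponent(fitLarge))
})

test_that("RW-GL reduces to the ideal chain without loops", {
  sep <- c(1, 4, 16, 64, 199)
  pr <- rwglProfile(200, loopSize = 0, replicates = 150, separations = sep,
                    seed = 12)
  z <- (pr$mean_r2 - sep) / pr$stderr
  expect_lt(max(abs(z)), 4)
})

test_that("within a giant loop distances follow the closed-loop form", {
  # one loop spanning the whole chain: every pair is intra-loop, so
  # <r2(s)> = s (m - s) / m exactly (Brownian-bridge covariance)
  m <- 100
  sep <- c(5, 10, 25, 50, 75, 95)
  pr <- rwglProfile(m, loopSize = m, replicates = 250, separations = sep,
                    seed = 21)
  expected <- sep * (m - sep) / m
  z <- (pr$mean_r2 - expected) / pr$stderr
  expect_lt(max(abs(z)), 4)
})

test_that("RW-GL profiles level off beyond the loop size", {
  pr <- rwglProfile(600, loopSize = 100, replicates = 80,
                    separations = c(2, 5, 10, 20, 200, 300, 400, 500),
                    seed = 5)
  small <- fitScalingExponent(pr[pr$s <= 20, ])
  large <- fitScalingExponent(pr[pr$s >= 200, ])
  expect_gt(scalingExponent(small), 0.3)
  expect_lt(scalingExponent(large), 0.15)
  # the radius of gyration is reported alongside
  expect_true(all(c("mean", "se") %in% names(attr(pr, "rg2"))))
  expect_gt(attr(pr, "rg2")[["mean"]], 0)
})

test_that("degenerate loop parameters are rejected", {
  expect_error(randomLoopTopology(100, 1.5), "\\[0, 1\\]")
  expect_error(rwglProfile(100, loopSize = 1), ">= 2")
  expect_error(rwglProfile(100, loopSize = 200), "exceed")
})
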