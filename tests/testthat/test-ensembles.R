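# Lattice FJC ensembles, contact statistics, scaling fits and moment
# ratios.

test_that("unconfined walks are ideal chains", {
  e <- fjcEnsemble(256, "unconfined", nChains = 40, seed = 3)
  ree <- ensembleRee2(e)
  expect_within_se(mean(ree), 255, sd(ree) / sqrt(length(ree)),
                   label = "<Ree2>")
  p <- msdProfile(e, separations = c(1, 4, 16, 64))
  expect_equal(p$mean_r2[1], 1)  # unit bonds: exact at s = 1
  z <- (p$mean_r2[-1] - p$s[-1]) / p$stderr[-1]
  expect_lt(max(abs(z)), 4)
})

test_that("confined walks never leave the box and match the density arithmetic", {
  e <- fjcEnsemble(512, "confined", nChains = 10, density = 0.5, seed = 4)
  expect_equal(e@boxSize, ceiling((512 / 0.5)^(1 / 3)))  # 11
  expect_true(all(e@coords >= 0 & e@coords <= e@boxSize - 1))
  expect_error(fjcEnsemble(100, "confined", density = 1.5), "density")
  expect_error(fjcEnsemble(100, "confined"), "boxSize or density")
})

test_that("confined size grows as N^(1/3) at fixed density", {
  sizes <- c(256, 512, 1024, 2048)
  rg <- vapply(seq_along(sizes), function(i) {
    e <- fjcEnsemble(sizes[i], "confined", nChains = 24, density = 0.5,
                     seed = splitSeed(17, i))
    sqrt(mean(ensembleRg2(e)))
  }, numeric(1))
  fit <- fitScalingExponent(sizes, rg)
  expect_lt(abs(scalingExponent(fit) - 1 / 3), 0.05)
})

test_that("the scaling fit recovers exact power laws and validates input", {
  s <- 1:100
  # noise-free power laws fit perfectly; lm's zero-residual warning is the
  # expected outcome here
  f <- suppressWarnings(fitScalingExponent(s, 2.7 * s^0.5))
  expect_equal(scalingExponent(f), 0.5, tolerance = 1e-6)
  expect_equal(f@prefactor, 2.7, tolerance = 1e-6)
  f2 <- suppressWarnings(fitScalingExponent(s, (3 * s^0.37)^2,
                                            squared = TRUE))
  expect_equal(scalingExponent(f2), 0.37, tolerance = 1e-6)
  expect_error(fitScalingExponent(1:3, 1:3), "at least 4")
  expect_error(fitScalingExponent(1:10, c(-1, 2:10)), "positive")
})

test_that("contact probabilities behave like Gaussian return probabilities", {
  e <- fjcEnsemble(512, "unconfined", nChains = 200, seed = 9)
  sep <- round(exp(seq(log(8), log(256), length.out = 10)))
  cp <- contactProbability(e, captureRadius = 2, separations = sep)
  expect_true(all(cp$contact_probability >= 0 &
                    cp$contact_probability <= 1))
  # monotone non-increasing within a small sampling slack
  expect_true(all(diff(cp$contact_probability) < 0.005))
  fit <- fitScalingExponent(cp$s, cp$contact_probability)
  expect_lt(abs(scalingExponent(fit) - (-1.5)), 0.15)
  # a second capture radius reaches the same regime once s >> radius^2
  sep4 <- round(exp(seq(log(64), log(400), length.out = 8)))
  cp4 <- contactProbability(e, captureRadius = 4, separations = sep4)
  fit4 <- fitScalingExponent(cp4$s, cp4$contact_probability)
  expect_lt(abs(scalingExponent(fit4) - (-1.5)), 0.15)
  # an absurdly large radius captures everything
  cpAll <- contactProbability(e, captureRadius = 1e6,
                              separations = c(1, 10, 100))
  expect_equal(cpAll$contact_probability, rep(1, 3))
})

test_that("moment ratios discriminate rod, Gaussian and general samples", {
  expect_equal(as.numeric(momentRatio(rep(3.7, 5000))), 1)
  set.seed(31)
  g <- sqrt(rowSums(matrix(rnorm(3 * 2e4), ncol = 3)^2))
  r <- momentRatio(g)
  # 3D Gaussian radial moments: <r^4>/<r^2>^2 = 15/9 = 5/3
  expect_lt(abs(as.numeric(r) - 5 / 3), 0.03)
  expect_equal(attr(r, "n"), 2e4)
  # Cauchy-Schwarz: always >= 1
  for (d in list(runif(2000), rexp(2000), rlnorm(2000)))
    expect_gte(as.numeric(momentRatio(d)), 1)
  expect_warning(momentRatio(rep(1, 10)), "wide error")
  # ensemble interface at a fixed separation
  e <- fjcEnsemble(64, "unconfined", nChains = 50, seed = 2)
  mr <- momentRatio(e, separation = 16)
  expect_lt(abs(as.numeric(mr) - 5 / 3), 0.1)
})

test_that("ensembles are reproducible from their seed", {
  a <- fjcEnsemble(64, "unconfined", nChains = 5, seed = 8)
  b <- fjcEnsemble(64, "unconfined", nChains = 5, seed = 8)
  expect_identical(a@coords, b@coords)
  # adding chains never reshuffles earlier ones (counter-based seeding)
  c10 <- fjcEnsemble(64, "unconfined", nChains = 10, seed = 8)
  expect_identical(c10@coords[, , 1:5], a@coords)
})
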