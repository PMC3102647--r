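# Lattice Monte Carlo engine: construction, stiffness maps, detailed
# balance, ideal-chain recovery, transfer-matrix stiffness oracle and
# tangent-correlation persistence length.

test_that("chain construction honours the lattice invariants", {
  rod <- buildChain(16, init = "rod")
  x <- coords(rod)
  expect_equal(sum((x[17, ] - x[1, ])^2), 256)  # straight rod end-to-end^2
  rnd <- buildChain(50, init = "random", seed = 7)
  expect_true(all(rowSums(abs(diff(coords(rnd)))) == 1))
  # determinism: same seed, bit-identical chain
  expect_identical(coords(buildChain(50, init = "random", seed = 7)),
                   coords(rnd))
  expect_error(buildChain(16, stiffness = rep(1, 3)), "length")
  expect_error(buildChain(1), ">= 2")
})

test_that("hinge maps place equally spaced flexible regions", {
  expect_equal(hingeStiffnessMap(16, 0), rep(2, 15))
  expect_equal(hingeStiffnessMap(16, 15, regionWidth = 1), rep(0, 15))
  m <- hingeStiffnessMap(16, 3)
  expect_equal(which(m == 0), c(4L, 8L, 12L))  # floor(j*16/4), j = 1..3
  expect_equal(sum(m == 2), 12)
  w <- hingeStiffnessMap(64, 2, regionWidth = 5)
  expect_equal(sum(w == 0), 10)
  expect_error(hingeStiffnessMap(16, 8, regionWidth = 2), "cannot place")
})

test_that("a 3-bond chain samples the exact Boltzmann energy distribution", {
  # uniform eps: the per-sample bending energy is recoverable from the
  # recorded vertex-average cosine, E = 2 eps (1 - meanCos), so the full
  # energy histogram can be checked against exhaustive 6^3 enumeration
  eps <- 2
  exact <- enumerate3BondEnergies(c(eps, eps))
  ch <- buildChain(3, c(eps, eps), init = "rod")
  os <- metropolisSample(ch, nSamples = 8000, sampleInterval = 3, seed = 5)
  E <- round(2 * eps * (1 - meanCosTheta(os)), 9)
  expect_setequal(unique(E), as.numeric(names(exact)))
  n <- length(E)
  for (lev in names(exact)) {
    p <- exact[[lev]]
    obs <- mean(E == as.numeric(lev))
    # multinomial sampling error (samples 3 sweeps apart are weakly
    # correlated; 4 SE absorbs the residual correlation)
    expect_within_se(obs, p, sqrt(p * (1 - p) / n), nSe = 4,
                     label = sprintf("P(E = %s)", lev))
  }
})

test_that("zero stiffness recovers the ideal lattice chain", {
  reps <- 10
  ree <- rg <- numeric(reps)
  for (r in seq_len(reps)) {
    os <- metropolisSample(buildChain(64), nSamples = 150, seed = 100 + r)
    ree[r] <- mean(ree2(os))
    rg[r] <- mean(rg2(os))
  }
  expect_within_se(mean(ree), 64, sd(ree) / sqrt(reps), label = "<Ree2>")
  # closed form validated against exhaustive 6^4 enumeration
  expect_equal(enumerateLatticeRg2(4), idealLatticeRg2(5), tolerance = 1e-12)
  expect_within_se(mean(rg), idealLatticeRg2(65), sd(rg) / sqrt(reps),
                   label = "<Rg2>")
  # tangent correlations vanish beyond s = 0
  os <- metropolisSample(buildChain(64), nSamples = 400, seed = 1)
  tc <- colMeans(tangentCorrelation(os))
  expect_equal(unname(tc[1]), 1)
  expect_lt(max(abs(tc[-1])), 0.05)
})

test_that("uniform stiffness matches the 6-state transfer matrix", {
  eps <- 2
  expected <- latticeCosTheta(eps)
  reps <- 8
  mcs <- numeric(reps)
  for (r in seq_len(reps)) {
    ch <- buildChain(128, rep(eps, 127), init = "random", seed = 200 + r)
    mcs[r] <- mean(meanCosTheta(metropolisSample(ch, nSamples = 250)))
  }
  expect_within_se(mean(mcs), expected, sd(mcs) / sqrt(reps),
                   label = "<cos theta> at eps = 2")
})

test_that("tangent-correlation fit recovers the transfer-matrix persistence length", {
  eps <- 2
  lpExpected <- -1 / log(latticeCosTheta(eps))  # 2.1601 bonds
  ch <- buildChain(256, rep(eps, 255), init = "random", seed = 31)
  os <- metropolisSample(ch, nSamples = 600, seed = 32)
  lp <- tangentCorrelationLp(os, fitRange = 1:4)
  expect_lt(abs(as.numeric(lp) - lpExpected) / lpExpected, 0.10)
  expect_false(attr(lp, "rodLike"))
})

test_that("flexible chains report a near-zero persistence length, stiff ones rod-like", {
  os0 <- metropolisSample(buildChain(128), nSamples = 500, seed = 77)
  lp0 <- tryCatch(tangentCorrelationLp(os0, fitRange = 1:2),
                  error = function(e) e)
  if (inherits(lp0, "error")) {
    expect_match(conditionMessage(lp0), "fit range")
  } else {
    expect_lt(as.numeric(lp0), 0.2)
  }
  # a 20 kBT chain is effectively a rod over 32 bonds
  chS <- buildChain(32, rep(20, 31), init = "rod")
  osS <- metropolisSample(chS, nSamples = 100, seed = 5)
  expect_warning(lpS <- tangentCorrelationLp(osS, fitRange = 1:4),
                 "rod-like")
  expect_true(attr(lpS, "rodLike"))
  expect_gt(as.numeric(lpS), 32)
})

test_that("observable series are reproducible from (chain, config, seed)", {
  ch <- buildChain(48, hingeStiffnessMap(48, 2), init = "rod")
  a <- metropolisSample(ch, nSamples = 60, seed = 99)
  b <- metropolisSample(ch, nSamples = 60, seed = 99)
  expect_identical(ree2(a), ree2(b))
  expect_identical(rg2(a), rg2(b))
  expect_identical(tangentCorrelation(a), tangentCorrelation(b))
  expect_error(metropolisSample(ch, nSamples = 0), "empty series")
})

test_that("hinges strictly shrink a stiff chain and the ratio trends hold", {
  df <- rgRatioExperiment(c(16, 48), hingeCounts = c(0, 3), replicates = 12,
                          nSamples = 120, seed = 4)
  for (nb in c(16, 48)) {
    sub <- df[df$n_bonds == nb, ]
    r0 <- sub$ratio[sub$hinges == 0]
    r3 <- sub$ratio[sub$hinges == 3]
    expect_gt(r0, 1)           # stiff background swells the chain
    expect_lt(r3, r0)          # hinges collapse it
  }
  # the all-flexible "hinge" chain is its own baseline: ratio ~ 1
  allFlex <- rgRatioExperiment(16, hingeCounts = 15, replicates = 12,
                               nSamples = 120, seed = 6)
  expect_within_se(allFlex$ratio, 1, allFlex$ratio_se, label = "self-ratio")
  expect_match(attr(df, "ratio_definition"), "fully flexible")
  expect_error(rgRatioExperiment(3, 0:1), "too short")
})

test_that("seed splitting is deterministic, in range, and collision-sparse", {
  s <- splitSeed(42, 1:10000)
  expect_identical(s, splitSeed(42, 1:10000))
  expect_true(all(s >= 1 & s <= 2147483647))
  expect_gt(length(unique(s)), 9990)
  expect_false(any(splitSeed(43, 1:100) == splitSeed(42, 1:100)))
})
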