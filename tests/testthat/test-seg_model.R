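test_that("gamete distributions renormalize after eliminating the null class", {
  # Mendelian limit, unlinked: all four haplotypes equal
  g <- gameteDistribution(TransmissionModel(), "male")
  expect_equal(unname(g), rep(0.25, 4))
  # full elimination through the queried sex: the three survivors at 1/3
  g <- gameteDistribution(TransmissionModel(tauM = 0), "male")
  expect_equal(unname(g), c(1, 1, 1, 0) / 3)
  # ...but not through the other sex
  g <- gameteDistribution(TransmissionModel(tauM = 0), "female")
  expect_equal(unname(g), rep(0.25, 4))
  # no recombination in repulsion: the lethal recombinant never arises
  g <- gameteDistribution(TransmissionModel(tauM = 0, r = 0), "male")
  expect_equal(unname(g), c(0, 0.5, 0.5, 0))
  # coupling phase swaps parental and recombinant roles
  g <- gameteDistribution(TransmissionModel(r = 0), "male", "coupling")
  expect_equal(unname(g), c(0.5, 0, 0, 0.5))
})

test_that("F2 genotype frequencies match the spec's worked marginals", {
  # Mendelian dihybrid limit at any recombination fraction
  for (r in c(0, 0.1, 0.5)) {
    jf <- f2GenotypeFreqs(TransmissionModel(r = r))
    expect_equal(unname(locusMarginal(jf, 1)), c(0.25, 0.5, 0.25))
    expect_equal(unname(locusMarginal(jf, 2)), c(0.25, 0.5, 0.25))
  }
  # full elimination in both sexes: 4:4:1 in functional-dosage order
  jf <- f2GenotypeFreqs(TransmissionModel(0, 0, 1, 0.5))
  expect_equal(unname(locusMarginal(jf, 2)), c(4, 4, 1) / 9)
  expect_equal(unname(locusMarginal(jf, 1)), c(4, 4, 1) / 9)
  # male-only elimination: functional:null male gametes 2:1, female 1:1
  jf <- f2GenotypeFreqs(TransmissionModel(0, 1, 1, 0.5))
  expect_equal(unname(locusMarginal(jf, 2)), c(1 / 3, 1 / 2, 1 / 6))
})

test_that("f2GenotypeFreqs equals brute-force gamete enumeration on a grid", {
  vals <- c(0, 0.25, 0.5, 0.75, 1)
  grid <- expand.grid(tauM = vals, tauF = vals, v = vals, r = c(0, 0.1, 0.5))
  expect_equal(nrow(grid), 375L)
  maxErr <- 0
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (g$tauM == 0 && g$tauF == 0 && g$v == 0 && g$r == 0) next  # no F2
    jf <- f2GenotypeFreqs(TransmissionModel(g$tauM, g$tauF, g$v, g$r))
    orc <- oracleF2(g$tauM, g$tauF, g$v, g$r)
    maxErr <- max(maxErr, max(abs(unname(jf) - orc)))
  }
  expect_lt(maxErr, 1e-12)
})

test_that("the joint matrix respects locus symmetry and monotonicity", {
  # swapping locus labels (with their null assignments) transposes the joint
  for (tm in c(0, 0.3, 1)) for (tf in c(0.2, 1)) {
    jf <- f2GenotypeFreqs(TransmissionModel(tm, tf, 0.7, 0.2))
    expect_equal(jf, t(jf), ignore_attr = TRUE)
  }
  # the sterile doubly-null class frequency is non-decreasing in tauM,
  # tauF and v
  nnFreq <- function(tm, tf, v)
    f2GenotypeFreqs(TransmissionModel(tm, tf, v))["nn", "nn"]
  s <- seq(0, 1, by = 0.25)
  expect_true(all(diff(vapply(s, function(x) nnFreq(x, 0.5, 0.5), 1)) >= 0))
  expect_true(all(diff(vapply(s, function(x) nnFreq(0.5, x, 0.5), 1)) >= 0))
  expect_true(all(diff(vapply(s, function(x) nnFreq(0.5, 0.5, x), 1)) >= 0))
})

test_that("chi-square goodness of fit reproduces the distorted-family test", {
  # the observed family: 99 W2W2 : 113 W2G2 : 14 G2G2 against Mendelian 1:2:1
  res <- chisqGof(c(99, 113, 14), c(1, 2, 1))
  expect_equal(res$statistic, 63.93805, tolerance = 1e-6)
  expect_equal(res$df, 2L)
  expect_equal(res$p, 1.306256e-14, tolerance = 1e-5)
  expect_lt(res$p, 0.001)
  # against the full-elimination model expectation 4:4:1
  res <- chisqGof(c(99, 113, 14), c(4, 4, 1))
  expect_equal(res$statistic, 6.506637, tolerance = 1e-6)
  expect_equal(res$expected, c(100.4444, 100.4444, 25.1111), tolerance = 1e-6)
  expect_equal(res$p, 0.03864575, tolerance = 1e-6)
  # exact proportionality gives a zero statistic
  res <- chisqGof(c(25, 50, 25), c(1, 2, 1))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # agreement with the stats oracle
  orc <- suppressWarnings(chisq.test(c(99, 113, 14), p = c(1, 2, 1) / 4))
  expect_equal(chisqGof(c(99, 113, 14), c(1, 2, 1))$statistic,
               unname(orc$statistic))
  expect_error(chisqGof(c(1, 2), c(1, 0)), "positive")
})

test_that("locus marginals conserve mass and reject bad locus ids", {
  jf <- matrix(0, 3, 3)
  jf[2, 3] <- 1
  expect_equal(unname(locusMarginal(jf, 1)), c(0, 1, 0))
  expect_equal(unname(locusMarginal(jf, 2)), c(0, 0, 1))
  jf <- f2GenotypeFreqs(TransmissionModel(0.3, 0.8, 0.5, 0.1))
  expect_equal(sum(locusMarginal(jf, 1)), 1)
  expect_equal(sum(locusMarginal(jf, 2)), 1)
  expect_error(locusMarginal(jf, 3), "locus")
})

test_that("fitTransmission recovers known parameters and stays optimal", {
  # undistorted data: the tied gamete viability is estimated at 1
  fit <- fitTransmission(c(FF = 2500, Fn = 5000, nn = 2500), free = "tau")
  expect_equal(tauM(fittedModel(fit)), 1, tolerance = 1e-4)
  expect_true(fit@converged)

  # tauM and tauF are only identifiable as an unordered pair (the F2
  # genotype distribution is sex-symmetric), so recovery is on sorted values
  truth <- TransmissionModel(0, 0.2, 1)
  for (s in 1:3) {
    sim <- simulateF2Counts(10000, truth, joint = TRUE, seed = s)
    fit <- fitTransmission(sim$counts, free = c("tauM", "tauF"))
    m <- fittedModel(fit)
    est <- sort(c(tauM(m), tauF(m)))
    expect_lt(max(abs(est - c(0, 0.2))), 0.05)
    # optimality: the estimate's likelihood cannot fall below the truth's
    # (multinomial log-likelihood over the observed classes)
    pTruth <- as.vector(t(f2GenotypeFreqs(truth)))
    obs <- sim$counts > 0
    llTruth <- sum(sim$counts[obs] * log(pTruth[obs]))
    expect_gte(logLik(fit), llTruth - 1e-6)
  }

  expect_error(fitTransmission(c(1, 2, 1), free = c("tauM", "tauF", "v")),
               "at most 2")
  expect_error(fitTransmission(c(1, 2, 1), free = c("tau", "tauM")),
               "cannot be combined")
})

test_that("cross compatibility follows the duplicate-loss truth table", {
  I <- hwsClass("I"); II <- hwsClass("II"); III <- hwsClass("III")
  # complementary gene loss: only II x III (either order) breaks down
  expect_equal(classifyCross(III, II), "incompatible")
  expect_equal(classifyCross(II, III), "incompatible")
  expect_equal(classifyCross(II, II), "compatible")
  expect_equal(classifyCross(III, III), "compatible")
  for (cls in list(I, II, III)) {
    expect_equal(classifyCross(I, cls), "compatible")
    expect_equal(classifyCross(cls, I), "compatible")
  }
  # symmetry over all pairs
  for (a in list(I, II, III)) for (b in list(I, II, III))
    expect_equal(classifyCross(a, b), classifyCross(b, a))
  expect_error(alleleClass(FALSE, FALSE), "not viable")
})
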