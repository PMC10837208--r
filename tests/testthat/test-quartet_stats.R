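test_that("site terms follow the frequency form of ABBA/BABA", {
  expect_equal(siteTerms(0, 1, 1, 0), list(abba = 1, baba = 0))
  expect_equal(siteTerms(1, 0, 1, 0), list(abba = 0, baba = 1))
  tm <- siteTerms(0.2, 0.8, 0.6, 0.0)
  expect_equal(tm$abba, 0.384)
  expect_equal(tm$baba, 0.024)
})

test_that("Patterson's D aggregates site terms with the right bounds", {
  expect_equal(pattersonD(freqTable(0, 1, 1, 0))$D, 1)
  expect_equal(pattersonD(freqTable(c(0, 1), c(1, 0), c(1, 1), c(0, 0)))$D, 0)
  expect_equal(pattersonD(freqTable(0.2, 0.8, 0.6, 0))$D, 0.36 / 0.408)
  expect_error(pattersonD(freqTable(0, 0, 0, 0)), "usable|denominator")

  set.seed(3)
  for (i in 1:20) {
    f <- freqTable(runif(50), runif(50), runif(50), runif(50, 0, 0.2))
    D <- pattersonD(f)$D
    expect_lte(abs(D), 1)
    # swapping P1 and P2 flips the sign
    fsw <- freqTable(f$p2, f$p1, f$p3, f$p4)
    expect_equal(pattersonD(fsw)$D, -D)
  }
})

test_that("block jackknife needs blocks and flags degenerate variance", {
  f <- freqTable(rep(0.2, 50), rep(0.4, 50), rep(0.5, 50), rep(0, 50),
                 pos = (0:49) * 1e4 + 1)
  # 50 identical sites in 10+ blocks of 3 sites each -> zero jackknife SE
  z <- jackknifeZ(f, blockSize = 3e4)
  expect_true(is.infinite(z$Z))
  expect_equal(z$se, 0)
  expect_error(jackknifeZ(f, blockSize = 1e6), ">= 10")
})

test_that("jackknife z is calibrated on null and powered on admixture", {
  zs <- vapply(1:20, function(s) {
    aw <- simulateAdmixedWindows(nWindows = 40, sitesPerWindow = 120,
                                 introgressedFraction = 0, seed = s)
    jackknifeZ(aw$freqs, blockSize = 3e5)$Z
  }, numeric(1))
  expect_gte(sum(abs(zs) < 3), 18L)
  za <- vapply(1:10, function(s) {
    aw <- simulateAdmixedWindows(nWindows = 40, sitesPerWindow = 120,
                                 introgressedFraction = 1, fAdmix = 0.2,
                                 seed = s)
    jackknifeZ(aw$freqs, blockSize = 3e5)$Z
  }, numeric(1))
  expect_gt(median(za), 3)
})

test_that("fd uses the dynamic donor and respects its domain", {
  r <- fdWindow(freqTable(0, 0.4, 0.8, 0), minSites = 1)
  expect_equal(r$numerator, 0.32)
  expect_equal(r$denominator, 0.64)
  expect_equal(r$fd, 0.5)
  # donor equals P2 when p2 = p3 site-wise: fd = 1
  f <- freqTable(c(0.1, 0.2), c(0.7, 0.5), c(0.7, 0.5), c(0, 0))
  expect_equal(fdWindow(f, minSites = 1)$fd, 1)
  # negative numerator: fd missing by convention
  r <- fdWindow(freqTable(0.9, 0.1, 0.8, 0), minSites = 1)
  expect_true(is.na(r$fd))
  expect_true(r$passed)
  # window filters: 99 good sites fail the 100-site minimum
  f <- freqTable(runif(99), runif(99), runif(99, 0.2, 0.8), rep(0, 99))
  r <- fdWindow(f, minSites = 100)
  expect_false(r$passed)
  expect_true(is.na(r$fd))
  expect_equal(r$nGood, 99L)
  # fd lies in [0, 1] (donor maximality) over random windows
  set.seed(8)
  for (i in 1:20) {
    f <- freqTable(runif(120), runif(120), runif(120), runif(120, 0, 0.1))
    r <- fdWindow(f, minSites = 100)
    if (!is.na(r$fd)) { expect_gte(r$fd, 0); expect_lte(r$fd, 1) }
  }
})

test_that("good sites require defined, polymorphic, well-genotyped calls", {
  f <- freqTable(c(0, 1, NA, 0.3), c(0, 1, 0.5, 0.4), c(0, 1, 0.5, 0.2),
                 c(0, 1, 0.5, 0))
  f$genotypedFraction <- c(1, 1, 1, 0.1)
  # sites 1-2 monomorphic-in-all, site 3 undefined, site 4 under-genotyped
  r <- fdWindow(f, minSites = 1, minGenotyped = 0.2)
  expect_equal(r$nGood, 0L)
  f$genotypedFraction[4] <- 0.5
  expect_equal(fdWindow(f, minSites = 1)$nGood, 1L)
})

test_that("window scans tile chromosomes and are order-invariant", {
  set.seed(21)
  n <- 500
  mk <- function(chrom) freqTable(runif(n), runif(n), runif(n, 0.2, 0.8),
                                  rep(0, n), pos = sort(sample(1e6, n)),
                                  chrom = chrom)
  f <- rbind(mk("chr1"), mk("chr2"))
  sw <- scanWindows(f, windowSize = 1e5, minSites = 10)
  expect_equal(nrow(sw), 20L)                     # 2 chromosomes x 10 windows
  expect_equal(unique(sw$end - sw$start + 1), 1e5)
  for (chr in c("chr1", "chr2")) {
    s <- sw[sw$chrom == chr, ]
    expect_equal(s$start, seq(1, 9e5 + 1, by = 1e5))  # non-overlapping tiles
  }
  expect_error(scanWindows(f[rev(seq_len(nrow(f))), ]), "sorted")
  # within-window site order does not change the statistics
  w1 <- f[f$chrom == "chr1" & f$pos <= 1e5, ]
  perm <- w1[sample(nrow(w1)), ]
  expect_equal(fdWindow(perm, minSites = 10), fdWindow(w1, minSites = 10))
  expect_equal(pattersonD(perm)$D, pattersonD(w1)$D)
})

test_that("outlier calling flags the top half-percent of fd values", {
  set.seed(4)
  fd <- runif(995, 0, 0.05)
  planted <- sample(1000, 5)
  full <- numeric(1000)
  full[-planted] <- fd
  full[planted] <- 0.5 + runif(5)
  expect_setequal(outlierWindows(full), planted)
  # below the minimum support the set is empty
  expect_equal(outlierWindows(runif(100)), integer(0))
  # all equal: at most the nominal-size lexicographically-first subset
  expect_equal(outlierWindows(rep(0.3, 1000)), 1:5)
  # spec exclusion semantics: missing values drop out entirely
  withNA <- full
  withNA[1:600] <- NA
  out <- outlierWindows(withNA, missingAsZero = FALSE)
  expect_true(all(!is.na(withNA[out])))
  expect_lte(length(out), 2 + sum(planted > 600))
})
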