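test_that("generators are deterministic given the global seed", {
  expect_identical(simulateF2Counts(226, seed = 3)$counts,
                   simulateF2Counts(226, seed = 3)$counts)
  expect_identical(simulateAdmixedWindows(nWindows = 5, sitesPerWindow = 20,
                                          seed = 3)$freqs,
                   simulateAdmixedWindows(nWindows = 5, sitesPerWindow = 20,
                                          seed = 3)$freqs)
  a <- simulateCodonPair(100, 0.05, 0.01, seed = 3)
  b <- simulateCodonPair(100, 0.05, 0.01, seed = 3)
  expect_identical(a$seqA, b$seqA)
  expect_identical(a$seqB, b$seqB)
  expect_identical(as.character(simulateQuartetAlignment(seed = 3,
                                                         nSites = 200)$alignment),
                   as.character(simulateQuartetAlignment(seed = 3,
                                                         nSites = 200)$alignment))
  # byte-identical VCF text
  expect_identical(simulateSnpRegion(1e4, 10, 0.01, seed = 3)$vcf,
                   simulateSnpRegion(1e4, 10, 0.01, seed = 3)$vcf)
  # different generators draw from distinct streams of the same seed
  expect_false(identical(deriveSeed(3, "f2_counts"),
                         deriveSeed(3, "snp_region")))
  # the caller's RNG state is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulateF2Counts(10, seed = 1))
  expect_identical(runif(1), before)
})

test_that("truth records serialize to YAML sidecars and back", {
  sim <- simulateF2Counts(100, TransmissionModel(0.3, 0.3, 0.9), seed = 6)
  f <- withr::local_tempfile(fileext = ".yaml")
  writeSimTruth(sim$truth, f)
  back <- readSimTruth(f)
  expect_s3_class(back, "SimTruth")
  expect_equal(back$generator, "simulate_f2_counts")
  expect_equal(back$seed, 6)
  expect_equal(back$params$tauM, 0.3)
})

test_that("simulated F2 families match their expected frequencies", {
  sim <- simulateF2Counts(226, TransmissionModel(0, 0, 1), seed = 11)
  expect_equal(sum(sim$counts), 226L)
  # near the 4:4:1 expectation (3 sigma on each class)
  expected <- 226 * c(4, 4, 1) / 9
  sds <- sqrt(expected * (1 - c(4, 4, 1) / 9))
  expect_true(all(abs(sim$counts - expected) <= 3 * sds))
  # law of large numbers at the Mendelian limit
  sim <- simulateF2Counts(10000, TransmissionModel(), seed = 12)
  expected <- 10000 * c(0.25, 0.5, 0.25)
  sds <- sqrt(expected * (1 - c(0.25, 0.5, 0.25)))
  expect_true(all(abs(sim$counts - expected) <= 3 * sds))
  # joint tables carry all nine classes
  sim <- simulateF2Counts(500, TransmissionModel(0.5, 0.5, 1), joint = TRUE,
                          seed = 13)
  expect_equal(names(sim$counts), genotypeClassNames(TRUE))
  expect_equal(sum(sim$counts), 500L)
})

test_that("quartet alignments follow the Jukes-Cantor expectations", {
  sim <- simulateQuartetAlignment(tipLength = 0, internalLength = 0,
                                  nSites = 500, seed = 8)
  expect_equal(length(unique(as.character(sim$alignment))), 1L)

  sim <- simulateQuartetAlignment(sister = c("A", "B"), tipLength = 0.01,
                                  internalLength = 0.05, nSites = 10000,
                                  seed = 9)
  d <- alignmentDistances(sim$alignment, "p")
  # each pairwise p-distance within 3 sigma of its JC expectation
  for (nm in names(sim$truth$truth$pathLengths)) {
    taxa <- strsplit(nm, "-")[[1]]
    L <- sim$truth$truth$pathLengths[[nm]]
    pExp <- 3 / 4 * (1 - exp(-4 / 3 * L))
    se <- sqrt(pExp * (1 - pExp) / 10000)
    expect_lt(abs(d[taxa[1], taxa[2]] - pExp), 3 * se + 1e-12)
  }
  expect_equal(quartetTopology(d, "O")$sister, c("A", "B"))
})

test_that("codon pairs record internally consistent substitution truth", {
  sim <- simulateCodonPair(200, 0, 0, seed = 14)
  expect_identical(sim$seqA, sim$seqB)
  expect_identical(sim$seqA, sim$ancestor)

  sim <- simulateCodonPair(5000, 0.05, 0.01, seed = 15)
  r <- ng86Pair(sim$seqA, sim$seqB)
  # realized synonymous substitutions per synonymous site approximate the
  # pre-correction proportion (multiple hits explain the small gap)
  realized <- sim$truth$truth$synSubstitutions / sim$truth$truth$S
  expect_lt(abs(realized - r@pS) / realized, 0.1)
  expect_error(simulateCodonPair(100, 0.6, 0.01, seed = 1), "saturated")
})

test_that("SNP regions honor theta and round-trip through the VCF reader", {
  sim <- simulateSnpRegion(1e4, 20, 0, seed = 16)
  expect_equal(nSites(sim$sites), 0L)
  expect_equal(length(sim$vcf), 4L)   # header only

  sim <- simulateSnpRegion(5e4, 20, 0.01, seed = 17)
  expect_gt(nSites(sim$sites), 0L)
  expect_true(all(diff(variantInfo(sim$sites)$pos) >= 0))
  expect_equal(unname(rowSums(genotypes(sim$sites))),
               as.integer(sim$truth$truth$derivedCounts))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(sim$vcf, f)
  back <- readVcfSites(f)
  expect_identical(genotypes(back), genotypes(sim$sites))
})

test_that("admixed windows are exchangeable under the null", {
  aw <- simulateAdmixedWindows(nWindows = 60, sitesPerWindow = 100,
                               introgressedFraction = 0, seed = 18)
  expect_equal(nrow(aw$freqs), 6000L)
  expect_equal(length(aw$truth$truth$introgressedWindows), 0L)
  # the null D symmetry comes from P1/P2 exchangeability (P3 is the deeper
  # split): sister frequencies have matching marginals
  expect_lt(abs(mean(aw$freqs$p1) - mean(aw$freqs$p2)), 0.02)
  expect_lt(abs(sd(aw$freqs$p1) - sd(aw$freqs$p2)), 0.02)
  # genome-wide D within 3 jackknife SE of zero
  z <- jackknifeZ(aw$freqs, blockSize = 3e5)
  expect_lt(abs(z$Z), 3)
  # introgressed windows raise fd above matched null windows
  aw2 <- simulateAdmixedWindows(nWindows = 100, sitesPerWindow = 150,
                                introgressedFraction = 0.2, fAdmix = 0.2,
                                seed = 19)
  sw <- scanWindows(aw2$freqs, minSites = 100)
  intro <- aw2$truth$truth$introgressedWindows
  isIn <- seq_len(nrow(sw)) %in% intro
  fd0 <- sw$fd; fd0[is.na(fd0)] <- 0
  expect_gt(mean(fd0[isIn]), mean(fd0[!isIn]))
})
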