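# Seeded synthetic-data generators. Every generator derives its own RNG
# stream from (seed, generator name), restores the caller's RNG state, and
# returns a SimTruth record alongside the data so downstream stages can be
# tested against known truth without external genomes.

#' Construct a simulation truth record
#'
#' @param generator generator name.
#' @param seed the global seed the dataset was generated from.
#' @param params named list of generator parameters.
#' @param truth named list of per-item truth labels.
#' @return list of class `"SimTruth"`.
#' @export
simTruth <- function(generator, seed, params, truth) {
  structure(list(generator = generator, seed = seed, params = params,
                 truth = truth), class = "SimTruth")
}

#' @export
print.SimTruth <- function(x, ...) {
  cat("SimTruth:", x$generator, "(seed", x$seed, ")\n")
  cat("  params:", paste(names(x$params), unlist(lapply(x$params, paste,
      collapse = ",")), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Write / read a SimTruth sidecar in YAML
#'
#' @param x a [simTruth()] record.
#' @param path sidecar file path.
#' @return `path` (write) or the SimTruth record (read).
#' @export
writeSimTruth <- function(x, path) {
  stopifnot(inherits(x, "SimTruth"))
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname writeSimTruth
#' @export
readSimTruth <- function(path) {
  x <- yaml::read_yaml(path)
  structure(x, class = "SimTruth")
}

#' Simulate F2 genotype counts under the transmission model
#'
#' Draws `n` plants from the multinomial distribution given by
#' [f2GenotypeFreqs()], reported as the 9-class joint table or the 3-class
#' marginal at one locus. The default family size matches the mapping
#' population (226 plants).
#'
#' @param n number of F2 plants.
#' @param model a [TransmissionModel-class].
#' @param joint report the 9-class joint table (`TRUE`) or the 3-class
#'   marginal (`FALSE`, default).
#' @param locus locus for the marginal report (1 or 2).
#' @param seed global seed.
#' @param phase F1 linkage phase.
#' @return list with `counts` (named integer vector in canonical class
#'   order) and `truth` (a [simTruth()] record storing the model and the
#'   expected frequencies).
#' @examples
#' simulateF2Counts(226, TransmissionModel(0, 0, 1), seed = 1)$counts
#' @export
simulateF2Counts <- function(n = 226, model = TransmissionModel(),
                             joint = FALSE, locus = 2, seed = 1,
                             phase = "repulsion") {
  stopifnot(n >= 1)
  jf <- f2GenotypeFreqs(model, phase)
  probs <- if (joint) as.vector(t(jf)) else locusMarginal(jf, locus)
  nm <- genotypeClassNames(joint)
  counts <- withSeed(deriveSeed(seed, "f2_counts"), {
    as.integer(rmultinom(1L, size = n, prob = probs))
  })
  names(counts) <- nm
  list(counts = counts,
       truth = simTruth("simulate_f2_counts", seed,
                        params = list(n = n, tauM = tauM(model),
                                      tauF = tauF(model),
                                      v = zygoteViability(model),
                                      r = recFraction(model), joint = joint,
                                      locus = locus, phase = phase),
                        truth = list(expectedFreqs = setNames(probs, nm))))
}

#' @noRd
.jcEvolve <- function(seqInt, branchLen) {
  # seqInt: integer 1..4 coding A,C,G,T; JC69: per site, substitution
  # probability 3/4 (1 - exp(-4/3 b)); new base uniform over the other three
  pChange <- 3 / 4 * (1 - exp(-4 / 3 * branchLen))
  hit <- which(runif(length(seqInt)) < pChange)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    seqInt[hit] <- ((seqInt[hit] - 1L + shift) %% 4L) + 1L
  }
  seqInt
}

#' Simulate a four-taxon alignment under the Jukes-Cantor model
#'
#' Sites evolve independently down a rooted quartet tree: the root joins the
#' outgroup and the ingroup; the internal branch subtends the sister pair.
#' All branch lengths are expected substitutions per site.
#'
#' @param sister character 2-vector naming the true sister pair among the
#'   three ingroup taxa.
#' @param labels the four taxon labels; the last is the outgroup.
#' @param tipLength branch length of each tip (scalar or named per-taxon
#'   vector).
#' @param internalLength length of the internal branch.
#' @param nSites alignment length.
#' @param seed global seed.
#' @return list with `alignment` (a [Biostrings::DNAStringSet]) and `truth`
#'   (records topology, branch lengths and the expected pairwise JC path
#'   lengths).
#' @export
simulateQuartetAlignment <- function(sister = c("A", "B"),
                                     labels = c("A", "B", "C", "O"),
                                     tipLength = 0.01, internalLength = 0.05,
                                     nSites = 10000, seed = 1) {
  stopifnot(length(labels) == 4L, all(sister %in% labels[1:3]),
            length(unique(sister)) == 2L, internalLength >= 0, nSites >= 1)
  outgroup <- labels[4L]
  third <- setdiff(labels[1:3], sister)
  if (length(tipLength) == 1L)
    tipLength <- setNames(rep(tipLength, 4L), labels)
  stopifnot(all(labels %in% names(tipLength)), all(tipLength >= 0))
  seqs <- withSeed(deriveSeed(seed, "quartet_alignment"), {
    root <- sample.int(4L, nSites, replace = TRUE)
    # root -> outgroup; root -> third tip; root -> internal node -> sisters
    anc <- .jcEvolve(root, internalLength)
    out <- list()
    out[[sister[1]]] <- .jcEvolve(anc, tipLength[[sister[1]]])
    out[[sister[2]]] <- .jcEvolve(anc, tipLength[[sister[2]]])
    out[[third]] <- .jcEvolve(root, tipLength[[third]])
    out[[outgroup]] <- .jcEvolve(root, tipLength[[outgroup]])
    out
  })
  bases <- c("A", "C", "G", "T")
  aln <- Biostrings::DNAStringSet(vapply(labels, function(l)
    paste(bases[seqs[[l]]], collapse = ""), character(1)))
  names(aln) <- labels
  pathLen <- function(x, y) {
    onSisterSide <- function(t) t %in% sister
    if (onSisterSide(x) && onSisterSide(y))
      tipLength[[x]] + tipLength[[y]]
    else if (onSisterSide(x) || onSisterSide(y)) {
      s <- if (onSisterSide(x)) x else y
      o <- setdiff(c(x, y), s)
      tipLength[[s]] + internalLength + tipLength[[o]]
    } else tipLength[[x]] + tipLength[[y]]
  }
  combs <- combn(labels, 2L)
  expPath <- apply(combs, 2L, function(p) pathLen(p[1], p[2]))
  names(expPath) <- apply(combs, 2L, paste, collapse = "-")
  list(alignment = aln,
       truth = simTruth("simulate_quartet_alignment", seed,
                        params = list(sister = sister, labels = labels,
                                      tipLength = as.list(tipLength),
                                      internalLength = internalLength,
                                      nSites = nSites),
                        truth = list(sister = sister,
                                     pathLengths = as.list(expPath))))
}

#' Uncorrected p-distance / JC distance matrix of an alignment
#'
#' Convenience distances for [quartetTopology()]. The mismatch proportion is
#' computed over ungapped, unambiguous columns; `method = "jc"` applies the
#' Jukes-Cantor correction `-3/4 log(1 - 4/3 p)`.
#'
#' @param aln a named [Biostrings::DNAStringSet] of equal-length sequences.
#' @param method `"p"` or `"jc"`.
#' @return symmetric distance matrix with taxon dimnames.
#' @export
alignmentDistances <- function(aln, method = c("p", "jc")) {
  method <- match.arg(method)
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  rownames(m) <- names(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] %in% c("A", "C", "G", "T") & m[j, ] %in% c("A", "C", "G", "T")
    p <- mean(m[i, ok] != m[j, ok])
    if (method == "jc") {
      if (p >= 3 / 4) stop("saturated p-distance: JC undefined", call. = FALSE)
      p <- -3 / 4 * log(1 - 4 / 3 * p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Simulate per-window site frequencies under drift with optional admixture
#'
#' Emulates the four-population setting of the windowed ABBA-BABA scan:
#' populations P1 and P2 are recently diverged sisters, P3 is a deeper
#' split, and the outgroup O is near-fixed ancestral. Per site, an ancestral
#' derived-allele frequency is drawn and each population drifts from it with
#' Gaussian noise (truncated to \[0,1\]); sample allele frequencies are then
#' binomial draws at the given haploid sample sizes, so P2 and P3 are
#' exchangeable in null windows. In introgressed windows a fraction
#' `fAdmix` of the P3 frequency is mixed into P2 before sampling.
#'
#' @param nWindows number of windows.
#' @param sitesPerWindow good sites per window.
#' @param introgressedFraction fraction of windows carrying admixture.
#' @param fAdmix admixture proportion mixed into P2 in introgressed windows.
#' @param nHap haploid sample sizes for P1, P2, P3, O.
#' @param driftSd drift standard deviations for P1, P2, P3 (P3 deeper).
#' @param ancShape Beta(shape1, shape2) of the ancestral derived frequency.
#' @param windowSize window span in bases (sites are placed inside
#'   consecutive windows so [scanWindows()] tiling recovers them).
#' @param chromName chromosome name.
#' @param seed global seed.
#' @return list with `freqs` (a [siteFrequencies()]-shaped data.frame) and
#'   `truth` (introgressed window indices and parameters).
#' @export
simulateAdmixedWindows <- function(nWindows = 800, sitesPerWindow = 500,
                                   introgressedFraction = 0.005,
                                   fAdmix = 0.2,
                                   nHap = c(40, 40, 40, 20),
                                   driftSd = c(0.02, 0.02, 0.25),
                                   ancShape = c(1, 3),
                                   windowSize = 3e5, chromName = "chr1",
                                   seed = 1) {
  stopifnot(fAdmix >= 0, fAdmix <= 1, length(nHap) == 4L,
            length(driftSd) == 3L, nWindows >= 1, sitesPerWindow >= 1)
  res <- withSeed(deriveSeed(seed, "admixed_windows"), {
    nIntro <- round(introgressedFraction * nWindows)
    intro <- if (nIntro > 0) sort(sample.int(nWindows, nIntro)) else integer(0)
    total <- nWindows * sitesPerWindow
    winOf <- rep(seq_len(nWindows), each = sitesPerWindow)
    z <- rbeta(total, ancShape[1], ancShape[2])
    clamp <- function(x) pmin(1, pmax(0, x))
    p1 <- clamp(z + rnorm(total, 0, driftSd[1]))
    p2 <- clamp(z + rnorm(total, 0, driftSd[2]))
    p3 <- clamp(z + rnorm(total, 0, driftSd[3]))
    p4 <- rbeta(total, 0.5, 15)
    isIntro <- winOf %in% intro
    p2[isIntro] <- (1 - fAdmix) * p2[isIntro] + fAdmix * p3[isIntro]
    draw <- function(p, n) rbinom(length(p), n, p) / n
    # positions: sitesPerWindow evenly spread inside each tiled window
    off <- round(seq(1, windowSize, length.out = sitesPerWindow))
    pos <- as.integer((winOf - 1) * windowSize + off)
    list(freqs = data.frame(chrom = chromName, pos = pos,
                            p1 = draw(p1, nHap[1]), n1 = nHap[1],
                            p2 = draw(p2, nHap[2]), n2 = nHap[2],
                            p3 = draw(p3, nHap[3]), n3 = nHap[3],
                            p4 = draw(p4, nHap[4]), n4 = nHap[4],
                            genotypedFraction = 1),
         intro = intro)
  })
  list(freqs = res$freqs,
       truth = simTruth("simulate_admixed_windows", seed,
                        params = list(nWindows = nWindows,
                                      sitesPerWindow = sitesPerWindow,
                                      introgressedFraction =
                                        introgressedFraction,
                                      fAdmix = fAdmix, nHap = nHap,
                                      driftSd = driftSd,
                                      windowSize = windowSize),
                        truth = list(introgressedWindows = res$intro)))
}

#' Simulate an aligned codon pair with known synonymous divergence
#'
#' Draws an ancestor of random sense codons, then on each of the two
#' lineages applies synonymous substitutions as a Poisson process with
#' expectation `(dSTrue / 2) * S` and nonsynonymous substitutions with
#' expectation `(dNTrue / 2) * N` (`S`, `N` counted on the ancestor),
#' rejecting changes that would create stop codons. Realized substitution
#' counts are recorded in the truth sidecar.
#'
#' @param nCodons number of codons.
#' @param dSTrue,dNTrue target synonymous / nonsynonymous divergence
#'   (implied pS must stay below 0.5 to avoid saturation).
#' @param seed global seed.
#' @return list with `seqA`, `seqB` (character), `ancestor`, and `truth`.
#' @export
simulateCodonPair <- function(nCodons = 5000, dSTrue = 0.05, dNTrue = 0.01,
                              seed = 1) {
  stopifnot(nCodons >= 1, dSTrue >= 0, dNTrue >= 0)
  tab <- .codonTables()
  # pS ~ dS at these scales; refuse clearly saturated regimes
  if (dSTrue >= 0.5 || dNTrue >= 0.5)
    stop("dSTrue/dNTrue too large: simulated pair would be saturated",
         call. = FALSE)
  res <- withSeed(deriveSeed(seed, "codon_pair"), {
    anc <- sample(tab$sense, nCodons, replace = TRUE)
    S <- sum(tab$sites[anc, "s"])
    N <- sum(tab$sites[anc, "n"])
    evolve <- function(codons) {
      nS <- rpois(1L, dSTrue / 2 * S)
      nN <- rpois(1L, dNTrue / 2 * N)
      applyChanges <- function(codons, nEvents, kind) {
        done <- 0L
        while (done < nEvents) {
          i <- sample.int(length(codons), 1L)
          ch <- tab[[kind]][[codons[i]]]
          if (!length(ch)) next   # e.g. ATG/TGG have no synonymous change
          pick <- ch[[sample.int(length(ch), 1L)]]
          cd <- codons[i]
          substring(cd, as.integer(pick["pos"]), as.integer(pick["pos"])) <-
            pick["base"]
          codons[i] <- cd
          done <- done + 1L
        }
        codons
      }
      codons <- applyChanges(codons, nS, "syn")
      codons <- applyChanges(codons, nN, "nsyn")
      list(codons = codons, nS = nS, nN = nN)
    }
    a <- evolve(anc)
    b <- evolve(anc)
    list(anc = anc, a = a, b = b, S = S, N = N)
  })
  list(seqA = paste(res$a$codons, collapse = ""),
       seqB = paste(res$b$codons, collapse = ""),
       ancestor = paste(res$anc, collapse = ""),
       truth = simTruth("simulate_codon_pair", seed,
                        params = list(nCodons = nCodons, dSTrue = dSTrue,
                                      dNTrue = dNTrue),
                        truth = list(S = res$S, N = res$N,
                                     synSubstitutions = res$a$nS + res$b$nS,
                                     nonsynSubstitutions =
                                       res$a$nN + res$b$nN)))
}

#' Simulate a neutral SNP region with known diversity
#'
#' Places segregating sites uniformly along the region; the number of sites
#' is Poisson with mean `theta * L * a_n` (`a_n` the Watterson harmonic
#' factor for `n` haplotypes), the derived-allele count of each site is
#' drawn from the neutral frequency spectrum (probability proportional to
#' `1/k`), and carriers are assigned uniformly, so the expected per-site
#' diversity equals `theta`. Haplotypes are paired into phased diploid
#' samples for the VCF.
#'
#' @param lengthBases region length (default 100 kb).
#' @param nHaplotypes even number of haplotypes (default 20).
#' @param thetaPerSite population-scaled mutation rate per site (< 0.1).
#' @param chromName chromosome name.
#' @param seed global seed.
#' @return list with `sites` (a [VariantSites-class]), `vcf` (VCF v4.2 text
#'   lines, byte-reproducible from the seed), and `truth`.
#' @export
simulateSnpRegion <- function(lengthBases = 1e5, nHaplotypes = 20,
                              thetaPerSite = 0.01, chromName = "chr1",
                              seed = 1) {
  stopifnot(lengthBases >= 1, nHaplotypes >= 4, nHaplotypes %% 2 == 0,
            thetaPerSite >= 0, thetaPerSite < 0.1)
  bases <- c("A", "C", "G", "T")
  res <- withSeed(deriveSeed(seed, "snp_region"), {
    an <- sum(1 / seq_len(nHaplotypes - 1L))
    nSeg <- rpois(1L, thetaPerSite * lengthBases * an)
    nSeg <- min(nSeg, lengthBases)
    if (nSeg == 0L) {
      list(pos = integer(0), k = integer(0),
           gt = matrix(integer(0), 0L, nHaplotypes),
           ref = character(0), alt = character(0))
    } else {
      pos <- sort(sample.int(lengthBases, nSeg))
      kprob <- 1 / seq_len(nHaplotypes - 1L)
      k <- sample.int(nHaplotypes - 1L, nSeg, replace = TRUE, prob = kprob)
      gt <- matrix(0L, nSeg, nHaplotypes)
      for (i in seq_len(nSeg))
        gt[i, sample.int(nHaplotypes, k[i])] <- 1L
      ref <- sample(bases, nSeg, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                    character(1))
      list(pos = pos, k = k, gt = gt, ref = unname(ref), alt = unname(alt))
    }
  })
  samples <- sprintf("hap%02d", seq_len(nHaplotypes / 2L))
  sites <- VariantSites(rep(chromName, length(res$pos)), res$pos, res$ref,
                        res$alt, res$gt, samples)
  truth <- simTruth("simulate_snp_region", seed,
                    params = list(lengthBases = lengthBases,
                                  nHaplotypes = nHaplotypes,
                                  thetaPerSite = thetaPerSite,
                                  chromName = chromName),
                    truth = list(nSegregating = length(res$pos),
                                 derivedCounts = res$k))
  list(sites = sites, vcf = writeVcfSites(sites), truth = truth)
}
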