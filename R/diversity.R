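# Sliding-window nucleotide diversity, pairwise LD r2 and the
# one-degree-of-freedom allelic case/control chi-square association test.

#' Unbiased per-site nucleotide diversity
#'
#' `pi = 2 * k * (n - k) / (n * (n - 1))`, the expected heterozygosity of a
#' site with `k` derived alleles among `n` called alleles (sample-size
#' corrected). Symmetric in `k` and `n - k`.
#'
#' @param k derived-allele count(s), `0 <= k <= n`.
#' @param n called-allele count(s), `n >= 2`.
#' @return numeric vector of per-site diversity values.
#' @examples
#' sitePi(1, 2)   # 1: two sequences that differ
#' sitePi(2, 4)   # 2/3
#' @export
sitePi <- function(k, n) {
  if (any(n < 2)) stop("sitePi needs n >= 2 called alleles", call. = FALSE)
  if (any(k < 0) || any(k > n)) stop("k must lie in [0, n]", call. = FALSE)
  2 * k * (n - k) / (n * (n - 1))
}

#' @noRd
.siteCounts <- function(x) {
  gt <- genotypes(x)
  data.frame(chrom = variantInfo(x)$chrom, pos = variantInfo(x)$pos,
             k = rowSums(gt == 1L, na.rm = TRUE),
             n = rowSums(!is.na(gt)))
}

#' Sliding-window nucleotide diversity
#'
#' Sums [sitePi()] over the variants in each window and divides by the full
#' window size (monomorphic and uncalled positions contribute zero, the
#' convention of the standard VCF windowed-pi tools); pass `accessibleBases`
#' to divide by a different denominator. Windows with no variants are
#' reported with `pi = 0`. Sites with fewer than 2 called alleles are skipped.
#'
#' @param x a [VariantSites-class] object, sorted by (chrom, pos).
#' @param windowSize window length in bases (default 5 kb).
#' @param step window step (defaults to `windowSize`).
#' @param accessibleBases optional per-window denominator override.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `nVariants`, `sumSitePi`, `pi`.
#' @export
windowPi <- function(x, windowSize = 5000, step = windowSize,
                     accessibleBases = NULL) {
  st <- .siteCounts(x)
  assertSorted(st$chrom, st$pos)
  st <- st[st$n >= 2L, , drop = FALSE]
  st$pi <- if (nrow(st)) sitePi(st$k, st$n) else numeric(0)
  denom <- if (is.null(accessibleBases)) windowSize else accessibleBases
  out <- list()
  for (chr in unique(variantInfo(x)$chrom)) {
    f <- st[st$chrom == chr, , drop = FALSE]
    maxPos <- max(variantInfo(x)$pos[variantInfo(x)$chrom == chr])
    win <- tileWindows(maxPos, windowSize, step)
    for (w in seq_len(nrow(win))) {
      inw <- f$pos > win$start0[w] & f$pos <= win$end0[w]
      s <- sum(f$pi[inw])
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = win$start0[w] + 1L, end = win$end0[w],
        nVariants = sum(inw), sumSitePi = s, pi = s / denom)
    }
  }
  do.call(rbind, out)
}

#' One-degree-of-freedom allelic case/control chi-square test
#'
#' Plain Pearson chi-square on the 2 x 2 allele-count table (no continuity
#' correction), `df = 1`, upper-tail p - the standard allelic association
#' test for a biallelic SNP.
#'
#' @param caseAlt,caseRef alternate/reference allele counts in cases.
#' @param ctrlAlt,ctrlRef alternate/reference allele counts in controls.
#' @return list with `table` (2 x 2 counts), `chi2`, `df`, `p`.
#' @examples
#' allelicChisq(30, 10, 10, 30)  # chi2 = 20
#' @export
allelicChisq <- function(caseAlt, caseRef, ctrlAlt, ctrlRef) {
  tab <- matrix(c(caseAlt, caseRef, ctrlAlt, ctrlRef), nrow = 2L,
                byrow = TRUE,
                dimnames = list(c("case", "control"), c("alt", "ref")))
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(tab)
  if (n <= 0) stop("total count must be positive", call. = FALSE)
  r <- rowSums(tab)
  cs <- colSums(tab)
  if (any(r == 0) || any(cs == 0))
    stop("degenerate margin: allelic chi-square undefined", call. = FALSE)
  chi2 <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    (r[1] * r[2] * cs[1] * cs[2])
  list(table = tab, chi2 = unname(chi2), df = 1L,
       p = pchisq(unname(chi2), df = 1L, lower.tail = FALSE))
}

#' Per-SNP allelic association scan
#'
#' Applies [allelicChisq()] to every site, counting alternate/reference
#' alleles over called haplotypes in the case and control sample sets.
#' Sites with a degenerate margin are reported with `NA` statistics.
#'
#' @param x a [VariantSites-class] object.
#' @param caseSamples character vector of case sample names; remaining
#'   samples are controls (or give `controlSamples` explicitly).
#' @param controlSamples optional explicit control sample names.
#' @return data.frame with columns `chrom`, `pos`, `caseAlt`, `caseRef`,
#'   `ctrlAlt`, `ctrlRef`, `chi2`, `p`.
#' @export
assocScan <- function(x, caseSamples, controlSamples = NULL) {
  stopifnot(is(x, "VariantSites"))
  if (is.null(controlSamples))
    controlSamples <- setdiff(sampleNames(x), caseSamples)
  bad <- setdiff(c(caseSamples, controlSamples), sampleNames(x))
  if (length(bad))
    stop("unknown sample(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cnt <- function(samps) {
    g <- genotypes(x[, samps])
    cbind(alt = rowSums(g == 1L, na.rm = TRUE),
          ref = rowSums(g == 0L, na.rm = TRUE))
  }
  ca <- cnt(caseSamples)
  co <- cnt(controlSamples)
  res <- lapply(seq_len(nSites(x)), function(i) {
    r <- tryCatch(allelicChisq(ca[i, "alt"], ca[i, "ref"],
                               co[i, "alt"], co[i, "ref"]),
                  error = function(e) NULL)
    if (is.null(r)) c(NA_real_, NA_real_) else c(r$chi2, r$p)
  })
  res <- do.call(rbind, res)
  data.frame(chrom = variantInfo(x)$chrom, pos = variantInfo(x)$pos,
             caseAlt = ca[, "alt"], caseRef = ca[, "ref"],
             ctrlAlt = co[, "alt"], ctrlRef = co[, "ref"],
             chi2 = res[, 1], p = res[, 2])
}

#' Pairwise LD r-squared between two sites (haploid expansion)
#'
#' Treats each sample's two haploid calls as independent observations (the
#' unphased approximation) and computes
#' `r2 = (pAB - pA * pB)^2 / (pA (1-pA) pB (1-pB))` over observations called
#' at both sites. Returns `NA` with attribute `undefined = TRUE` when either
#' site is monomorphic among the jointly-called observations.
#'
#' @param a,b haploid 0/1 call vectors of equal length (NA = missing), e.g.
#'   rows of [genotypes()].
#' @return r-squared in \[0, 1\], or `NA` when undefined.
#' @export
ldR2 <- function(a, b) {
  if (length(a) != length(b))
    stop("call vectors must have equal length", call. = FALSE)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L)
    stop("need >= 2 jointly-called observations", call. = FALSE)
  a <- a[ok]
  b <- b[ok]
  pA <- mean(a)
  pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(structure(NA_real_, undefined = TRUE))
  pAB <- mean(a * b)
  unname((pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

#' Long-format pairwise LD table over a set of sites
#'
#' @param x a [VariantSites-class] object (all site pairs are computed, so
#'   keep the region small).
#' @return data.frame with columns `posA`, `posB`, `r2`.
#' @export
ldPairs <- function(x) {
  stopifnot(is(x, "VariantSites"))
  gt <- genotypes(x)
  pos <- variantInfo(x)$pos
  n <- nSites(x)
  if (n < 2L) return(data.frame(posA = integer(0), posB = integer(0),
                                r2 = numeric(0)))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  r2 <- vapply(seq_len(nrow(idx)), function(i) {
    v <- tryCatch(ldR2(gt[idx[i, 1], ], gt[idx[i, 2], ]),
                  error = function(e) NA_real_)
    as.numeric(v)
  }, numeric(1))
  data.frame(posA = pos[idx[, 1]], posB = pos[idx[, 2]], r2 = r2)
}
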