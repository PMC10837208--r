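# Patterson's D and Martin's fd in the allele-frequency form, block-jackknife
# significance, genomic window scans and top-quantile outlier calling.

#' Per-population derived-allele frequencies from SNP calls
#'
#' Computes, per site, the alternate (treated as derived) allele frequency
#' and called-allele count in each of the four populations `P1`, `P2`, `P3`
#' and outgroup `O`, plus the overall genotyped fraction. This table is the
#' input to [pattersonD()], [fdWindow()] and [scanWindows()].
#'
#' @param x a [VariantSites-class] object.
#' @param popmap data.frame with columns `sample`, `label` (labels `P1`,
#'   `P2`, `P3`, `O`; see [readPopMap()]).
#' @return data.frame with columns `chrom`, `pos`, `p1..p4`, `n1..n4`,
#'   `genotypedFraction`. Frequencies are `NA` where a population has no
#'   called allele.
#' @export
siteFrequencies <- function(x, popmap) {
  stopifnot(is(x, "VariantSites"))
  roles <- c("P1", "P2", "P3", "O")
  if (!all(roles %in% popmap$label))
    stop("popmap must assign all four roles P1, P2, P3, O", call. = FALSE)
  miss <- setdiff(popmap$sample, sampleNames(x))
  if (length(miss))
    stop("popmap sample(s) not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  gt <- genotypes(x)
  info <- variantInfo(x)
  out <- data.frame(chrom = info$chrom, pos = info$pos)
  hapOf <- function(samps) {
    idx <- match(samps, sampleNames(x))
    as.vector(rbind(2L * idx - 1L, 2L * idx))
  }
  for (k in seq_along(roles)) {
    cols <- hapOf(popmap$sample[popmap$label == roles[k]])
    sub <- gt[, cols, drop = FALSE]
    ncalled <- rowSums(!is.na(sub))
    kder <- rowSums(sub, na.rm = TRUE)
    out[[paste0("p", k)]] <- ifelse(ncalled > 0, kder / ncalled, NA_real_)
    out[[paste0("n", k)]] <- ncalled
  }
  used <- hapOf(popmap$sample)
  out$genotypedFraction <-
    rowSums(!is.na(gt[, used, drop = FALSE])) / length(used)
  out
}

#' ABBA and BABA site terms in the allele-frequency form
#'
#' `abba = (1-p1) * p2 * p3 * (1-p4)`; `baba = p1 * (1-p2) * p3 * (1-p4)`.
#' The outgroup enters through `(1 - p4)` rather than being assumed fixed.
#'
#' @param p1,p2,p3,p4 derived-allele frequencies (vectorized).
#' @return list with numeric vectors `abba` and `baba`.
#' @examples
#' siteTerms(0, 1, 1, 0)              # fixed ABBA pattern
#' siteTerms(0.2, 0.8, 0.6, 0)        # (0.384, 0.024)
#' @export
siteTerms <- function(p1, p2, p3, p4) {
  list(abba = (1 - p1) * p2 * p3 * (1 - p4),
       baba = p1 * (1 - p2) * p3 * (1 - p4))
}

#' Mark sites usable for the four-taxon statistics
#'
#' A "good" site has defined frequencies in all four populations, a genotyped
#' fraction at least `minGenotyped`, and is not monomorphic across all four
#' populations.
#' @noRd
.goodSites <- function(freqs, minGenotyped = 0.2) {
  p <- as.matrix(freqs[, c("p1", "p2", "p3", "p4")])
  defined <- rowSums(is.na(p)) == 0L
  mono <- defined & (rowSums(p) == 0 | rowSums(1 - p) == 0)
  defined & !mono & freqs$genotypedFraction >= minGenotyped
}

#' Patterson's D over a set of sites
#'
#' `D = sum(abba - baba) / sum(abba + baba)` over usable sites.
#'
#' @param freqs site-frequency table from [siteFrequencies()] (or any
#'   data.frame with columns `p1..p4`; `genotypedFraction` defaults to 1).
#' @param minGenotyped per-site genotyped-fraction filter.
#' @return list with `D`, `numerator`, `denominator`, `nSites`.
#' @export
pattersonD <- function(freqs, minGenotyped = 0) {
  if (is.null(freqs$genotypedFraction)) freqs$genotypedFraction <- 1
  use <- .goodSites(freqs, minGenotyped)
  f <- freqs[use, , drop = FALSE]
  if (!nrow(f)) stop("no usable sites", call. = FALSE)
  tm <- siteTerms(f$p1, f$p2, f$p3, f$p4)
  num <- sum(tm$abba - tm$baba)
  den <- sum(tm$abba + tm$baba)
  if (den == 0) stop("undefined D: zero ABBA+BABA denominator", call. = FALSE)
  list(D = num / den, numerator = num, denominator = den, nSites = nrow(f))
}

#' Block-jackknife z-score for Patterson's D
#'
#' Delete-one-block jackknife over contiguous genomic blocks of `blockSize`
#' bases. With fewer than 10 non-empty blocks the jackknife is refused. A
#' zero jackknife standard error (all blocks identical) is reported as a
#' signed infinite z-score.
#'
#' @inheritParams pattersonD
#' @param blockSize block length in bases.
#' @return list with `D`, `se`, `Z`, `nBlocks`.
#' @export
jackknifeZ <- function(freqs, blockSize = 3e5, minGenotyped = 0) {
  if (is.null(freqs$genotypedFraction)) freqs$genotypedFraction <- 1
  use <- .goodSites(freqs, minGenotyped)
  f <- freqs[use, , drop = FALSE]
  if (!nrow(f)) stop("no usable sites", call. = FALSE)
  block <- paste0(f$chrom, ":", floor((f$pos - 1) / blockSize))
  blocks <- unique(block)
  if (length(blocks) < 10L)
    stop("block jackknife needs >= 10 non-empty blocks (got ",
         length(blocks), ")", call. = FALSE)
  tm <- siteTerms(f$p1, f$p2, f$p3, f$p4)
  numB <- tapply(tm$abba - tm$baba, block, sum)
  denB <- tapply(tm$abba + tm$baba, block, sum)
  num <- sum(numB)
  den <- sum(denB)
  if (den == 0) stop("undefined D: zero denominator", call. = FALSE)
  D <- num / den
  thetas <- vapply(seq_along(numB), function(i) {
    (num - numB[i]) / (den - denB[i])
  }, numeric(1))
  B <- length(thetas)
  se <- sqrt((B - 1) / B * sum((thetas - mean(thetas))^2))
  # a numerically-zero SE (all blocks identical) is flagged as infinite Z
  Z <- if (se <= 1e-14 * max(1, abs(D))) sign(D) * Inf else D / se
  list(D = D, se = se, Z = Z, nBlocks = B)
}

#' Martin's fd for one window of sites
#'
#' The numerator is the D numerator `sum(abba - baba)`; the denominator
#' recomputes the same quantity with both `p2` and `p3` replaced, site by
#' site, by the donor frequency `pD = max(p2, p3)` (its maximal value under
#' complete introgression from the dynamic donor). `fd` is reported missing
#' when the numerator is non-positive (negative-D windows are outside the
#' statistic's domain) or when the window filters fail.
#'
#' @inheritParams pattersonD
#' @param minSites minimum number of good sites required in the window.
#' @param minGenotyped per-site genotyped-fraction filter.
#' @return list with `fd`, `nGood`, `passed`, `numerator`, `denominator`.
#' @examples
#' fdWindow(data.frame(p1 = 0, p2 = 0.4, p3 = 0.8, p4 = 0), minSites = 1)
#' @export
fdWindow <- function(freqs, minSites = 100, minGenotyped = 0.2) {
  if (is.null(freqs$genotypedFraction)) freqs$genotypedFraction <- 1
  use <- .goodSites(freqs, minGenotyped)
  f <- freqs[use, , drop = FALSE]
  nGood <- nrow(f)
  passed <- nGood >= minSites
  if (!passed)
    return(list(fd = NA_real_, nGood = nGood, passed = FALSE,
                numerator = NA_real_, denominator = NA_real_))
  tm <- siteTerms(f$p1, f$p2, f$p3, f$p4)
  num <- sum(tm$abba - tm$baba)
  pd <- pmax(f$p2, f$p3)
  tmD <- siteTerms(f$p1, pd, pd, f$p4)
  den <- sum(tmD$abba - tmD$baba)
  fd <- if (num <= 0 || den <= 0) NA_real_ else num / den
  list(fd = fd, nGood = nGood, passed = TRUE, numerator = num,
       denominator = den)
}

#' Windowed D and fd scan over genome-ordered sites
#'
#' Tiles windows of `windowSize` bases (default step = size, non-overlapping)
#' along each chromosome and computes, per window, the number of good sites,
#' Patterson's D and fd with the window filters. Windows are 0-based
#' half-open internally; the returned `start`/`end` are 1-based inclusive.
#'
#' @inheritParams fdWindow
#' @param windowSize window length in bases (default 300 kb).
#' @param step window step (defaults to `windowSize`).
#' @return data.frame with columns `chrom`, `start`, `end`, `nGood`, `D`,
#'   `fd`, `passed`.
#' @export
scanWindows <- function(freqs, windowSize = 3e5, step = windowSize,
                        minSites = 100, minGenotyped = 0.2) {
  if (is.null(freqs$genotypedFraction)) freqs$genotypedFraction <- 1
  assertSorted(freqs$chrom, freqs$pos)
  out <- list()
  for (chr in unique(freqs$chrom)) {
    f <- freqs[freqs$chrom == chr, , drop = FALSE]
    win <- tileWindows(max(f$pos), windowSize, step)
    nonOverlap <- step == windowSize
    if (nonOverlap) {
      wid <- (f$pos - 1) %/% windowSize + 1  # 1-based window index
      grp <- split(seq_len(nrow(f)), wid)
    }
    for (w in seq_len(nrow(win))) {
      idx <- if (nonOverlap) grp[[as.character(w)]]
             else which(f$pos > win$start0[w] & f$pos <= win$end0[w])
      fw <- f[idx, , drop = FALSE]
      fdres <- fdWindow(fw, minSites, minGenotyped)
      Dres <- tryCatch(pattersonD(fw, minGenotyped), error = function(e) NULL)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = win$start0[w] + 1L, end = win$end0[w],
        nGood = fdres$nGood,
        D = if (is.null(Dres)) NA_real_ else Dres$D,
        fd = fdres$fd, passed = fdres$passed)
    }
  }
  do.call(rbind, out)
}

#' Top-quantile fd outlier windows
#'
#' Flags windows whose fd reaches the `1 - topFraction` quantile
#' (linear-interpolation quantile) of the non-missing fd values. Missing
#' values are excluded from both the quantile and the candidates, and at
#' least `minValues` non-missing values are required (otherwise the top
#' fraction is empty by construction). If ties at the threshold inflate the
#' outlier set beyond the nominal size, the lowest-index subset is kept and
#' the tie is logged.
#'
#' @param fd numeric vector of per-window fd values (NA = missing).
#' @param topFraction outlier tail fraction (default 0.005, the top 0.5%).
#' @param minValues minimum number of non-missing values required.
#' @param missingAsZero treat missing fd values as 0 instead of excluding
#'   them. Windows whose fd is undefined (non-positive numerator: no excess
#'   of the discordant pattern) carry no evidence of introgression; placing
#'   them at fd = 0 keeps them in the genome-wide distribution, so the top
#'   0.5% of windows is 0.5% of the genome rather than 0.5% of the
#'   positive-D subset. Set `FALSE` to exclude missing values from both the
#'   quantile and the candidates.
#' @return integer vector of outlier window indices (possibly empty).
#' @export
outlierWindows <- function(fd, topFraction = 0.005, minValues = 200L,
                           missingAsZero = TRUE) {
  if (missingAsZero) fd[is.na(fd)] <- 0
  ok <- which(!is.na(fd))
  if (length(ok) < minValues) return(integer(0))
  thr <- quantile(fd[ok], probs = 1 - topFraction, names = FALSE, type = 7)
  idx <- ok[fd[ok] >= thr]
  cap <- max(1L, ceiling(topFraction * length(ok)))
  if (length(idx) > cap) {
    nthr <- sum(fd[idx] == thr)
    if (nthr > 1L)
      hiLog("tie at the fd outlier threshold (", nthr,
            " windows); keeping the first ", cap)
    idx <- idx[seq_len(cap)]
  }
  idx
}
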