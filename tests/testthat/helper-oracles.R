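# Independent oracles and small builders shared across tests.
options(hybridils.verbose = FALSE)

# Brute-force F2 genotype frequencies by direct enumeration of the 16
# male x female gamete combinations. Written independently of the package
# implementation: haplotypes are enumerated as (locus1, locus2) functional
# indicators and classes accumulated into a 3x3 matrix keyed by dosage.
oracleF2 <- function(tauM, tauF, v, r, phase = "repulsion") {
  haps <- list(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  hapProb <- function(tau) {
    p <- numeric(4)
    for (h in 1:4) {
      parental <- if (phase == "repulsion")
        !identical(haps[[h]][1], haps[[h]][2])  # (1,0) and (0,1)
      else identical(haps[[h]][1], haps[[h]][2])
      p[h] <- if (parental) (1 - r) / 2 else r / 2
    }
    p[4] <- p[4] * tau   # haplotype (0,0) is the doubly-null one
    p / sum(p)
  }
  pm <- hapProb(tauM)
  pf <- hapProb(tauF)
  out <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    d1 <- haps[[i]][1] + haps[[j]][1]
    d2 <- haps[[i]][2] + haps[[j]][2]
    out[3 - d1, 3 - d2] <- out[3 - d1, 3 - d2] + pm[i] * pf[j]
  }
  out[3, 3] <- out[3, 3] * v
  out / sum(out)
}

# Frequency table builder for the four-taxon statistics.
freqTable <- function(p1, p2, p3, p4, pos = seq_along(p1), chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, p1 = p1, p2 = p2, p3 = p3, p4 = p4,
             genotypedFraction = 1)
}

# Additive quartet distances from branch lengths, sister pair (a, b).
additiveQuartet <- function(labels, sister, tips, internal) {
  d <- matrix(0, 4, 4, dimnames = list(labels, labels))
  path <- function(x, y) {
    bothSis <- x %in% sister && y %in% sister
    oneSis <- xor(x %in% sister, y %in% sister)
    tips[[x]] + tips[[y]] + if (bothSis) 0 else if (oneSis) internal else 0
  }
  for (i in 1:3) for (j in (i + 1):4) {
    d[i, j] <- d[j, i] <- path(labels[i], labels[j])
  }
  d
}
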