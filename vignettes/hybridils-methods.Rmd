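---
title: "Models and methods in hybridils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hybridils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridils)
options(hybridils.verbose = FALSE)
```

`hybridils` packages two connected analyses from the population genetics of
rice reproductive barriers: (i) a quantitative model of segregation
distortion caused by reciprocal loss of function at a duplicated gene pair,
and (ii) the molecular-evolution toolkit used to decide whether the
phylogenetic discordance observed at such loci reflects incomplete lineage
sorting (ILS) or introgression. This vignette explains the models, their
assumptions, the defaults, and what the synthetic-data generators do and do
not emulate.

## 1. The two-locus gamete-elimination model

Consider two unlinked duplicated loci, each segregating a functional (`F`)
and a loss-of-function (`n`) allele, with the F1 hybrid doubly heterozygous
in *repulsion*: each parental line contributes one functional and one null
allele, on opposite loci, so the haplotype carrying no functional copy at
either locus is a recombinant. Gametes lacking any functional copy are
assumed to fail with sex-specific severity:

* `tauM`, `tauF` — relative viability of the doubly-null gamete through
  pollen and ovules (`0` = complete elimination, `1` = Mendelian),
* `v` — relative viability of the doubly-homozygous-null zygote,
* `r` — recombination fraction between the loci (`0.5` for different
  chromosomes, the default).

`gameteDistribution()` renormalizes the four haplotype frequencies after
selection; `f2GenotypeFreqs()` convolves the male and female gamete
distributions over the sixteen gamete combinations, applies `v` to the
doubly-homozygous-null class only, and renormalizes. Selection on other
genotype classes, gametophyte-level mechanism, and more than two loci are
out of model. With full elimination in both sexes (`tauM = tauF = 0`) the
locus marginals are 4:4:1 — the shape observed in a distorted F2 family of
226 plants segregating 99:113:14, which `chisqGof()` rejects against
Mendelian 1:2:1 at $\chi^2 \approx 63.9$, $p \approx 1.3\times10^{-14}$,
while the 4:4:1 expectation fits far better ($p \approx 0.039$):

```{r seg}
chisqGof(c(99, 113, 14), c(1, 2, 1))$p
chisqGof(c(99, 113, 14), c(4, 4, 1))$p
locusMarginal(f2GenotypeFreqs(TransmissionModel(0, 0, 1)), 2)
```

Genotype classes are always ordered by functional-allele dosage
(`FF`, `Fn`, `nn`). In the mapping cross the *functional* allele at locus 1
is the one carried by the African-derived line, so published parent-label
tables at locus 1 read in the reverse order; `readCountsTable()` performs
that mapping.

### Fitting and identifiability

`fitTransmission()` maximizes the multinomial likelihood over free
parameters by a step-0.01 grid followed by bounded quasi-Newton refinement —
deterministic, with grid ties broken toward smaller viabilities. Two
identifiability facts shape the defaults:

* the F2 genotype distribution is symmetric under exchanging the sexes, so
  `tauM` and `tauF` are only identifiable as an unordered pair; the default
  ties them (`free = c("tau", "v")`);
* a 3-class marginal supports at most two free parameters.

Information about `v` comes almost exclusively from the
doubly-homozygous-null cell, whose expected count is $n q^2 v$ with $q \le
0.25$ the post-selection doubly-null gamete frequency. Under strong
elimination that cell is essentially empty and `v` is unidentifiable — the
biologically interesting regime is the statistically hopeless one. The
parameter-recovery benchmark therefore uses a mild-elimination regime,
`tau = 0.8`, `v = 0.2` at `n = 10000` (expected doubly-null count ≈ 90,
giving `sd(v̂) ≈ 0.025`), where a ±0.05 recovery band is a meaningful ~2σ
check rather than a coin flip.

### Cross compatibility

Varieties fall into three classes at the pair: Class I (`F`/`F`), Class II
(`F` at locus 1 only), Class III (`F` at locus 2 only). `classifyCross()`
predicts breakdown exactly when the two parents are null at complementary
loci (II × III), the configuration that lets a doubly-null recombinant
arise — the classical duplicate-gene-loss incompatibility.

## 2. Synonymous divergence and dating

`ng86Pair()` implements Nei–Gojobori (1986) counting on an in-frame pairwise
codon alignment: per-position synonymous-site fractions renormalized to
exclude stop-creating changes; difference counts averaged over all
substitution orderings between differing codons, excluding pathways through
stop codons (in the degenerate case where every ordering passes through a
stop, the average is taken without the exclusion); Jukes–Cantor correction
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$ applied to both proportions, with
a hard error at $p \ge 3/4$ (saturation). Gap- or `N`-containing codon
columns are dropped pairwise with a logged count. This is a single
deterministic default rather than a menu of codon models; ML codon models
and transition/transversion weighting are out of scope.

Dating uses the molecular clock $T = K_s / 2\lambda$ with the grass
synonymous rate $\lambda = 6.5\times10^{-9}$ site⁻¹ yr⁻¹ (overridable).
`ksPeak()` extracts the mode of a Ks cohort by Gaussian KDE (Silverman
bandwidth, 512-point grid spanning the data range) — appropriate when a
cohort of single-copy ortholog pairs dates one split and the distribution
is unimodal with possible contamination.

```{r dating}
divergenceTime(0.01196) / 1e6   # MYA
```

## 3. ILS versus introgression

Both ILS and introgression produce gene trees discordant with the species
tree; they differ in *when* the discordant lineages coalesce. ILS retains
ancestral polymorphism, so coalescence predates the species split;
introgression transfers material after it. `classifyDiscordance()` encodes
this as a point comparison with a relative tolerance band (default
`relTol = 0.1`; no formal uncertainty treatment is attempted, the band is a
conservative surrogate): older than `tSplit * (1 + relTol)` is ILS, younger
than `tSplit * (1 - relTol)` is introgression, in between is ambiguous. The
rule is scale invariant. `ilsScan()` composes the pieces: the species split
is dated from the Ks peak of an ortholog cohort, each candidate gene from
its own `ng86Pair()` distance; failed pairs are flagged, never dropped.

Topology itself is called by `quartetTopology()` from pairwise distances via
the four-point condition — the minimal machinery that yields the
decision-relevant output (the sister pair), replacing an external ML tree
search. The margin between the two smallest four-point sums is reported as
support; ties go to the lexicographically first pair with margin 0.

## 4. Windowed D and fd

For four populations `((P1, P2), P3, O)` with per-site derived-allele
frequencies, `siteTerms()` uses the frequency form
`abba = (1-p1) p2 p3 (1-p4)`, `baba = p1 (1-p2) p3 (1-p4)` — the outgroup
enters through `(1-p4)` rather than being assumed fixed. A *good* site has
defined frequencies in all four populations, genotyped fraction ≥ 0.2, and
is not monomorphic across all four. Defaults follow the windowed-scan
convention: 300-kb windows, step = size, at least 100 good sites per
window. `pattersonD()` aggregates; `jackknifeZ()` attaches a delete-one
block-jackknife z-score (≥ 10 blocks required; zero jackknife variance is
flagged as infinite Z rather than hidden).

`fdWindow()` normalizes the D numerator by its value under complete
introgression from a per-site dynamic donor `pD = max(p2, p3)`. `fd` is
reported missing when the numerator is non-positive (negative-D windows are
outside the statistic's domain) or the filters fail.

**Outlier convention.** A region is called introgressed when its fd reaches
the top 0.5% of the genome-wide distribution. Under the null, about half of
all windows have a non-positive numerator and hence missing fd; excluding
them would make "top 0.5%" mean 0.5% *of the positive-D subset*, half the
genome-wide count, and would structurally cap the recall of any outlier
scan at ~50% when the introgressed fraction equals the outlier fraction.
`outlierWindows()` therefore places no-evidence windows at `fd = 0` by
default (`missingAsZero = TRUE`), keeping the quantile genome-wide;
exclusion semantics remain available. Ties at the threshold are truncated
to the nominal set size, lowest indices first, with a logged message.

## 5. Diversity, LD and association

`sitePi()` is the unbiased per-site heterozygosity `2k(n-k)/(n(n-1))`;
`windowPi()` sums it over 5-kb windows and divides by the *full* window
size — monomorphic and uncalled positions count as invariant, matching the
convention of the standard VCF windowed-π tools; `accessibleBases`
overrides the denominator. `allelicChisq()` is the standard
one-degree-of-freedom Pearson test on the 2×2 allele table, no continuity
correction. `ldR2()` treats a sample's two haploid calls as independent
observations (the unphased haploid-expansion approximation; an EM haplotype
estimator is deliberately not implemented) and returns undefined, not an
error, for monomorphic pairs.

## 6. What the generators emulate — and what they do not

Each pipeline stage has a seeded generator whose truth it must recover;
every generator derives an RNG stream from `(seed, generator name)`,
restores the caller's RNG state, and records a `simTruth()` sidecar
(YAML-serializable) so datasets are reproducible byte for byte.

* `simulateF2Counts()` — multinomial families from `f2GenotypeFreqs()`;
  default size 226 plants, the observed family size.
* `simulateCodonPair()` — Poisson synonymous/nonsynonymous substitutions at
  rates `(dS/2)·S`, `(dN/2)·N` per lineage on a uniform sense-codon
  ancestor, rejecting stop-creating changes. Because both the generator and
  the estimator live in the Jukes–Cantor world, recovery tests are exact in
  expectation — a deliberate oracle-alignment choice over realism (no codon
  usage bias, no rate heterogeneity).
* `simulateQuartetAlignment()` — i.i.d. JC sites down a rooted quartet.
* `simulateSnpRegion()` — Poisson number of segregating sites
  `theta · L · a_n`, derived counts ∝ 1/k (the neutral frequency spectrum),
  uniform carrier assignment; expected per-site π equals θ by construction.
  No linkage, recombination map, or demography.
* `simulateAdmixedWindows()` — per-site ancestral frequency
  `z ~ Beta(1, 3)`; P1 and P2 drift from it with sd 0.02 (recently diverged
  sisters), P3 with sd 0.25 (a deeper split), outgroup ~ Beta(0.5, 15) near
  zero; sample frequencies are binomial draws at 40/40/40/20 haplotypes
  (panels of a few dozen accessions). The null D symmetry comes from P1/P2
  exchangeability — `E[abba - baba] = E[(1-p4) p3 (p2-p1)] = 0` whenever
  `(p1, p2)` are exchangeable with difference independent of `p3` — rather
  than from identical P2/P3 marginals. Introgressed windows replace `p2`
  with `(1-f)·p2 + f·p3` before sampling. Frequencies are manipulated
  directly instead of running a coalescent simulation: the D/fd stages
  consume frequencies, so this is the minimal sufficient structure. The
  default scan is 800 windows × 500 sites (rice SNP densities of ~1–2/kb
  make several hundred good sites per 300-kb window typical), sized so that
  the top-0.5% rule has adequate support on both sides.

Consequently, passing tests demonstrate correctness of the statistics and
calibration *under these idealized models* — independent sites, no
structure misspecification, known ancestral states. They do not demonstrate
robustness to real-data pathologies (reference bias, ancestral-state error,
linked selection), which is the usual caveat for this statistic family.

## 7. Numerical and design choices

* Windows are 0-based half-open internally; all user-facing coordinates are
  1-based inclusive (VCF convention). Missing genotypes are never imputed;
  they reduce per-site called-allele counts.
* Problem sizes in tests and the acceptance run: 375-point model grid
  against independent enumeration (agreement to 1e-12); 100 replicates each
  for parameter recovery (n = 10,000 plants), NG86 recovery (5,000-codon
  pairs at dS = 0.05), null jackknife calibration (40 windows × 120 sites),
  and π recovery (100-kb regions at θ = 0.01); 50 seeds × 800 windows for
  outlier recall.
* The grid-then-refine fit replaces boundary log-likelihoods of −∞ with a
  large finite penalty so bounded BFGS can evaluate them; refinement can
  never return a point worse than the grid optimum.
* `ksPeak()` returns the common value directly when all inputs are equal
  (the KDE bandwidth rule is undefined there).
* The observed-family χ² is the plain Pearson statistic. On (99, 113, 14)
  vs 1:2:1 it gives p = 1.31e-14; published figure legends sometimes print
  a slightly different value for this family (consistent with a test
  variant or rounding), so downstream conclusions should rely on the
  p < 0.001 bound, which is robust to the variant.

## 8. Known limitations

Single-pair NG86 only (no multi-sequence Ks, no ortholog inference); no
coalescent-model ILS probabilities or concordance factors; no f3/f4-ratio
or phased-haplotype statistics; association testing is the plain allelic
test without population-structure correction; LD is the unphased
approximation. The command-line surface is the R API plus
`scripts/acceptance.R`; the package is meant to be driven from R.
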