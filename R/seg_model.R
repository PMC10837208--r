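#' Gamete frequencies under sex-specific elimination of the doubly-null class
#'
#' An F1 doubly heterozygous for functional/null alleles at two duplicated
#' loci produces four haplotype classes. In repulsion phase (the mapping-cross
#' configuration: each parent contributed one functional and one null allele
#' on opposite loci) the parental haplotypes are `F1n2` and `n1F2`, each with
#' pre-selection frequency `(1-r)/2`, and the recombinants `F1F2` and `n1n2`
#' each `r/2`; in coupling phase the roles are exchanged. The doubly-null
#' haplotype `n1n2` (no functional copy at either locus) is then weighted by
#' the sex-specific viability `tauM`/`tauF` and the distribution renormalized.
#'
#' @param model a [TransmissionModel-class].
#' @param sex `"male"` (pollen) or `"female"` (ovule).
#' @param phase `"repulsion"` (default) or `"coupling"`.
#' @return named numeric vector of the four haplotype frequencies
#'   `F1F2, F1n2, n1F2, n1n2` (`F` = functional, `n` = null; locus order 1, 2).
#' @examples
#' gameteDistribution(TransmissionModel(tauM = 0, tauF = 0), "male")
#' @export
gameteDistribution <- function(model, sex = c("male", "female"),
                               phase = c("repulsion", "coupling")) {
  stopifnot(is(model, "TransmissionModel"))
  validObject(model)
  sex <- match.arg(sex)
  phase <- match.arg(phase)
  r <- recFraction(model)
  par <- (1 - r) / 2
  rec <- r / 2
  g <- if (phase == "repulsion")
    c(F1F2 = rec, F1n2 = par, n1F2 = par, n1n2 = rec)
  else
    c(F1F2 = par, F1n2 = rec, n1F2 = rec, n1n2 = par)
  tau <- if (sex == "male") tauM(model) else tauF(model)
  g["n1n2"] <- g["n1n2"] * tau
  tot <- sum(g)
  if (tot <= 0)
    stop("all gametes eliminated: empty gamete distribution", call. = FALSE)
  g / tot
}

#' Fast internal gamete distribution (no S4 construction)
#' @noRd
.gameteFast <- function(tau, r, phase) {
  par <- (1 - r) / 2
  rec <- r / 2
  g <- if (phase == "repulsion") c(rec, par, par, rec)
       else c(par, rec, rec, par)
  g[4L] <- g[4L] * tau
  g / sum(g)
}

#' Fast internal joint genotype frequencies; returns plain 3x3 matrix
#' (rows locus 1, cols locus 2, order FF, Fn, nn)
#' @noRd
.f2Fast <- function(tauMv, tauFv, v, r, phase = "repulsion") {
  gm <- .gameteFast(tauMv, r, phase)
  gf <- .gameteFast(tauFv, r, phase)
  pair <- outer(gm, gf)                       # 4 x 4 male x female
  joint <- matrix(0, 3L, 3L)
  for (i in 1:4) for (j in 1:4) {
    a <- .gameteRow[i] + .gameteRow[j]        # functional dosage locus 1
    b <- .gameteCol[i] + .gameteCol[j]        # functional dosage locus 2
    joint[3L - a, 3L - b] <- joint[3L - a, 3L - b] + pair[i, j]
  }
  joint[3L, 3L] <- joint[3L, 3L] * v
  joint / sum(joint)
}

.gameteRow <- c(1L, 1L, 0L, 0L)  # functional dosage at locus 1 per haplotype
.gameteCol <- c(1L, 0L, 1L, 0L)  # functional dosage at locus 2 per haplotype

#' Expected F2 joint genotype frequencies under the transmission model
#'
#' Sums the products of sex-specific gamete frequencies over the 4 x 4
#' male-by-female gamete combinations, applies the zygote viability `v` to the
#' doubly-homozygous-null class only, and renormalizes. Classes are ordered by
#' functional-allele dosage per locus: `FF` (homozygous functional), `Fn`
#' (heterozygous), `nn` (homozygous null).
#'
#' @inheritParams gameteDistribution
#' @return a 3 x 3 matrix of genotype frequencies (rows = locus 1 classes,
#'   columns = locus 2 classes), summing to 1.
#' @examples
#' f2GenotypeFreqs(TransmissionModel())             # Mendelian dihybrid
#' f2GenotypeFreqs(TransmissionModel(0, 0, 1, 0.5)) # full gamete elimination
#' @export
f2GenotypeFreqs <- function(model, phase = c("repulsion", "coupling")) {
  phase <- match.arg(phase)
  stopifnot(is(model, "TransmissionModel"))
  validObject(model)
  joint <- .f2Fast(tauM(model), tauF(model), zygoteViability(model),
                   recFraction(model), phase)
  if (any(!is.finite(joint)))
    stop("no viable zygotes under this model", call. = FALSE)
  cls <- c("FF", "Fn", "nn")
  dimnames(joint) <- list(locus1 = cls, locus2 = cls)
  joint
}

#' Marginal genotype frequencies at one locus
#'
#' @param joint a 3 x 3 joint genotype frequency matrix from
#'   [f2GenotypeFreqs()].
#' @param locus 1 or 2.
#' @return numeric 3-vector `(FF, Fn, nn)` summing to 1.
#' @export
locusMarginal <- function(joint, locus) {
  stopifnot(is.matrix(joint), all(dim(joint) == c(3L, 3L)))
  if (!length(locus) == 1L || !locus %in% c(1, 2))
    stop("locus must be 1 or 2", call. = FALSE)
  if (locus == 1) rowSums(joint) else colSums(joint)
}

#' Pearson chi-square goodness of fit of counts to an expected ratio
#'
#' Plain Pearson statistic `sum((obs - exp)^2 / exp)` with
#' `exp = total * ratio / sum(ratio)`, `df = classes - 1`, upper-tail p-value;
#' no continuity correction.
#'
#' @param counts non-negative integer counts (total > 0).
#' @param expectedRatio positive expected ratio, same length as `counts`
#'   (e.g. `c(1, 2, 1)` for a Mendelian monohybrid F2).
#' @return list with elements `statistic`, `df`, `p`, `expected`.
#' @examples
#' chisqGof(c(99, 113, 14), c(1, 2, 1))  # strong segregation distortion
#' chisqGof(c(99, 113, 14), c(4, 4, 1))  # gamete-elimination expectation
#' @export
chisqGof <- function(counts, expectedRatio) {
  counts <- as.numeric(counts)
  expectedRatio <- as.numeric(expectedRatio)
  if (length(counts) != length(expectedRatio))
    stop("counts and expectedRatio must have the same length", call. = FALSE)
  if (any(counts < 0) || sum(counts) <= 0)
    stop("counts must be non-negative with positive total", call. = FALSE)
  if (any(expectedRatio <= 0))
    stop("expected ratio entries must be positive", call. = FALSE)
  expected <- sum(counts) * expectedRatio / sum(expectedRatio)
  stat <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  list(statistic = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE), expected = expected)
}

#' @noRd
.modelProbs <- function(tauMv, tauFv, v, r, jointData, phase = "repulsion") {
  jf <- .f2Fast(tauMv, tauFv, v, r, phase)
  if (jointData) as.vector(t(jf)) else colSums(jf)
}

#' @noRd
.countsLogLik <- function(counts, probs) {
  use <- counts > 0
  # a huge finite penalty keeps boundary evaluations usable by L-BFGS-B
  if (any(probs[use] <= 0)) return(-1e12)
  sum(counts[use] * log(probs[use]))
}

#' Fit transmission parameters to F2 genotype counts
#'
#' Maximizes the multinomial log-likelihood of observed counts under
#' [f2GenotypeFreqs()] over the chosen free parameters, by a coarse grid
#' (step 0.01) followed by local refinement with bounded BFGS. The optimizer
#' is deterministic; grid ties are broken toward the smaller gamete viability.
#'
#' Marginal 3-class data support at most two free parameters
#' (identifiability); note also that `tauM` and `tauF` are only jointly
#' identifiable from F2 genotype data (the genotype distribution is symmetric
#' under exchanging the sexes), which is why the default ties them
#' (`free = c("tau", "v")`).
#'
#' @param counts named counts in canonical class order: length 3
#'   (`FF, Fn, nn` marginal) or 9 (joint, see [genotypeClassNames()]).
#'   Unnamed vectors of the right length are accepted as already canonical.
#' @param free character vector of free parameters, a subset of
#'   `"tau"` (ties `tauM = tauF`), `"tauM"`, `"tauF"`, `"v"`.
#' @param r fixed recombination fraction (default 0.5: unlinked loci).
#' @param fixed named list of values for the non-free parameters
#'   (defaults: `tauM = tauF = v = 1`).
#' @param phase F1 linkage phase (see [gameteDistribution()]).
#' @param gridStep coarse grid step.
#' @return a [FitResult-class].
#' @examples
#' sim <- simulateF2Counts(5000, TransmissionModel(0.2, 0.2, 0.8), seed = 1)
#' fitTransmission(sim$counts, free = c("tau", "v"))
#' @export
fitTransmission <- function(counts, free = c("tau", "v"), r = 0.5,
                            fixed = list(), phase = "repulsion",
                            gridStep = 0.01) {
  counts <- unlist(counts)
  if (!length(counts) %in% c(3L, 9L))
    stop("counts must be a 3-class marginal or 9-class joint table",
         call. = FALSE)
  jointData <- length(counts) == 9L
  allowed <- c("tau", "tauM", "tauF", "v")
  if (!length(free) || !all(free %in% allowed))
    stop("free must be a non-empty subset of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  if ("tau" %in% free && any(c("tauM", "tauF") %in% free))
    stop("'tau' (tied) cannot be combined with 'tauM'/'tauF'", call. = FALSE)
  nFree <- length(free)
  if (!jointData && nFree > 2L)
    stop("marginal 3-class data identify at most 2 free parameters",
         call. = FALSE)
  base <- list(tauM = 1, tauF = 1, v = 1)
  base[names(fixed)] <- fixed
  expand <- function(theta) {
    p <- base
    for (k in seq_along(free)) {
      if (free[k] == "tau") p$tauM <- p$tauF <- theta[k]
      else p[[free[k]]] <- theta[k]
    }
    p
  }
  objective <- function(theta) {
    p <- expand(theta)
    .countsLogLik(counts, .modelProbs(p$tauM, p$tauF, p$v, r, jointData,
                                      phase))
  }
  grid <- seq(0, 1, by = gridStep)
  thetas <- as.matrix(do.call(expand.grid, rep(list(grid), nFree)))
  ll <- apply(thetas, 1L, objective)
  # ties broken toward smaller parameter values: expand.grid enumerates in
  # increasing order and which.max takes the first maximum
  best <- thetas[which.max(ll), ]
  opt <- suppressWarnings(optim(best, objective, method = "L-BFGS-B",
                                lower = rep(0, nFree), upper = rep(1, nFree),
                                control = list(fnscale = -1)))
  if (opt$value < max(ll)) {  # refinement must never lose to the grid
    opt$par <- best
    opt$value <- max(ll)
    opt$convergence <- 0L
  }
  p <- expand(opt$par)
  new("FitResult",
      model = TransmissionModel(p$tauM, p$tauF, p$v, r),
      logLik = opt$value, converged = opt$convergence == 0L,
      free = as.character(free))
}

#' Allele-class constructor for a pure-line parent
#'
#' Varieties fall into three functional classes at the duplicated pair:
#' Class I carries functional copies at both loci, Class II only at locus 1,
#' Class III only at locus 2. A line null at both loci is not viable and is
#' rejected.
#'
#' @param locus1Functional,locus2Functional logical scalars.
#' @return named logical vector of length 2 with class `"AlleleClass"`.
#' @export
alleleClass <- function(locus1Functional, locus2Functional) {
  stopifnot(is.logical(locus1Functional), is.logical(locus2Functional))
  if (!locus1Functional && !locus2Functional)
    stop("a line null at both loci is not viable", call. = FALSE)
  structure(c(locus1 = locus1Functional, locus2 = locus2Functional),
            class = "AlleleClass")
}

#' @rdname alleleClass
#' @param class `"I"`, `"II"` or `"III"`.
#' @export
hwsClass <- function(class = c("I", "II", "III")) {
  class <- match.arg(class)
  switch(class,
         I   = alleleClass(TRUE, TRUE),
         II  = alleleClass(TRUE, FALSE),
         III = alleleClass(FALSE, TRUE))
}

#' Predict cross compatibility from parental allele classes
#'
#' A cross is incompatible exactly when the F1 is heterozygous for a
#' loss-of-function allele at both loci - one parent null at locus 1 and the
#' other null at locus 2 - so that a doubly-null recombinant gamete (and the
#' sterile doubly-null zygote) can arise in the F2. The predicate is symmetric
#' in its arguments.
#'
#' @param parentA,parentB [alleleClass()] objects (viable pure lines).
#' @return `"compatible"` or `"incompatible"`.
#' @examples
#' classifyCross(hwsClass("III"), hwsClass("II"))  # incompatible
#' classifyCross(hwsClass("II"), hwsClass("II"))   # compatible
#' @export
classifyCross <- function(parentA, parentB) {
  stopifnot(inherits(parentA, "AlleleClass"), inherits(parentB, "AlleleClass"))
  incompat <- (!parentA["locus1"] && !parentB["locus2"]) ||
    (!parentB["locus1"] && !parentA["locus2"])
  if (incompat) "incompatible" else "compatible"
}
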