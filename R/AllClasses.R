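#' Transmission model for a duplicated-gene-loss gamete barrier
#'
#' Parameters of the two-locus gamete-elimination model. The doubly-null
#' haplotype (no functional copy at either duplicated locus) passes through
#' pollen with relative viability `tauM` and through ovules with `tauF`;
#' the doubly-homozygous-null zygote survives with relative viability `v`;
#' `r` is the recombination fraction between the two loci. With
#' `tauM = tauF = v = 1` the model reduces to a Mendelian dihybrid.
#'
#' @slot tauM numeric in \[0,1\], male (pollen) viability of the doubly-null
#'   gamete.
#' @slot tauF numeric in \[0,1\], female (ovule) viability of the doubly-null
#'   gamete.
#' @slot v numeric in \[0,1\], viability of the doubly-homozygous-null zygote.
#' @slot r recombination fraction in \[0, 0.5\] between the two loci.
#' @export
setClass("TransmissionModel",
  representation(tauM = "numeric", tauF = "numeric", v = "numeric",
                 r = "numeric"),
  prototype(tauM = 1, tauF = 1, v = 1, r = 0.5))

setValidity("TransmissionModel", function(object) {
  msg <- character(0)
  chk1 <- function(x, nm, hi = 1) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > hi)
      sprintf("%s must be a single value in [0, %s]", nm, hi) else character(0)
  }
  msg <- c(chk1(object@tauM, "tauM"), chk1(object@tauF, "tauF"),
           chk1(object@v, "v"), chk1(object@r, "r", 0.5))
  if (length(msg)) msg else TRUE
})

#' Construct a TransmissionModel
#'
#' @param tauM,tauF viability in \[0,1\] of the doubly-null gamete through
#'   pollen / ovules.
#' @param v viability in \[0,1\] of the doubly-homozygous-null zygote.
#' @param r recombination fraction in \[0,0.5\]; 0.5 for unlinked loci.
#' @return a [TransmissionModel-class] object.
#' @examples
#' TransmissionModel(tauM = 0, tauF = 0, v = 1)
#' @export
TransmissionModel <- function(tauM = 1, tauF = 1, v = 1, r = 0.5) {
  new("TransmissionModel", tauM = as.numeric(tauM), tauF = as.numeric(tauF),
      v = as.numeric(v), r = as.numeric(r))
}

#' @describeIn TransmissionModel-class male gamete viability accessor
#' @param object,x a `TransmissionModel`
#' @export
setGeneric("tauM", function(x) standardGeneric("tauM"))
#' @export
setMethod("tauM", "TransmissionModel", function(x) x@tauM)

#' @describeIn TransmissionModel-class female gamete viability accessor
#' @export
setGeneric("tauF", function(x) standardGeneric("tauF"))
#' @export
setMethod("tauF", "TransmissionModel", function(x) x@tauF)

#' @describeIn TransmissionModel-class zygote viability accessor
#' @export
setGeneric("zygoteViability", function(x) standardGeneric("zygoteViability"))
#' @export
setMethod("zygoteViability", "TransmissionModel", function(x) x@v)

#' @describeIn TransmissionModel-class recombination fraction accessor
#' @export
setGeneric("recFraction", function(x) standardGeneric("recFraction"))
#' @export
setMethod("recFraction", "TransmissionModel", function(x) x@r)

setMethod("show", "TransmissionModel", function(object) {
  cat("TransmissionModel: tauM =", object@tauM, " tauF =", object@tauF,
      " v =", object@v, " r =", object@r, "\n")
  if (object@tauM == 1 && object@tauF == 1 && object@v == 1)
    cat("  (Mendelian dihybrid limit)\n")
})

#' Fit of the transmission model to F2 genotype counts
#'
#' @slot model the estimated [TransmissionModel-class].
#' @slot logLik multinomial log-likelihood at the estimate.
#' @slot converged logical; optimizer convergence flag.
#' @slot free character; names of the freely estimated parameters
#'   (subset of `"tau"`, `"tauM"`, `"tauF"`, `"v"`).
#' @export
setClass("FitResult",
  representation(model = "TransmissionModel", logLik = "numeric",
                 converged = "logical", free = "character"))

setMethod("show", "FitResult", function(object) {
  cat("FitResult (free:", paste(object@free, collapse = ", "), ")\n")
  show(object@model)
  cat("  logLik =", format(object@logLik, digits = 8),
      " converged =", object@converged, "\n")
})

#' @describeIn FitResult-class estimated model accessor
#' @param x a `FitResult`
#' @export
setGeneric("fittedModel", function(x) standardGeneric("fittedModel"))
#' @export
setMethod("fittedModel", "FitResult", function(x) x@model)

#' @importFrom stats logLik
#' @export
setMethod("logLik", "FitResult", function(object, ...) object@logLik)

#' Nei-Gojobori (1986) divergence estimate for one codon-alignment pair
#'
#' Site and difference counts with Jukes-Cantor-corrected distances.
#' Invariants: `S + N = 3 * nCodons`, `Sd <= S`, `Nd <= N`,
#' `dS >= pS` and `dN >= pN` where defined.
#'
#' @slot S,N synonymous / nonsynonymous site counts (real, averaged over the
#'   two sequences).
#' @slot Sd,Nd synonymous / nonsynonymous difference counts (real; pathway
#'   averaged).
#' @slot pS,pN proportions of differences per site.
#' @slot dS,dN Jukes-Cantor-corrected distances (Ks and Ka).
#' @slot nCodons number of codon columns compared.
#' @slot nDropped codon columns dropped for gaps/ambiguity.
#' @export
setClass("KsResult",
  representation(S = "numeric", N = "numeric", Sd = "numeric", Nd = "numeric",
                 pS = "numeric", pN = "numeric", dS = "numeric", dN = "numeric",
                 nCodons = "integer", nDropped = "integer"))

setValidity("KsResult", function(object) {
  msg <- character(0)
  if (abs(object@S + object@N - 3 * object@nCodons) > 1e-6)
    msg <- c(msg, "S + N must equal 3 * nCodons")
  if (object@Sd > object@S + 1e-9 || object@Nd > object@N + 1e-9)
    msg <- c(msg, "difference counts cannot exceed site counts")
  if (length(msg)) msg else TRUE
})

setMethod("show", "KsResult", function(object) {
  cat(sprintf("KsResult over %d codons (%d dropped)\n",
              object@nCodons, object@nDropped))
  cat(sprintf("  S=%.3f N=%.3f Sd=%.4f Nd=%.4f\n",
              object@S, object@N, object@Sd, object@Nd))
  cat(sprintf("  pS=%.6f pN=%.6f dS(Ks)=%.6f dN(Ka)=%.6f\n",
              object@pS, object@pN, object@dS, object@dN))
})

#' @describeIn KsResult-class synonymous (Ks) distance accessor
#' @param x a `KsResult`
#' @export
setGeneric("dS", function(x) standardGeneric("dS"))
#' @export
setMethod("dS", "KsResult", function(x) x@dS)

#' @describeIn KsResult-class nonsynonymous (Ka) distance accessor
#' @export
setGeneric("dN", function(x) standardGeneric("dN"))
#' @export
setMethod("dN", "KsResult", function(x) x@dN)

#' @describeIn KsResult-class all fields as a one-row data.frame
#' @param row.names,optional,... passed over from the generic, unused
#' @export
setMethod("as.data.frame", "KsResult",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(S = x@S, N = x@N, Sd = x@Sd, Nd = x@Nd, pS = x@pS, pN = x@pN,
               dS = x@dS, dN = x@dN, nCodons = x@nCodons,
               nDropped = x@nDropped)
  })

#' Biallelic SNP sites with per-haplotype calls
#'
#' Container for the common currency of the diversity, LD, association and
#' ABBA-BABA statistics: one row per biallelic SNP, and an integer matrix of
#' haploid calls (0 = reference, 1 = alternate, NA = missing) with two columns
#' per diploid sample (suffixes `_1`/`_2`).
#'
#' @slot info data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @slot gt integer matrix, `nSites x (2 * length(samples))`.
#' @slot samples character vector of sample names.
#' @export
setClass("VariantSites",
  representation(info = "data.frame", gt = "matrix", samples = "character"))

setValidity("VariantSites", function(object) {
  msg <- character(0)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, "info needs columns chrom, pos, ref, alt")
  else {
    if (any(object@info$pos < 1)) msg <- c(msg, "pos must be >= 1")
    if (any(object@info$ref == object@info$alt))
      msg <- c(msg, "ref must differ from alt")
  }
  if (nrow(object@gt) != nrow(object@info))
    msg <- c(msg, "gt must have one row per site")
  if (ncol(object@gt) != 2L * length(object@samples))
    msg <- c(msg, "gt must have two haploid columns per sample")
  if (!all(object@gt %in% c(0L, 1L, NA_integer_)))
    msg <- c(msg, "calls must be 0, 1 or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a VariantSites object
#'
#' @param chrom,pos,ref,alt per-site fields (`pos` 1-based).
#' @param gt integer matrix of haploid calls (0/1/NA), two columns per sample.
#' @param samples sample names.
#' @return a [VariantSites-class] object.
#' @export
VariantSites <- function(chrom, pos, ref, alt, gt, samples) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  colnames(gt) <- paste0(rep(samples, each = 2L), c("_1", "_2"))
  new("VariantSites",
      info = data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                        ref = as.character(ref), alt = as.character(alt)),
      gt = gt, samples = as.character(samples))
}

#' @describeIn VariantSites-class number of sites
#' @param x,object a `VariantSites`
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @export
setMethod("nSites", "VariantSites", function(x) nrow(x@info))

#' @describeIn VariantSites-class site table accessor (chrom/pos/ref/alt)
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' @export
setMethod("variantInfo", "VariantSites", function(x) x@info)

#' @describeIn VariantSites-class haploid call matrix accessor
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @export
setMethod("genotypes", "VariantSites", function(x) x@gt)

#' @describeIn VariantSites-class sample name accessor
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))
#' @export
setMethod("sampleNames", "VariantSites", function(x) x@samples)

#' @describeIn VariantSites-class subset sites (i) and/or samples (j, by name
#'   or index)
#' @param i site indices
#' @param j sample names or indices
#' @param drop ignored
#' @export
setMethod("[", "VariantSites", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSites(x))
  samples <- x@samples
  cols <- seq_len(ncol(x@gt))
  if (!missing(j)) {
    jj <- if (is.character(j)) match(j, samples) else j
    if (anyNA(jj)) stop("unknown sample(s): ",
                        paste(j[is.na(jj)], collapse = ", "), call. = FALSE)
    samples <- samples[jj]
    cols <- as.vector(rbind(2L * jj - 1L, 2L * jj))
  }
  VariantSites(x@info$chrom[i], x@info$pos[i], x@info$ref[i], x@info$alt[i],
               x@gt[i, cols, drop = FALSE], samples)
})

setMethod("show", "VariantSites", function(object) {
  cat(sprintf("VariantSites: %d biallelic SNPs x %d samples (%d haplotypes)\n",
              nSites(object), length(object@samples), ncol(object@gt)))
  if (nSites(object) > 0) {
    cat("  ", paste0(head(object@info$chrom, 1), ":",
                     head(object@info$pos, 1)), "...\n")
  }
})
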