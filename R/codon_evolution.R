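# Nei-Gojobori (1986) synonymous/nonsynonymous divergence with Jukes-Cantor
# correction, Ks-peak extraction and molecular-clock dating.

.codonEnv <- new.env(parent = emptyenv())

#' Codon bookkeeping tables from the universal genetic code
#' @noRd
.codonTables <- function() {
  if (!is.null(.codonEnv$tab)) return(.codonEnv$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  names(aa) <- codons
  bases <- c("A", "C", "G", "T")
  sites <- matrix(NA_real_, length(codons), 2L,
                  dimnames = list(codons, c("s", "n")))
  synCh <- vector("list", length(codons))   # synonymous non-stop changes
  nsynCh <- vector("list", length(codons))  # nonsynonymous non-stop changes
  names(synCh) <- names(nsynCh) <- codons
  for (cd in codons) {
    if (aa[cd] == "*") next
    s <- 0
    syn <- nsyn <- list()
    for (pos in 1:3) {
      cur <- substring(cd, pos, pos)
      alts <- setdiff(bases, cur)
      nSyn <- nTot <- 0L
      for (b in alts) {
        mut <- cd
        substring(mut, pos, pos) <- b
        if (aa[mut] == "*") next
        nTot <- nTot + 1L
        if (aa[mut] == aa[cd]) {
          nSyn <- nSyn + 1L
          syn[[length(syn) + 1L]] <- c(pos = pos, base = b)
        } else {
          nsyn[[length(nsyn) + 1L]] <- c(pos = pos, base = b)
        }
      }
      if (nTot > 0L) s <- s + nSyn / nTot
    }
    sites[cd, ] <- c(s, 3 - s)
    synCh[[cd]] <- syn
    nsynCh[[cd]] <- nsyn
  }
  .codonEnv$tab <- list(aa = aa, sites = sites, syn = synCh, nsyn = nsynCh,
                        sense = codons[aa != "*"])
  .codonEnv$tab
}

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' At each codon position the synonymous-site contribution is the fraction of
#' single-base changes that are synonymous, among changes not creating a stop
#' codon; the nonsynonymous count is the complement, so `s + n = 3` exactly.
#'
#' @param codon a 3-letter sense codon over `A C G T` (universal code).
#' @return named numeric vector `c(s = , n = )`.
#' @examples
#' codonSiteCounts("GGG")  # fourfold-degenerate third position: s = 1
#' codonSiteCounts("TTT")  # s = 1/3
#' @export
codonSiteCounts <- function(codon) {
  tab <- .codonTables()
  codon <- toupper(codon)
  if (!codon %in% rownames(tab$sites))
    stop("not a codon over {A,C,G,T}: ", codon, call. = FALSE)
  if (tab$aa[codon] == "*")
    stop("stop codon has no defined site counts: ", codon, call. = FALSE)
  c(s = unname(tab$sites[codon, "s"]), n = unname(tab$sites[codon, "n"]))
}

#' Pathway-averaged difference counts between two codons
#' @noRd
.codonPathDiffs <- function(c1, c2, tab) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(k,
                  list(1L),
                  list(c(1L, 2L), c(2L, 1L)),
                  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  walk <- function(ord) {
    cur <- c1
    sd <- nd <- 0
    for (step in ord) {
      p <- pos[step]
      nxt <- cur
      substring(nxt, p, p) <- substring(c2, p, p)
      if (tab$aa[nxt] == "*") return(NULL)   # pathway through a stop codon
      if (tab$aa[nxt] == tab$aa[cur]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- lapply(perms, walk)
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) {
    # every ordering passes through a stop codon (degenerate); fall back to
    # averaging over all orderings without the stop exclusion
    walkAll <- function(ord) {
      cur <- c1; sd <- nd <- 0
      for (step in ord) {
        p <- pos[step]
        nxt <- cur
        substring(nxt, p, p) <- substring(c2, p, p)
        if (tab$aa[nxt] != "*" && tab$aa[cur] != "*" &&
            tab$aa[nxt] == tab$aa[cur]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- lapply(perms, walkAll)
    ok <- rep(TRUE, length(res))
  }
  m <- colMeans(do.call(rbind, res[ok]))
  c(sd = m[1], nd = m[2])
}

#' @noRd
.asCodonString <- function(x) {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) x <- as.character(x)
  toupper(as.character(x))
}

#' Nei-Gojobori divergence for one pair of aligned coding sequences
#'
#' Counts synonymous/nonsynonymous sites (averaged over the two sequences)
#' and differences (averaged over all substitution orderings between
#' differing codons, excluding pathways through stop codons), then applies
#' the Jukes-Cantor correction `d = -3/4 * log(1 - 4/3 * p)` to both
#' proportions. Codon columns containing `N` or `-` in either sequence are
#' dropped pairwise with a logged count.
#'
#' @param seqA,seqB aligned coding sequences of equal length divisible by 3
#'   (character or `DNAString`); no internal stop codons.
#' @return a [KsResult-class].
#' @examples
#' a <- strrep("GGG", 50)
#' b <- paste0(strrep("GGG", 49), "GGA")
#' ng86Pair(a, b)  # Sd = 1, dS ~ 0.020272
#' @export
ng86Pair <- function(seqA, seqB) {
  tab <- .codonTables()
  a <- .asCodonString(seqA)
  b <- .asCodonString(seqB)
  if (length(a) != 1L || length(b) != 1L)
    stop("seqA and seqB must each be a single sequence", call. = FALSE)
  if (nchar(a) != nchar(b))
    stop("aligned sequences must have equal length", call. = FALSE)
  if (nchar(a) %% 3L != 0L)
    stop("alignment length must be divisible by 3", call. = FALSE)
  starts <- seq(1L, nchar(a), by = 3L)
  ca <- substring(a, starts, starts + 2L)
  cb <- substring(b, starts, starts + 2L)
  keep <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  nDropped <- sum(!keep)
  if (nDropped) hiLog("dropped ", nDropped, " gap/ambiguous codon column(s)")
  ca <- ca[keep]
  cb <- cb[keep]
  if (!length(ca)) stop("no comparable codon columns left", call. = FALSE)
  if (any(tab$aa[ca] == "*") || any(tab$aa[cb] == "*"))
    stop("internal stop codon in coding sequence", call. = FALSE)
  S <- (sum(tab$sites[ca, "s"]) + sum(tab$sites[cb, "s"])) / 2
  N <- (sum(tab$sites[ca, "n"]) + sum(tab$sites[cb, "n"])) / 2
  diff <- which(ca != cb)
  Sd <- Nd <- 0
  for (i in diff) {
    d <- .codonPathDiffs(ca[i], cb[i], tab)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  if (S <= 0) stop("no synonymous sites: dS undefined", call. = FALSE)
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p, what) {
    if (p >= 3 / 4)
      stop("saturation: ", what, " = ", format(p),
           " >= 3/4, Jukes-Cantor correction undefined", call. = FALSE)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  new("KsResult", S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
      dS = jc(pS, "pS"), dN = jc(pN, "pN"),
      nCodons = length(ca), nDropped = as.integer(nDropped))
}

#' Divergence time from a synonymous distance
#'
#' Molecular-clock conversion `T = Ks / (2 * lambda)` with the grass
#' synonymous substitution rate `lambda = 6.5e-9` per site per year by
#' default.
#'
#' @param ks synonymous distance (Ks), >= 0.
#' @param lambda substitution rate per site per year, > 0.
#' @return time in years (divide by 1e6 for MYA).
#' @examples
#' divergenceTime(0.01196) / 1e6  # 0.92 MYA
#' @export
divergenceTime <- function(ks, lambda = 6.5e-9) {
  if (any(ks < 0)) stop("ks must be >= 0", call. = FALSE)
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  ks / (2 * lambda)
}

#' Modal value of a Ks distribution
#'
#' Gaussian kernel density (Silverman's rule-of-thumb bandwidth) evaluated on
#' a 512-point grid spanning the data range; the peak is the grid argmax.
#'
#' @param values numeric vector of Ks estimates (>= 10 finite values).
#' @return list with elements `values`, `peak`, `density` (the
#'   [stats::density] object, or NULL when all values are equal).
#' @export
ksPeak <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 10L)
    stop("ksPeak needs at least 10 finite values", call. = FALSE)
  if (diff(range(values)) == 0)
    return(list(values = values, peak = values[1L], density = NULL))
  d <- density(values, bw = "nrd0", n = 512L,
               from = min(values), to = max(values))
  list(values = values, peak = d$x[which.max(d$y)], density = d)
}
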