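# Quartet topology calling from pairwise distances and the coalescence-time
# rule separating incomplete lineage sorting (ILS) from introgression.

#' Quartet topology from pairwise distances (four-point condition)
#'
#' For the three pairings of the ingroup taxa `{A, B, C}` with outgroup `O`,
#' computes the four-point sum `d(x, y) + d(z, O)`; the pairing minimizing
#' the sum is called the sister pair, with support margin equal to the
#' difference between the two smallest sums. Ties are reported with margin 0
#' and the lexicographically first sister pair.
#'
#' @param d symmetric 4 x 4 distance matrix (or `dist`) with taxon labels
#'   as dimnames; distances in substitutions/site or Ks.
#' @param outgroup label of the outgroup taxon (one of the four).
#' @return list with elements `sister` (character 2-vector), `margin`,
#'   `sums` (named 3-vector of four-point sums), `outgroup`.
#' @examples
#' d <- matrix(0.2, 4, 4, dimnames = list(c("A","B","C","O"), c("A","B","C","O")))
#' diag(d) <- 0; d["A","B"] <- d["B","A"] <- 0.02
#' d["A","C"] <- d["C","A"] <- d["B","C"] <- d["C","B"] <- 0.10
#' quartetTopology(d, "O")
#' @export
quartetTopology <- function(d, outgroup) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == 4L, ncol(d) == 4L)
  labs <- rownames(d)
  if (is.null(labs) || !identical(labs, colnames(d)))
    stop("distance matrix needs matching row/column taxon labels",
         call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12)
    stop("distance matrix must be symmetric", call. = FALSE)
  if (!outgroup %in% labs)
    stop("outgroup must be one of: ", paste(labs, collapse = ", "),
         call. = FALSE)
  ing <- sort(setdiff(labs, outgroup))
  pairs <- list(c(ing[1], ing[2]), c(ing[1], ing[3]), c(ing[2], ing[3]))
  sums <- vapply(pairs, function(p) {
    z <- setdiff(ing, p)
    d[p[1], p[2]] + d[z, outgroup]
  }, numeric(1))
  names(sums) <- vapply(pairs, paste, character(1), collapse = ",")
  best <- which.min(sums)   # first minimum = lexicographically first pair
  margin <- sort(sums)[2L] - sums[best]
  list(sister = pairs[[best]], margin = unname(margin), sums = sums,
       outgroup = outgroup)
}

#' Newick string for a quartet topology call
#'
#' @param topo result of [quartetTopology()].
#' @return single Newick string `((sister1,sister2),(other,outgroup));`.
#' @export
quartetNewick <- function(topo) {
  other <- setdiff(names(topo$sums), paste(topo$sister, collapse = ","))
  rest <- setdiff(unlist(strsplit(other, ",")), topo$sister)
  rest <- unique(rest)
  sprintf("((%s,%s),(%s,%s));", topo$sister[1], topo$sister[2],
          rest[1], topo$outgroup)
}

#' Classify gene-tree discordance as ILS or introgression
#'
#' Regions discordant through incomplete lineage sorting coalesce earlier
#' (deeper in time) than the speciation event, while introgressed regions
#' coalesce later. With relative tolerance `relTol`, the call is `"ILS"` when
#' `tGene > tSplit * (1 + relTol)`, `"introgression"` when
#' `tGene < tSplit * (1 - relTol)`, and `"ambiguous"` otherwise. The rule is
#' scale-invariant, so `tGene` and `tSplit` may be in years or MYA as long as
#' they agree.
#'
#' @param tGene gene coalescence time (>= 0).
#' @param tSplit species divergence time (>= 0).
#' @param relTol relative tolerance band (>= 0, default 0.1).
#' @return list with elements `tGene`, `tSplit`, `relTol`, `call`.
#' @examples
#' classifyDiscordance(0.92e6, 0.062e6)$call  # "ILS"
#' @export
classifyDiscordance <- function(tGene, tSplit, relTol = 0.1) {
  if (any(c(tGene, tSplit) < 0) || relTol < 0)
    stop("times and relTol must be non-negative", call. = FALSE)
  call <- if (tGene > tSplit * (1 + relTol)) "ILS"
  else if (tGene < tSplit * (1 - relTol)) "introgression"
  else "ambiguous"
  list(tGene = tGene, tSplit = tSplit, relTol = relTol, call = call)
}

#' ILS-vs-introgression scan over candidate gene pairs
#'
#' The species split time is dated from the modal Ks of a single-copy
#' ortholog cohort (`tSplit = divergenceTime(ksPeak(speciesKs)$peak)`);
#' each candidate gene pair across the discordant taxa is dated from its own
#' NG86 synonymous distance and classified with [classifyDiscordance()].
#' Gene pairs that fail (e.g. synonymous saturation) are flagged, not
#' dropped.
#'
#' @param genePairs named list; each element a list/character vector of the
#'   two aligned coding sequences (see [ng86Pair()]).
#' @param speciesKs numeric vector of Ks values from single-copy ortholog
#'   pairs between the two species (>= 10 values).
#' @param lambda substitution rate per site per year.
#' @param relTol relative tolerance for the time comparison.
#' @return data.frame with one row per gene: `gene`, `dS`, `tGene`, `tSplit`
#'   (years), `call`, `flagged`, `note`.
#' @export
ilsScan <- function(genePairs, speciesKs, lambda = 6.5e-9, relTol = 0.1) {
  stopifnot(is.list(genePairs), length(genePairs) >= 1L)
  if (is.null(names(genePairs)))
    names(genePairs) <- paste0("gene", seq_along(genePairs))
  tSplit <- divergenceTime(ksPeak(speciesKs)$peak, lambda)
  rows <- lapply(names(genePairs), function(g) {
    pair <- genePairs[[g]]
    res <- tryCatch(ng86Pair(pair[[1]], pair[[2]]), error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(gene = g, dS = NA_real_, tGene = NA_real_,
                        tSplit = tSplit, call = NA_character_,
                        flagged = TRUE, note = conditionMessage(res)))
    tg <- divergenceTime(dS(res), lambda)
    data.frame(gene = g, dS = dS(res), tGene = tg, tSplit = tSplit,
               call = classifyDiscordance(tg, tSplit, relTol)$call,
               flagged = FALSE, note = "")
  })
  do.call(rbind, rows)
}
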