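#' @noRd
hiVerbose <- function() isTRUE(getOption("hybridils.verbose", TRUE))

#' Log a message to standard error, honouring `options(hybridils.verbose)`
#' @noRd
hiLog <- function(...) {
  if (hiVerbose()) message("[hybridils] ", ...)
}

#' Derive a per-generator RNG stream from a global seed
#'
#' Stable arithmetic hash of `(seed, name)`; keeps the derived seed inside
#' the 32-bit integer range R requires.
#'
#' @param seed integer global seed.
#' @param name character scalar naming the stream (generator name).
#' @return integer seed.
#' @export
deriveSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * (131 * seq_len(nchar(name))))
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

#' Run an expression under a local, restored RNG state
#' @noRd
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Tile 0-based half-open windows over [0, maxEnd)
#'
#' @return data.frame with columns `start0`, `end0` (0-based half-open).
#' @noRd
tileWindows <- function(maxEnd, size, step = size) {
  stopifnot(size > 0, step > 0)
  if (maxEnd <= 0) return(data.frame(start0 = integer(0), end0 = integer(0)))
  starts <- seq(0, maxEnd - 1e-9, by = step)
  # drop trailing windows that start at/after maxEnd (possible when step<size)
  starts <- starts[starts < maxEnd]
  data.frame(start0 = starts, end0 = starts + size)
}

#' Check that a site table is sorted by (chrom, pos)
#' @noRd
assertSorted <- function(chrom, pos, what = "sites") {
  o <- order(chrom, pos)
  if (!identical(o, seq_along(pos)))
    stop(what, " must be sorted by (chrom, pos)", call. = FALSE)
  invisible(TRUE)
}
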