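#' Read a FASTA file of nucleotide records
#'
#' Thin validating front end over [Biostrings::readDNAStringSet()]. Records
#' are returned in file order, line wrapping is removed and sequences are
#' upper-cased. Only the alphabet `A C G T N -` is accepted.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] (names = record ids).
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT"), f)
#' readFasta(f)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank))
    stop("FASTA format error: file is empty: ", path, call. = FALSE)
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">"))
    stop("FASTA format error at line ", first,
         ": expected a '>' header", call. = FALSE)
  hdr <- which(startsWith(lines, ">"))
  bad <- hdr[!nzchar(trimws(substring(lines[hdr], 2L)))]
  if (length(bad))
    stop("FASTA format error at line ", bad[1L], ": empty header id",
         call. = FALSE)
  # validate sequence lines up front: readDNAStringSet silently drops
  # letters outside the DNA alphabet
  seqLines <- setdiff(which(nzchar(trimws(lines))), hdr)
  bad <- seqLines[grepl("[^ACGTNacgtn-]", trimws(lines[seqLines]))]
  if (length(bad))
    stop("FASTA format error at line ", bad[1L],
         ": letters outside {A,C,G,T,N,-}", call. = FALSE)
  x <- suppressWarnings(Biostrings::readDNAStringSet(path))
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  # keep only the first whitespace-delimited token as the id
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences to FASTA
#'
#' @param x a named [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("all records must be named", call. = FALSE)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read biallelic SNP sites from a VCF file
#'
#' Reads a VCF v4.x text file via [vcfR::read.vcfR()], keeps biallelic SNP
#' records only (multi-allelic and indel records are skipped with a logged
#' count), and parses GT fields into haploid calls. `./.` and `.` are parsed
#' as missing; phased (`|`) and unphased (`/`) separators are both accepted.
#' Missing genotypes are never imputed.
#'
#' @param path path to a VCF file.
#' @param samples optional character vector restricting (and ordering) the
#'   samples kept; unknown names are an error.
#' @return a [VariantSites-class] object (positions 1-based, as in the VCF).
#' @export
readVcfSites <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("VCF contains no variant records: ", path,
                       call. = FALSE)
  gtmat <- vcf@gt
  if (is.null(gtmat) || !ncol(gtmat))
    stop("VCF format error: no genotype (FORMAT/sample) columns", call. = FALSE)
  fmt <- strsplit(gtmat[, 1L], ":", fixed = TRUE)
  if (any(vapply(fmt, function(f) !"GT" %in% f, logical(1))))
    stop("VCF format error: GT missing from FORMAT field", call. = FALSE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T") &
    fix$REF != fix$ALT
  nskip <- sum(!keep)
  if (nskip) hiLog("skipped ", nskip, " non-biallelic-SNP record(s)")
  if (!any(keep))
    stop("no biallelic SNP records in ", path, call. = FALSE)
  allSamples <- colnames(gtmat)[-1L]
  if (is.null(samples)) samples <- allSamples
  miss <- setdiff(samples, allSamples)
  if (length(miss))
    stop("sample(s) not in VCF header: ", paste(miss, collapse = ", "),
         call. = FALSE)
  gtRaw <- vcfR::extract.gt(vcf, element = "GT")[keep, samples, drop = FALSE]
  nsite <- sum(keep)
  gt <- matrix(NA_integer_, nrow = nsite, ncol = 2L * length(samples))
  for (s in seq_along(samples)) {
    g <- gtRaw[, s]
    g[is.na(g)] <- "."
    parts <- strsplit(g, "[/|]")
    a1 <- vapply(parts, `[`, character(1), 1L)
    a2 <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else ".",
                 character(1))
    gt[, 2L * s - 1L] <- suppressWarnings(as.integer(a1))
    gt[, 2L * s] <- suppressWarnings(as.integer(a2))
  }
  bad <- gt[!is.na(gt)]
  if (any(bad < 0L | bad > 1L))
    stop("VCF format error: allele indices other than 0/1 at biallelic sites",
         call. = FALSE)
  VariantSites(fix$CHROM[keep], as.integer(fix$POS[keep]), fix$REF[keep],
               fix$ALT[keep], gt, samples)
}

#' Write a VariantSites object as minimal VCF v4.2 text
#'
#' Emits GT-only diploid records (phased `|` separator); the byte-for-byte
#' layout is deterministic so generator output can be reproduced exactly.
#'
#' @param x a [VariantSites-class] object.
#' @param path output path, or `NULL` to return the lines invisibly.
#' @return the VCF text lines, invisibly.
#' @export
writeVcfSites <- function(x, path = NULL) {
  stopifnot(is(x, "VariantSites"))
  info <- variantInfo(x)
  gt <- genotypes(x)
  n <- length(sampleNames(x))
  fmt <- function(a) ifelse(is.na(a), ".", as.character(a))
  body <- character(0)
  if (nrow(info) > 0L) {
    cols <- vapply(seq_len(n), function(s)
      paste0(fmt(gt[, 2L * s - 1L]), "|", fmt(gt[, 2L * s])),
      character(nrow(gt)))
    if (nrow(info) == 1L) cols <- matrix(cols, nrow = 1L)
    body <- paste(info$chrom, info$pos, ".", info$ref, info$alt, ".", "PASS",
                  ".", "GT", apply(cols, 1L, paste, collapse = "\t"),
                  sep = "\t")
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=hybridils",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sampleNames(x)), collapse = "\t"))
  lines <- c(header, body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

.marginalNames <- list(
  functional = c("FF", "Fn", "nn"),
  locus1 = c("W1W1", "W1G1", "G1G1"),
  locus2 = c("W2W2", "W2G2", "G2G2"))

#' Canonical two-locus genotype class names
#'
#' Marginal classes are named by functional-allele dosage `FF`, `Fn`, `nn`;
#' joint classes are `"<locus1>/<locus2>"` combinations in row-major order.
#' Parent-label names from the mapping cross are also understood by
#' [readCountsTable()]: `W2W2/W2G2/G2G2` at locus 2 map directly onto
#' `FF/Fn/nn` (the functional allele at locus 2 is the Asian one), while
#' `W1W1/W1G1/G1G1` at locus 1 map onto `nn/Fn/FF` (at locus 1 the Asian
#' allele is the silenced, null one).
#'
#' @param joint if `TRUE` return the 9 joint class names, else the 3 marginal
#'   names.
#' @return character vector of class names.
#' @export
genotypeClassNames <- function(joint = FALSE) {
  m <- .marginalNames$functional
  if (!joint) return(m)
  as.vector(t(outer(m, m, paste, sep = "/")))
}

#' @noRd
.canonicalizeCountNames <- function(nm) {
  canon <- genotypeClassNames(FALSE)
  mapMarg <- function(v) {
    if (all(v %in% canon)) return(v)
    if (all(v %in% .marginalNames$locus2))
      return(canon[match(v, .marginalNames$locus2)])
    if (all(v %in% .marginalNames$locus1))  # locus-1 null allele is W1
      return(rev(canon)[match(v, .marginalNames$locus1)])
    NULL
  }
  if (all(!grepl("/", nm))) {
    out <- mapMarg(nm)
    if (is.null(out) || anyDuplicated(out))
      stop("unknown genotype class name(s): ",
           paste(setdiff(nm, c(canon, .marginalNames$locus1,
                               .marginalNames$locus2)), collapse = ", "),
           "; valid marginal names: ",
           paste(unlist(.marginalNames), collapse = ", "), call. = FALSE)
    return(out)
  }
  parts <- strsplit(nm, "/", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("joint class names must be '<locus1>/<locus2>'", call. = FALSE)
  l1 <- mapMarg(vapply(parts, `[`, character(1), 1L))
  l2 <- mapMarg(vapply(parts, `[`, character(1), 2L))
  if (is.null(l1) || is.null(l2))
    stop("unknown genotype class name(s) in joint table; valid per-locus ",
         "names: ", paste(unlist(.marginalNames), collapse = ", "),
         call. = FALSE)
  paste(l1, l2, sep = "/")
}

#' Read a two-locus genotype counts table
#'
#' TSV with header columns `class` and `count`. Class names must be the 3
#' marginal or 9 joint two-locus genotype classes (see
#' [genotypeClassNames()]); parent-label names (`W2W2`, ...) are mapped onto
#' the canonical functional-dosage names. Counts are kept as exact integers.
#'
#' @param path path to a TSV file.
#' @return named integer vector in canonical class order, with attribute
#'   `"sourceNames"` preserving the file's class labels.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("class\tcount", "W2W2\t99", "W2G2\t113", "G2G2\t14"), f)
#' readCountsTable(f)
#' @export
readCountsTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("class", "count") %in% names(df)))
    stop("counts table needs header columns 'class' and 'count'",
         call. = FALSE)
  cnt <- df$count
  if (!is.numeric(cnt) || any(is.na(cnt)) || any(cnt < 0) ||
      any(cnt != round(cnt)))
    stop("counts must be non-negative integers", call. = FALSE)
  canon <- .canonicalizeCountNames(df$class)
  expect <- genotypeClassNames(joint = length(canon) == 9L)
  if (length(canon) != length(expect) || !setequal(canon, expect))
    stop("counts table must contain exactly the ", length(expect),
         " classes: ", paste(expect, collapse = ", "), call. = FALSE)
  out <- setNames(as.integer(cnt), canon)[expect]
  if (sum(out) <= 0L) stop("total count must be positive", call. = FALSE)
  attr(out, "sourceNames") <- setNames(df$class, canon)[expect]
  out
}

#' Write a counts table as TSV
#'
#' @param counts named integer vector of genotype class counts.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCountsTable <- function(counts, path) {
  df <- data.frame(class = names(counts), count = as.integer(counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' TSV with header columns `sample` and `label`. For quartet analyses labels
#' must include all of `P1`, `P2`, `P3`, `O`; for association analyses
#' `case`/`control` labels are used.
#'
#' @param path path to a TSV file.
#' @param requireQuartet require all four quartet roles to be present.
#' @return data.frame with columns `sample`, `label`.
#' @export
readPopMap <- function(path, requireQuartet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "label") %in% names(df)))
    stop("population map needs header columns 'sample' and 'label'",
         call. = FALSE)
  if (anyDuplicated(df$sample))
    stop("every sample must have exactly one label", call. = FALSE)
  if (requireQuartet && !all(c("P1", "P2", "P3", "O") %in% df$label))
    stop("quartet analyses require non-empty P1, P2, P3 and O groups",
         call. = FALSE)
  df[, c("sample", "label")]
}
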