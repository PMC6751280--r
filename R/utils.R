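## Shared low-level helpers: sequence manipulation, cluster agreement.

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  out <- vapply(x, function(s) {
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Used to score recovery of planted cluster structure.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return ARI in [-1, 1]; 1 means identical partitions up to relabeling.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)  # both partitions trivial
  (nij - expected) / (maxidx - expected)
}

## strand-aware orientation helper: TRUE when transcript 5' end is genomic left
is_forward <- function(strand) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  strand == "+"
}

## fetch genomic subsequence [start, end] 1-based inclusive from a genome
## (named character vector chrom -> sequence); errors when out of bounds
genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop("chromosome '", chrom, "' not present in genome", call. = FALSE)
  }
  len <- nchar(genome[[chrom]])
  if (start < 1L || end > len) {
    stop("interval [", start, ",", end, "] out of bounds for chromosome '",
         chrom, "' (length ", len, ")", call. = FALSE)
  }
  substr(genome[[chrom]], start, end)
}

## replace genomic bases in place; returns modified genome
genome_write <- function(genome, chrom, start, replacement) {
  end <- start + nchar(replacement) - 1L
  len <- nchar(genome[[chrom]])
  if (start < 1L || end > len) {
    stop("cannot write [", start, ",", end, "] on chromosome '", chrom, "'",
         call. = FALSE)
  }
  substr(genome[[chrom]], start, end) <- replacement
  genome
}

## GC fraction of a DNA string (N ignored in denominator)
gc_fraction <- function(seq) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  informative <- bases %in% c("A", "C", "G", "T")
  if (!any(informative)) return(NA_real_)
  mean(bases[informative] %in% c("G", "C"))
}
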