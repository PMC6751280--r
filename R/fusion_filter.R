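## Fusion-candidate filtering.
##
## A fusion candidate is one transcript whose alignment splits into
## segments on the genome. Segments on one chromosome closer than a small
## merge gap are first fused into loci; six criteria are then evaluated:
##   a  two or more loci
##   b  every locus on a placed chromosome (no contigs/scaffolds)
##   c  every locus covers >= 5% of the transcript
##   d  total coverage >= 95%
##   e  every locus pair on different chromosomes or >= 10 kb apart
##   f  the fusion junction is supported by short reads
## The locus merge gap (1 kb default) is deliberately smaller than the
## inter-locus distance threshold so that criterion e remains independently
## testable: two segments 5 kb apart form two loci and fail (e) rather
## than collapsing into one locus.

#' Construct a fusion candidate
#'
#' @param transcript_id identifier.
#' @param transcript_length nt.
#' @param segments data.frame with columns chrom, start, end, fraction
#'   (aligned fraction of the transcript, in [0,1]), placed (logical:
#'   on a placed chromosome).
#' @param junction_support count of short-read junction observations.
#' @return object of class \code{fusion_candidate}.
#' @export
fusion_candidate <- function(transcript_id, transcript_length, segments,
                             junction_support) {
  stopifnot(nrow(segments) >= 1)
  if (any(segments$fraction < 0 | segments$fraction > 1)) {
    stop("segment fractions must lie in [0,1]", call. = FALSE)
  }
  if (sum(segments$fraction) > 1 + 1e-6) {
    stop("candidate '", transcript_id,
         "': segment fractions sum to more than 1", call. = FALSE)
  }
  structure(list(transcript_id = transcript_id,
                 transcript_length = transcript_length,
                 segments = segments,
                 junction_support = junction_support),
            class = "fusion_candidate")
}

## merge same-chromosome segments with gap < merge_gap into loci
merge_segments_into_loci <- function(segments, merge_gap) {
  out <- list()
  for (ch in unique(segments$chrom)) {
    sub <- segments[segments$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    cur <- sub[1, ]
    flush <- function(x) out[[length(out) + 1]] <<- x
    if (nrow(sub) > 1) {
      for (i in 2:nrow(sub)) {
        gap <- sub$start[i] - cur$end - 1
        if (gap < merge_gap) {
          cur$end <- max(cur$end, sub$end[i])
          cur$fraction <- cur$fraction + sub$fraction[i]
          cur$placed <- cur$placed && sub$placed[i]
        } else {
          flush(cur)
          cur <- sub[i, ]
        }
      }
    }
    flush(cur)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Evaluate a fusion candidate against the six criteria
#'
#' @param c \code{fusion_candidate}.
#' @param min_locus_cov minimum per-locus transcript coverage (default
#'   0.05).
#' @param min_total_cov minimum summed coverage (default 0.95).
#' @param min_distance minimum inter-locus distance in nt, gap between
#'   nearest segment ends (default 10000).
#' @param min_junction_reads minimum short-read junction support (default
#'   1).
#' @param locus_merge_gap same-chromosome segments closer than this merge
#'   into one locus (default 1000).
#' @return object of class \code{fusion_verdict}: logicals a..f,
#'   \code{pass} (their conjunction), \code{n_loci}.
#' @export
evaluate_candidate <- function(c, min_locus_cov = 0.05, min_total_cov = 0.95,
                               min_distance = 10000, min_junction_reads = 1,
                               locus_merge_gap = 1000) {
  loci <- merge_segments_into_loci(c$segments, locus_merge_gap)
  n <- nrow(loci)
  crit <- c(a = n >= 2,
            b = all(loci$placed),
            c = all(loci$fraction >= min_locus_cov),
            d = sum(loci$fraction) >= min_total_cov,
            e = TRUE,
            f = c$junction_support >= min_junction_reads)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (loci$chrom[i] != loci$chrom[j]) next
        gap <- max(loci$start[i], loci$start[j]) -
          min(loci$end[i], loci$end[j]) - 1
        if (gap < min_distance) crit[["e"]] <- FALSE
      }
    }
  }
  structure(list(transcript_id = c$transcript_id,
                 a = crit[["a"]], b = crit[["b"]], c = crit[["c"]],
                 d = crit[["d"]], e = crit[["e"]], f = crit[["f"]],
                 pass = all(crit), n_loci = n),
            class = "fusion_verdict")
}

#' @export
print.fusion_verdict <- function(x, ...) {
  flags <- vapply(letters[1:6], function(k) x[[k]], logical(1))
  cat("<fusion_verdict>", x$transcript_id,
      if (x$pass) "PASS" else paste("FAIL:",
                                    paste(letters[1:6][!flags],
                                          collapse = ",")), "\n")
  invisible(x)
}

#' Filter a panel of fusion candidates
#'
#' @param cands list of \code{fusion_candidate}.
#' @param ... thresholds forwarded to \code{\link{evaluate_candidate}}.
#' @return list: \code{passing} (candidates, input order preserved),
#'   \code{verdicts} (data.frame transcript_id, a..f, pass, first_fail),
#'   \code{failure_tally} (named integer over a..f: first failing
#'   criterion).
#' @export
filter_candidates <- function(cands, ...) {
  verdicts <- lapply(cands, evaluate_candidate, ...)
  df <- do.call(rbind, lapply(verdicts, function(v) {
    flags <- vapply(letters[1:6], function(k) v[[k]], logical(1))
    data.frame(transcript_id = v$transcript_id, t(flags), pass = v$pass,
               first_fail = if (v$pass) NA_character_ else
                 letters[1:6][!flags][1],
               stringsAsFactors = FALSE)
  }))
  tally <- table(factor(df$first_fail, levels = letters[1:6]))
  list(passing = cands[df$pass],
       verdicts = df,
       failure_tally = stats::setNames(as.integer(tally), letters[1:6]))
}

#' Read fusion candidates from a segment TSV
#'
#' Long format: one row per segment with columns transcript_id,
#' transcript_length, chrom, start, end, fraction, placed, support.
#'
#' @param path TSV path.
#' @return list of \code{fusion_candidate}.
#' @export
read_fusion_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  lapply(split(df, factor(df$transcript_id, levels = unique(df$transcript_id))),
         function(d) {
           fusion_candidate(d$transcript_id[1], d$transcript_length[1],
                            data.frame(chrom = d$chrom, start = d$start,
                                       end = d$end, fraction = d$fraction,
                                       placed = as.logical(d$placed),
                                       stringsAsFactors = FALSE),
                            d$support[1])
         })
}

#' Write fusion candidates to a segment TSV
#'
#' @param cands list of \code{fusion_candidate}.
#' @param path output path.
#' @export
write_fusion_table <- function(cands, path) {
  df <- do.call(rbind, lapply(cands, function(c) {
    data.frame(transcript_id = c$transcript_id,
               transcript_length = c$transcript_length,
               chrom = c$segments$chrom, start = c$segments$start,
               end = c$segments$end, fraction = c$segments$fraction,
               placed = c$segments$placed, support = c$junction_support,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
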