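## Retained-intron characterization and premature-termination-codon (PTC)
## calling.
##
## Splice-site strength is a position-weight-matrix log-odds score trained
## on the input's own non-retained introns (donor window: 3 exonic + 6
## intronic nt; acceptor window: 20 intronic + 3 exonic nt). This is a
## self-contained monotone surrogate for dedicated splice-site scorers and
## is labelled "pwm_logodds" in all outputs.
##
## The PTC rule: a stop codon more than 50 nt upstream of the last
## exon-exon junction (spliced-transcript coordinates, measured from the
## stop codon's last base) marks the transcript as an NMD candidate.

BASES <- c("A", "C", "G", "T")

#' Features of retained introns
#'
#' One record per unique retained intron (deduplicated by gene and
#' coordinates). \code{position_ratio} is the transcript-oriented relative
#' start of the intron within the gene body: 0 at the gene's 5' end, so a
#' 3'-biased intron population has a high mean ratio.
#'
#' @param ir_events list of \code{as_event} of type IR.
#' @param genes list of \code{gene_model} indexed by the events' gene_ids.
#' @param genome named character vector of chromosome sequences.
#' @param pwm optional \code{splice_pwm}; when supplied, donor and acceptor
#'   log-odds scores are added.
#' @return data.frame: gene_id, chrom, strand, start, end, position_ratio,
#'   length, gc, canonical, donor_score, acceptor_score, score_method.
#' @export
retained_intron_features <- function(ir_events, genes, genome, pwm = NULL) {
  stopifnot(all(vapply(ir_events, `[[`, character(1), "event_type") == "IR"))
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  key <- vapply(ir_events, function(e) {
    paste(e$gene_id, e$signature[1], e$signature[2], sep = ":")
  }, character(1))
  ir_events <- ir_events[!duplicated(key)]
  rows <- lapply(ir_events, function(ev) {
    g <- genes[[match(ev$gene_id, gene_ids)]]
    if (is.na(match(ev$gene_id, gene_ids))) {
      stop("gene '", ev$gene_id, "' not found", call. = FALSE)
    }
    s <- ev$signature[1]; e <- ev$signature[2]
    if (s < g$span[1] || e > g$span[2]) {
      stop("retained intron [", s, ",", e, "] outside span of gene '",
           g$gene_id, "'", call. = FALSE)
    }
    glen <- g$span[2] - g$span[1] + 1
    ratio <- if (is_forward(g$strand)) (s - g$span[1]) / glen
             else (g$span[2] - e) / glen
    seq <- genome_subseq(genome, g$chrom, s, e)
    if (!is_forward(g$strand)) seq <- revcomp(seq)
    donor <- substr(seq, 1, 2)
    acceptor <- substr(seq, nchar(seq) - 1, nchar(seq))
    ds <- as_ <- NA_real_
    if (!is.null(pwm)) {
      sc <- score_splice_sites(list(chrom = g$chrom, strand = g$strand,
                                    start = s, end = e), pwm, genome)
      ds <- sc[["donor_score"]]; as_ <- sc[["acceptor_score"]]
    }
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               start = s, end = e, position_ratio = ratio,
               length = e - s + 1, gc = gc_fraction(seq),
               canonical = donor == "GT" && acceptor == "AG",
               donor_score = ds, acceptor_score = as_,
               score_method = "pwm_logodds", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## genomic windows for donor/acceptor site of an intron-like record
## (list/row with chrom, strand, start, end); returned in transcript
## orientation. Donor: 3 exonic + 6 intronic nt; acceptor: 20 intronic +
## 3 exonic nt.
splice_windows <- function(intron, genome) {
  s <- intron$start; e <- intron$end
  if (is_forward(intron$strand)) {
    donor <- genome_subseq(genome, intron$chrom, s - 3, s + 5)
    acceptor <- genome_subseq(genome, intron$chrom, e - 19, e + 3)
  } else {
    donor <- revcomp(genome_subseq(genome, intron$chrom, e - 5, e + 3))
    acceptor <- revcomp(genome_subseq(genome, intron$chrom, s - 3, s + 19))
  }
  list(donor = donor, acceptor = acceptor)
}

count_matrix <- function(windows, width) {
  m <- matrix(0, nrow = width, ncol = 4, dimnames = list(NULL, BASES))
  for (w in windows) {
    b <- strsplit(w, "", fixed = TRUE)[[1]]
    for (i in seq_len(width)) {
      if (b[i] %in% BASES) m[i, b[i]] <- m[i, b[i]] + 1
    }
  }
  m
}

#' Train a splice-site position weight matrix
#'
#' Probabilities are pseudocounted per position and normalized; the
#' background is the pooled base frequency over all training windows.
#'
#' @param introns data.frame of introns (columns chrom, strand, start, end)
#'   to train on — typically the catalog's non-retained introns.
#' @param genome named character vector of chromosome sequences.
#' @param pseudocount added to every base count (default 0.5).
#' @return object of class \code{splice_pwm} with elements \code{donor}
#'   (9 x 4), \code{acceptor} (23 x 4) and \code{background} (length 4),
#'   each row summing to 1.
#' @export
train_splice_pwm <- function(introns, genome, pseudocount = 0.5) {
  if (nrow(introns) == 0) stop("empty splice-site training set", call. = FALSE)
  wins <- lapply(seq_len(nrow(introns)), function(i) {
    splice_windows(introns[i, ], genome)
  })
  dc <- count_matrix(lapply(wins, `[[`, "donor"), 9L)
  ac <- count_matrix(lapply(wins, `[[`, "acceptor"), 23L)
  bg <- colSums(dc) + colSums(ac) + pseudocount
  bg <- bg / sum(bg)
  norm <- function(m) {
    m <- m + pseudocount
    m / rowSums(m)
  }
  structure(list(donor = norm(dc), acceptor = norm(ac), background = bg,
                 n_train = nrow(introns)),
            class = "splice_pwm")
}

#' @export
print.splice_pwm <- function(x, ...) {
  cat("<splice_pwm> trained on", x$n_train, "introns;",
      "donor consensus:", paste(BASES[apply(x$donor, 1, which.max)],
                                collapse = ""), "\n")
  invisible(x)
}

score_window <- function(window, mat, background) {
  b <- strsplit(window, "", fixed = TRUE)[[1]]
  sc <- 0
  for (i in seq_along(b)) {
    if (b[i] %in% BASES) {
      sc <- sc + log2(mat[i, b[i]] / unname(background[b[i]]))
    }
  }
  unname(sc)
}

#' Score an intron's splice sites against a PWM
#'
#' Log-odds in bits: \eqn{\sum_i \log_2 P(b_i | i) / P_{bg}(b_i)} over the
#' donor and acceptor windows. N bases contribute zero.
#'
#' @param intron list or data.frame row with chrom, strand, start, end.
#' @param pwm \code{splice_pwm}.
#' @param genome named character vector of chromosome sequences.
#' @return named numeric vector: donor_score, acceptor_score.
#' @export
score_splice_sites <- function(intron, pwm, genome) {
  w <- splice_windows(intron, genome)
  c(donor_score = score_window(w$donor, pwm$donor, pwm$background),
    acceptor_score = score_window(w$acceptor, pwm$acceptor, pwm$background))
}

#' Mann-Whitney rank-sum test
#'
#' U statistic with midrank tie handling. For pooled sizes up to 10 the
#' two-sided p-value is computed by exhaustive enumeration of group
#' assignments (\eqn{P(|U - n_a n_b / 2| \ge |U_{obs} - n_a n_b / 2|)});
#' larger samples use the normal approximation with tie-corrected variance
#' and continuity correction.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return list with \code{U} (statistic for sample_a), \code{p}
#'   (two-sided), and \code{method} ("exact" or "normal").
#' @export
rank_sum_test <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  na <- length(sample_a); nb <- length(sample_b)
  u_stat <- function(a, b) {
    sum(vapply(a, function(x) sum(x > b) + 0.5 * sum(x == b), numeric(1)))
  }
  U <- u_stat(sample_a, sample_b)
  mu <- na * nb / 2
  pooled <- c(sample_a, sample_b)
  if (length(unique(pooled)) == 1) {
    return(list(U = U, p = 1, method = "degenerate"))
  }
  if (na + nb <= 10) {
    idx <- utils::combn(na + nb, na)
    us <- apply(idx, 2, function(ii) u_stat(pooled[ii], pooled[-ii]))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p = p, method = "exact"))
  }
  n <- na + nb
  ties <- table(pooled)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(U = U, p = min(1, 2 * stats::pnorm(-z)), method = "normal")
}

#' Longest open reading frame
#'
#' Searches the three sense frames for the longest ATG-initiated ORF
#' ending at the first in-frame stop codon (TAA/TAG/TGA, included in the
#' ORF); length ties resolve to the 5'-most start.
#'
#' @param seq nucleotide string over A/C/G/T/N (transcript orientation).
#' @return list: \code{has_orf}; when TRUE, \code{start} and \code{stop}
#'   are 0-based coordinates of the first ORF base and the stop codon's
#'   last base, and \code{length} their inclusive span (a multiple of 3).
#' @export
longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- list(has_orf = FALSE, start = NA_integer_, stop = NA_integer_,
               length = 0L)
  if (n < 6) return(best)
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts0 <- seq.int(frame + 1L, n - 2L, by = 3L)
    codons <- substring(seq, starts0, starts0 + 2)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% stops)
    if (length(atg) == 0 || length(stp) == 0) next
    for (ai in atg) {
      after <- stp[stp > ai]
      if (length(after) == 0) break  # later ATGs in this frame also fail? no
      si <- after[1]
      len <- (si - ai + 1L) * 3L
      start0 <- starts0[ai] - 1L
      if (len > best$length ||
          (len == best$length && !is.na(best$start) && start0 < best$start)) {
        best <- list(has_orf = TRUE, start = start0,
                     stop = starts0[si] + 2L - 1L, length = len)
      }
    }
  }
  best
}

## 1-based transcript coordinate of the last exon-exon junction = the
## position of the final base of the penultimate exon in transcript order
last_junction_position <- function(t) {
  n <- nrow(t$exons)
  if (n < 2) stop("single-exon transcript has no junction", call. = FALSE)
  lens <- t$exons[, 2] - t$exons[, 1] + 1
  if (!is_forward(t$strand)) lens <- rev(lens)
  sum(lens[-n])
}

#' Classify a stop codon as premature (PTC)
#'
#' A stop codon is premature when its distance to the last exon-exon
#' junction exceeds 50 nt, measured in spliced-transcript coordinates from
#' the stop codon's 3'-most base (strictly greater than 50; a stop in the
#' last exon gives a negative distance and is never premature).
#'
#' @param t \code{transcript_model} with at least two exons.
#' @param orf result of \code{\link{longest_orf}} on the transcript's
#'   spliced sequence, with \code{has_orf = TRUE}.
#' @param min_distance rule threshold in nt (default 50).
#' @return logical, with attribute \code{distance} (junction minus stop
#'   end, nt).
#' @export
classify_ptc <- function(t, orf, min_distance = 50) {
  if (nrow(t$exons) < 2) {
    stop("PTC rule not evaluable on a single-exon transcript", call. = FALSE)
  }
  if (!isTRUE(orf$has_orf)) stop("transcript has no ORF", call. = FALSE)
  dist <- last_junction_position(t) - (orf$stop + 1L)
  structure(dist > min_distance, distance = dist)
}

#' Restrict IR transcripts to those informative for PTC analysis
#'
#' Keeps only IR-containing transcripts whose retained intron lies strictly
#' inside the representative transcript's genomic coding span; introns
#' falling outside the coding region, or overlapping its boundary, cannot
#' change the reading frame interpretation and are excluded with a reason.
#'
#' @param ir_transcripts data.frame with columns transcript_id, gene_id,
#'   intron_start, intron_end (genomic).
#' @param representatives data.frame with columns gene_id, cds_start,
#'   cds_end — the coding span of each gene's representative (longest
#'   annotated) transcript.
#' @return input data.frame with added columns \code{kept} (logical) and
#'   \code{reason} ("kept", "outside_cds", "overlapping_cds",
#'   "no_representative").
#' @export
filter_ir_transcripts_for_ptc <- function(ir_transcripts, representatives) {
  idx <- match(ir_transcripts$gene_id, representatives$gene_id)
  reason <- character(nrow(ir_transcripts))
  for (i in seq_len(nrow(ir_transcripts))) {
    if (is.na(idx[i])) {
      reason[i] <- "no_representative"
      next
    }
    cs <- representatives$cds_start[idx[i]]
    ce <- representatives$cds_end[idx[i]]
    s <- ir_transcripts$intron_start[i]
    e <- ir_transcripts$intron_end[i]
    if (cs < s && e < ce) {
      reason[i] <- "kept"
    } else if (e < cs || s > ce) {
      reason[i] <- "outside_cds"
    } else {
      reason[i] <- "overlapping_cds"
    }
  }
  if (any(reason == "no_representative")) {
    warning(sum(reason == "no_representative"),
            " IR transcript(s) skipped: gene has no representative",
            call. = FALSE)
  }
  ir_transcripts$kept <- reason == "kept"
  ir_transcripts$reason <- reason
  ir_transcripts
}
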