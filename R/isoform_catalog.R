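## Isoform catalog construction: redundancy collapse and classification of
## transcripts against a reference annotation into three groups (known /
## novel isoform of a known gene / novel locus).
##
## The collapse is exact-intron-chain based: differences confined to the 5'
## end are ignored, matching the convention of long-read pipelines that
## cannot trust 5' completeness of individual reads.

chain_key <- function(t) {
  ic <- tx_introns(t)
  paste(t$chrom, t$strand, paste(t(ic), collapse = ","), sep = "|")
}

## intron chain in transcript orientation (5' -> 3'); rows (start,end) genomic
oriented_chain <- function(t) {
  ic <- tx_introns(t)
  if (nrow(ic) > 0 && !is_forward(t$strand)) ic <- ic[rev(seq_len(nrow(ic))), , drop = FALSE]
  ic
}

## 3' terminal genomic coordinate of a transcript
three_prime_end <- function(t) {
  if (is_forward(t$strand)) t$exons[nrow(t$exons), 2] else t$exons[1, 1]
}

## TRUE when chain a (k rows) equals the last k introns of chain b
## (transcript orientation), with k < nrow(b)
is_5p_truncated_suffix <- function(ca, cb) {
  ka <- nrow(ca); kb <- nrow(cb)
  if (ka == 0 || ka >= kb) return(FALSE)
  tail_b <- cb[(kb - ka + 1):kb, , drop = FALSE]
  all(ca == tail_b)
}

merge_chain_group <- function(group) {
  ## identical intron chains: representative spans the union of exons
  rep_tx <- group[[order(vapply(group, `[[`, character(1),
                                "transcript_id"))[1]]]
  exons <- rep_tx$exons
  exons[1, 1] <- min(vapply(group, function(t) t$exons[1, 1], numeric(1)))
  nlast <- nrow(exons)
  exons[nlast, 2] <- max(vapply(group, function(t) t$exons[nrow(t$exons), 2],
                                numeric(1)))
  transcript_model(rep_tx$transcript_id, rep_tx$gene_id, rep_tx$chrom,
                   rep_tx$strand, exons)
}

#' Collapse redundant isoforms
#'
#' Multi-exon transcripts with identical intron chains are merged into one
#' representative spanning the union of their exons. A multi-exon
#' transcript whose intron chain is a 5'-truncated suffix of another's
#' (strand-aware) and whose 3' terminus matches is absorbed into the longer
#' chain. Mono-exon transcripts are merged when their intervals overlap
#' (same chromosome and strand). The representative keeps the
#' lexicographically smallest member transcript_id. The operation is
#' idempotent.
#'
#' @param transcripts flat list of \code{transcript_model}.
#' @return collapsed list of \code{transcript_model}.
#' @export
collapse_isoforms <- function(transcripts) {
  if (length(transcripts) == 0) return(list())
  nexon <- vapply(transcripts, function(t) nrow(t$exons), integer(1))
  multi <- transcripts[nexon > 1]
  mono <- transcripts[nexon == 1]

  ## step 1: merge identical chains
  if (length(multi) > 0) {
    keys <- vapply(multi, chain_key, character(1))
    multi <- unname(lapply(split(multi, keys), merge_chain_group))
  }

  ## step 2: absorb 5'-truncated suffixes with matching 3' terminus
  if (length(multi) > 1) {
    chains <- lapply(multi, oriented_chain)
    ends3 <- vapply(multi, three_prime_end, numeric(1))
    ctx <- paste(vapply(multi, `[[`, character(1), "chrom"),
                 vapply(multi, `[[`, character(1), "strand"))
    nint <- vapply(chains, nrow, integer(1))
    ord <- order(-nint)  # try absorbing into the longest chains first
    absorbed_into <- rep(NA_integer_, length(multi))
    for (i in seq_along(multi)) {
      for (j in ord) {
        if (i == j || ctx[i] != ctx[j] || !is.na(absorbed_into[j])) next
        if (ends3[i] == ends3[j] &&
            is_5p_truncated_suffix(chains[[i]], chains[[j]])) {
          absorbed_into[i] <- j
          break
        }
      }
    }
    ## follow absorption links to their root
    root <- function(i) {
      while (!is.na(absorbed_into[i])) i <- absorbed_into[i]
      i
    }
    roots <- vapply(seq_along(multi), root, integer(1))
    multi <- lapply(unique(roots), function(r) {
      members <- multi[roots == r]
      host <- multi[[r]]
      min_id <- sort(vapply(members, `[[`, character(1), "transcript_id"))[1]
      transcript_model(min_id, host$gene_id, host$chrom, host$strand,
                       host$exons)
    })
  }

  ## step 3: mono-exon overlap merging (connected components of overlap)
  if (length(mono) > 0) {
    ctx <- paste(vapply(mono, `[[`, character(1), "chrom"),
                 vapply(mono, `[[`, character(1), "strand"))
    merged_mono <- list()
    for (cx in unique(ctx)) {
      grp <- mono[ctx == cx]
      starts <- vapply(grp, function(t) t$exons[1, 1], numeric(1))
      ends <- vapply(grp, function(t) t$exons[1, 2], numeric(1))
      ord <- order(starts)
      grp <- grp[ord]; starts <- starts[ord]; ends <- ends[ord]
      comp <- integer(length(grp))
      cur <- 1L; cur_end <- ends[1]; comp[1] <- 1L
      for (i in seq_along(grp)[-1]) {
        if (starts[i] <= cur_end) {
          comp[i] <- cur
          cur_end <- max(cur_end, ends[i])
        } else {
          cur <- cur + 1L
          comp[i] <- cur
          cur_end <- ends[i]
        }
      }
      for (cc in unique(comp)) {
        members <- grp[comp == cc]
        min_id <- sort(vapply(members, `[[`, character(1),
                              "transcript_id"))[1]
        iv <- c(min(starts[comp == cc]), max(ends[comp == cc]))
        host <- members[[1]]
        merged_mono[[length(merged_mono) + 1]] <- transcript_model(
          min_id, host$gene_id, host$chrom, host$strand,
          matrix(iv, ncol = 2))
      }
    }
    mono <- merged_mono
  }

  out <- c(multi, mono)
  out[order(vapply(out, `[[`, character(1), "transcript_id"))]
}

#' Classify catalog transcripts against a reference annotation
#'
#' Each transcript falls in exactly one of three classes:
#' \describe{
#'   \item{known}{intron chain identical to a reference transcript's
#'     (mono-exon: interval contained in a same-strand reference exon)}
#'   \item{novel_isoform_known_gene}{same-strand exonic overlap with a
#'     reference gene but no chain match}
#'   \item{novel_locus}{no same-strand exonic overlap with any reference
#'     gene}
#' }
#'
#' @param catalog flat list of \code{transcript_model}.
#' @param reference list of \code{gene_model} (the annotation).
#' @return list with \code{classes} (data.frame transcript_id, class) and
#'   \code{counts} (named integer vector over the three classes).
#' @export
classify_against_annotation <- function(catalog, reference) {
  ref_tx <- all_transcripts(reference)
  ref_chains <- vapply(ref_tx, chain_key, character(1))
  ref_multi <- ref_chains[vapply(ref_tx, function(t) nrow(t$exons) > 1,
                                 logical(1))]
  ## reference exons for overlap / containment tests
  ref_exons <- do.call(rbind, lapply(ref_tx, function(t) {
    data.frame(chrom = t$chrom, strand = t$strand,
               start = t$exons[, 1], end = t$exons[, 2],
               stringsAsFactors = FALSE)
  }))

  classify_one <- function(t) {
    if (nrow(t$exons) > 1) {
      if (chain_key(t) %in% ref_multi) return("known")
    } else if (!is.null(ref_exons)) {
      contained <- ref_exons$chrom == t$chrom & ref_exons$strand == t$strand &
        ref_exons$start <= t$exons[1, 1] & ref_exons$end >= t$exons[1, 2]
      if (any(contained)) return("known")
    }
    if (!is.null(ref_exons)) {
      for (i in seq_len(nrow(t$exons))) {
        ov <- ref_exons$chrom == t$chrom & ref_exons$strand == t$strand &
          ref_exons$start <= t$exons[i, 2] & ref_exons$end >= t$exons[i, 1]
        if (any(ov)) return("novel_isoform_known_gene")
      }
    }
    "novel_locus"
  }

  classes <- vapply(catalog, classify_one, character(1))
  ids <- vapply(catalog, `[[`, character(1), "transcript_id")
  levels <- c("known", "novel_isoform_known_gene", "novel_locus")
  counts <- table(factor(classes, levels = levels))
  list(classes = data.frame(transcript_id = ids, class = classes,
                            stringsAsFactors = FALSE),
       counts = stats::setNames(as.integer(counts), levels))
}

#' Per-gene catalog complexity summary
#'
#' @param catalog flat list of \code{transcript_model}.
#' @return list with \code{per_gene} (data.frame gene_id, n_transcripts,
#'   mean_exons, max_exons, gene_length) and scalar summaries
#'   \code{n_genes}, \code{n_single_transcript},
#'   \code{pct_single_transcript} (percentage of genes represented by a
#'   single transcript).
#' @export
catalog_summary <- function(catalog) {
  genes <- group_into_genes(catalog)
  per_gene <- do.call(rbind, lapply(genes, function(g) {
    nex <- vapply(g$transcripts, function(t) nrow(t$exons), integer(1))
    data.frame(gene_id = g$gene_id,
               n_transcripts = length(g$transcripts),
               mean_exons = mean(nex), max_exons = max(nex),
               gene_length = g$span[2] - g$span[1] + 1,
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  n_single <- sum(per_gene$n_transcripts == 1)
  list(per_gene = per_gene,
       n_genes = nrow(per_gene),
       n_single_transcript = n_single,
       pct_single_transcript = round(100 * n_single / nrow(per_gene), 1))
}
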