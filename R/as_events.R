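## Alternative-splicing event detection from multi-isoform gene models.
##
## Five event modes are recognised from pairwise isoform comparison:
##   IR    intron retention: an intron of one isoform lies wholly inside a
##         single exon of another
##   ES    exon skipping: an internal exon with both flanking introns is
##         absent from an isoform that instead splices donor-to-acceptor
##         across it
##   A5SS  alternative 5' (donor) site: two introns share their acceptor
##         but differ at the donor
##   A3SS  alternative 3' (acceptor) site: shared donor, differing acceptor
##   MEE   mutually exclusive exons: two non-overlapping internal exons,
##         boundary-matched outer flanks, never co-occurring in one isoform
##
## Events are deduplicated within a gene by (type, coordinate signature),
## so one biological event supported by many isoform pairs counts once.

AS_TYPES <- c("IR", "ES", "A5SS", "A3SS", "MEE")

#' Construct an AS event
#'
#' @param event_type one of IR, ES, A5SS, A3SS, MEE.
#' @param gene_id,chrom,strand gene context.
#' @param signature numeric coordinate tuple identifying the event (see
#'   \code{\link{detect_events}} for the per-type layout).
#' @param supporting list of two character vectors of transcript ids, one
#'   per isoform form of the event.
#' @return object of class \code{as_event}.
#' @export
as_event <- function(event_type, gene_id, chrom, strand, signature,
                     supporting) {
  stopifnot(event_type %in% AS_TYPES)
  structure(list(event_type = event_type, gene_id = gene_id, chrom = chrom,
                 strand = strand, signature = as.numeric(signature),
                 supporting = supporting),
            class = "as_event")
}

#' @export
print.as_event <- function(x, ...) {
  cat("<as_event>", x$event_type, x$gene_id, x$strand,
      paste(x$signature, collapse = ","), "\n")
  invisible(x)
}

## intron matrix (start,end) for a transcript, zero rows if mono-exon
tx_introns <- function(t) {
  n <- nrow(t$exons)
  if (n < 2) return(matrix(numeric(0), ncol = 2))
  cbind(t$exons[-n, 2] + 1, t$exons[-1, 1] - 1)
}

sig_key <- function(type, sig) paste(type, paste(sig, collapse = ","), sep = ":")

#' Detect alternative splicing events in a gene
#'
#' All isoform pairs are compared under the five event-mode definitions and
#' the resulting events deduplicated by (type, signature). Signature
#' layouts: IR = (intron start, intron end); ES = (exon start, exon end,
#' left flanking intron start, right flanking intron end); A5SS/A3SS =
#' (smaller alternative boundary, larger alternative boundary, shared
#' boundary); MEE = (exon1 start, exon1 end, exon2 start, exon2 end, outer
#' left boundary, outer right boundary) with exon1 genomically left.
#'
#' @param gene \code{gene_model}. Genes with fewer than two isoforms give
#'   an empty result.
#' @return list of \code{as_event}.
#' @export
detect_events <- function(gene) {
  txs <- gene$transcripts
  if (length(txs) < 2) return(list())
  ids <- vapply(txs, `[[`, character(1), "transcript_id")
  introns <- lapply(txs, tx_introns)
  exons <- lapply(txs, `[[`, "exons")
  fwd <- is_forward(gene$strand)

  events <- new.env(parent = emptyenv())
  add <- function(type, sig, form1, form2) {
    key <- sig_key(type, sig)
    cur <- if (exists(key, envir = events)) get(key, envir = events) else
      list(type = type, sig = sig, f1 = character(0), f2 = character(0))
    cur$f1 <- union(cur$f1, form1)
    cur$f2 <- union(cur$f2, form2)
    assign(key, cur, envir = events)
  }

  n <- length(txs)
  for (a in seq_len(n)) {
    ia <- introns[[a]]
    ea <- exons[[a]]
    na <- nrow(ea)
    for (b in seq_len(n)) {
      if (a == b) next
      ib <- introns[[b]]
      eb <- exons[[b]]

      ## IR: intron of a retained within a single exon of b
      if (nrow(ia) > 0) {
        for (i in seq_len(nrow(ia))) {
          s <- ia[i, 1]; e <- ia[i, 2]
          if (any(eb[, 1] <= s - 1 & eb[, 2] >= e + 1)) {
            add("IR", c(s, e), ids[a], ids[b])
          }
        }
      }

      ## ES: internal exon of a skipped by an intron of b
      if (na >= 3 && nrow(ib) > 0) {
        for (j in seq(2, na - 1)) {
          ex <- ea[j, ]
          dL <- ea[j - 1, 2] + 1        # left flanking intron start
          aR <- ea[j + 1, 1] - 1        # right flanking intron end
          if (any(ib[, 1] == dL & ib[, 2] == aR)) {
            add("ES", c(ex[1], ex[2], dL, aR), ids[a], ids[b])
          }
        }
      }

      if (b <= a) next  # symmetric comparisons below done once per pair

      ## A5SS/A3SS: introns sharing exactly one boundary. The exons
      ## flanking the differing boundary must overlap between the two
      ## isoforms, otherwise the junction pair is a by-product of exon
      ## skipping or mutually exclusive exons, not a shifted splice site.
      if (nrow(ia) > 0 && nrow(ib) > 0) {
        for (i in seq_len(nrow(ia))) {
          for (j in seq_len(nrow(ib))) {
            same_s <- ia[i, 1] == ib[j, 1]
            same_e <- ia[i, 2] == ib[j, 2]
            if (same_s == same_e) next
            if (same_e) {
              ## differing start: compare upstream flanking exons
              if (!(ea[i, 2] >= eb[j, 1] && eb[j, 2] >= ea[i, 1])) next
            } else {
              ## differing end: compare downstream flanking exons
              if (!(ea[i + 1, 2] >= eb[j + 1, 1] &&
                    eb[j + 1, 2] >= ea[i + 1, 1])) next
            }
            ## form 1 is canonically the isoform using the smaller
            ## alternative boundary, so supporters never mix across pairs
            if (same_e) {
              ## differing start boundary = donor side on +, acceptor on -
              type <- if (fwd) "A5SS" else "A3SS"
              alts <- sort(c(ia[i, 1], ib[j, 1]))
              if (ia[i, 1] <= ib[j, 1]) {
                add(type, c(alts, ia[i, 2]), ids[a], ids[b])
              } else {
                add(type, c(alts, ia[i, 2]), ids[b], ids[a])
              }
            } else {
              type <- if (fwd) "A3SS" else "A5SS"
              alts <- sort(c(ia[i, 2], ib[j, 2]))
              if (ia[i, 2] <= ib[j, 2]) {
                add(type, c(alts, ia[i, 1]), ids[a], ids[b])
              } else {
                add(type, c(alts, ia[i, 1]), ids[b], ids[a])
              }
            }
          }
        }
      }

      ## MEE: boundary-matched mutually exclusive internal exons
      if (na >= 3 && nrow(eb) >= 3) {
        for (j in seq(2, na - 1)) {
          e1 <- ea[j, ]
          if (any(eb[, 1] == e1[1] & eb[, 2] == e1[2])) next  # present in b
          dL1 <- ea[j - 1, 2] + 1
          aR1 <- ea[j + 1, 1] - 1
          for (k in seq(2, nrow(eb) - 1)) {
            e2 <- eb[k, ]
            if (any(ea[, 1] == e2[1] & ea[, 2] == e2[2])) next
            if (e1[2] >= e2[1] && e2[2] >= e1[1]) next  # overlapping
            dL2 <- eb[k - 1, 2] + 1
            aR2 <- eb[k + 1, 1] - 1
            if (dL1 != dL2 || aR1 != aR2) next
            ## no isoform of the gene may contain both exons
            both <- vapply(exons, function(ex) {
              any(ex[, 1] == e1[1] & ex[, 2] == e1[2]) &&
                any(ex[, 1] == e2[1] & ex[, 2] == e2[2])
            }, logical(1))
            if (any(both)) next
            if (e1[1] <= e2[1]) {
              add("MEE", c(e1[1], e1[2], e2[1], e2[2], dL1, aR1),
                  ids[a], ids[b])
            } else {
              add("MEE", c(e2[1], e2[2], e1[1], e1[2], dL1, aR1),
                  ids[b], ids[a])
            }
          }
        }
      }
    }
  }

  keys <- sort(ls(events))
  lapply(keys, function(k) {
    ev <- get(k, envir = events)
    as_event(ev$type, gene$gene_id, gene$chrom, gene$strand, ev$sig,
             list(ev$f1, ev$f2))
  })
}

#' Tally AS events by type
#'
#' @param events list of \code{as_event}.
#' @return named integer vector over IR, ES, A5SS, A3SS, MEE.
#' @export
count_events_by_type <- function(events) {
  types <- vapply(events, `[[`, character(1), "event_type")
  tab <- table(factor(types, levels = AS_TYPES))
  stats::setNames(as.integer(tab), AS_TYPES)
}

#' Per-stage AS event presence counts
#'
#' An event is present at a stage when each of its two isoform forms has at
#' least one supporting transcript whose replicate-mean FPKM reaches
#' \code{min_fpkm} at that stage.
#'
#' @param events list of \code{as_event}.
#' @param expr \code{expression_matrix} covering every supporting isoform.
#' @param min_fpkm presence threshold on stage-mean FPKM (default 0.1).
#' @return integer matrix, event types x stages.
#' @export
stage_event_presence <- function(events, expr, min_fpkm = 0.1) {
  sm <- stage_means(expr)
  stages <- colnames(sm)
  out <- matrix(0L, nrow = length(AS_TYPES), ncol = length(stages),
                dimnames = list(AS_TYPES, stages))
  for (ev in events) {
    for (form in ev$supporting) {
      missing <- setdiff(form, rownames(sm))
      if (length(missing) > 0) {
        stop("supporting isoform '", missing[1],
             "' absent from expression matrix", call. = FALSE)
      }
    }
    for (s in stages) {
      present <- all(vapply(ev$supporting, function(form) {
        any(sm[form, s] >= min_fpkm)
      }, logical(1)))
      if (present) out[ev$event_type, s] <- out[ev$event_type, s] + 1L
    }
  }
  out
}
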