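# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately written as plain, direct transcriptions of the
# definitions, independent of the package's implementation paths.

# -- fixture builders ---------------------------------------------------

tm <- function(id, exons, strand = "+", gene = "g1", chrom = "chr1") {
  transcript_model(id, gene, chrom, strand, exons)
}

# constant genome long enough for toy coordinates
flat_genome <- function(base = "A", len = 5000, chrom = "chr1") {
  stats::setNames(paste(rep(base, len), collapse = ""), chrom)
}

# random multi-exon transcript on a coarse grid (shared boundaries likely)
random_transcript <- function(id, gene = "gR", chrom = "chr1",
                              strand = NULL, max_exons = 6) {
  if (is.null(strand)) strand <- sample(c("+", "-"), 1)
  n <- sample(1:max_exons, 1)
  # boundaries on a grid of 20 so isoforms share junctions often
  starts <- sort(sample(seq(1, 2000, by = 20), n))
  lens <- sample(c(10, 15, 18), n, replace = TRUE)
  exons <- cbind(starts, starts + lens - 1)
  # enforce gaps >= 2
  keep <- c(TRUE, diff(starts) > 20)
  exons <- exons[keep, , drop = FALSE]
  transcript_model(id, gene, chrom, strand, exons)
}

random_gene <- function(gene_id = "gR", n_iso = NULL, max_exons = 6) {
  if (is.null(n_iso)) n_iso <- sample(2:4, 1)
  strand <- sample(c("+", "-"), 1)
  gene_model(lapply(seq_len(n_iso), function(i) {
    random_transcript(sprintf("%s.t%d", gene_id, i), gene = gene_id,
                      strand = strand)
  }))
}

# toy expression matrix from a named list stage -> named FPKM vectors
toy_expr <- function(values, tx2gene, n_rep = 1) {
  # values: matrix transcripts x stages (stage means); replicate copies
  stages <- colnames(values)
  cols <- as.vector(t(outer(stages, seq_len(n_rep), paste, sep = "_")))
  m <- values[, rep(stages, each = n_rep), drop = FALSE]
  colnames(m) <- cols
  meta <- data.frame(sample = cols, stage = rep(stages, each = n_rep),
                     replicate = rep(seq_len(n_rep), times = length(stages)))
  expression_matrix(m, meta, tx2gene)
}

# -- independent oracles ------------------------------------------------

# brute-force AS event enumeration: direct nested-loop transcription of
# the event definitions over all isoform pairs, no indexing or sharing
# with the package implementation
oracle_events <- function(gene) {
  txs <- gene$transcripts
  if (length(txs) < 2) return(character(0))
  fwd <- gene$strand == "+"
  introns_of <- function(t) {
    n <- nrow(t$exons)
    if (n < 2) return(matrix(numeric(0), ncol = 2))
    cbind(t$exons[-n, 2] + 1, t$exons[-1, 1] - 1)
  }
  found <- character(0)
  rec <- function(type, sig) {
    found <<- c(found, paste(type, paste(sig, collapse = ","), sep = ":"))
  }
  for (A in txs) for (B in txs) {
    if (identical(A$transcript_id, B$transcript_id)) next
    ia <- introns_of(A); ib <- introns_of(B)
    ea <- A$exons; eb <- B$exons
    # IR
    if (nrow(ia) > 0) for (i in seq_len(nrow(ia))) {
      s <- ia[i, 1]; e <- ia[i, 2]
      for (j in seq_len(nrow(eb))) {
        if (eb[j, 1] <= s - 1 && eb[j, 2] >= e + 1) rec("IR", c(s, e))
      }
    }
    # ES
    if (nrow(ea) >= 3) for (j in 2:(nrow(ea) - 1)) {
      dL <- ea[j - 1, 2] + 1; aR <- ea[j + 1, 1] - 1
      if (nrow(ib) > 0) for (k in seq_len(nrow(ib))) {
        if (ib[k, 1] == dL && ib[k, 2] == aR) {
          rec("ES", c(ea[j, 1], ea[j, 2], dL, aR))
        }
      }
    }
    # A5SS / A3SS (each unordered pair seen twice; dedup at the end)
    if (nrow(ia) > 0 && nrow(ib) > 0) {
      for (i in seq_len(nrow(ia))) for (j in seq_len(nrow(ib))) {
        ss <- ia[i, 1] == ib[j, 1]; se <- ia[i, 2] == ib[j, 2]
        if (ss && se) next
        if (se && !ss) {
          # flanking upstream exons must overlap
          ua <- ea[i, ]; ub <- eb[j, ]
          if (ua[2] >= ub[1] && ub[2] >= ua[1]) {
            rec(if (fwd) "A5SS" else "A3SS",
                c(sort(c(ia[i, 1], ib[j, 1])), ia[i, 2]))
          }
        }
        if (ss && !se) {
          da <- ea[i + 1, ]; db <- eb[j + 1, ]
          if (da[2] >= db[1] && db[2] >= da[1]) {
            rec(if (fwd) "A3SS" else "A5SS",
                c(sort(c(ia[i, 2], ib[j, 2])), ia[i, 1]))
          }
        }
      }
    }
    # MEE
    if (nrow(ea) >= 3 && nrow(eb) >= 3) {
      for (i in 2:(nrow(ea) - 1)) for (j in 2:(nrow(eb) - 1)) {
        e1 <- ea[i, ]; e2 <- eb[j, ]
        in_b <- any(eb[, 1] == e1[1] & eb[, 2] == e1[2])
        in_a <- any(ea[, 1] == e2[1] & ea[, 2] == e2[2])
        if (in_b || in_a) next
        if (e1[2] >= e2[1] && e2[2] >= e1[1]) next
        if (ea[i - 1, 2] + 1 != eb[j - 1, 2] + 1) next
        if (ea[i + 1, 1] - 1 != eb[j + 1, 1] - 1) next
        both <- vapply(txs, function(t) {
          any(t$exons[, 1] == e1[1] & t$exons[, 2] == e1[2]) &&
            any(t$exons[, 1] == e2[1] & t$exons[, 2] == e2[2])
        }, logical(1))
        if (any(both)) next
        pair <- if (e1[1] <= e2[1]) c(e1, e2) else c(e2, e1)
        rec("MEE", c(pair, ea[i - 1, 2] + 1, ea[i + 1, 1] - 1))
      }
    }
  }
  sort(unique(found))
}

event_keys <- function(events) {
  sort(vapply(events, function(e) {
    paste(e$event_type, paste(e$signature, collapse = ","), sep = ":")
  }, character(1)))
}

# brute-force longest ORF: try every position as an ATG start
oracle_orf <- function(seq) {
  n <- nchar(seq)
  best_len <- 0L; best_start <- NA_integer_; best_stop <- NA_integer_
  for (i in seq_len(max(0, n - 5))) {
    if (substr(seq, i, i + 2) != "ATG") next
    j <- i + 3
    while (j + 2 <= n) {
      cod <- substr(seq, j, j + 2)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        len <- j + 2 - i + 1
        if (len > best_len) {
          best_len <- len; best_start <- i - 1L; best_stop <- j + 2L - 1L
        }
        break
      }
      j <- j + 3
    }
  }
  list(has_orf = best_len > 0, start = best_start, stop = best_stop,
       length = best_len)
}

# definitional Benjamini-Hochberg: adjusted p_i = min over j with
# p_(j) >= p_(i) of p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    candidates <- vapply(rank_i:m, function(j) {
      p[ord[j]] * m / j
    }, numeric(1))
    adj[i] <- min(1, min(candidates))
  }
  adj
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
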