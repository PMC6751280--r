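## Synthetic-data generators: genomes, isoform catalogs with planted
## splicing events, staged expression with designed IRT and expression
## archetypes, poly(A) sites with upstream signals, and fusion-candidate
## panels with known verdicts.
##
## Every generator is deterministic under its seed and leaves the caller's
## RNG state untouched. Planted constructions use boundary-matched flanking
## exons so each event has exactly one unambiguous signature.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

## apply accumulated (chrom, start, text) edits to a genome in one
## vectorized pass per chromosome
apply_edits <- function(genome, edits) {
  if (length(edits$txt) == 0) return(genome)
  for (ch in unique(edits$ch)) {
    sel <- which(edits$ch == ch)
    chars <- strsplit(genome[[ch]], "", fixed = TRUE)[[1]]
    for (i in sel) {
      b <- strsplit(edits$txt[i], "", fixed = TRUE)[[1]]
      chars[edits$pos[[i]]:(edits$pos[[i]] + length(b) - 1L)] <- b
    }
    genome[[ch]] <- paste(chars, collapse = "")
  }
  genome
}

#' Generate a random genome
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param gc target GC fraction (default 0.42, a typical avian value).
#' @param seed integer seed.
#' @return named character vector (chr1, chr2, ...).
#' @export
generate_genome <- function(n_chrom, chrom_length, gc = 0.42, seed) {
  stopifnot(chrom_length > 0 || n_chrom == 0, gc > 0, gc < 1)
  if (n_chrom == 0) return(stats::setNames(character(0), character(0)))
  with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(seq_len(n_chrom), function(i) {
      paste(sample(BASES, chrom_length, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    stats::setNames(seqs, paste0("chr", seq_len(n_chrom)))
  })
}

## exon-plan builders: each returns list(exons_a, exons_b, truth_sig, type
## specific info); coordinates relative to a gene start offset of 0
plan_event_gene <- function(type, rng_lens, strand, ir_bias) {
  ex <- function(n) round(rng_lens$exon(n))
  it <- function(n) round(rng_lens$intron(n))
  interleave <- function(e, i) {
    out <- numeric(length(e) + length(i))
    out[seq(1, by = 2, length.out = length(e))] <- e
    out[seq(2, by = 2, length.out = length(i))] <- i
    out
  }
  if (type == "IR") {
    e <- ex(4); i <- it(3)
    starts <- cumsum(c(1, utils::head(interleave(e, i), -1)))
    exons <- cbind(starts[c(1, 3, 5, 7)], starts[c(1, 3, 5, 7)] + e - 1)
    introns <- cbind(exons[-4, 2] + 1, exons[-1, 1] - 1)
    k <- switch(ir_bias,
                three_prime = if (strand == "+") 3L else 1L,
                uniform = sample(1:3, 1))
    retained <- introns[k, ]
    a <- exons
    b_rows <- setdiff(seq_len(4), c(k, k + 1))
    b <- rbind(exons[b_rows[b_rows < k], , drop = FALSE],
               c(exons[k, 1], exons[k + 1, 2]),
               exons[b_rows[b_rows > k], , drop = FALSE])
    list(a = a, b = b, sig = retained, type = "IR",
         introns = introns, retained_k = k)
  } else if (type == "ES") {
    e <- ex(3); i <- it(2)
    starts <- cumsum(c(1, utils::head(interleave(e, i), -1)))
    exons <- cbind(starts[c(1, 3, 5)], starts[c(1, 3, 5)] + e - 1)
    a <- exons
    b <- exons[c(1, 3), ]
    sig <- c(exons[2, 1], exons[2, 2], exons[1, 2] + 1, exons[3, 1] - 1)
    list(a = a, b = b, sig = sig, type = "ES",
         introns = rbind(c(exons[1, 2] + 1, exons[2, 1] - 1),
                         c(exons[2, 2] + 1, exons[3, 1] - 1),
                         c(exons[1, 2] + 1, exons[3, 1] - 1)))
  } else if (type %in% c("A5SS", "A3SS")) {
    e <- ex(2); i <- it(1); shift <- 30 + round(stats::runif(1, 0, 40))
    exons <- cbind(c(1, e[1] + i + 1), c(e[1], e[1] + i + e[2]))
    ## vary the transcript-5' boundary for A5SS, the 3' boundary for A3SS
    vary_start <- (type == "A5SS") == (strand == "+")
    a <- exons
    b <- exons
    if (vary_start) {
      b[1, 2] <- exons[1, 2] + shift   # longer first exon, later donor
      i1 <- c(exons[1, 2] + 1, exons[2, 1] - 1)
      i2 <- c(b[1, 2] + 1, exons[2, 1] - 1)
      sig <- c(sort(c(i1[1], i2[1])), i1[2])
    } else {
      b[2, 1] <- exons[2, 1] - shift
      i1 <- c(exons[1, 2] + 1, exons[2, 1] - 1)
      i2 <- c(exons[1, 2] + 1, b[2, 1] - 1)
      sig <- c(sort(c(i1[2], i2[2])), i1[1])
    }
    list(a = a, b = b, sig = sig, type = type, introns = rbind(i1, i2))
  } else if (type == "MEE") {
    e <- ex(4); i <- it(3)
    ## layout: E1 .. Ea .. Eb .. E4; A uses Ea, B uses Eb
    s1 <- 1; e1 <- e[1]
    sa <- e1 + i[1] + 1; ea <- sa + e[2] - 1
    sb <- ea + i[2] + 1; eb <- sb + e[3] - 1
    s4 <- eb + i[3] + 1; e4 <- s4 + e[4] - 1
    a <- rbind(c(s1, e1), c(sa, ea), c(s4, e4))
    b <- rbind(c(s1, e1), c(sb, eb), c(s4, e4))
    sig <- c(sa, ea, sb, eb, e1 + 1, s4 - 1)
    list(a = a, b = b, sig = sig, type = "MEE",
         introns = rbind(c(e1 + 1, sa - 1), c(ea + 1, s4 - 1),
                         c(e1 + 1, sb - 1), c(eb + 1, s4 - 1)))
  } else {  # control: single isoform, 3 exons
    e <- ex(3); i <- it(2)
    starts <- cumsum(c(1, utils::head(interleave(e, i), -1)))
    exons <- cbind(starts[c(1, 3, 5)], starts[c(1, 3, 5)] + e - 1)
    list(a = exons, b = NULL, sig = NULL, type = "control",
         introns = cbind(exons[-3, 2] + 1, exons[-1, 1] - 1))
  }
}

#' Generate gene models with planted AS events
#'
#' For each of the five AS modes, exactly \code{events_per_type} genes each
#' carry one unambiguous planted event (two isoforms); the remaining genes
#' are single-isoform controls. All splice sites are written into the
#' genome as GT..AG except a \code{degenerate_ir_fraction} of retained
#' introns, which receive non-canonical dinucleotides.
#'
#' @param genome named character vector from \code{\link{generate_genome}};
#'   must be long enough for the requested genes.
#' @param n_genes total genes (>= 5 * events_per_type; the rest are
#'   controls).
#' @param events_per_type planted events per AS mode.
#' @param seed integer seed.
#' @param degenerate_ir_fraction fraction of retained introns given
#'   degenerate (non-GT-AG) sites (default 0).
#' @param ir_bias "three_prime" (retained intron planted nearest the gene's
#'   3' end, the empirically observed bias) or "uniform".
#' @param gene_spacing intergenic gap in nt (default 2200, leaving room
#'   for downstream poly(A) placement without cross-gene interference).
#' @return list: \code{models} (list of \code{gene_model}), \code{genome}
#'   (with splice sites written), \code{truth} (list with
#'   \code{as_events} data.frame (event_type, gene_id, signature),
#'   \code{ir_transcripts} data.frame (gene_id, transcript_id,
#'   intron_start, intron_end, degenerate), \code{control_genes},
#'   \code{nonretained_introns} data.frame usable for PWM training).
#' @export
generate_gene_models <- function(genome, n_genes, events_per_type, seed,
                                 degenerate_ir_fraction = 0,
                                 ir_bias = c("three_prime", "uniform"),
                                 gene_spacing = 2200) {
  ir_bias <- match.arg(ir_bias)
  n_event <- 5L * events_per_type
  stopifnot(n_genes >= n_event)
  with_seed(seed, {
    ## splice-site edits are accumulated and applied to each chromosome
    ## in one vectorized pass (editing multi-megabase strings per site is
    ## quadratic)
    edits <- new.env(parent = emptyenv())
    edits$ch <- character(0); edits$pos <- list(); edits$txt <- character(0)
    put <- function(ch, start, what) {
      i <- length(edits$txt) + 1L
      edits$ch[i] <- ch; edits$pos[[i]] <- start; edits$txt[i] <- what
    }
    put_site <- function(ch, strand, s_, e_, canonical) {
      donor <- if (canonical) "GT" else "CA"
      acceptor <- if (canonical) "AG" else "TC"
      if (is_forward(strand)) {
        put(ch, s_, donor); put(ch, e_ - 1, acceptor)
      } else {
        put(ch, e_ - 1, revcomp(donor)); put(ch, s_, revcomp(acceptor))
      }
    }
    rng_lens <- list(exon = function(n) stats::runif(n, 80, 250),
                     intron = function(n) stats::runif(n, 150, 600))
    types <- c(rep(AS_TYPES, each = events_per_type),
               rep("control", n_genes - n_event))
    chroms <- names(genome)
    chrom_len <- nchar(genome[[1]])
    cursor <- stats::setNames(rep(1, length(chroms)), chroms)
    ci <- 1L
    models <- vector("list", n_genes)
    as_truth <- list(); ir_truth <- list(); nonret <- list()
    controls <- character(0)
    for (gi in seq_len(n_genes)) {
      gid <- sprintf("G%04d", gi)
      strand <- sample(c("+", "-"), 1)
      plan <- plan_event_gene(types[gi], rng_lens, strand, ir_bias)
      span_len <- max(plan$a[, 2], if (!is.null(plan$b)) plan$b[, 2] else 0)
      ## find a chromosome with room
      placed <- FALSE
      for (try in seq_along(chroms)) {
        ch <- chroms[ci]
        if (cursor[ch] + span_len + gene_spacing < nchar(genome[[ch]])) {
          placed <- TRUE
          break
        }
        ci <- ci %% length(chroms) + 1L
      }
      if (!placed) {
        stop("insufficient genome space for ", n_genes, " genes",
             call. = FALSE)
      }
      off <- cursor[ch] + round(gene_spacing / 2)
      cursor[ch] <- off + span_len + round(gene_spacing / 2)
      ci <- ci %% length(chroms) + 1L

      shift <- function(m) m + off - 1
      txs <- list(transcript_model(paste0(gid, ".t1"), gid, ch, strand,
                                   shift(plan$a)))
      if (!is.null(plan$b)) {
        txs[[2]] <- transcript_model(paste0(gid, ".t2"), gid, ch, strand,
                                     shift(plan$b))
      }
      models[[gi]] <- gene_model(txs)

      introns_g <- shift(plan$introns)
      degenerate <- FALSE
      retained_row <- NA_integer_
      if (plan$type == "IR") {
        retained_row <- plan$retained_k
        degenerate <- stats::runif(1) < degenerate_ir_fraction
      }
      for (r in seq_len(nrow(introns_g))) {
        canonical <- !(plan$type == "IR" && r == retained_row && degenerate)
        put_site(ch, strand, introns_g[r, 1], introns_g[r, 2], canonical)
        if (!(plan$type == "IR" && r == retained_row)) {
          nonret[[length(nonret) + 1]] <- data.frame(
            gene_id = gid, chrom = ch, strand = strand,
            start = introns_g[r, 1], end = introns_g[r, 2],
            stringsAsFactors = FALSE)
        }
      }
      if (plan$type == "control") {
        controls <- c(controls, gid)
      } else {
        sig_g <- plan$sig + off - 1
        as_truth[[length(as_truth) + 1]] <- data.frame(
          event_type = plan$type, gene_id = gid,
          signature = paste(sig_g, collapse = ","),
          stringsAsFactors = FALSE)
        if (plan$type == "IR") {
          ir_truth[[length(ir_truth) + 1]] <- data.frame(
            gene_id = gid, transcript_id = paste0(gid, ".t2"),
            intron_start = sig_g[1], intron_end = sig_g[2],
            degenerate = degenerate, stringsAsFactors = FALSE)
        }
      }
    }
    genome <- apply_edits(genome, edits)
    list(models = models, genome = genome,
         truth = list(
           as_events = if (length(as_truth)) do.call(rbind, as_truth) else
             data.frame(event_type = character(), gene_id = character(),
                        signature = character()),
           ir_transcripts = if (length(ir_truth)) do.call(rbind, ir_truth)
             else data.frame(gene_id = character(),
                             transcript_id = character(),
                             intron_start = numeric(),
                             intron_end = numeric(),
                             degenerate = logical()),
           control_genes = controls,
           nonretained_introns = do.call(rbind, nonret)))
  })
}

#' Default IRT archetypes (9 trajectories over 8 stages)
#'
#' Shapes span the qualitative families seen in development: monotone
#' rise/fall, stable high/low, mid peak/trough, early and late switches,
#' and oscillation; all values in [0, 1].
#'
#' @return 9 x 8 matrix, rows irt1..irt9, columns E1..E8.
#' @export
default_irt_archetypes <- function() {
  g <- exp(-((1:8 - 4.5)^2) / 2)
  m <- rbind(
    seq(0.1, 0.9, length.out = 8),
    seq(0.9, 0.1, length.out = 8),
    rep(0.80, 8),
    rep(0.15, 8),
    0.1 + 0.8 * g,
    0.9 - 0.8 * g,
    c(rep(0.20, 4), rep(0.75, 4)),
    c(rep(0.75, 4), rep(0.20, 4)),
    rep(c(0.2, 0.7), 4))
  dimnames(m) <- list(paste0("irt", 1:9), paste0("E", 1:8))
  m
}

#' Default expression archetypes (10 trajectories over 8 stages)
#'
#' Relative stage levels in (0, 1]; none is constant (constant profiles
#' cannot be z-scored for clustering).
#'
#' @return 10 x 8 matrix, rows expr1..expr10, columns E1..E8.
#' @export
default_expr_archetypes <- function() {
  g <- exp(-((1:8 - 4.5)^2) / 2)
  m <- rbind(
    seq(0.1, 1, length.out = 8),
    seq(1, 0.1, length.out = 8),
    c(0.6, 1, 0.6, 0.35, 0.2, 0.15, 0.1, 0.1),
    0.1 + 0.9 * g,
    rev(c(0.6, 1, 0.6, 0.35, 0.2, 0.15, 0.1, 0.1)),
    1 - 0.85 * g,
    c(0.1, 0.1, 1, 1, 1, 1, 1, 1),
    c(1, 1, 1, 1, 1, 0.1, 0.1, 0.1),
    rep(c(1, 0.25), 4),
    c(0.1, 0.1, 0.1, 0.1, 0.2, 0.5, 0.9, 1))
  dimnames(m) <- list(paste0("expr", 1:10), paste0("E", 1:8))
  m
}

#' Generate a staged expression matrix from gene models
#'
#' Per-stage gene totals follow the gene's expression archetype scaled by
#' \code{base_fpkm}; within a gene, the IR-containing transcripts' share
#' of the total equals the gene's IRT archetype value before noise, split
#' equally among them (non-IR transcripts share the remainder).
#' Replicate noise is multiplicative log-normal on FPKM. Archetypes are
#' assigned round-robin in gene order, recorded in the truth labels.
#'
#' @param models list of \code{gene_model}.
#' @param ir_ids character vector of IR-containing transcript ids (e.g.
#'   from the model generator's truth); genes without any get IRT share 0.
#' @param irt_archetypes rows = trajectories over the stages, values in
#'   [0,1] (default \code{\link{default_irt_archetypes}}).
#' @param expr_archetypes rows = positive relative stage levels (default
#'   \code{\link{default_expr_archetypes}}).
#' @param noise_sd log-scale (natural log) s.d. of replicate noise
#'   (default 0.2).
#' @param seed integer seed.
#' @param n_replicates replicates per stage (default 3).
#' @param base_fpkm scale of the most expressed stage (default 50).
#' @return list: \code{expr} (\code{expression_matrix}), \code{truth}
#'   (list with \code{irt_archetype}, \code{expr_archetype}: named integer
#'   vectors gene -> row index).
#' @export
generate_expression <- function(models, ir_ids = character(0),
                                irt_archetypes = default_irt_archetypes(),
                                expr_archetypes = default_expr_archetypes(),
                                noise_sd = 0.2, seed, n_replicates = 3,
                                base_fpkm = 50) {
  if (any(irt_archetypes < 0 | irt_archetypes > 1)) {
    stop("IRT archetype values must lie in [0,1]", call. = FALSE)
  }
  stages <- colnames(expr_archetypes)
  if (is.null(stages)) stages <- paste0("E", seq_len(ncol(expr_archetypes)))
  stopifnot(ncol(irt_archetypes) == length(stages))
  with_seed(seed, {
    gene_ids <- vapply(models, `[[`, character(1), "gene_id")
    expr_assign <- stats::setNames(
      rep(seq_len(nrow(expr_archetypes)), length.out = length(models)),
      gene_ids)
    has_ir <- vapply(models, function(g) {
      any(vapply(g$transcripts, `[[`, character(1), "transcript_id")
          %in% ir_ids)
    }, logical(1))
    irt_assign <- stats::setNames(rep(NA_integer_, length(models)), gene_ids)
    irt_assign[has_ir] <- rep(seq_len(nrow(irt_archetypes)),
                              length.out = sum(has_ir))
    samples <- as.vector(t(outer(stages, seq_len(n_replicates), paste,
                                 sep = "_")))
    meta <- data.frame(
      sample = samples,
      stage = rep(stages, each = n_replicates),
      replicate = rep(seq_len(n_replicates), times = length(stages)),
      stringsAsFactors = FALSE)
    tx_ids <- vapply(all_transcripts(models), `[[`, character(1),
                     "transcript_id")
    tx2gene <- stats::setNames(
      vapply(all_transcripts(models), `[[`, character(1), "gene_id"), tx_ids)
    values <- matrix(0, nrow = length(tx_ids), ncol = length(samples),
                     dimnames = list(tx_ids, samples))
    for (gi in seq_along(models)) {
      g <- models[[gi]]
      txs <- vapply(g$transcripts, `[[`, character(1), "transcript_id")
      is_ir <- txs %in% ir_ids
      totals <- base_fpkm * expr_archetypes[expr_assign[gi], ]
      irt <- if (any(is_ir)) irt_archetypes[irt_assign[gi], ] else
        rep(0, length(stages))
      for (si in seq_along(stages)) {
        mean_vals <- numeric(length(txs))
        if (any(is_ir)) {
          mean_vals[is_ir] <- totals[si] * irt[si] / sum(is_ir)
        }
        if (any(!is_ir)) {
          mean_vals[!is_ir] <- totals[si] * (1 - irt[si]) / sum(!is_ir)
        }
        for (ri in seq_len(n_replicates)) {
          col <- paste(stages[si], ri, sep = "_")
          noise <- if (noise_sd > 0)
            exp(stats::rnorm(length(txs), 0, noise_sd)) else 1
          values[txs, col] <- mean_vals * noise
        }
      }
    }
    list(expr = expression_matrix(values, meta, tx2gene),
         truth = list(irt_archetype = irt_assign,
                      expr_archetype = expr_assign))
  })
}

#' Generate poly(A) 3'-end records with microheterogeneity
#'
#' Plants \code{sites_per_gene} cleavage positions downstream of each
#' gene's 3' end (60 nt apart, so clusters built with a 20-nt window stay
#' separable under jitter), emits jittered copies of each (integer
#' offsets, truncated at +/-9 nt), and writes an AATAAA signal 20-30 nt
#' upstream of a \code{signal_rate} fraction of sites.
#'
#' @param models list of \code{gene_model}.
#' @param genome named character vector (modified copy returned).
#' @param sites_per_gene planted sites per gene (default 2).
#' @param heterogeneity_sd jitter s.d. in nt (default 2; 0 = no jitter).
#' @param signal_rate fraction of sites given an upstream AATAAA
#'   (default 0.9).
#' @param reads_per_site records emitted per planted site (default 5).
#' @param seed integer seed.
#' @return list: \code{records} (data.frame chrom, strand, position,
#'   count, gene_id), \code{genome}, \code{truth} (data.frame gene_id,
#'   site_index, position, has_signal).
#' @export
generate_polya_sites <- function(models, genome, sites_per_gene = 2,
                                 heterogeneity_sd = 2, signal_rate = 0.9,
                                 reads_per_site = 5, seed) {
  stopifnot(sites_per_gene >= 1, heterogeneity_sd >= 0,
            signal_rate >= 0, signal_rate <= 1)
  with_seed(seed, {
    edits <- new.env(parent = emptyenv())
    edits$ch <- character(0); edits$pos <- list(); edits$txt <- character(0)
    put <- function(ch, start, what) {
      i <- length(edits$txt) + 1L
      edits$ch[i] <- ch; edits$pos[[i]] <- start; edits$txt[i] <- what
    }
    recs <- list(); truth <- list()
    for (g in models) {
      fwd <- is_forward(g$strand)
      base <- if (fwd) g$span[2] else g$span[1]
      dirn <- if (fwd) 1 else -1
      positions <- base + dirn * (40 + (seq_len(sites_per_gene) - 1) * 60)
      if (any(diff(sort(positions)) < 40)) {
        stop("planted poly(A) sites closer than 40 nt", call. = FALSE)
      }
      len <- nchar(genome[[g$chrom]])
      if (any(positions < 60) || any(positions > len - 60)) {
        stop("gene '", g$gene_id,
             "' too close to a chromosome end for poly(A) planting",
             call. = FALSE)
      }
      for (k in seq_along(positions)) {
        pos <- positions[k]
        has_signal <- stats::runif(1) < signal_rate
        if (has_signal) {
          u <- sample(20:30, 1)  # hexamer 3' end sits 15-25 nt upstream
          if (fwd) {
            put(g$chrom, pos - u, "AATAAA")
          } else {
            put(g$chrom, pos + u - 5, revcomp("AATAAA"))
          }
        }
        offs <- if (heterogeneity_sd > 0) {
          pmin(9, pmax(-9, round(stats::rnorm(reads_per_site, 0,
                                              heterogeneity_sd))))
        } else rep(0L, reads_per_site)
        recs[[length(recs) + 1]] <- data.frame(
          chrom = g$chrom, strand = g$strand, position = pos + offs,
          count = 1, gene_id = g$gene_id, stringsAsFactors = FALSE)
        truth[[length(truth) + 1]] <- data.frame(
          gene_id = g$gene_id, site_index = k, position = pos,
          has_signal = has_signal, stringsAsFactors = FALSE)
      }
    }
    genome <- apply_edits(genome, edits)
    list(records = do.call(rbind, recs), genome = genome,
         truth = do.call(rbind, truth))
  })
}

#' Generate a labelled fusion-candidate panel
#'
#' \code{n_pass} candidates satisfy all six filter criteria; for each
#' criterion, \code{n_fail_per_criterion} candidates violate exactly that
#' criterion (a: single locus; b: one segment on a scaffold; c: a locus
#' under 5\% coverage; d: total coverage 90\%; e: same-chromosome loci
#' 5 kb apart; f: no junction support).
#'
#' @param n_pass,n_fail_per_criterion panel sizes.
#' @param seed integer seed.
#' @return list: \code{candidates} (list of \code{fusion_candidate}),
#'   \code{truth} (data.frame transcript_id, expected_pass,
#'   violated_criterion).
#' @export
generate_fusion_candidates <- function(n_pass, n_fail_per_criterion, seed) {
  with_seed(seed, {
    cands <- list(); truth <- list()
    mk <- function(id, segs, support) {
      fusion_candidate(id, 2000, segs, support)
    }
    seg <- function(chrom, start, frac, placed = TRUE) {
      data.frame(chrom = chrom, start = start, end = start + 999,
                 fraction = frac, placed = placed, stringsAsFactors = FALSE)
    }
    rpos <- function() round(stats::runif(1, 1e5, 5e6))
    add <- function(id, segs, support, pass, viol) {
      cands[[length(cands) + 1]] <<- mk(id, segs, support)
      truth[[length(truth) + 1]] <<- data.frame(
        transcript_id = id, expected_pass = pass,
        violated_criterion = viol, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_pass)) {
      total <- stats::runif(1, 0.955, 0.995)
      f1 <- stats::runif(1, 0.45, 0.55)
      add(sprintf("fus_pass_%02d", i),
          rbind(seg("chr1", rpos(), f1), seg("chr2", rpos(), total - f1)),
          sample(1:5, 1), TRUE, NA_character_)
    }
    for (i in seq_len(n_fail_per_criterion)) {
      add(sprintf("fus_fail_a_%02d", i),
          seg("chr1", rpos(), 0.97), 3, FALSE, "a")
      add(sprintf("fus_fail_b_%02d", i),
          rbind(seg("chr1", rpos(), 0.50),
                seg("NW_0001", rpos(), 0.47, placed = FALSE)),
          3, FALSE, "b")
      add(sprintf("fus_fail_c_%02d", i),
          rbind(seg("chr1", rpos(), 0.04), seg("chr2", rpos(), 0.93)),
          3, FALSE, "c")
      add(sprintf("fus_fail_d_%02d", i),
          rbind(seg("chr1", rpos(), 0.50), seg("chr2", rpos(), 0.40)),
          3, FALSE, "d")
      p <- rpos()
      add(sprintf("fus_fail_e_%02d", i),
          rbind(seg("chr1", p, 0.50), seg("chr1", p + 1000 + 5000, 0.47)),
          3, FALSE, "e")
      add(sprintf("fus_fail_f_%02d", i),
          rbind(seg("chr1", rpos(), 0.50), seg("chr2", rpos(), 0.47)),
          0, FALSE, "f")
    }
    list(candidates = cands, truth = do.call(rbind, truth))
  })
}
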