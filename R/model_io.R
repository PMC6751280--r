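## Core genomic containers and standard-format I/O.
##
## Coordinates are 1-based inclusive genomic intervals throughout (GTF
## convention); BED exports convert to 0-based half-open at the boundary.
## Strand must be "+" or "-" for every transcript: splice-site analysis is
## orientation-dependent and unstranded models are rejected.

#' Construct a transcript model
#'
#' An exon-chain transcript anchored on a genome. Exons are 1-based
#' inclusive genomic intervals, sorted by start, non-overlapping and
#' separated by at least one intronic base.
#'
#' @param transcript_id,gene_id identifier strings.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons two-column numeric matrix (start, end) or a list of
#'   length-2 vectors; rows are sorted by start internally.
#' @return an object of class \code{transcript_model}.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  if (is.list(exons)) exons <- do.call(rbind, exons)
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (!strand %in% c("+", "-")) {
    stop("transcript '", transcript_id, "': strand must be '+' or '-'",
         call. = FALSE)
  }
  if (any(exons[, 2] < exons[, 1])) {
    stop("transcript '", transcript_id, "': exon end < start", call. = FALSE)
  }
  if (nrow(exons) > 1) {
    gaps <- exons[-1, 1] - exons[-nrow(exons), 2]
    if (any(gaps < 2)) {
      stop("transcript '", transcript_id,
           "': exons overlap or are adjacent (intron gap must be >= 1 nt)",
           call. = FALSE)
    }
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model>", x$transcript_id, "(gene", x$gene_id, ")",
      x$chrom, x$strand, nrow(x$exons), "exons,",
      x$exons[1, 1], "-", x$exons[nrow(x$exons), 2], "\n")
  invisible(x)
}

#' Construct a gene model from its transcripts
#'
#' @param transcripts list of \code{transcript_model}, all sharing gene_id,
#'   chrom and strand.
#' @return an object of class \code{gene_model} with a \code{span} covering
#'   every exon.
#' @export
gene_model <- function(transcripts) {
  stopifnot(length(transcripts) > 0)
  gid <- unique(vapply(transcripts, `[[`, character(1), "gene_id"))
  chrom <- unique(vapply(transcripts, `[[`, character(1), "chrom"))
  strand <- unique(vapply(transcripts, `[[`, character(1), "strand"))
  if (length(gid) != 1 || length(chrom) != 1 || length(strand) != 1) {
    stop("all transcripts of a gene must share gene_id, chrom and strand",
         call. = FALSE)
  }
  starts <- vapply(transcripts, function(t) t$exons[1, 1], numeric(1))
  ends <- vapply(transcripts, function(t) t$exons[nrow(t$exons), 2], numeric(1))
  structure(
    list(gene_id = gid, chrom = chrom, strand = strand,
         transcripts = transcripts, span = c(min(starts), max(ends))),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model>", x$gene_id, x$chrom, x$strand,
      length(x$transcripts), "transcripts, span",
      x$span[1], "-", x$span[2], "\n")
  invisible(x)
}

## flat list of transcripts from a list of gene models
all_transcripts <- function(genes) {
  unlist(lapply(genes, `[[`, "transcripts"), recursive = FALSE)
}

## group a flat transcript list into gene models
group_into_genes <- function(transcripts) {
  gids <- vapply(transcripts, `[[`, character(1), "gene_id")
  lapply(split(transcripts, factor(gids, levels = unique(gids))), gene_model)
}

parse_gtf_attr <- function(attr, key, lineno) {
  m <- regmatches(attr, regexec(paste0(key, "\\s+\"([^\"]*)\""), attr))[[1]]
  if (length(m) < 2 || !nzchar(m[2])) {
    stop("GTF parse error at line ", lineno, ": missing attribute '", key, "'",
         call. = FALSE)
  }
  m[2]
}

#' Read transcript models from a GTF file
#'
#' Parses exon features (other feature types are ignored), groups exons by
#' transcript_id and transcripts by gene_id. Malformed lines are reported
#' with their line number.
#'
#' @param path GTF file path. Attributes must carry
#'   \code{gene_id "..."; transcript_id "...";}.
#' @return list of \code{gene_model}, one per gene_id, in order of first
#'   appearance.
#' @export
read_transcript_gtf <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(keep) == 0) return(list())
  recs <- list()
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      stop("GTF parse error at line ", i, ": expected 9 tab-separated fields",
           call. = FALSE)
    }
    if (f[3] != "exon") next
    start <- suppressWarnings(as.numeric(f[4]))
    end <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start) || is.na(end)) {
      stop("GTF parse error at line ", i, ": non-numeric coordinates",
           call. = FALSE)
    }
    if (f[7] == ".") {
      stop("GTF parse error at line ", i,
           ": unstranded exon (strand '.') not supported", call. = FALSE)
    }
    recs[[length(recs) + 1]] <- list(
      chrom = f[1], start = start, end = end, strand = f[7],
      gene_id = parse_gtf_attr(f[9], "gene_id", i),
      transcript_id = parse_gtf_attr(f[9], "transcript_id", i)
    )
  }
  if (length(recs) == 0) return(list())
  df <- do.call(rbind, lapply(recs, as.data.frame))
  txs <- lapply(split(df, factor(df$transcript_id,
                                 levels = unique(df$transcript_id))),
                function(d) {
    transcript_model(d$transcript_id[1], d$gene_id[1], d$chrom[1],
                     d$strand[1], cbind(d$start, d$end))
  })
  group_into_genes(unname(txs))
}

#' Write gene models to a GTF file
#'
#' Emits one exon line per exon, sorted by chromosome then start.
#'
#' @param models list of \code{gene_model}.
#' @param path output path.
#' @export
write_transcript_gtf <- function(models, path) {
  rows <- list()
  for (g in models) {
    for (t in g$transcripts) {
      for (i in seq_len(nrow(t$exons))) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = t$chrom, src = "splicedyn", feat = "exon",
          start = t$exons[i, 1], end = t$exons[i, 2], score = ".",
          strand = t$strand, frame = ".",
          attr = sprintf('gene_id "%s"; transcript_id "%s";',
                         t$gene_id, t$transcript_id),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(rows) == 0) return(invisible(NULL))
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start, df$end, df$attr), ]
  writeLines(apply(df, 1, paste, collapse = "\t"), con)
  invisible(NULL)
}

#' Read a genome FASTA into a named sequence vector
#'
#' @param path FASTA file path.
#' @return named character vector, one uppercase sequence per chromosome.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  genome <- toupper(as.character(ss))
  names(genome) <- sub("\\s.*$", "", names(genome))
  validate_genome(genome)
  genome
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(NULL)
}

validate_genome <- function(genome) {
  if (anyDuplicated(names(genome))) {
    stop("duplicate chromosome names in genome", call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad)) {
    stop("genome sequence '", names(genome)[bad][1],
         "' contains characters outside A/C/G/T/N", call. = FALSE)
  }
  invisible(genome)
}

#' Extract introns from a transcript model
#'
#' Returns one record per exon-exon junction, with boundary dinucleotides
#' read in transcript orientation (reverse-complemented on the minus
#' strand), so \code{donor_dinuc} is the first two intronic bases at the 5'
#' splice site and \code{acceptor_dinuc} the last two at the 3' site.
#'
#' @param t \code{transcript_model} (single-exon transcripts yield zero rows).
#' @param genome named character vector of chromosome sequences.
#' @return data.frame with columns gene_id, transcript_id, chrom, strand,
#'   start, end (1-based first/last intronic base, genomic orientation),
#'   donor_dinuc, acceptor_dinuc, canonical (GT-AG, strand-aware).
#' @export
extract_introns <- function(t, genome) {
  if (!t$chrom %in% names(genome)) {
    stop("chromosome '", t$chrom, "' not present in genome", call. = FALSE)
  }
  if (t$exons[1, 1] < 1 || t$exons[nrow(t$exons), 2] > nchar(genome[[t$chrom]])) {
    stop("transcript '", t$transcript_id, "' exon interval out of bounds for ",
         "chromosome '", t$chrom, "'", call. = FALSE)
  }
  n <- nrow(t$exons)
  empty <- data.frame(gene_id = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      start = numeric(), end = numeric(),
                      donor_dinuc = character(), acceptor_dinuc = character(),
                      canonical = logical(), stringsAsFactors = FALSE)
  if (n < 2) return(empty)
  starts <- t$exons[-n, 2] + 1
  ends <- t$exons[-1, 1] - 1
  left <- vapply(starts, function(s) genome_subseq(genome, t$chrom, s, s + 1),
                 character(1))
  right <- vapply(ends, function(e) genome_subseq(genome, t$chrom, e - 1, e),
                  character(1))
  if (is_forward(t$strand)) {
    donor <- left; acceptor <- right
  } else {
    donor <- revcomp(right); acceptor <- revcomp(left)
  }
  out <- data.frame(
    gene_id = t$gene_id, transcript_id = t$transcript_id, chrom = t$chrom,
    strand = t$strand, start = starts, end = ends,
    donor_dinuc = donor, acceptor_dinuc = acceptor,
    canonical = donor == "GT" & acceptor == "AG",
    stringsAsFactors = FALSE
  )
  if (!is_forward(t$strand)) out <- out[rev(seq_len(nrow(out))), ]
  rownames(out) <- NULL
  out
}

#' Spliced transcript sequence
#'
#' Concatenates exon sequences in transcript orientation
#' (reverse-complemented for minus-strand transcripts).
#'
#' @param t \code{transcript_model}.
#' @param genome named character vector of chromosome sequences.
#' @return nucleotide string of length equal to the summed exon lengths.
#' @export
transcript_sequence <- function(t, genome) {
  parts <- vapply(seq_len(nrow(t$exons)), function(i) {
    genome_subseq(genome, t$chrom, t$exons[i, 1], t$exons[i, 2])
  }, character(1))
  seq <- paste(parts, collapse = "")
  if (!is_forward(t$strand)) seq <- revcomp(seq)
  seq
}

#' Construct an expression matrix container
#'
#' @param values numeric matrix, transcripts x samples, FPKM (all >= 0).
#' @param sample_meta data.frame with columns sample, stage, replicate, one
#'   row per column of \code{values}.
#' @param tx2gene named character vector mapping transcript_id -> gene_id.
#' @return object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, sample_meta, tx2gene) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("FPKM values must be >= 0", call. = FALSE)
  if (anyDuplicated(rownames(values))) {
    stop("duplicate transcript rows in expression matrix", call. = FALSE)
  }
  if (!identical(colnames(values), sample_meta$sample)) {
    stop("sample_meta rows must match matrix columns in order", call. = FALSE)
  }
  missing <- setdiff(rownames(values), names(tx2gene))
  if (length(missing) > 0) {
    stop("transcripts without gene mapping: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  structure(list(values = values, sample_meta = sample_meta,
                 tx2gene = tx2gene[rownames(values)]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix>", nrow(x$values), "transcripts x",
      ncol(x$values), "samples;", length(unique(x$tx2gene)), "genes;",
      "stages:", paste(unique(x$sample_meta$stage), collapse = " "), "\n")
  invisible(x)
}

#' Read a per-sample transcript expression table
#'
#' Expects a TSV whose first column is transcript_id, second gene_id, and
#' remaining columns named \code{<stage>_<replicate>} (e.g. \code{E3_2}).
#'
#' @param path TSV file path.
#' @return \code{expression_matrix}.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3) stop("expression table needs id columns plus samples",
                         call. = FALSE)
  samples <- colnames(df)[-(1:2)]
  parsed <- regmatches(samples, regexec("^(.+)_([0-9]+)$", samples))
  bad <- vapply(parsed, length, integer(1)) != 3
  if (any(bad)) {
    stop("sample column '", samples[bad][1],
         "' is not of the form <stage>_<replicate>", call. = FALSE)
  }
  meta <- data.frame(
    sample = samples,
    stage = vapply(parsed, `[`, character(1), 2),
    replicate = as.integer(vapply(parsed, `[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df[[1]])) {
    stop("duplicate transcript row: ", df[[1]][duplicated(df[[1]])][1],
         call. = FALSE)
  }
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(values) <- df[[1]]
  if (any(values < 0)) stop("negative FPKM in expression table", call. = FALSE)
  tx2gene <- stats::setNames(df[[2]], df[[1]])
  expression_matrix(values, meta, tx2gene)
}

#' Write an expression matrix to TSV
#'
#' @param expr \code{expression_matrix}.
#' @param path output path.
#' @export
write_expression_table <- function(expr, path) {
  df <- data.frame(transcript_id = rownames(expr$values),
                   gene_id = unname(expr$tx2gene),
                   expr$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

## mean FPKM over replicates, transcripts x stages
stage_means <- function(expr) {
  stages <- unique(expr$sample_meta$stage)
  out <- vapply(stages, function(s) {
    cols <- expr$sample_meta$sample[expr$sample_meta$stage == s]
    rowMeans(expr$values[, cols, drop = FALSE])
  }, numeric(nrow(expr$values)))
  out <- matrix(out, nrow = nrow(expr$values),
                dimnames = list(rownames(expr$values), stages))
  out
}
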