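## Poly(A) cleavage-site clustering and sequence-context analysis.
##
## Individual 3'-end records scatter around true cleavage positions
## (microheterogeneity); single-linkage chaining with a 20-nt gap collapses
## them into clusters whose representative is the best-supported member
## (ties resolved to the 3'-most position in transcript orientation).

#' Cluster poly(A) 3'-end records
#'
#' Single-linkage chaining of sorted positions within each (chrom, strand):
#' consecutive positions at most \code{window} nt apart join one cluster.
#'
#' @param records data.frame with columns chrom, strand, position, and
#'   optionally count (records per exact position; default 1).
#' @param window maximum gap joining two adjacent positions (default 20 nt).
#' @return data.frame of clusters: chrom, strand, representative, support
#'   (total member count), n_positions, member_start, member_end.
#' @export
cluster_polya_sites <- function(records, window = 20) {
  if (nrow(records) == 0) {
    return(data.frame(chrom = character(), strand = character(),
                      representative = numeric(), support = numeric(),
                      n_positions = integer(), member_start = numeric(),
                      member_end = numeric(), stringsAsFactors = FALSE))
  }
  if (is.null(records$count)) records$count <- 1
  ## aggregate duplicate positions
  agg <- stats::aggregate(count ~ chrom + strand + position, data = records,
                          FUN = sum)
  out <- list()
  for (key in unique(paste(agg$chrom, agg$strand))) {
    sub <- agg[paste(agg$chrom, agg$strand) == key, ]
    sub <- sub[order(sub$position), ]
    gaps <- diff(sub$position)
    cl <- cumsum(c(1, as.integer(gaps > window)))
    for (cc in unique(cl)) {
      mem <- sub[cl == cc, ]
      best <- mem$count == max(mem$count)
      rep_pos <- if (is_forward(mem$strand[1])) max(mem$position[best])
                 else min(mem$position[best])
      out[[length(out) + 1]] <- data.frame(
        chrom = mem$chrom[1], strand = mem$strand[1],
        representative = rep_pos, support = sum(mem$count),
        n_positions = nrow(mem), member_start = min(mem$position),
        member_end = max(mem$position), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$strand, res$representative), , drop = FALSE]
}

#' Assign poly(A) clusters to genes and count sites per gene
#'
#' A cluster is assigned to a same-strand gene whose span, extended
#' \code{downstream_extension} nt past its 3' end, contains the
#' representative position; when several genes qualify the one whose 3'
#' end is nearest wins.
#'
#' @param clusters output of \code{\link{cluster_polya_sites}}.
#' @param genes list of \code{gene_model}.
#' @param min_support keep only clusters with at least this support
#'   (default 1).
#' @param downstream_extension nt past the annotated 3' end (default 1000).
#' @return list: \code{per_gene} (data.frame gene_id, n_sites),
#'   \code{mean_sites_per_gene} (over genes with >= 1 site, rounded to 2
#'   digits), \code{frac_multi_site}, \code{n_unassigned}.
#' @export
sites_per_gene <- function(clusters, genes, min_support = 1,
                           downstream_extension = 1000) {
  clusters <- clusters[clusters$support >= min_support, , drop = FALSE]
  ginfo <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    chrom = vapply(genes, `[[`, character(1), "chrom"),
    strand = vapply(genes, `[[`, character(1), "strand"),
    start = vapply(genes, function(g) g$span[1], numeric(1)),
    end = vapply(genes, function(g) g$span[2], numeric(1)),
    stringsAsFactors = FALSE)
  ginfo$lo <- ifelse(ginfo$strand == "+", ginfo$start,
                     ginfo$start - downstream_extension)
  ginfo$hi <- ifelse(ginfo$strand == "+", ginfo$end + downstream_extension,
                     ginfo$end)
  ginfo$end3 <- ifelse(ginfo$strand == "+", ginfo$end, ginfo$start)
  counts <- stats::setNames(integer(nrow(ginfo)), ginfo$gene_id)
  unassigned <- 0L
  for (i in seq_len(nrow(clusters))) {
    pos <- clusters$representative[i]
    hit <- which(ginfo$chrom == clusters$chrom[i] &
                   ginfo$strand == clusters$strand[i] &
                   ginfo$lo <= pos & pos <= ginfo$hi)
    if (length(hit) == 0) {
      unassigned <- unassigned + 1L
      next
    }
    if (length(hit) > 1) hit <- hit[which.min(abs(ginfo$end3[hit] - pos))]
    counts[ginfo$gene_id[hit]] <- counts[ginfo$gene_id[hit]] + 1L
  }
  with_site <- counts[counts > 0]
  list(per_gene = data.frame(gene_id = names(counts),
                             n_sites = as.integer(counts),
                             stringsAsFactors = FALSE),
       mean_sites_per_gene = if (length(with_site)) round(mean(with_site), 2)
                             else NA_real_,
       frac_multi_site = if (length(with_site)) mean(with_site > 1)
                         else NA_real_,
       n_unassigned = unassigned)
}

## TRUE when two site sets are equivalent under a positional tolerance:
## equal sizes and a greedy order-preserving match within `window` nt
sites_match <- function(a, b, window) {
  if (length(a) != length(b)) return(FALSE)
  a <- sort(a); b <- sort(b)
  all(abs(a - b) <= window)
}

#' Genes with identical poly(A) site sets across stages
#'
#' Per-stage cluster sets are assigned to genes and compared across all
#' stages; positions within \code{window} nt count as the same site.
#'
#' @param stage_clusters named list (stage -> cluster data.frame from
#'   \code{\link{cluster_polya_sites}}), length >= 2.
#' @param genes list of \code{gene_model}.
#' @param window positional tolerance (default 20 nt).
#' @param ... passed to \code{\link{sites_per_gene}}-style assignment
#'   (min_support, downstream_extension).
#' @return data.frame gene_id, unchanged (logical; TRUE when the gene has
#'   at least one site in every stage and the sets match across stages).
#' @export
stage_site_sharing <- function(stage_clusters, genes, window = 20, ...) {
  stopifnot(length(stage_clusters) >= 2)
  assign_positions <- function(clusters) {
    res <- list()
    sp <- sites_per_gene(clusters, genes, ...)
    ginfo_ids <- sp$per_gene$gene_id
    ## re-derive per-gene representative positions (assignment as above)
    out <- stats::setNames(vector("list", length(ginfo_ids)), ginfo_ids)
    dots <- list(...)
    ext <- if (!is.null(dots$downstream_extension))
      dots$downstream_extension else 1000
    msup <- if (!is.null(dots$min_support)) dots$min_support else 1
    clusters <- clusters[clusters$support >= msup, , drop = FALSE]
    for (g in genes) {
      lo <- if (g$strand == "+") g$span[1] else g$span[1] - ext
      hi <- if (g$strand == "+") g$span[2] + ext else g$span[2]
      sel <- clusters$chrom == g$chrom & clusters$strand == g$strand &
        clusters$representative >= lo & clusters$representative <= hi
      out[[g$gene_id]] <- sort(clusters$representative[sel])
    }
    out
  }
  per_stage <- lapply(stage_clusters, assign_positions)
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  unchanged <- vapply(gene_ids, function(g) {
    sets <- lapply(per_stage, `[[`, g)
    if (any(vapply(sets, length, integer(1)) == 0)) return(FALSE)
    ref <- sets[[1]]
    all(vapply(sets[-1], sites_match, logical(1), b = ref, window = window))
  }, logical(1))
  data.frame(gene_id = gene_ids, unchanged = unchanged,
             stringsAsFactors = FALSE)
}

## strand-oriented flank around a cleavage site: positions -flank..+flank,
## 0 = cleavage base; upstream = transcript 5' side. Out-of-bounds
## positions return NA.
site_flank_bases <- function(genome, chrom, strand, pos, flank) {
  offsets <- (-flank):flank
  gpos <- if (is_forward(strand)) pos + offsets else pos - offsets
  len <- nchar(genome[[chrom]])
  bases <- rep(NA_character_, length(gpos))
  ok <- gpos >= 1 & gpos <= len
  if (any(ok)) {
    raw <- vapply(gpos[ok], function(p) substr(genome[[chrom]], p, p),
                  character(1))
    bases[ok] <- if (is_forward(strand)) raw else chartr("ACGTN", "TGCAN", raw)
  }
  stats::setNames(bases, offsets)
}

#' Nucleotide composition around poly(A) cleavage sites
#'
#' @param clusters cluster data.frame (uses representative positions).
#' @param genome named character vector of chromosome sequences.
#' @param flank half-window in nt (default 50; positions -flank..+flank,
#'   strand-oriented, 0 = cleavage base).
#' @return numeric matrix, positions x bases (A,C,G,T), each row summing
#'   to 1 (rows with no in-bounds observations are NA).
#' @export
nucleotide_composition <- function(clusters, genome, flank = 50) {
  offsets <- (-flank):flank
  counts <- matrix(0, nrow = length(offsets), ncol = 4,
                   dimnames = list(offsets, BASES))
  for (i in seq_len(nrow(clusters))) {
    b <- site_flank_bases(genome, clusters$chrom[i], clusters$strand[i],
                          clusters$representative[i], flank)
    for (j in seq_along(offsets)) {
      if (!is.na(b[j]) && b[j] %in% BASES) counts[j, b[j]] <- counts[j, b[j]] + 1
    }
  }
  denom <- rowSums(counts)
  comp <- counts / ifelse(denom == 0, NA_real_, denom)
  comp
}

## all hexamers in fixed lexicographic order
all_hexamers <- function() {
  grid <- expand.grid(rep(list(BASES), 6), stringsAsFactors = FALSE)
  ## expand.grid varies the first factor fastest; reorder for lexicographic
  hx <- apply(grid[, 6:1], 1, paste, collapse = "")
  sort(hx)
}

#' Hexamer enrichment upstream of poly(A) sites
#'
#' For every DNA hexamer, counts the upstream windows (transcript
#' orientation, \code{upstream} nt ending just before the cleavage base)
#' containing at least one occurrence, against an order-0 expectation from
#' each window's own base composition; the p-value is an upper binomial
#' tail at the mean per-window occurrence probability. The canonical
#' poly(A) signal appears as DNA hexamer AATAAA.
#'
#' @param clusters cluster data.frame (uses representative positions).
#' @param genome named character vector of chromosome sequences.
#' @param upstream window length in nt (default 50).
#' @return data.frame ranked by p then observed: motif, observed, expected,
#'   p, rank.
#' @export
hexamer_enrichment <- function(clusters, genome, upstream = 50) {
  stopifnot(nrow(clusters) >= 1)
  windows <- character(0)
  for (i in seq_len(nrow(clusters))) {
    pos <- clusters$representative[i]
    chrom <- clusters$chrom[i]; strand <- clusters$strand[i]
    len <- nchar(genome[[chrom]])
    if (is_forward(strand)) {
      s <- max(1, pos - upstream); e <- pos - 1
      if (e < s) next
      w <- substr(genome[[chrom]], s, e)
    } else {
      s <- pos + 1; e <- min(len, pos + upstream)
      if (e < s) next
      w <- revcomp(substr(genome[[chrom]], s, e))
    }
    if (nchar(w) >= 6) windows <- c(windows, w)
  }
  hx <- all_hexamers()
  n_win <- length(windows)
  if (n_win == 0) stop("no usable upstream windows", call. = FALSE)

  ## observed: windows containing each hexamer at least once
  observed <- stats::setNames(integer(length(hx)), hx)
  for (w in windows) {
    L <- nchar(w)
    subs <- unique(substring(w, 1:(L - 5), 6:L))
    subs <- subs[subs %in% hx]  # drop N-containing
    observed[subs] <- observed[subs] + 1L
  }

  ## expected: per-window order-0 occurrence probability
  hx_mat <- t(vapply(strsplit(hx, "", fixed = TRUE), function(b) {
    vapply(BASES, function(base) sum(b == base), numeric(1))
  }, numeric(4)))  # 4096 x 4 base counts per hexamer
  q <- matrix(0, nrow = length(hx), ncol = n_win)
  for (wi in seq_len(n_win)) {
    b <- strsplit(windows[wi], "", fixed = TRUE)[[1]]
    b <- b[b %in% BASES]
    freq <- (vapply(BASES, function(base) sum(b == base), numeric(1)) + 0.25) /
      (length(b) + 1)
    log_p_hex <- hx_mat %*% log(freq)
    n_slots <- nchar(windows[wi]) - 5
    q[, wi] <- 1 - (1 - exp(log_p_hex))^n_slots
  }
  p_bar <- rowMeans(q)
  expected <- p_bar * n_win
  p <- stats::pbinom(observed - 1, n_win, p_bar, lower.tail = FALSE)
  out <- data.frame(motif = hx, observed = as.integer(observed),
                    expected = expected, p = p, stringsAsFactors = FALSE)
  out <- out[order(out$p, -out$observed, out$motif), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Export poly(A) clusters as BED6
#'
#' Score column carries the cluster support; coordinates are 0-based
#' half-open.
#'
#' @param clusters cluster data.frame.
#' @param path output path.
#' @export
write_polya_bed <- function(clusters, path) {
  df <- data.frame(chrom = clusters$chrom,
                   start = clusters$representative - 1,
                   end = clusters$representative,
                   name = sprintf("polya_%d", seq_len(nrow(clusters))),
                   score = clusters$support,
                   strand = clusters$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}
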