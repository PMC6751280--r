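## Stage-level expression structure: sample correlation, differential
## expression between stages, and temporal k-means clustering.
##
## Differential calling is a limma moderated t-test on log2(FPKM + 1) per
## gene (transcript FPKM summed per gene), Benjamini-Hochberg correction
## across genes, and a joint fold-change / FDR threshold. With three
## replicates per stage an unmoderated per-gene test has 2-4 degrees of
## freedom and cannot reach stringent FDR levels even for large, clean
## fold changes; empirical-Bayes variance moderation borrows strength
## across genes, which is the field's standard answer for this design.
## The test choice is recorded in the result metadata.

## gene-level FPKM matrix: sum transcript rows per gene
gene_level_values <- function(expr) {
  genes <- unname(expr$tx2gene)
  rowsum(expr$values, group = genes, reorder = TRUE)
}

#' Pearson correlation between samples
#'
#' Computed on log2(FPKM + 1) over transcripts. Zero-variance samples get
#' NA correlations (diagonal stays 1).
#'
#' @param expr \code{expression_matrix} with at least two samples.
#' @return symmetric samples x samples matrix with unit diagonal.
#' @export
sample_correlation <- function(expr) {
  stopifnot(ncol(expr$values) >= 2)
  lv <- log2(expr$values + 1)
  sds <- apply(lv, 2, stats::sd)
  r <- suppressWarnings(stats::cor(lv, method = "pearson"))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  r
}

#' Differential genes between two stages
#'
#' Per gene: log2 fold change of stage-mean FPKM (pseudocount 1), limma
#' moderated t-test on log2(FPKM + 1) across replicates, BH adjustment
#' across genes. A gene is differential when |log2FC| exceeds
#' \code{lfc_threshold} and FDR is below \code{fdr_threshold}; direction is
#' the sign of log2FC (stage_b relative to stage_a).
#'
#' @param expr \code{expression_matrix}; both stages need >= 2 replicates.
#' @param stage_a,stage_b stage labels.
#' @param lfc_threshold default 1.
#' @param fdr_threshold default 0.01.
#' @return object of class \code{stage_comparison}: \code{table}
#'   (data.frame gene_id, log2fc, p, fdr, de, direction), \code{n_up},
#'   \code{n_down}, \code{stages}, \code{method}.
#' @export
differential_genes <- function(expr, stage_a, stage_b, lfc_threshold = 1,
                               fdr_threshold = 0.01) {
  meta <- expr$sample_meta
  cols_a <- meta$sample[meta$stage == stage_a]
  cols_b <- meta$sample[meta$stage == stage_b]
  if (length(cols_a) < 2 || length(cols_b) < 2) {
    stop("need >= 2 replicates per stage for differential testing",
         call. = FALSE)
  }
  gv <- gene_level_values(expr)
  lv <- log2(gv[, c(cols_a, cols_b), drop = FALSE] + 1)
  design <- cbind(intercept = 1,
                  stage_b = rep(c(0, 1), c(length(cols_a), length(cols_b))))
  fit <- limma::eBayes(limma::lmFit(lv, design))
  p <- fit$p.value[, "stage_b"]
  p[is.na(p)] <- 1  # zero residual variance everywhere (degenerate input)
  fdr <- stats::p.adjust(p, method = "BH")
  log2fc <- log2(rowMeans(gv[, cols_b, drop = FALSE]) + 1) -
    log2(rowMeans(gv[, cols_a, drop = FALSE]) + 1)
  de <- abs(log2fc) > lfc_threshold & fdr < fdr_threshold
  direction <- ifelse(!de, "ns", ifelse(log2fc > 0, "up", "down"))
  tab <- data.frame(gene_id = rownames(gv), log2fc = log2fc, p = unname(p),
                    fdr = unname(fdr), de = de, direction = direction,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 n_up = sum(direction == "up"),
                 n_down = sum(direction == "down"),
                 stages = c(stage_a, stage_b),
                 method = "limma_moderated_t_log2_fpkm"),
            class = "stage_comparison")
}

#' @export
print.stage_comparison <- function(x, ...) {
  cat("<stage_comparison>", x$stages[1], "->", x$stages[2], ":",
      x$n_up, "up,", x$n_down, "down of", nrow(x$table), "genes\n")
  invisible(x)
}

#' Temporal k-means clustering of expressed genes
#'
#' Genes with max stage-mean FPKM below \code{min_fpkm} are dropped as
#' unexpressed; the remaining stage-mean log2(FPKM + 1) profiles are
#' z-scored per gene (constant profiles are dropped) and clustered with
#' \code{\link{kmeans_cluster}}.
#'
#' @param expr \code{expression_matrix}.
#' @param k number of clusters (default 10).
#' @param seed integer seed.
#' @param min_fpkm expression filter (default 0.1).
#' @param n_restarts restarts for k-means (default 10).
#' @return \code{cluster_assignment} over the retained genes.
#' @export
cluster_expression <- function(expr, k = 10, seed, min_fpkm = 0.1,
                               n_restarts = 10) {
  gv <- gene_level_values(expr)
  meta <- expr$sample_meta
  stages <- unique(meta$stage)
  sm <- vapply(stages, function(s) {
    rowMeans(gv[, meta$sample[meta$stage == s], drop = FALSE])
  }, numeric(nrow(gv)))
  sm <- matrix(sm, nrow = nrow(gv), dimnames = list(rownames(gv), stages))
  expressed <- apply(sm, 1, max) >= min_fpkm
  lm_ <- log2(sm[expressed, , drop = FALSE] + 1)
  mu <- rowMeans(lm_)
  sdv <- apply(lm_, 1, stats::sd)
  keep <- sdv > 0
  z <- (lm_[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  kmeans_cluster(z, k = k, seed = seed, n_restarts = n_restarts)
}
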