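## Per-gene IR-containing-transcript (IRT) value dynamics and temporal
## clustering.
##
## The IRT value of a gene at a stage is the ratio of summed FPKM of its
## IR-containing transcripts to summed FPKM of all its transcripts
## (replicates collapsed by mean first), a quantity in [0, 1] undefined
## when the gene is silent at that stage.

#' IRT value of one gene at one stage
#'
#' @param gene_id gene identifier.
#' @param stage stage label present in \code{expr}.
#' @param expr \code{expression_matrix}.
#' @param ir_ids character vector of the gene's IR-containing transcript
#'   ids; an id belonging to a different gene is an error.
#' @return value in [0, 1], or NA when the gene has zero total FPKM at the
#'   stage.
#' @export
irt_value <- function(gene_id, stage, expr, ir_ids) {
  tx <- names(expr$tx2gene)[expr$tx2gene == gene_id]
  if (length(tx) == 0) stop("gene '", gene_id, "' not in expression matrix",
                            call. = FALSE)
  foreign <- setdiff(intersect(ir_ids, rownames(expr$values)), tx)
  if (length(foreign) > 0) {
    stop("IR transcript '", foreign[1], "' belongs to gene '",
         expr$tx2gene[[foreign[1]]], "', not '", gene_id, "'", call. = FALSE)
  }
  sm <- stage_means(expr)
  if (!stage %in% colnames(sm)) stop("unknown stage '", stage, "'",
                                     call. = FALSE)
  total <- sum(sm[tx, stage])
  if (total == 0) return(NA_real_)
  ir_here <- intersect(ir_ids, tx)
  sum(sm[ir_here, stage]) / total
}

#' IRT profiles over all stages
#'
#' @param expr \code{expression_matrix}.
#' @param ir_ids character vector of IR-containing transcript ids; every id
#'   must be a row of \code{expr}.
#' @param genes optional character vector restricting the genes profiled;
#'   default: all genes with at least one IR-containing transcript.
#' @return list with \code{profiles} (genes x stages matrix of IRT
#'   values, NA where undefined) and \code{eligible} (named logical: no
#'   undefined stage).
#' @export
irt_profiles <- function(expr, ir_ids, genes = NULL) {
  unknown <- setdiff(ir_ids, rownames(expr$values))
  if (length(unknown) > 0) {
    stop("IR transcript '", unknown[1], "' not in expression matrix",
         call. = FALSE)
  }
  if (is.null(genes)) genes <- unique(unname(expr$tx2gene[ir_ids]))
  sm <- stage_means(expr)
  stages <- colnames(sm)
  is_ir <- rownames(sm) %in% ir_ids
  gene_of <- unname(expr$tx2gene)
  prof <- matrix(NA_real_, nrow = length(genes), ncol = length(stages),
                 dimnames = list(genes, stages))
  for (g in genes) {
    rows <- gene_of == g
    tot <- colSums(sm[rows, , drop = FALSE])
    irs <- colSums(sm[rows & is_ir, , drop = FALSE])
    prof[g, ] <- ifelse(tot > 0, irs / tot, NA_real_)
  }
  list(profiles = prof, eligible = apply(prof, 1, function(x) !anyNA(x)))
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, nrow = k, ncol = ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k)[-1]) {
    if (sum(d2) == 0) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- x[pick, ]
    nd <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  centers
}

lloyd <- function(x, centers, max_iter = 100) {
  n <- nrow(x); k <- nrow(centers)
  assign_pts <- function(centers) {
    d <- vapply(seq_len(k), function(j) {
      rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    }, numeric(n))
    d <- matrix(d, nrow = n)
    list(lab = max.col(-d, ties.method = "first"),
         d2 = d[cbind(seq_len(n), max.col(-d, ties.method = "first"))])
  }
  lab <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    a <- assign_pts(centers)
    ## re-seed empty clusters from the farthest point
    for (j in setdiff(seq_len(k), unique(a$lab))) {
      far <- which.max(a$d2)
      centers[j, ] <- x[far, ]
      a <- assign_pts(centers)
    }
    if (identical(a$lab, lab)) break
    lab <- a$lab
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[lab == j, , drop = FALSE])
    }
  }
  a <- assign_pts(centers)
  list(labels = a$lab, centers = centers, inertia = sum(a$d2))
}

#' K-means clustering of temporal profiles
#'
#' Lloyd's algorithm with k-means++ seeding, best of \code{n_restarts}
#' restarts by within-cluster sum of squares; deterministic for a fixed
#' seed. Empty clusters are re-seeded from the farthest point.
#'
#' @param profiles numeric matrix, items x dimensions (no NA).
#' @param k number of clusters (at most \code{nrow(profiles)}).
#' @param seed integer seed.
#' @param n_restarts independent initializations (default 10).
#' @return object of class \code{cluster_assignment}: \code{labels} (named
#'   integer vector in 1..k), \code{centroids} (k x dims), \code{k},
#'   \code{seed}, \code{inertia}.
#' @export
kmeans_cluster <- function(profiles, k, seed, n_restarts = 10) {
  x <- as.matrix(profiles)
  if (anyNA(x)) stop("profiles contain NA; drop ineligible items first",
                     call. = FALSE)
  if (nrow(x) < k) {
    stop("fewer items (", nrow(x), ") than clusters (", k, ")",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- lloyd(x, kmeanspp_init(x, k))
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  labels <- stats::setNames(best$labels, rownames(x))
  structure(list(labels = labels, centroids = best$centers, k = k,
                 seed = seed, inertia = best$inertia),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> k =", x$k, ";", length(x$labels), "items;",
      "inertia =", signif(x$inertia, 5), "\n")
  invisible(x)
}
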