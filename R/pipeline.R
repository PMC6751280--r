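## End-to-end orchestration from a single configuration.
##
## The config carries either a `synthetic` block (generator parameters;
## everything is produced in memory and also written to <out_dir>/inputs)
## or an `inputs` block of file paths. One seed governs every stochastic
## stage; sub-stages derive fixed offsets from it.

#' Default pipeline run configuration
#'
#' A synthetic-mode configuration with the package's stated-world defaults:
#' 60 genes (5 planted events per AS mode + controls) on a 2 x 400 kb
#' genome, log-normal replicate noise 0.2, 2 poly(A) sites per gene with
#' 2-nt microheterogeneity and 90\% AATAAA signal rate, a labelled fusion
#' panel, and the analysis thresholds (min FPKM 0.1, 20-nt APA window,
#' |log2FC| > 1 and FDR < 0.01, k = 9 for IRT and k = 10 for expression
#' clustering).
#'
#' @return config list accepted by \code{\link{run_pipeline}}.
#' @export
default_run_config <- function() {
  list(
    synthetic = list(n_chrom = 2, chrom_length = 400000, gc = 0.42,
                     n_genes = 60, events_per_type = 5,
                     degenerate_ir_fraction = 0.3, noise_sd = 0.2,
                     sites_per_gene = 2, heterogeneity_sd = 2,
                     signal_rate = 0.9, fusion_n_pass = 10,
                     fusion_n_fail = 2),
    thresholds = list(min_fpkm = 0.1, apa_window = 20, polya_min_support = 2,
                      lfc = 1, fdr = 0.01, k_irt = 9, k_expr = 10),
    seed = 1, out_dir = tempfile("splicedyn_run_")
  )
}

#' Run the full isoform-dynamics pipeline
#'
#' Executes catalog collapse and classification, AS event detection and
#' staging, retained-intron characterization, IRT profiling and
#' clustering, poly(A) clustering with motif enrichment, fusion filtering,
#' and expression dynamics, writing each stage's tables under
#' \code{cfg$out_dir}.
#'
#' @param cfg list with elements \code{seed}, \code{out_dir},
#'   \code{thresholds}, and exactly one of \code{synthetic} (generator
#'   parameters, see \code{default_run_config()}) or \code{inputs} (paths:
#'   gtf, fasta, expression, polya, fusion, reference).
#' @return run report (class \code{pipeline_report}): per-stage record
#'   counts, output manifest, seed, package version.
#' @export
run_pipeline <- function(cfg = default_run_config()) {
  has_syn <- !is.null(cfg$synthetic)
  has_inp <- !is.null(cfg$inputs)
  if (has_syn == has_inp) {
    stop("config must contain exactly one of 'synthetic' or 'inputs'",
         call. = FALSE)
  }
  if (is.null(cfg$seed)) stop("config field 'seed' is required", call. = FALSE)
  th <- utils::modifyList(default_run_config()$thresholds,
                          if (is.null(cfg$thresholds)) list() else
                            cfg$thresholds)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  counts <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <<- c(manifest, path)
    invisible(path)
  }
  log_stage <- function(...) message("[splicedyn] ", ...)

  if (has_syn) {
    sp <- utils::modifyList(default_run_config()$synthetic, cfg$synthetic)
    log_stage("generating synthetic inputs (seed ", cfg$seed, ")")
    genome <- generate_genome(sp$n_chrom, sp$chrom_length, sp$gc,
                              seed = cfg$seed)
    gm <- generate_gene_models(genome, sp$n_genes, sp$events_per_type,
                               seed = cfg$seed + 1,
                               degenerate_ir_fraction =
                                 sp$degenerate_ir_fraction)
    models <- gm$models
    pa <- generate_polya_sites(models, gm$genome,
                               sites_per_gene = sp$sites_per_gene,
                               heterogeneity_sd = sp$heterogeneity_sd,
                               signal_rate = sp$signal_rate,
                               seed = cfg$seed + 2)
    genome <- pa$genome
    ex <- generate_expression(models,
                              ir_ids = gm$truth$ir_transcripts$transcript_id,
                              noise_sd = sp$noise_sd, seed = cfg$seed + 3)
    expr <- ex$expr
    fus <- generate_fusion_candidates(sp$fusion_n_pass, sp$fusion_n_fail,
                                      seed = cfg$seed + 4)
    candidates <- fus$candidates
    polya_records <- pa$records
    reference <- models
    indir <- file.path(out_dir, "inputs")
    dir.create(indir, showWarnings = FALSE)
    write_transcript_gtf(models, file.path(indir, "models.gtf"))
    write_genome_fasta(genome, file.path(indir, "genome.fa"))
    write_expression_table(expr, file.path(indir, "expression.tsv"))
    utils::write.table(polya_records, file.path(indir, "polya_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_fusion_table(candidates, file.path(indir, "fusion_candidates.tsv"))
    utils::write.table(gm$truth$as_events,
                       file.path(indir, "truth_as_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- c(manifest, list.files(indir, full.names = TRUE))
    ir_ids <- gm$truth$ir_transcripts$transcript_id
    nonretained <- gm$truth$nonretained_introns
  } else {
    inp <- cfg$inputs
    for (f in c("gtf", "fasta", "expression")) {
      if (is.null(inp[[f]])) stop("config inputs missing field '", f, "'",
                                  call. = FALSE)
    }
    log_stage("reading inputs")
    genes_in <- read_transcript_gtf(inp$gtf)
    models <- genes_in
    genome <- read_genome_fasta(inp$fasta)
    expr <- read_expression_table(inp$expression)
    polya_records <- if (!is.null(inp$polya)) {
      utils::read.table(inp$polya, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    } else NULL
    candidates <- if (!is.null(inp$fusion)) read_fusion_table(inp$fusion)
                  else NULL
    reference <- if (!is.null(inp$reference))
      read_transcript_gtf(inp$reference) else NULL
    ir_ids <- NULL
    nonretained <- NULL
  }

  ## --- catalog ---
  log_stage("catalog: collapsing and classifying isoforms")
  catalog <- collapse_isoforms(all_transcripts(models))
  genes <- group_into_genes(catalog)
  if (!is.null(reference)) {
    cls <- classify_against_annotation(catalog, reference)
    emit(cls$classes, "catalog_classification.tsv")
    counts$catalog_classes <- cls$counts
  }
  summ <- catalog_summary(catalog)
  emit(summ$per_gene, "catalog_summary.tsv")
  counts$n_transcripts <- length(catalog)
  counts$n_genes <- summ$n_genes
  counts$pct_single_transcript <- summ$pct_single_transcript

  ## --- AS events ---
  log_stage("as-events: detecting and staging")
  events <- unlist(lapply(genes, detect_events), recursive = FALSE)
  counts$as_events <- count_events_by_type(events)
  ev_df <- do.call(rbind, lapply(events, function(e) {
    data.frame(event_type = e$event_type, gene_id = e$gene_id,
               signature = paste(e$signature, collapse = ","),
               form1 = paste(e$supporting[[1]], collapse = ";"),
               form2 = paste(e$supporting[[2]], collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(ev_df)) emit(ev_df, "as_events.tsv")
  known_tx <- rownames(expr$values)
  stageable <- Filter(function(e) all(unlist(e$supporting) %in% known_tx),
                      events)
  if (length(stageable) > 0) {
    presence <- stage_event_presence(stageable, expr,
                                     min_fpkm = th$min_fpkm)
    emit(data.frame(event_type = rownames(presence), presence,
                    check.names = FALSE), "as_stage_counts.tsv")
  }

  ## --- retained introns ---
  ir_events <- Filter(function(e) e$event_type == "IR", events)
  counts$ir_events <- length(ir_events)
  if (length(ir_events) > 0) {
    log_stage("ir: characterizing retained introns")
    if (is.null(nonretained)) {
      retained_key <- vapply(ir_events, function(e) {
        paste(e$gene_id, e$signature[1], e$signature[2])
      }, character(1))
      alli <- do.call(rbind, lapply(catalog, extract_introns, genome = genome))
      alli_key <- paste(alli$gene_id, alli$start, alli$end)
      nonretained <- alli[!alli_key %in% retained_key, ]
    }
    pwm <- if (nrow(nonretained) >= 10)
      train_splice_pwm(nonretained, genome) else NULL
    feats <- retained_intron_features(ir_events, genes, genome, pwm = pwm)
    emit(feats, "ir_features.tsv")

    ## IRT profiles and clustering
    if (is.null(ir_ids)) {
      ir_ids <- unique(unlist(lapply(ir_events, function(e)
        e$supporting[[2]])))
    }
    ir_ids <- intersect(ir_ids, rownames(expr$values))
    if (length(ir_ids) > 0) {
      log_stage("irt: profiling IR-containing transcript values")
      prof <- irt_profiles(expr, ir_ids)
      elig <- prof$profiles[prof$eligible, , drop = FALSE]
      emit(data.frame(gene_id = rownames(prof$profiles),
                      eligible = prof$eligible, prof$profiles,
                      check.names = FALSE), "irt_profiles.tsv")
      counts$irt_genes_eligible <- nrow(elig)
      if (nrow(elig) >= th$k_irt) {
        cl <- kmeans_cluster(elig, k = th$k_irt, seed = cfg$seed + 5)
        emit(data.frame(gene_id = names(cl$labels), cluster = cl$labels),
             "irt_clusters.tsv")
      }
    }
  }

  ## --- APA ---
  if (!is.null(polya_records) && nrow(polya_records) > 0) {
    log_stage("apa: clustering poly(A) sites")
    clusters <- cluster_polya_sites(polya_records, window = th$apa_window)
    counts$polya_clusters <- nrow(clusters)
    write_polya_bed(clusters, file.path(out_dir, "polya_clusters.bed"))
    manifest <- c(manifest, file.path(out_dir, "polya_clusters.bed"))
    spg <- sites_per_gene(clusters, genes,
                          min_support = th$polya_min_support)
    emit(spg$per_gene, "polya_sites_per_gene.tsv")
    counts$mean_sites_per_gene <- spg$mean_sites_per_gene
    comp <- nucleotide_composition(clusters, genome)
    emit(data.frame(position = rownames(comp), comp, check.names = FALSE),
         "polya_composition.tsv")
    hex <- hexamer_enrichment(clusters, genome)
    emit(utils::head(hex, 50), "polya_hexamers.tsv")
    counts$top_hexamer <- hex$motif[1]
  }

  ## --- fusion ---
  if (!is.null(candidates) && length(candidates) > 0) {
    log_stage("fusion: filtering candidates")
    ff <- filter_candidates(candidates)
    emit(ff$verdicts, "fusion_verdicts.tsv")
    counts$fusion_pass <- sum(ff$verdicts$pass)
    counts$fusion_failures <- ff$failure_tally
  }

  ## --- expression dynamics ---
  log_stage("dynamics: correlation, differential genes, clustering")
  corr <- sample_correlation(expr)
  emit(data.frame(sample = rownames(corr), corr, check.names = FALSE),
       "sample_correlation.tsv")
  stages <- unique(expr$sample_meta$stage)
  de_counts <- list()
  for (i in seq_len(length(stages) - 1)) {
    cmp <- differential_genes(expr, stages[i], stages[i + 1],
                              lfc_threshold = th$lfc,
                              fdr_threshold = th$fdr)
    de_counts[[paste(stages[i], stages[i + 1], sep = "_")]] <-
      c(up = cmp$n_up, down = cmp$n_down)
  }
  de_df <- data.frame(transition = names(de_counts),
                      do.call(rbind, de_counts))
  emit(de_df, "de_counts.tsv")
  counts$de_transitions <- nrow(de_df)
  n_expr_genes <- length(unique(unname(expr$tx2gene)))
  if (n_expr_genes >= th$k_expr) {
    cl <- cluster_expression(expr, k = th$k_expr, seed = cfg$seed + 6)
    emit(data.frame(gene_id = names(cl$labels), cluster = cl$labels),
         "expression_clusters.tsv")
    counts$expr_clustered_genes <- length(cl$labels)
  }

  report <- structure(
    list(counts = counts, manifest = manifest, seed = cfg$seed,
         version = as.character(utils::packageVersion("splicedyn")),
         out_dir = out_dir),
    class = "pipeline_report")
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "run_report.txt"))
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("splicedyn pipeline report (seed ", x$seed, ", v", x$version, ")\n",
      sep = "")
  for (nm in names(x$counts)) {
    v <- x$counts[[nm]]
    if (length(v) > 1) {
      cat("  ", nm, ": ", paste(names(v), v, sep = "=", collapse = " "),
          "\n", sep = "")
    } else {
      cat("  ", nm, ": ", v, "\n", sep = "")
    }
  }
  cat("  outputs: ", length(x$manifest), " files in ", x$out_dir, "\n",
      sep = "")
  invisible(x)
}
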