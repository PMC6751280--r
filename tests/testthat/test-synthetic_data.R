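test_that("genome generation is seeded, composition-faithful", {
  g1 <- generate_genome(2, 1e4, gc = 0.5, seed = 3)
  g2 <- generate_genome(2, 1e4, gc = 0.5, seed = 3)
  expect_identical(g1, g2)
  expect_named(g1, c("chr1", "chr2"))

  g <- generate_genome(1, 1e5, gc = 0.5, seed = 4)
  gc_obs <- splicedyn:::gc_fraction(g[["chr1"]])
  ## binomial s.d. at n = 1e5 is ~0.0016; 0.01 is > 3 s.d.
  expect_lt(abs(gc_obs - 0.5), 0.01)

  expect_length(generate_genome(0, 100, seed = 1), 0)
  expect_error(generate_genome(1, 100, gc = 1.2, seed = 1))
})

test_that("planted gene models carry the promised truth labels", {
  g <- generate_genome(2, 3e5, seed = 5)
  gm <- generate_gene_models(g, 30, 5, seed = 6)
  expect_equal(sum(gm$truth$as_events$event_type == "IR"), 5)
  expect_equal(nrow(gm$truth$as_events), 25)
  expect_length(gm$truth$control_genes, 5)
  expect_identical(gm$models,
                   generate_gene_models(g, 30, 5, seed = 6)$models)

  ## all planted donor sites are GT when no degeneracy is requested
  introns <- do.call(rbind, lapply(all_transcripts(gm$models),
                                   extract_introns, genome = gm$genome))
  expect_true(all(introns$donor_dinuc == "GT"))
  expect_true(all(introns$acceptor_dinuc == "AG"))

  ## degenerate retained-intron sites are non-canonical
  gm2 <- generate_gene_models(g, 30, 5, seed = 6,
                              degenerate_ir_fraction = 1)
  ir <- gm2$truth$ir_transcripts
  expect_true(all(ir$degenerate))
  feats <- retained_intron_features(
    unlist(lapply(gm2$models, detect_events), recursive = FALSE)[
      vapply(unlist(lapply(gm2$models, detect_events), recursive = FALSE),
             function(e) e$event_type == "IR", logical(1))],
    gm2$models, gm2$genome)
  expect_true(all(!feats$canonical))

  ## capacity error on a too-small genome
  tiny <- generate_genome(1, 5e3, seed = 7)
  expect_error(generate_gene_models(tiny, 30, 5, seed = 8), "insufficient")
})

test_that("3'-biased intron planting shifts position ratios upward", {
  g <- generate_genome(2, 6e5, seed = 9)
  ratios <- function(bias) {
    gm <- generate_gene_models(g, 60, 12, seed = 10, ir_bias = bias)
    ev <- unlist(lapply(gm$models, detect_events), recursive = FALSE)
    ir <- Filter(function(e) e$event_type == "IR", ev)
    retained_intron_features(ir, gm$models, gm$genome)$position_ratio
  }
  expect_gt(mean(ratios("three_prime")), mean(ratios("uniform")))
})

test_that("expression generator reproduces archetypes exactly without noise", {
  g <- generate_genome(1, 2e5, seed = 11)
  gm <- generate_gene_models(g, 20, 4, seed = 12)
  ir_ids <- gm$truth$ir_transcripts$transcript_id
  ex0 <- generate_expression(gm$models, ir_ids, noise_sd = 0, seed = 13)
  prof <- irt_profiles(ex0$expr, ir_ids)
  arch <- default_irt_archetypes()
  for (gid in rownames(prof$profiles)) {
    expect_equal(unname(prof$profiles[gid, ]),
                 unname(arch[ex0$truth$irt_archetype[[gid]], ]),
                 tolerance = 1e-12)
  }
  expect_identical(
    generate_expression(gm$models, ir_ids, noise_sd = 0.2, seed = 14)$expr,
    generate_expression(gm$models, ir_ids, noise_sd = 0.2, seed = 14)$expr)

  ## replicate means converge on the archetype as noise shrinks
  err_at <- function(sd) {
    ex <- generate_expression(gm$models, ir_ids, noise_sd = sd, seed = 15)
    p <- irt_profiles(ex$expr, ir_ids)$profiles
    mean(abs(p - arch[ex$truth$irt_archetype[rownames(p)], ]))
  }
  expect_lt(err_at(0.05), err_at(0.4))
  expect_lt(err_at(0.05), 0.02)

  bad <- default_irt_archetypes(); bad[1, 1] <- 1.5
  expect_error(generate_expression(gm$models, ir_ids, irt_archetypes = bad,
                                   noise_sd = 0, seed = 1), "\\[0,1\\]")
})

test_that("IRT parameter recovery holds at the stated noise level", {
  ## property: with noise_sd <= 0.2 the per-gene mean absolute IRT error
  ## over stages stays within 0.05
  g <- generate_genome(2, 5e5, seed = 16)
  gm <- generate_gene_models(g, 90, 18, seed = 17)
  ir_ids <- gm$truth$ir_transcripts$transcript_id
  ex <- generate_expression(gm$models, ir_ids, noise_sd = 0.2, seed = 18)
  prof <- irt_profiles(ex$expr, ir_ids)
  arch <- default_irt_archetypes()
  per_gene_err <- vapply(rownames(prof$profiles), function(gid) {
    mean(abs(prof$profiles[gid, ] -
               arch[ex$truth$irt_archetype[[gid]], ]))
  }, numeric(1))
  expect_true(all(per_gene_err <= 0.05))
})

test_that("poly(A) generator: exact positions, signals, recoverable truth", {
  g <- generate_genome(1, 2e5, seed = 19)
  gm <- generate_gene_models(g, 15, 3, seed = 20)
  pa0 <- generate_polya_sites(gm$models, gm$genome, sites_per_gene = 2,
                              heterogeneity_sd = 0, signal_rate = 1,
                              seed = 21)
  expect_true(all(pa0$records$position %in% pa0$truth$position))
  expect_true(all(pa0$truth$has_signal))

  ## every site has AATAAA in its 50-nt upstream window
  for (i in seq_len(nrow(pa0$truth))) {
    gene <- gm$models[[match(pa0$truth$gene_id[i],
                             vapply(gm$models, `[[`, character(1),
                                    "gene_id"))]]
    pos <- pa0$truth$position[i]
    win <- if (gene$strand == "+") {
      substr(pa0$genome[[gene$chrom]], pos - 50, pos - 1)
    } else {
      splicedyn:::revcomp(substr(pa0$genome[[gene$chrom]], pos + 1,
                                 pos + 50))
    }
    expect_true(grepl("AATAAA", win, fixed = TRUE))
  }

  ## jittered copies cluster back to exactly the planted sites
  pa <- generate_polya_sites(gm$models, gm$genome, sites_per_gene = 3,
                             heterogeneity_sd = 3, signal_rate = 0.5,
                             seed = 22)
  cl <- cluster_polya_sites(pa$records, window = 20)
  expect_equal(nrow(cl), nrow(pa$truth))
})

test_that("fusion panel truth matches the filter exactly", {
  panel <- generate_fusion_candidates(4, 2, seed = 23)
  expect_length(panel$candidates, 4 + 2 * 6)
  ff <- filter_candidates(panel$candidates)
  expect_equal(ff$verdicts$pass, panel$truth$expected_pass)
  fails <- !panel$truth$expected_pass
  expect_equal(ff$verdicts$first_fail[fails],
               panel$truth$violated_criterion[fails])
})
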