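test_that("single-linkage clustering with a 20-nt window", {
  recs <- data.frame(chrom = "chr1", strand = "+",
                     position = c(130, 100, 105))
  cl <- cluster_polya_sites(recs, window = 20)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$support, c(2, 1))
  expect_equal(cl$representative[1], 105)  # tie on support: 3'-most on +
  expect_equal(cl$representative[2], 130)

  one <- cluster_polya_sites(data.frame(chrom = "chr1", strand = "-",
                                        position = 500))
  expect_equal(one$support, 1)

  ## input order invariance and member conservation
  set.seed(41)
  recs2 <- data.frame(chrom = "chr1", strand = "+",
                      position = sample(c(1:5 * 100, 1:5 * 100 + 3)))
  a <- cluster_polya_sites(recs2)
  b <- cluster_polya_sites(recs2[sample(nrow(recs2)), ])
  expect_equal(a, b)
  expect_equal(sum(a$support), nrow(recs2))

  ## weighted records: representative is the best-supported member
  w <- data.frame(chrom = "chr1", strand = "+",
                  position = c(100, 105), count = c(5, 2))
  expect_equal(cluster_polya_sites(w)$representative, 100)
})

test_that("clusters are assigned to genes with downstream extension", {
  genes <- list(
    gene_model(list(tm("t1", rbind(c(1000, 1200), c(1400, 2000)),
                       gene = "gA"))),
    gene_model(list(tm("t2", cbind(5000, 6000), gene = "gB",
                       strand = "-"))))
  cl <- data.frame(chrom = "chr1", strand = c("+", "+", "-"),
                   representative = c(1500, 2300, 4800),
                   support = c(3, 2, 4))
  sp <- sites_per_gene(cl, genes)
  counts <- stats::setNames(sp$per_gene$n_sites, sp$per_gene$gene_id)
  expect_equal(unname(counts["gA"]), 2L)  # in-span + 300 nt downstream
  expect_equal(unname(counts["gB"]), 1L)  # minus strand: downstream is left
  expect_equal(sp$mean_sites_per_gene, 1.5)
  expect_equal(sp$frac_multi_site, 0.5)
  expect_equal(sp$n_unassigned, 0L)
})

test_that("cross-stage site sharing uses the 20-nt tolerance", {
  genes <- list(gene_model(list(tm("t1", cbind(1000, 2000), gene = "gA"))))
  mk <- function(pos) data.frame(chrom = "chr1", strand = "+",
                                 representative = pos,
                                 support = rep(3, length(pos)))
  same <- stage_site_sharing(list(E1 = mk(1500), E3 = mk(1500)), genes)
  expect_true(same$unchanged)
  near <- stage_site_sharing(list(E1 = mk(1002), E3 = mk(1010)), genes)
  expect_true(near$unchanged)  # within 20 nt: the same site
  extra <- stage_site_sharing(list(E1 = mk(1500), E3 = mk(c(1500, 1800))),
                              genes)
  expect_false(extra$unchanged)
})

test_that("nucleotide composition rows are frequencies summing to one", {
  g <- flat_genome("A", 2000)
  cl <- data.frame(chrom = "chr1", strand = "+", representative = 1000,
                   support = 1)
  comp <- nucleotide_composition(cl, g)
  expect_equal(dim(comp), c(101, 4))
  expect_true(all(abs(rowSums(comp) - 1) < 1e-9))
  expect_true(all(comp[, "A"] == 1))

  set.seed(43)
  g2 <- stats::setNames(random_dna(4000), "chr1")
  cl2 <- data.frame(chrom = "chr1", strand = c("+", "-"),
                    representative = c(1000, 3000), support = 1)
  comp2 <- nucleotide_composition(cl2, g2)
  expect_true(all(abs(rowSums(comp2) - 1) < 1e-9))
})

test_that("hexamer enrichment finds a planted AATAAA signal", {
  set.seed(47)
  n_sites <- 60
  chrlen <- 200 * (n_sites + 2)
  g <- stats::setNames(random_dna(chrlen), "chr1")
  pos <- 200 * (1:n_sites)
  ## plant the signal ~25 nt upstream of 80% of sites
  for (i in seq_len(round(0.8 * n_sites))) {
    substr(g[["chr1"]], pos[i] - 25, pos[i] - 20) <- "AATAAA"
  }
  cl <- data.frame(chrom = "chr1", strand = "+", representative = pos,
                   support = 1)
  hx <- hexamer_enrichment(cl, g)
  expect_equal(hx$motif[1], "AATAAA")
  expect_gte(hx$observed[1], round(0.8 * n_sites))
  expect_true(all(hx$p >= 0 & hx$p <= 1))
  expect_true(all(hx$observed <= n_sites))

  ## a single window containing the signal counts it once
  g1 <- flat_genome("C", 400)
  substr(g1[["chr1"]], 60, 66) <- "AAATAAA"
  one <- hexamer_enrichment(data.frame(chrom = "chr1", strand = "+",
                                       representative = 100, support = 1),
                            g1)
  expect_gte(one$observed[one$motif == "AATAAA"], 1)
})
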