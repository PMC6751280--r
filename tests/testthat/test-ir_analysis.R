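test_that("retained intron features: position, GC, canonicality", {
  g <- flat_genome("A", 1200)
  substr(g[["chr1"]], 901, 904) <- "GGCC"  # 4-nt "intron" placeholder
  gene <- gene_model(list(
    tm("a", rbind(c(1, 900), c(905, 1000))),
    tm("b", cbind(1, 1000))))
  ev <- detect_events(gene)
  feats <- retained_intron_features(ev, list(gene), g)
  expect_equal(feats$position_ratio, 0.9)
  expect_equal(feats$gc, 1.0)
  expect_equal(feats$length, 4)
  expect_false(feats$canonical)

  ## canonical GT..AG is recognized
  g2 <- flat_genome("A", 1200)
  substr(g2[["chr1"]], 901, 902) <- "GT"
  substr(g2[["chr1"]], 949, 950) <- "AG"
  gene2 <- gene_model(list(
    tm("a", rbind(c(1, 900), c(951, 1000)), gene = "g2"),
    tm("b", cbind(1, 1000), gene = "g2")))
  f2 <- retained_intron_features(detect_events(gene2), list(gene2), g2)
  expect_true(f2$canonical)

  ## an intron outside the gene span is an error
  bad <- as_event("IR", "g2", "chr1", "+", c(1100, 1150),
                  list("a", "b"))
  expect_error(retained_intron_features(list(bad), list(gene2), g2),
               "outside")
})

test_that("splice PWM training matches a hand tally and normalizes", {
  ## 3 identical planted introns: all-A genome with GT..AG sites
  g <- flat_genome("A", 2000)
  introns <- data.frame(chrom = "chr1", strand = "+",
                        start = c(101, 501, 901), end = c(200, 600, 1000))
  for (s in introns$start) substr(g[["chr1"]], s, s + 1) <- "GT"
  for (e in introns$end) substr(g[["chr1"]], e - 1, e) <- "AG"
  pwm <- train_splice_pwm(introns, g, pseudocount = 0.5)
  expect_equal(dim(pwm$donor), c(9, 4))
  expect_equal(dim(pwm$acceptor), c(23, 4))
  expect_equal(unname(rowSums(pwm$donor)), rep(1, 9))
  expect_equal(unname(rowSums(pwm$acceptor)), rep(1, 23))
  ## hand tally at donor position 4 (first intronic base): 3 G, pseudo 0.5
  expect_equal(unname(pwm$donor[4, "G"]), 3.5 / 5)
  expect_equal(unname(pwm$donor[4, "A"]), 0.5 / 5)
  ## position 1 (exonic): all A
  expect_equal(unname(pwm$donor[1, "A"]), 3.5 / 5)

  ## pseudocount -> 0 limit: P(G) -> 1 at the donor's first intronic base
  pwm0 <- train_splice_pwm(introns, g, pseudocount = 1e-9)
  expect_equal(unname(pwm0$donor[4, "G"]), 1, tolerance = 1e-6)

  expect_error(train_splice_pwm(introns[0, ], g), "empty")
})

test_that("PWM scoring is log-odds with the expected extremes", {
  uniform <- structure(list(
    donor = matrix(0.25, 9, 4, dimnames = list(NULL, c("A", "C", "G", "T"))),
    acceptor = matrix(0.25, 23, 4,
                      dimnames = list(NULL, c("A", "C", "G", "T"))),
    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)),
    class = "splice_pwm")
  g <- stats::setNames(random_dna(500), "chr1")
  sc <- score_splice_sites(list(chrom = "chr1", strand = "+",
                                start = 101, end = 200), uniform, g)
  expect_equal(unname(sc), c(0, 0))

  ## under a uniform background, the per-position argmax (consensus) site
  ## scores at least as high as any other site
  set.seed(3)
  bases <- c("A", "C", "G", "T")
  mk_mat <- function(width, consensus) {
    m <- matrix(0.1, width, 4, dimnames = list(NULL, bases))
    for (i in seq_len(width)) m[i, consensus[i]] <- 0.7
    m
  }
  d_cons <- c("C", "A", "G", "G", "T", "A", "A", "G", "T")
  a_cons <- c(rep("T", 18), "A", "G", "G", "C", "A")
  pwm <- structure(list(donor = mk_mat(9, d_cons),
                        acceptor = mk_mat(23, a_cons),
                        background = c(A = 0.25, C = 0.25, G = 0.25,
                                       T = 0.25)),
                   class = "splice_pwm")
  ## genome whose intron [101,200] presents exactly the consensus windows
  g_cons <- flat_genome("A", 400)
  substr(g_cons[["chr1"]], 98, 106) <- paste(d_cons, collapse = "")
  substr(g_cons[["chr1"]], 181, 203) <- paste(a_cons, collapse = "")
  site <- list(chrom = "chr1", strand = "+", start = 101, end = 200)
  cons <- score_splice_sites(site, pwm, g_cons)
  expect_equal(cons[["donor_score"]], 9 * log2(0.7 / 0.25))
  for (i in 1:20) {
    g_rnd <- stats::setNames(random_dna(400), "chr1")
    other <- score_splice_sites(site, pwm, g_rnd)
    expect_gte(cons[["donor_score"]], other[["donor_score"]])
    expect_gte(cons[["acceptor_score"]], other[["acceptor_score"]])
  }
})

test_that("rank-sum test: exact enumeration, ties, symmetry, wilcox check", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 6)
  expect_equal(r$method, "exact")

  expect_equal(rank_sum_test(c(5, 5, 5), c(5, 5))$p, 1)

  r1 <- rank_sum_test(c(1, 5, 7), c(2, 3, 9))
  r2 <- rank_sum_test(c(2, 3, 9), c(1, 5, 7))
  expect_equal(r2$U, 3 * 3 - r1$U)
  expect_equal(r2$p, r1$p)

  ## agreement with wilcox.test on tie-free data
  set.seed(17)
  for (i in 1:10) {
    a <- sample(1:1000, 4); b <- sample(2000:3000, 5)
    ours <- rank_sum_test(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value)
  }
  a <- rnorm(30); b <- rnorm(40, 0.5)
  ours <- rank_sum_test(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("longest ORF matches the brute-force scan", {
  o <- longest_orf("ATGAAATAA")
  expect_true(o$has_orf)
  expect_equal(o$start, 0)
  expect_equal(o$stop, 8)
  expect_false(longest_orf("CCCCCC")$has_orf)

  set.seed(23)
  for (i in 1:200) {
    s <- random_dna(300)
    got <- longest_orf(s)
    want <- oracle_orf(s)
    expect_equal(got$has_orf, want$has_orf, info = s)
    if (want$has_orf) {
      expect_equal(got$start, want$start, info = s)
      expect_equal(got$stop, want$stop, info = s)
    }
  }
})

test_that("PTC rule is a strict 50-nt junction distance", {
  ## two exons of 200 nt each: last junction at transcript position 200
  t <- tm("t1", rbind(c(1, 200), c(301, 500)))
  mk_orf <- function(stop_end_1based) {
    list(has_orf = TRUE, start = 0, stop = stop_end_1based - 1,
         length = stop_end_1based)
  }
  r51 <- classify_ptc(t, mk_orf(149))  # distance 200 - 149 = 51
  expect_true(as.logical(r51))
  expect_equal(attr(r51, "distance"), 51)
  expect_false(as.logical(classify_ptc(t, mk_orf(150))))  # exactly 50
  expect_false(as.logical(classify_ptc(t, mk_orf(380))))  # stop in last exon

  expect_error(classify_ptc(tm("m", cbind(1, 300)), mk_orf(100)),
               "single-exon")
})

test_that("IR transcripts are filtered by CDS containment of the intron", {
  ir <- data.frame(
    transcript_id = c("i1", "i2", "i3", "i4"),
    gene_id = c("g1", "g1", "g1", "g2"),
    intron_start = c(150, 900, 480, 10),
    intron_end = c(250, 950, 520, 60))
  reps <- data.frame(gene_id = "g1", cds_start = 100, cds_end = 500)
  expect_warning(out <- filter_ir_transcripts_for_ptc(ir, reps),
                 "no representative")
  expect_equal(out$reason,
               c("kept", "outside_cds", "overlapping_cds",
                 "no_representative"))
  expect_equal(out$kept, c(TRUE, FALSE, FALSE, FALSE))
})
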