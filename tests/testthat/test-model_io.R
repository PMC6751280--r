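test_that("GTF exon lines parse into grouped, sorted gene models", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t201\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
  ), path)
  genes <- read_transcript_gtf(path)
  expect_length(genes, 1)
  expect_length(genes[[1]]$transcripts, 1)
  expect_equal(unname(genes[[1]]$transcripts[[1]]$exons[, 1]), c(1, 201))
  expect_equal(genes[[1]]$span, c(1, 300))

  empty <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(0), empty)
  expect_identical(read_transcript_gtf(empty), list())
})

test_that("malformed GTF lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t200\t300\t.\t+\t.\tgene_id "g1";'
  ), path)
  expect_error(read_transcript_gtf(path), "line 2.*transcript_id")

  path2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines('chr1\tsrc\texon\t1\t100\t.\t.\t.\tgene_id "g"; transcript_id "t";',
             path2)
  expect_error(read_transcript_gtf(path2), "line 1")
})

test_that("overlapping or unstranded exons are rejected at construction", {
  expect_error(tm("t1", rbind(c(1, 100), c(50, 200))), "overlap")
  expect_error(tm("t1", rbind(c(1, 100), c(101, 200))), "overlap|adjacent")
  expect_error(transcript_model("t1", "g1", "chr1", ".", cbind(1, 100)),
               "strand")
})

test_that("GTF round-trip reproduces randomly generated models exactly", {
  set.seed(42)
  genes <- lapply(1:15, function(i) {
    random_gene(sprintf("g%02d", i), n_iso = sample(1:3, 1))
  })
  path <- withr::local_tempfile(fileext = ".gtf")
  write_transcript_gtf(genes, path)
  back <- read_transcript_gtf(path)
  key <- function(gs) {
    gs <- unname(gs)
    lapply(gs[order(vapply(gs, `[[`, character(1), "gene_id"))], function(g) {
      lapply(g$transcripts[order(vapply(g$transcripts, `[[`, character(1),
                                        "transcript_id"))],
             function(t) t[c("transcript_id", "gene_id", "chrom", "strand",
                             "exons")])
    })
  }
  expect_equal(key(back), key(genes))

  p2 <- withr::local_tempfile(fileext = ".gtf")
  write_transcript_gtf(list(), p2)
  expect_identical(read_transcript_gtf(p2), list())
})

test_that("extract_introns reads boundary dinucleotides strand-aware", {
  g <- flat_genome("A", 400)
  substr(g[["chr1"]], 101, 102) <- "GT"
  substr(g[["chr1"]], 199, 200) <- "AG"
  t_plus <- tm("tp", rbind(c(1, 100), c(201, 300)))
  ip <- extract_introns(t_plus, g)
  expect_equal(nrow(ip), 1)
  expect_equal(c(ip$start, ip$end), c(101, 200))
  expect_equal(ip$donor_dinuc, "GT")
  expect_equal(ip$acceptor_dinuc, "AG")
  expect_true(ip$canonical)

  ## same coordinates on the minus strand: donor comes from genomic 199-200
  g2 <- flat_genome("A", 400)
  substr(g2[["chr1"]], 199, 200) <- "AC"  # revcomp "GT"
  substr(g2[["chr1"]], 101, 102) <- "CT"  # revcomp "AG"
  t_minus <- tm("tn", rbind(c(1, 100), c(201, 300)), strand = "-")
  im <- extract_introns(t_minus, g2)
  expect_equal(im$donor_dinuc, "GT")
  expect_equal(im$acceptor_dinuc, "AG")

  expect_equal(nrow(extract_introns(tm("t1", cbind(1, 100)), g)), 0)
  expect_error(extract_introns(tm("t1", rbind(c(1, 100), c(395, 450))), g),
               "out of bounds")
})

test_that("exons and introns exactly tile the transcript span", {
  set.seed(7)
  g <- flat_genome("A", 3000)
  for (i in 1:20) {
    t <- random_transcript(paste0("t", i), strand = "+")
    ii <- extract_introns(t, g)
    covered <- sum(t$exons[, 2] - t$exons[, 1] + 1) +
      if (nrow(ii)) sum(ii$end - ii$start + 1) else 0
    expect_equal(unname(covered),
                 unname(t$exons[nrow(t$exons), 2] - t$exons[1, 1] + 1))
  }
})

test_that("transcript_sequence splices and orients exon sequence", {
  g <- stats::setNames("ATGCCCTAA", "chr1")
  t_plus <- tm("tp", rbind(c(1, 3), c(7, 9)))
  expect_equal(transcript_sequence(t_plus, g), "ATGTAA")
  t_minus <- tm("tn", rbind(c(1, 3), c(7, 9)), strand = "-")
  expect_equal(transcript_sequence(t_minus, g), "TTACAT")

  set.seed(11)
  gg <- stats::setNames(random_dna(3000), "chr1")
  for (i in 1:10) {
    t <- random_transcript(paste0("t", i))
    s <- transcript_sequence(t, gg)
    expect_equal(nchar(s), sum(t$exons[, 2] - t$exons[, 1] + 1))
    ## minus-strand extraction is the reverse complement of plus-strand
    t2 <- t; t2$strand <- if (t$strand == "+") "-" else "+"
    expect_equal(transcript_sequence(t2, gg),
                 splicedyn:::revcomp(s))
  }
})

test_that("expression tables parse sample metadata and reject bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tgene_id\tE1_1\tE2_3",
               "t1\tg1\t1.5\t0",
               "t2\tg1\t2\t4"), path)
  ex <- read_expression_table(path)
  expect_equal(dim(ex$values), c(2, 2))
  expect_equal(ex$sample_meta$stage, c("E1", "E2"))
  expect_equal(ex$sample_meta$replicate, c(1L, 3L))
  expect_equal(unname(ex$tx2gene), c("g1", "g1"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tgene_id\tE1_1", "t1\tg1\t-1"), bad)
  expect_error(read_expression_table(bad), "negative")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tgene_id\tE1_1", "t1\tg1\t1", "t1\tg1\t2"), dup)
  expect_error(read_expression_table(dup), "duplicate")
})
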