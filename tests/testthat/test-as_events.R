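test_that("the five event modes are detected with their defining signatures", {
  ## intron retention
  g_ir <- gene_model(list(
    tm("a", rbind(c(1, 100), c(201, 300))),
    tm("b", cbind(1, 300))))
  ev <- detect_events(g_ir)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$event_type, "IR")
  expect_equal(ev[[1]]$signature, c(101, 200))
  expect_setequal(ev[[1]]$supporting[[1]], "a")  # spliced form
  expect_setequal(ev[[1]]$supporting[[2]], "b")  # retained form

  ## exon skipping (and nothing else from the skip junction)
  g_es <- gene_model(list(
    tm("a", rbind(c(1, 100), c(201, 250), c(301, 400))),
    tm("b", rbind(c(1, 100), c(301, 400)))))
  ev <- detect_events(g_es)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$event_type, "ES")
  expect_equal(ev[[1]]$signature, c(201, 250, 101, 300))

  ## alternative donor on the plus strand
  g_a5 <- gene_model(list(
    tm("a", rbind(c(1, 100), c(201, 300))),
    tm("b", rbind(c(1, 120), c(201, 300)))))
  ev <- detect_events(g_a5)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$event_type, "A5SS")
  expect_equal(ev[[1]]$signature, c(101, 121, 200))
  ## same geometry on the minus strand is an acceptor shift
  g_a3 <- gene_model(list(
    tm("a", rbind(c(1, 100), c(201, 300)), strand = "-"),
    tm("b", rbind(c(1, 120), c(201, 300)), strand = "-")))
  expect_equal(detect_events(g_a3)[[1]]$event_type, "A3SS")

  ## mutually exclusive exons
  g_mee <- gene_model(list(
    tm("a", rbind(c(1, 100), c(201, 250), c(401, 500))),
    tm("b", rbind(c(1, 100), c(301, 350), c(401, 500)))))
  ev <- detect_events(g_mee)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$event_type, "MEE")
  expect_equal(ev[[1]]$signature, c(201, 250, 301, 350, 101, 400))

  ## single-isoform gene
  expect_identical(detect_events(gene_model(list(tm("a", cbind(1, 50))))),
                   list())
})

test_that("detection is invariant to isoform order and id relabeling", {
  set.seed(13)
  for (i in 1:30) {
    g <- random_gene(sprintf("g%02d", i))
    k1 <- event_keys(detect_events(g))
    g_rev <- gene_model(rev(g$transcripts))
    expect_identical(event_keys(detect_events(g_rev)), k1)
    relab <- gene_model(lapply(seq_along(g$transcripts), function(j) {
      t <- g$transcripts[[j]]
      t$transcript_id <- sprintf("zz%02d", length(g$transcripts) - j)
      t
    }))
    expect_identical(event_keys(detect_events(relab)), k1)
  }
})

test_that("detect_events agrees with the brute-force pairwise oracle", {
  set.seed(99)
  for (i in 1:120) {
    g <- random_gene(sprintf("g%03d", i))
    expect_identical(event_keys(detect_events(g)), oracle_events(g),
                     info = paste("gene", i))
  }
})

test_that("event tallies are complete and consistent", {
  genes <- list(
    gene_model(list(tm("a", rbind(c(1, 100), c(201, 300))),
                    tm("b", cbind(1, 300)))),
    gene_model(list(tm("a", rbind(c(1, 100), c(201, 250), c(301, 400))),
                    tm("b", rbind(c(1, 100), c(301, 400))))),
    gene_model(list(tm("a", rbind(c(1, 100), c(201, 300))),
                    tm("b", rbind(c(1, 120), c(201, 300))))),
    gene_model(list(tm("a", rbind(c(1, 100), c(201, 250), c(401, 500))),
                    tm("b", rbind(c(1, 100), c(301, 350), c(401, 500))))))
  events <- unlist(lapply(genes, detect_events), recursive = FALSE)
  tally <- count_events_by_type(events)
  expect_equal(tally, c(IR = 1L, ES = 1L, A5SS = 1L, A3SS = 0L, MEE = 1L))
  expect_equal(sum(tally), length(events))
  expect_equal(sum(count_events_by_type(list())), 0L)
})

test_that("stage presence requires both event forms above threshold", {
  g <- gene_model(list(tm("a", rbind(c(1, 100), c(201, 300))),
                       tm("b", cbind(1, 300))))
  ev <- detect_events(g)
  vals <- rbind(a = c(E1 = 0, E5 = 3, E8 = 5),
                b = c(E1 = 4, E5 = 2, E8 = 0))
  expr <- toy_expr(vals, c(a = "g1", b = "g1"))
  pres <- stage_event_presence(ev, expr, min_fpkm = 0.1)
  expect_equal(pres["IR", ], c(E1 = 0L, E5 = 1L, E8 = 0L))

  ## zero threshold on an all-positive matrix: present everywhere
  vals2 <- vals; vals2[vals2 == 0] <- 0.01
  pres2 <- stage_event_presence(ev, toy_expr(vals2, c(a = "g1", b = "g1")),
                                min_fpkm = 0)
  expect_true(all(pres2["IR", ] == 1L))

  ## monotone in the threshold
  thresholds <- c(0, 0.5, 2, 3, 10)
  counts <- vapply(thresholds, function(th) {
    sum(stage_event_presence(ev, expr, min_fpkm = th))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  expr_missing <- toy_expr(vals[1, , drop = FALSE], c(a = "g1"))
  expect_error(stage_event_presence(ev, expr_missing, 0.1), "'b'")
})
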