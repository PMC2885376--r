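test_that("expression TSVs parse, validate and round-trip", {
  tf <- tsv_fixture(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\t4"))
  e <- read_expression_matrix(tf)
  expect_equal(e$gene_id, c("g1", "g2"))
  expect_equal(e$s1, c(1, 3))
  expect_equal(e$s2, c(2, 4))

  # round-trip preserves values and id order
  set.seed(41)
  m <- random_table(7, 4) + 0.25
  e1 <- expr_tbl(m)
  out <- tempfile(fileext = ".tsv")
  write_expression_matrix(e1, out)
  expect_equal(read_expression_matrix(out), e1)

  # error reporting names the offending cell
  bad <- tsv_fixture(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t-1.0\t4"))
  expect_error(read_expression_matrix(bad), "g2.*s1",
               class = "miract_error_negative")
  nonnum <- tsv_fixture(c("gene_id\ts1\ts2", "g1\t1\tx", "g2\t3\t4"))
  expect_error(read_expression_matrix(nonnum), "g1.*s2",
               class = "miract_error_parse")
  dup <- tsv_fixture(c("gene_id\ts1\ts2", "g1\t1\t2", "g1\t3\t4"))
  expect_error(read_expression_matrix(dup), class = "miract_error_ids")
})

test_that("negative expression is shifted only on explicit opt-in", {
  tf <- tsv_fixture(c("gene_id\ts1\ts2", "g1\t-0.5\t2", "g2\t3\t4"))
  expect_error(read_expression_matrix(tf), class = "miract_error_negative")
  expect_warning(e <- read_expression_matrix(tf, allow_shift = TRUE),
                 "shifted")
  expect_equal(min(as.matrix(e[-1])), 0)
  expect_equal(e$s1, c(0, 3.5))
})

test_that("probe collapsing filters multi-gene probes and averages the rest", {
  pm <- matrix(c(1, 5, 3, 7, 10, 20), nrow = 3, byrow = TRUE,
               dimnames = list(c("P2", "P3", "P1"), c("s1", "s2")))
  probes <- expr_tbl(pm)
  map <- tibble::tibble(
    probe_id = c("P1", "P1", "P2", "P3"),
    gene_id  = c("geneA", "geneB", "geneC", "geneC"))
  out <- collapse_probes(probes, map)
  # P1 hits two genes -> contributes nowhere; P2,P3 average into geneC
  expect_equal(out$gene_id, "geneC")
  expect_equal(unlist(out[1, c("s1", "s2")], use.names = FALSE), c(2, 6))

  # one-to-one map renames probes to genes and keeps rows
  map1 <- tibble::tibble(probe_id = c("P2", "P3", "P1"),
                         gene_id = c("gA", "gB", "gC"))
  out1 <- collapse_probes(probes, map1)
  expect_equal(out1$gene_id, c("gA", "gB", "gC"))
  expect_equal(as.matrix(out1[-1]), unname(pm), ignore_attr = TRUE)

  # nothing surviving is an error
  expect_error(collapse_probes(probes,
                               tibble::tibble(probe_id = "PX", gene_id = "g")),
               class = "miract_error_empty")
})

test_that("probe collapsing equals per-gene mean recomputation on random maps", {
  set.seed(7)
  for (rep in 1:20) {
    n_probe <- sample(5:25, 1)
    m <- matrix(runif(n_probe * 4, 0.1, 10), n_probe, 4,
                dimnames = list(paste0("P", seq_len(n_probe)),
                                paste0("s", 1:4)))
    genes <- paste0("G", sample.int(6, n_probe, replace = TRUE))
    map <- tibble::tibble(probe_id = rownames(m), gene_id = genes)
    out <- collapse_probes(expr_tbl(m), map)
    for (g in out$gene_id) {
      expected <- colMeans(m[genes == g, , drop = FALSE])
      expect_lt(max(abs(unlist(out[out$gene_id == g, -1]) - expected)), 1e-12)
    }
  }
})

test_that("target records parse with defaults, comments and line-number errors", {
  tf <- tsv_fixture(c("# prediction export", "miR-1\tGENE1\t3", "miR-1\tGENE2"))
  rec <- read_target_records(tf)
  expect_equal(rec$site_count, c(3L, 1L))
  expect_equal(rec$mirna_id, c("miR-1", "miR-1"))

  zero <- tsv_fixture(c("miR-1\tGENE1\t0"))
  expect_error(read_target_records(zero), "line 1",
               class = "miract_error_parse")
  frac <- tsv_fixture(c("miR-1\tGENE1\t2", "miR-2\tGENE2\t1.5"))
  expect_error(read_target_records(frac), "line 2",
               class = "miract_error_parse")
})

test_that("target tables sum duplicates and guarantee positive margins", {
  rec <- tibble::tibble(mirna_id = c("miR-1", "miR-1"),
                        gene_id = c("G1", "G1"), site_count = c(1L, 2L))
  tt <- build_target_table(rec, "p")
  expect_equal(tt[["miR-1"]], 3)

  rec2 <- tibble::tibble(mirna_id = c("miR-1", "miR-2"),
                         gene_id = c("G1", "G2"), site_count = c(1L, 1L))
  tt2 <- build_target_table(rec2, "p")
  expect_equal(dim(tt2), c(2L, 3L))
  expect_equal(tt2[["miR-2"]], c(0, 1))
  expect_equal(tt2[["miR-1"]], c(1, 0))

  expect_error(build_target_table(rec[0, ]), class = "miract_error_empty")

  # binarize flattens multiplicities to presence
  ttb <- build_target_table(rec, "p", binarize = TRUE)
  expect_equal(ttb[["miR-1"]], 1)

  # order-insensitive up to reindexing; margins always >= 1
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    recs <- tibble::tibble(
      mirna_id = paste0("m", sample.int(6, n, replace = TRUE)),
      gene_id = paste0("g", sample.int(8, n, replace = TRUE)),
      site_count = sample.int(3, n, replace = TRUE))
    a <- build_target_table(recs, "p")
    b <- build_target_table(recs[sample.int(n), ], "p")
    am <- as.matrix(a[-1]); rownames(am) <- a$gene_id
    bm <- as.matrix(b[-1]); rownames(bm) <- b$gene_id
    expect_equal(am[rownames(bm), colnames(bm)], bm)
    expect_true(all(rowSums(am) >= 1) && all(colSums(am) >= 1))
  }
})

test_that("alignment restricts to shared genes in expression order", {
  em <- matrix(1:8 + 0.0, 4, 2,
               dimnames = list(c("A", "B", "C", "E"), c("s1", "s2")))
  tm <- matrix(c(1, 0, 2, 1, 1, 0, 3, 2), 4, 2,
               dimnames = list(c("C", "B", "E", "D"), c("m1", "m2")))
  # mD's only target is on D (not shared); m2 covers the shared genes
  tm2 <- matrix(c(0, 0, 0, 2, 1, 3, 2, 0), 4, 2,
                dimnames = list(c("B", "C", "E", "D"), c("mD", "m2")))
  expect_warning(al <- align_tables(expr_tbl(em), target_tbl(tm2)),
                 "mD")
  expect_equal(al$expression$gene_id, c("B", "C", "E"))
  expect_equal(al$targets$gene_id, c("B", "C", "E"))
  expect_equal(setdiff(names(al$targets), "gene_id"), "m2")

  al1 <- align_tables(expr_tbl(em), target_tbl(tm))
  expect_equal(al1$expression$gene_id, c("B", "C", "E"))
  expect_equal(al1$targets$gene_id, c("B", "C", "E"))

  # idempotence
  al2 <- align_tables(al1$expression, al1$targets)
  expect_equal(al2$expression, al1$expression)
  expect_equal(al2$targets, al1$targets, ignore_attr = TRUE)

  # too small an intersection is refused
  tiny <- matrix(c(1, 1), 1, 2, dimnames = list("B", c("m1", "m2")))
  expect_error(align_tables(expr_tbl(em), target_tbl(tiny)),
               class = "miract_error_alignment")
})
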