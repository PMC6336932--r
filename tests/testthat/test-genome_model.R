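test_that("FASTA reading normalizes case and U, enforces one record", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x some description", "acgu"), f)
  g <- read_fasta(f)
  expect_equal(g$seq, "ACGT")
  expect_equal(g$length, 4L)
  expect_equal(g$id, "x")

  writeLines(c(">x", "ACGN"), f)
  expect_equal(read_fasta(f)$seq, "ACGN")  # ambiguity codes retained

  writeLines(c(">a", "ACGT", ">b", "ACGT"), f)
  expect_error(read_fasta(f), "2")
})

test_that("feature extraction honors strand and the circular origin", {
  g <- genome_sequence("ATGAAA")
  expect_equal(extract_feature_sequence(g, list(start = 1, end = 3, strand = "+")),
               "ATG")
  expect_equal(extract_feature_sequence(g, list(start = 1, end = 3, strand = "-")),
               "CAT")
  # origin-spanning: positions 5,6 then 1,2; length (6-5+1)+2 = 4
  wrapped <- extract_feature_sequence(g, list(start = 5, end = 2, strand = "+"))
  expect_equal(wrapped, "AAAT")
  expect_equal(nchar(wrapped), (6 - 5 + 1) + 2)
  expect_equal(extract_feature_sequence(g, list(start = 5, end = 2, strand = "-")),
               revcomp("AAAT"))
})

test_that("extracted lengths equal annotated lengths on all strand/wrap cases", {
  g <- synth_sequence(100, seed = 11)
  cases <- expand.grid(start = c(1, 40, 95), strand = c("+", "-"),
                       stringsAsFactors = FALSE)
  for (r in seq_len(nrow(cases))) {
    s <- cases$start[r]
    e <- if (s == 95) 10 else s + 19  # the s = 95 case wraps
    len <- if (s <= e) e - s + 1 else (100 - s + 1) + e
    got <- extract_feature_sequence(g, list(start = s, end = e,
                                            strand = cases$strand[r]))
    expect_equal(nchar(got), len)
  }
})

test_that("feature-table parsing validates its contract", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tstrand\tstart\tend", "cox1\t+\t1\t30", "cox1\t+\t31\t60"), f)
  expect_error(parse_feature_table(f, 100), "duplicate")

  writeLines(c("gene\tstrand\tstart\tend", "cox1\t+\t1\t300"), f)
  expect_error(parse_feature_table(f, 100), "outside")

  writeLines(c("gene\tstrand\tstart\tend", "cox1\t?\t1\t30"), f)
  expect_error(parse_feature_table(f, 100), "strand")

  writeLines("gene\tstrand\tstart\tend", f)
  expect_error(parse_feature_table(f, 100), "no features")

  # start > end requires the explicit origin-spanning flag
  writeLines(c("gene\tstrand\tstart\tend", "trnW\t+\t10\t5"), f)
  expect_error(parse_feature_table(f, 100), "wrap")
  writeLines(c("gene\tstrand\tstart\tend\twrap", "trnW\t+\t10\t5\tTRUE"), f)
  ann <- parse_feature_table(f, 100)
  expect_equal(ann$features$length, (100 - 10 + 1) + 5)
})

test_that("feature tables round-trip through write + parse", {
  ann <- read_nsamayunkur()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ann, f)
  back <- parse_feature_table(f, ann$genome_length, genome_id = ann$genome_id)
  expect_equal(back$features, ann$features)
})

test_that("the packaged annotation matches the published feature table", {
  ann <- read_nsamayunkur()
  expect_equal(nrow(ann$features), 39L)
  expect_equal(sum(ann$features$feature_class != "CR"), 37L)
  f1 <- ann$features[1, ]
  expect_equal(f1$gene, "cox1")
  expect_equal(c(f1$start, f1$end), c(1L, 1536L))
  expect_equal(f1$strand, "+")
})

test_that("gene-name canonicalization resolves dialect forms", {
  expect_equal(canonical_gene_name(c("COI", "ND4L", "12S", "trnL-UUR", "CYTB")),
               c("cox1", "nad4L", "rrnS", "trnL2", "cytb"))
  expect_error(canonical_gene_name("not-a-gene"), "unknown")
})

test_that("signed gene orders canonicalize and compare circularly", {
  o <- gene_order(c("b", "c", "a"), c(1L, -1L, 1L), anchor = "a")
  expect_equal(o$labels[1], "a")
  expect_equal(o$signs[1], 1L)
  # rotation does not change the order
  o2 <- gene_order(c("c", "a", "b"), c(-1L, 1L, 1L), anchor = "a")
  expect_true(gene_order_equal(o, o2))
  # anchoring at a minus-strand gene reflects the whole order
  o3 <- gene_order(c("a", "b", "c"), c(-1L, 1L, -1L), anchor = "a")
  expect_equal(o3$signs[1], 1L)
  expect_true(gene_order_equal(o3, gene_order(c("a", "b", "c"),
                                              c(-1L, 1L, -1L), anchor = "b")))
  expect_equal(parse_gene_order(format_gene_order(o))$labels, o$labels)
})

test_that("the annotation's gene order excludes CRs and is rotation-invariant", {
  ann <- read_nsamayunkur()
  ord <- to_signed_gene_order(ann)
  expect_equal(length(ord$labels), 37L)
  expect_false(any(c("CR1", "CR2") %in% ord$labels))
  expect_equal(ord$labels[1:4], c("cox1", "nad3", "cox2", "trnD"))
  minus <- sort(ord$labels[ord$signs < 0])
  expect_equal(minus, sort(c("trnY", "atp8", "trnP", "nad5", "trnH",
                             "nad4", "nad4L")))
  # rotating the feature rows changes nothing (constructor re-sorts)
  rot <- ann$features[c(10:39, 1:9), ]
  ann2 <- mito_annotation(rot, ann$genome_length)
  expect_true(gene_order_equal(to_signed_gene_order(ann2), ord))
})

test_that("the packaged ancestral order has the conserved blocks and 14 minus genes", {
  anc <- ancestral_insect_order()
  expect_equal(length(anc$labels), 37L)
  expect_true(adjacency_present(anc, "trnL2", "cox2"))
  expect_true(adjacency_present(anc, "atp8", "atp6"))
  expect_equal(sum(anc$signs < 0), 14L)
})
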