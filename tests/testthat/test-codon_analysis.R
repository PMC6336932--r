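test_that("start/stop classification covers complete, incomplete and anomalous", {
  r <- start_stop_codons("ATGAAATAA")
  expect_equal(r$start_codon, "ATG")
  expect_equal(r$stop_codon, "TAA")
  expect_true(r$complete_stop)
  expect_equal(r$remainder, 0L)

  # remainder 1 with trailing T: polyadenylation-completed stop
  r1 <- start_stop_codons(paste0("ATC", strrep("AAA", 328), "T"))
  expect_equal(r1$stop_codon, "T(AA)")
  expect_false(r1$complete_stop)
  expect_equal(r1$remainder, 1L)

  r2 <- start_stop_codons("ATGAAACCCTA")
  expect_equal(r2$stop_codon, "TA(A)")

  r3 <- start_stop_codons("ATGAAAAAA")  # in-frame, no terminator
  expect_true(r3$anomalous)
  expect_true(is.na(r3$stop_codon))
  expect_error(start_stop_codons("ATGAA"), "shorter")
})

test_that("codon usage counts complete triplets and is additive", {
  u <- codon_usage(list("ATGAAATAA"))
  expect_equal(u$counts[["ATG"]], 1L)
  expect_equal(u$counts[["AAA"]], 1L)
  expect_equal(u$counts[["TAA"]], 1L)
  expect_equal(u$total_sense, 2L)  # TAA not a sense codon

  u2 <- codon_usage(list("ATGAAATAA", "ATGAAATAA"))
  expect_equal(u2$counts, 2L * u$counts)

  # trailing remainder never counted
  u3 <- codon_usage(list("ATGAAAAAAT"))
  expect_equal(sum(u3$counts), 3L)
})

test_that("RSCU follows the count * family size / family total formula", {
  # Lys family {AAA, AAG}: 3 vs 1 -> 1.5 / 0.5
  u <- codon_usage(list(paste0("ATG", "AAA", "AAA", "AAA", "AAG", "TAA")))
  r <- rscu(u)
  expect_equal(r[["AAA"]], 1.5)
  expect_equal(r[["AAG"]], 0.5)
  # uniform usage in a family gives RSCU 1 everywhere in it
  u2 <- codon_usage(list(paste0("ATG", "GGA", "GGC", "GGG", "GGT", "TAA")))
  r2 <- rscu(u2)
  expect_equal(unname(r2[c("GGA", "GGC", "GGG", "GGT")]), rep(1, 4))
  # unused families flagged with RSCU 0
  expect_true("C" %in% attr(r, "zero_families"))
  expect_equal(r[["TGC"]], 0)
})

test_that("RSCU family sums equal family sizes for all nonzero families", {
  sm <- synth_mitogenome(synth_spec(seed = 42))
  f <- sm$annotation$features
  pcg <- f[f$feature_class == "PCG", ]
  cds <- vapply(seq_len(nrow(pcg)), function(i)
    extract_feature_sequence(sm$genome, pcg[i, ]), character(1))
  u <- codon_usage(cds)
  r <- rscu(u)
  aa <- u$aa[names(r)]
  for (a in unique(aa)) {
    fam <- names(r)[aa == a]
    if (sum(u$counts[fam]) > 0)
      expect_equal(sum(r[fam]), length(fam))
  }
  # family counts partition the sense total
  expect_equal(sum(u$family_counts), u$total_sense)
})

test_that("serine and leucine families follow the invertebrate mitochondrial code", {
  code <- invertebrate_mito_code()
  expect_equal(code$codons[["AGA"]], "S")
  expect_equal(code$codons[["AGG"]], "S")
  expect_equal(code$codons[["ATA"]], "M")
  expect_equal(code$codons[["TGA"]], "W")
  expect_equal(sum(code$codons == "S"), 8L)
  expect_equal(sum(code$codons == "L"), 6L)
  expect_equal(sum(code$codons == "*"), 2L)
  expect_equal(length(code$codons), 64L)
})

test_that("absent codons are the unused sense codons", {
  u <- codon_usage(list("ATGTAA"))
  ab <- absent_codons(u)
  expect_equal(length(ab), 61L)  # 62 sense codons, one used
  expect_false("ATG" %in% ab)
  expect_false("TAA" %in% ab)   # stops never reported
  # planted zero-count codon
  u2 <- codon_usage(list(paste0("ATG", "GCA", "GCC", "GCT", "TAA")))
  expect_true("GCG" %in% absent_codons(u2))
})

test_that("amino-acid ranking sorts by count with alphabetical ties", {
  u <- codon_usage(list(paste0("ATG", strrep("AAA", 10), strrep("TTT", 5), "TAA")))
  rk <- aa_usage_ranking(u)
  expect_equal(rk[1:2], c("K", "F"))
  # tie between K and F resolves alphabetically
  u2 <- codon_usage(list(paste0("ATG", strrep("AAA", 5), strrep("TTT", 5), "TAA")))
  rk2 <- aa_usage_ranking(u2)
  expect_equal(rk2[1:2], c("F", "K"))
})

test_that("a codon bias planted in the generator surfaces in the ranking", {
  w <- stats::setNames(rep(1, 62), names(invertebrate_mito_code()$codons)[
    invertebrate_mito_code()$codons != "*"])
  w[c("AAA", "AAG")] <- 40      # lysine
  w[c("TTT", "TTC")] <- 25      # phenylalanine
  spec <- synth_spec(seed = 9, codon_weights = w)
  sm <- synth_mitogenome(spec)
  f <- sm$annotation$features
  pcg <- f[f$feature_class == "PCG", ]
  cds <- vapply(seq_len(nrow(pcg)), function(i)
    extract_feature_sequence(sm$genome, pcg[i, ]), character(1))
  rk <- aa_usage_ranking(codon_usage(cds))
  expect_equal(rk[1:2], c("K", "F"))
})

test_that("the fixture's start-codon census matches the published counts", {
  ann <- read_nsamayunkur()
  pcg <- ann$features[ann$features$feature_class == "PCG", ]
  census <- table(pcg$start_codon)
  expect_equal(census[["ATA"]], 5L)
  expect_equal(census[["ATT"]], 4L)
  expect_equal(census[["ATG"]], 3L)
  expect_equal(census[["ATC"]], 1L)
  # stop codons: TAA x10, TAG for atp6, incomplete in nad1 and nad2
  expect_equal(sum(pcg$stop_codon == "TAA"), 10L)
  expect_equal(pcg$stop_codon[pcg$gene == "atp6"], "TAG")
  expect_equal(sort(pcg$gene[pcg$stop_codon == "T(AA)"]), c("nad1", "nad2"))
})
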