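random_unit <- function(p, seed) synth_sequence(p, seed = seed)$seq

test_that("an exact planted 57 bp triplet is recovered as one family", {
  unit <- random_unit(57, 1)
  prefix <- synth_sequence(100, seed = 2)$seq
  s <- paste0(prefix, strrep(unit, 3), synth_sequence(40, seed = 3)$seq)
  fam <- tandem_repeats(s)
  hit <- fam[fam$period == 57 & fam$copies >= 3, ]
  expect_gte(nrow(hit), 1L)
  # phase may lock on slightly early when flanks tolerate mismatches,
  # but the family must cover the planted array
  expect_lte(hit$start[1], 101)
  expect_gte(hit$end[1], 101 + 3 * 57 - 1 - 15)
})

test_that("two near-identical copies (3 mismatches / 57 bp) form a family", {
  unit <- random_unit(57, 4)
  b <- strsplit(unit, "")[[1]]
  mut <- c(10, 25, 40)
  for (m in mut) b[m] <- setdiff(c("A", "C", "G", "T"), b[m])[1]
  unit2 <- paste(b, collapse = "")
  s <- paste0(synth_sequence(80, seed = 5)$seq, unit, unit2,
              synth_sequence(30, seed = 6)$seq)
  fam <- tandem_repeats(s)
  hit <- fam[fam$period == 57 & fam$copies == 2, ]
  expect_gte(nrow(hit), 1L)
  expect_gte(hit$mean_identity[1], 100 * 54 / 57 - 10)
})

test_that("i.i.d. random sequence yields no long repeat family", {
  s <- synth_sequence(200, seed = 7)$seq
  fam <- tandem_repeats(s, min_period = 20, min_identity = 80)
  expect_equal(nrow(fam), 0L)
})

test_that("planted repeats are recovered across many seeds", {
  hits <- 0L
  n_seeds <- 50L
  for (seed in seq_len(n_seeds)) {
    cr <- synth_control_region(320, unit = random_unit(57, 1000 + seed),
                               copies = 3, identity = 90,
                               motifs = c("TTTTTT", "TATA", "GAT"),
                               seed = seed)
    fam <- tandem_repeats(cr$seq)
    planted <- cr$log$repeat_starts[1]
    ok <- any(fam$period == 57 & fam$copies >= 3 &
              abs(fam$start - planted) <= 16)
    mo <- motif_scan(cr$seq)
    ok <- ok && any(mo$motif == "polyT" & mo$start == cr$log$motifs[["TTTTTT"]])
    ok <- ok && any(mo$motif == "TATA" & mo$start == cr$log$motifs[["TATA"]])
    ok <- ok && any(mo$motif == "GAT" & mo$start == cr$log$motifs[["GAT"]])
    if (ok) hits <- hits + 1L
  }
  expect_equal(hits, n_seeds)
})

test_that("requested copy identity is realized within tolerance", {
  ids <- vapply(1:20, function(seed) {
    cr <- synth_control_region(260, unit = random_unit(57, 2000 + seed),
                               copies = 3, identity = 90, seed = seed)
    mean(cr$log$realized_identity[-1])
  }, numeric(1))
  expect_lt(abs(mean(ids) - 90), 5)
})

test_that("pairwise identity matches hand alignments and the score oracle", {
  expect_equal(as.numeric(pairwise_identity("ACGT", "ACGT")), 100)
  expect_equal(as.numeric(pairwise_identity("AAAA", "AAAT")), 75)
  # one deletion: 7 matches over 8 columns
  expect_equal(as.numeric(pairwise_identity("ACGTACGT", "ACGACGT")), 87.5)
  expect_error(pairwise_identity("", "ACGT"), "empty")

  # the traceback's implied score equals the exponential-search optimum
  for (seed in 1:10) {
    a <- synth_sequence(sample(4:7, 1), seed = 300 + seed)$seq
    b <- synth_sequence(sample(4:7, 1), seed = 400 + seed)$seq
    id <- pairwise_identity(a, b)
    matches <- attr(id, "matches"); cols <- attr(id, "columns")
    pairs <- nchar(a) + nchar(b) - cols
    score <- matches - (pairs - matches) - 2 * (cols - pairs)
    expect_equal(score, oracle_align_score(a, b))
  }
})

test_that("pairwise identity is symmetric", {
  for (seed in 1:5) {
    a <- synth_sequence(30, seed = 500 + seed)$seq
    b <- synth_sequence(25, seed = 600 + seed)$seq
    expect_equal(as.numeric(pairwise_identity(a, b)),
                 as.numeric(pairwise_identity(b, a)))
  }
  expect_equal(as.numeric(pairwise_identity("GATTACA", "GATTACA")), 100)
})

test_that("motif scan finds 5' poly-T, TA(A)n, TATA and GAT", {
  s <- paste0("TTTTTT", "ACG", "TATAA", "CCGG", "TAATAATAA", "GGC", "GAT", "CC")
  m <- motif_scan(s)
  pt <- m[m$motif == "polyT", ]
  expect_equal(pt$start, 1L)
  expect_equal(pt$length, 6L)
  expect_true(pt$five_prime)
  expect_true(any(m$motif == "TATA" & m$start == 10L))
  expect_true(any(m$motif == "TAAn" & m$start == 19L & m$length == 9L))
  expect_true(any(m$motif == "GAT" & m$start == 31L))
  expect_equal(nrow(motif_scan("GCGCGCGC")), 0L)
  # overlapping TATA occurrences are all reported
  mm <- motif_scan("TATATA")
  expect_equal(mm$start[mm$motif == "TATA"], c(1L, 3L))
})

test_that("hairpin scan matches a hand case and rejects unstructured input", {
  hp <- hairpin_scan("GGGGAAAACCCC")
  expect_equal(nrow(hp), 1L)
  expect_equal(hp$stem, 4)
  expect_equal(hp$loop, 4)
  expect_equal(c(hp$arm1_start, hp$arm2_end), c(1, 12))
  expect_equal(nrow(hairpin_scan("AAAAAAAA")), 0L)
})

test_that("hairpin scan equals the exhaustive maximal-stem enumeration", {
  for (seed in 1:10) {
    s <- synth_sequence(100, c(A = .3, C = .2, G = .2, T = .3),
                        seed = 700 + seed)$seq
    mine <- hairpin_scan(s)
    mine <- as.matrix(mine[order(mine$arm1_start, mine$arm2_start, mine$stem), ])
    dimnames(mine) <- NULL
    oracle <- oracle_hairpins(s)
    dimnames(oracle) <- NULL
    expect_equal(mine, oracle, ignore_attr = TRUE)
  }
})
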