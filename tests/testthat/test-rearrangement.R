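test_that("event application matches the definitions", {
  o <- gene_order(as.character(1:4))
  inv <- apply_event(o, rearrangement_event("inversion", 2, 3))
  expect_equal(format_gene_order(inv), "1 -3 -2 4")
  # inversion is an involution
  expect_true(gene_order_equal(
    apply_event(inv, rearrangement_event("inversion", 2, 3)), o))

  o6 <- gene_order(as.character(1:6))
  # 'to' is where the block starts in the resulting order
  tr <- apply_event(o6, rearrangement_event("transposition", 2, 3, to = 5))
  expect_equal(format_gene_order(tr), "1 4 5 6 2 3")
  tr4 <- apply_event(o6, rearrangement_event("transposition", 2, 3, to = 4))
  expect_equal(format_gene_order(tr4), "1 4 5 2 3 6")
  itr <- apply_event(o6, rearrangement_event("inverse_transposition", 2, 3, to = 5))
  expect_equal(format_gene_order(itr), "1 4 5 6 -3 -2")

  td <- apply_event(o, rearrangement_event("tdrl", 1, 4,
                                           keep = c(TRUE, FALSE, TRUE, FALSE)))
  expect_equal(format_gene_order(td), "1 3 2 4")

  expect_error(apply_event(o, rearrangement_event("inversion", 2, 9)), "outside")
  expect_error(rearrangement_event("transposition", 2, 3), "insertion point")
  expect_error(rearrangement_event("tdrl", 1, 4, keep = c(TRUE, FALSE)), "keep")
})

test_that("transpositions round-trip via the reverse move", {
  o <- gene_order(letters[1:7])
  e <- rearrangement_event("transposition", 2, 3, to = 5)
  moved <- apply_event(o, e)
  # the block now sits at 5..6; moving it back to 2 restores the order
  back <- apply_event(moved, rearrangement_event("transposition", 5, 6, to = 2))
  expect_true(gene_order_equal(back, o))
})

test_that("single-event reachability analysis is complete over the event space", {
  # for every admissible event e, the inference must explain apply(e, o)
  # in one step with an event whose replay reproduces the same order
  o <- gene_order(letters[1:6])
  pool <- mitocompr:::enumerate_events(6)
  set.seed(5)
  pool <- pool[sample(length(pool), 120)]
  for (e in pool) {
    t1 <- apply_event(o, e)
    scens <- infer_scenario(o, t1, max_events = 1)
    expect_gte(length(scens), 1L)
    expect_true(attr(replay_scenario(scens[[1]]), "valid"))
  }
})

test_that("scenario inference recovers planted histories", {
  ref <- gene_order(letters[1:8])
  # equal orders: the empty scenario
  sc0 <- infer_scenario(ref, ref)
  expect_equal(length(sc0), 1L)
  expect_equal(length(sc0[[1]]$events), 0L)

  # one planted inversion is recovered as itself
  e <- rearrangement_event("inversion", 3, 6)
  sc1 <- infer_scenario(ref, apply_event(ref, e), max_events = 2)
  expect_equal(length(sc1[[1]]$events), 1L)
  expect_equal(sc1[[1]]$events[[1]]$kind, "inversion")
  expect_equal(c(sc1[[1]]$events[[1]]$i, sc1[[1]]$events[[1]]$j), c(3L, 6L))

  # transposition then inversion: a minimal length-2 scenario exists
  t2 <- apply_event(apply_event(ref, rearrangement_event("transposition", 2, 3, to = 6)),
                    rearrangement_event("inversion", 2, 4))
  sc2 <- infer_scenario(ref, t2, max_events = 2)
  expect_gte(length(sc2), 1L)
  expect_lte(length(sc2[[1]]$events), 2L)
  expect_true(all(vapply(sc2, function(s)
    isTRUE(attr(replay_scenario(s), "valid")), logical(1))))

  # two disjoint inversions cannot be explained by any single event
  two <- apply_event(apply_event(ref, rearrangement_event("inversion", 2, 3)),
                     rearrangement_event("inversion", 5, 6))
  sc3 <- infer_scenario(ref, two, max_events = 1)
  expect_equal(length(sc3), 0L)
  expect_true(isTRUE(attr(sc3, "unsolved")))
})

test_that("minimal scenario length agrees with an independent inversion BFS", {
  set.seed(77)
  for (rep in 1:20) {
    n <- 6
    ref <- gene_order(letters[1:n])
    k <- sample(1:2, 1)
    cur <- ref
    for (i in seq_len(k)) {
      ij <- sort(sample(2:n, 2))
      cur <- apply_event(cur, rearrangement_event("inversion", ij[1], ij[2]))
    }
    sv <- ref$signs * seq_len(n)
    tv <- cur$signs * match(cur$labels, ref$labels)  # target in ref's space
    want <- oracle_min_inversions(sv, tv, max_d = 2)
    expect_false(is.na(want))
    got <- infer_scenario(ref, cur, max_events = 2, kinds = "inversion")
    expect_equal(length(got[[1]]$events), want)
  }
})

test_that("replayed random scenarios reproduce their targets across seeds", {
  ref <- gene_order(letters[1:8])
  ok <- 0L
  for (seed in 1:100) {
    sr <- synth_rearranged(ref, 2, seed = seed)
    expect_true(attr(replay_scenario(sr$scenario), "valid"))
    scens <- infer_scenario(ref, sr$order, max_events = 2, max_scenarios = 5)
    if (length(scens) >= 1L &&
        isTRUE(attr(replay_scenario(scens[[1]]), "valid")) &&
        length(scens[[1]]$events) <= 2L) ok <- ok + 1L
  }
  expect_equal(ok, 100L)
})

test_that("one planted inversion's orientation changes are the inverted block", {
  anc <- ancestral_insect_order()
  e <- rearrangement_event("inversion", 5, 9)
  block <- anc$labels[5:9]
  out <- synth_rearranged(anc, list(e))
  expect_equal(orientation_changes(out$order, anc), sort(block))
})
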