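test_that("inversion distance equals the BFS adjacent-swap oracle", {
  # exhaustively for n = 4, sampled for n = 5 and 6
  p4 <- all_perms(4)
  for (i in seq_len(nrow(p4))) {
    expect_equal(inversion_distance(1:4, p4[i, ]),
                 bfs_swap_distance(1:4, p4[i, ]))
  }
  set.seed(11)
  for (n in 5:6) {
    for (r in 1:8) {
      a <- sample(n)
      b <- sample(n)
      expect_equal(inversion_distance(a, b), bfs_swap_distance(a, b))
    }
  }
})

test_that("inversion distance behaves like a metric on orderings", {
  expect_equal(inversion_distance(1:5, 1:5), 0L)
  expect_equal(inversion_distance(1:4, 4:1), 6L)
  set.seed(12)
  for (r in 1:25) {
    n <- sample(4:9, 1)
    a <- sample(n); b <- sample(n); c <- sample(n)
    expect_equal(inversion_distance(a, b), inversion_distance(b, a))
    expect_lte(inversion_distance(a, c),
               inversion_distance(a, b) + inversion_distance(b, c))
  }
  expect_error(inversion_distance(1:3, 1:4), "same index set")
  expect_error(inversion_distance(c(1, 1, 2), c(2, 1, 1)), "same index set")
})

test_that("words moved reproduces both printed scramblings of the example sentence", {
  expect_equal(words_moved(dogcat, c("dog", "the", "cat", "chased", "the")), 2L)
  expect_equal(words_moved(dogcat, c("the", "chased", "the", "cat", "dog")), 1L)
  expect_equal(words_moved(dogcat, dogcat), 0L)
  expect_error(words_moved(dogcat, c("a", "b", "c", "d", "e")), "permutation")
})

test_that("the printed intact/Scr7 pair has inversion distance 7 and 4 moved words", {
  perm <- match(scr7_example, int_example)
  expect_equal(inversion_distance(seq_along(int_example), perm), 7L)
  expect_equal(words_moved(int_example, scr7_example), 4L)
  # longest-increasing-subsequence oracle on the index permutation
  expect_equal(words_moved(int_example, scr7_example),
               length(perm) - lis_length(perm))
})

test_that("words moved never exceeds the inversion distance", {
  set.seed(13)
  for (r in 1:300) {
    n <- sample(3:12, 1)
    toks <- paste0("w", seq_len(n))
    perm <- sample(n)
    expect_lte(words_moved(toks, toks[perm]),
               inversion_distance(seq_len(n), perm))
  }
})

test_that("local swap scrambling enforces the requested inversion distance", {
  toks <- paste0("w", 1:12)
  r0 <- local_swap_scramble(toks, 0, seed = 5)
  expect_equal(r0$permutation, 1:12)
  expect_equal(r0$realized_inversion_distance, 0L)
  r1 <- local_swap_scramble(toks, 1, seed = 5)
  expect_equal(r1$realized_inversion_distance, 1L)
  expect_equal(words_moved(toks, r1$tokens), 1L)
  r7 <- local_swap_scramble(toks, 7, seed = 5)
  expect_equal(r7$realized_inversion_distance, 7L)
  expect_equal(sort(r7$permutation), 1:12)
  # reproducibility: identical draw for identical (tokens, k, seed)
  expect_identical(local_swap_scramble(toks, 7, seed = 5)$permutation,
                   r7$permutation)
  expect_false(identical(local_swap_scramble(toks, 7, seed = 6)$permutation,
                         r7$permutation))
  expect_error(local_swap_scramble(toks, 67, seed = 1), "k must lie")
  expect_error(local_swap_scramble(toks, 3, seed = 9, max_retries = 0),
               "seed 9")
  expect_error(local_swap_scramble("w1", 1, seed = 1), "at least 2")
})

test_that("duplicate surface forms are distinguished when verifying distance", {
  # with duplicated tokens the permutation is still on token indices, so a
  # swap of identical words counts toward the realized distance
  toks <- c("a", "a", "b", "a")
  r <- local_swap_scramble(toks, 2, seed = 3)
  expect_equal(r$realized_inversion_distance, 2L)
  expect_equal(sort(r$permutation), 1:4)
})

test_that("maximal-separation order reproduces the printed worked examples", {
  content <- c("larger", "firms", "international", "companies", "tended",
               "offer", "biggest", "pay", "rises")
  expect_equal(max_separation_order(content),
               c("larger", "international", "tended", "biggest", "rises",
                 "firms", "companies", "offer", "pay"))
  expect_equal(max_separation_order(c("and", "to", "the")),
               c("and", "the", "to"))
  expect_equal(max_separation_order(character()), character())
  expect_equal(max_separation_order("x"), "x")
})

test_that("maximal-separation order splits every originally adjacent pair across blocks", {
  for (n in 2:10) {
    out <- max_separation_order(seq_len(n))
    pos <- match(seq_len(n), out)
    seps <- abs(diff(pos))
    # consecutive items have opposite parity, so they always land in
    # different halves; with the function block inserted between halves the
    # realized separations grow further
    expect_true(all(seps >= floor(n / 2) - 1))
  }
})

test_that("the PMI-minimizing scramble reproduces the full printed stimulus", {
  rec <- min_pmi_scramble(lowpmi_input, function_words = c("and", "to", "the"))
  expect_equal(rec$tokens, lowpmi_expected)
  expect_equal(rec$condition_label, "ScrLowPMI")
  expect_equal(sort(rec$permutation), 1:12)
  # originally adjacent content words end up 8 and 7 positions apart
  expect_equal(adjacent_content_separation(rec), 7.5)
})

test_that("degenerate class compositions collapse to a single reordering", {
  rec <- min_pmi_scramble(c("a", "b", "c", "d"), function_words = character())
  expect_equal(rec$tokens, max_separation_order(c("a", "b", "c", "d")))
  recf <- min_pmi_scramble(c("of", "the"), function_words = c("of", "the"))
  expect_equal(sort(recf$permutation), 1:2)
  expect_error(min_pmi_scramble(c("a", "b")), "word_class")
  expect_error(min_pmi_scramble(c("a", "b"), word_class = c("content", "x")),
               "word_class")
})

test_that("condition characterization recovers the designed degradation profile", {
  g <- toy_grammar()
  st <- make_stimulus_set(g, 40, swap_levels = c(1, 3), seed = 17)
  ch <- characterize_conditions(st)
  int <- ch[ch$condition == "Int", ]
  expect_equal(int$mean_words_moved, 0)
  expect_equal(int$sd_words_moved, 0)
  scr1 <- ch[ch$condition == "Scr1", ]
  expect_equal(scr1$mean_words_moved, 1)
  expect_equal(scr1$sd_words_moved, 0)
  expect_equal(scr1$mean_inversion_distance, 1)
  scr3 <- ch[ch$condition == "Scr3", ]
  expect_equal(scr3$mean_inversion_distance, 3)
  expect_true(is.na(ch$mean_words_moved[ch$condition == "WordList"]))
  # missing intact row is an error
  expect_error(characterize_conditions(st[st$condition != "Int", ]),
               "missing Int row")
})

test_that("seven swaps move about four words on synthetic items", {
  g <- toy_grammar()
  st <- make_stimulus_set(g, 200, swap_levels = 7, seed = 19)
  ch <- characterize_conditions(st)
  m <- ch$mean_words_moved[ch$condition == "Scr7"]
  expect_gt(m, 3.5)
  expect_lt(m, 5.5)
})
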