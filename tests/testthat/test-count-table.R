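test_that("window pair extraction enumerates all ordered pairs up to window - 1", {
  tab <- count_corpus(list(c("a", "b", "c", "d")), window = 4)
  expect_equal(tab$total_pairs, 6L)
  got <- tab$pairs[order(tab$pairs$gap, tab$pairs$w1), c("w1", "w2", "gap")]
  expect_equal(
    unname(as.matrix(got)),
    unname(as.matrix(data.frame(
      w1 = c("a", "b", "c", "a", "b", "a"),
      w2 = c("b", "c", "d", "c", "d", "d"),
      gap = as.character(c(1, 1, 1, 2, 2, 3))))))
  # 3n - 6 pairs for a length-n string with a 4-word window
  tab12 <- count_corpus(list(paste0("w", 1:12)), window = 4)
  expect_equal(tab12$total_pairs, 30L)
  # degenerate lengths contribute only unigrams
  tab1 <- count_corpus(list("a"))
  expect_equal(tab1$total_pairs, 0L)
  expect_equal(unname(tab1$unigrams["a"]), 1L)
  expect_error(count_corpus(list()), "non-empty")
  expect_error(count_corpus(list(c("a", "b")), window = 1), "window")
})

test_that("Laplace-smoothed unigram probabilities match hand evaluation", {
  tab <- count_table(c(a = 3, b = 1), alpha = 0.1)
  expect_equal(unigram_prob(tab, "a"), 3.1 / 4.2)
  expect_equal(unigram_prob(tab, "b"), 1.1 / 4.2)
  # out-of-vocabulary words get the smoothing floor, never zero
  expect_equal(unigram_prob(tab, "zzz"), 0.1 / 4.2)
  expect_gt(unigram_prob(tab, "zzz"), 0)
  # uniform counts give uniform probabilities at any alpha
  tabu <- count_table(c(a = 2, b = 2), alpha = 0.1)
  expect_equal(unigram_prob(tabu, "a"), 0.5)
  expect_equal(unigram_prob(tabu, "b"), 0.5)
})

test_that("pair probabilities pool gaps by default and smooth unseen pairs", {
  tab <- count_table(c(a = 3, b = 1),
                     data.frame(w1 = "a", w2 = "b", gap = 1, count = 2),
                     alpha = 0.1)
  expect_equal(pair_prob(tab, "a", "b"), 2.1 / 2.4)
  expect_equal(pair_prob(tab, "b", "a"), 0.1 / 2.4)
  # per-gap variant uses that gap's total
  expect_equal(pair_prob(tab, "a", "b", pooled_gaps = FALSE, gap = 1), 2.1 / 2.4)
  expect_error(pair_prob(tab, "a", "b", pooled_gaps = FALSE, gap = 2), "gap")
  # no pairs at all is an error
  tab0 <- count_table(c(a = 1))
  expect_error(pair_prob(tab0, "a", "a"), "no pairs")
})

test_that("smoothed distributions normalize to one over the smoothed support", {
  corpus <- list(c("the", "cat", "sat", "on", "the", "mat"),
                 c("a", "dog", "sat"))
  tab <- count_corpus(corpus, window = 4, alpha = 0.1)
  words <- names(tab$unigrams)
  expect_equal(sum(unigram_prob(tab, words)), 1, tolerance = 1e-9)
  grid <- expand.grid(w1 = words, w2 = words, stringsAsFactors = FALSE)
  expect_equal(sum(pair_prob(tab, grid$w1, grid$w2)), 1, tolerance = 1e-9)
  for (g in 1:3)
    expect_equal(sum(pair_prob(tab, grid$w1, grid$w2, pooled_gaps = FALSE, gap = g)),
                 1, tolerance = 1e-9)
})

test_that("count tables round-trip exactly through their TSV serialization", {
  corpus <- list(c("b", "a", "c", "a"), c("a", "c"))
  tab <- count_corpus(corpus, window = 3, alpha = 0.25, lowercase = FALSE,
                      vocab_size = 10)
  dir <- withr::local_tempdir()
  write_counts(tab, dir)
  back <- read_counts(dir)
  expect_identical(back$unigrams, tab$unigrams)
  expect_identical(back$pairs, tab$pairs)
  expect_identical(back$alpha, tab$alpha)
  expect_identical(back$vocab_size, tab$vocab_size)
  expect_identical(back$window, tab$window)
  expect_identical(back$lowercase, tab$lowercase)
})

test_that("empirical pair probabilities factorize for an i.i.d. corpus", {
  # 1e5 tokens drawn independently from a fixed unigram distribution:
  # pair_prob(a, b) must approach unigram_prob(a) * unigram_prob(b)
  set.seed(77)
  vocab <- paste0("w", 1:12)
  probs <- (12:1) / sum(12:1)
  corpus <- lapply(seq_len(10000), function(i)
    sample(vocab, 10, replace = TRUE, prob = probs))
  tab <- count_corpus(corpus, window = 4, alpha = 0.1)
  for (pair in list(c("w1", "w2"), c("w2", "w1"), c("w3", "w6"))) {
    emp <- pair_prob(tab, pair[1], pair[2])
    ind <- unigram_prob(tab, pair[1]) * unigram_prob(tab, pair[2])
    expect_lt(abs(emp - ind) / ind, 0.10)
  }
})

test_that("tokens are case-folded at ingestion by default", {
  tab <- count_corpus(list(c("The", "THE", "the")))
  expect_equal(unname(tab$unigrams["the"]), 3L)
  expect_equal(unigram_prob(tab, "ThE"), unigram_prob(tab, "the"))
})
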