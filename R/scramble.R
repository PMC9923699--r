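#' Kendall-tau inversion distance between two orderings
#'
#' The minimum number of adjacent transpositions needed to turn ordering
#' `a` into ordering `b`, i.e. the inversion count of the relative
#' permutation. This is the "edit distance" used to verify that a requested
#' number of local word swaps was actually realized: a random swap can
#' directly undo an earlier one, so the realized distance can fall short of
#' the number of swaps applied.
#'
#' @param a,b Orderings (vectors) of the same index set, e.g. two
#'   permutations of `1:n`. Elements must be unique within each vector.
#' @return Integer distance, between 0 and `n (n - 1) / 2`.
#' @examples
#' inversion_distance(1:4, 4:1)  # 6
#' @export
inversion_distance <- function(a, b) {
  if (length(a) != length(b) || anyDuplicated(a) || anyDuplicated(b) ||
      !setequal(a, b))
    stop("a and b must be orderings of the same index set", call. = FALSE)
  # position of each element of b within a -> relative permutation
  rel <- match(b, a)
  count_inversions(rel)
}

# inversion count of a permutation of 1:n; O(n^2) is ample at stimulus sizes
count_inversions <- function(p) {
  n <- length(p)
  if (n < 2) return(0L)
  inv <- 0L
  for (i in seq_len(n - 1L)) inv <- inv + sum(p[(i + 1L):n] < p[i])
  as.integer(inv)
}

#' Number of words moved between two token sequences
#'
#' A move is a rightward or leftward displacement of one word across one or
#' more others. The minimal number of moved words equals `n - L`, where `L`
#' is the length of the longest common subsequence (LCS) of the two
#' sequences: the words in a longest common subsequence can be left in
#' place while every other word is moved. Duplicate surface forms are
#' resolved by the optimal LCS matching.
#'
#' @param original,scrambled Character vectors; `scrambled` must be a
#'   permutation of `original`'s token multiset.
#' @return Integer count of moved words.
#' @examples
#' words_moved(c("the","dog","chased","the","cat"),
#'             c("dog","the","cat","chased","the"))  # 2
#' @export
words_moved <- function(original, scrambled) {
  if (length(original) != length(scrambled) ||
      !identical(sort(original), sort(scrambled)))
    stop("scrambled must be a permutation of original's token multiset",
         call. = FALSE)
  length(original) - lcs_length(original, scrambled)
}

# classic O(n m) dynamic program
lcs_length <- function(x, y) {
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) return(0L)
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    eq <- x[i] == y
    for (j in seq_len(m)) {
      cur[j + 1L] <- if (eq[j]) prev[j] + 1L else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Scramble a sentence by repeated local word swaps
#'
#' Applies `k` random adjacent transpositions: at each step a word position
#' is chosen uniformly at random and the word is switched with one of its
#' immediate neighbors (side chosen uniformly for interior words; endpoint
#' words use their only neighbor). Because a swap can undo a previous one,
#' the whole draw is rejected and resampled until the realized inversion
#' distance from the intact order — computed on token indices, so duplicate
#' surface forms are distinguished — equals `k` exactly. The result is
#' deterministic given `seed`.
#'
#' @param tokens Character vector, length >= 2.
#' @param k Requested number of swaps; `0 <= k <= n (n - 1) / 2`.
#' @param seed Integer seed; required for reproducibility.
#' @param max_retries Maximum number of rejected draws before giving up.
#' @param condition_label Label stored on the record (default `"Scr<k>"`).
#' @return An object of class `scramble_record`: list with
#'   `original_tokens`, `tokens` (scrambled surface forms), `permutation`
#'   (original 1-based token indices in output order), `requested_swaps`,
#'   `realized_inversion_distance`, `seed`, `condition_label`.
#' @export
local_swap_scramble <- function(tokens, k, seed, max_retries = 10000L,
                                condition_label = NULL) {
  tokens <- check_tokens(tokens)
  n <- length(tokens)
  if (n < 2) stop("need at least 2 tokens", call. = FALSE)
  k <- as.integer(k)
  if (k < 0 || k > n * (n - 1) / 2)
    stop("k must lie in [0, n(n-1)/2] = [0, ", n * (n - 1) / 2, "]", call. = FALSE)
  label <- condition_label %||% if (k == 0) "Int" else paste0("Scr", k)

  perm <- with_seed(seed, {
    found <- NULL
    for (try in seq_len(max_retries)) {
      p <- seq_len(n)
      if (k > 0) {
        for (s in seq_len(k)) {
          i <- sample.int(n, 1L)
          j <- if (i == 1L) 2L
               else if (i == n) n - 1L
               else i + sample(c(-1L, 1L), 1L)
          tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
        }
      }
      if (count_inversions(p) == k) { found <- p; break }
    }
    if (is.null(found))
      stop("no draw with realized inversion distance ", k, " in ",
           max_retries, " tries (seed ", seed, ")", call. = FALSE)
    found
  })

  new_scramble_record(tokens, perm, requested_swaps = k, seed = seed,
                      condition_label = label)
}

new_scramble_record <- function(original_tokens, permutation, requested_swaps,
                                seed = NA_integer_, condition_label = NA_character_) {
  n <- length(original_tokens)
  if (length(permutation) != n || !setequal(permutation, seq_len(n)))
    stop("permutation must be a bijection on 1..n", call. = FALSE)
  rec <- list(
    original_tokens = original_tokens,
    tokens = original_tokens[permutation],
    permutation = as.integer(permutation),
    requested_swaps = requested_swaps,
    realized_inversion_distance = inversion_distance(seq_len(n), permutation),
    seed = seed,
    condition_label = condition_label
  )
  class(rec) <- "scramble_record"
  rec
}

#' @export
print.scramble_record <- function(x, ...) {
  cat("Scramble record [", x$condition_label, "]\n", sep = "")
  cat("  intact:   ", paste(x$original_tokens, collapse = " "), "\n")
  cat("  scrambled:", paste(x$tokens, collapse = " "), "\n")
  cat("  requested swaps:", x$requested_swaps,
      " realized inversion distance:", x$realized_inversion_distance, "\n")
  invisible(x)
}

#' Maximal-separation reordering
#'
#' Returns the odd-indexed items (1st, 3rd, 5th, ...) in their original
#' relative order, followed by the even-indexed items (2nd, 4th, ...) in
#' their original relative order. Splitting the sequence into these two
#' blocks places every originally adjacent pair of items in different
#' blocks, separating it by about half the sequence length; this is the
#' fixed reordering used to construct the low-PMI scrambled condition.
#'
#' @param items A vector (any type); may be empty.
#' @return The reordered vector.
#' @examples
#' max_separation_order(c("and", "to", "the"))  # and the to
#' @export
max_separation_order <- function(items) {
  n <- length(items)
  if (n == 0) return(items)
  items[c(seq(1L, n, by = 2L), if (n >= 2) seq(2L, n, by = 2L))]
}

# 1-based output positions for the same reordering
max_separation_indices <- function(n) {
  if (n == 0) return(integer())
  c(seq(1L, n, by = 2L), if (n >= 2) seq(2L, n, by = 2L))
}

#' PMI-minimizing scramble of a labeled sentence
#'
#' Constructs the low-PMI condition: content words are reordered by
#' [max_separation_order()] so that each pair of content words that was
#' adjacent in the original string (no content word between them) is
#' separated as much as possible; the function words are reordered the same
#' way and the whole function-word block is embedded in the center of the
#' reordered content words, after the first `ceiling(c / 2)` of the `c`
#' content words. Sentence length is preserved.
#'
#' @param tokens Character vector of tokens.
#' @param word_class Character vector, `"content"` or `"function"` per
#'   token. Alternatively supply `function_words`, a closed-class lexicon
#'   used to label the tokens (case-insensitive match).
#' @param function_words Optional character vector of function words.
#' @return A `scramble_record` with `condition_label = "ScrLowPMI"`.
#' @examples
#' min_pmi_scramble(
#'   c("Larger","firms","and","international","companies","tended",
#'     "to","offer","the","biggest","pay","rises"),
#'   function_words = c("and", "to", "the"))
#' @export
min_pmi_scramble <- function(tokens, word_class = NULL, function_words = NULL) {
  tokens <- check_tokens(tokens)
  n <- length(tokens)
  if (is.null(word_class)) {
    if (is.null(function_words))
      stop("supply word_class or function_words", call. = FALSE)
    word_class <- ifelse(tolower(tokens) %in% tolower(function_words),
                         "function", "content")
  }
  if (length(word_class) != n || !all(word_class %in% c("content", "function")))
    stop("word_class must label every token content or function", call. = FALSE)

  cont <- which(word_class == "content")
  func <- which(word_class == "function")
  cont_ord <- cont[max_separation_indices(length(cont))]
  func_ord <- func[max_separation_indices(length(func))]
  cc <- length(cont)
  head_n <- ceiling(cc / 2)
  perm <- c(cont_ord[seq_len(head_n)], func_ord,
            if (cc > head_n) cont_ord[(head_n + 1L):cc])
  rec <- new_scramble_record(tokens, perm, requested_swaps = NA_integer_,
                             condition_label = "ScrLowPMI")
  rec$word_class <- word_class
  rec
}

#' Separation of originally adjacent content words
#'
#' Mean absolute position difference, in the scrambled string, between
#' content-word pairs that were adjacent in the original string (i.e. had
#' no content word between them). Used to verify the low-PMI construction;
#' for the worked 12-word example the distances alternate 8 and 7
#' (mean 7.5).
#'
#' @param record A `scramble_record` carrying `word_class` (as produced by
#'   [min_pmi_scramble()]), or supply `word_class` explicitly.
#' @param word_class Optional content/function labels of the original tokens.
#' @return Numeric: mean separation (NA if fewer than 2 content words).
#' @export
adjacent_content_separation <- function(record, word_class = NULL) {
  stopifnot(inherits(record, "scramble_record"))
  word_class <- word_class %||% record$word_class
  if (is.null(word_class)) stop("word_class labels required", call. = FALSE)
  cont <- which(word_class == "content")
  if (length(cont) < 2) return(NA_real_)
  pos_out <- match(seq_along(record$original_tokens), record$permutation)
  mean(abs(diff(pos_out[cont])))
}

#' Characterize the conditions of a stimulus set
#'
#' Per-condition mean and SD, across items, of the two automatable
#' word-order degradation metrics: words moved ([words_moved()]) and
#' inversion distance ([inversion_distance()] on the stored index
#' permutation). Word-list rows are not permutations of their intact row
#' and are exempt (reported as `NA`).
#'
#' @param stimuli A [make_stimulus_set()] data.frame (or one read by
#'   [read_stimuli()]): columns `item_id`, `condition`, `tokens`
#'   (space-separated), `permutation` (comma-separated 1-based indices).
#' @return data.frame with one row per condition: `condition`, `n_items`,
#'   `mean_words_moved`, `sd_words_moved`, `mean_inversion_distance`,
#'   `sd_inversion_distance`.
#' @export
characterize_conditions <- function(stimuli) {
  stimuli <- as.data.frame(stimuli)
  need <- c("item_id", "condition", "tokens", "permutation")
  if (!all(need %in% names(stimuli)))
    stop("stimuli must have columns ", paste(need, collapse = ", "), call. = FALSE)
  ints <- stimuli[stimuli$condition == "Int", ]
  int_tokens <- stats::setNames(ints$tokens, ints$item_id)

  conds <- unique(stimuli$condition)
  rows <- lapply(conds, function(cond) {
    sub <- stimuli[stimuli$condition == cond, ]
    if (cond == "WordList") {
      return(data.frame(condition = cond, n_items = nrow(sub),
                        mean_words_moved = NA_real_, sd_words_moved = NA_real_,
                        mean_inversion_distance = NA_real_,
                        sd_inversion_distance = NA_real_))
    }
    wm <- id <- numeric(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      it <- as.character(sub$item_id[i])
      if (!it %in% names(int_tokens))
        stop("missing Int row for item ", it, call. = FALSE)
      orig <- strsplit(int_tokens[[it]], " ", fixed = TRUE)[[1]]
      scr <- strsplit(sub$tokens[i], " ", fixed = TRUE)[[1]]
      perm <- as.integer(strsplit(sub$permutation[i], ",", fixed = TRUE)[[1]])
      if (length(perm) != length(orig) || !setequal(perm, seq_along(orig)) ||
          !identical(orig[perm], scr))
        stop("item ", it, " (", cond, "): row is not a valid permutation of its Int row",
             call. = FALSE)
      wm[i] <- words_moved(orig, scr)
      id[i] <- inversion_distance(seq_along(orig), perm)
    }
    data.frame(condition = cond, n_items = nrow(sub),
               mean_words_moved = mean(wm),
               sd_words_moved = stats::sd(wm),
               mean_inversion_distance = mean(id),
               sd_inversion_distance = stats::sd(id))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
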