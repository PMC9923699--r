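#' Skip-gram co-occurrence count tables
#'
#' A `count_table` stores unigram counts and ordered word-pair counts
#' extracted with a sliding window, together with the Laplace pseudo-count
#' used for probability estimation. Pairs are ordered (the first word
#' precedes the second) and annotated with their positional gap, so a
#' four-word window yields bigrams (gap 1) plus 1- and 2-skip-grams
#' (gaps 2 and 3).
#'
#' @param corpus A list of character vectors, one tokenized sentence each.
#' @param window Sliding window width in words; pairs are extracted for all
#'   gaps `1 .. window - 1`. Default 4.
#' @param alpha Laplace smoothing pseudo-count added to every cell of the
#'   smoothed support. Default 0.1.
#' @param lowercase Fold tokens to lower case at ingestion? Default `TRUE`;
#'   co-occurrence estimation is case-free even when stimuli are displayed
#'   in capitals.
#' @param vocab_size Optional override for the smoothed vocabulary size `V`;
#'   defaults to the number of distinct tokens observed. Must be at least
#'   the observed number of distinct tokens.
#'
#' @return An object of class `count_table`: a list with elements
#'   `unigrams` (named integer vector), `pairs` (data.frame with columns
#'   `w1`, `w2`, `gap`, `count`), `total_tokens`, `total_pairs`,
#'   `gap_totals`, `vocab_size`, `alpha`, `window`, `lowercase`.
#'
#' @details Sentences shorter than two tokens contribute only unigrams. No
#'   padding is used and no pairs cross sentence boundaries: stimuli are
#'   isolated strings.
#'
#' @examples
#' tab <- count_corpus(list(c("a", "b", "c", "d")), window = 4)
#' tab$total_pairs  # 3 + 2 + 1 = 6
#' unigram_prob(tab, "a")
#' @export
count_corpus <- function(corpus, window = 4, alpha = 0.1, lowercase = TRUE,
                         vocab_size = NULL) {
  if (!is.list(corpus) || length(corpus) == 0)
    stop("corpus must be a non-empty list of token vectors", call. = FALSE)
  if (window < 2) stop("window must be >= 2", call. = FALSE)
  corpus <- lapply(corpus, function(s) {
    s <- check_tokens(s)
    if (lowercase) tolower(s) else s
  })
  tokens <- unlist(corpus, use.names = FALSE)
  if (length(tokens) == 0) stop("corpus contains no tokens", call. = FALSE)

  uni <- table(tokens)
  unigrams <- as.integer(uni)
  names(unigrams) <- names(uni)

  # sentence-id bookkeeping so no pair crosses a boundary
  lens <- lengths(corpus)
  sent <- rep.int(seq_along(corpus), lens)
  w1 <- w2 <- gp <- vector("list", window - 1L)
  for (g in seq_len(window - 1L)) {
    n <- length(tokens)
    if (n > g) {
      i <- seq_len(n - g)
      ok <- sent[i] == sent[i + g]
      w1[[g]] <- tokens[i][ok]
      w2[[g]] <- tokens[i + g][ok]
      gp[[g]] <- rep.int(g, sum(ok))
    }
  }
  w1 <- unlist(w1, use.names = FALSE)
  w2 <- unlist(w2, use.names = FALSE)
  gp <- unlist(gp, use.names = FALSE)

  if (length(w1)) {
    key <- gap_key(w1, w2, gp)
    ptab <- table(key)
    parts <- strsplit(names(ptab), KEY_SEP, fixed = TRUE)
    pairs <- data.frame(
      w1 = vapply(parts, `[`, "", 1L),
      w2 = vapply(parts, `[`, "", 2L),
      gap = as.integer(vapply(parts, `[`, "", 3L)),
      count = as.integer(ptab),
      stringsAsFactors = FALSE
    )
    pairs <- pairs[order(pairs$gap, pairs$w1, pairs$w2), , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(w1 = character(), w2 = character(),
                        gap = integer(), count = integer(),
                        stringsAsFactors = FALSE)
  }

  new_count_table(unigrams, pairs, alpha = alpha, window = window,
                  lowercase = lowercase, vocab_size = vocab_size)
}

#' Build a count table from explicit counts
#'
#' Constructs a `count_table` directly from unigram and pair counts,
#' bypassing corpus extraction — useful for worked examples and for tables
#' derived from external n-gram resources.
#'
#' @param unigrams Named integer vector of word counts.
#' @param pairs data.frame with columns `w1`, `w2`, `gap`, `count`; may be
#'   omitted for a unigram-only table.
#' @inheritParams count_corpus
#' @return A `count_table`.
#' @examples
#' tab <- count_table(c(a = 3, b = 1),
#'                    data.frame(w1 = "a", w2 = "b", gap = 1, count = 2))
#' pmi(tab, "a", "b")
#' @export
count_table <- function(unigrams, pairs = NULL, alpha = 0.1, window = 4,
                        lowercase = TRUE, vocab_size = NULL) {
  if (is.null(pairs))
    pairs <- data.frame(w1 = character(), w2 = character(),
                        gap = integer(), count = integer(),
                        stringsAsFactors = FALSE)
  new_count_table(unigrams, pairs, alpha = alpha, window = window,
                  lowercase = lowercase, vocab_size = vocab_size)
}

# Assemble a count_table from its parts, computing totals and lookup caches.
new_count_table <- function(unigrams, pairs, alpha = 0.1, window = 4,
                            lowercase = TRUE, vocab_size = NULL) {
  stopifnot(is.numeric(unigrams), !is.null(names(unigrams)))
  if (any(unigrams < 0) || any(pairs$count < 0))
    stop("counts must be nonnegative", call. = FALSE)
  V <- vocab_size %||% length(unigrams)
  if (V < length(unigrams))
    stop("vocab_size must be at least the number of distinct words", call. = FALSE)
  pooled <- tapply(pairs$count, pair_key(pairs$w1, pairs$w2), sum)
  gap_totals <- tapply(pairs$count, pairs$gap, sum)
  obj <- list(
    unigrams = unigrams,
    pairs = pairs,
    pooled = if (length(pooled)) c(pooled) else numeric(),
    bygap = stats::setNames(as.numeric(pairs$count),
                            gap_key(pairs$w1, pairs$w2, pairs$gap)),
    total_tokens = sum(unigrams),
    total_pairs = sum(pairs$count),
    gap_totals = if (length(gap_totals)) c(gap_totals) else numeric(),
    vocab_size = as.integer(V),
    alpha = alpha,
    window = as.integer(window),
    lowercase = isTRUE(lowercase)
  )
  class(obj) <- "count_table"
  obj
}

#' @export
print.count_table <- function(x, ...) {
  cat("Skip-gram count table\n")
  cat("  tokens:", x$total_tokens, " distinct:", length(x$unigrams),
      " V:", x$vocab_size, "\n")
  cat("  pairs:", x$total_pairs, " (window", x$window, ", gaps",
      paste(sort(unique(x$pairs$gap)), collapse = ","), ")\n")
  cat("  alpha:", x$alpha, " lowercase:", x$lowercase, "\n")
  invisible(x)
}

#' Smoothed unigram probability
#'
#' Returns `(count(w) + alpha) / (total_tokens + alpha * V)`. Words never
#' seen in the corpus use count 0, so every word has positive probability
#' whenever `alpha > 0`.
#'
#' @param table A [count_corpus()] table.
#' @param w Character vector of words (vectorized).
#' @return Numeric vector of probabilities in (0, 1].
#' @export
unigram_prob <- function(table, w) {
  stopifnot(inherits(table, "count_table"))
  if (table$total_tokens == 0) stop("empty count table", call. = FALSE)
  if (table$lowercase) w <- tolower(w)
  cnt <- table$unigrams[w]
  cnt[is.na(cnt)] <- 0
  unname((cnt + table$alpha) / (table$total_tokens + table$alpha * table$vocab_size))
}

#' Smoothed ordered-pair probability
#'
#' Joint probability of the ordered pair (`wi` before `wj`). With
#' `pooled_gaps = TRUE` (the default) counts are pooled over all gaps and the
#' smoothed support is the V^2 ordered pairs:
#' `(sum_gap count(wi, wj, gap) + alpha) / (total_pairs + alpha * V^2)`.
#' With `pooled_gaps = FALSE` a `gap` must be given and that gap's total is
#' used in the denominator.
#'
#' @inheritParams unigram_prob
#' @param wi,wj Character vectors (vectorized, recycled to common length).
#' @param pooled_gaps Pool counts across gaps? Default `TRUE`.
#' @param gap Positional gap when `pooled_gaps = FALSE`.
#' @return Numeric vector of probabilities.
#' @export
pair_prob <- function(table, wi, wj, pooled_gaps = TRUE, gap = NULL) {
  stopifnot(inherits(table, "count_table"))
  if (table$total_pairs == 0) stop("count table has no pairs", call. = FALSE)
  if (table$lowercase) { wi <- tolower(wi); wj <- tolower(wj) }
  V2 <- as.numeric(table$vocab_size)^2
  if (pooled_gaps) {
    cnt <- table$pooled[pair_key(wi, wj)]
    cnt[is.na(cnt)] <- 0
    denom <- table$total_pairs + table$alpha * V2
  } else {
    if (is.null(gap)) stop("gap must be supplied when pooled_gaps = FALSE", call. = FALSE)
    cnt <- table$bygap[gap_key(wi, wj, gap)]
    cnt[is.na(cnt)] <- 0
    tot <- table$gap_totals[as.character(gap)]
    if (is.na(tot)) tot <- 0
    if (tot == 0) stop("no pairs observed at gap ", gap, call. = FALSE)
    denom <- tot + table$alpha * V2
  }
  unname((cnt + table$alpha) / denom)
}

#' Read and write count tables as TSV
#'
#' A count table is serialized as a directory holding three UTF-8 TSV files
#' with header lines: `unigrams.tsv` (`word<TAB>count`), `pairs.tsv`
#' (`w1<TAB>w2<TAB>gap<TAB>count`) and `meta.tsv` (`key<TAB>value`, carrying
#' `alpha`, `vocab_size`, `window` and `lowercase`). Integer counts
#' round-trip exactly.
#'
#' @param table A `count_table`.
#' @param dir Directory to write to / read from (created if missing).
#' @return `write_counts` returns `dir` invisibly; `read_counts` returns a
#'   `count_table`.
#' @export
write_counts <- function(table, dir) {
  stopifnot(inherits(table, "count_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  uni <- data.frame(word = names(table$unigrams),
                    count = as.integer(table$unigrams),
                    stringsAsFactors = FALSE)
  utils::write.table(uni, file.path(dir, "unigrams.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(table$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  meta <- data.frame(
    key = c("alpha", "vocab_size", "window", "lowercase"),
    value = c(format(table$alpha, digits = 17), table$vocab_size,
              table$window, as.integer(table$lowercase)),
    stringsAsFactors = FALSE
  )
  utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}

#' @rdname write_counts
#' @export
read_counts <- function(dir) {
  read_tsv_strict <- function(path, cols) {
    if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
    df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                            stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                            colClasses = "character")
    if (!identical(names(df), cols))
      stop(path, ": expected header ", paste(cols, collapse = "\t"), call. = FALSE)
    df
  }
  uni <- read_tsv_strict(file.path(dir, "unigrams.tsv"), c("word", "count"))
  prs <- read_tsv_strict(file.path(dir, "pairs.tsv"), c("w1", "w2", "gap", "count"))
  meta <- read_tsv_strict(file.path(dir, "meta.tsv"), c("key", "value"))
  mv <- stats::setNames(meta$value, meta$key)
  unigrams <- stats::setNames(as.integer(uni$count), uni$word)
  pairs <- data.frame(w1 = prs$w1, w2 = prs$w2,
                      gap = as.integer(prs$gap), count = as.integer(prs$count),
                      stringsAsFactors = FALSE)
  new_count_table(unigrams, pairs,
                  alpha = as.numeric(mv[["alpha"]]),
                  window = as.integer(mv[["window"]]),
                  lowercase = as.integer(mv[["lowercase"]]) == 1L,
                  vocab_size = as.integer(mv[["vocab_size"]]))
}
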