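#' Pointwise mutual information of a word pair
#'
#' PMI(wi, wj) = log P(wi, wj) / (P(wi) P(wj)), in natural log units (nats),
#' with all probabilities Laplace-smoothed by the table's `alpha`. Positive
#' values indicate that the pair co-occurs more often than its word
#' frequencies predict; with `alpha > 0` the value is finite for any pair,
#' seen or unseen.
#'
#' @param table A [count_corpus()] table.
#' @param wi,wj Character vectors (vectorized).
#' @param pooled_gaps,gap Passed to [pair_prob()].
#' @return PMI values in nats.
#' @export
pmi <- function(table, wi, wj, pooled_gaps = TRUE, gap = NULL) {
  stopifnot(inherits(table, "count_table"))
  if (table$alpha <= 0) {
    # log of zero possible; keep failure explicit rather than returning -Inf
    pj <- pair_prob(table, wi, wj, pooled_gaps = pooled_gaps, gap = gap)
    p1 <- unigram_prob(table, wi)
    p2 <- unigram_prob(table, wj)
    if (any(pj == 0) || any(p1 == 0) || any(p2 == 0))
      stop("zero probability with alpha = 0; PMI undefined", call. = FALSE)
    return(log(pj / (p1 * p2)))
  }
  log(pair_prob(table, wi, wj, pooled_gaps = pooled_gaps, gap = gap) /
        (unigram_prob(table, wi) * unigram_prob(table, wj)))
}

#' Mean positive PMI profile of a token string
#'
#' Extracts every ordered word pair within a sliding window (exactly as
#' [count_corpus()] does: all pairs at gaps `1 .. window - 1`), computes the
#' PMI of each pair under `table`, and averages the positive values. This is
#' the statistic used to characterize the local combinability of a stimulus
#' string: scrambling by a few local swaps leaves it near the intact value,
#' while separating previously adjacent content words collapses it.
#'
#' Every window occurrence counts: repeated pair types are averaged over
#' pair tokens, not deduplicated. A string with no positive-PMI pair has
#' `mean_positive_pmi = 0` by convention.
#'
#' @inheritParams pmi
#' @param tokens Character vector of tokens.
#' @param window Sliding window width (default 4).
#' @param string_id Optional identifier stored in the profile.
#' @return An object of class `pmi_profile`: list with `string_id`,
#'   `pair_pmis` (data.frame `w1`, `w2`, `gap`, `pmi`), `mean_positive_pmi`,
#'   `n_positive_pairs`, `n_pairs`.
#' @export
string_profile <- function(table, tokens, window = 4, string_id = NA_character_) {
  stopifnot(inherits(table, "count_table"))
  tokens <- check_tokens(tokens)
  if (table$lowercase) tokens <- tolower(tokens)
  n <- length(tokens)
  w1 <- w2 <- gp <- list()
  if (n >= 2) {
    for (g in seq_len(min(window - 1L, n - 1L))) {
      i <- seq_len(n - g)
      w1[[g]] <- tokens[i]; w2[[g]] <- tokens[i + g]; gp[[g]] <- rep.int(g, n - g)
    }
  }
  w1 <- unlist(w1); w2 <- unlist(w2); gp <- unlist(gp)
  if (length(w1)) {
    vals <- pmi(table, w1, w2)
    pair_pmis <- data.frame(w1 = w1, w2 = w2, gap = gp, pmi = vals,
                            stringsAsFactors = FALSE)
  } else {
    vals <- numeric()
    pair_pmis <- data.frame(w1 = character(), w2 = character(),
                            gap = integer(), pmi = numeric(),
                            stringsAsFactors = FALSE)
  }
  pos <- vals[vals > 0]
  out <- list(
    string_id = string_id,
    pair_pmis = pair_pmis,
    mean_positive_pmi = if (length(pos)) mean(pos) else 0,
    n_positive_pairs = length(pos),
    n_pairs = length(vals)
  )
  class(out) <- "pmi_profile"
  out
}

#' @export
print.pmi_profile <- function(x, ...) {
  cat("PMI profile", if (!is.na(x$string_id)) paste0("[", x$string_id, "]"), "\n")
  cat("  pairs:", x$n_pairs, " positive:", x$n_positive_pairs,
      " mean positive PMI:", format(x$mean_positive_pmi, digits = 4), "nats\n")
  invisible(x)
}

#' Mean PMI as a function of interword distance
#'
#' For each gap `1 .. max_gap`, averages the gap-specific PMI over every
#' ordered pair token occurring at that gap in `corpus`. In natural text and
#' in the synthetic template language, PMI falls off with distance; in an
#' i.i.d. corpus all gap means are near zero.
#'
#' @inheritParams pmi
#' @param corpus List of token vectors.
#' @param max_gap Largest gap to report; gaps longer than every sentence are
#'   omitted from the output.
#' @return data.frame with columns `gap`, `mean_pmi`, `n_pairs`.
#' @export
pmi_by_distance <- function(table, corpus, max_gap) {
  stopifnot(inherits(table, "count_table"), max_gap >= 1)
  corpus <- lapply(corpus, function(s) {
    s <- check_tokens(s)
    if (table$lowercase) tolower(s) else s
  })
  out <- data.frame(gap = integer(), mean_pmi = numeric(), n_pairs = integer())
  for (g in seq_len(max_gap)) {
    w1 <- lapply(corpus, function(s) if (length(s) > g) s[seq_len(length(s) - g)] else character())
    w2 <- lapply(corpus, function(s) if (length(s) > g) s[-seq_len(g)] else character())
    w1 <- unlist(w1); w2 <- unlist(w2)
    if (!length(w1)) next
    if (!as.character(g) %in% names(table$gap_totals)) {
      warning("count table has no pairs at gap ", g, "; gap omitted", call. = FALSE)
      next
    }
    vals <- pmi(table, w1, w2, pooled_gaps = FALSE, gap = g)
    out <- rbind(out, data.frame(gap = g, mean_pmi = mean(vals), n_pairs = length(vals)))
  }
  out
}
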