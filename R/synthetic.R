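#' A toy template language with phrase-local dependencies
#'
#' Defines a fixed 12-word sentence template with interleaved content
#' (open-class) and function (closed-class) slots,
#' `F C C C C F C C F C C F`, the structure the stimuli of word-order
#' experiments emulate. The eight content slots form four disjoint
#' collocation pairs of adjacent content words (slots 2+3, 4+5, 7+8 and
#' 10+11); each pair draws a latent compatibility class and samples its two
#' members (without replacement) from that class's portion of the content
#' lexicon, creating excess co-occurrence — hence positive PMI — exactly
#' between nearby content words, the dependency structure that local swaps
#' preserve and that the maximal-separation scramble destroys. Function
#' slots sample independently from a closed-class lexicon. Content and
#' function slots are spread so that slot-position statistics stay close to
#' independence: positive PMI in the generated corpus is lexical, not an
#' artifact of the template layout.
#'
#' @param n_classes Number of latent compatibility classes (default 12).
#' @param words_per_class Content words per class (default 3, giving a
#'   36-word content lexicon).
#' @param n_function_words Size of the closed-class lexicon (default 8).
#' @param noise_rate Probability that a content slot ignores its pair's
#'   class and samples from the whole content lexicon (default 0.1).
#'   `noise_rate = 1` destroys the class structure entirely, leaving an
#'   (almost) independence corpus.
#' @return An object of class `toy_grammar`.
#' @export
toy_grammar <- function(n_classes = 12, words_per_class = 3,
                        n_function_words = 8, noise_rate = 0.1) {
  stopifnot(n_classes >= 1, words_per_class >= 1, n_function_words >= 1,
            noise_rate >= 0, noise_rate <= 1)
  template <- data.frame(
    slot = 1:12,
    class = c("function", "content", "content", "content", "content",
              "function", "content", "content", "function", "content",
              "content", "function"),
    # collocation-pair id driving the compatibility class of each content slot
    phrase = c(NA, 1, 1, 2, 2, NA, 3, 3, NA, 4, 4, NA),
    stringsAsFactors = FALSE
  )
  vocab <- list(
    content = sprintf("c%02d", seq_len(n_classes * words_per_class)),
    "function" = sprintf("f%02d", seq_len(n_function_words))
  )
  class_of <- rep(seq_len(n_classes), each = words_per_class)
  g <- list(template = template, vocab = vocab, class_of = class_of,
            n_classes = n_classes, words_per_class = words_per_class,
            noise_rate = noise_rate)
  class(g) <- "toy_grammar"
  g
}

#' @export
print.toy_grammar <- function(x, ...) {
  cat("Toy template grammar: 12 slots (",
      sum(x$template$class == "content"), " content, ",
      sum(x$template$class == "function"), " function)\n", sep = "")
  cat("  template:",
      paste(ifelse(x$template$class == "content", "C", "F"), collapse = " "), "\n")
  cat("  content lexicon:", length(x$vocab$content), "words in",
      x$n_classes, "classes; function lexicon:",
      length(x$vocab[["function"]]), "words\n")
  cat("  noise rate:", x$noise_rate, "\n")
  invisible(x)
}

#' Sample a corpus from the toy grammar
#'
#' Each sentence instantiates the 12-slot template. Per sentence, each of
#' the four collocation pairs draws a latent class uniformly; its two
#' content slots sample distinct words from that class (or, with
#' probability `noise_rate` per slot, from the whole content lexicon);
#' function slots sample uniformly from the closed-class lexicon.
#' Deterministic given `seed`.
#'
#' @param grammar A [toy_grammar()].
#' @param n_sentences Number of sentences (>= 1).
#' @param seed Integer seed.
#' @param distinct Resample any sentence containing duplicate tokens?
#'   Default `FALSE`.
#' @return List of character vectors (one sentence each).
#' @export
sample_corpus <- function(grammar, n_sentences, seed, distinct = FALSE) {
  stopifnot(inherits(grammar, "toy_grammar"), n_sentences >= 1)
  with_seed(seed, {
    out <- sample_sentences_raw(grammar, n_sentences)
    if (distinct) {
      bad <- which(vapply(out, anyDuplicated, 0L) > 0L)
      guard <- 0L
      while (length(bad)) {
        out[bad] <- sample_sentences_raw(grammar, length(bad))
        bad <- bad[vapply(out[bad], anyDuplicated, 0L) > 0L]
        guard <- guard + 1L
        if (guard > 1000L) stop("could not sample distinct-token sentences", call. = FALSE)
      }
    }
    out
  })
}

# vectorized template instantiation; assumes RNG state is already set
sample_sentences_raw <- function(grammar, n) {
  tpl <- grammar$template
  n_phrases <- max(tpl$phrase, na.rm = TRUE)
  # class per collocation pair per sentence
  ph_class <- matrix(sample.int(grammar$n_classes, n * n_phrases, replace = TRUE),
                     nrow = n, ncol = n_phrases)
  cwords <- grammar$vocab$content
  fwords <- grammar$vocab[["function"]]
  wpc <- grammar$words_per_class
  mat <- matrix("", nrow = n, ncol = nrow(tpl))
  # within-pair slot index (1 = first member, 2 = second): second member
  # avoids repeating the first when both draw from the same class
  pair_member <- integer(nrow(tpl))
  for (ph in seq_len(n_phrases))
    pair_member[which(tpl$phrase %in% ph)] <- seq_len(sum(tpl$phrase %in% ph))
  for (s in seq_len(nrow(tpl))) {
    if (tpl$class[s] == "function") {
      mat[, s] <- fwords[sample.int(length(fwords), n, replace = TRUE)]
      next
    }
    cls <- ph_class[, tpl$phrase[s]]
    pick <- character(n)
    noisy <- stats::runif(n) < grammar$noise_rate
    # class draw: offset within the class block of the content lexicon
    off <- sample.int(wpc, n, replace = TRUE)
    if (pair_member[s] == 2L && wpc > 1L) {
      # shift away from the first member's choice to keep the pair distinct
      prev_slot <- which(tpl$phrase == tpl$phrase[s])[1]
      prev_off <- match(mat[, prev_slot], cwords) - (cls - 1L) * wpc
      clash <- !is.na(prev_off) & prev_off >= 1 & prev_off <= wpc & off == prev_off
      off[clash] <- (off[clash] %% wpc) + 1L
    }
    pick <- cwords[(cls - 1L) * wpc + off]
    if (any(noisy))
      pick[noisy] <- cwords[sample.int(length(cwords), sum(noisy), replace = TRUE)]
    mat[, s] <- pick
  }
  # collocation is an order-free association: each pair surfaces in either
  # member order with equal probability
  for (ph in seq_len(n_phrases)) {
    sl <- which(tpl$phrase %in% ph)
    if (length(sl) == 2L) {
      flip <- stats::runif(n) < 0.5
      tmp <- mat[flip, sl[1]]
      mat[flip, sl[1]] <- mat[flip, sl[2]]
      mat[flip, sl[2]] <- tmp
    }
  }
  lapply(seq_len(n), function(i) mat[i, ])
}

#' Generate a full stimulus set across conditions
#'
#' For each item: an intact sentence (`Int`); one local-swap scrambled
#' version per entry of `swap_levels` (`Scr1`, `Scr3`, ... via
#' [local_swap_scramble()] with the realized inversion distance enforced);
#' a PMI-minimizing scramble (`ScrLowPMI`, via [min_pmi_scramble()] using
#' the template's content/function labels); and a word list (`WordList`)
#' in which every token is replaced by a different random token of the
#' same category, preserving each position's word class.
#'
#' @param grammar A [toy_grammar()].
#' @param n_items Number of items (>= 1).
#' @param swap_levels Integer vector of swap counts (default `c(1, 3, 5, 7)`).
#' @param seed Integer seed; all per-item scrambling seeds derive from it.
#' @param distinct Sample intact sentences with all-distinct tokens?
#'   Default `TRUE` (adjacent slots always hold different categories, so
#'   this mainly rules out repeats across phrases).
#' @return A data.frame of class `stimulus_set` with columns `item_id`,
#'   `condition`, `tokens` (space-separated), `permutation` (comma-separated
#'   1-based indices into the item's intact string; identity for `Int` and
#'   `WordList`), `word_class` (space-separated per-position labels).
#' @export
make_stimulus_set <- function(grammar, n_items, swap_levels = c(1, 3, 5, 7),
                              seed = 1L, distinct = TRUE) {
  stopifnot(inherits(grammar, "toy_grammar"), n_items >= 1)
  wclass <- grammar$template$class
  out <- with_seed(seed, {
    sents <- sample_sentences_raw(grammar, n_items)
    if (distinct) {
      bad <- which(vapply(sents, anyDuplicated, 0L) > 0L)
      while (length(bad)) {
        sents[bad] <- sample_sentences_raw(grammar, length(bad))
        bad <- bad[vapply(sents[bad], anyDuplicated, 0L) > 0L]
      }
    }
    # independent scrambling seed per item x swap level
    swap_seeds <- matrix(sample.int(2147483646L, n_items * length(swap_levels)),
                         nrow = n_items)
    wcl_str <- paste(wclass, collapse = " ")
    rows <- vector("list", n_items)
    for (i in seq_len(n_items)) {
      toks <- sents[[i]]
      n <- length(toks)
      id <- sprintf("item%04d", i)
      row1 <- function(cond, tk, perm) {
        data.frame(item_id = id, condition = cond,
                   tokens = paste(tk, collapse = " "),
                   permutation = paste(perm, collapse = ","),
                   word_class = wcl_str, stringsAsFactors = FALSE)
      }
      recs <- list(row1("Int", toks, seq_len(n)))
      for (j in seq_along(swap_levels)) {
        k <- swap_levels[j]
        rec <- local_swap_scramble(toks, k, seed = swap_seeds[i, j])
        recs[[length(recs) + 1L]] <- row1(paste0("Scr", k), rec$tokens,
                                          rec$permutation)
      }
      low <- min_pmi_scramble(toks, word_class = wclass)
      recs[[length(recs) + 1L]] <- row1("ScrLowPMI", low$tokens, low$permutation)
      # class-matched word-for-word replacement (always a different word)
      wl <- character(n)
      for (s in seq_len(n)) {
        pool <- setdiff(grammar$vocab[[wclass[s]]], toks[s])
        wl[s] <- pool[sample.int(length(pool), 1L)]
      }
      recs[[length(recs) + 1L]] <- row1("WordList", wl, seq_len(n))
      rows[[i]] <- do.call(rbind, recs)
    }
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  class(out) <- c("stimulus_set", class(out))
  out
}

#' Simulation parameters for behavioral and neural responses
#'
#' Bundles the generating model of [simulate_responses()]: a mean per
#' condition plus crossed Gaussian participant and item (or ROI) intercepts
#' and a residual. Two presets reproduce the effect structure of the
#' source experiments: `neural_sim_params()` uses the Experiment 2
#' language-network percent-signal-change estimates (intact mean 0.90, low-PMI
#' scramble 0.35 below intact, word lists 0.46 below intact, local-swap
#' conditions within 0.10 of intact) over 6 regions of interest and 32
#' participants; `rating_sim_params()` uses the 7-point naturalness-rating
#' deltas (-2.04, -1.42, -0.56, -0.23 for each successive increase in
#' scrambling, intact mean 6.294 so the grand mean is 3.54).
#'
#' @param condition_means Named numeric vector, one mean per condition.
#' @param participant_sd,item_sd,residual_sd Standard deviations of the
#'   participant intercept, item/unit intercept, and residual.
#' @param n_participants,n_items Design size (items are "units": stimuli
#'   for behavioral simulations, ROIs for neural ones).
#' @param family `"gaussian"` for continuous responses or `"binomial"` for
#'   Bernoulli accuracy outcomes (means are then on the log-odds scale and
#'   responses are drawn through the inverse-logit link).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(condition_means, participant_sd = 0, item_sd = 0,
                       residual_sd = 0, n_participants = 16, n_items = 30,
                       family = c("gaussian", "binomial")) {
  stopifnot(is.numeric(condition_means), !is.null(names(condition_means)),
            participant_sd >= 0, item_sd >= 0, residual_sd >= 0,
            n_participants >= 1, n_items >= 1)
  family <- match.arg(family)
  p <- list(condition_means = condition_means, participant_sd = participant_sd,
            item_sd = item_sd, residual_sd = residual_sd,
            n_participants = as.integer(n_participants),
            n_items = as.integer(n_items), family = family)
  class(p) <- "sim_params"
  p
}

#' @rdname sim_params
#' @export
neural_sim_params <- function(n_participants = 32, n_items = 6,
                              participant_sd = 0.5, item_sd = 0.25,
                              residual_sd = 0.8) {
  sim_params(
    condition_means = c(Int = 0.90, Scr1 = 0.93, Scr3 = 0.80, Scr5 = 0.88,
                        ScrLowPMI = 0.55, WordList = 0.44),
    participant_sd = participant_sd, item_sd = item_sd,
    residual_sd = residual_sd,
    n_participants = n_participants, n_items = n_items, family = "gaussian")
}

#' @rdname sim_params
#' @export
rating_sim_params <- function(n_participants = 76, n_items = 30,
                              participant_sd = 0.5, item_sd = 0.3,
                              residual_sd = 1.0) {
  means <- c(Int = 6.294, Scr1 = 6.294 - 2.04, Scr3 = 6.294 - 2.04 - 1.42,
             Scr5 = 6.294 - 2.04 - 1.42 - 0.56,
             Scr7 = 6.294 - 2.04 - 1.42 - 0.56 - 0.23)
  sim_params(condition_means = means, participant_sd = participant_sd,
             item_sd = item_sd, residual_sd = residual_sd,
             n_participants = n_participants, n_items = n_items,
             family = "gaussian")
}

#' Simulate a response table
#'
#' Draws `value = condition mean + participant intercept + item intercept +
#' residual` for every participant x item x condition cell (Gaussian
#' family), or a Bernoulli outcome with success probability
#' `plogis(condition mean + intercepts)` (binomial family). Deterministic
#' given `seed`.
#'
#' @param conditions Character vector of condition labels to simulate, or a
#'   `stimulus_set` (its distinct conditions are used). Every condition
#'   must have a mean in `params`.
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return A long data.frame (`response_table`): columns `participant`,
#'   `unit`, `condition`, `value`.
#' @export
simulate_responses <- function(conditions, params, seed) {
  stopifnot(inherits(params, "sim_params"))
  if (inherits(conditions, "stimulus_set") || is.data.frame(conditions))
    conditions <- unique(conditions$condition)
  unknown <- setdiff(conditions, names(params$condition_means))
  if (length(unknown))
    stop("no condition mean for: ", paste(unknown, collapse = ", "), call. = FALSE)
  np <- params$n_participants; ni <- params$n_items
  grid <- expand.grid(
    participant = sprintf("p%03d", seq_len(np)),
    unit = sprintf("u%03d", seq_len(ni)),
    condition = conditions,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  with_seed(seed, {
    p_int <- stats::rnorm(np, 0, params$participant_sd)
    i_int <- stats::rnorm(ni, 0, params$item_sd)
    eta <- params$condition_means[grid$condition] +
      p_int[match(grid$participant, sprintf("p%03d", seq_len(np)))] +
      i_int[match(grid$unit, sprintf("u%03d", seq_len(ni)))]
    grid$value <- if (params$family == "binomial") {
      stats::rbinom(nrow(grid), 1L, stats::plogis(eta))
    } else {
      eta + stats::rnorm(nrow(grid), 0, params$residual_sd)
    }
  })
  rownames(grid) <- NULL
  grid
}
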