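#' Read tokenized sentences
#'
#' One sentence per line, space-separated tokens, UTF-8. Empty or
#' whitespace-only lines are rejected with their line number.
#'
#' @param path File path.
#' @param lowercase Fold tokens to lower case? Default `TRUE`.
#' @return List of character vectors.
#' @export
read_sentences <- function(path, lowercase = TRUE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sents <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), " +")[[1]]
    if (length(toks) == 0 || all(!nzchar(toks)))
      stop(path, ": line ", i, ": sentence with zero tokens", call. = FALSE)
    sents[[i]] <- if (lowercase) tolower(toks) else toks
  }
  sents
}

#' Write tokenized sentences
#' @param sentences List of character vectors.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_sentences <- function(sentences, path) {
  writeLines(vapply(sentences, paste, "", collapse = " "), path, useBytes = TRUE)
  invisible(path)
}

#' Read a function-word lexicon
#'
#' One word per line. Duplicates are removed with a warning; blank lines
#' are ignored.
#'
#' @inheritParams read_sentences
#' @return Character vector of words.
#' @export
read_lexicon <- function(path, lowercase = TRUE) {
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- trimws(words)
  words <- words[nzchar(words)]
  if (lowercase) words <- tolower(words)
  if (anyDuplicated(words)) {
    warning(path, ": duplicate lexicon entries removed: ",
            paste(unique(words[duplicated(words)]), collapse = ", "),
            call. = FALSE)
    words <- unique(words)
  }
  words
}

#' Read and write stimulus tables
#'
#' TSV with header `item_id<TAB>condition<TAB>tokens<TAB>permutation`
#' (optionally a fifth `word_class` column): tokens are space-separated,
#' permutations are comma-separated 1-based positions into the item's
#' intact string.
#'
#' @param stimuli A stimulus data.frame.
#' @param path File path.
#' @return `read_stimuli` returns a `stimulus_set` data.frame.
#' @export
write_stimuli <- function(stimuli, path) {
  utils::write.table(as.data.frame(stimuli), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_stimuli
#' @export
read_stimuli <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          colClasses = "character")
  need <- c("item_id", "condition", "tokens", "permutation")
  if (!all(need %in% names(df)))
    stop(path, ": expected columns ", paste(need, collapse = ", "), call. = FALSE)
  class(df) <- c("stimulus_set", class(df))
  df
}

#' Read and write response tables
#'
#' Long-format TSV with header
#' `participant<TAB>unit<TAB>condition<TAB>value`.
#'
#' @param responses A response data.frame.
#' @param path File path.
#' @return `read_responses` returns the data.frame; `value` is numeric.
#' @export
write_responses <- function(responses, path) {
  utils::write.table(responses, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("participant", "unit", "condition", "value")
  if (!all(need %in% names(df)))
    stop(path, ": expected columns ", paste(need, collapse = ", "), call. = FALSE)
  if (!is.numeric(df$value)) stop(path, ": value column must be numeric", call. = FALSE)
  df
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end demonstration pipeline. All
#' stochastic stages take their own seed so any stage can be reproduced in
#' isolation; 1-based token positions are used throughout the file formats.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_sentences Corpus size for count estimation.
#' @param n_items Number of stimulus items.
#' @param swap_levels Local-swap levels for the scrambled conditions.
#' @param window Sliding window width for pair extraction.
#' @param alpha Laplace pseudo-count.
#' @param pooled_gaps Pool pair counts across gaps for PMI?
#' @param lowercase Case-fold at ingestion?
#' @param n_boot Bootstrap resamples for effect estimation.
#' @param seeds Named list of per-stage integer seeds
#'   (`corpus`, `stimuli`, `responses`, `bootstrap`).
#' @param grammar A [toy_grammar()] (default grammar if omitted).
#' @param sim A [sim_params()] for the response stage (neural preset if
#'   omitted).
#' @param sentences_path Optional file of pre-tokenized sentences used as
#'   the counting corpus instead of sampling one.
#' @param stimuli_path Optional existing stimulus TSV used instead of
#'   generating a stimulus set.
#' @param counts_path Optional existing count-table directory used instead
#'   of counting the corpus.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            n_sentences = 2000,
                            n_items = 24,
                            swap_levels = c(1, 3, 5, 7),
                            window = 4,
                            alpha = 0.1,
                            pooled_gaps = TRUE,
                            lowercase = TRUE,
                            n_boot = 500,
                            seeds = list(corpus = 101L, stimuli = 202L,
                                         responses = 303L, bootstrap = 404L),
                            grammar = toy_grammar(),
                            sim = NULL,
                            sentences_path = NULL,
                            stimuli_path = NULL,
                            counts_path = NULL) {
  stopifnot(is.character(out_dir), length(out_dir) == 1)
  for (nm in c("corpus", "stimuli", "responses", "bootstrap"))
    if (is.null(seeds[[nm]])) stop("seeds$", nm, " is required", call. = FALSE)
  for (p in c(sentences_path, stimuli_path, counts_path))
    if (!is.null(p) && !file.exists(p))
      stop("configured path does not exist: ", p, call. = FALSE)
  cfg <- list(out_dir = out_dir, n_sentences = n_sentences, n_items = n_items,
              swap_levels = swap_levels, window = window, alpha = alpha,
              pooled_gaps = pooled_gaps, lowercase = lowercase,
              n_boot = n_boot, seeds = seeds, grammar = grammar,
              sim = sim %||% neural_sim_params(),
              sentences_path = sentences_path,
              stimuli_path = stimuli_path,
              counts_path = counts_path)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [pipeline_config()] (scalar
#' values plus a `seeds` mapping and optional `grammar` parameters
#' `n_classes`, `words_per_class`, `n_function_words`, `noise_rate`).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) stop(path, ": out_dir is required", call. = FALSE)
  gr <- do.call(toy_grammar, y$grammar %||% list())
  args <- y[setdiff(names(y), "grammar")]
  args$grammar <- gr
  if (!is.null(args$seeds)) args$seeds <- lapply(args$seeds, as.integer)
  if (!is.null(args$swap_levels)) args$swap_levels <- as.integer(args$swap_levels)
  do.call(pipeline_config, args)
}

#' Run the end-to-end demonstration pipeline
#'
#' Executes five stages in order, writing every intermediate as TSV under
#' `config$out_dir`:
#' 1. `corpus` — sample the synthetic corpus, build the skip-gram count
#'    table (`corpus.txt`, `counts/`);
#' 2. `stimuli` — generate the stimulus set across conditions
#'    (`stimuli.tsv`);
#' 3. `pmi` — PMI-profile every string (`profiles.tsv`);
#' 4. `characterize` — word-order degradation metrics per condition
#'    (`characterization.tsv`);
#' 5. `analyze` — simulate responses and estimate condition contrasts
#'    (`responses.tsv`, `estimates.tsv`).
#'
#' A provenance manifest (`manifest.tsv`: stage, file, rows, seed, package
#' version) is written last; rerunning with the same config reproduces
#' every output byte-for-byte (the manifest's timestamp column aside).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest data.frame.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list()
  note <- function(stage, file, rows, seed = NA_integer_) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = file, rows = rows, seed = seed,
      stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # 1. corpus + counts
  counts <- run_stage("corpus", {
    if (!is.null(config$counts_path)) {
      tab <- read_counts(config$counts_path)
      write_counts(tab, out("counts"))
      note("corpus", "counts/unigrams.tsv", length(tab$unigrams))
      tab
    } else {
      corpus <- if (!is.null(config$sentences_path)) {
        read_sentences(config$sentences_path, lowercase = config$lowercase)
      } else {
        sample_corpus(config$grammar, config$n_sentences,
                      seed = config$seeds$corpus)
      }
      write_sentences(corpus, out("corpus.txt"))
      note("corpus", "corpus.txt", length(corpus), config$seeds$corpus)
      tab <- count_corpus(corpus, window = config$window, alpha = config$alpha,
                          lowercase = config$lowercase)
      write_counts(tab, out("counts"))
      note("corpus", "counts/unigrams.tsv", length(tab$unigrams))
      tab
    }
  })

  # 2. stimuli
  stimuli <- run_stage("stimuli", {
    st <- if (!is.null(config$stimuli_path)) {
      read_stimuli(config$stimuli_path)
    } else {
      make_stimulus_set(config$grammar, config$n_items,
                        swap_levels = config$swap_levels,
                        seed = config$seeds$stimuli)
    }
    write_stimuli(st, out("stimuli.tsv"))
    note("stimuli", "stimuli.tsv", nrow(st), config$seeds$stimuli)
    st
  })

  # 3. PMI profiles
  run_stage("pmi", {
    profs <- lapply(seq_len(nrow(stimuli)), function(i) {
      toks <- strsplit(stimuli$tokens[i], " ", fixed = TRUE)[[1]]
      pr <- string_profile(counts, toks, window = config$window,
                           string_id = stimuli$item_id[i])
      data.frame(string_id = stimuli$item_id[i],
                 condition = stimuli$condition[i],
                 n_pairs = pr$n_pairs, n_positive = pr$n_positive_pairs,
                 mean_positive_pmi = pr$mean_positive_pmi,
                 stringsAsFactors = FALSE)
    })
    profs <- do.call(rbind, profs)
    utils::write.table(profs, out("profiles.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    note("pmi", "profiles.tsv", nrow(profs))
  })

  # 4. characterization
  run_stage("characterize", {
    ch <- characterize_conditions(stimuli)
    utils::write.table(ch, out("characterization.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    note("characterize", "characterization.tsv", nrow(ch))
  })

  # 5. responses + effect estimates
  run_stage("analyze", {
    conds <- intersect(names(config$sim$condition_means),
                       unique(stimuli$condition))
    resp <- simulate_responses(conds, config$sim, seed = config$seeds$responses)
    write_responses(resp, out("responses.tsv"))
    note("analyze", "responses.tsv", nrow(resp), config$seeds$responses)
    sch <- contrast_scheme("dummy", levels = conds, reference = "Int")
    fit <- estimate_effects(resp, sch, n_boot = config$n_boot,
                            seed = config$seeds$bootstrap)
    utils::write.table(fit$estimates, out("estimates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    note("analyze", "estimates.tsv", nrow(fit$estimates), config$seeds$bootstrap)
  })

  man <- do.call(rbind, manifest)
  man$package_version <- as.character(utils::packageVersion("scramblex"))
  man$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  utils::write.table(man, out("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(man)
}
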