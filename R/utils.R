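# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
# Same save/restore pattern as stats::simulate().
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  expr
}

# key separator for pair lookups; tokens may not contain tabs (enforced at
# ingestion) so "\t" is collision-free and matches the TSV formats.
KEY_SEP <- "\t"

pair_key <- function(w1, w2) paste(w1, w2, sep = KEY_SEP)
gap_key <- function(w1, w2, gap) paste(w1, w2, gap, sep = KEY_SEP)

check_tokens <- function(tokens, what = "tokens") {
  if (!is.character(tokens)) tokens <- as.character(tokens)
  if (any(!nzchar(tokens))) stop(what, " must be non-empty strings", call. = FALSE)
  if (any(grepl("[\t\n ]", tokens))) {
    stop(what, " must not contain whitespace", call. = FALSE)
  }
  tokens
}

`%||%` <- function(a, b) if (is.null(a)) b else a
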