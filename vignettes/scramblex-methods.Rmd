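---
title: "Scrambled-sentence stimuli and their information-theoretic profile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scrambled-sentence stimuli and their information-theoretic profile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scramblex)
```

## The problem this package addresses

Experiments on composition in the brain's language system manipulate *word
order* while controlling *local combinability*: sentences are degraded by
repeated local word swaps (leaving nearby words about as associated as in
natural text) or by a construction that separates previously adjacent
content words as far as possible within the string (collapsing local
mutual information to word-list levels). Interpreting such designs requires
a set of desk-side computations: extracting skip-gram co-occurrence
statistics, profiling each stimulus string by its mean positive pointwise
mutual information (PMI), quantifying how much word order was degraded, and
estimating condition effects from behavioral or region-of-interest (ROI)
neural responses. scramblex implements that full pipeline, together with a
synthetic language so that every computation can be exercised and tested
without a large corpus or scanner data.

## Stimulus constructions

**Local swaps.** `local_swap_scramble(tokens, k, seed)` repeatedly picks a
word position uniformly at random and switches the word with an immediate
neighbor (side chosen uniformly for interior words; endpoints use their
only neighbor). Because a swap can undo an earlier one, the whole draw is
rejected and resampled until the *realized* number of inversions — the
Kendall-tau distance between the intact and scrambled orders, computed on
token indices so duplicated surface forms are distinguished — equals `k`
exactly. Without this enforcement a nominal `Scr3` item could be one swap
away from intact, blurring the factor levels. The neighbor-side convention
at endpoints is a design choice (the construction is otherwise
underdetermined); it is documented and fixed.

**Low-PMI (maximal separation) scramble.** `min_pmi_scramble()` reorders
the content words by the canonical odd-then-even interleave
(`max_separation_order()`): items 1, 3, 5, ... in original relative order,
then items 2, 4, .... Consecutive items have opposite parity, so every pair
of content words that was adjacent in the original string (no content word
between them) lands in different halves of the output; the function words,
reordered the same way, are embedded as a block in the center (after the
first half of the content words), pushing the two content halves further
apart. For a 12-word sentence with 9 content words the originally adjacent
content pairs end up 7–8 positions apart (mean 7.5), far beyond the
four-word window that drives local PMI. The odd-then-even interleave is the
field's standard published construction and reproduces its worked examples
token for token; note that it does not globally maximize the sum of
pairwise separations over all `n!` orderings (block-crossing arrangements
that also shuffle within-half order can add a few more position-steps), but
every originally adjacent pair is guaranteed a separation of about half the
content length, which is what removes those pairs from the sliding window.

**Word lists.** The synthetic word-list condition replaces every token with
a different random token of the same word class (open or closed), keeping
the per-position class profile while destroying lexical association.

## Word-order degradation metrics

*Inversion distance* (`inversion_distance()`) is the minimum number of
adjacent transpositions between two orderings — the quantity the swap
sampler enforces. *Words moved* (`words_moved()`) formalizes the manual
"how many words moved" annotation as `n - LCS`: the words in a longest
common subsequence of the two strings can stay in place while every other
word moves, and moving fewer words is impossible. This reproduces the
published hand-annotated examples, including the two scramblings of
"the dog chased the cat" (2 and 1 moved words). `words_moved()` never
exceeds `inversion_distance()` (each moved word costs at least one swap);
both are exercised against brute-force oracles (breadth-first search over
adjacent swaps; longest increasing subsequence) in the test suite.

## PMI profiling

Probabilities are Laplace-smoothed relative frequencies: for unigrams
`(count + alpha) / (N + alpha * V)`, for ordered pairs
`(count + alpha) / (P + alpha * V^2)`, with `alpha = 0.1` by default. Pairs
are extracted with a sliding four-word window — bigrams plus 1- and
2-skip-grams — with no padding and no pairs across string boundaries, and
are ordered; pair counts are pooled across gaps 1–3 by default (the PMI
ratio has a single joint term), with per-gap joints available for
distance curves (`pmi_by_distance()`). PMI is reported in natural log
units; every in-scope comparison is base-invariant. The per-string
statistic (`string_profile()`) is the arithmetic mean of the *positive*
pair PMIs, 0 by convention when no pair is positive; repeated pair types
count once per window occurrence. Tokens are case-folded at ingestion by
default (stimuli are often displayed in capitals; co-occurrence statistics
are case-free).

## The synthetic language

`toy_grammar()` defines a fixed 12-slot template, `F C C C C F C C F C C F`
(8 content, 4 function slots), whose eight content slots form four disjoint
collocation pairs of adjacent content words (slots 2+3, 4+5, 7+8, 10+11).
Per sentence each pair draws one of 12 latent compatibility classes and
samples its two members, without replacement, from that class's three words
in a 36-word open-class lexicon; with probability `noise_rate = 0.1` a slot
ignores its class. Function slots draw independently from an 8-word
closed-class lexicon. Two deliberate choices keep the corpus statistics
honest:

- **Pooled lexicons, balanced layout.** With one open-class and one
  closed-class lexicon and the classes spread as above, the rate at which
  word classes co-occur inside the window stays within a few percent of
  what their slot frequencies predict, so pooled-gap PMI between
  *unassociated* words is within about ±0.05 nats of zero. Fine-grained
  per-slot vocabularies would instead make template position itself a PMI
  source (a single-slot category adjacent to another yields ~+0.5 nats for
  *any* word pair of those categories), contaminating the word-list and
  low-PMI conditions with positional artifacts.
- **Order-free association.** Each collocation pair surfaces in either
  member order with equal probability. Association in natural text is
  largely symmetric at the level PMI measures; with strictly ordered pairs
  a single swap that reverses a pair would erase its (ordered-count) PMI
  and the swap conditions would lose local PMI much faster than the
  intended pattern.

On the default grammar (a corpus of roughly 1e5 tokens, 150 items) the mean
positive PMI of the swap conditions stays within 15% of intact while the
low-PMI scramble and the word lists fall below 0.6 of intact — the
qualitative condition ordering the constructions are meant to produce.
What the toy language does *not* emulate: morphology, agreement, topical
dependence between different collocation pairs, frequency spectra
(Zipfian tails), or any syntax beyond the fixed template. Consequently its
swap conditions shed slightly more positive PMI than natural materials do
(associations here are strictly pairwise, so a separated pair is pure
loss), and passing tests say nothing about absolute PMI magnitudes in any
real corpus — those depend on the corpus behind the count table.

Response simulation (`simulate_responses()`) uses a crossed random-effects
structure: condition mean + Gaussian participant intercept + item (or ROI)
intercept + residual, or a Bernoulli draw through the inverse logit for
accuracy outcomes. The neural preset encodes the published Experiment-2
percent-signal-change structure (intact 0.90; low-PMI scramble 0.35 below
intact; word lists 0.46 below; swap conditions within 0.10 of intact) for
32 participants and 6 ROIs, with SDs (participant 0.5, ROI 0.25, residual
0.8) chosen so that contrast standard errors match the published ~0.08.
The rating preset encodes the naturalness deltas (−2.04, −1.42, −0.56,
−0.23 successive steps; grand mean 3.54, hence intact 6.294 on the 7-point
scale) with plausible rating-scale SDs (0.5 / 0.3 / 1.0).

## Effect estimation

The published analyses fit Bayesian mixed-effects models with maximal
random effects. scramblex deliberately substitutes a design-based
estimator targeting the same estimands (condition contrasts):
stage 1 collapses to per-participant condition means (or
continuity-corrected log-odds, `log((s + 0.5) / (f + 0.5))`, for 0/1
outcomes); stage 2 applies the contrast scheme to each participant's means
and reports the across-participant mean with a percentile bootstrap CI
resampling participants (5,000 resamples by default; percentile rather
than BCa for transparency and determinism under a seed). Dummy coding
(differences from a reference level) and backwards-difference coding
(differences between successive levels, the successive-differences coding
matrix) are provided; both reduce, for balanced noise-free data, to the
corresponding differences of level means, which the tests assert exactly.
No numeric agreement with the published posterior summaries is claimed —
the estimator always clusters on participant, whereas the published models
vary their random-effect structure — but at the study's sample sizes the
95% CIs cover the generating contrasts at 92–96% in simulation, and the
sign/significance pattern of the published tables is recovered.

## Numerical and interface conventions

- Natural log throughout; `alpha > 0` keeps every PMI finite, and
  `alpha = 0` with an unseen word is an explicit error.
- 1-based token positions in every file format; permutations are stored as
  comma-separated original indices in output order.
- Strict TSV with headers; UTF-8; integer counts round-trip exactly.
- Every stochastic entry point takes an explicit seed and restores the
  caller's RNG state; per-item scrambling seeds are drawn up front so
  results do not depend on evaluation order.
- Degenerate inputs: strings shorter than 2 tokens profile as 0 pairs;
  all-content or all-function sentences reduce to a single
  `max_separation_order()` call; `k = 0` swaps is the identity.

## Problem sizes used by the tests

The suite validates the permutation metrics exhaustively to `n = 5` (BFS
oracle, all orderings), by sampling at `n = 6`, and with 10,000 random
permutations for the metric inequality; the PMI condition-ordering
property runs on an ~1e5-token corpus with 150 items; estimator coverage
uses 200 simulated datasets at the study's scale (32 participants, 6 ROIs,
400 bootstrap resamples); sign/significance recovery uses 20 replicate
neural datasets and 100 null accuracy datasets. These sizes keep the whole
suite in the low minutes on one CPU while leaving the assertions
comfortably away from their sampling noise.

## Known limitations

- The count table abstracts over its source; nothing is claimed about any
  specific external n-gram resource, and absolute PMI levels are
  corpus-dependent.
- `words_moved` is the minimal-displacement reading of a manual
  annotation; annotators could in principle count non-minimal moves.
- The two-stage estimator ignores item-level clustering in its CIs (it
  averages over items within participant); with few items and large item
  effects its CIs can undercover.
- The odd-then-even separation order is the published construction, not a
  global optimum of the separation sum (see above).
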