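# Independent oracles used to validate the permutation metrics.

# Breadth-first search over adjacent transpositions: exact minimum number of
# swaps from `a` to `b`. Exponential state space; for n <= 6 only.
bfs_swap_distance <- function(a, b) {
  stopifnot(length(a) <= 7)
  key <- function(p) paste(p, collapse = ",")
  target <- key(b)
  frontier <- list(a)
  seen <- new.env(hash = TRUE)
  assign(key(a), TRUE, envir = seen)
  d <- 0L
  repeat {
    hits <- vapply(frontier, key, "") == target
    if (any(hits)) return(d)
    nxt <- list()
    for (p in frontier) {
      for (i in seq_len(length(p) - 1L)) {
        q <- p
        q[c(i, i + 1L)] <- q[c(i + 1L, i)]
        k <- key(q)
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- q
        }
      }
    }
    frontier <- nxt
    d <- d + 1L
    if (d > length(a)^2) stop("BFS failed to reach target")
  }
}

# Longest increasing subsequence length (O(n^2)); on an index permutation,
# n - LIS is the minimal number of displaced elements.
lis_length <- function(p) {
  n <- length(p)
  best <- integer(n)
  for (i in seq_len(n)) {
    best[i] <- 1L
    for (j in seq_len(i - 1L)) {
      if (p[j] < p[i] && best[j] + 1L > best[i]) best[i] <- best[j] + 1L
    }
  }
  max(best)
}

# Sum over originally adjacent pairs of |output position difference|, for an
# output ordering given as the items' original indices in output order.
separation_sum <- function(perm) {
  pos <- order(perm)
  sum(abs(diff(pos)))
}

# Exhaustive maximum of separation_sum over all permutations of 1..n.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 1L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[r, ] <- append(sub[i, ], n, after = pos - 1L)
      r <- r + 1L
    }
  }
  out
}

brute_max_separation <- function(n) {
  perms <- all_perms(n)
  max(apply(perms, 1, separation_sum))
}

# Worked example strings
dogcat <- c("the", "dog", "chased", "the", "cat")
int_example <- c("on", "their", "last", "day", "they", "were", "overwhelmed",
                 "by", "farewell", "messages", "and", "gifts")
scr7_example <- c("their", "last", "on", "they", "overwhelmed", "were", "day",
                  "farewell", "by", "messages", "and", "gifts")
lowpmi_input <- c("larger", "firms", "and", "international", "companies",
                  "tended", "to", "offer", "the", "biggest", "pay", "rises")
lowpmi_expected <- c("larger", "international", "tended", "biggest", "rises",
                     "and", "the", "to", "firms", "companies", "offer", "pay")
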