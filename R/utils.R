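# Internal numeric kernels shared by the reactivity and permutation code.
# These operate on plain integer/double vectors for speed; the tibble-facing
# wrappers live in reactivity.R and asrs.R.

# Nearest-rank order statistic: the k-th smallest value with k = ceiling(q * n),
# over non-missing entries. Bracket-style percentile, not interpolated.
nearest_rank <- function(x, q) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  k <- max(1L, min(n, as.integer(ceiling(q * n))))
  sort(x, partial = k)[k]
}

# RT-stop counts over a 1-based closed window. The stop base is the base
# immediately 5' of the alignment start in transcript orientation: start - 1
# on the plus strand, end + 1 on the minus strand. Stops falling outside the
# window are dropped.
count_stops <- function(starts, ends, wstart, wend, strand = "+") {
  n <- wend - wstart + 1L
  pos <- if (identical(strand, "-")) ends + 1L else starts - 1L
  idx <- pos - wstart + 1L
  idx <- idx[idx >= 1L & idx <= n]
  tabulate(idx, nbins = n)
}

# Per-base read coverage over a 1-based closed window (difference-array trick).
count_coverage <- function(starts, ends, wstart, wend) {
  n <- wend - wstart + 1L
  s <- pmax(starts, wstart) - wstart + 1L
  e <- pmin(ends, wend) - wstart + 1L
  keep <- s <= e
  if (!any(keep)) return(integer(n))
  d <- tabulate(s[keep], nbins = n) - tabulate(e[keep] + 1L, nbins = n + 1L)[seq_len(n)]
  cumsum(d)
}

# Deterministic per-unit child seed below 2^31, so individual transcripts or
# sites can be re-simulated in isolation.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 9973) %% 2147483629)
}
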