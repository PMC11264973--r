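# Independent straight-line oracles, deliberately written element-by-element
# with full sorts and explicit loops, sharing no code with the package
# internals they check.

# q-th nearest-rank order statistic of the non-missing values.
oracle_rank <- function(x, q) {
  x <- sort(x[!is.na(x)])
  x[max(1, min(length(x), ceiling(q * length(x))))]
}

# Full reactivity chain on raw counts: percentile normalisation of each
# vector, enrichment, unit-interval rescaling with clamping.
oracle_reactivity <- function(rt, rc, bc, s = 0.25, pseudo = 0.25,
                              q_hi = 0.95, q_lo = 0.05) {
  n <- length(rt)
  norm <- function(v) {
    f <- oracle_rank(v, q_hi)
    if (f == 0) v else v / f
  }
  rt_n <- norm(rt)
  rc_n <- norm(rc)
  bc_n <- norm(bc)
  es <- numeric(n)
  for (i in seq_len(n)) {
    if (bc[i] == 0) {
      es[i] <- NA_real_
    } else {
      es[i] <- (rt_n[i] - s * rc_n[i]) / max(bc_n[i], pseudo)
    }
  }
  if (sum(!is.na(es)) < 2) {
    es[!is.na(es)] <- 0
    return(es)
  }
  lo <- oracle_rank(es, q_lo)
  hi <- oracle_rank(es, q_hi)
  out <- es
  for (i in seq_len(n)) {
    if (is.na(es[i])) next
    out[i] <- if (hi == lo) 0 else max(0, min(1, (es[i] - lo) / (hi - lo)))
  }
  out
}

# Naive sliding-window mean absolute difference, divisor fixed at 5.
oracle_strucdiff <- function(es_ref, es_alt) {
  n <- length(es_ref)
  out <- rep(NA_real_, n)
  if (n < 5) return(out)
  for (i in 3:(n - 2)) {
    acc <- 0
    ok <- TRUE
    for (k in (i - 2):(i + 2)) {
      if (is.na(es_ref[k]) || is.na(es_alt[k])) {
        ok <- FALSE
        break
      }
      acc <- acc + abs(es_alt[k] - es_ref[k])
    }
    if (ok) out[i] <- acc / 5
  }
  out
}

# All-pairs (Mann-Whitney) AUC with half-credit for ties.
oracle_auc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Small hand-built reads tibble: `n_ref`/`n_alt` spanning reads and
# `n_non` non-spanning reads around a SNP, split across arms.
make_site_reads <- function(site, n_ref, n_alt, n_non = 0, rl = 30,
                            arm_split = 0.5, seed = 1) {
  set.seed(seed)
  n <- n_ref + n_alt + n_non
  start_span <- site$pos - sample.int(rl - 1, n_ref + n_alt, replace = TRUE) + 1L
  start_non <- site$pos + sample.int(rl, n_non, replace = TRUE)
  start <- c(start_span, start_non)
  base <- c(rep(site$ref, n_ref), rep(site$alt, n_alt), rep(NA_character_, n_non))
  tibble::tibble(
    chrom = site$chrom,
    start = as.integer(start),
    end = as.integer(start + rl - 1L),
    arm = ifelse(stats::runif(n) < arm_split, "treated", "control"),
    replicate = 1L,
    snp_base = base
  )
}

demo_site <- function() {
  tibble::tibble(chrom = "tx1", pos = 100L, id = "rs_demo",
                 ref = "A", alt = "G")
}
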