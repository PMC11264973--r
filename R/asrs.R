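# Allelic structure difference statistics.
#
# The window-level statistic is the experimental structural disruption
# coefficient
#     eSDC = (1 - pCC) * sqrt(N)
# where pCC is the Pearson correlation of the two allele profiles over their
# jointly scored bases and N the window length. Significance comes from a
# read-label permutation null: SNP-spanning reads are reassigned to
# pseudo-alleles at an expected 1:1 ratio (pseudo-ref count drawn
# Poisson(R_d/2), truncated to [1, R_d - 1] by redrawing), the whole
# reactivity chain is recomputed, and the one-sided tail probability of the
# observed eSDC is estimated with the add-one estimator. The composite score
#     AStruct = -log10(P) * eSDC * (1 - log10(R_d / R))
# additionally rewards windows where most reads actually span the SNP
# (non-spanning reads are shared between alleles and dilute the contrast).

#' Experimental structural disruption coefficient (eSDC)
#'
#' @param es_ref,es_alt Structure-score vectors of the two alleles over the
#'   same window (`NA` = unscored base).
#' @param n Window length N used in the `sqrt(N)` factor; defaults to
#'   `length(es_ref)`.
#' @return One-row tibble with `pcc`, `esdc` and `degenerate` (`TRUE` when
#'   either profile has zero variance over the shared bases, in which case
#'   `esdc` is 0).
#' @export
#' @examples
#' esdc(c(0, 0.5, 1, 0.2), c(0, 0.5, 1, 0.2))   # identical: eSDC = 0
esdc <- function(es_ref, es_alt, n = length(es_ref)) {
  if (length(es_ref) != length(es_alt)) {
    stop("allele profiles cover different windows", call. = FALSE)
  }
  ok <- !is.na(es_ref) & !is.na(es_alt)
  if (sum(ok) < 3L) {
    stop("fewer than 3 jointly scored bases; cannot correlate profiles",
         call. = FALSE)
  }
  x <- es_ref[ok]
  y <- es_alt[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble(pcc = NA_real_, esdc = 0, degenerate = TRUE))
  }
  pcc <- stats::cor(x, y)
  tibble(pcc = pcc, esdc = (1 - pcc) * sqrt(n), degenerate = FALSE)
}

#' One-sided permutation P value (add-one estimator)
#'
#' `P = (1 + #\{null >= observed\}) / (1 + n_perm)`; never exactly zero, so
#' `-log10(P)` stays finite.
#'
#' @param observed Observed eSDC.
#' @param null Numeric vector of permuted eSDC values.
#' @return P value in `(0, 1]`.
#' @export
perm_pvalue <- function(observed, null) {
  if (length(null) == 0L) stop("empty permutation null", call. = FALSE)
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' Composite allele-specific structure score
#'
#' `-log10(P) * eSDC * (1 - log10(R_d / R))`. Since `R_d <= R` the last
#' factor is at least 1; `P = 1` or `eSDC = 0` gives a score of 0.
#'
#' @param p Permutation P value(s) in (0, 1].
#' @param esdc eSDC value(s), >= 0.
#' @param r_d Number of SNP-spanning reads (> 0).
#' @param r_total Total reads overlapping the window (>= `r_d`).
#' @return Numeric score(s), >= 0.
#' @export
#' @examples
#' astruct_score(0.01, 2, 50, 50)    # 2 * 2 * 1 = 4
#' astruct_score(0.1, 3, 10, 100)    # 1 * 3 * 2 = 6
astruct_score <- function(p, esdc, r_d, r_total) {
  stopifnot(all(p > 0), all(p <= 1), all(r_d > 0), all(r_d <= r_total))
  (-log10(p)) * esdc * (1 - log10(r_d / r_total))
}

#' Group a composite score as Low / Medium / High
#'
#' Low: score 0; Medium: (0, 1]; High: above 1.
#'
#' @param score Numeric score(s), >= 0.
#' @return Factor with levels `Low`, `Medium`, `High`.
#' @export
classify_group <- function(score) {
  stopifnot(all(score >= 0, na.rm = TRUE))
  cut(score, breaks = c(-Inf, 0, 1, Inf), labels = c("Low", "Medium", "High"))
}

#' Per-base allelic structure difference (StrucDiff)
#'
#' `StrucDiff_i = sum_{k=i-2}^{i+2} |ES_{k,alt} - ES_{k,ref}| / 5`, reported
#' only at bases with a complete, fully scored +/-2 neighbourhood (the
#' divisor is fixed at 5; edges and bases near missing values are `NA`).
#'
#' @inheritParams esdc
#' @return Numeric vector of length N.
#' @export
strucdiff <- function(es_ref, es_alt) {
  if (length(es_ref) != length(es_alt)) {
    stop("allele profiles cover different windows", call. = FALSE)
  }
  n <- length(es_ref)
  if (n < 5L) return(rep(NA_real_, n))
  d <- abs(es_alt - es_ref)
  as.numeric(stats::filter(d, rep(1 / 5, 5), sides = 2))
}

# ---- permutation engine ----------------------------------------------------

# Precomputed per-site context: spanning-read stop indices and clipped
# coverage intervals, plus the shared non-spanning count vectors per arm,
# so each permutation only re-tabulates the spanning subsets.
site_context <- function(partition, window, config) {
  part <- as_tibble(partition)
  sp <- part[part$read_class %in% c("ref", "alt"), , drop = FALSE]
  ns <- part[part$read_class == "nonspanning", , drop = FALSE]
  n <- window$n
  stop_pos <- if (identical(config$library_strand, "-")) sp$end + 1L else sp$start - 1L
  stop_idx <- stop_pos - window$start + 1L
  stop_idx[stop_idx < 1L | stop_idx > n] <- 0L
  ns_t <- ns[ns$arm == "treated", , drop = FALSE]
  ns_c <- ns[ns$arm == "control", , drop = FALSE]
  list(
    n = n,
    cfg = config,
    treated = sp$arm == "treated",
    is_ref = sp$read_class == "ref",
    stop_idx = as.integer(stop_idx),
    cs = as.integer(pmax(sp$start, window$start) - window$start + 1L),
    ce = as.integer(pmin(sp$end, window$end) - window$start + 1L),
    ns_stops_t = count_stops(ns_t$start, ns_t$end, window$start, window$end,
                             strand = config$library_strand),
    ns_stops_c = count_stops(ns_c$start, ns_c$end, window$start, window$end,
                             strand = config$library_strand),
    ns_cov_c = count_coverage(ns_c$start, ns_c$end, window$start, window$end),
    r_d = attr(partition, "r_d"),
    r_total = attr(partition, "r_total")
  )
}

# Structure scores for one pseudo-allele: `sel` selects its spanning reads.
allele_es_from_context <- function(ctx, sel) {
  sel_t <- sel & ctx$treated
  sel_c <- sel & !ctx$treated
  rt <- ctx$ns_stops_t
  idx <- ctx$stop_idx[sel_t]
  idx <- idx[idx > 0L]
  if (length(idx)) rt <- rt + tabulate(idx, nbins = ctx$n)
  rc <- ctx$ns_stops_c
  idx <- ctx$stop_idx[sel_c]
  idx <- idx[idx > 0L]
  if (length(idx)) rc <- rc + tabulate(idx, nbins = ctx$n)
  bc <- ctx$ns_cov_c
  if (any(sel_c)) {
    d <- tabulate(ctx$cs[sel_c], nbins = ctx$n) -
      tabulate(ctx$ce[sel_c] + 1L, nbins = ctx$n + 1L)[seq_len(ctx$n)]
    bc <- bc + cumsum(d)
  }
  es_from_raw(rt, rc, bc, ctx$cfg)
}

observed_profiles <- function(ctx) {
  list(
    ref = allele_es_from_context(ctx, ctx$is_ref),
    alt = allele_es_from_context(ctx, !ctx$is_ref)
  )
}

# Draw a pseudo-ref read count: Poisson(R_d / 2), redrawn until both
# pseudo-alleles are non-empty (at most `max_tries`; NA = give up).
draw_split <- function(r_d, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    k <- stats::rpois(1L, r_d / 2)
    if (k >= 1L && k <= r_d - 1L) return(k)
  }
  NA_integer_
}

#' Permutation null distribution of the eSDC
#'
#' Re-labels the SNP-spanning reads into pseudo-ref/pseudo-alt groups at an
#' expected 1:1 ratio (Poisson-distributed pseudo-ref count, truncated so
#' neither group is empty), recomputes both allele profiles and the eSDC
#' from scratch for each permutation. Non-spanning reads stay shared.
#' Permutations with a degenerate (zero-variance) profile, or where no valid
#' split could be drawn, record an eSDC of 0.
#'
#' @param partition Output of [partition_reads()].
#' @param window One-row tibble from [define_window()].
#' @param config [astruct_config()].
#' @param n_perm Number of permutations (default `config$n_perm`).
#' @param seed Optional integer seed set before drawing.
#' @return Numeric vector of `n_perm` permuted eSDC values.
#' @export
permutation_null <- function(partition, window, config = astruct_config(),
                             n_perm = config$n_perm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- site_context(partition, window, config)
  vapply(seq_len(n_perm), function(i) perm_esdc(ctx), numeric(1))
}

perm_esdc <- function(ctx) {
  k <- draw_split(ctx$r_d)
  if (is.na(k)) return(0)
  sel <- logical(ctx$r_d)
  sel[sample.int(ctx$r_d, k)] <- TRUE
  es_r <- allele_es_from_context(ctx, sel)
  es_a <- allele_es_from_context(ctx, !sel)
  esdc_value(es_r, es_a, ctx$n)
}

# Scalar fast path of esdc() used inside the permutation loop.
esdc_value <- function(es_ref, es_alt, n) {
  ok <- !is.na(es_ref) & !is.na(es_alt)
  if (sum(ok) < 3L) return(0)
  x <- es_ref[ok]
  y <- es_alt[ok]
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (is.na(sx) || sx == 0 || is.na(sy) || sy == 0) return(0)
  (1 - stats::cor(x, y)) * sqrt(n)
}

# Full per-site test: observed profiles + permutation loop, optionally
# accumulating per-base StrucDiff exceedance counts from the same
# permutation replicates as the window-level test.
test_site <- function(partition, window, config, n_perm, per_base = FALSE) {
  ctx <- site_context(partition, window, config)
  prof <- observed_profiles(ctx)
  obs <- esdc_stats(prof$ref, prof$alt, ctx$n)
  sd_obs <- if (per_base) strucdiff(prof$ref, prof$alt) else NULL
  exceed <- if (per_base) integer(ctx$n) else NULL
  valid <- if (per_base) integer(ctx$n) else NULL
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    k <- draw_split(ctx$r_d)
    if (is.na(k)) {
      null[i] <- 0
      next
    }
    sel <- logical(ctx$r_d)
    sel[sample.int(ctx$r_d, k)] <- TRUE
    es_r <- allele_es_from_context(ctx, sel)
    es_a <- allele_es_from_context(ctx, !sel)
    null[i] <- esdc_value(es_r, es_a, ctx$n)
    if (per_base) {
      sd_i <- strucdiff(es_r, es_a)
      cmp <- !is.na(sd_i) & !is.na(sd_obs)
      valid <- valid + cmp
      exceed <- exceed + (cmp & sd_i >= sd_obs)
    }
  }
  p <- perm_pvalue(obs$esdc, null)
  list(
    es_ref = as.numeric(prof$ref),
    es_alt = as.numeric(prof$alt),
    pcc = obs$pcc,
    esdc = obs$esdc,
    degenerate = obs$degenerate,
    null = null,
    p_value = if (obs$degenerate) 1 else p,
    r_d = ctx$r_d,
    r_total = ctx$r_total,
    strucdiff = sd_obs,
    strucdiff_p = if (per_base) {
      ifelse(is.na(sd_obs), NA_real_, (1 + exceed) / (1 + valid))
    } else NULL
  )
}

# esdc() without tibble overhead, tolerating degenerate/insufficient data.
esdc_stats <- function(es_ref, es_alt, n) {
  ok <- !is.na(es_ref) & !is.na(es_alt)
  if (sum(ok) < 3L) return(list(pcc = NA_real_, esdc = 0, degenerate = TRUE))
  x <- es_ref[ok]
  y <- es_alt[ok]
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (is.na(sx) || sx == 0 || is.na(sy) || sy == 0) {
    return(list(pcc = NA_real_, esdc = 0, degenerate = TRUE))
  }
  pcc <- stats::cor(x, y)
  list(pcc = pcc, esdc = (1 - pcc) * sqrt(n), degenerate = FALSE)
}
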