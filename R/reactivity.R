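# Per-allele reactivity scoring.
#
# For one allele in one sample arm, every read contributes (i) one RT-stop
# event at the base immediately 5' of its alignment start and (ii) background
# at every base it covers. Raw stop and background vectors are normalised by
# their within-window 95th-percentile value (nearest-rank), combined into an
# enrichment score
#     ES_i = (R_i^T - s * R_i^C) / B_i^C
# (treated stops minus a fraction s of control stops, over control
# background), and rescaled to [0, 1] between the window's 5th and 95th
# enrichment percentiles, clamping outside values. High scores mark
# flexible/unpaired bases.

#' Count RT-stop events and background coverage in a SNP window
#'
#' @param reads Reads tibble for one allele in one arm: that allele's
#'   spanning reads plus the shared non-spanning window reads.
#' @param window One-row tibble from [define_window()].
#' @param strand `"+"` (stop base = alignment start - 1, default) or `"-"`
#'   (stop base = alignment end + 1). Stops falling outside the window are
#'   not counted.
#' @return Tibble with `window_pos` (1..N), `stops` and `background` counts.
#' @export
count_stop_profile <- function(reads, window, strand = "+") {
  tibble(
    window_pos = seq_len(window$n),
    stops = count_stops(reads$start, reads$end, window$start, window$end,
                        strand = strand),
    background = count_coverage(reads$start, reads$end, window$start,
                                window$end)
  )
}

#' Percentile normalisation of a count vector
#'
#' Divides every entry by the nearest-rank `q`-th percentile (the
#' `ceiling(q * N)`-th order statistic) of the vector. A zero normaliser
#' (e.g. an all-zero window) leaves the vector unchanged and sets the
#' `degenerate` attribute.
#'
#' @param values Non-negative numeric vector.
#' @param q Percentile in (0, 1); default 0.95.
#' @return The normalised vector, with attributes `factor` (the divisor
#'   used) and `degenerate`.
#' @export
#' @examples
#' normalize_percentile(1:20)   # divides by 19, the ceiling(0.95*20)-th value
normalize_percentile <- function(values, q = 0.95) {
  if (any(values < 0, na.rm = TRUE)) {
    stop("percentile normalisation expects non-negative values", call. = FALSE)
  }
  f <- nearest_rank(values, q)
  if (is.na(f) || f == 0) {
    return(structure(values, factor = 0, degenerate = TRUE))
  }
  structure(values / f, factor = f, degenerate = FALSE)
}

#' Enrichment score of treated stops over control
#'
#' `ES_i = (R_i^T - s * R_i^C) / B_i^C` on percentile-normalised inputs.
#' The normalised control background is floored at
#' `config$background_pseudocount` before division; bases with zero *raw*
#' control coverage (no information) are set to `NA`.
#'
#' @param treated_stops,control_stops,control_background Equal-length
#'   normalised vectors (output of [normalize_percentile()]).
#' @param control_background_raw Optional raw control coverage vector used
#'   to mark uncovered bases missing.
#' @param config [astruct_config()].
#' @return Numeric vector of raw enrichment scores (may be negative; `NA`
#'   at uncovered bases).
#' @export
enrichment_scores <- function(treated_stops, control_stops,
                              control_background,
                              control_background_raw = NULL,
                              config = astruct_config()) {
  n <- length(treated_stops)
  if (length(control_stops) != n || length(control_background) != n) {
    stop("enrichment inputs must have equal length", call. = FALSE)
  }
  es <- (treated_stops - config$s_factor * control_stops) /
    pmax(control_background, config$background_pseudocount)
  if (!is.null(control_background_raw)) {
    es[control_background_raw == 0] <- NA_real_
  }
  es
}

#' Rescale raw enrichment scores to the unit interval
#'
#' Maps each score through
#' `max(0, min(1, (ES_i - ES[q_lo*N]) / (ES[q_hi*N] - ES[q_lo*N])))`, the
#' percentiles taken nearest-rank over non-missing values. If the two
#' percentiles coincide every non-missing score maps to 0 and the
#' `degenerate` attribute is set. Missing values stay missing.
#'
#' @param es Raw enrichment scores (may contain `NA`).
#' @param config [astruct_config()].
#' @return Vector of structure scores in `[0, 1]` (with `NA`s preserved)
#'   and a `degenerate` attribute.
#' @export
scale_unit <- function(es, config = astruct_config()) {
  ok <- !is.na(es)
  if (sum(ok) < 2L) {
    stop("cannot rescale a profile with fewer than two scored bases",
         call. = FALSE)
  }
  lo <- nearest_rank(es, config$norm_quantile_lo)
  hi <- nearest_rank(es, config$norm_quantile_hi)
  out <- es
  if (hi == lo) {
    out[ok] <- 0
    return(structure(out, degenerate = TRUE))
  }
  out[ok] <- pmin(1, pmax(0, (es[ok] - lo) / (hi - lo)))
  structure(out, degenerate = FALSE)
}

#' Structure scores from raw stop/background counts
#'
#' Runs the full per-allele scoring chain (percentile normalisation of
#' treated stops, control stops and control background; enrichment;
#' unit-interval rescaling) on raw count vectors for one allele.
#'
#' @param stops_treated,stops_control Raw RT-stop count vectors (length N).
#' @param background_control Raw control coverage vector (length N).
#' @param config [astruct_config()].
#' @return Tibble with `window_pos` and `es`; attribute `degenerate`.
#' @export
reactivity_profile <- function(stops_treated, stops_control,
                               background_control,
                               config = astruct_config()) {
  es <- es_from_raw(stops_treated, stops_control, background_control, config)
  structure(
    tibble(window_pos = seq_along(es), es = as.numeric(es)),
    degenerate = attr(es, "degenerate")
  )
}

# Fast internal path used by the caller and by every permutation: raw counts
# in, unit-interval scores out (NA = no control coverage).
es_from_raw <- function(rt, rc, bc, cfg) {
  rt_n <- normalize_percentile(rt, cfg$norm_quantile_hi)
  rc_n <- normalize_percentile(rc, cfg$norm_quantile_hi)
  bc_n <- normalize_percentile(bc, cfg$norm_quantile_hi)
  es <- as.vector((rt_n - cfg$s_factor * rc_n) /
                    pmax(bc_n, cfg$background_pseudocount))
  es[bc == 0] <- NA_real_
  ok <- !is.na(es)
  if (sum(ok) < 2L) {
    es[ok] <- 0
    return(structure(es, degenerate = TRUE))
  }
  lo <- nearest_rank(es, cfg$norm_quantile_lo)
  hi <- nearest_rank(es, cfg$norm_quantile_hi)
  if (hi == lo) {
    es[ok] <- 0
    return(structure(es, degenerate = TRUE))
  }
  es[ok] <- pmin(1, pmax(0, (es[ok] - lo) / (hi - lo)))
  structure(es, degenerate = FALSE)
}

#' Per-allele reactivity profiles around one SNP
#'
#' Computes the ref- and alt-allele structure score profiles over the SNP
#' window: each allele uses its own spanning reads plus the shared
#' non-spanning window reads, in both arms, through the counting,
#' normalisation, enrichment and rescaling chain.
#'
#' @param partition Output of [partition_reads()].
#' @param window One-row tibble from [define_window()].
#' @param config [astruct_config()].
#' @return Tibble with `window_pos`, `allele` (`"ref"`/`"alt"`) and `es`.
#' @export
allele_reactivity <- function(partition, window, config = astruct_config()) {
  ctx <- site_context(partition, window, config)
  prof <- observed_profiles(ctx)
  bind_rows(
    tibble(window_pos = seq_len(window$n), allele = "ref", es = as.numeric(prof$ref)),
    tibble(window_pos = seq_len(window$n), allele = "alt", es = as.numeric(prof$alt))
  )
}
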