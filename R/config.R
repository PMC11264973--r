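#' Configuration for ASRS calling
#'
#' Collects every tunable parameter of the calling pipeline in one list, with
#' the defaults used throughout the package.
#'
#' @param min_total_reads Minimum ref + alt spanning reads for a SNP to be
#'   retained (default 10).
#' @param min_allele_reads Minimum spanning reads per allele (default 2).
#' @param min_mapq Minimum mapping quality for a read to be used at all
#'   (BAM input only; default 20).
#' @param min_baseq Minimum base quality at the SNP base for a spanning read
#'   to be assigned an allele (BAM input only; default 13). Reads failing it
#'   still count towards total window coverage.
#' @param s_factor Background-subtraction factor `s` applied to the
#'   normalised control stop signal in the enrichment score (default 0.25,
#'   the icSHAPE-pipe lineage value).
#' @param norm_quantile_hi,norm_quantile_lo Percentiles used for the
#'   normalisation and unit-interval rescaling steps (defaults 0.95 / 0.05),
#'   applied as nearest-rank order statistics.
#' @param background_pseudocount Floor applied to the normalised control
#'   background before division, preventing a handful of barely covered
#'   bases from dominating the enrichment scale (default 0.25, i.e. a
#'   quarter of the 95th-percentile reference coverage). Bases with zero raw
#'   control coverage are reported missing regardless.
#' @param n_perm Number of read-label permutations for the null (default 1000).
#' @param library_strand Strand convention for the RT-stop position: `"+"`
#'   (stop at alignment start - 1, the default), `"-"` (stop at alignment
#'   end + 1).
#' @param pool_replicates Pool reads across replicates of the same arm
#'   (default `TRUE`). With `FALSE` each replicate pair is called separately
#'   and results carry a `replicate` column.
#'
#' @return A named list of class `astruct_config`.
#' @export
#' @examples
#' cfg <- astruct_config(n_perm = 200)
#' cfg$s_factor
astruct_config <- function(min_total_reads = 10L,
                           min_allele_reads = 2L,
                           min_mapq = 20L,
                           min_baseq = 13L,
                           s_factor = 0.25,
                           norm_quantile_hi = 0.95,
                           norm_quantile_lo = 0.05,
                           background_pseudocount = 0.25,
                           n_perm = 1000L,
                           library_strand = c("+", "-"),
                           pool_replicates = TRUE) {
  library_strand <- match.arg(library_strand)
  stopifnot(
    min_total_reads >= 1, min_allele_reads >= 0,
    s_factor >= 0,
    norm_quantile_lo > 0, norm_quantile_hi < 1,
    norm_quantile_lo < norm_quantile_hi,
    background_pseudocount > 0,
    n_perm >= 1
  )
  structure(
    list(
      min_total_reads = as.integer(min_total_reads),
      min_allele_reads = as.integer(min_allele_reads),
      min_mapq = as.integer(min_mapq),
      min_baseq = as.integer(min_baseq),
      s_factor = s_factor,
      norm_quantile_hi = norm_quantile_hi,
      norm_quantile_lo = norm_quantile_lo,
      background_pseudocount = background_pseudocount,
      n_perm = as.integer(n_perm),
      library_strand = library_strand,
      pool_replicates = isTRUE(pool_replicates)
    ),
    class = "astruct_config"
  )
}

config_string <- function(cfg) {
  flat <- vapply(cfg, function(x) paste(format(x), collapse = ","), character(1))
  paste(names(flat), flat, sep = "=", collapse = " ")
}
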