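# SNP observation, window definition and read partitioning.
#
# The in-memory representation of an alignment is a "reads tibble" with one
# row per aligned read and columns:
#   chrom      sequence (transcript/chromosome) name
#   start,end  1-based closed alignment span
#   arm        "treated" (NAI-N3) or "control" (DMSO)
#   replicate  integer replicate index (optional; assumed 1 when absent)
#   snp_base   the read's base at the SNP under consideration, NA when the
#              read does not cover the SNP or the base is uncallable
# astruct_call_bam() builds these per SNP from BAM; simulate_dataset() emits
# them directly.

#' Count allele-informative reads at a SNP and apply the retention filter
#'
#' A heterozygous SNP enters the analysis only when both alleles are seen:
#' at least `min_total_reads` (default 10) spanning reads with a called
#' ref/alt base, at least `min_allele_reads` (default 2) per allele.
#'
#' @param reads Reads tibble (see [astruct_call()]), already restricted to
#'   the SNP's sequence; treated and control arms pooled.
#' @param site One-row tibble or list with `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param config [astruct_config()] list.
#' @return One-row tibble: site columns plus `ref_reads`, `alt_reads`,
#'   `other_reads` (spanning reads carrying neither allele or with an
#'   uncallable base) and `retained`.
#' @export
observe_snp <- function(reads, site, config = astruct_config()) {
  covering <- reads$start <= site$pos & reads$end >= site$pos
  base <- reads$snp_base[covering]
  ref_reads <- sum(base == site$ref, na.rm = TRUE)
  alt_reads <- sum(base == site$alt, na.rm = TRUE)
  other_reads <- sum(covering) - ref_reads - alt_reads
  tibble(
    chrom = site$chrom, pos = as.integer(site$pos), id = site$id,
    ref = site$ref, alt = site$alt,
    ref_reads = ref_reads, alt_reads = alt_reads, other_reads = other_reads,
    retained = ref_reads + alt_reads >= config$min_total_reads &
      ref_reads >= config$min_allele_reads &
      alt_reads >= config$min_allele_reads
  )
}

#' Define the SNP window from the envelope of SNP-spanning reads
#'
#' The window runs from the start of the most upstream to the end of the
#' most downstream SNP-spanning read (both arms pooled); only spanning reads
#' with a called ref or alt base contribute.
#'
#' @inheritParams observe_snp
#' @return One-row tibble: `chrom`, `start`, `end` (1-based closed), `n`
#'   (window length) and `snp_offset` (1-based position of the SNP within
#'   the window).
#' @export
define_window <- function(reads, site) {
  spanning <- reads$start <= site$pos & reads$end >= site$pos &
    !is.na(reads$snp_base) & reads$snp_base %in% c(site$ref, site$alt)
  if (!any(spanning)) {
    stop("no allele-informative SNP-spanning reads at ", site$id, call. = FALSE)
  }
  wstart <- min(reads$start[spanning])
  wend <- max(reads$end[spanning])
  tibble(
    chrom = site$chrom,
    start = as.integer(wstart), end = as.integer(wend),
    n = as.integer(wend - wstart + 1L),
    snp_offset = as.integer(site$pos - wstart + 1L)
  )
}

#' Partition window-overlapping reads by the allele they carry
#'
#' Every read overlapping the SNP window is classified as `"ref"` or `"alt"`
#' (spanning, carrying that allele), `"other"` (spanning but with a third
#' base or uncallable base at the SNP: kept in the window total only) or
#' `"nonspanning"` (overlapping the window without covering the SNP base;
#' shared by both alleles).
#'
#' @inheritParams observe_snp
#' @param window One-row tibble from [define_window()].
#' @return The overlapping reads with an added `read_class` column, plus
#'   attributes `r_d` (ref + alt spanning reads) and `r_total` (all reads
#'   overlapping the window).
#' @export
partition_reads <- function(reads, window, site) {
  overlapping <- reads[reads$start <= window$end & reads$end >= window$start, ,
                       drop = FALSE]
  covering <- overlapping$start <= site$pos & overlapping$end >= site$pos
  cls <- rep("nonspanning", nrow(overlapping))
  cls[covering] <- "other"
  cls[covering & !is.na(overlapping$snp_base) &
        overlapping$snp_base == site$ref] <- "ref"
  cls[covering & !is.na(overlapping$snp_base) &
        overlapping$snp_base == site$alt] <- "alt"
  overlapping$read_class <- cls
  structure(
    overlapping,
    r_d = sum(cls %in% c("ref", "alt")),
    r_total = nrow(overlapping)
  )
}
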