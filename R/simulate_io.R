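# File-based simulator output: reference FASTA, per-arm/per-replicate
# sorted+indexed BAM files (written as SAM, converted with Rsamtools) and a
# plain-text truth manifest, so the BAM-reading front end can be exercised
# end to end on synthetic data.

sam_header <- function(trs) {
  c("@HD\tVN:1.6\tSO:unsorted",
    vapply(trs, function(tr) {
      sprintf("@SQ\tSN:%s\tLN:%d", tr$id, nchar(tr$seq))
    }, character(1)))
}

# Read sequence = transcript subsequence, with the alt base substituted for
# alt-allele reads that cover the SNP.
read_seqs <- function(reads, tr_by_id) {
  ids <- vapply(tr_by_id, `[[`, character(1), "id")
  j <- match(reads$chrom, ids)
  tx_seq <- vapply(tr_by_id, `[[`, character(1), "seq")[j]
  snp_pos <- vapply(tr_by_id, `[[`, integer(1), "snp_pos")[j]
  alt <- vapply(tr_by_id, `[[`, character(1), "alt")[j]
  s <- substring(tx_seq, reads$start, reads$end)
  swap <- reads$allele == "alt" & reads$start <= snp_pos &
    snp_pos <= reads$end
  if (any(swap)) {
    off <- snp_pos[swap] - reads$start[swap] + 1L
    rl <- nchar(s[swap])
    s[swap] <- paste0(substring(s[swap], 1L, off - 1L), alt[swap],
                      substring(s[swap], off + 1L, rl))
  }
  s
}

write_sim_bam <- function(reads, trs, sam_path) {
  tr_by_id <- setNames(trs, vapply(trs, `[[`, character(1), "id"))
  seqs <- read_seqs(reads, tr_by_id)
  lines <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                   reads$qname, reads$chrom, reads$start,
                   reads$end - reads$start + 1L, seqs,
                   strrep("I", reads$end - reads$start + 1L))
  writeLines(c(sam_header(trs), lines), sam_path)
  bam <- Rsamtools::asBam(sam_path, sub("\\.sam$", "", sam_path),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam_path)
  bam
}

#' Write a simulated benchmark dataset to disk
#'
#' Emits, for each requested coverage tier, a directory
#' `tier_<t>/` containing `reference.fa`, sorted and indexed
#' `treated_rep<i>.bam` / `control_rep<i>.bam`, a 5-column `snps.tsv`
#' usable with [read_snp_sites()], and the ground-truth `manifest.tsv`.
#' The transcript set (sequences, SNPs, masks, ASRS labels) is shared
#' across tiers; only read depth varies.
#'
#' @param cfg [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param tiers Coverage tiers to emit (default `cfg$tiers`).
#' @return Invisibly, a tibble with one row per tier and the file paths.
#' @export
astruct_simulate <- function(cfg = sim_config(), out_dir, tiers = cfg$tiers) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trs <- simulate_transcripts(cfg)
  fa <- Biostrings::DNAStringSet(
    setNames(vapply(trs, `[[`, character(1), "seq"),
             vapply(trs, `[[`, character(1), "id")))
  rows <- purrr::map(tiers, function(tier) {
    tdir <- file.path(out_dir, paste0("tier_", tier))
    dir.create(tdir, showWarnings = FALSE)
    fa_path <- file.path(tdir, "reference.fa")
    Biostrings::writeXStringSet(fa, fa_path)
    sim <- simulate_dataset(cfg, tier = tier)
    bams <- list()
    for (arm in c("treated", "control")) {
      for (r in seq_len(cfg$n_replicates)) {
        sel <- sim$reads$arm == arm & sim$reads$replicate == r
        nm <- sprintf("%s_rep%d", arm, r)
        bams[[nm]] <- write_sim_bam(
          sim$reads[sel, , drop = FALSE], trs,
          file.path(tdir, paste0(nm, ".sam")))
      }
    }
    readr::write_tsv(sim$snps, file.path(tdir, "snps.tsv"),
                     col_names = FALSE)
    readr::write_tsv(sim$manifest, file.path(tdir, "manifest.tsv"))
    tibble(
      tier = tier, dir = tdir, reference = fa_path,
      treated = paste(unlist(bams[paste0("treated_rep",
                                         seq_len(cfg$n_replicates))]),
                      collapse = ","),
      control = paste(unlist(bams[paste0("control_rep",
                                         seq_len(cfg$n_replicates))]),
                      collapse = ","),
      snps = file.path(tdir, "snps.tsv"),
      manifest = file.path(tdir, "manifest.tsv")
    )
  })
  invisible(bind_rows(rows))
}
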