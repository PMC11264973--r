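# BAM-facing front end. Reads are fetched per SNP in two passes: first the
# reads covering the SNP base (these define the observation counts and the
# SNP window), then every read overlapping the window. Per-read bases and
# base qualities at the SNP are extracted CIGAR-aware by laying the read
# sequence onto reference space.

bam_flag <- function() {
  Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                         isDuplicate = FALSE)
}

# Fetch reads overlapping `which_start..which_end` on `chrom` from one BAM,
# as a reads tibble with the base (and quality) each read shows at `pos`.
fetch_reads <- function(bam, chrom, which_start, which_end, pos, arm,
                        replicate, config) {
  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(which_start, which_end)),
    what = c("seq", "qual", "mapq"),
    flag = bam_flag()
  )
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(gal) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  arm = character(), replicate = integer(),
                  snp_base = character()))
  }
  mapq <- S4Vectors::mcols(gal)$mapq
  keep <- is.na(mapq) | mapq == 255L | mapq >= config$min_mapq
  gal <- gal[keep]
  if (length(gal) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  arm = character(), replicate = integer(),
                  snp_base = character()))
  }
  seq_ref <- GenomicAlignments::sequenceLayer(
    S4Vectors::mcols(gal)$seq, GenomicAlignments::cigar(gal))
  qual_ref <- GenomicAlignments::sequenceLayer(
    Biostrings::BStringSet(S4Vectors::mcols(gal)$qual),
    GenomicAlignments::cigar(gal))
  off <- pos - GenomicAlignments::start(gal) + 1L
  covered <- off >= 1L & off <= GenomicAlignments::width(gal)
  base <- rep(NA_character_, length(gal))
  base[covered] <- substring(as.character(seq_ref)[covered],
                             off[covered], off[covered])
  qchr <- rep(NA_character_, length(gal))
  qchr[covered] <- substring(as.character(qual_ref)[covered],
                             off[covered], off[covered])
  baseq <- ifelse(is.na(qchr) | nchar(qchr) != 1L, NA_integer_,
                  vapply(qchr, function(ch) utf8ToInt(ch) - 33L, integer(1),
                         USE.NAMES = FALSE))
  base[!base %in% c("A", "C", "G", "T")] <- NA_character_
  base[!is.na(baseq) & baseq < config$min_baseq] <- NA_character_
  tibble(
    chrom = chrom,
    start = GenomicAlignments::start(gal),
    end = GenomicAlignments::end(gal),
    arm = arm,
    replicate = as.integer(replicate),
    snp_base = base
  )
}

fetch_arm <- function(bams, chrom, which_start, which_end, pos, arm, config) {
  bind_rows(purrr::map(seq_along(bams), function(r) {
    fetch_reads(bams[[r]], chrom, which_start, which_end, pos, arm, r, config)
  }))
}

check_bam_inputs <- function(paths) {
  for (p in paths) {
    if (!file.exists(p)) stop("BAM not found: ", p, call. = FALSE)
    bai <- c(paste0(p, ".bai"), sub("\\.bam$", ".bai", p))
    if (!any(file.exists(bai))) {
      stop("BAM index (.bai) missing for ", p,
           "; run samtools index first", call. = FALSE)
    }
  }
  invisible(paths)
}

bam_contigs <- function(paths) {
  unique(unlist(lapply(paths, function(p) {
    names(Rsamtools::scanBamHeader(p)[[1]]$targets)
  })))
}

#' Call allele-specific RNA structure from BAM files
#'
#' File-based front end of [astruct_call()]: takes coordinate-sorted,
#' indexed, duplicate-collapsed BAM files for the treated (NAI-N3) and
#' control (DMSO) arms (one file per replicate) and a SNP list, fetches the
#' reads around each candidate SNP, and runs the calling pipeline.
#'
#' @param treated,control Character vectors of BAM paths (replicates of the
#'   NAI-N3 treated and DMSO control arms).
#' @param snps SNP tibble from [read_snp_sites()], or a path to a VCF/TSV.
#' @param fasta Optional reference FASTA; when given, SNPs whose stated ref
#'   allele disagrees with the reference base are dropped with a warning.
#' @inheritParams astruct_call
#' @return An `astruct_result` object.
#' @export
astruct_call_bam <- function(treated, control, snps,
                             config = astruct_config(),
                             n_perm = config$n_perm, seed = 1L,
                             per_base = FALSE, fasta = NULL) {
  check_bam_inputs(c(treated, control))
  if (is.character(snps) && length(snps) == 1L) snps <- read_snp_sites(snps)
  snps <- arrange(as_tibble(snps), .data$chrom, .data$pos)
  contigs <- bam_contigs(c(treated, control))
  missing_contig <- setdiff(unique(snps$chrom), contigs)
  if (length(missing_contig)) {
    stop("SNP contig(s) absent from the BAM headers: ",
         paste(head(missing_contig, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(fasta)) snps <- verify_ref_alleles(snps, fasta)

  set.seed(seed)
  obs_rows <- vector("list", nrow(snps))
  call_rows <- vector("list", nrow(snps))
  pb_rows <- if (per_base) vector("list", nrow(snps)) else NULL

  for (i in seq_len(nrow(snps))) {
    site <- snps[i, ]
    sub <- bind_rows(
      fetch_arm(treated, site$chrom, site$pos, site$pos, site$pos,
                "treated", config),
      fetch_arm(control, site$chrom, site$pos, site$pos, site$pos,
                "control", config)
    )
    obs <- observe_snp(sub, site, config)
    if (obs$retained) {
      window <- define_window(sub, site)
      sub <- bind_rows(
        fetch_arm(treated, site$chrom, window$start, window$end, site$pos,
                  "treated", config),
        fetch_arm(control, site$chrom, window$start, window$end, site$pos,
                  "control", config)
      )
    }
    res_i <- call_site(sub, site, config, n_perm, per_base)
    obs_rows[[i]] <- res_i$obs
    call_rows[[i]] <- res_i$call
    if (per_base) pb_rows[[i]] <- res_i$per_base
  }

  observations <- bind_rows(obs_rows)
  calls <- bind_rows(call_rows)
  if (nrow(calls) > 0L) {
    calls$group <- classify_group(calls$astruct_score)
    calls$p_adj <- stats::p.adjust(calls$p_value, method = "BH")
  }
  structure(
    list(
      calls = calls,
      per_base = if (per_base) bind_rows(pb_rows) else NULL,
      observations = observations,
      config = config,
      n_perm = as.integer(n_perm),
      seed = as.integer(seed),
      log = c(
        sites_seen = nrow(snps),
        heterozygous = sum(observations$ref_reads > 0 &
                             observations$alt_reads > 0),
        retained = sum(observations$retained),
        called = nrow(calls)
      )
    ),
    class = "astruct_result"
  )
}

verify_ref_alleles <- function(snps, fasta) {
  ref <- Biostrings::readDNAStringSet(fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  have <- snps$chrom %in% names(ref)
  base <- rep(NA_character_, nrow(snps))
  if (any(have)) {
    base[have] <- as.character(Biostrings::subseq(
      ref[snps$chrom[have]], start = snps$pos[have], width = 1L))
  }
  bad <- have & !is.na(base) & base != snps$ref
  if (any(bad)) {
    warning(sum(bad), " SNP(s) dropped: stated ref allele disagrees with ",
            "the reference sequence", call. = FALSE)
  }
  snps[!bad, , drop = FALSE]
}
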