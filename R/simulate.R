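# Synthetic RT-stop probing data with ground-truth ASRS labels.
#
# Each simulated transcript carries one heterozygous SNP near its middle and
# a paired/unpaired mask per allele: non-ASRS transcripts share one mask,
# ASRS transcripts have masks that differ around the SNP. Read counts per
# transcript, arm and replicate are Poisson; control reads start uniformly,
# while a fraction `stop_rate` of treated reads are RT-stop reads whose
# start is one base 3' of a uniformly chosen unpaired base of their allele's
# mask (the stop intervention is spread evenly over the unpaired bases).
# Reads are emitted either as an in-memory reads tibble or as genuine
# reference FASTA + sorted/indexed BAM files so the full alignment-reading
# path can be exercised.

#' Simulation settings
#'
#' @param n_transcripts Number of transcripts, one SNP each (default 200).
#' @param length Transcript length in nt (default 500).
#' @param asrs_fraction Fraction of transcripts with a true allelic
#'   structure difference (default 0.5).
#' @param tiers Increasing coverage tiers: mean reads per transcript, per
#'   arm, per replicate (default 2500, 5000, 10000). Genome-wide read totals
#'   do not translate to desk scale, so tiers are expressed per transcript;
#'   the default lowest tier yields roughly 600 SNP-spanning reads per site,
#'   the coverage regime in which the caller's discrimination sits at the
#'   lower end of its useful operating range.
#' @param stop_rate Probability that a treated-arm read is an RT-stop read
#'   (default 0.3).
#' @param read_length Read length in nt (default 30, a typical icSHAPE
#'   insert after trimming).
#' @param allele_ratio Probability a read comes from the ref allele
#'   (default 0.5, i.e. balanced alleles).
#' @param unpaired_frac Target unpaired fraction of the sampled structures
#'   (default 0.5).
#' @param min_struct_diff,struct_flank For ASRS transcripts, the alt mask
#'   must differ from the ref mask at >= `min_struct_diff` positions within
#'   +/- `struct_flank` nt of the SNP (defaults 10 and 25).
#' @param n_replicates Replicates per arm (default 2).
#' @param exact_split Make the number of ASRS transcripts exactly
#'   `round(n_transcripts * asrs_fraction)` (default `TRUE`); otherwise each
#'   transcript is labelled independently.
#' @param seed Master seed; per-transcript seeds are derived from it so any
#'   transcript can be re-simulated in isolation.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 200L, length = 500L,
                       asrs_fraction = 0.5, tiers = c(2500L, 5000L, 10000L),
                       stop_rate = 0.3, read_length = 30L,
                       allele_ratio = 0.5, unpaired_frac = 0.5,
                       min_struct_diff = 10L, struct_flank = 25L,
                       n_replicates = 2L, exact_split = TRUE, seed = 1L) {
  stopifnot(
    n_transcripts >= 1, length >= 20,
    asrs_fraction > 0, asrs_fraction < 1,
    all(tiers > 0), !is.unsorted(tiers),
    stop_rate > 0, stop_rate <= 1,
    read_length >= 10, read_length < length,
    allele_ratio > 0, allele_ratio < 1
  )
  structure(
    list(
      n_transcripts = as.integer(n_transcripts), length = as.integer(length),
      asrs_fraction = asrs_fraction, tiers = as.integer(tiers),
      stop_rate = stop_rate, read_length = as.integer(read_length),
      allele_ratio = allele_ratio, unpaired_frac = unpaired_frac,
      min_struct_diff = as.integer(min_struct_diff),
      struct_flank = as.integer(struct_flank),
      n_replicates = as.integer(n_replicates),
      exact_split = isTRUE(exact_split),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Parse a dot-bracket string into a paired mask
#'
#' @param db Dot-bracket string using `(`, `)` and `.`.
#' @return Logical vector, `TRUE` at paired positions.
#' @export
#' @examples
#' parse_dotbracket("((((....))))")
parse_dotbracket <- function(db) {
  chars <- strsplit(db, "")[[1]]
  if (!all(chars %in% c("(", ")", "."))) {
    stop("dot-bracket may only contain '(', ')' and '.'", call. = FALSE)
  }
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0) {
    stop("unbalanced dot-bracket string", call. = FALSE)
  }
  chars != "."
}

#' Sample a paired/unpaired mask from a stochastic stem-loop tiler
#'
#' Tiles the sequence with hairpin modules (stem, terminal loop, closing
#' stem, unpaired spacer) whose lengths are drawn so the expected unpaired
#' fraction matches `unpaired_frac`. A self-contained stand-in for an
#' external structure sampler; externally computed structures can be
#' supplied as dot-bracket strings via [parse_dotbracket()].
#'
#' @param length Sequence length (>= 20).
#' @param unpaired_frac Target unpaired fraction (default 0.5).
#' @param seed Optional seed.
#' @return Logical paired mask with attribute `dotbracket`.
#' @export
sample_structure <- function(length, unpaired_frac = 0.5, seed = NULL) {
  if (length < 20) stop("structures need length >= 20", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  kbar <- mean(3:6)
  lbar <- mean(3:8)
  f <- unpaired_frac
  s_mean <- max(0, (f * (2 * kbar + lbar) - lbar) / (1 - f))
  parts <- character(0)
  used <- 0L
  while (TRUE) {
    k <- sample(3:6, 1L)
    l <- sample(3:8, 1L)
    s <- stats::rpois(1L, s_mean)
    if (used + 2L * k + l > length) break
    s <- min(s, length - used - 2L * k - l)
    parts <- c(parts, strrep("(", k), strrep(".", l), strrep(")", k),
               strrep(".", s))
    used <- used + 2L * k + l + s
  }
  if (used < length) parts <- c(parts, strrep(".", length - used))
  db <- paste(parts, collapse = "")
  structure(parse_dotbracket(db), dotbracket = db)
}

#' Derive the alt-allele mask from the ref-allele mask
#'
#' Non-ASRS transcripts reuse the ref mask unchanged; ASRS transcripts get
#' an independently resampled mask, redrawn until it differs from the ref
#' mask at `min_diff` or more positions within `flank` nt of the SNP (best
#' draw kept after `max_tries`).
#'
#' @param mask_ref Logical paired mask of the ref allele.
#' @param is_asrs Truth label for the transcript.
#' @param snp_pos 1-based SNP position.
#' @param min_diff,flank Local difference requirement (defaults 10 within
#'   +/- 25 nt).
#' @param unpaired_frac Passed to [sample_structure()].
#' @param seed Optional seed.
#' @param max_tries Resampling budget (default 100).
#' @return Logical paired mask for the alt allele.
#' @export
derive_alt_structure <- function(mask_ref, is_asrs, snp_pos,
                                 min_diff = 10L, flank = 25L,
                                 unpaired_frac = 0.5, seed = NULL,
                                 max_tries = 100L) {
  if (!is_asrs) return(mask_ref)
  if (!is.null(seed)) set.seed(seed)
  len <- length(mask_ref)
  rgn <- max(1L, snp_pos - flank):min(len, snp_pos + flank)
  best <- NULL
  best_d <- -1L
  for (i in seq_len(max_tries)) {
    cand <- sample_structure(len, unpaired_frac)
    d <- sum(cand[rgn] != mask_ref[rgn])
    if (d >= min_diff) return(cand)
    if (d > best_d) {
      best <- cand
      best_d <- d
    }
  }
  best
}

# One transcript's fixed truth: sequence, SNP, per-allele masks.
make_transcript <- function(idx, cfg) {
  set.seed(child_seed(cfg$seed, idx))
  len <- cfg$length
  seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
  snp_pos <- as.integer(round(len / 2))
  ref <- substr(seq, snp_pos, snp_pos)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  mask_ref <- sample_structure(len, cfg$unpaired_frac)
  list(seq = seq, snp_pos = snp_pos, ref = ref, alt = alt,
       mask_ref = mask_ref)
}

#' Generate the fixed truth set of simulated transcripts
#'
#' Draws the transcript sequences, SNPs, per-allele paired/unpaired masks
#' and ASRS labels for a simulation configuration — everything that stays
#' constant across coverage tiers.
#'
#' @param cfg [sim_config()].
#' @return List of transcript truth objects (`id`, `seq`, `snp_pos`, `ref`,
#'   `alt`, `mask_ref`, `mask_alt`, `is_asrs`).
#' @export
simulate_transcripts <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_transcripts
  n_asrs <- as.integer(round(n * cfg$asrs_fraction))
  is_asrs <- if (cfg$exact_split) {
    sample(rep(c(TRUE, FALSE), c(n_asrs, n - n_asrs)))
  } else {
    stats::runif(n) < cfg$asrs_fraction
  }
  purrr::map(seq_len(n), function(i) {
    tr <- make_transcript(i, cfg)
    tr$id <- sprintf("tx%04d", i)
    tr$is_asrs <- is_asrs[i]
    tr$mask_alt <- derive_alt_structure(
      tr$mask_ref, tr$is_asrs, tr$snp_pos,
      min_diff = cfg$min_struct_diff, flank = cfg$struct_flank,
      unpaired_frac = cfg$unpaired_frac,
      seed = child_seed(cfg$seed, i + cfg$n_transcripts)
    )
    tr
  })
}

#' Simulate reads for one transcript at one coverage tier
#'
#' @param tr Transcript list element as produced inside
#'   [simulate_dataset()] (`seq`, `snp_pos`, `ref`, `alt`, `mask_ref`,
#'   `mask_alt`, `id`).
#' @param tier Mean reads per arm per replicate (Poisson).
#' @param cfg [sim_config()].
#' @param seed Optional seed.
#' @return Reads tibble (see [astruct_call()]) with extra columns `qname`
#'   and `allele` (the simulated truth).
#' @export
simulate_reads <- function(tr, tier, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (tier <= 0) stop("coverage tier must be positive", call. = FALSE)
  len <- nchar(tr$seq)
  rl <- cfg$read_length
  max_start <- len - rl + 1L
  unpaired <- list(
    ref = which(!tr$mask_ref),
    alt = which(!tr$mask_alt)
  )
  # stop base u must leave the read start u + 1 within the transcript
  unpaired <- lapply(unpaired, function(u) u[u + 1L <= max_start & u >= 1L])
  arms <- expand.grid(arm = c("treated", "control"),
                      rep = seq_len(cfg$n_replicates),
                      stringsAsFactors = FALSE)
  out <- purrr::map(seq_len(nrow(arms)), function(j) {
    arm <- arms$arm[j]
    rep_j <- arms$rep[j]
    n <- stats::rpois(1L, tier)
    if (n == 0L) return(NULL)
    allele <- ifelse(stats::runif(n) < cfg$allele_ratio, "ref", "alt")
    start <- sample.int(max_start, n, replace = TRUE)
    if (arm == "treated") {
      for (al in c("ref", "alt")) {
        u <- unpaired[[al]]
        sel <- which(allele == al & stats::runif(n) < cfg$stop_rate)
        if (length(u) && length(sel)) {
          start[sel] <- u[sample.int(length(u), length(sel), replace = TRUE)] + 1L
        }
      }
    }
    end <- start + rl - 1L
    covers <- start <= tr$snp_pos & end >= tr$snp_pos
    snp_base <- ifelse(covers, ifelse(allele == "ref", tr$ref, tr$alt),
                       NA_character_)
    tibble(
      qname = sprintf("%s_%s_r%d_%06d", tr$id, arm, rep_j, seq_len(n)),
      chrom = tr$id, start = start, end = end,
      arm = arm, replicate = rep_j,
      allele = allele, snp_base = snp_base
    )
  })
  bind_rows(out)
}

#' Simulate a full benchmark dataset in memory
#'
#' Generates transcripts with ground-truth allele masks and Poisson read
#' sets for both arms and all replicates at one coverage tier.
#'
#' @param cfg [sim_config()].
#' @param tier Mean reads per transcript per arm per replicate; defaults to
#'   the lowest configured tier.
#' @return List with `reads` (reads tibble across all transcripts), `snps`
#'   (SNP tibble for [astruct_call()]), `manifest` (truth tibble:
#'   `transcript_id`, `snp_id`, `snp_pos`, `ref`, `alt`, `is_asrs`) and
#'   `transcripts` (the full truth objects, including masks).
#' @export
simulate_dataset <- function(cfg = sim_config(), tier = cfg$tiers[1]) {
  trs <- simulate_transcripts(cfg)
  tier_tag <- match(tier, cfg$tiers)
  tier_tag <- if (is.na(tier_tag)) 0L else tier_tag
  reads <- bind_rows(purrr::map(seq_along(trs), function(i) {
    simulate_reads(trs[[i]], tier, cfg,
                   seed = child_seed(cfg$seed,
                                     1000000L + tier_tag * 10000L + i))
  }))
  snps <- bind_rows(purrr::map(trs, function(tr) {
    tibble(chrom = tr$id, pos = tr$snp_pos,
           id = paste0(tr$id, "_snp"), ref = tr$ref, alt = tr$alt)
  }))
  manifest <- bind_rows(purrr::map(trs, function(tr) {
    tibble(transcript_id = tr$id, snp_id = paste0(tr$id, "_snp"),
           snp_pos = tr$snp_pos, ref = tr$ref, alt = tr$alt,
           is_asrs = tr$is_asrs)
  }))
  list(reads = reads, snps = snps, manifest = manifest, transcripts = trs)
}
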