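#' Call allele-specific RNA structure at heterozygous SNPs
#'
#' The main in-memory entry point. Takes a reads tibble (one row per aligned
#' read) and a SNP tibble, and for every retained heterozygous SNP computes
#' the per-allele reactivity profiles, the eSDC with its permutation P
#' value, the composite score and the Low/Medium/High group.
#'
#' @param reads Tibble with columns `chrom`, `start`, `end` (1-based closed
#'   alignment span), `arm` (`"treated"`/`"control"`), optionally
#'   `replicate`, and `snp_base` (the read's base at the SNP on its `chrom`;
#'   `NA` when the read does not cover that SNP). [simulate_dataset()]
#'   produces this layout; [astruct_call_bam()] builds it from BAM.
#' @param snps Tibble with `chrom`, `pos` (1-based), `id`, `ref`, `alt`
#'   (e.g. from [read_snp_sites()]).
#' @param config [astruct_config()].
#' @param n_perm Permutations for the null (default `config$n_perm`).
#' @param seed Integer seed; the permutation stream is fully determined by
#'   it, so identical inputs and seed give identical results.
#' @param per_base Also compute the per-base StrucDiff track with its
#'   permutation P values (slower; default `FALSE`).
#' @return An `astruct_result` object; see [tidy.astruct_result()] for the
#'   per-SNP call table and [glance.astruct_result()] for run totals.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_transcripts = 4, seed = 7), tier = 300)
#' res <- astruct_call(sim$reads, sim$snps, n_perm = 50, seed = 1)
#' tidy(res)
astruct_call <- function(reads, snps, config = astruct_config(),
                         n_perm = config$n_perm, seed = 1L,
                         per_base = FALSE) {
  check_reads(reads)
  if (!config$pool_replicates && "replicate" %in% names(reads)) {
    reps <- sort(unique(reads$replicate))
    out <- purrr::map(reps, function(r) {
      cfg_r <- config
      cfg_r$pool_replicates <- TRUE
      res <- astruct_call(reads[reads$replicate == r, , drop = FALSE], snps,
                          config = cfg_r, n_perm = n_perm,
                          seed = child_seed(seed, r), per_base = per_base)
      res$calls$replicate <- r
      res
    })
    merged <- out[[1]]
    merged$calls <- bind_rows(purrr::map(out, "calls"))
    merged$per_base <- if (per_base) bind_rows(purrr::map(out, "per_base")) else NULL
    merged$observations <- bind_rows(purrr::map(out, "observations"))
    return(merged)
  }

  snps <- arrange(snps, .data$chrom, .data$pos)
  by_chrom <- split(seq_len(nrow(reads)), reads$chrom)
  set.seed(seed)

  obs_rows <- vector("list", nrow(snps))
  call_rows <- vector("list", nrow(snps))
  pb_rows <- if (per_base) vector("list", nrow(snps)) else NULL

  for (i in seq_len(nrow(snps))) {
    site <- snps[i, ]
    idx <- by_chrom[[site$chrom]]
    sub <- if (is.null(idx)) reads[0, , drop = FALSE] else reads[idx, , drop = FALSE]
    res_i <- call_site(sub, site, config, n_perm, per_base)
    obs_rows[[i]] <- res_i$obs
    call_rows[[i]] <- res_i$call
    if (per_base) pb_rows[[i]] <- res_i$per_base
  }

  observations <- bind_rows(obs_rows)
  calls <- bind_rows(call_rows)
  if (nrow(calls) > 0L) {
    calls$group <- classify_group(calls$astruct_score)
    # convenience column, not part of the core method
    calls$p_adj <- stats::p.adjust(calls$p_value, method = "BH")
  }
  log <- c(
    sites_seen = nrow(snps),
    heterozygous = sum(observations$ref_reads > 0 & observations$alt_reads > 0),
    retained = sum(observations$retained),
    called = nrow(calls)
  )
  structure(
    list(
      calls = calls,
      per_base = if (per_base) bind_rows(pb_rows) else NULL,
      observations = observations,
      config = config,
      n_perm = as.integer(n_perm),
      seed = as.integer(seed),
      log = log
    ),
    class = "astruct_result"
  )
}

# Shared per-site body: observe/filter, then (if retained) window,
# partition, permutation test and composite score. `sub` holds the reads of
# the site's sequence (BAM route: reads fetched around the site).
call_site <- function(sub, site, config, n_perm, per_base) {
  obs <- observe_snp(sub, site, config)
  if (!obs$retained) {
    return(list(obs = obs, call = NULL, per_base = NULL))
  }
  window <- define_window(sub, site)
  part <- partition_reads(sub, window, site)
  st <- test_site(part, window, config, n_perm = n_perm, per_base = per_base)
  score <- if (st$degenerate) 0 else
    astruct_score(st$p_value, st$esdc, st$r_d, st$r_total)
  call <- tibble(
    chrom = site$chrom, pos = as.integer(site$pos), snp_id = site$id,
    ref = site$ref, alt = site$alt,
    ref_reads = obs$ref_reads, alt_reads = obs$alt_reads,
    r_d = st$r_d, r_total = st$r_total,
    window_start = window$start, window_end = window$end, n = window$n,
    pcc = st$pcc, esdc = st$esdc, p_value = st$p_value,
    astruct_score = score
  )
  pb <- NULL
  if (per_base) {
    pb <- tibble(
      snp_id = site$id,
      window_pos = seq_len(window$n),
      es_ref = st$es_ref, es_alt = st$es_alt,
      strucdiff = st$strucdiff, strucdiff_p = st$strucdiff_p
    )
  }
  list(obs = obs, call = call, per_base = pb)
}

check_reads <- function(reads) {
  need <- c("chrom", "start", "end", "arm", "snp_base")
  miss <- setdiff(need, names(reads))
  if (length(miss)) {
    stop("reads tibble is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(reads$arm %in% c("treated", "control"))) {
    stop('reads$arm must be "treated" or "control"', call. = FALSE)
  }
  invisible(reads)
}

#' @export
print.astruct_result <- function(x, ...) {
  cat("<astruct_result>\n")
  cat(sprintf("  sites seen %d | heterozygous %d | retained %d | called %d\n",
              x$log[["sites_seen"]], x$log[["heterozygous"]],
              x$log[["retained"]], x$log[["called"]]))
  if (nrow(x$calls) > 0L) {
    tab <- table(x$calls$group)
    cat(sprintf("  groups: Low %d | Medium %d | High %d\n",
                tab[["Low"]], tab[["Medium"]], tab[["High"]]))
  }
  cat(sprintf("  n_perm %d, seed %d\n", x$n_perm, x$seed))
  invisible(x)
}
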