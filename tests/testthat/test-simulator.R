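test_that("dot-bracket strings are validated and converted to paired masks", {
  m <- parse_dotbracket("((((....))))")
  expect_equal(which(!m), 5:8)
  expect_equal(which(m), c(1:4, 9:12))
  expect_error(parse_dotbracket("((("), "unbalanced")
  expect_error(parse_dotbracket("(.x.)"), "may only contain")
})

test_that("the stem-loop tiler hits the target unpaired fraction on average", {
  fracs <- vapply(1:100, function(s) {
    mean(!sample_structure(100, unpaired_frac = 0.5, seed = s))
  }, numeric(1))
  expect_gt(mean(fracs), 0.40)
  expect_lt(mean(fracs), 0.60)
  # emitted dot-bracket is consistent with the mask
  st <- sample_structure(80, seed = 4)
  expect_equal(parse_dotbracket(attr(st, "dotbracket")), as.logical(st))
  expect_error(sample_structure(10), "length >= 20")
})

test_that("alt masks are identical without ASRS and locally distinct with it", {
  ref <- sample_structure(200, seed = 12)
  expect_identical(derive_alt_structure(ref, FALSE, 100), ref)
  alt <- derive_alt_structure(ref, TRUE, 100, min_diff = 10, flank = 25,
                              seed = 13)
  rgn <- 75:125
  expect_gte(sum(ref[rgn] != alt[rgn]), 10)
})

test_that("the stop intervention is even over unpaired bases and absent otherwise", {
  cfg <- sim_config(length = 200L, read_length = 30L, stop_rate = 1,
                    seed = 1)
  tr <- list(id = "txA", seq = strrep("A", 200), snp_pos = 100L,
             ref = "A", alt = "G")
  # fully paired: no legal stop sites, treated starts stay uniform
  tr$mask_ref <- tr$mask_alt <- rep(TRUE, 200)
  reads <- simulate_reads(tr, tier = 4000, cfg, seed = 2)
  tr_starts <- reads$start[reads$arm == "treated"]
  ct_starts <- reads$start[reads$arm == "control"]
  bins <- seq(0.5, 171.5, length.out = 10)
  tab <- rbind(table(cut(tr_starts, bins)), table(cut(ct_starts, bins)))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)

  # 50 unpaired bases: stop counts uniform within multinomial noise
  mask <- rep(TRUE, 200)
  unpaired <- seq(10, 108, by = 2)[1:50]
  mask[unpaired] <- FALSE
  tr$mask_ref <- tr$mask_alt <- mask
  reads <- simulate_reads(tr, tier = 10000, cfg, seed = 3)
  stops <- reads$start[reads$arm == "treated"] - 1L
  counts <- table(factor(stops[stops %in% unpaired], levels = unpaired))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("simulated truth is internally consistent", {
  cfg <- sim_config(n_transcripts = 12, length = 120, seed = 31,
                    tiers = c(200L, 400L))
  sim <- simulate_dataset(cfg, tier = 200)
  expect_equal(nrow(sim$manifest), 12L)
  expect_equal(sum(sim$manifest$is_asrs), 6L)   # exact split
  # every read's base at the SNP matches its true allele
  cov <- !is.na(sim$reads$snp_base)
  truth_base <- ifelse(sim$reads$allele == "ref",
                       sim$manifest$ref[match(sim$reads$chrom,
                                              sim$manifest$transcript_id)],
                       sim$manifest$alt[match(sim$reads$chrom,
                                              sim$manifest$transcript_id)])
  expect_true(all(sim$reads$snp_base[cov] == truth_base[cov]))
  # binomial labelling when the exact split is off
  cfg2 <- sim_config(n_transcripts = 200, asrs_fraction = 0.5,
                     exact_split = FALSE, seed = 8)
  n_asrs <- sum(vapply(simulate_transcripts(cfg2), `[[`, logical(1),
                       "is_asrs"))
  expect_gt(n_asrs, 70)
  expect_lt(n_asrs, 130)
})

test_that("ROC AUC matches all-pairs counting and handles the edge cases", {
  truth <- tibble::tibble(snp_id = sprintf("s%02d", 1:4),
                          is_asrs = c(TRUE, TRUE, FALSE, FALSE))
  calls <- tibble::tibble(snp_id = truth$snp_id,
                          astruct_score = c(0.9, 0.8, 0.7, 0.85))
  expect_equal(evaluate_auc(calls, truth)$auc, 0.75)
  # uninformative scorer
  flat <- dplyr::mutate(calls, astruct_score = 1)
  expect_equal(evaluate_auc(flat, truth)$auc, 0.5)
  # perfect separation
  perfect <- dplyr::mutate(calls, astruct_score = c(2, 3, 0.1, 0.2))
  expect_equal(evaluate_auc(perfect, truth)$auc, 1)
  # single-class truth is undefined
  expect_error(evaluate_auc(calls, dplyr::mutate(truth, is_asrs = TRUE)),
               "single class")
  # random scores agree with the quadratic-time oracle
  set.seed(14)
  for (i in 1:10) {
    n <- 30
    tr <- tibble::tibble(snp_id = sprintf("x%03d", 1:n),
                         is_asrs = c(TRUE, FALSE, runif(n - 2) < 0.5))
    cl <- tibble::tibble(snp_id = tr$snp_id,
                         astruct_score = sample(seq(0, 2, 0.25), n, TRUE))
    expect_equal(evaluate_auc(cl, tr)$auc,
                 oracle_auc(cl$astruct_score, tr$is_asrs))
  }
})
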