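# End-to-end checks of the file-based path: simulated BAMs read back through
# Rsamtools must reproduce the in-memory calls.

sim_fixture <- function() {
  cfg <- sim_config(n_transcripts = 6, length = 150, tiers = 400L,
                    read_length = 25L, seed = 77)
  dir <- file.path(tempdir(), "astructr-bamfix")
  if (!dir.exists(file.path(dir, "tier_400"))) {
    astruct_simulate(cfg, dir)
  }
  list(cfg = cfg, dir = file.path(dir, "tier_400"))
}

test_that("simulated BAM files round-trip through the BAM caller", {
  fx <- sim_fixture()
  treated <- file.path(fx$dir, c("treated_rep1.bam", "treated_rep2.bam"))
  control <- file.path(fx$dir, c("control_rep1.bam", "control_rep2.bam"))
  expect_true(all(file.exists(treated, control,
                              paste0(treated, ".bai"))))
  res_bam <- astruct_call_bam(treated, control,
                              file.path(fx$dir, "snps.tsv"),
                              n_perm = 40, seed = 5)
  sim <- simulate_dataset(fx$cfg, tier = 400)
  res_mem <- astruct_call(sim$reads, sim$snps, n_perm = 40, seed = 5)
  # permutation-independent columns must agree exactly between the two routes
  cols <- c("chrom", "pos", "snp_id", "ref", "alt", "ref_reads", "alt_reads",
            "r_d", "r_total", "window_start", "window_end", "n", "pcc", "esdc")
  expect_equal(as.data.frame(tidy(res_bam)[, cols]),
               as.data.frame(tidy(res_mem)[, cols]))
  # manifest written by the simulator matches the in-memory truth
  manifest <- readr::read_tsv(file.path(fx$dir, "manifest.tsv"),
                              show_col_types = FALSE)
  expect_equal(as.data.frame(manifest), as.data.frame(sim$manifest))
})

test_that("BAM input problems raise actionable errors", {
  fx <- sim_fixture()
  bam <- file.path(fx$dir, "treated_rep1.bam")
  ctl <- file.path(fx$dir, "control_rep1.bam")
  expect_error(astruct_call_bam("nope.bam", ctl, demo_site()), "not found")
  unindexed <- file.path(tempdir(), "unindexed.bam")
  file.copy(bam, unindexed, overwrite = TRUE)
  expect_error(astruct_call_bam(unindexed, ctl, demo_site()), "index")
  bad_site <- tibble::tibble(chrom = "chrMissing", pos = 10L, id = "x",
                             ref = "A", alt = "G")
  expect_error(astruct_call_bam(bam, ctl, bad_site), "absent from the BAM")
})

test_that("reference verification drops SNPs that contradict the FASTA", {
  fx <- sim_fixture()
  treated <- file.path(fx$dir, c("treated_rep1.bam", "treated_rep2.bam"))
  control <- file.path(fx$dir, c("control_rep1.bam", "control_rep2.bam"))
  snps <- read_snp_sites(file.path(fx$dir, "snps.tsv"))
  snps$ref[1] <- setdiff(c("A", "C", "G", "T"),
                         c(snps$ref[1], snps$alt[1]))[1]
  snps$alt[1] <- setdiff(c("A", "C", "G", "T"), snps$ref[1])[1]
  expect_warning(
    res <- astruct_call_bam(treated, control, snps, n_perm = 10, seed = 1,
                            fasta = file.path(fx$dir, "reference.fa")),
    "disagrees"
  )
  expect_equal(res$log[["sites_seen"]], nrow(snps) - 1L)
})

test_that("call tables are byte-identical across reruns with one seed", {
  fx <- sim_fixture()
  sim <- simulate_dataset(fx$cfg, tier = 400)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_calls(astruct_call(sim$reads, sim$snps, n_perm = 30, seed = 21), f1)
  write_calls(astruct_call(sim$reads, sim$snps, n_perm = 30, seed = 21), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # header records version, seed and parameters
  hdr <- readLines(f1, n = 3)
  expect_match(hdr[1], "astructr")
  expect_match(hdr[2], "seed=21")
  expect_match(hdr[3], "s_factor=0.25")
})

test_that("per-base output and exporters work together", {
  fx <- sim_fixture()
  sim <- simulate_dataset(fx$cfg, tier = 400)
  res <- astruct_call(sim$reads, sim$snps, n_perm = 30, seed = 2,
                      per_base = TRUE)
  pb <- res$per_base
  expect_true(all(c("es_ref", "es_alt", "strucdiff", "strucdiff_p") %in%
                    names(pb)))
  expect_true(all(pb$strucdiff_p > 0 & pb$strucdiff_p <= 1, na.rm = TRUE))
  # per-base track agrees with a direct strucdiff of the stored profiles
  one <- pb[pb$snp_id == pb$snp_id[1], ]
  expect_equal(one$strucdiff, strucdiff(one$es_ref, one$es_alt))
  tsv <- tempfile(fileext = ".tsv")
  write_per_base(res, tsv)
  expect_gt(file.size(tsv), 0)
  bg <- write_bedgraph(res, tempfile())
  expect_length(bg, 2L)
  expect_true(all(file.exists(bg)))
  # plots build without error
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_reactivity(res, pb$snp_id[1]), "ggplot")
})
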