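test_that("RT-stop and background counting follow the stop-base convention", {
  w <- tibble::tibble(chrom = "tx1", start = 90L, end = 129L, n = 40L,
                      snp_offset = 11L)
  reads <- tibble::tibble(chrom = "tx1", start = 95L, end = 124L,
                          arm = "treated", replicate = 1L, snp_base = "A")
  prof <- count_stop_profile(reads, w)
  expect_equal(which(prof$stops == 1L), 5L)       # stop base 94 = window pos 5
  expect_equal(which(prof$background == 1L), 6:35)
  # a read starting exactly at the window start leaves no in-window stop
  edge <- dplyr::mutate(reads, start = 90L, end = 119L)
  expect_equal(sum(count_stop_profile(edge, w)$stops), 0L)
  expect_equal(sum(count_stop_profile(edge, w)$background), 30L)
  # three reads with a common start pile three stops on one base
  trio <- dplyr::bind_rows(reads, reads, reads)
  expect_equal(max(count_stop_profile(trio, w)$stops), 3L)
  # minus-strand convention: stop one base 3' of the alignment end
  minus <- count_stop_profile(reads, w, strand = "-")
  expect_equal(which(minus$stops == 1L), 36L)     # base 125 = window pos 36
})

test_that("percentile normalisation uses the nearest-rank order statistic", {
  v <- normalize_percentile(1:20)
  expect_equal(attr(v, "factor"), 19)             # ceiling(0.95 * 20) = 19th
  expect_equal(as.numeric(v), (1:20) / 19)
  z <- normalize_percentile(rep(0, 20))
  expect_true(attr(z, "degenerate"))
  expect_equal(as.numeric(z), rep(0, 20))
  c5 <- normalize_percentile(rep(5, 10))
  expect_equal(as.numeric(c5), rep(1, 10))
  expect_error(normalize_percentile(c(1, -1)), "non-negative")
})

test_that("enrichment scores subtract scaled control and guard zero coverage", {
  cfg <- astruct_config()
  expect_equal(enrichment_scores(0.8, 0.4, 1.0, config = cfg), 0.7)
  expect_equal(enrichment_scores(0, 0.4, 0.5, config = cfg), -0.2)
  es <- enrichment_scores(c(0.8, 0.5), c(0.4, 0.2), c(1, 1),
                          control_background_raw = c(3, 0), config = cfg)
  expect_true(is.na(es[2]))
  expect_error(enrichment_scores(1:3, 1:2, 1:3), "equal length")
})

test_that("unit rescaling clamps to [0,1] and flags flat profiles", {
  cfg <- astruct_config()
  flat <- scale_unit(rep(0.3, 10), cfg)
  expect_true(attr(flat, "degenerate"))
  expect_equal(as.numeric(flat), rep(0, 10))
  x <- as.numeric(1:20)
  sc <- scale_unit(x, cfg)                         # lo = x[1] = 1, hi = x[19] = 19
  expect_equal(sc[1], 0)
  expect_equal(sc[19], 1)
  expect_equal(sc[20], 1)                          # clamped above
  expect_equal(sc[10], (10 - 1) / 18)
  ramp <- scale_unit(c(-1, 0:18), cfg)
  expect_true(all(diff(ramp) >= 0))
  expect_true(all(ramp >= 0 & ramp <= 1))
  expect_error(scale_unit(c(NA, NA, 1)), "fewer than two")
})

test_that("the scoring chain matches a straight-line oracle on random windows", {
  cfg <- astruct_config()
  set.seed(501)
  for (i in 1:120) {
    n <- sample(5:50, 1)
    rt <- rpois(n, sample(c(0.5, 2, 8), 1))
    rc <- rpois(n, sample(c(0.5, 2, 8), 1))
    bc <- rpois(n, sample(c(0.8, 4, 15), 1))
    got <- reactivity_profile(rt, rc, bc, cfg)$es
    want <- oracle_reactivity(rt, rc, bc)
    expect_equal(got, want, tolerance = 0)
    expect_true(all(got >= 0 & got <= 1, na.rm = TRUE))
  }
})

test_that("profiles are invariant to a global rescaling of the raw counts", {
  cfg <- astruct_config()
  set.seed(88)
  rt <- rpois(40, 4); rc <- rpois(40, 3); bc <- rpois(40, 10) + 1L
  base <- reactivity_profile(rt, rc, bc, cfg)$es
  scaled <- reactivity_profile(rt * 7L, rc * 7L, bc * 7L, cfg)$es
  expect_equal(scaled, base)
})

test_that("identical ref and alt read sets give identical profiles", {
  site <- demo_site()
  set.seed(9)
  starts <- site$pos - sample.int(29, 12, replace = TRUE) + 1L
  arms <- sample(c("treated", "control"), 12, replace = TRUE)
  mk <- function(base) tibble::tibble(chrom = "tx1", start = starts,
                                      end = starts + 29L, arm = arms,
                                      replicate = 1L, snp_base = base)
  reads <- dplyr::bind_rows(mk(site$ref), mk(site$alt))
  w <- define_window(reads, site)
  part <- partition_reads(reads, w, site)
  prof <- allele_reactivity(part, w)
  ref <- prof$es[prof$allele == "ref"]
  alt <- prof$es[prof$allele == "alt"]
  expect_identical(ref, alt)
})
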