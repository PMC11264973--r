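test_that("eSDC follows (1 - correlation) * sqrt(window length)", {
  x <- c(0, 0.2, 0.8, 1, 0.4)
  expect_equal(esdc(x, x, n = 100)$esdc, 0)
  expect_equal(esdc(x, x, n = 100)$pcc, 1)
  # perfectly anti-correlated profiles over a 25-base window
  y <- 1 - x
  expect_equal(esdc(x, y, n = 25)$esdc, 10)
  # arbitrary pair agrees with the definition computed directly
  set.seed(3)
  a <- runif(30); b <- runif(30)
  expect_equal(esdc(a, b)$esdc, (1 - cor(a, b)) * sqrt(30))
  # degenerate: a flat profile has no defined correlation
  flat <- esdc(rep(0.5, 10), runif(10))
  expect_true(flat$degenerate)
  expect_equal(flat$esdc, 0)
  expect_error(esdc(c(1, 2), c(1, 2)), "fewer than 3")
})

test_that("the add-one permutation P value counts the upper tail", {
  null <- seq(0.001, 1, length.out = 1000)
  expect_equal(perm_pvalue(2, null), 1 / 1001)
  expect_equal(perm_pvalue(0, null), 1)
  # observed at the median of a synthetic null: P close to 0.5
  expect_equal(perm_pvalue(null[500], null), (1 + 501) / 1001)
})

test_that("the composite score combines significance, magnitude and spanning fraction", {
  expect_equal(astruct_score(0.01, 2, 50, 50), 4)
  expect_equal(astruct_score(0.1, 3, 10, 100), 6)
  expect_equal(astruct_score(1, 5, 10, 40), 0)
  # monotone in eSDC at fixed P, decreasing in P at fixed eSDC
  e <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(astruct_score(rep(0.05, length(e)), e, 20, 40)) > 0))
  p <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(astruct_score(p, rep(2, length(p)), 20, 40)) < 0))
  # the spanning-fraction factor is exactly 1 when every read spans
  expect_equal(astruct_score(0.1, 1, 33, 33), 1)
  expect_error(astruct_score(0.5, 1, 0, 10))
})

test_that("scores are grouped Low (0), Medium (0,1], High (1,Inf)", {
  expect_equal(as.character(classify_group(c(0, 1e-9, 1, 1 + 1e-9, 8.74))),
               c("Low", "Medium", "Medium", "High", "High"))
  expect_error(classify_group(-0.1))
})

test_that("StrucDiff equals the naive sliding-window mean absolute difference", {
  # identical profiles: all computable positions are zero
  x <- runif(20)
  sd0 <- strucdiff(x, x)
  expect_true(all(sd0[3:18] == 0))
  expect_true(all(is.na(sd0[c(1, 2, 19, 20)])))
  # a single unit difference spreads 0.2 over five positions
  a <- rep(0, 15); b <- rep(0, 15); b[8] <- 1
  sd1 <- strucdiff(a, b)
  expect_equal(sd1[6:10], rep(0.2, 5))
  expect_true(all(sd1[c(3:5, 11:13)] == 0))
  # random pairs, with missing values sprinkled in, match the double loop
  set.seed(42)
  for (i in 1:40) {
    n <- sample(4:40, 1)
    p <- runif(n); q <- runif(n)
    p[sample(n, sample(0:3, 1))] <- NA
    expect_equal(strucdiff(p, q), oracle_strucdiff(p, q))
  }
})

test_that("the permutation null is reproducible and sized as requested", {
  site <- demo_site()
  reads <- make_site_reads(site, 8, 8, n_non = 10, seed = 5)
  w <- define_window(reads, site)
  part <- partition_reads(reads, w, site)
  n1 <- permutation_null(part, w, n_perm = 50, seed = 11)
  n2 <- permutation_null(part, w, n_perm = 50, seed = 11)
  expect_length(n1, 50)
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0))
})

test_that("alleles with identical stop patterns are not called different", {
  # both alleles' reads drawn from one start distribution: observed eSDC
  # should sit inside the bulk of its own permutation null
  site <- demo_site()
  set.seed(71)
  reads <- make_site_reads(site, 25, 25, n_non = 30, seed = 71)
  res <- astruct_call(reads, site, n_perm = 200, seed = 9)
  expect_gt(tidy(res)$p_value, 0.05)
})
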