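test_that("overlap permutation test: anchors, analytic null mean, determinism", {
  u <- sprintf("g%04d", 1:1000)
  s <- u[1:50]
  res <- overlap_permutation_test(list(s, s), list(u, u),
                                  n_replicates = 500, seed = 1)
  expect_equal(res$observed, 50)
  expect_gt(res$z, 5)
  expect_equal(res$p, 1 / 501)  # smallest attainable

  # disjoint universes: observed and null both zero
  res <- overlap_permutation_test(list(u[1:10], sprintf("h%d", 1:10)),
                                  list(u[1:100], sprintf("h%d", 1:100)),
                                  n_replicates = 200, seed = 2)
  expect_equal(res$observed, 0)
  expect_equal(res$null_mean, 0)
  expect_true(res$z_undefined)

  # random sets in a shared universe: null mean near |A||B|/|U|
  set.seed(3)
  big_u <- sprintf("g%04d", 1:2000)
  a <- sample(big_u, 20); b <- sample(big_u, 30)
  res <- overlap_permutation_test(list(a, b), list(big_u, big_u),
                                  n_replicates = 3000, seed = 4)
  expected <- 20 * 30 / 2000
  mc_se <- stats::sd(c(res$null_sd)) # placeholder; recompute below
  mc_se <- res$null_sd / sqrt(res$n_replicates)
  expect_lt(abs(res$null_mean - expected), 3 * mc_se + 0.02)

  # same seed -> identical result; z and p point the same way
  res2 <- overlap_permutation_test(list(a, b), list(big_u, big_u),
                                   n_replicates = 3000, seed = 4)
  expect_identical(res, res2)
  expect_error(overlap_permutation_test(list(c(a, "zzz"), b),
                                        list(big_u, big_u), 10, 1),
               "subset")

  # three-way support
  res3 <- overlap_permutation_test(list(s, s, s), list(u, u, u),
                                   n_replicates = 200, seed = 5)
  expect_equal(res3$observed, 50)
  expect_gt(res3$z, 5)
})

test_that("shift directions obey the call-rate rule, polarity, and a counting oracle", {
  low <- toy_gt(matrix(c(0L, 0L, 1L, 1L, 0L,   2L, 2L, 2L, 2L, 2L,
                         1L, 1L, NA, NA, NA), ncol = 3))
  high <- toy_gt(matrix(c(2L, 2L, 2L, 2L, 1L,  0L, 0L, 0L, 0L, 0L,
                          1L, 1L, 1L, 1L, 1L), ncol = 3))
  out <- shift_directions(low, high, low$sites$id, min_call_fraction = 0.6)
  expect_identical(out$direction, c("up", "down", "none"))  # third fails 60%

  # counting oracle on random tables
  lowr <- random_gt(10, 25, miss = 0.3, seed = 81)
  highr <- random_gt(10, 25, miss = 0.3, seed = 82)
  out <- shift_directions(lowr, highr, lowr$sites$id, 0.6)
  for (k in seq_len(nrow(out))) {
    gl <- lowr$calls[, out$site_id[k]]; gh <- highr$calls[, out$site_id[k]]
    fl <- sum(gl, na.rm = TRUE) / (2 * sum(!is.na(gl)))
    fh <- sum(gh, na.rm = TRUE) / (2 * sum(!is.na(gh)))
    want <- if (mean(!is.na(gl)) < 0.6 || mean(!is.na(gh)) < 0.6) "none"
    else if (fh > fl) "up" else if (fh < fl) "down" else "none"
    expect_identical(out$direction[k], want)
  }

  # swapped ref/alt re-orients the dosage; different alleles are excluded
  high2 <- high
  high2$sites$ref <- c("G", "A", "A")
  high2$sites$alt <- c("A", "G", "C")
  out2 <- shift_directions(low, high2, low$sites$id, 0.6)
  expect_identical(attr(out2, "n_excluded"), 1L)  # the A/C site
  k <- which(out2$site_id == low$sites$id[1])
  expect_identical(out2$direction[k], "down")  # flipped polarity flips it
})

test_that("end populations are the extremes in distance from the equator", {
  sam <- data.frame(population = rep(c("p1", "p2", "p3"), each = 2),
                    latitude = rep(c(-3, -55, -30), each = 2))
  ends <- end_populations(sam)
  expect_identical(ends$low, "p1")
  expect_identical(ends$high, "p2")
})

test_that("gene-level parallel calls follow the chosen rule", {
  tabs <- lapply(c("up", "up", "up"), function(d)
    data.frame(site_id = "chr1:10", direction = d))
  asg <- data.frame(site_id = c("chr1:10", "chr1:20"), gene_id = "gA")
  out <- gene_parallel_calls(tabs, asg)
  expect_true(out$concordant)

  # one concordant, one discordant SNP in the same gene
  tabs2 <- list(
    data.frame(site_id = c("chr1:10", "chr1:20"), direction = c("up", "up")),
    data.frame(site_id = c("chr1:10", "chr1:20"), direction = c("up", "down")),
    data.frame(site_id = c("chr1:10", "chr1:20"), direction = c("up", "up")))
  asg2 <- data.frame(site_id = c("chr1:10", "chr1:20"), gene_id = "gA")
  expect_false(gene_parallel_calls(tabs2, asg2, rule = "all")$concordant)
  expect_false(gene_parallel_calls(tabs2, asg2, rule = "majority")$concordant)
  expect_true(gene_parallel_calls(tabs2, asg2, rule = "any")$concordant)
  tabs3 <- tabs2
  tabs3[[2]]$direction <- c("up", "none")  # gene not evaluable in transect 2
  expect_equal(nrow(gene_parallel_calls(tabs3, asg2)), 1)

  # neutral single-SNP genes: concordance 25% for 3 transects, 50% for 2
  set.seed(83)
  n <- 4000
  ids <- sprintf("chr1:%d", seq_len(n))
  mk <- function() data.frame(site_id = ids,
                              direction = sample(c("up", "down"), n, TRUE))
  asg1 <- data.frame(site_id = ids, gene_id = sprintf("g%d", seq_len(n)))
  f3 <- mean(gene_parallel_calls(list(mk(), mk(), mk()), asg1)$concordant)
  f2 <- mean(gene_parallel_calls(list(mk(), mk()), asg1)$concordant)
  expect_lt(abs(f3 - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  expect_lt(abs(f2 - 0.50), 3 * sqrt(0.5 * 0.5 / n))
})

test_that("parallel chi-square matches the hand formula", {
  expect_equal(parallel_chisq(25, 100)$chisq, 0)
  expect_equal(parallel_chisq(25, 100)$p, 1)
  hand <- function(o, n, f = 0.25) {
    E <- c(n * f, n * (1 - f)); O <- c(o, n - o); sum((O - E)^2 / E)
  }
  res <- parallel_chisq(5, 5)
  expect_equal(res$chisq, hand(5, 5), tolerance = 1e-12)
  expect_false(res$small_expected)          # cells 1.25 and 3.75 are >= 1
  expect_true(parallel_chisq(1, 2)$small_expected)
  expect_equal(parallel_chisq(101, 173)$chisq, hand(101, 173),
               tolerance = 1e-9)
  expect_equal(parallel_chisq(116, 150)$chisq, hand(116, 150),
               tolerance = 1e-9)
  expect_equal(parallel_chisq(101, 173)$p,
               stats::pchisq(hand(101, 173), 1, lower.tail = FALSE))
  expect_error(parallel_chisq(10, 5), "n_parallel")
})

test_that("parallel permutation null matches the binomial and is deterministic", {
  set.seed(84)
  flags <- runif(3000) < 0.3
  res <- parallel_permutation(flags, n_select = 100, n_parallel = 50,
                              n_iter = 1000, seed = 9)
  f <- mean(flags)
  expect_lt(abs(res$null_mean - 100 * f),
            3 * sqrt(100 * f * (1 - f) / 1000))
  res2 <- parallel_permutation(flags, 100, 50, 1000, seed = 9)
  expect_identical(res, res2)
  # all-discordant universe with fully parallel observation: smallest p
  res3 <- parallel_permutation(rep(FALSE, 500), 20, 20, 500, seed = 10)
  expect_equal(res3$p, 1 / 501)
  # null count distribution is Binomial(n_select, f): sup distance between
  # the empirical CDF of resampled counts and the binomial CDF
  set.seed(85)
  null_counts <- replicate(1000, sum(sample(flags, 100, replace = TRUE)))
  ks_d <- max(vapply(0:100, function(k)
    abs(mean(null_counts <= k) - stats::pbinom(k, 100, f)), 0))
  expect_lt(ks_d, 0.05)
})
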