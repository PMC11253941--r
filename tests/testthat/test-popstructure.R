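test_that("allele frequencies match brute-force counting and the call-rate rule", {
  gt <- toy_gt(matrix(c(0L, 1L, 2L), nrow = 3))
  expect_equal(allele_frequencies(gt)$freq, 0.5)

  # 10 samples, 7 called, threshold 0.8 -> excluded
  calls <- matrix(c(rep(1L, 7), rep(NA, 3)), ncol = 1)
  af <- allele_frequencies(toy_gt(calls), min_call_fraction = 0.8)
  expect_true(af$excluded)
  expect_equal(af$freq, 0.5)  # frequency still reported over called alleles

  # counting oracle on a random table with missingness
  gt <- random_gt(12, 30, miss = 0.2, seed = 77)
  af <- allele_frequencies(gt)
  for (j in seq_len(30)) {
    x <- gt$calls[, j]
    expect_equal(af$freq[j], sum(x, na.rm = TRUE) / (2 * sum(!is.na(x))))
  }
  # a site with all calls missing is excluded, never NaN
  calls <- cbind(c(0L, 1L), c(NA, NA))
  af <- allele_frequencies(toy_gt(calls))
  expect_true(af$excluded[2])
  expect_true(is.na(af$freq[2]))
})

test_that("Weir-Cockerham theta hits its analytic anchors", {
  # identical frequency 0.5 with exact HWE counts: theta near 0, and the
  # finite-sample estimate sits slightly below it
  hwe <- c(rep(0L, 5), rep(1L, 10), rep(2L, 5))
  theta0 <- pairwise_wc_fst(toy_gt(matrix(hwe, ncol = 1)),
                            toy_gt(matrix(rev(hwe), ncol = 1)))$theta
  expect_lt(abs(theta0), 0.05)
  expect_lte(theta0, 0)

  # fixed alternative alleles: theta = 1
  a <- toy_gt(matrix(2L, 10, 1)); b <- toy_gt(matrix(0L, 10, 1))
  expect_equal(pairwise_wc_fst(a, b)$theta, 1)

  # hand-evaluated 1984 component formulas for stated genotype counts
  g1 <- c(2L, 2L, 1L, 1L, 0L); g2 <- c(0L, 0L, 1L, 1L, 2L)
  res <- pairwise_wc_fst(toy_gt(matrix(g1, ncol = 1)),
                         toy_gt(matrix(g2, ncol = 1)))
  n1 <- 5; n2 <- 5; r <- 2
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a_ <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) /
                         (nbar - 1))
  b_ <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c_ <- hbar / 2
  expect_equal(res$theta, a_ / (a_ + b_ + c_), tolerance = 1e-12)
  expect_equal(res$per_site$a, a_, tolerance = 1e-12)

  # multi-site aggregation is ratio of sums, uninformative sites counted
  ga <- random_gt(8, 20, seed = 1)
  gb <- random_gt(8, 20, seed = 2)
  res <- pairwise_wc_fst(ga, gb)
  ok <- !is.na(res$per_site$theta)
  expect_equal(res$theta,
               sum(res$per_site$a[ok]) /
                 sum(res$per_site$a[ok] + res$per_site$b[ok] +
                       res$per_site$c[ok]))
  expect_error(pairwise_wc_fst(toy_gt(matrix(NA_integer_, 2, 1)),
                               toy_gt(matrix(NA_integer_, 2, 1))),
               "informative")
})

test_that("Mann-Whitney U, tie-corrected z and p agree with oracles", {
  # symmetry: equal samples give U at its null mean and z = 0
  res <- mann_whitney(c(1, 2), c(1, 2))
  expect_equal(res$U, 2)
  expect_equal(res$z, 0)

  # exact enumeration oracle at n1 = n2 = 3: complete separation has
  # one-sided p = 1/20, so the normal two-sided p must sit nearby
  res <- mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(res$U, 9)  # maximal
  perms <- combn(6, 3)
  vals <- c(4, 5, 6, 1, 2, 3)  # exact U null distribution by enumeration
  ranks <- rank(vals)
  u_null <- apply(perms, 2, function(ix) sum(ranks[ix]) - 6)
  p_exact <- mean(u_null >= res$U)
  expect_equal(p_exact, 1 / 20)
  expect_lt(abs(res$p / 2 - p_exact), 0.03)  # normal approx error bound

  # z agrees with enumeration-based p across small configurations
  set.seed(4)
  for (rep in 1:10) {
    x <- sample(1:8, sample(3:6, 1), replace = TRUE)
    y <- sample(1:8, sample(3:6, 1), replace = TRUE)
    res <- mann_whitney(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, correct = FALSE,
                                               exact = FALSE))
    expect_equal(res$U, unname(ref$statistic))
    if (!res$degenerate) expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  }

  # all values identical -> flagged degenerate
  res <- mann_whitney(c(1, 1), c(1, 1, 1))
  expect_true(res$degenerate)
  expect_true(is.na(res$z))
})

test_that("Mantel correlation and permutation p behave as designed", {
  set.seed(10)
  d <- as.matrix(stats::dist(matrix(rnorm(12), 6)))
  res <- mantel_test(d, 2 * d, n_perm = 199, seed = 1)
  expect_equal(res$r, 1)
  # near the smallest attainable p; permutation draws that happen to fix the
  # matrix also reach |r| = 1, so allow a couple of ties
  expect_lte(res$p, 3 / 200)

  # exhaustive-permutation oracle at n = 4: compare against all 24 relabelings
  d1 <- as.matrix(stats::dist(matrix(rnorm(8), 4)))
  d2 <- as.matrix(stats::dist(matrix(rnorm(8), 4)))
  res <- mantel_test(d1, d2, n_perm = 999, seed = 2)
  perms <- rbind(1:4)
  allp <- expand.grid(1:4, 1:4, 1:4, 1:4)
  allp <- as.matrix(allp[apply(allp, 1, function(x) length(unique(x)) == 4), ])
  ut <- upper.tri(d1)
  rs <- apply(allp, 1, function(pm) stats::cor(d1[ut], d2[pm, pm][ut]))
  expect_equal(res$r, stats::cor(d1[ut], d2[ut]))
  p_exact <- mean(abs(rs) >= abs(res$r))
  expect_lt(abs(res$p - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 999))

  # independent cross-check against the community implementation
  ref <- vegan::mantel(d1, d2, permutations = 0)
  expect_equal(res$r, unname(ref$statistic), tolerance = 1e-12)

  # constant matrix flagged
  res <- mantel_test(matrix(0, 3, 3), d1[1:3, 1:3], n_perm = 9)
  expect_true(res$degenerate)
})

test_that("relatedness estimator and pruning follow the half-sib threshold logic", {
  # duplicated genotype column: r ~ 1 and one of the pair removed
  base <- random_gt(30, 800, seed = 12)
  calls <- rbind(base$calls, base$calls[1, ])
  gt <- toy_gt(calls, samples = c(base$samples, "s01_dup"))
  pr <- relatedness_prune(gt, 0.25)
  expect_gt(pr$relatedness["s01", "s01_dup"], 0.9)
  expect_true(any(c("s01", "s01_dup") %in% pr$removed))

  # parent-offspring by Mendelian transmission: r within 0.05 of 0.5
  set.seed(13)
  m <- 5000
  p <- runif(m, 0.1, 0.9)
  parent <- rbinom(m, 2, p)
  transmitted <- ifelse(parent == 0, 0L,
                        ifelse(parent == 2, 1L, rbinom(m, 1, 0.5)))
  child <- transmitted + rbinom(m, 1, p)
  panel <- t(vapply(1:100, function(i) rbinom(m, 2, p), integer(m)))
  gt <- toy_gt(rbind(parent, child, panel),
               samples = c("par", "kid", sprintf("u%03d", 1:100)))
  pr <- relatedness_prune(gt, 0.25)
  expect_lt(abs(pr$relatedness["par", "kid"] - 0.5), 0.05)
  # unrelated panel: no false removals beyond the true pair
  expect_true(all(pr$removed %in% c("par", "kid")))

  # idempotence: pruning the pruned table removes nobody
  gt2 <- subset_genotypes(gt, samples = pr$kept)
  expect_length(relatedness_prune(gt2, 0.25)$removed, 0)

  expect_error(relatedness_prune(gt, 0), "threshold")
})

test_that("PCA proportions are exact on analytic cases and well-formed", {
  # one varying variable
  x <- cbind(rnorm(20), rep(1, 20))
  res <- pca(x, standardize = TRUE)  # constant column dropped
  expect_equal(res$proportion[1], 1)

  # sample covariance exactly [[2,1],[1,2]] -> eigenvalues 3, 1
  set.seed(14)
  raw <- matrix(rnorm(40), 20)
  raw <- scale(raw, scale = FALSE)
  w <- raw %*% solve(chol(stats::cov(raw)))        # identity sample cov
  x <- w %*% chol(matrix(c(2, 1, 1, 2), 2))
  res <- pca(x, standardize = FALSE)
  expect_equal(res$proportion, c(3, 1) / 4, tolerance = 1e-10)

  res <- pca(matrix(rnorm(60), 12), standardize = TRUE)
  expect_equal(sum(res$proportion), 1, tolerance = 1e-9)
  expect_true(all(diff(res$proportion) <= 1e-12))
  expect_error(pca(matrix(1, 1, 3)), "observations")
})

test_that("corr_r2 equals the closed-form least-squares solution", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(suppressWarnings(corr_r2(x, 3 * x + 1)$r_squared), 1)
  set.seed(15)
  y <- 2 * x + rnorm(5)
  res <- corr_r2(x, y)
  sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
  expect_equal(res$slope, sxy / sxx)
  expect_equal(res$intercept, mean(y) - res$slope * mean(x))
  expect_equal(res$r_squared, stats::cor(x, y)^2)
  expect_error(corr_r2(rep(1, 5), y), "variance")
})
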