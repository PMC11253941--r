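#' Per-site alternate-allele frequencies with a call-rate filter
#'
#' @param gt a [genotype_table].
#' @param min_call_fraction minimum fraction of samples with a non-missing
#'   call for a site to be retained (e.g. 0.8 to keep sites called in at
#'   least 80% of individuals).
#' @return data.frame with one row per site: `site_id`, `freq` (alt-allele
#'   frequency over non-missing calls; `NA` when no calls), `call_fraction`,
#'   and logical `excluded` (below the call-rate threshold or uncallable).
#' @export
allele_frequencies <- function(gt, min_call_fraction = 0) {
  stopifnot(min_call_fraction >= 0, min_call_fraction <= 1)
  n <- length(gt$samples)
  called <- colSums(!is.na(gt$calls))
  freq <- ifelse(called > 0, colSums(gt$calls, na.rm = TRUE) / (2 * called),
                 NA_real_)
  cf <- called / n
  data.frame(site_id = gt$sites$id, freq = freq, call_fraction = cf,
             excluded = cf < min_call_fraction | called == 0,
             stringsAsFactors = FALSE)
}

#' Pairwise Weir-Cockerham F_ST between two populations
#'
#' Computes the Weir & Cockerham (1984) variance-component estimator theta for
#' each site, using observed heterozygote counts, and the multi-site value as
#' the ratio of summed components, sum(a) / sum(a + b + c). Per-site negative
#' values are retained. Sites where the denominator is undefined (e.g. no
#' calls in a population, or a + b + c = 0) are excluded and counted.
#'
#' @param gtA,gtB [genotype_table]s for the two populations over the same
#'   site set.
#' @return an object of class `fst_result`: list with `per_site` (data.frame
#'   of `site_id`, `a`, `b`, `c`, `theta`), `theta` (multi-site), and
#'   `n_excluded`.
#' @export
pairwise_wc_fst <- function(gtA, gtB) {
  if (!identical(gtA$sites$id, gtB$sites$id))
    stop("tables must share the same site set")
  comp <- wc_components(gtA$calls, gtB$calls)
  denom <- comp$a + comp$b + comp$c
  ok <- is.finite(denom) & denom != 0
  if (!any(ok)) stop("no informative sites for F_ST")
  per_site <- data.frame(site_id = gtA$sites$id, a = comp$a, b = comp$b,
                         c = comp$c,
                         theta = ifelse(ok, comp$a / denom, NA_real_),
                         stringsAsFactors = FALSE)
  structure(list(per_site = per_site,
                 theta = sum(comp$a[ok]) / sum(denom[ok]),
                 n_excluded = sum(!ok)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F_ST: theta = %.4f over %d sites (%d excluded)\n",
              x$theta, sum(!is.na(x$per_site$theta)), x$n_excluded))
  invisible(x)
}

# Weir & Cockerham (1984) a, b, c components for two populations (r = 2)
wc_components <- function(callsA, callsB) {
  r <- 2
  nA <- colSums(!is.na(callsA)); nB <- colSums(!is.na(callsB))
  pA <- ifelse(nA > 0, colSums(callsA, na.rm = TRUE) / (2 * nA), NA_real_)
  pB <- ifelse(nB > 0, colSums(callsB, na.rm = TRUE) / (2 * nB), NA_real_)
  hA <- ifelse(nA > 0, colSums(callsA == 1L, na.rm = TRUE) / nA, NA_real_)
  hB <- ifelse(nB > 0, colSums(callsB == 1L, na.rm = TRUE) / nB, NA_real_)
  nbar <- (nA + nB) / r
  # sample-size variation correction
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c <- hbar / 2
  bad <- !is.finite(pA) | !is.finite(pB) | nA < 2 | nB < 2 | !is.finite(nc) |
    nc <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; c[bad] <- NA_real_
  list(a = a, b = b, c = c)
}

#' Mean pairwise multi-site F_ST over the populations of a transect
#'
#' Splits a genotype table by a population label, computes the multi-site
#' Weir-Cockerham theta for every unordered pair, and returns the matrix of
#' pairwise values together with their unweighted mean.
#'
#' @param gt a [genotype_table].
#' @param populations population label per sample (recycled against
#'   `gt$samples`).
#' @return list: `pairs` (data.frame popA, popB, theta), `matrix` (symmetric),
#'   `mean` (unweighted mean over pairs).
#' @export
fst_matrix <- function(gt, populations) {
  populations <- as.character(populations)
  stopifnot(length(populations) == length(gt$samples))
  pops <- unique(populations)
  if (length(pops) < 2) stop("need >= 2 populations")
  tabs <- lapply(pops, function(p)
    subset_genotypes(gt, samples = which(populations == p)))
  names(tabs) <- pops
  prs <- utils::combn(pops, 2)
  theta <- apply(prs, 2L, function(pr)
    pairwise_wc_fst(tabs[[pr[1]]], tabs[[pr[2]]])$theta)
  m <- matrix(NA_real_, length(pops), length(pops), dimnames = list(pops, pops))
  diag(m) <- 0
  for (j in seq_len(ncol(prs))) {
    m[prs[1, j], prs[2, j]] <- theta[j]
    m[prs[2, j], prs[1, j]] <- theta[j]
  }
  list(pairs = data.frame(popA = prs[1, ], popB = prs[2, ], theta = theta,
                          stringsAsFactors = FALSE),
       matrix = m, mean = mean(theta))
}

#' Mann-Whitney U test (normal approximation with tie correction)
#'
#' U is computed from midrank sums; the z-score uses the tie-corrected null
#' variance and the two-sided p comes from the normal approximation (no
#' continuity correction).
#'
#' @param valuesA,valuesB numeric vectors (both non-empty).
#' @return list of class `mann_whitney_result`: `U` (for group A), `z`,
#'   `p` (two-sided), `tie_corrected`, and `degenerate` (TRUE when all values
#'   are identical, in which case `z` and `p` are `NA`).
#' @export
mann_whitney <- function(valuesA, valuesB) {
  stopifnot(length(valuesA) > 0, length(valuesB) > 0)
  n1 <- length(valuesA); n2 <- length(valuesB); N <- n1 + n2
  rk <- rank(c(valuesA, valuesB))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(valuesA, valuesB))
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  degenerate <- v <= 0
  z <- if (degenerate) NA_real_ else (U - mu) / sqrt(v)
  p <- if (degenerate) NA_real_ else 2 * stats::pnorm(-abs(z))
  structure(list(U = U, z = z, p = p, tie_corrected = tie_term > 0,
                 degenerate = degenerate, n1 = n1, n2 = n2),
            class = "mann_whitney_result")
}

#' @export
print.mann_whitney_result <- function(x, ...) {
  if (x$degenerate)
    cat("Mann-Whitney U =", x$U, "(all values identical; z undefined)\n")
  else
    cat(sprintf("Mann-Whitney U = %.1f, z = %.3f, two-sided p = %.3g\n",
                x$U, x$z, x$p))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' r is the Pearson correlation of the upper off-diagonal triangles; the
#' empirical two-sided p applies simultaneous row/column permutations to the
#' second matrix and uses the add-one estimator
#' (1 + #\{|r*| >= |r|\}) / (n_perm + 1).
#'
#' @param dist1,dist2 symmetric matrices of equal order >= 3 with zero
#'   diagonals.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations.
#' @return list of class `mantel_result`: `r`, `r_squared`, `p`,
#'   `n_perm`, and `degenerate` (constant matrix; `r` undefined).
#' @export
mantel_test <- function(dist1, dist2, n_perm = 999, seed = 1L) {
  stopifnot(is.matrix(dist1), is.matrix(dist2),
            nrow(dist1) == ncol(dist1), identical(dim(dist1), dim(dist2)),
            nrow(dist1) >= 3)
  if (max(abs(dist1 - t(dist1))) > 1e-8 || max(abs(dist2 - t(dist2))) > 1e-8)
    stop("matrices must be symmetric")
  ut <- upper.tri(dist1)
  x <- dist1[ut]
  if (stats::sd(x) == 0 || stats::sd(dist2[ut]) == 0)
    return(structure(list(r = NA_real_, r_squared = NA_real_, p = NA_real_,
                          n_perm = n_perm, degenerate = TRUE),
                     class = "mantel_result"))
  robs <- stats::cor(x, dist2[ut])
  n <- nrow(dist1)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    pm <- sample.int(n)
    rp <- stats::cor(x, dist2[pm, pm][ut])
    if (abs(rp) >= abs(robs) - 1e-12) hits <- hits + 1L
  }
  structure(list(r = robs, r_squared = robs^2,
                 p = (1 + hits) / (n_perm + 1), n_perm = n_perm,
                 degenerate = FALSE),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  if (x$degenerate) cat("Mantel test: constant matrix, r undefined\n")
  else cat(sprintf("Mantel r = %.4f (R^2 = %.4f), p = %.4g (%d permutations)\n",
                   x$r, x$r_squared, x$p, x$n_perm))
  invisible(x)
}

#' Pairwise relatedness and greedy relative pruning
#'
#' The relatedness estimate for samples i, j is the standardized-genotype
#' moment estimator
#' \deqn{\hat r_{ij} = \frac{1}{m}\sum_s \frac{(x_{is}-2p_s)(x_{js}-2p_s)}
#'   {2p_s(1-p_s)}}{r_ij = mean_s (x_is-2p_s)(x_js-2p_s)/(2 p_s (1-p_s))}
#' over pairwise-complete sites, which is approximately 1 for duplicates,
#' 0.5 for parent-offspring or full sibs, and 0.25 for half sibs. For every
#' pair above `threshold`, the member with more missing data is removed
#' (ties broken by lexicographic sample id), scanning pairs in deterministic
#' sample-id order.
#'
#' @param gt a [genotype_table].
#' @param threshold relatedness cut-off in (0, 1]; the conventional 0.25
#'   (half-sib) value flags close relatives.
#' @return list: `relatedness` (symmetric matrix), `kept` (sample ids),
#'   `removed` (sample ids).
#' @export
relatedness_prune <- function(gt, threshold = 0.25) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (length(gt$samples) < 2) stop("need >= 2 samples")
  p <- colMeans(gt$calls, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  X <- gt$calls[, keep, drop = FALSE]
  p <- p[keep]
  Zc <- sweep(X, 2L, 2 * p)
  W <- !is.na(Zc)
  Zc[!W] <- 0
  den <- 2 * p * (1 - p)
  # r_ij = mean over shared sites of z_is z_js / (2 p_s (1 - p_s))
  Zs <- sweep(Zc, 2L, sqrt(den), "/")
  num <- Zs %*% t(Zs)
  m_shared <- W %*% t(W)
  R <- num / pmax(m_shared, 1)
  dimnames(R) <- list(gt$samples, gt$samples)
  n_missing <- rowSums(is.na(gt$calls))
  names(n_missing) <- gt$samples
  ord <- order(gt$samples)
  removed <- character(0)
  ids <- gt$samples[ord]
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    a <- ids[i]; b <- ids[j]
    if (a %in% removed || b %in% removed) next
    if (R[a, b] > threshold) {
      drop_id <- if (n_missing[a] > n_missing[b]) a
      else if (n_missing[b] > n_missing[a]) b
      else max(a, b)  # lexicographic tie-break: later id goes
      removed <- c(removed, drop_id)
    }
  }
  list(relatedness = R, kept = setdiff(gt$samples, removed), removed = removed)
}

#' Principal component analysis with variance proportions
#'
#' Thin wrapper around [stats::prcomp] that drops zero-variance variables
#' when standardizing and returns scores plus the proportion of variance per
#' component (non-increasing, summing to 1).
#'
#' @param x observations x variables numeric matrix or data.frame.
#' @param standardize scale each variable to unit variance.
#' @return list: `scores` (observations x components), `proportion`
#'   (variance proportion per component), `sdev`.
#' @export
pca <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need >= 2 observations")
  if (standardize) {
    v <- apply(x, 2L, stats::var)
    x <- x[, v > 0, drop = FALSE]
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = standardize)
  prop <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x, proportion = prop, sdev = pr$sdev)
}

#' Simple linear fit with R-squared
#'
#' Ordinary least squares of y on x; R^2 equals the squared Pearson
#' correlation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list: `slope`, `intercept`, `r_squared`, `p` (slope t-test).
#' @export
corr_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p = unname(s$coefficients[2, 4]))
}
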