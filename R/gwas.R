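#' Kinship (genetic relationship) matrix
#'
#' Standardizes each polymorphic site by its mean (2p) and binomial s.d.
#' (sqrt(2p(1-p))), sets missing entries to 0 after centering, and returns
#' K = Z Z' / m over the m retained sites: the usual genetic relationship
#' matrix used as random-effect covariance in mixed-model association.
#'
#' @param gt a [genotype_table] with >= 2 samples.
#' @return symmetric samples x samples matrix (positive semi-definite up to
#'   numerical noise), with attribute `"n_sites"`.
#' @export
kinship_matrix <- function(gt) {
  if (length(gt$samples) < 2) stop("need >= 2 samples")
  Z <- standardize_genotypes(gt)
  if (ncol(Z) == 0) stop("no polymorphic sites")
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(gt$samples, gt$samples)
  attr(K, "n_sites") <- ncol(Z)
  K
}

# REML for y = W a + u + e, u ~ N(0, sg2 K), e ~ N(0, se2 I), via the
# spectral decomposition of S K S (S the projection off W). Returns the
# variance ratio delta = se2/sg2 and the components.
reml_null <- function(y, W, K) {
  n <- length(y)
  c <- ncol(W)
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < -1e-6) {
    warning("kinship matrix not PSD; clipping negative eigenvalues at 0")
    ev$values <- pmax(ev$values, 0)
    K <- ev$vectors %*% (ev$values * t(ev$vectors))
  }
  S <- diag(n) - W %*% solve(crossprod(W), t(W))
  es <- eigen(S %*% K %*% S, symmetric = TRUE)
  q <- n - c
  xi <- pmax(es$values[seq_len(q)], 0)
  eta <- as.numeric(crossprod(es$vectors[, seq_len(q), drop = FALSE], y))
  negll <- function(logd) {
    d <- exp(logd)
    r <- eta^2 / (xi + d)
    -0.5 * (q * log(q / (2 * pi)) - q - q * log(sum(r)) - sum(log(xi + d)))
  }
  opt <- stats::optimize(negll, interval = c(log(1e-5), log(1e5)))
  delta <- exp(opt$minimum)
  sg2 <- sum(eta^2 / (xi + delta)) / q
  list(delta = delta, sigma_g2 = sg2, sigma_e2 = delta * sg2,
       h2 = 1 / (1 + delta), K = K, reml_ll = -opt$objective)
}

#' Mixed-model association scan for a quantitative phenotype
#'
#' Single-random-effect linear mixed model y = W a + x b + u + e with
#' u ~ N(0, sg2 K): the variance ratio is estimated once under the null by
#' REML on the spectral decomposition of the kinship matrix, then each SNP is
#' tested by generalized least squares with a Wald test (the usual
#' one-variance-component approximation that re-uses the null variance ratio
#' across SNPs). SNPs are filtered by minor-allele frequency and missingness;
#' at a tested SNP, samples with a missing dosage are dropped (exact
#' subset-covariance GLS, not imputation). Benjamini-Hochberg FDR is applied
#' across tested SNPs.
#'
#' @param phenotype numeric vector, one value per sample of `gt` (no NA).
#' @param covariates data.frame or matrix of covariates (e.g. a sex
#'   indicator); an intercept is always added.
#' @param gt a [genotype_table].
#' @param kin kinship matrix from [kinship_matrix] (or any PSD matrix; an
#'   identity reduces the model to ordinary regression).
#' @param min_maf minimum minor-allele frequency (default 0.05).
#' @param max_missing maximum per-site missing fraction (default 0.10).
#' @param fdr_threshold significance level on q-values (default 0.05).
#' @return object of class `gwas_fit`: `table` (per tested SNP: `site_id`,
#'   `chrom`, `pos`, `n`, `effect`, `se`, `p`, `q`, `significant`), `vc`
#'   (REML variance components: `sigma_g2`, `sigma_e2`, `h2`, `delta`),
#'   `filters`.
#' @export
lmm_association <- function(phenotype, covariates, gt, kin,
                            min_maf = 0.05, max_missing = 0.10,
                            fdr_threshold = 0.05) {
  n <- length(gt$samples)
  stopifnot(length(phenotype) == n, !anyNA(phenotype))
  W <- cbind(intercept = rep(1, n), as.matrix(covariates))
  storage.mode(W) <- "double"
  if (qr(W)$rank < ncol(W)) stop("singular covariate design")
  stopifnot(nrow(kin) == n, ncol(kin) == n)

  af <- allele_frequencies(gt, 1 - max_missing)
  maf <- pmin(af$freq, 1 - af$freq)
  keep <- !af$excluded & !is.na(maf) & maf >= min_maf
  if (!any(keep)) stop("no SNPs pass the filters")
  X <- gt$calls[, keep, drop = FALSE]
  sites <- gt$sites[keep, , drop = FALSE]

  vc <- reml_null(phenotype, W, kin)
  delta <- vc$delta
  K <- vc$K

  ev <- eigen(K, symmetric = TRUE)
  U <- ev$vectors
  w <- 1 / (pmax(ev$values, 0) + delta)
  sw <- sqrt(w)
  yt <- sw * as.numeric(crossprod(U, phenotype))
  Wt <- sw * crossprod(U, W)
  # residualize on covariates once (Frisch-Waugh): shared across SNPs
  Qw <- qr(Wt)
  yr <- stats::residuals(stats::lm.fit(Wt, yt))
  c_ <- ncol(W)
  df <- n - c_ - 1

  m <- ncol(X)
  effect <- se <- pval <- rep(NA_real_, m)
  nn <- integer(m)
  complete <- !apply(X, 2L, anyNA)
  if (any(complete)) {
    Xt <- sw * crossprod(U, X[, complete, drop = FALSE])
    Xr <- Xt - Wt %*% qr.coef(Qw, Xt)
    sxx <- colSums(Xr^2)
    sxy <- as.numeric(crossprod(Xr, yr))
    b <- sxy / sxx
    rss <- sum(yr^2) - b^2 * sxx
    s2 <- rss / df
    effect[complete] <- b
    se[complete] <- sqrt(s2 / sxx)
    pval[complete] <- 2 * stats::pt(-abs(b / sqrt(s2 / sxx)), df)
    nn[complete] <- n
  }
  for (j in which(!complete)) {
    obs <- !is.na(X[, j])
    ns <- sum(obs)
    if (ns <= ncol(W) + 1) next
    Vs <- K[obs, obs] + delta * diag(ns)
    L <- chol(Vs)
    ys <- backsolve(L, phenotype[obs], transpose = TRUE)
    Ds <- backsolve(L, cbind(W[obs, , drop = FALSE], X[obs, j]),
                    transpose = TRUE)
    fit <- stats::lm.fit(Ds, ys)
    cf <- fit$coefficients
    dfj <- ns - length(cf)
    s2j <- sum(fit$residuals^2) / dfj
    XtXinv <- chol2inv(qr.R(fit$qr))
    sej <- sqrt(s2j * XtXinv[length(cf), length(cf)])
    effect[j] <- cf[length(cf)]
    se[j] <- sej
    pval[j] <- 2 * stats::pt(-abs(effect[j] / sej), dfj)
    nn[j] <- ns
  }
  ok <- !is.na(pval)
  qv <- rep(NA_real_, m)
  qv[ok] <- stats::p.adjust(pval[ok], "BH")
  tab <- data.frame(site_id = sites$id, chrom = sites$chrom, pos = sites$pos,
                    n = nn, effect = effect, se = se, p = pval, q = qv,
                    significant = !is.na(qv) & qv <= fdr_threshold,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 vc = vc[c("sigma_g2", "sigma_e2", "h2", "delta")],
                 filters = list(min_maf = min_maf, max_missing = max_missing,
                                fdr_threshold = fdr_threshold)),
            class = "gwas_fit")
}

#' @export
print.gwas_fit <- function(x, ...) {
  cat(sprintf(
    "gwas_fit: %d SNPs tested, %d significant at FDR <= %g; h2 = %.2f\n",
    nrow(x$table), sum(x$table$significant, na.rm = TRUE),
    x$filters$fdr_threshold, x$vc$h2))
  invisible(x)
}

#' @export
summary.gwas_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  variance components: sigma_g2 = %.3f, sigma_e2 = %.3f\n",
              object$vc$sigma_g2, object$vc$sigma_e2))
  hit <- object$table[object$table$significant %in% TRUE, ]
  if (nrow(hit)) {
    cat("  significant SNPs:\n")
    print(hit[order(hit$p), c("site_id", "effect", "se", "p", "q")],
          row.names = FALSE)
  }
  invisible(object)
}

#' Manhattan-style plot of a GWAS
#' @param x a `gwas_fit`.
#' @param ... passed to [graphics::plot].
#' @export
plot.gwas_fit <- function(x, ...) {
  tab <- x$table
  chr <- factor(tab$chrom, levels = unique(tab$chrom))
  off <- c(0, cumsum(tapply(tab$pos, chr, max)))[as.integer(chr)]
  graphics::plot(off + tab$pos, -log10(tab$p),
                 col = c("grey30", "steelblue")[1 + (as.integer(chr) %% 2)],
                 pch = 20, xlab = "genome position",
                 ylab = expression(-log[10](p)), main = "GWAS", ...)
  graphics::points((off + tab$pos)[tab$significant],
                   -log10(tab$p)[tab$significant], col = "firebrick", pch = 20)
  invisible(x)
}

#' Permutation overlap test between GWAS genes and scan candidate genes
#'
#' Same resampling engine as [overlap_permutation_test], with both sets drawn
#' from a common tested-gene universe.
#'
#' @param gwas_genes,scan_genes candidate gene sets.
#' @param universe common tested-gene universe containing both sets.
#' @param n_replicates,seed see [overlap_permutation_test].
#' @return an `overlap_test`.
#' @export
gwas_scan_overlap <- function(gwas_genes, scan_genes, universe,
                              n_replicates = 1000, seed = 1L) {
  overlap_permutation_test(list(gwas_genes, scan_genes),
                           list(universe, universe),
                           n_replicates = n_replicates, seed = seed)
}
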