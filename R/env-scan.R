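#' Scan configuration
#'
#' Thresholds and model size for the genotype-environment association scan.
#'
#' @param K number of latent factors absorbing neutral population structure
#'   (0 = plain regression). Typical choices follow the number of genetic
#'   clusters along a transect minus one (e.g. 2 or 3).
#' @param q_threshold q-value cut-off for outlier calling (0.01 for a
#'   headline single-transect scan, 0.05 for cross-transect comparisons).
#' @param z_threshold minimum |z-score| for outlier calling.
#' @param min_maf minimum minor-allele frequency for a site to be tested.
#' @param min_call_fraction minimum fraction of called genotypes per site.
#' @return a list of class `scan_config`.
#' @export
scan_config <- function(K = 2, q_threshold = 0.05, z_threshold = 2,
                        min_maf = 0.05, min_call_fraction = 0.8) {
  stopifnot(K >= 0, q_threshold > 0, q_threshold <= 1, z_threshold > 0,
            min_maf >= 0, min_maf < 0.5,
            min_call_fraction >= 0, min_call_fraction <= 1)
  structure(list(K = as.integer(K), q_threshold = q_threshold,
                 z_threshold = z_threshold, min_maf = min_maf,
                 min_call_fraction = min_call_fraction),
            class = "scan_config")
}

#' Fit the latent-factor association model
#'
#' Deterministic least-squares analogue of a latent factor mixed model:
#' sites are filtered by call rate and minor-allele frequency, missing
#' dosages are mean-imputed per site, the genotype matrix is projected off
#' the (standardized) environmental covariate, and the leading K left
#' singular vectors of the residual matrix become the latent factor scores.
#' Per-site environmental effects are then re-estimated jointly with the
#' factors by multiple regression, giving z = effect / s.e. with
#' n - K - 2 residual degrees of freedom.
#'
#' @param gt a [genotype_table].
#' @param env numeric environmental value per sample (no missing values).
#' @param config a [scan_config].
#' @return an object of class `latent_scan`: list with `factors` (samples x
#'   K, orthonormal columns), `loadings` (sites x K), `effect`, `se`, `z`
#'   per tested site, `site_id`, `df`, `config` and `n_filtered`.
#' @export
fit_latent_scan <- function(gt, env, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  n <- length(gt$samples)
  if (length(env) != n) stop("env length must match sample count")
  if (anyNA(env)) stop("env must have no missing values")
  if (stats::var(env) == 0) stop("constant environmental variable")
  if (config$K >= n) stop("K must be smaller than the sample count")

  af <- allele_frequencies(gt, config$min_call_fraction)
  maf <- pmin(af$freq, 1 - af$freq)
  keep <- !af$excluded & !is.na(maf) & maf >= config$min_maf
  if (!any(keep)) stop("no sites pass the filters")
  Y <- gt$calls[, keep, drop = FALSE]
  mu <- colMeans(Y, na.rm = TRUE)
  idx <- which(is.na(Y), arr.ind = TRUE)
  if (nrow(idx)) Y[idx] <- mu[idx[, 2]]

  x <- as.numeric(scale(env))
  W <- cbind(1, x)
  H <- W %*% solve(crossprod(W), t(W))
  M <- Y - H %*% Y
  K <- config$K
  if (K > 0) {
    sv <- svd(M, nu = K, nv = 0)
    U <- sv$u[, seq_len(K), drop = FALSE]
  } else U <- matrix(0, n, 0)

  D <- cbind(W, U)
  q <- ncol(D)
  DtDinv <- solve(crossprod(D))
  B <- DtDinv %*% crossprod(D, Y)            # q x p coefficients
  res <- Y - D %*% B
  df <- n - q
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * DtDinv[2, 2])
  effect <- B[2, ]
  z <- ifelse(se > 0, effect / se, 0)
  loadings <- if (K > 0) t(B[-(1:2), , drop = FALSE]) else
    matrix(0, sum(keep), 0)
  structure(list(factors = U, loadings = loadings,
                 effect = unname(effect), se = unname(se), z = unname(z),
                 site_id = gt$sites$id[keep], df = df, config = config,
                 n_filtered = sum(!keep)),
            class = "latent_scan")
}

#' @export
print.latent_scan <- function(x, ...) {
  cat("latent_scan: K =", x$config$K, ",", length(x$z), "sites tested,",
      x$n_filtered, "filtered\n")
  invisible(x)
}

#' Genomic-inflation calibration and FDR q-values
#'
#' The genomic inflation factor is lambda = median(z^2) / 0.4549 (the median
#' of a 1-d.f. chi-square). Calibrated p-values are the upper chi-square tail
#' of z^2 / lambda; q-values come from the Benjamini-Hochberg step-up
#' procedure on the calibrated p-values. When every z is zero, lambda = 0 is
#' flagged and no calibration is applied (raw p returned).
#'
#' @param z numeric vector of at least two finite z-scores.
#' @return list: `lambda`, `p_raw`, `p_cal`, `q`, `degenerate`.
#' @export
calibrate_pvalues <- function(z) {
  z <- as.numeric(z)
  if (sum(is.finite(z)) < 2) stop("need >= 2 finite z-scores")
  z2 <- z^2
  p_raw <- stats::pchisq(z2, df = 1, lower.tail = FALSE)
  lambda <- stats::median(z2, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
  if (lambda == 0) {
    return(list(lambda = 0, p_raw = p_raw, p_cal = p_raw,
                q = stats::p.adjust(p_raw, "BH"), degenerate = TRUE))
  }
  p_cal <- stats::pchisq(z2 / lambda, df = 1, lower.tail = FALSE)
  list(lambda = lambda, p_raw = p_raw, p_cal = p_cal,
       q = stats::p.adjust(p_cal, "BH"), degenerate = FALSE)
}

#' Run a genotype-environment association scan
#'
#' Convenience wrapper: [fit_latent_scan] then [calibrate_pvalues], returning
#' the per-site scan table.
#'
#' @param gt a [genotype_table].
#' @param env numeric environmental value per sample.
#' @param config a [scan_config].
#' @param variable label for the environmental variable (for reporting).
#' @return object of class `scan_result`: list with `table` (data.frame:
#'   `site_id`, `chrom`, `pos`, `effect`, `z`, `p_raw`, `p_cal`, `q`,
#'   `candidate`), `lambda`, `variable`, `config`, `model`.
#' @export
env_scan <- function(gt, env, config = scan_config(), variable = "env") {
  fit <- fit_latent_scan(gt, env, config)
  cal <- calibrate_pvalues(fit$z)
  m <- match(fit$site_id, gt$sites$id)
  tab <- data.frame(site_id = fit$site_id,
                    chrom = gt$sites$chrom[m], pos = gt$sites$pos[m],
                    effect = fit$effect, z = fit$z,
                    p_raw = cal$p_raw, p_cal = cal$p_cal, q = cal$q,
                    stringsAsFactors = FALSE)
  tab$candidate <- tab$q <= config$q_threshold &
    abs(tab$z) >= config$z_threshold
  structure(list(table = tab, lambda = cal$lambda, variable = variable,
                 config = config, model = fit),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "scan_result [%s]: %d sites, lambda = %.3f, %d candidates (q <= %g, |z| >= %g)\n",
    x$variable, nrow(x$table), x$lambda, sum(x$table$candidate),
    x$config$q_threshold, x$config$z_threshold))
  invisible(x)
}

#' @export
summary.scan_result <- function(object, ...) {
  tab <- object$table
  cat("Genotype-environment association scan:", object$variable, "\n")
  cat("  sites tested:   ", nrow(tab), "\n")
  cat(sprintf("  lambda:          %.3f\n", object$lambda))
  cat("  candidates:     ", sum(tab$candidate), "\n")
  if (any(tab$candidate)) {
    top <- tab[order(tab$p_cal, tab$chrom, tab$pos), ][1:min(5, sum(tab$candidate)), ]
    cat("  top sites:\n")
    print(top[, c("site_id", "effect", "z", "p_cal", "q")], row.names = FALSE)
  }
  invisible(object)
}

#' Manhattan-style plot of a scan
#' @param x a `scan_result`.
#' @param ... passed to [graphics::plot].
#' @export
plot.scan_result <- function(x, ...) {
  tab <- x$table
  chr <- factor(tab$chrom, levels = unique(tab$chrom))
  off <- c(0, cumsum(tapply(tab$pos, chr, max)))[as.integer(chr)]
  graphics::plot(off + tab$pos, -log10(tab$p_cal),
                 col = c("grey30", "steelblue")[1 + (as.integer(chr) %% 2)],
                 pch = 20, xlab = "genome position",
                 ylab = expression(-log[10](p)),
                 main = paste("Scan:", x$variable), ...)
  graphics::points((off + tab$pos)[tab$candidate],
                   -log10(tab$p_cal)[tab$candidate], col = "firebrick",
                   pch = 20)
  invisible(x)
}

#' Call outlier SNPs from a scan
#'
#' A site is a candidate iff q <= `q_threshold` and |z| >= `z_threshold`.
#'
#' @param scan a `scan_result`.
#' @param q_threshold,z_threshold thresholds; default to the scan's config.
#' @return character vector of candidate site ids.
#' @export
call_outliers <- function(scan, q_threshold = NULL, z_threshold = NULL) {
  stopifnot(inherits(scan, "scan_result"))
  qt <- if (is.null(q_threshold)) scan$config$q_threshold else q_threshold
  zt <- if (is.null(z_threshold)) scan$config$z_threshold else z_threshold
  tab <- scan$table
  tab$site_id[tab$q <= qt & abs(tab$z) >= zt]
}
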