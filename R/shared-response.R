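#' Permutation test for candidate-set overlap
#'
#' Observed statistic: size of the intersection of two (or three) candidate
#' gene sets. Each replicate draws |set| genes uniformly *with replacement*
#' from the corresponding tested-gene universe (duplicate draws collapse) and
#' records the intersection size. Returns the permutation z-score and the
#' add-one empirical p for the enrichment direction.
#'
#' @param sets list of 2 or 3 character vectors of candidate gene ids.
#' @param universes list (same length) of tested-gene universes; each set
#'   must be a subset of its universe.
#' @param n_replicates number of permutation replicates.
#' @param seed integer seed.
#' @param alternative `"greater"` (overlap larger than chance, the default)
#'   or `"less"`.
#' @return object of class `overlap_test`: `observed`, `null_mean`,
#'   `null_sd`, `z` (`NA` when the null s.d. is 0, flagged by
#'   `z_undefined`), `p` (add-one empirical), `n_replicates`.
#' @export
overlap_permutation_test <- function(sets, universes, n_replicates = 1000,
                                     seed = 1L,
                                     alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(is.list(sets), is.list(universes),
            length(sets) == length(universes),
            length(sets) %in% c(2L, 3L))
  for (i in seq_along(sets))
    if (!all(sets[[i]] %in% universes[[i]]))
      stop("set ", i, " is not a subset of its universe")
  obs <- length(Reduce(intersect, sets))
  sizes <- lengths(sets)
  set.seed(seed)
  null <- vapply(seq_len(n_replicates), function(b) {
    draws <- lapply(seq_along(sets), function(i)
      unique(sample(universes[[i]], sizes[i], replace = TRUE)))
    length(Reduce(intersect, draws))
  }, numeric(1))
  mu <- mean(null); sdv <- stats::sd(null)
  z <- if (sdv > 0) (obs - mu) / sdv else NA_real_
  hits <- if (alternative == "greater") sum(null >= obs) else sum(null <= obs)
  structure(list(observed = obs, null_mean = mu, null_sd = sdv, z = z,
                 z_undefined = !(sdv > 0), p = (1 + hits) / (n_replicates + 1),
                 n_replicates = n_replicates, alternative = alternative,
                 seed = seed),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "overlap permutation test: observed = %d, null = %.2f +/- %.2f, z = %s, p = %.4g (%d replicates)\n",
    x$observed, x$null_mean, x$null_sd,
    if (x$z_undefined) "undefined" else sprintf("%.2f", x$z),
    x$p, x$n_replicates))
  invisible(x)
}

#' Allele-frequency shift directions between transect end populations
#'
#' For each requested SNP, compares the alternate-allele frequency in the
#' high-latitude (far-from-equator) end population against the low-latitude
#' end. `direction` is `"up"`/`"down"` by the sign of
#' freq(high) - freq(low) and `"none"` when the frequencies are equal or
#' either end fails the per-population call-rate rule (data for at least
#' `min_call_fraction` of the individuals). Polarization is checked: when
#' ref/alt are swapped between the two tables the dosage is flipped (2 - d);
#' when the alleles differ altogether the SNP is excluded.
#'
#' @param endLow [genotype_table] for the low-latitude end population.
#' @param endHigh [genotype_table] for the high-latitude end population.
#' @param shared_snps site ids to evaluate.
#' @param min_call_fraction per-end call-rate rule (default 0.6).
#' @return data.frame: `site_id`, `freq_low`, `freq_high`, `call_low`,
#'   `call_high`, `direction`; SNPs absent from either table or with
#'   incompatible alleles are dropped, their count in attribute
#'   `"n_excluded"`.
#' @export
shift_directions <- function(endLow, endHigh, shared_snps,
                             min_call_fraction = 0.6) {
  iL <- match(shared_snps, endLow$sites$id)
  iH <- match(shared_snps, endHigh$sites$id)
  present <- !is.na(iL) & !is.na(iH)
  n_excluded <- sum(!present)
  iL <- iL[present]; iH <- iH[present]
  ids <- shared_snps[present]
  # polarization check
  same <- endLow$sites$ref[iL] == endHigh$sites$ref[iH] &
    endLow$sites$alt[iL] == endHigh$sites$alt[iH]
  swapped <- endLow$sites$ref[iL] == endHigh$sites$alt[iH] &
    endLow$sites$alt[iL] == endHigh$sites$ref[iH]
  ok <- same | swapped
  n_excluded <- n_excluded + sum(!ok)
  iL <- iL[ok]; iH <- iH[ok]; ids <- ids[ok]; swapped <- swapped[ok]

  fl <- allele_frequencies(endLow)[iL, ]
  fh <- allele_frequencies(endHigh)[iH, ]
  freq_high <- ifelse(swapped, 1 - fh$freq, fh$freq)
  callable <- fl$call_fraction >= min_call_fraction &
    fh$call_fraction >= min_call_fraction &
    !is.na(fl$freq) & !is.na(freq_high)
  delta <- freq_high - fl$freq
  direction <- rep("none", length(ids))
  direction[callable & delta > 0] <- "up"
  direction[callable & delta < 0] <- "down"
  out <- data.frame(site_id = ids, freq_low = fl$freq, freq_high = freq_high,
                    call_low = fl$call_fraction, call_high = fh$call_fraction,
                    direction = direction, stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' End populations of a transect
#'
#' Returns the population labels at the two extremes of a transect, measured
#' by distance from the equator (absolute latitude), matching the usual
#' high-latitude vs low-latitude end-population contrast.
#'
#' @param samples sample metadata data.frame with `population` and
#'   `latitude` columns.
#' @return list with `low` and `high` population labels.
#' @export
end_populations <- function(samples) {
  lat <- tapply(abs(samples$latitude), samples$population, mean)
  list(low = names(which.min(lat)), high = names(which.max(lat)))
}

#' Gene-level parallel-shift calls across transects
#'
#' A gene is evaluable when in every transect it has at least one shared SNP
#' with a non-"none" direction. Under the default majority rule a gene is
#' concordant when more than half of its evaluable shared SNPs have the same
#' direction in all transects; `"all"` (strict conjunction) requires every
#' SNP to agree and `"any"` requires at least one. With several effectively
#' independent SNPs per gene the conjunction rule drives the genome-wide
#' concordant fraction far below the single-SNP value and erases the signal
#' of genuinely parallel genes, while the majority rule preserves the
#' single-SNP logic (a one-SNP gene behaves identically under all three
#' rules) and lets a selected haplotype outvote unlinked neutral variation.
#'
#' @param shift_tables list of [shift_directions] tables, one per transect
#'   (>= 2).
#' @param assignment SNP-to-gene table ([map_snps_to_genes]).
#' @param rule `"majority"` (default), `"all"` (conjunction) or `"any"`.
#' @return data.frame: `gene_id`, `n_snps` (evaluable shared SNPs),
#'   `n_concordant_snps`, `concordant` (logical).
#' @export
gene_parallel_calls <- function(shift_tables, assignment,
                                rule = c("majority", "all", "any")) {
  rule <- match.arg(rule)
  stopifnot(length(shift_tables) >= 2)
  common <- Reduce(intersect, lapply(shift_tables, `[[`, "site_id"))
  dirs <- sapply(shift_tables, function(tb)
    tb$direction[match(common, tb$site_id)])
  if (length(common) == 1L) dirs <- matrix(dirs, nrow = 1)
  informative <- apply(dirs, 1L, function(d) all(d != "none"))
  snp_concord <- informative &
    apply(dirs, 1L, function(d) length(unique(d)) == 1L)
  # a SNP may map to several overlapping genes; keep every assignment
  asg <- assignment[assignment$site_id %in% common[informative], , drop = FALSE]
  if (nrow(asg) == 0)
    return(data.frame(gene_id = character(0), n_snps = integer(0),
                      n_concordant_snps = integer(0), concordant = logical(0)))
  by_gene <- split(snp_concord[match(asg$site_id, common)], asg$gene_id)
  n_snps <- lengths(by_gene)
  n_conc <- vapply(by_gene, sum, integer(1))
  concord <- switch(rule,
                    all = n_conc == n_snps,
                    any = n_conc >= 1L,
                    majority = n_conc > n_snps / 2)
  data.frame(gene_id = names(by_gene), n_snps = n_snps,
             n_concordant_snps = n_conc, concordant = unname(concord),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Chi-square test of parallel-gene counts against a null fraction
#'
#' One-degree-of-freedom goodness-of-fit chi-square of the observed
#' (parallel, non-parallel) split against the expected fraction (25% for
#' three transects with equiprobable shift directions).
#'
#' @param n_parallel observed parallel genes.
#' @param n_total genes evaluated.
#' @param expected_fraction null probability a gene is parallel.
#' @return list: `chisq`, `p` (upper tail), `expected`, `small_expected`
#'   (TRUE when an expected cell < 1; small-sample caveat).
#' @export
parallel_chisq <- function(n_parallel, n_total, expected_fraction = 0.25) {
  stopifnot(n_total >= 1, n_parallel >= 0, n_parallel <= n_total,
            expected_fraction > 0, expected_fraction < 1)
  E <- c(n_total * expected_fraction, n_total * (1 - expected_fraction))
  O <- c(n_parallel, n_total - n_parallel)
  chisq <- sum((O - E)^2 / E)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       expected = E, small_expected = any(E < 1))
}

#' Permutation test for the number of parallel genes
#'
#' Draws `n_select` genes with replacement from the genome-wide universe of
#' genes with shared SNPs (with their concordance flags), counts concordant
#' ones per iteration, and compares the observed parallel count against this
#' null: add-one p, z-score and the null 95th-percentile cutoff.
#'
#' @param concordant logical vector: genome-wide per-gene concordance flags
#'   (the universe).
#' @param n_select genes drawn per iteration (the observed overlap size).
#' @param n_parallel observed number of parallel genes among the selected.
#' @param n_iter iterations (default 1000).
#' @param seed integer seed.
#' @return list of class `parallel_perm`: `z`, `p`, `cutoff95`, `null_mean`,
#'   `null_sd`, `n_iter`, `seed`.
#' @export
parallel_permutation <- function(concordant, n_select, n_parallel,
                                 n_iter = 1000, seed = 1L) {
  stopifnot(length(concordant) >= n_select, n_select >= 1)
  set.seed(seed)
  null <- vapply(seq_len(n_iter), function(b)
    sum(sample(concordant, n_select, replace = TRUE)), numeric(1))
  mu <- mean(null); sdv <- stats::sd(null)
  structure(list(
    z = if (sdv > 0) (n_parallel - mu) / sdv else NA_real_,
    p = (1 + sum(null >= n_parallel)) / (n_iter + 1),
    cutoff95 = unname(stats::quantile(null, 0.95, type = 1)),
    null_mean = mu, null_sd = sdv, n_iter = n_iter, seed = seed),
    class = "parallel_perm")
}

#' @export
print.parallel_perm <- function(x, ...) {
  cat(sprintf(
    "parallel permutation: null = %.2f +/- %.2f, 95%% cutoff = %g, z = %.2f, p = %.4g\n",
    x$null_mean, x$null_sd, x$cutoff95, x$z, x$p))
  invisible(x)
}
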