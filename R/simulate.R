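#' Simulation configuration
#'
#' Parameters of the synthetic multi-transect dataset generator. Defaults mirror
#' the sampling design the pipeline targets: a few latitudinal transects of
#' populations genotyped at exome-like SNPs, with hierarchical drift
#' (Balding-Nichols), a small fraction of environmentally clinal loci, local
#' linkage blocks, genotype missingness, and a polygenic sex-affected body
#' weight.
#'
#' @param n_transects number of independent transects.
#' @param populations_per_transect populations sampled along each transect.
#' @param samples_per_population diploid individuals per population.
#' @param n_sites biallelic SNPs (shared site map across transects).
#' @param n_genes gene models laid out along two chromosomes.
#' @param exons_per_gene exons per gene model.
#' @param go_terms size of the GO-term pool.
#' @param drift_F Balding-Nichols per-population differentiation parameter in
#'   (0, 1); 0 disables drift.
#' @param clinal_fraction fraction of (genic) sites with an environmental
#'   effect on allele frequency.
#' @param clinal_slope effect of the standardized environmental value on the
#'   logit ancestral allele frequency.
#' @param shared_clinal_fraction fraction of clinal genes whose effect is
#'   present with the same sign in every transect; the remainder are clinal in
#'   a single transect only.
#' @param ld_block_span width (bases) of linkage blocks; within a block,
#'   non-leader sites echo the leader's genotype column.
#' @param ld_copy_prob probability a (non-clinal) site is such an echo.
#' @param missing_rate per-call missing probability.
#' @param env_spec list of per-transect environments: each element has
#'   `lat_range` (signed degrees) plus `mat_sd` (deg C noise around the linear
#'   latitude->MAT map) and `pdm_range` (mm, drawn independently of latitude).
#'   Defaults emulate one South-American-like transect (3 S to 55 S) and two
#'   North-American-like transects; mean annual temperature (MAT) runs from
#'   about 20 C at the equatorial end to about 5 C at the poleward end of each
#'   transect, and precipitation of the driest month (PDM) is orthogonal to
#'   latitude.
#' @param weight_model list: `intercept` (g), `sex_effect` (g, added for
#'   males), `n_causal` causal SNPs with per-allele effects `beta` (g),
#'   `polygenic_var` (g^2, genome-wide standardized-genotype burden) and
#'   `resid_sd` (g).
#' @param seed integer seed; the whole dataset is a deterministic function of
#'   the configuration.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_transects = 3,
                       populations_per_transect = 5,
                       samples_per_population = 10,
                       n_sites = 2000,
                       n_genes = 200,
                       exons_per_gene = 3,
                       go_terms = 50,
                       drift_F = 0.1,
                       clinal_fraction = 0.05,
                       clinal_slope = 1.5,
                       shared_clinal_fraction = 0.5,
                       ld_block_span = 5000,
                       ld_copy_prob = 0.5,
                       missing_rate = 0.05,
                       env_spec = NULL,
                       weight_model = NULL,
                       seed = 1L) {
  if (is.null(env_spec)) {
    ranges <- list(c(-55, -3), c(26, 44), c(32, 54))
    env_spec <- lapply(seq_len(n_transects), function(t) {
      r <- ranges[[((t - 1L) %% 3L) + 1L]]
      list(lat_range = r, mat_sd = 1, pdm_range = c(5, 120) + 40 * (t - 1))
    })
  }
  if (is.null(weight_model)) weight_model <- list()
  wm <- utils::modifyList(
    list(intercept = 15, sex_effect = 2, n_causal = 5, beta = 1.0,
         polygenic_var = 2.25, resid_sd = 1.5),
    weight_model)
  cfg <- list(n_transects = n_transects,
              populations_per_transect = populations_per_transect,
              samples_per_population = samples_per_population,
              n_sites = n_sites, n_genes = n_genes,
              exons_per_gene = exons_per_gene, go_terms = go_terms,
              drift_F = drift_F, clinal_fraction = clinal_fraction,
              clinal_slope = clinal_slope,
              shared_clinal_fraction = shared_clinal_fraction,
              ld_block_span = ld_block_span, ld_copy_prob = ld_copy_prob,
              missing_rate = missing_rate, env_spec = env_spec,
              weight_model = wm, seed = as.integer(seed))
  stopifnot(cfg$drift_F >= 0, cfg$drift_F < 1,
            cfg$clinal_fraction >= 0, cfg$clinal_fraction <= 1,
            cfg$shared_clinal_fraction >= 0, cfg$shared_clinal_fraction <= 1,
            cfg$ld_copy_prob >= 0, cfg$ld_copy_prob <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            cfg$n_sites >= cfg$n_genes,
              length(cfg$env_spec) == cfg$n_transects)
  class(cfg) <- "sim_config"
  cfg
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# gene models on two chromosomes: 4 kb genes separated by 4 kb gaps
make_gene_models <- function(cfg) {
  n <- cfg$n_genes
  half <- ceiling(n / 2)
  chrom <- rep(c("chr1", "chr2"), times = c(half, n - half))
  idx <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  start <- (idx - 1L) * 8000L + 2001L
  end <- start + 3999L
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                      chrom = chrom, start = start, end = end,
                      strand = rep_len(c("+", "-"), n),
                      stringsAsFactors = FALSE)
  ne <- cfg$exons_per_gene
  span <- 4000L
  exon_len <- as.integer(floor(span * 0.6 / ne))
  gap <- as.integer(floor((span - ne * exon_len) / max(1, ne)))
  exons <- do.call(rbind, lapply(seq_len(n), function(g) {
    s <- genes$start[g] + (seq_len(ne) - 1L) * (exon_len + gap)
    data.frame(gene_id = genes$gene_id[g], start = s, end = s + exon_len - 1L,
               stringsAsFactors = FALSE)
  }))
  gene_set(genes, exons)
}

#' Simulate a multi-transect dataset
#'
#' Generates, deterministically from `config$seed`: a shared SNP map laid over
#' synthetic gene models; ancestral allele frequencies Uniform(0.05, 0.95);
#' per-population frequencies from the Balding-Nichols model
#' Beta(p(1-F)/F, (1-p)(1-F)/F) after adding (for clinal sites) the product of
#' `clinal_slope` and the population's standardized distance from the equator
#' on the logit scale; binomial(2, freq) genotypes; block-leader linkage
#' copying; and uniform missingness. Environmental values (LAT, MAT, PDM) are
#' per-population constants; MAT is a noisy linear function of latitude and
#' PDM is independent of it.
#'
#' @param config a [sim_config].
#' @return an object of class `synthetic_dataset`: list with `transects` (each
#'   a list of `genotypes` ([genotype_table]) and `samples` (metadata
#'   data.frame)), `genes` ([gene_set]), `go` (gene -> GO terms list), and
#'   `truth` (per-transect truly clinal site ids, shared clinal genes, causal
#'   body-weight sites).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  gs <- make_gene_models(cfg)

  # shared site map: uniform positions over each chromosome's gene extent
  chrom_ext <- tapply(gs$genes$end, gs$genes$chrom, max) + 2000L
  n_chr1 <- round(cfg$n_sites * chrom_ext[["chr1"]] / sum(chrom_ext))
  pos1 <- sort(sample.int(chrom_ext[["chr1"]], n_chr1))
  pos2 <- sort(sample.int(chrom_ext[["chr2"]], cfg$n_sites - n_chr1))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  sites <- data.frame(chrom = rep(c("chr1", "chr2"), c(n_chr1, cfg$n_sites - n_chr1)),
                      pos = c(pos1, pos2), ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  site_id <- paste0(sites$chrom, ":", sites$pos)

  p0 <- stats::runif(cfg$n_sites, 0.05, 0.95)

  # truth: clinal sites must sit inside genes so clinal genes are well defined
  assign_gene <- map_snps_to_genes(sites, gs, mode = "gene_body")
  genic <- which(site_id %in% assign_gene$site_id)
  n_clinal <- round(cfg$clinal_fraction * cfg$n_sites)
  clinal_idx <- sort(sample(genic, min(n_clinal, length(genic))))
  clinal_sign <- sample(c(-1, 1), length(clinal_idx), replace = TRUE)
  clinal_genes <- unique(assign_gene$gene_id[
    assign_gene$site_id %in% site_id[clinal_idx]])
  n_shared <- round(cfg$shared_clinal_fraction * length(clinal_genes))
  shared_genes <- sort(sample(clinal_genes, n_shared))
  # non-shared clinal genes act in one randomly chosen transect only
  private_transect <- sample.int(cfg$n_transects,
                                 length(clinal_genes), replace = TRUE)
  names(private_transect) <- clinal_genes
  site_gene <- assign_gene$gene_id[match(site_id[clinal_idx],
                                         assign_gene$site_id)]

  # linkage: within each ld_block_span window non-leader sites echo the
  # block leader. The leader is the block's first clinal site when it has
  # one (linked neutral variation hitchhikes on the selected haplotype,
  # which is what makes non-causal candidate SNPs informative), otherwise
  # the first site. Copier status is decided once so linkage structure is
  # consistent across transects; clinal sites never copy.
  block <- paste(sites$chrom, (sites$pos - 1L) %/% cfg$ld_block_span)
  is_clinal <- seq_len(cfg$n_sites) %in% clinal_idx
  leader_idx_by_block <- vapply(split(seq_len(cfg$n_sites), block),
                                function(ii) {
                                  cl <- ii[is_clinal[ii]]
                                  if (length(cl)) cl[1] else ii[1]
                                }, integer(1))
  leader_idx <- leader_idx_by_block[block]
  copier <- seq_len(cfg$n_sites) != leader_idx &
    stats::runif(cfg$n_sites) < cfg$ld_copy_prob
  copier[clinal_idx] <- FALSE

  transects <- vector("list", cfg$n_transects)
  truth_sites <- vector("list", cfg$n_transects)
  for (t in seq_len(cfg$n_transects)) {
    es <- cfg$env_spec[[t]]
    lat <- seq(es$lat_range[1], es$lat_range[2],
               length.out = cfg$populations_per_transect)
    dist_eq <- abs(lat)
    e_std <- as.numeric(scale(dist_eq))
    mat <- 20 - 15 * (dist_eq - min(dist_eq)) / diff(range(dist_eq)) +
      stats::rnorm(length(lat), 0, es$mat_sd)
    pdm <- stats::runif(length(lat), es$pdm_range[1], es$pdm_range[2])

    # which clinal sites act in this transect
    active <- rep(FALSE, length(clinal_idx))
    active[site_gene %in% shared_genes] <- TRUE
    priv <- !(site_gene %in% shared_genes) &
      private_transect[site_gene] == t
    active[priv] <- TRUE
    truth_sites[[t]] <- site_id[clinal_idx[active]]

    n_pop <- cfg$populations_per_transect
    n_per <- cfg$samples_per_population
    calls <- matrix(NA_integer_, nrow = n_pop * n_per, ncol = cfg$n_sites)
    for (k in seq_len(n_pop)) {
      lp <- logit(p0)
      act <- clinal_idx[active]
      lp[act] <- lp[act] + cfg$clinal_slope * clinal_sign[active] * e_std[k]
      pk0 <- inv_logit(lp)
      if (cfg$drift_F > 0) {
        shp <- (1 - cfg$drift_F) / cfg$drift_F
        pk <- stats::rbeta(cfg$n_sites, pk0 * shp, (1 - pk0) * shp)
      } else pk <- pk0
      rows <- (k - 1L) * n_per + seq_len(n_per)
      g <- matrix(stats::rbinom(n_per * cfg$n_sites, 2L,
                                rep(pk, each = n_per)),
                  nrow = n_per)
      calls[rows, ] <- g
    }
    calls[, copier] <- calls[, leader_idx[copier]]
    if (cfg$missing_rate > 0) {
      miss <- stats::runif(length(calls)) < cfg$missing_rate
      calls[miss] <- NA_integer_
    }
    pop_lab <- sprintf("t%d_p%d", t, seq_len(n_pop))
    sample_id <- sprintf("t%d_p%d_s%02d",
                         t, rep(seq_len(n_pop), each = n_per),
                         rep(seq_len(n_per), n_pop))
    gt <- genotype_table(sample_id, sites, calls)
    samples <- data.frame(
      sample_id = sample_id,
      population = rep(pop_lab, each = n_per),
      transect = sprintf("T%d", t),
      sex = sample(c("F", "M"), n_pop * n_per, replace = TRUE),
      latitude = rep(lat, each = n_per),
      LAT = rep(dist_eq, each = n_per),
      MAT = rep(mat, each = n_per),
      PDM = rep(pdm, each = n_per),
      age_class = "adult",
      stringsAsFactors = FALSE)
    transects[[t]] <- list(genotypes = gt, samples = samples)
  }
  names(transects) <- sprintf("T%d", seq_len(cfg$n_transects))

  go <- stats::setNames(lapply(seq_len(cfg$n_genes), function(g)
    sort(sample(sprintf("GO:%07d", seq_len(cfg$go_terms)),
                sample(1:3, 1L)))), gs$genes$gene_id)

  wm <- cfg$weight_model
  # body weight is itself a clinal trait: its causal alleles are drawn from
  # the clinal sites shared across transects when any exist (so association
  # hits coincide with selection-scan candidates), topped up from neutral
  # sites otherwise
  shared_site_rows <- clinal_idx[site_gene %in% shared_genes]
  n_from_clinal <- min(round(0.8 * wm$n_causal), length(shared_site_rows))
  causal_idx <- if (n_from_clinal > 0)
    sample(shared_site_rows, n_from_clinal) else integer(0)
  if (n_from_clinal < wm$n_causal) {
    pool <- setdiff(seq_len(cfg$n_sites), clinal_idx)
    causal_idx <- c(causal_idx,
                    sample(pool, wm$n_causal - n_from_clinal))
  }
  causal_idx <- sort(causal_idx)
  causal <- data.frame(site_id = site_id[causal_idx],
                       beta = rep_len(wm$beta, wm$n_causal),
                       stringsAsFactors = FALSE)

  structure(list(
    transects = transects, genes = gs, go = go,
    truth = list(clinal_sites = stats::setNames(truth_sites, names(transects)),
                 shared_clinal_genes = shared_genes,
                 causal_sites = causal),
    config = cfg), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", length(x$transects), "transect(s),",
      nrow(x$transects[[1]]$genotypes$sites), "sites,",
      nrow(x$genes$genes), "genes\n")
  for (t in names(x$transects))
    cat("  ", t, ": ", length(x$transects[[t]]$genotypes$samples),
        " samples, ", length(x$truth$clinal_sites[[t]]),
        " truly clinal sites\n", sep = "")
  invisible(x)
}

#' Simulate body weight for a synthetic dataset
#'
#' weight = intercept + sex_effect * 1[male] + sum(beta_j * dosage_j) +
#' polygenic term + Gaussian noise. The polygenic term is `Z a` with `Z` the
#' per-site standardized genotypes (missing -> 0 after centering) and
#' `a ~ N(0, polygenic_var / m)`, so its variance is approximately
#' `polygenic_var`. Missing causal dosages are replaced by the
#' population-mean dosage at that site.
#'
#' @param dataset a `synthetic_dataset`.
#' @param config the [sim_config] used to build it.
#' @return `dataset` with a `body_weight` column filled in every transect's
#'   sample table.
#' @export
simulate_body_weight <- function(dataset, config) {
  wm <- config$weight_model
  set.seed(config$seed + 1L)
  for (t in names(dataset$transects)) {
    gt <- dataset$transects[[t]]$genotypes
    sam <- dataset$transects[[t]]$samples
    n <- length(gt$samples)
    ci <- match(dataset$truth$causal_sites$site_id, gt$sites$id)
    genet <- numeric(n)
    for (j in seq_along(ci)) {
      d <- gt$calls[, ci[j]]
      if (anyNA(d)) {
        pops <- sam$population
        mns <- tapply(d, pops, mean, na.rm = TRUE)
        mns[is.na(mns)] <- mean(d, na.rm = TRUE)
        d[is.na(d)] <- mns[pops[is.na(d)]]
      }
      genet <- genet + dataset$truth$causal_sites$beta[j] * d
    }
    poly <- numeric(n)
    if (wm$polygenic_var > 0) {
      Z <- standardize_genotypes(gt)
      a <- stats::rnorm(ncol(Z), 0, sqrt(wm$polygenic_var / max(1, ncol(Z))))
      poly <- as.numeric(Z %*% a)
    }
    w <- wm$intercept + wm$sex_effect * (sam$sex == "M") + genet + poly +
      stats::rnorm(n, 0, wm$resid_sd)
    dataset$transects[[t]]$samples$body_weight <- w
  }
  dataset
}

# per-site standardized genotype matrix: center by 2p, scale by sqrt(2p(1-p)),
# missing -> 0 after centering; monomorphic sites dropped
standardize_genotypes <- function(gt) {
  p <- colMeans(gt$calls, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  Z <- sweep(gt$calls[, keep, drop = FALSE], 2L, 2 * p[keep])
  Z[is.na(Z)] <- 0
  sweep(Z, 2L, sqrt(2 * p[keep] * (1 - p[keep])), "/")
}

#' Write a synthetic dataset to plain-text files
#'
#' One VCF + sample TSV per transect, a gene (and exon) BED, a GO TSV and a
#' truth TSV, all under `dir`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in names(dataset$transects)) {
    write_vcf(dataset$transects[[t]]$genotypes,
              file.path(dir, paste0(t, ".vcf")))
    write_sample_table(dataset$transects[[t]]$samples,
                       file.path(dir, paste0(t, "_samples.tsv")))
  }
  write_gene_bed(dataset$genes, file.path(dir, "genes.bed"),
                 file.path(dir, "exons.bed"))
  write_go_map(dataset$go, file.path(dir, "go.tsv"))
  truth <- data.frame(
    transect = rep(names(dataset$truth$clinal_sites),
                   lengths(dataset$truth$clinal_sites)),
    site_id = unlist(dataset$truth$clinal_sites, use.names = FALSE))
  utils::write.table(truth, file.path(dir, "truth_clinal_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
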