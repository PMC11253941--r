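small_cfg <- function(...) {
  sim_config(n_transects = 2, populations_per_transect = 4,
             samples_per_population = 8, n_sites = 400, n_genes = 40, ...)
}

test_that("the same seed reproduces the dataset exactly", {
  a <- simulate_dataset(small_cfg(seed = 21))
  b <- simulate_dataset(small_cfg(seed = 21))
  expect_identical(a, b)
  wa <- simulate_body_weight(a, small_cfg(seed = 21))
  wb <- simulate_body_weight(b, small_cfg(seed = 21))
  expect_identical(wa, wb)
  c <- simulate_dataset(small_cfg(seed = 22))
  expect_false(identical(a$transects[[1]]$genotypes$calls,
                         c$transects[[1]]$genotypes$calls))
})

test_that("truth bookkeeping is internally consistent", {
  ds <- simulate_dataset(small_cfg(seed = 5, clinal_fraction = 0.1,
                                   shared_clinal_fraction = 0.5))
  ids <- ds$transects[[1]]$genotypes$sites$id
  for (t in names(ds$transects))
    expect_true(all(ds$truth$clinal_sites[[t]] %in% ids))
  # every shared clinal gene holds >= 1 truly clinal site in every transect
  asg <- map_snps_to_genes(ds$transects[[1]]$genotypes, ds$genes, "gene_body")
  for (g in ds$truth$shared_clinal_genes) {
    snps_in_g <- asg$site_id[asg$gene_id == g]
    for (t in names(ds$transects))
      expect_true(any(ds$truth$clinal_sites[[t]] %in% snps_in_g))
  }
  expect_true(all(ds$truth$causal_sites$site_id %in% ids))
})

test_that("vanishing drift gives no differentiation; drift_F = 0.1 is recovered", {
  cfg <- sim_config(n_transects = 1, populations_per_transect = 2,
                    samples_per_population = 100, n_sites = 2000,
                    n_genes = 100, clinal_fraction = 0, drift_F = 0.001,
                    ld_copy_prob = 0, missing_rate = 0, seed = 31)
  ds <- simulate_dataset(cfg)
  tr <- ds$transects[[1]]
  pops <- tr$samples$population[match(tr$genotypes$samples,
                                      tr$samples$sample_id)]
  expect_lt(abs(fst_matrix(tr$genotypes, pops)$mean), 0.01)

  cfg$drift_F <- 0.1
  ds <- simulate_dataset(cfg)
  tr <- ds$transects[[1]]
  theta <- fst_matrix(tr$genotypes, pops)$mean
  expect_lt(abs(theta - 0.1), 0.02)
})

test_that("clinal sites carry detectable frequency-environment correlation", {
  cfg <- sim_config(n_transects = 1, populations_per_transect = 6,
                    samples_per_population = 15, n_sites = 2000,
                    n_genes = 200, clinal_fraction = 0.05, clinal_slope = 1.5,
                    shared_clinal_fraction = 1, ld_copy_prob = 0,
                    missing_rate = 0, seed = 32)
  ds <- simulate_dataset(cfg)
  tr <- ds$transects[[1]]
  sam <- tr$samples[match(tr$genotypes$samples, tr$samples$sample_id), ]
  # brute-force per-site population-frequency ~ environment correlation
  pops <- sort(unique(sam$population))
  env <- vapply(pops, function(p) sam$LAT[sam$population == p][1], 0)
  pf <- vapply(pops, function(p)
    colMeans(tr$genotypes$calls[sam$population == p, , drop = FALSE]) / 2,
    numeric(nrow(tr$genotypes$sites)))
  cc <- suppressWarnings(abs(apply(pf, 1L, stats::cor, y = env)))
  truth <- tr$genotypes$sites$id %in% ds$truth$clinal_sites[[1]]
  expect_gt(stats::median(cc[truth], na.rm = TRUE),
            stats::quantile(cc[!truth], 0.95, na.rm = TRUE))
})

test_that("linkage blocks echo their leader and missingness hits at the set rate", {
  cfg <- small_cfg(seed = 8, ld_copy_prob = 1, missing_rate = 0)
  ds <- simulate_dataset(cfg)
  calls <- ds$transects[[1]]$genotypes$calls
  sites <- ds$transects[[1]]$genotypes$sites
  block <- paste(sites$chrom, (sites$pos - 1L) %/% cfg$ld_block_span)
  # with copy probability 1, any two non-clinal sites of a block either both
  # echo the leader or one of them is it: every block collapses to at most
  # 1 + #clinal distinct columns
  for (b in unique(block)[1:10]) {
    idx <- which(block == b)
    ncol_distinct <- nrow(unique(t(calls[, idx, drop = FALSE])))
    nclin <- sum(sites$id[idx] %in% ds$truth$clinal_sites[[1]])
    expect_lte(ncol_distinct, 1L + nclin)
  }
  ds2 <- simulate_dataset(small_cfg(seed = 8, missing_rate = 0.1))
  expect_lt(abs(mean(is.na(ds2$transects[[1]]$genotypes$calls)) - 0.1), 0.02)
})

test_that("environmental values are population constants, MAT tracks latitude", {
  ds <- simulate_dataset(small_cfg(seed = 9))
  sam <- ds$transects[[1]]$samples
  for (v in c("LAT", "MAT", "PDM"))
    expect_true(all(tapply(sam[[v]], sam$population,
                           function(x) length(unique(x))) == 1))
  pops <- !duplicated(sam$population)
  expect_lt(cor(sam$MAT[pops], abs(sam$latitude[pops])), -0.7)
})

test_that("body weight responds to sex, causal dosage, and nothing else when null", {
  # single causal site with beta = 2: OLS recovers it within 3 s.e.
  cfg <- sim_config(n_transects = 1, populations_per_transect = 4,
                    samples_per_population = 100, n_sites = 500,
                    n_genes = 50, clinal_fraction = 0, missing_rate = 0,
                    weight_model = list(n_causal = 1, beta = 2,
                                        polygenic_var = 0, resid_sd = 1),
                    seed = 41)
  ds <- simulate_body_weight(simulate_dataset(cfg), cfg)
  tr <- ds$transects[[1]]
  sam <- tr$samples[match(tr$genotypes$samples, tr$samples$sample_id), ]
  dos <- tr$genotypes$calls[, match(ds$truth$causal_sites$site_id,
                                    tr$genotypes$sites$id)]
  fit <- summary(stats::lm(sam$body_weight ~ dos + factor(sam$sex)))
  expect_lt(abs(fit$coefficients["dos", 1] - 2),
            3 * fit$coefficients["dos", 2])
  # sex effect 3: male - female difference within 3 s.e.
  cfg$weight_model$beta <- 0
  cfg$weight_model$sex_effect <- 3
  ds <- simulate_body_weight(simulate_dataset(cfg), cfg)
  sam <- ds$transects[[1]]$samples
  tt <- stats::t.test(sam$body_weight[sam$sex == "M"],
                      sam$body_weight[sam$sex == "F"])
  expect_lt(abs(diff(rev(tt$estimate)) - 3), 3 * tt$stderr)
})

test_that("with no genetic effects the per-site regression p-values are uniform", {
  cfg <- sim_config(n_transects = 1, populations_per_transect = 1,
                    samples_per_population = 150, n_sites = 400, n_genes = 40,
                    clinal_fraction = 0, drift_F = 0, ld_copy_prob = 0,
                    missing_rate = 0,
                    weight_model = list(n_causal = 0, polygenic_var = 0,
                                        resid_sd = 1),
                    seed = 42)
  ds <- simulate_body_weight(simulate_dataset(cfg), cfg)
  tr <- ds$transects[[1]]
  sam <- tr$samples[match(tr$genotypes$samples, tr$samples$sample_id), ]
  y <- stats::resid(stats::lm(sam$body_weight ~ sam$sex))
  p <- apply(tr$genotypes$calls, 2L, function(g) {
    if (stats::sd(g) == 0) return(NA_real_)
    summary(stats::lm(y ~ g))$coefficients[2, 4]
  })
  ks <- stats::ks.test(p[!is.na(p)], "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("write_dataset emits readable plain-text files", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(small_cfg(seed = 51))
  write_dataset(ds, dir)
  back <- read_vcf(file.path(dir, "T1.vcf"))
  expect_identical(back$calls, ds$transects[["T1"]]$genotypes$calls)
  gs <- read_gene_bed(file.path(dir, "genes.bed"), file.path(dir, "exons.bed"))
  expect_identical(gs$genes, ds$genes$genes)
  go <- read_go_map(file.path(dir, "go.tsv"))
  expect_identical(go[order(names(go))],
                   ds$go[order(names(ds$go))])
})
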