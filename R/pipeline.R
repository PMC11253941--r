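#' Pipeline configuration
#'
#' Bundles the stage parameters for [run_full_pipeline]. A single master
#' seed derives per-stage seeds by fixed offsets, so the whole run is
#' deterministic while stages stay independent.
#'
#' @param sim a [sim_config] describing the synthetic dataset (or `NULL`
#'   when `data` is supplied to [run_full_pipeline]).
#' @param scan a [scan_config] shared by all transects, or a list of one per
#'   transect.
#' @param variables environmental variables to scan (columns of the sample
#'   tables).
#' @param relatedness_threshold relatedness cut-off for pruning close
#'   relatives before scanning (`NULL` disables pruning).
#' @param n_overlap_reps replicates for the candidate-overlap permutation
#'   tests.
#' @param n_parallel_iter iterations for the parallel-shift permutation test.
#' @param min_end_call_fraction per-end-population call-rate rule for shift
#'   directions.
#' @param expected_parallel_fraction chi-square null fraction for three-way
#'   parallel shifts (0.25 = three independent equiprobable directions).
#' @param enrich_modes subset of `c("snp", "gene", "ld")` to run.
#' @param enrich_sims simulations per enrichment mode.
#' @param gwas run the pooled body-weight GWAS stage.
#' @param seed master seed.
#' @param out_dir optional directory for TSV outputs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            scan = scan_config(),
                            variables = c("LAT", "MAT"),
                            relatedness_threshold = 0.25,
                            n_overlap_reps = 1000,
                            n_parallel_iter = 1000,
                            min_end_call_fraction = 0.6,
                            expected_parallel_fraction = 0.25,
                            enrich_modes = "snp",
                            enrich_sims = 200,
                            gwas = TRUE,
                            seed = 1L,
                            out_dir = NULL) {
  structure(list(sim = sim, scan = scan, variables = variables,
                 relatedness_threshold = relatedness_threshold,
                 n_overlap_reps = n_overlap_reps,
                 n_parallel_iter = n_parallel_iter,
                 min_end_call_fraction = min_end_call_fraction,
                 expected_parallel_fraction = expected_parallel_fraction,
                 enrich_modes = enrich_modes, enrich_sims = enrich_sims,
                 gwas = gwas, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full comparative-adaptation pipeline
#'
#' Stages, mirroring the analysis order: simulate (or accept) multi-transect
#' data -> optional relative pruning -> per-transect per-variable
#' environmental scans and outlier calling -> candidate gene sets ->
#' pairwise and three-way overlap permutation tests -> end-population
#' allele-frequency shift directions, gene-level parallelism, chi-square and
#' permutation tests -> GO enrichment -> pooled mixed-model GWAS for body
#' weight and the GWAS x scan overlap test.
#'
#' @param config a [pipeline_config].
#' @param data optional `synthetic_dataset`-shaped input (list with
#'   `transects`, `genes`, `go`); when `NULL`, data are simulated from
#'   `config$sim`.
#' @return object of class `pipeline_report`.
#' @export
run_full_pipeline <- function(config = pipeline_config(), data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (is.null(data)) {
    data <- stage("simulate", {
      cfg <- config$sim
      cfg$seed <- seed
      ds <- simulate_dataset(cfg)
      simulate_body_weight(ds, cfg)
    })
  }
  tnames <- names(data$transects)
  n_tr <- length(tnames)
  scan_cfgs <- if (inherits(config$scan, "scan_config"))
    stats::setNames(rep(list(config$scan), n_tr), tnames) else config$scan

  # relative pruning, within populations so drift-driven structure is not
  # mistaken for kinship
  pruned <- stage("relatedness_prune", {
    lapply(tnames, function(t) {
      tr <- data$transects[[t]]
      if (is.null(config$relatedness_threshold)) return(tr)
      removed <- character(0)
      for (pop in unique(tr$samples$population)) {
        ids <- tr$samples$sample_id[tr$samples$population == pop]
        if (length(ids) < 2) next
        pr <- relatedness_prune(
          subset_genotypes(tr$genotypes, samples = ids),
          config$relatedness_threshold)
        removed <- c(removed, pr$removed)
      }
      keep <- setdiff(tr$genotypes$samples, removed)
      tr$genotypes <- subset_genotypes(tr$genotypes, samples = keep)
      tr$samples <- tr$samples[tr$samples$sample_id %in% keep, ]
      tr$n_removed_relatives <- length(removed)
      tr
    })
  })
  names(pruned) <- tnames

  assign_body <- map_snps_to_genes(data$transects[[1]]$genotypes, data$genes,
                                   "gene_body")
  assign_exon <- map_snps_to_genes(data$transects[[1]]$genotypes, data$genes,
                                   "exon_only")

  # per-transect scans
  scans <- stage("env_scan", {
    out <- list()
    for (t in tnames) {
      tr <- pruned[[t]]
      for (v in config$variables) {
        env <- tr$samples[[v]][match(tr$genotypes$samples,
                                     tr$samples$sample_id)]
        out[[t]][[v]] <- env_scan(tr$genotypes, env, scan_cfgs[[t]],
                                  variable = v)
      }
    }
    out
  })

  cand_snps <- lapply(scans, lapply, call_outliers)
  cand_genes <- lapply(cand_snps, lapply, candidate_genes,
                       assignment = assign_body)
  universes <- lapply(scans, function(s)
    candidate_genes(s[[1]]$table$site_id, assign_body))

  # overlap tests per variable: pairwise and (if >= 3 transects) three-way
  overlaps <- stage("overlap", {
    out <- list()
    for (v in config$variables) {
      sets <- lapply(tnames, function(t) cand_genes[[t]][[v]])
      names(sets) <- tnames
      prs <- utils::combn(tnames, 2, simplify = FALSE)
      pair <- lapply(seq_along(prs), function(i) {
        pr <- prs[[i]]
        overlap_permutation_test(sets[pr], universes[pr],
                                 config$n_overlap_reps,
                                 seed = seed + 100L + i)
      })
      names(pair) <- vapply(prs, paste, "", collapse = "-")
      three <- if (n_tr >= 3)
        overlap_permutation_test(sets[1:3], universes[1:3],
                                 config$n_overlap_reps, seed = seed + 110L)
      else NULL
      out[[v]] <- list(sets = sets, pairwise = pair, threeway = three)
    }
    out
  })

  # parallelism across all transects
  parallelism <- stage("parallelism", {
    shift_tabs <- lapply(tnames, function(t) {
      tr <- pruned[[t]]
      ends <- end_populations(tr$samples)
      ids_low <- tr$samples$sample_id[tr$samples$population == ends$low]
      ids_high <- tr$samples$sample_id[tr$samples$population == ends$high]
      shift_directions(subset_genotypes(tr$genotypes, samples = ids_low),
                       subset_genotypes(tr$genotypes, samples = ids_high),
                       tr$genotypes$sites$id,
                       config$min_end_call_fraction)
    })
    names(shift_tabs) <- tnames
    genome <- gene_parallel_calls(shift_tabs, assign_body)
    out <- list(genome = genome, shift_tables = shift_tabs, tests = list())
    for (v in config$variables) {
      shared <- Reduce(intersect, lapply(tnames, function(t)
        cand_genes[[t]][[v]]))
      eval_genes <- genome[genome$gene_id %in% shared, ]
      n_total <- nrow(eval_genes)
      n_par <- sum(eval_genes$concordant)
      tst <- if (n_total >= 1) list(
        n_parallel = n_par, n_total = n_total,
        chisq = parallel_chisq(n_par, n_total,
                               config$expected_parallel_fraction),
        perm = parallel_permutation(genome$concordant, n_total, n_par,
                                    config$n_parallel_iter,
                                    seed = seed + 120L + match(v, config$variables)))
      else list(n_parallel = 0L, n_total = 0L, chisq = NULL, perm = NULL)
      out$tests[[v]] <- tst
    }
    out
  })

  # enrichment on the first transect, first variable
  enrichment <- stage("enrichment", {
    v <- config$variables[1]
    t <- tnames[1]
    cand <- cand_snps[[t]][[v]]
    bg <- scans[[t]][[v]]$table$site_id
    out <- list()
    if (length(config$enrich_modes) > 0 && length(cand) >= 1) {
      if ("snp" %in% config$enrich_modes)
        out$snp <- permutation_enrichment(cand, bg, assign_exon, data$go,
                                          "snp", config$enrich_sims,
                                          seed = seed + 130L)
      if ("gene" %in% config$enrich_modes)
        out$gene <- permutation_enrichment(cand, bg, assign_exon, data$go,
                                           "gene", config$enrich_sims,
                                           seed = seed + 131L)
      if ("ld" %in% config$enrich_modes)
        out$ld <- ld_pruned_enrichment(pruned[[t]]$genotypes, cand, bg,
                                       assign_exon, data$go,
                                       n_sim = config$enrich_sims,
                                       seed = seed + 132L)
    }
    out
  })

  # pooled GWAS for body weight
  gwas_res <- NULL
  if (isTRUE(config$gwas)) {
    gwas_res <- stage("gwas", {
      calls <- do.call(rbind, lapply(pruned, function(tr) tr$genotypes$calls))
      samp <- do.call(rbind, lapply(pruned, function(tr)
        tr$samples[match(tr$genotypes$samples, tr$samples$sample_id), ]))
      adult <- samp$age_class == "adult" & !is.na(samp$body_weight)
      gt_all <- genotype_table(samp$sample_id[adult],
                               pruned[[1]]$genotypes$sites[,
                                 c("chrom", "pos", "ref", "alt")],
                               calls[adult, , drop = FALSE])
      kin <- kinship_matrix(gt_all)
      fit <- lmm_association(samp$body_weight[adult],
                             cbind(sexM = as.numeric(samp$sex[adult] == "M")),
                             gt_all, kin)
      hit_genes <- candidate_genes(fit$table$site_id[fit$table$significant],
                                   assign_body)
      scan_union <- sort(unique(unlist(lapply(cand_genes, function(x)
        unlist(x, use.names = FALSE)))))
      tested_universe <- candidate_genes(fit$table$site_id, assign_body)
      ov <- if (length(hit_genes) >= 1 && length(scan_union) >= 1)
        gwas_scan_overlap(hit_genes,
                          intersect(scan_union, tested_universe),
                          tested_universe,
                          config$n_overlap_reps, seed = seed + 140L)
      else NULL
      list(fit = fit, hit_genes = hit_genes, overlap = ov)
    })
  }

  report <- structure(list(
    config = config,
    n_transects = n_tr,
    n_removed_relatives = vapply(pruned, function(tr)
      tr$n_removed_relatives %||% 0L, numeric(1)),
    scans = scans, candidate_snps = cand_snps, candidate_genes = cand_genes,
    overlaps = overlaps, parallelism = parallelism,
    enrichment = enrichment, gwas = gwas_res,
    truth = data$truth, seed = seed),
    class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (seed ", x$seed, ")\n", sep = "")
  cat("  transects:", x$n_transects,
      "| relatives removed:", sum(x$n_removed_relatives), "\n")
  for (t in names(x$scans)) for (v in names(x$scans[[t]]))
    cat(sprintf("  scan %s/%s: lambda = %.3f, %d candidate SNPs, %d genes\n",
                t, v, x$scans[[t]][[v]]$lambda,
                length(x$candidate_snps[[t]][[v]]),
                length(x$candidate_genes[[t]][[v]])))
  for (v in names(x$overlaps)) {
    ov <- x$overlaps[[v]]
    for (pr in names(ov$pairwise))
      cat(sprintf("  overlap %s %s: obs = %d, z = %.2f, p = %.4g\n", v, pr,
                  ov$pairwise[[pr]]$observed, ov$pairwise[[pr]]$z,
                  ov$pairwise[[pr]]$p))
    if (!is.null(ov$threeway))
      cat(sprintf("  overlap %s three-way: obs = %d, z = %.2f, p = %.4g\n",
                  v, ov$threeway$observed, ov$threeway$z, ov$threeway$p))
  }
  for (v in names(x$parallelism$tests)) {
    tst <- x$parallelism$tests[[v]]
    if (tst$n_total >= 1)
      cat(sprintf(
        "  parallel %s: %d/%d genes, chisq = %.2f (p = %.3g), perm p = %.4g\n",
        v, tst$n_parallel, tst$n_total, tst$chisq$chisq, tst$chisq$p,
        tst$perm$p))
    else cat("  parallel", v, ": no evaluable shared genes\n")
  }
  if (!is.null(x$gwas)) {
    cat(sprintf("  gwas: %d significant SNPs in %d genes\n",
                sum(x$gwas$fit$table$significant, na.rm = TRUE),
                length(x$gwas$hit_genes)))
    if (!is.null(x$gwas$overlap))
      cat(sprintf("  gwas x scan overlap: z = %.2f, p = %.4g\n",
                  x$gwas$overlap$z, x$gwas$overlap$p))
  }
  invisible(x)
}

#' Write a pipeline report's tables to TSV files
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  for (t in names(report$scans)) for (v in names(report$scans[[t]]))
    wt(report$scans[[t]][[v]]$table, sprintf("scan_%s_%s.tsv", t, v))
  wt(report$parallelism$genome, "parallel_genes.tsv")
  if (!is.null(report$gwas)) wt(report$gwas$fit$table, "gwas.tsv")
  summ <- utils::capture.output(print(report))
  writeLines(summ, file.path(dir, "report.txt"))
  invisible(dir)
}
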