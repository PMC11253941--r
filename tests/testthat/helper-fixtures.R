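# small deterministic fixtures shared across test files

# genotype table with given call matrix on chr1 at positions 10, 20, ...
toy_gt <- function(calls, samples = NULL, chrom = "chr1") {
  calls <- as.matrix(calls)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(calls)))
  n_sites <- ncol(calls)
  sites <- data.frame(chrom = chrom, pos = seq_len(n_sites) * 10L,
                      ref = "A", alt = "G")
  genotype_table(samples, sites, calls)
}

# random genotype table (iid dosages), optionally with missingness
random_gt <- function(n_samples, n_sites, miss = 0, seed = 1) {
  set.seed(seed)
  p <- runif(n_sites, 0.1, 0.9)
  calls <- matrix(rbinom(n_samples * n_sites, 2, rep(p, each = n_samples)),
                  nrow = n_samples)
  if (miss > 0) calls[runif(length(calls)) < miss] <- NA
  toy_gt(calls)
}

# gene set with n genes of width 100 at offsets 1, 201, 401, ... on chr1
toy_genes <- function(n, chrom = "chr1", width = 100L, gap = 100L) {
  start <- (seq_len(n) - 1L) * (width + gap) + 1L
  gene_set(data.frame(gene_id = sprintf("g%02d", seq_len(n)), chrom = chrom,
                      start = start, end = start + width - 1L))
}

# brute-force SNP -> gene interval scan (test oracle for map_snps_to_genes)
brute_overlap <- function(sites, intervals) {
  out <- NULL
  for (i in seq_len(nrow(sites))) for (j in seq_len(nrow(intervals))) {
    if (sites$chrom[i] == intervals$chrom[j] &&
        sites$pos[i] >= intervals$start[j] &&
        sites$pos[i] <= intervals$end[j])
      out <- rbind(out, data.frame(site_id = sites$id[i],
                                   gene_id = intervals$gene_id[j]))
  }
  if (is.null(out))
    data.frame(site_id = character(0), gene_id = character(0))
  else unique(out)
}

# direct evaluation of the BH step-up definition (test oracle)
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(o == i)  # rank of p[i]
    q[i] <- min(m * p[o][j:m] / (j:m))
  }
  pmin(q, 1)
}
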