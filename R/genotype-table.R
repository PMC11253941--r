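#' Genotype table
#'
#' The central data container of the package: called genotypes for a set of
#' samples at a set of biallelic SNPs, stored as alternate-allele dosages.
#'
#' @param samples character vector of unique sample identifiers.
#' @param sites data.frame with columns `chrom` (character), `pos` (1-based
#'   integer position), `ref` and `alt` (single bases). Positions must be
#'   strictly increasing within each chromosome and (chrom, pos) keys unique.
#' @param calls integer matrix, samples x sites, values in \{0, 1, 2\} counting
#'   copies of the alternate allele; missing calls are `NA`.
#'
#' @return An object of class `genotype_table`: a list with elements
#'   `samples`, `sites` (with an added `id` column `"chrom:pos"`) and `calls`
#'   (dimnames set to sample and site ids).
#'
#' @details Dosage coding follows the usual VCF GT collapse: 0/0 -> 0,
#'   0/1 or 1/0 -> 1, 1/1 -> 2, ./. -> NA. Phase is ignored throughout.
#'
#' @examples
#' gt <- genotype_table(
#'   samples = c("s1", "s2"),
#'   sites = data.frame(chrom = "chr1", pos = c(100L, 200L),
#'                      ref = c("A", "C"), alt = c("G", "T")),
#'   calls = matrix(c(0L, 1L, 2L, NA), nrow = 2)
#' )
#' dim(gt$calls)
#' @export
genotype_table <- function(samples, sites, calls) {
  samples <- as.character(samples)
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  sites <- data.frame(chrom = as.character(sites$chrom),
                      pos = as.integer(sites$pos),
                      ref = as.character(sites$ref),
                      alt = as.character(sites$alt),
                      stringsAsFactors = FALSE)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  gt <- structure(
    list(samples = samples, sites = sites, calls = calls),
    class = "genotype_table"
  )
  gt$sites$id <- site_ids(gt)
  dimnames(gt$calls) <- list(samples, gt$sites$id)
  validate_genotype_table(gt)
  gt
}

#' Validate a genotype table
#'
#' Checks the structural invariants: matching dimensions, dosage values in
#' \{0,1,2,NA\}, unique sample ids, unique (chrom, pos) keys, and positions
#' strictly increasing within each chromosome.
#'
#' @param gt a `genotype_table`.
#' @return `gt`, invisibly; stops on violation.
#' @export
validate_genotype_table <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  if (anyDuplicated(gt$samples))
    stop("duplicate sample ids")
  if (nrow(gt$calls) != length(gt$samples) || ncol(gt$calls) != nrow(gt$sites))
    stop("calls matrix dimensions do not match samples/sites")
  vals <- gt$calls[!is.na(gt$calls)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("calls must be 0, 1, 2 or NA")
  key <- paste(gt$sites$chrom, gt$sites$pos)
  if (anyDuplicated(key))
    stop("duplicate (chromosome, position) site keys")
  by_chr <- split(gt$sites$pos, gt$sites$chrom)
  for (p in by_chr)
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome")
  invisible(gt)
}

site_ids <- function(gt) {
  if (nrow(gt$sites) == 0) return(character(0))
  paste0(gt$sites$chrom, ":", gt$sites$pos)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$samples), "samples x", nrow(x$sites),
      "sites\n")
  miss <- mean(is.na(x$calls))
  cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a genotype table
#'
#' @param x a `genotype_table`.
#' @param samples sample ids or indices to keep (default all).
#' @param sites site ids (`"chrom:pos"`) or indices to keep (default all).
#' @param ... unused.
#' @return a `genotype_table` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(x, samples = NULL, sites = NULL, ...) {
  si <- if (is.null(samples)) seq_along(x$samples) else
    if (is.character(samples)) match(samples, x$samples) else samples
  vi <- if (is.null(sites)) seq_len(nrow(x$sites)) else
    if (is.character(sites)) match(sites, x$sites$id) else sites
  if (anyNA(si)) stop("unknown sample id in subset")
  if (anyNA(vi)) stop("unknown site id in subset")
  genotype_table(x$samples[si],
                 x$sites[vi, c("chrom", "pos", "ref", "alt"), drop = FALSE],
                 x$calls[si, vi, drop = FALSE])
}
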