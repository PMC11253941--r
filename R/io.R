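#' Read a VCF file into a genotype table
#'
#' Parses a VCF v4.x file (via [vcfR::read.vcfR]) and keeps only biallelic SNP
#' records. GT fields are collapsed to alternate-allele dosage: 0/0 -> 0,
#' 0/1 or 1/0 -> 1, 1/1 -> 2, ./. -> NA; phased separators are accepted and
#' treated as unphased.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @return a [genotype_table]; the number of skipped (multi-allelic or
#'   non-SNP) records is attached as attribute `"skipped"`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  # take the fixed columns as a matrix slice: getFIX() drops to a bare
  # vector when the file has a single record
  fix <- vcf@fix[, c("CHROM", "POS", "REF", "ALT"), drop = FALSE]
  if (is.null(fix) || nrow(vcf@fix) == 0L) {
    gtm <- vcf@gt
    samples <- if (is.null(gtm)) character(0) else colnames(gtm)[-1]
    empty <- genotype_table(samples,
                            data.frame(chrom = character(0), pos = integer(0),
                                       ref = character(0), alt = character(0)),
                            matrix(integer(0), nrow = length(samples), ncol = 0))
    attr(empty, "skipped") <- 0L
    return(empty)
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  is_snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!is_snp)
  if (n_skip > 0)
    message("read_vcf: skipped ", n_skip, " non-biallelic-SNP record(s)")
  gtm <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gtm)) stop("VCF has no GT genotype field")
  samples <- colnames(gtm)
  gtm <- gtm[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g == "1/1"] <- 2L
    out
  }
  m <- nrow(gtm)
  calls <- if (length(samples) == 0) matrix(integer(0), m, 0) else
    vapply(seq_along(samples), function(j) code(gtm[, j]), integer(m))
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = m)
  gt <- genotype_table(
    samples,
    data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
               ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE),
    t(calls)
  )
  attr(gt, "skipped") <- n_skip
  gt
}

#' Write a genotype table as a plain-text VCF v4.2 file
#'
#' Emits a GT-only VCF; missing calls are written `./.`.
#'
#' @param gt a [genotype_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path) {
  validate_genotype_table(gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=clinescan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gt$samples), collapse = "\t")
  ), con)
  if (nrow(gt$sites) > 0) {
    code <- c("0/0", "0/1", "1/1")
    gstr <- matrix("./.", nrow = nrow(gt$calls), ncol = ncol(gt$calls))
    ok <- !is.na(gt$calls)
    gstr[ok] <- code[gt$calls[ok] + 1L]
    lines <- vapply(seq_len(nrow(gt$sites)), function(j) {
      paste(c(gt$sites$chrom[j], gt$sites$pos[j], gt$sites$id[j],
              gt$sites$ref[j], gt$sites$alt[j], ".", "PASS", ".", "GT",
              gstr[, j]), collapse = "\t")
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Gene annotation set
#'
#' Container for gene models: spans plus exon intervals, all 1-based inclusive.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`).
#' @param exons data.frame with columns `gene_id`, `start`, `end`; every exon
#'   must lie within its gene's span. If `NULL`, each gene gets a single exon
#'   covering its whole span.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(genes, exons = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (is.null(genes$strand)) genes$strand <- "+"
  genes <- data.frame(gene_id = as.character(genes$gene_id),
                      chrom = as.character(genes$chrom),
                      start = as.integer(genes$start),
                      end = as.integer(genes$end),
                      strand = as.character(genes$strand),
                      stringsAsFactors = FALSE)
  if (any(genes$start > genes$end)) stop("degenerate gene span (start > end)")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (is.null(exons)) {
    exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                        end = genes$end, stringsAsFactors = FALSE)
  }
  exons <- data.frame(gene_id = as.character(exons$gene_id),
                      start = as.integer(exons$start),
                      end = as.integer(exons$end), stringsAsFactors = FALSE)
  if (any(exons$start > exons$end)) stop("degenerate exon (start > end)")
  m <- match(exons$gene_id, genes$gene_id)
  if (anyNA(m)) stop("exon refers to unknown gene")
  if (any(exons$start < genes$start[m] | exons$end > genes$end[m]))
    stop("exon outside gene span")
  structure(list(genes = genes, exons = exons), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set:", nrow(x$genes), "genes,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Read gene models from BED-like files
#'
#' The gene file has tab-separated columns chrom, start, end, gene_id and an
#' optional strand column, in 0-based half-open BED coordinates; these are
#' converted to the package's 1-based inclusive convention at the boundary
#' (BED 999..1000 becomes 1000..1000). An optional companion exon file has
#' columns chrom, start, end, gene_id in the same convention.
#'
#' @param path path to the gene BED file (no header).
#' @param exon_path optional path to a companion exon BED file.
#' @return a [gene_set].
#' @export
read_gene_bed <- function(path, exon_path = NULL) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("gene BED needs >= 4 columns")
  if (any(bed[[2]] >= bed[[3]])) stop("BED start must be < end")
  genes <- data.frame(gene_id = as.character(bed[[4]]),
                      chrom = as.character(bed[[1]]),
                      start = as.integer(bed[[2]]) + 1L,
                      end = as.integer(bed[[3]]),
                      strand = if (ncol(bed) >= 5) as.character(bed[[5]]) else "+",
                      stringsAsFactors = FALSE)
  exons <- NULL
  if (!is.null(exon_path)) {
    eb <- utils::read.table(exon_path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (any(eb[[2]] >= eb[[3]])) stop("BED start must be < end")
    exons <- data.frame(gene_id = as.character(eb[[4]]),
                        start = as.integer(eb[[2]]) + 1L,
                        end = as.integer(eb[[3]]), stringsAsFactors = FALSE)
  }
  gene_set(genes, exons)
}

#' Write gene models to BED-like files (inverse of [read_gene_bed])
#'
#' @param gs a [gene_set].
#' @param path output gene BED path.
#' @param exon_path optional output exon BED path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(gs, path, exon_path = NULL) {
  g <- gs$genes
  utils::write.table(
    data.frame(g$chrom, g$start - 1L, g$end, g$gene_id, g$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(exon_path)) {
    e <- gs$exons
    chrom <- g$chrom[match(e$gene_id, g$gene_id)]
    utils::write.table(
      data.frame(chrom, e$start - 1L, e$end, e$gene_id),
      exon_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  invisible(path)
}

#' Read per-sample metadata
#'
#' Tab-separated, header row. Required columns: `sample_id`, `population`,
#' `transect`, `sex` (F/M), `latitude`. Any additional numeric column (e.g.
#' `MAT`, `PDM`, `LAT`) is treated as an environmental variable;
#' `body_weight`, `age_class` and `reproductive_status` are recognised
#' phenotype/status columns.
#'
#' @param path path to the TSV file.
#' @return a data.frame with unique `sample_id`s.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  req <- c("sample_id", "population", "transect", "sex", "latitude")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("sample table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in sample table")
  tab
}

#' Write per-sample metadata
#' @param tab a sample-metadata data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-GO mapping
#'
#' Tab-separated with header `gene_id`, `go_term`, one pair per row.
#'
#' @param path path to the TSV file.
#' @return named list: gene_id -> character vector of GO term ids. Genes
#'   absent from the file simply have no entry (empty term set).
#' @export
read_go_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "go_term") %in% names(tab)))
  if (any(!nzchar(tab$go_term))) stop("empty GO term identifier")
  lapply(split(tab$go_term, tab$gene_id), unique)
}

#' Write a gene-to-GO mapping
#' @param go named list gene_id -> GO terms.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_go_map <- function(go, path) {
  tab <- data.frame(
    gene_id = rep(names(go), lengths(go)),
    go_term = unlist(go, use.names = FALSE), stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
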