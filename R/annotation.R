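#' Functional-consequence priority classes
#'
#' The six-class "primary consequence" scheme, lower ordinal = higher
#' priority: 1 missense / stop lost / stop gained; 2 3' or 5' UTR;
#' 3 synonymous; 4 non-coding exon or non-coding transcript; 5 intron or
#' splice site; 6 upstream or downstream.
#'
#' @return data.frame with columns `label`, `class`.
#' @export
consequence_classes <- function() {
  data.frame(
    label = c("missense", "stop_lost", "stop_gained",
              "utr3", "utr5",
              "synonymous",
              "non_coding_exon", "non_coding_transcript",
              "intron", "splice",
              "upstream", "downstream"),
    class = c(1L, 1L, 1L, 2L, 2L, 3L, 4L, 4L, 5L, 5L, 6L, 6L),
    stringsAsFactors = FALSE)
}

#' Classify a SNP's primary functional consequence
#'
#' Given one or more per-transcript consequence labels for a SNP, returns the
#' highest-priority (lowest ordinal) class.
#'
#' @param labels character vector of consequence labels (see
#'   [consequence_classes] for the vocabulary).
#' @return integer class ordinal in 1..6.
#' @export
classify_consequence <- function(labels) {
  stopifnot(length(labels) >= 1)
  cc <- consequence_classes()
  m <- match(labels, cc$label)
  if (anyNA(m))
    stop("unrecognized consequence label(s): ",
         paste(unique(labels[is.na(m)]), collapse = ", "))
  min(cc$class[m])
}

#' Map SNPs to genes by interval overlap
#'
#' A SNP is assigned to a gene when its position falls within the gene body
#' (`mode = "gene_body"`, 1-based inclusive boundaries) or within one of the
#' gene's exons (`mode = "exon_only"`). A SNP overlapping several genes is
#' assigned to each; unmapped SNPs are absent from the table.
#'
#' @param sites data.frame with `chrom` and `pos` columns (e.g.
#'   `gt$sites`), or a [genotype_table].
#' @param genes a [gene_set].
#' @param mode `"gene_body"` or `"exon_only"`.
#' @return data.frame with columns `site_id`, `gene_id`.
#' @export
map_snps_to_genes <- function(sites, genes, mode = c("gene_body", "exon_only")) {
  mode <- match.arg(mode)
  if (inherits(sites, "genotype_table")) sites <- sites$sites
  if (is.null(sites$id)) sites$id <- paste0(sites$chrom, ":", sites$pos)
  snp_gr <- GenomicRanges::GRanges(sites$chrom,
                                   IRanges::IRanges(sites$pos, sites$pos))
  if (mode == "gene_body") {
    g <- genes$genes
    tgt <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
    gid <- g$gene_id
  } else {
    e <- genes$exons
    chrom <- genes$genes$chrom[match(e$gene_id, genes$genes$gene_id)]
    tgt <- GenomicRanges::GRanges(chrom, IRanges::IRanges(e$start, e$end))
    gid <- e$gene_id
  }
  hits <- GenomicRanges::findOverlaps(snp_gr, tgt)
  out <- unique(data.frame(
    site_id = sites$id[S4Vectors::queryHits(hits)],
    gene_id = gid[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Synthetic variant-consequence annotation from gene models
#'
#' A self-contained annotator over the package's simple gene models (no
#' external effect-prediction tool): exonic SNPs in a gene get a codon call -
#' the reading frame is fixed by cumulative exon offset and strand, a
#' deterministic pseudo-reference codon is derived from the site position,
#' the alternate base is substituted at the codon offset, and both codons are
#' translated with the standard genetic code
#' ([Biostrings::GENETIC_CODE]) to yield `missense`, `synonymous`,
#' `stop_gained` or `stop_lost`. Intra-gene non-exonic SNPs are `intron`;
#' SNPs within `flank` bases of a gene are `upstream`/`downstream` by strand;
#' all other SNPs get no label.
#'
#' @param sites site data.frame (`chrom`, `pos`, `ref`, `alt`) or a
#'   [genotype_table].
#' @param genes a [gene_set].
#' @param flank flanking distance in bases for up/downstream calls.
#' @return data.frame: `site_id`, `gene_id`, `label`, plus `class` (the
#'   per-SNP primary class across all its labels, repeated on each row).
#' @export
annotate_consequences <- function(sites, genes, flank = 2000L) {
  if (inherits(sites, "genotype_table")) sites <- sites$sites
  if (is.null(sites$id)) sites$id <- paste0(sites$chrom, ":", sites$pos)
  g <- genes$genes
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", nrow(g))
  for (gi in seq_len(nrow(g))) {
    ex <- genes$exons[genes$exons$gene_id == g$gene_id[gi], , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    on_chr <- sites$chrom == g$chrom[gi]
    in_body <- on_chr & sites$pos >= g$start[gi] & sites$pos <= g$end[gi]
    lab <- rep(NA_character_, nrow(sites))
    if (any(in_body)) {
      for (s in which(in_body)) {
        pos <- sites$pos[s]
        exi <- which(pos >= ex$start & pos <= ex$end)
        if (length(exi) == 0) { lab[s] <- "intron"; next }
        # cumulative coding offset in transcription order
        if (g$strand[gi] == "+") {
          before <- if (exi > 1) sum(ex$end[seq_len(exi - 1)] -
                                       ex$start[seq_len(exi - 1)] + 1L) else 0L
          off <- before + (pos - ex$start[exi])
        } else {
          nex <- nrow(ex)
          after <- if (exi < nex) sum(ex$end[(exi + 1):nex] -
                                        ex$start[(exi + 1):nex] + 1L) else 0L
          off <- after + (ex$end[exi] - pos)
        }
        frame <- off %% 3L
        # deterministic pseudo-reference codon: the two partner bases come
        # from a position hash; the SNP's own slot holds its ref base
        partner <- bases[(c(pos * 7L + 3L, pos * 13L + 5L) %% 4L) + 1L]
        ref_b <- sites$ref[s]; alt_b <- sites$alt[s]
        if (g$strand[gi] == "-") {
          comp <- c(A = "T", C = "G", G = "C", T = "A")
          ref_b <- comp[[ref_b]]; alt_b <- comp[[alt_b]]
        }
        codon <- partner[c(1, 1, 2)]
        codon_ref <- codon; codon_ref[frame + 1L] <- ref_b
        codon_alt <- codon; codon_alt[frame + 1L] <- alt_b
        aa_ref <- code[[paste(codon_ref, collapse = "")]]
        aa_alt <- code[[paste(codon_alt, collapse = "")]]
        lab[s] <- if (aa_ref == aa_alt) "synonymous"
        else if (aa_alt == "*") "stop_gained"
        else if (aa_ref == "*") "stop_lost"
        else "missense"
      }
    }
    up <- on_chr & sites$pos >= g$start[gi] - flank & sites$pos < g$start[gi]
    dn <- on_chr & sites$pos > g$end[gi] & sites$pos <= g$end[gi] + flank
    if (g$strand[gi] == "+") {
      lab[up] <- "upstream"; lab[dn] <- "downstream"
    } else {
      lab[up] <- "downstream"; lab[dn] <- "upstream"
    }
    hit <- !is.na(lab)
    if (any(hit))
      rows[[gi]] <- data.frame(site_id = sites$id[hit],
                               gene_id = g$gene_id[gi], label = lab[hit],
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(site_id = character(0), gene_id = character(0),
                      label = character(0), class = integer(0)))
  cls <- vapply(split(out$label, out$site_id), classify_consequence,
                integer(1))
  out$class <- cls[out$site_id]
  rownames(out) <- NULL
  out
}

#' Candidate genes from outlier SNPs
#'
#' @param outlier_sites character vector of candidate site ids.
#' @param assignment SNP-to-gene table from [map_snps_to_genes].
#' @return sorted character vector of gene ids containing >= 1 outlier SNP.
#' @export
candidate_genes <- function(outlier_sites, assignment) {
  sort(unique(assignment$gene_id[assignment$site_id %in% outlier_sites]))
}

#' Genes of the n lowest-p SNPs
#'
#' SNPs are ranked by (calibrated p, chromosome, position) ascending; the
#' first `n` are taken and the union of their genes returned. Ties at the
#' boundary are resolved by genomic coordinate, so the output is
#' deterministic.
#'
#' @param scan a `scan_result` (or its `table`).
#' @param assignment SNP-to-gene table from [map_snps_to_genes].
#' @param n number of top SNPs (e.g. 100 per variable, 200 for a shared-top
#'   criterion).
#' @return sorted character vector of gene ids.
#' @export
top_candidate_genes <- function(scan, assignment, n = 100) {
  stopifnot(n >= 1)
  tab <- if (inherits(scan, "scan_result")) scan$table else scan
  ord <- order(tab$p_cal, tab$chrom, tab$pos)
  if (n > nrow(tab)) {
    warning("fewer SNPs than n; using all ", nrow(tab))
    n <- nrow(tab)
  }
  top <- tab$site_id[ord[seq_len(n)]]
  candidate_genes(top, assignment)
}
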