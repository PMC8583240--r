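# cis-eQTL overlap: intersect lncRNA exons with eSNP positions from an
# association table and correlate lncRNA expression with eGene expression.

#' Read a SNP-gene association table
#'
#' Minimal TSV interchange with columns `snp_id`, `chrom`, `pos` (1-based),
#' `egene_id`, `pvalue`. Rows failing the association p-value threshold are
#' dropped on load. (GTEx associations can be exported to this layout with
#' one join of the significant-pairs file against the SNP lookup table.)
#'
#' @param path TSV path.
#' @param p_threshold keep associations with `pvalue < p_threshold`
#'   (default 1e-8; the looser 1e-7 used for locus-level reporting is a
#'   reasonable alternative).
#' @return data.frame of class `snp_table`: `snp_id`, `chrom`, `start`,
#'   `end` (0-based half-open, width 1), `egene_id`, `pvalue`.
#' @export
read_snp_table <- function(path, p_threshold = 1e-8) {
  if (!file.exists(path)) abort("SNP table not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "chrom"))
  need <- c("snp_id", "chrom", "pos", "egene_id", "pvalue")
  if (!all(need %in% names(dt))) {
    abort("SNP table needs columns: %s", paste(need, collapse = ", "))
  }
  pos <- suppressWarnings(as.numeric(dt$pos))
  if (anyNA(pos)) {
    abort("non-numeric SNP position at row %d", which(is.na(pos))[1L])
  }
  p <- as.numeric(dt$pvalue)
  if (any(!is.finite(p) | p <= 0 | p > 1)) abort("pvalue must lie in (0, 1]")
  check_scalar(p_threshold, "p_threshold", lo = 0, hi = 1)
  keep <- p < p_threshold
  out <- data.frame(snp_id = as.character(dt$snp_id)[keep],
                    chrom = as.character(dt$chrom)[keep],
                    start = pos[keep] - 1, end = pos[keep],
                    egene_id = as.character(dt$egene_id)[keep],
                    pvalue = p[keep], stringsAsFactors = FALSE)
  class(out) <- c("snp_table", "data.frame")
  out
}

#' Overlap transcript exons with eSNP positions
#'
#' Reports every (exon, SNP) containment pair; a SNP on the first or last
#' base of an exon counts. Strand is ignored for point containment. The
#' output order is canonical (transcript, exon, SNP), so it does not
#' depend on input order.
#'
#' @param catalog an [annotation_catalog()] (typically lncRNA candidates).
#' @param snps a `snp_table` from [read_snp_table()] (or a data.frame with
#'   `snp_id`, `chrom`, `start`, `end`, `egene_id`).
#' @return data.frame: `transcript_id`, `exon_index`, `snp_id`, `egene_id`.
#' @export
overlap_exons_with_snps <- function(catalog, snps) {
  stopifnot(inherits(catalog, "annotation_catalog"), is.data.frame(snps))
  empty <- data.frame(transcript_id = character(0), exon_index = integer(0),
                      snp_id = character(0), egene_id = character(0))
  if (nrow(catalog$exons) == 0L || nrow(snps) == 0L) return(empty)
  exons <- catalog_granges(catalog, "exons")
  sgr <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$start + 1, end = snps$end))
  ov <- GenomicRanges::findOverlaps(sgr, exons, ignore.strand = TRUE)
  if (!length(ov)) return(empty)
  out <- data.frame(
    transcript_id = S4Vectors::mcols(exons)$transcript_id[
      S4Vectors::subjectHits(ov)],
    exon_index = S4Vectors::mcols(exons)$exon_index[
      S4Vectors::subjectHits(ov)],
    snp_id = snps$snp_id[S4Vectors::queryHits(ov)],
    egene_id = snps$egene_id[S4Vectors::queryHits(ov)],
    stringsAsFactors = FALSE)
  out <- out[order(out$transcript_id, out$exon_index, out$snp_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate lncRNA expression with eGene expression
#'
#' Pearson correlation across samples for each (lncRNA, eGene) pair, with
#' the two-sided t-distribution p-value. A pair whose members are missing
#' from the matrix yields an error record, not a crash. When a module
#' `assignment` is supplied, the result also reports whether both members
#' sit in the same co-expression module.
#'
#' @param expr expression matrix, features x samples.
#' @param pairs data.frame with columns `lncrna_id`, `egene_id`.
#' @param assignment optional named module-label vector.
#' @return data.frame: `lncrna_id`, `egene_id`, `pcc`, `pvalue`,
#'   `same_module`, `error`.
#' @export
lncrna_egene_correlation <- function(expr, pairs, assignment = NULL) {
  stopifnot(is.matrix(expr), is.data.frame(pairs))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$lncrna_id[i]; b <- pairs$egene_id[i]
    out <- data.frame(lncrna_id = a, egene_id = b, pcc = NA_real_,
                      pvalue = NA_real_, same_module = NA,
                      error = NA_character_, stringsAsFactors = FALSE)
    missing <- setdiff(c(a, b), rownames(expr))
    if (length(missing)) {
      out$error <- sprintf("not in expression matrix: %s",
                           paste(missing, collapse = ", "))
      return(out)
    }
    ct <- cor.test(expr[a, ], expr[b, ], method = "pearson")
    out$pcc <- unname(ct$estimate)
    out$pvalue <- ct$p.value
    if (!is.null(assignment) && all(c(a, b) %in% names(assignment))) {
      out$same_module <- assignment[[a]] > 0 &&
        assignment[[a]] == assignment[[b]]
    }
    out
  })
  do.call(rbind, rows)
}
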