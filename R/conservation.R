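# Per-exon conservation from a base-wise score track (phastCons-like:
# every base scored in [0, 1], higher = more conserved), plus class-wise
# summaries for profile comparison between novel lncRNAs, annotated lncRNAs
# and protein-coding transcripts.

#' Read a conservation score track from bedGraph
#'
#' Loads a 4-column bedGraph (0-based half-open) of per-base conservation
#' scores. Intervals are sorted on load; overlapping intervals or values
#' outside `[0, 1]` are errors, since the track is phastCons-like by
#' contract.
#'
#' @param path bedGraph file path.
#' @return object of class `score_track` wrapping a sorted `GRanges` with a
#'   `score` metadata column.
#' @export
read_score_track <- function(path) {
  if (!file.exists(path)) abort("bedGraph file not found: %s", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  score_track(gr)
}

#' Build a score track from a GRanges or interval table
#'
#' @param x a `GRanges` with a numeric `score` column, or a data.frame with
#'   `chrom`, `start`, `end` (0-based half-open) and `score`.
#' @return a `score_track`.
#' @export
score_track <- function(x) {
  if (is.data.frame(x)) {
    x <- GenomicRanges::GRanges(
      seqnames = x$chrom,
      ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
      score = x$score)
  }
  stopifnot(methods::is(x, "GRanges"))
  score <- S4Vectors::mcols(x)$score
  if (is.null(score)) abort("score track needs a 'score' column")
  if (any(!is.finite(score)) || any(score < 0 | score > 1)) {
    abort("conservation scores must lie in [0, 1]")
  }
  x <- GenomicRanges::sort(GenomicRanges::granges(x, use.mcols = TRUE),
                           ignore.strand = TRUE)
  if (length(x) > 1L) {
    ov <- GenomicRanges::findOverlaps(x, drop.self = TRUE,
                                      drop.redundant = TRUE,
                                      ignore.strand = TRUE)
    if (length(ov)) abort("score track has overlapping intervals")
  }
  structure(list(granges = x), class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("<score_track> %d interval(s), %d chromosome(s), %.0f scored bases\n",
              length(x$granges),
              length(unique(as.character(GenomicRanges::seqnames(x$granges)))),
              sum(IRanges::width(x$granges))))
  invisible(x)
}

#' Mean conservation score per exon
#'
#' For every exon of every transcript, the mean of per-base scores over the
#' bases the track covers. Uncovered bases are excluded from both numerator
#' and denominator (mean-over-overlaps semantics); a fully uncovered exon
#' gets `NA`. Set `uncovered_as_zero = TRUE` to instead count uncovered
#' bases as score 0.
#'
#' @param catalog an [annotation_catalog()].
#' @param track a `score_track`.
#' @param uncovered_as_zero impute uncovered bases as 0 instead of
#'   excluding them.
#' @return data.frame: `transcript_id`, `exon_index`, `mean_score`,
#'   `covered_bases`, `exon_length`, `biotype`.
#' @export
exon_mean_scores <- function(catalog, track, uncovered_as_zero = FALSE) {
  stopifnot(inherits(catalog, "annotation_catalog"),
            inherits(track, "score_track"))
  ex <- catalog$exons
  out <- data.frame(
    transcript_id = ex$transcript_id, exon_index = ex$exon_index,
    mean_score = NA_real_, covered_bases = 0,
    exon_length = ex$end - ex$start,
    biotype = catalog$transcripts$biotype[
      match(ex$transcript_id, catalog$transcripts$transcript_id)],
    stringsAsFactors = FALSE)
  if (nrow(ex) == 0L || length(track$granges) == 0L) return(out)
  exons <- catalog_granges(catalog, "exons")
  ov <- GenomicRanges::findOverlaps(exons, track$granges,
                                    ignore.strand = TRUE)
  if (length(ov)) {
    w <- IRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(exons)[S4Vectors::queryHits(ov)],
      GenomicRanges::ranges(track$granges)[S4Vectors::subjectHits(ov)]))
    s <- S4Vectors::mcols(track$granges)$score[S4Vectors::subjectHits(ov)]
    q <- S4Vectors::queryHits(ov)
    covered <- tapply(w, q, sum)
    weighted <- tapply(w * s, q, sum)
    idx <- as.integer(names(covered))
    out$covered_bases[idx] <- as.numeric(covered)
    out$mean_score[idx] <- as.numeric(weighted) / as.numeric(covered)
  }
  if (uncovered_as_zero) {
    tot <- out$exon_length
    out$mean_score <- ifelse(out$covered_bases > 0,
                             out$mean_score * out$covered_bases / tot, 0)
    out$covered_bases <- tot
  }
  out
}

#' Class-wise summaries of exon conservation
#'
#' Summarizes per-exon mean scores by transcript class (e.g. novel lncRNA,
#' annotated lncRNA, mRNA): exon count, mean, median and deciles, suitable
#' for density plotting. Exons without coverage are dropped; empty classes
#' are omitted with a warning.
#'
#' @param scores data.frame from [exon_mean_scores()].
#' @param classes named character vector mapping transcript ids to class
#'   labels; defaults to the `biotype` column of `scores`.
#' @return data.frame, one row per class: `class`, `n_exons`, `mean`,
#'   `median`, `d10` ... `d90`.
#' @export
class_profiles <- function(scores, classes = NULL) {
  stopifnot(is.data.frame(scores))
  lab <- if (is.null(classes)) scores$biotype else
    unname(classes[scores$transcript_id])
  keep <- !is.na(scores$mean_score)
  empty <- setdiff(unique(lab), unique(lab[keep]))
  if (length(empty)) {
    warnf("class(es) without scored exons omitted: %s",
          paste(empty, collapse = ", "))
  }
  lab <- lab[keep]; x <- scores$mean_score[keep]
  if (!length(x)) abort("no scored exons")
  dec <- seq(0.1, 0.9, by = 0.1)
  rows <- lapply(split(x, lab), function(v) {
    c(n_exons = length(v), mean = mean(v), median = median(v),
      setNames(quantile(v, dec, names = FALSE), paste0("d", dec * 10)))
  })
  out <- data.frame(class = names(rows),
                    do.call(rbind, rows), row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' Export exon mean scores as BED
#'
#' BED6 export with the mean score scaled to `[0, 1000]` in column 5;
#' uncovered exons are skipped.
#'
#' @param scores data.frame from [exon_mean_scores()].
#' @param catalog the [annotation_catalog()] the scores came from.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_score_bed <- function(scores, catalog, path) {
  ex <- catalog$exons
  m <- match(paste(scores$transcript_id, scores$exon_index),
             paste(ex$transcript_id, ex$exon_index))
  keep <- !is.na(scores$mean_score)
  bed <- data.frame(
    chrom = ex$chrom[m][keep],
    start = format(ex$start[m][keep], scientific = FALSE, trim = TRUE),
    end = format(ex$end[m][keep], scientific = FALSE, trim = TRUE),
    name = sprintf("%s_exon%d", scores$transcript_id[keep],
                   scores$exon_index[keep]),
    score = as.integer(round(scores$mean_score[keep] * 1000)),
    strand = ex$strand[m][keep])
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
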