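# Core genomic data types. All coordinates are 0-based half-open internally;
# GTF I/O (gtf.R) converts to/from the 1-based closed GTF convention.

#' Create a genomic interval
#'
#' A stranded interval on a chromosome, in 0-based half-open coordinates.
#'
#' @param chrom chromosome name (non-empty string).
#' @param start 0-based start (inclusive).
#' @param end end (exclusive); must be greater than `start`.
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @return a one-row data.frame with columns `chrom`, `start`, `end`,
#'   `strand`, of class `genomic_interval`.
#' @export
#' @examples
#' genomic_interval("chr1", 99, 200, "+")
genomic_interval <- function(chrom, start, end, strand = ".") {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom)) {
    abort("interval 'chrom' must be a non-empty string")
  }
  if (!strand %in% c("+", "-", ".")) abort("strand must be '+', '-' or '.'")
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start < 0 || start >= end) {
    abort("interval requires 0 <= start < end (got [%s, %s))", start, end)
  }
  out <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_interval", "data.frame")
  out
}

#' Create a transcript model
#'
#' A stranded, possibly multi-exon gene structure on one chromosome. Exons
#' must be sorted by start and strictly disjoint; overlapping exons signal
#' corrupt assembler output and are rejected rather than merged.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param exons data.frame with numeric columns `start`, `end`
#'   (0-based half-open), one row per exon.
#' @param biotype optional label, e.g. `"mRNA"`, `"lncRNA"`, `"other"`.
#' @return an object of class `transcript_model`.
#' @export
#' @examples
#' tx <- transcript_model("t1", "g1", "chr1", "+",
#'                        data.frame(start = c(0, 20), end = c(10, 30)))
#' transcript_length(tx)
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             biotype = NA_character_) {
  stopifnot(is.character(transcript_id), nzchar(transcript_id),
            is.character(gene_id), nzchar(gene_id))
  if (!strand %in% c("+", "-", ".")) abort("strand must be '+', '-' or '.'")
  if (!is.data.frame(exons) || nrow(exons) < 1L ||
      !all(c("start", "end") %in% names(exons))) {
    abort("transcript '%s' needs >= 1 exon with start/end columns",
          transcript_id)
  }
  exons <- data.frame(start = as.numeric(exons$start),
                      end = as.numeric(exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start >= exons$end) || any(exons$start < 0)) {
    abort("transcript '%s': exons must satisfy 0 <= start < end",
          transcript_id)
  }
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    abort("transcript '%s': overlapping exons (corrupt input, not merged)",
          transcript_id)
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons, biotype = biotype),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%d-%d(%s), %d exon(s), %d nt\n",
              x$transcript_id, x$gene_id, x$chrom,
              as.integer(min(x$exons$start)), as.integer(max(x$exons$end)),
              x$strand, nrow(x$exons), transcript_length(x)))
  invisible(x)
}

#' Spliced transcript length
#'
#' Sum of exon lengths (not the genomic span). This is the length the
#' `> 200` nt lncRNA criterion is applied to.
#'
#' @param t a `transcript_model`.
#' @return integer nucleotide count.
#' @export
transcript_length <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  as.integer(sum(t$exons$end - t$exons$start))
}

#' Intron chain of a transcript
#'
#' The ordered gaps between consecutive exons. A single-exon transcript has
#' an empty chain. Intron-chain identity (with terminal exon ends free)
#' defines a structural transcript match (class code `=`).
#'
#' @param t a `transcript_model`.
#' @return object of class `intron_chain`: list with `chrom`, `strand` and
#'   an `introns` data.frame (`start`, `end`, 0-based half-open).
#' @export
#' @examples
#' tx <- transcript_model("t1", "g1", "chr1", "+",
#'                        data.frame(start = c(0, 20), end = c(10, 30)))
#' intron_chain(tx)$introns  # one intron [10, 20)
intron_chain <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  n <- nrow(t$exons)
  introns <- if (n < 2L) {
    data.frame(start = numeric(0), end = numeric(0))
  } else {
    data.frame(start = t$exons$end[-n], end = t$exons$start[-1L])
  }
  structure(list(chrom = t$chrom, strand = t$strand, introns = introns),
            class = "intron_chain")
}

# String key identifying an intron chain (chrom, strand, intron coordinates).
# Single-exon transcripts get an empty coordinate part.
chain_key <- function(t) {
  ic <- intron_chain(t)
  paste0(ic$chrom, "|", ic$strand, "|",
         paste(ic$introns$start, ic$introns$end, sep = "-", collapse = ";"))
}

#' Build an annotation catalog from an exon table
#'
#' The catalog is the container for reference and candidate annotations:
#' an exon-level table plus a derived transcript-level table and the
#' gene-to-transcript mapping.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (0-based half-open), one row per exon.
#'   An optional `biotype` column (constant within transcript) and an
#'   `attributes` column of opaque GTF attribute text are carried through.
#' @return object of class `annotation_catalog` with elements `exons`
#'   (data.table, one row per exon, with `exon_index`) and `transcripts`
#'   (data.table, one row per transcript).
#' @export
annotation_catalog <- function(exons) {
  cols <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  if (!is.data.frame(exons)) abort("'exons' must be a data.frame")
  if (!all(cols %in% names(exons))) {
    abort("exon table must have columns: %s", paste(cols, collapse = ", "))
  }
  dt <- data.table::as.data.table(exons)
  if (nrow(dt) == 0L) {
    empty_exons <- data.table::data.table(
      transcript_id = character(0), gene_id = character(0),
      chrom = character(0), start = numeric(0), end = numeric(0),
      strand = character(0), exon_index = integer(0))
    empty_tx <- data.table::data.table(
      transcript_id = character(0), gene_id = character(0),
      chrom = character(0), strand = character(0), tx_start = numeric(0),
      tx_end = numeric(0), n_exons = integer(0), length_nt = numeric(0),
      biotype = character(0), attributes = character(0))
    return(structure(list(exons = empty_exons, transcripts = empty_tx),
                     class = "annotation_catalog"))
  }
  dt[, `:=`(transcript_id = as.character(transcript_id),
            gene_id = as.character(gene_id),
            chrom = as.character(chrom),
            start = as.numeric(start), end = as.numeric(end),
            strand = as.character(strand))]
  if (!all(dt$strand %in% c("+", "-", "."))) {
    abort("strand must be '+', '-' or '.'")
  }
  if (any(dt$start < 0 | dt$start >= dt$end)) {
    abort("exons must satisfy 0 <= start < end")
  }
  if (is.null(dt$biotype)) dt[, biotype := NA_character_]
  if (is.null(dt$attributes)) dt[, attributes := NA_character_]
  data.table::setorder(dt, transcript_id, start)
  # per-transcript invariants: one chrom/strand, disjoint exons
  bad_cs <- dt[, .(ok = data.table::uniqueN(chrom) == 1L &&
                     data.table::uniqueN(strand) == 1L), by = transcript_id]
  if (any(!bad_cs$ok)) {
    abort("transcript(s) with exons on multiple chroms/strands: %s",
          paste(head(bad_cs$transcript_id[!bad_cs$ok], 5), collapse = ", "))
  }
  ovl <- dt[, .(ok = .N < 2L || all(start[-1L] >= end[-.N])),
            by = transcript_id]
  if (any(!ovl$ok)) {
    abort("transcript(s) with overlapping exons (corrupt input): %s",
          paste(head(ovl$transcript_id[!ovl$ok], 5), collapse = ", "))
  }
  dt[, exon_index := seq_len(.N), by = transcript_id]
  tx <- dt[, .(gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
               tx_start = min(start), tx_end = max(end), n_exons = .N,
               length_nt = sum(end - start), biotype = biotype[1L],
               attributes = attributes[1L]),
           by = transcript_id]
  gid <- dt[, .(n = data.table::uniqueN(gene_id)), by = transcript_id]
  if (any(gid$n > 1L)) {
    abort("transcript(s) mapped to multiple gene_ids: %s",
          paste(head(gid$transcript_id[gid$n > 1L], 5), collapse = ", "))
  }
  structure(list(
    exons = dt[, .(transcript_id, gene_id, chrom, start, end, strand,
                   exon_index)],
    transcripts = tx
  ), class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf("<annotation_catalog> %d transcripts, %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$transcripts),
              data.table::uniqueN(x$transcripts$gene_id),
              nrow(x$exons), data.table::uniqueN(x$exons$chrom)))
  invisible(x)
}

#' @export
length.annotation_catalog <- function(x) nrow(x$transcripts)

#' Transcript identifiers of a catalog
#' @param catalog an `annotation_catalog`.
#' @return character vector.
#' @export
transcript_ids <- function(catalog) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  catalog$transcripts$transcript_id
}

#' Gene to transcript mapping
#' @param catalog an `annotation_catalog`.
#' @return named list: gene_id -> character vector of transcript ids.
#' @export
gene_map <- function(catalog) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  split(catalog$transcripts$transcript_id, catalog$transcripts$gene_id)
}

#' Extract one transcript as a `transcript_model`
#' @param catalog an `annotation_catalog`.
#' @param id transcript identifier.
#' @return a `transcript_model`.
#' @export
get_transcript <- function(catalog, id) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  ex <- catalog$exons[catalog$exons$transcript_id == id]
  if (nrow(ex) == 0L) abort("no transcript '%s' in catalog", id)
  tx <- catalog$transcripts[catalog$transcripts$transcript_id == id]
  transcript_model(id, tx$gene_id, tx$chrom, tx$strand,
                   data.frame(start = ex$start, end = ex$end),
                   biotype = tx$biotype)
}

#' Subset a catalog by transcript ids
#' @param catalog an `annotation_catalog`.
#' @param ids transcript ids to keep (order ignored).
#' @return an `annotation_catalog`.
#' @export
subset_catalog <- function(catalog, ids) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  keep <- catalog$exons[catalog$exons$transcript_id %in% ids]
  tx <- catalog$transcripts[match(keep$transcript_id, catalog$transcripts$transcript_id)]
  out <- annotation_catalog(cbind(keep[, c("transcript_id", "gene_id", "chrom",
                                           "start", "end", "strand")],
                                  biotype = tx$biotype,
                                  attributes = tx$attributes))
  out
}

#' Combine catalogs
#' @param ... `annotation_catalog` objects with disjoint transcript ids.
#' @return an `annotation_catalog`.
#' @export
bind_catalogs <- function(...) {
  cats <- list(...)
  stopifnot(all(vapply(cats, inherits, TRUE, "annotation_catalog")))
  all_ids <- unlist(lapply(cats, transcript_ids))
  if (anyDuplicated(all_ids)) abort("catalogs share transcript ids")
  ex <- data.table::rbindlist(lapply(cats, function(ct) {
    tx <- ct$transcripts
    m <- match(ct$exons$transcript_id, tx$transcript_id)
    cbind(ct$exons[, c("transcript_id", "gene_id", "chrom", "start", "end",
                       "strand")],
          biotype = tx$biotype[m], attributes = tx$attributes[m])
  }))
  annotation_catalog(ex)
}

# Internal '.' strand maps to the GRanges '*' spelling.
gr_strand <- function(s) ifelse(s == ".", "*", s)

# GRanges view of catalog features, converting internal 0-based half-open
# to the 1-based closed convention GenomicRanges uses.
catalog_granges <- function(catalog, what = c("exons", "spans", "introns")) {
  what <- match.arg(what)
  tx <- catalog$transcripts
  if (what == "spans") {
    if (nrow(tx) == 0L) return(GenomicRanges::GRanges())
    return(GenomicRanges::GRanges(
      seqnames = tx$chrom,
      ranges = IRanges::IRanges(start = tx$tx_start + 1, end = tx$tx_end),
      strand = gr_strand(tx$strand), transcript_id = tx$transcript_id))
  }
  if (what == "exons") {
    ex <- catalog$exons
    if (nrow(ex) == 0L) return(GenomicRanges::GRanges())
    return(GenomicRanges::GRanges(
      seqnames = ex$chrom,
      ranges = IRanges::IRanges(start = ex$start + 1, end = ex$end),
      strand = gr_strand(ex$strand), transcript_id = ex$transcript_id,
      exon_index = ex$exon_index))
  }
  # introns
  ex <- catalog$exons[catalog$exons$transcript_id %in%
                        tx$transcript_id[tx$n_exons > 1L]]
  if (nrow(ex) == 0L) return(GenomicRanges::GRanges())
  ints <- ex[, .(start = end[-.N], end = start[-1L],
                 chrom = chrom[1L], strand = strand[1L],
                 intron_index = seq_len(.N - 1L)),
             by = transcript_id]
  GenomicRanges::GRanges(
    seqnames = ints$chrom,
    ranges = IRanges::IRanges(start = ints$start + 1, end = ints$end),
    strand = gr_strand(ints$strand), transcript_id = ints$transcript_id,
    intron_index = ints$intron_index)
}
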