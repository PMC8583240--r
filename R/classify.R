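# Class-code assignment of candidate transcripts against a reference
# annotation. The codes follow gffcompare usage for the subset relevant to
# lncRNA discovery:
#   '='  identical intron chain to a reference transcript (same strand)
#   'y'  a whole reference transcript lies inside one intron of the candidate
#   'x'  exonic overlap with reference exons on the opposite strand only
#   'i'  candidate entirely inside one reference intron, no exon overlap
#   'u'  intergenic: no overlap with any reference exon/intron/span
#   'o*' any remaining overlap pattern (catch-all)
# Precedence: '=' > 'y' > 'x' > 'i' > 'o*' > 'u'.

CLASS_CODES <- c("=", "y", "x", "i", "o*", "u")

#' Build an overlap index over a reference annotation
#'
#' Precomputes per-strand interval indexes over reference exons, introns and
#' transcript spans, plus a hash of reference intron chains, so candidates
#' can be classified without a quadratic scan.
#'
#' @param ref an [annotation_catalog()] of reference transcripts.
#' @return an object of class `reference_index`.
#' @export
build_reference_index <- function(ref) {
  stopifnot(inherits(ref, "annotation_catalog"))
  chains <- new.env(parent = emptyenv())
  tx <- ref$transcripts
  for (i in seq_len(nrow(tx))) {
    key <- chain_key(get_transcript(ref, tx$transcript_id[i]))
    chains[[key]] <- c(chains[[key]], tx$transcript_id[i])
  }
  structure(list(
    ref = ref,
    exons = catalog_granges(ref, "exons"),
    introns = catalog_granges(ref, "introns"),
    spans = catalog_granges(ref, "spans"),
    chains = chains,
    chroms = unique(tx$chrom)
  ), class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("<reference_index> %d reference transcripts, %d chromosome(s)\n",
              nrow(x$ref$transcripts), length(x$chroms)))
  invisible(x)
}

#' Test intron-chain identity between two transcripts
#'
#' Two multi-exon transcripts match when they sit on the same chromosome and
#' strand and their intron coordinate lists are identical base-for-base;
#' terminal exon ends are free to differ. For two single-exon transcripts the
#' intron-chain condition is vacuous, so the match is defined as same-strand
#' overlap of their single exons.
#'
#' @param a,b `transcript_model` objects.
#' @return logical.
#' @export
match_intron_chains <- function(a, b) {
  stopifnot(inherits(a, "transcript_model"), inherits(b, "transcript_model"))
  if (a$chrom != b$chrom || a$strand != b$strand) return(FALSE)
  na <- nrow(a$exons); nb <- nrow(b$exons)
  if (na == 1L && nb == 1L) {
    return(a$exons$start < b$exons$end && b$exons$start < a$exons$end)
  }
  if (na == 1L || nb == 1L) return(FALSE)
  ia <- intron_chain(a)$introns
  ib <- intron_chain(b)$introns
  nrow(ia) == nrow(ib) && all(ia$start == ib$start) && all(ia$end == ib$end)
}

#' Classify one candidate transcript against a reference index
#'
#' Assigns exactly one class code by the precedence
#' `'=' > 'y' > 'x' > 'i' > 'o*' > 'u'`. Candidates with strand `"."` skip
#' the strand-dependent codes (`'='`, `'x'`) and carry a warning flag in the
#' evidence string.
#'
#' @param cand a `transcript_model`.
#' @param index a `reference_index` from [build_reference_index()].
#' @param same_strand_intronic if `TRUE`, code `'i'` additionally requires
#'   the host reference transcript to share the candidate's strand
#'   (off by default: intronic candidates are not strand-restricted).
#' @param antisense_exclusive if `TRUE` (default), code `'x'` requires that
#'   the candidate has opposite-strand exonic overlap and *no* same-strand
#'   exonic overlap; if `FALSE`, any antisense exonic overlap qualifies.
#' @return a one-row data.frame: `candidate_id`, `code`, `best_ref`,
#'   `evidence`.
#' @export
classify_transcript <- function(cand, index,
                                same_strand_intronic = FALSE,
                                antisense_exclusive = TRUE) {
  stopifnot(inherits(cand, "transcript_model"),
            inherits(index, "reference_index"))
  unknown_strand <- identical(cand$strand, ".")
  # findOverlaps warns when query and subject share no seqlevels; for a
  # candidate on a chromosome absent from the reference that is the expected
  # situation (it classifies 'u'), not a defect worth surfacing per call
  fo <- function(...) suppressWarnings(GenomicRanges::findOverlaps(...))
  note <- if (unknown_strand) " [strand '.': strand-dependent codes skipped]" else ""
  res <- function(code, best_ref, why) {
    data.frame(candidate_id = cand$transcript_id, code = code,
               best_ref = best_ref, evidence = paste0(why, note),
               stringsAsFactors = FALSE)
  }

  cand_exons <- GenomicRanges::GRanges(
    seqnames = cand$chrom,
    ranges = IRanges::IRanges(start = cand$exons$start + 1,
                              end = cand$exons$end),
    strand = gr_strand(cand$strand))
  span <- range(GenomicRanges::granges(cand_exons), ignore.strand = TRUE)

  # '=': identical intron chain on the same strand
  if (!unknown_strand) {
    hit <- index$chains[[chain_key(cand)]]
    if (nrow(cand$exons) == 1L) {
      # single-exon '=': same-strand overlap of single-exon reference exons
      one <- index$ref$transcripts$transcript_id[index$ref$transcripts$n_exons == 1L]
      if (length(one)) {
        ov <- fo(cand_exons, index$exons, ignore.strand = FALSE)
        cand_hits <- unique(S4Vectors::mcols(index$exons)$transcript_id[
          S4Vectors::subjectHits(ov)])
        hit <- intersect(cand_hits, one)
      } else hit <- character(0)
    }
    if (length(hit)) {
      best <- best_by_exon_overlap(cand_exons, index, hit)
      return(res("=", best, sprintf("identical intron chain to %s", best)))
    }
  }

  # 'y': a whole reference transcript span inside one intron of the candidate
  if (nrow(cand$exons) > 1L) {
    ic <- intron_chain(cand)$introns
    cand_introns <- GenomicRanges::GRanges(
      seqnames = cand$chrom,
      ranges = IRanges::IRanges(start = ic$start + 1, end = ic$end))
    within <- fo(index$spans, cand_introns, type = "within",
                 ignore.strand = TRUE)
    if (length(within)) {
      contained <- unique(S4Vectors::mcols(index$spans)$transcript_id[
        S4Vectors::queryHits(within)])
      best <- contained[order(contained)][1L]
      return(res("y", best,
                 sprintf("reference transcript %s contained in intron", best)))
    }
  }

  # exonic overlap bookkeeping (needed by 'x' and the catch-all)
  ov_any <- fo(cand_exons, index$exons, ignore.strand = TRUE)
  hit_tx <- S4Vectors::mcols(index$exons)$transcript_id[
    S4Vectors::subjectHits(ov_any)]
  hit_strand <- as.character(GenomicRanges::strand(index$exons))[
    S4Vectors::subjectHits(ov_any)]
  same <- hit_strand == cand$strand
  opp <- (hit_strand == "+" & cand$strand == "-") |
    (hit_strand == "-" & cand$strand == "+")

  # 'x': antisense exonic overlap
  if (!unknown_strand && any(opp) && (!antisense_exclusive || !any(same))) {
    best <- best_by_exon_overlap(cand_exons, index, unique(hit_tx[opp]),
                                 ignore_strand = TRUE)
    return(res("x", best,
               sprintf("antisense exonic overlap with %s", best)))
  }

  # 'i': candidate entirely inside one reference intron, no exon overlap
  if (length(ov_any) == 0L && length(index$introns)) {
    host_introns <- index$introns
    if (same_strand_intronic && !unknown_strand) {
      host_introns <- host_introns[
        as.character(GenomicRanges::strand(host_introns)) == cand$strand]
    }
    inside <- fo(span, host_introns, type = "within",
                 ignore.strand = TRUE)
    if (length(inside)) {
      hosts <- unique(S4Vectors::mcols(host_introns)$transcript_id[
        S4Vectors::subjectHits(inside)])
      best <- hosts[order(hosts)][1L]
      return(res("i", best,
                 sprintf("contained in an intron of %s", best)))
    }
  }

  # remaining overlap with any reference feature -> catch-all; none -> 'u'
  ov_span <- fo(span, index$spans, ignore.strand = TRUE)
  if (length(ov_any)) {
    best <- best_by_exon_overlap(cand_exons, index, unique(hit_tx),
                                 ignore_strand = TRUE)
    return(res("o*", best, sprintf("exonic overlap with %s", best)))
  }
  if (length(ov_span)) {
    touched <- unique(S4Vectors::mcols(index$spans)$transcript_id[
      S4Vectors::subjectHits(ov_span)])
    best <- touched[order(touched)][1L]
    return(res("o*", best,
               sprintf("overlaps span of %s without exonic overlap", best)))
  }
  res("u", NA_character_, "no overlap with any reference feature")
}

# Among candidate reference transcript ids, pick the one sharing the most
# exonic bases with the candidate; ties broken lexicographically.
best_by_exon_overlap <- function(cand_exons, index, ids,
                                 ignore_strand = FALSE) {
  if (length(ids) == 1L) return(ids)
  sub <- index$exons[S4Vectors::mcols(index$exons)$transcript_id %in% ids]
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(cand_exons, sub,
                                ignore.strand = ignore_strand))
  if (length(ov) == 0L) return(ids[order(ids)][1L])
  w <- IRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(cand_exons)[S4Vectors::queryHits(ov)],
    GenomicRanges::ranges(sub)[S4Vectors::subjectHits(ov)]))
  tot <- tapply(w, S4Vectors::mcols(sub)$transcript_id[
    S4Vectors::subjectHits(ov)], sum)
  nm <- names(tot)[tot == max(tot)]
  nm[order(nm)][1L]
}

#' Classify every candidate in a catalog
#'
#' @param cands candidate [annotation_catalog()].
#' @param ref reference [annotation_catalog()], or a prebuilt
#'   `reference_index`.
#' @param ... passed to [classify_transcript()].
#' @return data.frame with one row per candidate (`candidate_id`, `code`,
#'   `best_ref`, `evidence`), in the candidate catalog's transcript order.
#'   Per-code counts are attached as attribute `"code_counts"` and emitted
#'   as a message.
#' @export
classify_catalog <- function(cands, ref, ...) {
  stopifnot(inherits(cands, "annotation_catalog"))
  index <- if (inherits(ref, "reference_index")) ref else
    build_reference_index(ref)
  novel_chroms <- setdiff(unique(cands$transcripts$chrom), index$chroms)
  if (length(novel_chroms) && nrow(index$ref$transcripts) > 0L) {
    warnf("chromosome(s) absent from reference: %s; candidates there are 'u'",
          paste(novel_chroms, collapse = ", "))
  }
  rows <- lapply(transcript_ids(cands), function(id) {
    classify_transcript(get_transcript(cands, id), index, ...)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(candidate_id = character(0), code = character(0),
                      best_ref = character(0), evidence = character(0))
  }
  counts <- table(factor(out$code, levels = CLASS_CODES))
  message("class-code counts: ",
          paste(sprintf("%s=%d", names(counts), counts), collapse = " "))
  attr(out, "code_counts") <- counts
  out
}

#' Write a classification report as TSV
#' @param classified data.frame from [classify_catalog()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_classification <- function(classified, path) {
  data.table::fwrite(classified, path, sep = "\t")
  invisible(path)
}
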