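# GTF2.2 reading and writing. GTF is 1-based closed; internal catalogs are
# 0-based half-open, so start shifts by one on the way in and out. Attribute
# text beyond gene_id/transcript_id is preserved as an opaque string.

#' Read a GTF annotation into a catalog
#'
#' Parses exon features of a GTF2.2 file. Every exon line must carry
#' `gene_id` and `transcript_id` attributes; non-exon features and comment
#' lines are ignored. Coordinates are converted from the GTF 1-based closed
#' convention to internal 0-based half-open.
#'
#' @param path path to a GTF file.
#' @return an [annotation_catalog()].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort("GTF file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) {
    return(annotation_catalog(data.frame(
      transcript_id = character(0), gene_id = character(0),
      chrom = character(0), start = numeric(0), end = numeric(0),
      strand = character(0))))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    bad <- keep[which(nf < 9L)[1L]]
    abort("malformed GTF line %d: expected 9 tab-separated fields, got %d",
          bad, nf[which(nf < 9L)[1L]])
  }
  feat <- vapply(fields, `[[`, "", 3L)
  exon_rows <- which(feat == "exon")
  if (length(exon_rows) == 0L) {
    return(annotation_catalog(data.frame(
      transcript_id = character(0), gene_id = character(0),
      chrom = character(0), start = numeric(0), end = numeric(0),
      strand = character(0))))
  }
  fx <- fields[exon_rows]
  lineno <- keep[exon_rows]
  chrom <- vapply(fx, `[[`, "", 1L)
  start1 <- suppressWarnings(as.numeric(vapply(fx, `[[`, "", 4L)))
  end1 <- suppressWarnings(as.numeric(vapply(fx, `[[`, "", 5L)))
  strand <- vapply(fx, `[[`, "", 7L)
  attrs <- vapply(fx, `[[`, "", 9L)
  bad <- which(!is.finite(start1) | !is.finite(end1) | start1 < 1 |
                 end1 < start1)
  if (length(bad)) {
    abort("malformed GTF line %d: invalid coordinates", lineno[bad[1L]])
  }
  tid <- gtf_attr(attrs, "transcript_id")
  gid <- gtf_attr(attrs, "gene_id")
  if (anyNA(tid)) {
    abort("GTF line %d: exon record lacks transcript_id attribute",
          lineno[which(is.na(tid))[1L]])
  }
  if (anyNA(gid)) {
    abort("GTF line %d: exon record lacks gene_id attribute",
          lineno[which(is.na(gid))[1L]])
  }
  biotype <- gtf_attr(attrs, "transcript_biotype")
  bt2 <- gtf_attr(attrs, "transcript_type")
  biotype[is.na(biotype)] <- bt2[is.na(biotype)]
  annotation_catalog(data.frame(
    transcript_id = tid, gene_id = gid, chrom = chrom,
    start = start1 - 1, end = end1, strand = strand,
    biotype = biotype, attributes = attrs, stringsAsFactors = FALSE))
}

# Extract one quoted GTF attribute value; NA where absent.
gtf_attr <- function(attrs, key) {
  pat <- paste0('(^|;)\\s*', key, '\\s+"([^"]*)"')
  m <- regexec(pat, attrs)
  vapply(regmatches(attrs, m), function(g) {
    if (length(g) >= 3L) g[3L] else NA_character_
  }, "")
}

#' Write a catalog as GTF
#'
#' Emits one `exon` feature line per exon, converting back to GTF 1-based
#' closed coordinates. Attribute text captured by [read_gtf()] is written
#' back verbatim; otherwise a minimal `gene_id`/`transcript_id` attribute
#' string is constructed. `read_gtf(write_gtf(c))` reproduces `c` exactly.
#'
#' @param catalog an [annotation_catalog()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gtf <- function(catalog, path) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  tx <- catalog$transcripts
  ex <- catalog$exons
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) abort("cannot write GTF: %s",
                                            conditionMessage(e)))
  on.exit(close(con), add = TRUE)
  writeLines("##gtf-version 2.2", con)
  if (nrow(ex) == 0L) return(invisible(path))
  m <- match(ex$transcript_id, tx$transcript_id)
  attrs <- tx$attributes[m]
  need <- is.na(attrs)
  attrs[need] <- sprintf('gene_id "%s"; transcript_id "%s";',
                         tx$gene_id[m][need], tx$transcript_id[m][need])
  lines <- sprintf("%s\tlncforge\texon\t%d\t%d\t.\t%s\t.\t%s",
                   ex$chrom, as.integer(ex$start + 1), as.integer(ex$end),
                   ex$strand, attrs)
  # keep transcripts grouped, exons in genomic order
  lines <- lines[order(m, ex$start)]
  writeLines(lines, con)
  invisible(path)
}
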