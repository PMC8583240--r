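# The novelty pipeline: prevalence filter on counts, the five lncRNA
# criteria (length > 200 nt, multi-exonic, permissive class code, lack of
# coding potential, canonical chromosome), cross-platform validation by
# intron-chain identity, and re-annotation against updated databases.

#' Discovery configuration
#'
#' Thresholds of the novelty filter. Defaults are the study conditions:
#' detection in at least half the samples, spliced length above 200 nt,
#' at least two exons, class code in `{u, i, x, y}`, coding probability
#' below the CPAT-style human cutoff, and location on the 22 autosomes or X.
#'
#' @param min_sample_fraction fraction of samples that must have count > 0.
#' @param min_length_nt transcripts must be strictly longer than
#'   `min_length_nt - 1` nt (default 201, i.e. length > 200).
#' @param allowed_codes class codes admitted as putative novel lncRNAs.
#' @param allowed_chroms admissible chromosome names; both `chrN` and bare
#'   `N` spellings are accepted by default.
#' @param coding_cutoff probability below which a transcript counts as
#'   noncoding.
#' @return a list of class `discovery_config`.
#' @export
discovery_config <- function(min_sample_fraction = 0.5,
                             min_length_nt = 201,
                             allowed_codes = c("u", "i", "x", "y"),
                             allowed_chroms = c(paste0("chr", c(1:22, "X")),
                                                c(1:22, "X")),
                             coding_cutoff = 0.364) {
  check_scalar(min_sample_fraction, "min_sample_fraction", 1e-9, 1)
  check_scalar(min_length_nt, "min_length_nt", 1)
  check_scalar(coding_cutoff, "coding_cutoff", 1e-12, 1 - 1e-12)
  structure(list(min_sample_fraction = min_sample_fraction,
                 min_length_nt = min_length_nt,
                 allowed_codes = allowed_codes,
                 allowed_chroms = as.character(allowed_chroms),
                 coding_cutoff = coding_cutoff),
            class = "discovery_config")
}

#' Prevalence filter on a count matrix
#'
#' Keeps features detected (count > 0) in at least
#' `ceiling(min_fraction * n_samples)` samples; the bound is inclusive, so
#' with 10 samples and the default 0.5 a feature seen in exactly 5 samples
#' survives.
#'
#' @param counts numeric matrix, features x samples, non-negative.
#' @param min_fraction minimum fraction of samples with a nonzero count.
#' @return character vector of surviving feature ids (rownames).
#' @export
prevalence_filter <- function(counts, min_fraction = 0.5) {
  if (!is.matrix(counts) || nrow(counts) == 0L || ncol(counts) == 0L) {
    abort("'counts' must be a non-empty matrix")
  }
  if (any(counts < 0)) abort("counts must be non-negative")
  check_scalar(min_fraction, "min_fraction", 1e-9, 1)
  need <- ceiling(min_fraction * ncol(counts))
  rownames(counts)[rowSums(counts > 0) >= need]
}

#' Apply the five novelty criteria to classified candidates
#'
#' A candidate survives iff its spliced length exceeds
#' `cfg$min_length_nt - 1`, it has at least two exons, its class code is in
#' `cfg$allowed_codes`, its coding probability is below `cfg$coding_cutoff`,
#' and it lies on an allowed chromosome. Per-criterion booleans are
#' recorded so failures can be audited; a candidate without a sequence
#' fails the coding criterion with a logged reason rather than crashing.
#'
#' @param cands candidate [annotation_catalog()].
#' @param codes classification table from [classify_catalog()].
#' @param seqs named character vector or `DNAStringSet` of spliced
#'   transcript sequences (names = transcript ids).
#' @param model a `coding_model`.
#' @param table the `hexamer_table` backing the model.
#' @param cfg a [discovery_config()].
#' @return data.frame, one row per candidate: `transcript_id`, per-criterion
#'   pass flags (`pass_length`, `pass_multiexon`, `pass_code`,
#'   `pass_noncoding`, `pass_chrom`), `coding_prob`, `code`, `pass`
#'   (all criteria), `reason` for the first failure.
#' @export
apply_novelty_criteria <- function(cands, codes, seqs, model, table,
                                   cfg = discovery_config()) {
  stopifnot(inherits(cands, "annotation_catalog"),
            inherits(cfg, "discovery_config"))
  seqs <- setNames(as.character(seqs), names(seqs))
  tx <- cands$transcripts
  code <- codes$code[match(tx$transcript_id, codes$candidate_id)]
  if (anyNA(code)) {
    abort("candidate(s) missing from classification table: %s",
          paste(head(tx$transcript_id[is.na(code)], 5), collapse = ", "))
  }
  prob <- rep(NA_real_, nrow(tx))
  has_seq <- tx$transcript_id %in% names(seqs)
  prob[has_seq] <- vapply(seqs[tx$transcript_id[has_seq]],
                          coding_probability, 0,
                          model = model, table = table, USE.NAMES = FALSE)
  out <- data.frame(
    transcript_id = tx$transcript_id,
    code = code,
    coding_prob = prob,
    pass_length = tx$length_nt > (cfg$min_length_nt - 1),
    pass_multiexon = tx$n_exons >= 2L,
    pass_code = code %in% cfg$allowed_codes,
    pass_noncoding = !is.na(prob) & prob < cfg$coding_cutoff,
    pass_chrom = tx$chrom %in% cfg$allowed_chroms,
    stringsAsFactors = FALSE)
  out$pass <- out$pass_length & out$pass_multiexon & out$pass_code &
    out$pass_noncoding & out$pass_chrom
  out$reason <- ifelse(out$pass, "",
    ifelse(!out$pass_length, "length <= threshold",
    ifelse(!out$pass_multiexon, "single-exon",
    ifelse(!out$pass_code, "class code not permissive",
    ifelse(!out$pass_noncoding,
           ifelse(is.na(prob), "no sequence available",
                  "coding probability above cutoff"),
           "chromosome not allowed")))))
  out
}

#' Cross-platform validation by intron-chain identity
#'
#' Compares novelty survivors from two sequencing platforms and keeps the
#' pairs whose intron chains match exactly (class code `=` semantics,
#' terminal exon ends free). The platform-A model is retained as the
#' representative of each validated pair.
#'
#' @param set_a,set_b [annotation_catalog()]s of surviving candidates from
#'   the two platforms.
#' @return list with `pairs` (data.frame `id_a`, `id_b`), `validated`
#'   (catalog of the platform-A representatives), `unmatched_a`,
#'   `unmatched_b` (character vectors).
#' @export
cross_platform_validate <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "annotation_catalog"),
            inherits(set_b, "annotation_catalog"))
  keys_b <- new.env(parent = emptyenv())
  for (id in transcript_ids(set_b)) {
    k <- chain_key(get_transcript(set_b, id))
    keys_b[[k]] <- c(keys_b[[k]], id)
  }
  rows <- list()
  single_b <- subset_catalog(
    set_b, set_b$transcripts$transcript_id[set_b$transcripts$n_exons == 1L])
  for (id in transcript_ids(set_a)) {
    a <- get_transcript(set_a, id)
    if (nrow(a$exons) > 1L) {
      hits <- keys_b[[chain_key(a)]]
    } else {
      # single-exon pairs match by same-strand exon overlap
      hits <- Filter(function(bid) {
        match_intron_chains(a, get_transcript(single_b, bid))
      }, transcript_ids(single_b))
    }
    if (length(hits)) {
      rows[[length(rows) + 1L]] <- data.frame(
        id_a = id, id_b = sort(unlist(hits))[1L], stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id_a = character(0), id_b = character(0))
  list(pairs = pairs,
       validated = subset_catalog(set_a, pairs$id_a),
       unmatched_a = setdiff(transcript_ids(set_a), pairs$id_a),
       unmatched_b = setdiff(transcript_ids(set_b), pairs$id_b))
}

#' Partition validated transcripts into previously annotated vs novel
#'
#' Re-annotates validated candidates against updated database catalogs
#' (e.g. newer GENCODE, FANTOM CAT, NONCODE). A transcript counts as
#' previously annotated when some database transcript matches it by
#' intron-chain identity or, in the default mode, by same-strand exonic
#' overlap covering at least half of the shorter transcript; the first
#' matching database (in the order given) is recorded as provenance.
#'
#' @param validated [annotation_catalog()] of validated transcripts.
#' @param dbs named list of [annotation_catalog()]s.
#' @param db_match_mode `"chain_or_overlap"` (default) or `"chain_only"`.
#' @param min_overlap minimum shared same-strand exonic fraction of the
#'   shorter transcript for an overlap match.
#' @return data.frame: `transcript_id`, `status`
#'   (`"previously_annotated"`/`"novel"`), `db` (provenance or `NA`),
#'   `db_transcript`, `match_type` (`"intron_chain"`, `"exon_overlap"` or
#'   `NA`).
#' @export
annotate_against_databases <- function(validated, dbs,
                                       db_match_mode = c("chain_or_overlap",
                                                         "chain_only"),
                                       min_overlap = 0.5) {
  stopifnot(inherits(validated, "annotation_catalog"))
  db_match_mode <- match.arg(db_match_mode)
  if (length(dbs) == 0L) {
    warnf("no databases given; every validated transcript reported novel")
  }
  if (is.null(names(dbs)) && length(dbs)) {
    names(dbs) <- paste0("db", seq_along(dbs))
  }
  check_scalar(min_overlap, "min_overlap", 1e-9, 1)
  out <- data.frame(transcript_id = transcript_ids(validated),
                    status = "novel", db = NA_character_,
                    db_transcript = NA_character_,
                    match_type = NA_character_, stringsAsFactors = FALSE)
  for (db_name in names(dbs)) {
    db <- dbs[[db_name]]
    stopifnot(inherits(db, "annotation_catalog"))
    todo <- which(out$status == "novel")
    if (!length(todo)) break
    chains <- new.env(parent = emptyenv())
    for (id in transcript_ids(db)) {
      k <- chain_key(get_transcript(db, id))
      chains[[k]] <- c(chains[[k]], id)
    }
    db_exons <- catalog_granges(db, "exons")
    for (i in todo) {
      t <- get_transcript(validated, out$transcript_id[i])
      hit <- if (nrow(t$exons) > 1L) chains[[chain_key(t)]] else NULL
      if (length(hit)) {
        out$status[i] <- "previously_annotated"
        out$db[i] <- db_name
        out$db_transcript[i] <- sort(hit)[1L]
        out$match_type[i] <- "intron_chain"
        next
      }
      if (db_match_mode == "chain_only" || length(db_exons) == 0L) next
      gr <- GenomicRanges::GRanges(
        seqnames = t$chrom,
        ranges = IRanges::IRanges(start = t$exons$start + 1,
                                  end = t$exons$end),
        strand = gr_strand(t$strand))
      ov <- GenomicRanges::findOverlaps(gr, db_exons, ignore.strand = FALSE)
      if (!length(ov)) next
      w <- IRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(gr)[S4Vectors::queryHits(ov)],
        GenomicRanges::ranges(db_exons)[S4Vectors::subjectHits(ov)]))
      shared <- tapply(w, S4Vectors::mcols(db_exons)$transcript_id[
        S4Vectors::subjectHits(ov)], sum)
      cand_len <- transcript_length(t)
      db_len <- db$transcripts$length_nt[
        match(names(shared), db$transcripts$transcript_id)]
      frac <- shared / pmin(cand_len, db_len)
      if (any(frac >= min_overlap)) {
        best <- names(shared)[which.max(frac)]
        out$status[i] <- "previously_annotated"
        out$db[i] <- db_name
        out$db_transcript[i] <- best
        out$match_type[i] <- "exon_overlap"
      }
    }
  }
  out
}
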