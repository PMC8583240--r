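# TPM computation, the paired pre/post differential test, BH adjustment,
# and the high-confidence selection rule (padj < 0.001, |FC| > 1.2, and for
# annotated genes >= 90% of each group at >= 0.5 TPM).

#' Build a paired pre/post design
#'
#' @param sample sample ids (must match expression matrix columns).
#' @param subject subject id per sample.
#' @param condition `"pre"` or `"post"` per sample; every subject must have
#'   exactly one of each.
#' @return data.frame of class `paired_design`.
#' @export
paired_design <- function(sample, subject, condition) {
  d <- data.frame(sample = as.character(sample),
                  subject = as.character(subject),
                  condition = as.character(condition),
                  stringsAsFactors = FALSE)
  if (!all(d$condition %in% c("pre", "post"))) {
    abort("condition must be 'pre' or 'post'")
  }
  if (anyDuplicated(d$sample)) abort("duplicate sample ids")
  tab <- table(d$subject, d$condition)
  if (!all(tab == 1L) || ncol(tab) != 2L) {
    abort("every subject needs exactly one 'pre' and one 'post' sample")
  }
  class(d) <- c("paired_design", "data.frame")
  d
}

#' Read a features-by-samples expression matrix from TSV
#'
#' First column holds feature ids, remaining columns one sample each.
#'
#' @param path TSV path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  if (any(!is.finite(m)) || any(m < 0)) {
    abort("expression matrix must be finite and non-negative")
  }
  m
}

#' Write an expression matrix as TSV
#' @param m numeric matrix with rownames.
#' @param path output path.
#' @param id_col name of the feature-id column.
#' @return invisibly, the path.
#' @export
write_expression_matrix <- function(m, path, id_col = "feature_id") {
  dt <- data.table::data.table(id = rownames(m))
  data.table::setnames(dt, "id", id_col)
  data.table::fwrite(cbind(dt, data.table::as.data.table(m)), path,
                     sep = "\t")
  invisible(path)
}

#' Transcripts-per-million normalization
#'
#' `tpm_ij = (c_ij / len_i) / sum_k (c_kj / len_k) * 1e6`; every column of
#' the result sums to one million.
#'
#' @param counts non-negative count matrix, features x samples.
#' @param lengths positive effective lengths, one per feature (named or in
#'   row order).
#' @return TPM matrix of the same shape.
#' @export
compute_tpm <- function(counts, lengths) {
  if (!is.matrix(counts) || any(counts < 0)) {
    abort("'counts' must be a non-negative matrix")
  }
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts) || any(!is.finite(lengths)) ||
      any(lengths <= 0)) {
    abort("'lengths' must be positive, one per feature")
  }
  rate <- counts / lengths
  denom <- colSums(rate)
  if (any(denom == 0)) {
    abort("all-zero count column(s): %s",
          paste(colnames(counts)[denom == 0] %||%
              which(denom == 0), collapse = ", "))
  }
  sweep(rate, 2L, denom, "/") * 1e6
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), via
#' [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in `[0, 1]`; `NA`/`NaN` is an
#'   error (exclude untestable features before adjusting).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals)) {
    abort("p-values must be numeric with no NA/NaN")
  }
  if (any(pvals < 0 | pvals > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Paired pre/post differential-expression test
#'
#' For each feature, a paired t-test on per-subject `log2(TPM + 1)`
#' differences (post minus pre), two-sided. The signed fold change follows
#' the post/pre ratio convention: with
#' `r = (mean post TPM + pseudo) / (mean pre TPM + pseudo)`, `FC = r` when
#' `r >= 1` and `-1/r` otherwise, so a halving is reported as -2 and
#' `r = 0.714` as about -1.4. Features whose paired differences have zero
#' variance are flagged: all-zero differences give p = 1, constant nonzero
#' differences give p = NA (excluded from the BH denominator).
#'
#' @param tpm TPM matrix, features x samples.
#' @param design a [paired_design()]; needs at least 3 subject pairs.
#' @param pseudo_fc pseudocount added to group means in the fold-change
#'   ratio.
#' @param tpm_detect TPM detection threshold used for the per-group
#'   detection fractions (default 0.5).
#' @return data.frame of class `de_result`: `feature_id`, `log2fc` (mean
#'   paired difference of `log2(TPM + 1)`), `fold_change` (signed), `pvalue`,
#'   `padj`, `mean_tpm_pre`, `mean_tpm_post`, `frac_detected_pre`,
#'   `frac_detected_post`, `zero_variance`.
#' @export
paired_de_test <- function(tpm, design, pseudo_fc = 0.01, tpm_detect = 0.5) {
  stopifnot(is.matrix(tpm), inherits(design, "paired_design"))
  miss <- setdiff(design$sample, colnames(tpm))
  if (length(miss)) {
    abort("design sample(s) absent from matrix: %s",
          paste(miss, collapse = ", "))
  }
  subjects <- unique(design$subject)
  if (length(subjects) < 3L) abort("need at least 3 subject pairs")
  pre_cols <- design$sample[match(paste0(subjects, ".pre"),
                                  paste(design$subject, design$condition,
                                        sep = "."))]
  post_cols <- design$sample[match(paste0(subjects, ".post"),
                                   paste(design$subject, design$condition,
                                         sep = "."))]
  pre <- tpm[, pre_cols, drop = FALSE]
  post <- tpm[, post_cols, drop = FALSE]
  d <- log2(post + 1) - log2(pre + 1)
  n <- length(subjects)
  m <- rowMeans(d)
  s <- apply(d, 1L, sd)
  tstat <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  zero_var <- s == 0
  p[zero_var & m == 0] <- 1
  p[zero_var & m != 0] <- NA_real_
  mean_pre <- rowMeans(pre)
  mean_post <- rowMeans(post)
  r <- (mean_post + pseudo_fc) / (mean_pre + pseudo_fc)
  fc <- ifelse(r >= 1, r, -1 / r)
  padj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  padj[ok] <- bh_adjust(p[ok])
  out <- data.frame(
    feature_id = rownames(tpm) %||% as.character(seq_len(nrow(tpm))),
    log2fc = m, fold_change = fc, pvalue = p, padj = padj,
    mean_tpm_pre = mean_pre, mean_tpm_post = mean_post,
    frac_detected_pre = rowMeans(pre >= tpm_detect),
    frac_detected_post = rowMeans(post >= tpm_detect),
    zero_variance = zero_var,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}

#' High-confidence differential-expression selection
#'
#' Keeps features with adjusted p strictly below `max_padj`, absolute
#' signed fold change strictly above `min_fc`, and - for annotated features
#' only - detection at `>= min_tpm` TPM in at least `min_detect_frac` of
#' both the pre and post groups. Novel transcripts are exempt from the
#' detection criterion by default (set `exempt_novel = FALSE` to apply it
#' to them too). Any per-feature table with the `de_result` columns works,
#' so externally fitted results (e.g. DESeq2 output mapped to `padj` and
#' `fold_change`) can be substituted for the shipped paired test.
#'
#' @param res a `de_result` (or compatible data.frame).
#' @param annotated logical vector (or character vector of annotated
#'   feature ids) marking annotated features; the rest count as novel.
#' @param max_padj,min_fc,min_tpm,min_detect_frac thresholds; defaults are
#'   the study's (0.001, 1.2, 0.5 TPM, 90%).
#' @param exempt_novel exempt novel features from the detection criterion.
#' @return character vector of selected feature ids.
#' @export
de_select <- function(res, annotated = TRUE, max_padj = 0.001,
                      min_fc = 1.2, min_tpm = 0.5, min_detect_frac = 0.9,
                      exempt_novel = TRUE) {
  stopifnot(is.data.frame(res))
  if (is.character(annotated)) annotated <- res$feature_id %in% annotated
  annotated <- rep_len(annotated, nrow(res))
  sel <- !is.na(res$padj) & res$padj < max_padj &
    abs(res$fold_change) > min_fc
  detect <- res$frac_detected_pre >= min_detect_frac &
    res$frac_detected_post >= min_detect_frac
  need_detect <- if (exempt_novel) annotated else rep(TRUE, nrow(res))
  sel <- sel & (!need_detect | detect)
  res$feature_id[sel]
}
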