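# Coding-potential scoring in the CPAT style: four sequence features
# (ORF length, ORF coverage, Fickett TESTCODE statistic, hexamer usage
# log-odds) combined by logistic regression. Model weights are always
# trained from sequence corpora (shipped synthetic ones or user FASTA);
# no opaque pretrained constants are distributed.

# Fickett TESTCODE lookup tables (position-asymmetry and base-content
# parameters with their probability-of-coding conversions and weights).
FICKETT_POSITION_BREAKS <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1)
FICKETT_CONTENT_BREAKS <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.17)
FICKETT_POSITION_PROB <- rbind(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
FICKETT_CONTENT_PROB <- rbind(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51))
FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find the longest ATG-initiated open reading frame
#'
#' Scans the three forward frames of the sense strand for the longest ORF
#' starting at ATG and ending at the first in-frame stop codon (stop
#' included) or, absent one, at the last complete codon of the frame. Ties
#' are broken by the smallest start offset.
#'
#' @param seq a nucleotide string over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive), length >= 3.
#' @return list of class `orf_call`: `start` (0-based offset), `end`
#'   (half-open), `frame` (0, 1 or 2), `length_nt`. A sequence with no ATG
#'   yields the zero-length sentinel (all fields 0).
#' @export
#' @examples
#' find_longest_orf("ATGAAATAG")  # start 0, length 9
find_longest_orf <- function(seq) {
  seq <- check_nt(seq, min_len = 3L)
  n <- nchar(seq)
  best <- list(start = 0L, end = 0L, frame = 0L, length_nt = 0L)
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3L
    if (n_codons < 1L) next
    starts <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
    codons <- substring(seq, starts, starts + 2L)
    atg <- which(codons == "ATG")
    if (!length(atg)) next
    stops <- which(codons %in% STOP_CODONS)
    # codon index of the ORF end (inclusive) for each ATG
    nxt <- if (length(stops)) {
      stops[findInterval(atg - 1L, stops) + 1L]  # first stop at/after atg
    } else rep(NA_integer_, length(atg))
    endc <- ifelse(is.na(nxt), n_codons, nxt)
    lens <- (endc - atg + 1L) * 3L
    i <- which.max(lens)  # earliest ATG wins ties (which.max takes first)
    if (lens[i] > best$length_nt ||
        (lens[i] == best$length_nt && lens[i] > 0L &&
         starts[atg[i]] - 1L < best$start)) {
      best <- list(start = starts[atg[i]] - 1L,
                   end = starts[atg[i]] - 1L + lens[i],
                   frame = frame, length_nt = lens[i])
    }
  }
  class(best) <- "orf_call"
  best
}

check_nt <- function(seq, min_len = 1L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) < min_len) abort("sequence shorter than %d nt", min_len)
  if (grepl("[^ACGTN]", seq)) abort("sequence has letters outside ACGTN")
  seq
}

#' Fickett TESTCODE statistic
#'
#' Weighted sum of eight lookup-table-converted parameters: for each base,
#' a position-asymmetry parameter (codon-position counts,
#' `max / (min + 1)`) and a content fraction, each mapped through the
#' published probability tables. Higher values indicate codon-like
#' periodicity and composition. Deterministic and case-insensitive;
#' `N` bases are excluded from content fractions.
#'
#' @param seq nucleotide string; lengths below 200 nt score but warn.
#' @return numeric score (bounded by the lookup tables' range).
#' @export
fickett_score <- function(seq) {
  seq <- check_nt(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (mean(!chars %in% c("A", "C", "G", "T")) > 0.10) {
    abort("more than 10%% of bases are not A/C/G/T")
  }
  if (length(chars) < 200L) {
    warnf("Fickett score on %d nt (< 200 nt recommended)", length(chars))
  }
  score <- 0
  acgt_total <- sum(chars %in% c("A", "C", "G", "T"))
  for (b in c("A", "C", "G", "T")) {
    pos_counts <- vapply(0:2, function(k) {
      sum(chars[seq_along(chars) %% 3L == (k + 1L) %% 3L] == b)
    }, 0)
    position <- max(pos_counts) / (min(pos_counts) + 1)
    content <- if (acgt_total > 0) sum(chars == b) / acgt_total else 0
    pos_idx <- 1L + sum(FICKETT_POSITION_BREAKS > position)
    con_idx <- 1L + sum(FICKETT_CONTENT_BREAKS > content)
    score <- score +
      FICKETT_POSITION_PROB[b, pos_idx] * FICKETT_POSITION_WEIGHT[[b]] +
      FICKETT_CONTENT_PROB[b, con_idx] * FICKETT_CONTENT_WEIGHT[[b]]
  }
  unname(score)
}

#' Train a hexamer usage log-odds table
#'
#' In-frame hexamer frequencies from the longest ORFs of coding sequences
#' versus any-frame hexamer frequencies from noncoding sequences, as
#' log-odds with a shared pseudocount. Hexamers containing `N` are skipped.
#'
#' @param coding,noncoding character vectors (or `DNAStringSet`s) of
#'   nucleotide sequences; at least 10 per class recommended, empty is an
#'   error.
#' @param pseudocount positive real added to every hexamer count.
#' @return object of class `hexamer_table`: list with `logodds`
#'   (named numeric, 4096 entries) and `pseudocount`.
#' @export
train_hexamer_table <- function(coding, noncoding, pseudocount = 1) {
  coding <- as.character(coding); noncoding <- as.character(noncoding)
  if (length(coding) == 0L || length(noncoding) == 0L) {
    abort("both coding and noncoding corpora must be non-empty")
  }
  if (length(coding) < 10L || length(noncoding) < 10L) {
    warnf("fewer than 10 sequences in a class; hexamer table will be noisy")
  }
  check_scalar(pseudocount, "pseudocount", lo = .Machine$double.eps)
  orfs <- vapply(coding, function(s) {
    s <- toupper(s)
    o <- find_longest_orf(s)
    if (o$length_nt > 0L) substr(s, o$start + 1L, o$end) else ""
  }, "", USE.NAMES = FALSE)
  orfs <- orfs[nzchar(orfs)]
  cod_counts <- hexamer_counts(orfs, step = 3L)
  non_counts <- hexamer_counts(toupper(noncoding), step = 1L)
  f_cod <- (cod_counts + pseudocount) / (sum(cod_counts) + pseudocount * 4096)
  f_non <- (non_counts + pseudocount) / (sum(non_counts) + pseudocount * 4096)
  structure(list(logodds = log(f_cod / f_non), pseudocount = pseudocount),
            class = "hexamer_table")
}

hexamer_counts <- function(seqs, step) {
  seqs <- seqs[nchar(seqs) >= 6L]
  if (!length(seqs)) {
    return(setNames(numeric(4096),
                    Biostrings::mkAllStrings(c("A", "C", "G", "T"), 6)))
  }
  m <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = 6L, step = step)
  colSums(m)
}

#' Mean hexamer log-odds of a sequence
#'
#' Average log-odds over the in-frame hexamers of the longest ORF, or over
#' frame-0 hexamers of the whole sequence when no ORF exists. Hexamers
#' containing `N` are skipped; a sequence with no scorable hexamer scores 0.
#'
#' @param seq nucleotide string, length >= 6.
#' @param table a `hexamer_table`.
#' @return numeric score.
#' @export
hexamer_score <- function(seq, table) {
  stopifnot(inherits(table, "hexamer_table"))
  seq <- check_nt(seq, min_len = 6L)
  orf <- find_longest_orf(seq)
  sub <- if (orf$length_nt >= 6L) substr(seq, orf$start + 1L, orf$end) else seq
  counts <- hexamer_counts(sub, step = 3L)
  n <- sum(counts)
  if (n == 0) return(0)
  sum(counts * table$logodds[names(counts)]) / n
}

#' Compute the four coding-potential features of a sequence
#'
#' Features: longest-ORF length (nt), ORF coverage (ORF length over
#' transcript length), Fickett score, and mean hexamer log-odds. A terminal
#' poly(A) run is removed before feature computation, so scores are
#' invariant to poly(A) tails.
#'
#' @param seq nucleotide string.
#' @param table a `hexamer_table`.
#' @return named numeric vector
#'   `c(orf_length, orf_coverage, fickett, hexamer)`.
#' @export
coding_features <- function(seq, table) {
  seq <- check_nt(seq, min_len = 6L)
  seq <- sub("A+$", "", seq)
  if (nchar(seq) < 6L) {
    return(c(orf_length = 0, orf_coverage = 0, fickett = 0, hexamer = 0))
  }
  orf <- find_longest_orf(seq)
  fick <- suppressWarnings(fickett_score(seq))
  c(orf_length = orf$length_nt,
    orf_coverage = orf$length_nt / nchar(seq),
    fickett = fick,
    hexamer = hexamer_score(seq, table))
}

#' Train the logistic coding-potential model
#'
#' Maximum-likelihood logistic regression (IRLS, via [stats::glm()]) of the
#' coding/noncoding label on the four features. Perfect separation triggers
#' a ridge-stabilized fit (glmnet, `alpha = 0`) with a warning.
#'
#' @param features numeric matrix or data.frame, one row per sequence,
#'   columns `orf_length`, `orf_coverage`, `fickett`, `hexamer`.
#' @param labels vector with values `"coding"`/`"noncoding"` (or a logical
#'   where `TRUE` means coding); both classes must be present, n >= 40.
#' @param cutoff decision cutoff on the coding probability; below it a
#'   transcript is called noncoding. Default 0.364, the published human
#'   default of the CPAT-style model.
#' @return object of class `coding_model`: `coefficients` (length 4),
#'   `intercept`, `cutoff`, `features`.
#' @export
train_logistic <- function(features, labels, cutoff = 0.364) {
  features <- as.matrix(features)
  if (is.logical(labels)) labels <- ifelse(labels, "coding", "noncoding")
  y <- as.integer(labels == "coding")
  if (nrow(features) != length(y)) abort("features/labels length mismatch")
  if (nrow(features) < 40L) abort("need at least 40 labeled sequences")
  if (length(unique(y)) < 2L) abort("both classes must be present")
  check_scalar(cutoff, "cutoff", lo = 1e-12, hi = 1 - 1e-12)
  if (ncol(features) != 4L) abort("expected 4 feature columns")
  df <- data.frame(y = y, features)
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial(), control = list(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  separated <- !fit$converged ||
    any(abs(coef(fit)[-1L]) > 1e3, na.rm = TRUE) ||
    anyNA(coef(fit))
  if (separated) {
    warnf("(near-)perfect separation; falling back to ridge-stabilized fit")
    rf <- glmnet::glmnet(features, y, family = "binomial", alpha = 0,
                         lambda = 1e-3, standardize = TRUE)
    beta <- as.numeric(rf$beta)
    intercept <- as.numeric(rf$a0)
  } else {
    beta <- unname(coef(fit)[-1L])
    intercept <- unname(coef(fit)[1L])
  }
  structure(list(coefficients = setNames(beta, colnames(features)),
                 intercept = intercept, cutoff = cutoff,
                 features = colnames(features)),
            class = "coding_model")
}

#' @export
print.coding_model <- function(x, ...) {
  cat("<coding_model> logit(p) =", format(x$intercept, digits = 3), "+",
      paste(sprintf("%s*%s", format(x$coefficients, digits = 3),
                    x$features), collapse = " + "),
      "\n  noncoding iff p <", x$cutoff, "\n")
  invisible(x)
}

#' Coding probability of a transcript sequence
#'
#' @param seq nucleotide string (spliced transcript sequence).
#' @param model a `coding_model` from [train_logistic()].
#' @param table the `hexamer_table` the model was trained with.
#' @return probability in `[0, 1]` that the sequence is coding. A transcript
#'   is labeled noncoding iff the probability is below `model$cutoff`.
#' @export
coding_probability <- function(seq, model, table) {
  stopifnot(inherits(model, "coding_model"))
  f <- coding_features(seq, table)[model$features]
  unname(plogis(model$intercept + sum(model$coefficients * f)))
}
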