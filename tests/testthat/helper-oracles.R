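# Independent reference implementations used as oracles. These deliberately
# avoid the package's index/vectorized code paths: plain loops over plain
# data frames, so they can disagree with the implementation when it is wrong.

# Shorthand transcript constructor.
tm <- function(id, chrom, strand, starts, ends, gene = paste0(id, ".g")) {
  transcript_model(id, gene, chrom, strand,
                   data.frame(start = starts, end = ends))
}

# Quadratic-time classifier: compares one candidate against every reference
# transcript directly with interval arithmetic on 0-based half-open coords.
oracle_classify <- function(cand, ref_catalog,
                            antisense_exclusive = TRUE) {
  overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  cand_introns <- intron_chain(cand)$introns
  unknown <- cand$strand == "."
  has_eq <- FALSE; has_y <- FALSE; has_i <- FALSE
  any_exon_same <- FALSE; any_exon_opp <- FALSE; any_span <- FALSE
  for (rid in transcript_ids(ref_catalog)) {
    r <- get_transcript(ref_catalog, rid)
    if (r$chrom != cand$chrom) next
    r_span <- c(min(r$exons$start), max(r$exons$end))
    c_span <- c(min(cand$exons$start), max(cand$exons$end))
    # '='
    if (!unknown && match_intron_chains(cand, r)) has_eq <- TRUE
    # 'y': reference span inside one candidate intron
    if (nrow(cand_introns) > 0) {
      for (k in seq_len(nrow(cand_introns))) {
        if (r_span[1] >= cand_introns$start[k] &&
            r_span[2] <= cand_introns$end[k]) has_y <- TRUE
      }
    }
    # exon-exon overlaps by strand
    for (i in seq_len(nrow(cand$exons))) {
      for (j in seq_len(nrow(r$exons))) {
        if (overlaps(cand$exons$start[i], cand$exons$end[i],
                     r$exons$start[j], r$exons$end[j])) {
          if (r$strand == cand$strand) any_exon_same <- TRUE
          if ((r$strand == "+" && cand$strand == "-") ||
              (r$strand == "-" && cand$strand == "+")) {
            any_exon_opp <- TRUE
          } else if (cand$strand == ".") {
            # unknown strand: counts as overlap but not as antisense
            any_exon_same <- any_exon_same
          }
          any_span <- TRUE
        }
      }
    }
    if (overlaps(c_span[1], c_span[2], r_span[1], r_span[2])) {
      any_span <- TRUE
    }
    # 'i': candidate span inside one reference intron
    ri <- intron_chain(r)$introns
    if (nrow(ri) > 0) {
      for (k in seq_len(nrow(ri))) {
        if (c_span[1] >= ri$start[k] && c_span[2] <= ri$end[k]) {
          has_i <- TRUE
        }
      }
    }
  }
  any_exon <- any_exon_same || any_exon_opp || (cand$strand == "." && {
    # recompute ignoring strand for '.' candidates
    found <- FALSE
    for (rid in transcript_ids(ref_catalog)) {
      r <- get_transcript(ref_catalog, rid)
      if (r$chrom != cand$chrom) next
      for (i in seq_len(nrow(cand$exons))) {
        for (j in seq_len(nrow(r$exons))) {
          if (overlaps(cand$exons$start[i], cand$exons$end[i],
                       r$exons$start[j], r$exons$end[j])) found <- TRUE
        }
      }
    }
    found
  })
  if (has_eq) return("=")
  if (has_y) return("y")
  if (!unknown && any_exon_opp && (!antisense_exclusive || !any_exon_same)) {
    return("x")
  }
  if (!any_exon && has_i) return("i")
  if (any_exon || any_span) return("o*")
  "u"
}

oracle_classify_catalog <- function(cands, ref) {
  vapply(transcript_ids(cands), function(id) {
    oracle_classify(get_transcript(cands, id), ref)
  }, "")
}

# Step-up BH, written from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (k in n:1) {
    running <- min(running, p[o[k]] * n / k)
    adj[o[k]] <- running
  }
  adj
}

# Direct triple-loop TOM.
oracle_tom <- function(a) {
  n <- nrow(a)
  out <- matrix(1, n, n)
  k <- numeric(n)
  for (i in 1:n) k[i] <- sum(a[i, -i])
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    s <- 0
    for (u in 1:n) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Exhaustive ORF enumeration: every ATG, scan forward codon by codon until
# the first stop (included) or the last complete codon.
oracle_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- list(start = 0L, end = 0L, length_nt = 0L)
  for (s in seq_len(max(n - 2, 0))) {
    if (substr(seq, s, s + 2) != "ATG") next
    len <- 0L
    e <- s
    while (e + 2 <= n) {
      len <- len + 3L
      if (substr(seq, e, e + 2) %in% c("TAA", "TAG", "TGA")) break
      e <- e + 3L
    }
    if (len > best$length_nt) {
      best <- list(start = s - 1L, end = s - 1L + len, length_nt = len)
    }
  }
  best
}

# Per-base mean conservation of one exon against a track data.frame
# (chrom, start, end, score; 0-based half-open).
oracle_exon_mean <- function(chrom, start, end, track_df) {
  vals <- c(); covered <- 0
  for (pos in start:(end - 1)) {
    hit <- which(track_df$chrom == chrom & track_df$start <= pos &
                   track_df$end > pos)
    if (length(hit)) {
      vals <- c(vals, track_df$score[hit[1]])
      covered <- covered + 1
    }
  }
  list(mean = if (covered) mean(vals) else NA_real_, covered = covered)
}

# Independent scale-free power selection: adjacency by explicit loops over
# gene pairs, histogram fit with lm.
oracle_pick_beta <- function(expr, powers = 1:20, target = 0.8,
                             min_mean_k = 1) {
  n <- nrow(expr)
  cc <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) cc[i, j] <- abs(cor(expr[i, ], expr[j, ]))
  diag(cc) <- 0
  for (b in powers) {
    k <- rowSums(cc^b)
    if (mean(k) < min_mean_k) next
    br <- cut(k, 10)
    pk <- as.numeric(table(br)) / n
    mid <- tapply(k, br, mean)
    keep <- pk > 0 & !is.na(mid)
    if (sum(keep) < 3) next
    f <- lm(log10(pk[keep]) ~ log10(mid[keep]))
    if (summary(f)$r.squared >= target && coef(f)[2] < 0) return(b)
  }
  6L
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

expect_catalog_equal <- function(a, b) {
  expect_equal(as.data.frame(a$exons), as.data.frame(b$exons))
  expect_equal(as.data.frame(a$transcripts), as.data.frame(b$transcripts))
}
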