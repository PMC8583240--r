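test_that("find_longest_orf handles canonical and degenerate inputs", {
  o <- find_longest_orf("ATGAAATAG")
  expect_equal(o$start, 0L)
  expect_equal(o$length_nt, 9L)
  expect_equal(o$frame, 0L)
  sentinel <- find_longest_orf("CCCCCC")
  expect_equal(sentinel$length_nt, 0L)
  # ORF without a stop runs to the last complete codon of its frame
  open <- find_longest_orf("CATGAAAAAA")
  expect_equal(open$start, 1L)
  expect_equal(open$length_nt, 9L)
  expect_error(find_longest_orf("AXG"), "ACGTN")
})

test_that("find_longest_orf equals exhaustive enumeration on random input", {
  set.seed(8)
  for (i in 1:100) {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
    got <- find_longest_orf(seq)
    want <- oracle_orf(seq)
    expect_equal(got$length_nt, want$length_nt)
    expect_equal(got$start, want$start)
  }
})

test_that("fickett_score is deterministic, case-insensitive and bounded", {
  set.seed(9)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  expect_identical(fickett_score(seq), fickett_score(seq))
  expect_identical(fickett_score(seq), fickett_score(tolower(seq)))
  expect_gt(fickett_score(seq), 0)
  expect_lt(fickett_score(seq), 1.7)  # sum of all table maxima bound
  expect_warning(fickett_score("ATGATGATG"), "200 nt")
  expect_error(suppressWarnings(fickett_score("ANNNNNNNNA")), "10%")
})

test_that("poly-A input reproduces the hand-computed table lookup", {
  # position parameter: A = 100/101 (< 1.1 bin), C/G/T = 0 (< 1.1 bin);
  # content: A = 1.0 (>= 0.33 bin), C/G/T = 0 (< 0.17 bin)
  want <- 0.22 * 0.26 + 0.23 * 0.18 + 0.08 * 0.31 + 0.09 * 0.33 +
    0.28 * 0.11 + 0.39 * 0.12 + 0.33 * 0.15 + 0.51 * 0.14
  expect_equal(fickett_score(strrep("A", 300)), want)
})

test_that("codon-structured sequences outscore their shuffles on average", {
  sq <- generate_sequences(400, 0.5, seed = 7)
  coding <- sq$seqs[sq$labels$label == "coding"]
  shuffled <- sq$seqs[sq$labels$label == "noncoding"]
  f <- function(s) suppressWarnings(fickett_score(s))
  expect_gt(mean(vapply(coding, f, 0)), mean(vapply(shuffled, f, 0)))
})

test_that("hexamer table training obeys its symmetries", {
  sq <- generate_sequences(40, 1, seed = 15)
  same <- train_hexamer_table(sq$seqs[1:20], sq$seqs[1:20])
  # identical corpora give log-odds 0 only when counted the same way;
  # in-frame vs any-frame counting differs, so use literal identical counts
  s <- c("ATGAAACCCGGGTTTTAA", "ATGCCCAAAGGGTTTTAA")
  s <- rep(s, 10)
  tab <- suppressWarnings(train_hexamer_table(s, s))
  expect_true(all(is.finite(tab$logodds)))
  # a hexamer absent from both corpora is 0 by pseudocount symmetry
  absent <- setdiff(names(tab$logodds),
                    unlist(lapply(s, function(x) {
                      substring(x, 1:(nchar(x) - 5), 6:nchar(x))
                    })))
  expect_true(all(tab$logodds[absent[1:100]] ==
                    tab$logodds[absent[1]]) || length(absent) == 0)
  expect_error(train_hexamer_table(character(0), s), "non-empty")
})

test_that("hexamer_score averages the in-frame table entries", {
  tab <- structure(list(
    logodds = setNames(numeric(4096),
                       Biostrings::mkAllStrings(c("A", "C", "G", "T"), 6)),
    pseudocount = 1), class = "hexamer_table")
  expect_equal(hexamer_score("ACGTACGTACGT", tab), 0)
  tab$logodds["AAACCC"] <- 1.5
  # no ORF here, whole sequence in frame 0 is the single hexamer AAACCC
  expect_equal(hexamer_score("AAACCC", tab), 1.5)
})

test_that("trained hexamer scores separate planted coding sequences", {
  sq <- generate_sequences(500, 0.6, seed = 11)
  coding <- sq$seqs[sq$labels$label == "coding"]
  noncod <- sq$seqs[sq$labels$label == "noncoding"]
  tab <- train_hexamer_table(coding[1:100], noncod[1:100])
  held_out <- coding[101:300]
  pos <- vapply(held_out, hexamer_score, 0, table = tab)
  expect_gte(mean(pos > 0), 0.95)
})

test_that("logistic training behaves under null, separable and real cases", {
  sq <- generate_sequences(400, 0.5, seed = 5)
  tab <- train_hexamer_table(sq$seqs[sq$labels$label == "coding"][1:80],
                             sq$seqs[sq$labels$label == "noncoding"][1:80])
  feats <- t(vapply(sq$seqs, coding_features, numeric(4), table = tab))

  # permuted labels: accuracy near the majority-class rate
  set.seed(3)
  perm <- sample(sq$labels$label)
  m0 <- suppressWarnings(train_logistic(feats, perm))
  p0 <- plogis(m0$intercept + feats %*% m0$coefficients)
  acc0 <- mean((p0 > 0.5) == (perm == "coding"))
  expect_lt(abs(acc0 - max(mean(perm == "coding"),
                           1 - mean(perm == "coding"))), 0.1)

  # a perfectly separating feature gives AUC 1 on the training set
  sep <- cbind(orf_length = ifelse(sq$labels$label == "coding", 1, 0),
               orf_coverage = 0, fickett = 0, hexamer = 0)
  msep <- suppressWarnings(train_logistic(sep, sq$labels$label))
  psep <- plogis(msep$intercept + sep %*% msep$coefficients)
  expect_gt(min(psep[sq$labels$label == "coding"]),
            max(psep[sq$labels$label == "noncoding"]))

  # held-out accuracy >= 0.9 on the synthetic benchmark
  idx <- seq(1, 400, by = 2)          # alternate rows: both classes present
  m <- train_logistic(feats[idx, ], sq$labels$label[idx])
  p <- plogis(m$intercept + feats[-idx, ] %*% m$coefficients)
  expect_gte(mean((p > 0.5) == (sq$labels$label[-idx] == "coding")), 0.9)

  expect_error(train_logistic(feats[1:30, ], sq$labels$label[1:30]),
               "40")
  expect_error(train_logistic(feats, rep("coding", nrow(feats))),
               "both classes")
})

test_that("coding_probability follows the logistic contract", {
  tab <- structure(list(
    logodds = setNames(numeric(4096),
                       Biostrings::mkAllStrings(c("A", "C", "G", "T"), 6)),
    pseudocount = 1), class = "hexamer_table")
  zero <- structure(list(coefficients = setNames(numeric(4),
                                                 c("orf_length",
                                                   "orf_coverage",
                                                   "fickett", "hexamer")),
                         intercept = 0, cutoff = 0.364,
                         features = c("orf_length", "orf_coverage",
                                      "fickett", "hexamer")),
                    class = "coding_model")
  expect_equal(coding_probability("ATGAAACCCGGGTAA", zero, tab), 0.5)

  # monotone in ORF length when its coefficient is positive
  mono <- zero
  mono$coefficients["orf_length"] <- 0.01
  short <- paste0("ATG", strrep("AAA", 10), "TAACCCCCC")
  long <- paste0("ATG", strrep("AAA", 40), "TAACCCCCC")
  expect_gt(coding_probability(long, mono, tab),
            coding_probability(short, mono, tab))
})

test_that("planted noncoding sequences mostly fall below the cutoff", {
  sq <- generate_sequences(400, 0.5, seed = 5)
  tab <- train_hexamer_table(sq$seqs[sq$labels$label == "coding"][1:100],
                             sq$seqs[sq$labels$label == "noncoding"][1:100])
  feats <- t(vapply(sq$seqs, coding_features, numeric(4), table = tab))
  idx <- seq(1, 400, by = 2)
  model <- train_logistic(feats[idx, ], sq$labels$label[idx])
  non <- sq$seqs[sq$labels$label == "noncoding"]
  probs <- vapply(non, coding_probability, 0, model = model, table = tab)
  expect_gte(mean(probs < model$cutoff), 0.9)
})

test_that("features are invariant to a trailing poly-A tail", {
  sq <- generate_sequences(10, 1, seed = 33)
  s <- sq$seqs[[1]]
  tab <- structure(list(
    logodds = setNames(rep(0.1, 4096),
                       Biostrings::mkAllStrings(c("A", "C", "G", "T"), 6)),
    pseudocount = 1), class = "hexamer_table")
  base <- coding_features(s, tab)
  tailed <- coding_features(paste0(s, strrep("A", 30)), tab)
  expect_equal(base, tailed)
})
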