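test_that("reference index answers overlap queries like a linear scan", {
  empty <- build_reference_index(annotation_catalog(data.frame(
    transcript_id = character(0), gene_id = character(0),
    chrom = character(0), start = numeric(0), end = numeric(0),
    strand = character(0))))
  expect_equal(length(empty$exons), 0)
  expect_equal(length(empty$spans), 0)

  ref <- generate_reference(30, seed = 21)
  index <- build_reference_index(ref)
  ex <- as.data.frame(ref$exons)
  set.seed(21)
  for (q in 1:100) {
    chrom <- sample(unique(ex$chrom), 1)
    s <- sample.int(1.5e6, 1); e <- s + sample.int(5000, 1)
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1, e)),
      index$exons, ignore.strand = TRUE)
    got <- sort(unique(
      S4Vectors::mcols(index$exons)$transcript_id[
        S4Vectors::subjectHits(hits)]))
    want <- sort(unique(ex$transcript_id[
      ex$chrom == chrom & ex$start < e & s < ex$end]))
    expect_equal(got, want)
  }
})

test_that("intron-chain matching permits terminal slack but not shifts", {
  a <- tm("a", "chr1", "+", c(100, 500, 900), c(200, 600, 1000))
  expect_true(match_intron_chains(a, a))
  b <- tm("b", "chr1", "+", c(50, 500, 900), c(200, 600, 1080))
  expect_true(match_intron_chains(a, b))
  expect_true(match_intron_chains(b, a))  # symmetry
  shifted <- tm("c", "chr1", "+", c(100, 501, 900), c(200, 600, 1000))
  expect_false(match_intron_chains(a, shifted))
  opp <- tm("d", "chr1", "-", c(100, 500, 900), c(200, 600, 1000))
  expect_false(match_intron_chains(a, opp))
  # single-exon pairs: same-strand overlap rule
  s1 <- tm("s1", "chr1", "+", 100, 300)
  s2 <- tm("s2", "chr1", "+", 250, 500)
  s3 <- tm("s3", "chr1", "+", 300, 500)
  expect_true(match_intron_chains(s1, s2))
  expect_false(match_intron_chains(s1, s3))
  expect_false(match_intron_chains(s1, a))
})

test_that("classify_transcript assigns the expected codes", {
  ref <- annotation_catalog(data.frame(
    transcript_id = c("r1", "r1", "r1", "r2"),
    gene_id = c("gr1", "gr1", "gr1", "gr2"),
    chrom = "chr1",
    start = c(1000, 3000, 5000, 3400),
    end = c(1500, 3500, 5600, 3600),
    strand = c("+", "+", "+", "-")))
  index <- build_reference_index(ref)
  # identical to r1
  eq <- classify_transcript(get_transcript(ref, "r1"), index)
  expect_equal(eq$code, "=")
  expect_equal(eq$best_ref, "r1")
  # nothing within 10 kb
  far <- classify_transcript(tm("f", "chr1", "+", c(5e5, 5.1e5),
                                c(5.005e5, 5.11e5)), index)
  expect_equal(far$code, "u")
  expect_true(is.na(far$best_ref))
  # inside r1's first intron, no exon overlap (r2 is exonic there, avoid it)
  intr <- classify_transcript(tm("i", "chr1", "+", c(1600, 2500),
                                 c(1900, 2800)), index)
  expect_equal(intr$code, "i")
  # antisense exonic overlap
  anti <- classify_transcript(tm("x", "chr1", "-", c(1200, 2500),
                                 c(1600, 2600)), index)
  expect_equal(anti$code, "x")
  # same-strand partial exon overlap falls into the catch-all
  part <- classify_transcript(tm("o", "chr1", "+", c(1200, 2500),
                                 c(1600, 2600)), index)
  expect_equal(part$code, "o*")
  # strand '.' skips strand-dependent codes
  dot <- classify_transcript(tm("d", "chr1", ".", c(1200, 2500),
                                c(1600, 2600)), index)
  expect_equal(dot$code, "o*")
  expect_match(dot$evidence, "strand")
})

test_that("classify_catalog matches itself and flags foreign chromosomes", {
  ref <- generate_reference(15, seed = 31)
  self <- suppressMessages(classify_catalog(ref, ref))
  expect_true(all(self$code == "="))
  expect_equal(self$best_ref, self$candidate_id)

  foreign <- annotation_catalog(data.frame(
    transcript_id = "t", gene_id = "g", chrom = "chr9",
    start = c(100, 900), end = c(400, 1200), strand = "+"))
  expect_warning(
    res <- suppressMessages(classify_catalog(foreign, ref)),
    "absent from reference")
  expect_equal(res$code, "u")
})

test_that("classification equals the quadratic oracle on random fixtures", {
  set.seed(77)
  for (rep in 1:4) {
    ref <- generate_reference(25, seed = 100 + rep)
    plan <- c("=" = 3, u = 5, i = 4, x = 3, y = 1)
    planted <- generate_candidates(ref, plan, seed = 200 + rep)
    # add fully random candidates to cover the catch-all patterns
    rnd <- lapply(1:15, function(k) {
      n_ex <- sample(1:3, 1)
      w <- sample(100:2000, n_ex, replace = TRUE)
      gaps <- sample(200:5000, n_ex, replace = TRUE)
      starts <- sample.int(1.5e6, 1) + cumsum(c(0, (w + gaps)[-n_ex]))
      data.frame(transcript_id = sprintf("RND%d_%d", rep, k),
                 gene_id = sprintf("RND%d_%d.g", rep, k),
                 chrom = sample(c("chr1", "chr2"), 1),
                 start = starts, end = starts + w,
                 strand = sample(c("+", "-"), 1))
    })
    rnd <- annotation_catalog(do.call(rbind, rnd))
    cands <- bind_catalogs(planted$catalog, rnd)
    got <- suppressMessages(suppressWarnings(classify_catalog(cands, ref)))
    want <- oracle_classify_catalog(cands, ref)
    expect_equal(setNames(got$code, got$candidate_id), want)
  }
})

test_that("classification is independent of candidate order", {
  ref <- generate_reference(20, seed = 41)
  cand <- generate_candidates(ref, c(u = 5, i = 4, x = 3), seed = 41)
  fwd <- suppressMessages(classify_catalog(cand$catalog, ref))
  ids_rev <- rev(transcript_ids(cand$catalog))
  rev_cat <- subset_catalog(cand$catalog, ids_rev)
  bwd <- suppressMessages(classify_catalog(rev_cat, ref))
  m <- match(fwd$candidate_id, bwd$candidate_id)
  expect_equal(fwd$code, bwd$code[m])
  expect_equal(fwd$best_ref, bwd$best_ref[m])
})
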