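test_that("generators are bit-reproducible and stream-isolated", {
  r1 <- generate_reference(20, seed = 55)
  r2 <- generate_reference(20, seed = 55)
  expect_catalog_equal(r1, r2)
  expect_false(identical(as.data.frame(generate_reference(20, seed = 56)$exons),
                         as.data.frame(r1$exons)))
  # derive_seed gives distinct per-label streams
  expect_false(derive_seed(55, "reference") == derive_seed(55, "candidates"))
  expect_equal(derive_seed(55, "reference"), derive_seed(55, "reference"))
  # the global RNG stream is left untouched
  set.seed(999); before <- runif(1)
  set.seed(999); invisible(generate_reference(5, seed = 1)); after <- runif(1)
  expect_equal(before, after)
})

test_that("reference genes are disjoint and span both strands", {
  ref <- generate_reference(50, seed = 57, chrom_sizes = c(chr1 = 1e6,
                                                           chr2 = 1e6))
  tx <- as.data.frame(ref$transcripts)
  for (cn in unique(tx$chrom)) {
    s <- tx[tx$chrom == cn, ]
    s <- s[order(s$tx_start), ]
    if (nrow(s) > 1) {
      expect_true(all(s$tx_start[-1] >= head(s$tx_end, -1)))
    }
  }
  expect_setequal(unique(tx$strand), c("+", "-"))
  expect_equal(length(generate_reference(0, seed = 1)), 0)
  expect_error(generate_reference(500, seed = 1,
                                  chrom_sizes = c(chr1 = 1e5)),
               "too small")
})

test_that("candidate plans are honored and infeasible plans rejected", {
  ref <- generate_reference(30, seed = 59)
  plan <- c("=" = 3, u = 19, i = 13, x = 5, y = 1)
  cand <- generate_candidates(ref, plan, seed = 59)
  expect_equal(length(cand$catalog), sum(plan))
  expect_equal(unname(table(cand$truth$true_code)[names(plan)]),
               unname(plan), ignore_attr = TRUE)
  expect_setequal(cand$truth$transcript_id, transcript_ids(cand$catalog))
  # zero jitter reproduces the reference template exactly
  exact <- generate_candidates(ref, c("=" = 2), seed = 59, jitter = 0)
  for (i in 1:2) {
    t <- get_transcript(exact$catalog, exact$truth$transcript_id[i])
    r <- get_transcript(ref, exact$truth$template_ref[i])
    expect_equal(t$exons, r$exons)
  }
  # 'i' needs reference introns
  single <- annotation_catalog(data.frame(
    transcript_id = "s", gene_id = "s.g", chrom = "chr1",
    start = 5000, end = 6000, strand = "+"))
  expect_error(generate_candidates(single, c(i = 1), seed = 1,
                                   chrom_sizes = c(chr1 = 1e5)),
               "intron")
})

test_that("sequence corpora have exact composition-preserving shuffles", {
  sq0 <- generate_sequences(20, 0, seed = 61)
  expect_true(all(sq0$labels$label == "noncoding"))
  sq <- generate_sequences(30, 0.5, seed = 61)
  expect_equal(sum(sq$labels$label == "coding"), 15)
  # dinucleotide (and GC) content is preserved exactly by the shuffle
  s <- sq$seqs[[1]]
  sh <- dinuc_shuffle(s)
  expect_equal(nchar(sh), nchar(s))
  din <- function(x) {
    table(substring(x, 1:(nchar(x) - 1), 2:nchar(x)))
  }
  d1 <- din(s); d2 <- din(sh)
  expect_setequal(names(d1), names(d2))
  expect_equal(as.vector(d1[names(d1)]), as.vector(d2[names(d1)]))
  gc <- function(x) mean(strsplit(x, "")[[1]] %in% c("G", "C"))
  expect_equal(gc(s), gc(sh), tolerance = 1e-9)
})

test_that("conservation tracks reflect their class parameters", {
  ref <- generate_reference(20, seed = 63, lncrna_fraction = 0.5)
  tr1 <- generate_conservation_track(ref, seed = 63)
  tr2 <- generate_conservation_track(ref, seed = 63)
  expect_equal(as.data.frame(tr1$granges), as.data.frame(tr2$granges))
  # symmetric Beta parameters give class means near 0.5
  flat <- generate_conservation_track(
    ref, class_params = list(mRNA = c(5, 5), lncRNA = c(5, 5),
                             default = c(5, 5)), seed = 63)
  sc <- exon_mean_scores(ref, flat)
  expect_lt(abs(mean(sc$mean_score, na.rm = TRUE) - 0.5), 0.02)
})

test_that("expression generator plants effects, modules and the design", {
  sim <- generate_expression(100, 10, seed = 65,
                             de = list(n = 8, effect = 2),
                             modules = list(list(size = 20, loading = 0.9,
                                                 trait_cor = 0.5)))
  expect_equal(dim(sim$tpm), c(100, 20))
  expect_equal(colSums(sim$tpm), setNames(rep(1e6, 20),
                                          colnames(sim$tpm)),
               tolerance = 1e-6)
  expect_s3_class(sim$design, "paired_design")
  expect_equal(nrow(sim$truth$de), 8)
  expect_equal(nrow(sim$truth$modules), 20)
  expect_true(all(sim$counts >= 0))
  expect_error(generate_expression(10, 10, seed = 1,
                                   modules = list(list(size = 11,
                                                       loading = 0.9))),
               "exceed")
  expect_error(generate_expression(10, 2, seed = 1), "3 subject pairs")
  # all-unity effects mean a global null
  null_sim <- generate_expression(50, 10, seed = 66,
                                  de = list(n = 10, effect = 1))
  res <- paired_de_test(null_sim$tpm, null_sim$design)
  expect_gt(min(res$pvalue, na.rm = TRUE), 1e-6)
})

test_that("SNP planting is deterministic and respects categories", {
  ref <- generate_reference(10, seed = 67)
  target <- transcript_ids(ref)[1]
  g1 <- generate_snps(ref, target, seed = 67, in_exon = 3, decoys = 5,
                      weak = 4)
  g2 <- generate_snps(ref, target, seed = 67, in_exon = 3, decoys = 5,
                      weak = 4)
  expect_equal(g1$table, g2$table)
  f <- tempfile(); write_snp_table(g1$table, f)
  loaded <- read_snp_table(f)
  # weak rows are filtered on load
  expect_equal(nrow(loaded), 8)
  ov <- overlap_exons_with_snps(ref, loaded)
  expect_setequal(ov$snp_id[ov$transcript_id == target],
                  g1$truth$snp_id[g1$truth$category == "in_exon"])
  none <- generate_snps(ref, target, seed = 68, in_exon = 0, decoys = 5)
  f2 <- tempfile(); write_snp_table(none$table, f2)
  ov0 <- overlap_exons_with_snps(subset_catalog(ref, target),
                                 read_snp_table(f2))
  expect_equal(nrow(ov0), 0)
})
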