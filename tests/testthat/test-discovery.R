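# Shared lightweight coding model for criteria tests: trained once per file.
local_coding_model <- local({
  sq <- generate_sequences(300, 0.5, seed = 5)
  tab <- train_hexamer_table(sq$seqs[sq$labels$label == "coding"][1:80],
                             sq$seqs[sq$labels$label == "noncoding"][1:80])
  feats <- t(vapply(sq$seqs, coding_features, numeric(4), table = tab))
  list(model = train_logistic(feats, sq$labels$label), table = tab,
       corpus = sq)
})

test_that("prevalence filter keeps features seen in at least half the samples", {
  m <- matrix(0, 3, 10,
              dimnames = list(c("zero", "half", "most"), paste0("s", 1:10)))
  m["half", 1:5] <- 3
  m["most", 1:9] <- 1
  expect_setequal(prevalence_filter(m, 0.5), c("half", "most"))
  # planted: exactly 40 of 100 rows above threshold
  set.seed(123)
  plan <- matrix(0, 100, 20, dimnames = list(sprintf("f%03d", 1:100), NULL))
  hot <- sample(100, 40)
  plan[hot, 1:12] <- 5
  cold <- setdiff(1:100, hot)
  plan[cold, 1:7] <- 5
  expect_setequal(prevalence_filter(plan, 0.5),
                  rownames(plan)[hot])
  expect_error(prevalence_filter(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(prevalence_filter(m - 1), "non-negative")
})

test_that("novelty criteria pass and fail for the documented reasons", {
  ref <- generate_reference(10, seed = 51)
  cands <- annotation_catalog(data.frame(
    transcript_id = rep(c("good", "badchrom"), each = 2),
    gene_id = rep(c("good.g", "badchrom.g"), each = 2),
    chrom = rep(c("chr5", "chrY"), each = 2),
    start = c(1000, 2000, 1000, 2000),
    end = c(1300, 2300, 1300, 2300),
    strand = "+"))
  codes <- data.frame(candidate_id = c("good", "badchrom"),
                      code = c("u", "u"),
                      best_ref = NA_character_, evidence = "")
  non <- local_coding_model$corpus$seqs[
    local_coding_model$corpus$labels$label == "noncoding"][1:2]
  seqs <- setNames(as.character(non), c("good", "badchrom"))
  rep1 <- apply_novelty_criteria(cands, codes, seqs,
                                 local_coding_model$model,
                                 local_coding_model$table)
  expect_true(rep1$pass[rep1$transcript_id == "good"])
  bad <- rep1[rep1$transcript_id == "badchrom", ]
  expect_false(bad$pass)
  expect_false(bad$pass_chrom)
  expect_true(bad$pass_length && bad$pass_multiexon && bad$pass_code)
  # a candidate without a sequence fails criterion v with a reason
  rep2 <- apply_novelty_criteria(cands, codes, seqs["good"],
                                 local_coding_model$model,
                                 local_coding_model$table)
  nos <- rep2[rep2$transcript_id == "badchrom", ]
  expect_false(nos$pass_noncoding)
  expect_true(is.na(nos$coding_prob))
})

test_that("criteria are monotone in their thresholds", {
  ref <- generate_reference(20, seed = 61)
  cand <- generate_candidates(ref, c(u = 10, i = 5), seed = 61)
  codes <- suppressMessages(classify_catalog(cand$catalog, ref))
  labels <- local_coding_model$corpus$labels$label
  non <- local_coding_model$corpus$seqs[labels == "noncoding"]
  seqs <- setNames(as.character(non[seq_len(length(cand$catalog))]),
                   transcript_ids(cand$catalog))
  base <- apply_novelty_criteria(cand$catalog, codes, seqs,
                                 local_coding_model$model,
                                 local_coding_model$table)
  strict_len <- apply_novelty_criteria(
    cand$catalog, codes, seqs, local_coding_model$model,
    local_coding_model$table, discovery_config(min_length_nt = 700))
  strict_cut <- apply_novelty_criteria(
    cand$catalog, codes, seqs, local_coding_model$model,
    local_coding_model$table, discovery_config(coding_cutoff = 0.05))
  expect_true(all(strict_len$pass <= base$pass))
  expect_true(all(strict_cut$pass <= base$pass))
})

test_that("cross-platform validation matches exactly the shared chains", {
  ref <- generate_reference(20, seed = 71)
  a <- generate_candidates(ref, c(u = 8, i = 4), seed = 71)
  # identical sets validate completely
  self <- cross_platform_validate(a$catalog, a$catalog)
  expect_equal(nrow(self$pairs), length(a$catalog))
  expect_equal(length(self$unmatched_a), 0)
  # disjoint chromosomes validate nothing
  moved <- as.data.frame(a$catalog$exons)
  moved$chrom <- "chr17"
  none <- cross_platform_validate(a$catalog, annotation_catalog(moved))
  expect_equal(nrow(none$pairs), 0)
  expect_equal(length(none$unmatched_a), length(a$catalog))
  # jittered copies of a subset validate exactly that subset
  shared <- transcript_ids(a$catalog)[c(2, 5, 7)]
  b <- make_jittered_copies(a$catalog, shared, seed = 72)
  res <- cross_platform_validate(a$catalog, b)
  expect_setequal(res$pairs$id_a, shared)
  expect_setequal(res$pairs$id_b, paste0(shared, "_nano"))
  expect_setequal(transcript_ids(res$validated), shared)
})

test_that("database re-annotation partitions validated transcripts", {
  ref <- generate_reference(20, seed = 81)
  cand <- generate_candidates(ref, c(u = 6), seed = 81)
  # the candidate itself in a db -> previously annotated
  res_self <- annotate_against_databases(cand$catalog,
                                         list(self = cand$catalog))
  expect_true(all(res_self$status == "previously_annotated"))
  expect_true(all(res_self$match_type == "intron_chain"))
  # empty database list -> everything novel, with a warning
  expect_warning(res_empty <- annotate_against_databases(cand$catalog,
                                                         list()),
                 "novel")
  expect_true(all(res_empty$status == "novel"))
  # partial db with jittered copies
  known <- transcript_ids(cand$catalog)[1:4]
  db <- make_jittered_copies(cand$catalog, known, seed = 82,
                             id_suffix = "_db")
  res <- annotate_against_databases(cand$catalog, list(mockdb = db))
  expect_setequal(res$transcript_id[res$status == "previously_annotated"],
                  known)
  expect_equal(sum(res$status == "novel"), length(cand$catalog) - 4)
  # chain_only mode ignores plain exon overlap
  half <- as.data.frame(subset_catalog(cand$catalog, known)$exons)
  half$transcript_id <- paste0(half$transcript_id, "_ov")
  half$gene_id <- paste0(half$gene_id, "_ov")
  # single-exon overlapping fragments: exon overlap only, no chain match
  half <- half[!duplicated(half$transcript_id), ]
  db_ov <- annotation_catalog(half)
  res_chain <- annotate_against_databases(cand$catalog, list(ov = db_ov),
                                          db_match_mode = "chain_only")
  expect_true(all(res_chain$status == "novel"))
  res_ov <- annotate_against_databases(cand$catalog, list(ov = db_ov))
  expect_setequal(res_ov$transcript_id[res_ov$status ==
                                         "previously_annotated"], known)
})
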