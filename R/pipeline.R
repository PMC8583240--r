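# End-to-end orchestration: discover -> conserve -> DE -> modules -> eQTL
# from one YAML config, with per-stage record counts collected into a run
# report. Reports carry no timestamps, so identical config + seed gives
# byte-identical output.

#' Default run configuration
#'
#' @param ... named overrides of the defaults (see Details).
#' @details Fields: input paths (`reference`, `candidates`, `validation`,
#'   `sequences`, `counts`, `tpm`, `lengths`, `design`, `dbs` (named list),
#'   `snps`, `track`, `egene_pairs`), thresholds (`discovery` sub-list as
#'   in [discovery_config()]; `de` sub-list `max_padj`, `min_fc`,
#'   `min_tpm`, `min_detect_frac`; `network` sub-list `beta` (integer or
#'   `"auto"`), `cut_height`, `min_size`, `kme_threshold`;
#'   `eqtl_p_threshold`), and `seed`. Optional stages (`track`, `snps`,
#'   `counts`) are skipped when their path is `NULL`.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    reference = NULL, candidates = NULL, validation = NULL,
    sequences = NULL, counts = NULL, tpm = NULL, lengths = NULL,
    design = NULL, dbs = list(), snps = NULL, track = NULL,
    egene_pairs = NULL,
    discovery = list(min_sample_fraction = 0.5, min_length_nt = 201,
                     allowed_codes = c("u", "i", "x", "y"),
                     coding_cutoff = 0.364),
    de = list(max_padj = 0.001, min_fc = 1.2, min_tpm = 0.5,
              min_detect_frac = 0.9),
    network = list(beta = 6, cut_height = 0.99, min_size = 10,
                   kme_threshold = 0.7, restrict_hubs_to_de = TRUE),
    eqtl_p_threshold = 1e-8,
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      utils::modifyList(cfg[[nm]], over[[nm]])
    } else over[[nm]]
  }
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#' @param path YAML file; relative input paths are resolved against its
#'   directory.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base, p)
  }
  for (f in c("reference", "candidates", "validation", "sequences",
              "counts", "tpm", "lengths", "design", "snps", "track",
              "egene_pairs")) {
    cfg[[f]] <- fix(cfg[[f]])
  }
  cfg$dbs <- lapply(cfg$dbs, fix)
  cfg
}

#' Validate a run configuration
#'
#' @param cfg a `run_config`.
#' @return character vector of problems; empty when runnable.
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  need <- function(field) {
    if (is.null(cfg[[field]])) {
      problems <<- c(problems, sprintf("missing required path '%s'", field))
    } else if (!file.exists(cfg[[field]])) {
      problems <<- c(problems,
                     sprintf("%s file not found: %s", field, cfg[[field]]))
    }
  }
  for (f in c("reference", "candidates", "validation", "sequences")) need(f)
  for (f in c("counts", "tpm", "lengths", "design", "snps", "track",
              "egene_pairs")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      problems <- c(problems,
                    sprintf("%s file not found: %s", f, cfg[[f]]))
    }
  }
  for (db in names(cfg$dbs)) {
    if (!file.exists(cfg$dbs[[db]])) {
      problems <- c(problems,
                    sprintf("database '%s' not found: %s", db, cfg$dbs[[db]]))
    }
  }
  d <- cfg$discovery
  if (d$min_sample_fraction <= 0 || d$min_sample_fraction > 1) {
    problems <- c(problems, "discovery$min_sample_fraction outside (0, 1]")
  }
  if (d$min_length_nt < 1) problems <- c(problems,
                                         "discovery$min_length_nt < 1")
  if (d$coding_cutoff <= 0 || d$coding_cutoff >= 1) {
    problems <- c(problems, "discovery$coding_cutoff outside (0, 1)")
  }
  nw <- cfg$network
  if (!identical(nw$beta, "auto") && (!is.numeric(nw$beta) || nw$beta < 1)) {
    problems <- c(problems, "network$beta must be 'auto' or >= 1")
  }
  if (nw$min_size < 1) problems <- c(problems, "network$min_size < 1")
  if (nw$cut_height <= 0 || nw$cut_height > 1) {
    problems <- c(problems, "network$cut_height outside (0, 1]")
  }
  if (nw$kme_threshold <= 0 || nw$kme_threshold >= 1) {
    problems <- c(problems, "network$kme_threshold outside (0, 1)")
  }
  de <- cfg$de
  if (de$max_padj <= 0 || de$max_padj > 1) {
    problems <- c(problems, "de$max_padj outside (0, 1]")
  }
  if (de$min_fc < 1) problems <- c(problems, "de$min_fc < 1")
  if (cfg$eqtl_p_threshold <= 0 || cfg$eqtl_p_threshold > 1) {
    problems <- c(problems, "eqtl_p_threshold outside (0, 1]")
  }
  problems
}

#' Run the full discovery and characterization pipeline
#'
#' Stages: classify candidates from both platforms against the reference;
#' apply the novelty criteria (plus the prevalence filter when counts are
#' given); cross-platform validate by intron-chain identity; re-annotate
#' against database catalogs; then, where the corresponding inputs exist,
#' profile exon conservation, run the paired differential test with
#' high-confidence selection, build the co-expression network with module
#' eigengenes/kME/hubs, and intersect novel lncRNA exons with eSNPs. The
#' coding-potential model is trained at run time from a synthetic labeled
#' corpus derived from the run seed. All stage outputs are TSV/GTF files
#' under `out_dir`; the run report is returned and serialized as JSON and
#' text.
#'
#' @param cfg a `run_config` (or path to a YAML config).
#' @param out_dir output directory, created if needed.
#' @return the run report (list), invisibly also written to
#'   `out_dir/report.json` and `out_dir/report.txt`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  problems <- validate_config(cfg)
  if (length(problems)) {
    abort("invalid configuration:\n%s",
          paste(paste0("  - ", problems), collapse = "\n"))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(tool = "lncforge", seed = cfg$seed, stages = list())
  note <- function(stage, ...) {
    report$stages[[stage]] <<- c(report$stages[[stage]] %||% list(),
                                 list(...))
    message(sprintf("[%s] %s", stage,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
  }

  # --- discover -------------------------------------------------------------
  ref <- read_gtf(cfg$reference)
  cand_a <- read_gtf(cfg$candidates)
  cand_b <- read_gtf(cfg$validation)
  seqs <- Biostrings::readDNAStringSet(cfg$sequences)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  note("discover", reference_transcripts = length(ref),
       candidates_a = length(cand_a), candidates_b = length(cand_b))

  corpus <- generate_sequences(200, 0.5,
                               seed = derive_seed(cfg$seed, "coding-model"))
  table <- train_hexamer_table(
    corpus$seqs[corpus$labels$label == "coding"],
    corpus$seqs[corpus$labels$label == "noncoding"])
  feats <- t(vapply(corpus$seqs, coding_features, numeric(4),
                    table = table))
  model <- train_logistic(feats, corpus$labels$label,
                          cutoff = cfg$discovery$coding_cutoff)

  dcfg <- discovery_config(
    min_sample_fraction = cfg$discovery$min_sample_fraction,
    min_length_nt = cfg$discovery$min_length_nt,
    allowed_codes = cfg$discovery$allowed_codes,
    coding_cutoff = cfg$discovery$coding_cutoff)

  index <- build_reference_index(ref)
  codes_a <- classify_catalog(cand_a, index)
  codes_b <- classify_catalog(cand_b, index)
  write_classification(codes_a, file.path(out_dir, "classification_a.tsv"))
  write_classification(codes_b, file.path(out_dir, "classification_b.tsv"))

  crit_a <- apply_novelty_criteria(cand_a, codes_a, as.character(seqs),
                                   model, table, dcfg)
  crit_b <- apply_novelty_criteria(cand_b, codes_b, as.character(seqs),
                                   model, table, dcfg)
  surv_a <- crit_a$transcript_id[crit_a$pass]
  if (!is.null(cfg$counts)) {
    counts <- read_expression_matrix(cfg$counts)
    prev <- prevalence_filter(counts, dcfg$min_sample_fraction)
    note("discover", prevalence_survivors = length(prev))
    surv_a <- intersect(surv_a, prev)
  }
  surv_b <- crit_b$transcript_id[crit_b$pass]
  data.table::fwrite(crit_a, file.path(out_dir, "criteria_a.tsv"),
                     sep = "\t")
  data.table::fwrite(crit_b, file.path(out_dir, "criteria_b.tsv"),
                     sep = "\t")
  note("discover", criteria_survivors_a = length(surv_a),
       criteria_survivors_b = length(surv_b))

  xval <- cross_platform_validate(subset_catalog(cand_a, surv_a),
                                  subset_catalog(cand_b, surv_b))
  validated <- xval$validated
  note("discover", cross_platform_validated = nrow(xval$pairs))
  write_gtf(validated, file.path(out_dir, "validated.gtf"))

  dbs <- lapply(cfg$dbs, read_gtf)
  ann <- annotate_against_databases(validated, dbs)
  novel_ids <- ann$transcript_id[ann$status == "novel"]
  data.table::fwrite(ann, file.path(out_dir, "novelty.tsv"), sep = "\t")
  note("discover", previously_annotated = sum(ann$status ==
                                                "previously_annotated"),
       novel = length(novel_ids))
  novel_catalog <- subset_catalog(validated, novel_ids)
  write_gtf(novel_catalog, file.path(out_dir, "novel.gtf"))

  # --- conserve -------------------------------------------------------------
  if (!is.null(cfg$track)) {
    track <- read_score_track(cfg$track)
    classes <- c(
      setNames(rep("novel_lncRNA", length(novel_ids)), novel_ids),
      setNames(ifelse(ref$transcripts$biotype %in% "mRNA", "mRNA",
                      "annotated_lncRNA"),
               ref$transcripts$transcript_id))
    combined <- bind_catalogs(novel_catalog, ref)
    scores <- exon_mean_scores(combined, track)
    prof <- class_profiles(scores, classes)
    data.table::fwrite(scores, file.path(out_dir, "exon_scores.tsv"),
                       sep = "\t")
    data.table::fwrite(prof, file.path(out_dir, "conservation_profiles.tsv"),
                       sep = "\t")
    note("conserve", scored_exons = sum(!is.na(scores$mean_score)),
         classes = nrow(prof))
  }

  # --- differential expression ---------------------------------------------
  de_ids <- character(0)
  tpm <- NULL; design <- NULL
  if (!is.null(cfg$design) && (!is.null(cfg$tpm) || !is.null(cfg$counts))) {
    dtab <- data.table::fread(cfg$design, sep = "\t")
    design <- paired_design(dtab$sample, dtab$subject, dtab$condition)
    tpm <- if (!is.null(cfg$tpm)) {
      read_expression_matrix(cfg$tpm)
    } else {
      lengths_tab <- data.table::fread(cfg$lengths, sep = "\t")
      compute_tpm(read_expression_matrix(cfg$counts),
                  setNames(lengths_tab[[2]], lengths_tab[[1]]))
    }
    res <- paired_de_test(tpm, design)
    annotated <- !res$feature_id %in% transcript_ids(cand_a)
    de_ids <- de_select(res, annotated = annotated,
                        max_padj = cfg$de$max_padj, min_fc = cfg$de$min_fc,
                        min_tpm = cfg$de$min_tpm,
                        min_detect_frac = cfg$de$min_detect_frac)
    data.table::fwrite(res, file.path(out_dir, "de_results.tsv"),
                       sep = "\t")
    writeLines(de_ids, file.path(out_dir, "de_selected.txt"))
    note("de", features_tested = nrow(res), de_selected = length(de_ids))
  }

  # --- co-expression modules -----------------------------------------------
  if (!is.null(tpm) && !is.null(design)) {
    expr <- log2(tpm + 1)
    expr <- expr[apply(expr, 1L, sd) > 0, , drop = FALSE]
    beta <- if (identical(cfg$network$beta, "auto")) {
      pick_soft_threshold(expr)$power
    } else cfg$network$beta
    a <- adjacency(expr, beta)
    tom <- topological_overlap(a)
    assignment <- detect_modules(tom, min_size = cfg$network$min_size,
                                 cut_height = cfg$network$cut_height)
    eg <- module_eigengenes(expr, assignment)
    trait <- as.integer(design$condition[match(colnames(expr),
                                               design$sample)] == "post")
    mt <- if (ncol(eg)) module_trait_correlation(eg, trait) else
      data.frame(module = character(0), pcc = numeric(0),
                 pvalue = numeric(0))
    kme <- if (ncol(eg)) module_membership(expr, eg) else NULL
    hubs <- if (!is.null(kme)) {
      hub_genes(kme, assignment, threshold = cfg$network$kme_threshold,
                restrict_to = if (isTRUE(cfg$network$restrict_hubs_to_de))
                  de_ids else NULL)
    } else data.frame(gene = character(0), module = integer(0),
                      kme = numeric(0))
    data.table::fwrite(
      data.frame(gene = names(assignment), module = assignment),
      file.path(out_dir, "modules.tsv"), sep = "\t")
    if (ncol(eg)) {
      write_expression_matrix(t(eg), file.path(out_dir, "eigengenes.tsv"),
                              id_col = "module")
      write_expression_matrix(round(kme, 6),
                              file.path(out_dir, "kme.tsv"),
                              id_col = "gene")
    }
    data.table::fwrite(mt, file.path(out_dir, "module_trait.tsv"),
                       sep = "\t")
    data.table::fwrite(hubs, file.path(out_dir, "hubs.tsv"), sep = "\t")
    note("modules", beta = beta,
         modules = length(unique(assignment[assignment > 0])),
         assigned_genes = sum(assignment > 0), hubs = nrow(hubs))
  }

  # --- eQTL overlap ---------------------------------------------------------
  if (!is.null(cfg$snps)) {
    snps <- read_snp_table(cfg$snps, p_threshold = cfg$eqtl_p_threshold)
    lnc_catalog <- if (length(novel_ids)) novel_catalog else validated
    overlaps <- overlap_exons_with_snps(lnc_catalog, snps)
    data.table::fwrite(overlaps, file.path(out_dir, "eqtl_overlaps.tsv"),
                       sep = "\t")
    note("eqtl", significant_snps = nrow(snps),
         exon_overlaps = nrow(overlaps))
    if (!is.null(tpm) && nrow(overlaps)) {
      pairs <- unique(data.frame(lncrna_id = overlaps$transcript_id,
                                 egene_id = overlaps$egene_id,
                                 stringsAsFactors = FALSE))
      corr <- lncrna_egene_correlation(tpm, pairs)
      data.table::fwrite(corr, file.path(out_dir, "eqtl_correlations.tsv"),
                         sep = "\t")
      note("eqtl", correlated_pairs = sum(!is.na(corr$pcc)))
    }
  }

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  writeLines(json, file.path(out_dir, "report.json"))
  txt <- unlist(lapply(names(report$stages), function(s) {
    vals <- unlist(report$stages[[s]])
    c(sprintf("== %s ==", s),
      sprintf("  %s: %s", names(vals), vals))
  }))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(report)
}

#' Generate a complete set of pipeline inputs with planted truth
#'
#' Writes every file [run_pipeline()] consumes (reference GTF, candidate
#' GTFs for two platforms, spliced-sequence FASTA, counts/TPM/length
#' matrices, paired design, mock database GTF, conservation bedGraph, SNP
#' table and a YAML config) into `dir`, with the planted ground truth
#' returned for assertions.
#'
#' @param dir output directory (created).
#' @param seed master seed.
#' @return list with `config_path` and the planted `truth` (candidate
#'   codes, validated pair count, database-annotated ids, DE/module plans,
#'   SNP plan).
#' @export
simulate_run_inputs <- function(dir, seed = 100L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom_sizes <- c(chr1 = 2e6, chr2 = 2e6)
  ref <- generate_reference(40, seed = seed, chrom_sizes = chrom_sizes)
  plan_a <- c("=" = 4, u = 10, i = 6, x = 3, y = 1)
  ca <- generate_candidates(ref, plan_a, seed = seed,
                            chrom_sizes = chrom_sizes, id_prefix = "CANDA")
  # platform B: intron-chain copies of a subset of A's novel candidates,
  # plus B-only candidates that must not validate
  novel_a <- ca$truth$transcript_id[ca$truth$true_code %in%
                                      c("u", "i", "x", "y")]
  shared <- with_seed(derive_seed(seed, "shared-subset"),
                      sort(sample(novel_a, 13)))
  cb_shared <- make_jittered_copies(ca$catalog, shared, seed = seed)
  cb_extra <- generate_candidates(ref, c(u = 4, i = 2), seed = seed + 1,
                                  chrom_sizes = chrom_sizes,
                                  id_prefix = "CANDB")
  cb <- bind_catalogs(cb_shared, cb_extra$catalog)
  # mock updated database: 9 of the 13 shared candidates, re-jittered
  db_ids <- head(shared, 9)
  db <- make_jittered_copies(ca$catalog, db_ids, seed = seed + 2,
                             id_suffix = "_db")

  write_gtf(ref, file.path(dir, "reference.gtf"))
  write_gtf(ca$catalog, file.path(dir, "candidates_a.gtf"))
  write_gtf(cb, file.path(dir, "candidates_b.gtf"))
  write_gtf(db, file.path(dir, "db_gencode_new.gtf"))

  # spliced sequences: shuffled (noncoding-like) sequences of matching length
  all_tx <- bind_catalogs(ca$catalog, cb)
  lens <- all_tx$transcripts$length_nt
  seqs <- with_seed(derive_seed(seed, "candidate-seqs"), {
    vapply(lens, function(l) {
      dinuc_shuffle(random_utr(max(l, 50)))
    }, "")
  })
  names(seqs) <- all_tx$transcripts$transcript_id
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                              file.path(dir, "sequences.fa"))

  n_cand_a <- length(ca$catalog)
  sim <- generate_expression(
    n_features = 40 + n_cand_a, n_pairs = 20, seed = seed,
    de = list(n = 5, effect = 1.8),
    modules = list(list(size = 15, loading = 0.9, trait_cor = -0.7),
                   list(size = 10, loading = 0.85, trait_cor = 0.6)))
  ids <- c(unique(ref$transcripts$gene_id), transcript_ids(ca$catalog))
  rownames(sim$counts) <- ids
  rownames(sim$tpm) <- ids
  names(sim$lengths) <- ids
  sim$truth$de$feature_id <- ids[match(sim$truth$de$feature_id,
                                       sprintf("G%05d", seq_along(ids)))]
  sim$truth$modules$feature_id <- ids[match(sim$truth$modules$feature_id,
                                            sprintf("G%05d",
                                                    seq_along(ids)))]
  write_expression_matrix(sim$counts, file.path(dir, "counts.tsv"))
  write_expression_matrix(sim$tpm, file.path(dir, "tpm.tsv"))
  data.table::fwrite(data.frame(feature_id = ids,
                                length = unname(sim$lengths)),
                     file.path(dir, "lengths.tsv"), sep = "\t")
  data.table::fwrite(sim$design, file.path(dir, "design.tsv"), sep = "\t")

  track <- generate_conservation_track(bind_catalogs(ref, ca$catalog),
                                       seed = seed)
  write_score_track(track, file.path(dir, "conservation.bedgraph"))

  # eSNPs planted in a candidate that survives to the novel set
  target <- setdiff(shared, db_ids)[1L]
  snps <- generate_snps(ca$catalog, target = target, seed = seed,
                        in_exon = 5L, decoys = 10L,
                        egene_id = unique(ref$transcripts$gene_id)[1L])
  write_snp_table(snps$table, file.path(dir, "snps.tsv"))

  cfg <- list(
    reference = "reference.gtf", candidates = "candidates_a.gtf",
    validation = "candidates_b.gtf", sequences = "sequences.fa",
    counts = "counts.tsv", tpm = "tpm.tsv", lengths = "lengths.tsv",
    design = "design.tsv",
    dbs = list(gencode_new = "db_gencode_new.gtf"),
    snps = "snps.tsv", track = "conservation.bedgraph",
    seed = as.integer(seed))
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, config_path)
  list(config_path = config_path,
       truth = list(candidate_codes = ca$truth,
                    shared_ids = shared, db_ids = db_ids,
                    n_validated = length(shared),
                    n_novel = length(shared) - length(db_ids),
                    eqtl_target = target, snp_truth = snps$truth,
                    expression = sim$truth))
}
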