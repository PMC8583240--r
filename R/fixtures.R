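# Deterministic synthetic-fixture generators with planted ground truth for
# every pipeline input: reference and candidate annotations (with planted
# class codes), coding/noncoding sequence corpora, conservation tracks,
# paired expression matrices with planted DE features and co-expression
# modules, and SNP association tables. Every generator derives its own RNG
# stream from the master seed via derive_seed(), so adding one generator
# to a fixture never perturbs the others.

#' Generate a synthetic reference annotation
#'
#' Non-overlapping multi-exon genes laid out left to right along each
#' chromosome with intergenic gaps, both strands represented, and (by
#' default) generous introns so that intronic and gene-in-intron
#' candidates can be planted. Biotypes alternate between mRNA and lncRNA;
#' the biotype is also written into the GTF attribute string so catalogs
#' round-trip through GTF exactly.
#'
#' @param n_genes number of genes (one transcript each).
#' @param seed integer seed.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param exon_range min/max exons per gene.
#' @param exon_len,intron_len,gap_len min/max lengths (nt) for exons,
#'   introns and intergenic gaps.
#' @param lncrna_fraction fraction of genes labeled lncRNA (rest mRNA).
#' @return an [annotation_catalog()].
#' @export
generate_reference <- function(n_genes, seed = 1L,
                               chrom_sizes = c(chr1 = 2e6, chr2 = 2e6),
                               exon_range = c(2L, 5L),
                               exon_len = c(150L, 500L),
                               intron_len = c(1500L, 6000L),
                               gap_len = c(4000L, 12000L),
                               lncrna_fraction = 0.3) {
  stopifnot(n_genes >= 0, length(chrom_sizes) >= 1)
  with_seed(derive_seed(seed, "reference"), {
    rows <- list()
    if (n_genes > 0) {
      chroms <- rep(names(chrom_sizes), length.out = n_genes)
      cursor <- setNames(rep(1000, length(chrom_sizes)), names(chrom_sizes))
      for (g in seq_len(n_genes)) {
        chrom <- chroms[g]
        pos <- cursor[[chrom]] +
          round(runif(1, gap_len[1], gap_len[2]))
        n_ex <- sample(exon_range[1]:exon_range[2], 1L)
        ex_len <- round(runif(n_ex, exon_len[1], exon_len[2]))
        in_len <- if (n_ex > 1L) {
          round(runif(n_ex - 1L, intron_len[1], intron_len[2]))
        } else numeric(0)
        starts <- pos + cumsum(c(0, head(ex_len, -1) + in_len))
        ends <- starts + ex_len
        if (max(ends) > chrom_sizes[[chrom]]) {
          abort("chromosome %s too small for %d genes", chrom, n_genes)
        }
        strand <- if (runif(1) < 0.5) "+" else "-"
        biotype <- if (runif(1) < lncrna_fraction) "lncRNA" else "mRNA"
        tid <- sprintf("REFT%04d", g)
        gid <- sprintf("REFG%04d", g)
        rows[[g]] <- data.frame(
          transcript_id = tid, gene_id = gid, chrom = chrom,
          start = starts, end = ends, strand = strand, biotype = biotype,
          attributes = sprintf(
            'gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
            gid, tid, biotype),
          stringsAsFactors = FALSE)
        cursor[[chrom]] <- max(ends)
      }
    }
    annotation_catalog(
      if (length(rows)) do.call(rbind, rows) else
        data.frame(transcript_id = character(0), gene_id = character(0),
                   chrom = character(0), start = numeric(0),
                   end = numeric(0), strand = character(0)))
  })
}

# Registry of intergenic gaps of a catalog, used to place candidates
# without collisions. alloc() carves a locus of the requested width from
# the first gap that fits (plus margins) and shrinks the gap.
gap_registry <- function(catalog, chrom_sizes, margin = 500) {
  gaps <- list()
  tx_all <- as.data.frame(catalog$transcripts)
  for (cn in names(chrom_sizes)) {
    occ <- tx_all[tx_all$chrom == cn, , drop = FALSE]
    occ <- occ[order(occ$tx_start), , drop = FALSE]
    bounds <- c(0, as.vector(rbind(occ$tx_start, occ$tx_end)),
                chrom_sizes[[cn]])
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ends - starts > 2 * margin
    gaps[[cn]] <- data.frame(start = starts[keep] + margin,
                             end = ends[keep] - margin)
  }
  env <- new.env(parent = emptyenv())
  env$gaps <- gaps
  env$alloc <- function(width, chrom = NULL) {
    chroms <- if (is.null(chrom)) names(env$gaps) else chrom
    for (cn in chroms) {
      g <- env$gaps[[cn]]
      fit <- which(g$end - g$start >= width)
      if (length(fit)) {
        i <- fit[1L]
        locus <- c(g$start[i], g$start[i] + width)
        env$gaps[[cn]]$start[i] <- locus[2] + 200
        return(list(chrom = cn, start = locus[1], end = locus[2]))
      }
    }
    abort("no intergenic gap of width %d available", width)
  }
  env
}

#' Generate candidate transcripts with planted class codes
#'
#' Constructs candidates geometrically so that each one's true class code
#' is known: `=` copies a reference intron chain with jittered terminal
#' exon ends; `u` occupies an intergenic gap; `i` sits inside a reference
#' intron; `x` overlaps a reference exon on the opposite strand; `y` places
#' one exon on each side of a small reference gene so the whole reference
#' span falls in the candidate's intron.
#'
#' @param ref reference [annotation_catalog()] from [generate_reference()].
#' @param plan named counts per class code, e.g.
#'   `c("=" = 3, u = 19, i = 13, x = 5, y = 1)`.
#' @param seed integer seed.
#' @param chrom_sizes the chromosome sizes the reference was built with.
#' @param jitter maximum shift (nt) applied to terminal exon ends of `=`
#'   candidates; 0 reproduces the template exactly.
#' @param id_prefix prefix for candidate transcript/gene ids.
#' @return list: `catalog` (an [annotation_catalog()]) and `truth`
#'   (data.frame `transcript_id`, `true_code`, `template_ref`).
#' @export
generate_candidates <- function(ref, plan, seed = 1L,
                                chrom_sizes = c(chr1 = 2e6, chr2 = 2e6),
                                jitter = 60L, id_prefix = "CAND") {
  stopifnot(inherits(ref, "annotation_catalog"))
  plan <- plan[plan > 0]
  if (!all(names(plan) %in% c("=", "u", "i", "x", "y"))) {
    abort("plan codes must be among '=', 'u', 'i', 'x', 'y'")
  }
  with_seed(derive_seed(seed, paste0("candidates-", id_prefix)), {
    reg <- gap_registry(ref, chrom_sizes)
    tx <- ref$transcripts
    multi <- tx$transcript_id[tx$n_exons > 1L]
    rows <- list(); truth <- list(); k <- 0L
    add <- function(code, exdf, chrom, strand, template) {
      k <<- k + 1L
      tid <- sprintf("%s_%s%03d", id_prefix,
                     c("=" = "EQ", u = "U", i = "I", x = "X",
                       y = "Y")[[code]], k)
      rows[[k]] <<- data.frame(
        transcript_id = tid, gene_id = paste0(tid, ".g"), chrom = chrom,
        start = exdf$start, end = exdf$end, strand = strand,
        stringsAsFactors = FALSE)
      truth[[k]] <<- data.frame(transcript_id = tid, true_code = code,
                                template_ref = template,
                                stringsAsFactors = FALSE)
    }
    for (code in names(plan)) {
      n <- plan[[code]]
      if (code == "=") {
        if (!length(multi)) abort("'=' planted codes need multi-exon reference")
        picks <- sample(rep(multi, length.out = n))
        for (id in picks) {
          t <- get_transcript(ref, id)
          ex <- t$exons
          if (jitter > 0) {
            first_room <- min(jitter, ex$end[1] - ex$start[1] - 1, ex$start[1])
            last_room <- min(jitter, ex$end[nrow(ex)] - ex$start[nrow(ex)] - 1)
            ex$start[1] <- ex$start[1] +
              sample(seq(-first_room, first_room), 1L)
            ex$end[nrow(ex)] <- ex$end[nrow(ex)] +
              sample(seq(-last_room, last_room), 1L)
          }
          add("=", ex, t$chrom, t$strand, id)
        }
      } else if (code == "u") {
        for (j in seq_len(n)) {
          w <- round(runif(1, 1500, 3000))
          locus <- reg$alloc(w)
          e1 <- round(runif(1, 250, 500)); e2 <- round(runif(1, 250, 500))
          add("u", data.frame(start = c(locus$start,
                                        locus$end - e2),
                              end = c(locus$start + e1, locus$end)),
              locus$chrom, sample(c("+", "-"), 1L), NA_character_)
        }
      } else if (code == "i") {
        if (!length(multi)) abort("'i' planted codes need reference introns")
        hosts <- sample(rep(multi, length.out = n))
        for (id in hosts) {
          t <- get_transcript(ref, id)
          ic <- intron_chain(t)$introns
          ic <- ic[ic$end - ic$start >= 1200, , drop = FALSE]
          if (!nrow(ic)) abort("host %s lacks an intron >= 1200 nt", id)
          intr <- ic[sample.int(nrow(ic), 1L), ]
          intr_len <- intr$end - intr$start
          w <- min(1000, intr_len - 250)
          s0 <- intr$start + round(runif(1, 100, intr_len - w - 100))
          gap <- round(w * runif(1, 0.25, 0.4))
          e1 <- round((w - gap) * runif(1, 0.35, 0.65))
          add("i", data.frame(start = c(s0, s0 + e1 + gap),
                              end = c(s0 + e1, s0 + w)),
              t$chrom, sample(c("+", "-"), 1L), id)
        }
      } else if (code == "x") {
        picks <- sample(rep(tx$transcript_id, length.out = n))
        for (id in picks) {
          t <- get_transcript(ref, id)
          ex <- t$exons[1L, ]
          anti <- if (t$strand == "+") "-" else "+"
          # one exon straddling the reference exon interior, a second exon
          # upstream in the flanking gap
          mid <- ex$start + round(runif(1, 0.3, 0.7) * (ex$end - ex$start))
          over_len <- round(runif(1, 150, 350))
          up_end <- max(ex$start - round(runif(1, 250, 450)), 1)
          up_len <- round(runif(1, 150, 300))
          add("x", data.frame(start = c(max(up_end - up_len, 0), mid),
                              end = c(up_end, mid + over_len)),
              t$chrom, anti, id)
        }
      } else if (code == "y") {
        small <- tx$transcript_id[order(tx$tx_end - tx$tx_start)]
        picks <- head(rep(small, length.out = n), n)
        for (id in picks) {
          t <- get_transcript(ref, id)
          span <- c(min(t$exons$start), max(t$exons$end))
          lpad <- round(runif(1, 700, 1100))
          rpad <- round(runif(1, 700, 1100))
          llen <- round(runif(1, 250, 450))
          rlen <- round(runif(1, 250, 450))
          left <- c(span[1] - lpad - llen, span[1] - lpad)
          right <- c(span[2] + rpad, span[2] + rpad + rlen)
          if (left[1] < 0) abort("no room left of %s for a 'y' candidate", id)
          add("y", data.frame(start = c(left[1], right[1]),
                              end = c(left[2], right[2])),
              t$chrom, sample(c("+", "-"), 1L), id)
        }
      }
    }
    list(catalog = annotation_catalog(do.call(rbind, rows)),
         truth = do.call(rbind, truth))
  })
}

#' Make intron-chain-preserving copies of selected transcripts
#'
#' Builds a second-platform catalog: copies of `ids` whose intron chains
#' are identical to the originals but whose terminal exon ends are
#' jittered, so [match_intron_chains()] is `TRUE` for each (original,
#' copy) pair.
#'
#' @param catalog source [annotation_catalog()].
#' @param ids transcripts to copy.
#' @param seed integer seed.
#' @param jitter maximum terminal-end shift (nt).
#' @param id_suffix appended to each transcript/gene id.
#' @return an [annotation_catalog()] of the copies.
#' @export
make_jittered_copies <- function(catalog, ids, seed = 1L, jitter = 40L,
                                 id_suffix = "_nano") {
  with_seed(derive_seed(seed, "jittered-copies"), {
    rows <- lapply(ids, function(id) {
      t <- get_transcript(catalog, id)
      ex <- t$exons
      n <- nrow(ex)
      if (jitter > 0) {
        first_room <- min(jitter, ex$end[1] - ex$start[1] - 1, ex$start[1])
        last_room <- min(jitter, ex$end[n] - ex$start[n] - 1)
        ex$start[1] <- ex$start[1] + sample(seq(-first_room, first_room), 1L)
        ex$end[n] <- ex$end[n] + sample(seq(-last_room, last_room), 1L)
      }
      data.frame(transcript_id = paste0(id, id_suffix),
                 gene_id = paste0(t$gene_id, id_suffix),
                 chrom = t$chrom, start = ex$start, end = ex$end,
                 strand = t$strand, stringsAsFactors = FALSE)
    })
    annotation_catalog(do.call(rbind, rows))
  })
}

# -- sequences ---------------------------------------------------------------

# Codon pool for synthetic coding ORFs: a biased subset of non-stop codons
# (codon usage skew is what the hexamer table learns).
CODING_CODON_POOL <- c("GAG", "AAG", "CTG", "GAC", "GCC", "GTG", "ATC",
                       "CAG", "TTC", "ACC", "GGC", "AAC")

#' Generate a coding/noncoding sequence corpus
#'
#' Coding sequences carry a long codon-biased ATG...stop ORF inside random
#' UTR-like flanks; noncoding sequences are exact dinucleotide-preserving
#' shuffles of coding ones (mono- and dinucleotide composition, hence GC
#' content, is preserved exactly).
#'
#' @param n number of sequences.
#' @param coding_fraction fraction labeled coding.
#' @param seed integer seed.
#' @param length_range min/max sequence length (nt).
#' @param orf_fraction fraction of a coding sequence occupied by the ORF.
#' @return list: `seqs` (named character vector), `labels` (data.frame
#'   `seq_id`, `label`).
#' @export
generate_sequences <- function(n, coding_fraction = 0.5, seed = 1L,
                               length_range = c(400L, 1200L),
                               orf_fraction = 0.6) {
  with_seed(derive_seed(seed, "sequences"), {
    n_cod <- round(n * coding_fraction)
    labels <- c(rep("coding", n_cod), rep("noncoding", n - n_cod))
    seqs <- character(n)
    for (i in seq_len(n)) {
      len <- round(runif(1, length_range[1], length_range[2]))
      core_len <- 3 * floor(len * orf_fraction / 3)
      n_codons <- max(core_len %/% 3 - 2L, 10L)
      orf <- paste0("ATG",
                    paste(sample(CODING_CODON_POOL, n_codons,
                                 replace = TRUE,
                                 prob = seq(2, 0.5,
                                            length.out = length(CODING_CODON_POOL))),
                          collapse = ""),
                    "TAA")
      flank_len <- max(len - nchar(orf), 0L)
      utr5 <- random_utr(ceiling(flank_len / 2))
      utr3 <- random_utr(floor(flank_len / 2))
      full <- paste0(utr5, orf, utr3)
      seqs[i] <- if (labels[i] == "coding") full else dinuc_shuffle(full)
    }
    names(seqs) <- sprintf("SEQ%04d", seq_len(n))
    list(seqs = seqs,
         labels = data.frame(seq_id = names(seqs), label = labels,
                             stringsAsFactors = FALSE))
  })
}

# Random flank without ATG-free guarantee but stop-rich, so flank ORFs
# stay short.
random_utr <- function(len) {
  if (len <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
}

#' Exact dinucleotide-preserving shuffle
#'
#' Altschul-Erikson shuffle: permutes a sequence so that every
#' dinucleotide (and therefore every mononucleotide) count is preserved
#' exactly, destroying longer-range structure such as codon bias.
#'
#' @param seq nucleotide string.
#' @return shuffled string of the same length and dinucleotide content.
#' @export
dinuc_shuffle <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 3L) return(paste(chars, collapse = ""))
  verts <- unique(chars)
  edges <- split(chars[-1L], factor(chars[-n], levels = verts))
  last <- chars[n]
  repeat {
    # pick a candidate terminal edge for every non-terminal vertex and
    # keep the draw only if those edges connect every vertex to the sink
    last_edge <- vapply(verts, function(v) {
      if (v == last || !length(edges[[v]])) NA_character_ else
        sample(edges[[v]], 1L)
    }, "")
    reach <- setNames(verts == last, verts)
    for (dummy in seq_along(verts)) {
      for (v in verts) {
        if (!reach[[v]] && !is.na(last_edge[[v]]) &&
            reach[[last_edge[[v]]]]) {
          reach[[v]] <- TRUE
        }
      }
    }
    active <- vapply(verts, function(v) length(edges[[v]]) > 0, TRUE)
    if (all(reach[verts[active]] | verts[active] == last)) break
  }
  shuffled <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (!length(e)) return(e)
    if (v == last) return(sample(e))
    i <- match(last_edge[[v]], e)
    c(sample(e[-i]), e[i])
  })
  names(shuffled) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1L] <- chars[1L]
  v <- chars[1L]
  for (i in 2:n) {
    nx <- shuffled[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    out[i] <- nx
    v <- nx
  }
  paste(out, collapse = "")
}

#' Generate a conservation score track over a catalog's exons
#'
#' Per-base scores drawn from a class-specific Beta distribution
#' (protein-coding exons conserved, noncoding exons not), run-length
#' aggregated into bedGraph-style intervals. Regions covered by exons of
#' several transcripts are scored once, by the first covering class.
#'
#' @param catalog an [annotation_catalog()] with biotypes.
#' @param class_params named list of `c(alpha, beta)` per biotype;
#'   unlisted biotypes fall back to `default`.
#' @param seed integer seed.
#' @param digits score rounding used for run-length aggregation.
#' @return a `score_track`.
#' @export
generate_conservation_track <- function(catalog,
                                        class_params = list(
                                          mRNA = c(8, 2),
                                          lncRNA = c(2, 8),
                                          default = c(2, 8)),
                                        seed = 1L, digits = 3L) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  with_seed(derive_seed(seed, "conservation"), {
    ex <- catalog$exons
    bt <- catalog$transcripts$biotype[
      match(ex$transcript_id, catalog$transcripts$transcript_id)]
    covered <- GenomicRanges::GRanges()
    pieces <- list()
    for (i in seq_len(nrow(ex))) {
      gr <- GenomicRanges::GRanges(ex$chrom[i],
                                   IRanges::IRanges(ex$start[i] + 1,
                                                    ex$end[i]))
      new <- suppressWarnings(
        GenomicRanges::setdiff(gr, covered, ignore.strand = TRUE))
      if (!length(new)) next
      covered <- suppressWarnings(
        GenomicRanges::union(covered, gr, ignore.strand = TRUE))
      par <- class_params[[bt[i]]] %||% class_params$default
      for (j in seq_along(new)) {
        s0 <- GenomicRanges::start(new)[j] - 1
        w <- GenomicRanges::width(new)[j]
        vals <- round(rbeta(w, par[1], par[2]), digits)
        r <- rle(vals)
        ends <- s0 + cumsum(r$lengths)
        starts <- ends - r$lengths
        pieces[[length(pieces) + 1L]] <- data.frame(
          chrom = ex$chrom[i], start = starts, end = ends,
          score = r$values, stringsAsFactors = FALSE)
      }
    }
    if (!length(pieces)) abort("catalog has no exons to score")
    score_track(do.call(rbind, pieces))
  })
}

#' Write a score track as bedGraph
#' @param track a `score_track`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_score_track <- function(track, path) {
  stopifnot(inherits(track, "score_track"))
  gr <- track$granges
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = format(GenomicRanges::start(gr) - 1,
                                  scientific = FALSE, trim = TRUE),
                   end = format(GenomicRanges::end(gr),
                                scientific = FALSE, trim = TRUE),
                   score = S4Vectors::mcols(gr)$score)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Generate paired pre/post expression with planted DE and modules
#'
#' Baseline log-normal abundances; planted DE features multiply the
#' post-condition mean by their effect size; module genes follow
#' `loading * latent + sqrt(1 - loading^2) * noise` on the log scale, with
#' the latent factor optionally correlated to the pre/post trait. TPM is
#' the column-normalized noisy abundance; counts are Poisson draws with
#' expected value proportional to abundance at the requested depth.
#'
#' @param n_features number of features.
#' @param n_pairs number of subject pairs (>= 3).
#' @param seed integer seed.
#' @param de list: `n` planted DE features, `effect` fold change applied
#'   post, or a vector of effects (length `n`).
#' @param modules list of module plans, each
#'   `list(size =, loading =, trait_cor =)`; module genes are disjoint
#'   from DE genes.
#' @param sigma per-sample log2 noise sd.
#' @param base_mean,base_sd log2 baseline mean/sd across features.
#' @param depth expected total counts per sample.
#' @param feature_lengths effective lengths (recycled).
#' @return list: `counts`, `tpm`, `log_expr` (features x samples; the
#'   log2-scale abundance before library normalization, the natural input
#'   for co-expression analysis), `lengths`, `design` (a
#'   [paired_design()]), `trait` (0/1 per sample), `truth` (list with `de`
#'   data.frame, `modules` data.frame, `latents` matrix).
#' @export
generate_expression <- function(n_features, n_pairs, seed = 1L,
                                de = list(n = 0, effect = 2),
                                modules = list(), sigma = 0.25,
                                base_mean = 4, base_sd = 1.5,
                                depth = 2e6, feature_lengths = 1000) {
  if (n_pairs < 3L) abort("need at least 3 subject pairs")
  mod_sizes <- vapply(modules, function(m) m$size, 0)
  if (sum(mod_sizes) + (de$n %||% 0) > n_features) {
    abort("module sizes plus DE features exceed feature count")
  }
  with_seed(derive_seed(seed, "expression"), {
    n_samp <- 2L * n_pairs
    subjects <- sprintf("P%03d", seq_len(n_pairs))
    design <- paired_design(
      sample = c(paste0(subjects, "_pre"), paste0(subjects, "_post")),
      subject = rep(subjects, 2L),
      condition = rep(c("pre", "post"), each = n_pairs))
    trait <- as.integer(design$condition == "post")
    features <- sprintf("G%05d", seq_len(n_features))
    mu <- rnorm(n_features, base_mean, base_sd)
    logx <- matrix(rnorm(n_features * n_samp, 0, sigma),
                   nrow = n_features,
                   dimnames = list(features, design$sample))
    # planted modules occupy the head of the feature list
    mod_truth <- list(); latents <- NULL; at <- 1L
    zt <- as.numeric(scale(trait))
    for (mi in seq_along(modules)) {
      m <- modules[[mi]]
      rho <- m$trait_cor %||% 0
      z <- rnorm(n_samp)
      latent <- rho * zt + sqrt(max(1 - rho^2, 0)) * as.numeric(scale(z))
      latent <- as.numeric(scale(latent))
      idx <- at:(at + m$size - 1L)
      loading <- rep_len(m$loading, m$size)
      for (k in seq_along(idx)) {
        g <- idx[k]
        logx[g, ] <- loading[k] * latent +
          sqrt(1 - loading[k]^2) * rnorm(n_samp)
      }
      mod_truth[[mi]] <- data.frame(feature_id = features[idx],
                                    module = mi, loading = loading,
                                    stringsAsFactors = FALSE)
      latents <- cbind(latents, latent)
      at <- at + m$size
    }
    # planted DE features follow the modules
    de_n <- de$n %||% 0
    de_truth <- data.frame(feature_id = character(0), effect = numeric(0))
    if (de_n > 0) {
      effects <- rep_len(de$effect, de_n)
      idx <- at:(at + de_n - 1L)
      post_cols <- design$condition == "post"
      logx[idx, post_cols] <- logx[idx, post_cols] + log2(effects)
      de_truth <- data.frame(feature_id = features[idx], effect = effects,
                             stringsAsFactors = FALSE)
    }
    abundance <- 2^(mu + logx)
    tpm <- sweep(abundance, 2L, colSums(abundance), "/") * 1e6
    lengths <- setNames(rep_len(feature_lengths, n_features), features)
    rate <- sweep(abundance * lengths, 2L,
                  colSums(abundance * lengths), "/") * depth
    counts <- matrix(rpois(length(rate), rate), nrow = n_features,
                     dimnames = dimnames(tpm))
    list(counts = counts, tpm = tpm, log_expr = mu + logx,
         lengths = lengths, design = design, trait = trait,
         truth = list(de = de_truth,
                      modules = if (length(mod_truth))
                        do.call(rbind, mod_truth) else
                          data.frame(feature_id = character(0),
                                     module = integer(0),
                                     loading = numeric(0)),
                      latents = latents))
  })
}

#' Generate a SNP association table with planted exon overlaps
#'
#' Plants `in_exon` significant eSNPs inside the exons of a target
#' transcript, `decoys` significant eSNPs outside every exon of the
#' catalog (introns or flanks), and `weak` associations above the p-value
#' threshold that a loader should drop.
#'
#' @param catalog an [annotation_catalog()].
#' @param target transcript id whose exons receive the planted SNPs.
#' @param seed integer seed.
#' @param in_exon,decoys,weak row counts per category.
#' @param egene_id the associated eGene.
#' @param p_threshold planted SNPs get p below this, weak rows above it.
#' @return list: `table` (data.frame `snp_id`, `chrom`, `pos` (1-based),
#'   `egene_id`, `pvalue`), `truth` (data.frame `snp_id`, `category`,
#'   `intended_transcript`).
#' @export
generate_snps <- function(catalog, target, seed = 1L, in_exon = 5L,
                          decoys = 20L, weak = 0L, egene_id = "EGENE1",
                          p_threshold = 1e-8) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  with_seed(derive_seed(seed, "snps"), {
    t <- get_transcript(catalog, target)
    ex_all <- catalog$exons
    rows <- list(); truth <- list(); k <- 0L
    add <- function(chrom, pos1, p, category, intended) {
      k <<- k + 1L
      rows[[k]] <<- data.frame(snp_id = sprintf("rs%06d", k),
                               chrom = chrom, pos = pos1,
                               egene_id = egene_id, pvalue = p,
                               stringsAsFactors = FALSE)
      truth[[k]] <<- data.frame(snp_id = sprintf("rs%06d", k),
                                category = category,
                                intended_transcript = intended,
                                stringsAsFactors = FALSE)
    }
    # planted in-exon eSNPs, spread over the target's exons
    exi <- rep_len(seq_len(nrow(t$exons)), in_exon)
    for (i in seq_len(in_exon)) {
      e <- t$exons[exi[i], ]
      pos0 <- floor(runif(1, e$start, e$end))          # 0-based base
      add(t$chrom, pos0 + 1, 10^runif(1, -12, log10(p_threshold) - 0.5),
          "in_exon", target)
    }
    # decoys: significant but outside every exon of the catalog
    exon_gr <- catalog_granges(catalog, "exons")
    n_done <- 0L
    while (n_done < decoys) {
      span <- c(min(ex_all$start), max(ex_all$end) + 5000)
      pos0 <- floor(runif(1, span[1], span[2]))
      hit <- GenomicRanges::countOverlaps(
        GenomicRanges::GRanges(t$chrom, IRanges::IRanges(pos0 + 1, pos0 + 1)),
        exon_gr, ignore.strand = TRUE)
      if (hit == 0L) {
        add(t$chrom, pos0 + 1, 10^runif(1, -12, log10(p_threshold) - 0.5),
            "decoy", NA_character_)
        n_done <- n_done + 1L
      }
    }
    for (i in seq_len(weak)) {
      e <- t$exons[rep_len(seq_len(nrow(t$exons)), weak)[i], ]
      pos0 <- floor(runif(1, e$start, e$end))
      add(t$chrom, pos0 + 1, 10^runif(1, log10(p_threshold) + 0.5, -1),
          "weak", target)
    }
    list(table = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Write a SNP association table as TSV
#' @param snp_table data.frame from [generate_snps()]`$table`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_snp_table <- function(snp_table, path) {
  data.table::fwrite(snp_table, path, sep = "\t")
  invisible(path)
}
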