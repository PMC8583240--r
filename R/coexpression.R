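# Unsigned weighted co-expression network analysis: soft threshold by the
# scale-free fit criterion, adjacency |cor|^beta, topological overlap,
# average-linkage module detection with a static tree cut, module
# eigengenes, module-trait correlation, module membership (kME) and hub
# calling.

#' Pick the soft-thresholding power
#'
#' Chooses the smallest candidate power whose connectivity distribution is
#' approximately scale-free: the linear fit of `log10 p(k)` on `log10 k`
#' over 10 connectivity bins must reach R-squared >= `rsq_target` with a
#' negative slope, and the network must not be degenerate (mean
#' connectivity at least `min_mean_k`; an all-but-empty network fits a
#' power law trivially without carrying any topology). If no candidate
#' qualifies the conventional fallback power 6 is returned with a warning;
#' a single-element `powers` grid is returned as-is, there being nothing
#' to choose. Constant-expression genes are removed (with a warning)
#' before correlation.
#'
#' @param expr expression matrix, genes x samples (>= 8 samples).
#' @param powers candidate integer powers.
#' @param rsq_target scale-free fit threshold.
#' @param min_mean_k minimum mean connectivity for a qualifying power.
#' @return list: `power`, `fit_table` (power, rsq, slope, mean_k).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, rsq_target = 0.8,
                                min_mean_k = 1) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 8L) abort("need at least 8 samples")
  keep <- apply(expr, 1L, sd) > 0
  if (!all(keep)) {
    warnf("removed %d constant-expression gene(s)", sum(!keep))
    expr <- expr[keep, , drop = FALSE]
  }
  ac <- abs(cor(t(expr)))
  diag(ac) <- 0
  fit <- lapply(powers, function(b) {
    k <- rowSums(ac^b)
    data.frame(power = b, rsq = scale_free_rsq(k)["rsq"],
               slope = scale_free_rsq(k)["slope"], mean_k = mean(k))
  })
  fit <- do.call(rbind, fit)
  rownames(fit) <- NULL
  ok <- which(fit$rsq >= rsq_target & fit$slope < 0 &
                fit$mean_k >= min_mean_k)
  if (length(ok)) {
    list(power = fit$power[ok[1L]], fit_table = fit)
  } else if (length(powers) == 1L) {
    list(power = powers, fit_table = fit)
  } else {
    warnf("no candidate power reaches scale-free fit R^2 >= %g; falling back to power 6",
          rsq_target)
    list(power = 6L, fit_table = fit)
  }
}

# R^2 and slope of log10 p(k) vs log10 k over 10 connectivity bins.
scale_free_rsq <- function(k, n_bins = 10L) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < n_bins) return(c(rsq = 0, slope = 0))
  cuts <- cut(k, breaks = n_bins)
  pk <- tabulate(cuts, nbins = n_bins) / length(k)
  mids <- tapply(k, cuts, mean)
  keep <- pk > 0 & !is.na(mids)
  if (sum(keep) < 3L) return(c(rsq = 0, slope = 0))
  f <- lm(log10(pk[keep]) ~ log10(mids[keep]))
  c(rsq = summary(f)$r.squared, slope = unname(coef(f)[2L]))
}

#' Unsigned weighted adjacency
#'
#' `a_ij = |pearson(x_i, x_j)|^beta`, unit diagonal. `signed = TRUE`
#' instead uses `((1 + cor) / 2)^beta` (exposed for completeness; the
#' analysis defaults to the unsigned network).
#'
#' @param expr expression matrix, genes x samples, no constant rows.
#' @param beta soft-thresholding power.
#' @param signed use the signed transform.
#' @return symmetric adjacency matrix with entries in `[0, 1]`.
#' @export
adjacency <- function(expr, beta, signed = FALSE) {
  stopifnot(is.matrix(expr))
  check_scalar(beta, "beta", lo = 1e-9)
  if (any(apply(expr, 1L, sd) == 0)) {
    abort("constant-expression rows present; remove them first")
  }
  cc <- cor(t(expr))
  a <- if (signed) ((1 + cc) / 2)^beta else abs(cc)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' the shared-neighbor sum over `u != i, j` and `k_i = sum_u != i a_iu`;
#' the diagonal is 1. Genes sharing many strong neighbors get overlap close
#' to 1 even when their direct adjacency is moderate.
#'
#' @param a adjacency matrix from [adjacency()].
#' @return TOM matrix, symmetric, entries in `[0, 1]`.
#' @export
topological_overlap <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  a0 <- a
  diag(a0) <- 0
  shared <- a0 %*% a0          # (i,j) entry: sum over all u != i, j
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  tom <- (shared + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut statically at
#' `cut_height`. Clusters smaller than `min_size` are left unassigned
#' (module 0); surviving modules are labeled 1, 2, ... by decreasing size.
#'
#' @param tom TOM matrix.
#' @param min_size minimum module size (default 30).
#' @param cut_height static cut height on `1 - TOM` (default 0.99).
#' @return integer vector of module labels, named by gene.
#' @export
detect_modules <- function(tom, min_size = 30L, cut_height = 0.99) {
  stopifnot(is.matrix(tom))
  h <- hclust(as.dist(1 - tom), method = "average")
  raw <- cutree(h, h = cut_height)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= min_size]
  out <- integer(length(raw))
  if (length(big)) {
    ord <- big[order(-sizes[big], as.integer(big))]
    for (i in seq_along(ord)) out[raw == as.integer(ord[i])] <- i
  } else {
    warnf("no cluster reaches min_size = %d; all genes unassigned", min_size)
  }
  names(out) <- rownames(tom) %||% names(raw)
  out
}

#' Module eigengene
#'
#' First principal component of the per-gene standardized member expression
#' matrix, scaled to unit variance and oriented so that it correlates
#' positively with the mean member expression profile.
#'
#' @param expr expression matrix, genes x samples.
#' @param members gene ids (or row indices) of the module; at least 2.
#' @return list: `eigengene` (length = samples, unit variance),
#'   `var_explained` (fraction of member variance captured).
#' @export
module_eigengene <- function(expr, members) {
  stopifnot(is.matrix(expr))
  x <- expr[members, , drop = FALSE]
  if (nrow(x) < 2L) abort("module eigengene needs at least 2 members")
  xs <- t(scale(t(x)))                 # standardize each gene
  if (anyNA(xs)) abort("constant-expression member(s) in module")
  pc <- prcomp(t(xs), center = FALSE, scale. = FALSE)
  eg <- pc$x[, 1L]
  if (cor(eg, colMeans(xs)) < 0) eg <- -eg
  eg <- as.numeric(scale(eg))
  list(eigengene = setNames(eg, colnames(expr)),
       var_explained = pc$sdev[1L]^2 / sum(pc$sdev^2))
}

#' Eigengenes of every detected module
#'
#' @param expr expression matrix, genes x samples.
#' @param assignment module labels from [detect_modules()] (module 0 =
#'   unassigned, skipped).
#' @return samples x modules matrix of eigengenes, columns `ME1`, `ME2`, ...
#' @export
module_eigengenes <- function(expr, assignment) {
  mods <- sort(unique(assignment[assignment > 0]))
  if (!length(mods)) {
    warnf("no assigned modules")
    return(matrix(numeric(0), nrow = ncol(expr), ncol = 0,
                  dimnames = list(colnames(expr), NULL)))
  }
  out <- vapply(mods, function(m) {
    module_eigengene(expr, names(assignment)[assignment == m])$eigengene
  }, numeric(ncol(expr)))
  colnames(out) <- paste0("ME", mods)
  rownames(out) <- colnames(expr)
  out
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with a sample trait (here
#' typically ischemia status: pre = 0, post = 1), with the two-sided
#' t-distribution p-value (df = n - 2).
#'
#' @param eigengenes samples x modules matrix from [module_eigengenes()].
#' @param trait numeric vector, one value per sample.
#' @return data.frame: `module`, `pcc`, `pvalue`.
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  stopifnot(is.matrix(eigengenes))
  if (length(trait) != nrow(eigengenes)) {
    abort("trait length must match the number of samples")
  }
  if (sd(trait) == 0) abort("trait has zero variance")
  n <- length(trait)
  pcc <- as.numeric(cor(eigengenes, trait))
  tt <- pcc * sqrt((n - 2) / pmax(1 - pcc^2, .Machine$double.eps))
  data.frame(module = colnames(eigengenes), pcc = pcc,
             pvalue = 2 * pt(-abs(tt), df = n - 2),
             stringsAsFactors = FALSE)
}

#' Module membership (kME)
#'
#' `kME_gm = pearson(x_g, eigengene_m)` for every gene and every module
#' eigengene. A gene's kME in its own module measures intramodular
#' connectivity.
#'
#' @param expr expression matrix, genes x samples.
#' @param eigengenes samples x modules matrix.
#' @return genes x modules kME matrix.
#' @export
module_membership <- function(expr, eigengenes) {
  stopifnot(is.matrix(expr), is.matrix(eigengenes))
  cor(t(expr), eigengenes)
}

#' Hub genes of each module
#'
#' Genes whose kME in their own module strictly exceeds `threshold`
#' (default 0.7). When `restrict_to` is given (typically the
#' differential-expression survivors), hub calling is limited to those
#' genes, mirroring a module filtered to DE genes before reporting.
#'
#' @param kme genes x modules kME matrix from [module_membership()].
#' @param assignment module labels, named by gene.
#' @param threshold kME threshold in (0, 1), strict.
#' @param restrict_to optional character vector of eligible gene ids.
#' @return data.frame: `gene`, `module`, `kme`.
#' @export
hub_genes <- function(kme, assignment, threshold = 0.7, restrict_to = NULL) {
  stopifnot(is.matrix(kme))
  check_scalar(threshold, "threshold", lo = 1e-9, hi = 1 - 1e-9)
  genes <- names(assignment)[assignment > 0]
  if (!is.null(restrict_to)) genes <- intersect(genes, restrict_to)
  rows <- lapply(genes, function(g) {
    m <- assignment[[g]]
    v <- kme[g, paste0("ME", m)]
    if (!is.na(v) && v > threshold) {
      data.frame(gene = g, module = m, kme = unname(v),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), module = integer(0),
                      kme = numeric(0))
  }
  out[order(out$module, -out$kme), , drop = FALSE]
}

#' Export a TOM edge list
#'
#' @param tom TOM matrix with gene dimnames.
#' @param path output TSV path.
#' @param min_tom drop edges below this overlap.
#' @return invisibly, the path.
#' @export
write_edge_list <- function(tom, path, min_tom = 0) {
  idx <- which(upper.tri(tom) & tom >= min_tom, arr.ind = TRUE)
  out <- data.frame(gene_i = rownames(tom)[idx[, 1L]],
                    gene_j = colnames(tom)[idx[, 2L]],
                    tom = tom[idx])
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
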