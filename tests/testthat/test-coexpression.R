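test_that("adjacency follows the unsigned power transform", {
  set.seed(22)
  x <- matrix(rnorm(200), 10, 20, dimnames = list(paste0("g", 1:10), NULL))
  x[2, ] <- x[1, ]                          # identical pair
  a1 <- adjacency(x, 1)
  a6 <- adjacency(x, 6)
  expect_equal(unname(a1), unname(abs(cor(t(x)))), tolerance = 1e-12)
  expect_equal(a6["g1", "g2"], 1)
  expect_true(all(a6 >= 0 & a6 <= 1))
  expect_true(isSymmetric(a6))
  # raising beta never increases an off-diagonal entry
  off <- upper.tri(a1)
  expect_true(all(a6[off] <= a1[off] + 1e-12))
  # near-orthogonal genes get near-zero adjacency at high power
  expect_lt(max(a6[off][a1[off] < 0.5]), 0.02)
  xc <- x; xc[3, ] <- 5
  expect_error(adjacency(xc, 6), "constant")
})

test_that("topological overlap matches its closed form and oracle", {
  # 2-gene network: TOM_12 = a_12
  a2 <- matrix(c(1, 0.37, 0.37, 1), 2, 2)
  expect_equal(topological_overlap(a2)[1, 2], 0.37)
  # identity adjacency: off-diagonal 0
  expect_true(all(topological_overlap(diag(4))[upper.tri(diag(4))] == 0))
  # random 30-gene adjacency equals the direct triple loop
  set.seed(24)
  r <- matrix(runif(900), 30, 30)
  a <- (r + t(r)) / 2
  diag(a) <- 1
  tom <- topological_overlap(a)
  expect_equal(tom, oracle_tom(a), tolerance = 1e-12)
  expect_true(isSymmetric(tom))
  expect_true(all(tom >= 0 & tom <= 1))
})

test_that("module detection recovers planted blocks and handles edges", {
  sim <- generate_expression(60, 20, seed = 29, modules = list(
    list(size = 30, loading = sqrt(0.9), trait_cor = 0),
    list(size = 30, loading = sqrt(0.9), trait_cor = 0)))
  tom <- topological_overlap(adjacency(sim$log_expr, 6))
  mods <- detect_modules(tom, min_size = 10)
  expect_equal(ari(mods, sim$truth$modules$module), 1)
  # min_size above the gene count leaves everything unassigned
  expect_warning(all0 <- detect_modules(tom, min_size = 100), "unassigned")
  expect_true(all(all0 == 0))
  # a single block collapses into one module
  sim1 <- generate_expression(40, 20, seed = 30, modules = list(
    list(size = 40, loading = sqrt(0.9), trait_cor = 0)))
  tom1 <- topological_overlap(adjacency(sim1$log_expr, 6))
  mods1 <- detect_modules(tom1, min_size = 10)
  expect_true(all(mods1 == 1))
})

test_that("module eigengenes summarize and orient correctly", {
  # identical member profiles: eigengene equals the standardized profile
  prof <- sin(seq_len(20))
  x <- matrix(rep(prof, each = 5), 5, 20,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:20)))
  x <- x + 0  # no noise
  eg <- module_eigengene(x, paste0("g", 1:5))
  expect_equal(unname(eg$eigengene), as.numeric(scale(prof)),
               tolerance = 1e-8)
  expect_equal(eg$var_explained, 1)
  expect_error(module_eigengene(x, "g1"), "2 members")

  # latent factor recovery at loading 0.9
  sim <- generate_expression(50, 20, seed = 31, modules = list(
    list(size = 50, loading = 0.9, trait_cor = 0)))
  eg2 <- module_eigengene(sim$log_expr, rownames(sim$log_expr))
  expect_gte(abs(cor(eg2$eigengene, sim$truth$latents[, 1])), 0.95)

  # flipping every member leaves the orientation contract intact
  flipped <- -sim$log_expr
  eg3 <- module_eigengene(flipped, rownames(flipped))
  mean_flipped <- colMeans(t(scale(t(flipped))))
  expect_gte(cor(eg3$eigengene, mean_flipped), 0)
})

test_that("module-trait correlation has calibrated nulls and recovery", {
  sim <- generate_expression(40, 20, seed = 35, modules = list(
    list(size = 40, loading = 0.85, trait_cor = 0)))
  eg <- module_eigengenes(sim$log_expr,
                          setNames(rep(1L, 40), rownames(sim$log_expr)))
  expect_equal(module_trait_correlation(eg, eg[, 1])$pcc, 1,
               tolerance = 1e-12)
  expect_error(module_trait_correlation(eg, rep(1, 40)), "zero variance")
  # permutation null: |PCC| 95th percentile within the 2.1/sqrt(n) bound
  set.seed(37)
  n <- nrow(eg)
  null_pcc <- replicate(500, abs(cor(eg[, 1], sample(sim$trait))))
  expect_lte(quantile(null_pcc, 0.95), 2.1 / sqrt(n))
  # planted module-trait correlation recovered within 0.1
  simt <- generate_expression(60, 81, seed = 39, modules = list(
    list(size = 60, loading = 0.9, trait_cor = -0.69)))
  egt <- module_eigengenes(simt$log_expr,
                           setNames(rep(1L, 60), rownames(simt$log_expr)))
  mt <- module_trait_correlation(egt, simt$trait)
  expect_lt(abs(abs(mt$pcc) - 0.69), 0.1)
})

test_that("kME separates hubs from peripheral members", {
  sim <- generate_expression(30, 40, seed = 41, modules = list(
    list(size = 30, loading = c(rep(0.9, 3), rep(0.45, 27)),
         trait_cor = 0)))
  expr <- sim$log_expr
  assignment <- setNames(rep(1L, 30), rownames(expr))
  eg <- module_eigengenes(expr, assignment)
  kme <- module_membership(expr, eg)
  # gene identical to the eigengene scores kME 1
  expr2 <- rbind(expr, ME = eg[, 1])
  kme2 <- module_membership(expr2, eg)
  expect_equal(unname(kme2["ME", 1]), 1, tolerance = 1e-12)
  # planted hubs (loading 0.9) exceed every peripheral member (0.45)
  hubs_true <- sim$truth$modules$feature_id[
    sim$truth$modules$loading > 0.7]
  expect_gt(min(kme[hubs_true, 1]),
            max(kme[setdiff(rownames(expr), hubs_true), 1]))
  got <- hub_genes(kme, assignment, threshold = 0.7)
  expect_setequal(got$gene, hubs_true)
  # strict threshold and DE restriction
  kme_edge <- matrix(c(0.7, 0.9), 2, 1,
                     dimnames = list(c("at", "above"), "ME1"))
  asg <- setNames(c(1L, 1L), c("at", "above"))
  expect_equal(hub_genes(kme_edge, asg, 0.7)$gene, "above")
  expect_equal(nrow(hub_genes(kme_edge, asg, 0.7, restrict_to = "at")), 0)
})

test_that("hub ordering is reproducible across repeated simulations", {
  wins <- vapply(1:20, function(s) {
    sim <- generate_expression(20, 40, seed = 500 + s, modules = list(
      list(size = 20, loading = c(0.95, rep(0.5, 19)), trait_cor = 0)))
    eg <- module_eigengenes(sim$log_expr,
                            setNames(rep(1L, 20), rownames(sim$log_expr)))
    kme <- module_membership(sim$log_expr, eg)
    which.max(kme[, 1]) == 1
  }, TRUE)
  expect_true(all(wins))
})

test_that("soft-threshold selection reaches scale-free fit or falls back", {
  sim <- generate_expression(60, 25, seed = 23, modules = list(
    list(size = 6, loading = 0.95, trait_cor = 0),
    list(size = 12, loading = 0.85, trait_cor = 0),
    list(size = 18, loading = 0.7, trait_cor = 0)))
  got <- suppressWarnings(pick_soft_threshold(sim$log_expr, powers = 1:14))
  want <- oracle_pick_beta(sim$log_expr, powers = 1:14)
  expect_lte(abs(got$power - want), 2)
  expect_equal(pick_soft_threshold(sim$log_expr, powers = 1)$power, 1)
  # independent noise genes never look scale-free: fallback 6
  set.seed(45)
  noise <- matrix(rnorm(50 * 20), 50, 20,
                  dimnames = list(paste0("g", 1:50), NULL))
  expect_warning(fb <- pick_soft_threshold(noise), "falling back")
  expect_equal(fb$power, 6L)
  expect_error(pick_soft_threshold(noise[, 1:5]), "8 samples")
})
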