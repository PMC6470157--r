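test_that("the call-rate filter retains exactly the genes meeting the threshold", {
  pm <- generate_panel(n_genes = 10, donors = 5, low_call_frac = 0, seed = 1)
  pm$calls[] <- TRUE
  expect_equal(nrow(call_rate_filter(pm, 0.5)$values), 10)
  # a gene detected in 4 of 10 samples fails a 50% threshold
  pm$calls["gene_003", ] <- c(rep(TRUE, 4), rep(FALSE, 6))
  flt <- call_rate_filter(pm, 0.5)
  expect_false("gene_003" %in% flt$genes)
  expect_equal(nrow(flt$values), 9)
  # boundary: exactly 50% is retained (>= threshold)
  pm$calls["gene_004", ] <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_true("gene_004" %in% call_rate_filter(pm, 0.5)$genes)
  # monotonicity: a higher threshold never retains more genes
  pm2 <- generate_panel(n_genes = 96, donors = 5, seed = 7)
  n_kept <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                   function(th) nrow(call_rate_filter(pm2, th)$values),
                   numeric(1))
  expect_true(all(diff(n_kept) <= 0))
  expect_error(call_rate_filter(pm2, 0), "\\(0, 1\\]")
})

test_that("a panel constructed with 60 of 96 informative genes filters to exactly 60", {
  pm <- generate_panel(n_genes = 96, donors = 5, low_call_frac = 0, seed = 5)
  # deterministically silence 36 genes below the 50% call rate
  silenced <- pm$genes[61:96]
  pm$calls[] <- TRUE
  # detected in 4 of 10 samples for every silenced gene (columns 1-4)
  pm$calls[silenced, ] <- matrix(rep(c(rep(TRUE, 4), rep(FALSE, 6)),
                                     each = length(silenced)),
                                 nrow = length(silenced))
  flt <- call_rate_filter(pm, 0.5)
  expect_equal(nrow(flt$values), 60)
  expect_setequal(flt$genes, pm$genes[1:60])
  # and the default missingness model lands near 60 retained on average
  kept <- vapply(1:40, function(s) {
    nrow(call_rate_filter(generate_panel(n_genes = 96, donors = 5,
                                         seed = s), 0.5)$values)
  }, numeric(1))
  expect_gt(mean(kept), 55)
  expect_lt(mean(kept), 68)
})

test_that("a 40% call probability fails the 50% filter at the binomial rate", {
  retained <- vapply(1:300, function(s) {
    pm <- generate_panel(n_genes = 5, donors = 5, low_call_frac = 0,
                         missing_spec = c(gene_003 = 0.4), seed = s)
    "gene_003" %in% call_rate_filter(pm, 0.5)$genes
  }, logical(1))
  # binomial oracle: P(Bin(10, 0.4) >= 5) = 1 - pbinom(4, 10, 0.4)
  p_retain <- 1 - pbinom(4, 10, 0.4)
  expect_lt(mean(retained), 0.5)  # typically dropped
  # within 3 binomial standard errors of the oracle probability
  expect_lt(abs(mean(retained) - p_retain),
            3 * sqrt(p_retain * (1 - p_retain) / 300))
})

test_that("Ward clustering matches a brute-force minimum-variance oracle", {
  set.seed(42)
  X <- matrix(rnorm(24), 6, 4)
  wc <- hierarchical_cluster(X)
  expect_equal(wc$height, ward_heights_brute(X), tolerance = 1e-6)
  # identical rows merge at height zero, first
  Y <- rbind(X, X[2, ])
  wy <- hierarchical_cluster(Y)
  expect_equal(min(wy$height), 0)
  # the close pair merges first: pairwise distances ~ (1, 1, 2)
  Z <- matrix(c(0, 0, 1, 0, 0.5, 10), ncol = 2, byrow = TRUE)
  wz <- hierarchical_cluster(Z)
  expect_equal(wz$tree$merge[1, ], c(-1, -2))
  # determinism: same matrix, same tree
  expect_identical(hierarchical_cluster(X)$height, wc$height)
  expect_identical(hierarchical_cluster(X)$order, wc$order)
  # constant matrix: valid tree with zero heights
  C <- matrix(1, 4, 3)
  expect_equal(hierarchical_cluster(C)$height, rep(0, 3))
  expect_error(hierarchical_cluster(X[1, , drop = FALSE]), "at least 2")
})

test_that("two-way panel clustering clusters both genes and samples", {
  pm <- generate_panel(n_genes = 12, donors = 4, seed = 6)
  cl <- cluster_panel(pm)
  expect_length(cl$genes$order, 12)
  expect_length(cl$samples$order, 8)
})

test_that("PCA coordinates match the covariance eigendecomposition on a small fixture", {
  set.seed(17)
  M <- matrix(rnorm(20), nrow = 4, ncol = 5,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  pc <- pca_top3(M)
  # eigen oracle on the sample covariance of the centered samples
  Xc <- scale(t(M), scale = FALSE)
  ev <- eigen(cov(Xc))
  scores_oracle <- Xc %*% ev$vectors[, 1:3]
  got <- as.matrix(pc$scores[, c("PC1", "PC2", "PC3")])
  expect_equal(abs(unname(got)), abs(unname(scores_oracle)),
               tolerance = 1e-6)
  expect_equal(pc$var_fraction, (ev$values / sum(ev$values))[1:3],
               tolerance = 1e-6)
  # variance fractions nonincreasing and summing to at most 1
  expect_true(all(diff(pc$var_fraction) <= 1e-12))
  expect_lte(sum(pc$var_fraction), 1 + 1e-12)
  # sign convention: largest-magnitude loading positive, so repeated runs
  # are identical
  expect_identical(pca_top3(M)$scores, pc$scores)
  for (j in 1:3) {
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
})

test_that("PCA degrades gracefully on collinear data", {
  # samples on a line: one component explains ~all variance
  set.seed(23)
  base <- rnorm(5)
  M <- outer(base, c(1, 2, 3, 4)) +
    matrix(rnorm(20, sd = 1e-4), 5, 4)
  colnames(M) <- paste0("s", 1:4)
  pc <- suppressWarnings(pca_top3(M))
  expect_gt(pc$var_fraction[1], 0.999)
  # rank-deficient matrix: fewer components, flagged
  M2 <- outer(rnorm(5), c(1, 2, 3, 4))
  colnames(M2) <- paste0("s", 1:4)
  expect_warning(pc2 <- pca_top3(M2), "rank")
  expect_true(pc2$rank_deficient)
  expect_lt(ncol(pc2$loadings), 3)
  expect_error(pca_top3(M[, 1:3]), "at least 4 samples")
})

test_that("paired testing matches hand-worked statistics and BH step-up", {
  pm <- generate_panel(n_genes = 10, donors = 5, low_call_frac = 0,
                       high_call_prob = 1, frac_de = 0.5, seed = 12)
  de <- paired_de(pm)
  expect_equal(nrow(de), 10)
  expect_true(all(de$n_pairs == 5))
  # per-gene p equals a directly computed paired t-test
  g <- 4
  v <- pm$values[g, pm$samples$arm == "vehicle"]
  tr <- pm$values[g, pm$samples$arm == "cocktail"]
  expect_equal(de$p_value[g], t.test(tr, v, paired = TRUE)$p.value)
  expect_equal(de$fold_change[g], 2^mean(tr - v))
  # BH adjustment equals the independent step-up oracle
  expect_equal(de$p_adjusted, bh_stepup_brute(de$p_value), tolerance = 1e-12)
  expect_true(all(de$p_adjusted >= de$p_value - 1e-15))
  # step-up monotonicity: sorted raw p gives nondecreasing adjusted p
  o <- order(de$p_value)
  expect_true(all(diff(de$p_adjusted[o]) >= -1e-15))
})

test_that("BH equals the hand oracle on a fixed 10-value p-vector", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  expect_equal(p.adjust(p, method = "BH"), bh_stepup_brute(p),
               tolerance = 1e-12)
})

test_that("all-zero paired differences yield maximal p-values", {
  pm <- generate_panel(n_genes = 6, donors = 4, low_call_frac = 0,
                       frac_de = 0, noise_sd = 0, donor_sd = 0.5, seed = 3)
  de <- paired_de(pm)
  expect_true(all(de$p_value == 1))
  expect_true(all(de$p_adjusted == 1))
  expect_false(any(de$significant))
})

test_that("undetected entries drop pairs per gene and sparse genes go untested", {
  pm <- generate_panel(n_genes = 6, donors = 4, low_call_frac = 0,
                       high_call_prob = 1, seed = 8)
  pm$calls["gene_002", 1] <- FALSE          # drops donor 1 for that gene
  pm$calls["gene_005", c(1, 3, 5, 7)] <- FALSE  # one vehicle per donor
  expect_warning(de <- paired_de(pm), "not tested")
  expect_equal(de$n_pairs[de$gene == "gene_002"], 3)
  expect_equal(de$n_pairs[de$gene == "gene_005"], 0)
  expect_true(is.na(de$p_value[de$gene == "gene_005"]))
  # adjustment runs across tested genes only
  tested <- !is.na(de$p_value)
  expect_equal(de$p_adjusted[tested],
               bh_stepup_brute(de$p_value[tested]), tolerance = 1e-12)
})

test_that("fold-change set logic applies a strict threshold in either direction", {
  fc_a <- c(g1 = 6, g2 = 5, g3 = 1 / 6, g4 = 2, g5 = 12)
  fc_b <- c(g1 = 7, g2 = 9, g3 = 1.2, g4 = 1 / 8, g6 = 5.5)
  fs <- fold_change_sets(fc_a, fc_b, threshold = 5)
  expect_setequal(fs$set_a, c("g1", "g3", "g5"))  # g2 = 5 exactly: excluded
  expect_setequal(fs$set_b, c("g1", "g2", "g4", "g6"))
  expect_setequal(fs$both, "g1")
  expect_equal(fs$counts$n_only_a, 2)
  expect_equal(fs$counts$n_only_b, 3)
  # identical inputs: intersection is the whole set, uniques empty
  fs2 <- fold_change_sets(fc_a, fc_a)
  expect_equal(fs2$counts$n_both, fs2$counts$n_a)
  expect_equal(fs2$counts$n_only_a, 0)
  expect_error(fold_change_sets(fc_a, fc_b, threshold = 1), "> 1")
  expect_error(fold_change_sets(unname(fc_a), fc_b), "named")
})

test_that("volcano flags require both the significance and the fold-change criterion", {
  de <- tibble::tibble(
    gene = paste0("g", 1:4),
    mean_log2_diff = c(log2(3), log2(1.5), log2(3), log2(0.2)),
    fold_change = c(3, 1.5, 3, 0.2),
    p_value = c(0.001, 0.001, 0.2, 0.001),
    p_adjusted = c(0.04, 0.04, 0.4, 0.04)
  )
  v <- volcano_table(de, fc_threshold = 2, alpha = 0.05)
  expect_identical(v$significant, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(v$neg_log10_p_adjusted, -log10(de$p_adjusted))
  # flag count equals a brute-force filter
  expect_equal(sum(v$significant),
               sum(de$p_adjusted < 0.05 &
                     pmax(de$fold_change, 1 / de$fold_change) > 2))
})

test_that("strong simulated effects are recovered by the volcano criterion", {
  eff <- setNames(rep(2.5, 4), sprintf("gene_%03d", 1:4))
  hits <- vapply(1:50, function(s) {
    pm <- generate_panel(n_genes = 24, donors = 5, effect_spec = eff,
                         low_call_frac = 0, noise_sd = 0.5, seed = s)
    v <- volcano_table(paired_de(call_rate_filter(pm)))
    mean(v$significant[v$gene %in% names(eff)])
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
  # a >5-fold effect lands in the >5-fold set downstream with high probability
  eff5 <- c(gene_010 = log2(6.5))
  in_set <- vapply(1:30, function(s) {
    pm <- generate_panel(n_genes = 24, donors = 5, effect_spec = eff5,
                         low_call_frac = 0, noise_sd = 0.5, seed = 100 + s)
    de <- paired_de(pm)
    "gene_010" %in% fold_change_sets(de, de, threshold = 5)$set_a
  }, logical(1))
  expect_gte(mean(in_set), 0.7)
})

test_that("identical panels give identical cluster trees, PCA and DE tables", {
  pm <- generate_panel(n_genes = 20, donors = 5, seed = 31)
  expect_identical(cluster_panel(pm)$genes$height,
                   cluster_panel(pm)$genes$height)
  expect_identical(pca_top3(pm)$scores, pca_top3(pm)$scores)
  expect_identical(paired_de(call_rate_filter(pm)),
                   paired_de(call_rate_filter(pm)))
})
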