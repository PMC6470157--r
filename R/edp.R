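#' Call-rate filter
#'
#' Retains a gene only if its detection-call fraction across all samples is at
#' least `threshold` (the informative-gene filter applied before any
#' normalization or testing, compensating for assay dropout in long-archived
#' samples).
#'
#' @param panel A `panel_matrix`.
#' @param threshold Required detected fraction, in `(0, 1]`.
#' @return A `panel_matrix` restricted to the retained genes, with attributes
#'   `threshold` and `call_rate` (named vector over the input genes).
#' @export
call_rate_filter <- function(panel, threshold = 0.5) {
  stopifnot(inherits(panel, "panel_matrix"))
  if (!(threshold > 0 && threshold <= 1)) {
    abort("threshold must lie in (0, 1]")
  }
  rate <- rowMeans(panel$calls)
  keep <- rate >= threshold
  if (!any(keep)) {
    warn("no genes pass the call-rate filter")
  }
  out <- new_panel(panel$values[keep, , drop = FALSE],
                   panel$calls[keep, , drop = FALSE],
                   panel$samples,
                   effects = panel$effects[names(panel$effects) %in%
                                             rownames(panel$values)[keep]])
  attr(out, "threshold") <- threshold
  attr(out, "call_rate") <- rate
  out
}

#' Hierarchical clustering with Euclidean distance and Ward linkage
#'
#' Agglomerative clustering of the rows of a matrix using the Euclidean
#' distance metric and Ward's minimum-variance linkage. The merge tree is
#' deterministic given the input row order. Use [cluster_panel()] for the
#' two-way (genes and samples) clustering of an expression panel.
#'
#' @param mat Numeric matrix; rows are the items clustered.
#' @return A list of class `ward_clustering`: `tree` (an `hclust` object),
#'   `order` (leaf order), `height` (merge heights), `labels`.
#' @export
hierarchical_cluster <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) abort("need at least 2 items to cluster")
  tree <- hclust(dist(mat, method = "euclidean"), method = "ward.D2")
  structure(
    list(tree = tree, order = tree$order, height = tree$height,
         labels = tree$labels %||% as.character(seq_len(nrow(mat)))),
    class = "ward_clustering"
  )
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat(sprintf("<ward_clustering> %d leaves; merge heights %.3g .. %.3g\n",
              length(x$order), min(x$height), max(x$height)))
  invisible(x)
}

#' Two-way clustering of an expression panel
#'
#' Clusters genes (rows) and samples (columns) with [hierarchical_cluster()],
#' on detected values only (undetected entries are imputed with the gene mean
#' of detected values for distance computation).
#'
#' @param panel A `panel_matrix`.
#' @return A list with `genes` and `samples`, each a `ward_clustering`.
#' @export
cluster_panel <- function(panel) {
  stopifnot(inherits(panel, "panel_matrix"))
  vals <- impute_undetected(panel)
  list(genes = hierarchical_cluster(vals),
       samples = hierarchical_cluster(t(vals)))
}

impute_undetected <- function(panel) {
  vals <- panel$values
  vals[!panel$calls] <- NA_real_
  gm <- rowMeans(vals, na.rm = TRUE)
  gm[is.nan(gm)] <- 0
  idx <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(idx)) vals[idx] <- gm[idx[, 1]]
  vals
}

#' Principal components of the samples (top 3)
#'
#' Principal component analysis of the samples on the detected expression
#' values (genes as variables, mean-centered, unscaled), returning the
#' coordinates of each sample on the top three variance contributors together
#' with the fraction of variance each explains. For reproducibility the sign
#' of each component is fixed so that its largest-magnitude gene loading is
#' positive. If the matrix has rank below 3, fewer components are returned
#' and `rank_deficient` is set.
#'
#' @param x A `panel_matrix` or a genes x samples numeric matrix.
#' @return A list of class `panel_pca`: `scores` (tibble `sample_id`, `PC1`,
#'   `PC2`, `PC3` as available, plus `donor_id`/`arm` when known),
#'   `var_fraction`, `loadings`, `rank_deficient`.
#' @export
pca_top3 <- function(x) {
  samples <- NULL
  if (inherits(x, "panel_matrix")) {
    samples <- x$samples
    mat <- impute_undetected(x)
  } else {
    mat <- as.matrix(x)
  }
  if (ncol(mat) < 4) abort("need at least 4 samples for a 3-component PCA")
  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2
  n_comp <- min(3L, sum(var_all > max(var_all) * 1e-12))
  rank_deficient <- n_comp < 3L
  if (rank_deficient) {
    warn(sprintf("matrix rank supports only %d component(s)", n_comp))
  }
  rot <- pc$rotation[, seq_len(n_comp), drop = FALSE]
  scr <- pc$x[, seq_len(n_comp), drop = FALSE]
  for (j in seq_len(n_comp)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scr[, j] <- -scr[, j]
    }
  }
  scores <- tibble::as_tibble(scr, rownames = "sample_id")
  if (!is.null(samples)) {
    scores <- dplyr::left_join(scores, samples, by = "sample_id")
  }
  structure(
    list(scores = scores,
         var_fraction = var_all[seq_len(n_comp)] / sum(var_all),
         loadings = rot, rank_deficient = rank_deficient),
    class = "panel_pca"
  )
}

#' Paired differential expression with Benjamini-Hochberg adjustment
#'
#' For every gene, a paired two-tailed t-test of treated versus vehicle log2
#' values across donors, followed by Benjamini-Hochberg step-up adjustment
#' across all tested genes. Undetected entries are treated as missing and a
#' donor pair contributes to a gene only when both of its entries are
#' detected; genes with fewer than 2 complete pairs are reported untested
#' (`NA` p-value) and excluded from the adjustment. Fold change is the
#' geometric-mean linear ratio, `2^(mean paired log2 difference)`.
#'
#' @param panel A `panel_matrix` (typically after [call_rate_filter()]).
#' @param alpha Significance level on the adjusted p-value.
#' @return A tibble of class `paired_de`: one row per gene with `gene`,
#'   `n_pairs`, `mean_log2_diff`, `fold_change`, `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
paired_de <- function(panel, alpha = 0.05) {
  stopifnot(inherits(panel, "panel_matrix"))
  s <- panel$samples
  donors <- unique(s$donor_id)
  if (length(donors) < 2) abort("need at least 2 donor pairs")
  v_idx <- match(paste(donors, "vehicle", sep = "_"), s$sample_id)
  c_idx <- match(paste(donors, "cocktail", sep = "_"), s$sample_id)
  if (anyNA(v_idx) || anyNA(c_idx)) {
    # fall back to matching by columns rather than id naming convention
    v_idx <- vapply(donors, function(d) {
      which(s$donor_id == d & s$arm == "vehicle")[1]
    }, integer(1))
    c_idx <- vapply(donors, function(d) {
      which(s$donor_id == d & s$arm == "cocktail")[1]
    }, integer(1))
  }
  res <- purrr::map_dfr(seq_len(nrow(panel$values)), function(g) {
    ok <- panel$calls[g, v_idx] & panel$calls[g, c_idx]
    d <- panel$values[g, c_idx][ok] - panel$values[g, v_idx][ok]
    if (length(d) < 2) {
      return(tibble::tibble(gene = panel$genes[g], n_pairs = length(d),
                            mean_log2_diff = NA_real_,
                            fold_change = NA_real_, p_value = NA_real_))
    }
    p <- if (sd(d) == 0) {
      if (mean(d) == 0) 1 else 0
    } else {
      t.test(d, mu = 0, alternative = "two.sided")$p.value
    }
    tibble::tibble(gene = panel$genes[g], n_pairs = length(d),
                   mean_log2_diff = mean(d), fold_change = 2^mean(d),
                   p_value = p)
  })
  if (sum(!is.na(res$p_value)) < 1) {
    abort("no gene has at least 2 complete pairs")
  }
  if (any(is.na(res$p_value))) {
    warn(sprintf("%d gene(s) lack complete pairs and were not tested",
                 sum(is.na(res$p_value))))
  }
  res$p_adjusted <- NA_real_
  tested <- !is.na(res$p_value)
  res$p_adjusted[tested] <- p.adjust(res$p_value[tested], method = "BH")
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  class(res) <- c("paired_de", class(res))
  res
}

#' Fold-change set logic
#'
#' Builds the sets of genes whose linear fold-change magnitude strictly
#' exceeds a threshold in each of two analyses and returns their unique and
#' overlapping memberships (the Venn comparison of dysregulated genes).
#' Magnitude is direction-agnostic: `max(FC, 1/FC) > threshold`, so 5-fold
#' induction and 5-fold repression both qualify; a fold change of exactly the
#' threshold does not (strict `>`).
#'
#' @param de_a,de_b `paired_de` tibbles, or named numeric vectors of linear
#'   fold changes.
#' @param threshold Linear fold-change threshold (> 1).
#' @return A list of class `fold_change_sets`: `set_a`, `set_b`, `both`,
#'   `only_a`, `only_b` (character vectors) and `counts` (one-row tibble).
#' @export
fold_change_sets <- function(de_a, de_b, threshold = 5) {
  if (!(is.numeric(threshold) && length(threshold) == 1 && threshold > 1)) {
    abort("threshold must be a single number > 1")
  }
  fc_a <- as_fc_vector(de_a)
  fc_b <- as_fc_vector(de_b)
  universe <- union(names(fc_a), names(fc_b))
  hits <- function(fc) {
    fc <- fc[!is.na(fc)]
    names(fc)[pmax(fc, 1 / fc) > threshold]
  }
  set_a <- hits(fc_a)
  set_b <- hits(fc_b)
  both <- intersect(set_a, set_b)
  structure(
    list(set_a = set_a, set_b = set_b, both = both,
         only_a = setdiff(set_a, both), only_b = setdiff(set_b, both),
         universe = universe,
         counts = tibble::tibble(
           n_a = length(set_a), n_b = length(set_b), n_both = length(both),
           n_only_a = length(set_a) - length(both),
           n_only_b = length(set_b) - length(both)
         )),
    class = "fold_change_sets"
  )
}

as_fc_vector <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x))) abort("fold-change vectors must be named by gene")
    return(x)
  }
  if (is.data.frame(x) && all(c("gene", "fold_change") %in% names(x))) {
    return(setNames(x$fold_change, x$gene))
  }
  abort("inputs must be paired_de results or named fold-change vectors")
}

#' @export
print.fold_change_sets <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Volcano table
#'
#' Per-gene table for a volcano display: log2 fold change on the x-axis,
#' -log10 adjusted p-value on the y-axis, and a significance flag that is true
#' iff the adjusted p-value is below `alpha` and the linear fold-change
#' magnitude strictly exceeds `fc_threshold`.
#'
#' @param de A `paired_de` tibble.
#' @param fc_threshold Linear fold-change threshold.
#' @param alpha Adjusted-p significance level.
#' @return A tibble: `gene`, `log2_fold_change`, `neg_log10_p_adjusted`,
#'   `significant`.
#' @export
volcano_table <- function(de, fc_threshold = 2, alpha = 0.05) {
  stopifnot(is.data.frame(de),
            all(c("gene", "mean_log2_diff", "fold_change", "p_adjusted")
                %in% names(de)))
  fc_mag <- pmax(de$fold_change, 1 / de$fold_change)
  tibble::tibble(
    gene = de$gene,
    log2_fold_change = de$mean_log2_diff,
    neg_log10_p_adjusted = -log10(de$p_adjusted),
    significant = !is.na(de$p_adjusted) & de$p_adjusted < alpha &
      !is.na(fc_mag) & fc_mag > fc_threshold
  )
}
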