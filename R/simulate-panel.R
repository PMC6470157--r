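#' Generate a paired expression-panel matrix
#'
#' Simulates a genes x samples log2-expression matrix for a paired
#' vehicle/treatment design: every donor contributes exactly one vehicle and
#' one treated sample. Values follow a simple hierarchical model:
#' gene baseline + donor random effect + gene-specific treatment effect
#' (treated arm only) + measurement noise, all on the log2 scale. Each entry
#' additionally carries a detection-call flag drawn per gene, emulating assay
#' dropout after long sample archiving: by default a minority of genes have a
#' low per-sample call probability, so that with five donor pairs roughly 60
#' of 96 genes survive a 50% call-rate filter.
#'
#' @param n_genes Number of genes (panel size).
#' @param donors Number of donors (>= 2); samples = 2 * donors.
#' @param effect_spec Named numeric vector of per-gene log2 treatment effects.
#'   Names must be gene ids; genes not named get effect 0. `NULL` draws
#'   effects for a random `frac_de` fraction of genes from
#'   `N(0, effect_sd^2)`.
#' @param missing_spec Named numeric vector of per-gene detection-call
#'   probabilities in `[0, 1]`. `NULL` assigns `low_call_prob` to a random
#'   `low_call_frac` fraction of genes and `high_call_prob` to the rest.
#' @param frac_de Fraction of genes given a nonzero treatment effect when
#'   `effect_spec` is `NULL`.
#' @param effect_sd SD of drawn log2 effects.
#' @param baseline_mean,baseline_sd Gene baseline distribution (log2 scale).
#' @param donor_sd SD of the shared donor random effect.
#' @param noise_sd Per-entry measurement noise SD (log2 scale).
#' @param low_call_frac,low_call_prob,high_call_prob Detection-call model when
#'   `missing_spec` is `NULL`.
#' @param seed Integer seed; identical seeds reproduce the panel exactly.
#' @return An object of class `panel_matrix`: a list with `values` (genes x
#'   samples numeric matrix), `calls` (logical matrix, same shape), `samples`
#'   (tibble `sample_id`, `donor_id`, `arm`), `genes` (character), and
#'   `effects` (the per-gene log2 effects actually used).
#' @examples
#' pm <- generate_panel(n_genes = 24, donors = 4, seed = 1)
#' pm
#' @export
generate_panel <- function(n_genes = 96, donors = 5, effect_spec = NULL,
                           missing_spec = NULL, frac_de = 0.25,
                           effect_sd = 2, baseline_mean = 5, baseline_sd = 2,
                           donor_sd = 0.5, noise_sd = 0.5,
                           low_call_frac = 0.375, low_call_prob = 0.2,
                           high_call_prob = 0.98, seed = 1) {
  check_num(donors, "donors", lower = 2)
  check_num(n_genes, "n_genes", lower = 1)
  genes <- sprintf("gene_%03d", seq_len(n_genes))
  if (!is.null(effect_spec)) {
    unknown <- setdiff(names(effect_spec), genes)
    if (length(unknown)) {
      abort(sprintf("effect_spec names unknown genes: %s",
                    paste(head(unknown, 3), collapse = ", ")))
    }
  }
  if (!is.null(missing_spec)) {
    unknown <- setdiff(names(missing_spec), genes)
    if (length(unknown)) {
      abort(sprintf("missing_spec names unknown genes: %s",
                    paste(head(unknown, 3), collapse = ", ")))
    }
    if (any(missing_spec < 0 | missing_spec > 1)) {
      abort("missing_spec probabilities must lie in [0, 1]")
    }
  }
  withr::with_seed(seed, {
    donor_ids <- sprintf("donor_%02d", seq_len(donors))
    samples <- tibble::tibble(
      donor_id = rep(donor_ids, each = 2),
      arm = rep(c("vehicle", "cocktail"), times = donors)
    )
    samples$sample_id <- paste(samples$donor_id, samples$arm, sep = "_")

    effects <- setNames(numeric(n_genes), genes)
    if (is.null(effect_spec)) {
      n_de <- round(frac_de * n_genes)
      if (n_de > 0) {
        de_genes <- sample(genes, n_de)
        effects[de_genes] <- rnorm(n_de, mean = 0, sd = effect_sd)
      }
    } else {
      effects[names(effect_spec)] <- as.numeric(effect_spec)
    }

    call_prob <- setNames(rep(high_call_prob, n_genes), genes)
    if (is.null(missing_spec)) {
      n_low <- round(low_call_frac * n_genes)
      if (n_low > 0) {
        call_prob[sample(genes, n_low)] <- low_call_prob
      }
    } else {
      call_prob[names(missing_spec)] <- as.numeric(missing_spec)
    }

    baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
    donor_eff <- rnorm(donors, 0, donor_sd)
    n_samp <- nrow(samples)
    values <- matrix(baseline, n_genes, n_samp) +
      matrix(rep(rep(donor_eff, each = 2), each = n_genes), n_genes, n_samp) +
      outer(effects, as.numeric(samples$arm == "cocktail")) +
      matrix(rnorm(n_genes * n_samp, 0, noise_sd), n_genes, n_samp)
    dimnames(values) <- list(genes, samples$sample_id)
    calls <- matrix(
      stats::runif(n_genes * n_samp) < rep(call_prob, times = n_samp),
      n_genes, n_samp, dimnames = dimnames(values))

    new_panel(values, calls, samples[, c("sample_id", "donor_id", "arm")],
              effects = effects)
  })
}

new_panel <- function(values, calls, samples, effects = NULL) {
  stopifnot(is.matrix(values), is.matrix(calls),
            identical(dim(values), dim(calls)))
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample_id", "donor_id", "arm") %in% names(samples)),
            identical(samples$sample_id, colnames(values)))
  tab <- table(samples$donor_id, samples$arm)
  if (!all(tab == 1) || !identical(sort(colnames(tab)),
                                   c("cocktail", "vehicle"))) {
    abort("every donor must have exactly one vehicle and one cocktail sample")
  }
  structure(
    list(values = values, calls = calls, samples = samples,
         genes = rownames(values), effects = effects),
    class = "panel_matrix"
  )
}

#' @export
print.panel_matrix <- function(x, ...) {
  cat(sprintf(
    "<panel_matrix> %d genes x %d samples (%d donors, paired vehicle/cocktail); %.1f%% entries detected\n",
    nrow(x$values), ncol(x$values), nrow(x$samples) / 2,
    100 * mean(x$calls)))
  invisible(x)
}

#' @export
as_tibble.panel_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id",
                        values_to = "log2_expr") |>
    dplyr::left_join(
      tibble::as_tibble(x$calls, rownames = "gene") |>
        tidyr::pivot_longer(-"gene", names_to = "sample_id",
                            values_to = "detected"),
      by = c("gene", "sample_id")
    ) |>
    dplyr::left_join(x$samples, by = "sample_id")
}

#' Write or read a panel as a CSV trio
#'
#' Writes `<prefix>_values.csv` (genes as rows, samples as columns),
#' `<prefix>_calls.csv` (same shape, TRUE/FALSE detection flags) and
#' `<prefix>_samples.csv` (`sample_id`, `donor_id`, `arm`).
#'
#' @param panel A `panel_matrix`.
#' @param prefix Path prefix for the three files.
#' @return `write_panel_csv()` returns the three paths invisibly;
#'   `read_panel_csv()` returns a `panel_matrix`.
#' @export
write_panel_csv <- function(panel, prefix) {
  stopifnot(inherits(panel, "panel_matrix"))
  paths <- paste0(prefix, c("_values.csv", "_calls.csv", "_samples.csv"))
  readr::write_csv(tibble::as_tibble(panel$values, rownames = "gene"),
                   paths[1])
  readr::write_csv(tibble::as_tibble(panel$calls, rownames = "gene"),
                   paths[2])
  readr::write_csv(panel$samples, paths[3])
  invisible(paths)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(prefix) {
  paths <- paste0(prefix, c("_values.csv", "_calls.csv", "_samples.csv"))
  miss <- paths[!file.exists(paths)]
  if (length(miss)) {
    abort(sprintf("missing panel file(s): %s", paste(miss, collapse = ", ")))
  }
  vals <- readr::read_csv(paths[1], show_col_types = FALSE)
  calls <- readr::read_csv(paths[2], show_col_types = FALSE)
  samples <- readr::read_csv(paths[3], show_col_types = FALSE,
                             col_types = "ccc")
  vm <- as.matrix(vals[, -1])
  rownames(vm) <- vals$gene
  cm <- as.matrix(calls[, -1]) == TRUE
  rownames(cm) <- calls$gene
  new_panel(vm, cm, samples)
}
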