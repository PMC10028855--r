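#' Signature reliability metrics
#'
#' Computes the five quality-check metrics for one scored signature on a
#' dataset:
#' \enumerate{
#'   \item the per-observation average expression of the signature genes
#'     present in the data;
#'   \item the per-observation percentage of zero entries among those
#'     genes;
#'   \item the correlation between the signature scores and the
#'     per-observation total counts of the whole matrix;
#'   \item the correlation between the scores and the per-observation
#'     percentage of zeros over the whole matrix;
#'   \item the percentage of signature genes used for the score.
#' }
#' High zero fractions combined with low gene coverage flag scores driven
#' by dropout rather than biology; score/total-count correlations flag
#' residual depth effects (in spatial data, where total counts per spot
#' track the number and type of captured cells, such correlations can be
#' biological — a note, not a different formula).
#'
#' @param ds The expression dataset the score was computed on.
#' @param sig The `sig_definition` (or name resolved against `catalog`).
#' @param result The `sig_score` from [compute_signature()].
#' @param catalog Catalog for name resolution.
#' @param method Correlation type, `"pearson"` (default) or
#'   `"spearman"`.
#' @param obs_subset Optional character/integer subset of observations;
#'   metrics are then computed on the subset only.
#' @return A `sig_evaluation` object.
#' @export
evaluate_signature <- function(ds, sig, result, catalog = NULL,
                               method = c("pearson", "spearman"),
                               obs_subset = NULL) {
  method <- match.arg(method)
  if (is.character(sig)) {
    catalog <- catalog %||% load_catalog()
    sig <- get_signature(catalog, sig)
  }
  stopifnot(inherits(result, "sig_score"))
  mat <- expr_matrix(ds)
  if (!is.null(obs_subset)) mat <- mat[, obs_subset, drop = FALSE]
  if (ncol(mat) == 0L) sigc_stop("no observations to evaluate", "validation")
  values <- result$values[colnames(mat)]

  sig_genes <- if (identical(sig$method, "consensus_centroid"))
    rownames(sig$centroids) else sig$genes$symbol
  present <- match(sig_genes, toupper(rownames(mat)))
  sub <- mat[present[!is.na(present)], , drop = FALSE]
  if (nrow(sub) == 0L)
    sigc_stop("no signature genes present in the dataset", "validation")

  mean_expr <- colMeans(sub, na.rm = TRUE)
  pct_zero <- 100 * colMeans(sub == 0, na.rm = TRUE)
  totals <- colSums(mat, na.rm = TRUE)
  pct_zero_total <- 100 * colMeans(mat == 0, na.rm = TRUE)

  safe_cor <- function(a, b) {
    if (anyNA(a) || sd(a, na.rm = TRUE) == 0 || sd(b, na.rm = TRUE) == 0)
      return(NA_real_)
    cor(a, b, method = method)
  }
  structure(list(
    signature_name = result$signature_name,
    mean_expr_per_obs = mean_expr,
    pct_zero_per_obs = pct_zero,
    cor_score_totalcounts = safe_cor(values, totals),
    cor_score_pctzero = safe_cor(values, pct_zero_total),
    pct_genes_used = 100 * result$genes_used / result$genes_requested,
    n_obs = ncol(mat),
    correlation_method = method,
    spatial_note = identical(ds_technology(ds), "spatial")
  ), class = "sig_evaluation")
}

#' @export
print.sig_evaluation <- function(x, ...) {
  cat(sprintf("<sig_evaluation> %s (n = %d)\n", x$signature_name, x$n_obs))
  cat(sprintf("  median mean expression: %.4g\n",
              median(x$mean_expr_per_obs)))
  cat(sprintf("  median %% zeros in signature genes: %.1f\n",
              median(x$pct_zero_per_obs)))
  cat(sprintf("  cor(score, total counts): %s\n",
              format(x$cor_score_totalcounts, digits = 3)))
  cat(sprintf("  cor(score, %% zeros): %s\n",
              format(x$cor_score_pctzero, digits = 3)))
  cat(sprintf("  %% signature genes used: %.1f\n", x$pct_genes_used))
  if (x$spatial_note)
    cat("  note: spatial data - per-spot totals carry biological signal;\n",
        "       interpret score/total-count correlations in context\n")
  invisible(x)
}

#' Tabulate reliability metrics for many signatures
#'
#' One row per scored signature, in deterministic (input) order, with the
#' per-observation vectors summarized by their medians for tabular
#' export.
#'
#' @param ds The expression dataset.
#' @param results A list of `sig_score` objects (or a single one).
#' @inheritParams evaluate_signature
#' @return A data.frame with columns `signature`, `median_mean_expr`,
#'   `median_pct_zero`, `cor_score_totalcounts`, `cor_score_pctzero`,
#'   `pct_genes_used`, `n_obs`. The full `sig_evaluation` objects are
#'   attached as the `"evaluations"` attribute.
#' @export
evaluate_all <- function(ds, results, catalog = NULL,
                         method = c("pearson", "spearman"),
                         obs_subset = NULL) {
  method <- match.arg(method)
  if (inherits(results, "sig_score")) results <- list(results)
  if (!length(results)) {
    return(data.frame(signature = character(0), median_mean_expr = numeric(0),
                      median_pct_zero = numeric(0),
                      cor_score_totalcounts = numeric(0),
                      cor_score_pctzero = numeric(0),
                      pct_genes_used = numeric(0), n_obs = integer(0)))
  }
  catalog <- catalog %||% load_catalog()
  evals <- lapply(results, function(r)
    evaluate_signature(ds, r$signature_name, r, catalog = catalog,
                       method = method, obs_subset = obs_subset))
  tab <- data.frame(
    signature = vapply(evals, `[[`, character(1), "signature_name"),
    median_mean_expr = vapply(evals, function(e)
      median(e$mean_expr_per_obs), numeric(1)),
    median_pct_zero = vapply(evals, function(e)
      median(e$pct_zero_per_obs), numeric(1)),
    cor_score_totalcounts = vapply(evals, `[[`, numeric(1),
                                   "cor_score_totalcounts"),
    cor_score_pctzero = vapply(evals, `[[`, numeric(1), "cor_score_pctzero"),
    pct_genes_used = vapply(evals, `[[`, numeric(1), "pct_genes_used"),
    n_obs = vapply(evals, `[[`, integer(1), "n_obs"),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(tab, "evaluations") <- evals
  tab
}

#' Filter signatures by reliability
#'
#' Implements the sparse-data filtering rule: a signature is dropped when
#' its median per-observation zero percentage exceeds `max_pct_zero`
#' \emph{and} its gene coverage is below `min_pct_genes_used` (the two
#' conditions are conjunctive — a sparse but well-covered signature is
#' kept).
#'
#' @param evals The table returned by [evaluate_all()] (or a list of
#'   `sig_evaluation` objects).
#' @param max_pct_zero Dropping threshold on the median percentage of
#'   zeros among signature genes (default 90).
#' @param min_pct_genes_used Dropping threshold on the percentage of
#'   signature genes used (default 30).
#' @return A list with `kept` and `dropped` (character vectors of
#'   signature names) and `reasons` (a data.frame with the decision and
#'   the two metrics per signature).
#' @export
filter_by_qc <- function(evals, max_pct_zero = 90, min_pct_genes_used = 30) {
  if (is.list(evals) && !is.data.frame(evals)) {
    evals <- data.frame(
      signature = vapply(evals, `[[`, character(1), "signature_name"),
      median_pct_zero = vapply(evals, function(e)
        median(e$pct_zero_per_obs), numeric(1)),
      pct_genes_used = vapply(evals, `[[`, numeric(1), "pct_genes_used"),
      stringsAsFactors = FALSE)
  }
  if (!nrow(evals)) sigc_stop("no evaluations to filter", "validation")
  drop <- evals$median_pct_zero > max_pct_zero &
    evals$pct_genes_used < min_pct_genes_used
  reasons <- data.frame(
    signature = evals$signature,
    median_pct_zero = evals$median_pct_zero,
    pct_genes_used = evals$pct_genes_used,
    decision = ifelse(drop, "dropped", "kept"),
    reason = ifelse(
      drop,
      sprintf("median %% zeros %.1f > %g and %% genes used %.1f < %g",
              evals$median_pct_zero, max_pct_zero,
              evals$pct_genes_used, min_pct_genes_used),
      "passed QC"),
    stringsAsFactors = FALSE)
  list(kept = evals$signature[!drop],
       dropped = evals$signature[drop],
       reasons = reasons)
}
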