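#' Scoring method families
#'
#' The packaged signatures are normalized into six scoring families. Each
#' family is exposed as a plain-matrix function so it can be tested
#' against independent oracles; [compute_signature()] handles catalog
#' lookup, scale conversion, gene intersection and dispatch.
#'
#' @name scoring-families
NULL

row_zscores <- function(x) {
  mu <- rowMeans(x, na.rm = TRUE)
  s <- apply(x, 1L, sd, na.rm = TRUE)
  flat <- is.na(s) | s == 0
  z <- (x - mu) / ifelse(flat, 1, s)
  z[flat, ] <- 0
  z
}

#' Weighted-sum score
#'
#' `value_o = sum_g w_g * x[g, o]` over the signature genes present in
#' the matrix.
#'
#' @param x Numeric matrix (signature genes x observations).
#' @param weights Numeric vector aligned with `rownames(x)` (or named).
#' @return Named numeric vector of per-observation scores.
#' @rdname scoring-families
#' @export
score_weighted_sum <- function(x, weights) {
  x <- as.matrix(x)
  if (!is.null(names(weights))) weights <- weights[rownames(x)]
  if (length(weights) != nrow(x))
    sigc_stop("weights must align with matrix rows", "validation")
  if (!all(is.finite(weights)))
    sigc_stop("weighted_sum requires finite weights", "validation")
  colSums(x * weights, na.rm = TRUE)
}

#' Mean z-score
#'
#' Each gene is z-scored across observations (`(x - mean) / sd`,
#' zero-variance genes get z = 0); the score is the mean over genes of
#' the z (negated for down-regulated genes). Requires at least two
#' observations.
#'
#' @param directions Character vector (`"up"`/`"down"`/`"none"`) aligned
#'   with the rows of `x`; `"none"` counts as `"up"`.
#' @rdname scoring-families
#' @export
score_zscore_mean <- function(x, directions = NULL) {
  x <- as.matrix(x)
  if (ncol(x) < 2L)
    sigc_stop("zscore_mean requires at least 2 observations (sd undefined)",
              "validation")
  if (is.null(directions)) directions <- rep("up", nrow(x))
  z <- row_zscores(x)
  sign <- ifelse(directions == "down", -1, 1)
  colMeans(z * sign, na.rm = TRUE)
}

#' Up/down contrast score
#'
#' `value_o = mean(up genes) - mean(down genes)`; with no down genes
#' present the second term is zero. Refused when no up gene is present.
#'
#' @rdname scoring-families
#' @export
score_up_down <- function(x, directions) {
  x <- as.matrix(x)
  up <- directions == "up"
  dn <- directions == "down"
  if (!any(up))
    sigc_stop("up_down_diff requires at least one up-regulated gene present",
              "validation")
  up_mean <- colMeans(x[up, , drop = FALSE], na.rm = TRUE)
  dn_mean <- if (any(dn)) colMeans(x[dn, , drop = FALSE], na.rm = TRUE)
  else 0
  up_mean - dn_mean
}

#' Single-sample rank enrichment (ssGSEA-style)
#'
#' For each observation, all background genes are ranked by expression
#' (ascending, ties given mid-ranks; the walk order among tied ranks is
#' lexicographic by gene ID). Walking the list from the highest-ranked
#' gene down, the enrichment score is the running sum of the difference
#' between the weighted in-set empirical CDF (weight `rank^alpha`,
#' normalized over the set) and the uniform out-of-set empirical CDF.
#' The score depends on expression only through ranks, so it is invariant
#' under strictly monotone per-observation transforms.
#'
#' @param x Full background matrix (all genes x observations), not only
#'   the signature genes.
#' @param gene_set Character vector of signature genes (at least 2 present
#'   in the background; must not exhaust the background).
#' @param alpha Rank-weight exponent (default 0.25).
#' @rdname scoring-families
#' @export
score_ssgsea <- function(x, gene_set, alpha = 0.25) {
  x <- as.matrix(x)
  genes <- rownames(x)
  in_set <- genes %in% gene_set
  n <- length(genes)
  n_in <- sum(in_set)
  if (n_in < 2L)
    sigc_stop("ssgsea requires >= 2 signature genes in the background",
              "validation")
  if (n_in == n)
    sigc_stop("ssgsea background must contain genes outside the set",
              "validation")
  vapply(seq_len(ncol(x)), function(o) {
    r <- rank(x[, o], ties.method = "average")
    ord <- order(-r, genes)      # walk high -> low, ties by gene id
    rs <- r[ord]
    s <- in_set[ord]
    w <- rs^alpha
    p_in <- cumsum(ifelse(s, w, 0)) / sum(w[s])
    p_out <- cumsum(!s) / (n - n_in)
    sum(p_in - p_out)
  }, numeric(1)) |> setNames(colnames(x))
}

#' Immunophenoscore-style composite
#'
#' Genes carry a category (`EC` effector cells, `SC` suppressor cells,
#' `MHC`, `CP` checkpoints), a subclass and a subclass weight. Per
#' observation: genes are z-scored across observations; each subclass
#' scores `weight * mean(z of its genes)`; each category is the mean of
#' its subclass scores; the aggregate `AZ` is the mean of the four
#' category scores; the composite `IPS` is 0 when `AZ <= 0` and
#' `min(10, 10 * AZ / 3)` otherwise.
#'
#' @param class_labels Category per row of `x` (`EC`/`SC`/`MHC`/`CP`).
#' @param subclasses Subclass per row (genes of one subclass are averaged
#'   before weighting).
#' @param weights One weight per row (constant within a subclass).
#' @return A list with `components` (observations x EC/SC/MHC/CP matrix),
#'   `AZ` and `IPS` vectors.
#' @rdname scoring-families
#' @export
score_ips <- function(x, class_labels, subclasses, weights) {
  x <- as.matrix(x)
  if (ncol(x) < 2L)
    sigc_stop("ips_composite requires at least 2 observations", "validation")
  cats <- c("EC", "SC", "MHC", "CP")
  missing_cat <- setdiff(cats, unique(class_labels))
  if (length(missing_cat))
    sigc_stop(sprintf("ips_composite: no genes present for category %s; composite refused",
                      paste(missing_cat, collapse = ", ")), "validation")
  z <- row_zscores(x)
  comp <- sapply(cats, function(cc) {
    rows <- class_labels == cc
    sub_scores <- sapply(unique(subclasses[rows]), function(sc) {
      r <- rows & subclasses == sc
      w <- weights[r][1L]
      w * colMeans(z[r, , drop = FALSE], na.rm = TRUE)
    })
    if (is.null(dim(sub_scores))) sub_scores
    else rowMeans(sub_scores)
  })
  comp <- matrix(comp, ncol = 4L,
                 dimnames = list(colnames(x), cats))
  az <- rowMeans(comp)
  ips <- ifelse(az <= 0, 0, pmin(10, 10 * az / 3))
  list(components = comp, AZ = az, IPS = setNames(ips, colnames(x)))
}

#' Consensus-centroid subtype scores
#'
#' Per observation, the score for each subtype is the Pearson correlation
#' between the observation's expression over the genes shared with the
#' centroid matrix and that subtype's centroid; the label is the argmax
#' (ties resolved to the lexicographically first subtype, with a
#' warning). Observations with zero variance over the shared genes get
#' missing scores.
#'
#' @param centroids Gene-by-subtype numeric matrix.
#' @return A list with `scores` (observations x subtypes matrix) and
#'   `label` (character vector).
#' @rdname scoring-families
#' @export
score_consensus_subtypes <- function(x, centroids) {
  x <- as.matrix(x)
  shared <- intersect(rownames(x), rownames(centroids))
  if (length(shared) < 3L)
    sigc_stop("consensus_centroid requires >= 3 genes shared with the centroids",
              "validation")
  xs <- x[shared, , drop = FALSE]
  cs <- centroids[shared, , drop = FALSE]
  subtypes <- colnames(cs)
  scores <- matrix(NA_real_, ncol(xs), ncol(cs),
                   dimnames = list(colnames(xs), subtypes))
  for (o in seq_len(ncol(xs))) {
    v <- xs[, o]
    if (sd(v) == 0) next
    scores[o, ] <- apply(cs, 2L, function(cent) cor(v, cent))
  }
  if (anyNA(scores[, 1L]))
    sigc_warn(sprintf("%d observation(s) with zero variance over shared genes: scores missing",
                      sum(is.na(scores[, 1L]))))
  label <- apply(scores, 1L, function(s) {
    if (anyNA(s)) return(NA_character_)
    best <- which(s == max(s))
    sort(subtypes[best])[1L]
  })
  ties <- apply(scores, 1L, function(s)
    !anyNA(s) && sum(s == max(s)) > 1L)
  if (any(ties))
    sigc_warn(sprintf("%d observation(s) with tied subtype scores: lexicographically first label used",
                      sum(ties)))
  list(scores = scores, label = label)
}

# ---- dispatch --------------------------------------------------------------

new_sig_score <- function(signature_name, values, genes_requested,
                          genes_used, components = NULL, label = NULL,
                          options_fingerprint = "", warnings = character(0)) {
  structure(list(
    signature_name = signature_name,
    values = values,
    components = components,
    label = label,
    genes_requested = as.integer(genes_requested),
    genes_used = as.integer(genes_used),
    options_fingerprint = options_fingerprint,
    warnings = warnings
  ), class = "sig_score")
}

#' @export
print.sig_score <- function(x, ...) {
  cat(sprintf("<sig_score> %s: %d observation(s), %d/%d gene(s) used (%.1f%%)\n",
              x$signature_name, length(x$values), x$genes_used,
              x$genes_requested, 100 * x$genes_used / x$genes_requested))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Compute one signature score on a dataset
#'
#' Resolves the signature (by name against `catalog`, or directly from a
#' [signature_definition()]), converts the expression metric to the
#' signature's required scale on a copy if needed, intersects genes
#' case-insensitively, checks gene coverage against `min_coverage`, and
#' dispatches to the method family. The result records how many genes
#' were requested and actually used. Identical inputs and options give
#' bit-identical results.
#'
#' @param ds An expression dataset.
#' @param sig A `sig_definition` or a signature name.
#' @param catalog Catalog used to resolve `sig` when it is a name;
#'   defaults to the packaged catalog.
#' @param min_coverage Minimum fraction of signature genes that must be
#'   present in the dataset (default 0.05); below it scoring is refused.
#' @param opts Named list of method options (`alpha` for ssgsea,
#'   `pseudocount` for the log transform).
#' @return A `sig_score`.
#' @export
compute_signature <- function(ds, sig, catalog = NULL, min_coverage = 0.05,
                              opts = list()) {
  if (is.character(sig)) {
    catalog <- catalog %||% load_catalog()
    sig <- get_signature(catalog, sig)
  }
  stopifnot(inherits(sig, "sig_definition"))
  if (!sig$genes_available)
    sigc_stop(sprintf(
      "signature '%s' is a metadata-only catalog entry: its gene list is not packaged, so it cannot be scored",
      sig$name), "validation")

  warnings <- character(0)
  if (!identical(ds_metric(ds), sig$required_scale)) {
    ds <- withCallingHandlers(
      transform_metric(ds, sig$required_scale,
                       pseudocount = opts$pseudocount %||% 1),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  mat <- expr_matrix(ds)
  data_upper <- toupper(rownames(mat))

  sig_genes <- if (identical(sig$method, "consensus_centroid"))
    rownames(sig$centroids) else sig$genes$symbol
  requested <- length(sig_genes)
  hit <- match(sig_genes, data_upper)
  present <- !is.na(hit)
  used <- sum(present)
  coverage <- used / requested
  if (coverage < min_coverage)
    sigc_stop(sprintf(
      "signature '%s': only %d/%d genes (%.1f%%) present, below min_coverage = %.1f%%",
      sig$name, used, requested, 100 * coverage, 100 * min_coverage),
      "coverage")
  if (coverage < 1)
    warnings <- c(warnings, sprintf("%d/%d signature genes absent from data",
                                    requested - used, requested))

  sub <- mat[hit[present], , drop = FALSE]
  rownames(sub) <- sig_genes[present]
  g <- sig$genes[match(rownames(sub), sig$genes$symbol), , drop = FALSE]

  fingerprint <- paste0(
    "method=", sig$method, ";scale=", sig$required_scale,
    ";min_coverage=", format(min_coverage),
    ";alpha=", format(opts$alpha %||% 0.25),
    ";pseudocount=", format(opts$pseudocount %||% 1))

  res <- switch(
    sig$method,
    weighted_sum = {
      v <- score_weighted_sum(sub, g$weight)
      new_sig_score(sig$name, v, requested, used,
                    options_fingerprint = fingerprint, warnings = warnings)
    },
    zscore_mean = {
      v <- score_zscore_mean(sub, g$direction)
      new_sig_score(sig$name, v, requested, used,
                    options_fingerprint = fingerprint, warnings = warnings)
    },
    up_down_diff = {
      v <- score_up_down(sub, g$direction)
      new_sig_score(sig$name, v, requested, used,
                    options_fingerprint = fingerprint, warnings = warnings)
    },
    ssgsea = {
      full <- mat
      rownames(full) <- data_upper
      v <- score_ssgsea(full, sig_genes, alpha = opts$alpha %||% 0.25)
      new_sig_score(sig$name, v, requested, used,
                    options_fingerprint = fingerprint, warnings = warnings)
    },
    ips_composite = {
      r <- withCallingHandlers(
        score_ips(sub, g$class_label, g$subclass, g$weight),
        warning = function(w) {
          warnings <<- c(warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      comp <- cbind(r$components, AZ = r$AZ)
      new_sig_score(sig$name, r$IPS, requested, used,
                    components = comp,
                    options_fingerprint = fingerprint, warnings = warnings)
    },
    consensus_centroid = {
      r <- withCallingHandlers(
        score_consensus_subtypes(sub, sig$centroids),
        warning = function(w) {
          warnings <<- c(warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      best <- vapply(seq_len(nrow(r$scores)), function(i) {
        s <- r$scores[i, ]
        if (anyNA(s)) NA_real_ else max(s)
      }, numeric(1))
      new_sig_score(sig$name, setNames(best, rownames(r$scores)),
                    requested, used, components = r$scores,
                    label = r$label,
                    options_fingerprint = fingerprint, warnings = warnings)
    },
    sigc_stop(sprintf("unknown method '%s'", sig$method), "validation"))
  res
}

#' Compute and attach many signatures at once
#'
#' Selects signatures from the catalog with a [catalog_filter()], scores
#' each scoreable one with [compute_signature()], and attaches the
#' results. Per-signature failures (e.g. coverage below threshold) are
#' logged in the returned summary, not fatal; metadata-only entries are
#' skipped with a logged reason.
#'
#' @inheritParams compute_signature
#' @param catalog A `sig_catalog`.
#' @param filter A [catalog_filter()]; must match at least one signature
#'   with a packaged gene list.
#' @return A list with `dataset` (scores attached) and `summary` (a
#'   data.frame with one row per selected signature: name, status,
#'   message).
#' @export
compute_many <- function(ds, catalog = load_catalog(),
                         filter = catalog_filter(), min_coverage = 0.05,
                         opts = list()) {
  tab <- available_signatures(catalog, filter)
  if (nrow(tab) == 0L)
    sigc_stop("filter matches no catalog signatures", "validation")
  if (!any(tab$genes_available))
    sigc_stop("filter matches no signature with a packaged gene list",
              "validation")
  rows <- list()
  for (nm in tab$name) {
    if (!tab$genes_available[tab$name == nm]) {
      rows[[nm]] <- data.frame(signature = nm, status = "skipped",
                               message = "gene list not packaged")
      next
    }
    res <- tryCatch(
      suppressWarnings(compute_signature(ds, nm, catalog = catalog,
                                         min_coverage = min_coverage,
                                         opts = opts)),
      sigc_error = function(e) e)
    if (inherits(res, "sig_score")) {
      ds <- suppressWarnings(attach_scores(ds, res))
      rows[[nm]] <- data.frame(signature = nm, status = "ok",
                               message = sprintf("%d/%d genes used",
                                                 res$genes_used,
                                                 res$genes_requested))
    } else {
      rows[[nm]] <- data.frame(signature = nm, status = "failed",
                               message = conditionMessage(res))
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(dataset = ds, summary = summary)
}
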