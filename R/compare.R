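#' Correlation matrix across signature scores
#'
#' Pairwise-complete correlations between score columns; symmetric with
#' unit diagonal. Zero-variance signatures are dropped from the matrix
#' with a warning.
#'
#' @param score_table A data.frame/matrix of scores, observations in
#'   rows, signatures in columns (e.g. from [score_table()]).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Signatures-by-signatures correlation matrix.
#' @export
score_correlation_matrix <- function(score_table,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.matrix(as.data.frame(score_table))
  storage.mode(x) <- "double"
  if (ncol(x) < 2L)
    sigc_stop("need at least 2 signatures", "validation")
  if (nrow(x) < 3L)
    sigc_stop("need at least 3 observations", "validation")
  sds <- apply(x, 2L, sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    bad <- colnames(x)[sds == 0 | is.na(sds)]
    sigc_warn(sprintf("dropping zero-variance signature(s): %s",
                      paste(bad, collapse = ", ")))
    x <- x[, !(colnames(x) %in% bad), drop = FALSE]
    if (ncol(x) < 2L)
      sigc_stop("fewer than 2 signatures with variance", "validation")
  }
  cm <- cor(x, use = "pairwise.complete.obs", method = method)
  diag(cm) <- 1
  cm
}

#' Hierarchically cluster signatures by score correlation
#'
#' Distances are Euclidean between rows of the correlation matrix;
#' agglomeration is complete linkage. Cutting the tree at any `k`
#' returns cluster labels.
#'
#' @param corr Correlation matrix from [score_correlation_matrix()].
#' @param k Optional number of clusters for which labels are returned.
#' @return A list with `linkage` (an `hclust` object), `dist` (the
#'   distance object) and, when `k` is given, `labels`.
#' @export
cluster_scores <- function(corr, k = NULL) {
  corr <- as.matrix(corr)
  if (anyNA(corr))
    sigc_stop("correlation matrix has missing values; drop the affected signatures first",
              "validation")
  d <- dist(corr, method = "euclidean")
  h <- hclust(d, method = "complete")
  out <- list(linkage = h, dist = d)
  if (!is.null(k)) out$labels <- cutree(h, k = k)
  out
}

# mean silhouette width for labels on a distance matrix
silhouette_mean <- function(dmat, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) { s[i] <- 0; next }   # singleton cluster
    a <- mean(dmat[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(dmat[i, labels == cl]), numeric(1)))
    if (max(a, b) == 0)
      sigc_stop("silhouette undefined: zero distances within and between clusters",
                "validation")
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Choose the number of clusters by mean silhouette
#'
#' Evaluates the mean silhouette width over `k_range` using the same
#' Euclidean distances as [cluster_scores()]; the best `k` is the argmax
#' (ties resolved to the smallest `k`).
#'
#' @param corr Correlation matrix (at least 3 signatures).
#' @param clustering Optional result of [cluster_scores()] to reuse.
#' @param k_range Candidate cluster numbers; default `2:min(10, n - 1)`.
#' @return A list with `k_best` and `profile` (a data.frame of `k` and
#'   `mean_silhouette`).
#' @export
select_k_silhouette <- function(corr, clustering = NULL, k_range = NULL) {
  corr <- as.matrix(corr)
  n <- nrow(corr)
  if (n < 3L) sigc_stop("need at least 3 signatures", "validation")
  clustering <- clustering %||% cluster_scores(corr)
  k_range <- k_range %||% seq(2L, min(10L, n - 1L))
  dmat <- as.matrix(clustering$dist)
  prof <- vapply(k_range, function(k) {
    labels <- cutree(clustering$linkage, k = k)
    silhouette_mean(dmat, labels)
  }, numeric(1))
  profile <- data.frame(k = k_range, mean_silhouette = prof)
  k_best <- k_range[which.max(prof)]   # which.max -> first (smallest) k on ties
  list(k_best = k_best, profile = profile)
}

#' Survival association of one signature score
#'
#' Dichotomizes observations at the split value (default: the median;
#' ties go to the low arm), fits Kaplan-Meier curves per arm, and tests
#' the arms with the two-sample log-rank test.
#'
#' @param scores Numeric score vector.
#' @param time Survival time in days.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param split `"median"` or a numeric split value.
#' @param signature Name used in the output row.
#' @return A list with `row` (signature, split_value, n_low, n_high,
#'   logrank_stat, p), `fit` (a `survfit` object for the curves) and
#'   `arm` (the per-observation arm labels). With fewer than 2 events in
#'   an arm the p-value is missing, with a warning.
#' @export
survival_association <- function(scores, time, event, split = "median",
                                 signature = "signature") {
  keep <- complete.cases(scores, time, event)
  scores <- scores[keep]; time <- time[keep]; event <- event[keep]
  split_value <- if (identical(split, "median")) median(scores)
  else as.numeric(split)
  arm <- factor(ifelse(scores <= split_value, "low", "high"),
                levels = c("low", "high"))
  fit <- survival::survfit(survival::Surv(time, event) ~ arm)
  ev_per_arm <- tapply(event, arm, sum)
  stat <- NA_real_; p <- NA_real_
  if (any(is.na(ev_per_arm)) || any(ev_per_arm < 2)) {
    sigc_warn("fewer than 2 events in an arm: log-rank p-value missing")
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ arm)
    stat <- sd$chisq
    p <- pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  }
  list(row = data.frame(signature = signature,
                        split_value = split_value,
                        n_low = sum(arm == "low"),
                        n_high = sum(arm == "high"),
                        logrank_stat = stat, p = p,
                        stringsAsFactors = FALSE),
       fit = fit, arm = arm)
}

#' Compare score distributions between observation groups
#'
#' For every signature and every pair of groups of at least
#' `min_group_size` observations, performs a Welch (unequal-variance)
#' two-sample t-test; p-values are Benjamini-Hochberg adjusted across
#' the whole table. Groups below the minimum size are excluded with a
#' warning.
#'
#' @param score_table Data.frame of scores (observations x signatures).
#' @param group_labels Group label per observation.
#' @param min_group_size Minimum observations per group (default 20).
#' @param p_adjust Adjustment method passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return A data.frame with one row per signature and group pair:
#'   `signature`, `groupA`, `groupB`, `n_A`, `n_B`, `t_stat`, `p`,
#'   `p_adj`.
#' @export
group_compare <- function(score_table, group_labels, min_group_size = 20,
                          p_adjust = "BH") {
  score_table <- as.data.frame(score_table)
  group_labels <- as.character(group_labels)
  sizes <- table(group_labels)
  eligible <- names(sizes)[sizes >= min_group_size]
  if (length(eligible) < length(sizes))
    sigc_warn(sprintf("excluding group(s) below %d observations: %s",
                      min_group_size,
                      paste(setdiff(names(sizes), eligible),
                            collapse = ", ")))
  if (length(eligible) < 2L)
    sigc_stop("fewer than 2 groups meet the minimum size", "validation")
  eligible <- sort(eligible)
  pairs <- utils::combn(eligible, 2L)
  rows <- list()
  for (sig in colnames(score_table)) {
    v <- score_table[[sig]]
    for (j in seq_len(ncol(pairs))) {
      ga <- pairs[1L, j]; gb <- pairs[2L, j]
      va <- v[group_labels == ga]; vb <- v[group_labels == gb]
      tt <- tryCatch(stats::t.test(va, vb, var.equal = FALSE),
                     error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        signature = sig, groupA = ga, groupB = gb,
        n_A = length(va), n_B = length(vb),
        t_stat = if (is.null(tt)) 0 else unname(tt$statistic),
        p = if (is.null(tt)) 1 else tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = p_adjust)
  rownames(out) <- NULL
  out
}

#' Full cross-signature comparison report
#'
#' Convenience wrapper producing the comparison bundle: score correlation
#' matrix, complete-linkage clustering of its rows, silhouette-selected
#' number of clusters and the corresponding labels, plus optional
#' survival associations (per signature, median split) and group tests.
#'
#' @param score_table Data.frame of scores (observations x signatures),
#'   at least 2 signatures and 3 observations.
#' @param survival_time,survival_event Optional survival annotation
#'   vectors (days; 0/1).
#' @param group_labels Optional group label per observation.
#' @param method Correlation method.
#' @param min_group_size Passed to [group_compare()].
#' @return A `sig_comparison` list: `corr`, `linkage`, `k_best`,
#'   `cluster_labels`, `silhouette_by_k`, `survival` (or NULL),
#'   `group_tests` (or NULL).
#' @export
compare_signatures <- function(score_table, survival_time = NULL,
                               survival_event = NULL, group_labels = NULL,
                               method = "pearson", min_group_size = 20) {
  corr <- score_correlation_matrix(score_table, method = method)
  clustering <- cluster_scores(corr)
  sel <- if (nrow(corr) >= 3L)
    select_k_silhouette(corr, clustering) else
      list(k_best = NA_integer_, profile = NULL)
  labels <- if (!is.na(sel$k_best))
    cutree(clustering$linkage, k = sel$k_best) else NULL
  surv <- NULL
  if (!is.null(survival_time) && !is.null(survival_event)) {
    surv <- do.call(rbind, lapply(colnames(corr), function(sig)
      suppressWarnings(
        survival_association(score_table[[sig]], survival_time,
                             survival_event, signature = sig))$row))
  }
  tests <- NULL
  if (!is.null(group_labels)) {
    tests <- group_compare(score_table[, colnames(corr), drop = FALSE],
                           group_labels, min_group_size = min_group_size)
  }
  structure(list(corr = corr, linkage = clustering$linkage,
                 k_best = sel$k_best, cluster_labels = labels,
                 silhouette_by_k = sel$profile, survival = surv,
                 group_tests = tests),
            class = "sig_comparison")
}

#' @export
print.sig_comparison <- function(x, ...) {
  cat(sprintf("<sig_comparison> %d signature(s); best k = %s\n",
              nrow(x$corr), x$k_best))
  if (!is.null(x$cluster_labels)) {
    for (k in sort(unique(x$cluster_labels)))
      cat(sprintf("  cluster %d: %s\n", k,
                  paste(names(x$cluster_labels)[x$cluster_labels == k],
                        collapse = ", ")))
  }
  invisible(x)
}
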