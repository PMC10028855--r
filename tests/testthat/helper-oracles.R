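# Independent brute-force oracles, deliberately naive loop
# implementations kept separate from the vectorized package code paths.

oracle_weighted <- function(x, w) {
  vapply(seq_len(ncol(x)), function(o) {
    s <- 0
    for (g in seq_len(nrow(x))) s <- s + w[g] * x[g, o]
    s
  }, numeric(1))
}

oracle_zscore <- function(x, dirs) {
  z <- x * NA
  for (g in seq_len(nrow(x))) {
    mu <- mean(x[g, ]); s <- sd(x[g, ])
    z[g, ] <- if (s == 0) 0 else (x[g, ] - mu) / s
    if (dirs[g] == "down") z[g, ] <- -z[g, ]
  }
  unname(colMeans(z))
}

oracle_ssgsea <- function(x, set, alpha) {
  genes <- rownames(x)
  vapply(seq_len(ncol(x)), function(o) {
    r <- rank(x[, o], ties.method = "average")
    ord <- genes[order(-r, genes)]
    in_set <- ord %in% set
    w_sum <- sum(r[ord[in_set]]^alpha)
    n_out <- sum(!in_set)
    p_in <- p_out <- 0
    es <- 0
    for (i in seq_along(ord)) {
      if (in_set[i]) p_in <- p_in + r[ord[i]]^alpha / w_sum
      else p_out <- p_out + 1 / n_out
      es <- es + (p_in - p_out)
    }
    es
  }, numeric(1))
}

# Brute-force oracles for clustering, silhouette and the log-rank test.

oracle_complete_linkage <- function(dmat) {
  # naive O(n^3) agglomeration; returns merge heights in order
  clusters <- as.list(seq_len(nrow(dmat)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- max(dmat[clusters[[i]], clusters[[j]]])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

oracle_silhouette <- function(dmat, labels) {
  s <- numeric(length(labels))
  for (i in seq_along(labels)) {
    same <- which(labels == labels[i] & seq_along(labels) != i)
    if (!length(same)) { s[i] <- 0; next }
    a <- mean(dmat[i, same])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(dmat[i, labels == cl]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_logrank <- function(time, event, arm) {
  # expected-events arithmetic over distinct event times
  stopifnot(length(unique(arm)) == 2)
  arms <- sort(unique(arm))
  times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & arm == arms[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & arm == arms[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}
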