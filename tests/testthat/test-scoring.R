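test_that("weighted sum matches the dot-product oracle and is linear", {
  x <- matrix(c(2, 0.5, 3, 1, 4, 2), 3, 2,
              dimnames = list(c("G1", "G2", "G3"), c("A", "B")))
  w <- c(1, -2, 0.5)
  expect_equal(unname(score_weighted_sum(x, w)), oracle_weighted(x, w))
  # hand value (column-major fill): A = 1*2 - 2*0.5 + 0.5*3 = 2.5 ;
  # B = 1*1 - 2*4 + 0.5*2 = -6
  expect_equal(unname(score_weighted_sum(x, w)), c(2.5, -6))
  expect_equal(unname(score_weighted_sum(x, rep(0, 3))), c(0, 0))
  expect_equal(unname(score_weighted_sum(x[1, , drop = FALSE], 1)),
               unname(x[1, ]))
  # linearity in the weights
  expect_equal(score_weighted_sum(x, 3.7 * w),
               3.7 * score_weighted_sum(x, w))
})

test_that("zscore mean matches the oracle, centers, and handles edge cases", {
  set.seed(11)
  x <- matrix(rnorm(12, 5), 4, 3,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:3)))
  dirs <- c("up", "down", "up", "up")
  expect_equal(unname(score_zscore_mean(x, dirs)), oracle_zscore(x, dirs))
  # up-only scores have mean zero across observations
  up <- score_zscore_mean(x, rep("up", 4))
  expect_equal(mean(up), 0, tolerance = 1e-12)
  # constant matrix -> all zero (zero-variance rule)
  expect_equal(unname(score_zscore_mean(matrix(7, 3, 4), rep("up", 3))),
               rep(0, 4))
  # two observations, one up gene -> symmetric +/- 1/sqrt(2)
  two <- matrix(c(1, 3), 1, 2, dimnames = list("G1", c("A", "B")))
  expect_equal(unname(score_zscore_mean(two, "up")),
               c(-1, 1) / sqrt(2))
  expect_sigc_error(score_zscore_mean(x[, 1, drop = FALSE], dirs),
                    "sigc_validation_error")
})

test_that("up/down contrast matches arithmetic oracle", {
  x <- matrix(c(4, 2, 1, 3, 6, 2, 2, 2), 4, 2,
              dimnames = list(paste0("G", 1:4), c("A", "B")))
  dirs <- c("up", "up", "down", "down")
  expect_equal(unname(score_up_down(x, dirs)),
               c(mean(x[1:2, 1]) - mean(x[3:4, 1]),
                 mean(x[1:2, 2]) - mean(x[3:4, 2])))
  # same set up and down -> zero
  x2 <- rbind(x[1:2, ], x[1:2, ])
  rownames(x2) <- paste0("H", 1:4)
  expect_equal(unname(score_up_down(x2, dirs)), c(0, 0))
  # empty down set -> mean of up genes
  expect_equal(unname(score_up_down(x[1:2, ], c("up", "up"))),
               unname(colMeans(x[1:2, ])))
  expect_sigc_error(score_up_down(x, rep("down", 4)),
                    "sigc_validation_error")
})

test_that("ssgsea matches the step-walk oracle and is rank-invariant", {
  set.seed(21)
  x <- matrix(rlnorm(10 * 4), 10, 4,
              dimnames = list(sprintf("G%02d", 1:10), paste0("S", 1:4)))
  set <- c("G02", "G05", "G09")
  es <- score_ssgsea(x, set, alpha = 0.25)
  expect_equal(unname(es), oracle_ssgsea(x, set, 0.25), tolerance = 1e-12)
  # invariant under strictly monotone per-observation transforms
  expect_equal(score_ssgsea(2 * x, set), es)
  expect_equal(score_ssgsea(log1p(x), set), es)
  expect_equal(score_ssgsea(x^3, set), es)
  # changing expression of genes outside set and ranks order unchanged:
  # permuting gene order does not change scores
  perm <- sample(nrow(x))
  expect_equal(score_ssgsea(x[perm, ], set), es)
  # degenerate cases
  expect_sigc_error(score_ssgsea(x, rownames(x)), "sigc_validation_error")
  expect_sigc_error(score_ssgsea(x, "G01"), "sigc_validation_error")
})

test_that("ssgsea handles ties deterministically", {
  x <- matrix(c(5, 5, 5, 2, 2, 1, 7, 3, 3, 3), 10, 1,
              dimnames = list(sprintf("G%02d", 1:10), "S1"))
  set <- c("G01", "G04", "G08")
  expect_equal(unname(score_ssgsea(x, set)),
               oracle_ssgsea(x, set, 0.25), tolerance = 1e-12)
  # identical under a shuffle of the tied rows
  perm <- c(2, 1, 3, 5, 4, 6, 7, 9, 10, 8)
  expect_equal(score_ssgsea(x[perm, , drop = FALSE], set),
               score_ssgsea(x, set))
})

test_that("immunophenoscore composite matches hand-computed means", {
  # 8 genes, 2 per category, one subclass each, unit weights
  x <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8,
                2, 1, 4, 3, 6, 5, 8, 7,
                0, 0, 0, 0, 0, 0, 0, 0), 8, 3,
              dimnames = list(paste0("G", 1:8), c("A", "B", "C")))
  cl <- rep(c("EC", "SC", "MHC", "CP"), each = 2)
  sub <- cl
  w <- rep(1, 8)
  r <- score_ips(x, cl, sub, w)
  # oracle: z per gene then mean of the two genes per category
  z <- t(apply(x, 1, function(v) (v - mean(v)) / sd(v)))
  for (i in seq_along(unique(cl))) {
    cc <- unique(cl)[i]
    expect_equal(unname(r$components[, cc]),
                 unname(colMeans(z[cl == cc, ])), tolerance = 1e-12)
  }
  expect_equal(unname(r$AZ), unname(colMeans(z)), tolerance = 1e-12)
  expect_equal(unname(r$IPS),
               unname(ifelse(r$AZ <= 0, 0, pmin(10, 10 * r$AZ / 3))))
  # constant matrix: all z zero -> components and composite zero
  r0 <- score_ips(matrix(5, 8, 3), cl, sub, w)
  expect_true(all(r0$components == 0))
  expect_true(all(r0$IPS == 0))
  # negative weights flip the sign of a subclass
  w2 <- ifelse(cl %in% c("SC", "CP"), -1, 1)
  r2 <- score_ips(x, cl, sub, w2)
  expect_equal(r2$components[, "SC"], -r$components[, "SC"])
  # missing category refused
  expect_sigc_error(score_ips(x[1:6, ], cl[1:6], sub[1:6], w[1:6]),
                    "sigc_validation_error")
})

test_that("AZ scale endpoints map to the 0-10 composite range", {
  # craft components via direct formula: AZ = 3 must give IPS = 10
  az <- c(-1, 0, 1.5, 3, 6)
  ips <- ifelse(az <= 0, 0, pmin(10, 10 * az / 3))
  expect_equal(ips, c(0, 0, 5, 10, 10))
})

test_that("consensus centroid correlation matches the Pearson oracle", {
  set.seed(31)
  genes <- sprintf("G%02d", 1:6)
  centroids <- matrix(rnorm(24), 6, 4,
                      dimnames = list(genes, c("DIF", "IMR", "MES", "PRO")))
  x <- matrix(rnorm(18), 6, 3, dimnames = list(genes, c("A", "B", "C")))
  r <- score_consensus_subtypes(x, centroids)
  for (o in 1:3) for (k in 1:4) {
    a <- x[, o]; b <- centroids[, k]
    oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(r$scores[o, k], oracle, tolerance = 1e-12)
  }
  expect_true(all(r$scores >= -1 & r$scores <= 1))
  # label is the argmax subtype for every observation
  for (o in 1:3)
    expect_equal(unname(r$label[o]),
                 colnames(centroids)[which.max(r$scores[o, ])])
  # observation identical to a centroid scores 1 there
  x2 <- cbind(PROlike = centroids[, "PRO"], x)
  r2 <- score_consensus_subtypes(x2, centroids)
  expect_equal(unname(r2$scores["PROlike", "PRO"]), 1)
  expect_equal(unname(r2$label["PROlike"]), "PRO")
  # negation scores -1
  x3 <- cbind(neg = -centroids[, "DIF"], x)
  r3 <- score_consensus_subtypes(x3, centroids)
  expect_equal(unname(r3$scores["neg", "DIF"]), -1)
  # zero-variance observation -> missing scores with warning
  x4 <- cbind(flat = rep(1, 6), x)
  expect_warning(r4 <- score_consensus_subtypes(x4, centroids),
                 "zero variance")
  expect_true(all(is.na(r4$scores["flat", ])))
  # tie -> lexicographically first subtype, warning
  cent2 <- cbind(B_sub = centroids[, 1], A_sub = centroids[, 1])
  expect_warning(r5 <- score_consensus_subtypes(x, cent2), "tied")
  expect_equal(unname(r5$label), rep("A_sub", 3))
  expect_sigc_error(score_consensus_subtypes(x[1:2, ], centroids[1:2, ]),
                    "sigc_validation_error")
})

test_that("compute_signature dispatches, converts scale, tracks coverage", {
  set.seed(41)
  counts <- matrix(rnbinom(50 * 8, mu = 30, size = 2), 50, 8,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("s%d", 1:8)))
  ds <- expression_dataset(counts, "counts", "bulk_rnaseq")
  def <- toy_zscore_def(sprintf("G%02d", 1:10), name = "Cov_Sig")
  res <- suppressWarnings(compute_signature(ds, def))
  expect_s3_class(res, "sig_score")
  expect_equal(res$genes_requested, 10L)
  expect_equal(res$genes_used, 10L)   # case-insensitive intersection
  # identical to scoring the log-transformed submatrix directly
  lg <- log2(counts + 1)[sprintf("g%02d", 1:10), ]
  expect_equal(unname(res$values), unname(score_zscore_mean(lg)))
  # determinism: recomputation is bit-identical
  res2 <- suppressWarnings(compute_signature(ds, def))
  expect_identical(res$values, res2$values)
  # gene-order permutation of the data leaves scores unchanged
  perm <- sample(nrow(counts))
  dsp <- expression_dataset(counts[perm, ], "counts", "bulk_rnaseq")
  resp <- suppressWarnings(compute_signature(dsp, def))
  expect_equal(resp$values, res$values)
})

test_that("coverage thresholds: boundary computed, below refused", {
  m <- toy_matrix(10, 5)
  ds <- toy_dataset(m)
  # 2/40 genes present = exactly 5% -> computed with a warning recorded
  genes40 <- c("G01", "G02", sprintf("ZZ%02d", 1:38))
  def <- toy_zscore_def(genes40, name = "Boundary_Sig")
  res <- suppressWarnings(compute_signature(ds, def))
  expect_equal(res$genes_used, 2L)
  expect_match(res$warnings, "38/40", all = FALSE)
  # 1/40 -> refused with coverage report
  def1 <- toy_zscore_def(c("G01", sprintf("ZZ%02d", 1:39)),
                         name = "Refused_Sig")
  err <- tryCatch(compute_signature(ds, def1),
                  sigc_coverage_error = function(e) conditionMessage(e))
  expect_match(err, "1/40")
  # unconvertible scale -> conversion error
  def_counts <- signature_definition(
    "Counts_Sig", "Synthetic activity",
    data.frame(symbol = c("G01", "G02")), "zscore_mean", "counts")
  expect_sigc_error(compute_signature(ds, def_counts),
                    "sigc_conversion_error")
})

test_that("compute_many attaches matches and logs failures", {
  set.seed(51)
  m <- toy_matrix(30, 6)
  ds <- toy_dataset(m)
  cat <- empty_catalog()
  cat <- register_signature(cat, toy_zscore_def(rownames(m)[1:5], name = "Ok_One"))
  cat <- register_signature(cat, toy_weighted_def(rownames(m)[6:10],
                                                  weights = rep(1, 5),
                                                  name = "Ok_Two"))
  cat <- register_signature(cat, toy_zscore_def(
    c(rownames(m)[1], sprintf("QQ%02d", 1:39)), name = "Low_Coverage"))
  out <- compute_many(ds, cat)
  expect_equal(sort(colnames(score_table(out$dataset))),
               c("Ok_One", "Ok_Two"))
  expect_equal(out$summary$status[out$summary$signature == "Low_Coverage"],
               "failed")
  # filter matching nothing -> error
  expect_sigc_error(
    compute_many(ds, cat, catalog_filter(topic = "Synthetic activity",
                                         name_pattern = "NoMatch")),
    "sigc_validation_error")
})
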