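test_that("dense reader handles both orientations and delimiters", {
  m <- toy_matrix(5, 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(m), m), tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)
  ds <- read_dense_table(tsv, "genes_rows", metric = "log",
                         technology = "bulk_rnaseq")
  expect_equal(dim(expr_matrix(ds)), c(5L, 3L))
  expect_equal(unname(expr_matrix(ds)), unname(m))
  # transposed CSV with genes in columns gives the identical dataset
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(sample = colnames(m), t(m)), csv, row.names = FALSE,
            quote = FALSE)
  ds2 <- read_dense_table(csv, "genes_cols", metric = "log",
                          technology = "bulk_rnaseq")
  expect_equal(expr_matrix(ds2), expr_matrix(ds))
  # duplicated gene row -> error
  bad <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = c("G1", "G1"), A = c(1, 2), B = c(3, 4)),
              bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_sigc_error(read_dense_table(bad, metric = "log",
                                     technology = "bulk_rnaseq"),
                    "sigc_format_error")
  # non-numeric cell -> parse error naming the position
  bad2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = c("G1", "G2"), A = c(1, "oops"),
                         B = c(3, 4)),
              bad2, sep = "\t", quote = FALSE, row.names = FALSE)
  err <- tryCatch(read_dense_table(bad2, metric = "log",
                                   technology = "bulk_rnaseq"),
                  sigc_format_error = function(e) conditionMessage(e))
  expect_match(err, "oops")
  expect_match(err, "row 2")
})

write_triplet_dir <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE)
  sm <- Matrix::Matrix(m, sparse = TRUE)
  Matrix::writeMM(sm, file.path(dir, "matrix.mtx"))
  write.table(data.frame(id = paste0("ENS", seq_len(nrow(m))),
                         symbol = rownames(m)),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  dir
}

test_that("sparse triplet reader reconstructs the dense matrix", {
  m <- matrix(0, 4, 3, dimnames = list(paste0("G", 1:4), paste0("BC", 1:3)))
  m[cbind(c(1, 2, 3, 4, 1), c(1, 2, 3, 1, 3))] <- c(5, 2, 7, 1, 4)
  stopifnot(sum(m != 0) == 5)
  dir <- write_triplet_dir(m, withr::local_tempdir())
  ds <- read_sparse_triplet(dir, metric = "counts", technology = "scrnaseq")
  expect_equal(sum(expr_matrix(ds) == 0), 4 * 3 - 5)   # 7 zeros
  expect_equal(unname(expr_matrix(ds)), unname(m))
  expect_equal(colnames(ds), paste0("BC", 1:3))
  # empty matrix -> all-zero dataset
  m0 <- matrix(0, 4, 3, dimnames = dimnames(m))
  dir0 <- write_triplet_dir(m0, withr::local_tempdir())
  ds0 <- read_sparse_triplet(dir0, metric = "counts",
                             technology = "scrnaseq")
  expect_true(all(expr_matrix(ds0) == 0))
  # barcode/matrix mismatch -> format error
  writeLines(paste0("BC", 1:2), file.path(dir, "barcodes.tsv"))
  expect_sigc_error(read_sparse_triplet(dir, metric = "counts",
                                        technology = "scrnaseq"),
                    "sigc_format_error")
})

test_that("spatial positions join by barcode and round-trip", {
  m <- toy_matrix(4, 3)
  colnames(m) <- paste0("BC", 1:3)
  dir <- write_triplet_dir(m, withr::local_tempdir())
  pos <- file.path(dir, "positions.csv")
  write.csv(data.frame(barcode = paste0("BC", 3:1), x = c(3, 2, 1),
                       y = c(30, 20, 10)), pos, row.names = FALSE,
            quote = FALSE)
  ds <- read_sparse_triplet(dir, metric = "counts", technology = "spatial",
                            positions = pos)
  co <- ds_coordinates(ds)
  expect_equal(co$x, c(1, 2, 3))   # realigned to barcode order
  expect_equal(co$y, c(10, 20, 30))
  # coordinates on non-spatial data are rejected
  expect_sigc_error(
    expression_dataset(m, "counts", "bulk_rnaseq",
                       coordinates = data.frame(x = 1:3, y = 1:3)),
    "sigc_validation_error")
})

test_that("gene-id translation drops, renames and resolves collisions", {
  m <- toy_matrix(3, 4)
  ds <- toy_dataset(m)
  map <- data.frame(from_id = c("G01", "G02", "G03"),
                    to_id = c("A", "B", "C"))
  tr <- translate_gene_ids(ds, map)
  expect_equal(rownames(tr), c("A", "B", "C"))
  expect_equal(unname(expr_matrix(tr)), unname(m))
  # two sources to one target: row with highest total signal kept
  map2 <- data.frame(from_id = c("G01", "G02"), to_id = c("X", "X"))
  suppressMessages(tr2 <- translate_gene_ids(ds, map2))
  keep <- if (sum(m["G01", ]) >= sum(m["G02", ])) "G01" else "G02"
  expect_equal(nrow(tr2), 1L)
  expect_equal(unname(expr_matrix(tr2)[1, ]), unname(m[keep, ]))
  # collision aggregation by sum
  suppressMessages(tr3 <- translate_gene_ids(ds, map2, collision = "sum"))
  expect_equal(unname(expr_matrix(tr3)[1, ]),
               unname(m["G01", ] + m["G02", ]))
  # disjoint mapping -> error; row count never increases
  expect_sigc_error(
    translate_gene_ids(ds, data.frame(from_id = "ZZZ", to_id = "Q")),
    "sigc_validation_error")
  expect_lte(nrow(tr2), nrow(ds))
})

test_that("metric conversions scale per observation and guard zeros", {
  counts <- matrix(c(5e5, 1.5e6, 10, 20, 0, 0), 3, 2, byrow = TRUE,
                   dimnames = list(c("G1", "G2", "G3"), c("A", "B")))
  ds <- expression_dataset(counts, "counts", "bulk_rnaseq")
  cpm <- transform_metric(ds, "cpm")
  expect_equal(ds_metric(cpm), "cpm")
  expect_equal(colSums(expr_matrix(cpm)), c(A = 1e6, B = 1e6))
  # column summing to 2e6 halves: A total = 5e5+10 -> check exact scaling
  expect_equal(expr_matrix(cpm)["G1", "A"], 5e5 / (5e5 + 10) * 1e6)
  # zeros stay zero
  expect_equal(unname(expr_matrix(cpm)["G3", ]), c(0, 0))
  # all-zero observation: warning, left unscaled
  ds0 <- expression_dataset(matrix(c(1, 2, 0, 0), 2, 2,
                                   dimnames = list(c("G1", "G2"),
                                                   c("A", "B"))),
                            "counts", "bulk_rnaseq")
  expect_warning(cpm0 <- transform_metric(ds0, "cpm"), "all-zero")
  expect_equal(unname(expr_matrix(cpm0)[, "B"]), c(0, 0))
  # fpkm -> tpm renormalizes to 1e6
  fp <- expression_dataset(counts + 1, "fpkm", "bulk_rnaseq")
  tpm <- transform_metric(fp, "tpm")
  expect_equal(unname(colSums(expr_matrix(tpm))), c(1e6, 1e6))
  # log transform and unsupported paths
  lg <- transform_metric(ds, "log")
  expect_equal(expr_matrix(lg), log2(counts + 1))
  expect_sigc_error(transform_metric(lg, "counts"), "sigc_conversion_error")
  expect_sigc_error(transform_metric(ds, "tpm"), "sigc_conversion_error")
})

test_that("cpm columns sum to 1e6 on random count matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rpois(200, 50), 20, 10)
    ds <- expression_dataset(m, "counts", "bulk_rnaseq")
    expect_equal(unname(colSums(expr_matrix(transform_metric(ds, "cpm")))),
                 rep(1e6, 10), tolerance = 1e-9)
  }
})

test_that("score attachment and TSV export are deterministic", {
  ds <- toy_dataset(toy_matrix(6, 4),
                    obs_annotations = data.frame(group = c("a", "a",
                                                           "b", "b")))
  sc <- fake_score("SigB", setNames(c(4, 3, 2, 1), colnames(ds)), 10, 8)
  sc2 <- fake_score("SigA", setNames(1:4 / 7, colnames(ds)), 5, 5)
  ds <- attach_scores(ds, sc)
  ds <- attach_scores(ds, sc2)
  expect_equal(colnames(score_table(ds)), c("SigB", "SigA"))
  # overwrite warns
  expect_warning(attach_scores(ds, sc), "overwriting")
  # unknown observation id -> alignment error
  bad <- fake_score("SigC", setNames(1, "nope"), 2, 2)
  expect_sigc_error(attach_scores(ds, bad), "sigc_validation_error")
  # write: annotations then lexicographic scores; byte-identical rewrite
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_scores(ds, f1)
  write_scores(ds, f2)
  expect_identical(readLines(f1), readLines(f2))
  tab <- read.delim(f1)
  expect_equal(colnames(tab), c("obs_id", "group", "SigA", "SigB"))
  expect_equal(tab$SigB, c(4, 3, 2, 1))
  # no scores -> error
  expect_sigc_error(write_scores(toy_dataset(), f1),
                    "sigc_validation_error")
})

test_that("microarray missing values are allowed, sequencing must be complete", {
  m <- toy_matrix(4, 3)
  m[2, 2] <- NA
  expect_sigc_error(expression_dataset(m, "log", "bulk_rnaseq"),
                    "sigc_validation_error")
  ds <- expression_dataset(m, "log", "microarray")
  def <- toy_zscore_def(c("G01", "G02"))
  res <- suppressWarnings(compute_signature(ds, def))
  expect_true(all(is.finite(res$values)))
})
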