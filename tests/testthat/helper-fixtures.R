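# shared fixtures: everything is built in code, nothing is read from disk

# small deterministic matrix with named genes/observations
toy_matrix <- function(n_genes = 6, n_obs = 4, seed = 42, zeros = 0) {
  set.seed(seed)
  m <- matrix(round(rlnorm(n_genes * n_obs, 2, 1), 3), n_genes, n_obs,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_obs))))
  if (zeros > 0) m[sample(length(m), zeros)] <- 0
  m
}

toy_dataset <- function(mat = toy_matrix(), metric = "log",
                        technology = "bulk_rnaseq", ...) {
  expression_dataset(mat, metric = metric, technology = technology, ...)
}

# 5-gene weighted-sum definition over the toy gene ids
toy_weighted_def <- function(genes = sprintf("G%02d", 1:5),
                             weights = c(1, -2, 0.5, 1, 1),
                             name = "Toy_Weighted") {
  signature_definition(
    name = name, topic = "Synthetic activity",
    genes = data.frame(symbol = genes, weight = weights),
    method = "weighted_sum", required_scale = "log")
}

toy_zscore_def <- function(genes, name = "Toy_Zscore",
                           direction = rep("up", length(genes))) {
  signature_definition(
    name = name, topic = "Synthetic activity",
    genes = data.frame(symbol = genes, direction = direction),
    method = "zscore_mean", required_scale = "log")
}

# fake score result (for qc tests that need a controlled score vector)
fake_score <- function(name, values, genes_requested, genes_used) {
  structure(list(signature_name = name, values = values,
                 components = NULL, label = NULL,
                 genes_requested = as.integer(genes_requested),
                 genes_used = as.integer(genes_used),
                 options_fingerprint = "", warnings = character(0)),
            class = "sig_score")
}

expect_sigc_error <- function(expr, class = "sigc_error") {
  expect_error(expr, class = class)
}
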