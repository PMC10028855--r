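#' Describe a simulation
#'
#' A simulation design fixes everything the generators need: the size of
#' the gene universe and the number of observations, negative-binomial
#' expression hyperparameters (gene means are lognormal; counts are NB
#' with a common dispersion), a logistic dropout model for single-cell
#' data, an integer grid with region labels for spatial data, a list of
#' planted signals, and a seed that fully determines the output.
#'
#' Defaults describe a desk-scale but realistic experiment: 2000 genes,
#' 200 observations, lognormal gene means with `meanlog = 1.5` and
#' `sdlog = 1.2` (median mean about 4.5 counts with a heavy right tail),
#' NB dispersion 0.4, and a dropout curve
#' `P(drop) = plogis(1 - 0.8 * log(mu))` giving single-cell zero
#' fractions around 60-70%.
#'
#' @param n_genes,n_obs Gene universe and observation count.
#' @param technology `"bulk_rnaseq"`, `"scrnaseq"` or `"spatial"`.
#' @param nb_mean_log_mu,nb_mean_log_sd Lognormal hyperparameters of the
#'   per-gene mean (natural-log scale).
#' @param nb_dispersion NB dispersion; the NB size parameter is its
#'   reciprocal.
#' @param dropout_logit_intercept,dropout_logit_slope Dropout
#'   probability is `plogis(intercept + slope * log(mu))` per entry
#'   (single-cell only); the default slope is negative so
#'   highly-expressed genes drop out less.
#' @param grid_dims Integer `c(nx, ny)` spot grid (spatial only).
#' @param region_map Character vector of length `nx * ny` assigning each
#'   spot a region label, in column-major grid order (spatial only).
#' @param planted List of planted signals; each element is a list with
#'   `genes` (gene IDs or indices), `lfc` (log2 fold change) and either
#'   `obs` (observation indices) or `region` (a region label, spatial).
#' @param seed Integer seed; the same design always generates the same
#'   data.
#' @return A `sim_design` object.
#' @export
simulation_design <- function(n_genes = 2000, n_obs = 200,
                              technology = "bulk_rnaseq",
                              nb_mean_log_mu = 1.5, nb_mean_log_sd = 1.2,
                              nb_dispersion = 0.4,
                              dropout_logit_intercept = 1.0,
                              dropout_logit_slope = -0.8,
                              grid_dims = NULL, region_map = NULL,
                              planted = list(), seed = 1L) {
  d <- structure(list(
    n_genes = as.integer(n_genes), n_obs = as.integer(n_obs),
    technology = match.arg(technology,
                           c("bulk_rnaseq", "scrnaseq", "spatial")),
    nb_mean_log_mu = nb_mean_log_mu, nb_mean_log_sd = nb_mean_log_sd,
    nb_dispersion = nb_dispersion,
    dropout_logit_intercept = dropout_logit_intercept,
    dropout_logit_slope = dropout_logit_slope,
    grid_dims = if (!is.null(grid_dims)) as.integer(grid_dims),
    region_map = region_map,
    planted = planted, seed = as.integer(seed)), class = "sim_design")
  validate_design(d)
  d
}

validate_design <- function(d) {
  if (d$n_genes < 1L || d$n_obs < 1L)
    sigc_stop("n_genes and n_obs must be positive", "validation")
  if (d$nb_dispersion <= 0)
    sigc_stop("nb_dispersion must be positive", "validation")
  if (d$technology == "spatial") {
    if (is.null(d$grid_dims) || length(d$grid_dims) != 2L)
      sigc_stop("spatial designs need grid_dims = c(nx, ny)", "validation")
    if (prod(d$grid_dims) != d$n_obs)
      sigc_stop("n_obs must equal prod(grid_dims)", "validation")
    if (is.null(d$region_map) || length(d$region_map) != d$n_obs)
      sigc_stop("region_map must assign a label to every spot", "validation")
  }
  for (p in d$planted) {
    if (is.null(p$genes) || is.null(p$lfc))
      sigc_stop("each planted entry needs genes and lfc", "validation")
    if (is.numeric(p$genes) && any(p$genes > d$n_genes))
      sigc_stop("planted gene indices outside the gene universe",
                "validation")
    if (is.null(p$obs) && is.null(p$region))
      sigc_stop("each planted entry needs obs indices or a region label",
                "validation")
    if (!is.null(p$obs) && any(p$obs > d$n_obs))
      sigc_stop("planted obs indices outside the observation range",
                "validation")
  }
  invisible(d)
}

sim_gene_ids <- function(n) sprintf("SIMG%04d", seq_len(n))
sim_obs_ids <- function(n, prefix) sprintf("%s%04d", prefix, seq_len(n))

resolve_planted_genes <- function(p, gene_ids) {
  if (is.numeric(p$genes)) gene_ids[p$genes] else toupper(p$genes)
}

# base NB mean matrix with planted multiplicative effects
sim_mu_matrix <- function(design, gene_ids, obs_region = NULL) {
  mu_g <- rlnorm(design$n_genes, design$nb_mean_log_mu,
                 design$nb_mean_log_sd)
  mu <- matrix(mu_g, design$n_genes, design$n_obs)
  rownames(mu) <- gene_ids
  for (p in design$planted) {
    g <- match(resolve_planted_genes(p, gene_ids), gene_ids)
    obs <- if (!is.null(p$obs)) p$obs
    else which(obs_region == p$region)
    mu[g, obs] <- mu[g, obs] * 2^p$lfc
  }
  mu
}

sim_truth <- function(design, obs_ids, gene_ids, region = NULL) {
  truth <- data.frame(obs_id = obs_ids, stringsAsFactors = FALSE)
  if (!is.null(region)) truth$region <- region
  planted_sets <- list()
  for (i in seq_along(design$planted)) {
    p <- design$planted[[i]]
    col <- sprintf("signal_%d", i)
    in_sig <- rep(FALSE, design$n_obs)
    if (!is.null(p$obs)) in_sig[p$obs] <- TRUE
    else in_sig[region == p$region] <- TRUE
    truth[[col]] <- in_sig
    planted_sets[[col]] <- list(genes = resolve_planted_genes(p, gene_ids),
                                lfc = p$lfc)
  }
  attr(truth, "planted_sets") <- planted_sets
  truth
}

#' Simulate a bulk RNA-seq dataset with planted signal
#'
#' Counts are negative binomial with lognormal gene means; planted gene
#' sets are multiplied by `2^lfc` in their signal observations. The
#' returned truth table records, per observation, membership in every
#' planted subset; the planted gene sets are attached as the
#' `"planted_sets"` attribute.
#'
#' @param design A [simulation_design()] with
#'   `technology = "bulk_rnaseq"`.
#' @return A list with `dataset` (an expression dataset, metric
#'   `"counts"`) and `truth` (a data.frame).
#' @export
simulate_bulk <- function(design) {
  validate_design(design)
  if (design$technology != "bulk_rnaseq")
    sigc_stop("simulate_bulk needs technology = 'bulk_rnaseq'", "validation")
  set.seed(design$seed)
  gene_ids <- sim_gene_ids(design$n_genes)
  obs_ids <- sim_obs_ids(design$n_obs, "sample")
  mu <- sim_mu_matrix(design, gene_ids)
  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = 1 / design$nb_dispersion),
    nrow(mu), ncol(mu), dimnames = list(gene_ids, obs_ids))
  ds <- expression_dataset(counts, metric = "counts",
                           technology = "bulk_rnaseq")
  list(dataset = ds, truth = sim_truth(design, obs_ids, gene_ids))
}

#' Expected zero fraction of a single-cell design
#'
#' Closed-form expectation, integrating dropout and NB sampling zeros
#' over the lognormal gene-mean distribution by Monte Carlo quadrature
#' over a fixed large grid of quantiles (deterministic).
#'
#' @param design A [simulation_design()].
#' @param n_quad Number of quantile nodes.
#' @return The expected fraction of zero entries, ignoring planted
#'   effects.
#' @export
expected_zero_fraction <- function(design, n_quad = 10000) {
  q <- (seq_len(n_quad) - 0.5) / n_quad
  mu <- qlnorm(q, design$nb_mean_log_mu, design$nb_mean_log_sd)
  size <- 1 / design$nb_dispersion
  p_drop <- plogis(design$dropout_logit_intercept +
                     design$dropout_logit_slope * log(mu))
  p_nb0 <- (size / (size + mu))^size
  mean(p_drop + (1 - p_drop) * p_nb0)
}

#' Simulate a single-cell RNA-seq dataset
#'
#' The bulk process plus per-entry dropout: each count is zeroed with
#' probability logistic in the log of its (planted-effect-adjusted) NB
#' mean. The realized overall zero fraction is attached to the result.
#'
#' @param design A [simulation_design()] with `technology = "scrnaseq"`.
#' @return A list with `dataset`, `truth` and `zero_fraction`.
#' @export
simulate_single_cell <- function(design) {
  validate_design(design)
  if (design$technology != "scrnaseq")
    sigc_stop("simulate_single_cell needs technology = 'scrnaseq'",
              "validation")
  set.seed(design$seed)
  gene_ids <- sim_gene_ids(design$n_genes)
  obs_ids <- sim_obs_ids(design$n_obs, "cell")
  mu <- sim_mu_matrix(design, gene_ids)
  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = 1 / design$nb_dispersion),
    nrow(mu), ncol(mu), dimnames = list(gene_ids, obs_ids))
  p_drop <- plogis(design$dropout_logit_intercept +
                     design$dropout_logit_slope * log(mu))
  keep <- matrix(rbinom(length(mu), 1L, 1 - p_drop), nrow(mu), ncol(mu))
  counts <- counts * keep
  ds <- expression_dataset(counts, metric = "counts",
                           technology = "scrnaseq")
  list(dataset = ds, truth = sim_truth(design, obs_ids, gene_ids),
       zero_fraction = mean(counts == 0))
}

#' Simulate a spatial transcriptomics dataset
#'
#' Spots lie on an integer grid with coordinates; each spot belongs to a
#' region (`region_map`), and planted signals may target a region by
#' label (e.g. a proliferation-like set up-regulated in the "tumor"
#' region). The count process is the bulk NB process; spot-level
#' sparsity beyond NB zeros is not modelled.
#'
#' @param design A [simulation_design()] with `technology = "spatial"`,
#'   `grid_dims` and `region_map`.
#' @return A list with `dataset` (coordinates attached) and `truth`
#'   (including the region label per spot).
#' @export
simulate_spatial <- function(design) {
  validate_design(design)
  if (design$technology != "spatial")
    sigc_stop("simulate_spatial needs technology = 'spatial'", "validation")
  set.seed(design$seed)
  gene_ids <- sim_gene_ids(design$n_genes)
  obs_ids <- sim_obs_ids(design$n_obs, "spot")
  grid <- expand.grid(x = seq_len(design$grid_dims[1L]),
                      y = seq_len(design$grid_dims[2L]))
  region <- as.character(design$region_map)
  mu <- sim_mu_matrix(design, gene_ids, obs_region = region)
  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = 1 / design$nb_dispersion),
    nrow(mu), ncol(mu), dimnames = list(gene_ids, obs_ids))
  ds <- expression_dataset(
    counts, metric = "counts", technology = "spatial",
    obs_annotations = data.frame(region = region),
    coordinates = grid)
  list(dataset = ds,
       truth = sim_truth(design, obs_ids, gene_ids, region = region))
}

#' Generate a catalog of random, valid signatures
#'
#' Draws one signature per entry of `method_mix` over a gene universe,
#' each valid under [validate_signature()]: random gene subsets, standard
#' normal weights for weighted sums, mixed up/down directions for
#' contrasts, all four categories for the immunophenoscore family, and
#' block-structured random centroids for consensus subtyping.
#'
#' @param n_sigs Number of signatures (method families are recycled over
#'   `method_mix`).
#' @param gene_universe Character vector of gene IDs to draw from.
#' @param size_range Integer range of signature sizes (min 2).
#' @param method_mix Character vector of method families to cycle over.
#' @param seed Integer seed.
#' @return A `sig_catalog` of `n_sigs` synthetic definitions named
#'   `Synthetic<i>_<Family>`.
#' @export
make_synthetic_catalog <- function(n_sigs, gene_universe,
                                   size_range = c(10, 50),
                                   method_mix = sig_methods,
                                   seed = 1L) {
  if (min(size_range) < 2L)
    sigc_stop("signature sizes must be >= 2", "validation")
  set.seed(seed)
  cat <- empty_catalog()
  for (i in seq_len(n_sigs)) {
    method <- method_mix[(i - 1L) %% length(method_mix) + 1L]
    size <- sample(seq(size_range[1L], size_range[2L]), 1L)
    genes <- sample(gene_universe, min(size, length(gene_universe)))
    name <- sprintf("Synthetic%d_%s", i,
                    gsub("_", "", tools::toTitleCase(method)))
    df <- data.frame(symbol = genes, stringsAsFactors = FALSE)
    centroids <- NULL
    if (method == "weighted_sum") {
      df$weight <- rnorm(nrow(df))
    } else if (method == "up_down_diff") {
      df$direction <- sample(c("up", "down"), nrow(df), replace = TRUE)
      df$direction[1L] <- "up"
    } else if (method == "ips_composite") {
      cats <- rep(c("EC", "SC", "MHC", "CP"), length.out = nrow(df))
      df$class_label <- cats
      df$subclass <- paste0(cats, "_s",
                            ave(seq_len(nrow(df)), cats, FUN = seq_along) %% 2L)
      df$weight <- ifelse(cats %in% c("SC", "CP"), -1, 1)
    } else if (method == "consensus_centroid") {
      n_sub <- sample(2:4, 1L)
      centroids <- matrix(rnorm(nrow(df) * n_sub), nrow(df), n_sub,
                          dimnames = list(toupper(genes),
                                          paste0("ST", seq_len(n_sub))))
      blocks <- rep(seq_len(n_sub), length.out = nrow(df))
      for (j in seq_len(n_sub))
        centroids[blocks == j, j] <- centroids[blocks == j, j] + 2
    }
    def <- signature_definition(
      name = name, topic = "Synthetic activity", genes = df,
      method = method, required_scale = "log",
      tumor_types = "pan-cancer", first_author = "Sim",
      reference_id = "synthetic", centroids = centroids,
      genes_synthetic = TRUE)
    cat <- register_signature(cat, def)
  }
  cat
}
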