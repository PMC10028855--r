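#' Build an expression dataset
#'
#' The package's container for gene-by-observation expression data is a
#' [SummarizedExperiment::SummarizedExperiment] with one assay (`"exprs"`),
#' gene IDs as row names, observation IDs as column names, observation
#' annotations in `colData`, and the declared expression metric,
#' technology and gene-ID type in `metadata()$sigcompass`. Signature
#' scores are attached as extra `colData` columns and tracked so they can
#' be separated from user annotations.
#'
#' @param mat Numeric matrix, genes in rows, observations in columns, with
#'   row and column names (generated when absent).
#' @param metric Declared expression metric: `"counts"`, `"cpm"`,
#'   `"fpkm"`, `"tpm"` or `"log"`.
#' @param technology One of `"microarray"`, `"bulk_rnaseq"`, `"scrnaseq"`,
#'   `"spatial"`.
#' @param id_type Gene identifier type: `"symbol"`, `"ensembl"` or
#'   `"entrez"`.
#' @param obs_annotations Optional data.frame of per-observation
#'   annotations (row order = column order of `mat`). May include
#'   `survival_time` (days), `survival_event` (0/1), `cell_type`, etc.
#' @param coordinates Optional data.frame/matrix with columns `x`, `y`
#'   (one row per observation); only allowed for `technology = "spatial"`.
#' @return A `SummarizedExperiment` ("expression dataset").
#' @export
expression_dataset <- function(mat, metric, technology, id_type = "symbol",
                               obs_annotations = NULL, coordinates = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  metric <- match.arg(metric, sig_scales)
  technology <- match.arg(technology,
                          c("microarray", "bulk_rnaseq", "scrnaseq",
                            "spatial"))
  id_type <- match.arg(id_type, c("symbol", "ensembl", "entrez"))
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("g%04d", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("obs%04d", seq_len(ncol(mat)))
  if (anyDuplicated(rownames(mat))) {
    dup <- unique(rownames(mat)[duplicated(rownames(mat))])
    sigc_stop(sprintf("duplicate gene ids: %s",
                      paste(head(dup, 10), collapse = ", ")), "validation")
  }
  if (metric == "counts" && any(mat < 0, na.rm = TRUE))
    sigc_stop("metric 'counts' requires non-negative entries", "validation")
  if (technology != "microarray" && anyNA(mat))
    sigc_stop("missing values are only allowed for microarray input",
              "validation")

  cd <- S4Vectors::DataFrame(row.names = colnames(mat))
  if (!is.null(obs_annotations)) {
    obs_annotations <- as.data.frame(obs_annotations)
    if (nrow(obs_annotations) != ncol(mat))
      sigc_stop("obs_annotations rows must equal observation count",
                "validation")
    rownames(obs_annotations) <- colnames(mat)
    cd <- S4Vectors::DataFrame(obs_annotations)
  }
  if (!is.null(coordinates)) {
    if (technology != "spatial")
      sigc_stop("coordinates are only allowed for spatial data",
                "validation")
    coordinates <- as.data.frame(coordinates)
    if (nrow(coordinates) != ncol(mat))
      sigc_stop("coordinates rows must equal observation count", "validation")
    cd$coord_x <- as.numeric(coordinates$x)
    cd$coord_y <- as.numeric(coordinates$y)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat), colData = cd)
  S4Vectors::metadata(se)$sigcompass <- list(
    metric = metric, technology = technology, id_type = id_type,
    annotation_columns = setdiff(colnames(cd), c("coord_x", "coord_y")),
    score_columns = character(0))
  se
}

sigc_meta <- function(ds) {
  m <- S4Vectors::metadata(ds)$sigcompass
  if (is.null(m))
    sigc_stop("not a sigcompass expression dataset", "validation")
  m
}

`sigc_meta<-` <- function(ds, value) {
  S4Vectors::metadata(ds)$sigcompass <- value
  ds
}

#' Accessors for expression datasets
#'
#' @param ds An expression dataset built by [expression_dataset()].
#' @return `expr_matrix()` the numeric matrix; `ds_metric()`,
#'   `ds_technology()`, `ds_id_type()` the declared metadata strings;
#'   `score_table()` a data.frame of attached score columns;
#'   `obs_annotation_table()` a data.frame of user annotations;
#'   `ds_coordinates()` the spatial coordinates or `NULL`.
#' @export
expr_matrix <- function(ds) SummarizedExperiment::assay(ds, "exprs")

#' @rdname expr_matrix
#' @export
ds_metric <- function(ds) sigc_meta(ds)$metric

#' @rdname expr_matrix
#' @export
ds_technology <- function(ds) sigc_meta(ds)$technology

#' @rdname expr_matrix
#' @export
ds_id_type <- function(ds) sigc_meta(ds)$id_type

#' @rdname expr_matrix
#' @export
score_table <- function(ds) {
  sc <- sigc_meta(ds)$score_columns
  as.data.frame(SummarizedExperiment::colData(ds)[, sc, drop = FALSE])
}

#' @rdname expr_matrix
#' @export
obs_annotation_table <- function(ds) {
  an <- sigc_meta(ds)$annotation_columns
  an <- intersect(an, colnames(SummarizedExperiment::colData(ds)))
  as.data.frame(SummarizedExperiment::colData(ds)[, an, drop = FALSE])
}

#' @rdname expr_matrix
#' @export
ds_coordinates <- function(ds) {
  cd <- SummarizedExperiment::colData(ds)
  if (!all(c("coord_x", "coord_y") %in% colnames(cd))) return(NULL)
  data.frame(x = cd$coord_x, y = cd$coord_y, row.names = rownames(cd))
}

# ---- readers ---------------------------------------------------------------

detect_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

#' Read a dense delimited expression table
#'
#' Reads a TSV/CSV table with a header row and a leading gene (or
#' observation) ID column; the delimiter is auto-detected. Values must be
#' numeric; `NA` entries are allowed only for microarray data.
#'
#' @param path File path.
#' @param orientation `"genes_rows"` (default) or `"genes_cols"`; the
#'   matrix is stored genes-by-observations either way.
#' @inheritParams expression_dataset
#' @return An expression dataset.
#' @export
read_dense_table <- function(path, orientation = c("genes_rows", "genes_cols"),
                             metric, technology, id_type = "symbol") {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    sigc_stop(sprintf("input file not found: %s", path), "config")
  sep <- detect_delim(path)
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           row.names = NULL, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  ids <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  num <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L)
  bad <- which(is.na(num) & !(body == "NA" | body == "" | is.na(body)),
               arr.ind = TRUE)
  if (length(bad)) {
    sigc_stop(sprintf(
      "non-numeric value '%s' at table row %d, column '%s'",
      as.matrix(body)[bad[1, 1], bad[1, 2]], bad[1, 1],
      colnames(body)[bad[1, 2]]), "format")
  }
  rownames(num) <- ids
  if (orientation == "genes_cols") num <- t(num)
  if (anyDuplicated(rownames(num))) {
    dup <- unique(rownames(num)[duplicated(rownames(num))])
    sigc_stop(sprintf("duplicate gene ids in %s: %s", path,
                      paste(head(dup, 10), collapse = ", ")), "format")
  }
  expression_dataset(num, metric = metric, technology = technology,
                     id_type = id_type)
}

find_triplet_file <- function(dir, stems) {
  for (s in stems) for (ext in c("", ".gz")) {
    p <- file.path(dir, paste0(s, ext))
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Read a sparse triplet (10x-convention) expression directory
#'
#' Expects `matrix.mtx[.gz]`, `features.tsv[.gz]` (or `genes.tsv`) and
#' `barcodes.tsv[.gz]` in `dir`. An optional positions CSV
#' (`barcode,x,y`, no header required) attaches spatial coordinates by
#' barcode.
#'
#' @param dir Directory with the three files.
#' @param positions Optional path to a spot-positions CSV.
#' @inheritParams expression_dataset
#' @return A dense-backed expression dataset.
#' @export
read_sparse_triplet <- function(dir, metric, technology, id_type = "symbol",
                                positions = NULL) {
  mtx <- find_triplet_file(dir, c("matrix.mtx"))
  feat <- find_triplet_file(dir, c("features.tsv", "genes.tsv"))
  bc <- find_triplet_file(dir, c("barcodes.tsv"))
  if (is.null(mtx) || is.null(feat) || is.null(bc))
    sigc_stop(sprintf(
      "directory %s must contain matrix.mtx, features.tsv (or genes.tsv) and barcodes.tsv",
      dir), "format")
  m <- as.matrix(Matrix::readMM(mtx))
  features <- utils::read.delim(feat, header = FALSE,
                                stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(bc, header = FALSE,
                                stringsAsFactors = FALSE)[[1L]]
  if (nrow(features) != nrow(m))
    sigc_stop(sprintf("features file has %d rows but matrix has %d",
                      nrow(features), nrow(m)), "format")
  if (length(barcodes) != ncol(m))
    sigc_stop(sprintf("barcodes file has %d entries but matrix has %d columns",
                      length(barcodes), ncol(m)), "format")
  ids <- if (id_type == "symbol" && ncol(features) >= 2L)
    features[[2L]] else features[[1L]]
  rownames(m) <- ids
  colnames(m) <- barcodes
  coords <- NULL
  if (!is.null(positions)) {
    pos <- utils::read.csv(positions, header = FALSE,
                           stringsAsFactors = FALSE)
    if (is.character(pos[[2L]])) # header present
      pos <- utils::read.csv(positions, header = TRUE,
                             stringsAsFactors = FALSE)
    colnames(pos)[1:3] <- c("barcode", "x", "y")
    idx <- match(barcodes, pos$barcode)
    if (anyNA(idx))
      sigc_stop("positions file does not cover all barcodes", "format")
    coords <- data.frame(x = as.numeric(pos$x[idx]),
                         y = as.numeric(pos$y[idx]))
  }
  expression_dataset(m, metric = metric, technology = technology,
                     id_type = id_type, coordinates = coords)
}

# ---- transformations -------------------------------------------------------

#' Translate gene identifiers
#'
#' Renames rows according to a `from_id -> to_id` mapping. Unmapped genes
#' are dropped (with a message reporting the count); when several source
#' IDs map to the same target, one row is kept according to
#' `collision` (default: the row with the highest total signal).
#'
#' @param ds An expression dataset.
#' @param mapping A data.frame with columns `from_id` and `to_id`.
#' @param target_id_type New `id_type` of the dataset.
#' @param collision `"highest_total"` (keep the row with the largest row
#'   sum) or `"sum"` (sum colliding rows).
#' @return The translated dataset (never more rows than the input).
#' @export
translate_gene_ids <- function(ds, mapping, target_id_type = "symbol",
                               collision = c("highest_total", "sum")) {
  collision <- match.arg(collision)
  mat <- expr_matrix(ds)
  map <- mapping[!is.na(mapping$from_id) & !is.na(mapping$to_id), ]
  idx <- match(rownames(mat), map$from_id)
  mapped <- !is.na(idx)
  if (!any(mapped)) sigc_stop("no genes mapped", "validation")
  n_drop <- sum(!mapped)
  if (n_drop > 0)
    message(sprintf("translate_gene_ids: dropping %d unmapped gene(s)",
                    n_drop))
  mat <- mat[mapped, , drop = FALSE]
  target <- map$to_id[idx[mapped]]
  if (anyDuplicated(target)) {
    keep <- rep(TRUE, nrow(mat))
    if (collision == "highest_total") {
      ord <- order(rowSums(mat, na.rm = TRUE), decreasing = TRUE)
      dup_after <- duplicated(target[ord])
      keep[ord] <- !dup_after
      message(sprintf(
        "translate_gene_ids: %d id collision(s) resolved by highest total signal",
        sum(!keep)))
      mat <- mat[keep, , drop = FALSE]
      target <- target[keep]
    } else {
      mat <- rowsum(mat, group = target)
      target <- rownames(mat)
    }
  }
  rownames(mat) <- target
  meta <- sigc_meta(ds)
  out <- expression_dataset(
    mat, metric = meta$metric, technology = meta$technology,
    id_type = target_id_type,
    obs_annotations = if (ncol(obs_annotation_table(ds)))
      obs_annotation_table(ds) else NULL,
    coordinates = ds_coordinates(ds))
  out
}

#' Convert between expression metrics
#'
#' Defined conversion paths: `counts -> cpm` (per-observation scaling to
#' one million), `fpkm -> tpm` (per-observation renormalization to one
#' million), `counts -> fpkm` (requires `gene_lengths`, in bases), and
#' any linear metric `-> log` (`log2(x + pseudocount)`). Conversions are
#' per observation and leave zero entries zero; all-zero observations are
#' passed through unchanged with a warning. Undefined paths (e.g.
#' `log -> counts`) raise an unsupported-conversion error.
#'
#' @param ds An expression dataset.
#' @param target Target metric.
#' @param pseudocount Pseudocount for the log transform (default 1).
#' @param gene_lengths Named numeric vector of gene lengths in bases;
#'   required only for `counts -> fpkm`.
#' @return The converted dataset with its `metric` field updated.
#' @export
transform_metric <- function(ds, target, pseudocount = 1,
                             gene_lengths = NULL) {
  target <- match.arg(target, sig_scales)
  from <- ds_metric(ds)
  if (identical(from, target)) return(ds)
  mat <- expr_matrix(ds)

  per_million <- function(x) {
    tot <- colSums(x, na.rm = TRUE)
    zero <- tot == 0
    if (any(zero)) {
      sigc_warn(sprintf("%d all-zero observation(s) left unscaled",
                        sum(zero)))
      tot[zero] <- 1
    }
    sweep(x, 2L, tot / 1e6, "/")
  }

  out <- if (target == "log" && from %in% c("counts", "cpm", "fpkm", "tpm")) {
    log2(mat + pseudocount)
  } else if (from == "counts" && target == "cpm") {
    per_million(mat)
  } else if (from == "fpkm" && target == "tpm") {
    per_million(mat)
  } else if (from == "counts" && target == "fpkm") {
    if (is.null(gene_lengths))
      sigc_stop("counts -> fpkm requires gene_lengths", "conversion")
    len <- gene_lengths[rownames(mat)]
    if (anyNA(len))
      sigc_stop("gene_lengths must cover all genes", "conversion")
    per_million(mat) / (len / 1e3)
  } else {
    sigc_stop(sprintf("unsupported metric conversion: %s -> %s",
                      from, target), "conversion")
  }

  meta <- sigc_meta(ds)
  meta$metric <- target
  SummarizedExperiment::assay(ds, "exprs") <- out
  sigc_meta(ds) <- meta
  ds
}

# ---- scores ----------------------------------------------------------------

#' Attach a score result to a dataset
#'
#' Adds the score vector (and, for composite methods, its component and
#' label columns) to the dataset's observation table. Recomputing an
#' already-attached signature overwrites the columns with a warning.
#'
#' @param ds An expression dataset.
#' @param result A `sig_score` from [compute_signature()].
#' @return The dataset with new score column(s).
#' @export
attach_scores <- function(ds, result) {
  stopifnot(inherits(result, "sig_score"))
  obs <- colnames(ds)
  ids <- names(result$values)
  if (!all(ids %in% obs))
    sigc_stop(sprintf(
      "score observations not in dataset: %s",
      paste(head(setdiff(ids, obs), 5), collapse = ", ")), "validation")
  meta <- sigc_meta(ds)
  cd <- SummarizedExperiment::colData(ds)

  new_cols <- result$signature_name
  if (!is.null(result$components))
    new_cols <- c(new_cols, paste(result$signature_name,
                                  colnames(result$components), sep = "_"))
  if (!is.null(result$label))
    new_cols <- c(new_cols, paste0(result$signature_name, "_label"))
  if (any(new_cols %in% meta$score_columns))
    sigc_warn(sprintf("overwriting existing score column(s) for '%s'",
                      result$signature_name))

  put <- function(col, vals) {
    v <- rep(NA, length(obs))
    v[match(ids, obs)] <- vals
    cd[[col]] <<- v
  }
  put(result$signature_name, unname(result$values))
  if (!is.null(result$components)) {
    for (j in colnames(result$components))
      put(paste(result$signature_name, j, sep = "_"),
          unname(result$components[, j]))
  }
  if (!is.null(result$label))
    put(paste0(result$signature_name, "_label"),
        as.character(result$label))

  SummarizedExperiment::colData(ds) <- cd
  meta$score_columns <- union(meta$score_columns, new_cols)
  sigc_meta(ds) <- meta
  ds
}

#' Write attached scores (and annotations) to a TSV file
#'
#' Emits one row per observation: observation ID, annotation columns
#' (original order), then score columns in lexicographic order. Numeric
#' values are written with 6 significant digits; the output is
#' deterministic, so rewriting an unchanged dataset reproduces the file
#' byte for byte.
#'
#' @param ds An expression dataset with at least one attached score.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(ds, path) {
  meta <- sigc_meta(ds)
  if (!length(meta$score_columns))
    sigc_stop("dataset has no attached scores", "validation")
  ann <- obs_annotation_table(ds)
  sc <- score_table(ds)
  sc <- sc[, order(colnames(sc)), drop = FALSE]
  fmt <- function(x) {
    if (is.numeric(x)) {
      out <- vapply(x, function(v)
        if (is.na(v)) "NA" else format(signif(v, 6), scientific = FALSE,
                                       trim = TRUE), character(1))
      out
    } else as.character(x)
  }
  out <- data.frame(obs_id = colnames(ds), stringsAsFactors = FALSE)
  for (cn in colnames(ann)) out[[cn]] <- fmt(ann[[cn]])
  for (cn in colnames(sc)) out[[cn]] <- fmt(sc[[cn]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
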