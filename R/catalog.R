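#' Construct a signature definition
#'
#' A signature definition couples a gene list (optionally with per-gene
#' directions, weights and class labels) with the metadata needed to score
#' it: the method family, the expression scale the method expects, and the
#' catalog metadata (topic, tumor types, authorship).
#'
#' Gene symbols are uppercased on construction; duplicates after
#' uppercasing collapse to one entry keeping the first weight, with a
#' warning.
#'
#' @param name Signature name. The catalog convention is
#'   `<Topic>_<Author>` (e.g. `"Hypoxia_Buffa"`); names that do not follow
#'   it are accepted but flagged by [validate_signature()].
#' @param topic Free-text category, e.g. `"Hypoxia activity"`.
#' @param genes A `data.frame` with column `symbol` and optional columns
#'   `direction` (`"up"`, `"down"` or `"none"`), `weight` (numeric),
#'   `class_label` and `subclass` (used by the immunophenoscore family).
#'   A bare character vector is accepted as a list of up-regulated genes.
#' @param method One of `"weighted_sum"`, `"zscore_mean"`, `"up_down_diff"`,
#'   `"ssgsea"`, `"ips_composite"`, `"consensus_centroid"`.
#' @param required_scale Expression scale the method expects: one of
#'   `"counts"`, `"cpm"`, `"fpkm"`, `"tpm"`, `"log"`.
#' @param tumor_types Character vector of applicable tumor types;
#'   `"pan-cancer"` marks tissue-agnostic signatures.
#' @param input_types Subset of `c("sequencing", "microarray")`.
#' @param first_author,reference_id Catalog provenance metadata.
#' @param centroids Gene-by-subtype numeric matrix, required for the
#'   `consensus_centroid` family (at least 2 subtype columns).
#' @param genes_available Logical; `FALSE` marks catalog entries whose full
#'   gene list is not packaged. Such entries answer metadata queries but
#'   are refused by the scoring engine.
#' @param genes_synthetic Logical; `TRUE` marks gene lists that are
#'   synthetic stand-ins rather than transcriptions of the original
#'   publication.
#' @return An object of class `sig_definition`.
#' @seealso [validate_signature()], [register_signature()]
#' @export
signature_definition <- function(name, topic, genes, method, required_scale,
                                 tumor_types = "pan-cancer",
                                 input_types = "sequencing",
                                 first_author = NA_character_,
                                 reference_id = NA_character_,
                                 centroids = NULL,
                                 genes_available = TRUE,
                                 genes_synthetic = FALSE) {
  if (is.character(genes)) {
    genes <- data.frame(symbol = genes, stringsAsFactors = FALSE)
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (is.null(genes$symbol)) sigc_stop("genes must have a 'symbol' column",
                                       "validation")
  nr <- nrow(genes)
  if (is.null(genes$direction)) genes$direction <- rep("up", nr)
  if (is.null(genes$weight)) genes$weight <- rep(NA_real_, nr)
  if (is.null(genes$class_label)) genes$class_label <- rep(NA_character_, nr)
  if (is.null(genes$subclass)) genes$subclass <- rep(NA_character_, nr)
  genes$symbol <- toupper(genes$symbol)
  genes$weight <- as.numeric(genes$weight)
  if (anyDuplicated(genes$symbol)) {
    dup <- unique(genes$symbol[duplicated(genes$symbol)])
    sigc_warn(sprintf(
      "%s: %d gene symbol(s) duplicated after uppercasing (%s); keeping first occurrence",
      name, length(dup), paste(head(dup, 5), collapse = ", ")))
    genes <- genes[!duplicated(genes$symbol), , drop = FALSE]
  }
  rownames(genes) <- NULL
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)
    rownames(centroids) <- toupper(rownames(centroids))
    storage.mode(centroids) <- "double"
  }
  structure(list(
    name = name,
    topic = topic,
    tumor_types = as.character(tumor_types),
    first_author = first_author,
    reference_id = as.character(reference_id),
    input_types = as.character(input_types),
    required_scale = required_scale,
    method = method,
    genes = genes[, c("symbol", "direction", "weight",
                      "class_label", "subclass")],
    centroids = centroids,
    genes_available = isTRUE(genes_available),
    genes_synthetic = isTRUE(genes_synthetic)
  ), class = "sig_definition")
}

sig_methods <- c("weighted_sum", "zscore_mean", "up_down_diff",
                 "ssgsea", "ips_composite", "consensus_centroid")
sig_scales <- c("counts", "cpm", "fpkm", "tpm", "log")
sig_input_types <- c("sequencing", "microarray")

#' @export
print.sig_definition <- function(x, ...) {
  cat(sprintf("<sig_definition> %s (%s)\n", x$name, x$topic))
  cat(sprintf("  method: %s on %s-scale input\n", x$method, x$required_scale))
  cat(sprintf("  tumor types: %s\n", paste(x$tumor_types, collapse = "; ")))
  if (x$genes_available) {
    cat(sprintf("  genes: %d%s\n", nrow(x$genes),
                if (x$genes_synthetic) " (synthetic stand-in list)" else ""))
  } else {
    cat("  genes: not packaged (metadata-only entry)\n")
  }
  invisible(x)
}

#' Validate a signature definition against the inclusion criteria
#'
#' Checks the machine-checkable catalog inclusion rules: a non-empty gene
#' list of well-formed symbols, an unambiguous scoring method, and a
#' declared input scale, plus the structural requirements of each method
#' family (finite weights for weighted sums, at least one up-regulated
#' gene for up/down contrasts, a centroid matrix with two or more subtype
#' columns for consensus subtyping). Genes whose symbol is not
#' well-formed (empty or containing whitespace) are flagged for removal;
#' the remainder of the definition can still be valid.
#'
#' @param def A [signature_definition()].
#' @return A `sig_validation` object: a list with `valid` (logical),
#'   `checks` (a data.frame of criterion/status/detail rows),
#'   `removed_genes` (character), and `definition` (the definition with
#'   flagged genes removed).
#' @export
validate_signature <- function(def) {
  checks <- list()
  add <- function(criterion, ok, detail = "") {
    checks[[length(checks) + 1]] <<- data.frame(
      criterion = criterion, status = if (ok) "pass" else "fail",
      detail = detail, stringsAsFactors = FALSE)
  }

  genes <- def$genes
  well_formed <- !is.na(genes$symbol) & nzchar(genes$symbol) &
    !grepl("\\s", genes$symbol)
  removed <- genes$symbol[!well_formed]
  genes_ok <- genes[well_formed, , drop = FALSE]

  add("gene_list",
      def$genes_available && nrow(genes_ok) > 0,
      if (!def$genes_available) "gene list not packaged"
      else if (nrow(genes_ok) == 0) "no well-formed gene symbols"
      else sprintf("%d gene(s) retained%s", nrow(genes_ok),
                   if (length(removed))
                     sprintf(", %d removed (malformed symbol)",
                             length(removed)) else ""))
  add("method",
      length(def$method) == 1L && def$method %in% sig_methods,
      if (!def$method %in% sig_methods)
        sprintf("unknown method '%s'", def$method) else def$method)
  add("input_scale",
      length(def$required_scale) == 1L && def$required_scale %in% sig_scales,
      as.character(def$required_scale))

  if (identical(def$method, "weighted_sum")) {
    ok <- nrow(genes_ok) > 0 && all(is.finite(genes_ok$weight))
    add("weights_finite", ok,
        if (!ok) "weighted_sum requires a finite weight per gene" else "")
  }
  if (identical(def$method, "up_down_diff")) {
    ok <- any(genes_ok$direction == "up")
    add("has_up_genes", ok,
        if (!ok) "up_down_diff requires at least one up-regulated gene" else "")
  }
  if (identical(def$method, "consensus_centroid")) {
    ok <- !is.null(def$centroids) && ncol(def$centroids) >= 2L
    add("centroids", ok,
        if (!ok) "consensus_centroid requires centroids with >= 2 subtypes"
        else sprintf("%d subtype(s)", ncol(def$centroids)))
  }
  if (identical(def$method, "ips_composite")) {
    cls <- unique(genes_ok$class_label)
    ok <- all(c("EC", "SC", "MHC", "CP") %in% cls)
    add("ips_classes", ok,
        if (!ok) "ips_composite requires genes in all of EC, SC, MHC, CP"
        else "all four categories present")
  }

  # advisory only: the catalog itself contains historical names that do not
  # follow the <Topic>_<Author> convention (e.g. IPSOV)
  conv <- grepl("^[A-Za-z0-9]+_[A-Za-z0-9]+$", def$name)
  add("name_convention", TRUE,
      if (conv) "follows <Topic>_<Author>"
      else "does not follow <Topic>_<Author> (advisory)")

  checks <- do.call(rbind, checks)
  clean <- def
  clean$genes <- genes_ok
  structure(list(
    valid = all(checks$status == "pass"),
    checks = checks,
    removed_genes = removed,
    definition = clean
  ), class = "sig_validation")
}

#' @export
print.sig_validation <- function(x, ...) {
  cat(sprintf("<sig_validation> %s: %s\n", x$definition$name,
              if (x$valid) "VALID" else "INVALID"))
  print(x$checks, row.names = FALSE)
  invisible(x)
}

#' Create an empty signature catalog
#'
#' @return A `sig_catalog` holding no definitions.
#' @export
empty_catalog <- function() {
  structure(list(signatures = list()), class = "sig_catalog")
}

#' Add a signature definition to a catalog
#'
#' The definition must pass [validate_signature()]; genes flagged as
#' malformed are removed before registration. Duplicate names are
#' rejected. Metadata-only entries (`genes_available = FALSE`) are
#' registered on metadata checks alone.
#'
#' @param catalog A `sig_catalog`.
#' @param def A [signature_definition()].
#' @return The catalog containing `def`.
#' @export
register_signature <- function(catalog, def) {
  stopifnot(inherits(catalog, "sig_catalog"), inherits(def, "sig_definition"))
  if (def$name %in% names(catalog$signatures)) {
    sigc_stop(sprintf("signature '%s' is already registered", def$name),
              "conflict")
  }
  rep <- validate_signature(def)
  if (def$genes_available && !rep$valid) {
    bad <- rep$checks[rep$checks$status == "fail", ]
    sigc_stop(sprintf(
      "signature '%s' failed validation:\n%s", def$name,
      paste(sprintf("  - %s: %s", bad$criterion, bad$detail),
            collapse = "\n")), "validation")
  }
  if (!def$genes_available) {
    meta_ok <- rep$checks$criterion %in% c("method", "input_scale")
    if (any(rep$checks$status[meta_ok] == "fail")) {
      sigc_stop(sprintf("signature '%s' has invalid metadata", def$name),
                "validation")
    }
    catalog$signatures[[def$name]] <- def
  } else {
    catalog$signatures[[def$name]] <- rep$definition
  }
  catalog
}

#' Retrieve one signature definition by name
#'
#' @param catalog A `sig_catalog`.
#' @param name Signature name (exact match).
#' @return The `sig_definition`; unknown names raise a lookup error that
#'   suggests the nearest registered names.
#' @export
get_signature <- function(catalog, name) {
  stopifnot(inherits(catalog, "sig_catalog"))
  def <- catalog$signatures[[name]]
  if (is.null(def)) {
    near <- agrep(name, names(catalog$signatures), max.distance = 0.3,
                  ignore.case = TRUE, value = TRUE)
    sigc_stop(sprintf(
      "unknown signature '%s'%s", name,
      if (length(near)) sprintf("; nearest matches: %s",
                                paste(head(near, 3), collapse = ", "))
      else ""), "lookup")
  }
  def
}

#' @export
print.sig_catalog <- function(x, ...) {
  cat(sprintf("<sig_catalog> %d signature(s), %d with packaged gene lists\n",
              length(x$signatures),
              sum(vapply(x$signatures, function(d) d$genes_available,
                         logical(1)))))
  invisible(x)
}

#' Build a catalog filter
#'
#' Filters are conjunctive: a signature is selected when it matches every
#' non-`NULL` field. Tissue matching is case-insensitive substring
#' matching over the tumor-type strings, with a small alias table (e.g.
#' `"ovary"` matches tumor types containing `"ovarian"`); pan-cancer
#' entries match any tissue query when `include_pan = TRUE`.
#'
#' @param topic Exact catalog topic, e.g. `"Ferroptosis activity"`.
#' @param tissue Free-text tissue/tumor query, e.g. `"ovarian"`.
#' @param input_type `"sequencing"` or `"microarray"`.
#' @param name_pattern Regular expression matched against signature names.
#' @param include_pan Should pan-cancer signatures satisfy a tissue query?
#'   Default `TRUE`.
#' @return A `catalog_filter` object.
#' @export
catalog_filter <- function(topic = NULL, tissue = NULL, input_type = NULL,
                           name_pattern = NULL, include_pan = TRUE) {
  if (!is.null(input_type) && !input_type %in% sig_input_types) {
    sigc_stop(sprintf("input_type must be one of: %s",
                      paste(sig_input_types, collapse = ", ")),
              "config")
  }
  structure(list(topic = topic, tissue = tissue, input_type = input_type,
                 name_pattern = name_pattern,
                 include_pan = isTRUE(include_pan)),
            class = "catalog_filter")
}

# free-text tissue queries -> substrings searched in the tumor_types strings
tissue_aliases <- list(
  ovary = "ovarian",
  kidney = c("renal", "clear cell renal"),
  brain = c("glioma", "glioblastoma", "brain"),
  skin = "melanoma",
  stomach = "gastric",
  colon = "colorectal",
  mouth = "oral",
  liver = "hepatocellular"
)

tissue_patterns <- function(tissue) {
  key <- tolower(tissue)
  unique(c(key, unlist(tissue_aliases[key], use.names = FALSE)))
}

sig_matches_filter <- function(def, filter) {
  if (!is.null(filter$topic) && !identical(def$topic, filter$topic))
    return(FALSE)
  if (!is.null(filter$input_type) &&
      !filter$input_type %in% def$input_types)
    return(FALSE)
  if (!is.null(filter$name_pattern) &&
      !grepl(filter$name_pattern, def$name))
    return(FALSE)
  if (!is.null(filter$tissue)) {
    tt <- tolower(def$tumor_types)
    is_pan <- any(grepl("pan-cancer", tt, fixed = TRUE))
    if (is_pan) return(filter$include_pan)
    pats <- tissue_patterns(filter$tissue)
    hit <- any(vapply(pats, function(p) any(grepl(p, tt, fixed = TRUE)),
                      logical(1)))
    if (!hit) return(FALSE)
  }
  TRUE
}

#' List catalog signatures and their metadata
#'
#' The catalog query of the package: returns one metadata row per
#' signature matching the filter, ordered lexicographically by name.
#' Metadata-only entries (no packaged gene list) are included; they carry
#' `genes_available = FALSE`.
#'
#' @param catalog A `sig_catalog`; defaults to the packaged catalog.
#' @param filter A [catalog_filter()]; the empty filter selects everything.
#' @return A data.frame with columns `name`, `topic`, `tumor_types`,
#'   `first_author`, `reference_id`, `input_types`, `required_scale`,
#'   `method`, `n_genes`, `genes_available`.
#' @examples
#' cat <- load_catalog()
#' nrow(available_signatures(cat))                               # all entries
#' available_signatures(cat, catalog_filter(topic = "Hypoxia activity"))
#' @export
available_signatures <- function(catalog = load_catalog(),
                                 filter = catalog_filter()) {
  stopifnot(inherits(catalog, "sig_catalog"))
  if (!inherits(filter, "catalog_filter"))
    sigc_stop("filter must be built with catalog_filter()", "config")
  sigs <- catalog$signatures
  if (!is.null(filter$topic) && length(sigs)) {
    topics <- sort(unique(vapply(sigs, `[[`, character(1), "topic")))
    if (!filter$topic %in% topics) {
      sigc_warn(sprintf("unknown topic '%s'; valid topics: %s",
                        filter$topic, paste(topics, collapse = "; ")))
      sigs <- list()
    }
  }
  keep <- vapply(sigs, sig_matches_filter, logical(1), filter = filter)
  sigs <- sigs[keep]
  out <- data.frame(
    name = vapply(sigs, `[[`, character(1), "name"),
    topic = vapply(sigs, `[[`, character(1), "topic"),
    tumor_types = vapply(sigs, function(d)
      paste(d$tumor_types, collapse = "; "), character(1)),
    first_author = vapply(sigs, `[[`, character(1), "first_author"),
    reference_id = vapply(sigs, `[[`, character(1), "reference_id"),
    input_types = vapply(sigs, function(d)
      paste(sort(d$input_types), collapse = ","), character(1)),
    required_scale = vapply(sigs, `[[`, character(1), "required_scale"),
    method = vapply(sigs, `[[`, character(1), "method"),
    n_genes = vapply(sigs, function(d)
      if (d$genes_available) nrow(d$genes) else NA_integer_, integer(1)),
    genes_available = vapply(sigs, `[[`, logical(1), "genes_available"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- serialization ---------------------------------------------------------

def_to_list <- function(def) {
  x <- unclass(def)
  g <- as.list(def$genes)
  # omit all-default columns to keep the documents small and diffable
  if (all(g$direction == "up")) g$direction <- NULL
  for (cc in c("weight", "class_label", "subclass"))
    if (all(is.na(g[[cc]]))) g[[cc]] <- NULL
  x$genes <- g
  if (!is.null(def$centroids)) {
    x$centroids <- list(
      genes = rownames(def$centroids),
      subtypes = colnames(def$centroids),
      values = unname(lapply(seq_len(ncol(def$centroids)),
                             function(j) unname(def$centroids[, j])))
    )
  }
  x
}

def_from_list <- function(x) {
  centroids <- NULL
  if (!is.null(x$centroids)) {
    centroids <- do.call(cbind, lapply(x$centroids$values, unlist))
    rownames(centroids) <- unlist(x$centroids$genes)
    colnames(centroids) <- unlist(x$centroids$subtypes)
  }
  genes <- x$genes
  if (!is.null(genes) && length(genes$symbol)) {
    genes <- data.frame(
      symbol = unlist(genes$symbol),
      direction = unlist(genes$direction) %||% "up",
      weight = as.numeric(unlist(genes$weight) %||% NA_real_),
      class_label = as.character(unlist(genes$class_label) %||% NA),
      subclass = as.character(unlist(genes$subclass) %||% NA),
      stringsAsFactors = FALSE)
  } else {
    genes <- data.frame(symbol = character(0))
  }
  signature_definition(
    name = x$name, topic = x$topic, genes = genes, method = x$method,
    required_scale = x$required_scale, tumor_types = unlist(x$tumor_types),
    input_types = unlist(x$input_types),
    first_author = x$first_author %||% NA_character_,
    reference_id = as.character(x$reference_id %||% NA),
    centroids = centroids,
    genes_available = isTRUE(x$genes_available),
    genes_synthetic = isTRUE(x$genes_synthetic))
}

#' Serialize a signature definition to JSON
#'
#' One JSON document per signature is the catalog's on-disk format; the
#' representation round-trips through [read_signature_json()] bit-exactly.
#'
#' @param def A `sig_definition`.
#' @param path Output file; if `NULL`, the JSON string is returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
write_signature_json <- function(def, path = NULL) {
  json <- jsonlite::toJSON(def_to_list(def), auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_signature_json
#' @param json_or_path A JSON string or file path.
#' @export
read_signature_json <- function(json_or_path) {
  x <- jsonlite::fromJSON(json_or_path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  def_from_list(x)
}

#' Load a signature catalog from a directory of JSON files
#'
#' The directory must contain `index.json` (an array of file names) and
#' one JSON document per signature. With no arguments this loads the
#' packaged catalog, which transcribes the published metadata of all 47
#' collected signatures and packages full gene lists for a representative
#' subset covering every method family.
#'
#' @param dir Catalog directory; defaults to the packaged catalog.
#' @return A `sig_catalog`.
#' @export
load_catalog <- function(dir = system.file("extdata", "catalog",
                                           package = "sigcompass")) {
  idx_path <- file.path(dir, "index.json")
  if (!file.exists(idx_path))
    sigc_stop(sprintf("catalog index not found: %s", idx_path), "config")
  files <- jsonlite::fromJSON(idx_path)
  cat <- empty_catalog()
  for (f in files) {
    def <- read_signature_json(file.path(dir, f))
    cat <- suppressWarnings(register_signature(cat, def))
  }
  cat
}
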