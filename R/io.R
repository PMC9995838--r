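#' Read a feature table from TSV or BIOM-JSON
#'
#' The TSV layout is features as rows: a `feature_id` header column, one
#' integer column per sample, and optionally a final `taxonomy` column holding
#' a semicolon-delimited lineage (`kingdom;phylum;...;genus`, `k__`-style
#' prefixes tolerated).
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"` (BIOM-JSON as written by
#'   [write_feature_table()]).
#' @param metadata optional per-sample data frame passed through to
#'   [feature_table()].
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, format = c("tsv", "biom"), metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    counts <- as(biomformat::biom_data(b), "matrix")
    tax <- tryCatch({
      om <- biomformat::observation_metadata(b)
      if (is.null(om)) NULL else parse_lineage(apply(as.matrix(om), 1, paste, collapse = ";"),
                                               rownames(counts))
    }, error = function(e) NULL)
    return(feature_table(counts, tax, metadata))
  }
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(raw)[1] != "feature_id") {
    stop("TSV feature tables start with a `feature_id` column", call. = FALSE)
  }
  dup_col <- names(raw)[duplicated(names(raw))]
  if (length(dup_col) > 0) {
    stop("duplicated sample column(s): ", paste(unique(dup_col), collapse = ", "),
         call. = FALSE)
  }
  tax <- NULL
  if ("taxonomy" %in% names(raw)) {
    tax <- parse_lineage(raw$taxonomy, raw$feature_id)
    raw$taxonomy <- NULL
  }
  counts <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(counts)) stop("non-numeric counts in ", path, call. = FALSE)
  rownames(counts) <- raw$feature_id
  feature_table(counts, tax, metadata)
}

parse_lineage <- function(lineage, feature_id) {
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  bad <- lengths(parts) > length(.ranks) + 1  # allow a trailing species field
  if (any(bad)) {
    stop("malformed lineage (too many ranks) for: ",
         paste(feature_id[bad], collapse = ", "), call. = FALSE)
  }
  mat <- t(vapply(parts, function(p) {
    p <- sub("^[a-z]__", "", trimws(p))
    p[!nzchar(p)] <- NA_character_
    c(p, rep(NA_character_, length(.ranks) - length(p)))[seq_along(.ranks)]
  }, character(length(.ranks))))
  colnames(mat) <- .ranks
  dplyr::bind_cols(tibble::tibble(feature_id = feature_id),
                   tibble::as_tibble(mat))
}

format_lineage <- function(taxonomy) {
  ranks <- intersect(.ranks, names(taxonomy))
  apply(as.matrix(taxonomy[, ranks, drop = FALSE]), 1, function(p) {
    p <- p[!is.na(p) & nzchar(p)]
    paste(p, collapse = ";")
  })
}

#' Write a feature table to TSV or BIOM-JSON
#'
#' TSV output round-trips bit-exactly through [read_feature_table()].
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @param format `"tsv"` or `"biom"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, format = c("tsv", "biom")) {
  stopifnot(inherits(table, "feature_table"))
  format <- match.arg(format)
  if (format == "biom") {
    om <- NULL
    if (!is.null(table$taxonomy)) {
      om <- data.frame(taxonomy = format_lineage(table$taxonomy),
                       row.names = rownames(table$counts))
    }
    b <- biomformat::make_biom(table$counts, observation_metadata = om)
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  df <- data.frame(feature_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy)) df$taxonomy <- format_lineage(table$taxonomy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a square distance matrix as TSV
#' @param d a `dist` object or square matrix with labels.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write all components of a synthetic cohort to a directory
#'
#' Emits the feature table (TSV and BIOM-JSON), the tree (newick), the sample
#' metadata/phenotype, metabolite and cytokine tables (TSV), and the ground
#' truth record (YAML).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(cohort$features, file.path(dir, "features.tsv"))
  write_feature_table(cohort$features, file.path(dir, "features.biom"), "biom")
  ape::write.tree(cohort$tree, file.path(dir, "tree.nwk"))
  utils::write.table(cohort$features$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  wt <- function(m, f) {
    utils::write.table(data.frame(sample_id = rownames(m), m, check.names = FALSE),
                       file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(cohort$metabolites, "metabolites.tsv")
  wt(cohort$cytokines, "cytokines.tsv")
  truth <- cohort$truth
  truth$log_basis <- NULL              # matrix-scale truth stays in memory
  truth <- rapply(truth, unname, how = "replace")
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
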