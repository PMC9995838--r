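#' Construct a feature table
#'
#' The central container of the package: a features-by-samples matrix of
#' non-negative integer counts (0 = not detected), with optional per-feature
#' taxonomy and per-sample metadata. Mirrors the on-disk layout (features as
#' rows) used by standard OTU tables.
#'
#' @param counts numeric matrix, features x samples, with unique rownames
#'   (feature identifiers) and colnames (sample identifiers). Values must be
#'   non-negative whole numbers.
#' @param taxonomy optional data frame with a `feature_id` column and lineage
#'   columns among `kingdom, phylum, class, order, family, genus`. Missing
#'   ranks are `NA`.
#' @param metadata optional data frame with a `sample_id` column covering every
#'   sample in `counts`; typical columns are `cohort`, `breed`, `sex`,
#'   `weight` (kg) and a two-level `group` label.
#'
#' @return An object of class `feature_table`: a list with elements `counts`,
#'   `taxonomy` and `metadata`.
#' @export
#' @examples
#' m <- matrix(c(1L, 2L, 3L, 4L), 2, 2,
#'             dimnames = list(c("OTU1", "OTU2"), c("S1", "S2")))
#' ft <- feature_table(m)
#' ft
feature_table <- function(counts, taxonomy = NULL, metadata = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("`counts` must have feature rownames and sample colnames", call. = FALSE)
  }
  if (is.null(dimnames(counts))) dimnames(counts) <- list(character(0), character(0))
  dup_f <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_f) > 0) {
    stop("duplicated feature identifier(s): ", paste(unique(dup_f), collapse = ", "),
         call. = FALSE)
  }
  dup_s <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_s) > 0) {
    stop("duplicated sample identifier(s): ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(counts)) stop("`counts` contains missing values", call. = FALSE)
  if (any(counts < 0)) stop("`counts` contains negative values", call. = FALSE)
  if (!inherits(counts[1], "integer") && any(abs(counts - round(counts)) > 1e-8)) {
    stop("`counts` contains non-integer values", call. = FALSE)
  }
  storage.mode(counts) <- "double"

  if (!is.null(taxonomy)) {
    taxonomy <- tibble::as_tibble(taxonomy)
    if (!"feature_id" %in% names(taxonomy)) {
      stop("`taxonomy` needs a `feature_id` column", call. = FALSE)
    }
    missing_tax <- setdiff(rownames(counts), taxonomy$feature_id)
    if (length(missing_tax) > 0) {
      extra <- tibble::tibble(feature_id = missing_tax)
      taxonomy <- dplyr::bind_rows(taxonomy, extra)
    }
    taxonomy <- taxonomy[match(rownames(counts), taxonomy$feature_id), ]
  }
  if (!is.null(metadata)) {
    metadata <- tibble::as_tibble(metadata)
    if (!"sample_id" %in% names(metadata)) {
      stop("`metadata` needs a `sample_id` column", call. = FALSE)
    }
    uncovered <- setdiff(colnames(counts), metadata$sample_id)
    if (length(uncovered) > 0) {
      stop("metadata missing for sample(s): ", paste(uncovered, collapse = ", "),
           call. = FALSE)
    }
    metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  }
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  kind <- if (inherits(x, "relabund_table")) "relative-abundance table" else "feature table"
  cat(sprintf("<%s> %d features x %d samples\n", kind,
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$taxonomy)) cat("  taxonomy: yes\n")
  if (!is.null(x$metadata)) {
    cat("  metadata:", paste(setdiff(names(x$metadata), "sample_id"),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Sample and feature identifiers of a feature table
#' @param x a [feature_table()]
#' @return character vector of identifiers.
#' @export
sample_ids <- function(x) colnames(x$counts)

#' @rdname sample_ids
#' @export
feature_ids <- function(x) rownames(x$counts)

#' Subset a feature table
#'
#' @param x a [feature_table()]
#' @param features,samples identifiers, indices or logical vectors selecting
#'   rows/columns; `NULL` keeps everything.
#' @return a `feature_table` (taxonomy and metadata subset accordingly).
#' @export
ft_subset <- function(x, features = NULL, samples = NULL) {
  counts <- x$counts
  if (!is.null(features)) counts <- counts[features, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  tax <- x$taxonomy
  if (!is.null(tax)) tax <- tax[tax$feature_id %in% rownames(counts), ]
  md <- x$metadata
  if (!is.null(md)) md <- md[md$sample_id %in% colnames(counts), ]
  out <- feature_table(counts, tax, md)
  class(out) <- class(x)
  out
}

#' Convert a feature table to a long tibble
#'
#' One row per (feature, sample) pair, joined with metadata, for piping into
#' dplyr/ggplot2.
#'
#' @param x a [feature_table()]
#' @param ... unused.
#' @return tibble with `feature_id`, `sample_id`, `count` (or `proportion`
#'   for relative-abundance tables) and any metadata columns.
#' @method tidy feature_table
#' @export
tidy.feature_table <- function(x, ...) {
  value_name <- if (inherits(x, "relabund_table")) "proportion" else "count"
  out <- tibble::as_tibble(as.table(x$counts), .name_repair = "minimal")
  names(out) <- c("feature_id", "sample_id", value_name)
  if (!is.null(x$metadata)) out <- dplyr::left_join(out, x$metadata, by = "sample_id")
  out
}
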