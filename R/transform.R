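#' Per-sample relative abundances
#'
#' Converts counts to column-stochastic proportions (each sample sums to 1).
#'
#' @param table a [feature_table()]; every sample must have a positive total.
#' @return a `relabund_table` (subclass of `feature_table`) whose `counts`
#'   element holds proportions in `[0, 1]`.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  totals <- colSums(table$counts)
  if (any(totals <= 0)) {
    bad <- colnames(table$counts)[totals <= 0]
    stop("sample(s) with zero total count: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  props <- sweep(table$counts, 2, totals, "/")
  out <- table
  out$counts <- props
  class(out) <- unique(c("relabund_table", class(table)))
  out
}

#' Filter features on mean relative abundance and prevalence
#'
#' Retains features whose mean relative abundance across samples is strictly
#' greater than `min_mean_rel_abund` AND that are detected (count > 0) in
#' strictly more than `min_prevalence` of samples. The two standard settings
#' used in this pipeline are (1e-4, 0.10) for diversity/association work and
#' (5e-4, 0.20) ahead of co-abundance-group construction.
#'
#' @param table a [feature_table()] of counts.
#' @param min_mean_rel_abund proportion in `[0, 1)`.
#' @param min_prevalence proportion in `[0, 1)`.
#' @return filtered `feature_table` (sample set unchanged). An empty result
#'   triggers a warning, not an error.
#' @export
prevalence_abundance_filter <- function(table, min_mean_rel_abund = 1e-4,
                                        min_prevalence = 0.1) {
  stopifnot(inherits(table, "feature_table"))
  if (min_mean_rel_abund < 0 || min_mean_rel_abund >= 1 ||
      min_prevalence < 0 || min_prevalence >= 1) {
    stop("filter thresholds must lie in [0, 1)", call. = FALSE)
  }
  rel <- relative_abundance(table)$counts
  mean_rel <- rowMeans(rel)
  prev <- rowMeans(table$counts > 0)
  keep <- mean_rel > min_mean_rel_abund & prev > min_prevalence
  if (!any(keep)) {
    warning("no feature passed the abundance/prevalence filter", call. = FALSE)
  }
  ft_subset(table, features = which(keep))
}

#' Rarefy samples to a common sequencing depth
#'
#' Classic rarefaction: per sample, draws `depth` reads without replacement.
#' Samples whose total is below `depth` are dropped with a warning; a sample
#' whose total equals `depth` is returned unchanged.
#'
#' @param table a [feature_table()] of counts.
#' @param depth positive integer target depth (tags per sample).
#' @param seed optional integer seed; given the seed the result is
#'   deterministic.
#' @return rarefied `feature_table`; every retained sample totals exactly
#'   `depth`.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (inherits(table, "relabund_table")) {
    stop("rarefaction needs raw counts, not relative abundances", call. = FALSE)
  }
  if (length(depth) != 1 || depth <= 0 || depth != round(depth)) {
    stop("`depth` must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  totals <- colSums(table$counts)
  drop <- totals < depth
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(colnames(table$counts)[drop], collapse = ", "), call. = FALSE)
  }
  tab <- table$counts[, !drop, drop = FALSE]
  if (ncol(tab) == 0) stop("no sample reaches the requested depth", call. = FALSE)
  rare <- apply(tab, 2, function(x) {
    if (sum(x) == depth) return(x)
    picked <- sample.int(sum(x), depth)
    # map read indices back to features via cumulative counts
    tabulate(findInterval(picked - 1, cumsum(x)) + 1, nbins = length(x))
  })
  rownames(rare) <- rownames(tab)
  ft_subset(feature_table(rare, table$taxonomy, table$metadata), samples = colnames(tab))
}

.ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Aggregate a feature table at a taxonomic rank
#'
#' Sums counts over features sharing the lineage down to `rank`. Features not
#' annotated at `rank` are grouped under a label that preserves the deepest
#' known rank, e.g. an OTU known only to family Desulfovibrionaceae aggregates
#' at genus level as `norank_f_Desulfovibrionaceae`.
#'
#' @param table a [feature_table()] with taxonomy.
#' @param rank one of kingdom, phylum, class, order, family, genus.
#' @return aggregated `feature_table`; per-sample totals are conserved.
#' @export
aggregate_taxonomy <- function(table, rank = "genus") {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$taxonomy)) stop("table carries no taxonomy", call. = FALSE)
  rank <- match.arg(rank, .ranks)
  idx <- match(rank, .ranks)
  tax <- table$taxonomy
  for (r in .ranks[seq_len(idx)]) if (!r %in% names(tax)) tax[[r]] <- NA_character_
  labels <- vapply(seq_len(nrow(tax)), function(i) {
    lineage <- as.character(unlist(tax[i, .ranks[seq_len(idx)]]))
    known <- !is.na(lineage) & nzchar(lineage)
    if (known[idx]) return(paste(lineage[seq_len(idx)], collapse = ";"))
    if (!any(known)) return("norank")
    deepest <- max(which(known))
    paste0(paste(lineage[seq_len(deepest)], collapse = ";"), ";norank_",
           substr(.ranks[deepest], 1, 1), "_", lineage[deepest])
  }, character(1))
  agg <- rowsum(table$counts, group = labels)
  # display name: last lineage element
  short <- vapply(strsplit(rownames(agg), ";", fixed = TRUE),
                  function(x) x[length(x)], character(1))
  if (anyDuplicated(short)) short <- rownames(agg)
  first <- !duplicated(labels)
  new_tax <- tax[first, c("feature_id", .ranks[seq_len(idx)])]
  new_tax$feature_id <- short[match(labels[first], rownames(agg))]
  rownames(agg) <- short
  feature_table(agg, new_tax, table$metadata)
}
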