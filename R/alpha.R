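#' Alpha-diversity indices
#'
#' Per-sample community indices in the variants used throughout this package:
#' Shannon entropy in natural log (nats), the unbiased Simpson dominance
#' estimator, bias-corrected Chao1, ACE with the usual rare-class cutoff, and
#' Faith's phylogenetic diversity including the stem to the root.
#'
#' @param counts non-negative integer vector of per-feature counts for one
#'   sample.
#' @return a single numeric value.
#' @name alpha_indices
NULL

check_counts <- function(counts) {
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  if (sum(counts) <= 0) stop("all-zero count vector", call. = FALSE)
}

#' @rdname alpha_indices
#' @export
shannon <- function(counts) {
  check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' @rdname alpha_indices
#' @details Simpson is reported as the unbiased dominance form
#'   `sum n_i (n_i - 1) / (N (N - 1))`; subtract from 1 for the
#'   Gini-Simpson diversity.
#' @export
simpson <- function(counts) {
  check_counts(counts)
  n <- sum(counts)
  if (n < 2) stop("Simpson's unbiased estimator needs a total of at least 2",
                  call. = FALSE)
  sum(counts * (counts - 1)) / (n * (n - 1))
}

#' @rdname alpha_indices
#' @export
chao1 <- function(counts) {
  check_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @rdname alpha_indices
#' @param rare_cutoff rare/abundant boundary for ACE (features with counts
#'   <= cutoff form the rare class); default 10.
#' @export
ace <- function(counts, rare_cutoff = 10) {
  check_counts(counts)
  counts <- counts[counts > 0]
  rare <- counts[counts <= rare_cutoff]
  s_abund <- sum(counts > rare_cutoff)
  if (length(rare) == 0) return(s_abund)
  s_rare <- length(rare)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    stop("ACE undefined: every rare read is a singleton; merge counts first",
         call. = FALSE)
  }
  fi <- tabulate(rare, nbins = rare_cutoff)
  gamma2 <- max(s_rare / c_ace * sum(seq_len(rare_cutoff) *
                                       (seq_len(rare_cutoff) - 1) * fi) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' @rdname alpha_indices
#' @param present_features character vector of tip labels observed in the
#'   sample (must be a subset of the tree's tips).
#' @param tree rooted `phylo` tree with branch lengths.
#' @details Faith's PD sums the branch lengths on the union of root-to-tip
#'   paths of the present features (root-inclusive convention).
#' @export
faith_pd <- function(present_features, tree) {
  stopifnot(inherits(tree, "phylo"))
  present_features <- as.character(present_features)
  missing <- setdiff(present_features, tree$tip.label)
  if (length(missing) > 0) {
    stop("feature(s) not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(present_features) == 0) return(0)
  pres <- tree$tip.label %in% present_features
  on_path <- edge_presence_matrix(tree, matrix(pres, ncol = 1))
  sum(attr(on_path, "edge.length")[on_path[, 1] > 0])
}

# For each edge of `tree`, whether any descendant tip is present in each
# community. presence: tips x communities logical/0-1 matrix (tip order =
# tree$tip.label). Returns edges x communities 0/1 matrix.
edge_presence_matrix <- function(tree, presence) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  acc <- matrix(0, ntip + nnode, ncol(presence))
  acc[seq_len(ntip), ] <- presence * 1
  tr <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]
    ch <- tr$edge[i, 2]
    acc[p, ] <- acc[p, ] + acc[ch, ]
  }
  out <- (acc[tr$edge[, 2], , drop = FALSE] > 0) * 1
  # report in the same edge order as tree$edge.length of the reordered tree:
  # return alongside lengths to avoid index mismatch
  attr(out, "edge.length") <- tr$edge.length
  out
}

#' Alpha diversity profile for every sample in a table
#'
#' @param table a [feature_table()] of counts.
#' @param tree optional rooted `phylo`; when supplied, Faith's PD is included
#'   (presence = count > 0).
#' @param rare_cutoff passed to [ace()].
#' @return tibble with one row per sample: `sample_id`, `shannon`, `simpson`,
#'   `chao1`, `ace`, and `faith_pd` when a tree is given; metadata columns are
#'   joined when present. ACE values are `NA` (with a warning) for samples
#'   where the estimator is undefined.
#' @export
alpha_diversity <- function(table, tree = NULL, rare_cutoff = 10) {
  stopifnot(inherits(table, "feature_table"))
  counts <- table$counts
  res <- tibble::tibble(
    sample_id = colnames(counts),
    shannon = apply(counts, 2, shannon),
    simpson = apply(counts, 2, simpson),
    chao1 = apply(counts, 2, chao1),
    ace = apply(counts, 2, function(x) {
      tryCatch(ace(x, rare_cutoff), error = function(e) NA_real_)
    })
  )
  if (anyNA(res$ace)) warning("ACE undefined for some sample(s); returned NA",
                              call. = FALSE)
  if (!is.null(tree)) {
    res$faith_pd <- apply(counts, 2, function(x) {
      faith_pd(rownames(counts)[x > 0], tree)
    })
  }
  if (!is.null(table$metadata)) {
    res <- dplyr::left_join(res, table$metadata, by = "sample_id")
  }
  res
}
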