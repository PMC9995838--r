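#' Cluster features into co-abundance groups (CAGs)
#'
#' Converts the correlation matrix to the distance `1 - r`, runs Ward-linkage
#' agglomerative clustering, and cuts into `k` groups or at height `h`.
#' Features are processed in identifier order so the partition does not depend
#' on input order.
#'
#' @param network a `correlation_network` (SparCC or Spearman).
#' @param threshold correlation above which an edge is retained for export /
#'   hub ranking; recorded on the partition. Convention: 0.55.
#' @param k number of CAGs; default `max(2, round(D / 9))`, the granularity of
#'   a ~30-cluster partition of ~260 features.
#' @param h cut height on the dendrogram (overrides `k` when given).
#' @return object of class `cag_partition`: list with `assignment` (tibble of
#'   `feature_id`, `cag`), `k`, `threshold`, `network_method` and a
#'   `validation` slot filled by [validate_cags_permanova()].
#' @export
cluster_cags <- function(network, threshold = 0.55, k = NULL, h = NULL) {
  stopifnot(inherits(network, "correlation_network"))
  ids <- sort(network$feature_ids)
  r <- network$r[ids, ids]
  D <- length(ids)
  if (!is.null(k) && k > D) stop("k exceeds the feature count", call. = FALSE)
  if (is.null(k) && is.null(h)) k <- max(2L, round(D / 9))
  hc <- stats::hclust(stats::as.dist(1 - r), method = "ward.D2")
  cl <- if (!is.null(h)) stats::cutree(hc, h = h) else stats::cutree(hc, k = k)
  labels <- paste0("CAG", formatC(cl, width = 2, flag = "0"))
  structure(list(
    assignment = tibble::tibble(feature_id = ids, cag = labels),
    k = length(unique(labels)), threshold = threshold,
    network_method = network$method, validation = NULL
  ), class = "cag_partition")
}

#' @export
print.cag_partition <- function(x, ...) {
  cat(sprintf("<cag_partition> %d features in %d CAGs (%s network)\n",
              nrow(x$assignment), x$k, x$network_method))
  if (!is.null(x$validation)) {
    cat(sprintf("  validated: %d/%d accepted (p < 0.005)\n",
                sum(x$validation$accepted, na.rm = TRUE), nrow(x$validation)))
  }
  invisible(x)
}

#' Validate CAGs by per-group PERMANOVA
#'
#' Treats features as observations: each feature's profile is its relative
#' abundance across samples normalized to sum 1, distances are Bray-Curtis
#' among features, and each CAG is tested members-vs-rest with the
#' [permanova()] engine. A CAG is accepted when `p < 0.005`; single-member
#' CAGs are flagged not testable.
#'
#' @param table the [feature_table()] the network was built from.
#' @param partition a [cluster_cags()] result with at least 2 CAGs.
#' @param n_perm permutations per CAG (study convention 999).
#' @param seed optional integer seed.
#' @return the partition with a `validation` tibble: `cag`, `n_members`,
#'   `pseudo_f`, `p_value`, `accepted`, `testable`.
#' @export
validate_cags_permanova <- function(table, partition, n_perm = 999, seed = NULL) {
  stopifnot(inherits(partition, "cag_partition"))
  asg <- partition$assignment
  if (length(unique(asg$cag)) < 2) {
    stop("need at least 2 CAGs to validate", call. = FALSE)
  }
  rel <- relative_abundance(table)$counts[asg$feature_id, , drop = FALSE]
  prof <- sweep(rel, 1, rowSums(rel), "/")          # feature profiles
  d <- vegan::vegdist(prof, method = "bray")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(sort(unique(asg$cag)), function(g) {
    member <- asg$cag == g
    n_g <- sum(member)
    if (n_g < 2 || sum(!member) < 2) {
      return(tibble::tibble(cag = g, n_members = n_g, pseudo_f = NA_real_,
                            p_value = NA_real_, accepted = NA, testable = FALSE))
    }
    fit <- permanova(d, ifelse(member, "member", "rest"), n_perm = n_perm)
    tibble::tibble(cag = g, n_members = n_g, pseudo_f = fit$pseudo_f,
                   p_value = fit$p_value, accepted = fit$p_value < 0.005,
                   testable = TRUE)
  })
  partition$validation <- dplyr::bind_rows(rows)
  partition
}

#' Per-sample CAG abundances
#'
#' @param table a [feature_table()].
#' @param partition a [cluster_cags()] result.
#' @return matrix CAGs x samples of summed member relative abundances.
#' @export
cag_abundance <- function(table, partition) {
  rel <- relative_abundance(table)$counts
  asg <- partition$assignment
  rowsum(rel[asg$feature_id, , drop = FALSE], group = asg$cag)
}

#' Compare CAG abundances between two groups
#'
#' Per-sample CAG abundance is the sum of member relative abundances; each CAG
#' is compared between the two groups with a two-sided Wilcoxon rank-sum test
#' and p-values are Benjamini-Hochberg adjusted across CAGs.
#'
#' @param table a [feature_table()].
#' @param partition a [cluster_cags()] result.
#' @param groups per-sample labels with exactly two levels.
#' @return tibble: `cag`, per-group mean abundances, `p_value`, `q_value`.
#' @export
cag_group_test <- function(table, partition, groups) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required", call. = FALSE)
  ab <- cag_abundance(table, partition)
  res <- purrr::map_dfr(rownames(ab), function(g) {
    v <- ab[g, ]
    wt <- compare_groups_wilcoxon(v, groups)
    tibble::tibble(cag = g,
                   mean_1 = mean(v[groups == lv[1]]),
                   mean_2 = mean(v[groups == lv[2]]),
                   p_value = wt$p_value)
  })
  names(res)[2:3] <- paste0("mean_", lv)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Hub ranking by Maximal Clique Centrality
#'
#' Scores each node of the thresholded co-abundance network as
#' `MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!`
#' (cliques of size 1, i.e. isolated nodes, score 0). This is cytoHubba's
#' "MCC" — Maximal Clique Centrality (sometimes mis-expanded as Matthews
#' Correlation Coefficient). Ties are broken by degree, then identifier.
#'
#' @param network a `correlation_network`.
#' @param threshold absolute correlation defining an edge (strictly greater).
#' @param top_n how many hubs to return.
#' @return tibble `feature_id`, `mcc`, `degree`, ordered by rank.
#' @export
hub_ranking_mcc <- function(network, threshold = 0.55, top_n = 20) {
  stopifnot(inherits(network, "correlation_network"))
  adj <- abs(network$r) > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  score <- stats::setNames(numeric(length(network$feature_ids)),
                           network$feature_ids)
  if (igraph::ecount(g) > 0) {
    for (cl in igraph::max_cliques(g, min = 2)) {
      nm <- names(cl)
      score[nm] <- score[nm] + factorial(length(cl) - 1)
    }
  }
  deg <- igraph::degree(g)
  out <- tibble::tibble(feature_id = names(score), mcc = unname(score),
                        degree = unname(deg[names(score)]))
  out <- dplyr::arrange(out, dplyr::desc(.data$mcc), dplyr::desc(.data$degree),
                        .data$feature_id)
  utils::head(out, top_n)
}

#' Export a co-abundance network as GraphML
#'
#' Nodes carry the CAG label and mean relative abundance; edges exist where
#' `|r|` strictly exceeds the partition threshold and carry the correlation
#' and its sign.
#'
#' @param network a `correlation_network`.
#' @param partition a [cluster_cags()] result (also supplies the threshold).
#' @param path output file.
#' @param table optional [feature_table()] for node mean abundances.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(network, partition, path, table = NULL) {
  stopifnot(inherits(network, "correlation_network"),
            inherits(partition, "cag_partition"))
  ids <- network$feature_ids
  r <- network$r
  adj <- abs(r) > partition$threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  asg <- partition$assignment
  igraph::V(g)$cag <- asg$cag[match(ids, asg$feature_id)]
  if (!is.null(table)) {
    igraph::V(g)$mean_abundance <-
      rowMeans(relative_abundance(table)$counts)[ids]
  }
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    rv <- r[cbind(el[, 1], el[, 2])]
    igraph::E(g)$r <- rv
    igraph::E(g)$sign <- ifelse(rv >= 0, "positive", "negative")
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
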