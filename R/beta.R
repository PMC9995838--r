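#' Unweighted UniFrac distances
#'
#' Presence/absence phylogenetic beta diversity: for a pair of samples, the
#' branch length unique to one of the two communities divided by the total
#' branch length observed in either.
#'
#' @param table a [feature_table()]; features must all be tips of `tree` and
#'   every sample must contain at least one feature.
#' @param tree rooted `phylo` with branch lengths; extra tips are pruned.
#' @return a `dist` object over samples with values in `[0, 1]`.
#' @export
unweighted_unifrac <- function(table, tree) {
  stopifnot(inherits(table, "feature_table"), inherits(tree, "phylo"))
  feats <- rownames(table$counts)
  missing <- setdiff(feats, tree$tip.label)
  if (length(missing) > 0) {
    stop("feature(s) not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  empty <- colSums(table$counts > 0) == 0
  if (any(empty)) {
    stop("empty sample(s): ", paste(colnames(table$counts)[empty], collapse = ", "),
         call. = FALSE)
  }
  tree <- ape::keep.tip(tree, feats)
  presence <- (table$counts > 0)[match(tree$tip.label, feats), , drop = FALSE]
  B <- edge_presence_matrix(tree, presence)          # edges x samples
  w <- attr(B, "edge.length")
  observed <- as.numeric(crossprod(B, w))            # per-sample branch length
  shared <- crossprod(B * w, B)                      # pairwise shared length
  union <- outer(observed, observed, "+") - shared
  d <- (union - shared) / union
  d[union == 0] <- 0
  dimnames(d) <- list(colnames(table$counts), colnames(table$counts))
  stats::as.dist(d)
}

#' Principal coordinate analysis (classical MDS)
#'
#' Double-centers `-d^2 / 2` and eigendecomposes it; axes are ordered by
#' eigenvalue, negative eigenvalues are reported but their axes dropped.
#'
#' @param d a `dist` or square symmetric distance matrix with labels.
#' @param k number of axes requested; reduced with a warning if fewer positive
#'   eigenvalues exist.
#' @return object of class `pcoa_ord`: list with `points` (tibble of
#'   `sample_id` and `Axis1..Axisk`), `eigenvalues` (all, including any
#'   negatives) and `var_explained` (per returned axis, relative to the sum of
#'   positive eigenvalues).
#' @export
pcoa_ordination <- function(d, k = 2) {
  dm <- as.matrix(d)
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("s", seq_len(nrow(dm)))
  n <- nrow(dm)
  G <- -0.5 * dm^2
  H <- diag(n) - matrix(1 / n, n, n)
  B <- H %*% G %*% H
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- eig$values > sqrt(.Machine$double.eps) * abs(eig$values[1])
  n_pos <- sum(pos)
  if (n_pos == 0) {
    k_use <- 1
    pts <- matrix(0, n, 1)
  } else {
    if (k > n_pos) {
      warning("only ", n_pos, " positive eigenvalue(s); returning ", n_pos,
              " axes", call. = FALSE)
      k <- n_pos
    }
    k_use <- k
    pts <- eig$vectors[, seq_len(k_use), drop = FALSE] %*%
      diag(sqrt(eig$values[seq_len(k_use)]), k_use)
  }
  colnames(pts) <- paste0("Axis", seq_len(k_use))
  ve <- if (n_pos > 0) eig$values[seq_len(k_use)] / sum(eig$values[pos]) else rep(0, k_use)
  structure(list(
    points = dplyr::bind_cols(tibble::tibble(sample_id = rownames(dm)),
                              tibble::as_tibble(pts)),
    eigenvalues = eig$values,
    var_explained = ve
  ), class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat(sprintf("<pcoa> %d samples, %d axes (%.1f%%, %.1f%% ...)\n",
              nrow(x$points), ncol(x$points) - 1,
              100 * x$var_explained[1],
              100 * ifelse(length(x$var_explained) > 1, x$var_explained[2], 0)))
  invisible(x)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the squared distances into among- and within-group sums of
#' squares and assesses the pseudo-F statistic by permuting group labels.
#' The permutation p-value uses the +1 correction and so never returns 0:
#' `p = (1 + #permuted F >= observed F) / (1 + n_perm)`.
#'
#' @param d `dist` or square symmetric distance matrix.
#' @param groups group labels, at least 2 groups with at least 2 members each.
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer seed.
#' @return object of class `permanova_fit` with elements `pseudo_f`, `p_value`,
#'   `df_among`, `df_within`, `ss_among`, `ss_within`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  dm <- as.matrix(d)
  groups <- as.character(groups)
  n <- nrow(dm)
  stopifnot(length(groups) == n)
  if (n_perm < 99) stop("use at least 99 permutations", call. = FALSE)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 members: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  d2 <- dm^2
  if (all(d2 == 0)) stop("all distances are zero", call. = FALSE)
  ss_tot <- sum(d2) / (2 * n)
  a <- length(sizes)
  ss_within <- function(lab) {
    s <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  f_stat <- function(lab) {
    ssw <- ss_within(lab)
    ((ss_tot - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(groups)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (f_stat(sample(groups)) >= f_obs) exceed <- exceed + 1L
  }
  ssw <- ss_within(groups)
  structure(list(pseudo_f = f_obs, p_value = (1 + exceed) / (1 + n_perm),
                 df_among = a - 1, df_within = n - a,
                 ss_among = ss_tot - ssw, ss_within = ssw, n_perm = n_perm),
            class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f (df %d, %d), p = %.4g [%d permutations]\n",
              x$pseudo_f, x$df_among, x$df_within, x$p_value, x$n_perm))
  invisible(x)
}

#' Two-group Wilcoxon rank-sum comparison
#'
#' Two-sided rank-sum test: exact when both groups have 20 or fewer
#' observations and no ties are present, otherwise the normal approximation
#' with tie correction.
#'
#' @param values numeric per-sample statistic.
#' @param groups vector with exactly two distinct labels.
#' @return tibble with `statistic` (W), `p_value` and `method`.
#' @export
compare_groups_wilcoxon <- function(values, groups) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required", call. = FALSE)
  x <- values[groups == lv[1]]
  y <- values[groups == lv[2]]
  if (length(x) == 0 || length(y) == 0) stop("a group is empty", call. = FALSE)
  use_exact <- min(length(x), length(y)) <= 20 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact)
  )
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = if (use_exact) "exact" else "normal approximation")
}
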