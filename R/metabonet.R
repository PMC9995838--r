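#' Log-normalize a metabolite intensity matrix
#'
#' Elementwise log10 of strictly positive intensities followed by
#' per-metabolite standardization (zero mean, unit variance), the scale on
#' which the correlation network is built. Zero-variance metabolites after the
#' log are flagged degenerate (set to 0 with a warning).
#'
#' @param m numeric matrix, samples x metabolites, with dimnames; all values
#'   strictly positive.
#' @return standardized matrix with attribute `degenerate` naming flagged
#'   metabolites.
#' @export
log_normalize <- function(m) {
  m <- as.matrix(m)
  bad <- which(!(m > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(utils::head(bad, 10), 1, function(ij) {
      paste0("[", rownames(m)[ij[1]] %||% ij[1], ", ",
             colnames(m)[ij[2]] %||% ij[2], "]")
    })
    stop("non-positive intensities at: ", paste(cells, collapse = " "),
         if (nrow(bad) > 10) " ..." else "", call. = FALSE)
  }
  lg <- log10(m)
  sdv <- apply(lg, 2, stats::sd)
  degenerate <- colnames(lg)[sdv == 0]
  if (length(degenerate) > 0) {
    warning("zero-variance metabolite(s) after log: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
    sdv[sdv == 0] <- 1
  }
  out <- sweep(sweep(lg, 2, colMeans(lg)), 2, sdv, "/")
  attr(out, "degenerate") <- degenerate
  out
}

#' Choose a soft-threshold power by scale-free fit
#'
#' For each candidate power, the adjacency is `|corr|^beta`; connectivities
#' are binned and the scale-free topology fit is the R-squared of
#' `log10 p(k)` on `log10 k` across occupied bins. Returns the smallest power
#' reaching `target_r2`, falling back (with a warning) to the power with the
#' best fit when none qualifies.
#'
#' @param corr metabolite correlation matrix.
#' @param powers integer grid (default 1:20).
#' @param target_r2 required scale-free fit (default 0.8).
#' @param n_bins connectivity histogram bins.
#' @return list `beta`, `fit` (tibble power/r_squared/mean_k).
#' @export
soft_threshold_select <- function(corr, powers = 1:20, target_r2 = 0.8,
                                  n_bins = 10) {
  corr <- as.matrix(corr)
  off <- abs(corr[upper.tri(corr)])
  if (length(unique(round(off, 12))) == 1 && off[1] > 0) {
    stop("degenerate correlation matrix (all off-diagonal values equal)",
         call. = FALSE)
  }
  fit <- purrr::map_dfr(powers, function(b) {
    a <- abs(corr)^b
    diag(a) <- 0
    k <- colSums(a)
    tibble::tibble(power = b, r_squared = scale_free_r2(k, n_bins),
                   mean_k = mean(k))
  })
  ok <- fit$power[!is.na(fit$r_squared) & fit$r_squared >= target_r2]
  if (length(ok) > 0) return(list(beta = min(ok), fit = fit))
  warning("no power reaches scale-free fit R^2 >= ", target_r2,
          "; using the best fit", call. = FALSE)
  best <- fit$power[which.max(fit$r_squared)]
  list(beta = best, fit = fit)
}

scale_free_r2 <- function(k, n_bins = 10) {
  if (all(k <= 0) || stats::sd(k) == 0) return(NA_real_)
  cuts <- cut(k, n_bins)
  pk <- tapply(k, cuts, length) / length(k)
  km <- tapply(k, cuts, mean)
  keep <- !is.na(pk) & pk > 0 & !is.na(km) & km > 0
  if (sum(keep) < 3) return(NA_real_)
  stats::cor(log10(km[keep]), log10(pk[keep]))^2
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `TOM_ii = 1`; the module-detection dissimilarity is `1 - TOM`.
#'
#' @param adjacency symmetric matrix in `[0, 1]` with zero diagonal.
#' @return TOM matrix (symmetric, values in `[0, 1]`, unit diagonal).
#' @export
tom <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (any(a < 0) || any(a > 1)) stop("adjacency values must lie in [0, 1]",
                                     call. = FALSE)
  diag(a) <- 0
  k <- colSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  t <- num / den
  diag(t) <- 1
  dimnames(t) <- dimnames(adjacency)
  t
}

# ordered WGCNA-style module color labels
.module_colors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow", "tan",
                    "salmon", "cyan", "midnightblue", "lightcyan")

#' Cluster metabolites into modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut at a fixed
#' height; clusters smaller than `min_module_size` are merged into their
#' nearest (lowest mean dissimilarity) large module, or labeled `"grey"` when
#' no large module exists. Modules are named by WGCNA-style colors in
#' decreasing size order.
#'
#' @param diss dissimilarity matrix (`1 - TOM`).
#' @param min_module_size smallest allowed module (default 5).
#' @param cut_height dendrogram cut height (default 0.5).
#' @return tibble `metabolite_id`, `module`.
#' @export
cluster_modules <- function(diss, min_module_size = 5, cut_height = 0.5) {
  diss <- as.matrix(diss)
  ids <- rownames(diss) %||% paste0("m", seq_len(nrow(diss)))
  if (nrow(diss) < min_module_size) {
    return(tibble::tibble(metabolite_id = ids,
                          module = rep("grey", nrow(diss))))
  }
  ord <- order(ids)
  diss <- diss[ord, ord]; ids <- ids[ord]
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  large <- as.integer(names(sizes)[sizes >= min_module_size])
  small <- setdiff(unique(cl), large)
  for (s in small) {
    if (length(large) == 0) { cl[cl == s] <- 0L; next }
    md <- vapply(large, function(g) {
      mean(diss[cl == s, cl == g, drop = FALSE])
    }, numeric(1))
    cl[cl == s] <- large[which.min(md)]
  }
  lab <- rep("grey", length(cl))
  if (length(large) > 0) {
    ord_mod <- large[order(-as.vector(table(factor(cl, levels = large))))]
    colors <- rep(.module_colors, length.out = length(ord_mod))
    for (i in seq_along(ord_mod)) lab[cl == ord_mod[i]] <- colors[i]
  }
  tibble::tibble(metabolite_id = ids, module = lab)
}

#' Module eigenvector (eigengene) of one module
#'
#' Leading principal component of the standardized intensities, returned as
#' standardized per-sample scores with sign fixed to correlate positively with
#' the module's mean profile.
#'
#' @param m_std standardized intensity matrix (samples x metabolites of one
#'   module, >= 2 metabolites, not all zero-variance).
#' @return list `scores` (named, mean 0 / sd 1), `var_explained` (fraction of
#'   module variance carried by the component).
#' @export
module_eigenvector <- function(m_std) {
  m_std <- as.matrix(m_std)
  if (ncol(m_std) < 2) stop("a module needs at least 2 metabolites", call. = FALSE)
  if (all(apply(m_std, 2, stats::sd) == 0)) {
    stop("zero-variance module", call. = FALSE)
  }
  sv <- svd(m_std)
  scores <- sv$u[, 1]
  if (stats::cor(scores, rowMeans(m_std)) < 0) scores <- -scores
  scores <- as.vector(scale(scores))
  names(scores) <- rownames(m_std)
  list(scores = scores, var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Full metabolite module pipeline
#'
#' [log_normalize()] -> Pearson correlation -> [soft_threshold_select()] ->
#' adjacency `|r|^beta` (unsigned network) -> [tom()] -> [cluster_modules()]
#' -> per-module [module_eigenvector()].
#'
#' @param m samples x metabolites positive intensity matrix.
#' @param powers,target_r2 passed to [soft_threshold_select()].
#' @param min_module_size,cut_height passed to [cluster_modules()].
#' @return object of class `module_set`: list with `assignment` (tibble),
#'   `eigenvectors` (samples x modules matrix, grey excluded),
#'   `var_explained` (per module), `beta` and `fit`.
#' @export
metabolite_modules <- function(m, powers = 1:20, target_r2 = 0.8,
                               min_module_size = 5, cut_height = 0.5) {
  ms <- log_normalize(m)
  corr <- stats::cor(ms)
  st <- soft_threshold_select(corr, powers, target_r2)
  a <- abs(corr)^st$beta
  diag(a) <- 0
  d <- 1 - tom(a)
  assignment <- cluster_modules(d, min_module_size, cut_height)
  mods <- setdiff(unique(assignment$module), "grey")
  eig <- NULL; ve <- NULL
  if (length(mods) > 0) {
    eig <- sapply(mods, function(md) {
      ids <- assignment$metabolite_id[assignment$module == md]
      module_eigenvector(ms[, ids, drop = FALSE])$scores
    })
    ve <- vapply(mods, function(md) {
      ids <- assignment$metabolite_id[assignment$module == md]
      module_eigenvector(ms[, ids, drop = FALSE])$var_explained
    }, numeric(1))
    rownames(eig) <- rownames(ms)
  }
  structure(list(assignment = assignment, eigenvectors = eig,
                 var_explained = ve, beta = st$beta, fit = st$fit),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> beta = %d; %d modules (+grey): %s\n", x$beta,
              length(x$var_explained),
              paste(names(x$var_explained), collapse = ", ")))
  invisible(x)
}

#' Correlate module eigenvectors with genus abundances
#'
#' Pearson correlation between each module eigenvector and each genus relative
#' abundance over the shared samples, with two-sided p-values and BH
#' adjustment across the whole matrix.
#'
#' @param modules a [metabolite_modules()] result.
#' @param genus_table a [feature_table()] at genus level.
#' @return tibble `module`, `feature_id`, `r`, `p_value`, `q_value`.
#' @export
module_taxon_correlation <- function(modules, genus_table) {
  stopifnot(inherits(modules, "module_set"),
            inherits(genus_table, "feature_table"))
  if (is.null(modules$eigenvectors)) stop("no non-grey module", call. = FALSE)
  rel <- relative_abundance(genus_table)$counts
  shared <- intersect(rownames(modules$eigenvectors), colnames(rel))
  if (length(shared) < 5) stop("fewer than 5 shared samples", call. = FALSE)
  eig <- modules$eigenvectors[shared, , drop = FALSE]
  rel <- rel[, shared, drop = FALSE]
  out <- tidyr::expand_grid(module = colnames(eig), feature_id = rownames(rel))
  stats_df <- purrr::map2_dfr(out$module, out$feature_id, function(md, f) {
    ct <- stats::cor.test(eig[, md], rel[f, ])
    tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- dplyr::bind_cols(out, stats_df)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Pairwise Spearman correlations between two tables
#'
#' Spearman rank correlation (average ranks for ties) for every column pair
#' of `x_table` and `y_table` over their shared samples, with t-approximation
#' p-values and BH adjustment across all pairs. Supports taxa x metabolites,
#' taxa x cytokines and cytokines x phenotype screens. Constant variables are
#' flagged (`rho` NA).
#'
#' @param x_table,y_table numeric matrices/data frames, samples x variables,
#'   with sample rownames.
#' @return tibble `x`, `y`, `rho`, `p_value`, `q_value`, `flagged`.
#' @export
pairwise_spearman <- function(x_table, y_table) {
  x <- as.matrix(x_table); y <- as.matrix(y_table)
  shared <- intersect(rownames(x), rownames(y))
  if (length(shared) < 5) stop("fewer than 5 shared samples", call. = FALSE)
  x <- x[shared, , drop = FALSE]; y <- y[shared, , drop = FALSE]
  n <- length(shared)
  rx <- apply(x, 2, rank); ry <- apply(y, 2, rank)
  rho <- suppressWarnings(stats::cor(rx, ry))
  const_x <- apply(x, 2, function(v) stats::sd(v) == 0)
  const_y <- apply(y, 2, function(v) stats::sd(v) == 0)
  out <- tidyr::expand_grid(x = colnames(x) %||% paste0("x", seq_len(ncol(x))),
                            y = colnames(y) %||% paste0("y", seq_len(ncol(y))))
  out$rho <- as.vector(t(rho))
  out$flagged <- as.vector(t(outer(const_x, const_y, "|")))
  out$rho[out$flagged] <- NA_real_
  tval <- out$rho * sqrt((n - 2) / pmax(1 - out$rho^2, .Machine$double.eps))
  out$p_value <- 2 * stats::pt(-abs(tval), n - 2)
  out$q_value <- NA_real_
  ok <- !out$flagged
  out$q_value[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  out
}
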