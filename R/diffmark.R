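#' Kruskal-Wallis screen for class-associated features
#'
#' Per-feature Kruskal-Wallis test (equivalent to the rank-sum test for two
#' classes) on relative abundances; features with `p < alpha` survive.
#' Constant features get p = 1.
#'
#' @param table a [feature_table()].
#' @param classes per-sample labels with two levels, each with >= 3 samples.
#' @param alpha screening level (default 0.05).
#' @return tibble `feature_id`, `p_value`, `keep`.
#' @export
kw_screen <- function(table, classes, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  classes <- factor(classes)
  if (nlevels(classes) != 2) stop("exactly two classes required", call. = FALSE)
  if (any(base::table(classes) < 3)) stop("each class needs at least 3 samples",
                                    call. = FALSE)
  rel <- if (inherits(table, "relabund_table")) table$counts else
    relative_abundance(table)$counts
  p <- apply(rel, 1, function(x) {
    if (stats::sd(x) == 0) return(1)
    stats::kruskal.test(x, classes)$p.value
  })
  tibble::tibble(feature_id = rownames(rel), p_value = unname(p),
                 keep = unname(p) < alpha)
}

#' LEfSe-style linear discriminant effect sizes
#'
#' Bootstrapped effect-size ranking of (pre-screened) features. Abundances are
#' put on the conventional per-million scale; per bootstrap a fraction of each
#' class is subsampled, a one-dimensional linear discriminant is fitted on
#' standardized abundances (within-class scatter ridge-regularized by 1e-6),
#' and each feature's effect size is the absolute class-mean difference
#' projected on the discriminant, mapped back to original abundance units,
#' floored at 1, and log10-transformed. Scores are averaged over bootstraps
#' and signed toward the enriched class (positive = first class level). A
#' feature passes when its screening p < 0.05 AND |score| > 2.
#'
#' @param table a [feature_table()] restricted to screened features (>= 2).
#' @param classes per-sample two-level labels.
#' @param n_boot bootstrap rounds (default 30).
#' @param subsample_fraction per-class subsample fraction (default 2/3).
#' @param seed optional integer seed.
#' @param p_values optional per-feature screening p-values aligned with the
#'   table; computed by [kw_screen()] when NULL.
#' @return tibble of class `effect_size_result`: `feature_id`, `kw_p`,
#'   `enriched_class`, `lda_score`, `passes`.
#' @export
lda_effect_size <- function(table, classes, n_boot = 30,
                            subsample_fraction = 2 / 3, seed = NULL,
                            p_values = NULL) {
  stopifnot(inherits(table, "feature_table"))
  classes <- factor(classes)
  if (nlevels(classes) != 2) stop("exactly two classes required", call. = FALSE)
  rel <- if (inherits(table, "relabund_table")) table$counts else
    relative_abundance(table)$counts
  if (nrow(rel) < 2) stop("need at least 2 features", call. = FALSE)
  X <- t(rel) * 1e6                       # samples x features, per-million units
  lv <- levels(classes)
  if (is.null(p_values)) p_values <- kw_screen(table, classes)$p_value
  if (!is.null(seed)) set.seed(seed)

  scores <- matrix(NA_real_, n_boot, ncol(X))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(lv, function(l) {
      pool <- which(classes == l)
      sample(pool, max(2, ceiling(subsample_fraction * length(pool))))
    }), use.names = FALSE)
    Xi <- X[idx, , drop = FALSE]
    ci <- classes[idx]
    mu <- colMeans(Xi)
    sdv <- apply(Xi, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(Xi, 2, mu), 2, sdv, "/")
    m1 <- colMeans(Xs[ci == lv[1], , drop = FALSE])
    m2 <- colMeans(Xs[ci == lv[2], , drop = FALSE])
    sw <- (stats::cov(Xs[ci == lv[1], , drop = FALSE]) * (sum(ci == lv[1]) - 1) +
           stats::cov(Xs[ci == lv[2], , drop = FALSE]) * (sum(ci == lv[2]) - 1)) /
      (length(ci) - 2)
    w <- solve(sw + diag(1e-6, ncol(Xs)), m1 - m2)
    w <- w / sqrt(sum(w^2))
    delta <- abs(sum(w * (m1 - m2)))
    eff <- abs(w) * delta * sdv           # back to original (per-million) units
    scores[b, ] <- log10(pmax(eff, 1))
  }
  mean_score <- colMeans(scores)
  class_means <- rowsum(X, classes) / as.vector(base::table(classes))
  enriched <- ifelse(class_means[lv[1], ] >= class_means[lv[2], ], lv[1], lv[2])
  signed <- ifelse(enriched == lv[1], mean_score, -mean_score)
  out <- tibble::tibble(feature_id = colnames(X), kw_p = p_values,
                        enriched_class = unname(enriched),
                        lda_score = unname(signed),
                        passes = p_values < 0.05 & abs(signed) > 2)
  class(out) <- c("effect_size_result", class(out))
  out
}

#' Random-forest biomarker ranking with out-of-bag ROC
#'
#' Trains a random forest on relative abundances, ranks features by
#' permutation importance (mean decrease in accuracy), and computes the ROC
#' curve and AUC from out-of-bag class votes (no extra held-out split is
#' carved from these small cohorts).
#'
#' @param table a [feature_table()].
#' @param classes per-sample two-level labels, each class >= 5 samples.
#' @param n_trees forest size (study convention 1000).
#' @param top_k biomarkers to report.
#' @param seed optional integer seed.
#' @return object of class `rf_biomarkers`: list with `ranking` (tibble
#'   `feature_id`, `importance`), `auc`, `roc` (tibble of
#'   specificity/sensitivity points), `votes` and the positive class label.
#' @export
rf_biomarkers <- function(table, classes, n_trees = 1000, top_k = 10,
                          seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  classes <- factor(classes)
  if (nlevels(classes) != 2) stop("exactly two classes required", call. = FALSE)
  sizes <- base::table(classes)
  if (any(sizes < 5)) stop("each class needs at least 5 samples", call. = FALSE)
  if (max(sizes) / min(sizes) > 10) {
    warning("severe class imbalance (> 10:1)", call. = FALSE)
  }
  rel <- if (inherits(table, "relabund_table")) table$counts else
    relative_abundance(table)$counts
  X <- t(rel)
  if (!is.null(seed)) set.seed(seed)
  fit <- randomForest::randomForest(x = X, y = classes, ntree = n_trees,
                                    importance = TRUE)
  imp <- randomForest::importance(fit, type = 1)[, 1]
  ranking <- tibble::tibble(feature_id = names(imp), importance = unname(imp))
  ranking <- dplyr::arrange(ranking, dplyr::desc(.data$importance),
                            .data$feature_id)
  positive <- levels(classes)[2]
  votes <- fit$votes[, positive]
  roc <- pROC::roc(response = classes, predictor = votes,
                   levels = levels(classes), direction = "<", quiet = TRUE)
  structure(list(
    ranking = utils::head(ranking, top_k),
    auc = as.numeric(pROC::auc(roc)),
    roc = tibble::tibble(specificity = roc$specificities,
                         sensitivity = roc$sensitivities),
    votes = votes, positive_class = positive
  ), class = "rf_biomarkers")
}

#' @export
print.rf_biomarkers <- function(x, ...) {
  cat(sprintf("<rf_biomarkers> AUC = %.4f (OOB votes, positive = %s)\n",
              x$auc, x$positive_class))
  print(x$ranking)
  invisible(x)
}
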