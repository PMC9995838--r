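#' Cross-validated variance in the phenotype explained by the microbiota
#'
#' Repeats, `n_rounds` times: split samples into train/test (stratified by
#' breed when available), run [two_part_scan()] on the training samples, and
#' for each significance threshold select the features with `p_final` below
#' it; fit a ridge regression of the adjusted phenotype on the selected
#' features' presence indicators and (zero-filled) log10 abundances, with the
#' penalty chosen by generalized cross-validation inside the training set; and
#' score held-out variance explained `1 - SSE / SStot` on the test samples.
#' Rounds where no feature is selected contribute a 0 for that threshold.
#'
#' The phenotype is covariate-adjusted once on the full cohort (the
#' correction step precedes the microbial model); the train/test machinery
#' applies to the microbial model only.
#'
#' @param table a [feature_table()] of counts.
#' @param y phenotype per sample.
#' @param covariates optional covariate data frame (breed/sex); the `breed`
#'   column, when present, stratifies the split.
#' @param thresholds significance grid on `p_final` (non-empty).
#' @param n_rounds number of train/test rounds (>= 2; study convention 100).
#' @param train_fraction fraction of each stratum used for training.
#' @param seed optional integer seed; the curve is deterministic given it.
#' @param lambda ridge penalty grid searched by GCV.
#' @param allocation passed to [two_part_scan()].
#' @return tibble of class `ve_curve`: `threshold`, `mean_ve`, `sd_ve`,
#'   `n_rounds`, with the full rounds-by-thresholds matrix in attribute
#'   `"rounds"`. Held-out VE can be negative; values are reported as computed
#'   (clip at 0 for display).
#' @export
variance_explained_cv <- function(table, y, covariates = NULL,
                                  thresholds = c(5e-4, 1e-3, 1e-2, 5e-2),
                                  n_rounds = 100, train_fraction = 0.8,
                                  seed = NULL, lambda = 10^seq(-2, 4, length.out = 25),
                                  allocation = "bonferroni") {
  stopifnot(inherits(table, "feature_table"))
  if (length(thresholds) == 0) stop("empty threshold grid", call. = FALSE)
  if (n_rounds < 2) stop("n_rounds must be at least 2", call. = FALSE)
  counts <- table$counts
  n <- ncol(counts)
  y_adj <- if (is.null(covariates)) y - mean(y) else
    residualize_covariates(y, covariates)
  rel <- relative_abundance(table)$counts
  strat <- if (!is.null(covariates) && "breed" %in% names(as.data.frame(covariates))) {
    as.character(as.data.frame(covariates)$breed)
  } else rep("all", n)

  if (!is.null(seed)) set.seed(seed)
  ve <- matrix(NA_real_, n_rounds, length(thresholds))
  for (rd in seq_len(n_rounds)) {
    train <- unlist(lapply(split(seq_len(n), strat), function(idx) {
      sample(idx, max(2, floor(train_fraction * length(idx))))
    }), use.names = FALSE)
    test <- setdiff(seq_len(n), train)
    if (length(test) < 2) stop("train_fraction leaves too few test samples",
                               call. = FALSE)
    tr_tab <- ft_subset(table, samples = train)
    scan <- suppressMessages(
      two_part_scan(tr_tab, y_adj[train], covariates = NULL,
                    allocation = allocation)
    )
    for (k in seq_along(thresholds)) {
      sel <- scan$feature_id[scan$testable & scan$p_final < thresholds[k]]
      ve[rd, k] <- ridge_holdout_ve(sel, counts, rel, y_adj, train, test, lambda)
    }
  }
  out <- tibble::tibble(threshold = thresholds,
                        mean_ve = colMeans(ve),
                        sd_ve = apply(ve, 2, stats::sd),
                        n_rounds = n_rounds)
  attr(out, "rounds") <- ve
  class(out) <- c("ve_curve", class(out))
  out
}

# Held-out R^2 of a ridge model on [presence, filled log10 abundance] of the
# selected features; GCV over the lambda grid inside train.
ridge_holdout_ve <- function(sel, counts, rel, y_adj, train, test, lambda) {
  if (length(sel) == 0) return(0)
  build_x <- function(idx) {
    pres <- t(counts[sel, idx, drop = FALSE] > 0) * 1
    qm <- t(rel[sel, idx, drop = FALSE])
    colnames(pres) <- paste0("p_", sel)
    colnames(qm) <- paste0("q_", sel)
    list(pres = pres, q = qm)
  }
  tr <- build_x(train); te <- build_x(test)
  # center log10 abundance on the training present-sample mean; absences sit
  # at 0 so the presence column alone carries the on/off contrast (the same
  # decomposition the two-part model tests)
  fills <- vapply(seq_along(sel), function(j) {
    v <- tr$q[, j][tr$q[, j] > 0]
    if (length(v) == 0) 0 else mean(log10(v))
  }, numeric(1))
  fill_log <- function(b) {
    for (j in seq_along(sel)) {
      pos <- b$q[, j] > 0
      b$q[pos, j] <- log10(b$q[pos, j]) - fills[j]
      b$q[!pos, j] <- 0
    }
    b
  }
  tr <- fill_log(tr); te <- fill_log(te)
  Xtr <- cbind(tr$pres, tr$q); Xte <- cbind(te$pres, te$q)
  keep <- apply(Xtr, 2, function(v) stats::sd(v) > 0)
  if (!any(keep)) return(0)
  Xtr <- Xtr[, keep, drop = FALSE]; Xte <- Xte[, keep, drop = FALSE]
  ytr <- y_adj[train]; yte <- y_adj[test]
  fit <- MASS::lm.ridge(ytr ~ Xtr, lambda = lambda)
  co <- stats::coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1)
  best <- which.min(fit$GCV)
  pred <- drop(cbind(1, Xte) %*% co[best, ])
  1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
}

#' @export
print.ve_curve <- function(x, ...) {
  cat("<variance-explained curve>\n")
  df <- as.data.frame(x)
  df$mean_ve <- sprintf("%.3f", df$mean_ve)
  print(df, row.names = FALSE)
  invisible(x)
}
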