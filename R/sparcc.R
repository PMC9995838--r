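#' SparCC compositional correlation inference
#'
#' Estimates correlations between underlying (basis) abundances from
#' compositional count data. Log-ratio variances
#' `t_ij = var(log x_i - log x_j)` are computed on per-sample fractions (after
#' adding a pseudocount), basis variances are solved from the SparCC linear
#' system under a sparsity assumption, and correlations follow as
#' `rho_ij = (w_i^2 + w_j^2 - t_ij) / (2 w_i w_j)`, clipped to `[-1, 1]`.
#' Strongly correlated pairs violate the sparsity assumption, so the
#' most-correlated pair above `exclusion_threshold` is iteratively removed
#' from the variance system and the basis variances re-solved, for up to
#' `n_exclusion_rounds` rounds.
#'
#' @param table a [feature_table()] of counts with at least 4 features (the
#'   basis-variance system is not solvable below that) and no feature that is
#'   zero in every sample.
#' @param n_exclusion_rounds maximum pair-exclusion iterations.
#' @param exclusion_threshold absolute correlation above which a pair is
#'   excluded from the variance system.
#' @param pseudocount added to every count before forming fractions (zeros
#'   cannot enter a log-ratio); 0.5 by default.
#' @return object of class `correlation_network`: list with `feature_ids`,
#'   symmetric correlation matrix `r` (unit diagonal), `p` (NULL until
#'   [sparcc_bootstrap()] is run) and `method = "sparcc"`.
#' @seealso [sparcc_bootstrap()], [spearman_network()]
#' @export
sparcc <- function(table, n_exclusion_rounds = 10, exclusion_threshold = 0.1,
                   pseudocount = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  counts <- table$counts
  D <- nrow(counts)
  if (D < 4) stop("SparCC needs at least 4 features", call. = FALSE)
  allzero <- rowSums(counts) == 0
  if (any(allzero)) {
    stop("feature(s) zero in every sample: ",
         paste(rownames(counts)[allzero], collapse = ", "), call. = FALSE)
  }
  fr <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  lf <- t(log(fr))                       # samples x features
  V <- stats::cov(lf)
  vars <- diag(V)
  TT <- outer(vars, vars, "+") - 2 * V   # log-ratio variance matrix
  M <- matrix(TRUE, D, D); diag(M) <- FALSE

  solve_rho <- function(M) {
    A <- M * 1
    diag(A) <- rowSums(M)
    t_i <- rowSums(TT * M)
    w2 <- tryCatch(solve(A, t_i), error = function(e) stats::lsfit(A, t_i, intercept = FALSE)$coefficients)
    w2 <- pmax(w2, 1e-10)
    w <- sqrt(w2)
    rho <- (outer(w2, w2, "+") - TT) / (2 * outer(w, w))
    rho[rho > 1] <- 1; rho[rho < -1] <- -1
    diag(rho) <- 1
    rho
  }
  rho <- solve_rho(M)
  for (r in seq_len(n_exclusion_rounds)) {
    cand <- abs(rho) * M
    diag(cand) <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    idx <- which(cand == mx, arr.ind = TRUE)[1, ]
    # keep every feature attached to at least 3 partners so the system stays
    # well conditioned
    if (sum(M[idx[1], ]) <= 3 || sum(M[idx[2], ]) <= 3) break
    M[idx[1], idx[2]] <- M[idx[2], idx[1]] <- FALSE
    rho <- solve_rho(M)
  }
  dimnames(rho) <- list(rownames(counts), rownames(counts))
  structure(list(feature_ids = rownames(counts), r = rho, p = NULL,
                 method = "sparcc"),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("<correlation_network:%s> %d features; |r| max %.3f%s\n",
              x$method, length(x$feature_ids), max(abs(off)),
              if (is.null(x$p)) "" else "; bootstrap p attached"))
  invisible(x)
}

#' Bootstrap significance for a correlation network
#'
#' Null distributions are built by independently permuting each feature's
#' counts across samples (destroying between-feature association while keeping
#' marginals), re-estimating the correlation matrix, and counting how often
#' the null absolute correlation reaches the observed one:
#' `p = (1 + #exceedances) / (1 + n_boot)`, so p lies in
#' `[1/(n_boot+1), 1]`.
#'
#' @param table the [feature_table()] the network was estimated from.
#' @param network a `correlation_network` from [sparcc()]; recomputed if NULL.
#' @param n_boot number of null resamples (>= 20); the study convention is 100.
#' @param seed optional integer seed; results are deterministic given it.
#' @param ... passed on to [sparcc()].
#' @return the network with a symmetric matrix `p` of two-sided p-values
#'   (diagonal NA).
#' @export
sparcc_bootstrap <- function(table, network = NULL, n_boot = 100, seed = NULL, ...) {
  if (n_boot < 20) stop("n_boot must be at least 20", call. = FALSE)
  if (is.null(network)) network <- sparcc(table, ...)
  if (!is.null(seed)) set.seed(seed)
  r_obs <- abs(network$r)
  exceed <- matrix(0, nrow(r_obs), ncol(r_obs))
  counts <- table$counts
  for (b in seq_len(n_boot)) {
    shuf <- t(apply(counts, 1, sample))
    rownames(shuf) <- rownames(counts); colnames(shuf) <- colnames(counts)
    rb <- sparcc(feature_table(shuf), ...)$r
    exceed <- exceed + (abs(rb) >= r_obs)
  }
  p <- (1 + exceed) / (1 + n_boot)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(network$r)
  network$p <- p
  network
}

#' Spearman correlation network on relative abundances
#'
#' Pairwise Spearman rank correlations (average ranks for ties) between
#' features, computed on per-sample proportions. Constant features have
#' undefined correlations; these are reported as 0 and flagged.
#'
#' @param table a [feature_table()] with at least 2 samples.
#' @return a `correlation_network` with `method = "spearman"` and an attribute
#'   `constant_features` naming any flagged features.
#' @export
spearman_network <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (ncol(table$counts) < 2) stop("need at least 2 samples", call. = FALSE)
  rel <- if (inherits(table, "relabund_table")) table$counts else
    relative_abundance(table)$counts
  rho <- suppressWarnings(stats::cor(t(rel), method = "spearman"))
  const <- apply(rel, 1, function(x) stats::sd(x) == 0)
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  out <- structure(list(feature_ids = rownames(rel), r = rho, p = NULL,
                        method = "spearman"),
                   class = "correlation_network")
  attr(out, "constant_features") <- rownames(rel)[const]
  out
}
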