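# Closed-form simple linear regression y ~ x with two-sided t test.
# Returns a "untestable" marker instead of erroring so genome-wide scans
# proceed past degenerate features.
ols1 <- function(y, x) {
  n <- length(y)
  if (n < 3) return(list(testable = FALSE, beta = 0, p = 1, sign = 0))
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  if (sxx == 0) return(list(testable = FALSE, beta = 0, p = 1, sign = 0))
  sxy <- sum(xc * yc)
  beta <- sxy / sxx
  sse <- sum(yc^2) - beta * sxy
  df <- n - 2
  sigma2 <- max(sse, 0) / df
  if (sigma2 == 0) {
    p <- 1e-300
  } else {
    tval <- beta / sqrt(sigma2 / sxx)
    p <- max(2 * stats::pt(-abs(tval), df), 1e-300)
  }
  list(testable = TRUE, beta = beta, p = p, sign = sign(beta))
}

#' Remove breed and sex effects from the phenotype
#'
#' Fits an additive fixed-effect linear model of the phenotype on the
#' covariates and returns the residuals (zero mean). Association models
#' downstream carry no covariate terms; correction happens here, once.
#'
#' @param y numeric phenotype (e.g. market weight, kg).
#' @param covariates data frame of categorical covariates (e.g. `breed`,
#'   `sex`), one row per sample, no missing labels.
#' @return numeric vector of adjusted phenotypes.
#' @export
residualize_covariates <- function(y, covariates) {
  covariates <- as.data.frame(covariates)
  covariates$sample_id <- NULL
  if (anyNA(covariates)) stop("missing covariate label(s)", call. = FALSE)
  if (nrow(covariates) != length(y)) stop("covariate rows must match y", call. = FALSE)
  for (nm in names(covariates)) {
    tb <- table(covariates[[nm]])
    if (any(tb == 1)) {
      warning("covariate `", nm, "` has single-sample level(s): ",
              paste(names(tb)[tb == 1], collapse = ", "), call. = FALSE)
    }
    covariates[[nm]] <- factor(covariates[[nm]])
  }
  keep <- vapply(covariates, function(f) nlevels(f) > 1, logical(1))
  if (!any(keep)) return(y - mean(y))
  fit <- stats::lm(y ~ ., data = covariates[, keep, drop = FALSE])
  unname(stats::residuals(fit))
}

#' Binary (presence/absence) association
#'
#' Ordinary least squares of the adjusted phenotype on the 0/1 presence
#' indicator (`y = beta1 * b + e`), two-sided p from the t statistic. A
#' constant presence vector yields an untestable result (beta 0, p 1) rather
#' than an error.
#'
#' @param y_adj covariate-adjusted phenotype.
#' @param presence 0/1 (or logical) per sample.
#' @return list `beta`, `p`, `sign`, `testable`.
#' @export
binary_association <- function(y_adj, presence) {
  ols1(y_adj, as.numeric(presence))
}

#' Quantitative (conditional abundance) association
#'
#' Restricts to samples where the feature is present, takes
#' `q = log10(relative abundance)` (zeros never logged), and regresses the
#' adjusted phenotype on q (`y = beta2 * q + e`). Fewer than 3 present
#' samples, or constant q, yields an untestable result.
#'
#' @param y_adj covariate-adjusted phenotype.
#' @param abundance per-sample relative abundance.
#' @return list `beta`, `p`, `sign`, `testable`, `n_present`.
#' @export
quantitative_association <- function(y_adj, abundance) {
  present <- abundance > 0
  n_present <- sum(present)
  if (n_present < 3) {
    return(list(testable = FALSE, beta = 0, p = 1, sign = 0, n_present = n_present))
  }
  out <- ols1(y_adj[present], log10(abundance[present]))
  out$n_present <- n_present
  out
}

#' Combine the two components with the unweighted Z method
#'
#' Each two-sided component p is converted to a signed Z,
#' `Z_i = sign_i * qnorm(1 - p_i / 2)`, the Zs are combined unweighted,
#' `z_meta = (Z_b + Z_q) / sqrt(2)`, and converted back to a two-sided
#' meta-p. `z_meta > 0` means a positive microbe-phenotype association.
#'
#' @param p_binary,p_quant two-sided component p-values.
#' @param sign_binary,sign_quant component effect signs (+1/-1/0).
#' @return list `z_meta`, `p_meta`.
#' @export
meta_combine <- function(p_binary, sign_binary, p_quant, sign_quant) {
  zb <- sign_binary * stats::qnorm(p_binary / 2, lower.tail = FALSE)
  zq <- sign_quant * stats::qnorm(p_quant / 2, lower.tail = FALSE)
  z <- (zb + zq) / sqrt(2)
  list(z_meta = z, p_meta = min(max(2 * stats::pnorm(-abs(z)), 1e-300), 1))
}

#' Two-part microbe-phenotype association scan
#'
#' For every feature: covariate-adjust the phenotype, run the binary and
#' quantitative components and their unweighted-Z meta-analysis, take the
#' minimum of the candidate p-values, apply the allocation coefficient
#' (a Bonferroni factor equal to the number of candidate tests, capped at 1;
#' set `allocation = "minp"` for the raw minimum), record which component won
#' and its signed Z, and Benjamini-Hochberg adjust the final p-values across
#' features. Features absent from every sample are excluded with a message.
#'
#' @param table a [feature_table()] (typically genus-level, filtered).
#' @param y phenotype per sample, aligned with the table's samples.
#' @param covariates optional covariate data frame for
#'   [residualize_covariates()]; NULL mean-centers y.
#' @param allocation `"bonferroni"` (default) or `"minp"`.
#' @return tibble of class `two_part_scan`: one row per feature with
#'   `beta_binary`, `p_binary`, `beta_quant`, `p_quant`, `z_meta`, `p_meta`,
#'   `p_final`, `winning_component`, `z_signed`, `q_bh`, `n_present`,
#'   `testable`.
#' @export
two_part_scan <- function(table, y, covariates = NULL,
                          allocation = c("bonferroni", "minp")) {
  stopifnot(inherits(table, "feature_table"))
  allocation <- match.arg(allocation)
  counts <- table$counts
  if (length(y) != ncol(counts)) stop("`y` must align with samples", call. = FALSE)
  y_adj <- if (is.null(covariates)) y - mean(y) else
    residualize_covariates(y, covariates)
  rel <- if (inherits(table, "relabund_table")) counts else
    relative_abundance(table)$counts

  absent <- rowSums(counts > 0) == 0
  if (any(absent)) {
    message("excluding ", sum(absent), " feature(s) absent from every sample")
  }
  feats <- rownames(counts)[!absent]
  rows <- lapply(feats, function(f) {
    pres <- counts[f, ] > 0
    b <- binary_association(y_adj, pres)
    q <- quantitative_association(y_adj, rel[f, ])
    if (b$testable && q$testable) {
      m <- meta_combine(b$p, b$sign, q$p, q$sign)
      cand <- c(binary = b$p, quantitative = q$p, meta = m$p_meta)
    } else {
      m <- list(z_meta = NA_real_, p_meta = NA_real_)
      cand <- c(binary = if (b$testable) b$p else NA,
                quantitative = if (q$testable) q$p else NA,
                meta = NA)
      cand <- cand[!is.na(cand)]
    }
    if (length(cand) == 0) {
      return(tibble::tibble(
        feature_id = f, n_present = q$n_present,
        beta_binary = b$beta, p_binary = b$p,
        beta_quant = q$beta, p_quant = q$p,
        z_meta = m$z_meta, p_meta = m$p_meta,
        p_final = 1, winning_component = NA_character_,
        z_signed = 0, testable = FALSE))
    }
    win <- names(cand)[which.min(cand)]
    mult <- if (allocation == "bonferroni") length(cand) else 1
    p_final <- min(min(cand) * mult, 1)
    z_signed <- switch(win,
      binary = b$sign * stats::qnorm(b$p / 2, lower.tail = FALSE),
      quantitative = q$sign * stats::qnorm(q$p / 2, lower.tail = FALSE),
      meta = m$z_meta)
    tibble::tibble(
      feature_id = f, n_present = q$n_present,
      beta_binary = b$beta, p_binary = b$p,
      beta_quant = q$beta, p_quant = q$p,
      z_meta = m$z_meta, p_meta = m$p_meta,
      p_final = p_final, winning_component = win,
      z_signed = z_signed, testable = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0 || !any(out$testable)) {
    stop("no testable feature in the table", call. = FALSE)
  }
  out$q_bh <- stats::p.adjust(out$p_final, method = "BH")
  class(out) <- c("two_part_scan", class(out))
  out
}
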