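#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study design the pipeline targets: a 24-sample
#' experimental cohort plus a 79-sample validation cohort split across two
#' further breeds (55 + 24), sequencing depth 75,007 tags/sample, planted
#' correlation blocks among features (the co-abundance structure), a handful
#' of features with presence and/or conditional-abundance effects on weight,
#' additive breed and sex effects, metabolite module structure and a
#' cytokine (IL-6-like) negatively coupled to weight through a detrimental
#' taxon.
#'
#' @param n_samples_per_cohort positive integers; one breed group per entry
#'   (first = experimental cohort, rest = validation).
#' @param n_features number of OTU-like features.
#' @param depth sequencing depth (tags per sample).
#' @param block_spec list of `c(size, r)` pairs: correlation blocks planted in
#'   the log basis abundances; sizes must sum to at most `n_features`, r in
#'   (-1, 1).
#' @param causal_effects data frame `feature` (index), `beta_binary` (kg per
#'   presence), `beta_quant` (kg per log10 relative-abundance unit, centered
#'   over present samples).
#' @param covariate_effects list with `breed` (kg per breed group, recycled)
#'   and `sex` (kg added for males).
#' @param noise_sd residual weight standard deviation, kg.
#' @param metabolite_spec list `n_metabolites`, `n_modules`,
#'   `module_correlation`.
#' @param cytokine_spec named list (names = cytokine labels) of
#'   `list(feature, sign, weight_effect)`; `feature = NA` means an uncoupled,
#'   pure-noise cytokine.
#' @param baseline_weight intercept weight, kg.
#' @param seed integer seed (keep below 2^31).
#' @return a `synth_config` list, validated.
#' @export
synth_config <- function(n_samples_per_cohort = c(24, 55, 24),
                         n_features = 300,
                         depth = 75007,
                         block_spec = list(c(20, 0.8), c(15, 0.7), c(10, 0.65)),
                         causal_effects = data.frame(
                           feature = c(5, 60, 90),
                           beta_binary = c(0.15, -0.10, 0.00),
                           beta_quant = c(0.25, -0.20, -0.20)),
                         covariate_effects = list(breed = c(0, 0.49, 0.21),
                                                  sex = 0.15),
                         noise_sd = 0.2,
                         metabolite_spec = list(n_metabolites = 100,
                                                n_modules = 4,
                                                module_correlation = 0.7),
                         cytokine_spec = list(
                           `INF-g` = list(feature = NA, sign = 0, weight_effect = 0),
                           `IL-1b` = list(feature = NA, sign = 0, weight_effect = 0),
                           `IL-5` = list(feature = NA, sign = 0, weight_effect = 0),
                           `IL-6` = list(feature = 60, sign = 1, weight_effect = -0.08),
                           `IL-17` = list(feature = NA, sign = 0, weight_effect = 0),
                           `IL-22` = list(feature = NA, sign = 0, weight_effect = 0)),
                         baseline_weight = 1.4,
                         seed = 1L) {
  cfg <- list(n_samples_per_cohort = as.integer(n_samples_per_cohort),
              n_features = as.integer(n_features), depth = as.integer(depth),
              block_spec = block_spec, causal_effects = causal_effects,
              covariate_effects = covariate_effects, noise_sd = noise_sd,
              metabolite_spec = metabolite_spec, cytokine_spec = cytokine_spec,
              baseline_weight = baseline_weight, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (any(cfg$n_samples_per_cohort <= 0)) {
    stop("cohort sizes must be positive", call. = FALSE)
  }
  if (cfg$depth <= 0) stop("depth must be positive", call. = FALSE)
  sizes <- vapply(cfg$block_spec, `[`, numeric(1), 1)
  rs <- vapply(cfg$block_spec, `[`, numeric(1), 2)
  if (sum(sizes) > cfg$n_features) {
    stop("block sizes exceed n_features", call. = FALSE)
  }
  if (any(rs <= -1 | rs >= 1)) stop("block correlations must lie in (-1, 1)",
                                    call. = FALSE)
  mc <- cfg$metabolite_spec$module_correlation
  if (mc <= -1 || mc >= 1) stop("module correlation must lie in (-1, 1)",
                                call. = FALSE)
  ce <- cfg$causal_effects
  if (nrow(ce) > 0 && any(ce$feature < 1 | ce$feature > cfg$n_features)) {
    stop("causal feature index out of range", call. = FALSE)
  }
  invisible(cfg)
}

#' Generate a random feature phylogeny
#'
#' Random bifurcating rooted tree with strictly positive branch lengths and
#' tip labels matching the generator's feature identifiers.
#'
#' @param n_features number of tips (>= 2).
#' @param seed integer seed.
#' @return a rooted `phylo` object with `n_features` tips and
#'   `n_features - 1` internal nodes.
#' @export
generate_tree <- function(n_features, seed = 1L) {
  if (n_features < 2) stop("need at least 2 features for a tree", call. = FALSE)
  set.seed(seed)
  ape::rtree(n_features, rooted = TRUE,
             tip.label = sprintf("OTU%04d", seq_len(n_features)))
}

equicorr_draw <- function(n, size, r) {
  # equicorrelated normal block via common-factor construction (r >= 0) or
  # Cholesky for the general case
  if (r >= 0) {
    f <- stats::rnorm(n)
    sqrt(r) * matrix(f, n, size) +
      sqrt(1 - r) * matrix(stats::rnorm(n * size), n, size)
  } else {
    if (r < -1 / (size - 1)) {
      stop("negative block correlation below the feasibility bound -1/(size-1)",
           call. = FALSE)
    }
    sig <- matrix(r, size, size); diag(sig) <- 1
    matrix(stats::rnorm(n * size), n, size) %*% chol(sig)
  }
}

#' Generate a synthetic cohort
#'
#' Basis abundances are log-normal with the planted block correlation
#' structure; zeros come from a per-feature logistic detection model on the
#' log basis abundance (rarer features drop out more often); observed counts
#' are multinomial draws of size `depth` given the per-sample basis
#' proportions, so the data are compositional by construction. Weight is
#' baseline + breed + sex + per-feature presence and centered log10-abundance
#' effects + cytokine-mediated effects + Gaussian noise. Metabolites follow a
#' module factor model; cytokines respond linearly to the log10 abundance of
#' their coupled taxon. Everything is reproducible from the seed.
#'
#' @param config a [synth_config()].
#' @return object of class `synth_cohort`: list with `features`
#'   (a [feature_table()] whose metadata holds cohort, breed, sex, weight and
#'   a within-breed High/Low group label), `tree`, `phenotype` (tibble),
#'   `metabolites` and `cytokines` (samples x variables matrices), and
#'   `truth` (planted blocks, causal effects, module membership, cytokine
#'   couplings, per-sample signal components and the realized fraction of
#'   weight variance attributable to the microbiota).
#' @export
generate_cohort <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  validate_synth_config(config)
  set.seed(config$seed)
  D <- config$n_features
  n <- sum(config$n_samples_per_cohort)
  feature_id <- sprintf("OTU%04d", seq_len(D))
  sample_id <- sprintf("S%03d", seq_len(n))
  n_cohorts <- length(config$n_samples_per_cohort)
  breed <- rep(paste0("breed_", seq_len(n_cohorts)), config$n_samples_per_cohort)
  cohort <- rep(c("experimental", rep("validation", n_cohorts - 1))[seq_len(n_cohorts)],
                config$n_samples_per_cohort)
  sex <- sample(c("male", "female"), n, replace = TRUE)

  # features are indexed in decreasing order of expected basis abundance, so
  # planted block/causal indices refer to a predictable abundance tier;
  # correlation blocks occupy the leading features
  mu <- sort(stats::rnorm(D, 0, 1.5), decreasing = TRUE)
  Z <- matrix(stats::rnorm(n * D), n, D)
  blocks <- list()
  at <- 1
  for (bs in config$block_spec) {
    size <- bs[1]; r <- bs[2]
    idx <- seq(at, at + size - 1)
    Z[, idx] <- equicorr_draw(n, size, r)
    blocks[[length(blocks) + 1]] <- list(features = feature_id[idx], r = r)
    at <- at + size
  }
  log_basis <- sweep(Z, 2, mu, "+")

  # logistic detection: abundant features (high mu, high per-sample draw)
  # are detected more often
  det_lin <- sweep(0.8 * Z, 2, 1.0 + 0.9 * (mu - mean(mu)), "+")
  present <- matrix(stats::rbinom(n * D, 1, stats::plogis(det_lin)), n, D)
  for (i in which(rowSums(present) == 0)) present[i, which.max(mu)] <- 1

  basis <- exp(log_basis) * present
  prop <- basis / rowSums(basis)
  counts <- vapply(seq_len(n), function(i) {
    stats::rmultinom(1, config$depth, prop[i, ])[, 1]
  }, numeric(D))
  dimnames(counts) <- list(feature_id, sample_id)

  # microbial signal on weight
  signal <- numeric(n)
  ce <- config$causal_effects
  for (k in seq_len(nrow(ce))) {
    f <- ce$feature[k]
    pres <- present[, f] == 1
    qc <- numeric(n)
    if (sum(pres) > 1) {
      q <- log10(prop[pres, f])
      qc[pres] <- q - mean(q)
    }
    signal <- signal + ce$beta_binary[k] * pres + ce$beta_quant[k] * qc
  }

  # cytokines: linear response to the coupled taxon's log10 abundance
  cyt_names <- names(config$cytokine_spec)
  cytokines <- matrix(NA_real_, n, length(cyt_names),
                      dimnames = list(sample_id, cyt_names))
  cyt_signal <- numeric(n)
  couplings <- list()
  for (j in seq_along(cyt_names)) {
    spec <- config$cytokine_spec[[j]]
    eps <- stats::rnorm(n)
    if (is.na(spec$feature)) {
      z <- eps
    } else {
      f <- spec$feature
      qf <- prop[, f]
      qf[qf == 0] <- min(qf[qf > 0], 1 / config$depth) / 2
      zq <- as.vector(scale(log10(qf)))
      z <- spec$sign * (0.9 * zq + sqrt(1 - 0.81) * eps)
      cyt_signal <- cyt_signal + spec$weight_effect * z
      couplings[[cyt_names[j]]] <- list(feature = feature_id[f],
                                        sign = spec$sign,
                                        weight_effect = spec$weight_effect)
    }
    cytokines[, j] <- pmax(50 + 15 * z, 1)
  }

  breed_eff <- rep(config$covariate_effects$breed,
                   length.out = n_cohorts)[match(breed, paste0("breed_", seq_len(n_cohorts)))]
  sex_eff <- config$covariate_effects$sex * (sex == "male")
  noise <- stats::rnorm(n, 0, config$noise_sd)
  weight <- config$baseline_weight + breed_eff + sex_eff + signal +
    cyt_signal + noise

  # within-breed High/Low split, the label used by two-group comparisons
  group <- character(n)
  for (b in unique(breed)) {
    idx <- which(breed == b)
    group[idx] <- ifelse(weight[idx] >= stats::median(weight[idx]),
                         "High", "Low")
  }

  metadata <- tibble::tibble(sample_id = sample_id, cohort = cohort,
                             breed = breed, sex = sex, weight = weight,
                             group = unname(group))

  # metabolites: module factor model on the log10 scale
  ms <- config$metabolite_spec
  n_met <- ms$n_metabolites
  met_id <- sprintf("M%04d", seq_len(n_met))
  mod_size <- floor(0.8 * n_met / ms$n_modules)
  module <- rep("grey", n_met)
  logI <- matrix(stats::rnorm(n * n_met), n, n_met)
  for (m in seq_len(ms$n_modules)) {
    idx <- seq((m - 1) * mod_size + 1, m * mod_size)
    logI[, idx] <- equicorr_draw(n, length(idx), ms$module_correlation)
    module[idx] <- paste0("module_", m)
  }
  metabolites <- 10^(5 + 0.5 * logI)
  dimnames(metabolites) <- list(sample_id, met_id)

  tree <- generate_tree(D, seed = config$seed + 1L)

  total_sig <- signal + cyt_signal
  truth <- list(
    log_basis = structure(log_basis, dimnames = list(sample_id, feature_id)),
    blocks = blocks,
    causal = tibble::tibble(feature_id = feature_id[ce$feature],
                            beta_binary = ce$beta_binary,
                            beta_quant = ce$beta_quant),
    module_assignment = tibble::tibble(metabolite_id = met_id, module = module),
    cytokine_couplings = couplings,
    signal = total_sig,
    noise_sd = config$noise_sd,
    var_explained_by_microbiota = stats::var(total_sig) /
      stats::var(total_sig + noise)
  )

  features <- feature_table(counts, metadata = metadata)
  structure(list(features = features, tree = tree,
                 phenotype = metadata[, c("sample_id", "weight")],
                 metabolites = metabolites, cytokines = cytokines,
                 truth = truth, config = config),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d samples (%s), %d features, depth %d\n",
              ncol(x$features$counts),
              paste(x$config$n_samples_per_cohort, collapse = "+"),
              nrow(x$features$counts), x$config$depth))
  cat(sprintf("  planted: %d blocks, %d causal features; realized microbial VE %.2f\n",
              length(x$truth$blocks), nrow(x$truth$causal),
              x$truth$var_explained_by_microbiota))
  invisible(x)
}
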