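# samples x metabolites intensity matrix with two planted modules
module_fixture <- function(n = 40, per_module = 8, n_noise = 6, r = 0.8,
                           seed = 1) {
  set.seed(seed)
  total <- 2 * per_module + n_noise
  x <- matrix(rnorm(n * total), n, total)
  for (b in 0:1) {
    idx <- b * per_module + seq_len(per_module)
    f <- rnorm(n)
    x[, idx] <- sqrt(r) * f + sqrt(1 - r) * x[, idx]
  }
  m <- 10^(5 + 0.5 * x)
  dimnames(m) <- list(sprintf("S%03d", seq_len(n)),
                      sprintf("M%03d", seq_len(total)))
  m
}

test_that("log normalization standardizes intensities and rejects bad cells", {
  m <- matrix(10^c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("S1", "S2"), c("M1", "M2")))
  out <- log_normalize(m)
  expect_equal(colMeans(out), c(M1 = 0, M2 = 0))
  expect_equal(apply(out, 2, sd), c(M1 = 1, M2 = 1))

  bad <- m; bad[1, 2] <- 0
  expect_error(log_normalize(bad), "M2")

  const <- m; const[, 1] <- 1
  expect_warning(out <- log_normalize(const), "zero-variance")
  expect_equal(attr(out, "degenerate"), "M1")
  expect_equal(unname(out[, "M1"]), c(0, 0))
})

test_that("soft-threshold selection returns the first adequate power", {
  m <- module_fixture(n = 60, per_module = 15, n_noise = 10, seed = 2)
  corr <- cor(log_normalize(m))
  st <- suppressWarnings(soft_threshold_select(corr, powers = 1:12))
  expect_true(st$beta %in% 1:12)
  # the choice is the smallest power whose fit reaches the target, per the
  # recorded fit table itself (independent recomputation)
  ok <- st$fit$power[!is.na(st$fit$r_squared) & st$fit$r_squared >= 0.8]
  if (length(ok) > 0) expect_equal(st$beta, min(ok))

  # independent recomputation of the fit at the chosen power
  a <- abs(corr)^st$beta; diag(a) <- 0
  k <- colSums(a)
  cuts <- cut(k, 10)
  pk <- tapply(k, cuts, length) / length(k)
  km <- tapply(k, cuts, mean)
  keep <- !is.na(pk) & pk > 0 & km > 0
  expect_equal(st$fit$r_squared[st$fit$power == st$beta],
               cor(log10(km[keep]), log10(pk[keep]))^2, tolerance = 1e-12)

  # all-zero correlations: warning + fallback
  z <- diag(1, 10)
  expect_warning(stz <- soft_threshold_select(z, powers = 1:3), "best fit")
  expect_true(is.numeric(stz$beta))

  expect_error(soft_threshold_select(matrix(1, 5, 5)), "degenerate")
})

test_that("TOM follows its formula and stays in [0, 1]", {
  # triangle with unit adjacency
  a <- matrix(1, 3, 3); diag(a) <- 0
  t3 <- tom(a)
  expect_equal(t3[1, 2], 1)              # (1+1)/(2+1-1)
  expect_equal(unname(diag(t3)), rep(1, 3))

  # empty adjacency: off-diagonal all zero
  t0 <- tom(matrix(0, 4, 4))
  expect_equal(unique(t0[upper.tri(t0)]), 0)

  # random valid adjacencies stay within bounds and symmetric
  set.seed(4)
  for (i in 1:10) {
    a <- matrix(runif(64), 8, 8)
    a <- (a + t(a)) / 2; diag(a) <- 0
    tt <- tom(a)
    expect_true(all(tt >= 0 & tt <= 1 + 1e-12))
    expect_equal(tt, t(tt))
  }
  expect_error(tom(matrix(2, 3, 3)), "\\[0, 1\\]")
})

test_that("module clustering recovers planted modules exactly", {
  m <- module_fixture(n = 50, per_module = 10, n_noise = 0, r = 0.8, seed = 6)
  mods <- suppressWarnings(
    metabolite_modules(m, min_module_size = 5, cut_height = 0.6))
  asg <- mods$assignment
  g1 <- asg$module[asg$metabolite_id %in% sprintf("M%03d", 1:10)]
  g2 <- asg$module[asg$metabolite_id %in% sprintf("M%03d", 11:20)]
  expect_equal(length(unique(g1)), 1)
  expect_equal(length(unique(g2)), 1)
  expect_false(unique(g1) == unique(g2))
  expect_false("grey" %in% c(g1, g2))

  # assignment invariant to metabolite order
  perm <- sample(ncol(m))
  mods_p <- suppressWarnings(
    metabolite_modules(m[, perm], min_module_size = 5, cut_height = 0.6))
  j <- dplyr::inner_join(asg, mods_p$assignment, by = "metabolite_id")
  expect_equal(dplyr::n_distinct(paste(j$module.x, j$module.y)),
               dplyr::n_distinct(asg$module))

  # degenerate cases
  few <- cluster_modules(matrix(0.5, 3, 3) - diag(0.5, 3), min_module_size = 5)
  expect_true(all(few$module == "grey"))
  same <- matrix(rep(10^rnorm(30), 4), 30, 4,
                 dimnames = list(sprintf("S%03d", 1:30), paste0("M", 1:4)))
  d_same <- 1 - tom(abs(cor(log_normalize(same)))^1 - diag(1, 4))
  cl <- cluster_modules(d_same, min_module_size = 2, cut_height = 0.5)
  expect_equal(dplyr::n_distinct(cl$module), 1)
})

test_that("module eigenvectors behave like standardized leading PCs", {
  # identical profiles: scores equal the standardized profile, fraction 1
  set.seed(8)
  prof <- rnorm(30)
  m_std <- matrix(rep(scale(prof), 3), 30, 3)
  rownames(m_std) <- sprintf("S%03d", 1:30)
  ev <- module_eigenvector(m_std)
  expect_equal(unname(ev$scores), as.vector(scale(prof)), tolerance = 1e-9)
  expect_equal(ev$var_explained, 1)

  # orthogonal two-metabolite module: symmetric eigenvalues, fraction 0.5
  a <- scale(rnorm(40)); b <- scale(resid(lm(rnorm(40) ~ a)))
  ev2 <- module_eigenvector(cbind(as.vector(a), as.vector(b) / sd(b)))
  expect_equal(ev2$var_explained, 0.5, tolerance = 1e-9)

  # global sign flip leaves the scores unchanged (sign convention)
  ev3 <- module_eigenvector(-m_std)
  expect_equal(ev3$scores, module_eigenvector(m_std)$scores *
                 sign(cor(module_eigenvector(m_std)$scores,
                          rowMeans(-m_std))) * -1 * -1,
               tolerance = 1e-9)
  expect_equal(unname(abs(ev3$scores)), unname(abs(ev$scores)), tolerance = 1e-9)

  expect_error(module_eigenvector(m_std[, 1, drop = FALSE]), "at least 2")
})

test_that("module-taxon correlations detect planted couplings with BH control", {
  # eigenvector equal to a genus profile -> r = 1
  set.seed(12)
  n <- 21
  genus <- matrix(rexp(5 * n), 5, n,
                  dimnames = list(paste0("g", 1:5), sprintf("S%03d", 1:n)))
  genus_rel <- sweep(genus, 2, colSums(genus), "/")
  m_couple <- 10^(5 + outer(as.vector(scale(genus_rel[1, ])), rep(0.5, 8)) +
                    matrix(rnorm(n * 8, 0, 0.05), n, 8))
  dimnames(m_couple) <- list(sprintf("S%03d", 1:n), sprintf("M%03d", 1:8))
  mods <- suppressWarnings(
    metabolite_modules(m_couple, min_module_size = 3, cut_height = 0.8))
  ftg <- feature_table(round(genus * 1000))
  mtc <- module_taxon_correlation(mods, ftg)
  expect_gt(max(mtc$r[mtc$feature_id == "g1"]), 0.95)

  # planted coupling r ~ 0.7 at n = 21: detected (q < 0.05) in >= 70% of sims
  hits <- vapply(1:200, function(s) {
    set.seed(3000 + s)
    eig <- rnorm(n)
    g1 <- 0.7 * scale(eig) + sqrt(1 - 0.49) * rnorm(n)
    ct <- cor.test(eig, g1)
    p <- c(ct$p.value, replicate(9, cor.test(rnorm(n), rnorm(n))$p.value))
    q <- p.adjust(p, "BH")
    q[1] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.7)

  # independent data: BH-controlled type I
  fp <- vapply(1:100, function(s) {
    set.seed(4000 + s)
    p <- replicate(12, cor.test(rnorm(n), rnorm(n))$p.value)
    any(p.adjust(p, "BH") < 0.05)
  }, logical(1))
  expect_lte(mean(fp), 0.07)
})

test_that("pairwise Spearman agrees with the rank-then-Pearson oracle", {
  set.seed(14)
  x <- matrix(rnorm(30 * 4), 30, 4,
              dimnames = list(sprintf("S%03d", 1:30), paste0("x", 1:4)))
  y <- matrix(rnorm(30 * 3), 30, 3,
              dimnames = list(sprintf("S%03d", 1:30), paste0("y", 1:3)))
  y[, 1] <- exp(x[, 1])                   # monotone pair
  y[, 2] <- 5                             # constant -> flagged
  res <- pairwise_spearman(x, y)
  expect_equal(res$rho[res$x == "x1" & res$y == "y1"], 1)
  expect_lt(res$p_value[res$x == "x1" & res$y == "y1"], 1e-10)
  expect_true(all(res$flagged[res$y == "y2"]))
  expect_true(all(is.na(res$rho[res$y == "y2"])))
  for (i in 1:4) for (j in c(1, 3)) {
    expect_equal(res$rho[res$x == paste0("x", i) & res$y == paste0("y", j)],
                 oracle_spearman(x[, i], y[, j]), tolerance = 1e-12)
  }
  expect_error(pairwise_spearman(x[1:4, ], y[1:4, ]), "5 shared")
})

test_that("the default cytokine coupling yields a negative IL-6/weight correlation", {
  cfg <- synth_config(n_samples_per_cohort = c(40, 39), n_features = 80,
                      depth = 20000,
                      block_spec = list(c(10, 0.7)),
                      causal_effects = data.frame(feature = 60,
                                                  beta_binary = -0.1,
                                                  beta_quant = -0.2),
                      seed = 51)
  signs <- vapply(1:40, function(s) {
    cfg$seed <- 51 + s
    co <- generate_cohort(cfg)
    w <- co$features$metadata$weight
    cor(co$cytokines[, "IL-6"], w, method = "spearman") < 0
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})
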