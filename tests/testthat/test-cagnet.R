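make_block_counts <- function(n, D, r, pairs = list(c(1, 2)), depth = 5e4,
                              seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * D), n, D)
  for (p in pairs) z[, p[2]] <- r * z[, p[1]] + sqrt(1 - r^2) * z[, p[2]]
  basis <- exp(sweep(z, 2, rnorm(D, 0, 1), "+"))
  counts <- vapply(seq_len(n), function(i) {
    rmultinom(1, depth, basis[i, ])[, 1]
  }, numeric(D))
  dimnames(counts) <- list(sprintf("OTU%02d", seq_len(D)),
                           sprintf("S%03d", seq_len(n)))
  feature_table(counts)
}

test_that("SparCC recovers planted basis correlations and stays near zero for independent features", {
  # planted r = 0.9 between features 1-2: mean estimate within +/- 0.1
  est <- sapply(1:20, function(s) {
    ft <- make_block_counts(200, 20, 0.9, seed = s)
    sparcc(ft)$r["OTU01", "OTU02"]
  })
  expect_lt(abs(mean(est) - 0.9), 0.1)

  # independent basis variables: max |off-diagonal| < 0.2
  set.seed(99)
  n <- 500; D <- 30
  basis <- exp(matrix(rnorm(n * D), n, D) +
                 matrix(rnorm(D, 0, 1), n, D, byrow = TRUE))
  counts <- vapply(seq_len(n), function(i) {
    rmultinom(1, 5e4, basis[i, ])[, 1]
  }, numeric(D))
  dimnames(counts) <- list(sprintf("OTU%02d", 1:D), sprintf("S%03d", 1:n))
  r <- sparcc(feature_table(counts))$r
  diag(r) <- 0
  expect_lt(max(abs(r)), 0.2)

  # structural guarantees
  net <- sparcc(make_block_counts(50, 10, 0.8, seed = 3))
  expect_equal(net$r, t(net$r))
  expect_equal(unname(diag(net$r)), rep(1, 10))
  expect_true(all(net$r >= -1 & net$r <= 1))

  # rank condition and all-zero feature errors
  expect_error(sparcc(random_ft(3, 20, seed = 1)), "at least 4")
  ft0 <- random_ft(6, 10, seed = 1); ft0$counts[2, ] <- 0
  expect_error(sparcc(ft0), "OTU0002")
})

test_that("SparCC is insensitive to per-sample count rescaling", {
  ft <- make_block_counts(40, 8, 0.8, depth = 1e5, seed = 5)
  r1 <- sparcc(ft)$r
  ft$counts[, 3] <- ft$counts[, 3] * 5    # same composition, deeper sample
  r2 <- sparcc(ft)$r
  expect_lt(max(abs(r1 - r2)), 0.02)      # exact up to the pseudocount
})

test_that("bootstrap p-values are +1-corrected, bounded, and deterministic", {
  ft <- make_block_counts(100, 8, 0.9, depth = 2e4, seed = 2)
  net <- sparcc_bootstrap(ft, n_boot = 50, seed = 7)
  p <- net$p
  off <- p[upper.tri(p)]
  expect_true(all(off >= 1 / 51 & off <= 1))
  # planted pair reaches the minimum attainable p
  expect_equal(p["OTU01", "OTU02"], 1 / 51)
  # deterministic given seed
  net2 <- sparcc_bootstrap(ft, n_boot = 50, seed = 7)
  expect_identical(net$p, net2$p)
  expect_error(sparcc_bootstrap(ft, n_boot = 5), "at least 20")
})

test_that("Spearman network equals the rank-then-Pearson oracle and handles degenerate features", {
  ft <- random_ft(10, 20, depth = 3000, seed = 8)
  net <- spearman_network(ft)
  rel <- relative_abundance(ft)$counts
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(net$r[i, j], oracle_spearman(rel[i, ], rel[j, ]),
                 tolerance = 1e-12)
  }

  # monotone / anti-monotone pairs; column totals constant so feature d has
  # constant proportions
  m <- rbind(a = 1:8, b = seq(2, 16, 2), c = 8:1, e = seq(16, 2, -2),
             d = rep(5, 8))
  colnames(m) <- paste0("S", 1:8)
  net <- spearman_network(feature_table(m))
  expect_equal(net$r["a", "b"], 1)
  expect_equal(net$r["a", "c"], -1)
  expect_equal(attr(net, "constant_features"), "d")
  expect_equal(net$r["d", "a"], 0)
})

test_that("Ward clustering recovers planted blocks and honors k", {
  ft <- two_block_ft(block_size = 6, n_extra = 0, n_samples = 80, r = 0.9,
                     seed = 4)
  net <- spearman_network(ft)
  part <- cluster_cags(net, k = 2)
  asg <- part$assignment
  lab1 <- asg$cag[asg$feature_id %in% sprintf("OTU%04d", 1:6)]
  lab2 <- asg$cag[asg$feature_id %in% sprintf("OTU%04d", 7:12)]
  expect_equal(length(unique(lab1)), 1)
  expect_equal(length(unique(lab2)), 1)
  expect_false(unique(lab1) == unique(lab2))

  # k = n features -> all singletons
  all_single <- cluster_cags(net, k = 12)
  expect_equal(dplyr::n_distinct(all_single$assignment$cag), 12)

  # duplicated feature rows have distance 0 and merge first
  ftd <- random_ft(6, 30, seed = 9)
  ftd$counts <- rbind(ftd$counts, dup = ftd$counts[1, ])
  netd <- spearman_network(feature_table(ftd$counts))
  partd <- cluster_cags(netd, k = 6)
  a <- partd$assignment
  expect_equal(a$cag[a$feature_id == "OTU0001"], a$cag[a$feature_id == "dup"])

  expect_error(cluster_cags(net, k = 50), "exceeds")

  # invariant to feature order
  perm <- sample(nrow(ft$counts))
  netp <- spearman_network(feature_table(ft$counts[perm, ]))
  partp <- cluster_cags(netp, k = 2)
  m <- dplyr::inner_join(part$assignment, partp$assignment, by = "feature_id")
  expect_equal(dplyr::n_distinct(paste(m$cag.x, m$cag.y)), 2)
})

test_that("per-CAG PERMANOVA accepts planted blocks and rejects shuffled labels", {
  ft <- two_block_ft(block_size = 10, n_extra = 0, n_samples = 60, r = 0.9,
                     seed = 10)
  part <- cluster_cags(spearman_network(ft), k = 2)
  part <- validate_cags_permanova(ft, part, n_perm = 999, seed = 5)
  v <- part$validation
  expect_equal(nrow(v), 2)
  expect_true(all(v$accepted))
  expect_equal(v$p_value, c(0.001, 0.001))

  # single CAG cannot be validated
  single <- part; single$assignment$cag <- "CAG01"
  expect_error(validate_cags_permanova(ft, single), "at least 2")

  # exchangeable features with random CAG labels: acceptance is rare
  accept <- 0; tested <- 0
  for (i in 1:60) {
    ftn <- random_ft(12, 30, depth = 2000, seed = 100 + i)
    pn <- cluster_cags(spearman_network(ftn), k = 2)
    pn$assignment$cag <- sample(pn$assignment$cag)
    pn <- validate_cags_permanova(ftn, pn, n_perm = 199, seed = i)
    accept <- accept + sum(pn$validation$accepted, na.rm = TRUE)
    tested <- tested + sum(pn$validation$testable)
  }
  expect_lte(accept / tested, 0.01)
})

test_that("CAG group tests find planted enrichment and BH matches the step-up oracle", {
  # identical groups -> all p = 1
  ft <- random_ft(8, 12, depth = 1000, seed = 2)
  ft$counts <- cbind(ft$counts, ft$counts)
  colnames(ft$counts) <- sprintf("S%03d", 1:24)
  ftd <- feature_table(ft$counts)
  part <- cluster_cags(spearman_network(ftd), k = 3)
  res <- cag_group_test(ftd, part, rep(c("H", "L"), each = 12))
  expect_true(all(res$p_value == 1))

  # planted 3x enrichment of a CAG in group H at n = 12 + 12
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    base <- matrix(rexp(10 * 24) + 0.2, 10, 24,
                   dimnames = list(sprintf("F%02d", 1:10), sprintf("S%03d", 1:24)))
    base[1:3, 1:12] <- base[1:3, 1:12] * 3
    counts <- round(base * 500)
    ftp <- feature_table(counts)
    partp <- structure(list(
      assignment = tibble::tibble(feature_id = rownames(counts),
                                  cag = rep(c("CAG01", "CAG02"), c(3, 7))),
      k = 2, threshold = 0.55, network_method = "spearman", validation = NULL),
      class = "cag_partition")
    resp <- cag_group_test(ftp, partp, rep(c("H", "L"), each = 12))
    hits <- hits + (resp$p_value[resp$cag == "CAG01"] < 0.05)
  }
  expect_gte(hits / 100, 0.8)

  # BH equals the brute-force step-up definition
  set.seed(42)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("MCC hub scores follow the maximal-clique formula", {
  mk_net <- function(adj) {
    ids <- rownames(adj)
    structure(list(feature_ids = ids, r = adj, p = NULL, method = "sparcc"),
              class = "correlation_network")
  }
  # triangle: every node (3-1)! = 2
  tri <- matrix(0.9, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(tri) <- 1
  res <- hub_ranking_mcc(mk_net(tri), threshold = 0.55)
  expect_equal(res$mcc, rep(2, 3))

  # star K1,3: center 3, leaves 1
  star <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  star["a", c("b", "c", "d")] <- 0.9
  star[c("b", "c", "d"), "a"] <- 0.9
  diag(star) <- 1
  res <- hub_ranking_mcc(mk_net(star), threshold = 0.55)
  expect_equal(res$mcc[res$feature_id == "a"], 3)
  expect_equal(res$mcc[res$feature_id != "a"], rep(1, 3))
  expect_equal(res$feature_id[1], "a")

  # isolated node scores 0
  iso <- diag(1, 2); dimnames(iso) <- list(c("x", "y"), c("x", "y"))
  expect_equal(hub_ranking_mcc(mk_net(iso))$mcc, c(0, 0))
})

test_that("GraphML export respects the threshold and round-trips edge counts", {
  ft <- two_block_ft(block_size = 5, n_extra = 10, n_samples = 120, r = 0.9,
                     seed = 12)
  net <- spearman_network(ft)
  part <- cluster_cags(net, k = 3)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, part, path, table = ft)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 20)
  expect_equal(igraph::ecount(g), sum(abs(net$r[upper.tri(net$r)]) > 0.55))
  # planted blocks share no cross-block edge at the 0.55 threshold
  el <- igraph::as_edgelist(g)
  blk <- function(id) (as.integer(sub("OTU", "", id)) - 1) %/% 5
  expect_true(all(blk(el[, 1]) == blk(el[, 2])))
  expect_true(all(blk(el[, 1]) <= 1))   # only the two planted blocks carry edges

  # empty edge set still yields a valid file
  iso <- structure(list(feature_ids = c("x", "y"),
                        r = diag(1, 2, 2) + 0,
                        p = NULL, method = "sparcc"),
                   class = "correlation_network")
  dimnames(iso$r) <- list(c("x", "y"), c("x", "y"))
  part0 <- structure(list(assignment = tibble::tibble(
    feature_id = c("x", "y"), cag = c("CAG01", "CAG02")),
    k = 2, threshold = 0.55, network_method = "sparcc", validation = NULL),
    class = "cag_partition")
  path0 <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(iso, part0, path0)
  g0 <- igraph::read_graph(path0, format = "graphml")
  expect_equal(igraph::vcount(g0), 2)
  expect_equal(igraph::ecount(g0), 0)
})
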