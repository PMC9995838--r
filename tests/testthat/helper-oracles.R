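# Independent oracle implementations, written before (and kept independent
# of) the package code paths they check.

# brute-force unweighted UniFrac: per-branch tally over all edges
oracle_unifrac_pair <- function(tree, present_a, present_b) {
  tips_under <- function(tree, node) {
    ntip <- length(tree$tip.label)
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_under, tree = tree))
  }
  unique_len <- 0; union_len <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tips_under(tree, tree$edge[e, 2])
    in_a <- any(tips %in% present_a)
    in_b <- any(tips %in% present_b)
    if (in_a || in_b) union_len <- union_len + tree$edge.length[e]
    if (xor(in_a, in_b)) unique_len <- unique_len + tree$edge.length[e]
  }
  if (union_len == 0) 0 else unique_len / union_len
}

# Faith PD by explicit root-to-tip path union
oracle_faith_pd <- function(tree, present) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  edges_on_paths <- integer(0)
  for (tip in match(present, tree$tip.label)) {
    node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      edges_on_paths <- union(edges_on_paths, e)
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[edges_on_paths])
}

# Benjamini-Hochberg by the literal step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (i in rev(seq_len(m))) {
    running_min <- min(running_min, p[o[i]] * m / i)
    adj[o[i]] <- running_min
  }
  adj
}

# Spearman rho as rank-then-Pearson
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# ACE written straight from the published formula
oracle_ace <- function(counts, cutoff = 10) {
  counts <- counts[counts > 0]
  s_abund <- sum(counts > cutoff)
  rare <- counts[counts <= cutoff]
  if (length(rare) == 0) return(s_abund)
  n_rare <- sum(rare)
  f <- vapply(seq_len(cutoff), function(i) sum(rare == i), numeric(1))
  c_ace <- 1 - f[1] / n_rare
  g2 <- max(length(rare) / c_ace *
              sum(sapply(seq_len(cutoff), function(i) i * (i - 1) * f[i])) /
              (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + length(rare) / c_ace + f[1] / c_ace * g2
}

# exact two-sided rank-sum p by exhaustive enumeration of group assignments
oracle_wilcoxon_exact <- function(x, y) {
  n <- length(x) + length(y)
  vals <- c(x, y)
  r_obs <- sum(rank(vals)[seq_along(x)])
  combos <- utils::combn(n, length(x))
  stats <- apply(combos, 2, function(idx) sum(rank(vals)[idx]))
  mu <- length(x) * (n + 1) / 2
  mean(abs(stats - mu) >= abs(r_obs - mu))
}

# small random multinomial feature table
random_ft <- function(n_features, n_samples, depth = 1000, seed = 1) {
  set.seed(seed)
  base <- rexp(n_features) + 0.05
  counts <- vapply(seq_len(n_samples), function(i) {
    stats::rmultinom(1, depth, base * exp(stats::rnorm(n_features, 0, 0.5)))[, 1]
  }, numeric(n_features))
  dimnames(counts) <- list(sprintf("OTU%04d", seq_len(n_features)),
                           sprintf("S%03d", seq_len(n_samples)))
  feature_table(counts)
}

# feature table with two planted correlated blocks (log-normal basis,
# multinomial counts) and unstructured remainder
two_block_ft <- function(block_size = 6, n_extra = 8, n_samples = 60,
                         r = 0.9, depth = 5e4, seed = 1) {
  set.seed(seed)
  D <- 2 * block_size + n_extra
  z <- matrix(stats::rnorm(n_samples * D), n_samples, D)
  for (b in 0:1) {
    idx <- b * block_size + seq_len(block_size)
    f <- stats::rnorm(n_samples)
    z[, idx] <- sqrt(r) * f + sqrt(1 - r) * z[, idx]
  }
  basis <- exp(sweep(z, 2, stats::rnorm(D, 0, 0.8), "+"))
  counts <- vapply(seq_len(n_samples), function(i) {
    stats::rmultinom(1, depth, basis[i, ])[, 1]
  }, numeric(D))
  dimnames(counts) <- list(sprintf("OTU%04d", seq_len(D)),
                           sprintf("S%03d", seq_len(n_samples)))
  feature_table(counts)
}

parse_lineage_fixture <- function(ids) {
  tibble::tibble(
    feature_id = ids,
    kingdom = "Bacteria",
    phylum = rep(c("Firmicutes", "Bacteroidetes"), length.out = length(ids)),
    class = "c", order = "o", family = "f",
    genus = paste0("g", seq_along(ids)))
}
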