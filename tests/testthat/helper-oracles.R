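# Independent oracles and fixture builders. Everything here deliberately
# avoids the package's own code paths: the UniFrac oracle enumerates
# root-to-leaf paths edge by edge, the Bray-Curtis oracle is a literal
# transcription of the formula, and the permutation oracle enumerates
# relabelings recursively.

# --- brute-force UniFrac oracle ---------------------------------------------
# Edge descendant sets found by walking from every leaf up to the root and
# recording which edges the path crosses (no postorder accumulation).
oracle_edge_sets <- function(tree) {
  n <- length(tree$tip.label)
  parent_of <- integer(max(tree$edge))
  edge_to <- integer(max(tree$edge))       # edge index arriving at node
  for (i in seq_len(nrow(tree$edge))) {
    parent_of[tree$edge[i, 2]] <- tree$edge[i, 1]
    edge_to[tree$edge[i, 2]] <- i
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  sets <- vector("list", nrow(tree$edge))
  for (leaf in seq_len(n)) {
    node <- leaf
    while (node != root) {
      e <- edge_to[node]
      sets[[e]] <- c(sets[[e]], tree$tip.label[leaf])
      node <- parent_of[node]
    }
  }
  sets
}

oracle_unweighted_unifrac <- function(tree, x, y) {
  sets <- oracle_edge_sets(tree)
  px <- names(x)[x > 0]; py <- names(y)[y > 0]
  uniq <- 0; tot <- 0
  for (i in seq_along(sets)) {
    inx <- length(intersect(sets[[i]], px)) > 0
    iny <- length(intersect(sets[[i]], py)) > 0
    b <- tree$edge.length[i]
    if (inx || iny) tot <- tot + b
    if (xor(inx, iny)) uniq <- uniq + b
  }
  if (tot == 0) 0 else uniq / tot
}

oracle_weighted_unifrac <- function(tree, x, y, normalized = TRUE) {
  sets <- oracle_edge_sets(tree)
  px <- x / sum(x); py <- y / sum(y)
  raw <- 0; den <- 0
  for (i in seq_along(sets)) {
    ax <- sum(px[sets[[i]]]); ay <- sum(py[sets[[i]]])
    raw <- raw + tree$edge.length[i] * abs(ax - ay)
    den <- den + tree$edge.length[i] * (ax + ay)
  }
  if (!normalized) raw else if (den == 0) 0 else raw / den
}

oracle_bray_curtis <- function(x, y) {
  num <- 0
  for (i in seq_along(x)) num <- num + min(x[i], y[i])
  1 - 2 * num / (sum(x) + sum(y))
}

# --- permutation enumeration oracle -----------------------------------------
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

oracle_mantel_exact_p <- function(D1, D2) {
  lv <- function(M) M[lower.tri(M)]
  r_obs <- cor(lv(D1), lv(D2))
  rs <- vapply(all_permutations(nrow(D2)), function(p) {
    cor(lv(D1), lv(D2[p, p]))
  }, numeric(1))
  mean(rs >= r_obs - 1e-12)
}

# --- fixtures ----------------------------------------------------------------
random_tree_fixture <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = TRUE,
                   tip.label = paste0("t", seq_len(n_leaves)))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  tr
}

random_counts_fixture <- function(taxa, seed, max_count = 20, p_zero = 0.3) {
  set.seed(seed)
  x <- rpois(length(taxa), sample(1:max_count, length(taxa), replace = TRUE))
  x[runif(length(taxa)) < p_zero] <- 0
  if (all(x == 0)) x[1] <- 1
  names(x) <- taxa
  x
}

# small two-region community fixture used by several dynamics tests
small_sim <- function(seed, ...) {
  simulate_dataset(synthetic_params(seed = seed, ...))
}
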