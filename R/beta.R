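#' Bray-Curtis dissimilarity between two count vectors
#'
#' `BC = 1 - 2 * sum_i min(x_i, y_i) / (sum x + sum y)`; 0 for identical
#' samples, 1 for disjoint taxon supports.
#'
#' @param x,y equal-length non-negative count (or abundance) vectors.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  sx <- sum(x); sy <- sum(y)
  if (sx + sy == 0) stop("both samples are all-zero")
  1 - 2 * sum(pmin(x, y)) / (sx + sy)
}

# Per-edge tip-descendant structure of a tree: for each edge, which tips lie
# below it. Computed once per tree and reused across all pairwise distances.
edge_tip_structure <- function(tree) {
  tree <- validate_tree(tree)
  n <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  M <- matrix(FALSE, n + tr$Nnode, n)
  M[cbind(seq_len(n), seq_len(n))] <- TRUE
  for (i in seq_len(nrow(tr$edge))) {
    M[tr$edge[i, 1], ] <- M[tr$edge[i, 1], ] | M[tr$edge[i, 2], ]
  }
  list(edge_mat = M[tr$edge[, 2], , drop = FALSE],   # edges x tips
       lengths = tr$edge.length,
       tips = tr$tip.label)
}

# Map a named count vector onto the tree's tip ordering; error on taxa with
# nonzero counts that are not leaves.
match_to_tips <- function(x, tips) {
  if (is.null(names(x))) {
    if (length(x) != length(tips)) {
      stop("unnamed count vector must match the number of tree leaves")
    }
    return(as.numeric(x))
  }
  present <- names(x)[x > 0]
  missing <- setdiff(present, tips)
  if (length(missing) > 0) {
    stop("taxa not found in tree: ", paste(missing, collapse = ", "))
  }
  out <- stats::setNames(numeric(length(tips)), tips)
  shared <- intersect(names(x), tips)
  out[shared] <- x[shared]
  as.numeric(out)
}

#' Unweighted UniFrac distance
#'
#' Presence/absence phylogenetic dissimilarity: the branch length leading
#' exclusively to taxa present in one of the two samples, divided by the
#' branch length leading to taxa present in either. Branches subtending no
#' present taxon are ignored. The tree is used as rooted and given — no
#' re-rooting — because the measure is root-sensitive.
#'
#' @param tree rooted `phylo` with branch lengths covering all present taxa.
#' @param x,y count vectors named by taxon (or unnamed in tip order).
#' @param structure optional precomputed [edge_tip_structure] (internal reuse).
#' @return distance in [0, 1].
#' @export
unweighted_unifrac <- function(tree, x, y, structure = NULL) {
  st <- if (is.null(structure)) edge_tip_structure(tree) else structure
  px <- match_to_tips(x, st$tips) > 0
  py <- match_to_tips(y, st$tips) > 0
  ax <- (st$edge_mat %*% px) > 0
  ay <- (st$edge_mat %*% py) > 0
  either <- ax | ay
  if (!any(either)) stop("no present taxa on the tree")
  unique_len <- sum(st$lengths[xor(ax, ay)])
  total_len <- sum(st$lengths[either])
  if (total_len == 0) return(0)
  unique_len / total_len
}

#' Weighted UniFrac distance
#'
#' Abundance-weighted phylogenetic dissimilarity:
#' `raw = sum_branches b * |p_x - p_y|`, where `p_s` is the fraction of
#' sample s reads descending through the branch. The normalized form
#' (default) divides by `sum_branches b * (p_x + p_y)`, keeping the value in
#' [0, 1] and comparable with the other metrics.
#'
#' @inheritParams unweighted_unifrac
#' @param normalized return the normalized form (default `TRUE`).
#' @return distance (in [0, 1] when normalized).
#' @export
weighted_unifrac <- function(tree, x, y, normalized = TRUE, structure = NULL) {
  st <- if (is.null(structure)) edge_tip_structure(tree) else structure
  xv <- match_to_tips(x, st$tips)
  yv <- match_to_tips(y, st$tips)
  if (sum(xv) == 0 || sum(yv) == 0) stop("empty sample")
  px <- as.numeric(st$edge_mat %*% (xv / sum(xv)))
  py <- as.numeric(st$edge_mat %*% (yv / sum(yv)))
  raw <- sum(st$lengths * abs(px - py))
  if (!normalized) return(raw)
  denom <- sum(st$lengths * (px + py))
  if (denom == 0) return(0)
  raw / denom
}

#' Pairwise distance matrix over a community table
#'
#' Assembles all pairwise dissimilarities for one metric, optionally after
#' rarefying every sample to a common depth (one fixed seed-controlled
#' subsample per sample — normalization first, distances second, mirroring
#' the subsample-then-analyze order of depth normalization).
#'
#' @param table taxa x samples count matrix.
#' @param metric one of `"bray_curtis"`, `"unifrac_unweighted"`,
#'   `"unifrac_weighted"`.
#' @param tree rooted `phylo`; required for the UniFrac metrics.
#' @param subsample_depth depth for per-sample rarefying, or `NULL` for raw
#'   counts.
#' @param seed integer seed for the rarefying step.
#' @return symmetric matrix with zero diagonal, sample ids as dimnames and a
#'   `metric` attribute.
#' @export
distance_matrix <- function(table,
                            metric = c("bray_curtis", "unifrac_unweighted",
                                       "unifrac_weighted"),
                            tree = NULL, subsample_depth = NULL, seed = 1) {
  metric <- match.arg(metric)
  if (metric != "bray_curtis" && is.null(tree)) {
    stop("tree required for UniFrac metrics")
  }
  n <- ncol(table)
  if (!is.null(subsample_depth)) {
    taxa <- rownames(table); ids <- colnames(table)
    table <- vapply(seq_len(n), function(j) {
      rarefy_counts(table[, j], subsample_depth, seed = seed + j)
    }, numeric(nrow(table)))
    dimnames(table) <- list(taxa, ids)
  }
  D <- matrix(0, n, n)
  if (metric == "bray_curtis") {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- bray_curtis(table[, i], table[, j])
      }
    }
  } else {
    st <- edge_tip_structure(tree)
    # per-sample edge quantities computed once, then combined pairwise
    P <- vapply(seq_len(n), function(j) {
      v <- match_to_tips(stats::setNames(table[, j], rownames(table)), st$tips)
      if (sum(v) == 0) stop("empty sample column ", j)
      as.numeric(st$edge_mat %*% (v / sum(v)))
    }, numeric(nrow(st$edge_mat)))
    if (metric == "unifrac_unweighted") {
      A <- vapply(seq_len(n), function(j) {
        v <- match_to_tips(stats::setNames(table[, j], rownames(table)), st$tips)
        as.numeric((st$edge_mat %*% (v > 0)) > 0)
      }, numeric(nrow(st$edge_mat)))
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          either <- A[, i] > 0 | A[, j] > 0
          tot <- sum(st$lengths[either])
          D[i, j] <- D[j, i] <- if (tot == 0) 0 else
            sum(st$lengths[xor(A[, i] > 0, A[, j] > 0)]) / tot
        }
      }
    } else {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          raw <- sum(st$lengths * abs(P[, i] - P[, j]))
          den <- sum(st$lengths * (P[, i] + P[, j]))
          D[i, j] <- D[j, i] <- if (den == 0) 0 else raw / den
        }
      }
    }
  }
  dimnames(D) <- list(colnames(table), colnames(table))
  attr(D, "metric") <- metric
  D
}
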