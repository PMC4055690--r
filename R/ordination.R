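as_square <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  D
}

lower_vec <- function(D) D[lower.tri(D)]

#' Principal coordinates analysis (classical MDS on a distance matrix)
#'
#' Gower double-centering of `-D^2/2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square roots of the positive
#' eigenvalues. Negative eigenvalues (possible for non-Euclidean
#' dissimilarities such as Bray-Curtis) are reported but their axes dropped.
#'
#' @param D symmetric distance matrix.
#' @param k number of axes requested; truncated with a warning if fewer
#'   positive eigenvalues exist.
#' @return list of class `comm_ord` with `points` (n x k'), `eigenvalues`
#'   (all, decreasing), `method = "pcoa"`, `sample_ids`.
#' @export
pcoa <- function(D, k = 2) {
  D <- as_square(D)
  n <- nrow(D)
  if (k >= n) stop("k must be < n")
  G <- -0.5 * D^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values), 0) * 1e-10
  npos <- sum(e$values > tol)
  if (k > npos) {
    warning(sprintf("only %d positive eigenvalue(s); truncating k from %d",
                    npos, k))
    k <- npos
  }
  pts <- if (k > 0) {
    e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(e$values[seq_len(k)]), k)
  } else matrix(0, n, 0)
  rownames(pts) <- rownames(D)
  structure(list(points = pts, eigenvalues = e$values, method = "pcoa",
                 stress = NULL, sample_ids = rownames(D)),
            class = "comm_ord")
}

# all PCoA axes with positive eigenvalues, scaled by sqrt(eigenvalue);
# substrate of CAP (negative-eigenvalue axes dropped)
pcoa_axes <- function(D, tol_factor = 1e-8) {
  D <- as_square(D)
  G <- -0.5 * D^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values), 1e-300) * tol_factor
  pos <- which(e$values > tol)
  Y <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), length(pos))
  list(Y = Y, eig = e$values, pos = pos)
}

#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Iterative stress majorization (SMACOF/Guttman transform) alternated with
#' monotone (isotonic, pool-adjacent-violators) regression of configuration
#' distances on the rank order of the input dissimilarities; best solution
#' over `n_starts` random starts. Depends on the dissimilarities only through
#' their ranks. Updates are accepted only while stress decreases, so the
#' recorded stress trajectory is non-increasing.
#'
#' @param D symmetric dissimilarity matrix.
#' @param k embedding dimension (default 2).
#' @param n_starts random starts (default 20).
#' @param max_iter iterations per start (default 500).
#' @param tol stress-improvement convergence tolerance (default 1e-7).
#' @param seed integer seed.
#' @return `comm_ord` list: `points`, `stress` (Kruskal stress-1),
#'   `method = "nmds"`, `trajectory` (accepted stresses of the best start),
#'   `converged`.
#' @export
nmds <- function(D, k = 2, n_starts = 20, max_iter = 500, tol = 1e-7,
                 seed = 1) {
  D <- as_square(D)
  n <- nrow(D)
  if (n < k + 2) stop("need n >= k + 2")
  dvec <- lower_vec(D)
  ord <- order(dvec)
  m <- length(dvec)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    X <- matrix(stats::rnorm(n * k), n, k)
    X <- scale(X, center = TRUE, scale = FALSE)
    Xbest_it <- X
    prev <- Inf
    traj <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dh <- as.matrix(stats::dist(X))
      dhv <- lower_vec(dh)
      ss_dh <- sum(dhv^2)
      if (ss_dh == 0) break
      # disparities: monotone regression of dhat on the rank order of D
      dstar <- numeric(m)
      dstar[ord] <- stats::isoreg(dhv[ord])$yf
      dstar <- dstar * sqrt(ss_dh / sum(dstar^2))
      stress <- sqrt(sum((dhv - dstar)^2) / ss_dh)
      if (stress < prev) {
        traj <- c(traj, stress)
        Xbest_it <- X
        if (prev - stress < tol) {
          prev <- stress
          converged <- TRUE
          break
        }
        prev <- stress
      } else {
        converged <- TRUE
        break
      }
      # Guttman transform
      Dstar <- matrix(0, n, n)
      Dstar[lower.tri(Dstar)] <- dstar
      Dstar <- Dstar + t(Dstar)
      ratio <- ifelse(dh > 0, Dstar / dh, 0)
      B <- -ratio
      diag(B) <- rowSums(ratio)
      X <- (B %*% X) / n
      X <- scale(X, center = TRUE, scale = FALSE)
    }
    if (is.null(best) || prev < best$stress) {
      best <- list(points = Xbest_it, stress = prev, trajectory = traj,
                   converged = converged)
    }
  }
  # rotate to principal axes so axis 1 carries the dominant spread
  # (rotation leaves configuration distances and stress untouched)
  ctr <- scale(best$points, center = TRUE, scale = FALSE)
  best$points <- ctr %*% svd(ctr)$v
  rownames(best$points) <- rownames(D)
  structure(list(points = best$points, stress = best$stress, method = "nmds",
                 trajectory = best$trajectory, converged = best$converged,
                 eigenvalues = NULL, sample_ids = rownames(D)),
            class = "comm_ord")
}

#' @export
print.comm_ord <- function(x, ...) {
  cat(sprintf("%s ordination: %d samples, %d axes\n", toupper(x$method),
              nrow(x$points), ncol(x$points)))
  if (!is.null(x$stress)) cat(sprintf("  stress-1 = %.4f\n", x$stress))
  if (!is.null(x$eigenvalues)) {
    cat("  eigenvalues:", paste(signif(utils::head(x$eigenvalues, 5), 4),
                                collapse = ", "), "...\n")
  }
  invisible(x)
}

#' Procrustes superimposition with PROTEST permutation test
#'
#' Symmetric Procrustes: both configurations are centered and scaled to unit
#' sum of squares; the optimal rotation comes from the SVD of the
#' cross-product and the optimal scaling from its singular values. The
#' statistic `m2` is the residual sum of squares (in [0, 1] under this
#' scaling) and `correlation = sqrt(1 - m2)`. The PROTEST p-value is the
#' fraction of row-permuted `Y` (observed included) achieving `m2` at most
#' the observed: `p = (count + 1) / (n_perm + 1)`.
#'
#' @param X,Y n x k configurations over the same samples (row order aligned;
#'   matching rownames enforced when both are named). Columns are zero-padded
#'   to a common k.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list of class `procrustes_result`: `m2`, `correlation`, `p`,
#'   `permutations`.
#' @export
procrustes <- function(X, Y, n_perm = 999, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("configurations must have the same rows")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y))) {
    stop("sample ids of the two configurations do not match")
  }
  k <- max(ncol(X), ncol(Y))
  pad <- function(M) cbind(M, matrix(0, nrow(M), k - ncol(M)))
  X <- pad(X); Y <- pad(Y)
  m2_stat <- function(Yp) {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    Yc <- scale(Yp, center = TRUE, scale = FALSE)
    Xc <- Xc / sqrt(sum(Xc^2))
    Yc <- Yc / sqrt(sum(Yc^2))
    1 - sum(svd(crossprod(Xc, Yc))$d)^2
  }
  m2 <- m2_stat(Y)
  set.seed(seed)
  hits <- 0
  for (i in seq_len(n_perm)) {
    if (m2_stat(Y[sample(nrow(Y)), , drop = FALSE]) <= m2) hits <- hits + 1
  }
  structure(list(m2 = m2, correlation = sqrt(max(1 - m2, 0)),
                 p = (hits + 1) / (n_perm + 1), permutations = n_perm),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("Procrustes/PROTEST: m2 = %.4f, correlation = %.4f, p = %.4g (%d permutations)\n",
              x$m2, x$correlation, x$p, x$permutations))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the `n(n-1)/2` off-diagonal entries, with
#' significance from simultaneous row/column permutations of the second
#' matrix; one-sided (r at least observed), `p = (count + 1) / (n_perm + 1)`.
#'
#' @param D1,D2 symmetric matrices over the same samples in the same order.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list of class `mantel_result`: `r`, `p`, `permutations`.
#' @export
mantel <- function(D1, D2, n_perm = 999, seed = 1) {
  D1 <- as_square(D1); D2 <- as_square(D2)
  if (nrow(D1) != nrow(D2)) stop("matrices must have the same samples")
  v1 <- lower_vec(D1)
  if (stats::sd(v1) == 0 || stats::sd(lower_vec(D2)) == 0) {
    stop("constant distance matrix: Mantel r undefined")
  }
  r_obs <- stats::cor(v1, lower_vec(D2))
  set.seed(seed)
  n <- nrow(D2)
  hits <- 0
  for (i in seq_len(n_perm)) {
    p <- sample(n)
    if (stats::cor(v1, lower_vec(D2[p, p])) >= r_obs) hits <- hits + 1
  }
  structure(list(r = r_obs, p = (hits + 1) / (n_perm + 1),
                 permutations = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$permutations))
  invisible(x)
}

#' Canonical analysis of principal coordinates (distance-based RDA)
#'
#' Anderson & Willis construction: PCoA axes carrying the positive
#' eigenvalues are regressed on the (standardized, centered) constraints;
#' the eigen-analysis of the fitted values gives the constrained inertia.
#' `pseudo-F = (constrained/q) / (residual/(n - q - 1))`; its significance
#' comes from permuting constraint rows, `p = (count >= observed + 1) /
#' (n_perm + 1)`. Negative PCoA eigenvalues are dropped (no Lingoes/Cailliez
#' correction). Samples with missing covariates are dropped with a message;
#' constant or collinear constraint columns are dropped with a warning.
#'
#' @param D symmetric distance matrix.
#' @param constraints sample x variable numeric matrix or data.frame, rows
#'   aligned with `D`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list of class `cap_result`: `constrained_eig`,
#'   `prop_constrained`, `pseudo_F`, `p`, `constraint_names`, `n`, `q`.
#' @export
cap <- function(D, constraints, n_perm = 999, seed = 1) {
  D <- as_square(D)
  X <- as.matrix(constraints)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != nrow(D)) stop("constraint rows must align with samples")
  keep <- stats::complete.cases(X)
  if (!all(keep)) {
    message(sum(!keep), " sample(s) dropped for missing covariates")
    D <- D[keep, keep, drop = FALSE]
    X <- X[keep, , drop = FALSE]
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant constraint(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no usable constraints: test undefined")
  X <- scale(X)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_idx <- qr_x$pivot[(qr_x$rank + 1):ncol(X)]
    warning("dropping collinear constraint(s): ",
            paste(colnames(X)[drop_idx], collapse = ", "))
    X <- X[, -drop_idx, drop = FALSE]
    X <- scale(X)
  }
  ax <- pcoa_axes(D)
  Y <- ax$Y
  n <- nrow(Y); q <- ncol(X)
  if (n - q - 1 <= 0) stop("too few samples for ", q, " constraints")
  total <- sum(Y^2)
  f_stat <- function(Xp) {
    fit <- qr.fitted(qr(cbind(1, Xp)), Y)
    constrained <- sum(fit^2)
    (constrained / q) / ((total - constrained) / (n - q - 1))
  }
  F_obs <- f_stat(X)
  fit <- qr.fitted(qr(cbind(1, X)), Y)
  constrained <- sum(fit^2)
  ce <- eigen(crossprod(fit), symmetric = TRUE, only.values = TRUE)$values
  ce <- ce[ce > max(ce, 0) * 1e-10]
  set.seed(seed)
  hits <- 0
  for (i in seq_len(n_perm)) {
    if (f_stat(X[sample(n), , drop = FALSE]) >= F_obs) hits <- hits + 1
  }
  structure(list(constrained_eig = ce, prop_constrained = constrained / total,
                 pseudo_F = F_obs, p = (hits + 1) / (n_perm + 1),
                 constraint_names = colnames(X), n = n, q = q,
                 permutations = n_perm),
            class = "cap_result")
}

#' @export
print.cap_result <- function(x, ...) {
  cat(sprintf("CAP (db-RDA): %d samples, constraints: %s\n", x$n,
              paste(x$constraint_names, collapse = ", ")))
  cat(sprintf("  constrained inertia = %.1f%%, pseudo-F = %.4g, p = %.4g (%d permutations)\n",
              100 * x$prop_constrained, x$pseudo_F, x$p, x$permutations))
  invisible(x)
}
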