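test_that("PCoA recovers Euclidean configurations and flags degenerate input", {
  # collinear points: one positive eigenvalue, distances reproduced
  pts <- cbind(c(0, 1, 3, 7))
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_warning(ord <- pcoa(D, k = 2), "truncating")
  expect_equal(sum(ord$eigenvalues > 1e-8 * max(ord$eigenvalues)), 1)
  expect_lt(max(abs(as.matrix(dist(ord$points)) - D)), 1e-10)

  # planar configuration: first two eigenvalues carry all inertia
  set.seed(2)
  p2 <- matrix(rnorm(14), 7, 2)
  D2 <- as.matrix(dist(p2))
  ord2 <- pcoa(D2, k = 2)
  expect_lt(max(abs(as.matrix(dist(ord2$points)) - D2)), 1e-10)
  expect_lt(sum(abs(ord2$eigenvalues[-(1:2)])), 1e-8 * sum(ord2$eigenvalues[1:2]))

  # eigenvalues reported in decreasing order
  expect_true(all(diff(ord2$eigenvalues) <= 1e-12))

  # degenerate all-zero matrix: no positive axes, all-zero configuration
  D0 <- matrix(0, 4, 4)
  expect_warning(ord0 <- pcoa(D0, k = 2), "truncating")
  expect_true(all(ord0$points == 0))
})

test_that("PCoA agrees with classical cmdscale on non-Euclidean input", {
  sim <- small_sim(23)
  D <- distance_matrix(sim$tables$V4[, 1:8], "bray_curtis")
  ord <- pcoa(D, k = 3)
  cs <- cmdscale(as.dist(D), k = 3, eig = TRUE)
  # axes match up to sign
  for (j in 1:3) {
    expect_lt(min(max(abs(ord$points[, j] - cs$points[, j])),
                  max(abs(ord$points[, j] + cs$points[, j]))), 1e-8)
  }
  expect_equal(ord$eigenvalues[1:3], cs$eig[1:3], tolerance = 1e-8)
})

test_that("NMDS embeds embeddable data, depends on ranks only, and descends", {
  set.seed(5)
  pts <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(pts))
  ord <- nmds(D, k = 2, n_starts = 8, seed = 3)
  expect_lt(ord$stress, 0.01)
  expect_true(all(diff(ord$trajectory) <= 1e-12))

  # stress invariant under strictly monotone transform of the distances
  ord_t <- nmds(sqrt(D / (1 + D)), k = 2, n_starts = 8, seed = 3)
  expect_equal(ord$stress, ord_t$stress, tolerance = 1e-10)

  # well-separated clusters recovered on the first axis
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    cl <- rbind(matrix(rnorm(10, 0, 0.2), 5, 2),
                matrix(rnorm(10, 20, 0.2), 5, 2))
    Dc <- as.matrix(dist(cl))
    o <- nmds(Dc, k = 2, n_starts = 5, max_iter = 200, seed = s)
    ax <- o$points[, 1]
    if (max(ax[1:5]) < min(ax[6:10]) || min(ax[1:5]) > max(ax[6:10])) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 19)
})

test_that("Procrustes recognizes congruence and uses the permutation-p convention", {
  set.seed(9)
  X <- matrix(rnorm(24), 12, 2)
  theta <- 0.7
  Rm <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  Y <- 2.5 * X %*% Rm + 3
  pr <- procrustes(X, Y, n_perm = 99, seed = 1)
  expect_lt(pr$m2, 1e-12)
  expect_equal(pr$correlation, 1, tolerance = 1e-6)
  expect_equal(pr$p, 1 / 100)  # observed included: min achievable p
  # column padding: 1-D config against 2-D
  pr2 <- procrustes(X[, 1, drop = FALSE], X, n_perm = 9, seed = 1)
  expect_true(pr2$m2 >= 0 && pr2$m2 <= 1)
  expect_error(procrustes(X, Y[1:6, ]), "same rows")
})

test_that("Mantel statistic is exact under affine maps and identity", {
  sim <- small_sim(29)
  D1 <- distance_matrix(sim$tables$V1V3[, 1:8], "bray_curtis")
  m <- mantel(D1, D1, n_perm = 199, seed = 2)
  expect_equal(m$r, 1)
  expect_equal(m$p, 1 / 200)
  m2 <- mantel(D1, 0.1 + 0.7 * D1, n_perm = 19, seed = 2)
  expect_equal(m2$r, 1, tolerance = 1e-12)
  expect_error(mantel(D1, matrix(0.5, 8, 8) - diag(0.5, 8)), "constant")
})

test_that("Mantel r agrees with vegan", {
  skip_if_not_installed("vegan")
  sim <- small_sim(31)
  D1 <- distance_matrix(sim$tables$V1V3[, 1:10], "bray_curtis")
  D2 <- distance_matrix(sim$tables$V4[, 1:10], "bray_curtis")
  m <- mantel(D1, D2, n_perm = 99, seed = 1)
  vm <- vegan::mantel(as.dist(D1), as.dist(D2), permutations = 99)
  expect_equal(m$r, unname(vm$statistic), tolerance = 1e-10)
})

test_that("CAP detects a planted gradient and rejects degenerate constraints", {
  # temperature-coupled communities: constraint recovered as significant
  hits <- 0
  for (s in 1:20) {
    sim <- simulate_dataset(synthetic_params(seed = 400 + s, n_core = 15,
                                             n_transient = 25,
                                             temp_coupling = 0.15))
    d <- design_region(sim$design, "V1V3")
    D <- distance_matrix(sim$tables$V1V3, "bray_curtis")
    res <- cap(D, cbind(temperature = d$temperature), n_perm = 199,
               seed = s)
    if (res$p <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)

  # constant constraint: undefined test
  D <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  expect_error(suppressWarnings(cap(D, matrix(1, 10, 1))), "no usable")
  # collinear columns dropped with a warning
  x <- rnorm(10)
  expect_warning(cap(D, cbind(a = x, b = 2 * x), n_perm = 9, seed = 1),
                 "collinear")
})

test_that("CAP proportions and inertia behave like a projection", {
  sim <- small_sim(37)
  d <- design_region(sim$design, "V4")
  D <- distance_matrix(sim$tables$V4, "bray_curtis")
  res <- cap(D, cbind(temp = d$temperature, noise = rnorm(24)), n_perm = 49,
             seed = 4)
  expect_true(res$prop_constrained >= 0 && res$prop_constrained <= 1)
  expect_true(all(res$constrained_eig >= 0))
  expect_true(res$p > 0 && res$p <= 1)
})
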