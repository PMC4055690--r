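test_that("rarefying subsamples without replacement under the stated contract", {
  x <- c(a = 3, b = 2, c = 5)
  out <- rarefy_counts(x, 5, seed = 1)
  expect_equal(sum(out), 5)
  expect_true(all(out <= x))
  expect_named(out, names(x))
  # full depth is the identity
  expect_equal(rarefy_counts(x, 10, seed = 1), c(a = 3L, b = 2L, c = 5L))
  expect_error(rarefy_counts(x, 11), "exceeds")
  # determinism
  expect_identical(rarefy_counts(x, 5, seed = 7), rarefy_counts(x, 5, seed = 7))
})

test_that("rarefying is hypergeometric: per-taxon means match depth*Ni/N", {
  x <- c(30, 10, 5, 55)
  set.seed(99)
  draws <- vapply(1:2000, function(i) rarefy_counts(x, 20, seed = NULL),
                  numeric(4))
  expected <- 20 * x / sum(x)
  # s.e. bounded by the binomial envelope
  se <- sqrt(expected * (1 - x / sum(x)) / 2000)
  expect_true(all(abs(rowMeans(draws) - expected) < 4 * se + 1e-9))
})

test_that("closed-form expected richness matches binomial-coefficient arithmetic", {
  expect_equal(expected_richness(c(5, 5), 5), 2 * (1 - 1 / choose(10, 5)),
               tolerance = 1e-12)
  expect_equal(expected_richness(c(1, 1, 1), 1), 1.0)
  # full depth counts every nonzero taxon
  expect_equal(expected_richness(c(4, 0, 2, 1), 7), 3)
  # monotone non-decreasing in depth
  x <- c(12, 7, 3, 1, 1)
  vals <- vapply(1:24, function(d) expected_richness(x, d), numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("expected richness agrees with vegan's rarefy", {
  skip_if_not_installed("vegan")
  set.seed(5)
  for (i in 1:10) {
    x <- rpois(15, 8); x[x < 0] <- 0; x[1] <- x[1] + 5
    d <- sample(3:sum(x), 1)
    expect_equal(expected_richness(x, d),
                 as.numeric(suppressWarnings(vegan::rarefy(matrix(x, 1), d))),
                 tolerance = 1e-8)
  }
})

test_that("rarefaction curves track the closed-form oracle", {
  x <- c(40, 25, 10, 5, 3, 1, 1)
  rc <- rarefaction_curve(x, depths = c(5, 15, 40, 80), iterations = 400,
                          seed = 3)
  expect_equal(attr(rc, "iterations"), 400)
  expect_true(all(diff(rc$mean_richness) >= 0))
  expect_true(all(rc$lower <= rc$mean_richness & rc$mean_richness <= rc$upper))
  for (i in seq_len(nrow(rc))) {
    mu <- expected_richness(x, rc$depth[i])
    # Monte-Carlo s.e. of a mean of at most `length(x)`-bounded richness
    expect_lt(abs(rc$mean_richness[i] - mu), 3 * sqrt(length(x)^2 / 4 / 400))
  }
  # degenerate single-taxon community: flat curve, zero-width interval
  rc1 <- rarefaction_curve(c(50), depths = c(1, 10, 25), iterations = 50,
                           seed = 1)
  expect_true(all(rc1$mean_richness == 1))
  expect_true(all(rc1$lower == 1 & rc1$upper == 1))
})

test_that("Shannon index follows the natural-log closed forms", {
  expect_equal(shannon(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon(c(10, 0, 0)), 0)
  expect_equal(shannon(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_error(shannon(c(0, 0)), "all-zero")
  # bounds: 0 <= H <= ln(S_obs), equality at uniform
  set.seed(21)
  for (i in 1:20) {
    x <- rpois(12, 4); if (all(x == 0)) x[1] <- 1
    H <- shannon(x)
    expect_gte(H, 0)
    expect_lte(H, log(observed_richness(x)) + 1e-12)
  }
})

test_that("Shannon agrees with vegan's diversity", {
  skip_if_not_installed("vegan")
  set.seed(31)
  x <- rpois(20, 6)
  expect_equal(shannon(x), unname(vegan::diversity(matrix(x, 1))),
               tolerance = 1e-12)
})

test_that("rarefied Shannon cannot exceed ln(depth)", {
  set.seed(41)
  for (i in 1:10) {
    x <- rpois(200, 3) + 1
    d <- 50
    expect_lte(shannon(rarefy_counts(x, d, seed = i)), log(d))
  }
})

test_that("alpha records report rarefied richness and Shannon per sample", {
  sim <- small_sim(13)
  rec <- alpha_records(sim$tables$V1V3, depth = 500, seed = 2)
  expect_equal(nrow(rec), 24)
  expect_true(all(rec$depth == 500))
  expect_true(all(rec$observed_otus <= nrow(sim$tables$V1V3)))
  expect_true(all(rec$shannon <= log(rec$observed_otus) + 1e-12))
})

test_that("paired alpha comparison behaves at the edges and under signal", {
  a <- c(4.1, 4.3, 3.9, 4.4, 4.0, 4.2)
  r <- compare_alpha(a, a)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # constant shift with zero difference variance: degenerate, p -> 0
  r2 <- compare_alpha(a + 1, a)
  expect_true(r2$degenerate)
  expect_equal(r2$p, 0)
  expect_error(compare_alpha(a[1:2], a[1:2]), ">= 3")
  # power: shift of 1 with sd 0.1 over 12 points is detected essentially always
  set.seed(77)
  hits <- sum(vapply(1:200, function(i) {
    b <- rnorm(12, 0, 0.3) + 4
    compare_alpha(b + rnorm(12, 1, 0.1), b)$p < 0.05
  }, logical(1)))
  expect_gte(hits / 200, 0.95)
})
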