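# compact deterministic fixture: 2 time points x 2 replicates, one region
tiny_design <- function(T_points = 3, R = 2, region = "V1V3") {
  d <- expand.grid(replicate = seq_len(R), time_point = seq_len(T_points))
  d$region <- region
  d$sample_id <- sprintf("%s_t%02d_r%d", region, d$time_point, d$replicate)
  ts_design(d)
}

test_that("core detection implements presence-at-every-time-point", {
  des <- tiny_design(T_points = 3)
  tab <- rbind(
    always = c(5, 1, 2, 3, 4, 1),
    one_gap = c(2, 1, 0, 0, 3, 1),   # absent (both reps) at t=2
    rep_gap = c(2, 0, 1, 0, 3, 1),   # always present in >= 1 replicate
    never2 = c(1, 1, 1, 1, 0, 0)
  )
  colnames(tab) <- des$sample_id[order(des$time_point, des$replicate)]
  core <- detect_core(tab, des, "V1V3")
  expect_true("always" %in% core$core_taxa)
  expect_true("rep_gap" %in% core$core_taxa)
  expect_false("one_gap" %in% core$core_taxa)
  expect_equal(unname(core$occupancy["one_gap"]), 2)
  expect_equal(unname(core$occupancy["never2"]), 2)
  expect_equal(core$core_share,
               sum(tab[c("always", "rep_gap"), ]) / sum(tab))
  # strict per-replicate mode shrinks the core
  strict <- detect_core(tab, des, "V1V3", per_replicate = TRUE)
  expect_false("rep_gap" %in% strict$core_taxa)
  expect_true(all(strict$core_taxa %in% core$core_taxa))
})

test_that("raising the occupancy threshold never grows the core", {
  sim <- small_sim(43)
  core <- detect_core(sim$tables$V1V3, sim$design, "V1V3")
  for (thr in 1:12) {
    set_thr <- names(core$occupancy)[core$occupancy >= thr]
    if (thr > 1) expect_true(all(set_thr %in% prev))
    prev <- set_thr
  }
  expect_equal(sort(names(core$occupancy)[core$occupancy >= core$T]),
               sort(core$core_taxa))
})

test_that("planted cores are recovered from sequenced counts", {
  sim <- small_sim(47)
  truth <- sim$truth
  planted <- truth$taxon_ids[truth$is_core]
  for (rg in c("V1V3", "V4")) {
    core <- detect_core(sim$tables[[rg]], sim$design, rg)
    # the abundance floor applies to the biased composition each region
    # actually sequences, not the latent truth
    biased <- apply_primer_bias(truth, truth$params$regions[[rg]])
    abundant <- planted[apply(biased$rel_abund[planted, ], 1, min) >= 0.005]
    expect_true(all(abundant %in% core$core_taxa))
    # transient taxa can never enter the core
    expect_false(any(truth$taxon_ids[!truth$is_core] %in% core$core_taxa))
  }
})

test_that("shared core aggregates and intersects at the chosen rank", {
  des <- tiny_design(T_points = 3, R = 1)
  desB <- tiny_design(T_points = 3, R = 1, region = "V4")
  tabA <- rbind(u1 = c(20, 20, 20), u2 = c(10, 10, 10), u3 = c(10, 15, 15))
  tabB <- rbind(v1 = c(10, 10, 10), v2 = c(25, 20, 25))
  colnames(tabA) <- des$sample_id
  colnames(tabB) <- desB$sample_id
  taxonomy <- data.frame(
    taxon_id = c("u1", "u2", "u3", "v1", "v2"),
    class = c("C1", "C1", "C2", "C1", "C3"),
    order = c("O1", "O2", "O2", "O1", "O3"),
    stringsAsFactors = FALSE
  )
  coreA <- detect_core(tabA, des, "V1V3")
  coreB <- detect_core(tabB, desB, "V4")
  sc <- shared_core(coreA, coreB, tabA, tabB, des, desB, taxonomy)
  expect_equal(sc$shared, "O1")
  expect_equal(unname(sc$shareA), 60 / 130)
  expect_equal(unname(sc$shareB), 30 / 100)
  # identical order sets: full share on both sides
  sc2 <- shared_core(coreA, coreA, tabA, tabA, des, des, taxonomy)
  expect_equal(sc2$shareA, 1)
  # unclassified-at-order taxa fall back to parent-labeled groups
  taxonomy$order[3] <- ""
  sc3 <- shared_core(coreA, coreB, tabA, tabB, des, desB, taxonomy)
  expect_true("unclassified_C2" %in% names(sc3$profileA))
})

test_that("moving-window averages all replicate pairings per interval", {
  des <- tiny_design(T_points = 3, R = 2)
  ids <- des$sample_id
  n <- length(ids)
  D <- matrix(0.5, n, n, dimnames = list(ids, ids)); diag(D) <- 0
  # interval 1->2 gets 4 known values
  a <- ids[des$time_point == 1]; b <- ids[des$time_point == 2]
  vals <- c(0.1, 0.2, 0.3, 0.4)
  k <- 0
  for (i in a) for (j in b) { k <- k + 1; D[i, j] <- D[j, i] <- vals[k] }
  mw <- moving_window(D, des, "V1V3")
  expect_equal(nrow(mw), 2)
  expect_equal(mw$n_pairs, c(4, 4))
  expect_equal(mw$mean_dissimilarity[1], mean(vals))
  expect_equal(mw$sem[1], sd(vals) / 2)

  # constant community: all zeros
  D0 <- matrix(0, n, n, dimnames = list(ids, ids))
  mw0 <- moving_window(D0, des, "V1V3")
  expect_true(all(mw0$mean_dissimilarity == 0))

  # single replicate: one pairing, SEM flagged undefined and reported 0
  des1 <- tiny_design(T_points = 2, R = 1)
  D1 <- matrix(c(0, 0.6, 0.6, 0), 2,
               dimnames = list(des1$sample_id, des1$sample_id))
  mw1 <- moving_window(D1, des1, "V1V3")
  expect_equal(mw1$mean_dissimilarity, 0.6)
  expect_equal(mw1$sem, 0)
  expect_false(mw1$sem_defined)
})

test_that("similarity decay recovers exact log-linear structure", {
  des <- tiny_design(T_points = 8, R = 1)
  ids <- des$sample_id
  D <- outer(des$time_point, des$time_point,
             function(a, b) 1 - 10^(-0.02 * abs(a - b)))
  dimnames(D) <- list(ids, ids)
  fits <- similarity_decay(D, des, "V1V3")
  expect_length(fits, 1)
  expect_equal(fits[[1]]$slope, -0.02, tolerance = 1e-12)
  expect_equal(fits[[1]]$r2, 1)
  expect_equal(fits[[1]]$n_excluded, 0)

  # constant similarity: flat fit, no decay evidence
  Dc <- matrix(0.5, 8, 8, dimnames = list(ids, ids)); diag(Dc) <- 0
  fc <- similarity_decay(Dc, des, "V1V3")[[1]]
  expect_equal(fc$slope, 0)
  expect_equal(fc$p_slope, 1)

  # zero/negative similarities are excluded, not floored
  Dx <- D; Dx[1, 8] <- Dx[8, 1] <- 1
  fx <- similarity_decay(Dx, des, "V1V3")[[1]]
  expect_equal(fx$n_excluded, 1)
  expect_equal(fx$n_pairs, choose(8, 2) - 1)
})

test_that("pooled-variance slope comparison matches hand computation", {
  r <- compare_slopes(c(-1, -3), c(-2, -4))
  expect_equal(r$t, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-1 / sqrt(2), 2), tolerance = 1e-12)
  same <- compare_slopes(c(-1, -2), c(-1, -2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  degen <- compare_slopes(c(-1, -1), c(-2, -2))
  expect_true(degen$degenerate)
  expect_error(compare_slopes(-1, c(-2, -3)), ">= 2")
})

test_that("taxa-time power law is fitted exactly and degenerately", {
  f <- fit_str(10 * (1:12)^0.5)
  expect_equal(f$w, 0.5, tolerance = 1e-12)
  expect_equal(f$c, 10, tolerance = 1e-10)
  expect_equal(f$r2, 1)
  fconst <- fit_str(rep(30, 10))
  expect_equal(fconst$w, 0)
  expect_error(fit_str(c(0, 3, 4)), "first time point")
})

test_that("STR on tables: singleton removal, relabeling and scale invariance", {
  sim <- small_sim(53)
  tab <- sim$tables$V1V3
  # drop whole-series singletons so the scale-invariance property is exact
  d1 <- design_region(sim$design, "V1V3")
  keep <- rowSums(tab[, d1$sample_id[d1$replicate == 1]]) != 1 &
    rowSums(tab[, d1$sample_id[d1$replicate == 2]]) != 1
  tab <- tab[keep, ]
  fit <- taxa_time_relationship(tab, sim$design, "V1V3")
  expect_length(fit$fits, 2)
  expect_true(all(vapply(fit$fits, function(f) is.finite(f$w), logical(1))))
  # relabeling taxa
  tab_rl <- tab
  rownames(tab_rl) <- rev(rownames(tab))
  fit_rl <- taxa_time_relationship(tab_rl, sim$design, "V1V3")
  expect_equal(fit_rl$mean_w, fit$mean_w, tolerance = 1e-12)
  # multiplying all counts by a constant
  fit_sc <- taxa_time_relationship(tab * 3L, sim$design, "V1V3")
  expect_equal(fit_sc$mean_w, fit$mean_w, tolerance = 1e-12)
  # genus aggregation runs and can only reduce cumulative counts
  taxonomy <- data.frame(taxon_id = rownames(tab),
                         genus = sub("_[0-9]+$", "", rownames(tab)),
                         stringsAsFactors = FALSE)
  fit_g <- taxa_time_relationship(tab, sim$design, "V1V3", level = "genus",
                                  taxonomy = taxonomy)
  expect_lte(fit_g$fits[[1]]$S[12], fit$fits[[1]]$S[12])
})

test_that("self-comparison of a region with itself is the identity case", {
  sim <- small_sim(59)
  tabA <- sim$tables$V1V3
  desA <- design_region(sim$design, "V1V3")
  # clone the region under a second label
  desB <- as.data.frame(desA)
  desB$region <- "CLONE"
  desB$sample_id <- sub("V1V3", "CLONE", desB$sample_id)
  tabB <- tabA
  colnames(tabB) <- desB$sample_id
  design <- ts_design(rbind(as.data.frame(desA), desB))
  rep_cmp <- run_region_comparison(tabA, tabB, sim$tree, design,
                                   regionA = "V1V3", regionB = "CLONE",
                                   n_perm = 49, seed = 3)
  for (m in names(rep_cmp$mantel)) {
    expect_equal(rep_cmp$mantel[[m]]$r, 1, tolerance = 1e-12)
  }
  expect_gt(rep_cmp$procrustes$correlation, 0.99)
  for (m in names(rep_cmp$moving_window)) {
    expect_equal(rep_cmp$moving_window[[m]]$pearson_r, 1, tolerance = 1e-12)
  }
  for (m in names(rep_cmp$decay)) {
    expect_equal(rep_cmp$decay[[m]]$comparison$p, 1)
  }
  expect_equal(rep_cmp$str$comparison$p, 1)
  expect_identical(sort(rep_cmp$core$A$core_taxa),
                   sort(rep_cmp$core$B$core_taxa))
})
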