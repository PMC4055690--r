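#' Detect the temporal core community of a region
#'
#' A taxon is counted present at a time point when its summed count over that
#' time point's technical replicates is > 0 (permissive reading; set
#' `per_replicate = TRUE` to require presence in every replicate). The core
#' is the set of taxa present at ALL time points of the series.
#'
#' @param table taxa x samples count matrix.
#' @param design a [ts_design()] covering the table's samples.
#' @param region region label to analyze.
#' @param per_replicate strict mode: presence required in each replicate.
#' @return list of class `core_set`: `region`, `core_taxa`, `occupancy`
#'   (named integer, time points present per taxon), `core_share` (fraction
#'   of the region's total reads in core taxa), `T` (number of time points).
#' @export
detect_core <- function(table, design, region, per_replicate = FALSE) {
  d <- design_region(design, region)
  tps <- sort(unique(d$time_point))
  Tn <- length(tps)
  pres_by_tp <- vapply(tps, function(t) {
    ids <- d$sample_id[d$time_point == t]
    sub <- table[, ids, drop = FALSE]
    if (per_replicate) rowSums(sub > 0) == ncol(sub) else rowSums(sub) > 0
  }, logical(nrow(table)))
  occupancy <- rowSums(pres_by_tp)
  names(occupancy) <- rownames(table)
  core <- names(occupancy)[occupancy == Tn]
  region_counts <- table[, d$sample_id, drop = FALSE]
  core_share <- sum(region_counts[core, , drop = FALSE]) / sum(region_counts)
  structure(list(region = region, core_taxa = core, occupancy = occupancy,
                 core_share = core_share, T = Tn),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("Temporal core of region %s: %d/%d taxa present at all %d time points\n",
              x$region, length(x$core_taxa), length(x$occupancy), x$T))
  cat(sprintf("  core abundance share: %.1f%%\n", 100 * x$core_share))
  invisible(x)
}

# rank label per taxon; taxa unclassified at the rank are grouped as
# "unclassified_<nearest classified parent>"
rank_labels <- function(taxa, taxonomy, rank) {
  ranks <- setdiff(names(taxonomy), "taxon_id")
  ri <- match(rank, ranks)
  if (is.na(ri)) stop("rank '", rank, "' not in taxonomy")
  vapply(taxa, function(tx) {
    row <- taxonomy[match(tx, taxonomy$taxon_id), , drop = FALSE]
    if (nrow(row) == 0 || is.na(row$taxon_id)) return("unclassified_root")
    val <- row[[rank]]
    if (!is.null(val) && !is.na(val) && nzchar(val)) return(val)
    for (j in rev(seq_len(ri - 1))) {
      parent <- row[[ranks[j]]]
      if (!is.na(parent) && nzchar(parent)) {
        return(paste0("unclassified_", parent))
      }
    }
    "unclassified_root"
  }, character(1))
}

# aggregate a per-taxon named numeric by a taxonomy rank
aggregate_rank <- function(values, taxonomy, rank) {
  labels <- rank_labels(names(values), taxonomy, rank)
  tapply(values, labels, sum)
}

#' Shared core between two regions at a taxonomy rank
#'
#' Cross-region cores cannot be matched OTU-by-OTU (different amplified
#' regions yield different OTU spaces), so each region's core abundance
#' profile is aggregated to a taxonomic rank (order, by convention) and the
#' shared core is the set of rank labels present in both.
#'
#' @param coreA,coreB `core_set` objects.
#' @param tableA,tableB the regions' count matrices (for abundance profiles).
#' @param designA,designB the regions' designs.
#' @param taxonomy taxonomy data.frame (see [read_taxonomy()]).
#' @param rank rank at which to match (default `"order"`).
#' @return list of class `shared_core`: `rank`, `shared` (labels),
#'   `profileA`, `profileB` (rank-level relative profiles of each core),
#'   `shareA`, `shareB` (fraction of each core profile in shared labels).
#' @export
shared_core <- function(coreA, coreB, tableA, tableB, designA, designB,
                        taxonomy, rank = "order") {
  profile <- function(core, table, design) {
    d <- design_region(design, core$region)
    counts <- rowSums(table[core$core_taxa, d$sample_id, drop = FALSE])
    agg <- aggregate_rank(counts, taxonomy, rank)
    agg / sum(agg)
  }
  pA <- profile(coreA, tableA, designA)
  pB <- profile(coreB, tableB, designB)
  shared <- intersect(names(pA), names(pB))
  structure(list(rank = rank, shared = shared, profileA = pA, profileB = pB,
                 shareA = sum(pA[shared]), shareB = sum(pB[shared])),
            class = "shared_core")
}

#' @export
print.shared_core <- function(x, ...) {
  cat(sprintf("Shared core at rank '%s': %d shared labels\n", x$rank,
              length(x$shared)))
  cat(sprintf("  core abundance share in shared labels: %.1f%% / %.1f%%\n",
              100 * x$shareA, 100 * x$shareB))
  invisible(x)
}

#' Moving-window analysis of community change
#'
#' For each consecutive time-point pair (t, t+1) the distances between all
#' replicate pairings (replicate i at t vs replicate j at t+1) are collected;
#' their mean tracks the month-to-month rate of community change, with SEM
#' over the pairings (reported as 0, flagged, when only one pairing exists).
#'
#' @param D distance matrix covering the region's samples.
#' @param design a [ts_design()].
#' @param region region label.
#' @return data.frame of class `moving_window`: `t_from`, `t_to`,
#'   `mean_dissimilarity`, `sem`, `n_pairs`, `sem_defined`.
#' @export
moving_window <- function(D, design, region) {
  d <- design_region(design, region)
  tps <- sort(unique(d$time_point))
  if (length(tps) < 2) stop("need >= 2 time points")
  out <- lapply(tps[-length(tps)], function(t) {
    a <- d$sample_id[d$time_point == t]
    b <- d$sample_id[d$time_point == t + 1]
    if (length(b) == 0) stop("missing interval ", t, " -> ", t + 1)
    vals <- as.vector(D[a, b, drop = FALSE])
    data.frame(t_from = t, t_to = t + 1,
               mean_dissimilarity = mean(vals),
               sem = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else 0,
               n_pairs = length(vals),
               sem_defined = length(vals) > 1)
  })
  out <- do.call(rbind, out)
  attr(out, "metric") <- attr(D, "metric")
  class(out) <- c("moving_window", "data.frame")
  out
}

#' Similarity-decay regression per replicate
#'
#' Distances are converted to similarity (`1 - D`) and log10-transformed;
#' within each technical replicate, ordinary least squares of log10
#' similarity on the time lag (months) over all within-replicate sample
#' pairs with lag >= 1. Pairs with similarity <= 0 are excluded (not
#' floored) and counted. The slope measures the per-month divergence rate.
#'
#' @param D distance matrix covering the region's samples.
#' @param design a [ts_design()].
#' @param region region label.
#' @return list of `decay_fit` objects (one per replicate), each with
#'   `slope`, `intercept`, `stderr_slope`, `p_slope`, `r2`, `n_pairs`,
#'   `n_excluded`, `replicate`, `metric`.
#' @export
similarity_decay <- function(D, design, region) {
  d <- design_region(design, region)
  reps <- sort(unique(d$replicate))
  fits <- lapply(reps, function(r) {
    dr <- d[d$replicate == r, , drop = FALSE]
    dr <- dr[order(dr$time_point), , drop = FALSE]
    n <- nrow(dr)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    dt <- dr$time_point[pairs[, 2]] - dr$time_point[pairs[, 1]]
    sim <- 1 - D[cbind(match(dr$sample_id[pairs[, 1]], rownames(D)),
                       match(dr$sample_id[pairs[, 2]], rownames(D)))]
    keep <- sim > 0
    n_excl <- sum(!keep)
    if (length(unique(dt[keep])) < 3) {
      stop("fewer than 3 distinct time lags with positive similarity")
    }
    ls <- log10(sim[keep]); lag <- dt[keep]
    if (stats::sd(ls) == 0) {
      # flat similarity series: slope 0 by definition, no evidence of decay
      fit <- list(slope = 0, intercept = ls[1], stderr_slope = 0, p_slope = 1,
                  r2 = 0)
    } else {
      lmfit <- stats::lm(ls ~ lag)
      # summary.lm warns on an exact fit; zero residuals are legitimate here
      sm <- suppressWarnings(summary(lmfit))
      p <- sm$coefficients[2, 4]
      fit <- list(slope = unname(stats::coef(lmfit)[2]),
                  intercept = unname(stats::coef(lmfit)[1]),
                  stderr_slope = sm$coefficients[2, 2],
                  p_slope = if (is.nan(p)) 0 else p,  # exact fit: se = 0
                  r2 = sm$r.squared)
    }
    structure(c(fit, list(n_pairs = sum(keep), n_excluded = n_excl,
                          replicate = r, metric = attr(D, "metric"))),
              class = "decay_fit")
  })
  names(fits) <- paste0("replicate_", reps)
  fits
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Similarity decay (replicate %s%s): slope = %.4g +/- %.2g per month, p = %.3g, r2 = %.3f (%d pairs, %d excluded)\n",
              x$replicate,
              if (is.null(x$metric)) "" else paste0(", ", x$metric),
              x$slope, x$stderr_slope, x$p_slope, x$r2, x$n_pairs, x$n_excluded))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Unpaired two-sample comparison of regression slopes
#'
#' Pooled-variance two-tailed Student's t-test between two groups of slopes
#' (e.g. the per-replicate decay slopes of two primer regions);
#' `df = nA + nB - 2`. Zero pooled variance with equal means gives t = 0,
#' p = 1; with unequal means the comparison is degenerate and flagged.
#'
#' @param slopesA,slopesB numeric vectors (>= 2 values each).
#' @return list of class `slope_comparison`: `t`, `df`, `p`,
#'   `mean_difference`, `degenerate`.
#' @export
compare_slopes <- function(slopesA, slopesB) {
  nA <- length(slopesA); nB <- length(slopesB)
  if (nA < 2 || nB < 2) stop("need >= 2 slopes per group")
  md <- mean(slopesA) - mean(slopesB)
  sp2 <- ((nA - 1) * stats::var(slopesA) + (nB - 1) * stats::var(slopesB)) /
    (nA + nB - 2)
  df <- nA + nB - 2
  if (sp2 == 0) {
    res <- list(t = if (md == 0) 0 else Inf * sign(md), df = df,
                p = if (md == 0) 1 else 0, mean_difference = md,
                degenerate = md != 0)
  } else {
    t_stat <- md / sqrt(sp2 * (1 / nA + 1 / nB))
    res <- list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df),
                mean_difference = md, degenerate = FALSE)
  }
  class(res) <- "slope_comparison"
  res
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("Slope comparison: mean difference = %.4g, t = %.4g, df = %d, p = %.4g%s\n",
              x$mean_difference, x$t, x$df, x$p,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Fit the power law S = c T^w to a cumulative-richness series
#'
#' OLS of log10 S on log10 t for t = 1..length(S); `w` is the slope and
#' `c = 10^intercept`. The workhorse behind [taxa_time_relationship()],
#' exported so precomputed accumulation series can be fitted directly.
#'
#' @param S cumulative distinct-taxon counts at time points 1..T (all > 0).
#' @param level,replicate,region metadata carried into the fit object.
#' @return object of class `str_fit` with `c`, `w`, `stderr_w`, `r2`, `S`.
#' @export
fit_str <- function(S, level = "otu", replicate = NA, region = NA) {
  if (length(S) < 3) stop("need >= 3 time points")
  if (S[1] <= 0) stop("no taxa observed at the first time point")
  tt <- seq_along(S)
  fit <- stats::lm(log10(S) ~ log10(tt))
  # summary.lm warns on an exact power law; that case is a valid input here
  sm <- suppressWarnings(summary(fit))
  se <- sm$coefficients[2, 2]
  structure(list(c = 10^unname(stats::coef(fit)[1]),
                 w = unname(stats::coef(fit)[2]),
                 stderr_w = if (is.nan(se)) 0 else se,
                 r2 = sm$r.squared,
                 S = S, level = level, replicate = replicate, region = region),
            class = "str_fit")
}

#' Taxa-time relationship (power law S = c T^w)
#'
#' The cumulative number of distinct taxa observed through time points 1..t
#' is fitted as a power law by OLS of log10 S on log10 t; the exponent `w`
#' is the taxon replacement rate. Fits are per technical replicate (each
#' replicate's series is an independent realization). Taxa represented by a
#' single read in a replicate's whole series are removed first, a standard
#' guard against spurious singletons inflating turnover. At `level =
#' "genus"` counts are aggregated through the taxonomy before accumulation;
#' reads unclassified at genus form parent-labeled pseudo-genera.
#'
#' @param table taxa x samples count matrix.
#' @param design a [ts_design()].
#' @param region region label.
#' @param level `"otu"` (default) or `"genus"`.
#' @param taxonomy taxonomy data.frame, required for `level = "genus"`.
#' @return list of class `str_fit_set`: per-replicate `str_fit` objects
#'   (`c`, `w`, `stderr_w`, `r2`, `S`, `level`, `replicate`), plus `mean_w`
#'   and `sem_w` across replicates.
#' @export
taxa_time_relationship <- function(table, design, region,
                                   level = c("otu", "genus"),
                                   taxonomy = NULL) {
  level <- match.arg(level)
  if (level == "genus" && is.null(taxonomy)) stop("taxonomy required for genus level")
  d <- design_region(design, region)
  tps <- sort(unique(d$time_point))
  if (length(tps) < 3) stop("need >= 3 time points")
  reps <- sort(unique(d$replicate))
  fits <- lapply(reps, function(r) {
    dr <- d[d$replicate == r, , drop = FALSE]
    dr <- dr[order(dr$time_point), , drop = FALSE]
    sub <- table[, dr$sample_id, drop = FALSE]
    sub <- sub[rowSums(sub) != 1, , drop = FALSE]      # whole-series singletons out
    if (level == "genus") {
      sub <- rowsum(sub, group = rank_labels(rownames(sub), taxonomy, "genus"))
    }
    seen <- rep(FALSE, nrow(sub))
    S <- vapply(seq_len(ncol(sub)), function(j) {
      seen <<- seen | sub[, j] > 0
      sum(seen)
    }, numeric(1))
    fit_str(S, level = level, replicate = r, region = region)
  })
  ws <- vapply(fits, `[[`, numeric(1), "w")
  structure(list(fits = fits, mean_w = mean(ws),
                 sem_w = if (length(ws) > 1) stats::sd(ws) / sqrt(length(ws)) else 0,
                 level = level, region = region),
            class = "str_fit_set")
}

#' @export
print.str_fit <- function(x, ...) {
  cat(sprintf("Taxa-time relationship (%s, %s, replicate %s): S = %.3g * T^%.3f (se %.3g, r2 = %.3f)\n",
              x$region, x$level, x$replicate, x$c, x$w, x$stderr_w, x$r2))
  invisible(x)
}

#' @export
coef.str_fit <- function(object, ...) c(c = object$c, w = object$w)

#' @export
print.str_fit_set <- function(x, ...) {
  for (f in x$fits) print(f)
  cat(sprintf("  mean w = %.3f +/- %.3f (SEM over replicates)\n",
              x$mean_w, x$sem_w))
  invisible(x)
}

#' End-to-end comparison of two primer regions
#'
#' Orchestrates the full bias-robustness analysis on two regions sharing the
#' same time points: per-region distance matrices for the three metrics and
#' Mantel tests between regions; NMDS per region and Procrustes/PROTEST;
#' moving-window series per region with their Pearson correlation;
#' similarity-decay slope comparison per metric; taxa-time relationship
#' exponent comparison; core detection (plus order-level shared core when a
#' taxonomy is supplied).
#'
#' @param tableA,tableB count matrices of the two regions.
#' @param tree rooted phylogeny covering the taxa of both tables.
#' @param design a [ts_design()] covering both regions' samples.
#' @param regionA,regionB region labels (defaults: the two regions found in
#'   `design`, in order).
#' @param taxonomy optional taxonomy for the shared-core summary.
#' @param subsample_depth per-sample rarefaction depth for the distance
#'   matrices (`NULL` = raw counts).
#' @param n_perm permutations for Mantel and PROTEST.
#' @param seed integer seed.
#' @return list of class `region_comparison`; see components in the
#'   implementation (mantel per metric, procrustes, moving-window
#'   correlation, decay comparisons, STR comparison, cores).
#' @export
run_region_comparison <- function(tableA, tableB, tree, design,
                                  regionA = NULL, regionB = NULL,
                                  taxonomy = NULL, subsample_depth = NULL,
                                  n_perm = 999, seed = 1) {
  regions <- unique(design$region)
  if (is.null(regionA)) regionA <- regions[1]
  if (is.null(regionB)) regionB <- regions[2]
  dA <- design_region(design, regionA)
  dB <- design_region(design, regionB)
  if (!identical(paste(dA$time_point, dA$replicate),
                 paste(dB$time_point, dB$replicate))) {
    stop("regions do not share the same (time point, replicate) layout")
  }
  tableA <- tableA[, dA$sample_id, drop = FALSE]
  tableB <- tableB[, dB$sample_id, drop = FALSE]
  metrics <- c("bray_curtis", "unifrac_unweighted", "unifrac_weighted")
  DA <- lapply(metrics, function(m) {
    distance_matrix(tableA, m, tree = tree, subsample_depth = subsample_depth,
                    seed = seed)
  })
  DB <- lapply(metrics, function(m) {
    distance_matrix(tableB, m, tree = tree, subsample_depth = subsample_depth,
                    seed = seed + 1)
  })
  names(DA) <- names(DB) <- metrics

  mantel_res <- lapply(metrics, function(m) {
    mantel(DA[[m]], DB[[m]], n_perm = n_perm, seed = seed)
  })
  names(mantel_res) <- metrics

  # rows are aligned positionally by the shared (time, replicate) layout;
  # sample ids legitimately differ between regions
  ordA <- nmds(DA$bray_curtis, k = 2, seed = seed)
  ordB <- nmds(DB$bray_curtis, k = 2, seed = seed + 1)
  proc <- procrustes(unname(ordA$points), unname(ordB$points),
                     n_perm = n_perm, seed = seed)

  mw <- lapply(metrics, function(m) {
    a <- moving_window(DA[[m]], design, regionA)
    b <- moving_window(DB[[m]], design, regionB)
    list(A = a, B = b,
         pearson_r = stats::cor(a$mean_dissimilarity, b$mean_dissimilarity))
  })
  names(mw) <- metrics

  decay <- lapply(metrics, function(m) {
    fa <- similarity_decay(DA[[m]], design, regionA)
    fb <- similarity_decay(DB[[m]], design, regionB)
    list(A = fa, B = fb,
         comparison = compare_slopes(vapply(fa, `[[`, numeric(1), "slope"),
                                     vapply(fb, `[[`, numeric(1), "slope")))
  })
  names(decay) <- metrics

  strA <- taxa_time_relationship(tableA, design, regionA)
  strB <- taxa_time_relationship(tableB, design, regionB)
  str_cmp <- compare_slopes(vapply(strA$fits, `[[`, numeric(1), "w"),
                            vapply(strB$fits, `[[`, numeric(1), "w"))

  coreA <- detect_core(tableA, design, regionA)
  coreB <- detect_core(tableB, design, regionB)
  shared <- if (!is.null(taxonomy)) {
    shared_core(coreA, coreB, tableA, tableB, design, design, taxonomy)
  } else NULL

  structure(list(regionA = regionA, regionB = regionB,
                 distances = list(A = DA, B = DB),
                 mantel = mantel_res, nmds = list(A = ordA, B = ordB),
                 procrustes = proc, moving_window = mw, decay = decay,
                 str = list(A = strA, B = strB, comparison = str_cmp),
                 core = list(A = coreA, B = coreB, shared = shared)),
            class = "region_comparison")
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf("Region comparison: %s vs %s\n", x$regionA, x$regionB))
  for (m in names(x$mantel)) {
    cat(sprintf("  Mantel (%s): r = %.3f, p = %.4g\n", m, x$mantel[[m]]$r,
                x$mantel[[m]]$p))
  }
  cat(sprintf("  Procrustes correlation = %.3f, p = %.4g\n",
              x$procrustes$correlation, x$procrustes$p))
  for (m in names(x$moving_window)) {
    cat(sprintf("  moving-window Pearson r (%s) = %.3f\n", m,
                x$moving_window[[m]]$pearson_r))
  }
  for (m in names(x$decay)) {
    cat(sprintf("  decay slope difference (%s): p = %.3g\n", m,
                x$decay[[m]]$comparison$p))
  }
  cat(sprintf("  STR: w(%s) = %.3f, w(%s) = %.3f, p = %.3g\n", x$regionA,
              x$str$A$mean_w, x$regionB, x$str$B$mean_w, x$str$comparison$p))
  cat(sprintf("  core: %d taxa (%.1f%%) / %d taxa (%.1f%%)\n",
              length(x$core$A$core_taxa), 100 * x$core$A$core_share,
              length(x$core$B$core_taxa), 100 * x$core$B$core_share))
  invisible(x)
}
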