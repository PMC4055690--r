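#' Rarefy a sample to a fixed depth
#'
#' Subsamples reads WITHOUT replacement (multivariate hypergeometric), the
#' normalization applied to every sample before alpha- and beta-diversity so
#' unequal sequencing depth does not masquerade as diversity differences.
#'
#' @param counts per-taxon non-negative integer vector.
#' @param depth number of reads to keep; must not exceed `sum(counts)`.
#' @param seed integer seed; the draw is deterministic given (counts, depth,
#'   seed).
#' @return integer vector of the same length (names preserved) summing to
#'   `depth`, each entry at most its input value.
#' @export
rarefy_counts <- function(counts, depth, seed = 1) {
  total <- sum(counts)
  if (depth > total) {
    stop(sprintf("depth %d exceeds total reads %d", depth, total))
  }
  if (!is.null(seed)) set.seed(seed)
  if (depth == total) {
    return(stats::setNames(as.integer(counts), names(counts)))
  }
  pool <- rep.int(seq_along(counts), counts)
  keep <- sample(pool, depth, replace = FALSE)
  out <- tabulate(keep, nbins = length(counts))
  names(out) <- names(counts)
  out
}

#' Closed-form expected richness under rarefaction
#'
#' The exact hypergeometric expectation of the number of taxa observed when
#' `depth` reads are drawn without replacement:
#' `sum_i [1 - C(N - N_i, depth) / C(N, depth)]` with `N = sum(counts)`,
#' evaluated through `lchoose` for numerical stability.
#'
#' @param counts per-taxon non-negative integer vector.
#' @param depth subsample size (<= `sum(counts)`).
#' @return expected number of observed taxa (real).
#' @export
expected_richness <- function(counts, depth) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (depth > N) stop("depth exceeds total reads")
  sum(1 - exp(lchoose(N - counts, depth) - lchoose(N, depth)))
}

#' Monte-Carlo rarefaction curve
#'
#' For each depth, the mean and empirical 95% interval (2.5/97.5 percentiles)
#' of observed richness over `iterations` independent subsamples.
#'
#' @param counts per-taxon integer vector.
#' @param depths increasing vector of subsample sizes.
#' @param iterations number of subsampling iterations (default 1000).
#' @param seed integer seed.
#' @return data.frame of class `rarefaction_curve` with columns `depth`,
#'   `mean_richness`, `lower`, `upper`; `iterations` stored as an attribute.
#' @export
rarefaction_curve <- function(counts, depths, iterations = 1000, seed = 1) {
  if (max(depths) > sum(counts)) stop("max depth exceeds total reads")
  set.seed(seed)
  pool <- rep.int(seq_along(counts), counts)
  res <- lapply(depths, function(d) {
    rich <- vapply(seq_len(iterations), function(i) {
      length(unique(sample(pool, d, replace = FALSE)))
    }, numeric(1))
    c(mean(rich), stats::quantile(rich, c(0.025, 0.975), names = FALSE))
  })
  out <- data.frame(depth = depths,
                    mean_richness = vapply(res, `[`, numeric(1), 1),
                    lower = vapply(res, `[`, numeric(1), 2),
                    upper = vapply(res, `[`, numeric(1), 3))
  attr(out, "iterations") <- iterations
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Shannon diversity index (natural log)
#'
#' `H = -sum p_i ln p_i` over taxa with nonzero counts, `p_i` the relative
#' abundances. Natural-log convention (as in mothur); bounded by
#' `0 <= H <= ln(S_obs)` with equality at a uniform composition.
#'
#' @param counts per-taxon non-negative vector with positive sum.
#' @return H in nats.
#' @export
shannon <- function(counts) {
  if (sum(counts) <= 0) stop("all-zero count vector")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Observed richness
#' @param counts per-taxon count vector.
#' @return number of taxa with nonzero counts.
#' @export
observed_richness <- function(counts) sum(counts > 0)

#' Per-sample alpha-diversity records
#'
#' Optionally rarefies each sample to a common depth first (one fixed
#' seed-controlled subsample per sample), then reports observed richness and
#' Shannon H.
#'
#' @param table taxa x samples count matrix.
#' @param depth rarefaction depth, or `NULL` to use raw counts.
#' @param seed integer seed for the subsampling.
#' @return data.frame with columns `sample_id`, `depth`, `observed_otus`,
#'   `shannon`.
#' @export
alpha_records <- function(table, depth = 2125, seed = 1) {
  out <- lapply(seq_len(ncol(table)), function(j) {
    x <- table[, j]
    if (!is.null(depth)) x <- rarefy_counts(x, depth, seed = seed + j)
    data.frame(sample_id = colnames(table)[j],
               depth = sum(x),
               observed_otus = observed_richness(x),
               shannon = shannon(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Paired comparison of per-time-point alpha diversity between regions
#'
#' Two-tailed paired t-test across time points on replicate-averaged values
#' (time point as the blocking factor). With zero variance of the paired
#' differences the test is degenerate: identical series give t = 0, p = 1; a
#' constant nonzero shift is reported with p = 0 and `degenerate = TRUE`.
#'
#' @param valuesA,valuesB aligned per-time-point values (replicates already
#'   averaged).
#' @return list of class `paired_comparison`: `difference` (mean A - B),
#'   `t`, `df`, `p`, `degenerate`.
#' @export
compare_alpha <- function(valuesA, valuesB) {
  if (length(valuesA) != length(valuesB)) stop("series must be aligned")
  n <- length(valuesA)
  if (n < 3) stop("need >= 3 paired time points")
  d <- valuesA - valuesB
  if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    res <- list(difference = mean(d),
                t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                df = n - 1,
                p = if (mean(d) == 0) 1 else 0,
                degenerate = mean(d) != 0)
  } else {
    tt <- stats::t.test(valuesA, valuesB, paired = TRUE)
    res <- list(difference = unname(tt$estimate), t = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE)
  }
  class(res) <- "paired_comparison"
  res
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat("Paired comparison across time points\n")
  cat(sprintf("  mean difference = %.4g, t = %.4g, df = %d, p = %.4g%s\n",
              x$difference, x$t, x$df, x$p,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}
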