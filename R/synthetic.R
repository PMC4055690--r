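#' Parameters for the synthetic community time series
#'
#' The defaults encode the study design the package targets: a one-year
#' monthly series (T = 12) of activated sludge sequenced in two 16S rRNA
#' regions ("V1V3", "V4") with two technical replicates each, normalized to
#' 2125 reads per sample; a dominant temporally stable core holding about two
#' thirds of total abundance; transient rare taxa occupying sub-windows of
#' the series; a seasonal temperature covariate; and one bloom taxon (the
#' Thiothrix-style case) whose amplification differs strongly between
#' regions (12-fold by default).
#'
#' Latent dynamics are an AR(1) walk on log abundance — the simplest
#' stationary autocorrelated positive process; `ar_rho` is the lag-1
#' autocorrelation and `ar_sigma` the innovation s.d. in log units. The
#' innovation amplitude is modulated seasonally (`season_amp`), following
#' the observation that activated-sludge communities change faster during
#' warm months: the s.d. at month t is
#' `ar_sigma * (1 + season_amp * (temp_t - mean) / amplitude)`. Both
#' regions observe the SAME latent series through their own multiplicative
#' per-taxon bias vector; only bias and sequencing noise differ between
#' regions. Technical replicates are modelled as independent PCR
#' amplifications: each replicate carries a small lognormal per-taxon bias
#' vector of its own (`replicate_bias_sdlog`) plus per-sample lognormal
#' amplification jitter (`replicate_jitter_sdlog`) before the multinomial
#' read draw, so replicate-to-replicate variability is amplification-level,
#' not merely multinomial. `temp_coupling` (s.d. of per-taxon temperature
#' coefficients on the log scale, per degC) is 0 by default, making
#' temperature a recorded covariate without compositional effect; set it > 0
#' to generate temperature-driven communities for constrained-ordination
#' power studies.
#'
#' @param n_core,n_transient counts of core and transient taxa.
#' @param T_points number of time points (months).
#' @param R technical replicates per region.
#' @param regions named list of per-taxon multiplicative bias vectors
#'   (length `n_core + n_transient`, all > 0), or a character vector of
#'   region labels, in which case lognormal(meanlog 0, sdlog
#'   `bias_sdlog`) vectors are drawn per region under `seed`.
#' @param depth reads per sample (multinomial size).
#' @param core_fraction share of total abundance held by core taxa.
#' @param ar_rho,ar_sigma AR(1) parameters of the latent log-abundance walk.
#' @param season_amp seasonal modulation of the innovation s.d. (0 disables).
#' @param bias_sdlog sdlog of drawn bias vectors when `regions` is labels.
#' @param replicate_bias_sdlog sdlog of the per-replicate PCR bias vector.
#' @param replicate_jitter_sdlog sdlog of the per-sample amplification jitter.
#' @param bloom `NULL`, or list with `taxon` (index), `peak_times` (integer
#'   vector), `peak_abundance` (latent relative abundance at peak),
#'   `width` (Gaussian bump s.d., months), `region_bias` (named numeric,
#'   extra bias multiplier per region), `baseline_log` (baseline log-weight
#'   of the bloom taxon, default -2: bloomers sit at a low background share
#'   so the bloom profile dominates their trajectory).
#' @param temperature list with `mean`, `amplitude` (degC), `phase` (months)
#'   for the sinusoid `mean + amplitude * sin(2*pi*(t - phase)/12)`.
#' @param temp_coupling s.d. of per-taxon temperature coefficients (log
#'   abundance per degC); 0 disables compositional temperature forcing.
#' @param seed integer seed governing every random draw.
#' @return list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_core = 20, n_transient = 80, T_points = 12,
                             R = 2, regions = c("V1V3", "V4"), depth = 2125,
                             core_fraction = 0.66, ar_rho = 0.8,
                             ar_sigma = 0.4, season_amp = 0.5,
                             bias_sdlog = 0.25,
                             replicate_bias_sdlog = 0.30,
                             replicate_jitter_sdlog = 0.15,
                             bloom = list(taxon = 1, peak_times = c(2, 11),
                                          peak_abundance = 0.05, width = 1,
                                          region_bias = c(V1V3 = 1.5,
                                                          V4 = 1 / 8)),
                             temperature = list(mean = 20, amplitude = 7,
                                                phase = 8),
                             temp_coupling = 0, seed = 1) {
  n <- n_core + n_transient
  if (n < 2) stop("need at least 2 taxa")
  if (depth < 1) stop("depth must be >= 1")
  if (core_fraction < 0 || core_fraction > 1) stop("core_fraction must be in [0,1]")
  if (is.character(regions)) {
    labels <- regions
    set.seed(seed + 1000L)
    regions <- stats::setNames(lapply(labels, function(r) {
      exp(stats::rnorm(n, 0, bias_sdlog))
    }), labels)
  }
  for (r in names(regions)) {
    b <- regions[[r]]
    if (length(b) != n) stop("bias vector for region '", r, "' has wrong length")
    if (any(b <= 0)) stop("bias factors must be > 0 (region '", r, "')")
  }
  if (!is.null(bloom)) {
    if (!is.null(bloom$region_bias)) {
      for (r in names(bloom$region_bias)) {
        if (r %in% names(regions)) {
          regions[[r]][bloom$taxon] <- regions[[r]][bloom$taxon] *
            bloom$region_bias[[r]]
        }
      }
    }
    if (is.null(bloom$width)) bloom$width <- 1
    if (is.null(bloom$baseline_log)) bloom$baseline_log <- -2
  }
  structure(list(n_core = n_core, n_transient = n_transient,
                 T_points = T_points, R = R, regions = regions, depth = depth,
                 core_fraction = core_fraction, ar_rho = ar_rho,
                 ar_sigma = ar_sigma, season_amp = season_amp,
                 replicate_bias_sdlog = replicate_bias_sdlog,
                 replicate_jitter_sdlog = replicate_jitter_sdlog,
                 bloom = bloom, temperature = temperature,
                 temp_coupling = temp_coupling, seed = seed),
            class = "synthetic_params")
}

#' Generate the latent (true) community series
#'
#' Core taxa are strictly positive at every time point; each transient taxon
#' occupies one contiguous random window of length < T. Log abundances follow
#' AR(1) dynamics around lognormal per-taxon baselines; each time-point
#' column is renormalized so core taxa jointly hold `core_fraction` of
#' abundance whenever any transient is present. The bloom, if any, is imposed
#' as a Gaussian-shaped floor on the bloom taxon's relative abundance at its
#' peak months, with the rest of the column rescaled.
#'
#' @param params a [synthetic_params()] object.
#' @return list of class `true_series` with elements `rel_abund` (taxa x T
#'   simplex columns), `occupancy` (taxa x T logical), `is_core`,
#'   `temperature` (length-T), `taxon_ids`, `params`.
#' @export
generate_true_series <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  n_core <- params$n_core; n_tr <- params$n_transient
  n <- n_core + n_tr; Tn <- params$T_points
  set.seed(params$seed)
  taxon_ids <- c(if (n_core > 0) sprintf("core_%03d", seq_len(n_core)),
                 if (n_tr > 0) sprintf("trans_%03d", seq_len(n_tr)))
  is_core <- rep(c(TRUE, FALSE), c(n_core, n_tr))

  tp <- seq_len(Tn)
  temp <- params$temperature$mean +
    params$temperature$amplitude * sin(2 * pi * (tp - params$temperature$phase) / 12)

  mu <- stats::rnorm(n, mean = 0, sd = 1)            # per-taxon baseline (log)
  if (!is.null(params$bloom)) {
    # bloomers have a low background share; their trajectory is the bloom
    mu[params$bloom$taxon] <- params$bloom$baseline_log
  }
  beta_temp <- if (params$temp_coupling > 0)
    stats::rnorm(n, 0, params$temp_coupling) else rep(0, n)

  rho <- params$ar_rho; sig <- params$ar_sigma
  # warm months innovate more (seasonal heteroscedasticity)
  amp <- params$temperature$amplitude
  ztemp <- if (amp > 0) (temp - params$temperature$mean) / amp else rep(0, Tn)
  sig_t <- sig * pmax(1 + params$season_amp * ztemp, 0)
  z <- matrix(0, n, Tn)
  sd0 <- if (sig > 0) sig_t[1] / sqrt(max(1 - rho^2, 1e-12)) else 0
  z[, 1] <- stats::rnorm(n, 0, sd0)
  if (Tn > 1) {
    for (t in 2:Tn) z[, t] <- rho * z[, t - 1] + stats::rnorm(n, 0, sig_t[t])
  }
  loga <- mu + z + outer(beta_temp, temp - mean(temp))

  occ <- matrix(TRUE, n, Tn)
  if (n_tr > 0) {
    for (i in seq_len(n_tr)) {
      len <- sample.int(Tn - 1, 1)
      start <- sample.int(Tn - len + 1, 1)
      w <- rep(FALSE, Tn); w[start:(start + len - 1)] <- TRUE
      occ[n_core + i, ] <- w
    }
  }

  w <- exp(loga) * occ
  p <- matrix(0, n, Tn)
  cf <- params$core_fraction
  for (t in seq_len(Tn)) {
    core_sum <- if (n_core > 0) sum(w[is_core, t]) else 0
    tr_sum <- if (n_tr > 0) sum(w[!is_core, t]) else 0
    if (core_sum > 0 && tr_sum > 0) {
      p[is_core, t] <- cf * w[is_core, t] / core_sum
      p[!is_core, t] <- (1 - cf) * w[!is_core, t] / tr_sum
    } else if (core_sum + tr_sum > 0) {
      p[, t] <- w[, t] / (core_sum + tr_sum)
    } else {
      stop("no taxa present at time point ", t)
    }
  }
  if (n_core > 0 && n_tr > 0 && abs(cf - sum(p[is_core, 1])) > 0.05) {
    warning("core_fraction not attained; best effort")
  }

  bloom <- params$bloom
  if (!is.null(bloom)) {
    idx <- bloom$taxon
    prof <- vapply(tp, function(t) {
      bloom$peak_abundance *
        max(exp(-0.5 * ((t - bloom$peak_times) / bloom$width)^2))
    }, numeric(1))
    for (t in seq_len(Tn)) {
      if (prof[t] > p[idx, t] && p[idx, t] >= 0) {
        others <- setdiff(seq_len(n), idx)
        p[others, t] <- p[others, t] * (1 - prof[t]) / max(1 - p[idx, t], 1e-12)
        p[idx, t] <- prof[t]
      }
    }
  }

  dimnames(p) <- list(taxon_ids, paste0("t", tp))
  structure(list(rel_abund = p, occupancy = p > 0, is_core = is_core,
                 temperature = temp, taxon_ids = taxon_ids, params = params),
            class = "true_series")
}

#' Apply multiplicative per-taxon primer bias to a series
#'
#' Models differential PCR amplification: each taxon's relative abundance is
#' multiplied by its bias factor and the column renormalized,
#' `p'_i = b_i p_i / sum_j b_j p_j`. A zero abundance stays zero — bias can
#' never create presence.
#'
#' @param series a `true_series` or a taxa x time simplex matrix.
#' @param bias positive numeric vector, one factor per taxon.
#' @return object of the same shape with biased columns.
#' @export
apply_primer_bias <- function(series, bias) {
  p <- if (inherits(series, "true_series")) series$rel_abund else as.matrix(series)
  if (length(bias) != nrow(p)) stop("bias length must equal number of taxa")
  if (any(bias <= 0)) stop("all bias factors must be > 0")
  bp <- p * bias
  bp <- sweep(bp, 2, colSums(bp), "/")
  if (inherits(series, "true_series")) {
    series$rel_abund <- bp
    series
  } else bp
}

#' Draw sequencing reads from a (possibly biased) series
#'
#' For each time point and each of `R` technical replicates, one independent
#' multinomial draw of `depth` reads. Replicates model independent PCR
#' amplifications: with `replicate_bias_sdlog > 0` each replicate carries
#' its own fixed lognormal per-taxon bias vector, and with
#' `replicate_jitter_sdlog > 0` every sample additionally receives
#' per-taxon lognormal amplification jitter before the draw. Both default
#' to 0, giving pure multinomial replicates. Absent taxa stay absent under
#' any amplification distortion.
#'
#' @param series `true_series` or taxa x time simplex matrix.
#' @param depth reads per sample.
#' @param R replicates per time point.
#' @param seed integer seed.
#' @param region region label recorded in the design and sample ids.
#' @param temperature optional length-T vector copied into the design
#'   (taken from the series when it is a `true_series`).
#' @param replicate_bias_sdlog sdlog of the per-replicate PCR bias vector.
#' @param replicate_jitter_sdlog sdlog of the per-sample amplification
#'   jitter.
#' @return list with `table` (count matrix) and `design` ([ts_design()]).
#' @export
sample_reads <- function(series, depth = 2125, R = 2, seed = 1,
                         region = "V1V3", temperature = NULL,
                         replicate_bias_sdlog = 0,
                         replicate_jitter_sdlog = 0) {
  p <- if (inherits(series, "true_series")) series$rel_abund else as.matrix(series)
  if (is.null(temperature) && inherits(series, "true_series")) {
    temperature <- series$temperature
  }
  Tn <- ncol(p)
  set.seed(seed)
  n <- nrow(p)
  rep_bias <- lapply(seq_len(R), function(r) {
    if (replicate_bias_sdlog > 0) {
      exp(stats::rnorm(n, 0, replicate_bias_sdlog))
    } else rep(1, n)
  })
  counts <- matrix(0L, nrow(p), Tn * R)
  ids <- character(Tn * R)
  tps <- integer(Tn * R); reps <- integer(Tn * R)
  k <- 0
  for (t in seq_len(Tn)) {
    for (r in seq_len(R)) {
      k <- k + 1
      pj <- p[, t] * rep_bias[[r]]
      if (replicate_jitter_sdlog > 0) {
        pj <- pj * exp(stats::rnorm(n, 0, replicate_jitter_sdlog))
      }
      counts[, k] <- stats::rmultinom(1, depth, pj / sum(pj))[, 1]
      ids[k] <- sprintf("%s_t%02d_r%d", region, t, r)
      tps[k] <- t; reps[k] <- r
    }
  }
  dimnames(counts) <- list(rownames(p), ids)
  design <- data.frame(sample_id = ids, time_point = tps, replicate = reps,
                       region = region, stringsAsFactors = FALSE)
  if (!is.null(temperature)) design$temperature <- temperature[tps]
  list(table = counts, design = ts_design(design))
}

#' Generate a random rooted binary tree over the taxa
#'
#' Random topology via [ape::rtree()]; branch lengths i.i.d. exponential with
#' mean 0.1. Deterministic under `seed`.
#'
#' @param taxon_ids character vector of leaf labels (>= 2).
#' @param seed integer seed.
#' @param mean_branch mean branch length.
#' @return a `phylo` object with `2n - 2` edges.
#' @export
generate_tree <- function(taxon_ids, seed = 1, mean_branch = 0.1) {
  n <- length(taxon_ids)
  if (n < 2) stop("need at least 2 taxa to build a tree")
  set.seed(seed)
  tree <- ape::rtree(n, rooted = TRUE, tip.label = taxon_ids)
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / mean_branch)
  tree
}

#' Generate one full two-region synthetic study
#'
#' Convenience orchestration: latent series, per-region primer bias,
#' multinomial read sampling, and a random phylogeny, mirroring the
#' 12 x 2 x 2 design. Regions share the latent series; only bias and
#' sampling noise differ.
#'
#' @param params a [synthetic_params()].
#' @param independent_regions if `TRUE`, each region gets its OWN latent
#'   series (negative control for bias-robustness analyses).
#' @return list with `truth` (the latent series; a named list of series when
#'   `independent_regions`), `tables` and `designs` (named by region),
#'   `table`/`design` (all regions combined), and `tree`.
#' @export
simulate_dataset <- function(params = synthetic_params(),
                             independent_regions = FALSE) {
  region_names <- names(params$regions)
  if (independent_regions) {
    truths <- lapply(seq_along(region_names), function(i) {
      pp <- params; pp$seed <- params$seed + 7919L * i
      generate_true_series(pp)
    })
    names(truths) <- region_names
  } else {
    truth <- generate_true_series(params)
    truths <- stats::setNames(rep(list(truth), length(region_names)), region_names)
  }
  tables <- list(); designs <- list()
  for (i in seq_along(region_names)) {
    rg <- region_names[i]
    biased <- apply_primer_bias(truths[[rg]], params$regions[[rg]])
    ds <- sample_reads(biased, depth = params$depth, R = params$R,
                       seed = params$seed + 101L * i, region = rg,
                       replicate_bias_sdlog = params$replicate_bias_sdlog,
                       replicate_jitter_sdlog = params$replicate_jitter_sdlog)
    tables[[rg]] <- ds$table
    designs[[rg]] <- ds$design
  }
  combined <- do.call(cbind, tables)
  design_all <- ts_design(do.call(rbind, lapply(designs, as.data.frame)))
  tree <- generate_tree(rownames(combined), seed = params$seed + 5L)
  list(truth = if (independent_regions) truths else truths[[1]],
       tables = tables, designs = designs,
       table = combined, design = design_all, tree = tree)
}

#' Generate synthetic FISH fields of view
#'
#' Each field of view (FOV) gets a DAPI mask of random circular blobs and a
#' probe mask drawn as a random subset of the DAPI-positive pixels covering a
#' per-FOV fraction `target_fraction + N(0, noise_sd)` truncated to [0, 1] —
#' probe is a subset of DAPI by construction.
#'
#' @param target_fraction true biovolume fraction in [0, 1].
#' @param n_fov number of fields of view.
#' @param noise_sd s.d. of the per-FOV fraction perturbation.
#' @param image_size image side length in pixels (square images).
#' @param n_blobs number of DAPI blobs per FOV.
#' @param seed integer seed.
#' @return list of `n_fov` lists with logical matrices `probe` and `dapi`.
#' @export
generate_fish_fovs <- function(target_fraction, n_fov = 30, noise_sd = 0.02,
                               image_size = 512, n_blobs = 8, seed = 1) {
  if (target_fraction < 0 || target_fraction > 1) {
    stop("target_fraction must be in [0,1]")
  }
  set.seed(seed)
  xs <- matrix(rep(seq_len(image_size), image_size), image_size)
  ys <- t(xs)
  lapply(seq_len(n_fov), function(f) {
    dapi <- matrix(FALSE, image_size, image_size)
    for (b in seq_len(n_blobs)) {
      cx <- stats::runif(1, 1, image_size); cy <- stats::runif(1, 1, image_size)
      r <- stats::runif(1, image_size / 40, image_size / 10)
      dapi <- dapi | ((xs - cx)^2 + (ys - cy)^2 <= r^2)
    }
    npix <- sum(dapi)
    frac <- min(max(target_fraction + stats::rnorm(1, 0, noise_sd), 0), 1)
    probe <- matrix(FALSE, image_size, image_size)
    if (npix > 0 && frac > 0) {
      take <- round(frac * npix)
      if (take > 0) {
        idx <- which(dapi)
        probe[sample(idx, take)] <- TRUE
      }
    }
    list(probe = probe, dapi = dapi)
  })
}
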