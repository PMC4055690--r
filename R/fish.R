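#' Biovolume fraction of one field of view
#'
#' Ratio of probe-positive (Cy3) to DAPI-positive pixel counts of a paired
#' mask image — the per-FOV estimate of the fraction of total biomass the
#' probed population occupies. A FOV with an empty DAPI mask carries no
#' information and returns `NA` (the exclusion signal), never an error.
#' By default probe pixels outside the DAPI mask still count; set
#' `intersect = TRUE` to restrict the numerator to probe AND DAPI.
#'
#' @param fov list with binary matrices `probe` and `dapi` of identical
#'   dimensions.
#' @param intersect count only probe pixels inside the DAPI mask.
#' @return probe/DAPI pixel ratio, or `NA_real_` when DAPI is empty.
#' @export
biovolume_fov <- function(fov, intersect = FALSE) {
  probe <- fov$probe; dapi <- fov$dapi
  if (!all(dim(probe) == dim(dapi))) stop("probe and DAPI masks differ in size")
  n_dapi <- sum(dapi != 0)
  if (n_dapi == 0) return(NA_real_)
  n_probe <- if (intersect) sum(probe != 0 & dapi != 0) else sum(probe != 0)
  n_probe / n_dapi
}

#' Biovolume estimate for a sample from its fields of view
#'
#' Per-FOV probe/DAPI ratios averaged over usable FOVs (the quoted per-FOV
#' averaging procedure, not pooled pixel totals; `pooled = TRUE` switches to
#' the pooled-pixel alternative). FOVs with empty DAPI masks are excluded
#' and counted.
#'
#' @param fovs list of FOV pairs (see [biovolume_fov()]).
#' @param intersect passed to [biovolume_fov()].
#' @param pooled use pooled pixel totals across FOVs instead of the per-FOV
#'   ratio average.
#' @return list of class `biovolume_estimate`: `mean`, `sem`, `ratios`,
#'   `n_fov` (usable), `n_excluded`.
#' @export
biovolume_sample <- function(fovs, intersect = FALSE, pooled = FALSE) {
  ratios <- vapply(fovs, biovolume_fov, numeric(1), intersect = intersect)
  usable <- !is.na(ratios)
  if (!any(usable)) stop("no usable fields of view (all DAPI masks empty)")
  r <- ratios[usable]
  if (pooled) {
    probe_tot <- sum(vapply(fovs[usable], function(f) {
      if (intersect) sum(f$probe != 0 & f$dapi != 0) else sum(f$probe != 0)
    }, numeric(1)))
    dapi_tot <- sum(vapply(fovs[usable], function(f) sum(f$dapi != 0),
                           numeric(1)))
    m <- probe_tot / dapi_tot
  } else {
    m <- mean(r)
  }
  structure(list(mean = m,
                 sem = if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else 0,
                 ratios = r, n_fov = length(r), n_excluded = sum(!usable)),
            class = "biovolume_estimate")
}

#' @export
print.biovolume_estimate <- function(x, ...) {
  cat(sprintf("Biovolume fraction: %.3f +/- %.3f (SEM, %d FOV%s)\n",
              x$mean, x$sem, x$n_fov,
              if (x$n_excluded > 0) sprintf(", %d excluded", x$n_excluded) else ""))
  invisible(x)
}

#' Correlate FISH biovolumes with amplicon relative abundance
#'
#' Pearson correlation across aligned time points between the
#' sequencing-independent FISH biovolume series and a region's relative
#' abundance series for the same taxon, with a two-tailed p-value from the
#' t transform — the validation that amplicon data track a population's
#' true trajectory even when its absolute relative abundance is biased.
#'
#' @param biovolumes per-time-point biovolume fractions.
#' @param rel_abund per-time-point relative abundances, same alignment.
#' @return list of class `fish_correlation`: `r`, `p`, `n`.
#' @export
correlate_fish_amplicon <- function(biovolumes, rel_abund) {
  if (length(biovolumes) != length(rel_abund)) stop("series must be aligned")
  n <- length(biovolumes)
  if (n < 3) stop("need >= 3 time points")
  if (stats::sd(biovolumes) == 0 || stats::sd(rel_abund) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(biovolumes, rel_abund, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n),
            class = "fish_correlation")
}

#' @export
print.fish_correlation <- function(x, ...) {
  cat(sprintf("FISH-amplicon correlation: r = %.3f, p = %.4g (n = %d)\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' Write a binary mask as a plain-text PGM (P2) image
#' @param mask binary matrix (0/1 or logical).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pgm <- function(mask, path) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "1"), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a plain-text PGM (P2) mask image
#' @param path file path.
#' @return logical matrix (pixel > 0).
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1] != "P2") stop("only plain (P2) PGM supported")
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- as.integer(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
  matrix(vals > 0, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}
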