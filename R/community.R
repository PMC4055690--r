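#' Construct and validate a community count table
#'
#' A community table is the substrate of every metric in the package: a plain
#' numeric matrix of non-negative integer read counts with taxa as rows and
#' samples as columns, both carrying unique names. Using a base matrix (rather
#' than a bespoke container) keeps the table directly usable with `apply()`,
#' subsetting and the rest of base R, the way community matrices are handled
#' in vegan.
#'
#' @param counts numeric matrix, taxa x samples, non-negative integers.
#' @param taxon_ids,sample_ids optional character vectors overriding dimnames.
#' @return the validated integer matrix with dimnames set.
#' @export
community_table <- function(counts, taxon_ids = rownames(counts),
                            sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(taxon_ids) || is.null(sample_ids)) {
    stop("community_table requires taxon and sample ids (dimnames)")
  }
  rownames(counts) <- taxon_ids
  colnames(counts) <- sample_ids
  storage.mode(counts) <- "double"
  validate_community_table(counts)
  storage.mode(counts) <- "integer"
  counts
}

#' Validate the community-table invariants
#'
#' Checks non-negativity, integrality, unique ids and positive sample sums.
#' Called by every reader and constructor; exported so pipelines can re-check
#' tables after manual filtering.
#'
#' @param counts taxa x samples matrix.
#' @return invisibly, `counts`.
#' @export
validate_community_table <- function(counts) {
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer or negative count for taxon '%s' in sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  cs <- colSums(counts)
  if (any(cs == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[cs == 0], collapse = ", "))
  }
  invisible(counts)
}

#' Construct and validate a time-series design
#'
#' Maps each sample to its (time point, technical replicate, primer region)
#' coordinate plus optional operational covariates (temperature, MLSS, SVI,
#' BOD in the activated-sludge setting). Time points are 1-based consecutive
#' integers (months).
#'
#' @param df data.frame with columns `sample_id`, `time_point`, `replicate`,
#'   `region`; any further columns are treated as real-valued covariates.
#' @return data.frame of class `ts_design`.
#' @export
ts_design <- function(df) {
  req <- c("sample_id", "time_point", "replicate", "region")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("design is missing required column(s): ",
         paste(missing_cols, collapse = ", "),
         " (required: ", paste(req, collapse = ", "), ")")
  }
  df$sample_id <- as.character(df$sample_id)
  df$time_point <- as.integer(df$time_point)
  df$replicate <- as.integer(df$replicate)
  df$region <- as.character(df$region)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in design")
  key <- paste(df$time_point, df$replicate, df$region, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (time_point, replicate, region) triple in design")
  }
  tp <- sort(unique(df$time_point))
  if (!identical(tp, seq.int(tp[1], tp[length(tp)]))) {
    warning("time points are not contiguous")
  }
  for (cv in setdiff(names(df), req)) {
    df[[cv]] <- suppressWarnings(as.numeric(df[[cv]]))
  }
  class(df) <- c("ts_design", "data.frame")
  df
}

#' Subset a design to one region, ordered by time then replicate
#' @param design a `ts_design`.
#' @param region region label.
#' @return the subset, ordered by (time_point, replicate).
#' @export
design_region <- function(design, region) {
  d <- design[design$region == region, , drop = FALSE]
  if (nrow(d) == 0) stop("no samples for region '", region, "'")
  d[order(d$time_point, d$replicate), , drop = FALSE]
}

#' Relative abundances of a community table
#' @param counts taxa x samples count matrix.
#' @return matrix of column-normalized proportions.
#' @export
relative_abundance <- function(counts) {
  sweep(counts, 2, colSums(counts), "/")
}
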