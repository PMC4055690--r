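#' Read a community table from a tab-separated file
#'
#' Expected layout: header row of sample ids, first column taxon ids, integer
#' cells (taxa as rows, samples as columns).
#'
#' @param path file path.
#' @return validated count matrix (see [community_table()]).
#' @export
read_community_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("community table needs a taxon-id column plus >= 1 sample")
  taxa <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      stop(sprintf("invalid count '%s' for taxon '%s' in sample '%s'",
                   raw[[j + 1]][bad[1]], taxa[bad[1]], sample_ids[j]))
    }
    mat[, j] <- v
  }
  community_table(mat, taxon_ids = taxa, sample_ids = sample_ids)
}

#' Write a community table as TSV
#' @param counts taxa x samples count matrix.
#' @param path output file path.
#' @param id_column name for the taxon-id column (default "taxon_id").
#' @return invisibly, `path`.
#' @export
write_community_table <- function(counts, path, id_column = "taxon_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a time-series design (sample metadata) from TSV
#' @param path file path; must provide columns sample_id, time_point,
#'   replicate, region; further columns become numeric covariates.
#' @return a [ts_design()].
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ts_design(df)
}

#' Write a time-series design as TSV
#' @param design a `ts_design`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from a newick file
#'
#' Thin wrapper over [ape::read.tree()] adding the validation the rest of the
#' package relies on: unique leaf labels and a branch length on every edge
#' (missing lengths are set to 0 with a warning, so UniFrac sees a complete
#' edge-length vector).
#'
#' @param path newick file path.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file '", path, "'")
  validate_tree(tree)
}

#' Validate a phylo object for use as a UniFrac substrate
#' @param tree a `phylo` object.
#' @return the tree, with missing branch lengths replaced by 0.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' Write a distance matrix to file
#'
#' Two dialects: `"square"` writes a full symmetric TSV with a header row and
#' a leading `# metric:` comment; `"lower_triangle"` writes the PHYLIP-style
#' layout (count line, then one row per sample with the distances to the
#' previous samples), also with the metric comment.
#'
#' @param D symmetric distance matrix with sample ids as dimnames; a `metric`
#'   attribute, if present, is preserved in the file header.
#' @param path output file path.
#' @param dialect `"square"` (default) or `"lower_triangle"`.
#' @return invisibly, `path`.
#' @export
write_distance_matrix <- function(D, path, dialect = c("square", "lower_triangle")) {
  dialect <- match.arg(dialect)
  ids <- colnames(D)
  metric <- attr(D, "metric")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metric)) writeLines(paste0("# metric: ", metric), con)
  if (dialect == "square") {
    writeLines(paste(c("sample_id", ids), collapse = "\t"), con)
    for (i in seq_along(ids)) {
      writeLines(paste(c(ids[i], format(D[i, ], digits = 17, trim = TRUE)),
                       collapse = "\t"), con)
    }
  } else {
    writeLines(as.character(length(ids)), con)
    for (i in seq_along(ids)) {
      row <- if (i == 1) ids[1] else
        paste(c(ids[i], format(D[i, seq_len(i - 1)], digits = 17, trim = TRUE)),
              collapse = "\t")
      writeLines(row, con)
    }
  }
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' The dialect is detected from the file: a leading integer line means
#' PHYLIP lower-triangle, otherwise a square TSV with header is assumed.
#'
#' @param path file path.
#' @return symmetric matrix with `metric` attribute restored when present.
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  metric <- NULL
  if (length(lines) > 0 && grepl("^# metric:", lines[1])) {
    metric <- trimws(sub("^# metric:", "", lines[1]))
    lines <- lines[-1]
  }
  first <- strsplit(lines[1], "\t")[[1]]
  if (length(first) == 1 && grepl("^[0-9]+$", first)) {
    n <- as.integer(first)
    ids <- character(n)
    D <- matrix(0, n, n)
    for (i in seq_len(n)) {
      parts <- strsplit(lines[i + 1], "\t")[[1]]
      ids[i] <- parts[1]
      if (i > 1) {
        vals <- as.numeric(parts[-1])
        D[i, seq_len(i - 1)] <- vals
        D[seq_len(i - 1), i] <- vals
      }
    }
  } else {
    ids <- first[-1]
    n <- length(ids)
    D <- matrix(0, n, n)
    for (i in seq_len(n)) {
      parts <- strsplit(lines[i + 1], "\t")[[1]]
      D[i, ] <- as.numeric(parts[-1])
    }
  }
  dimnames(D) <- list(ids, ids)
  if (max(abs(D - t(D))) > 1e-12) stop("matrix in '", path, "' is not symmetric")
  if (!is.null(metric)) attr(D, "metric") <- metric
  D
}

#' Read a taxonomy table
#'
#' TSV with a `taxon_id` column and one column per rank (e.g. domain, phylum,
#' class, order, family, genus). Empty cells are treated as unclassified.
#'
#' @param path file path.
#' @return data.frame keyed by taxon_id.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"taxon_id" %in% names(df)) stop("taxonomy needs a 'taxon_id' column")
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon ids in taxonomy")
  df
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values that parse
#' as numbers are returned numeric.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
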