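#' Construct a validated taxonomic count matrix
#'
#' Wraps an n-by-p matrix of sequencing read counts (rows = samples, columns =
#' taxa) after validating that all entries are non-negative integers and that
#' sample and taxon labels are unique. All taxa are assumed to be at the same
#' taxonomic level.
#'
#' @param values numeric matrix of non-negative integer counts.
#' @param sample_ids optional character vector of n sample labels; defaults to
#'   existing rownames or `sample1..n`.
#' @param taxon_ids optional character vector of p taxon labels; defaults to
#'   existing colnames or `taxon1..p`.
#' @return an object of class `count_matrix` (an integer-valued matrix with
#'   dimnames).
#' @export
count_matrix <- function(values, sample_ids = NULL, taxon_ids = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.numeric(values)) stop("counts must be numeric")
  n <- nrow(values); p <- ncol(values)
  if (n < 2L || p < 2L) stop("count matrix needs at least 2 samples and 2 taxa")
  bad <- which(!is.finite(values) | values < 0 | values != round(values))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(values))
    stop(sprintf("invalid count at sample row %d, taxon column %d: %s",
                 ij[1L], ij[2L], format(values[bad[1L]])))
  }
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  if (is.null(taxon_ids)) taxon_ids <- colnames(values)
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(p))
  if (anyDuplicated(sample_ids)) stop("duplicate sample labels")
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon labels")
  if (length(sample_ids) != n || length(taxon_ids) != p)
    stop("label lengths do not match matrix dimensions")
  dimnames(values) <- list(sample_ids, taxon_ids)
  structure(values, class = c("count_matrix", "matrix", "array"))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d samples x %d taxa, %.1f%% zeros\n",
              nrow(x), ncol(x), 100 * mean(x == 0)))
  invisible(x)
}

#' Read a taxonomic count table from TSV
#'
#' Expects a tab-separated file with a header row of taxon IDs and a first
#' column of sample IDs (samples in rows). Use `transpose = TRUE` for tables
#' stored taxa-by-samples.
#'
#' @param path path to the TSV file.
#' @param transpose logical; if TRUE the file is taxa x samples.
#' @return a [count_matrix].
#' @export
read_count_table <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("count table not found: ", path)
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L) {
    bad_line <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged TSV: line %d has %d fields, expected %d",
                 bad_line, nf[bad_line], nf[1L]))
  }
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                   check.names = FALSE, quote = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(as.numeric(m))) & !is.na(m))[1L]
    ij <- arrayInd(bad, dim(m))
    stop(sprintf("non-numeric count at row '%s', column '%s'",
                 rownames(m)[ij[1L]], colnames(m)[ij[2L]]))
  }
  bad <- which(m < 0 | m != round(m))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(m))
    stop(sprintf("invalid count at row '%s', column '%s': %s",
                 rownames(m)[ij[1L]], colnames(m)[ij[2L]], format(m[bad[1L]])))
  }
  if (transpose) m <- t(m)
  count_matrix(m)
}

#' Write a count matrix (or any labelled matrix) to TSV
#'
#' @param x matrix with dimnames.
#' @param path output path.
#' @param id_col name for the first (row label) column.
#' @export
write_count_table <- function(x, path, id_col = "sample_id") {
  if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("col", seq_len(ncol(x)))
  df <- data.frame(rownames(x), as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE)
  names(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter low-abundance taxa
#'
#' Removes taxa whose counts are zero in more than a given fraction of samples:
#' a taxon is kept iff its nonzero fraction is at least `min_nonzero_frac`.
#' The default 0.5 drops taxa with zeros in more than half the samples, the
#' common pre-filter for network analysis of genus-level tables; 0.1 is a more
#' permissive setting.
#'
#' @param counts a [count_matrix].
#' @param min_nonzero_frac minimum fraction of samples with a nonzero count.
#' @return the filtered [count_matrix] with column order preserved.
#' @export
filter_low_abundance <- function(counts, min_nonzero_frac = 0.5) {
  if (min_nonzero_frac < 0 || min_nonzero_frac > 1)
    stop("min_nonzero_frac must be in [0, 1]")
  frac <- colMeans(counts > 0)
  keep <- frac >= min_nonzero_frac
  if (!any(keep))
    stop("all taxa filtered out; lower min_nonzero_frac")
  count_matrix(unclass(counts)[, keep, drop = FALSE])
}
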