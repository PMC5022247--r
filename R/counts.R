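#' Validate a gene-by-sample count matrix
#'
#' Checks that `x` is a numeric matrix of non-negative integer-valued counts
#' with unique, non-missing row (gene) and column (sample) identifiers, and
#' returns it with storage coerced to double. All fitting, normalization and
#' simulation functions in this package use the genes-by-samples orientation
#' (rows are genes).
#'
#' @param x A matrix of read counts, genes in rows, samples in columns.
#'   Dimnames are required: rownames are gene identifiers, colnames are
#'   sample identifiers.
#' @return The validated count matrix.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' as_count_matrix(m)
#' @export
as_count_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("counts must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("count matrix must have at least one gene and one sample", call. = FALSE)
  }
  bad <- which(!is.finite(x) | x < 0 | x != round(x), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    g <- rownames(x)[bad[1L, 1L]]
    s <- colnames(x)[bad[1L, 2L]]
    stop(sprintf(
      "counts must be non-negative integers; offending entry at gene '%s', sample '%s' (value %s)",
      if (is.null(g)) bad[1L, 1L] else g,
      if (is.null(s)) bad[1L, 2L] else s,
      format(x[bad[1L, 1L], bad[1L, 2L]])
    ), call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("count matrix must have gene identifiers as rownames and sample identifiers as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop(sprintf("duplicate gene identifier: '%s'",
                 rownames(x)[duplicated(rownames(x))][1L]), call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop(sprintf("duplicate sample identifier: '%s'",
                 colnames(x)[duplicated(colnames(x))][1L]), call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

sep_for_path <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a count matrix from delimited text
#'
#' Reads a TSV/CSV file with a header row and a leading identifier column
#' into a validated genes-by-samples count matrix. Files stored
#' samples-by-genes (rows are samples) are transposed on read via
#' `orientation = "samples_by_genes"`.
#'
#' @param path Path to a delimited text file. The delimiter is inferred from
#'   the extension (`.csv` is comma, anything else tab) unless `sep` is given.
#' @param orientation Layout of the file: `"genes_by_samples"` (default, rows
#'   are genes) or `"samples_by_genes"` (rows are samples; transposed on read).
#' @param sep Optional field separator overriding the extension-based default.
#' @return A validated count matrix, genes in rows.
#' @seealso [write_counts()], [as_count_matrix()]
#' @export
read_counts <- function(path,
                        orientation = c("genes_by_samples", "samples_by_genes"),
                        sep = NULL) {
  orientation <- match.arg(orientation)
  sep <- sep_for_path(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    stop(sprintf("non-numeric entries in '%s'; counts must be integers", path),
         call. = FALSE)
  }
  if (orientation == "samples_by_genes") m <- t(m)
  as_count_matrix(m)
}

#' Write a count matrix to delimited text
#'
#' Inverse of [read_counts()]: writes the genes-by-samples matrix with a
#' header row and a leading `gene_id` column so that reading the file back
#' reproduces the matrix exactly.
#'
#' @param counts A count matrix (genes x samples) as accepted by
#'   [as_count_matrix()].
#' @param path Output file path; delimiter inferred from extension unless
#'   `sep` is given.
#' @param sep Optional field separator.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, sep = NULL) {
  counts <- as_count_matrix(counts)
  sep <- sep_for_path(path, sep)
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample class labels
#'
#' Reads a two-column delimited file (sample identifier, class name) and
#' returns a factor of class labels aligned to `sample_ids`. Class names may
#' be arbitrary strings; factor levels (and hence the class indices used
#' throughout the package) are assigned in lexicographic order of the class
#' names, which makes the index mapping deterministic.
#'
#' @param path Path to a two-column delimited file with a header row.
#' @param sample_ids Character vector of sample identifiers, typically
#'   `colnames` of the paired count matrix; the returned factor follows this
#'   order.
#' @param sep Optional field separator (extension-based default).
#' @return A factor of length `length(sample_ids)`; `nlevels` is the number
#'   of classes K.
#' @export
read_labels <- function(path, sample_ids, sep = NULL) {
  sep <- sep_for_path(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) {
    stop("label file must have two columns: sample_id, class", call. = FALSE)
  }
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample identifier in label file: '%s'",
                 ids[duplicated(ids)][1L]), call. = FALSE)
  }
  unknown <- setdiff(ids, sample_ids)
  if (length(unknown) > 0L) {
    stop(sprintf("label file contains unknown sample(s): %s",
                 paste(utils::head(unknown, 3L), collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(sample_ids, ids)
  if (length(missing) > 0L) {
    stop(sprintf("no label for sample(s): %s",
                 paste(utils::head(missing, 3L), collapse = ", ")), call. = FALSE)
  }
  y <- factor(df[[2L]][match(sample_ids, ids)])
  if (nlevels(y) == 1L) {
    warning("all samples share a single class (K = 1); the fitted model will always predict it",
            call. = FALSE)
  }
  y
}

# Labels as validated factor aligned to a count matrix; every level observed.
validate_labels <- function(y, counts) {
  y <- droplevels(as.factor(y))
  if (length(y) != ncol(counts)) {
    stop(sprintf("labels have length %d but counts has %d samples",
                 length(y), ncol(counts)), call. = FALSE)
  }
  if (anyNA(y)) stop("labels contain missing values", call. = FALSE)
  y
}
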