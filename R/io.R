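# Readers/writers for feature x sample matrices (TSV or MatrixMarket with
# sidecar id lists), phenotype tables and split assignments.

#' Read a feature x sample matrix
#'
#' TSV files carry feature ids in the first column and sample ids in the
#' header. MatrixMarket files (`.mtx`) require sidecar id files (one id per
#' line) for rows and columns.
#'
#' @param path Path to `.tsv`/`.txt` or `.mtx`.
#' @param row_ids,col_ids Sidecar id file paths (MatrixMarket only;
#'   defaults `<path>.rows` / `<path>.cols`).
#' @return Numeric matrix with dimnames.
#' @export
read_feature_matrix <- function(path, row_ids = paste0(path, ".rows"),
                                col_ids = paste0(path, ".cols")) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(row_ids, warn = FALSE)
    colnames(m) <- readLines(col_ids, warn = FALSE)
    return(m)
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a feature x sample matrix as TSV
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the feature id column (default `feature_id`).
#' @export
write_feature_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV or CSV (by extension) with a header; must contain `sample_id` and
#' `label` columns, labels coded 0/1.
#'
#' @param path Path to the phenotype file.
#' @return `data.frame` with at least `sample_id` and `label`.
#' @export
read_pheno <- function(path) {
  df <- if (grepl("\\.csv$", path)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("phenotype table must contain 'sample_id' and 'label' columns")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in phenotype table")
  if (!all(df$label %in% c(0, 1))) stop("labels must be coded 0/1")
  df
}

#' Write / read a split assignment
#'
#' Tab-separated `sample_id`, `split`, `fold`.
#'
#' @param split `data.frame` from [split_dataset()].
#' @param path File path.
#' @export
write_split <- function(split, path) {
  utils::write.table(split, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
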