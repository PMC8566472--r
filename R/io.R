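#' Read a delimited expression matrix
#'
#' Reads a CSV/TSV file with a header row and an identifier first column
#' into a samples-by-variables numeric matrix. Expression files often come
#' genes-in-rows; set `orientation = "samples_in_columns"` to transpose on
#' read rather than have the reader guess. Non-numeric or missing cells are
#' an error that names the offending row and column.
#'
#' @param path File path; delimiter inferred from the extension (`.tsv`/
#'   `.txt` tab, otherwise comma) unless `delim` is given.
#' @param orientation `"samples_in_rows"` (default) or
#'   `"samples_in_columns"`.
#' @param delim Optional explicit field delimiter.
#' @return Numeric matrix with sample ids as row names.
#' @export
read_expression <- function(path,
                            orientation = c("samples_in_rows", "samples_in_columns"),
                            delim = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) abort("expected an id column plus at least one data column")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  vals <- df[-1]
  for (nm in names(vals)) {
    col <- vals[[nm]]
    if (!is.numeric(col)) col <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(col))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric or missing value at row '%s', column '%s'",
                    ids[bad[1]], nm))
    }
    vals[[nm]] <- col
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (orientation == "samples_in_columns") m <- t(m)
  as_expression_matrix(m)
}

#' Read a two-column sample label file
#'
#' @param path Delimited text with columns `sample_id` and `label` (header
#'   optional names; the first two columns are used).
#' @param delim Optional delimiter (inferred from the extension otherwise).
#' @return Factor of labels named by sample id.
#' @export
read_labels <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) abort("expected two columns: sample_id, label")
  setNames(factor(as.character(df[[2]])), as.character(df[[1]]))
}

#' Write a square (dis)similarity matrix as delimited text
#'
#' @param m A `band_similarity`/`band_dissimilarity` or numeric matrix.
#' @param path Output file (CSV).
#' @param layout `"square"` (ids as header and first column) or `"dist"`
#'   (lower triangle, one `id_1,id_2,value` row per pair).
#' @param digits Significant digits for floating output (default 10).
#' @return `path`, invisibly.
#' @export
write_dissimilarity <- function(m, path, layout = c("square", "dist"),
                                digits = 10) {
  layout <- match.arg(layout)
  mm <- as.matrix(m)
  if (layout == "square") {
    df <- tibble::as_tibble(signif(mm, digits), rownames = "sample_id")
    readr::write_csv(df, path)
  } else {
    idx <- which(lower.tri(mm), arr.ind = TRUE)
    df <- tibble::tibble(sample_1 = rownames(mm)[idx[, 1]],
                         sample_2 = colnames(mm)[idx[, 2]],
                         value = signif(mm[idx], digits))
    readr::write_csv(df, path)
  }
  invisible(path)
}
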