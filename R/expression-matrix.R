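#' Coerce input to a samples-by-variables expression matrix
#'
#' All band computations operate on a plain numeric matrix with samples in
#' rows and quantitative variables (genes) in columns. This helper accepts a
#' matrix or a data frame / tibble; in the data-frame case an identifier
#' column may be named via `id_col`, otherwise row names (or `"sample_<i>"`
#' fallbacks) are used. Missing or non-finite entries are rejected: the band
#' machinery assumes complete data.
#'
#' @param x A numeric matrix or a data frame with numeric columns.
#' @param id_col Optional name of the column holding sample identifiers
#'   (data-frame input only).
#' @return A numeric matrix with unique row names (sample ids) and column
#'   names (variable ids).
#' @examples
#' as_expression_matrix(data.frame(id = c("a", "b"), g1 = c(1, 2), g2 = c(3, 4)),
#'                      id_col = "id")
#' @export
as_expression_matrix <- function(x, id_col = NULL) {
  if (is.data.frame(x)) {
    ids <- NULL
    if (!is.null(id_col)) {
      if (!id_col %in% names(x)) {
        abort(paste0("column '", id_col, "' not found in input"))
      }
      ids <- as.character(x[[id_col]])
      x <- x[setdiff(names(x), id_col)]
    }
    not_num <- names(x)[!vapply(x, is.numeric, logical(1))]
    if (length(not_num) > 0) {
      abort(paste0("non-numeric columns: ", paste(not_num, collapse = ", ")))
    }
    m <- as.matrix(x)
    if (!is.null(ids)) {
      rownames(m) <- ids
    } else if (is.null(rownames(m)) || all(rownames(m) == as.character(seq_len(nrow(m))))) {
      rownames(m) <- paste0("sample_", seq_len(nrow(m)))
    }
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("input must be a numeric matrix or a data frame of numeric columns")
  }
  if (nrow(x) < 2 || ncol(x) < 1) {
    abort("need at least 2 samples and 1 variable")
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite value at sample %d, variable %d; complete data required",
                  bad[1], bad[2]))
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("sample_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) abort("duplicate sample ids")
  x
}

check_band_j <- function(j, n, what = "j") {
  if (length(j) != 1 || !is.finite(j) || j != round(j)) {
    abort(paste0("'", what, "' must be a single integer"))
  }
  if (j < 2 || j > n) {
    abort(sprintf("'%s' must lie in [2, n] = [2, %d], got %s", what, n, format(j)))
  }
  as.integer(j)
}
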