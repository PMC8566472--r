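#' Binary similarity coefficients
#'
#' The eight supported coefficients, identified by their conventional
#' one/two-letter codes: simple matching (`SM`), Jaccard (`J`), Simpson
#' (`S`), Forbes (`F`), Dice (`D`), Anderberg (`A`), Ochiai (`O`) and
#' Russell-Rao (`RR`).
#'
#' @format Character vector of length 8.
#' @export
band_coefficients <- c("SM", "J", "S", "F", "D", "A", "O", "RR")

coef_code <- function(coefficient) {
  coefficient <- match.arg(coefficient, band_coefficients)
  match(coefficient, band_coefficients) - 1L
}

agg_code <- function(aggregation) {
  aggregation <- match.arg(aggregation, c("coordinate", "pooled"))
  c(coordinate = 0L, pooled = 1L)[[aggregation]]
}

#' Band-inclusion contingency table for one coordinate and band size
#'
#' Given the numbers of j-bands whose k-th interval contains the first
#' point's coordinate (`N1`), the second point's (`N2`) and both
#' simultaneously (`Npair`), builds the 2x2 contingency table
#' `(a, b, c, d) = (Npair, N1 - Npair, N2 - Npair, C(n,j) - N1 - N2 + Npair)`
#' over the universe of all `C(n, j)` bands.
#'
#' @param N1,N2 Band counts of the two points at this coordinate.
#' @param Npair Joint band count.
#' @param n Sample size defining the bands.
#' @param j Band size.
#' @return A tibble with columns `a`, `b`, `c`, `d` and `n_bands`.
#' @examples
#' contingency_table(3, 5, 2, n = 4, j = 2)  # a=2 b=1 c=3 d=0
#' @export
contingency_table <- function(N1, N2, Npair, n, j) {
  j <- check_band_j(j, n)
  total <- band_binom(n, j)
  a <- Npair
  b <- N1 - Npair
  cc <- N2 - Npair
  d <- total - N1 - N2 + Npair
  if (any(c(a, b, cc, d) < 0)) {
    abort("inconsistent band counts: negative contingency cell")
  }
  tibble::tibble(a = a, b = b, c = cc, d = d, n_bands = total)
}

#' Evaluate a binary similarity coefficient on contingency tables
#'
#' Applies the chosen coefficient to one or more `(a, b, c, d)` tables.
#' Formulas: `SM = (a+d)/(a+b+c+d)`, `J = a/(a+b+c)`,
#' `S = a/min(a+b, a+c)`, `F = a(a+b+c+d)/((a+b)(a+c))`,
#' `D = 2a/(2a+b+c)`, `A = a/(a+2(b+c))`, `O = a/sqrt((a+b)(a+c))`,
#' `RR = a/(a+b+c+d)`. A zero denominator can only occur together with
#' `a = 0` (possible for out-of-sample queries lying outside every band);
#' the coefficient is then defined as 0, the limit of each formula as
#' `a -> 0`.
#'
#' @param table A data frame with columns `a`, `b`, `c`, `d` (e.g. from
#'   [contingency_table()]), or a numeric vector `c(a, b, c, d)`.
#' @param coefficient One of [band_coefficients].
#' @return Numeric vector of coefficient values, one per table row.
#' @examples
#' coefficient_value(c(2, 1, 3, 0), "S")  # 2/3
#' @export
coefficient_value <- function(table, coefficient = band_coefficients) {
  coefficient <- match.arg(coefficient)
  if (is.numeric(table) && is.null(dim(table))) {
    table <- tibble::tibble(a = table[1], b = table[2], c = table[3], d = table[4])
  }
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  if (any(c(a, b, cc, d) < 0)) abort("negative contingency cell")
  tot <- a + b + cc + d
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  switch(coefficient,
    SM = (a + d) / tot,
    J  = safe(a, a + b + cc),
    S  = safe(a, pmin(a + b, a + cc)),
    F  = safe(a * tot, (a + b) * (a + cc)),
    D  = safe(2 * a, 2 * a + b + cc),
    A  = safe(a, a + 2 * (b + cc)),
    O  = safe(a, sqrt((a + b) * (a + cc))),
    RR = a / tot
  )
}

new_band_similarity <- function(values, ids_row, ids_col, coefficient, J,
                                aggregation, n_reference, cross = FALSE) {
  dimnames(values) <- list(ids_row, ids_col)
  structure(values,
            coefficient = coefficient, J = J, aggregation = aggregation,
            n_reference = n_reference, cross = cross,
            class = c("band_similarity", "matrix", "array"))
}

#' Band-based similarity matrix of a sample
#'
#' For every pair of observations, builds the per-coordinate, per-band-size
#' contingency tables from the closed-form band counts and aggregates the
#' chosen binary coefficient into a single sample-dependent similarity
#' `S = sum_{j=2}^J sum_{k=1}^d S[k,j] / (d (J - 1))`.
#'
#' Two observations whose coordinates fall together inside many bands score
#' as similar; the measure reflects shape relative to the rest of the
#' sample rather than spatial proximity, and is invariant to strictly
#' increasing transformations applied per coordinate.
#'
#' @param x Expression input accepted by [as_expression_matrix()].
#' @param J Maximum band size (default 2; `J` of 2 or 3 is recommended in
#'   practice, and results are stable in `J`).
#' @param coefficient One of [band_coefficients] (default `"S"`, Simpson,
#'   the strongest performer for expression-like data).
#' @param aggregation `"coordinate"` (default): apply the coefficient to
#'   each coordinate's table and average across coordinates, which keeps
#'   per-coordinate agreement information. `"pooled"`: sum the `d` tables
#'   entrywise per band size and apply the coefficient once.
#' @return A `band_similarity` matrix (n x n, symmetric) carrying
#'   `coefficient`, `J` and `aggregation` attributes. The diagonal is
#'   exactly 1 for SM, J, S, D, A and O; Forbes self-similarity is `>= 1`
#'   and Russell-Rao self-similarity is generally below 1.
#' @seealso [band_dissimilarity()], [cross_band_similarity()]
#' @examples
#' y <- matrix(c(1, 2, 3, 4), ncol = 1)
#' band_similarity(y, J = 2, coefficient = "S")
#' @export
band_similarity <- function(x, J = 2, coefficient = "S",
                            aggregation = c("coordinate", "pooled")) {
  aggregation <- match.arg(aggregation)
  st <- column_order_stats(x)
  n <- nrow(st$values)
  J <- check_band_j(J, n, "J")
  values <- cpp_band_similarity(st$values, st$l, st$eta, J,
                                coef_code(coefficient), agg_code(aggregation))
  new_band_similarity(values, rownames(st$values), rownames(st$values),
                      coefficient, J, aggregation, n)
}

#' Band similarity between query points and a reference sample
#'
#' Computes the rectangular block of band-based similarities between each
#' query row and each training observation. By default (`reference =
#' "train"`) the bands are defined by the training sample alone, so a new
#' observation can be compared inductively without redefining the geometry;
#' query coordinates outside the training range simply fall in zero bands.
#' With `reference = "pooled"` the bands are formed from the union of
#' training and query rows (transductive).
#'
#' @param train Training expression input.
#' @param queries Numeric matrix (or vector) of query points, same variables
#'   as `train`.
#' @inheritParams band_similarity
#' @param reference `"train"` (default) or `"pooled"`.
#' @return A `band_similarity` matrix of size `nrow(queries) x nrow(train)`.
#' @export
cross_band_similarity <- function(train, queries, J = 2, coefficient = "S",
                                  aggregation = c("coordinate", "pooled"),
                                  reference = c("train", "pooled")) {
  aggregation <- match.arg(aggregation)
  reference <- match.arg(reference)
  tr <- as_expression_matrix(train)
  if (is.null(dim(queries))) queries <- matrix(queries, nrow = 1)
  if (ncol(queries) != ncol(tr)) abort("queries and train must share variables")
  if (!all(is.finite(queries))) abort("non-finite query values")
  if (is.null(rownames(queries))) {
    rownames(queries) <- paste0("query_", seq_len(nrow(queries)))
  }
  ref <- if (reference == "train") {
    tr
  } else {
    pooled <- rbind(tr, queries)
    rownames(pooled) <- make.unique(rownames(pooled))
    pooled
  }
  st <- column_order_stats(ref)
  n <- nrow(ref)
  J <- check_band_j(J, n, "J")
  qs <- order_stats_for(st, queries)
  ts <- order_stats_for(st, tr)
  values <- cpp_cross_band_similarity(queries, qs$l, qs$eta,
                                      tr, ts$l, ts$eta, n, J,
                                      coef_code(coefficient),
                                      agg_code(aggregation))
  new_band_similarity(values, rownames(queries), rownames(tr),
                      match.arg(coefficient, band_coefficients), J,
                      aggregation, n, cross = TRUE)
}

#' Convert a similarity matrix to a dissimilarity matrix
#'
#' For coefficients bounded by 1 the conversion is `D = 1 - S` entrywise.
#' The Forbes coefficient is not bounded by 1, so its matrix is first
#' rescaled by its maximum entry (mapping it into `[0, 1]`) and then
#' converted; the rescaling strategy is exposed so alternatives can be
#' plugged in. Results are clamped at 0 against floating-point fuzz.
#'
#' Russell-Rao dissimilarity is not reflexive: the self-dissimilarity
#' `1 - a / C(n,j)` is positive unless a point lies in every band. The
#' conversion preserves this, flags the result with attribute
#' `nonreflexive = TRUE`, and warns.
#'
#' @param s A `band_similarity` object.
#' @param forbes_rescale Function mapping the raw Forbes matrix into
#'   `[0, 1]`; default divides by the maximum entry.
#' @return A `band_dissimilarity` object (matrix with the source
#'   coefficient's attributes).
#' @export
to_dissimilarity <- function(s, forbes_rescale = function(m) m / max(m)) {
  stopifnot(inherits(s, "band_similarity"))
  values <- unclass(s)
  coefficient <- attr(s, "coefficient")
  if (coefficient == "F" && max(values) > 0) {
    values <- forbes_rescale(values)
  }
  d <- pmax(1 - values, 0)
  nonreflexive <- FALSE
  if (coefficient == "RR") {
    nonreflexive <- TRUE
    warn("Russell-Rao dissimilarity is not reflexive: self-dissimilarity may exceed 0")
  }
  structure(d,
            coefficient = coefficient, J = attr(s, "J"),
            aggregation = attr(s, "aggregation"),
            nonreflexive = nonreflexive, cross = attr(s, "cross"),
            class = c("band_dissimilarity", "matrix", "array"))
}

#' One-call band dissimilarity
#'
#' Convenience wrapper chaining [band_similarity()] and
#' [to_dissimilarity()].
#'
#' @inheritParams band_similarity
#' @return A `band_dissimilarity` matrix.
#' @export
band_dissimilarity <- function(x, J = 2, coefficient = "S",
                               aggregation = c("coordinate", "pooled")) {
  s <- band_similarity(x, J = J, coefficient = coefficient,
                       aggregation = aggregation)
  if (attr(s, "coefficient") == "RR") {
    suppressWarnings(to_dissimilarity(s))
  } else {
    to_dissimilarity(s)
  }
}

#' @export
print.band_similarity <- function(x, ...) {
  cat(sprintf("Band %s: %s coefficient, J = %d, %s aggregation (%d x %d)\n",
              if (isTRUE(attr(x, "cross"))) "similarity block" else "similarity matrix",
              attr(x, "coefficient"), attr(x, "J"), attr(x, "aggregation"),
              nrow(x), ncol(x)))
  print(head(unclass(x)[, seq_len(min(ncol(x), 6)), drop = FALSE], 6), ...)
  invisible(x)
}

#' @export
print.band_dissimilarity <- function(x, ...) {
  cat(sprintf("Band dissimilarity (%s, J = %d): %d x %d%s\n",
              attr(x, "coefficient") %||% "classical", attr(x, "J") %||% NA,
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "nonreflexive"))) " [non-reflexive]" else ""))
  print(head(unclass(x)[, seq_len(min(ncol(x), 6)), drop = FALSE], 6), ...)
  invisible(x)
}

#' @importFrom rlang %||%
NULL

#' @export
as.dist.band_dissimilarity <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(unclass(m), diag = diag, upper = upper)
}

#' Tidy a similarity or dissimilarity matrix into a long tibble
#'
#' @param x A `band_similarity` or `band_dissimilarity` object.
#' @param ... Unused.
#' @return Tibble with columns `sample_1`, `sample_2` and `value`.
#' @exportS3Method generics::tidy
tidy.band_similarity <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    sample_1 = rep(rownames(m), times = ncol(m)),
    sample_2 = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
}

#' @rdname tidy.band_similarity
#' @exportS3Method generics::tidy
tidy.band_dissimilarity <- tidy.band_similarity

#' Heatmap of a band similarity/dissimilarity matrix
#'
#' @param object A `band_similarity` or `band_dissimilarity` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.band_similarity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_2, y = .data$sample_1,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = attr(object, "coefficient") %||% "value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @rdname autoplot.band_similarity
#' @exportS3Method ggplot2::autoplot
autoplot.band_dissimilarity <- autoplot.band_similarity
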