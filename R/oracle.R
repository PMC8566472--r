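#' Enumerate all j-bands of a sample
#'
#' Reference implementation that lists every j-element subset of the sample
#' in lexicographic order together with its per-coordinate min/max envelope.
#' Intended for validating the closed-form counts on small instances only; a
#' cap on `C(n, j)` guards against accidental combinatorial explosions.
#'
#' @param x Expression input accepted by [as_expression_matrix()].
#' @param j Band size.
#' @param cap Maximum number of bands to enumerate (default 10000).
#' @return List with `index` (a `j x C(n,j)` matrix of sample indices, one
#'   band per column, lexicographic), `lower` and `upper` (each
#'   `C(n,j) x d` envelope matrices).
#' @export
enumerate_bands <- function(x, j, cap = 10000) {
  y <- as_expression_matrix(x)
  n <- nrow(y)
  j <- check_band_j(j, n)
  if (choose(n, j) > cap) {
    abort(sprintf("C(%d, %d) exceeds the enumeration cap (%d)", n, j, cap))
  }
  idx <- combn(n, j)
  lower <- t(apply(idx, 2, function(s) apply(y[s, , drop = FALSE], 2, min)))
  upper <- t(apply(idx, 2, function(s) apply(y[s, , drop = FALSE], 2, max)))
  if (ncol(y) == 1) {
    lower <- matrix(lower, ncol = 1)
    upper <- matrix(upper, ncol = 1)
  }
  list(index = idx, lower = lower, upper = upper)
}

#' Explicit band-inclusion binary matrix of a point
#'
#' Builds the `C(n,j) x d` 0/1 matrix whose `(p, k)` entry records whether
#' the point's k-th coordinate lies inside the k-th interval of the p-th
#' j-band. Column sums reproduce the closed-form counts of
#' [count_bands_single()]; used as the testing oracle.
#'
#' @inheritParams enumerate_bands
#' @param point Numeric vector of length `d`.
#' @return Binary matrix with `C(n, j)` rows and `d` columns.
#' @export
band_matrix <- function(x, point, j, cap = 10000) {
  bands <- enumerate_bands(x, j, cap = cap)
  p <- matrix(point, nrow = nrow(bands$lower), ncol = length(point), byrow = TRUE)
  (bands$lower <= p & p <= bands$upper) * 1L
}

#' Boolean (elementwise) product of two band matrices
#'
#' The entrywise AND of the band matrices of two points marks the bands that
#' contain both coordinates simultaneously; its column sums reproduce
#' [count_bands_pair()].
#'
#' @param m1,m2 Binary matrices of identical shape.
#' @return Binary matrix of the same shape.
#' @export
boolean_product <- function(m1, m2) {
  stopifnot(all(dim(m1) == dim(m2)))
  (m1 & m2) * 1L
}

#' Brute-force Modified Band Depth
#'
#' Direct double-sum evaluation of the depth from explicitly enumerated
#' bands; the independent check for [mbd()].
#'
#' @inheritParams enumerate_bands
#' @param J Maximum band size.
#' @return Numeric vector of depths.
#' @export
oracle_mbd <- function(x, J, cap = 10000) {
  y <- as_expression_matrix(x)
  n <- nrow(y)
  d <- ncol(y)
  depth <- numeric(n)
  for (j in 2:J) {
    for (i in seq_len(n)) {
      m <- band_matrix(y, y[i, ], j, cap = cap)
      depth[i] <- depth[i] + sum(m) / (d * choose(n, j))
    }
  }
  depth
}
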