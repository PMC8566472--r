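#' Specify a dissimilarity measure
#'
#' A lightweight description of a dissimilarity to be computed from a
#' samples-by-variables matrix, covering the classical distances used as
#' baselines (Euclidean, Manhattan, Minkowski for any `p > 0` including
#' fractional exponents, Pearson correlation distance `1 - r`) and the
#' band-based measures (any coefficient of [band_coefficients], any band
#' size `J`).
#'
#' @param family One of `"euclidean"`, `"manhattan"`, `"minkowski"`,
#'   `"pearson"`, `"band"`.
#' @param p Minkowski exponent (`p > 0`; the formula is applied verbatim
#'   also for `p < 1`, where it is no longer a metric).
#' @param coefficient,J,aggregation Band-measure parameters, see
#'   [band_similarity()].
#' @param reference Band reference sample for query-to-train blocks, see
#'   [cross_band_similarity()].
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("minkowski", p = 0.5)
#' dist_spec("band", coefficient = "S", J = 3)
#' @export
dist_spec <- function(family = c("euclidean", "manhattan", "minkowski",
                                 "pearson", "band"),
                      p = NULL, coefficient = "S", J = 2,
                      aggregation = "coordinate", reference = "train") {
  family <- match.arg(family)
  if (family == "minkowski") {
    if (is.null(p) || !is.numeric(p) || length(p) != 1 || p <= 0) {
      abort("minkowski requires a single exponent p > 0")
    }
  }
  if (family == "band") {
    coefficient <- match.arg(coefficient, band_coefficients)
    aggregation <- match.arg(aggregation, c("coordinate", "pooled"))
    reference <- match.arg(reference, c("train", "pooled"))
    if (J < 2) abort("band measures need J >= 2")
  }
  structure(list(family = family, p = p, coefficient = coefficient,
                 J = as.integer(J), aggregation = aggregation,
                 reference = reference),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("Dissimilarity spec:", spec_label(x), "\n")
  invisible(x)
}

#' Short label for a dissimilarity spec
#'
#' @param spec A [dist_spec()] object.
#' @return A single string, e.g. `"minkowski_0.5"` or `"S_2"`.
#' @export
spec_label <- function(spec) {
  switch(spec$family,
    minkowski = paste0("minkowski_", format(spec$p)),
    band = paste0(spec$coefficient, "_", spec$J),
    spec$family
  )
}

#' The classical distance grid used as a baseline
#'
#' Euclidean, Manhattan, Minkowski for
#' `p` in 0.25, 0.5, 0.75, 3, 4, 5 and the Pearson correlation distance.
#'
#' @return Named list of [dist_spec()] objects.
#' @export
classical_specs <- function() {
  specs <- c(
    list(dist_spec("euclidean"), dist_spec("manhattan")),
    lapply(c(0.25, 0.5, 0.75, 3, 4, 5), function(p) dist_spec("minkowski", p = p)),
    list(dist_spec("pearson"))
  )
  setNames(specs, vapply(specs, spec_label, character(1)))
}

#' Band-based dissimilarity specs for a set of coefficients and band sizes
#'
#' @param coefficients Subset of [band_coefficients].
#' @param J Vector of maximum band sizes.
#' @param aggregation,reference Passed to [dist_spec()].
#' @return Named list of [dist_spec()] objects (names like `"S_2"`).
#' @export
band_specs <- function(coefficients = band_coefficients, J = c(2, 3),
                       aggregation = "coordinate", reference = "train") {
  specs <- list()
  for (co in coefficients) {
    for (jj in J) {
      specs[[paste0(co, "_", jj)]] <-
        dist_spec("band", coefficient = co, J = jj,
                  aggregation = aggregation, reference = reference)
    }
  }
  specs
}

new_classical_dissimilarity <- function(values, spec, cross = FALSE) {
  structure(values, coefficient = NULL, J = NULL, aggregation = NULL,
            nonreflexive = FALSE, cross = cross, family = spec_label(spec),
            class = c("band_dissimilarity", "matrix", "array"))
}

#' Compute a dissimilarity matrix from an expression matrix
#'
#' Dispatches on a [dist_spec()]: classical distances go through
#' [stats::dist()] (Pearson via `1 - cor` across coordinates), band
#' measures through [band_dissimilarity()] (Forbes rescaled by its maximum
#' before conversion; Russell-Rao flagged non-reflexive).
#'
#' @param x Expression input accepted by [as_expression_matrix()].
#' @param spec A [dist_spec()].
#' @return A `band_dissimilarity` matrix (n x n).
#' @export
dissimilarity <- function(x, spec) {
  stopifnot(inherits(spec, "dist_spec"))
  y <- as_expression_matrix(x)
  if (spec$family == "band") {
    return(band_dissimilarity(y, J = spec$J, coefficient = spec$coefficient,
                              aggregation = spec$aggregation))
  }
  values <- switch(spec$family,
    euclidean = as.matrix(dist(y, method = "euclidean")),
    manhattan = as.matrix(dist(y, method = "manhattan")),
    minkowski = as.matrix(dist(y, method = "minkowski", p = spec$p)),
    pearson = pearson_distance(y, y)
  )
  new_classical_dissimilarity(values, spec)
}

pearson_distance <- function(a, b) {
  sda <- apply(a, 1, stats::sd)
  sdb <- apply(b, 1, stats::sd)
  if (any(sda == 0) || any(sdb == 0)) {
    abort("Pearson distance undefined for zero-variance profiles")
  }
  1 - cor(t(a), t(b))
}

#' Query-to-train dissimilarity block
#'
#' Rectangular counterpart of [dissimilarity()], used to classify new
#' observations: rows are queries, columns are training samples. For band
#' measures the reference sample that defines the bands is controlled by
#' the spec's `reference` field (training-only by default).
#'
#' @param train Training expression input.
#' @param queries Numeric matrix of query rows with the same variables.
#' @param spec A [dist_spec()].
#' @return A `band_dissimilarity` matrix of size `nrow(queries) x nrow(train)`.
#' @export
cross_dissimilarity <- function(train, queries, spec) {
  stopifnot(inherits(spec, "dist_spec"))
  tr <- as_expression_matrix(train)
  if (is.null(dim(queries))) queries <- matrix(queries, nrow = 1)
  if (spec$family == "band") {
    s <- cross_band_similarity(tr, queries, J = spec$J,
                               coefficient = spec$coefficient,
                               aggregation = spec$aggregation,
                               reference = spec$reference)
    d <- if (spec$coefficient == "RR") {
      suppressWarnings(to_dissimilarity(s))
    } else {
      to_dissimilarity(s)
    }
    return(d)
  }
  values <- switch(spec$family,
    euclidean = minkowski_block(queries, tr, 2),
    manhattan = minkowski_block(queries, tr, 1),
    minkowski = minkowski_block(queries, tr, spec$p),
    pearson = pearson_distance(queries, tr)
  )
  dimnames(values) <- list(rownames(queries), rownames(tr))
  new_classical_dissimilarity(values, spec, cross = TRUE)
}

minkowski_block <- function(q, tr, p) {
  t(apply(q, 1, function(row) {
    rowSums(abs(sweep(tr, 2, row))^p)^(1 / p)
  }))
}
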