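# Shared fixture builders: everything is generated in code at test time.

# Small random matrix with ties made likely (half-integer grid), so the
# multiplicity machinery is exercised.
random_tied_matrix <- function(n, d) {
  matrix(sample(0:5, n * d, replace = TRUE) +
           ifelse(runif(n * d) < 0.5, 0, 0.5), n, d)
}

# One-dimensional toy whose 2-band counts mirror the worked configuration:
# four samples with first coordinates 0, 1, 2, 3 give 6 two-element bands,
# of which 3 contain the first sample's coordinate, 5 contain the third's,
# and 2 contain both.
toy_fig_column <- function() matrix(c(0, 1, 2, 3), ncol = 1)

# Independent similarity oracle: explicit band matrices and their Boolean
# products, aggregated coordinate-wise exactly as the closed-form path.
oracle_similarity <- function(y, J, coefficient) {
  n <- nrow(y)
  d <- ncol(y)
  out <- matrix(0, n, n)
  for (j in 2:J) {
    cnj <- choose(n, j)
    bms <- lapply(seq_len(n), function(i) band_matrix(y, y[i, ], j))
    for (i1 in seq_len(n)) {
      for (i2 in seq_len(n)) {
        acc <- 0
        for (k in seq_len(d)) {
          n1 <- sum(bms[[i1]][, k])
          n2 <- sum(bms[[i2]][, k])
          a <- sum(bms[[i1]][, k] & bms[[i2]][, k])
          acc <- acc + coefficient_value(c(a, n1 - a, n2 - a, cnj - n1 - n2 + a),
                                         coefficient)
        }
        out[i1, i2] <- out[i1, i2] + acc / d
      }
    }
  }
  out / (J - 1)
}
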