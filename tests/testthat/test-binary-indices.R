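test_that("contingency tables assemble from band counts", {
  t1 <- contingency_table(3, 5, 2, n = 4, j = 2)
  expect_equal(unlist(t1[c("a", "b", "c", "d")]), c(a = 2, b = 1, c = 3, d = 0))
  expect_equal(t1$n_bands, 6)

  # identical points: everything concentrates in a and d
  t2 <- contingency_table(4, 4, 4, n = 4, j = 2)
  expect_equal(unlist(t2[c("a", "b", "c", "d")]), c(a = 4, b = 0, c = 0, d = 2))

  t3 <- contingency_table(3, 3, 1, n = 4, j = 2)
  expect_equal(unlist(t3[c("a", "b", "c", "d")]), c(a = 1, b = 2, c = 2, d = 1))

  expect_error(contingency_table(3, 5, 4, n = 4, j = 2), "inconsistent")
})

test_that("coefficient formulas evaluate correctly, including fallbacks", {
  tab <- c(2, 1, 3, 0)
  expect_equal(coefficient_value(tab, "S"), 2 / 3)
  expect_equal(coefficient_value(tab, "F"), 2 * 6 / (3 * 5))
  expect_equal(coefficient_value(tab, "O"), 2 / sqrt(15))
  expect_equal(coefficient_value(tab, "SM"), 1 / 3)
  expect_equal(coefficient_value(tab, "J"), 1 / 3)
  expect_equal(coefficient_value(tab, "D"), 4 / 8)
  expect_equal(coefficient_value(tab, "A"), 2 / 10)
  expect_equal(coefficient_value(tab, "RR"), 1 / 3)

  # ordering sanity on the worked table: S >= O >= J
  expect_true(coefficient_value(tab, "S") >= coefficient_value(tab, "O"))
  expect_true(coefficient_value(tab, "O") >= coefficient_value(tab, "J"))

  # self-comparison table: all bounded indices hit 1
  self <- c(7, 0, 0, 3)
  for (co in c("SM", "J", "S", "D", "A", "O")) {
    expect_equal(coefficient_value(self, co), 1)
  }
  # zero-denominator fallback (possible only out-of-sample): define as 0
  empty <- c(0, 0, 0, 10)
  for (co in setdiff(band_coefficients, c("SM", "RR"))) {
    expect_equal(coefficient_value(empty, co), 0)
  }
  expect_equal(coefficient_value(empty, "SM"), 1)
  expect_equal(coefficient_value(empty, "RR"), 0)
})

test_that("band similarity matrices are symmetric with the expected diagonal", {
  set.seed(11)
  y <- random_tied_matrix(7, 3)
  for (co in band_coefficients) {
    s <- band_similarity(y, J = 3, coefficient = co)
    m <- unclass(s)
    expect_equal(max(abs(m - t(m))), 0)
    if (co %in% c("SM", "J", "S", "D", "A", "O")) {
      expect_equal(unname(diag(m)), rep(1, 7))
    }
    if (co == "F") {
      expect_true(all(diag(m) >= 1))     # observed/expected self-ratio
      expect_true(all(m >= 0))
    } else {
      expect_true(all(m >= 0 & m <= 1 + 1e-12))
    }
  }
})

test_that("similarity values agree with the explicit band-matrix oracle", {
  set.seed(202)
  # worked one-dimensional case: samples with values 2 and 3 share 4 of
  # their 5 bands, so Simpson = 4/5 (frozen from the oracle)
  s <- band_similarity(matrix(1:4, ncol = 1), J = 2, coefficient = "S")
  expect_equal(unclass(s)[2, 3], 0.8)
  expect_equal(unclass(s)[2, 3], oracle_similarity(matrix(1:4, ncol = 1), 2, "S")[2, 3])

  for (rep in 1:6) {
    n <- sample(4:7, 1)
    d <- sample(1:3, 1)
    y <- random_tied_matrix(n, d)
    J <- min(4, n)
    for (co in band_coefficients) {
      expect_equal(unclass(band_similarity(y, J = J, coefficient = co)),
                   oracle_similarity(y, J, co),
                   ignore_attr = TRUE, tolerance = 1e-12)
    }
  }
})

test_that("pooled-table aggregation applies the coefficient to summed tables", {
  set.seed(8)
  y <- random_tied_matrix(5, 3)
  s <- band_similarity(y, J = 3, coefficient = "J", aggregation = "pooled")
  # independent evaluation from raw counts
  st <- column_order_stats(y)
  expected <- 0
  for (j in 2:3) {
    cnj <- band_binom(5, j)
    n1 <- count_bands_single(st, y[1, ], j)
    n2 <- count_bands_single(st, y[4, ], j)
    np <- count_bands_pair(st, y[1, ], y[4, ], j)
    a <- sum(np); b <- sum(n1 - np); cc <- sum(n2 - np)
    d <- 3 * cnj - a - b - cc
    expected <- expected + coefficient_value(c(a, b, cc, d), "J")
  }
  expect_equal(unclass(s)[1, 4], expected / 2, tolerance = 1e-12)
})

test_that("similarities are invariant to increasing per-coordinate transforms", {
  set.seed(77)
  y <- random_tied_matrix(6, 3)
  z <- cbind(exp(y[, 1]), 2 * y[, 2] + 5, y[, 3]^3)
  for (co in c("S", "F", "RR")) {
    expect_equal(unclass(band_similarity(y, J = 3, coefficient = co)),
                 unclass(band_similarity(z, J = 3, coefficient = co)),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("cross-similarity blocks handle in-sample, pooled and extreme queries", {
  set.seed(5)
  y <- matrix(rnorm(24), 6, 4)
  rownames(y) <- paste0("t", 1:6)
  s <- band_similarity(y, J = 3, coefficient = "O")
  cb <- cross_band_similarity(y, y[3, , drop = FALSE], J = 3, coefficient = "O")
  expect_equal(unname(unclass(cb)[1, ]), unname(unclass(s)[3, ]), tolerance = 1e-12)

  # pooled reference equals the full-matrix rows on the stacked sample
  q <- matrix(rnorm(8), 2, 4, dimnames = list(c("q1", "q2"), NULL))
  sp <- band_similarity(rbind(y, q), J = 2, coefficient = "S")
  cbp <- cross_band_similarity(y, q, J = 2, coefficient = "S", reference = "pooled")
  expect_equal(unclass(cbp), unclass(sp)[7:8, 1:6],
               ignore_attr = TRUE, tolerance = 1e-12)

  # a query beyond every training range lies in zero bands: fallback gives 0
  far <- cross_band_similarity(y, rep(1e6, 4), J = 2, coefficient = "S")
  expect_equal(max(unclass(far)), 0)

  # out-of-sample count example: value 2.5 against column 1..4
  st <- column_order_stats(matrix(1:4, ncol = 1))
  expect_equal(count_bands_single(st, 2.5, 2), 4)

  expect_error(cross_band_similarity(y, matrix(0, 1, 3), J = 2), "share variables")
})

test_that("dissimilarity conversion rescales Forbes and flags Russell-Rao", {
  set.seed(14)
  y <- random_tied_matrix(6, 3)
  dj <- to_dissimilarity(band_similarity(y, J = 2, coefficient = "J"))
  expect_equal(unname(diag(unclass(dj))), rep(0, 6))
  expect_true(all(unclass(dj) >= 0))

  sf <- band_similarity(y, J = 2, coefficient = "F")
  df <- to_dissimilarity(sf)
  expect_equal(unclass(df), pmax(1 - unclass(sf) / max(unclass(sf)), 0),
               ignore_attr = TRUE)
  expect_equal(min(unclass(df)), 0)  # the max entry maps to dissimilarity 0

  srr <- band_similarity(y, J = 2, coefficient = "RR")
  expect_warning(drr <- to_dissimilarity(srr), "not reflexive")
  expect_true(isTRUE(attr(drr, "nonreflexive")))
  expect_true(any(diag(unclass(drr)) > 0))
})

test_that("tidy and autoplot work on similarity objects", {
  y <- random_tied_matrix(4, 2)
  s <- band_similarity(y, J = 2)
  td <- tidy(s)
  expect_equal(nrow(td), 16)
  expect_named(td, c("sample_1", "sample_2", "value"))
  expect_s3_class(autoplot(s), "ggplot")
})
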