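test_that("choose_k returns the largest odd integer below sqrt(n)", {
  expect_equal(choose_k(200), 13)
  expect_equal(choose_k(9), 3)
  expect_equal(choose_k(4), 1)
  expect_equal(choose_k(1), 1)
  expect_error(choose_k(0), ">= 1")
})

test_that("classical dissimilarities follow their formulas", {
  x <- rbind(c(0, 0), c(3, 4))
  expect_equal(unclass(dissimilarity(x, dist_spec("euclidean")))[1, 2], 5)
  expect_equal(unclass(dissimilarity(x, dist_spec("manhattan")))[1, 2], 7)
  expect_equal(unclass(dissimilarity(x, dist_spec("minkowski", p = 0.5)))[1, 2],
               (sqrt(3) + sqrt(4))^2, tolerance = 1e-12)
  # perfectly linearly related profiles are at Pearson distance 0
  z <- rbind(1:5, 2 * (1:5) + 3, 5:1)
  pd <- unclass(dissimilarity(z, dist_spec("pearson")))
  expect_equal(pd[1, 2], 0, tolerance = 1e-12)
  expect_equal(pd[1, 3], 2, tolerance = 1e-12)
  expect_error(dissimilarity(rbind(c(1, 1, 1), 1:3), dist_spec("pearson")),
               "zero-variance")
  expect_error(dist_spec("minkowski", p = -1), "p > 0")

  # cross blocks agree with the square matrix on shared rows
  set.seed(40)
  y <- matrix(rnorm(30), 6, 5)
  for (spec in list(dist_spec("euclidean"), dist_spec("minkowski", p = 0.5),
                    dist_spec("pearson"))) {
    full <- unclass(dissimilarity(y, spec))
    blk <- unclass(cross_dissimilarity(y, y[2:3, ], spec))
    expect_equal(blk, full[2:3, ], ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("knn classification applies the vote and tie rules deterministically", {
  # k = 1: label of the argmin
  d1 <- matrix(c(0.3, 0.1, 0.9), 1)
  expect_equal(as.character(knn_classify(d1, c("A", "B", "A"), 1)), "B")
  # k = 3 majority
  d3 <- matrix(c(0.1, 0.2, 0.3, 0.9), 1)
  expect_equal(as.character(knn_classify(d3, c("A", "B", "B", "A"), 3)), "B")
  # k = 4 vote tie resolved by the nearest neighbour
  d4 <- matrix(c(0.2, 0.1, 0.3, 0.4), 1)
  expect_equal(as.character(knn_classify(d4, c("A", "B", "A", "B"), 4)), "B")
  # all-equal distances: ties fall back to lowest training index
  dz <- matrix(0, 2, 4)
  expect_equal(as.character(knn_classify(dz, c("B", "A", "A", "B"), 3)),
               c("A", "A"))
  expect_error(knn_classify(d1, c("A", "B", "A"), 4), "n_train")

  # matches an exhaustive reference on random Euclidean data
  set.seed(41)
  tr <- matrix(rnorm(60), 20, 3)
  lab <- factor(rep(c("u", "v"), 10))
  qs <- matrix(rnorm(15), 5, 3)
  blk <- cross_dissimilarity(tr, qs, dist_spec("euclidean"))
  for (k in c(1, 3, 5)) {
    ref <- apply(qs, 1, function(q) {
      dd <- sqrt(colSums((t(tr) - q)^2))
      nb <- lab[order(dd)][1:k]
      tt <- table(nb)
      top <- names(tt)[tt == max(tt)]
      if (length(top) == 1) top else as.character(nb[1])
    })
    expect_equal(as.character(knn_classify(blk, lab, k)), ref)
  }
})

test_that("cross-validated error is near 0 for separated and 0.5 for permuted labels", {
  set.seed(42)
  x <- rbind(matrix(rnorm(50 * 4), 50, 4),
             matrix(rnorm(50 * 4, mean = 8), 50, 4))
  lab <- rep(c("a", "b"), each = 50)
  res <- cv_error(x, lab, dist_spec("euclidean"), repeats = 2, seed = 1)
  expect_equal(res$error, c(0, 0))

  perm <- sample(lab)
  res2 <- cv_error(x, perm, dist_spec("euclidean"), repeats = 5, seed = 2)
  expect_gt(mean(res2$error), 0.35)
  expect_lt(mean(res2$error), 0.65)

  # determinism: same seed, same folds, same errors
  r1 <- cv_error(x, lab, dist_spec("manhattan"), repeats = 3, seed = 7)
  r2 <- cv_error(x, lab, dist_spec("manhattan"), repeats = 3, seed = 7)
  expect_identical(r1, r2)

  small <- c(1:6, 51:56)  # 6 per class, fewer than the 10 folds
  expect_error(cv_error(x[small, ], lab[small], dist_spec("euclidean")),
               "at least as many samples as folds")
})

test_that("feature rules are refit inside training folds", {
  set.seed(43)
  n <- 60
  informative <- c(rnorm(n / 2), rnorm(n / 2, mean = 6))
  x <- cbind(informative, matrix(rnorm(n * 30), n, 30))
  colnames(x) <- paste0("g", 1:31)
  lab <- rep(c("a", "b"), each = n / 2)
  res <- cv_error(x, lab, dist_spec("euclidean"), repeats = 1,
                  feature_rule = function(xt, lt) bw_select(xt, lt, 1),
                  seed = 3)
  expect_lt(res$error, 0.1)
})

test_that("B/W ranking prefers separated low-noise variables", {
  # 4-sample toy, hand arithmetic:
  # g1: between = 2*(1-2)^2 + 2*(3-2)^2 = 4; within = 2*0.5^2*2 = 1 -> BW 4
  x <- cbind(g1 = c(0.5, 1.5, 2.5, 3.5),
             g2 = c(1, 1, 1, 1),            # constant: 0/0, ranks last
             g3 = c(0, 10, 0.2, 10.2))      # strong signal when relabelled
  lab <- c("u", "u", "v", "v")
  bw3 <- function(xx) {
    mu <- mean(xx); m1 <- mean(xx[1:2]); m2 <- mean(xx[3:4])
    b <- 2 * (m1 - mu)^2 + 2 * (m2 - mu)^2
    w <- sum((xx[1:2] - m1)^2) + sum((xx[3:4] - m2)^2)
    b / w
  }
  expect_equal(bw3(x[, "g1"]), 4)
  sel <- bw_select(x, lab, 2)
  ord <- order(-c(bw3(x[, 1]), -Inf, bw3(x[, 3])))
  expect_equal(unname(sel), sort(ord[1:2]))

  # higher separation at equal noise ranks first
  set.seed(44)
  noise <- rnorm(20, sd = 0.1)
  y <- cbind(big = rep(c(0, 10), each = 10) + noise,
             small = rep(c(0, 1), each = 10) + noise)
  lab2 <- rep(c("a", "b"), each = 10)
  expect_equal(names(bw_select(y, lab2, 1)), "big")
  # zero within-group variance with signal ranks first (infinite ratio)
  z <- cbind(perfect = rep(c(0, 1), each = 10),
             noisy = rep(c(0, 5), each = 10) + rnorm(20))
  expect_equal(names(bw_select(z, lab2, 1)), "perfect")
  expect_error(bw_select(y, rep("a", 20), 1), "two classes")
})

test_that("variance filter keeps the most variable columns", {
  x <- cbind(flat = rep(1, 6), wide = c(0, 10, 0, 10, 0, 10),
             mid = c(1, 2, 1, 2, 1, 2))
  expect_equal(names(variance_select(x, 1)), "wide")
  expect_equal(names(variance_select(x, 2)), c("wide", "mid"))
  expect_error(variance_select(x, 5), "exceeds")
})

test_that("pam clustering is deterministic and finds obvious partitions", {
  set.seed(45)
  x <- rbind(matrix(rnorm(20, sd = 0.2), 10, 2),
             matrix(rnorm(20, mean = 5, sd = 0.2), 10, 2))
  d <- dissimilarity(x, dist_spec("euclidean"))
  p <- pam_cluster(d, 2)
  expect_equal(clustering_error(p$assignment, rep(1:2, each = 10)), 0)
  expect_identical(p$assignment, pam_cluster(d, 2)$assignment)

  # degenerate all-zero dissimilarity still runs with zero cost
  z <- matrix(0, 6, 6)
  pz <- pam_cluster(z, 2)
  expect_equal(pz$cost, 0)

  # 5-point dissimilarity with a clear 2 + 3 split: matches exhaustive search
  dm <- as.matrix(dist(c(0, 0.5, 10, 10.5, 11)))
  p5 <- pam_cluster(dm, 2)
  best <- Inf
  for (m1 in 1:4) for (m2 in (m1 + 1):5) {
    cost <- sum(pmin(dm[, m1], dm[, m2]))
    if (cost < best) { best <- cost; bestpair <- c(m1, m2) }
  }
  expect_equal(sum(pmin(dm[, p5$medoids[1]], dm[, p5$medoids[2]])), best)
  expect_equal(unname(p5$assignment), c(1, 1, 2, 2, 2))
  expect_error(pam_cluster(dm, 1), "2 <= G")
})

test_that("complete linkage merges reproduce hand-simulated heights", {
  dm <- matrix(0, 3, 3)
  dm[1, 2] <- dm[2, 1] <- 1
  dm[1, 3] <- dm[3, 1] <- 5
  dm[2, 3] <- dm[3, 2] <- 4
  hc <- complete_linkage_tree(dm)
  expect_equal(hc$height, c(1, 5))
  expect_equal(hc$merge[1, ], c(-1, -2))

  # ultrametric input: heights reproduce the ultrametric levels
  um <- matrix(c(0, 1, 3, 3, 1, 0, 3, 3, 3, 3, 0, 2, 3, 3, 2, 0), 4)
  expect_equal(sort(complete_linkage_tree(um)$height), c(1, 2, 3))

  # n = 2: a single merge
  expect_equal(nrow(complete_linkage_tree(matrix(c(0, 2, 2, 0), 2))$merge), 1)

  nw <- tree_newick(hc)
  expect_match(nw, "^\\(")
})

test_that("clustering error is the minimum disagreement over label permutations", {
  expect_equal(clustering_error(c(1, 2, 2, 2), c("A", "A", "B", "B")), 0.25)
  expect_equal(clustering_error(1:4, 1:4), 0)
  # permutation invariance in both arguments
  set.seed(46)
  pred <- sample(1:3, 30, replace = TRUE)
  truth <- sample(c("x", "y", "z"), 30, replace = TRUE)
  base <- clustering_error(pred, truth)
  relab <- c(3, 1, 2)[pred]
  expect_equal(clustering_error(relab, truth), base)
  expect_equal(clustering_error(pred, c(z = "y", y = "x", x = "z")[truth]), base)
  expect_error(clustering_error(1:3, 1:4), "equal length")
  expect_error(clustering_error(1:8, 8:1), NA)
  expect_error(clustering_error(1:9, 1:9), "8 distinct")
})

test_that("adjusted Rand index matches the closed form and the mclust oracle", {
  expect_equal(adjusted_rand_index(1:5, 1:5), 1)
  expect_equal(adjusted_rand_index(c(1, 2, 2, 2), c("A", "A", "B", "B")), 0)
  # degenerate conventions
  expect_equal(adjusted_rand_index(1:4, rep(1, 4)), 0)
  expect_equal(adjusted_rand_index(1:4, 4:1), 1)

  set.seed(47)
  for (rep in 1:10) {
    pred <- sample(1:4, 40, replace = TRUE)
    truth <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(pred, truth),
                 mclust::adjustedRandIndex(pred, truth), tolerance = 1e-12)
  }
})
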