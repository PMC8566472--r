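#' Default neighbourhood size for kNN
#'
#' The rule of thumb used throughout the benchmarks: the largest odd integer
#' not exceeding the square root of the number of training samples (at least
#' 1). `k` remains an explicit argument everywhere, so the rule is only the
#' default; small-class designs may need a manual override.
#'
#' @param n_train Number of training samples.
#' @return An odd integer `>= 1`.
#' @examples
#' choose_k(200)  # 13
#' @export
choose_k <- function(n_train) {
  if (n_train < 1) abort("n_train must be >= 1")
  k <- floor(sqrt(n_train))
  if (k %% 2 == 0) k <- k - 1
  max(1L, as.integer(k))
}

#' k-nearest-neighbour classification from a precomputed dissimilarity block
#'
#' Classifies each query row by majority vote among its `k` nearest
#' training samples. Vote ties are broken by the label of the single
#' nearest neighbour (as if `k = 1`); exact distance ties are broken by the
#' lowest training index, so predictions are fully deterministic.
#'
#' @param d_block Queries x train dissimilarity matrix (e.g. from
#'   [cross_dissimilarity()]).
#' @param train_labels Vector/factor of training labels, one per column.
#' @param k Number of neighbours, `1 <= k <= n_train`.
#' @return Factor of predicted labels, one per query row.
#' @export
knn_classify <- function(d_block, train_labels, k) {
  d_block <- as.matrix(d_block)
  n_train <- ncol(d_block)
  if (length(train_labels) != n_train) {
    abort("one training label per column of the dissimilarity block required")
  }
  if (k < 1 || k > n_train) abort("k must be in [1, n_train]")
  train_labels <- as.factor(train_labels)
  pred <- character(nrow(d_block))
  for (i in seq_len(nrow(d_block))) {
    ord <- order(d_block[i, ])  # stable: distance ties keep training order
    nb <- train_labels[ord[seq_len(k)]]
    votes <- table(nb)
    top <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(top) == 1) top else as.character(nb[1])
  }
  factor(pred, levels = levels(train_labels))
}

#' Supervised gene ranking by the B/W criterion
#'
#' Ranks variables by the ratio of between-class to within-class sums of
#' squares,
#' `BW(g) = sum_c n_c (xbar_cg - xbar_g)^2 / sum_c sum_{i in c} (x_ig - xbar_cg)^2`,
#' and returns the top `m`. A variable with zero within-class variance but
#' positive between-class spread ranks first (infinite ratio); a variable
#' constant everywhere (0/0) ranks last. Ties keep the original variable
#' order.
#'
#' @param x Expression input accepted by [as_expression_matrix()].
#' @param labels Class labels, one per sample (at least two classes).
#' @param m Number of variables to keep.
#' @return Integer vector of selected column indices (named by variable id).
#' @export
bw_select <- function(x, labels, m) {
  y <- as_expression_matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) abort("bw_select needs at least two classes")
  if (m > ncol(y)) abort("m exceeds the number of variables")
  overall <- colMeans(y)
  between <- numeric(ncol(y))
  within <- numeric(ncol(y))
  for (cl in levels(labels)) {
    rows <- labels == cl
    mu_c <- colMeans(y[rows, , drop = FALSE])
    between <- between + sum(rows) * (mu_c - overall)^2
    within <- within + colSums((y[rows, , drop = FALSE] -
                                  matrix(mu_c, sum(rows), ncol(y), byrow = TRUE))^2)
  }
  bw <- ifelse(within > 0, between / within,
               ifelse(between > 0, Inf, -Inf))  # 0/0: no signal, rank last
  ord <- order(-bw)
  sel <- sort(ord[seq_len(m)])
  setNames(sel, colnames(y)[sel])
}

#' Unsupervised gene ranking by variance
#'
#' Keeps the `m` most variable columns; ties keep the original variable
#' order, and constant variables rank last.
#'
#' @inheritParams bw_select
#' @return Integer vector of selected column indices (named by variable id).
#' @export
variance_select <- function(x, m) {
  y <- as_expression_matrix(x)
  if (m > ncol(y)) abort("m exceeds the number of variables")
  v <- apply(y, 2, var)
  sel <- sort(order(-v)[seq_len(m)])
  setNames(sel, colnames(y)[sel])
}

#' Stratified repeated cross-validated kNN error
#'
#' Estimates the misclassification rate of kNN under a given dissimilarity
#' by stratified `folds`-fold cross-validation repeated `repeats` times.
#' When a `feature_rule` is supplied (a function of the training matrix and
#' training labels returning column indices, e.g. a top-200 B/W filter) it
#' is re-fitted inside every training fold, so the selection bias of
#' filtering on the full data is avoided.
#'
#' @param x Expression input accepted by [as_expression_matrix()].
#' @param labels Class labels, one per sample.
#' @param spec A [dist_spec()].
#' @param folds Number of folds (default 10).
#' @param repeats Number of independent fold repartitions.
#' @param feature_rule Optional `function(x_train, labels_train)` returning
#'   column indices to keep.
#' @param k Neighbourhood size; default [choose_k()] of the training size.
#' @param seed Optional integer seed making fold splits reproducible.
#' @return Tibble with columns `repeat_id` and `error` (proportion of the
#'   `n` samples misclassified in that repetition).
#' @export
cv_error <- function(x, labels, spec, folds = 10, repeats = 1,
                     feature_rule = NULL, k = NULL, seed = NULL) {
  y <- as_expression_matrix(x)
  labels <- as.factor(labels)
  if (length(labels) != nrow(y)) abort("one label per sample required")
  if (folds < 2) abort("folds must be >= 2")
  if (min(table(labels)) < folds) {
    abort("every class must have at least as many samples as folds")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(y)
  purrr::map_dfr(seq_len(repeats), function(r) {
    fold <- integer(n)
    for (cl in levels(labels)) {
      rows <- which(labels == cl)
      fold[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
    wrong <- 0L
    for (f in seq_len(folds)) {
      test_idx <- which(fold == f)
      train_idx <- which(fold != f)
      xtr <- y[train_idx, , drop = FALSE]
      ltr <- droplevels(labels[train_idx])
      keep <- if (is.null(feature_rule)) seq_len(ncol(y)) else feature_rule(xtr, ltr)
      block <- cross_dissimilarity(xtr[, keep, drop = FALSE],
                                   y[test_idx, keep, drop = FALSE], spec)
      kk <- if (is.null(k)) choose_k(length(train_idx)) else k
      pred <- knn_classify(block, ltr, kk)
      wrong <- wrong + sum(as.character(pred) != as.character(labels[test_idx]))
    }
    tibble::tibble(repeat_id = r, error = wrong / n)
  })
}

#' Partitioning around medoids on a precomputed dissimilarity
#'
#' Runs the classical deterministic BUILD + SWAP k-medoids algorithm (via
#' [cluster::pam()]) directly on a dissimilarity matrix.
#'
#' @param d A `band_dissimilarity`, `dist` or square numeric matrix.
#' @param G Number of clusters, `2 <= G < n`.
#' @return A list of class `band_partition` with `assignment` (integer
#'   cluster ids, named by sample), `medoids` (sample indices) and `cost`
#'   (final total dissimilarity to medoids).
#' @export
pam_cluster <- function(d, G) {
  dm <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  n <- nrow(dm)
  if (G < 2 || G >= n) abort("G must satisfy 2 <= G < n")
  fit <- cluster::pam(stats::as.dist(dm), k = G, diss = TRUE,
                      variant = "original")
  structure(list(assignment = fit$clustering,
                 medoids = as.integer(fit$id.med),
                 cost = unname(fit$objective["swap"])),
            class = "band_partition")
}

#' @export
print.band_partition <- function(x, ...) {
  cat(sprintf("PAM partition: %d clusters, cost %.6g\n",
              length(x$medoids), x$cost))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Complete-linkage hierarchical clustering of a dissimilarity
#'
#' Thin wrapper over [stats::hclust()] with complete linkage, returning the
#' standard merge tree. Use [tree_newick()] to export it with heights.
#'
#' @param d A `band_dissimilarity`, `dist` or square numeric matrix.
#' @return An `hclust` object.
#' @export
complete_linkage_tree <- function(d) {
  dm <- if (inherits(d, "dist")) d else stats::as.dist(as.matrix(d))
  hclust(dm, method = "complete")
}

#' Export a merge tree as a Newick string
#'
#' @param tree An `hclust` object.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when written to file.
#' @export
tree_newick <- function(tree, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the 'ape' package is required for Newick export")
  }
  phy <- ape::as.phylo(tree)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

all_permutations <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_permutations(v[-i]))
  }))
}

#' Clustering error rate against known classes
#'
#' The minimum, over all permutations of the cluster labels, of the
#' proportion of samples whose cluster label disagrees with the true class.
#' Invariant to relabelling of either argument. The permutation search is
#' exact and limited to at most 8 distinct labels (8! mappings over a
#' confusion matrix).
#'
#' @param pred Predicted cluster assignment.
#' @param truth True class labels (same length).
#' @return Error rate in `[0, 1 - 1/G]`.
#' @examples
#' clustering_error(c(1, 2, 2, 2), c("A", "A", "B", "B"))  # 0.25
#' @export
clustering_error <- function(pred, truth) {
  if (length(pred) != length(truth)) abort("pred and truth must have equal length")
  pi <- as.integer(factor(pred))
  ti <- as.integer(factor(truth))
  G <- max(max(pi), max(ti))
  if (G > 8) abort("exact permutation search limited to 8 distinct labels")
  conf <- matrix(0, G, G)
  for (i in seq_along(pi)) conf[pi[i], ti[i]] <- conf[pi[i], ti[i]] + 1
  perms <- all_permutations(seq_len(G))
  agree <- apply(perms, 1, function(p) sum(conf[cbind(seq_len(G), p)]))
  1 - max(agree) / length(pi)
}

#' Adjusted Rand index of two partitions
#'
#' Chance-corrected pair-counting agreement (Hubert-Arabie form) computed
#' from the contingency table of the two partitions. Returns 1 for
#' identical partitions; in the degenerate case where the expected index
#' equals the maximum index (e.g. all singletons versus one block, where
#' no pair is informative) the value is defined as 1 if the partitions
#' coincide up to relabelling and 0 otherwise.
#'
#' @param pred,truth Two partitions of the same elements.
#' @return ARI value `<= 1`.
#' @export
adjusted_rand_index <- function(pred, truth) {
  if (length(pred) != length(truth)) abort("pred and truth must have equal length")
  conf <- table(pred, truth)
  n <- length(pred)
  sum_ij <- sum(choose(conf, 2))
  sum_a <- sum(choose(rowSums(conf), 2))
  sum_b <- sum(choose(colSums(conf), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) {
    same <- all(rowSums(conf > 0) <= 1) && all(colSums(conf > 0) <= 1)
    return(if (same && sum_ij == maximum) 1 else 0)
  }
  (sum_ij - expected) / (maximum - expected)
}
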