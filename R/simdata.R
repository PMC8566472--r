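#' Deterministic per-replicate child seeds
#'
#' Experiments derive one child seed per replicate from the root seed with
#' the fixed rule `((seed * 48271 + r * 16807) mod (2^31 - 2)) + 1`, so a
#' run is a pure function of `(config, seed)` and replicates can be
#' regenerated individually.
#'
#' @param seed Root integer seed.
#' @param r Replicate number (1-based).
#' @return A positive integer seed below 2^31.
#' @export
child_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(r) * 16807) %% 2147483645) + 1L
}

new_labeled_data <- function(x, labels) {
  x <- as_expression_matrix(x)
  labels <- as.factor(labels)
  names(labels) <- rownames(x)
  structure(list(x = x, labels = labels), class = "labeled_data")
}

#' @export
print.labeled_data <- function(x, ...) {
  cat(sprintf("Labeled data: %d samples x %d variables, %d classes\n",
              nrow(x$x), ncol(x$x), nlevels(x$labels)))
  print(table(x$labels))
  invisible(x)
}

#' Two overlapping spherical Gaussian groups in 100 dimensions
#'
#' A simple emulation of group-structured expression profiles: two groups
#' of independent unit-variance coordinates with means 0 and 0.5 in every
#' one of the 100 variables.
#'
#' @param n_per_group Samples per group.
#' @param seed Optional integer seed.
#' @return A `labeled_data` object (fields `x`, `labels`).
#' @export
model1 <- function(n_per_group = 50, seed = NULL) {
  if (n_per_group < 1) abort("n_per_group must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  d <- 100
  x1 <- matrix(rnorm(n_per_group * d, mean = 0), n_per_group, d)
  x2 <- matrix(rnorm(n_per_group * d, mean = 0.5), n_per_group, d)
  x <- rbind(x1, x2)
  rownames(x) <- paste0("s", seq_len(2 * n_per_group))
  colnames(x) <- paste0("V", seq_len(d))
  new_labeled_data(x, rep(c("g1", "g2"), each = n_per_group))
}

#' Two Gaussian groups in 10 dimensions with an inflatable noise coordinate
#'
#' Group means are `0` and `(1, 0.8, 0.6, 0.4, 0.2, 0, 0, 0, 0, 0)`: the
#' last five variables are pure noise. Both groups share a diagonal
#' covariance `0.1 * I` whose 6th diagonal entry is increased by `delta`
#' (`noise_form = "covariance"`, the default reading of the model as a
#' covariance matrix). The alternative reading `noise_form = "sd"` adds
#' `delta` to the standard deviation of the 6th coordinate instead.
#'
#' @param delta Noise inflation of the 6th coordinate (0, 1 or 2 in the
#'   benchmarks).
#' @param n_per_group Samples per group.
#' @param seed Optional integer seed.
#' @param noise_form `"covariance"` (default) or `"sd"`.
#' @return A `labeled_data` object.
#' @export
model2 <- function(delta = 0, n_per_group = 50, seed = NULL,
                   noise_form = c("covariance", "sd")) {
  noise_form <- match.arg(noise_form)
  if (delta < 0) abort("delta must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  d <- 10
  sigma2 <- rep(0.1, d)
  if (noise_form == "covariance") {
    sigma2[6] <- sigma2[6] + delta
  } else {
    sigma2[6] <- (sqrt(0.1) + delta)^2
  }
  mu2 <- c(seq(1, 0.2, by = -0.2), rep(0, 5))
  sd_row <- sqrt(sigma2)
  x1 <- matrix(rnorm(n_per_group * d, sd = rep(sd_row, each = n_per_group)),
               n_per_group, d)
  x2 <- matrix(rnorm(n_per_group * d,
                     mean = rep(mu2, each = n_per_group),
                     sd = rep(sd_row, each = n_per_group)),
               n_per_group, d)
  x <- rbind(x1, x2)
  rownames(x) <- paste0("s", seq_len(2 * n_per_group))
  colnames(x) <- paste0("V", seq_len(d))
  new_labeled_data(x, rep(c("g1", "g2"), each = n_per_group))
}

#' Sample labelled data from an explicit Gaussian mixture specification
#'
#' Draws `n_per_group` observations from each component of a Gaussian
#' mixture given by explicit mean vectors and covariance matrices (e.g.
#' overlap-calibrated parameters produced elsewhere).
#'
#' @param means List of `G` mean vectors of equal length.
#' @param covariances List of `G` symmetric positive semi-definite matrices.
#' @param n_per_group Samples per component (scalar or length-`G` vector).
#' @param seed Optional integer seed.
#' @return A `labeled_data` object.
#' @export
gaussian_mixture_from_spec <- function(means, covariances, n_per_group,
                                       seed = NULL) {
  G <- length(means)
  if (length(covariances) != G) abort("one covariance per component required")
  d <- length(means[[1]])
  n_per_group <- rep_len(n_per_group, G)
  if (!is.null(seed)) set.seed(seed)
  blocks <- vector("list", G)
  for (g in seq_len(G)) {
    sig <- covariances[[g]]
    if (!isSymmetric(unname(sig), tol = 1e-8)) abort("covariance must be symmetric")
    ev <- eigen(sig, symmetric = TRUE)
    if (min(ev$values) < -1e-8 * max(abs(ev$values))) {
      abort("covariance must be positive semi-definite")
    }
    root <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    z <- matrix(rnorm(n_per_group[g] * d), n_per_group[g], d)
    blocks[[g]] <- sweep(z %*% root, 2, means[[g]], "+")
  }
  x <- do.call(rbind, blocks)
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  colnames(x) <- paste0("V", seq_len(d))
  new_labeled_data(x, rep(paste0("g", seq_len(G)), times = n_per_group))
}

new_band_experiment <- function(task, results, config) {
  structure(list(task = task, results = results, config = config),
            class = "band_experiment")
}

#' Benchmark dissimilarities in a train/test classification protocol
#'
#' For each replicate, draws an independent training set and test set from
#' the generator, builds each dissimilarity's query-to-train block,
#' classifies the test set with kNN (`k` defaulting to [choose_k()] of the
#' training size) and records the test error rate.
#'
#' @param generator A `function(n_per_group, seed)` returning
#'   `labeled_data`, e.g. [model1()] or a wrapper around [model2()].
#' @param specs Named list of [dist_spec()] objects.
#' @param B Number of replicates.
#' @param n_train_per_group,n_test_per_group Per-group sizes of the two
#'   independent draws.
#' @param k Neighbourhood size override (default: rule of thumb).
#' @param seed Root seed; replicate `r` uses [child_seed()] values
#'   `2r - 1` (train) and `2r` (test).
#' @return A `band_experiment` object; see [tidy.band_experiment()] and
#'   [glance.band_experiment()].
#' @export
run_classification_experiment <- function(generator, specs, B = 200,
                                          n_train_per_group = 100,
                                          n_test_per_group = 25,
                                          k = NULL, seed = 1) {
  if (B < 1) abort("B must be >= 1")
  if (is.null(names(specs))) names(specs) <- vapply(specs, spec_label, character(1))
  results <- purrr::map_dfr(seq_len(B), function(r) {
    train <- generator(n_train_per_group, child_seed(seed, 2 * r - 1))
    test <- generator(n_test_per_group, child_seed(seed, 2 * r))
    kk <- if (is.null(k)) choose_k(nrow(train$x)) else k
    purrr::map_dfr(names(specs), function(nm) {
      block <- cross_dissimilarity(train$x, test$x, specs[[nm]])
      pred <- knn_classify(block, train$labels, kk)
      tibble::tibble(replicate = r, method = nm,
                     error = mean(as.character(pred) != as.character(test$labels)))
    })
  })
  new_band_experiment("classification", results,
                      list(B = B, n_train_per_group = n_train_per_group,
                           n_test_per_group = n_test_per_group,
                           k = k, seed = seed, specs = specs))
}

#' Benchmark dissimilarities in a PAM clustering protocol
#'
#' For each replicate, draws one data set from the generator, computes each
#' dissimilarity matrix, partitions it with [pam_cluster()] into the true
#' number of groups and records the clustering error rate and the adjusted
#' Rand index against the generating labels.
#'
#' @inheritParams run_classification_experiment
#' @param n_per_group Samples per group in each simulated data set.
#' @return A `band_experiment` object with per-replicate `error` and `ari`.
#' @export
run_clustering_experiment <- function(generator, specs, B = 200,
                                      n_per_group = 50, seed = 1) {
  if (B < 1) abort("B must be >= 1")
  if (is.null(names(specs))) names(specs) <- vapply(specs, spec_label, character(1))
  results <- purrr::map_dfr(seq_len(B), function(r) {
    dat <- generator(n_per_group, child_seed(seed, r))
    G <- nlevels(dat$labels)
    purrr::map_dfr(names(specs), function(nm) {
      d <- dissimilarity(dat$x, specs[[nm]])
      part <- pam_cluster(d, G)
      tibble::tibble(replicate = r, method = nm,
                     error = clustering_error(part$assignment, dat$labels),
                     ari = adjusted_rand_index(part$assignment, dat$labels))
    })
  })
  new_band_experiment("clustering", results,
                      list(B = B, n_per_group = n_per_group, seed = seed,
                           specs = specs))
}

#' @export
print.band_experiment <- function(x, ...) {
  cat(sprintf("Band %s experiment: %d replicates, %d methods\n",
              x$task, x$config$B, length(x$config$specs)))
  print(glance(x), ...)
  invisible(x)
}

#' Per-replicate results of a band experiment
#'
#' @param x A `band_experiment` object.
#' @param ... Unused.
#' @return Tibble with one row per (replicate, method).
#' @exportS3Method generics::tidy
tidy.band_experiment <- function(x, ...) x$results

#' Per-method summary of a band experiment
#'
#' Means and standard deviations across replicates of the error rate (and,
#' for clustering, the adjusted Rand index) for each dissimilarity.
#'
#' @param x A `band_experiment` object.
#' @param ... Unused.
#' @return Tibble with one row per method.
#' @exportS3Method generics::glance
glance.band_experiment <- function(x, ...) {
  out <- x$results |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mean_error = mean(.data$error),
      sd_error = stats::sd(.data$error),
      .groups = "drop"
    )
  if ("ari" %in% names(x$results)) {
    ari <- x$results |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(mean_ari = mean(.data$ari),
                       sd_ari = stats::sd(.data$ari), .groups = "drop")
    out <- dplyr::left_join(out, ari, by = "method")
  }
  out
}

#' Boxplot of per-replicate error rates by method
#'
#' @param object A `band_experiment` object.
#' @param metric `"error"` or (clustering only) `"ari"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.band_experiment <- function(object, metric = c("error", "ari"), ...) {
  metric <- match.arg(metric)
  if (metric == "ari" && !"ari" %in% names(object$results)) {
    abort("this experiment has no ARI column")
  }
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = stats::reorder(.data$method,
                                                  .data[[metric]], mean),
                               y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
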