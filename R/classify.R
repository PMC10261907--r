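#' Scale a raw feature matrix to the [-2, 2] attribute range
#'
#' Per column: center and scale to Z-scores, truncate to `[-2, 2]` to remove
#' outliers, then linearly rescale so the column minimum maps to -2 and the
#' maximum to 2 (constant columns become all zeros). Every non-constant
#' column therefore attains both interval ends.
#'
#' @param m Numeric matrix (variants x attributes), no missing values.
#' @return Matrix of the same shape with values in `[-2, 2]` (class
#'   `ScaledFeatureMatrix`).
#' @export
scale_features <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 rows to scale")
  if (anyNA(m)) stop("missing values in feature matrix")
  out <- apply(m, 2, function(x) {
    s <- sd(x)
    if (s == 0) return(rep(0, length(x)))
    z <- (x - mean(x)) / s
    z <- pmin(pmax(z, -2), 2)
    lo <- min(z); hi <- max(z)
    -2 + 4 * (z - lo) / (hi - lo)
  })
  out <- matrix(out, nrow = nrow(m), dimnames = dimnames(m))
  class(out) <- c("ScaledFeatureMatrix", class(out))
  out
}

#' Leiden clustering of fusion variants on a kNN graph
#'
#' Builds the undirected, unweighted union of the directed Euclidean
#' k-nearest-neighbor relations and partitions it with the Leiden algorithm
#' (modularity objective). Deterministic for a fixed seed.
#'
#' @param m Scaled feature matrix (rows = variants).
#' @param k Neighbors per variant (default 50; reduced with a warning when
#'   fewer than `k + 1` rows are supplied).
#' @param resolution Leiden resolution parameter (default 3; granularity is
#'   data-set dependent — smaller values give coarser clusters).
#' @param seed Integer RNG seed.
#' @param n_iterations Leiden refinement iterations.
#' @return Integer vector of cluster labels (1-based), one per row.
#' @export
leiden_cluster <- function(m, k = 50L, resolution = 3, seed = 1L,
                           n_iterations = 10L) {
  m <- unclass(as.matrix(m))
  n <- nrow(m)
  if (k < 1) stop("k must be at least 1")
  if (n < k + 1) {
    k <- n - 1L
    warning("k reduced to ", k, " (only ", n, " rows)")
  }
  nn <- FNN::get.knn(m, k = k)$nn.index
  edges <- cbind(rep(seq_len(n), times = k), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution,
                                 n_iterations = n_iterations)
  as.integer(igraph::membership(comm))
}

#' Per-cluster COSMIC enrichment (one-sided Fisher's exact test)
#'
#' For each cluster, tests whether COSMIC-flagged variants are
#' over-represented inside the cluster versus outside (hypergeometric upper
#' tail), with Benjamini-Hochberg adjustment across clusters.
#'
#' @param labels Cluster labels, one per variant.
#' @param cosmic_flags Logical vector, one per variant.
#' @return data.frame: `cluster`, `n_cosmic_in`, `n_other_in`,
#'   `n_cosmic_out`, `n_other_out`, `p`, `q` (BH-adjusted), sorted by `p`.
#' @export
cosmic_enrichment <- function(labels, cosmic_flags) {
  stopifnot(length(labels) == length(cosmic_flags), !anyNA(cosmic_flags))
  cosmic_flags <- as.logical(cosmic_flags)
  K <- sum(cosmic_flags)
  N <- length(labels)
  res <- lapply(sort(unique(labels)), function(cl) {
    inside <- labels == cl
    a <- sum(cosmic_flags & inside)
    b <- sum(!cosmic_flags & inside)
    c_ <- K - a
    d <- N - a - b - c_
    # P(X >= a), X ~ Hypergeom(N, K, a + b)
    p <- phyper(a - 1, K, N - K, a + b, lower.tail = FALSE)
    data.frame(cluster = cl, n_cosmic_in = a, n_other_in = b,
               n_cosmic_out = c_, n_other_out = d, p = p)
  })
  res <- do.call(rbind, res)
  res$q <- p.adjust(res$p, method = "BH")
  res[order(res$p), , drop = FALSE]
}

#' Train a random forest to predict cluster labels
#'
#' Downsamples each cluster to at most `max_per_cluster` members, splits the
#' sample stratified into `train_frac` training and the rest held-out
#' testing, fits a random forest on the training fold and reports held-out
#' accuracy.
#'
#' @param m Scaled feature matrix.
#' @param labels Cluster labels (at least two clusters, each with at least
#'   three members).
#' @param max_per_cluster Per-cluster cap before the split (default 300).
#' @param train_frac Training fraction (default 2/3).
#' @param seed Integer RNG seed (controls downsampling, split and forest).
#' @param annotation_map Optional named character vector mapping cluster
#'   labels (as character) to category strings such as "COSMIC-like";
#'   unmapped labels default to "other" at prediction time.
#' @param ntree Number of trees (default 500).
#' @return A `ClusterModel`: `forest`, `classes`, `feature_names`, `labels`,
#'   `annotation_map`, `knn_k`/`resolution` slots for provenance, `seed`,
#'   `holdout_accuracy`, `test_index`.
#' @export
train_cluster_classifier <- function(m, labels, max_per_cluster = 300L,
                                     train_frac = 2 / 3, seed = 1L,
                                     annotation_map = NULL, ntree = 500L) {
  m <- unclass(as.matrix(m))
  labels <- as.vector(labels)
  stopifnot(nrow(m) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least two clusters to train a classifier")
  if (any(tab < 3)) stop("every cluster needs at least three members")
  set.seed(seed)
  keep <- unlist(lapply(names(tab), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) > max_per_cluster) sample(idx, max_per_cluster) else idx
  }), use.names = FALSE)
  train <- unlist(lapply(names(tab), function(cl) {
    idx <- keep[labels[keep] == cl]
    sample(idx, max(1L, round(train_frac * length(idx))))
  }), use.names = FALSE)
  test <- setdiff(keep, train)

  classes <- sort(unique(as.character(labels)))
  y <- match(as.character(labels), classes) - 1L
  mtry <- max(1L, floor(sqrt(ncol(m))))
  forest <- .rf_train_cpp(m[train, , drop = FALSE], y[train],
                          n_class = length(classes), ntree = as.integer(ntree),
                          mtry = mtry, min_node = 5L, max_depth = 25L,
                          seed = as.integer(seed))
  acc <- NA_real_
  if (length(test) > 0) {
    pred <- .rf_predict_cpp(forest, m[test, , drop = FALSE], length(classes))
    acc <- mean(classes[pred + 1L] == as.character(labels)[test])
  }
  structure(
    list(forest = forest, classes = classes,
         feature_names = colnames(m), labels = labels,
         annotation_map = annotation_map, knn_k = NA_integer_,
         resolution = NA_real_, seed = seed, ntree = ntree,
         holdout_accuracy = acc, test_index = test),
    class = "ClusterModel"
  )
}

#' @export
print.ClusterModel <- function(x, ...) {
  cat(sprintf("ClusterModel: %d clusters, %d trees, held-out accuracy %.3f\n",
              length(x$classes), x$ntree, x$holdout_accuracy))
  invisible(x)
}

#' Predict cluster label and category for fusion variants
#'
#' Runs the trained forest and maps predicted cluster labels through the
#' model's annotation map; labels without an annotation become "other".
#'
#' @param model A `ClusterModel` from [train_cluster_classifier()].
#' @param m Scaled feature matrix with the training column order.
#' @return data.frame: `cluster` (predicted label), `category`.
#' @export
predict_category <- function(model, m) {
  m <- unclass(as.matrix(m))
  if (!is.null(model$feature_names) && !is.null(colnames(m)) &&
      !identical(colnames(m), model$feature_names)) {
    stop("feature columns do not match the training order")
  }
  if (ncol(m) != length(model$feature_names)) {
    stop("feature columns do not match the training order")
  }
  pred <- .rf_predict_cpp(model$forest, m, length(model$classes))
  cluster <- model$classes[pred + 1L]
  category <- rep("other", length(cluster))
  if (!is.null(model$annotation_map)) {
    hit <- cluster %in% names(model$annotation_map)
    category[hit] <- unname(model$annotation_map[cluster[hit]])
  }
  data.frame(cluster = cluster, category = category, stringsAsFactors = FALSE)
}

#' Adjusted Rand index between two partitions
#'
#' Convenience metric for validating recovered cluster structure against a
#' known generating partition.
#'
#' @param a,b Two label vectors of equal length.
#' @return ARI in `[-1, 1]` (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
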