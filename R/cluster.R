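#' Fit the rhythm-state cluster model
#'
#' The classification model for 200-s segments: z-score each feature across
#' the dataset (sample SD), project onto the top principal components
#' (default 10), and cluster the scores with k-means (default k = 3, 50
#' restarts, best inertia kept, fixed seed). When per-segment rhythm
#' statistics are supplied, clusters are mapped to the three rhythm
#' categories: the cluster with the highest mean long-IC-burst count (ties
#' broken by lowest period CV) is the gastric mill rhythm (GMR), the cluster
#' with the lowest count is NONE, and the remainder IRREGULAR.
#'
#' `NA` feature sentinels are imputed at the dataset mean (z-score 0);
#' zero-variance features are dropped from the z-scoring with a warning.
#'
#' @param vectors numeric matrix, one 120-length feature row per segment.
#' @param cfg a [gm_config()]; uses `n_pca_components`, `k_clusters`,
#'   `rng_seed`.
#' @param info optional per-segment data frame with columns
#'   `n_long_ic_bursts` and `period_cv` (as from [featurize_batch()]`$info`)
#'   enabling the cluster-to-category mapping.
#' @return An object of class `gm_cluster_model` with elements `center`,
#'   `scale`, `kept` (features with nonzero variance), `rotation`,
#'   `explained_variance` (fraction captured by the retained components),
#'   `centroids`, `cluster` (training assignments), `mapping`, `category`
#'   (training labels, when `info` given) and `seed`.
#' @export
fit_cluster_model <- function(vectors, cfg = gm_config(), info = NULL) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < cfg$k_clusters)
    stop(sprintf("need at least %d segments to fit %d clusters",
                 cfg$k_clusters, cfg$k_clusters))
  center <- colMeans(vectors, na.rm = TRUE)
  center[is.nan(center)] <- 0
  scale_ <- apply(vectors, 2L, stats::sd, na.rm = TRUE)
  scale_[is.na(scale_)] <- 0
  kept <- scale_ > 0
  if (!all(kept))
    warning(sprintf("%d zero-variance feature(s) dropped from z-scoring",
                    sum(!kept)))
  z <- sweep(vectors, 2L, center, "-")
  z <- sweep(z, 2L, ifelse(kept, scale_, 1), "/")
  z[is.na(z)] <- 0          # sentinel: dataset mean
  z[, !kept] <- 0
  if (nrow(unique(z)) == 1L)
    stop("all feature vectors identical; clustering is degenerate")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ncomp <- min(cfg$n_pca_components, ncol(pc$rotation))
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  expl <- sum(pc$sdev[seq_len(ncomp)]^2) / sum(pc$sdev^2)
  if (expl <= 0.95)
    warning(sprintf(
      "retained components explain %.1f%% of total variance (<= 95%%)",
      100 * expl))
  km <- .with_seed(cfg$rng_seed,
                   stats::kmeans(scores, centers = cfg$k_clusters,
                                 nstart = 50L, iter.max = 100L))
  mapping <- NULL; category <- NULL
  if (!is.null(info)) {
    mapping <- map_clusters_to_categories(km$cluster, info, cfg$k_clusters)
    category <- unname(mapping[as.character(km$cluster)])
  }
  structure(list(center = center, scale = ifelse(kept, scale_, 1),
                 kept = kept, rotation = pc$rotation[, seq_len(ncomp),
                                                     drop = FALSE],
                 explained_variance = expl, centroids = km$centers,
                 cluster = unname(km$cluster), mapping = mapping,
                 category = category, inertia = km$tot.withinss,
                 seed = cfg$rng_seed),
            class = "gm_cluster_model")
}

# Cluster -> category bijection from per-segment rhythm statistics.
map_clusters_to_categories <- function(cluster, info, k = 3L) {
  stopifnot(length(cluster) == nrow(info))
  ids <- sort(unique(cluster))
  mean_long <- vapply(ids, function(cl)
    mean(info$n_long_ic_bursts[cluster == cl]), numeric(1))
  mean_cv <- vapply(ids, function(cl) {
    v <- info$period_cv[cluster == cl]
    if (all(is.na(v))) Inf else mean(v, na.rm = TRUE)
  }, numeric(1))
  # GMR: most long bursts, lowest period CV on ties; NONE: fewest long bursts
  ord <- order(-mean_long, mean_cv)
  gmr <- ids[ord[1L]]
  none <- ids[order(mean_long, -mean_cv)][1L]
  if (gmr == none) stop("degenerate mapping: clusters indistinguishable")
  mapping <- rep("IRREGULAR", length(ids))
  names(mapping) <- as.character(ids)
  mapping[as.character(gmr)] <- "GMR"
  mapping[as.character(none)] <- "NONE"
  mapping
}

#' @export
print.gm_cluster_model <- function(x, ...) {
  cat(sprintf(
    "<gm_cluster_model> %d clusters on %d components (%.1f%% variance)\n",
    nrow(x$centroids), ncol(x$centroids), 100 * x$explained_variance))
  if (!is.null(x$mapping)) {
    cat("  mapping:",
        paste(sprintf("%s -> %s", names(x$mapping), x$mapping),
              collapse = ", "), "\n")
  }
  cat("  training sizes:",
      paste(table(x$cluster), collapse = ", "), "\n")
  invisible(x)
}

#' Project feature vectors through a fitted cluster model
#'
#' Applies the stored z-scoring and PCA rotation, then assigns each row to
#' the nearest k-means centroid.
#'
#' @param object a [fit_cluster_model()] result.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return A list with `scores` (retained-component coordinates), `cluster`
#'   (assignments) and `category` (mapped labels, when the model has a
#'   mapping).
#' @export
predict.gm_cluster_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  z <- sweep(newdata, 2L, object$center, "-")
  z <- sweep(z, 2L, object$scale, "/")
  z[is.na(z)] <- 0
  z[, !object$kept] <- 0
  scores <- z %*% object$rotation
  d2 <- vapply(seq_len(nrow(object$centroids)), function(j)
    rowSums(sweep(scores, 2L, object$centroids[j, ], "-")^2),
    numeric(nrow(scores)))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1L)
  cl <- max.col(-d2, ties.method = "first")
  cat_ <- if (is.null(object$mapping)) NULL else
    unname(object$mapping[as.character(cl)])
  list(scores = scores, cluster = cl, category = cat_)
}

#' Two-dimensional embedding of segment features
#'
#' Projects segments into the plane for visualization by classical metric
#' multidimensional scaling of the Euclidean distances between their
#' retained-component scores, so nearby segments in the clustering space stay
#' nearby in the plot. Visualization only; never used for classification.
#'
#' @param vectors feature matrix.
#' @param model a fitted [fit_cluster_model()].
#' @param cfg a [gm_config()] (unused; accepted for interface symmetry).
#' @return An n-by-2 matrix of coordinates.
#' @export
embed_2d <- function(vectors, model, cfg = gm_config()) {
  scores <- predict(model, vectors)$scores
  if (nrow(scores) < 3L)
    return(cbind(scores[, 1L, drop = TRUE],
                 if (ncol(scores) > 1L) scores[, 2L] else 0))
  xy <- stats::cmdscale(stats::dist(scores), k = 2L)
  colnames(xy) <- c("dim1", "dim2")
  xy
}
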