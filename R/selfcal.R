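# Unsupervised block-wise self-calibration: a bounded class-balanced buffer
# of unlabeled testing windows, manifold pseudo-labeling, and partial
# replacement of the appended trees.

#' Configuration for self-calibration
#'
#' @param capacity buffer capacity in samples (default 1500, about 500 KB
#'   of 80-dimensional 32-bit features).
#' @param embed_dim dimension of the manifold embedding (default 3).
#' @param use_tsne if `FALSE`, K-Means runs on the raw high-dimensional
#'   features (ablation).
#' @param use_kmeans if `FALSE`, pseudo-labels are simply the model's
#'   predictions, and the embedding is skipped entirely (ablation).
#' @param replace_fraction fraction of appended trees replaced per
#'   calibration round (default 0.4; count is rounded up).
#' @param perplexity t-SNE perplexity (reduced automatically when the
#'   buffer is small).
#' @param tsne_iter gradient-descent iterations; with the n/12 adaptive
#'   learning rate and early exaggeration, 200 iterations are ample for a
#'   3-D embedding of at most 1,500 points.
#' @param kmeans_iter maximum Lloyd iterations.
#' @return A list of class `selfcal_config`.
#' @export
selfcal_config <- function(capacity = 1500L, embed_dim = 3L, use_tsne = TRUE,
                           use_kmeans = TRUE, replace_fraction = 0.4,
                           perplexity = 30, tsne_iter = 200L,
                           kmeans_iter = 100L) {
  stopifnot(replace_fraction > 0 || replace_fraction == 0,
            replace_fraction <= 1, capacity >= 1, embed_dim >= 1)
  structure(list(capacity = as.integer(capacity),
                 embed_dim = as.integer(embed_dim),
                 use_tsne = isTRUE(use_tsne), use_kmeans = isTRUE(use_kmeans),
                 replace_fraction = replace_fraction,
                 perplexity = perplexity, tsne_iter = as.integer(tsne_iter),
                 kmeans_iter = as.integer(kmeans_iter)),
            class = "selfcal_config")
}

#' Bounded buffer of unlabeled testing windows
#'
#' Stores feature vectors with the label the model predicted at insertion
#' time and a monotone arrival index. When full, an insertion evicts the
#' oldest entry whose predicted class is (one of) the most frequent in the
#' buffer, ties going to the lowest class index, so no class can crowd the
#' others out.
#'
#' @param capacity maximum number of entries (default 1500).
#' @param n_features feature dimension.
#' @return Object of class `emg_buffer`.
#' @export
new_buffer <- function(capacity = 1500L, n_features = 80L) {
  structure(list(features = matrix(NA_real_, 0L, n_features),
                 predicted = integer(0), arrival = integer(0),
                 capacity = as.integer(capacity), next_arrival = 1L),
            class = "emg_buffer")
}

#' @export
print.emg_buffer <- function(x, ...) {
  cat(sprintf("<emg_buffer> %d/%d entries, %d features\n",
              length(x$predicted), x$capacity, ncol(x$features)))
  invisible(x)
}

#' Number of stored entries
#' @param buffer an `emg_buffer`.
#' @return Integer count.
#' @export
buffer_size <- function(buffer) length(buffer$predicted)

#' Insert testing samples into the buffer
#'
#' @param buffer an `emg_buffer`.
#' @param features a feature vector, or a matrix of rows to insert in order.
#' @param predicted_label integer label(s) assigned by the current model at
#'   insertion time, one per row.
#' @return The updated buffer.
#' @export
buffer_add <- function(buffer, features, predicted_label) {
  stopifnot(inherits(buffer, "emg_buffer"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  predicted_label <- as.integer(predicted_label)
  stopifnot(nrow(features) == length(predicted_label),
            ncol(features) == ncol(buffer$features))
  for (r in seq_len(nrow(features))) {
    if (length(buffer$predicted) < buffer$capacity) {
      buffer$features <- rbind(buffer$features, features[r, ])
      buffer$predicted <- c(buffer$predicted, predicted_label[r])
      buffer$arrival <- c(buffer$arrival, buffer$next_arrival)
    } else {
      counts <- tabulate(buffer$predicted)
      modal <- which.max(counts)           # ties -> lowest class index
      members <- which(buffer$predicted == modal)
      evict <- members[which.min(buffer$arrival[members])]
      buffer$features[evict, ] <- features[r, ]
      buffer$predicted[evict] <- predicted_label[r]
      buffer$arrival[evict] <- buffer$next_arrival
    }
    buffer$next_arrival <- buffer$next_arrival + 1L
  }
  buffer
}

#' Snapshot buffer contents in arrival order
#' @param buffer an `emg_buffer`.
#' @return List with `features`, `predicted`, `arrival`, oldest first.
#' @export
buffer_samples <- function(buffer) {
  ord <- order(buffer$arrival)
  list(features = buffer$features[ord, , drop = FALSE],
       predicted = buffer$predicted[ord], arrival = buffer$arrival[ord])
}

#' Manifold embedding of buffered samples
#'
#' Maps the buffered feature vectors into a low-dimensional (default 3-D)
#' space with exact t-SNE before clustering, which simplifies the
#' distribution that K-Means has to partition. With `use_tsne = FALSE` the
#' features pass through unchanged (clustering then operates in the
#' original space). If the sample count is too small to support even a
#' minimal perplexity, the embedding falls back to pass-through with a
#' warning.
#'
#' @param X samples x features matrix.
#' @param cfg a [selfcal_config()].
#' @return samples x `embed_dim` coordinates (or `X` when passing through).
#' @export
embed_features <- function(X, cfg = selfcal_config()) {
  X <- as.matrix(X)
  if (!cfg$use_tsne) return(X)
  n <- nrow(X)
  perp <- min(cfg$perplexity, floor((n - 1) / 3))
  if (n < 8L || perp < 2) {
    warning("too few samples (", n, ") for t-SNE; passing features through")
    return(X)
  }
  tsne_cpp(X, cfg$embed_dim, perp, cfg$tsne_iter,
           exaggeration = 12, exag_iter = min(50L, cfg$tsne_iter %/% 4L),
           eta = -1, momentum_switch = min(60L, cfg$tsne_iter %/% 3L))
}

# Lloyd iterations with fixed centroid order; empty clusters keep their
# previous centroid. Assignment ties go to the lowest cluster index.
lloyd_kmeans <- function(X, centers, max_iter = 100L) {
  n <- nrow(X)
  k <- nrow(centers)
  assign_old <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    assign_new <- max.col(-d2, ties.method = "first")
    if (identical(assign_new, assign_old)) break
    for (j in seq_len(k)) {
      if (any(assign_new == j))
        centers[j, ] <- colMeans(X[assign_new == j, , drop = FALSE])
    }
    assign_old <- assign_new
  }
  list(cluster = assign_old, centers = centers)
}

#' Pseudo-label buffered samples by prediction-seeded K-Means
#'
#' Runs K-Means with exactly `k` clusters whose centroids are initialized
#' at the per-class centroids of the embedded points grouped by the model's
#' predicted labels. Each cluster inherits the class identity of its
#' initializing prediction group, so the clustering can only move samples
#' between classes, not rename them. Classes absent from the predictions
#' get a farthest-point (k-means++-style) centroid among the remaining
#' points. With `use_kmeans = FALSE` the predictions are returned as-is.
#'
#' @param embedded samples x dims coordinates from [embed_features()].
#' @param predicted_labels integer model predictions aligned with rows.
#' @param k number of classes.
#' @param cfg a [selfcal_config()].
#' @return Integer pseudo-labels in 1..k, one per row.
#' @export
pseudo_label <- function(embedded, predicted_labels, k,
                         cfg = selfcal_config()) {
  predicted_labels <- as.integer(predicted_labels)
  if (!cfg$use_kmeans) return(predicted_labels)
  X <- as.matrix(embedded)
  stopifnot(nrow(X) == length(predicted_labels))
  centers <- matrix(NA_real_, k, ncol(X))
  for (j in seq_len(k)) {
    rows <- predicted_labels == j
    if (any(rows)) centers[j, ] <- colMeans(X[rows, , drop = FALSE])
  }
  missing <- which(is.na(centers[, 1L]))
  if (length(missing)) {
    message("class(es) ", paste(missing, collapse = ", "),
            " absent from predictions; seeding centroid(s) by farthest point")
    for (j in missing) {
      have <- centers[!is.na(centers[, 1L]), , drop = FALSE]
      d2 <- vapply(seq_len(nrow(X)), function(i)
        min(colSums((t(have) - X[i, ])^2)), numeric(1))
      centers[j, ] <- X[which.max(d2), ]
    }
  }
  lloyd_kmeans(X, centers, cfg$kmeans_iter)$cluster
}

#' Assemble the balanced self-calibration dataset
#'
#' Takes `m` = the minimum per-class pseudo-label count, keeps each class's
#' `m` most recent buffer entries (by arrival), and mixes them with the
#' ground-truth calibration samples. Returns `NULL` when some class has no
#' pseudo-labeled samples (`m` = 0), signalling that this block's
#' self-calibration should be skipped.
#'
#' @param buffer an `emg_buffer`.
#' @param pseudo_labels integer labels aligned with
#'   `buffer_samples(buffer)` rows (arrival order).
#' @param X_calib,y_calib the one-shot calibration set (normalized features
#'   and true labels).
#' @param n_classes number of classes.
#' @return List with `X`, `y`, `provenance`
#'   (`"pseudo"`/`"calibration"`), or `NULL` to skip.
#' @export
build_selfcal_dataset <- function(buffer, pseudo_labels, X_calib, y_calib,
                                  n_classes = max(y_calib)) {
  snap <- buffer_samples(buffer)
  pseudo_labels <- as.integer(pseudo_labels)
  stopifnot(length(pseudo_labels) == length(snap$predicted))
  counts <- tabulate(pseudo_labels, nbins = n_classes)
  m <- min(counts)
  if (m == 0L) return(NULL)
  take <- unlist(lapply(seq_len(n_classes), function(cl) {
    rows <- which(pseudo_labels == cl)
    rows[order(snap$arrival[rows], decreasing = TRUE)][seq_len(m)]
  }))
  X <- rbind(snap$features[take, , drop = FALSE], as.matrix(X_calib))
  y <- c(pseudo_labels[take], as.integer(y_calib))
  provenance <- c(rep("pseudo", length(take)),
                  rep("calibration", length(y_calib)))
  list(X = X, y = y, provenance = provenance)
}

#' Replace part of the appended trees with self-calibrated ones
#'
#' Selects `ceiling(replace_fraction * n_appended)` appended trees
#' uniformly at random and retrains them on the self-calibration dataset
#' with the same hyperparameters as the original appended trees (full-size
#' bootstrap). Pruned pretrained trees are never touched and the total tree
#' count is conserved (80 of 200 appended trees at the defaults).
#'
#' @param forest a fine-tuned `emg_forest` containing appended trees.
#' @param dataset list with `X` and `y` from [build_selfcal_dataset()].
#' @param cfg a [selfcal_config()].
#' @param max_features candidate features per split for the new trees.
#' @param min_leaf minimum leaf size.
#' @return The updated `emg_forest`.
#' @export
self_calibrate <- function(forest, dataset, cfg = selfcal_config(),
                           max_features = max(1L, floor(sqrt(forest$n_features))),
                           min_leaf = 1L) {
  stopifnot(inherits(forest, "emg_forest"))
  app <- which(forest$provenance == "appended")
  if (length(app) == 0L) stop("forest has no appended trees to replace")
  if (cfg$replace_fraction == 0) return(forest)
  if (is.null(dataset) || length(dataset$y) == 0L)
    stop("self-calibration dataset is empty")
  n_rep <- ceiling(cfg$replace_fraction * length(app))
  chosen <- app[sample.int(length(app), n_rep)]
  for (i in chosen) {
    forest$trees[[i]] <- train_tree(dataset$X, dataset$y,
                                    n_classes = forest$n_classes,
                                    bootstrap_fraction = 1,
                                    max_features = max_features,
                                    min_leaf = min_leaf)
  }
  forest
}
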