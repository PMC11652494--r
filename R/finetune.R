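# One-shot adaptation: reduced-error pruning of pretrained trees against the
# new user's calibration data, plus appended user-specific trees.

# Which validation rows reach each node. Children always have larger row
# indices than their parent (preorder layout), so one forward pass suffices.
route_samples <- function(tree, X) {
  n_nodes <- nrow(tree)
  reach <- vector("list", n_nodes)
  reach[[1L]] <- seq_len(nrow(X))
  for (i in seq_len(n_nodes)) {
    f <- tree[i, "feature"]
    if (f == 0) next
    idx <- reach[[i]]
    if (length(idx) == 0L) {
      reach[[tree[i, "left"]]] <- integer(0)
      reach[[tree[i, "right"]]] <- integer(0)
      next
    }
    go_left <- X[idx, f] <= tree[i, "threshold"]
    reach[[tree[i, "left"]]] <- idx[go_left]
    reach[[tree[i, "right"]]] <- idx[!go_left]
  }
  reach
}

# drop nodes no longer reachable after collapses and reindex children
compact_tree <- function(tree) {
  keep <- logical(nrow(tree))
  stack <- 1L
  while (length(stack)) {
    i <- stack[1L]; stack <- stack[-1L]
    keep[i] <- TRUE
    if (tree[i, "feature"] > 0)
      stack <- c(tree[i, "left"], tree[i, "right"], stack)
  }
  newid <- cumsum(keep)
  out <- tree[keep, , drop = FALSE]
  internal <- out[, "feature"] > 0
  out[internal, "left"] <- newid[out[internal, "left"]]
  out[internal, "right"] <- newid[out[internal, "right"]]
  out
}

#' Reduced-error pruning of one decision tree
#'
#' Inspects nodes bottom-up, deepest first, and collapses a subtree to a
#' leaf (predicting the majority class stored at that node during training)
#' whenever the tree's accuracy on the validation set does not decrease.
#' Equal accuracy collapses, favoring smaller trees. Every node up to and
#' including the root is inspected, so node count never increases and
#' validation accuracy never decreases.
#'
#' @param tree an `emg_tree` from [train_tree()].
#' @param X_val,y_val validation features and integer labels (the one-shot
#'   calibration set in the decoding protocol).
#' @return The pruned `emg_tree`.
#' @export
prune_tree <- function(tree, X_val, y_val) {
  stopifnot(nrow(as.matrix(X_val)) == length(y_val), length(y_val) > 0)
  X_val <- as.matrix(X_val)
  y_val <- as.integer(y_val)
  at <- attributes(tree)
  m <- unclass(tree)
  if (nrow(m) == 1L) return(tree)

  reach <- route_samples(m, X_val)
  n_nodes <- nrow(m)
  # correct[i]: validation hits within node i's current (possibly collapsed)
  # subtree. Collapsing node i changes whole-tree accuracy by exactly
  # leaf_correct(i) - correct[i], so the local comparison is the whole-tree
  # comparison.
  correct <- numeric(n_nodes)
  ord <- order(m[, "depth"], seq_len(n_nodes), decreasing = TRUE)
  for (i in ord) {
    idx <- reach[[i]]
    leaf_correct <- sum(y_val[idx] == m[i, "label"])
    if (m[i, "feature"] == 0) {
      correct[i] <- leaf_correct
      next
    }
    sub_correct <- correct[m[i, "left"]] + correct[m[i, "right"]]
    if (leaf_correct >= sub_correct) {
      m[i, "feature"] <- 0
      m[i, "threshold"] <- 0
      m[i, "left"] <- 0
      m[i, "right"] <- 0
      correct[i] <- leaf_correct
    } else {
      correct[i] <- sub_correct
    }
  }
  m <- compact_tree(m)
  structure(m, class = "emg_tree", n_features = at$n_features)
}

#' One-shot fine-tuning of a pre-trained forest
#'
#' Adapts a pre-trained forest to a new user from a single calibration
#' repetition per gesture: every pretrained tree is pruned against the
#' calibration set ([prune_tree()]), and `n_appended` user-specific trees
#' are trained from scratch on the calibration set alone (full-size
#' bootstrap, since the set is small). With the 200-tree default pretrained
#' forest and `n_appended = 200` the result is the standard 400-tree
#' fine-tuned model.
#'
#' @param pretrained an `emg_forest` containing only pretrained trees.
#' @param X_calib,y_calib calibration features (already normalized with the
#'   user's frozen z-score statistics) and integer labels; every class must
#'   be present.
#' @param n_appended number of user-specific trees to append (default 200).
#' @param max_features candidate features per split for appended trees.
#' @param min_leaf minimum leaf size for appended trees.
#' @return An `emg_forest` with pruned `"pretrained"` trees followed by
#'   `"appended"` trees.
#' @export
fine_tune <- function(pretrained, X_calib, y_calib, n_appended = 200L,
                      max_features = max(1L, floor(sqrt(ncol(X_calib)))),
                      min_leaf = 1L) {
  stopifnot(inherits(pretrained, "emg_forest"))
  if (any(pretrained$provenance != "pretrained"))
    stop("fine_tune expects a forest of pretrained trees only")
  X_calib <- as.matrix(X_calib)
  y_calib <- as.integer(y_calib)
  missing <- setdiff(seq_len(pretrained$n_classes), unique(y_calib))
  if (length(missing))
    stop("calibration set is missing class(es): ",
         paste(missing, collapse = ", "))

  pruned <- lapply(pretrained$trees, prune_tree, X_val = X_calib,
                   y_val = y_calib)
  appended <- lapply(seq_len(n_appended), function(i)
    train_tree(X_calib, y_calib, n_classes = pretrained$n_classes,
               bootstrap_fraction = 1, max_features = max_features,
               min_leaf = min_leaf))
  new_forest(c(pruned, appended),
             c(rep("pretrained", length(pruned)),
               rep("appended", n_appended)),
             pretrained$n_classes, pretrained$n_features)
}

#' Participant-specific forest trained on calibration data only
#'
#' The conventional baseline: a forest of `n_trees` trees (same size as the
#' fine-tuned model) trained from scratch on the one-shot calibration set,
#' with no pre-trained knowledge and no self-calibration.
#'
#' @inheritParams fine_tune
#' @param n_trees total number of trees (default 400).
#' @param n_classes number of classes.
#' @return An `emg_forest` (all trees tagged `"appended"`).
#' @export
standard_forest <- function(X_calib, y_calib, n_classes = max(y_calib),
                            n_trees = 400L,
                            max_features = max(1L, floor(sqrt(ncol(X_calib)))),
                            min_leaf = 1L) {
  X_calib <- as.matrix(X_calib)
  trees <- lapply(seq_len(n_trees), function(i)
    train_tree(X_calib, y_calib, n_classes = n_classes,
               bootstrap_fraction = 1, max_features = max_features,
               min_leaf = min_leaf))
  new_forest(trees, rep("appended", n_trees), n_classes, ncol(X_calib))
}
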