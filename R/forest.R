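#' Train a single CART decision tree
#'
#' Grows a classification tree by recursive binary splitting on the Gini
#' criterion, to purity (or until no candidate split reduces impurity),
#' examining `max_features` randomly drawn candidate features per split.
#' The training sample is a bootstrap draw (with replacement) of
#' `round(bootstrap_fraction * n)` rows. Every node, internal or leaf,
#' stores the majority class of the training samples that reach it, which
#' is what later allows subtrees to be collapsed during pruning.
#'
#' @param X samples x features numeric matrix.
#' @param y integer class labels in 1..n_classes.
#' @param n_classes number of classes (default `max(y)`).
#' @param bootstrap_fraction fraction of rows drawn (with replacement) for
#'   this tree; 1 draws n rows.
#' @param max_features candidate features per split
#'   (default `floor(sqrt(ncol(X)))`).
#' @param min_leaf minimum samples per leaf (default 1, i.e. grow to purity).
#' @return Numeric matrix of class `emg_tree`, one row per node, columns
#'   `feature, threshold, left, right, label, depth, n` (see package
#'   vignette for the layout).
#' @export
train_tree <- function(X, y, n_classes = max(y), bootstrap_fraction = 1,
                       max_features = max(1L, floor(sqrt(ncol(X)))),
                       min_leaf = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), nrow(X) > 0, all(y >= 1L),
            all(y <= n_classes), bootstrap_fraction > 0,
            bootstrap_fraction <= 1)
  n_boot <- max(1L, round(bootstrap_fraction * nrow(X)))
  idx <- sample.int(nrow(X), n_boot, replace = TRUE)
  tr <- grow_tree_cpp(X, y, as.integer(n_classes), idx,
                      as.integer(max_features), as.integer(min_leaf))
  structure(tr, class = "emg_tree", n_features = ncol(X),
            n_boot = n_boot, inbag = idx)
}

tree_node_count <- function(tree) nrow(tree)

#' Predict classes with a single tree
#' @param object an `emg_tree`.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @return Integer vector of predicted labels.
#' @export
predict.emg_tree <- function(object, newdata, ...) {
  predict_tree_cpp(unclass(object), as.matrix(newdata))
}

#' Construct a provenance-tagged forest
#'
#' @param trees list of `emg_tree` node matrices.
#' @param provenance character vector, one of `"pretrained"`, `"appended"`
#'   per tree.
#' @param n_classes number of classes.
#' @param n_features feature dimension the trees were trained on.
#' @return Object of class `emg_forest`.
#' @export
new_forest <- function(trees, provenance, n_classes, n_features) {
  stopifnot(length(trees) == length(provenance),
            all(provenance %in% c("pretrained", "appended")))
  structure(list(trees = trees, provenance = provenance,
                 n_classes = as.integer(n_classes),
                 n_features = as.integer(n_features)),
            class = "emg_forest")
}

#' @export
print.emg_forest <- function(x, ...) {
  cat(sprintf("<emg_forest> %d trees (%d pretrained, %d appended), %d classes, %d features\n",
              length(x$trees), sum(x$provenance == "pretrained"),
              sum(x$provenance == "appended"), x$n_classes, x$n_features))
  invisible(x)
}

#' Pre-train a forest on pooled multi-user data
#'
#' Trains `n_trees` independent trees, each on a small bootstrap draw
#' (default 2% of the pooled sample) to encourage diversity and keep trees
#' small. The pooled data are expected to be per-participant z-scored
#' features; see [fit_normalizer()].
#'
#' @inheritParams train_tree
#' @param n_trees number of trees (default 200).
#' @param bootstrap_fraction bootstrap fraction per tree (default 0.02).
#' @return An `emg_forest` whose trees all carry provenance `"pretrained"`.
#' @export
pretrain_forest <- function(X, y, n_classes = max(y), n_trees = 200L,
                            bootstrap_fraction = 0.02,
                            max_features = max(1L, floor(sqrt(ncol(X)))),
                            min_leaf = 1L) {
  if (n_trees <= 0L) stop("n_trees must be positive")
  X <- as.matrix(X)
  trees <- lapply(seq_len(n_trees), function(i)
    train_tree(X, y, n_classes = n_classes,
               bootstrap_fraction = bootstrap_fraction,
               max_features = max_features, min_leaf = min_leaf))
  new_forest(trees, rep("pretrained", n_trees), n_classes, ncol(X))
}

#' Predict gestures by majority vote over trees
#'
#' Each tree votes with its leaf label; the forest output is the class with
#' the most votes, ties broken deterministically toward the lowest class
#' index. Prediction does not depend on tree order.
#'
#' @param object an `emg_forest`.
#' @param newdata feature vector or samples x features matrix.
#' @param type `"label"` for hard labels, `"votes"` for the samples x
#'   classes vote-count matrix.
#' @param ... unused.
#' @return Integer labels, or a vote-count matrix.
#' @export
predict.emg_forest <- function(object, newdata,
                               type = c("label", "votes"), ...) {
  type <- match.arg(type)
  if (length(object$trees) == 0L) stop("cannot predict with an empty forest")
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("feature dimension mismatch: forest expects ", object$n_features,
         ", got ", ncol(newdata))
  votes <- forest_votes_cpp(lapply(object$trees, unclass), newdata,
                            object$n_classes)
  if (type == "votes") return(votes)
  max.col(votes, ties.method = "first")
}

SERIAL_VERSION <- "selfcalrf-forest-1"

#' Serialize a forest to versioned JSON
#'
#' The JSON encodes the schema version, class/feature counts, per-tree
#' provenance and the flat node tables at full double precision, so a
#' round trip reproduces predictions bitwise.
#'
#' @param forest an `emg_forest`.
#' @return A JSON string (class `json`).
#' @export
forest_to_json <- function(forest) {
  stopifnot(inherits(forest, "emg_forest"))
  payload <- list(
    schema = SERIAL_VERSION,
    n_classes = forest$n_classes,
    n_features = forest$n_features,
    provenance = forest$provenance,
    trees = lapply(forest$trees, function(tr) {
      m <- unclass(tr)
      attributes(m) <- list(dim = dim(m))
      m
    })
  )
  jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
}

#' Deserialize a forest from JSON
#' @param txt JSON string or parsed list as produced by [forest_to_json()].
#' @return An `emg_forest`.
#' @export
forest_from_json <- function(txt) {
  obj <- tryCatch(jsonlite::fromJSON(txt, simplifyMatrix = TRUE),
                  error = function(e) stop("malformed forest payload: ",
                                           conditionMessage(e)))
  if (is.null(obj$schema) || !identical(as.character(obj$schema), SERIAL_VERSION))
    stop("unsupported forest schema: ",
         if (is.null(obj$schema)) "<missing>" else obj$schema)
  trees <- lapply(obj$trees, function(m) {
    m <- as.matrix(m)
    colnames(m) <- c("feature", "threshold", "left", "right", "label",
                     "depth", "n")
    structure(m, class = "emg_tree", n_features = obj$n_features)
  })
  new_forest(trees, as.character(obj$provenance), obj$n_classes,
             obj$n_features)
}

#' Write / read a forest model file
#' @param forest an `emg_forest`.
#' @param path file path (JSON).
#' @return `read_forest` returns the forest; `write_forest` its path,
#'   invisibly.
#' @export
write_forest <- function(forest, path) {
  writeLines(forest_to_json(forest), path)
  invisible(path)
}

#' @rdname write_forest
#' @export
read_forest <- function(path) forest_from_json(paste(readLines(path), collapse = "\n"))
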