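test_that("buffer appends below capacity and evicts oldest of modal class", {
  buf <- new_buffer(capacity = 5, n_features = 2)
  for (i in 1:3) buf <- buffer_add(buf, c(i, i), predicted_label = 1L)
  expect_equal(buffer_size(buf), 3)

  buf <- buffer_add(buf, c(9, 9), 2L)
  buf <- buffer_add(buf, c(10, 10), 2L)
  expect_equal(buffer_size(buf), 5)
  # class 1 is modal (3 vs 2); its oldest entry (arrival 1) must go
  buf <- buffer_add(buf, c(11, 11), 3L)
  expect_equal(buffer_size(buf), 5)
  snap <- buffer_samples(buf)
  expect_false(1L %in% snap$arrival)
  expect_equal(sum(snap$predicted == 1L), 2)

  # 2/2/1 tie between classes 1 and 2 -> lowest class index evicted
  buf <- buffer_add(buf, c(12, 12), 3L)
  snap <- buffer_samples(buf)
  expect_equal(sum(snap$predicted == 1L), 1)
  expect_equal(sum(snap$predicted == 2L), 2)

  # all one class degenerates to FIFO
  fifo <- new_buffer(capacity = 3, n_features = 1)
  for (i in 1:6) fifo <- buffer_add(fifo, i, 4L)
  expect_equal(sort(buffer_samples(fifo)$features[, 1]), c(4, 5, 6))
  expect_equal(buffer_samples(fifo)$arrival, 4:6)
})

test_that("embedding keeps shape, passes through when disabled or tiny", {
  set.seed(111)
  b <- make_blobs(40, matrix(c(rep(0, 10), rep(4, 10)), 2, byrow = TRUE),
                  sd = 1)
  cfg <- selfcal_config(tsne_iter = 120)
  set.seed(1)
  emb <- embed_features(b$X, cfg)
  expect_equal(dim(emb), c(80L, 3L))
  set.seed(1)
  emb2 <- embed_features(b$X, cfg)
  expect_identical(emb, emb2) # deterministic given the RNG state

  off <- selfcal_config(use_tsne = FALSE)
  expect_identical(embed_features(b$X, off), b$X)
  expect_warning(tiny <- embed_features(b$X[1:5, ], cfg), "too few")
  expect_identical(tiny, b$X[1:5, ])
})

test_that("embedding sharpens separation of distinct clusters", {
  set.seed(112)
  b <- make_blobs(60, matrix(c(rep(0, 20), rep(2.5, 20)), 2, byrow = TRUE),
                  sd = 1.2)
  raw_sil <- silhouette_mean(b$X, b$y)
  emb <- embed_features(b$X, selfcal_config())
  emb_sil <- silhouette_mean(emb, b$y)
  expect_gte(emb_sil, raw_sil)
})

test_that("pseudo-labels fix isolated mispredictions, inherit class ids", {
  set.seed(121)
  b <- make_blobs(15, matrix(c(0, 0, 8, 8), 2, byrow = TRUE), sd = 0.4)
  cfg <- selfcal_config(use_tsne = FALSE)

  # correct predictions are a fixed point
  pl <- pseudo_label(b$X, b$y, k = 2, cfg)
  expect_equal(pl, b$y)

  # one point deep inside cluster 2 but predicted 1 gets relabeled
  wrong <- b$y
  wrong[20] <- 1L
  pl <- pseudo_label(b$X, wrong, k = 2, cfg)
  expect_equal(pl[20], 2L)
  expect_equal(pl, b$y)

  # agreement with stats::kmeans Lloyd iterations from the same centroids
  centers <- rbind(colMeans(b$X[wrong == 1, ]), colMeans(b$X[wrong == 2, ]))
  km <- stats::kmeans(b$X, centers = centers, algorithm = "Lloyd",
                      iter.max = 100)
  expect_equal(pl, unname(km$cluster))

  # K-Means disabled: predictions pass through untouched
  off <- selfcal_config(use_kmeans = FALSE)
  expect_equal(pseudo_label(b$X, wrong, k = 2, off), wrong)

  # an absent class gets a farthest-point seeded centroid, k preserved
  absent <- rep(1L, nrow(b$X))
  expect_message(pl2 <- pseudo_label(b$X, absent, k = 2, cfg), "absent")
  expect_setequal(sort(unique(pl2)), 1:2)
})

test_that("self-calibration dataset is balanced, recent, calib-augmented", {
  set.seed(131)
  buf <- new_buffer(capacity = 100, n_features = 3)
  counts <- c(10, 7, 9, 7, 8, 12)
  labs <- rep(1:6, counts)
  labs <- sample(labs)
  for (i in seq_along(labs))
    buf <- buffer_add(buf, rnorm(3), labs[i])
  snap <- buffer_samples(buf)
  calib <- list(X = matrix(rnorm(54 * 3), 54), y = rep(1:6, each = 9))
  ds <- build_selfcal_dataset(buf, snap$predicted, calib$X, calib$y, 6)
  expect_equal(length(ds$y), 6 * 7 + 54)
  expect_equal(as.vector(table(ds$y[ds$provenance == "pseudo"])), rep(7L, 6))
  expect_equal(sum(ds$provenance == "calibration"), 54)

  # recency: per class, selected arrivals are that class's most recent
  sel_arr <- snap$arrival[match(
    apply(ds$X[ds$provenance == "pseudo", ], 1, paste, collapse = ","),
    apply(snap$features, 1, paste, collapse = ","))]
  for (cl in 1:6) {
    cls_arr <- snap$arrival[snap$predicted == cl]
    picked <- sel_arr[ds$y[ds$provenance == "pseudo"] == cl]
    expect_setequal(picked, sort(cls_arr, decreasing = TRUE)[1:7])
  }

  # a class with zero pseudo-labels signals a skip
  pl0 <- snap$predicted
  pl0[pl0 == 3] <- 2L
  expect_null(build_selfcal_dataset(buf, pl0, calib$X, calib$y, 6))
})

test_that("one round on stationary data barely moves held-out accuracy", {
  deltas <- vapply(1:10, function(seed) {
    set.seed(seed + 900)
    centers <- matrix(rnorm(6 * 8, 0, 1.5), 6)
    pool <- make_blobs(80, centers, sd = 1)
    pre <- pretrain_forest(pool$X, pool$y, n_trees = 50,
                           bootstrap_fraction = 0.1)
    calib <- make_blobs(9, centers, sd = 1)
    tuned <- fine_tune(pre, calib$X, calib$y, n_appended = 50)
    held <- make_blobs(50, centers, sd = 1)
    stream <- make_blobs(100, centers, sd = 1)
    # well-fit model: pseudo-labels are its own predictions (stationary,
    # no clustering correction needed for the stability property)
    ds <- list(X = rbind(stream$X, calib$X),
               y = c(predict(tuned, stream$X), calib$y))
    recal <- self_calibrate(tuned, ds)
    mean(predict(recal, held$X) == held$y) -
      mean(predict(tuned, held$X) == held$y)
  }, numeric(1))
  expect_lt(mean(abs(deltas)), 0.03)
})

test_that("tree replacement conserves size and pretrained trees", {
  set.seed(141)
  pool <- make_noisy_dataset(n = 400, p = 6, k = 6, flip = 0.1)
  pre <- pretrain_forest(pool$X, pool$y, n_trees = 20, bootstrap_fraction = 0.1)
  calib <- make_noisy_dataset(n = 54, p = 6, k = 6, flip = 0)
  tuned <- fine_tune(pre, calib$X, calib$y, n_appended = 20)
  pretrained_before <- forest_to_json(
    new_forest(tuned$trees[1:20], rep("pretrained", 20), 6, 6))

  ds <- make_noisy_dataset(n = 120, p = 6, k = 6, flip = 0.1)
  cfg <- selfcal_config(replace_fraction = 0.4)
  cur <- tuned
  for (round in 1:4) {
    cur <- self_calibrate(cur, list(X = ds$X, y = ds$y), cfg)
    expect_length(cur$trees, 40)
    expect_equal(cur$provenance, tuned$provenance)
  }
  pretrained_after <- forest_to_json(
    new_forest(cur$trees[1:20], rep("pretrained", 20), 6, 6))
  expect_identical(pretrained_after, pretrained_before)

  # exactly ceil(0.4 * 20) = 8 appended trees are swapped per round
  set.seed(5)
  one <- self_calibrate(tuned, list(X = ds$X, y = ds$y), cfg)
  changed <- sum(vapply(21:40, function(i)
    !identical(unclass(one$trees[[i]]), unclass(tuned$trees[[i]])),
    logical(1)))
  expect_equal(changed, 8)

  # boundary and error cases
  zero <- self_calibrate(tuned, list(X = ds$X, y = ds$y),
                         selfcal_config(replace_fraction = 0))
  expect_identical(forest_to_json(zero), forest_to_json(tuned))
  expect_error(self_calibrate(pre, list(X = ds$X, y = ds$y), cfg),
               "appended")

  # determinism
  set.seed(7)
  a <- self_calibrate(tuned, list(X = ds$X, y = ds$y), cfg)
  set.seed(7)
  b <- self_calibrate(tuned, list(X = ds$X, y = ds$y), cfg)
  expect_identical(forest_to_json(a), forest_to_json(b))
})
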