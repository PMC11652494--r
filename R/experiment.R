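# End-to-end protocol replay: pretrain -> one-shot fine-tune -> 11 testing
# blocks with per-window prediction and block-boundary self-calibration.
# The replay is an ordered, deterministic stand-in for the real-time loop;
# ground truth is only ever consulted for scoring, never by the decoder.

#' Decoder configuration
#'
#' @param win_ms,step_ms sliding-window length and step in milliseconds.
#' @param groups enabled feature groups, see [extract_features()].
#' @param eps ZC/SSC deadzone.
#' @param n_pretrained trees in the pre-trained forest (default 200).
#' @param pretrain_bootstrap bootstrap fraction per pretrained tree
#'   (default 0.02).
#' @param n_appended user-specific trees appended at fine-tuning
#'   (default 200).
#' @param max_features candidate features per split (default
#'   `floor(sqrt(d))` of the feature dimension, i.e. 8 for the 80-length
#'   vector).
#' @return List of class `decoder_config`.
#' @export
decoder_config <- function(win_ms = 200, step_ms = 100,
                           groups = c("energy", "distribution", "spectrum"),
                           eps = 0, n_pretrained = 200L,
                           pretrain_bootstrap = 0.02, n_appended = 200L,
                           max_features = NULL) {
  structure(list(win_ms = win_ms, step_ms = step_ms, groups = groups,
                 eps = eps, n_pretrained = as.integer(n_pretrained),
                 pretrain_bootstrap = pretrain_bootstrap,
                 n_appended = as.integer(n_appended),
                 max_features = max_features),
            class = "decoder_config")
}

cfg_max_features <- function(cfg, d) {
  if (is.null(cfg$max_features)) max(1L, floor(sqrt(d))) else cfg$max_features
}

#' Featurize a list of trials into a labeled sample matrix
#'
#' @param trials list of [emg_trial()]s.
#' @param cfg a [decoder_config()].
#' @return List with `X` (windows x features), `y` (gesture per window),
#'   `position`, and `trial` (trial index per window).
#' @export
featurize_trials <- function(trials, cfg = decoder_config()) {
  parts <- lapply(seq_along(trials), function(i) {
    Xi <- trial_features(trials[[i]], win_ms = cfg$win_ms,
                         step_ms = cfg$step_ms, groups = cfg$groups,
                         eps = cfg$eps)
    list(X = Xi, y = rep(as.integer(trials[[i]]$gesture), nrow(Xi)),
         position = rep(trials[[i]]$position, nrow(Xi)),
         trial = rep(i, nrow(Xi)))
  })
  list(X = do.call(rbind, lapply(parts, `[[`, "X")),
       y = unlist(lapply(parts, `[[`, "y")),
       position = unlist(lapply(parts, `[[`, "position")),
       trial = unlist(lapply(parts, `[[`, "trial")))
}

#' Pre-train the generic forest from a multi-user pool
#'
#' Features are extracted per user, z-scored with that user's own
#' statistics, pooled, and used to train the pre-trained forest (small
#' bootstrap per tree).
#'
#' @param users list of users, each a list of [emg_trial()]s (see
#'   [generate_pretrain_users()]).
#' @param n_classes number of gesture classes.
#' @param cfg a [decoder_config()].
#' @return An `emg_forest` of pretrained trees.
#' @export
pretrain_decoder <- function(users, n_classes = 6L, cfg = decoder_config()) {
  pooled <- lapply(users, function(trials) {
    f <- featurize_trials(trials, cfg)
    norm <- fit_normalizer(f$X)
    list(X = apply_normalizer(norm, f$X), y = f$y)
  })
  X <- do.call(rbind, lapply(pooled, `[[`, "X"))
  y <- unlist(lapply(pooled, `[[`, "y"))
  pretrain_forest(X, y, n_classes = n_classes, n_trees = cfg$n_pretrained,
                  bootstrap_fraction = cfg$pretrain_bootstrap,
                  max_features = cfg_max_features(cfg, ncol(X)))
}

#' Replay the 11-block protocol with one or more decoder variants
#'
#' All variants share the same replayed data and the same one-shot
#' calibration: the user's z-score normalizer is fitted on the calibration
#' features and frozen, the pre-trained forest is fine-tuned once, and then
#' each testing block is decoded window by window in causal order.
#' Variants:
#' \describe{
#'   \item{`"standard"`}{participant-specific forest trained on the
#'     calibration set only (no pre-training, never updated).}
#'   \item{`"fixed"`}{the fine-tuned forest, never updated.}
#'   \item{`"selfcal"`}{starts from the same fine-tuned forest; every test
#'     window enters the bounded buffer with its predicted label, and at
#'     each block boundary the buffer is pseudo-labeled (t-SNE +
#'     prediction-seeded K-Means) and part of the appended trees is
#'     retrained. The update is skipped when some class has no
#'     pseudo-labels, and after the final block (no block remains that
#'     could use it).}
#' }
#' Accuracy is the proportion of correctly classified sliding windows of
#' the gesture-hold periods.
#'
#' @param pretrained pre-trained `emg_forest` (needed unless `variants` is
#'   only `"standard"`).
#' @param session an `emg_session` from [generate_experiment()].
#' @param cfg a [decoder_config()].
#' @param scfg a [selfcal_config()].
#' @param variants subset of `c("standard", "fixed", "selfcal")`.
#' @return List of class `protocol_result`: `blocks` (one row per variant
#'   and block: position, n_windows, accuracy, and for the selfcal variant
#'   the buffer fill level), `windows` (per-window truths and
#'   predictions), `pseudo` (per-block pseudo-label accuracy of the
#'   self-calibrating variant, a diagnostic computed after the fact),
#'   `models` (final model per variant), `group`.
#' @export
run_protocol <- function(pretrained = NULL, session,
                         cfg = decoder_config(), scfg = selfcal_config(),
                         variants = c("standard", "fixed", "selfcal")) {
  variants <- match.arg(variants, several.ok = TRUE)
  stopifnot(inherits(session, "emg_session"))
  if (length(session$calibration) == 0L)
    stop("session has no calibration trials")

  calib <- featurize_trials(session$calibration, cfg)
  n_classes <- max(calib$y)
  norm <- fit_normalizer(calib$X)
  Xc <- apply_normalizer(norm, calib$X)

  models <- list()
  if ("standard" %in% variants)
    models$standard <- standard_forest(Xc, calib$y, n_classes = n_classes,
                                       n_trees = cfg$n_pretrained + cfg$n_appended,
                                       max_features = cfg_max_features(cfg, ncol(Xc)))
  if (any(c("fixed", "selfcal") %in% variants)) {
    if (is.null(pretrained)) stop("pretrained forest required")
    tuned <- fine_tune(pretrained, Xc, calib$y, n_appended = cfg$n_appended,
                       max_features = cfg_max_features(cfg, ncol(Xc)))
    if ("fixed" %in% variants) models$fixed <- tuned
    if ("selfcal" %in% variants) models$selfcal <- tuned
  }

  buffer <- new_buffer(capacity = scfg$capacity, n_features = ncol(Xc))
  blocks <- list()
  windows <- list()
  pseudo <- list()

  for (b in seq_along(session$blocks)) {
    f <- featurize_trials(session$blocks[[b]], cfg)
    Xb <- apply_normalizer(norm, f$X)
    for (v in names(models)) {
      pred <- predict(models[[v]], Xb)
      row <- data.frame(
        variant = v, block = b, position = session$plan$position[b],
        n_windows = nrow(Xb), accuracy = mean(pred == f$y),
        buffer_size = NA_integer_)
      windows[[length(windows) + 1L]] <- data.frame(
        variant = v, block = b, position = session$plan$position[b],
        trial = f$trial, truth = f$y, prediction = pred)
      if (v == "selfcal") {
        buffer <- buffer_add(buffer, Xb, pred)
        row$buffer_size <- buffer_size(buffer)
        # the model refreshed after the final block would never be used,
        # so the update is only computed while blocks remain
        if (b < length(session$blocks) && scfg$replace_fraction > 0) {
          snap <- buffer_samples(buffer)
          emb <- embed_features(snap$features, scfg)
          pl <- pseudo_label(emb, snap$predicted, n_classes, scfg)
          ds <- build_selfcal_dataset(buffer, pl, Xc, calib$y,
                                      n_classes = n_classes)
          if (!is.null(ds)) {
            models$selfcal <- self_calibrate(models$selfcal, ds, scfg,
                                             max_features = cfg_max_features(cfg, ncol(Xc)))
            # pseudo-label accuracy is diagnostic only (never seen by the
            # decoder): match buffered windows back to their true labels
            truth_map <- buffer_truth(windows, snap$arrival)
            ok <- !is.na(truth_map)
            pseudo[[length(pseudo) + 1L]] <- data.frame(
              block = b, n = sum(ok),
              accuracy = mean(pl[ok] == truth_map[ok]))
          }
        }
      }
      blocks[[length(blocks) + 1L]] <- row
    }
  }
  structure(list(
    blocks = do.call(rbind, blocks),
    windows = do.call(rbind, windows),
    pseudo = if (length(pseudo)) do.call(rbind, pseudo) else NULL,
    models = models,
    group = session$group
  ), class = "protocol_result")
}

# Reconstruct true labels of buffered entries from the selfcal window log;
# arrival indices count selfcal-variant windows in insertion order.
buffer_truth <- function(windows, arrival) {
  w <- do.call(rbind, windows)
  w <- w[w$variant == "selfcal", , drop = FALSE]
  truths <- w$truth # in causal order of insertion
  out <- rep(NA_integer_, length(arrival))
  valid <- arrival <= length(truths)
  out[valid] <- truths[arrival[valid]]
  out
}

#' @export
print.protocol_result <- function(x, ...) {
  agg <- aggregate(accuracy ~ variant, data = x$blocks, FUN = mean)
  cat("<protocol_result> group", x$group, "- mean window accuracy:\n")
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-9s %.3f\n", agg$variant[i], agg$accuracy[i]))
  invisible(x)
}

#' Average block accuracies by arm position
#'
#' Averages block-level accuracy over the blocks sharing a position tag
#' within each session, then over sessions, separately per decoder
#' variant. The symmetric block sequences make this average robust to
#' within-session time trends.
#'
#' @param results a `protocol_result` or a list of them (e.g. one per
#'   group or seed).
#' @return Data frame with columns `variant`, `position`, `accuracy`.
#' @export
aggregate_by_position <- function(results) {
  if (inherits(results, "protocol_result")) results <- list(results)
  per_session <- lapply(results, function(r)
    aggregate(accuracy ~ variant + position, data = r$blocks, FUN = mean))
  all <- do.call(rbind, per_session)
  out <- aggregate(accuracy ~ variant + position, data = all, FUN = mean)
  out[order(out$variant, out$position), , drop = FALSE]
}

#' Component-ablation replay
#'
#' Re-runs the self-calibrating pipeline end to end on the same session
#' under a grid of configurations: each feature group removed in turn,
#' pseudo-labeling without t-SNE (K-Means in the raw feature space),
#' pseudo-labeling without K-Means (predictions used directly, t-SNE
#' dropped too since nothing is clustered), and the full default. The
#' pre-trained forest is rebuilt per configuration because the feature
#' space changes.
#'
#' @param session an `emg_session`.
#' @param users pre-training pool, see [generate_pretrain_users()].
#' @param cfg base [decoder_config()].
#' @param scfg base [selfcal_config()].
#' @param seed integer seed applied before each configuration so every
#'   configuration sees identical model-training randomness.
#' @return Data frame: configuration name, component flags, mean and sd of
#'   block accuracies of the self-calibrating variant.
#' @export
run_ablation <- function(session, users, cfg = decoder_config(),
                         scfg = selfcal_config(), seed = 1L) {
  grid <- list(
    no_energy = list(groups = c("distribution", "spectrum"),
                     use_tsne = TRUE, use_kmeans = TRUE),
    no_distribution = list(groups = c("energy", "spectrum"),
                           use_tsne = TRUE, use_kmeans = TRUE),
    no_spectrum = list(groups = c("energy", "distribution"),
                       use_tsne = TRUE, use_kmeans = TRUE),
    no_kmeans = list(groups = cfg$groups, use_tsne = FALSE,
                     use_kmeans = FALSE),
    no_tsne = list(groups = cfg$groups, use_tsne = FALSE, use_kmeans = TRUE),
    full = list(groups = cfg$groups, use_tsne = TRUE, use_kmeans = TRUE)
  )
  rows <- lapply(names(grid), function(nm) {
    g <- grid[[nm]]
    cfg_i <- cfg
    cfg_i$groups <- g$groups
    scfg_i <- scfg
    scfg_i$use_tsne <- g$use_tsne
    scfg_i$use_kmeans <- g$use_kmeans
    set.seed(seed)
    pre <- pretrain_decoder(users, n_classes = 6L, cfg = cfg_i)
    res <- run_protocol(pre, session, cfg = cfg_i, scfg = scfg_i,
                        variants = "selfcal")
    data.frame(config = nm,
               energy = "energy" %in% g$groups,
               distribution = "distribution" %in% g$groups,
               spectrum = "spectrum" %in% g$groups,
               kmeans = g$use_kmeans, tsne = g$use_tsne,
               n_features = sum(c(5, 1, 4)[match(g$groups,
                 c("energy", "distribution", "spectrum"))]) * 8L,
               mean_accuracy = mean(res$blocks$accuracy),
               sd_accuracy = sd(res$blocks$accuracy))
  })
  do.call(rbind, rows)
}
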