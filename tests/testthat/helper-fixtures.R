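# Programmatic fixtures shared across test files.

# isotropic Gaussian class blobs in d dimensions
make_blobs <- function(n_per_class, centers, sd = 0.3) {
  k <- nrow(centers)
  X <- do.call(rbind, lapply(seq_len(k), function(j)
    matrix(rnorm(n_per_class * ncol(centers), 0, sd), n_per_class) +
      matrix(centers[j, ], n_per_class, ncol(centers), byrow = TRUE)))
  list(X = X, y = rep(seq_len(k), each = n_per_class))
}

# a small multi-class dataset with label noise, for tree/pruning tests
make_noisy_dataset <- function(n = 60, p = 5, k = 3, flip = 0.2) {
  centers <- matrix(rnorm(k * p, 0, 1.5), k)
  b <- make_blobs(ceiling(n / k), centers, sd = 1)
  keep <- seq_len(n)
  y <- b$y[keep]
  nf <- round(flip * n)
  if (nf > 0) {
    i <- sample(n, nf)
    y[i] <- sample(k, nf, replace = TRUE)
  }
  list(X = b$X[keep, , drop = FALSE], y = y)
}

# one full synthetic experiment for one seeded user; heavy, used by the
# acceptance suite
run_session <- function(seed, group, shift, variants = c("standard", "fixed", "selfcal"),
                        scfg = selfcal_config()) {
  set.seed(seed)
  base <- default_specs(shift)
  users <- generate_pretrain_users(base)
  pre <- pretrain_decoder(users)
  user <- perturb_specs(base)
  sess <- generate_experiment(group, user)
  run_protocol(pre, sess, scfg = scfg, variants = variants)
}

mean_variant_accuracy <- function(res, variant) {
  mean(res$blocks$accuracy[res$blocks$variant == variant])
}
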