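# Independent naive-loop oracles. Deliberately written as explicit loops /
# direct formula transcriptions, sharing no code with the package.

naive_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}

naive_wl <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + abs(x[i] - x[i - 1])
  s
}

naive_rms <- function(x) {
  s <- 0
  for (v in x) s <- s + v^2
  sqrt(s / length(x))
}

naive_zc <- function(x, eps = 0) {
  n <- 0
  for (i in 1:(length(x) - 1)) {
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= eps) n <- n + 1
  }
  n
}

naive_ssc <- function(x, eps = 0) {
  n <- 0
  for (i in 2:(length(x) - 1)) {
    d1 <- x[i] - x[i - 1]
    d2 <- x[i] - x[i + 1]
    if (d1 * d2 > 0 && (abs(d1) >= eps || abs(d2) >= eps)) n <- n + 1
  }
  n
}

naive_skew <- function(x) {
  mu <- 0
  for (v in x) mu <- mu + v
  mu <- mu / length(x)
  s2 <- 0
  s3 <- 0
  for (v in x) {
    s2 <- s2 + (v - mu)^2
    s3 <- s3 + (v - mu)^3
  }
  s2 <- s2 / length(x)
  s3 <- s3 / length(x)
  if (s2 <= 0) return(0)
  s3 / s2^1.5
}

# direct DFT periodogram over bins (0, fs/2], mean removed, no padding
naive_spectral <- function(x, fs) {
  n <- length(x)
  x <- x - sum(x) / n
  if (all(x == 0)) return(c(pkf = 0, mdf = 0, mnf = 0, vcf = 0))
  nb <- floor(n / 2)
  pw <- numeric(nb)
  f <- numeric(nb)
  for (k in 1:nb) {
    re <- 0
    im <- 0
    for (t in 1:n) {
      ang <- -2 * pi * k * (t - 1) / n
      re <- re + x[t] * cos(ang)
      im <- im + x[t] * sin(ang)
    }
    pw[k] <- (re^2 + im^2) / n
    f[k] <- k * fs / n
  }
  tot <- sum(pw)
  pkf <- f[which.max(pw)]
  mnf <- sum(f * pw) / tot
  cum <- 0
  mdf <- f[nb]
  for (k in 1:nb) {
    cum <- cum + pw[k]
    if (cum >= tot / 2) { mdf <- f[k]; break }
  }
  vcf <- sum((f - mnf)^2 * pw) / tot
  c(pkf = pkf, mdf = mdf, mnf = mnf, vcf = vcf)
}

# strip class/attrs down to the bare node matrix for structural comparison
tree_mat <- function(t) {
  m <- unclass(t)
  attributes(m) <- list(dim = dim(m))
  m
}

# predict one sample through a flat tree matrix, by hand
oracle_tree_predict <- function(tree, x) {
  i <- 1
  while (tree[i, "feature"] > 0) {
    i <- if (x[tree[i, "feature"]] <= tree[i, "threshold"])
      tree[i, "left"] else tree[i, "right"]
  }
  tree[i, "label"]
}

oracle_tree_accuracy <- function(tree, X, y) {
  pred <- apply(X, 1, function(x) oracle_tree_predict(tree, x))
  mean(pred == y)
}

# Brute-force reduced-error pruning: walk nodes deepest-first and collapse
# a node whenever whole-tree validation accuracy, re-evaluated from
# scratch on the partially collapsed tree, does not drop. Returns the
# compacted tree for structural comparison.
oracle_prune <- function(tree, X, y) {
  m <- unclass(tree)
  ord <- order(m[, "depth"], seq_len(nrow(m)), decreasing = TRUE)
  for (i in ord) {
    if (m[i, "feature"] == 0) next
    acc_before <- oracle_tree_accuracy(m, X, y)
    collapsed <- m
    collapsed[i, c("feature", "threshold", "left", "right")] <- 0
    if (oracle_tree_accuracy(collapsed, X, y) >= acc_before) m <- collapsed
  }
  # drop unreachable rows, keeping preorder numbering
  keep <- logical(nrow(m))
  stack <- 1
  while (length(stack)) {
    i <- stack[1]
    stack <- stack[-1]
    keep[i] <- TRUE
    if (m[i, "feature"] > 0) stack <- c(m[i, "left"], m[i, "right"], stack)
  }
  newid <- cumsum(keep)
  out <- m[keep, , drop = FALSE]
  int <- out[, "feature"] > 0
  out[int, "left"] <- newid[out[int, "left"]]
  out[int, "right"] <- newid[out[int, "right"]]
  out
}

# mean silhouette width for a 2-cluster labeling, direct definition
silhouette_mean <- function(X, lab) {
  n <- nrow(X)
  d <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in 1:n) {
    own <- lab == lab[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- mean(d[i, !own])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
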