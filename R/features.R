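#' EMG trial container
#'
#' Bundles one gesture repetition: an 8-channel raw signal, the sampling
#' rate, the gesture and arm-position labels, and the sample index at which
#' the gesture-hold period starts. Only the hold period is ever featurized
#' or scored; the first part of a trial is the reaction/transition phase.
#'
#' @param signal numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param gesture gesture label (integer 1..K or character).
#' @param position arm-position tag, one of `"P2","P4","P5","P6","P8"`.
#' @param hold_start 1-based sample index where the hold period begins.
#' @return An object of class `emg_trial`.
#' @export
emg_trial <- function(signal, fs, gesture, position = "P5", hold_start = 1L) {
  signal <- as.matrix(signal)
  stopifnot(is.numeric(signal), fs > 0, hold_start >= 1,
            hold_start <= ncol(signal))
  structure(list(signal = signal, fs = fs, gesture = gesture,
                 position = position, hold_start = as.integer(hold_start)),
            class = "emg_trial")
}

#' @export
print.emg_trial <- function(x, ...) {
  cat(sprintf("<emg_trial> %d ch x %d samples @ %g Hz, gesture=%s, position=%s, hold from sample %d\n",
              nrow(x$signal), ncol(x$signal), x$fs, as.character(x$gesture),
              x$position, x$hold_start))
  invisible(x)
}

#' Sliding analysis windows over the gesture-hold period
#'
#' Segments the hold period of a trial into overlapping windows of
#' `win_ms` milliseconds advanced by `step_ms`. A trailing partial window
#' is discarded, so a hold of H ms yields `floor((H - win_ms)/step_ms) + 1`
#' windows.
#'
#' @param trial an [emg_trial()].
#' @param win_ms window length in milliseconds (default 200).
#' @param step_ms step between window starts in milliseconds (default 100).
#' @return List of channel x window-length signal matrices, with attribute
#'   `starts` giving each window's 1-based start sample in the trial.
#' @export
sliding_windows <- function(trial, win_ms = 200, step_ms = 100) {
  stopifnot(inherits(trial, "emg_trial"))
  wlen <- round(win_ms * trial$fs / 1000)
  step <- round(step_ms * trial$fs / 1000)
  hold <- ncol(trial$signal) - trial$hold_start + 1L
  if (hold < wlen)
    stop("gesture-hold period (", hold, " samples) is shorter than one ",
         wlen, "-sample window")
  starts <- seq(trial$hold_start, ncol(trial$signal) - wlen + 1L, by = step)
  out <- lapply(starts, function(s) trial$signal[, s:(s + wlen - 1L), drop = FALSE])
  attr(out, "starts") <- as.integer(starts)
  out
}

#' Time-domain energy features of one EMG channel window
#'
#' Computes the five classical amplitude descriptors: mean absolute value
#' (MAV), waveform length (WL), root mean square (RMS), slope sign changes
#' (SSC) and zero crossings (ZC). ZC counts sign changes whose amplitude
#' step is at least `eps`; SSC counts local slope reversals where at least
#' one adjacent step is at least `eps`. The deadzone `eps` defaults to 0 and
#' only matters on noisy baselines.
#'
#' @param x numeric vector, one channel's window (length >= 3).
#' @param eps deadzone threshold for ZC/SSC.
#' @return Named numeric vector `c(mav, wl, rms, ssc, zc)`.
#' @export
energy_features <- function(x, eps = 0) {
  n <- length(x)
  if (n == 0L) stop("empty window")
  if (n < 3L) stop("window too short for energy features (need >= 3 samples)")
  d <- diff(x)
  mav <- mean(abs(x))
  wl <- sum(abs(d))
  rms <- sqrt(mean(x^2))
  zc <- sum(x[-n] * x[-1L] < 0 & abs(d) >= eps)
  mid <- x[2:(n - 1L)]
  ssc <- sum((mid - x[1:(n - 2L)]) * (mid - x[3:n]) > 0 &
               (abs(mid - x[1:(n - 2L)]) >= eps | abs(mid - x[3:n]) >= eps))
  c(mav = mav, wl = wl, rms = rms, ssc = ssc, zc = zc)
}

#' Sample skewness of one EMG channel window
#'
#' Population (biased) skewness `mean(((x - mu)/sigma)^3)` with the biased
#' standard deviation. A constant window returns 0 by convention.
#'
#' @param x numeric vector.
#' @return Skewness as a single number.
#' @export
distribution_feature <- function(x) {
  if (length(x) == 0L) stop("empty window")
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 <= 0) return(c(skew = 0))
  c(skew = mean((x - mu)^3) / s2^1.5)
}

#' Spectral features of one EMG channel window
#'
#' Periodogram-based descriptors of the window after mean removal: peak
#' frequency (PKF), median frequency (MDF), mean frequency (MNF) and the
#' variance of central frequency (VCF), all over FFT bins in (0, fs/2]
#' (DC excluded, no zero padding). An all-zero (or constant) window returns
#' all four as 0 by convention.
#'
#' @param x numeric vector (length >= 8).
#' @param fs sampling rate in Hz.
#' @return Named numeric vector `c(pkf, mdf, mnf, vcf)` in Hz (vcf in Hz^2).
#' @export
spectral_features <- function(x, fs) {
  n <- length(x)
  if (n < 8L) stop("window too short for spectral features (need >= 8 samples)")
  x <- x - mean(x)
  if (all(x == 0)) return(c(pkf = 0, mdf = 0, mnf = 0, vcf = 0))
  sp <- fft(x)
  nb <- floor(n / 2)
  pw <- (Mod(sp[2:(nb + 1L)])^2) / n      # bins 1..floor(n/2): (0, fs/2]
  f <- (1:nb) * fs / n
  tot <- sum(pw)
  pkf <- f[which.max(pw)]
  mnf <- sum(f * pw) / tot
  mdf <- f[which(cumsum(pw) >= tot / 2)[1L]]
  vcf <- sum((f - mnf)^2 * pw) / tot
  c(pkf = pkf, mdf = mdf, mnf = mnf, vcf = vcf)
}

#' Per-window feature vector across channels
#'
#' Concatenates the enabled feature groups channel by channel
#' (channel-major order, features within a channel ordered
#' MAV, WL, RMS, SSC, ZC, SKEW, PKF, MDF, MNF, VCF). With all three groups
#' and 8 channels this is the standard 80-length descriptor; disabling
#' groups supports feature-ablation experiments.
#'
#' @param window channels x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param groups character subset of `c("energy", "distribution", "spectrum")`.
#' @param eps ZC/SSC deadzone, see [energy_features()].
#' @return Named numeric vector of length `n_channels * (5/1/4 per group)`.
#' @export
extract_features <- function(window, fs,
                             groups = c("energy", "distribution", "spectrum"),
                             eps = 0) {
  if (length(groups) == 0L) stop("at least one feature group must be enabled")
  groups <- match.arg(groups, c("energy", "distribution", "spectrum"),
                      several.ok = TRUE)
  window <- as.matrix(window)
  per_ch <- function(x) {
    v <- numeric(0)
    if ("energy" %in% groups) v <- c(v, energy_features(x, eps = eps))
    if ("distribution" %in% groups) v <- c(v, distribution_feature(x))
    if ("spectrum" %in% groups) v <- c(v, spectral_features(x, fs))
    v
  }
  out <- lapply(seq_len(nrow(window)), function(c) {
    v <- per_ch(window[c, ])
    names(v) <- paste0("ch", c, "_", names(v))
    v
  })
  unlist(out)
}

#' Feature matrix for one trial
#'
#' Applies [sliding_windows()] and [extract_features()] to a trial,
#' returning one row per window of the gesture-hold period.
#'
#' @inheritParams sliding_windows
#' @inheritParams extract_features
#' @return Numeric matrix windows x features with attributes `gesture`,
#'   `position` and `window_index`.
#' @export
trial_features <- function(trial, win_ms = 200, step_ms = 100,
                           groups = c("energy", "distribution", "spectrum"),
                           eps = 0) {
  wins <- sliding_windows(trial, win_ms = win_ms, step_ms = step_ms)
  X <- t(vapply(wins, extract_features, fs = trial$fs, groups = groups,
                eps = eps,
                FUN.VALUE = extract_features(wins[[1L]], trial$fs, groups, eps)))
  attr(X, "gesture") <- trial$gesture
  attr(X, "position") <- trial$position
  attr(X, "window_index") <- seq_len(nrow(X))
  X
}

#' Fit per-dimension z-score statistics
#'
#' Mean and (population-style, `stats::sd`) standard deviation per feature
#' dimension. During pre-training the statistics are fitted separately per
#' participant; for a new user they are fitted on the one-shot calibration
#' session and then frozen for all testing blocks.
#'
#' @param X samples x features numeric matrix (>= 2 rows).
#' @return Object of class `emg_normalizer` with fields `mean` and `sd`.
#' @export
fit_normalizer <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples to fit a normalizer")
  structure(list(mean = colMeans(X), sd = apply(X, 2L, sd)),
            class = "emg_normalizer")
}

#' Apply a fitted z-score normalizer
#'
#' Degenerate dimensions (zero standard deviation in the fitting set) map
#' to 0 rather than NaN.
#'
#' @param stats an `emg_normalizer` from [fit_normalizer()].
#' @param X numeric vector or samples x features matrix.
#' @return Normalized object of the same shape as `X`.
#' @export
apply_normalizer <- function(stats, X) {
  stopifnot(inherits(stats, "emg_normalizer"))
  vec <- is.null(dim(X))
  X <- if (vec) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != length(stats$mean))
    stop("feature dimension mismatch: normalizer has ", length(stats$mean),
         ", data has ", ncol(X))
  s <- stats$sd
  keep <- s > 0
  Z <- sweep(X, 2L, stats$mean, "-")
  Z[, keep] <- sweep(Z[, keep, drop = FALSE], 2L, s[keep], "/")
  Z[, !keep] <- 0
  if (vec) drop(Z) else Z
}
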