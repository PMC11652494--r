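# Plain-text interchange: trials as CSV (one row per sample, ch1..ch8)
# with a JSON metadata sidecar; feature tables as CSV.

#' Write / read an EMG trial as CSV plus JSON sidecar
#'
#' The CSV holds one row per sample with columns `ch1..chN`; the sidecar
#' `<path>.meta.json` records `fs`, `gesture`, `position` and
#' `hold_start`.
#'
#' @param trial an [emg_trial()].
#' @param path CSV file path.
#' @return `read_trial_csv` returns the trial; `write_trial_csv` the path,
#'   invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "emg_trial"))
  df <- as.data.frame(t(trial$signal))
  names(df) <- paste0("ch", seq_len(nrow(trial$signal)))
  write.csv(df, path, row.names = FALSE)
  meta <- list(fs = trial$fs, gesture = trial$gesture,
               position = trial$position, hold_start = trial$hold_start)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".meta.json"))
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) stop("missing metadata sidecar: ", meta_path)
  meta <- jsonlite::fromJSON(meta_path)
  emg_trial(t(as.matrix(df)), fs = meta$fs, gesture = meta$gesture,
            position = meta$position, hold_start = meta$hold_start)
}

#' Write / read a feature table as CSV
#'
#' Columns `f000..f0NN` hold the feature vector, followed by `gesture`,
#' `position`, `block` and `window_index`.
#'
#' @param X windows x features matrix.
#' @param y gesture label per window.
#' @param position position tag per window (recycled if scalar).
#' @param block block index per window (recycled if scalar).
#' @param path CSV file path.
#' @return `read_feature_table` returns a list with `X`, `y`, `position`,
#'   `block`, `window_index`.
#' @export
write_feature_table <- function(X, y, position = "P5", block = 1L, path) {
  X <- as.matrix(X)
  df <- as.data.frame(X)
  names(df) <- sprintf("f%03d", seq_len(ncol(X)) - 1L)
  df$gesture <- y
  df$position <- position
  df$block <- block
  df$window_index <- seq_len(nrow(X))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  list(X = as.matrix(df[, fcols, drop = FALSE]),
       y = df$gesture, position = df$position, block = df$block,
       window_index = df$window_index)
}
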