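# Seeded synthetic surface-EMG generator. The carrier is band-limited
# (20-450 Hz) zero-mean Gaussian noise, amplitude-modulated per channel by
# gesture-specific activation gains; arm position acts on each channel as a
# multiplicative gain plus an additive baseline-activity offset, which is
# the covariate-shift structure the self-calibrating decoder must absorb.
# No physiological fidelity is claimed beyond that feature-level structure.

GESTURE_NAMES <- c("rest", "fist", "open", "tripod", "pointer", "lateral")
POSITION_NAMES <- c("P2", "P4", "P5", "P6", "P8")

# per-channel activation gains, gestures x 8 channels (frozen fixture)
GESTURE_GAINS <- matrix(c(
  0.08, 0.10, 0.09, 0.08, 0.10, 0.09, 0.08, 0.09,  # rest
  0.95, 0.85, 0.70, 0.45, 0.25, 0.20, 0.18, 0.22,  # fist
  0.20, 0.25, 0.30, 0.45, 0.80, 0.90, 0.75, 0.60,  # open
  0.30, 0.70, 0.85, 0.40, 0.30, 0.65, 0.25, 0.20,  # tripod
  0.25, 0.35, 0.75, 0.80, 0.30, 0.25, 0.70, 0.30,  # pointer
  0.70, 0.30, 0.25, 0.30, 0.75, 0.70, 0.30, 0.45   # lateral
), nrow = 6, byrow = TRUE, dimnames = list(GESTURE_NAMES, NULL))

# full-strength multiplicative gain per position (P2/P6 raise activity,
# P4/P8 lower it, P5 is the identity reference)
POSITION_GAIN <- matrix(c(
  1.35, 1.25, 1.30, 1.20, 1.25, 1.40, 1.20, 1.30,  # P2
  0.75, 0.80, 0.70, 0.85, 0.80, 0.70, 0.85, 0.75,  # P4
  1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00,  # P5
  1.30, 1.35, 1.25, 1.30, 1.20, 1.45, 1.25, 1.35,  # P6
  0.70, 0.75, 0.80, 0.70, 0.75, 0.65, 0.80, 0.70   # P8
), nrow = 5, byrow = TRUE, dimnames = list(POSITION_NAMES, NULL))

# full-strength additive baseline-activity offsets (shift the rest-class
# feature cloud at non-reference positions; small against active gains)
POSITION_OFFSET <- matrix(c(
  0.020, 0.008, 0.015, 0.005, 0.012, 0.022, 0.010, 0.016,  # P2
  0.010, 0.018, 0.006, 0.014, 0.008, 0.005, 0.016, 0.011,  # P4
  0.000, 0.000, 0.000, 0.000, 0.000, 0.000, 0.000, 0.000,  # P5
  0.016, 0.022, 0.010, 0.018, 0.006, 0.024, 0.012, 0.020,  # P6
  0.012, 0.006, 0.018, 0.008, 0.015, 0.010, 0.020, 0.007   # P8
), nrow = 5, byrow = TRUE, dimnames = list(POSITION_NAMES, NULL))

#' Generator specification: gestures, positions and noise levels
#'
#' Returns the frozen gesture-activation and arm-position effect tables,
#' scaled by `shift_strength`: at 0 all positions are identical to P5, at 1
#' the full configured position effect applies. Trial-to-trial variability
#' enters as a lognormal whole-trial amplitude factor and per-channel
#' factors, which is what makes single-window classification non-trivial.
#'
#' @param shift_strength scalar in `[0, 1]` scaling the arm-position
#'   effect (default 0.5).
#' @param amp_jitter_sd log-sd of the whole-trial amplitude factor.
#' @param channel_jitter_sd log-sd of per-channel trial factors.
#' @param sigma0 additive sensor-noise standard deviation.
#' @return List of class `emg_specs` with `gesture_gains` (6 x 8),
#'   `position_gain`, `position_offset` (5 x 8), noise parameters, and the
#'   gesture/position name tables.
#' @export
default_specs <- function(shift_strength = 0.5, amp_jitter_sd = 0.35,
                          channel_jitter_sd = 0.25, sigma0 = 0.08) {
  stopifnot(shift_strength >= 0, shift_strength <= 1)
  structure(list(
    gesture_gains = GESTURE_GAINS,
    position_gain = 1 + shift_strength * (POSITION_GAIN - 1),
    position_offset = shift_strength * POSITION_OFFSET,
    shift_strength = shift_strength,
    amp_jitter_sd = amp_jitter_sd,
    channel_jitter_sd = channel_jitter_sd,
    sigma0 = sigma0,
    gestures = GESTURE_NAMES,
    positions = POSITION_NAMES
  ), class = "emg_specs")
}

#' Derive an individual user from the base specification
#'
#' Perturbs the gesture-activation table with lognormal factors per
#' gesture-channel cell plus a per-channel scale (electrode placement and
#' skin impedance differences), emulating inter-participant variability in
#' the pre-training pool and in target users.
#'
#' @param specs an `emg_specs` from [default_specs()].
#' @param gain_sd log-sd of per-cell activation perturbation.
#' @param channel_sd log-sd of per-channel scale.
#' @return A new `emg_specs` for one user.
#' @export
perturb_specs <- function(specs, gain_sd = 0.25, channel_sd = 0.15) {
  g <- specs$gesture_gains
  g <- g * exp(matrix(rnorm(length(g), 0, gain_sd), nrow(g), ncol(g)))
  g <- sweep(g, 2L, exp(rnorm(ncol(g), 0, channel_sd)), "*")
  specs$gesture_gains <- g
  specs
}

# unit-variance band-limited Gaussian noise via Hermitian spectral synthesis
bandlimited_noise <- function(n, fs, f_lo = 20, f_hi = 450) {
  half <- floor(n / 2)
  f <- (1:half) * fs / n
  band <- which(f >= f_lo & f <= f_hi)
  if (length(band) == 0L) stop("no FFT bins inside the requested band")
  nyq <- if (n %% 2 == 0) half else -1L
  reg <- band[band != nyq]
  z <- complex(length.out = n)
  vals <- complex(real = rnorm(length(reg)), imaginary = rnorm(length(reg))) /
    sqrt(2)
  z[reg + 1L] <- vals
  z[n - reg + 1L] <- Conj(vals)
  total <- 2 * length(reg)
  if (nyq %in% band) {
    z[nyq + 1L] <- complex(real = rnorm(1), imaginary = 0)
    total <- total + 1
  }
  Re(fft(z, inverse = TRUE)) / sqrt(total)
}

#' Generate one synthetic EMG trial
#'
#' Per channel c the signal is
#' `x_c(t) = (a[g,c] * jitter * m[p,c] + b[p,c]) * n_c(t) + sigma0 * w_c(t)`
#' where `n_c` is unit-variance band-limited (20-450 Hz) Gaussian noise and
#' `w_c` white sensor noise. During the reaction phase (everything before
#' `hold_s` seconds from the end) the activation ramps from the rest level
#' to the target gesture's level; only the hold period is featurized.
#'
#' @param gesture gesture index (1..6) or name.
#' @param position position name (`"P2","P4","P5","P6","P8"`).
#' @param specs an `emg_specs`.
#' @param duration_s trial length in seconds (default 2).
#' @param fs sampling rate in Hz (default 2000).
#' @param hold_s length of the terminal gesture-hold period in seconds.
#' @return An [emg_trial()] with `hold_start` at the hold boundary.
#' @export
generate_trial <- function(gesture, position, specs, duration_s = 2,
                           fs = 2000, hold_s = 1) {
  if (is.character(gesture)) gesture <- match(gesture, specs$gestures)
  if (is.na(gesture) || gesture < 1 || gesture > nrow(specs$gesture_gains))
    stop("unknown gesture")
  if (!position %in% specs$positions) stop("unknown position: ", position)
  stopifnot(duration_s > 0, hold_s > 0, hold_s <= duration_s)
  n <- round(duration_s * fs)
  n_ch <- ncol(specs$gesture_gains)
  hold_start <- n - round(hold_s * fs) + 1L

  a_target <- specs$gesture_gains[gesture, ]
  a_rest <- specs$gesture_gains[1L, ]
  m <- specs$position_gain[position, ]
  b <- specs$position_offset[position, ]
  jit <- exp(rnorm(1, 0, specs$amp_jitter_sd)) *
    exp(rnorm(n_ch, 0, specs$channel_jitter_sd))

  # activation envelope: rest level, ramp across the middle of the
  # reaction phase, full level through the hold period
  env <- rep(1, n)
  if (hold_start > 1L) {
    pre <- hold_start - 1L
    ramp_lo <- max(1L, round(pre * 0.25))
    ramp_hi <- max(ramp_lo + 1L, round(pre * 0.75))
    env[seq_len(pre)] <- approx(x = c(1, ramp_lo, ramp_hi, pre),
                                y = c(0, 0, 1, 1), xout = seq_len(pre),
                                rule = 2)$y
  }

  sig <- matrix(0, n_ch, n)
  for (c in seq_len(n_ch)) {
    act <- a_rest[c] + env * (a_target[c] - a_rest[c])
    gain <- act * jit[c] * m[c] + b[c]
    sig[c, ] <- gain * bandlimited_noise(n, fs) + specs$sigma0 * rnorm(n)
  }
  emg_trial(sig, fs, gesture = gesture, position = position,
            hold_start = hold_start)
}

#' Arm-position sequence of the 11-block testing protocol
#'
#' Group A rotates the arm clockwise then counterclockwise
#' (P5-P4-P2-P6-P8-P5-P8-P6-P2-P4-P5); group B is the mirrored order. Both
#' sequences are symmetric around block 6, which cancels time trends when
#' accuracies are averaged by position.
#'
#' @param group `"A"` or `"B"`.
#' @return Data frame with columns `block` and `position`.
#' @export
session_plan <- function(group = c("A", "B")) {
  group <- match.arg(group)
  pos <- switch(group,
    A = c("P5", "P4", "P2", "P6", "P8", "P5", "P8", "P6", "P2", "P4", "P5"),
    B = c("P5", "P8", "P6", "P2", "P4", "P5", "P4", "P2", "P6", "P8", "P5"))
  data.frame(block = 1:11, position = pos)
}

#' Generate a full calibration + testing session for one user
#'
#' One 2 s calibration trial per gesture at P5, then 11 testing blocks of
#' 30 trials (5 per gesture, order randomized within block) at the
#' positions given by [session_plan()].
#'
#' @param group `"A"` or `"B"`.
#' @param specs an `emg_specs` (typically a [perturb_specs()] user).
#' @param fs sampling rate in Hz.
#' @param duration_s trial duration in seconds.
#' @param trials_per_gesture trials per gesture per block (default 5).
#' @return List of class `emg_session` with `calibration` (list of trials),
#'   `blocks` (list of 11 lists of trials), `plan`, and `group`.
#' @export
generate_experiment <- function(group = c("A", "B"), specs, fs = 2000,
                                duration_s = 2, trials_per_gesture = 5L) {
  group <- match.arg(group)
  plan <- session_plan(group)
  n_g <- nrow(specs$gesture_gains)
  calibration <- lapply(seq_len(n_g), function(g)
    generate_trial(g, "P5", specs, duration_s = duration_s, fs = fs))
  blocks <- lapply(seq_len(nrow(plan)), function(b) {
    gestures <- sample(rep(seq_len(n_g), trials_per_gesture))
    lapply(gestures, function(g)
      generate_trial(g, plan$position[b], specs, duration_s = duration_s,
                     fs = fs))
  })
  structure(list(calibration = calibration, blocks = blocks, plan = plan,
                 group = group), class = "emg_session")
}

#' Generate a synthetic pre-training pool
#'
#' Draws `n_users` individual users via [perturb_specs()] and records
#' `trials_per_gesture` repetitions of every gesture per user at the
#' reference position P5.
#'
#' @param specs base `emg_specs`.
#' @param n_users number of synthetic participants (default 10).
#' @param trials_per_gesture repetitions per gesture per user (default 4).
#' @param fs sampling rate in Hz.
#' @param duration_s trial duration in seconds.
#' @return List of users, each a list of [emg_trial()]s.
#' @export
generate_pretrain_users <- function(specs, n_users = 10L,
                                    trials_per_gesture = 4L, fs = 2000,
                                    duration_s = 2) {
  lapply(seq_len(n_users), function(u) {
    uspec <- perturb_specs(specs)
    n_g <- nrow(uspec$gesture_gains)
    unlist(lapply(seq_len(n_g), function(g)
      lapply(seq_len(trials_per_gesture), function(r)
        generate_trial(g, "P5", uspec, duration_s = duration_s, fs = fs))),
      recursive = FALSE)
  })
}
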