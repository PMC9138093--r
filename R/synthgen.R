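# Emotiv EPOC+ montage (international 10-20 labels), in headset order.
EPOC_CHANNELS <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                   "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")

# Frontal electrodes carrying the preference effect; left/right pairing.
FRONTAL_LEFT  <- c("AF3", "F3")
FRONTAL_RIGHT <- c("AF4", "F4")
FRONTAL_CHANNELS <- c(FRONTAL_LEFT, FRONTAL_RIGHT)

# Canonical EEG frequency bands (Hz). Upper edges are exclusive except
# gamma, whose ceiling is the 45 Hz bandpass limit and is inclusive.
EEG_BANDS <- list(
  theta = c(4, 8),
  alpha = c(8, 12),
  beta  = c(12, 30),
  gamma = c(30, 45)
)

#' Configuration for the synthetic EEG generator
#'
#' Builds a validated configuration describing a simulated like/dislike
#' neuromarketing study: a panel of subjects each contributing a fixed
#' number of single-product trials, recorded on the 14-channel 10-20
#' montage at 128 Hz. Each trial is a 4 s epoch made of band-limited
#' oscillations (theta, alpha, beta, gamma) plus 1/f pink noise. The
#' preference effect is a left/right amplitude asymmetry confined to the
#' frontal electrodes AF3/F3/AF4/F4: for a "like" trial, alpha amplitude
#' on the left is scaled by (1 - delta) and on the right by (1 + delta),
#' with the mirror-image scaling applied to beta; "dislike" trials get the
#' reverse. Non-frontal channels never carry a class effect.
#'
#' @param n_subjects Number of subjects (default 25).
#' @param n_trials_per_subject Trials per subject (default 42).
#' @param epoch_seconds Epoch duration in seconds (default 4, i.e. 512
#'   samples at 128 Hz).
#' @param fs Sampling rate in Hz (default 128).
#' @param band_amplitudes Named numeric vector of per-band oscillation
#'   amplitudes (arbitrary microvolt-like units) for theta, alpha, beta
#'   and gamma.
#' @param asymmetry_effect Unitless effect size \eqn{\delta \in [0, 1)}
#'   scaling the class-dependent frontal left/right amplitude difference.
#'   At 0, like and dislike epochs are drawn from the same distribution.
#' @param pink_noise_sd Standard deviation of the additive pink (1/f)
#'   noise per channel.
#' @param subject_sd Log-scale standard deviation of the multiplicative
#'   between-subject jitter applied to band amplitudes.
#' @param seed Integer RNG seed; the full dataset is a pure function of
#'   the configuration including this seed.
#' @return An object of class \code{synth_config} (a named list).
#' @examples
#' cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 4, seed = 1)
#' ds <- make_dataset(cfg)
#' length(ds$epochs)
#' @export
synth_config <- function(n_subjects = 25,
                         n_trials_per_subject = 42,
                         epoch_seconds = 4,
                         fs = 128,
                         band_amplitudes = c(theta = 4, alpha = 6,
                                             beta = 3, gamma = 1.5),
                         asymmetry_effect = 0.5,
                         pink_noise_sd = 5,
                         subject_sd = 0.2,
                         seed = 1L) {
  stopifnot(n_subjects >= 1, n_trials_per_subject >= 1,
            epoch_seconds > 0, fs > 0,
            asymmetry_effect >= 0, asymmetry_effect < 1,
            pink_noise_sd >= 0, subject_sd >= 0)
  if (!all(names(EEG_BANDS) %in% names(band_amplitudes)))
    stop("band_amplitudes must name theta, alpha, beta and gamma")
  if (any(band_amplitudes < 0)) stop("band amplitudes must be non-negative")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_subject = as.integer(n_trials_per_subject),
    epoch_seconds = epoch_seconds,
    fs = fs,
    band_amplitudes = band_amplitudes[names(EEG_BANDS)],
    asymmetry_effect = asymmetry_effect,
    pink_noise_sd = pink_noise_sd,
    subject_sd = subject_sd,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic EEG study design\n")
  cat(sprintf("  %d subjects x %d trials = %d epochs\n", x$n_subjects,
              x$n_trials_per_subject, x$n_subjects * x$n_trials_per_subject))
  cat(sprintf("  epoch: %.3g s at %g Hz (%d samples), 14 channels\n",
              x$epoch_seconds, x$fs, round(x$epoch_seconds * x$fs)))
  cat(sprintf("  frontal asymmetry effect delta = %.3g\n", x$asymmetry_effect))
  invisible(x)
}

# Pink (1/f) noise: white Gaussian noise spectrally reshaped so amplitude
# falls as 1/sqrt(f), rescaled to standard deviation `sd`.
pink_noise <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- c(1, seq_len(n - 1))          # guard DC bin
  f <- pmin(k - 1, n - (k - 1))      # symmetric frequency index
  f[f < 1] <- 1
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x * (sd / s)
  x
}

# Multiplicative log-normal between-subject jitter on band amplitudes.
# Drawn from a dedicated stream keyed on (config seed, subject id) so a
# subject's amplitude profile is stable no matter where their epochs are
# generated; the caller's RNG state is left untouched.
subject_band_jitter <- function(config, subject_id) {
  if (config$subject_sd == 0)
    return(stats::setNames(rep(1, length(EEG_BANDS)), names(EEG_BANDS)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((abs(config$seed) %% 1000000L) * 2000L + subject_id %% 2000L)
  j <- exp(stats::rnorm(length(EEG_BANDS), 0, config$subject_sd))
  stats::setNames(j, names(EEG_BANDS))
}

# Class-dependent amplitude scaling for one channel and band. The alpha
# asymmetry is the approach/withdrawal signature (right alpha up, left
# alpha down for "like"); beta mirrors it so valence-type ratio indices
# also separate the classes.
class_scale <- function(channel, band, label, delta) {
  if (delta == 0) return(1)
  side <- if (channel %in% FRONTAL_LEFT) -1
          else if (channel %in% FRONTAL_RIGHT) 1
          else return(1)
  sgn <- if (identical(label, "like")) 1 else -1
  if (band == "alpha") 1 + delta * side * sgn
  else if (band == "beta") 1 - delta * side * sgn
  else 1
}

#' Simulate one EEG epoch
#'
#' Draws a single trial's channels-by-samples signal from the generative
#' model described in \code{\link{synth_config}}: per channel, three
#' random-phase sinusoids per band (frequencies uniform within the band)
#' plus pink noise. Consumes the caller's RNG stream; seed it (or use
#' \code{\link{make_dataset}}) for reproducibility.
#'
#' @param config A \code{synth_config}.
#' @param subject_id Positive integer subject identifier.
#' @param label \code{"like"} or \code{"dislike"}.
#' @param trial_id Positive integer trial identifier (metadata only).
#' @return An object of class \code{eeg_epoch}: a list with \code{signal}
#'   (14 x n_samples matrix, channel names as rownames), \code{channel_names},
#'   \code{fs}, \code{label}, \code{subject_id} and \code{trial_id}.
#' @examples
#' cfg <- synth_config(seed = 7)
#' set.seed(7)
#' ep <- make_epoch(cfg, subject_id = 1, label = "like")
#' dim(ep$signal)
#' @export
make_epoch <- function(config, subject_id, label, trial_id = 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (!label %in% c("like", "dislike"))
    stop("label must be 'like' or 'dislike'")
  n <- round(config$epoch_seconds * config$fs)
  if (n < 1) stop("non-positive epoch length")
  t <- (seq_len(n) - 1) / config$fs
  jit <- subject_band_jitter(config, subject_id)
  sig <- matrix(0, nrow = length(EPOC_CHANNELS), ncol = n,
                dimnames = list(EPOC_CHANNELS, NULL))
  n_osc <- 3L
  for (ch in EPOC_CHANNELS) {
    x <- numeric(n)
    for (band in names(EEG_BANDS)) {
      rng <- EEG_BANDS[[band]]
      amp <- config$band_amplitudes[[band]] * jit[[band]] *
        class_scale(ch, band, label, config$asymmetry_effect)
      freqs <- stats::runif(n_osc, rng[1], rng[2])
      phases <- stats::runif(n_osc, 0, 2 * pi)
      for (o in seq_len(n_osc))
        x <- x + amp * sin(2 * pi * freqs[o] * t + phases[o])
    }
    sig[ch, ] <- x + pink_noise(n, config$pink_noise_sd)
  }
  structure(list(signal = sig, channel_names = EPOC_CHANNELS,
                 fs = config$fs, label = label,
                 subject_id = as.integer(subject_id),
                 trial_id = as.integer(trial_id)),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("EEG epoch: subject %d trial %d (%s), %d ch x %d samples at %g Hz\n",
              x$subject_id, x$trial_id, x$label, nrow(x$signal),
              ncol(x$signal), x$fs))
  invisible(x)
}

#' Simulate a full labeled dataset
#'
#' Generates \code{n_subjects * n_trials_per_subject} epochs. Each
#' subject's like rate is drawn from Beta(5, 5) clipped to [0.2, 0.8], so
#' both classes are present whenever a subject has at least two trials.
#' The dataset is bit-identical across runs for identical configurations
#' (the RNG is seeded from \code{config$seed}).
#'
#' @param config A \code{synth_config}.
#' @return An object of class \code{epoch_set}: list with \code{epochs}
#'   (list of \code{eeg_epoch}) and \code{labels} (character vector).
#' @examples
#' ds <- make_dataset(synth_config(n_subjects = 2, n_trials_per_subject = 3))
#' table(ds$labels)
#' @export
make_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  nt <- config$n_trials_per_subject
  epochs <- vector("list", config$n_subjects * nt)
  labels <- character(length(epochs))
  i <- 0L
  for (s in seq_len(config$n_subjects)) {
    p_like <- min(0.8, max(0.2, stats::rbeta(1, 5, 5)))
    n_like <- round(p_like * nt)
    if (nt >= 2) n_like <- min(nt - 1L, max(1L, n_like))
    lab <- c(rep("like", n_like), rep("dislike", nt - n_like))
    for (tr in seq_len(nt)) {
      i <- i + 1L
      epochs[[i]] <- make_epoch(config, s, lab[tr], trial_id = tr)
      labels[i] <- lab[tr]
    }
  }
  structure(list(epochs = epochs, labels = labels, config = config),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Labeled EEG epoch set: %d epochs (%d like / %d dislike)\n",
              length(x$epochs), sum(x$labels == "like"),
              sum(x$labels == "dislike")))
  invisible(x)
}

#' @export
length.epoch_set <- function(x) length(x$epochs)

#' Write epochs to delimited text
#'
#' Long format, one row per sample: columns \code{subject}, \code{trial},
#' \code{channel}, \code{sample} (1-based index), \code{value}. A
#' companion labels file holds one row per epoch: \code{subject},
#' \code{trial}, \code{label}. Round-trips with \code{\link{read_epochs}}.
#'
#' @param epoch_set An \code{epoch_set}.
#' @param signal_file,labels_file Output paths (tab-separated).
#' @return Invisibly, the two paths.
#' @export
write_epochs <- function(epoch_set, signal_file, labels_file) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  rows <- lapply(epoch_set$epochs, function(ep) {
    n <- ncol(ep$signal)
    data.frame(subject = ep$subject_id, trial = ep$trial_id,
               channel = rep(rownames(ep$signal), each = n),
               sample = rep(seq_len(n), times = nrow(ep$signal)),
               value = as.vector(t(ep$signal)))
  })
  long <- do.call(rbind, rows)
  utils::write.table(long, signal_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  labs <- data.frame(
    subject = vapply(epoch_set$epochs, `[[`, integer(1), "subject_id"),
    trial = vapply(epoch_set$epochs, `[[`, integer(1), "trial_id"),
    label = epoch_set$labels)
  utils::write.table(labs, labels_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(signal_file, labels_file))
}

#' Read epochs written by \code{write_epochs}
#'
#' @param signal_file,labels_file Paths written by \code{\link{write_epochs}}.
#' @param fs Sampling rate of the stored signals (Hz).
#' @return An \code{epoch_set}.
#' @export
read_epochs <- function(signal_file, labels_file, fs = 128) {
  long <- utils::read.table(signal_file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  labs <- utils::read.table(labels_file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  epochs <- vector("list", nrow(labs))
  for (i in seq_len(nrow(labs))) {
    sub <- long[long$subject == labs$subject[i] & long$trial == labs$trial[i], ]
    chans <- unique(sub$channel)
    n <- max(sub$sample)
    sig <- matrix(NA_real_, nrow = length(chans), ncol = n,
                  dimnames = list(chans, NULL))
    for (ch in chans) {
      rows <- sub[sub$channel == ch, ]
      sig[ch, rows$sample] <- rows$value
    }
    epochs[[i]] <- structure(list(signal = sig, channel_names = chans,
                                  fs = fs, label = labs$label[i],
                                  subject_id = labs$subject[i],
                                  trial_id = labs$trial[i]),
                             class = "eeg_epoch")
  }
  structure(list(epochs = epochs, labels = labs$label), class = "epoch_set")
}
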