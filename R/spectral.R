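# Floor applied to band powers before they reach any logarithm.
POWER_EPS <- 1e-12

#' One-sided FFT power spectral density
#'
#' Full-epoch periodogram: a 512-sample epoch at 128 Hz yields
#' nfft/2 + 1 = 257 one-sided bins per channel. Normalisation follows the
#' Parseval convention: the sum of PSD bins times the bin width
#' (fs / nfft) equals the mean squared signal.
#'
#' @param epoch An \code{eeg_epoch}.
#' @param channels Channel names to transform (default: the four frontal
#'   preference electrodes).
#' @param nfft FFT length; defaults to the epoch's sample count.
#' @return A \code{psd_matrix}: list with \code{values} (channel x bin
#'   power matrix) and \code{freqs} (Hz, 0 to fs/2).
#' @examples
#' set.seed(1)
#' ep <- make_epoch(synth_config(seed = 1), 1, "like")
#' psd <- psd_fft(ep)
#' dim(psd$values)  # 4 x 257
#' @export
psd_fft <- function(epoch, channels = FRONTAL_CHANNELS, nfft = NULL) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  missing_ch <- setdiff(channels, rownames(epoch$signal))
  if (length(missing_ch))
    stop("unknown channel(s): ", paste(missing_ch, collapse = ", "))
  n <- ncol(epoch$signal)
  if (n < 1) stop("empty signal")
  if (is.null(nfft)) nfft <- n
  fs <- epoch$fs
  n_bins <- nfft %/% 2 + 1
  vals <- matrix(0, nrow = length(channels), ncol = n_bins,
                 dimnames = list(channels, NULL))
  for (ch in channels) {
    x <- epoch$signal[ch, ]
    if (length(x) < nfft) x <- c(x, numeric(nfft - length(x)))
    X <- stats::fft(x[seq_len(nfft)])
    p <- Mod(X[seq_len(n_bins)])^2 / (nfft * fs)
    # double interior bins so the one-sided spectrum conserves power
    if (n_bins > 2) p[2:(n_bins - 1)] <- 2 * p[2:(n_bins - 1)]
    if (nfft %% 2 == 1) p[n_bins] <- 2 * p[n_bins]
    vals[ch, ] <- p
  }
  structure(list(values = vals,
                 freqs = (seq_len(n_bins) - 1) * fs / nfft,
                 fs = fs),
            class = "psd_matrix")
}

#' Average band power from a PSD
#'
#' Mean of the PSD bins whose frequency falls in the band's half-open
#' interval [low, high); the gamma ceiling (45 Hz, the bandpass limit) is
#' inclusive. The result is floored at 1e-12 so downstream logarithms are
#' always defined.
#'
#' @param psd A \code{psd_matrix}.
#' @param electrode Channel name.
#' @param band Band name in \code{names(EEG_BANDS)} or a numeric
#'   \code{c(low, high)} range in Hz.
#' @return Scalar average power.
#' @export
band_power <- function(psd, electrode, band) {
  stopifnot(inherits(psd, "psd_matrix"))
  if (!electrode %in% rownames(psd$values))
    stop("unknown electrode: ", electrode)
  inclusive_hi <- FALSE
  if (is.character(band)) {
    if (!band %in% names(EEG_BANDS)) stop("unknown band: ", band)
    inclusive_hi <- band == "gamma"
    band <- EEG_BANDS[[band]]
  }
  if (band[1] < 0 || band[2] > psd$fs / 2)
    stop("band outside the [0, fs/2] Nyquist range")
  sel <- psd$freqs >= band[1] &
    (if (inclusive_hi) psd$freqs <= band[2] else psd$freqs < band[2])
  if (!any(sel)) return(POWER_EPS)
  max(mean(psd$values[electrode, sel]), POWER_EPS)
}

#' Band-power table for the frontal electrodes
#'
#' Average theta/alpha/beta/gamma power at AF3, F3, AF4 and F4 — the
#' 16 quantities feeding the ten preference indices.
#'
#' @param epoch An \code{eeg_epoch}.
#' @return A \code{band_power_table}: 4 x 4 numeric matrix, electrodes in
#'   rows, bands in columns.
#' @export
band_power_table <- function(epoch) {
  psd <- psd_fft(epoch, FRONTAL_CHANNELS)
  out <- matrix(NA_real_, nrow = length(FRONTAL_CHANNELS),
                ncol = length(EEG_BANDS),
                dimnames = list(FRONTAL_CHANNELS, names(EEG_BANDS)))
  for (el in FRONTAL_CHANNELS)
    for (b in names(EEG_BANDS))
      out[el, b] <- band_power(psd, el, b)
  structure(out, class = c("band_power_table", "matrix"))
}

# Complex Morlet wavelet transform of one signal at one centre frequency,
# via FFT convolution. w_cycles fixes the time/frequency trade-off.
morlet_power_at <- function(x, fs, f0, w_cycles = 7) {
  n <- length(x)
  sigma_t <- w_cycles / (2 * pi * f0)
  t <- (seq_len(n) - 1 - (n - 1) / 2) / fs
  psi <- exp(2i * pi * f0 * t) * exp(-t^2 / (2 * sigma_t^2))
  psi <- psi / sqrt(sum(Mod(psi)^2))              # unit energy
  X <- stats::fft(x)
  P <- stats::fft(psi)
  conv <- stats::fft(X * Conj(P), inverse = TRUE) / n
  mean(Mod(conv)^2)
}

#' Morlet wavelet average power features
#'
#' Time-averaged squared magnitude of a complex Morlet transform at 61
#' linearly spaced centre frequencies spanning 4-45 Hz (7-cycle wavelet).
#'
#' @param epoch An \code{eeg_epoch}.
#' @param electrode Channel name.
#' @param n_freqs Number of centre frequencies (default 61).
#' @param f_range Frequency span in Hz (default c(4, 45), the analysis
#'   bandpass).
#' @param w_cycles Wavelet width in cycles (default 7).
#' @return Named numeric vector of length \code{n_freqs}, all >= 0.
#' @export
morlet_avg_power <- function(epoch, electrode, n_freqs = 61,
                             f_range = c(4, 45), w_cycles = 7) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (!electrode %in% rownames(epoch$signal))
    stop("unknown electrode: ", electrode)
  x <- epoch$signal[electrode, ]
  freqs <- seq(f_range[1], f_range[2], length.out = n_freqs)
  out <- vapply(freqs, function(f0)
    morlet_power_at(x, epoch$fs, f0, w_cycles), numeric(1))
  names(out) <- sprintf("%05.2fHz", freqs)
  out
}

#' Hann-window spectrogram features
#'
#' Short-time Fourier transform with 128-sample Hann-windowed segments at
#' 50\% overlap; the feature vector is the time-averaged power per
#' frequency row (128/2 + 1 = 65 rows for a one-sided spectrum).
#' Row powers use the same Parseval PSD normalisation as
#' \code{\link{psd_fft}} with the window's energy correction, so a
#' stationary tone yields rows comparable to a 128-point periodogram.
#'
#' @param epoch An \code{eeg_epoch}.
#' @param electrode Channel name.
#' @param n_seg Segment length in samples (default 128).
#' @param overlap Overlap in samples (default \code{n_seg / 2}).
#' @return Named numeric vector of length \code{n_seg/2 + 1}.
#' @export
spectrogram_hann <- function(epoch, electrode, n_seg = 128,
                             overlap = n_seg / 2) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (!electrode %in% rownames(epoch$signal))
    stop("unknown electrode: ", electrode)
  x <- epoch$signal[electrode, ]
  n <- length(x)
  if (n < n_seg) stop("epoch shorter than one spectrogram segment")
  w <- as.numeric(signal::hanning(n_seg))
  step <- n_seg - overlap
  starts <- seq(1, n - n_seg + 1, by = step)
  n_bins <- n_seg %/% 2 + 1
  acc <- numeric(n_bins)
  for (s in starts) {
    X <- stats::fft(x[s:(s + n_seg - 1)] * w)
    p <- Mod(X[seq_len(n_bins)])^2 / (epoch$fs * sum(w^2))
    if (n_bins > 2) p[2:(n_bins - 1)] <- 2 * p[2:(n_bins - 1)]
    acc <- acc + p
  }
  out <- acc / length(starts)
  names(out) <- sprintf("%05.1fHz", (seq_len(n_bins) - 1) * epoch$fs / n_seg)
  out
}

#' Assemble the full spectral + index feature vector for one epoch
#'
#' Concatenates, with namespaced names, the per-channel 257-bin PSD for
#' AF3/F3/AF4/F4, the cross-channel sum and average 257-bin blocks, the
#' per-channel 61-point Morlet block, the per-channel 65-point Hann
#' spectrogram block and the ten preference indices: 4*257 + 2*257 +
#' 4*61 + 4*65 + 10 = 2056 features. Use \code{blocks} to restrict the
#' composition. Features are keyed by name, never by channel position.
#'
#' @param epoch An \code{eeg_epoch}.
#' @param blocks Character subset of
#'   \code{c("psd", "psd_agg", "morlet", "hann", "indices")}.
#' @return Named numeric vector (a feature vector).
#' @examples
#' set.seed(1)
#' ep <- make_epoch(synth_config(seed = 1), 1, "like")
#' length(assemble_features(ep))  # 2056
#' @export
assemble_features <- function(epoch,
                              blocks = c("psd", "psd_agg", "morlet",
                                         "hann", "indices")) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  missing_ch <- setdiff(FRONTAL_CHANNELS, rownames(epoch$signal))
  if (length(missing_ch))
    stop("missing electrode(s): ", paste(missing_ch, collapse = ", "))
  out <- numeric(0)
  psd <- NULL
  if (any(c("psd", "psd_agg") %in% blocks))
    psd <- psd_fft(epoch, FRONTAL_CHANNELS)
  if ("psd" %in% blocks) {
    for (ch in FRONTAL_CHANNELS) {
      v <- psd$values[ch, ]
      names(v) <- sprintf("psd_%s_%03d", ch, seq_along(v))
      out <- c(out, v)
    }
  }
  if ("psd_agg" %in% blocks) {
    sm <- colSums(psd$values)
    av <- sm / nrow(psd$values)
    names(sm) <- sprintf("psd_sum_%03d", seq_along(sm))
    names(av) <- sprintf("psd_avg_%03d", seq_along(av))
    out <- c(out, sm, av)
  }
  if ("morlet" %in% blocks) {
    for (ch in FRONTAL_CHANNELS) {
      v <- morlet_avg_power(epoch, ch)
      names(v) <- sprintf("morlet_%s_%02d", ch, seq_along(v))
      out <- c(out, v)
    }
  }
  if ("hann" %in% blocks) {
    for (ch in FRONTAL_CHANNELS) {
      v <- spectrogram_hann(epoch, ch)
      names(v) <- sprintf("hann_%s_%02d", ch, seq_along(v))
      out <- c(out, v)
    }
  }
  if ("indices" %in% blocks) {
    v <- compute_indices(band_power_table(epoch))
    out <- c(out, unlist(v[INDEX_NAMES]))
  }
  out
}

#' Extract a trials-by-features table from an epoch set
#'
#' @param epoch_set An \code{epoch_set}.
#' @param blocks Feature blocks, as in \code{\link{assemble_features}}.
#' @return A \code{feature_table}; see \code{\link{feature_table}}.
#' @export
extract_feature_table <- function(epoch_set,
                                  blocks = c("psd", "psd_agg", "morlet",
                                             "hann", "indices")) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  rows <- lapply(epoch_set$epochs, assemble_features, blocks = blocks)
  mat <- do.call(rbind, rows)
  feature_table(mat, labels = epoch_set$labels,
                subject = vapply(epoch_set$epochs, `[[`, integer(1),
                                 "subject_id"),
                trial = vapply(epoch_set$epochs, `[[`, integer(1),
                               "trial_id"))
}

#' Write a feature table as delimited text
#'
#' Tab-separated, one row per trial: \code{subject}, \code{trial},
#' \code{label}, then one column per named feature.
#'
#' @param ft A \code{feature_table}.
#' @param file Output path.
#' @return Invisibly, \code{file}.
#' @export
write_feature_table <- function(ft, file) {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(subject = ft$subject, trial = ft$trial,
                   label = ft$labels, check.names = FALSE)
  df <- cbind(df, as.data.frame(ft$matrix, check.names = FALSE))
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a feature table written by \code{write_feature_table}
#'
#' @param file Path written by \code{\link{write_feature_table}}.
#' @return A \code{feature_table}.
#' @export
read_feature_table <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("subject", "trial", "label")
  feature_table(as.matrix(df[, setdiff(names(df), meta), drop = FALSE]),
                labels = df$label, subject = df$subject, trial = df$trial)
}
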