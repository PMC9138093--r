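# Shared fixtures and independent oracles. Expensive objects are memoised
# so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small labeled dataset with the default (delta = 0.5) planted asymmetry.
tiny_dataset <- function() cached("tiny_ds", {
  make_dataset(synth_config(n_subjects = 3, n_trials_per_subject = 8,
                            seed = 42))
})

# Full-size study design (25 subjects x 42 trials) with the default
# planted asymmetry; shared by the structural and recovery suites.
planted_dataset <- function() cached("planted_ds", {
  make_dataset(synth_config(seed = 2024))
})

planted_index_table <- function() cached("planted_it", {
  index_table(planted_dataset())
})

# Index features plus `p_noise` standard-normal noise columns.
noise_augmented_table <- function(p_noise = 200, seed = 77) {
  it <- planted_index_table()
  idx <- as.matrix(it[, -(1:3)])
  set.seed(seed)
  noise <- matrix(rnorm(nrow(idx) * p_noise), nrow(idx), p_noise,
                  dimnames = list(NULL, sprintf("noise_%03d",
                                                seq_len(p_noise))))
  feature_table(cbind(idx, noise), it$label, it$subject, it$trial)
}

# A single epoch holding a pure sinusoid on every channel.
sinusoid_epoch <- function(freq = 10, amp = 1, fs = 128, n = 512) {
  t <- (seq_len(n) - 1) / fs
  sig <- matrix(rep(amp * sin(2 * pi * freq * t), 14), nrow = 14,
                byrow = TRUE, dimnames = list(eegpref:::EPOC_CHANNELS, NULL))
  structure(list(signal = sig, channel_names = rownames(sig), fs = fs,
                 label = "like", subject_id = 1L, trial_id = 1L),
            class = "eeg_epoch")
}

zero_epoch <- function(fs = 128, n = 512) {
  sig <- matrix(0, 14, n, dimnames = list(eegpref:::EPOC_CHANNELS, NULL))
  structure(list(signal = sig, channel_names = rownames(sig), fs = fs,
                 label = "like", subject_id = 1L, trial_id = 1L),
            class = "eeg_epoch")
}

# Band-power table with arbitrary named entries (defaults symmetric).
make_bp <- function(...) {
  bp <- matrix(2, 4, 4, dimnames = list(c("AF3", "F3", "AF4", "F4"),
                                        c("theta", "alpha", "beta", "gamma")))
  ov <- list(...)
  for (nm in names(ov)) {
    parts <- strsplit(nm, "\\.")[[1]]   # e.g. alpha.F4 = 3
    bp[parts[2], parts[1]] <- ov[[nm]]
  }
  class(bp) <- c("band_power_table", "matrix")
  bp
}

# ---- independent oracles --------------------------------------------------

# Plug-in MI (bits) on already-discrete vectors, via direct enumeration.
oracle_mi <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  s <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb))
    if (tab[i, j] > 0) s <- s + tab[i, j] * log2(tab[i, j] / (pa[i] * pb[j]))
  s
}

# Brute-force greedy mRMR re-implementation (own MI path: equal-frequency
# quantile binning + oracle_mi), evaluating the criterion exhaustively at
# every step.
oracle_mrmr <- function(X, y, k, scheme, n_bins = 3) {
  disc <- function(v) {
    if (length(unique(v)) <= n_bins) return(as.integer(factor(v)))
    br <- unique(quantile(v, seq(0, 1, length.out = n_bins + 1),
                          names = FALSE))
    if (length(br) < 2) rep(1L, length(v)) else
      as.integer(cut(v, br, include.lowest = TRUE))
  }
  Xd <- apply(X, 2, disc)
  yd <- as.integer(factor(y))
  p <- ncol(X)
  rel <- vapply(seq_len(p), function(j) oracle_mi(Xd[, j], yd), numeric(1))
  sel <- integer(0)
  for (step in seq_len(k)) {
    avail <- setdiff(seq_len(p), sel)
    crit <- vapply(avail, function(a) {
      if (!length(sel)) return(rel[a])
      red <- mean(vapply(sel, function(b) oracle_mi(Xd[, a], Xd[, b]),
                         numeric(1)))
      if (scheme == "MID") rel[a] - red else rel[a] / max(red, .Machine$double.eps)
    }, numeric(1))
    sel <- c(sel, avail[which.max(crit)])
  }
  colnames(X)[sel]
}

# Direct ReliefF weight evaluation: literal loop over instances, hits and
# prior-weighted misses on min-max-normalised features.
oracle_relieff <- function(X, y, n_neighbors) {
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
  Xn <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
  Xn[, rng[2, ] == rng[1, ]] <- 0
  prior <- table(y) / n
  W <- numeric(p)
  for (i in seq_len(n)) {
    d <- rowSums(abs(sweep(Xn, 2, Xn[i, ])))
    d[i] <- Inf
    hits <- order(ifelse(y == y[i], d, Inf))[seq_len(n_neighbors)]
    for (h in hits) W <- W - abs(Xn[h, ] - Xn[i, ]) / (n * n_neighbors)
    for (cl in setdiff(names(prior), y[i])) {
      miss <- order(ifelse(y == cl, d, Inf))[seq_len(n_neighbors)]
      wcl <- prior[[cl]] / (1 - prior[[y[i]]])
      for (m in miss) W <- W + wcl * abs(Xn[m, ] - Xn[i, ]) / (n * n_neighbors)
    }
  }
  W
}

# O(n^2) concordant/discordant pair counting with tie correction (tau-b).
oracle_kendall <- function(x, y) {
  n <- length(x)
  C <- D <- Tx <- Ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    else if (dx == 0) Tx <- Tx + 1
    else if (dy == 0) Ty <- Ty + 1
    else if (dx == dy) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + Tx) * (C + D + Ty))
}

# Brute-force rank AUC: fraction of (positive, negative) pairs ordered
# correctly, ties counted half.
oracle_auc <- function(x, positive) {
  xp <- x[positive]; xn <- x[!positive]
  (sum(outer(xp, xn, ">")) + 0.5 * sum(outer(xp, xn, "=="))) /
    (length(xp) * length(xn))
}
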