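# Canonical order of the ten preference indices.
INDEX_NAMES <- c("touchette_aw", "aw", "vamv_valence", "kirk_valence",
                 "ram12_valence", "ram15_valence", "choice_gamma",
                 "choice_beta", "effort_1", "effort_2")

#' Two-electrode band power
#'
#' Several indices take a band power over an electrode pair, e.g.
#' alpha(AF4, F4). The pair value is the arithmetic mean of the two
#' electrodes' band powers, which keeps log differences and power ratios
#' on the same scale as their single-electrode variants.
#'
#' @param bp A \code{band_power_table} (electrodes x bands).
#' @param band Band name: theta, alpha, beta or gamma.
#' @param pair Character vector of two electrode names.
#' @return Scalar power.
#' @examples
#' bp <- matrix(1:16, 4, 4, dimnames = list(c("AF3","F3","AF4","F4"),
#'              c("theta","alpha","beta","gamma")))
#' class(bp) <- c("band_power_table", "matrix")
#' pair_power(bp, "alpha", c("AF4", "F4"))
#' @export
pair_power <- function(bp, band, pair) {
  stopifnot(length(pair) == 2)
  if (!band %in% colnames(bp)) stop("unknown band: ", band)
  miss <- setdiff(pair, rownames(bp))
  if (length(miss)) stop("unknown electrode(s): ", paste(miss, collapse = ", "))
  mean(c(bp[pair[1], band], bp[pair[2], band]))
}

#' The ten frontal preference indices
#'
#' Computes, from the 4 x 4 frontal band-power table, the ten scalar
#' indices used to quantify a consumer's response to a stimulus:
#' \describe{
#'   \item{touchette_aw}{(alpha(F4) - alpha(F3)) / (alpha(F4) + alpha(F3)),
#'     the normalised frontal alpha asymmetry (approach/withdrawal).}
#'   \item{aw}{alpha(AF4, F4) - alpha(AF3, F3), the raw alpha asymmetry
#'     over the electrode pairs.}
#'   \item{vamv_valence}{beta(AF3, F3)/alpha(AF3, F3) -
#'     beta(AF4, F4)/alpha(AF4, F4), a beta/alpha-ratio valence score.}
#'   \item{kirk_valence}{ln alpha(AF3, F3) - ln alpha(AF4, F4).}
#'   \item{ram12_valence}{alpha(F4) - beta(F3).}
#'   \item{ram15_valence}{alpha(F4)/beta(F4) - alpha(F3)/beta(F3).}
#'   \item{choice_gamma}{(log gamma(AF3) - log gamma(AF4)) /
#'     (log gamma(AF3) + log gamma(AF4)), a frontal gamma log-asymmetry
#'     linked to choice likelihood.}
#'   \item{choice_beta}{the same ratio on the beta band.}
#'   \item{effort_1}{(theta(F4) - theta(F3)) / (theta(F4) + theta(F3)),
#'     normalised frontal theta asymmetry (cognitive effort).}
#'   \item{effort_2}{theta(AF4, F4) - theta(AF3, F3).}
#' }
#' Pair arguments use \code{\link{pair_power}}. The choice indices use the
#' natural logarithm; their ratio structure makes them invariant to the
#' log base. When a choice-index denominator is within 1e-9 of zero
#' (a band power crossing 1 flips the sign of its log) the value is still
#' returned but a warning is raised, as the index is unstable there.
#'
#' @param bp A \code{band_power_table} with strictly positive entries.
#' @return Named list of class \code{preference_indices} with the ten
#'   scalars, in the order given above.
#' @export
compute_indices <- function(bp) {
  need <- c("AF3", "F3", "AF4", "F4")
  miss <- setdiff(need, rownames(bp))
  if (length(miss)) stop("missing electrode(s): ", paste(miss, collapse = ", "))
  if (any(bp[need, ] <= 0))
    stop("band powers must be positive (upstream flooring failed)")
  L <- c("AF3", "F3"); R <- c("AF4", "F4")
  a_L <- pair_power(bp, "alpha", L); a_R <- pair_power(bp, "alpha", R)
  b_L <- pair_power(bp, "beta",  L); b_R <- pair_power(bp, "beta",  R)
  t_L <- pair_power(bp, "theta", L); t_R <- pair_power(bp, "theta", R)

  choice <- function(p_left, p_right) {
    num <- log(p_left) - log(p_right)
    den <- log(p_left) + log(p_right)
    if (abs(den) < 1e-9)
      warning("choice index denominator within 1e-9 of zero; ",
              "value is numerically unstable")
    num / den
  }

  out <- list(
    touchette_aw = (bp["F4", "alpha"] - bp["F3", "alpha"]) /
                   (bp["F4", "alpha"] + bp["F3", "alpha"]),
    aw = a_R - a_L,
    vamv_valence = b_L / a_L - b_R / a_R,
    kirk_valence = log(a_L) - log(a_R),
    ram12_valence = bp["F4", "alpha"] - bp["F3", "beta"],
    ram15_valence = bp["F4", "alpha"] / bp["F4", "beta"] -
                    bp["F3", "alpha"] / bp["F3", "beta"],
    choice_gamma = choice(bp["AF3", "gamma"], bp["AF4", "gamma"]),
    choice_beta = choice(bp["AF3", "beta"], bp["AF4", "beta"]),
    effort_1 = (bp["F4", "theta"] - bp["F3", "theta"]) /
               (bp["F4", "theta"] + bp["F3", "theta"]),
    effort_2 = t_R - t_L
  )
  structure(out, class = "preference_indices")
}

#' @export
print.preference_indices <- function(x, ...) {
  cat("Frontal preference indices:\n")
  for (nm in INDEX_NAMES) cat(sprintf("  %-14s %+.4f\n", nm, x[[nm]]))
  invisible(x)
}

#' Per-trial index table
#'
#' Computes the ten preference indices for every epoch in a set.
#'
#' @param epoch_set An \code{epoch_set}.
#' @return Data frame with \code{subject}, \code{trial}, \code{label} and
#'   the ten index columns, one row per epoch.
#' @export
index_table <- function(epoch_set) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  rows <- lapply(epoch_set$epochs, function(ep)
    unlist(compute_indices(band_power_table(ep))[INDEX_NAMES]))
  df <- data.frame(
    subject = vapply(epoch_set$epochs, `[[`, integer(1), "subject_id"),
    trial = vapply(epoch_set$epochs, `[[`, integer(1), "trial_id"),
    label = epoch_set$labels)
  cbind(df, as.data.frame(do.call(rbind, rows)))
}

#' Write a per-trial index table as delimited text
#'
#' @param tab Data frame from \code{\link{index_table}}.
#' @param file Output path (tab-separated).
#' @return Invisibly, \code{file}.
#' @export
write_index_table <- function(tab, file) {
  utils::write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
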