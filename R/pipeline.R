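PIPELINE_KEYS <- c("n_subjects", "n_trials_per_subject", "epoch_seconds",
                   "band_theta", "band_alpha", "band_beta", "band_gamma",
                   "asymmetry_effect", "pink_noise_sd", "subject_sd",
                   "seed", "blocks", "selectors", "k", "pca_components",
                   "classifiers", "train_fraction", "out_dir")

#' Pipeline configuration
#'
#' Validated configuration for \code{\link{run_pipeline}}. All stage
#' seeds are derived deterministically from the single master seed.
#'
#' @param out_dir Output directory (created if absent).
#' @param n_subjects,n_trials_per_subject,epoch_seconds,asymmetry_effect,pink_noise_sd,subject_sd
#'   Passed to \code{\link{synth_config}}.
#' @param band_amplitudes Per-band oscillation amplitudes.
#' @param blocks Feature blocks for \code{\link{extract_feature_table}}.
#' @param selectors Selector names for \code{\link{benchmark_grid}}.
#' @param k Features kept by name-selecting methods.
#' @param pca_components Components kept by PCA.
#' @param classifiers Classifier kinds to benchmark.
#' @param train_fraction Holdout training fraction.
#' @param seed Master seed.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir,
                            n_subjects = 25, n_trials_per_subject = 42,
                            epoch_seconds = 4,
                            band_amplitudes = c(theta = 4, alpha = 6,
                                                beta = 3, gamma = 1.5),
                            asymmetry_effect = 0.5, pink_noise_sd = 5,
                            subject_sd = 0.2,
                            blocks = c("psd", "psd_agg", "morlet", "hann",
                                       "indices"),
                            selectors = SELECTOR_KINDS,
                            k = 10, pca_components = 1,
                            classifiers = CLASSIFIER_KINDS,
                            train_fraction = 0.8, seed = 1L) {
  blocks <- match.arg(blocks, c("psd", "psd_agg", "morlet", "hann",
                                "indices"), several.ok = TRUE)
  selectors <- match.arg(selectors, SELECTOR_KINDS, several.ok = TRUE)
  classifiers <- match.arg(classifiers, CLASSIFIER_KINDS, several.ok = TRUE)
  synth <- synth_config(n_subjects = n_subjects,
                        n_trials_per_subject = n_trials_per_subject,
                        epoch_seconds = epoch_seconds,
                        band_amplitudes = band_amplitudes,
                        asymmetry_effect = asymmetry_effect,
                        pink_noise_sd = pink_noise_sd,
                        subject_sd = subject_sd,
                        seed = seed)
  structure(list(out_dir = out_dir, synth = synth, blocks = blocks,
                 selectors = selectors, k = k,
                 pca_components = pca_components,
                 classifiers = classifiers,
                 train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a key-value text file
#'
#' One \code{key = value} pair per line; \code{#} starts a comment.
#' List-valued keys (\code{blocks}, \code{selectors}, \code{classifiers})
#' take comma-separated values. Unknown keys are rejected.
#'
#' @param file Path to the configuration file.
#' @param out_dir Output directory, overriding any \code{out_dir} line.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(file, out_dir = NULL) {
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lines[vapply(kv, length, integer(1)) != 2]
  if (length(bad)) stop("malformed config line(s): ", paste(bad, collapse = "; "))
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, `[[`, character(1), 2)
  unknown <- setdiff(keys, PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys)) stop("duplicate config key(s)")
  g <- function(key, default) if (key %in% keys) vals[keys == key] else default
  num <- function(key, default) as.numeric(g(key, default))
  lst <- function(key, default)
    if (key %in% keys) trimws(strsplit(vals[keys == key], ",")[[1]]) else default
  amps <- c(theta = num("band_theta", 4), alpha = num("band_alpha", 6),
            beta = num("band_beta", 3), gamma = num("band_gamma", 1.5))
  pipeline_config(
    out_dir = if (is.null(out_dir)) g("out_dir", ".") else out_dir,
    n_subjects = num("n_subjects", 25),
    n_trials_per_subject = num("n_trials_per_subject", 42),
    epoch_seconds = num("epoch_seconds", 4),
    band_amplitudes = amps,
    asymmetry_effect = num("asymmetry_effect", 0.5),
    pink_noise_sd = num("pink_noise_sd", 5),
    subject_sd = num("subject_sd", 0.2),
    blocks = lst("blocks", c("psd", "psd_agg", "morlet", "hann", "indices")),
    selectors = lst("selectors", SELECTOR_KINDS),
    k = num("k", 10),
    pca_components = num("pca_components", 1),
    classifiers = lst("classifiers", CLASSIFIER_KINDS),
    train_fraction = num("train_fraction", 0.8),
    seed = as.integer(num("seed", 1)))
}

pipeline_log <- function(stage, t0) {
  message(sprintf("[eegpref] %-10s %.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full simulate-extract-select-classify pipeline
#'
#' Executes every stage in order and writes the artifact files into
#' \code{config$out_dir}: \code{epochs.tsv} + \code{labels.tsv} (raw
#' signals), \code{features.tsv} (trials x features), \code{indices.tsv}
#' (the ten per-trial preference indices), \code{selection_<method>.tsv}
#' for each name-selecting method, \code{importance.tsv} (ANOVA F and
#' Kendall tau of the top features), \code{benchmark.tsv} /
#' \code{benchmark_full.tsv} (the selector x classifier grid) and
#' \code{manifest.tsv} (package version, seeds and per-file checksums).
#' A rerun with an identical configuration reproduces every file
#' byte-for-byte.
#'
#' @param config A \code{pipeline_config}.
#' @param write_epochs_file Write the (large) long-format signal file
#'   (default TRUE).
#' @return Invisibly, a list with the in-memory stage outputs
#'   (\code{dataset}, \code{features}, \code{indices}, \code{selections},
#'   \code{importance}, \code{benchmark}) and \code{files}.
#' @export
run_pipeline <- function(config, write_epochs_file = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  t0 <- as.numeric(Sys.time())

  ds <- make_dataset(config$synth)
  if (write_epochs_file) {
    write_epochs(ds, path("epochs.tsv"), path("labels.tsv"))
    files <- c(files, path("epochs.tsv"), path("labels.tsv"))
  }
  pipeline_log("simulate", t0)

  ft <- extract_feature_table(ds, blocks = config$blocks)
  write_feature_table(ft, path("features.tsv"))
  files <- c(files, path("features.tsv"))
  pipeline_log("extract", t0)

  idx <- index_table(ds)
  write_index_table(idx, path("indices.tsv"))
  files <- c(files, path("indices.tsv"))
  pipeline_log("indices", t0)

  selections <- list()
  for (m in setdiff(config$selectors, c("none", "pca"))) {
    res <- switch(m,
      mrmr = mrmr_rank(ft, k = config$k),
      relieff = relieff_rank(ft, k = config$k,
                             n_neighbors = min(10, min(table(ft$labels)) - 1)),
      rfe = rfe_select(ft, n_select = config$k, seed = config$seed + 11L),
      importance = {
        imp <- rf_importance(ft, seed = config$seed + 12L)
        top <- order(-imp, seq_along(imp))[seq_len(min(config$k, length(imp)))]
        selection_result("rf_importance", names(imp)[top], imp[top],
                         config$k)
      })
    selections[[m]] <- res
    f <- path(sprintf("selection_%s.tsv", m))
    write_selection(res, f)
    files <- c(files, f)
  }
  pipeline_log("select", t0)

  top_names <- if (length(selections))
    selections[[1]]$selected else ft$feature_names[seq_len(min(10, ncol(ft$matrix)))]
  fstats <- anova_f(subset_table(ft, features = top_names))
  cm <- correlation_heatmap_table(ft, top_names)
  imp_df <- data.frame(feature = top_names, anova_f = fstats[top_names],
                       kendall_tau_label = cm[top_names, "label"])
  utils::write.table(imp_df, path("importance.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_correlation_matrix(cm, path("correlation_matrix.tsv"))
  files <- c(files, path("importance.tsv"), path("correlation_matrix.tsv"))
  pipeline_log("importance", t0)

  specs <- lapply(config$classifiers, classifier_spec,
                  seed = config$seed + 17L)
  grid <- benchmark_grid(ft, selectors = config$selectors, specs = specs,
                         k = config$k,
                         pca_components = config$pca_components,
                         train_fraction = config$train_fraction,
                         seed = config$seed + 23L)
  write_benchmark(grid, path("benchmark.tsv"))
  files <- c(files, path("benchmark.tsv"), path("benchmark_full.tsv"))
  pipeline_log("classify", t0)

  manifest <- data.frame(
    file = basename(files),
    md5 = vapply(files, function(f) as.character(tools::md5sum(f)),
                 character(1)),
    row.names = NULL)
  manifest <- rbind(
    data.frame(file = "package_version",
               md5 = as.character(utils::packageVersion("eegpref"))),
    data.frame(file = "master_seed", md5 = as.character(config$seed)),
    manifest)
  utils::write.table(manifest, path("manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  invisible(list(dataset = ds, features = ft, indices = idx,
                 selections = selections, importance = imp_df,
                 benchmark = grid, files = c(files, path("manifest.tsv"))))
}
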