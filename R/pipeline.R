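#' Pipeline run configuration
#'
#' Bundles the stage configurations of one reproducible run: cohort
#' simulation, epoching, complexity parameters, spectral bands, and the
#' significance level.  Fully serialized into the run manifest so a run
#' can be reproduced from the manifest alone.
#'
#' @param cohort A [cohort_config()].
#' @param epochs An [epoch_spec()].
#' @param k_max Higuchi delay bound.
#' @param sampen_m,sampen_r Sample-entropy template length and tolerance
#'   factor.
#' @param bands List of [band()] objects, or NULL to skip band power.
#' @param f_lo,f_hi Band-pass edges in Hz, used when \code{filter = TRUE}.
#' @param filter Apply the digital band-pass before epoching (default
#'   FALSE).  The synthetic recordings already emulate hardware-filtered
#'   acquisition, and complexity is conventionally computed on the
#'   broadband signal: re-filtering with a sharp 70 Hz low-pass leaves the
#'   1-8-sample scales probed by the Higuchi regression smooth and
#'   compresses every fractal dimension toward 1 (see the methods
#'   vignette), so the digital filter is an opt-in for imported raw data.
#' @param amplitude_limit Artifact-rejection threshold (NULL to skip).
#' @param aggregate Ensemble for the global ANOVA: "none" (every subject,
#'   epoch, channel value) or "electrodes" (channel-averaged per subject
#'   and epoch); see [ensemble_anova()].
#' @param alpha Significance level for all tests.
#' @param output_dir Directory for stage outputs (NULL: nothing written).
#' @return A \code{run_config} object.
#' @export
run_config <- function(cohort = default_cohort_config(),
                       epochs = epoch_spec(),
                       k_max = 8L, sampen_m = 2L, sampen_r = 0.15,
                       bands = default_bands(),
                       f_lo = 0.5, f_hi = 70, filter = FALSE,
                       amplitude_limit = NULL,
                       aggregate = c("none", "electrodes"),
                       alpha = 0.05, output_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(epochs, "epoch_spec"))
  aggregate <- match.arg(aggregate)
  if (alpha <= 0 || alpha >= 1) stop_param("alpha must be in (0, 1)")
  structure(list(cohort = cohort, epochs = epochs, k_max = k_max,
                 sampen_m = sampen_m, sampen_r = sampen_r, bands = bands,
                 f_lo = f_lo, f_hi = f_hi, filter = filter,
                 amplitude_limit = amplitude_limit, aggregate = aggregate,
                 alpha = alpha, output_dir = output_dir),
            class = "run_config")
}

#' Run the full pipeline: simulate, preprocess, features, statistics, PCA
#'
#' Processes the cohort subject by subject (simulate, filter, epoch,
#' reject, complexity and band-power features) so only the feature table
#' is retained in memory, then runs the statistical chain on the ensemble:
#' log10 normalization, global one-way ANOVA with Bonferroni post hoc per
#' measure, the same per electrode, and PCA of the (subject x epoch) by
#' (channel x measure) matrix.  Identical configurations produce
#' bit-identical outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return A \code{pipeline_result}: list with \code{features} (long
#'   table), \code{global} (per-measure ANOVA + post hoc on log10 values),
#'   \code{per_electrode}, \code{normality}, \code{pca}, \code{scatter_ratio},
#'   and \code{manifest} (counts, config echo, undefined/rejected tallies).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$output_dir)) {
    ok <- dir.exists(config$output_dir) ||
      dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || file.access(config$output_dir, 2) != 0)
      stop_param("configuration error: output_dir '%s' is not writable",
                 config$output_dir)
  }
  sizes <- vapply(config$cohort$groups, function(g) g$n_subjects,
                  numeric(1))
  total <- sum(sizes)
  feats <- vector("list", total)
  n_rejected <- 0L
  for (i in seq_len(total)) {
    rec <- generate_recording(config$cohort, i)
    if (config$filter)
      rec <- filter_recording(rec, config$f_lo, config$f_hi)
    eps <- extract_epochs(rec, config$epochs)
    if (!is.null(config$amplitude_limit)) {
      part <- reject_epochs(eps, config$amplitude_limit)
      n_rejected <- n_rejected + length(part$rejected)
      eps <- part$kept
    }
    tabs <- list(features_for_epochs(eps, config$k_max, config$sampen_m,
                                     config$sampen_r))
    if (!is.null(config$bands) && length(config$bands))
      tabs <- c(tabs, list(band_power_table(eps, config$bands)))
    feats[[i]] <- do.call(rbind, tabs)
    if (!quiet) message(sprintf("subject %d/%d (%s) done", i, total,
                                rec$subject_id))
  }
  features <- do.call(rbind, feats)
  n_undefined <- sum(!features$defined)

  cx_measures <- c("HFD", "SampEn")
  # log10 normalization needs positive values: undefined or exactly-zero
  # sample entropies are excluded listwise, with a tally in the manifest
  positive <- features$defined & features$value > 0
  n_nonpositive <- sum(features$defined & features$value <= 0 &
                         features$measure %in% cx_measures)
  stats_features <- features[!(features$measure %in% cx_measures) |
                               positive, , drop = FALSE]
  global <- list(); normality <- list()
  for (ms in cx_measures) {
    sub <- stats_features[stats_features$measure == ms, ]
    normality[[ms]] <- ks_normality(log10_normalize(sub$value))
    global[[ms]] <- ensemble_anova(sub, ms, aggregate = config$aggregate,
                                   log10_transform = TRUE,
                                   alpha = config$alpha,
                                   group_levels =
                                     names(config$cohort$groups))
  }
  per_electrode <- lapply(stats::setNames(cx_measures, cx_measures),
                          function(ms)
    per_electrode_anova(stats_features, ms, alpha = config$alpha,
                        log10_transform = TRUE))
  fm <- feature_matrix(features, measures = cx_measures)
  pca <- pca_top3(fm$matrix)
  scatter <- group_scatter_ratio(pca$scores, fm$groups)

  manifest <- list(
    n_recordings = total,
    n_epochs = nrow(features[features$measure == "HFD", ]),
    n_feature_rows = nrow(features),
    n_rejected_epochs = n_rejected,
    n_undefined_values = n_undefined,
    n_nonpositive_excluded = n_nonpositive,
    pca_dropped_observations = fm$dropped,
    seed = config$cohort$seed,
    alpha = config$alpha,
    aggregate = config$aggregate,
    groups = as.list(sizes),
    k_max = config$k_max, sampen_m = config$sampen_m,
    sampen_r = config$sampen_r,
    filter = config$filter,
    band = if (config$filter) c(config$f_lo, config$f_hi) else NULL,
    epoch_offsets = config$epochs$offsets,
    epoch_length = config$epochs$length,
    package_version = as.character(utils::packageVersion("neurocx")))

  res <- structure(list(features = features, global = global,
                        per_electrode = per_electrode,
                        normality = normality,
                        pca = pca, scatter_ratio = scatter,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_outputs(res, config)
  res
}

write_pipeline_outputs <- function(res, config) {
  od <- config$output_dir
  tsv <- function(df, name)
    utils::write.table(df, file.path(od, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  tsv(res$features, "features.tsv")
  glob <- do.call(rbind, lapply(names(res$global), function(ms) {
    a <- res$global[[ms]]$anova
    data.frame(measure = ms, F = a$F, df_between = a$df_between,
               df_within = a$df_within, p = a$p)
  }))
  tsv(glob, "anova_global.tsv")
  pe <- do.call(rbind, lapply(names(res$per_electrode), function(ms) {
    cbind(measure = ms, res$per_electrode[[ms]]$anova)
  }))
  tsv(pe, "anova_per_electrode.tsv")
  ph <- do.call(rbind, lapply(names(res$global), function(ms) {
    cbind(measure = ms, scope = "global", channel = NA,
          res$global[[ms]]$posthoc)
  }))
  ph2 <- do.call(rbind, lapply(names(res$per_electrode), function(ms) {
    p <- res$per_electrode[[ms]]$posthoc
    cbind(measure = ms, scope = "electrode",
          p[c("channel", setdiff(names(p), "channel"))])
  }))
  tsv(rbind(ph, ph2[names(ph)]), "posthoc.tsv")
  sc <- data.frame(res$pca$scores)
  tsv(sc, "pca_scores.tsv")
  jsonlite::write_json(
    list(explained_variance_ratio = res$pca$explained_variance_ratio,
         scatter_ratio = res$scatter_ratio,
         rank_deficient = res$pca$rank_deficient),
    file.path(od, "pca_summary.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(od)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d recordings, %d epochs, %d feature rows\n",
              x$manifest$n_recordings, x$manifest$n_epochs,
              x$manifest$n_feature_rows))
  for (ms in names(x$global)) {
    a <- x$global[[ms]]$anova
    cat(sprintf("  %s: F[%d,%d] = %.3f, p = %.3g; group means %s\n",
                ms, a$df_between, a$df_within, a$F, a$p,
                paste(sprintf("%s=%.4f", names(x$global[[ms]]$group_means),
                              x$global[[ms]]$group_means), collapse = " ")))
  }
  cat(sprintf("  PCA top-%d explained variance ratio %.3f, scatter ratio %.2f\n",
              ncol(x$pca$scores), x$pca$explained_variance_ratio,
              x$scatter_ratio))
  invisible(x)
}
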