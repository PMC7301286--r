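#' Base-10 log normalization
#'
#' Elementwise \code{log10}; the normalization applied to complexity values
#' before ANOVA so that their right-skewed distributions approach
#' normality.  Values must be strictly positive: undefined or zero sample
#' entropies have to be excluded (or offset) upstream.
#'
#' @param values Positive numeric vector.
#' @return \code{log10(values)}.
#' @export
log10_normalize <- function(values) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    stop_param("log10 normalization needs positive values; offending row(s): %s",
               paste(utils::head(bad, 5), collapse = ", "))
  log10(values)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic \eqn{D = \sup_x |F_{emp}(x) - \Phi((x-\mu)/\sigma)|}.
#' By default \eqn{\mu, \sigma} are estimated from the sample (Lilliefors
#' situation: the returned p-value is then anti-conservative and should be
#' read as a screening diagnostic only, which is how it is used here);
#' passing explicit \code{mean}/\code{sd} gives the classical fixed-reference
#' test.
#'
#' @param values Numeric sample.
#' @param mean,sd Optional reference parameters; estimated from the sample
#'   when NULL.
#' @return List with \code{D} and \code{p}.
#' @export
ks_normality <- function(values, mean = NULL, sd = NULL) {
  if (length(values) < 1) stop_param("empty sample")
  if (is.null(mean)) mean <- base::mean(values)
  if (is.null(sd)) {
    if (length(values) < 2 || stats::sd(values) == 0)
      stop_param("zero-variance sample: KS reference SD cannot be estimated")
    sd <- stats::sd(values)
  }
  if (sd <= 0) stop_param("reference sd must be positive")
  kt <- suppressWarnings(ks.test(values, "pnorm", mean, sd))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA from between/within sums of
#' squares, computed via [stats::oneway.test()] with equal variances
#' assumed.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return An \code{anova_result}: list with \code{F}, \code{df_between},
#'   \code{df_within}, \code{p}.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop_param("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop_param("every group needs >= 2 values (got sizes %s)",
               paste(sizes, collapse = ", "))
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), sizes))
  ow <- stats::oneway.test(values ~ fac, var.equal = TRUE)
  structure(list(F = unname(ow$statistic),
                 df_between = as.integer(unname(ow$parameter[1])),
                 df_within = as.integer(unname(ow$parameter[2])),
                 p = ow$p.value),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F[%d,%d] = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Bonferroni-corrected pairwise post hoc comparisons
#'
#' All \eqn{C(g, 2)} pairwise two-sample t tests with pooled variance; raw
#' p-values are multiplied by the number of comparisons and capped at 1.
#'
#' @param groups List of numeric vectors.
#' @param labels Group labels (defaults to names of \code{groups}).
#' @param alpha Significance level for the \code{significant} flag
#'   (default 0.05).
#' @return A data.frame (class \code{posthoc_table}) with one row per pair:
#'   \code{group1}, \code{group2}, \code{mean_difference}
#'   (\code{mean(group2) - mean(group1)}), \code{p_raw}, \code{p_adjusted},
#'   \code{significant}.
#' @export
bonferroni_posthoc <- function(groups, labels = names(groups),
                               alpha = 0.05) {
  if (length(groups) < 2) stop_param("need at least two groups")
  if (is.null(labels)) labels <- paste0("G", seq_along(groups))
  if (any(lengths(groups) < 2)) stop_param("every group needs >= 2 values")
  pairs <- utils::combn(length(groups), 2)
  n_comp <- ncol(pairs)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    tt <- t.test(groups[[i]], groups[[j]], var.equal = TRUE)
    data.frame(group1 = labels[i], group2 = labels[j],
               mean_difference = mean(groups[[j]]) - mean(groups[[i]]),
               p_raw = tt$p.value,
               p_adjusted = min(1, tt$p.value * n_comp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adjusted < alpha
  class(out) <- c("posthoc_table", "data.frame")
  out
}

#' Per-electrode ANOVA with post hoc contrasts
#'
#' Repeats the one-way ANOVA and Bonferroni post hoc independently for
#' every channel of a long-format feature table.  Each (subject, epoch)
#' value of the requested measure enters the per-channel ensemble.  Also
#' reports the set of channels for which all pairwise contrasts are
#' significant after correction -- the criterion used to mark electrodes
#' that fully separate the groups.
#'
#' @param feature_table Long-format data.frame (see
#'   [features_for_epochs()]).
#' @param measure Which measure to analyze (e.g. "HFD", "SampEn", or a
#'   band name).
#' @param alpha Significance level.
#' @param log10_transform Apply [log10_normalize()] to the values first
#'   (default FALSE; the pipeline does it once upstream).
#' @return List with \code{anova} (one row per channel: channel, F,
#'   df_between, df_within, p), \code{posthoc} (pairwise rows per channel),
#'   and \code{fully_significant_channels}.
#' @export
per_electrode_anova <- function(feature_table, measure, alpha = 0.05,
                                log10_transform = FALSE) {
  ft <- feature_table[feature_table$measure == measure &
                        feature_table$defined, , drop = FALSE]
  if (nrow(ft) == 0) stop_param("no defined rows for measure %s", measure)
  if (log10_transform) ft$value <- log10_normalize(ft$value)
  glabs <- unique(ft$group)
  miss <- character(0)
  channels <- unique(ft$channel)
  for (ch in channels) for (g in glabs)
    if (sum(ft$channel == ch & ft$group == g) < 2)
      miss <- c(miss, sprintf("%s/%s", ch, g))
  if (length(miss))
    stop_param("channel/group cells with < 2 values: %s",
               paste(miss, collapse = ", "))
  an_rows <- list(); ph_rows <- list()
  for (ch in channels) {
    sub <- ft[ft$channel == ch, ]
    grps <- split(sub$value, factor(sub$group, levels = glabs))
    a <- one_way_anova(grps)
    an_rows[[ch]] <- data.frame(channel = ch, F = a$F,
                                df_between = a$df_between,
                                df_within = a$df_within, p = a$p,
                                stringsAsFactors = FALSE)
    ph <- bonferroni_posthoc(grps, labels = glabs, alpha = alpha)
    ph$channel <- ch
    ph_rows[[ch]] <- ph
  }
  anova_tab <- do.call(rbind, an_rows)
  posthoc_tab <- do.call(rbind, ph_rows)
  rownames(anova_tab) <- rownames(posthoc_tab) <- NULL
  full <- vapply(channels, function(ch)
    all(posthoc_tab$significant[posthoc_tab$channel == ch]), logical(1))
  list(anova = anova_tab, posthoc = posthoc_tab,
       fully_significant_channels = channels[full])
}

#' Global ensemble ANOVA with selectable aggregation
#'
#' Runs the one-way group ANOVA plus Bonferroni post hoc on a measure's
#' ensemble.  With \code{aggregate = "none"} every (subject, epoch,
#' channel) value is one observation; with \code{aggregate = "electrodes"}
#' values are first averaged over channels within (subject, epoch), so a
#' 42-subject, 3-epoch cohort yields 126 units and a between/within df of
#' (2, 123).  Exactly which ensemble a published analysis used is often
#' recoverable only from its degrees of freedom, so both are exposed.
#'
#' @param feature_table Long-format feature data.frame.
#' @param measure Measure to analyze.
#' @param aggregate "none" or "electrodes".
#' @param log10_transform Apply [log10_normalize()] first.
#' @param alpha Significance level for the post hoc flags.
#' @param group_levels Optional group ordering (defaults to appearance
#'   order).
#' @return List with \code{anova}, \code{posthoc}, \code{group_means}
#'   (on the untransformed scale) and \code{n_units}.
#' @export
ensemble_anova <- function(feature_table, measure,
                           aggregate = c("none", "electrodes"),
                           log10_transform = FALSE, alpha = 0.05,
                           group_levels = NULL) {
  aggregate <- match.arg(aggregate)
  ft <- feature_table[feature_table$measure == measure &
                        feature_table$defined, , drop = FALSE]
  if (nrow(ft) == 0) stop_param("no defined rows for measure %s", measure)
  if (is.null(group_levels)) group_levels <- unique(ft$group)
  if (aggregate == "electrodes") {
    key <- interaction(ft$subject, ft$epoch, drop = TRUE)
    val <- tapply(ft$value, key, mean)
    grp <- tapply(ft$group, key, function(g) g[1])
    ft <- data.frame(value = as.numeric(val), group = as.character(grp),
                     stringsAsFactors = FALSE)
  }
  raw_groups <- split(ft$value, factor(ft$group, levels = group_levels))
  vals <- if (log10_transform) log10_normalize(ft$value) else ft$value
  groups <- split(vals, factor(ft$group, levels = group_levels))
  list(anova = one_way_anova(groups),
       posthoc = bonferroni_posthoc(groups, labels = names(groups),
                                    alpha = alpha),
       group_means = vapply(raw_groups, mean, numeric(1)),
       n_units = nrow(ft))
}

#' Principal components of the feature matrix
#'
#' Mean-centers the columns and eigendecomposes the sample covariance
#' matrix (via [stats::prcomp()], no scaling); keeps the leading
#' \code{n_components} (default 3).  The explained-variance ratio is the
#' ratio of the summed variances of the retained components to the summed
#' variances of the original variables,
#' \eqn{(\lambda_1+\lambda_2+\lambda_3)/\sum_i \lambda_i}.
#'
#' @param x Numeric matrix, observations x variables (>= 4 observations,
#'   >= 3 variables, no missing values).
#' @param n_components Components to keep (default 3).
#' @return A \code{pca_result}: list with \code{loadings} (variables x
#'   kept), \code{scores} (observations x kept),
#'   \code{explained_variance_ratio}, \code{rank_deficient} flag, and
#'   \code{sdev} (all component standard deviations).
#' @export
pca_top3 <- function(x, n_components = 3L) {
  x <- as.matrix(x)
  if (anyNA(x)) stop_param("feature matrix contains missing values")
  if (nrow(x) < 4) stop_param("need >= 4 observations")
  if (ncol(x) < n_components)
    stop_param("need >= %d variables", n_components)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  navail <- sum(pc$sdev > 1e-12 * pc$sdev[1])
  keep <- min(n_components, navail)
  rank_def <- keep < n_components
  if (rank_def)
    warning(sprintf("rank %d < %d requested components; ratio uses %d",
                    navail, n_components, keep))
  idx <- seq_len(keep)
  structure(list(loadings = pc$rotation[, idx, drop = FALSE],
                 scores = pc$x[, idx, drop = FALSE],
                 explained_variance_ratio =
                   sum(pc$sdev[idx]^2) / sum(pc$sdev^2),
                 rank_deficient = rank_def,
                 sdev = pc$sdev),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components, explained variance ratio %.3f\n",
              ncol(x$scores), x$explained_variance_ratio))
  invisible(x)
}

#' Between/within group scatter ratio of PCA scores
#'
#' Quantifies group separability in a score space: ratio of the
#' between-group scatter (per degree of freedom) to the within-group
#' scatter (per degree of freedom), i.e. a multivariate pseudo-F on the
#' traces of the scatter matrices.  Values above 1 mean group centroids
#' are farther apart than the within-group spread.
#'
#' @param scores Numeric matrix, observations x dimensions.
#' @param groups Group label per observation.
#' @return Scalar ratio.
#' @export
group_scatter_ratio <- function(scores, groups) {
  scores <- as.matrix(scores)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_param("need >= 2 groups")
  mu <- colMeans(scores)
  between <- 0; within <- 0
  for (g in levels(groups)) {
    sg <- scores[groups == g, , drop = FALSE]
    mg <- colMeans(sg)
    between <- between + nrow(sg) * sum((mg - mu)^2)
    within <- within + sum(sweep(sg, 2, mg)^2)
  }
  (between / (nlevels(groups) - 1)) /
    (within / (nrow(scores) - nlevels(groups)))
}

#' Wide feature matrix for PCA
#'
#' Reshapes the long feature table into observations = (subject, epoch)
#' rows and variables = (channel, measure) columns.  Rows with any
#' undefined cell are dropped listwise.
#'
#' @param feature_table Long-format feature data.frame.
#' @param measures Measures to include (default HFD and SampEn).
#' @return List with \code{matrix} (numeric), \code{groups} (label per
#'   row), and \code{dropped} (number of incomplete observations removed).
#' @export
feature_matrix <- function(feature_table,
                           measures = c("HFD", "SampEn")) {
  ft <- feature_table[feature_table$measure %in% measures, , drop = FALSE]
  ft$value[!ft$defined] <- NA_real_
  obs <- interaction(ft$subject, ft$epoch, drop = TRUE)
  var <- interaction(ft$channel, ft$measure, drop = TRUE)
  mat <- tapply(ft$value, list(obs, var), function(v) v[1])
  grp <- tapply(ft$group, obs, function(g) g[1])
  ok <- stats::complete.cases(mat)
  list(matrix = mat[ok, , drop = FALSE],
       groups = as.character(grp[ok]),
       dropped = sum(!ok))
}
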