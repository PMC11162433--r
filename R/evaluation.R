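# Stratification-aware evaluation: CV planners, intra-country correlation,
# replicate-based noise ceiling, Simpson's-paradox diagnostics and the
# country-classification metrics.

#' Build a cross-validation plan
#'
#' * `"random-kfold"`: seeded random assignment to k near-equal folds.
#' * `"country-stratified"`: whole countries are assigned to folds greedily
#'   (largest country first, to the currently smallest fold); no country
#'   ever spans two folds.
#' * `"tl-leakage-safe"`: random k-fold where, by contract, the
#'   pretraining-task (T1) training set of each fold equals the target-task
#'   training set — test samples appear in neither, preventing leakage
#'   from T1 to T2.
#'
#' @param samples sample ids.
#' @param mode plan mode (above).
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @param countries country label per sample (required for stratified mode).
#' @return A `cv_plan`: data.frame mapping sample to fold, plus mode/k/seed.
#' @export
make_cv_plan <- function(samples,
                         mode = c("random-kfold", "country-stratified",
                                  "tl-leakage-safe"),
                         k = 5L, seed = 1L, countries = NULL) {
  mode <- match.arg(mode)
  samples <- as.character(samples)
  n <- length(samples)
  if (n < k) stop("fewer samples (", n, ") than folds (", k, ")")
  fold <- integer(n)
  if (mode == "country-stratified") {
    if (is.null(countries)) stop("country labels required for stratified mode")
    countries <- as.character(countries)
    tab <- sort(table(countries), decreasing = TRUE)
    if (length(tab) < k) {
      stop("fewer countries (", length(tab), ") than folds (", k, ")")
    }
    sizes <- rep(0L, k)
    assign_c <- integer(length(tab))
    names(assign_c) <- names(tab)
    for (ci in seq_along(tab)) {
      f <- which.min(sizes)
      assign_c[ci] <- f
      sizes[f] <- sizes[f] + tab[ci]
    }
    fold <- assign_c[countries]
  } else {
    fold <- with_private_rng(seed, {
      rep_len(seq_len(k), n)[sample.int(n)]
    })
  }
  structure(list(assignment = data.frame(sample = samples,
                                         fold = as.integer(fold),
                                         stringsAsFactors = FALSE),
                 mode = mode, k = as.integer(k), seed = as.integer(seed)),
            class = "cv_plan")
}

#' Train/test (and T1-pretraining) sample sets of one fold
#'
#' @param plan a `cv_plan`.
#' @param fold fold index in 1..k.
#' @return list with `train`, `test` and `t1_train` id vectors (`t1_train`
#'   equals `train` under the leakage-safe contract, NULL otherwise).
#' @export
plan_sets <- function(plan, fold) {
  a <- plan$assignment
  test <- a$sample[a$fold == fold]
  train <- a$sample[a$fold != fold]
  list(train = train, test = test,
       t1_train = if (plan$mode == "tl-leakage-safe") train else NULL)
}

pearson_vec <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

col_pearson <- function(pred, obs) {
  vapply(seq_len(ncol(pred)),
         function(j) pearson_vec(pred[, j], obs[, j]), numeric(1))
}

#' Intra-country Pearson correlations
#'
#' Per-task Pearson correlation of predictions vs observations within each
#' country holding more than `min_n` samples, plus the unweighted mean over
#' included countries per task.  Countries whose correlation is undefined
#' (zero variance) are excluded from the mean with a warning.
#'
#' @param pred,obs aligned N x T matrices.
#' @param countries country label per sample.
#' @param min_n inclusion threshold: a country must have strictly more than
#'   `min_n` samples (default 50, the studied cutoff).
#' @return list with `per_country` (data.frame: country, task, n, r) and
#'   `mean_r` (named per-task vector).
#' @export
intra_country_pearson <- function(pred, obs, countries, min_n = 50) {
  pred <- as.matrix(pred); obs <- as.matrix(obs)
  stopifnot(nrow(pred) == nrow(obs), ncol(pred) == ncol(obs),
            nrow(pred) == length(countries))
  tasks <- colnames(obs)
  if (is.null(tasks)) tasks <- paste0("task", seq_len(ncol(obs)))
  tab <- table(countries)
  keep <- names(tab)[tab > min_n]
  if (!length(keep)) {
    warning("no country exceeds min_n = ", min_n, " samples")
    return(list(per_country = data.frame(country = character(0),
                                         task = character(0),
                                         n = integer(0), r = numeric(0)),
                mean_r = stats::setNames(rep(NA_real_, length(tasks)), tasks)))
  }
  rows <- list()
  for (co in keep) {
    idx <- which(countries == co)
    r <- col_pearson(pred[idx, , drop = FALSE], obs[idx, , drop = FALSE])
    rows[[co]] <- data.frame(country = co, task = tasks,
                             n = length(idx), r = r,
                             stringsAsFactors = FALSE)
  }
  per_country <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (anyNA(per_country$r)) {
    warning("excluding ", sum(is.na(per_country$r)),
            " country/task cells with undefined correlation from the mean")
  }
  mean_r <- tapply(per_country$r, factor(per_country$task, levels = tasks),
                   function(r) mean(r, na.rm = TRUE))
  list(per_country = per_country,
       mean_r = stats::setNames(as.numeric(mean_r), tasks))
}

#' Pooled (global) Pearson correlation per task
#'
#' Correlation over all samples pooled, ignoring grouping — the score that
#' between-country differences can inflate.
#'
#' @param pred,obs aligned N x T matrices.
#' @return named per-task vector (NA where variance is zero).
#' @export
global_pool_pearson <- function(pred, obs) {
  pred <- as.matrix(pred); obs <- as.matrix(obs)
  stopifnot(nrow(pred) == nrow(obs), nrow(pred) >= 2)
  r <- col_pearson(pred, obs)
  names(r) <- task_names(obs)
  r
}

task_names <- function(m) {
  if (is.null(colnames(m))) paste0("task", seq_len(ncol(m))) else colnames(m)
}

#' Noise ceiling on Pearson correlation from replicate measurements
#'
#' Labels carrying measurement error cap the attainable correlation.  With
#' per-sample replicates, the error variance of a replicate-mean label is
#' estimated as the mean over samples of `var(replicates)/R_i` (each
#' sample's own replicate count), the signal variance as the variance of
#' replicate means minus that error variance (floored at 0), and the bound
#' as `sqrt(sig / (sig + err))`.
#'
#' @param reps N x R matrix of replicate measurements for one task (NA for
#'   missing replicate slots).
#' @param labels_are_means if TRUE (default) labels are replicate means, so
#'   the error variance is divided by the replicate count; FALSE treats a
#'   single replicate as the label.
#' @return the bound in \[0, 1\] (NA if fewer than 2 samples have >= 2
#'   replicates).
#' @export
pearson_upper_bound <- function(reps, labels_are_means = TRUE) {
  reps <- as.matrix(reps)
  r_i <- rowSums(!is.na(reps))
  use <- r_i >= 2
  if (sum(use) < 2) {
    warning("need >= 2 replicates for >= 2 samples; bound undefined")
    return(NA_real_)
  }
  v_i <- apply(reps[use, , drop = FALSE], 1, stats::var, na.rm = TRUE)
  err <- if (labels_are_means) mean(v_i / r_i[use]) else mean(v_i)
  means <- rowMeans(reps[use, , drop = FALSE], na.rm = TRUE)
  sig <- max(stats::var(means) - err, 0)
  if (sig + err == 0) return(1)
  sqrt(sig / (sig + err))
}

#' Simpson's-paradox diagnostic
#'
#' Contrasts the pooled correlation with the mean intra-group correlation
#' per task and flags tasks whose gap exceeds `flag_gap` as
#' stratification-inflated: good pooled scores driven by between-group
#' level differences rather than within-group signal.
#'
#' @param pred,obs aligned N x T matrices.
#' @param groups group label per sample (>= 2 groups for a meaningful gap).
#' @param flag_gap gap threshold for flagging (default 0.3).
#' @param min_n per-group inclusion threshold passed to
#'   [intra_country_pearson()]; defaults to 1 so every group counts.
#' @return data.frame: task, global_r, intra_r, gap, flagged.
#' @export
simpson_diagnostic <- function(pred, obs, groups, flag_gap = 0.3, min_n = 1) {
  pred <- as.matrix(pred); obs <- as.matrix(obs)
  glob <- global_pool_pearson(pred, obs)
  if (length(unique(groups)) < 2) {
    intra <- glob   # single group: intra == global, gap 0 by definition
  } else {
    intra <- suppressWarnings(
      intra_country_pearson(pred, obs, groups, min_n = min_n)$mean_r)
  }
  gap <- glob - intra
  data.frame(task = names(glob), global_r = as.numeric(glob),
             intra_r = as.numeric(intra), gap = as.numeric(gap),
             flagged = !is.na(gap) & gap > flag_gap,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Macro F1 and multi-class Matthews correlation from a confusion matrix
#'
#' Rows are true classes, columns predicted.  Macro F1 averages per-class
#' F1 (classes never predicted and never occurring get F1 = 0); the MCC is
#' the generalized (multi-class) correlation of the confusion matrix.
#'
#' @param confusion K x K non-negative count matrix.
#' @return list with `macro_f1` and `mcc`.
#' @export
classification_metrics <- function(confusion) {
  m <- as.matrix(confusion)
  if (length(m) == 0 || sum(m) == 0) stop("empty confusion matrix")
  if (nrow(m) != ncol(m) || nrow(m) < 2) stop("need a square K x K matrix, K >= 2")
  if (any(m < 0)) stop("negative counts")
  tp <- diag(m)
  rowt <- rowSums(m)   # true class totals
  colt <- colSums(m)   # predicted class totals
  prec <- ifelse(colt > 0, tp / colt, 0)
  rec <- ifelse(rowt > 0, tp / rowt, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  n <- sum(m)
  cov_yp <- n * sum(tp) - sum(rowt * colt)
  cov_yy <- n^2 - sum(rowt^2)
  cov_pp <- n^2 - sum(colt^2)
  mcc <- if (cov_yy == 0 || cov_pp == 0) 0 else cov_yp / sqrt(cov_yy * cov_pp)
  list(macro_f1 = mean(f1), mcc = mcc)
}

#' Evaluate predictions into a full report
#'
#' Bundles intra-country correlations, pooled correlations, the Simpson
#' diagnostic and (when replicates are provided) the per-task noise
#' ceiling into one `evaluation_report`.
#'
#' @param pred,obs aligned N x T matrices.
#' @param countries country label per sample.
#' @param replicates optional N x T x R array of replicate measurements.
#' @param min_n country inclusion threshold (strictly greater than).
#' @param model_id free-text model identifier.
#' @param flag_gap Simpson flag threshold.
#' @return An `evaluation_report`.
#' @export
evaluate_predictions <- function(pred, obs, countries, replicates = NULL,
                                 min_n = 50, model_id = "model",
                                 flag_gap = 0.3) {
  pred <- as.matrix(pred); obs <- as.matrix(obs)
  intra <- intra_country_pearson(pred, obs, countries, min_n = min_n)
  glob <- global_pool_pearson(pred, obs)
  simpson <- simpson_diagnostic(pred, obs, countries, flag_gap = flag_gap,
                                min_n = min_n)
  bounds <- NULL
  if (!is.null(replicates)) {
    bounds <- vapply(seq_len(dim(replicates)[2]), function(j)
      pearson_upper_bound(replicates[, j, ]), numeric(1))
    names(bounds) <- colnames(obs)
  }
  structure(list(model_id = model_id, per_country = intra$per_country,
                 intra_mean_r = intra$mean_r, global_r = glob,
                 upper_bound = bounds, simpson = simpson, min_n = min_n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report for '", x$model_id, "'\n", sep = "")
  cat(sprintf("  mean intra-country r (over tasks): %.4f\n",
              mean(x$intra_mean_r, na.rm = TRUE)))
  cat(sprintf("  mean pooled r (over tasks):        %.4f\n",
              mean(x$global_r, na.rm = TRUE)))
  if (!is.null(x$upper_bound)) {
    cat(sprintf("  mean noise ceiling:                %.4f\n",
                mean(x$upper_bound, na.rm = TRUE)))
  }
  if (any(x$simpson$flagged)) {
    cat("  stratification-inflated tasks: ",
        paste(x$simpson$task[x$simpson$flagged], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Express correlations as a percentage of the noise ceiling
#'
#' Adds `pct_of_bound = 100 * r / bound` per task to a report.  Tasks
#' exceeding the bound are flagged, not clipped (crossings are expected by
#' chance when predictions approach the ceiling); a zero bound leaves the
#' percentage undefined and flagged.
#'
#' @param report an `evaluation_report` with bounds present.
#' @return the report with a `contextual` data.frame added.
#' @export
contextualize <- function(report) {
  if (is.null(report$upper_bound)) stop("report carries no upper bounds")
  r <- report$intra_mean_r
  b <- report$upper_bound
  pct <- ifelse(b > 0, 100 * r / b, NA_real_)
  report$contextual <- data.frame(
    task = names(r), r = as.numeric(r), bound = as.numeric(b),
    pct_of_bound = as.numeric(pct),
    exceeds_bound = !is.na(pct) & pct > 100,
    zero_bound = b == 0,
    stringsAsFactors = FALSE, row.names = NULL)
  report
}

#' Paired model comparison over (task, country) correlations
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-country, per-task
#' correlations of two reports (a pragmatic substitute where no specific
#' test is mandated).
#'
#' @param report_a,report_b two `evaluation_report`s on the same data.
#' @return the `htest` object.
#' @export
compare_models <- function(report_a, report_b) {
  a <- report_a$per_country
  b <- report_b$per_country
  key <- function(d) paste(d$country, d$task)
  common <- intersect(key(a), key(b))
  stats::wilcox.test(a$r[match(common, key(a))],
                     b$r[match(common, key(b))],
                     paired = TRUE, exact = FALSE)
}
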