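# Plain-text table IO for phenotypes, replicate measurements and reports.

#' Write / read a phenotype + metadata table
#'
#' CSV with columns `sample`, `country`, `lat`, `lon`, then one column per
#' element-by-tissue task.
#'
#' @param phenotypes data.frame in that layout.
#' @param path file path.
#' @return the path (write) or the data.frame (read).
#' @export
write_phenotype_csv <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_csv
#' @export
read_phenotype_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read replicate measurements (long CSV)
#'
#' Long format: `sample`, `task`, `replicate`, `value`.  The array form is
#' N samples x T tasks x R replicate slots, NA for missing slots.
#'
#' @param replicates N x T x R array with dimnames on the first two axes.
#' @param path file path.
#' @return the path (write) or the array (read).
#' @export
write_replicates_csv <- function(replicates, path) {
  d <- dim(replicates)
  df <- data.frame(
    sample = rep(dimnames(replicates)[[1]], times = d[2] * d[3]),
    task = rep(rep(dimnames(replicates)[[2]], each = d[1]), times = d[3]),
    replicate = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(replicates))
  df <- df[!is.na(df$value), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_replicates_csv
#' @export
read_replicates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  samples <- unique(df$sample)
  tasks <- unique(df$task)
  r_max <- max(df$replicate)
  arr <- array(NA_real_, c(length(samples), length(tasks), r_max),
               dimnames = list(samples, tasks, NULL))
  arr[cbind(match(df$sample, samples), match(df$task, tasks), df$replicate)] <-
    df$value
  arr
}

#' Write an evaluation report to CSV + JSON
#'
#' @param report an `evaluation_report`.
#' @param prefix path prefix; writes `<prefix>_per_country.csv`,
#'   `<prefix>_summary.csv` and `<prefix>.json`.
#' @return the prefix, invisibly.
#' @export
write_report <- function(report, prefix) {
  utils::write.csv(report$per_country, paste0(prefix, "_per_country.csv"),
                   row.names = FALSE)
  summ <- data.frame(task = names(report$intra_mean_r),
                     intra_mean_r = as.numeric(report$intra_mean_r),
                     global_r = as.numeric(report$global_r))
  if (!is.null(report$upper_bound)) {
    summ$upper_bound <- as.numeric(report$upper_bound)
  }
  utils::write.csv(summ, paste0(prefix, "_summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(model_id = report$model_id, min_n = report$min_n,
         intra_mean_r = as.list(report$intra_mean_r),
         global_r = as.list(report$global_r),
         upper_bound = if (is.null(report$upper_bound)) NULL
                       else as.list(report$upper_bound),
         simpson = report$simpson),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}
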