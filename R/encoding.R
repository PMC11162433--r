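# Gene-centric encoding of annotated variant tables: per sample and gene, a
# 17-bin histogram over variant types, with MAF filtering and the three
# studied standardization dialects.

#' The fixed 17-label variant-type vocabulary
#'
#' Ordered labels of the variant types assigned by region/effect annotation
#' of whole-genome variants.  The index/label bijection is fixed: position
#' `t` of every gene histogram always refers to `variant_vocabulary()[t]`.
#'
#' @return character vector of length 17.
#' @export
variant_vocabulary <- function() {
  c("nonsynonymous",
    "nonframeshift_insertion",
    "nonframeshift_deletion",
    "stoploss",
    "frameshift_insertion",
    "frameshift_deletion",
    "UTR3",
    "UTR5",
    "ncRNA_exonic",
    "ncRNA_intronic",
    "upstream",
    "downstream",
    "intergenic",
    "intronic",
    "splicing",
    "ncRNA_splicing",
    "stopgain")
}

#' Annotated variant table
#'
#' Long-format table of carried variants: one record per (sample, gene,
#' variant type) occurrence, with an optional `variant_id` identifying the
#' genomic site (needed for MAF filtering).  The sample and gene universes
#' are carried explicitly so samples or genes without any variant still
#' yield all-zero rows.
#'
#' @param records data.frame with columns `sample`, `gene`, `variant_type`
#'   and optionally `variant_id`.
#' @param genes ordered gene universe.
#' @param samples ordered sample universe; defaults to samples observed.
#' @return A `variant_table`.
#' @export
variant_table <- function(records, genes, samples = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("sample", "gene", "variant_type")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  genes <- as.character(genes)
  if (length(genes) == 0) stop("gene universe is empty")
  if (is.null(samples)) samples <- unique(as.character(records$sample))
  samples <- as.character(samples)
  vocab <- variant_vocabulary()
  bad_t <- setdiff(unique(as.character(records$variant_type)), vocab)
  if (length(bad_t)) {
    stop("unknown variant-type label(s): ", paste(bad_t, collapse = ", "))
  }
  bad_g <- setdiff(unique(as.character(records$gene)), genes)
  if (length(bad_g)) {
    stop("gene id(s) outside the gene universe: ",
         paste(utils::head(bad_g, 5), collapse = ", "))
  }
  bad_s <- setdiff(unique(as.character(records$sample)), samples)
  if (length(bad_s)) {
    stop("sample id(s) outside the sample universe: ",
         paste(utils::head(bad_s, 5), collapse = ", "))
  }
  structure(list(records = records, genes = genes, samples = samples),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d records, %d samples, %d genes\n",
              nrow(x$records), length(x$samples), length(x$genes)))
  invisible(x)
}

#' Read an annotated variant table (long TSV)
#'
#' Expects a tab-separated file with columns `sample`, `gene`,
#' `variant_type` and optionally `variant_id` (the long export of a
#' multianno-style annotation).
#'
#' @param path file path.
#' @param genes gene universe; defaults to genes observed in the file.
#' @param samples sample universe; defaults to samples observed.
#' @return A [variant_table()].
#' @export
read_variant_table <- function(path, genes = NULL, samples = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(genes)) genes <- unique(df$gene)
  variant_table(df, genes, samples)
}

#' Write an annotated variant table to TSV
#' @param table a [variant_table()].
#' @param path output file.
#' @export
write_variant_table <- function(table, path) {
  utils::write.table(table$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Encode variants into the gene-centric count tensor
#'
#' Counts, for every sample and gene, the occurrences of each of the 17
#' variant types, yielding an N x G x 17 array in raw (integer-count)
#' state.  Counting is order-invariant and conserves the number of records
#' per sample.
#'
#' @param table a [variant_table()].
#' @return A `gene_mutation_tensor` in `"raw"` state.
#' @export
encode_variants <- function(table) {
  stopifnot(inherits(table, "variant_table"))
  n <- length(table$samples)
  g <- length(table$genes)
  vocab <- variant_vocabulary()
  tv <- length(vocab)
  vals <- array(0, dim = c(n, g, tv),
                dimnames = list(table$samples, table$genes, vocab))
  if (nrow(table$records)) {
    si <- match(as.character(table$records$sample), table$samples)
    gi <- match(as.character(table$records$gene), table$genes)
    ti <- match(as.character(table$records$variant_type), vocab)
    lin <- si + n * (gi - 1L) + n * g * (ti - 1L)
    tab <- tabulate(lin, nbins = n * g * tv)
    vals[] <- tab
  }
  new_gene_mutation_tensor(vals, state = "raw")
}

new_gene_mutation_tensor <- function(values, state, std_params = NULL) {
  structure(list(values = values, state = state, std_params = std_params),
            class = "gene_mutation_tensor")
}

#' @export
print.gene_mutation_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("gene_mutation_tensor: %d samples x %d genes x %d types, state=%s\n",
              d[1], d[2], d[3], x$state))
  invisible(x)
}

#' @export
dim.gene_mutation_tensor <- function(x) dim(x$values)

#' Minor-carrier-frequency variant filter
#'
#' Removes variant sites whose carrier frequency, folded to the minor side
#' (`min(f, 1 - f)` with `f` = carriers / samples), is at or below the
#' threshold.  Presence/absence carrier counting is used rather than
#' diploid dosage (appropriate for a selfing, near-homozygous organism).
#' Records must carry a `variant_id` column identifying sites.
#'
#' @param table a [variant_table()] whose records have `variant_id`.
#' @param threshold folded-frequency cutoff in \[0, 0.5\].
#' @return The filtered [variant_table()] (same universes).
#' @export
maf_filter <- function(table, threshold) {
  stopifnot(inherits(table, "variant_table"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 0.5) {
    stop("MAF threshold must be a single value in [0, 0.5]")
  }
  if (length(table$samples) < 1) stop("need at least one sample")
  rec <- table$records
  if (!nrow(rec)) return(table)
  if (is.null(rec$variant_id)) {
    stop("maf_filter requires a 'variant_id' column identifying sites")
  }
  n <- length(table$samples)
  carriers <- tapply(as.character(rec$sample), as.character(rec$variant_id),
                     function(s) length(unique(s)))
  f <- carriers / n
  folded <- pmin(f, 1 - f)
  drop_ids <- names(folded)[folded <= threshold]
  keep <- !(as.character(rec$variant_id) %in% drop_ids)
  variant_table(rec[keep, , drop = FALSE], table$genes, table$samples)
}

#' Standardize an encoded tensor
#'
#' Three dialects:
#' * `"global-z"`: each of the G x 17 feature positions is z-scored with
#'   mean/sd estimated on `fit_on` (default: all samples).  Zero-variance
#'   features map to 0.  The fitted transform is stored so it can be
#'   applied to held-out samples with [apply_standardization()].
#' * `"per-gene-frequency"`: each (sample, gene) 17-vector is divided by
#'   its own sum, so nonzero rows sum to 1; all-zero rows stay all-zero.
#' * `"none"`: identity.
#'
#' Fitting on the full dataset (the default here) mirrors the original
#' study but leaks test-set moments; pipeline drivers fit on the training
#' split unless their `paper_compat` flag is set.
#'
#' @param tensor a raw `gene_mutation_tensor`.
#' @param mode `"global-z"`, `"per-gene-frequency"` or `"none"`.
#' @param fit_on sample ids or indices used to estimate the moments
#'   (global-z only); default all samples.
#' @return A standardized `gene_mutation_tensor`.
#' @export
standardize <- function(tensor, mode = c("global-z", "per-gene-frequency", "none"),
                        fit_on = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(tensor, "gene_mutation_tensor"))
  if (tensor$state != "raw") {
    stop("tensor is already standardized (state = '", tensor$state,
         "'); re-standardization is not allowed")
  }
  if (mode == "none") return(tensor)
  v <- tensor$values
  d <- dim(v)
  if (mode == "per-gene-frequency") {
    tot <- rowSums(v, dims = 2)            # N x G totals over types
    scl <- ifelse(tot > 0, 1 / tot, 0)
    out <- v * as.vector(scl)              # recycles over the type axis
    return(new_gene_mutation_tensor(out, "per-gene-frequency"))
  }
  # global-z
  if (is.null(fit_on)) {
    idx <- seq_len(d[1])
  } else if (is.character(fit_on)) {
    idx <- match(fit_on, dimnames(v)[[1]])
    if (anyNA(idx)) stop("fit_on contains unknown sample ids")
  } else {
    idx <- as.integer(fit_on)
  }
  m <- matrix(v[idx, , , drop = FALSE], nrow = length(idx))
  mu <- colMeans(m)
  sdv <- sqrt(colMeans(m^2) - mu^2)        # population sd over fit subset
  params <- list(mu = mu, sd = sdv)
  new_gene_mutation_tensor(apply_z(v, params), "global-z", std_params = params)
}

apply_z <- function(v, params) {
  d <- dim(v)
  m <- matrix(v, nrow = d[1])
  scl <- ifelse(params$sd > 0, 1 / params$sd, 0)
  m <- sweep(m, 2, params$mu, "-")
  m <- sweep(m, 2, scl, "*")
  m[, params$sd == 0] <- 0
  array(m, d, dimnames = dimnames(v))
}

#' Apply a previously fitted global-z transform
#'
#' Applies the affine per-feature map stored by [standardize()] (fitted on
#' one sample subset) to another raw tensor over the same genes — the
#' leakage-safe way to standardize held-out data.
#'
#' @param tensor a raw `gene_mutation_tensor`.
#' @param params the `std_params` of a global-z standardized tensor.
#' @return A `gene_mutation_tensor` in `"global-z"` state.
#' @export
apply_standardization <- function(tensor, params) {
  stopifnot(inherits(tensor, "gene_mutation_tensor"))
  if (tensor$state != "raw") {
    stop("tensor is already standardized (state = '", tensor$state, "')")
  }
  if (length(params$mu) != prod(dim(tensor$values)[-1])) {
    stop("standardization parameters do not match tensor shape")
  }
  new_gene_mutation_tensor(apply_z(tensor$values, params), "global-z",
                           std_params = params)
}

#' Write / read an encoded tensor
#'
#' The tensor values go to `<prefix>.bin` as little-endian doubles in
#' column-major order; `<prefix>.json` records the shape, sample ids, gene
#' ids, vocabulary, standardization state and parameters.
#'
#' @param tensor a `gene_mutation_tensor`.
#' @param prefix path prefix for the two files.
#' @return The prefix, invisibly.
#' @export
write_tensor <- function(tensor, prefix) {
  v <- tensor$values
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(v), con, size = 8, endian = "little")
  meta <- list(dim = dim(v),
               samples = dimnames(v)[[1]], genes = dimnames(v)[[2]],
               vocabulary = dimnames(v)[[3]], state = tensor$state,
               std_params = tensor$std_params)
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = 8, endian = "little")
  vals <- array(v, meta$dim,
                dimnames = list(meta$samples, meta$genes, meta$vocabulary))
  sp <- meta$std_params
  if (!is.null(sp) && length(sp) == 0) sp <- NULL
  new_gene_mutation_tensor(vals, meta$state, std_params = sp)
}
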