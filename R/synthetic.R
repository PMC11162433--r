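# Synthetic country-structured genotype/phenotype generator.  Emulates the
# statistical structure the pipeline assumes — Poisson variant-type counts
# with country-shifted rates, phenotypes mixing genetic, country and noise
# components, replicate measurements, clustered GPS coordinates and a
# gene-to-pathway map — so every stage is testable without downloads.

#' Synthetic dataset configuration
#'
#' Defaults describe the scaled-down analogue of the studied dataset used
#' throughout the test suite: 500 samples from 5 countries with mixing
#' weights proportional to the five largest real cohorts, 200 genes, 20
#' pathways, a 0.5/0.3/0.2 split of phenotypic variance into genetic,
#' country and residual components, and 6 replicate measurements with
#' noise sd 0.8 (on the unit-variance phenotype scale).
#'
#' @param n_samples number of samples.
#' @param n_genes gene-universe size.
#' @param n_pathways real pathway count (a dummy is added downstream).
#' @param n_tasks target-task count (36 = 18 elements x 2 tissues).
#' @param n_tasks_t1 optional pretraining-task label width (288 mirrors the
#'   studied pretraining task; 0 disables).
#' @param countries country labels; defaults to five European/US cohorts.
#' @param mix_weights sampling weight per country.
#' @param centroids matrix of per-country (lat, lon) centroids in degrees.
#' @param gps_jitter_sd GPS jitter sd in degrees around the centroid.
#' @param type_intensity length-17 Poisson base rate per variant type.
#' @param stratification s >= 0: sd of the per-(country, gene) log-rate
#'   shift; 0 removes population structure.
#' @param n_causal causal genes per task.
#' @param causal_pool size of the shared pool causal genes are drawn from
#'   (sharing induces the multi-task synergy seen in real traits).
#' @param h genetic variance fraction; `c_country` country fraction
#'   (`h + c_country <= 1`; remainder is residual noise).
#' @param c_country country-effect variance fraction.
#' @param replicates replicate measurements per sample-task.
#' @param replicate_sd replicate noise sd.
#' @param unannotated_frac fraction of genes left off the pathway map
#'   (absorbed by the dummy pathway; 0.28 mirrors the studied annotation
#'   coverage).
#' @param seed RNG seed; fixed seed gives bitwise-identical datasets.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 500L, n_genes = 200L,
                             n_pathways = 20L, n_tasks = 36L,
                             n_tasks_t1 = 0L,
                             countries = c("SE", "ES", "US", "DE", "IT"),
                             mix_weights = c(243, 180, 123, 118, 73),
                             centroids = rbind(SE = c(62, 15), ES = c(40, -4),
                                               US = c(39, -98), DE = c(51, 10),
                                               IT = c(42, 12)),
                             gps_jitter_sd = 1.5,
                             type_intensity = NULL,
                             stratification = 0.5,
                             n_causal = 10L, causal_pool = 30L,
                             h = 0.5, c_country = 0.3,
                             replicates = 6L, replicate_sd = 0.8,
                             unannotated_frac = 0.28,
                             seed = 1L) {
  if (is.null(type_intensity)) {
    # heavier mass on non-coding/regulatory classes, rare truncating events;
    # totals ~2.5 expected variants per gene
    type_intensity <- c(0.30, 0.02, 0.02, 0.005, 0.01, 0.01, 0.15, 0.10,
                        0.03, 0.05, 0.35, 0.35, 0.45, 0.55, 0.02, 0.01, 0.01)
  }
  stopifnot(length(type_intensity) == 17, all(type_intensity >= 0),
            h >= 0, c_country >= 0, h + c_country <= 1,
            stratification >= 0, gps_jitter_sd >= 0, replicate_sd >= 0,
            length(countries) == length(mix_weights),
            nrow(centroids) == length(countries),
            n_causal <= causal_pool, causal_pool <= n_genes)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_pathways = as.integer(n_pathways),
                 n_tasks = as.integer(n_tasks),
                 n_tasks_t1 = as.integer(n_tasks_t1),
                 countries = countries,
                 mix_weights = mix_weights / sum(mix_weights),
                 centroids = centroids, gps_jitter_sd = gps_jitter_sd,
                 type_intensity = type_intensity,
                 stratification = stratification,
                 n_causal = as.integer(n_causal),
                 causal_pool = as.integer(causal_pool),
                 h = h, c_country = c_country,
                 replicates = as.integer(replicates),
                 replicate_sd = replicate_sd,
                 unannotated_frac = unannotated_frac,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

zcol <- function(m) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  s[s == 0] <- 1
  sweep(sweep(m, 2, mu, "-"), 2, s, "/")
}

# Fixed type weights defining how variant classes contribute to a gene's
# functional load (truncating > coding > regulatory > neutral-ish).
load_type_weights <- function() {
  c(1.0, 0.8, 0.8, 1.2, 1.5, 1.5, 0.3, 0.3, 0.2, 0.2,
    0.3, 0.3, 0.05, 0.1, 1.2, 0.6, 1.5)
}

#' Generate a stratified synthetic population
#'
#' Draws per-(sample, gene, type) counts from a Poisson law whose rates
#' carry a per-(country, gene) multiplicative shift, builds per-task
#' phenotypes as `sqrt(h) * genetic + sqrt(c) * country + sqrt(1-h-c) *
#' noise` (each component column-standardized), adds replicate noise, and
#' emits GPS coordinates clustered by country plus a pathway map whose
#' first pathways hold the causal genes.
#'
#' @param cfg a [synthetic_config()].
#' @param emit_table also materialize the long [variant_table()] (needed to
#'   exercise the encoder on generated data; off by default at large N).
#' @return list with `tensor` (raw `gene_mutation_tensor`), `phenotypes`
#'   (data.frame: sample, country, lat, lon, task columns = replicate-mean
#'   labels), `phenotype_true` (N x T matrix before replicate noise),
#'   `replicates` (N x T x R array), `pathway_map`, `genes`, optionally
#'   `table` and `labels_t1`, and `truth` (components and causal sets).
#' @export
generate_population <- function(cfg, emit_table = FALSE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  out <- with_private_rng(cfg$seed, {
    n <- cfg$n_samples
    g <- cfg$n_genes
    tv <- 17L
    genes <- sprintf("g%04d", seq_len(g))
    samples <- sprintf("s%04d", seq_len(n))
    country <- sample(cfg$countries, n, replace = TRUE, prob = cfg$mix_weights)
    ci <- match(country, cfg$countries)
    lat <- cfg$centroids[ci, 1] + stats::rnorm(n, 0, cfg$gps_jitter_sd)
    lon <- cfg$centroids[ci, 2] + stats::rnorm(n, 0, cfg$gps_jitter_sd)
    lat <- pmin(pmax(lat, -90), 90)
    lon <- pmin(pmax(lon, -180), 180)

    # country-shifted Poisson rates
    delta <- matrix(stats::rnorm(length(cfg$countries) * g), ncol = g)
    lam <- array(0, c(n, g, tv))
    shift <- exp(cfg$stratification * delta[ci, , drop = FALSE])  # n x g
    for (t in seq_len(tv)) lam[, , t] <- cfg$type_intensity[t] * shift
    counts <- array(stats::rpois(n * g * tv, lam), c(n, g, tv),
                    dimnames = list(samples, genes, variant_vocabulary()))

    # gene loads -> genetic values
    w <- load_type_weights()
    loads <- matrix(0, n, g)
    for (t in seq_len(tv)) loads <- loads + counts[, , t] * w[t]
    loads_z <- zcol(loads)

    pool <- sample.int(g, cfg$causal_pool)
    n_all_tasks <- cfg$n_tasks + cfg$n_tasks_t1
    causal <- vector("list", n_all_tasks)
    beta <- vector("list", n_all_tasks)
    gmat <- matrix(0, n, n_all_tasks)
    for (j in seq_len(n_all_tasks)) {
      causal[[j]] <- sort(sample(pool, cfg$n_causal))
      beta[[j]] <- stats::rnorm(cfg$n_causal)
      gmat[, j] <- loads_z[, causal[[j]], drop = FALSE] %*% beta[[j]]
    }
    gmat <- zcol(gmat)

    ceff <- matrix(stats::rnorm(length(cfg$countries) * n_all_tasks),
                   ncol = n_all_tasks)
    cmat <- zcol(ceff[ci, , drop = FALSE])
    nmat <- zcol(matrix(stats::rnorm(n * n_all_tasks), ncol = n_all_tasks))
    resid <- sqrt(max(1 - cfg$h - cfg$c_country, 0))
    pheno <- sqrt(cfg$h) * gmat + sqrt(cfg$c_country) * cmat + resid * nmat

    elements <- c("Se82", "Mo98", "Mn55", "Cd114", "Sr88", "Mg25", "K39",
                  "Rb85", "Cu65", "Ca43", "P31", "S34", "Li7", "As75",
                  "Na23", "Fe57", "Zn66", "Co59")
    tasks <- if (cfg$n_tasks == 36) {
      paste0(rep(elements, 2), "_", rep(c("leaf", "seed"), each = 18))
    } else sprintf("task%03d", seq_len(cfg$n_tasks))
    y <- pheno[, seq_len(cfg$n_tasks), drop = FALSE]
    colnames(y) <- tasks
    rownames(y) <- samples

    if (cfg$replicates > 0) {
      reps <- array(y, c(n, cfg$n_tasks, cfg$replicates),
                    dimnames = list(samples, tasks, NULL)) +
        array(stats::rnorm(n * cfg$n_tasks * cfg$replicates, 0,
                           cfg$replicate_sd),
              c(n, cfg$n_tasks, cfg$replicates))
      labels <- apply(reps, c(1, 2), mean)
    } else {
      reps <- NULL
      labels <- y
    }

    # pathway map: every causal-pool gene goes into one of the first bins
    # (causal genes are annotated by construction); the unannotated
    # fraction is drawn from the non-causal remainder only.
    pw <- sprintf("bin_%02d", seq_len(cfg$n_pathways))
    noncausal <- setdiff(seq_len(g), pool)
    n_unann <- min(round(cfg$unannotated_frac * g), length(noncausal))
    annotated <- c(pool, setdiff(noncausal, sample(noncausal, n_unann)))
    annotated <- sort(annotated)
    map_gene <- genes[annotated]
    map_pw <- character(length(annotated))
    is_causal <- annotated %in% pool
    # one causal bin per ~4 causal genes (small gene-family scale), capped
    # at half the universe: trait regulation spans several distinct
    # processes, not one or two mega-pathways
    n_causal_bins <- max(1L, min(ceiling(cfg$causal_pool / 4),
                                 ceiling(cfg$n_pathways / 2)))
    map_pw[is_causal] <- sample(pw[seq_len(n_causal_bins)],
                                sum(is_causal), replace = TRUE)
    map_pw[!is_causal] <- sample(pw, sum(!is_causal), replace = TRUE)
    pmap <- pathway_map(map_gene, map_pw, pathways = pw)

    phenotypes <- data.frame(sample = samples, country = country,
                             lat = lat, lon = lon,
                             stringsAsFactors = FALSE)
    phenotypes <- cbind(phenotypes, as.data.frame(labels))

    labels_t1 <- if (cfg$n_tasks_t1 > 0) {
      m <- pheno[, cfg$n_tasks + seq_len(cfg$n_tasks_t1), drop = FALSE]
      colnames(m) <- sprintf("t1_%03d", seq_len(cfg$n_tasks_t1))
      rownames(m) <- samples
      m
    } else NULL

    res <- list(tensor = new_gene_mutation_tensor(counts, "raw"),
                phenotypes = phenotypes, phenotype_true = y,
                replicates = reps, pathway_map = pmap, genes = genes,
                labels_t1 = labels_t1,
                truth = list(causal = causal[seq_len(cfg$n_tasks)],
                             beta = beta[seq_len(cfg$n_tasks)],
                             pool = genes[pool],
                             genetic = gmat[, seq_len(cfg$n_tasks), drop = FALSE],
                             country_eff = cmat[, seq_len(cfg$n_tasks), drop = FALSE],
                             noise = nmat[, seq_len(cfg$n_tasks), drop = FALSE],
                             delta = delta, loads = loads_z),
                config = cfg)
    if (emit_table) res$table <- counts_to_table(counts, samples, genes)
    res
  })
  out
}

# Expand a count tensor into the long annotated-variant record format.
# Occurrences of a type on a gene are attributed to a small pool of sites
# so carrier frequencies (and hence MAF filtering) are meaningful.
counts_to_table <- function(counts, samples, genes) {
  idx <- which(counts > 0, arr.ind = TRUE)
  k <- counts[idx]
  rep_idx <- idx[rep(seq_len(nrow(idx)), k), , drop = FALSE]
  occ <- sequence(k)
  vocab <- variant_vocabulary()
  rec <- data.frame(
    sample = samples[rep_idx[, 1]],
    gene = genes[rep_idx[, 2]],
    variant_type = vocab[rep_idx[, 3]],
    variant_id = sprintf("%s:%s:site%d", genes[rep_idx[, 2]],
                         vocab[rep_idx[, 3]], occ),
    stringsAsFactors = FALSE)
  variant_table(rec, genes, samples)
}

#' Generate a Simpson's-paradox construction
#'
#' Groups whose means lie on a line of slope `between_slope` (in sd units
#' of the standardized group score), with within-group variation that is
#' pure noise at `within_signal = 0` and fully predictable at
#' `within_signal = 1`.  Two ready-made predictors are returned: a
#' group-level one (`group_pred`: the group score plus a small jitter, the
#' geography-only analogue) and a within-informative one (`within_pred`).
#'
#' @param n_groups number of groups (>= 2).
#' @param between_slope slope of the group means.
#' @param within_signal fraction in \[0, 1\] of within-group variance that
#'   `within_pred` explains.
#' @param n_per_group samples per group.
#' @param seed RNG seed.
#' @return data.frame: sample, group, group_pred, within_pred, obs.
#' @export
generate_simpson_dataset <- function(n_groups = 5L, between_slope = 2,
                                     within_signal = 0, n_per_group = 200L,
                                     seed = 1L) {
  stopifnot(n_groups >= 2, within_signal >= 0, within_signal <= 1)
  with_private_rng(seed, {
    n <- n_groups * n_per_group
    group <- rep(sprintf("grp%02d", seq_len(n_groups)), each = n_per_group)
    zg <- as.numeric(scale(rep(seq_len(n_groups), each = n_per_group)))
    sig <- stats::rnorm(n)
    noi <- stats::rnorm(n)
    within <- sqrt(within_signal) * sig + sqrt(1 - within_signal) * noi
    obs <- between_slope * zg + within
    data.frame(sample = sprintf("s%04d", seq_len(n)), group = group,
               group_pred = zg + stats::rnorm(n, 0, 0.05),
               within_pred = sig, obs = obs, stringsAsFactors = FALSE)
  })
}
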