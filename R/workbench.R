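# Experiment orchestration: configuration, seed fan-out, the cross-validated
# train/predict/evaluate loop (with in-fold pretraining for the transfer
# variants), the leakage audit, and a small command-line front end.

#' Deterministic per-component seed derived from a run seed
#'
#' One global seed fans out to stable per-component streams so subsystems
#' stay reproducible independently of each other.
#'
#' @param seed integer run seed.
#' @param component component name.
#' @return integer seed in \[1, 2^31 - 2\].
#' @export
seed_for <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483646 + 1)
}

#' Experiment configuration
#'
#' Exactly one of `synthetic` (a [synthetic_config()]) or `inputs` (paths
#' to a variant TSV, phenotype CSV, optional replicate CSV and pathway TSV)
#' must be provided.
#'
#' @param synthetic a [synthetic_config()] or NULL.
#' @param inputs named list of file paths (`variants`, `phenotypes`,
#'   `replicates`, `pathways`) or NULL.
#' @param variant model family: `"galiana-dense"`, `"bmsnn"`,
#'   `"gps-baseline"`, `"frozen-head"` or `"fine-tune"`.
#' @param arch named list of [architecture_spec()] overrides (`H`, `d`,
#'   `g_hidden`, `T_out`); `head_H` sets the transfer-head width.
#' @param train a [train_config()].
#' @param pretrain a [train_config()] for in-fold T1 pretraining (transfer
#'   variants only); defaults to `train`.
#' @param cv_mode,k cross-validation mode and fold count.
#' @param standardization input dialect: `"global-z"`,
#'   `"per-gene-frequency"` or `"none"`.
#' @param paper_compat if TRUE, fit the global-z moments on the full
#'   dataset (reproduces the original study's leaky preprocessing);
#'   default fits on each fold's training split only.
#' @param maf_threshold optional folded carrier-frequency cutoff applied
#'   before encoding (requires record-level input).
#' @param mask_rule `"primary"` or `"all-edges"` for the sparsified trunk.
#' @param min_n country inclusion cutoff for evaluation (strictly greater).
#' @param flag_gap Simpson flag threshold.
#' @param outdir output directory for artifacts, or NULL for none.
#' @param seed global run seed.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(synthetic = NULL, inputs = NULL,
                              variant = "bmsnn", arch = list(),
                              train = train_config(), pretrain = NULL,
                              cv_mode = "random-kfold", k = 5L,
                              standardization = "global-z",
                              paper_compat = FALSE, maf_threshold = NULL,
                              mask_rule = "primary", min_n = 50,
                              flag_gap = 0.3, outdir = NULL, seed = 1L) {
  if (is.null(synthetic) == is.null(inputs)) {
    stop("provide exactly one of 'synthetic' or 'inputs'")
  }
  if (!is.null(inputs)) {
    need <- c("variants", "phenotypes")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) stop("inputs missing: ", paste(miss, collapse = ", "))
    for (p in unlist(inputs)) {
      if (!file.exists(p)) stop("input file does not exist: ", p)
    }
  }
  structure(list(synthetic = synthetic, inputs = inputs, variant = variant,
                 arch = arch, train = train,
                 pretrain = if (is.null(pretrain)) train else pretrain,
                 cv_mode = cv_mode, k = as.integer(k),
                 standardization = standardization,
                 paper_compat = paper_compat, maf_threshold = maf_threshold,
                 mask_rule = mask_rule, min_n = min_n, flag_gap = flag_gap,
                 outdir = outdir, seed = as.integer(seed)),
            class = "experiment_config")
}

load_experiment_data <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    syn$seed <- seed_for(cfg$seed, "data")
    if (cfg$variant %in% c("frozen-head", "fine-tune") && syn$n_tasks_t1 == 0) {
      syn$n_tasks_t1 <- 288L
    }
    pop <- generate_population(syn, emit_table = !is.null(cfg$maf_threshold))
  } else {
    tab <- read_variant_table(cfg$inputs$variants)
    if (!is.null(cfg$maf_threshold)) tab <- maf_filter(tab, cfg$maf_threshold)
    phen <- read_phenotype_csv(cfg$inputs$phenotypes)
    tab$samples <- as.character(phen$sample)
    reps <- if (!is.null(cfg$inputs$replicates)) {
      read_replicates_csv(cfg$inputs$replicates)
    } else NULL
    pmap <- if (!is.null(cfg$inputs$pathways)) {
      read_pathway_map(cfg$inputs$pathways)
    } else NULL
    pop <- list(tensor = encode_variants(tab), phenotypes = phen,
                replicates = reps, pathway_map = pmap, genes = tab$genes,
                labels_t1 = NULL)
  }
  if (!is.null(cfg$maf_threshold) && !is.null(pop$table)) {
    pop$tensor <- encode_variants(maf_filter(pop$table, cfg$maf_threshold))
  }
  pop
}

fold_input <- function(cfg, raw, train_ids, all_ids) {
  if (cfg$standardization == "none") return(raw$values)
  if (cfg$standardization == "per-gene-frequency") {
    return(standardize(raw, "per-gene-frequency")$values)
  }
  fit_on <- if (cfg$paper_compat) NULL else train_ids
  standardize(raw, "global-z", fit_on = fit_on)$values
}

#' Run a full cross-validated experiment
#'
#' Generates or loads the data, builds the requested model inside each CV
#' fold (pretraining on the T1 label table first for the transfer
#' variants), trains, predicts the held-out fold, and evaluates the pooled
#' out-of-fold predictions with the stratification-aware report.  When
#' `cfg$outdir` is set, the resolved configuration, plan audit, per-fold
#' histories, predictions and the report are written there.
#'
#' @param cfg an [experiment_config()].
#' @return list with `report` (an `evaluation_report`), `predictions`,
#'   `observed`, `plan`, `audit`, `histories`, and `failed_folds`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  pop <- load_experiment_data(cfg)
  phen <- pop$phenotypes
  meta_cols <- c("sample", "country", "lat", "lon")
  tasks <- setdiff(names(phen), meta_cols)
  obs <- as.matrix(phen[, tasks, drop = FALSE])
  rownames(obs) <- phen$sample
  n <- nrow(obs)

  cv_mode <- if (cfg$variant %in% c("frozen-head", "fine-tune") &&
                 cfg$cv_mode == "random-kfold") "tl-leakage-safe" else cfg$cv_mode
  plan <- make_cv_plan(phen$sample, cv_mode, k = cfg$k,
                       seed = seed_for(cfg$seed, "cv"),
                       countries = phen$country)
  audit <- audit_plan(plan, countries = phen$country)
  if (!audit$ok) stop("cross-validation plan failed its audit")

  pred <- matrix(NA_real_, n, length(tasks),
                 dimnames = list(phen$sample, tasks))
  histories <- vector("list", cfg$k)
  failed <- integer(0)

  for (f in seq_len(cfg$k)) {
    res <- tryCatch(
      run_fold(cfg, pop, obs, plan, f),
      error = function(e) {
        warning("fold ", f, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) {
      failed <- c(failed, f)
      next
    }
    pred[rownames(res$pred), ] <- res$pred
    histories[[f]] <- res$history
  }

  ok <- !is.na(pred[, 1])
  report <- evaluate_predictions(pred[ok, , drop = FALSE],
                                 obs[ok, , drop = FALSE],
                                 phen$country[ok],
                                 replicates = if (!is.null(pop$replicates))
                                   pop$replicates[ok, , , drop = FALSE] else NULL,
                                 min_n = cfg$min_n,
                                 model_id = cfg$variant,
                                 flag_gap = cfg$flag_gap)
  if (!is.null(report$upper_bound)) report <- contextualize(report)
  out <- list(report = report, predictions = pred, observed = obs,
              plan = plan, audit = audit, histories = histories,
              failed_folds = failed)
  if (!is.null(cfg$outdir)) write_run_artifacts(cfg, out)
  out
}

run_fold <- function(cfg, pop, obs, plan, f) {
  sets <- plan_sets(plan, f)
  phen <- pop$phenotypes
  tr <- match(sets$train, phen$sample)
  te <- match(sets$test, phen$sample)
  seed_f <- seed_for(cfg$seed, paste0("fold", f))

  # task-wise label standardization fitted on the training split
  mu <- colMeans(obs[tr, , drop = FALSE], na.rm = TRUE)
  sd <- apply(obs[tr, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
  sd[!is.finite(sd) | sd == 0] <- 1
  y_tr <- sweep(sweep(obs[tr, , drop = FALSE], 2, mu, "-"), 2, sd, "/")

  tcfg <- cfg$train
  tcfg$seed <- seed_for(cfg$seed, paste0("train", f))

  if (cfg$variant == "gps-baseline") {
    x_all <- gps_features(phen$lat, phen$lon)
    spec <- architecture_spec("gps-baseline",
                              H = cfg$arch$H %||% 500L,
                              T_out = ncol(obs))
    model <- build_model(spec, seed = seed_f)
    fit <- train(model, x_all[tr, , drop = FALSE], y_tr, tcfg)
    pr <- predict(fit$model, x_all[te, , drop = FALSE])
  } else {
    x_vals <- fold_input(cfg, pop$tensor, sets$train, phen$sample)
    x_tr <- x_vals[tr, , , drop = FALSE]
    x_te <- x_vals[te, , , drop = FALSE]
    g <- dim(x_vals)[2]
    if (cfg$variant %in% c("galiana-dense", "frozen-head", "fine-tune")) {
      t_pre <- if (!is.null(pop$labels_t1)) ncol(pop$labels_t1) else ncol(obs)
      spec <- architecture_spec("galiana-dense", G = g,
                                d = cfg$arch$d %||% 50L,
                                g_hidden = cfg$arch$g_hidden %||% 8L,
                                T_out = if (cfg$variant == "galiana-dense")
                                  ncol(obs) else t_pre)
      model <- build_model(spec, seed = seed_f)
      if (cfg$variant == "galiana-dense") {
        fit <- train(model, x_tr, y_tr, tcfg)
      } else {
        if (is.null(pop$labels_t1)) stop("transfer variant needs T1 labels")
        pcfg <- cfg$pretrain
        pcfg$seed <- seed_for(cfg$seed, paste0("pretrain", f))
        y1 <- pop$labels_t1[tr, , drop = FALSE]
        y1 <- sweep(sweep(y1, 2, colMeans(y1), "-"), 2,
                    apply(y1, 2, stats::sd), "/")
        pre <- train(model, x_tr, y1, pcfg)
        if (cfg$variant == "frozen-head") {
          tl <- freeze_and_extend(pre$model,
                                  i_module_spec(spec$d,
                                                cfg$arch$head_H %||% 200L,
                                                ncol(obs)),
                                  seed = seed_f + 1L)
          fit <- train(tl, x_tr, y_tr, tcfg)
        } else {
          fit <- fine_tune(pre$model, x_tr, y_tr, tcfg, t_out = ncol(obs),
                           seed = seed_f + 1L)
        }
      }
    } else if (cfg$variant == "bmsnn") {
      if (is.null(pop$pathway_map)) stop("bmsnn variant needs a pathway map")
      mask <- build_mask(pop$pathway_map, pop$genes, rule = cfg$mask_rule)
      spec <- architecture_spec("bmsnn", G = g,
                                P_real = mask$p_real,
                                H = cfg$arch$H %||% 50L,
                                g_hidden = cfg$arch$g_hidden %||% 8L,
                                T_out = ncol(obs))
      model <- build_model(spec, mask = mask, seed = seed_f)
      fit <- train(model, x_tr, y_tr, tcfg)
    } else {
      stop("unknown variant: ", cfg$variant)
    }
    pr <- predict(fit$model, x_te)
  }
  rownames(pr) <- sets$test
  list(pred = pr, history = fit$history)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Audit a cross-validation plan
#'
#' Machine-checkable proof that the plan upholds its contracts: folds
#' partition the samples; under the leakage-safe mode every fold's test
#' set is disjoint from the T1-pretraining set; under country
#' stratification no country spans two folds.  Violating sample ids are
#' named.
#'
#' @param plan a `cv_plan`.
#' @param countries country labels (enables the stratification check).
#' @param t1_train optional explicit per-fold T1-training id lists to check
#'   instead of the plan's own contract (used as a negative control).
#' @return A `cv_audit`: list with `ok`, `violations` and per-fold sets.
#' @export
audit_plan <- function(plan, countries = NULL, t1_train = NULL) {
  a <- plan$assignment
  violations <- list()
  if (anyDuplicated(a$sample)) {
    violations$duplicate_samples <- a$sample[duplicated(a$sample)]
  }
  if (!setequal(unique(a$fold), seq_len(plan$k))) {
    violations$empty_folds <- setdiff(seq_len(plan$k), unique(a$fold))
  }
  folds <- lapply(seq_len(plan$k), function(f) {
    s <- plan_sets(plan, f)
    if (!is.null(t1_train)) s$t1_train <- t1_train[[f]]
    s
  })
  if (plan$mode == "tl-leakage-safe" || !is.null(t1_train)) {
    for (f in seq_len(plan$k)) {
      leak <- intersect(folds[[f]]$test, folds[[f]]$t1_train)
      if (length(leak)) {
        violations[[paste0("t1_leak_fold", f)]] <- leak
      }
    }
  }
  if (plan$mode == "country-stratified") {
    if (is.null(countries)) {
      violations$missing_countries <- "country labels required to audit stratification"
    } else {
      split_c <- tapply(a$fold, countries, function(f) length(unique(f)))
      bad <- names(split_c)[split_c > 1]
      if (length(bad)) violations$split_countries <- bad
    }
  }
  structure(list(ok = length(violations) == 0, violations = violations,
                 folds = folds, mode = plan$mode),
            class = "cv_audit")
}

#' @export
print.cv_audit <- function(x, ...) {
  cat("cv_audit (", x$mode, "): ", if (x$ok) "PASS" else "FAIL", "\n", sep = "")
  for (nm in names(x$violations)) {
    cat("  ", nm, ": ", paste(x$violations[[nm]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

write_run_artifacts <- function(cfg, out) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_ser <- cfg
  cfg_ser$synthetic <- unclass(cfg_ser$synthetic)
  cfg_ser$train <- unclass(cfg_ser$train)
  cfg_ser$pretrain <- unclass(cfg_ser$pretrain)
  if (!is.null(cfg_ser$synthetic$centroids)) {
    cfg_ser$synthetic$centroids <- as.data.frame(cfg_ser$synthetic$centroids)
  }
  jsonlite::write_json(c(unclass(cfg_ser),
                         list(r_version = R.version.string,
                              package_version =
                                as.character(utils::packageVersion("bmsnn")))),
                       file.path(cfg$outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  write_report(out$report, file.path(cfg$outdir, "report"))
  utils::write.csv(cbind(sample = rownames(out$predictions),
                         as.data.frame(out$predictions)),
                   file.path(cfg$outdir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(out$plan$assignment, file.path(cfg$outdir, "cv_plan.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(ok = out$audit$ok,
                            violations = out$audit$violations,
                            failed_folds = out$failed_folds),
                       file.path(cfg$outdir, "audit.json"),
                       auto_unbox = TRUE, null = "null")
  hist <- do.call(rbind, lapply(seq_along(out$histories), function(f) {
    h <- out$histories[[f]]
    if (is.null(h)) return(NULL)
    cbind(fold = f, h)
  }))
  if (!is.null(hist)) {
    utils::write.csv(hist, file.path(cfg$outdir, "history.csv"),
                     row.names = FALSE)
  }
  invisible(cfg$outdir)
}

#' Command-line entry point
#'
#' Verbs: `simulate <config.json> <outdir>`, `run <config.json>`,
#' `audit <config.json>`, `report <outdir>`.  The JSON config mirrors
#' [experiment_config()]; the `synthetic` entry mirrors
#' [synthetic_config()].
#'
#' @param args character vector (defaults to the command line).
#' @return exit status, invisibly (0 = success).
#' @export
bmsnn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) {
    message("usage: bmsnn <simulate|run|audit|report> ...")
    return(invisible(1L))
  }
  verb <- args[1]
  status <- 0L
  if (verb == "simulate") {
    cfg <- cli_read_config(args[2])
    outdir <- args[3]
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    pop <- generate_population(cfg$synthetic_cfg, emit_table = TRUE)
    write_variant_table(pop$table, file.path(outdir, "variants.tsv"))
    write_phenotype_csv(pop$phenotypes, file.path(outdir, "phenotypes.csv"))
    write_replicates_csv(pop$replicates, file.path(outdir, "replicates.csv"))
    write_pathway_map(pop$pathway_map, file.path(outdir, "pathways.tsv"))
    jsonlite::write_json(list(seed = cfg$synthetic_cfg$seed,
                              n_samples = cfg$synthetic_cfg$n_samples),
                         file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE)
    message("simulated dataset written to ", outdir)
  } else if (verb == "run") {
    cfg <- cli_read_config(args[2])
    out <- run_experiment(cfg$experiment_cfg)
    print(out$report)
    if (length(out$failed_folds)) status <- 1L
  } else if (verb == "audit") {
    cfg <- cli_read_config(args[2])
    pop <- load_experiment_data(cfg$experiment_cfg)
    ec <- cfg$experiment_cfg
    plan <- make_cv_plan(pop$phenotypes$sample, ec$cv_mode, k = ec$k,
                         seed = seed_for(ec$seed, "cv"),
                         countries = pop$phenotypes$country)
    audit <- audit_plan(plan, countries = pop$phenotypes$country)
    print(audit)
    if (!audit$ok) status <- 1L
  } else if (verb == "report") {
    path <- file.path(args[2], "report.json")
    cat(paste(readLines(path), collapse = "\n"), "\n")
  } else {
    message("unknown verb: ", verb)
    status <- 1L
  }
  invisible(status)
}

cli_read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- NULL
  if (!is.null(raw$synthetic)) {
    syn_args <- raw$synthetic
    if (!is.null(syn_args$centroids)) {
      syn_args$centroids <- as.matrix(syn_args$centroids)
    }
    syn <- do.call(synthetic_config, syn_args)
  }
  tr <- if (!is.null(raw$train)) do.call(train_config, raw$train)
        else train_config()
  exp_args <- raw[setdiff(names(raw), c("synthetic", "train"))]
  ec <- do.call(experiment_config,
                c(list(synthetic = syn, train = tr), exp_args))
  list(experiment_cfg = ec, synthetic_cfg = syn)
}
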