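smoke_cfg <- function(outdir = NULL, seed = 3, variant = "bmsnn", ...) {
  experiment_config(
    synthetic = synthetic_config(n_samples = 120, n_genes = 40,
                                 n_pathways = 8, n_tasks = 6, n_causal = 4,
                                 causal_pool = 12, replicates = 3),
    variant = variant, train = train_config(epochs = 3),
    k = 4, min_n = 10, outdir = outdir, seed = seed, ...)
}

test_that("seed fan-out is deterministic, component-specific and in range", {
  expect_identical(seed_for(1, "data"), seed_for(1, "data"))
  expect_false(seed_for(1, "data") == seed_for(1, "cv"))
  expect_false(seed_for(1, "data") == seed_for(2, "data"))
  s <- vapply(c("a", "data", "train3", "a-very-long-component-name"),
              function(nm) seed_for(123456, nm), integer(1))
  expect_true(all(s >= 1 & s <= 2147483646))
})

test_that("experiment_config enforces its exclusivity contract", {
  expect_error(experiment_config(), "exactly one")
  expect_error(experiment_config(synthetic = synthetic_config(),
                                 inputs = list(variants = "x")), "exactly one")
  expect_error(experiment_config(inputs = list(variants = "/nope.tsv",
                                               phenotypes = "/nope.csv")),
               "does not exist")
  expect_error(experiment_config(inputs = list(variants = "/nope.tsv")),
               "phenotypes")
})

test_that("a synthetic smoke run completes and writes a well-formed report", {
  outdir <- withr::local_tempdir()
  out <- run_experiment(smoke_cfg(outdir))
  expect_length(out$failed_folds, 0)
  expect_s3_class(out$report, "evaluation_report")
  expect_true(all(!is.na(out$predictions)))
  expect_length(out$report$intra_mean_r, 6)
  expect_true(out$audit$ok)
  # artifacts
  for (f in c("config.json", "report.json", "report_summary.csv",
              "predictions.csv", "cv_plan.csv", "audit.json", "history.csv")) {
    expect_true(file.exists(file.path(outdir, f)), info = f)
  }
  rj <- jsonlite::read_json(file.path(outdir, "report.json"),
                            simplifyVector = TRUE)
  expect_equal(length(rj$intra_mean_r), 6)
  # replicate bounds present and contextualized
  expect_false(is.null(out$report$contextual))
})

test_that("the same config and seed reproduce the report exactly", {
  o1 <- run_experiment(smoke_cfg())
  o2 <- run_experiment(smoke_cfg())
  expect_identical(o1$report$intra_mean_r, o2$report$intra_mean_r)
  expect_identical(o1$predictions, o2$predictions)
  o3 <- run_experiment(smoke_cfg(seed = 4))
  expect_false(identical(o1$report$intra_mean_r, o3$report$intra_mean_r))
})

test_that("file-based inputs run through the same pipeline", {
  dirs <- withr::local_tempdir()
  pop <- generate_population(
    synthetic_config(n_samples = 60, n_genes = 20, n_pathways = 5,
                     n_tasks = 4, n_causal = 3, causal_pool = 6,
                     replicates = 3, seed = 2),
    emit_table = TRUE)
  write_variant_table(pop$table, file.path(dirs, "variants.tsv"))
  write_phenotype_csv(pop$phenotypes, file.path(dirs, "phenotypes.csv"))
  write_replicates_csv(pop$replicates, file.path(dirs, "replicates.csv"))
  write_pathway_map(pop$pathway_map, file.path(dirs, "pathways.tsv"))
  cfg <- experiment_config(
    inputs = list(variants = file.path(dirs, "variants.tsv"),
                  phenotypes = file.path(dirs, "phenotypes.csv"),
                  replicates = file.path(dirs, "replicates.csv"),
                  pathways = file.path(dirs, "pathways.tsv")),
    variant = "bmsnn", train = train_config(epochs = 2), k = 3,
    min_n = 5, seed = 6)
  out <- run_experiment(cfg)
  expect_length(out$failed_folds, 0)
  expect_length(out$report$intra_mean_r, 4)
})

test_that("audit catches a deliberately corrupted plan", {
  plan <- make_cv_plan(sprintf("s%d", 1:20), "tl-leakage-safe", k = 4,
                       seed = 1)
  good <- audit_plan(plan)
  expect_true(good$ok)
  # inject one test id of fold 2 into fold 2's T1-training set
  t1 <- lapply(1:4, function(f) plan_sets(plan, f)$train)
  victim <- plan_sets(plan, 2)$test[1]
  t1[[2]] <- c(t1[[2]], victim)
  bad <- audit_plan(plan, t1_train = t1)
  expect_false(bad$ok)
  expect_true(victim %in% bad$violations$t1_leak_fold2)
})

test_that("country-stratified plans pass the stratification audit", {
  countries <- rep(c("A", "B", "C", "D"), c(10, 8, 5, 3))
  plan <- make_cv_plan(sprintf("s%d", 1:26), "country-stratified", k = 3,
                       countries = countries)
  audit <- audit_plan(plan, countries = countries)
  expect_true(audit$ok)
  # corrupting the assignment splits a country
  plan$assignment$fold[1] <- plan$assignment$fold[1] %% 3 + 1
  bad <- audit_plan(plan, countries = countries)
  expect_false(bad$ok)
  expect_equal(bad$violations$split_countries, "A")
})

test_that("transfer variants pretrain inside each fold without leakage", {
  cfg <- experiment_config(
    synthetic = synthetic_config(n_samples = 60, n_genes = 15,
                                 n_pathways = 4, n_tasks = 3, n_causal = 2,
                                 causal_pool = 4, replicates = 0,
                                 n_tasks_t1 = 6),
    variant = "frozen-head", arch = list(d = 8, head_H = 10),
    train = train_config(epochs = 2), pretrain = train_config(epochs = 2),
    k = 3, min_n = 5, seed = 9)
  out <- run_experiment(cfg)
  expect_length(out$failed_folds, 0)
  expect_equal(out$plan$mode, "tl-leakage-safe")
  expect_true(out$audit$ok)
})

test_that("the CLI simulate and audit verbs work end to end", {
  dirs <- withr::local_tempdir()
  cfgfile <- file.path(dirs, "config.json")
  jsonlite::write_json(list(
    synthetic = list(n_samples = 40, n_genes = 12, n_pathways = 4,
                     n_tasks = 3, n_causal = 2, causal_pool = 4,
                     replicates = 2, seed = 5),
    train = list(epochs = 1), variant = "bmsnn", k = 3, min_n = 5, seed = 5),
    cfgfile, auto_unbox = TRUE)
  datadir <- file.path(dirs, "data")
  expect_equal(suppressMessages(bmsnn_cli(c("simulate", cfgfile, datadir))), 0L)
  for (f in c("variants.tsv", "phenotypes.csv", "replicates.csv",
              "pathways.tsv", "manifest.json")) {
    expect_true(file.exists(file.path(datadir, f)), info = f)
  }
  expect_equal(bmsnn_cli(c("audit", cfgfile)), 0L)
  expect_equal(suppressMessages(bmsnn_cli("nonsense")), 1L)
})

test_that("plot writers produce non-empty image files", {
  set.seed(1)
  n <- 60
  countries <- rep(c("A", "B"), each = 30)
  obs <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("el", 1:4)))
  pred <- obs + rnorm(n * 4, 0, 0.5)
  rep1 <- evaluate_predictions(pred, obs, countries, min_n = 10)
  dirs <- withr::local_tempdir()
  p1 <- file.path(dirs, "radar.svg")
  plot_radar(list(model = rep1), p1)
  expect_gt(file.size(p1), 500)
  p2 <- file.path(dirs, "scatter.png")
  plot_best_scatter(pred, obs, countries, p2, n_panels = 4, min_n = 10)
  expect_gt(file.size(p2), 500)
})
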