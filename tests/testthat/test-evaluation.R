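test_that("random k-fold plans partition samples into near-equal folds", {
  plan <- make_cv_plan(sprintf("s%d", 1:10), "random-kfold", k = 5, seed = 3)
  expect_equal(sort(table(plan$assignment$fold)), sort(rep(2L, 5)),
               ignore_attr = TRUE)
  expect_setequal(plan$assignment$sample, sprintf("s%d", 1:10))
  for (f in 1:5) {
    s <- plan_sets(plan, f)
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), sprintf("s%d", 1:10))
  }
  expect_error(make_cv_plan(sprintf("s%d", 1:3), "random-kfold", k = 5),
               "fewer samples")
})

test_that("country-stratified plans use greedy largest-first balancing", {
  countries <- rep(c("A", "B", "C"), c(6, 3, 1))
  plan <- make_cv_plan(sprintf("s%d", 1:10), "country-stratified", k = 2,
                       countries = countries)
  a <- plan$assignment
  fold_of <- tapply(a$fold, countries, unique)
  expect_length(fold_of[["A"]], 1)             # no country split
  expect_equal(fold_of[["B"]], fold_of[["C"]]) # B, C share the smaller fold
  expect_false(fold_of[["A"]] == fold_of[["B"]])
  expect_error(make_cv_plan(sprintf("s%d", 1:10), "country-stratified",
                            k = 4, countries = countries), "fewer countries")
  expect_error(make_cv_plan(sprintf("s%d", 1:10), "country-stratified", k = 2),
               "country labels")
})

test_that("tl-leakage-safe plans expose a T1 set equal to the train set", {
  plan <- make_cv_plan(sprintf("s%d", 1:20), "tl-leakage-safe", k = 4,
                       seed = 9)
  for (f in 1:4) {
    s <- plan_sets(plan, f)
    expect_identical(s$t1_train, s$train)
    expect_length(intersect(s$test, s$t1_train), 0)
  }
})

test_that("intra-country Pearson matches closed forms and filters by n", {
  set.seed(5)
  n <- 120
  countries <- rep(c("A", "B"), each = n / 2)
  obs <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("t1", "t2")))
  ic <- intra_country_pearson(obs, obs, countries, min_n = 50)
  expect_equal(unname(ic$mean_r), c(1, 1))
  # 3-point closed form
  pred <- cbind(c(1, 2, 3))
  obs3 <- cbind(c(1, 2, 4))
  ic3 <- suppressWarnings(
    intra_country_pearson(pred, obs3, rep("A", 3), min_n = 2))
  expect_equal(unname(ic3$per_country$r), 0.981981, tolerance = 1e-5)
  # min_n is strict: a country with exactly min_n samples is excluded
  expect_warning(
    ic4 <- intra_country_pearson(obs, obs, countries, min_n = n / 2),
    "no country")
  expect_equal(nrow(ic4$per_country), 0)
  ic5 <- intra_country_pearson(obs, obs, countries, min_n = n / 2 - 1)
  expect_equal(sort(unique(ic5$per_country$country)), c("A", "B"))
})

test_that("per-country constant predictors are excluded, not averaged", {
  # two countries with distinct means; prediction = country mean of obs
  set.seed(6)
  countries <- rep(c("A", "B"), each = 60)
  obs <- cbind(rnorm(120) + ifelse(countries == "A", 3, -3))
  pred <- cbind(ifelse(countries == "A", mean(obs[countries == "A"]),
                       mean(obs[countries == "B"])))
  expect_warning(
    ic <- intra_country_pearson(pred, obs, countries, min_n = 50),
    "undefined")
  expect_true(all(is.na(ic$per_country$r)))
  expect_gt(unname(global_pool_pearson(pred, obs)), 0.8)
})

test_that("global pooled Pearson behaves at the sign extremes", {
  set.seed(7)
  obs <- matrix(rnorm(40), 20, 2)
  expect_equal(unname(global_pool_pearson(obs, obs)), c(1, 1))
  expect_equal(unname(global_pool_pearson(-obs, obs)), c(-1, -1))
  expect_true(is.na(global_pool_pearson(matrix(1, 20, 1), obs[, 1, drop = FALSE])))
})

test_that("upper bound hits its degenerate limits", {
  # zero replicate spread -> bound 1
  reps <- matrix(rep(rnorm(10), 3), 10, 3)
  expect_equal(pearson_upper_bound(reps), 1)
  # replicate means identical across samples but replicates noisy:
  # signal variance floors at 0
  reps <- cbind(-1, 1, -2, 2) [rep(1, 20), ] * (1 + 0.1 * seq_len(20))
  expect_true(all(abs(rowMeans(reps)) < 1e-12))
  expect_equal(pearson_upper_bound(reps), 0)
  expect_warning(b <- pearson_upper_bound(matrix(rnorm(5), 5, 1)), "undefined")
  expect_true(is.na(b))
})

test_that("upper bound decreases monotonically with replicate noise", {
  set.seed(9)
  truth <- rnorm(400)
  bounds <- vapply(c(0.2, 0.5, 1, 2), function(s) {
    reps <- matrix(truth, 400, 6) + matrix(rnorm(2400, 0, s), 400, 6)
    pearson_upper_bound(reps)
  }, numeric(1))
  expect_true(all(diff(bounds) < 0))
  expect_true(all(bounds >= 0 & bounds <= 1))
})

test_that("simpson diagnostic flags stratification-inflated tasks", {
  set.seed(10)
  obs <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  g <- rep(c("x", "y", "z"), each = 10)
  d <- simpson_diagnostic(obs, obs, g)
  expect_equal(d$gap, c(0, 0))
  expect_false(any(d$flagged))
  # single group: gap 0 by definition
  d1 <- simpson_diagnostic(obs, obs, rep("x", 30))
  expect_equal(d1$gap, c(0, 0))
  # constructed two-group inflation
  sim <- generate_simpson_dataset(n_groups = 2, between_slope = 3,
                                  n_per_group = 100, seed = 11)
  ds <- simpson_diagnostic(cbind(sim$group_pred), cbind(sim$obs), sim$group)
  expect_true(ds$flagged)
})

test_that("classification metrics match closed forms", {
  perfect <- diag(c(5, 7, 9))
  m <- classification_metrics(perfect)
  expect_equal(m$macro_f1, 1)
  expect_equal(m$mcc, 1)
  uniform <- matrix(4, 3, 3)
  expect_equal(classification_metrics(uniform)$mcc, 0)
  cm <- matrix(c(8, 1, 2, 9), 2, 2)  # rows=truth: [[8,2],[1,9]]
  m2 <- classification_metrics(cm)
  expect_equal(m2$mcc, 0.7035265, tolerance = 1e-6)
  expect_equal(m2$macro_f1, 0.8496241, tolerance = 1e-6)
  expect_error(classification_metrics(matrix(0, 2, 2)), "empty")
  expect_error(classification_metrics(matrix(1, 2, 3)), "square")
})

test_that("contextualize reports percentages of the bound, flagging edge cases", {
  rep0 <- structure(
    list(model_id = "m",
         intra_mean_r = c(a = 0.42, b = 0, c = 0.21, d = 0.5, e = 0.1),
         upper_bound = c(a = 0.42, b = 0.9, c = 0.42, d = 0.4, e = 0),
         global_r = c(a = 0.5, b = 0.1, c = 0.3, d = 0.5, e = 0.2),
         per_country = data.frame(), simpson = data.frame(), min_n = 50),
    class = "evaluation_report")
  ctx <- contextualize(rep0)$contextual
  expect_equal(ctx$pct_of_bound[ctx$task == "a"], 100)
  expect_equal(ctx$pct_of_bound[ctx$task == "b"], 0)
  expect_equal(ctx$pct_of_bound[ctx$task == "c"], 50)
  expect_true(ctx$exceeds_bound[ctx$task == "d"])   # flagged, not clipped
  expect_gt(ctx$pct_of_bound[ctx$task == "d"], 100)
  expect_true(is.na(ctx$pct_of_bound[ctx$task == "e"]))
  expect_true(ctx$zero_bound[ctx$task == "e"])
  rep0$upper_bound <- NULL
  expect_error(contextualize(rep0), "no upper bounds")
})

test_that("intra-country mean is invariant to relabeling and affine maps", {
  set.seed(12)
  n <- 160
  countries <- rep(c("A", "B"), each = n / 2)
  pred <- matrix(rnorm(n), n, 1)
  obs <- pred + matrix(rnorm(n, 0, 0.5), n, 1)
  base <- intra_country_pearson(pred, obs, countries, min_n = 10)$mean_r
  relab <- intra_country_pearson(pred, obs,
                                 c(A = "zz", B = "aa")[countries],
                                 min_n = 10)$mean_r
  expect_equal(unname(base), unname(relab))
  # per-country positive affine transform of both pred and obs
  scale_p <- ifelse(countries == "A", 2.5, 0.3)
  shift_p <- ifelse(countries == "A", -4, 7)
  aff <- intra_country_pearson(pred * scale_p + shift_p,
                               obs * (scale_p * 2) - shift_p,
                               countries, min_n = 10)$mean_r
  expect_equal(unname(base), unname(aff))
})

test_that("evaluate_predictions assembles a coherent report", {
  set.seed(13)
  n <- 150
  countries <- sample(c("A", "B"), n, replace = TRUE)
  obs <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("x", "y", "z")))
  pred <- obs + matrix(rnorm(n * 3, 0, 0.7), n, 3)
  reps <- array(obs, c(n, 3, 4)) + array(rnorm(n * 3 * 4, 0, 0.5), c(n, 3, 4))
  rep1 <- evaluate_predictions(pred, obs, countries, replicates = reps,
                               min_n = 20, model_id = "toy")
  expect_s3_class(rep1, "evaluation_report")
  expect_length(rep1$upper_bound, 3)
  expect_true(all(rep1$upper_bound > 0 & rep1$upper_bound < 1))
  expect_equal(sort(unique(rep1$per_country$country)), c("A", "B"))
  # model comparison runs on paired cells
  rep2 <- evaluate_predictions(matrix(rnorm(n * 3), n, 3), obs, countries,
                               min_n = 20, model_id = "noise")
  ht <- compare_models(rep1, rep2)
  expect_lt(ht$p.value, 0.05)
})
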