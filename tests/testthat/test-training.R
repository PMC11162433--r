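# Small trainable fixtures used throughout.
toy_linear_data <- function(n = 20, g = 3, seed = 1) {
  set.seed(seed)
  x <- array(rnorm(n * g * 17), c(n, g, 17))
  # one causal gene: task depends on the mean of its 17-vector
  y <- matrix(rowMeans(x[, 1, ]) * 2, n, 1)
  list(x = x, y = y)
}

toy_model <- function(g = 3, t_out = 1, seed = 5) {
  build_model(architecture_spec("galiana-dense", G = g, d = 4, g_hidden = 3,
                                T_out = t_out), seed = seed)
}

test_that("LR schedule decays by exactly 1/3 after 3 non-improving epochs", {
  # strictly decreasing: never decays
  expect_equal(lr_schedule(c(1, 0.9, 0.8, 0.7, 0.6)), rep(1e-2, 5))
  # first epoch sets the running best, then 3 flat epochs -> one decay
  lrs <- lr_schedule(c(1, 1, 1, 1, 0.5))
  expect_equal(lrs, c(rep(1e-2, 4), 1e-2 / 3))
  expect_equal(lrs[5], 3.333e-3, tolerance = 1e-3)
  # 6 flat epochs -> two decay events
  lrs <- lr_schedule(c(1, rep(1, 6), 0.1))
  expect_equal(lrs[8], 1e-2 / 9)
  expect_equal(lrs[8], 1.111e-3, tolerance = 1e-3)
  # trace (1.0, 0.9, 0.9, 0.9, 0.9): epochs 3-5 fail to improve the
  # running best, so the decayed rate applies from the 6th epoch on
  lrs <- lr_schedule(c(1, 0.9, 0.9, 0.9, 0.9, 0.9))
  expect_equal(lrs, c(rep(1e-2, 5), 1e-2 / 3))
})

test_that("lr_schedule_step replays the counter with resets", {
  expect_equal(lr_schedule_step(c(1, 0.9, 0.8), 1e-2), 1e-2)
  expect_equal(lr_schedule_step(c(1, 1, 1, 1), 1e-2), 1e-2 / 3)
  # counter reset after a decay: 3 more flat epochs needed for the next
  expect_equal(lr_schedule_step(c(1, 1, 1, 1, 1), 1e-2 / 3), 1e-2 / 3)
  expect_equal(lr_schedule_step(c(1, rep(1, 6)), 1e-2 / 3), 1e-2 / 9)
  # the recorded lr trace is a non-increasing step function
  set.seed(1)
  trace <- cumsum(rnorm(30, 0, 0.3))
  lrs <- lr_schedule(trace)
  expect_true(all(diff(lrs) <= 0))
  pow <- log(lrs / 1e-2) / log(1 / 3)
  expect_lt(max(abs(pow - round(pow))), 1e-9)
})

test_that("training reduces the loss on a solvable toy problem", {
  d <- toy_linear_data()
  fit <- train(toy_model(), d$x, d$y,
               train_config(epochs = 15, batch_size = 5, seed = 2))
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  expect_equal(nrow(fit$history), 15)
  expect_true(all(diff(fit$history$lr) <= 0))
})

test_that("fixed seed gives bitwise-identical training histories", {
  d <- toy_linear_data()
  cfg <- train_config(epochs = 5, batch_size = 7, seed = 42)
  f1 <- train(toy_model(), d$x, d$y, cfg)
  f2 <- train(toy_model(), d$x, d$y, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$layers[[2]]$params$W, f2$model$layers[[2]]$params$W)
})

test_that("all-missing task is rejected by name", {
  d <- toy_linear_data()
  y <- cbind(d$y, NA)
  colnames(y) <- c("ok_task", "empty_task")
  expect_error(train(toy_model(t_out = 2), d$x, y, train_config(epochs = 1)),
               "empty_task")
})

test_that("missing labels are excluded from loss and gradients", {
  set.seed(3)
  pred <- matrix(rnorm(12), 4, 3)
  y <- matrix(rnorm(12), 4, 3)
  obs <- matrix(TRUE, 4, 3)
  obs[2, 1] <- FALSE
  lo <- bmsnn:::masked_mse(pred, y, obs)
  expect_equal(lo$dpred[2, 1], 0)
  expect_equal(lo$loss, sum(((pred - y)[obs])^2) / sum(obs))
  # appending a sample with no observed labels changes nothing
  lo2 <- bmsnn:::masked_mse(rbind(pred, 0), rbind(y, 0),
                            rbind(obs, c(FALSE, FALSE, FALSE)))
  expect_equal(lo2$loss, lo$loss)
  expect_equal(lo2$dpred[1:4, ], lo$dpred)
  expect_equal(lo2$dpred[5, ], c(0, 0, 0))
})

test_that("L2 decay shrinks weights when the data gradient vanishes", {
  set.seed(8)
  m <- build_model(architecture_spec("gps-baseline", H = 6, T_out = 2), seed = 1)
  x <- matrix(rnorm(30), 10, 3)
  y <- predict(m, x)   # labels equal outputs: pure-decay regime at step 1
  norm0 <- sqrt(sum(unlist(lapply(m$layers, function(l) unlist(l$params)))^2))
  fit <- train(m, x, y, train_config(epochs = 3, batch_size = 10,
                                     lr = 1e-4, lambda = 0.1, seed = 4))
  norm1 <- sqrt(sum(unlist(lapply(fit$model$layers,
                                  function(l) unlist(l$params)))^2))
  expect_lt(norm1, norm0)
})

test_that("freeze_and_extend freezes the body and counts only the head", {
  spec <- architecture_spec("galiana-dense", G = 5, d = 50, g_hidden = 3,
                            T_out = 8)
  pre <- build_model(spec, seed = 10)
  tl <- freeze_and_extend(pre, i_module_spec(50, 200, 36), seed = 11)
  expect_identical(count_parameters(tl), 17836L)
  tl500 <- freeze_and_extend(pre, i_module_spec(50, 500, 36), seed = 11)
  expect_identical(count_parameters(tl500), 44536L)
  expect_error(freeze_and_extend(pre, i_module_spec(49, 200, 36)), "latent")

  # body weights bitwise unchanged by TL training
  set.seed(12)
  x <- array(rnorm(12 * 5 * 17), c(12, 5, 17))
  y <- matrix(rnorm(12 * 36), 12, 36)
  body_before <- lapply(tl$layers[1:tl$body_end], `[[`, "params")
  fit <- train(tl, x, y, train_config(epochs = 3, batch_size = 4, seed = 13))
  body_after <- lapply(fit$model$layers[1:tl$body_end], `[[`, "params")
  expect_identical(body_before, body_after)
})

test_that("fine_tune re-heads the model and respects the epoch budget", {
  spec <- architecture_spec("galiana-dense", G = 4, d = 6, g_hidden = 3,
                            T_out = 10)
  pre <- build_model(spec, seed = 20)
  set.seed(21)
  x <- array(rnorm(10 * 4 * 17), c(10, 4, 17))
  y <- matrix(rnorm(10 * 3), 10, 3)
  # E = 0: body untouched, fresh head untouched after init
  ft0 <- fine_tune(pre, x, y, train_config(epochs = 0), t_out = 3, seed = 22)
  expect_identical(ft0$model$layers[[2]]$params$W, pre$layers[[2]]$params$W)
  expect_equal(nrow(ft0$history), 0)
  expect_equal(ft0$model$layers[[4]]$d_out, 3L)
  for (e in c(2, 4)) {
    ft <- fine_tune(pre, x, y, train_config(epochs = e, batch_size = 5),
                    t_out = 3, seed = 22)
    expect_equal(nrow(ft$history), e)
  }
  expect_true(all(ft0$model$trainable))
  # input-space mismatch rejected
  xbad <- array(rnorm(10 * 7 * 17), c(10, 7, 17))
  expect_error(fine_tune(pre, xbad, y, train_config(epochs = 1)), "genes")
})

test_that("warm-started fine tuning converges faster than cold start", {
  # T1 and T2 share causal structure; majority vote over 5 seeds
  wins <- 0
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30; g <- 4
    x <- array(rnorm(n * g * 17), c(n, g, 17))
    sig <- rowMeans(x[, 2, ])
    y1 <- matrix(sig * 1.5 + rnorm(n, 0, 0.1), n, 1)
    y2 <- matrix(sig * -0.8 + rnorm(n, 0, 0.1), n, 1)
    spec <- architecture_spec("galiana-dense", G = g, d = 4, g_hidden = 3,
                              T_out = 1)
    pre <- train(build_model(spec, seed = seed), x, y1,
                 train_config(epochs = 20, batch_size = 10, seed = seed))
    warm <- fine_tune(pre$model, x, y2,
                      train_config(epochs = 8, batch_size = 10, seed = seed),
                      t_out = 1, seed = seed + 100)
    cold <- train(build_model(spec, seed = seed + 200), x, y2,
                  train_config(epochs = 8, batch_size = 10, seed = seed))
    if (tail(warm$history$loss, 1) < tail(cold$history$loss, 1)) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 3)
})

test_that("checkpoints serialize the full parameter state", {
  m <- toy_model()
  prefix <- file.path(withr::local_tempdir(), "ckpt")
  save_checkpoint(m, prefix, extra = list(seed = 5))
  expect_true(file.exists(paste0(prefix, ".bin")))
  manifest <- jsonlite::read_json(paste0(prefix, ".json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$variant, "galiana-dense")
  expect_equal(manifest$seed, 5)
  con <- file(paste0(prefix, ".bin"), "rb")
  flat <- readBin(con, "double", n = 1e6, size = 8, endian = "little")
  close(con)
  expect_length(flat, count_parameters(m))
})
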