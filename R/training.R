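# Multi-task regression training: masked MSE loss, RMSprop with L2 weight
# decay, patience-based learning-rate decay, and the two transfer-learning
# schemes (frozen feature extractor, fine tuning).

#' Training configuration
#'
#' Defaults follow the studied setup: 50 epochs, batch size 10, MSE loss
#' over the tasks, RMSprop at learning rate 1e-2 with a reduction to 1/3
#' after 3 consecutive epochs without a training-loss decrease, and L2
#' regularization (1e-6 for dense/transfer models, 1e-4 for the sparsified
#' model — pass `lambda` accordingly).
#'
#' @param epochs training epochs (> 0).
#' @param batch_size minibatch size (>= 1); the last partial batch is kept.
#' @param lr initial learning rate.
#' @param decay_factor multiplicative LR decay per event, in (0, 1).
#' @param patience consecutive non-improving epochs that trigger a decay.
#' @param lambda L2 coefficient (added to gradients as `lambda * theta`).
#' @param rms_alpha,rms_eps RMSprop smoothing constant and epsilon.
#' @param seed RNG seed controlling initialization-free parts of training
#'   (batch shuffling); fixed seed gives bitwise-identical histories.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 10L, lr = 1e-2,
                         decay_factor = 1 / 3, patience = 3L,
                         lambda = 1e-6, rms_alpha = 0.99, rms_eps = 1e-8,
                         seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, lambda >= 0,
            decay_factor > 0, decay_factor < 1, patience >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 decay_factor = decay_factor, patience = as.integer(patience),
                 lambda = lambda, rms_alpha = rms_alpha, rms_eps = rms_eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' One learning-rate schedule decision
#'
#' Replays the running-best / patience counter over a completed loss trace
#' and returns the learning rate to use next: if the trailing epochs show
#' `patience` consecutive failures to strictly improve the running best
#' (counter resets after each decay event), the rate is multiplied by
#' `decay_factor`.
#'
#' @param trace numeric vector of completed per-epoch training losses.
#' @param current_lr learning rate in force after the last epoch.
#' @param decay_factor,patience see [train_config()].
#' @return The (possibly decayed) learning rate.
#' @export
lr_schedule_step <- function(trace, current_lr, decay_factor = 1 / 3,
                             patience = 3L) {
  stopifnot(length(trace) >= 1)
  best <- Inf
  counter <- 0L
  fired <- FALSE
  for (loss in trace) {
    fired <- FALSE
    if (loss < best) {
      best <- loss
      counter <- 0L
    } else {
      counter <- counter + 1L
      if (counter >= patience) {
        counter <- 0L
        fired <- TRUE
      }
    }
  }
  if (fired) current_lr * decay_factor else current_lr
}

#' Full learning-rate trajectory for a loss trace
#'
#' @param trace per-epoch training losses.
#' @param lr0 initial learning rate.
#' @param decay_factor,patience see [train_config()].
#' @return numeric vector: the learning rate in force *during* each epoch.
#' @export
lr_schedule <- function(trace, lr0 = 1e-2, decay_factor = 1 / 3,
                        patience = 3L) {
  lr <- lr0
  best <- Inf
  counter <- 0L
  out <- numeric(length(trace))
  for (e in seq_along(trace)) {
    out[e] <- lr
    if (trace[e] < best) {
      best <- trace[e]
      counter <- 0L
    } else {
      counter <- counter + 1L
      if (counter >= patience) {
        counter <- 0L
        lr <- lr * decay_factor
      }
    }
  }
  out
}

masked_mse <- function(pred, y, obs_mask) {
  n_obs <- sum(obs_mask)
  if (n_obs == 0) return(list(loss = NA_real_, dpred = array(0, dim(pred))))
  resid <- (pred - y)
  resid[!obs_mask] <- 0
  list(loss = sum(resid^2) / n_obs, dpred = 2 * resid / n_obs)
}

#' Train a model
#'
#' Minibatch training with the masked multi-task MSE loss (missing labels
#' are excluded per sample-task cell), RMSprop updates with L2 weight
#' decay on trainable layers, per-epoch reshuffling, and the patience-based
#' LR schedule monitored on the training loss.  Labels are expected to be
#' standardized per task by the caller.
#'
#' @param model a `gi_model`.
#' @param x input: matrix, N x G x 17 array, or `gene_mutation_tensor`.
#' @param y N x T label matrix; NA marks a missing label.
#' @param cfg a [train_config()].
#' @return list with `model` (trained) and `history` (data.frame of epoch,
#'   loss, lr).
#' @export
train <- function(model, x, y, cfg = train_config()) {
  x <- as_model_input(x)
  y <- as.matrix(y)
  n <- if (length(dim(x)) == 3) dim(x)[1] else nrow(x)
  stopifnot(nrow(y) == n)
  all_missing <- colSums(!is.na(y)) == 0
  if (any(all_missing)) {
    nm <- colnames(y)[all_missing]
    if (is.null(nm)) nm <- which(all_missing)
    stop("task(s) with no observed labels: ", paste(nm, collapse = ", "))
  }
  obs <- !is.na(y)
  y0 <- y
  y0[!obs] <- 0

  opt <- lapply(model$layers, function(l) lapply(l$params, function(p) p * 0))
  lr <- cfg$lr
  best <- Inf
  counter <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))

  run <- function() {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      epoch_loss <- 0
      n_obs_epoch <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        xb <- if (length(dim(x)) == 3) x[idx, , , drop = FALSE]
              else x[idx, , drop = FALSE]
        yb <- y0[idx, , drop = FALSE]
        mb <- obs[idx, , drop = FALSE]
        fw <- forward_model(model, xb, keep_caches = TRUE)
        lo <- masked_mse(fw$out, yb, mb)
        if (!is.na(lo$loss)) {
          epoch_loss <- epoch_loss + lo$loss * sum(mb)
          n_obs_epoch <- n_obs_epoch + sum(mb)
        }
        bw <- backward_model(model, fw$caches, lo$dpred)
        for (i in seq_along(model$layers)) {
          if (!model$trainable[i] || is.null(bw$grads[[i]])) next
          for (pn in names(model$layers[[i]]$params)) {
            g <- bw$grads[[i]][[pn]] + cfg$lambda * model$layers[[i]]$params[[pn]]
            v <- cfg$rms_alpha * opt[[i]][[pn]] + (1 - cfg$rms_alpha) * g^2
            opt[[i]][[pn]] <<- v
            model$layers[[i]]$params[[pn]] <<-
              model$layers[[i]]$params[[pn]] - lr * g / (sqrt(v) + cfg$rms_eps)
          }
        }
      }
      epoch_loss <- epoch_loss / n_obs_epoch
      history[nrow(history) + 1L, ] <<- list(epoch, epoch_loss, lr)
      if (epoch_loss < best) {
        best <<- epoch_loss
        counter <<- 0L
      } else {
        counter <<- counter + 1L
        if (counter >= cfg$patience) {
          counter <<- 0L
          lr <<- lr * cfg$decay_factor
        }
      }
    }
  }
  with_private_rng(cfg$seed, run())
  list(model = model, history = history)
}

#' Freeze a pretrained body and attach a fresh transfer head
#'
#' Marks every body layer (through the latent) non-trainable, drops the
#' pretraining-task output layer, and attaches a newly initialized I head.
#' Only the head's parameters train afterwards; frozen parameters receive
#' no gradients.
#'
#' @param model a pretrained `gi_model` exposing a latent (dense or
#'   sparsified variants).
#' @param head an [i_module_spec()] whose `d_in` must equal the latent size.
#' @param seed optional seed for head initialization.
#' @return A `gi_model` with variant `"frozen-head"`.
#' @export
freeze_and_extend <- function(model, head, seed = NULL) {
  if (is.na(model$body_end)) stop("model has no designated body/latent split")
  latent <- latent_size(model)
  if (latent != head$d_in) {
    stop("latent size ", latent, " does not match head d_in = ", head$d_in)
  }
  body <- model$layers[seq_len(model$body_end)]
  hd <- if (is.null(seed)) build_i_head(head)
        else with_private_rng(seed, build_i_head(head))
  new_model(c(body, hd$layers),
            trainable = c(rep(FALSE, length(body)), rep(TRUE, 4L)),
            variant = "frozen-head", body_end = length(body),
            spec = model$spec, input_kind = model$input_kind)
}

latent_size <- function(model) {
  for (i in rev(seq_len(model$body_end))) {
    l <- model$layers[[i]]
    if (l$type == "dense") return(l$d_out)
    if (l$type == "masked_linear") return(l$d_out - 1L)
  }
  stop("cannot determine latent size")
}

#' Fine-tune a pretrained model on a new task set
#'
#' Uses the pretrained weights as an informed initialization: the output
#' layer is replaced by a fresh dense map to `t_out` tasks, every weight is
#' trainable, and training runs for `cfg$epochs` epochs (commonly 30 or
#' 50).  `epochs = 0` returns the re-headed model untouched.
#'
#' @param model pretrained `gi_model` (same input space as `x`).
#' @param x,y new-task data as in [train()].
#' @param cfg a [train_config()].
#' @param t_out number of target tasks (default 36).
#' @param seed optional seed for the fresh output layer.
#' @return list with `model` and `history` as in [train()].
#' @export
fine_tune <- function(model, x, y, cfg = train_config(), t_out = ncol(y),
                      seed = NULL) {
  x <- as_model_input(x)
  check_input_space(model, x)
  last <- model$layers[[length(model$layers)]]
  if (last$type != "dense") stop("expected a dense output layer to replace")
  fresh <- if (is.null(seed)) layer_dense(last$d_in, t_out, bias = TRUE)
           else with_private_rng(seed, layer_dense(last$d_in, t_out, bias = TRUE))
  model$layers[[length(model$layers)]] <- fresh
  model$trainable <- rep(TRUE, length(model$layers))
  model$variant <- paste0(model$variant, "-finetuned")
  if (cfg$epochs == 0) {
    return(list(model = model,
                history = data.frame(epoch = integer(0), loss = numeric(0),
                                     lr = numeric(0))))
  }
  train(model, x, y, cfg)
}

check_input_space <- function(model, x) {
  if (model$input_kind == "array3d") {
    if (length(dim(x)) != 3) stop("model expects an N x G x 17 array input")
    if (!is.null(model$spec) && !is.null(model$spec$G) &&
        dim(x)[2] != model$spec$G) {
      stop("input has ", dim(x)[2], " genes but model was built for ",
           model$spec$G)
    }
  } else if (length(dim(x)) != 2) {
    stop("model expects a matrix input")
  }
  invisible(TRUE)
}

#' Save / load a model checkpoint
#'
#' Flat parameter table (binary doubles) plus a JSON manifest describing
#' layers, trainability, the architecture spec and the seed.
#'
#' @param model a `gi_model`.
#' @param prefix path prefix (`<prefix>.bin`, `<prefix>.json`).
#' @param extra optional list merged into the manifest (e.g. train config).
#' @return the prefix, invisibly.
#' @export
save_checkpoint <- function(model, prefix, extra = list()) {
  flat <- unlist(lapply(model$layers, function(l) unlist(l$params)))
  con <- file(paste0(prefix, ".bin"), "wb")
  writeBin(as.vector(flat), con, size = 8, endian = "little")
  close(con)
  shapes <- lapply(model$layers, function(l)
    lapply(l$params, function(p) if (is.null(dim(p))) length(p) else dim(p)))
  manifest <- c(list(variant = model$variant, trainable = model$trainable,
                     body_end = model$body_end, input_kind = model$input_kind,
                     layer_types = vapply(model$layers, `[[`, "", "type"),
                     shapes = shapes, spec = unclass(model$spec)),
                extra)
  jsonlite::write_json(manifest, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}
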