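# Minimal feed-forward layer toolkit with explicit reverse-mode gradients.
#
# Each layer is a plain list with a `type`, a named list of `params`, and
# whatever static fields the forward pass needs.  `layer_forward()` returns
# the output plus a cache; `layer_backward()` consumes the cache and the
# upstream gradient and returns the input gradient plus per-parameter
# gradients with the same shapes as `params`.  Models are sequences of
# layers (see networks.R).  There is deliberately no autograd: the layer
# set is small and the sparse layer needs hand-written gradients anyway.

#' @importFrom Matrix sparseMatrix t colSums
NULL

uniform_fan_in <- function(nrow, ncol = NULL, fan_in = nrow) {
  lim <- 1 / sqrt(fan_in)
  if (is.null(ncol)) {
    stats::runif(nrow, -lim, lim)
  } else {
    matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
  }
}

new_layer <- function(type, params = list(), ...) {
  structure(list(type = type, params = params, ...),
            class = c(paste0("layer_", type), "nn_layer"))
}

layer_dense <- function(d_in, d_out, bias = TRUE) {
  params <- list(W = uniform_fan_in(d_in, d_out))
  if (bias) params$b <- uniform_fan_in(d_out, fan_in = d_in)
  new_layer("dense", params, d_in = d_in, d_out = d_out, bias = bias)
}

layer_tanh <- function() new_layer("tanh")

# Affine layer normalization over the feature axis: gain + offset per unit.
layer_layernorm <- function(d, eps = 1e-5) {
  new_layer("layernorm", list(g = rep(1, d), b = rep(0, d)), d = d, eps = eps)
}

# Knowledge-sparsified linear map.  Only the (gene i -> pathway j) positions
# listed in the mask carry trainable weights; a single offset is shared by
# every output node.  Everything else is structurally zero, so gradients at
# masked-out positions do not exist, let alone update.
layer_masked_linear <- function(mask_i, mask_j, d_in, d_out) {
  stopifnot(length(mask_i) == length(mask_j))
  e <- length(mask_i)
  new_layer("masked_linear",
            list(w = uniform_fan_in(e, fan_in = max(1, e / d_out)),
                 b = 0),
            mask_i = as.integer(mask_i), mask_j = as.integer(mask_j),
            d_in = d_in, d_out = d_out, n_edges = e)
}

# Drops the final column (the dummy-pathway node) so it does not feed the
# hidden layer; backward pads a zero gradient back in.
layer_drop_last <- function() new_layer("drop_last")

# Shared per-gene compressor: every gene's 17-type histogram goes through the
# same two dense layers (tanh in between) down to one scalar mutational-load
# value.  Input is an N x G x Tv array, output an N x G matrix.
layer_gene_module <- function(d_types, d_hidden) {
  new_layer("gene_module",
            list(W1 = uniform_fan_in(d_types, d_hidden),
                 b1 = uniform_fan_in(d_hidden, fan_in = d_types),
                 W2 = uniform_fan_in(d_hidden, 1),
                 b2 = uniform_fan_in(1, fan_in = d_hidden)),
            d_types = d_types, d_hidden = d_hidden)
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    dense = {
      out <- x %*% layer$params$W
      if (layer$bias) out <- sweep(out, 2, layer$params$b, "+")
      list(out = out, cache = list(x = x))
    },
    tanh = {
      out <- tanh(x)
      list(out = out, cache = list(out = out))
    },
    layernorm = {
      mu <- rowMeans(x)
      xc <- x - mu
      v <- rowMeans(xc^2)
      inv <- 1 / sqrt(v + layer$eps)
      xhat <- xc * inv
      out <- sweep(sweep(xhat, 2, layer$params$g, "*"), 2, layer$params$b, "+")
      list(out = out, cache = list(xhat = xhat, inv = inv))
    },
    masked_linear = {
      W <- Matrix::sparseMatrix(i = layer$mask_i, j = layer$mask_j,
                                x = layer$params$w,
                                dims = c(layer$d_in, layer$d_out))
      out <- as.matrix(x %*% W) + layer$params$b
      list(out = out, cache = list(x = x, W = W))
    },
    drop_last = {
      list(out = x[, -ncol(x), drop = FALSE], cache = list(d = ncol(x)))
    },
    gene_module = {
      dm <- dim(x)
      xm <- matrix(x, nrow = dm[1] * dm[2], ncol = dm[3])
      a1 <- sweep(xm %*% layer$params$W1, 2, layer$params$b1, "+")
      h <- tanh(a1)
      o <- h %*% layer$params$W2 + layer$params$b2[1]
      list(out = matrix(o, dm[1], dm[2]),
           cache = list(xm = xm, h = h, dm = dm))
    },
    stop("unknown layer type: ", layer$type)
  )
}

# Returns list(dx = ..., grads = list matching layer$params or NULL).
layer_backward <- function(layer, cache, dout, want_grads = TRUE) {
  switch(layer$type,
    dense = {
      dx <- dout %*% t(layer$params$W)
      grads <- NULL
      if (want_grads) {
        grads <- list(W = crossprod(cache$x, dout))
        if (layer$bias) grads$b <- colSums(dout)
      }
      list(dx = dx, grads = grads)
    },
    tanh = {
      list(dx = dout * (1 - cache$out^2), grads = NULL)
    },
    layernorm = {
      xhat <- cache$xhat
      dxhat <- sweep(dout, 2, layer$params$g, "*")
      m1 <- rowMeans(dxhat)
      m2 <- rowMeans(dxhat * xhat)
      dx <- cache$inv * (dxhat - m1 - xhat * m2)
      grads <- NULL
      if (want_grads) {
        grads <- list(g = colSums(dout * xhat), b = colSums(dout))
      }
      list(dx = dx, grads = grads)
    },
    masked_linear = {
      dx <- as.matrix(dout %*% Matrix::t(cache$W))
      grads <- NULL
      if (want_grads) {
        dw <- colSums(cache$x[, layer$mask_i, drop = FALSE] *
                        dout[, layer$mask_j, drop = FALSE])
        grads <- list(w = dw, b = sum(dout))
      }
      list(dx = dx, grads = grads)
    },
    drop_last = {
      dx <- cbind(dout, 0)
      list(dx = dx, grads = NULL)
    },
    gene_module = {
      dm <- cache$dm
      do <- matrix(dout, nrow = dm[1] * dm[2], ncol = 1)
      da1 <- (do %*% t(layer$params$W2)) * (1 - cache$h^2)
      dxm <- da1 %*% t(layer$params$W1)
      grads <- NULL
      if (want_grads) {
        grads <- list(W1 = crossprod(cache$xm, da1),
                      b1 = colSums(da1),
                      W2 = crossprod(cache$h, do),
                      b2 = sum(do))
      }
      list(dx = array(dxm, dm), grads = grads)
    },
    stop("unknown layer type: ", layer$type)
  )
}

n_layer_params <- function(layer) {
  if (is.null(layer$params)) return(0L)
  sum(vapply(layer$params, length, integer(1)))
}
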