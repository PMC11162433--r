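# Architecture family: shared gene module, dense trunk, knowledge-sparsified
# trunk, transfer-learning head and the GPS-only baseline, with exact
# parameter accounting.

#' Declarative architecture description
#'
#' @param variant one of `"galiana-dense"`, `"bmsnn"`, `"gps-baseline"`.
#'   (`"frozen-head"` models are produced by [freeze_and_extend()], not
#'   built directly.)
#' @param G number of genes.
#' @param n_types variant types per gene (17).
#' @param d gene-latent size of the dense trunk (50; reverse-derived from
#'   the transfer-head arithmetic, see the vignette).
#' @param g_hidden hidden width of the shared per-gene compressor.
#' @param P_real number of real pathway nodes (sparsified trunk only).
#' @param H hidden width (sparsified trunk / heads).
#' @param T_out number of output tasks (36 = 18 elements x 2 tissues).
#' @param lambda L2 coefficient carried for bookkeeping.
#' @return An `architecture_spec`.
#' @export
architecture_spec <- function(variant = c("galiana-dense", "bmsnn", "gps-baseline"),
                              G = NULL, n_types = 17L, d = 50L, g_hidden = 8L,
                              P_real = NULL, H = 50L, T_out = 36L,
                              lambda = if (match.arg(variant) == "bmsnn") 1e-4 else 1e-6) {
  variant <- match.arg(variant)
  sizes <- c(n_types = n_types, d = d, g_hidden = g_hidden, H = H, T_out = T_out)
  if (any(sizes <= 0)) stop("all sizes must be positive")
  if (variant != "gps-baseline" && (is.null(G) || G <= 0)) {
    stop("variant '", variant, "' requires a positive gene count G")
  }
  if (variant == "bmsnn" && (is.null(P_real) || P_real <= 0)) {
    stop("variant 'bmsnn' requires a positive pathway count P_real")
  }
  structure(list(variant = variant, G = G, n_types = as.integer(n_types),
                 d = as.integer(d), g_hidden = as.integer(g_hidden),
                 P_real = if (is.null(P_real)) NULL else as.integer(P_real),
                 H = as.integer(H), T_out = as.integer(T_out),
                 lambda = lambda),
            class = "architecture_spec")
}

#' Specification of the transfer-learning head (I module)
#'
#' Dense map to `H` hidden units, affine layer normalization (gain and
#' offset per unit), tanh, then a dense map with offsets to `T_out` tasks.
#' Trainable parameter count is `d_in*H + H + 2H + H*T_out + T_out`.
#'
#' @param d_in input size (50 for the frozen-body latent, 3 for GPS).
#' @param H hidden units (200 or 500 in the studied configurations).
#' @param T_out output tasks (36).
#' @return An `i_module_spec`.
#' @export
i_module_spec <- function(d_in, H, T_out = 36L) {
  stopifnot(d_in > 0, H > 0, T_out > 0)
  structure(list(d_in = as.integer(d_in), H = as.integer(H),
                 T_out = as.integer(T_out)),
            class = "i_module_spec")
}

new_model <- function(layers, trainable = rep(TRUE, length(layers)),
                      variant = "custom", body_end = NA_integer_,
                      spec = NULL, input_kind = "matrix") {
  structure(list(layers = layers, trainable = trainable, variant = variant,
                 body_end = body_end, spec = spec, input_kind = input_kind),
            class = "gi_model")
}

#' Build the shared per-gene compressor (G module)
#'
#' A two-layer dense map, shared across all genes, that compresses each
#' gene's 17-dimensional variant-type histogram to one scalar mutational
#' load.  Weight sharing means permuting gene order permutes the outputs
#' identically.
#'
#' @param spec an [architecture_spec()] with a gene dimension.
#' @return A `gi_model` mapping N x G x 17 arrays to N x G matrices.
#' @export
build_g_module <- function(spec) {
  if (spec$variant == "gps-baseline") stop("GPS baseline has no gene module")
  new_model(list(layer_gene_module(spec$n_types, spec$g_hidden)),
            variant = "g-module", input_kind = "array3d")
}

#' Build the transfer-learning head (I module)
#'
#' @param spec an [i_module_spec()].
#' @return A `gi_model`.
#' @export
build_i_head <- function(spec) {
  new_model(list(layer_dense(spec$d_in, spec$H, bias = TRUE),
                 layer_layernorm(spec$H),
                 layer_tanh(),
                 layer_dense(spec$H, spec$T_out, bias = TRUE)),
            variant = "i-head")
}

#' Build the knowledge-sparsified trunk
#'
#' Gene scalars feed the pathway layer through the masked linear map (one
#' trainable weight per mask edge plus one offset shared by all pathway
#' nodes), then the real pathway nodes (dummy excluded) feed `H` hidden
#' units through an offset-free dense map.  Trunk weight count is
#' `E + 1 + P_real * H`.
#'
#' @param spec an [architecture_spec()] with variant `"bmsnn"`.
#' @param mask a `sparsity_mask` from [build_mask()] over the same genes.
#' @return A `gi_model` for the trunk alone (gene scalars in, hidden out).
#' @export
build_bmsnn_trunk <- function(spec, mask) {
  if (mask$n_genes != spec$G) {
    stop("mask covers ", mask$n_genes, " genes but spec$G = ", spec$G)
  }
  if (mask$p_real != spec$P_real) {
    stop("mask has ", mask$p_real, " pathways but spec$P_real = ", spec$P_real)
  }
  new_model(list(layer_masked_linear(mask$i, mask$j, spec$G, mask$p_total),
                 layer_drop_last(),
                 layer_dense(spec$P_real, spec$H, bias = FALSE)),
            variant = "bmsnn-trunk")
}

#' Build the fully connected trunk
#'
#' Dense map from G gene scalars to the d-dimensional latent (with offsets)
#' followed by tanh.  This is the over-parameterized reference trunk the
#' sparsified one replaces.
#'
#' @param spec an [architecture_spec()] with variant `"galiana-dense"`.
#' @return A `gi_model`.
#' @export
build_dense_trunk <- function(spec) {
  new_model(list(layer_dense(spec$G, spec$d, bias = TRUE), layer_tanh()),
            variant = "dense-trunk")
}

#' Assemble a complete predictive model
#'
#' * `galiana-dense`: gene module -> dense trunk to the d-latent -> dense
#'   T-task output layer.
#' * `bmsnn`: gene module -> masked pathway layer -> offset-free dense map
#'   to H hidden units -> tanh -> dense T-task output layer.
#' * `gps-baseline`: the I head applied to the 3-dimensional unit-sphere
#'   GPS features (H hidden units, default 500).
#'
#' @param spec an [architecture_spec()].
#' @param mask `sparsity_mask`, required for the `"bmsnn"` variant.
#' @param seed optional integer; when given, initialization is drawn from a
#'   private RNG stream so model building does not disturb the caller's.
#' @return A `gi_model`.
#' @export
build_model <- function(spec, mask = NULL, seed = NULL) {
  build <- function() {
    switch(spec$variant,
      "galiana-dense" = {
        layers <- c(build_g_module(spec)$layers,
                    build_dense_trunk(spec)$layers,
                    list(layer_dense(spec$d, spec$T_out, bias = TRUE)))
        new_model(layers, variant = "galiana-dense", body_end = 3L,
                  spec = spec, input_kind = "array3d")
      },
      "bmsnn" = {
        if (is.null(mask)) stop("variant 'bmsnn' requires a sparsity mask")
        layers <- c(build_g_module(spec)$layers,
                    build_bmsnn_trunk(spec, mask)$layers,
                    list(layer_tanh(),
                         layer_dense(spec$H, spec$T_out, bias = TRUE)))
        new_model(layers, variant = "bmsnn", body_end = 5L,
                  spec = spec, input_kind = "array3d")
      },
      "gps-baseline" = {
        m <- build_i_head(i_module_spec(3L, spec$H, spec$T_out))
        m$variant <- "gps-baseline"
        m$spec <- spec
        m
      },
      stop("unknown variant: ", spec$variant))
  }
  if (is.null(seed)) build() else with_private_rng(seed, build())
}

# Run `expr` under a seeded private RNG stream, restoring the caller's.
with_private_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

forward_model <- function(model, x, keep_caches = FALSE) {
  caches <- if (keep_caches) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    fw <- layer_forward(model$layers[[i]], x)
    x <- fw$out
    if (keep_caches) caches[[i]] <- fw$cache
  }
  list(out = x, caches = caches)
}

backward_model <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    bw <- layer_backward(model$layers[[i]], caches[[i]], dout,
                         want_grads = model$trainable[i])
    grads[i] <- list(bw$grads)   # plain [[<-]] would drop NULL entries
    dout <- bw$dx
  }
  list(dx = dout, grads = grads)
}

#' Predict from a fitted model
#' @param object a `gi_model`.
#' @param newdata input matrix (or N x G x 17 array for genomic variants);
#'   a `gene_mutation_tensor` is accepted and unwrapped.
#' @param ... unused.
#' @return N x T matrix of predictions.
#' @export
predict.gi_model <- function(object, newdata, ...) {
  newdata <- as_model_input(newdata)
  forward_model(object, newdata)$out
}

as_model_input <- function(x) {
  if (inherits(x, "gene_mutation_tensor")) unclass(x)$values else x
}

#' Count trainable parameters
#'
#' Counts the trainable scalar parameters of a layer or model.  Masked
#' layers contribute only their masked-in weights (plus the shared offset);
#' frozen layers contribute nothing.
#'
#' @param x a `gi_model` or single layer.
#' @param trainable_only count only trainable layers (default TRUE).
#' @return integer.
#' @export
count_parameters <- function(x, trainable_only = TRUE) {
  UseMethod("count_parameters")
}

#' @export
count_parameters.gi_model <- function(x, trainable_only = TRUE) {
  keep <- if (trainable_only) x$trainable else rep(TRUE, length(x$layers))
  as.integer(sum(vapply(x$layers[keep], n_layer_params, numeric(1))))
}

#' @export
count_parameters.nn_layer <- function(x, trainable_only = TRUE) {
  as.integer(n_layer_params(x))
}

#' @export
print.gi_model <- function(x, ...) {
  cat(sprintf("gi_model '%s': %d layers, %d trainable parameters\n",
              x$variant, length(x$layers), count_parameters(x)))
  for (i in seq_along(x$layers)) {
    cat(sprintf("  [%d] %-14s %7d params%s\n", i, x$layers[[i]]$type,
                n_layer_params(x$layers[[i]]),
                if (x$trainable[i]) "" else "  (frozen)"))
  }
  invisible(x)
}

#' Unit-sphere GPS feature map
#'
#' Maps latitude/longitude in degrees to the 3-vector
#' `(sin(lat), sin(lon), cos(lon))` after degree-to-radian conversion, so
#' geographically close origins get close features and longitude wraps
#' continuously (the last two components lie on the unit circle).
#'
#' @param lat latitude in degrees, in \[-90, 90\].
#' @param lon longitude in degrees, in \[-180, 180\].
#' @return N x 3 matrix.
#' @export
gps_features <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90 | lat > 90)) {
    stop("latitude out of range [-90, 90]")
  }
  if (any(lon < -180 | lon > 180)) stop("longitude out of range [-180, 180]")
  la <- lat * pi / 180
  lo <- lon * pi / 180
  cbind(sin_lat = sin(la), sin_lon = sin(lo), cos_lon = cos(lo))
}
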