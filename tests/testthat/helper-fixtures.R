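# Shared fixtures: all tiny objects are built in code.

vocab <- bmsnn::variant_vocabulary()

# toy table: s1 carries 2 nonsynonymous + 1 intronic on g1
toy_records <- function() {
  data.frame(
    sample = c("s1", "s1", "s1"),
    gene = c("g1", "g1", "g1"),
    variant_type = c("nonsynonymous", "nonsynonymous", "intronic"),
    variant_id = c("v1", "v1b", "v2"),
    stringsAsFactors = FALSE)
}

toy_table <- function(genes = c("g1", "g2", "g3")) {
  variant_table(toy_records(), genes = genes, samples = "s1")
}

# random long table over n samples, g genes, ~lambda records per sample
random_table <- function(n = 8, g = 6, lambda = 10, seed = 1) {
  set.seed(seed)
  n_rec <- stats::rpois(1, n * lambda)
  rec <- data.frame(
    sample = sprintf("s%02d", sample.int(n, n_rec, replace = TRUE)),
    gene = sprintf("g%02d", sample.int(g, n_rec, replace = TRUE)),
    variant_type = sample(vocab, n_rec, replace = TRUE),
    stringsAsFactors = FALSE)
  rec$variant_id <- paste(rec$gene, rec$variant_type, sep = ":")
  variant_table(rec, genes = sprintf("g%02d", seq_len(g)),
                samples = sprintf("s%02d", seq_len(n)))
}

toy_mask <- function() {
  pm <- pathway_map(c("g1", "g2", "g2"), c("p1", "p1", "p2"),
                    pathways = c("p1", "p2"))
  build_mask(pm, c("g1", "g2", "g3"), rule = "primary")
}

# dense-layer oracle for the masked layer: same edge weights in a dense
# matrix with structural zeros elsewhere; gradients computed with the
# standard dense formulas.
dense_oracle <- function(layer, x, dout) {
  W <- matrix(0, layer$d_in, layer$d_out)
  W[cbind(layer$mask_i, layer$mask_j)] <- layer$params$w
  out <- x %*% W + layer$params$b
  dW <- crossprod(x, dout)
  list(out = out, dW = dW, db = sum(dout), dx = dout %*% t(W), W = W)
}

random_masked_layer <- function(d_in, d_out, density = 0.3) {
  keep <- which(matrix(stats::runif(d_in * d_out) < density, d_in, d_out),
                arr.ind = TRUE)
  if (nrow(keep) == 0) keep <- cbind(1L, 1L)
  l <- bmsnn:::layer_masked_linear(keep[, 1], keep[, 2], d_in, d_out)
  l$params$w <- stats::rnorm(length(l$params$w))
  l$params$b <- stats::rnorm(1)
  l
}
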