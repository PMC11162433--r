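# Gene-to-pathway annotation maps and the sparse connectivity mask they
# induce for the knowledge-sparsified trunk.

#' Gene-to-pathway annotation map
#'
#' Holds a bipartite gene/pathway annotation in the two-column "bin export"
#' style used by plant pathway databases: one row per (gene, pathway)
#' association, genes possibly annotated to several pathways, genes absent
#' from the map treated as unannotated.
#'
#' @param gene character vector of gene ids (repeated for multi-membership).
#' @param pathway character vector of pathway ids, same length as `gene`.
#' @param pathways optional ordered pathway universe; defaults to the
#'   pathways observed, in first-appearance order.
#' @return A `pathway_map` object.
#' @export
pathway_map <- function(gene, pathway, pathways = NULL) {
  stopifnot(length(gene) == length(pathway))
  gene <- as.character(gene)
  pathway <- as.character(pathway)
  if (is.null(pathways)) pathways <- unique(pathway)
  if (!all(pathway %in% pathways)) {
    bad <- setdiff(unique(pathway), pathways)
    stop("pathway ids not in universe: ", paste(bad, collapse = ", "))
  }
  structure(list(gene = gene, pathway = pathway,
                 pathways = as.character(pathways)),
            class = "pathway_map")
}

#' Read a two-column gene/pathway table
#'
#' @param path tab-separated file with columns `gene` and `pathway`
#'   (header optional; two unnamed columns are accepted).
#' @return A [pathway_map()].
#' @export
read_pathway_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "pathway") %in% names(df))) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1:2] <- c("gene", "pathway")
  }
  pathway_map(df$gene, df$pathway)
}

#' Write a pathway map to a two-column TSV
#' @param map a [pathway_map()].
#' @param path output file.
#' @export
write_pathway_map <- function(map, path) {
  utils::write.table(data.frame(gene = map$gene, pathway = map$pathway),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the sparse gene-to-pathway connectivity mask
#'
#' Produces the binary G x (P_real + 1) connectivity pattern of the
#' sparsified trunk.  The extra final column is the dummy pathway that
#' absorbs unannotated genes so their signal is not discarded.  Under the
#' `"primary"` rule every gene contributes exactly one edge (its first
#' listed pathway, ties broken by pathway-universe order), so the edge count
#' equals the number of genes; under `"all-edges"` every (gene, pathway)
#' association becomes an edge.
#'
#' @param map a [pathway_map()].
#' @param genes ordered gene universe (character).
#' @param rule `"primary"` (default) or `"all-edges"`.
#' @return A `sparsity_mask`: list with integer vectors `i` (gene index),
#'   `j` (pathway-node index), the dimensions, and the edge count `E`.
#' @export
build_mask <- function(map, genes, rule = c("primary", "all-edges")) {
  rule <- match.arg(rule)
  genes <- as.character(genes)
  if (length(genes) == 0) stop("gene universe is empty")
  p_real <- length(map$pathways)
  dummy <- p_real + 1L
  g_idx <- match(map$gene, genes)
  keep <- !is.na(g_idx)
  p_idx <- match(map$pathway[keep], map$pathways)
  g_idx <- g_idx[keep]

  if (rule == "primary") {
    j <- rep.int(dummy, length(genes))
    if (length(g_idx)) {
      # first listed association wins; among duplicates of the first listed
      # position, pathway-universe order is already the tiebreak because
      # match() returns universe indices and we take the first record.
      first <- !duplicated(g_idx)
      j[g_idx[first]] <- p_idx[first]
    }
    i <- seq_along(genes)
  } else {
    pairs <- unique(cbind(g_idx, p_idx))
    annotated <- unique(pairs[, 1])
    un <- setdiff(seq_along(genes), annotated)
    i <- c(pairs[, 1], un)
    j <- c(pairs[, 2], rep.int(dummy, length(un)))
    o <- order(i, j)
    i <- i[o]; j <- j[o]
  }
  structure(list(i = as.integer(i), j = as.integer(j),
                 n_genes = length(genes), p_real = p_real,
                 p_total = dummy, E = length(i), rule = rule,
                 genes = genes,
                 pathways = c(map$pathways, ".dummy")),
            class = "sparsity_mask")
}

#' @export
print.sparsity_mask <- function(x, ...) {
  cat(sprintf("sparsity_mask: %d genes x %d pathway nodes (+dummy), %d edges, rule=%s\n",
              x$n_genes, x$p_real, x$E, x$rule))
  invisible(x)
}

#' Export a mask as a sparse triplet table
#' @param mask a `sparsity_mask`.
#' @return data.frame with columns gene, pathway, value (all 1).
#' @export
mask_triplets <- function(mask) {
  data.frame(gene = mask$genes[mask$i],
             pathway = mask$pathways[mask$j],
             value = 1L)
}
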