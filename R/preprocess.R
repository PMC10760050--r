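#' LSI embedding of a tile matrix
#'
#' Term frequency-inverse document frequency (TF-IDF) normalization followed
#' by a truncated singular value decomposition, the standard latent semantic
#' indexing used for sparse chromatin count matrices. Tiles are ranked by
#' count variance and the top `var_features` retained before the
#' decomposition.
#'
#' @param tiles A `tile_matrix`.
#' @param n_dims Number of embedding dimensions (default 30).
#' @param var_features Number of most-variable tiles to use (default 25000).
#' @return spots x `n_dims` matrix; rownames are barcodes. Component signs
#'   follow the largest-magnitude-loading-positive convention, so the result
#'   is deterministic.
#' @export
lsi_embed <- function(tiles, n_dims = 30L, var_features = 25000L) {
  X <- tiles$counts
  stop_if(sum(X) == 0, "all-zero tile matrix")
  csums <- Matrix::colSums(X)
  stop_if(any(csums == 0), "spots with zero total counts: ",
          paste(utils::head(tiles$barcodes[csums == 0]), collapse = ", "))

  rmean <- Matrix::rowMeans(X)
  rvar <- Matrix::rowMeans(X^2) - rmean^2
  keep <- which(rvar > 0)
  stop_if(length(keep) < n_dims + 1L,
          "need more than n_dims tiles with nonzero variance")
  if (length(keep) > var_features)
    keep <- keep[order(rvar[keep], decreasing = TRUE)[seq_len(var_features)]]
  X <- X[keep, , drop = FALSE]

  # TF: per-spot frequencies; IDF: log(1 + n_spots / n_spots_with_tile)
  tf <- X %*% Matrix::Diagonal(x = 1 / csums)
  idf <- log1p(ncol(X) / Matrix::rowSums(X > 0))
  A <- Matrix::Diagonal(x = idf) %*% tf

  n_dims <- min(n_dims, ncol(A) - 1L, nrow(A))
  # spots x spots Gram matrix keeps the decomposition cheap for tall matrices
  G <- as.matrix(Matrix::crossprod(A))
  eig <- eigen(G, symmetric = TRUE)
  d2 <- pmax(eig$values[seq_len(n_dims)], 0)
  emb <- eig$vectors[, seq_len(n_dims), drop = FALSE] %*% diag(sqrt(d2), n_dims)
  emb <- apply(emb, 2L, fix_sign)
  rownames(emb) <- tiles$barcodes
  colnames(emb) <- paste0("LSI", seq_len(n_dims))
  attr(emb, "features") <- keep
  emb
}

#' Cluster spots on a shared-nearest-neighbor graph
#'
#' Builds a kNN graph in embedding space, reweights edges by the Jaccard
#' overlap of neighborhoods (shared nearest neighbors), prunes weak edges
#' and runs Louvain community detection.
#'
#' @param embedding spots x dims matrix (e.g. from [lsi_embed()]).
#' @param resolution Louvain resolution (default 1).
#' @param k Number of nearest neighbors for the SNN graph (default 40;
#'   small neighborhoods fragment contiguous clusters under modularity
#'   optimization).
#' @param prune Jaccard pruning threshold (default 1/15).
#' @param seed Random seed; clustering is deterministic given the seed.
#' @return A `cluster_assignment`: integer vector of labels `0..K-1` named
#'   by barcode, with attribute `K`. Labels are ordered by cluster size.
#' @export
cluster_spots <- function(embedding, resolution = 1.0, k = 40L,
                          prune = 1 / 15, seed = 1L) {
  stop_if(nrow(embedding) < 2L, "need at least 2 spots to cluster")
  stop_if(!all(is.finite(embedding)), "embedding must be finite")
  n <- nrow(embedding)
  k <- min(k, n - 1L)
  d2 <- cross_dist2(embedding, embedding)
  # neighborhoods include the spot itself, as is conventional for SNN graphs
  nbrs <- lapply(seq_len(n), function(i)
    order(d2[i, ])[seq_len(k + 1L)])
  memb <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k + 1L), j = unlist(nbrs), x = 1,
    dims = c(n, n))
  shared <- Matrix::tcrossprod(memb)
  jac <- as.matrix(shared) / (2 * (k + 1L) - as.matrix(shared))
  jac[jac < prune] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  comm <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  lab <- as.integer(igraph::membership(comm))
  # relabel by decreasing size, ties by first occurrence, to 0..K-1
  sizes <- table(lab)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relab <- match(lab, as.integer(names(sizes))[ord]) - 1L
  res <- stats::setNames(relab, rownames(embedding))
  attr(res, "K") <- length(sizes)
  class(res) <- "cluster_assignment"
  res
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", length(x), "spots in", attr(x, "K"),
      "clusters\n")
  print(table(unclass(x)))
  invisible(x)
}

#' Externally supplied cluster labels
#'
#' Wraps given labels (e.g. planted region labels of a synthetic layout, or
#' an annotation from another tool) as a `cluster_assignment`, bypassing
#' graph clustering.
#'
#' @param labels Vector of labels named by barcode (factor/character/integer).
#' @return A `cluster_assignment` with labels recoded to `0..K-1` in order
#'   of first appearance.
#' @export
as_cluster_assignment <- function(labels) {
  stop_if(is.null(names(labels)), "labels must be named by barcode")
  lv <- unique(as.character(labels))
  res <- stats::setNames(match(as.character(labels), lv) - 1L, names(labels))
  attr(res, "K") <- length(lv)
  attr(res, "level_names") <- lv
  class(res) <- "cluster_assignment"
  res
}

#' Per-cluster pseudobulk tracks
#'
#' Sums insertion events of all spots in each cluster into fixed-width bins
#' and binarizes at a count cutoff (the track preparation used for chromatin
#' state segmentation).
#'
#' @param frags A `fragment_set`.
#' @param assign A `cluster_assignment` covering the fragment barcodes.
#' @param bin_bp Bin width (default 100).
#' @param binarize_cutoff Binarization cutoff, flag = count >= cutoff
#'   (default 5).
#' @param chrom_lengths Optional named chromosome lengths so all clusters
#'   share one bin layout (default: derived from the fragments).
#' @param per_spot_mean Also return the per-spot mean track (raw / cluster
#'   size) as the `mean_bins` element (default TRUE).
#' @return Named list of `signal_track`, one per cluster label.
#' @export
make_pseudobulk <- function(frags, assign, bin_bp = 100L, binarize_cutoff = 5,
                            chrom_lengths = NULL, per_spot_mean = TRUE) {
  miss <- setdiff(unique(frags$barcode), names(assign))
  stop_if(length(miss) > 0L,
          "barcodes without cluster label: ", paste(utils::head(miss), collapse = ", "))
  if (is.null(chrom_lengths)) {
    mx <- tapply(frags$end, frags$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(mx), names(mx))
  }
  labs <- sort(unique(unclass(assign)))
  out <- lapply(labs, function(cl) {
    bc <- names(assign)[unclass(assign) == cl]
    sub <- frags[frags$barcode %in% bc, ]
    stop_if(nrow(sub) == 0L, "cluster ", cl, " has no fragments")
    tr <- bin_insertions(sub, bin_bp, binarize_cutoff, chrom_lengths)
    if (per_spot_mean)
      tr$mean_bins <- lapply(tr$bins, function(v) v / length(bc))
    tr$n_spots <- length(bc)
    tr
  })
  names(out) <- as.character(labs)
  out
}
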