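#' Build a spatial kNN network over spots
#'
#' Each spot is linked to its `k` nearest neighbors strictly closer than
#' `max_dist` micrometers; the edge set is symmetrized by union, so a node
#' can end up with more than `k` incident edges but selected at most `k`
#' itself. Isolated spots are allowed (`min_k = 0`). The strict inequality
#' means that on a grid of pitch `p` with `max_dist = 2p`, interior spots
#' link to their 8 immediate (rook + diagonal) neighbors but not to the
#' second rook ring at exactly `2p`.
#'
#' @param spots A `spot_grid`.
#' @param k Neighbors per spot (default 10).
#' @param max_dist Maximal edge length in the physical units of the grid
#'   (default 40).
#' @param min_k Minimum neighbors to keep regardless of `max_dist`
#'   (default 0; only 0 is currently supported).
#' @return A `spatial_network`: list with `nodes` (barcodes) and `edges`
#'   (data.frame from, to, length; `from < to` as indices into `nodes`).
#' @export
build_spatial_network <- function(spots, k = 10L, max_dist = 40, min_k = 0L) {
  stop_if(k < 0, "k must be non-negative")
  stop_if(min_k != 0L, "only min_k = 0 is supported")
  xy <- cbind(spots$x, spots$y)
  stop_if(!all(is.finite(xy)), "spot coordinates must be finite")
  n <- nrow(xy)
  edges <- NULL
  if (k > 0L && n > 1L) {
    d2 <- cross_dist2(xy, xy)
    diag(d2) <- Inf
    kk <- min(k, n - 1L)
    pairs <- lapply(seq_len(n), function(i) {
      nb <- order(d2[i, ])[seq_len(kk)]
      nb <- nb[d2[i, nb] < max_dist^2]
      if (length(nb)) cbind(i, nb) else NULL
    })
    pr <- do.call(rbind, pairs)
    if (!is.null(pr) && nrow(pr)) {
      a <- pmin(pr[, 1L], pr[, 2L]); b <- pmax(pr[, 1L], pr[, 2L])
      keep <- !duplicated(cbind(a, b))
      edges <- data.frame(from = a[keep], to = b[keep],
                          length = sqrt(d2[cbind(a[keep], b[keep])]))
    }
  }
  if (is.null(edges))
    edges <- data.frame(from = integer(), to = integer(), length = numeric())
  structure(list(nodes = spots$barcode, edges = edges, k = k,
                 max_dist = max_dist),
            class = "spatial_network")
}

#' @export
print.spatial_network <- function(x, ...) {
  cat("spatial_network:", length(x$nodes), "spots,", nrow(x$edges),
      "edges (k =", x$k, ", max_dist =", x$max_dist, ")\n")
  invisible(x)
}

#' Binarize a gene's spot scores
#'
#' Rank binarization: the top `fraction` of spots by score are set to 1.
#' Exactly `ceiling(fraction * n)` spots are selected; ties at the threshold
#' are broken by input (barcode) order. A constant gene cannot be binarized
#' and returns all zeros with attribute `constant = TRUE`.
#'
#' @param scores Numeric per-spot scores (named by barcode if available).
#' @param method Only "rank" is implemented.
#' @param fraction Fraction of spots set to 1 (default 0.3).
#' @return Integer 0/1 vector of the same length and names.
#' @export
binarize_gene <- function(scores, method = "rank", fraction = 0.3) {
  method <- match.arg(method, "rank")
  n <- length(scores)
  out <- stats::setNames(integer(n), names(scores))
  if (length(unique(scores)) < 2L) {
    attr(out, "constant") <- TRUE
    return(out)
  }
  n1 <- ceiling(fraction * n)
  ord <- order(-scores, seq_len(n))
  out[ord[seq_len(n1)]] <- 1L
  out
}

# 2x2 edge contingency table; each undirected edge is counted in both
# orientations, giving the symmetric table [[2*HH, M], [M, 2*LL]]
binspect_table <- function(binary, net) {
  f <- binary[net$edges$from] == 1L
  t <- binary[net$edges$to] == 1L
  hh <- sum(f & t)
  ll <- sum(!f & !t)
  m <- nrow(net$edges) - hh - ll
  matrix(c(2 * hh, m, m, 2 * ll), 2L, 2L,
         dimnames = list(c("high", "low"), c("high", "low")))
}

#' Edge-based spatial coherence test for one binarized gene
#'
#' Classifies every network edge by its endpoint pattern (1-1, mixed, 0-0;
#' both orientations counted) and applies a one-sided Fisher exact test for
#' enrichment of 1-1 edges. A gene whose high spots clump together in the
#' network produces an excess of 1-1 edges and a small p-value.
#'
#' @param binary 0/1 vector over all network nodes (see [binarize_gene()]).
#' @param net A `spatial_network`.
#' @return List with `odds_ratio` (sample odds ratio of the 2x2 table; `NA`
#'   when degenerate), `p_value`, and `table`.
#' @export
binspect_test <- function(binary, net) {
  stop_if(nrow(net$edges) == 0L, "network has no edges")
  stop_if(length(binary) != length(net$nodes),
          "binary vector must cover all network nodes")
  tab <- binspect_table(binary, net)
  or <- (tab[1L, 1L] * tab[2L, 2L]) / (tab[1L, 2L] * tab[2L, 1L])
  if (!is.finite(or)) or <- NA_real_
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(odds_ratio = or, p_value = p, table = tab)
}

#' Spatially coherent gene detection over a score matrix
#'
#' Runs [binarize_gene()] + [binspect_test()] for every gene of a gene
#' score matrix against a spatial network.
#'
#' @param scores genes x spots matrix; columns must match `net$nodes`.
#' @param net A `spatial_network`.
#' @param fraction Binarization fraction (default 0.3).
#' @return data.frame with columns gene, odds_ratio, p_value, constant.
#' @export
binspect <- function(scores, net, fraction = 0.3) {
  stop_if(ncol(scores) != length(net$nodes),
          "score matrix columns must match network nodes")
  ef <- net$edges$from; et <- net$edges$to
  n_edges <- nrow(net$edges)
  stop_if(n_edges == 0L, "network has no edges")
  res <- lapply(seq_len(nrow(scores)), function(g) {
    b <- binarize_gene(scores[g, ], fraction = fraction)
    if (isTRUE(attr(b, "constant")))
      return(data.frame(odds_ratio = NA_real_, p_value = 1, constant = TRUE))
    r <- binspect_test(b, net)
    data.frame(odds_ratio = r$odds_ratio, p_value = r$p_value, constant = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(gene = rownames(scores), out)
  rownames(out) <- NULL
  out
}

#' Rank spatial genes by adjusted p-value
#'
#' Benjamini-Hochberg adjustment over all tested genes, then ranking by
#' ascending adjusted p; ties broken by raw p, then descending odds ratio,
#' then gene name.
#'
#' @param results data.frame from [binspect()] (columns gene, odds_ratio,
#'   p_value).
#' @param top_n Number of top genes to return (default 200; `Inf` for all).
#' @return data.frame gene, odds_ratio, p_value, adj_p_value, rank --
#'   the top `top_n` rows in rank order. Adjustment is computed over all
#'   input genes before truncation.
#' @export
rank_spatial_genes <- function(results, top_n = 200L) {
  stop_if(nrow(results) == 0L, "no tested genes")
  adj <- stats::p.adjust(results$p_value, method = "BH")
  or_key <- ifelse(is.na(results$odds_ratio), -Inf, results$odds_ratio)
  ord <- order(adj, results$p_value, -or_key, results$gene)
  out <- results[ord, , drop = FALSE]
  out$adj_p_value <- adj[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Group spatial genes into co-localization modules
#'
#' Each gene's score vector is smoothed over the spatial network (mean over
#' the spot and its neighbors), genes are correlated (Pearson) on the
#' smoothed profiles, and hierarchically clustered with Ward linkage
#' (ward.D2) on distance `1 - correlation`, cut at `k_modules`.
#'
#' @param scores genes x spots matrix restricted to the spatial genes.
#' @param net A `spatial_network` over the same spots.
#' @param k_modules Number of modules (default 8).
#' @return A `module_assignment`: integer vector 1..k named by gene, with
#'   attributes `smoothed` (the smoothed profile matrix) and `excluded`
#'   (genes with constant smoothed profiles, dropped with a warning).
#' @export
spatial_cor_modules <- function(scores, net, k_modules = 8L) {
  stop_if(nrow(scores) < k_modules, "need at least k_modules genes")
  sm <- smooth_over_network(scores, net)
  const <- apply(sm, 1L, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("excluding ", sum(const), " gene(s) with constant smoothed profile")
    sm <- sm[!const, , drop = FALSE]
  }
  stop_if(nrow(sm) < k_modules, "fewer non-constant genes than k_modules")
  cc <- stats::cor(t(sm))
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "ward.D2")
  mod <- stats::cutree(hc, k = k_modules)
  res <- stats::setNames(as.integer(mod), rownames(sm))
  attr(res, "smoothed") <- sm
  attr(res, "excluded") <- rownames(scores)[const]
  class(res) <- "module_assignment"
  res
}

# network smoothing: value at a spot becomes the mean over {self} u neighbors
smooth_over_network <- function(scores, net) {
  n <- length(net$nodes)
  i <- c(seq_len(n), net$edges$from, net$edges$to)
  j <- c(seq_len(n), net$edges$to, net$edges$from)
  W <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  W <- W %*% Matrix::Diagonal(x = 1 / Matrix::colSums(W))
  out <- as.matrix(scores %*% W)
  dimnames(out) <- dimnames(scores)
  out
}

#' Module metagenes
#'
#' Summarizes each module's spatial pattern as the per-spot mean of its
#' member genes' z-scored (across spots) activity.
#'
#' @param assign A `module_assignment` (or named integer vector gene ->
#'   module).
#' @param scores genes x spots matrix containing all member genes.
#' @return modules x spots matrix of metagene values.
#' @export
metagene <- function(assign, scores) {
  genes <- names(assign)
  stop_if(!all(genes %in% rownames(scores)),
          "scores are missing some module genes")
  z <- t(scale(t(scores[genes, , drop = FALSE])))
  z[!is.finite(z)] <- 0  # constant genes contribute flat zero profiles
  mods <- sort(unique(as.integer(assign)))
  out <- do.call(rbind, lapply(mods, function(m) {
    member <- genes[as.integer(assign) == m]
    stop_if(length(member) == 0L, "module ", m, " has no members")
    colMeans(z[member, , drop = FALSE])
  }))
  rownames(out) <- paste0("M", mods)
  colnames(out) <- colnames(scores)
  out
}
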