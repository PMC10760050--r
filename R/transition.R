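#' Diffusion map embedding of gene scores
#'
#' Projects spots into a low-dimensional diffusion space: Gaussian kernel
#' with a single locally estimated bandwidth (median distance to the
#' `local_k`-th neighbor), density normalization (alpha = 1), and the top
#' non-trivial eigenvectors of the normalized transition operator as
#' diffusion components (DC1, DC2, ...). Eigenvector signs follow the
#' largest-magnitude-loading-positive convention, so the embedding is
#' deterministic.
#'
#' @param scores genes x spots matrix.
#' @param n_components Number of diffusion components (default 2).
#' @param local_k Neighbor index for the bandwidth estimate (default 10).
#' @return spots x `n_components` matrix (columns DC1, DC2, ...).
#' @export
diffusion_map <- function(scores, n_components = 2L, local_k = 10L) {
  X <- t(scores)
  n <- nrow(X)
  stop_if(n < n_components + 2L, "need at least n_components + 2 spots")
  d2 <- cross_dist2(X, X)
  kth <- min(local_k + 1L, n)
  knn_d <- apply(d2, 1L, function(r) sqrt(sort(r)[kth]))
  sigma <- stats::median(knn_d)
  if (sigma == 0) sigma <- max(sqrt(d2)) / 2
  stop_if(sigma == 0, "all spots coincident")
  K <- exp(-d2 / (2 * sigma^2))

  q <- rowSums(K)
  K1 <- K / outer(q, q)
  d1 <- rowSums(K1)
  if (any(d1 <= 0)) {
    warning("kernel graph nearly disconnected; regularizing")
    K1 <- K1 + 1e-12
    d1 <- rowSums(K1)
  }
  A <- K1 / sqrt(outer(d1, d1))
  eig <- eigen(A, symmetric = TRUE)
  # first eigenvector is the trivial stationary component
  idx <- seq_len(n_components) + 1L
  psi <- eig$vectors[, idx, drop = FALSE] / sqrt(d1)
  psi <- apply(psi, 2L, fix_sign)
  rownames(psi) <- colnames(scores)
  colnames(psi) <- paste0("DC", seq_len(n_components))
  psi
}

#' Spatial pseudo-distance to a tissue centroid
#'
#' Combines physical and chromatin-state distance: for each spot, `S` is
#' the Euclidean distance of its physical coordinates to the centroid of
#' the reference spots, and `D` the Euclidean distance of its diffusion
#' coordinates to the reference centroid in diffusion space. Both are
#' min-max normalized to [0, 1] over all spots and summed.
#'
#' @param spots A `spot_grid`.
#' @param dcs spots x components diffusion coordinates (rownames =
#'   barcodes), from [diffusion_map()].
#' @param reference Barcodes of the reference tissue spots.
#' @param normalize Normalization of S and D before summing: "minmax"
#'   (default) or "none".
#' @return A `pseudo_distance_field` data.frame: barcode, S, D, S_norm,
#'   D_norm, pseudo_distance.
#' @export
pseudo_distance <- function(spots, dcs, reference,
                            normalize = c("minmax", "none")) {
  normalize <- match.arg(normalize)
  stop_if(length(reference) == 0L, "reference spot set is empty")
  stop_if(!all(reference %in% spots$barcode), "unknown reference barcodes")
  stop_if(!all(spots$barcode %in% rownames(dcs)),
          "diffusion coordinates missing for some spots")
  xy <- cbind(spots$x, spots$y)
  dc <- dcs[spots$barcode, , drop = FALSE]
  ref <- spots$barcode %in% reference
  cen_xy <- colMeans(xy[ref, , drop = FALSE])
  cen_dc <- colMeans(dc[ref, , drop = FALSE])
  S <- sqrt(rowSums(sweep(xy, 2L, cen_xy)^2))
  D <- sqrt(rowSums(sweep(dc, 2L, cen_dc)^2))
  norm01 <- function(v) {
    r <- range(v)
    stop_if(r[1L] == r[2L], "zero range: all spots coincident on this axis")
    (v - r[1L]) / (r[2L] - r[1L])
  }
  Sn <- if (normalize == "minmax") norm01(S) else S
  Dn <- if (normalize == "minmax") norm01(D) else D
  res <- data.frame(barcode = spots$barcode, S = S, D = D,
                    S_norm = Sn, D_norm = Dn,
                    pseudo_distance = Sn + Dn, stringsAsFactors = FALSE)
  class(res) <- c("pseudo_distance_field", "data.frame")
  res
}

#' Divide spots into equidistance groups
#'
#' Equal-width bins over the pseudo-distance range: group 1 is nearest the
#' tissue centroid. Bins are half-open `[lo, hi)` -- a value exactly on an
#' edge goes to the higher bin -- except the last bin, which is closed so
#' the maximum belongs to group `n_groups`. A quantile mode (equal spot
#' counts) is available.
#'
#' @param field A `pseudo_distance_field` (or numeric vector of distances
#'   named by barcode).
#' @param n_groups Number of groups (default 20).
#' @param mode "width" (equal-width bins, default) or "quantile".
#' @return Integer group labels 1..n_groups named by barcode.
#' @export
equidistance_groups <- function(field, n_groups = 20L, mode = c("width", "quantile")) {
  mode <- match.arg(mode)
  pd <- if (is.data.frame(field))
    stats::setNames(field$pseudo_distance, field$barcode) else field
  r <- range(pd)
  stop_if(r[1L] == r[2L], "constant pseudo-distance field")
  if (length(pd) < n_groups)
    warning("fewer spots than groups; some groups will be empty")
  breaks <- if (mode == "width") seq(r[1L], r[2L], length.out = n_groups + 1L)
    else unique(stats::quantile(pd, probs = seq(0, 1, length.out = n_groups + 1L)))
  g <- findInterval(pd, breaks, rightmost.closed = TRUE)
  g <- pmin(g, n_groups)
  stats::setNames(as.integer(g), names(pd))
}

#' Domain width per equidistance group at a locus
#'
#' Builds a depth-normalized pseudobulk track per group inside a declared
#' locus window, binarizes it, and reports the width (bp of significant
#' bins) per group together with the Spearman rank correlation of width
#' against group index (the transition trend). Depth normalization scales
#' each group's per-spot mean signal to a common reference group size so
#' unequal group sizes cannot masquerade as width changes.
#'
#' @param frags A `fragment_set` for one mark.
#' @param groups Integer group labels named by barcode (from
#'   [equidistance_groups()]).
#' @param window List or data.frame with `chrom`, `start`, `end`: the locus
#'   window within which significant bins are counted.
#' @param bin_bp Bin width (default 100).
#' @param cutoff Binarization cutoff on the depth-scaled counts (default 5).
#' @param ref_spots Reference group size for depth scaling (default: mean
#'   group size).
#' @param min_spots Minimum spots a group needs for a width estimate
#'   (default 5). Below this the scaled binarization cutoff degenerates
#'   (a single background insertion can cross it), so the group's width is
#'   recorded as missing and excluded from the trend, as for empty groups.
#' @return A `transition_profile`: data.frame group, n_spots, width_bp plus
#'   attributes `trend` (Spearman rho; 0 with attribute `flat = TRUE` when
#'   width is constant) and `window`.
#' @export
group_domain_width <- function(frags, groups, window, bin_bp = 100L,
                               cutoff = 5, ref_spots = NULL,
                               min_spots = 5L) {
  window <- as.list(window)
  labs <- sort(unique(groups))
  sizes <- table(groups)
  ref_spots <- ref_spots %||% mean(sizes)
  n_bins <- ceiling((window$end - window$start) / bin_bp)

  width <- numeric(length(labs)); nsp <- integer(length(labs))
  for (i in seq_along(labs)) {
    bc <- names(groups)[groups == labs[i]]
    nsp[i] <- length(bc)
    if (nsp[i] < min_spots) {
      width[i] <- NA_real_
      next
    }
    sub <- frags[frags$barcode %in% bc & frags$chrom == window$chrom, ]
    ins <- insertion_table(sub)
    ins <- ins[ins$pos >= window$start & ins$pos < window$end, ]
    v <- numeric(n_bins)
    if (nrow(ins)) {
      idx <- floor((ins$pos - window$start) / bin_bp) + 1L
      agg <- rowsum(as.numeric(ins$count), idx)
      v[as.integer(rownames(agg))] <- agg[, 1L]
    }
    scaled <- v / nsp[i] * ref_spots
    width[i] <- sum(scaled >= cutoff) * bin_bp
  }
  res <- data.frame(group = labs, n_spots = nsp, width_bp = width)
  ok <- nsp >= min_spots & !is.na(width)
  trend <- if (stats::sd(width[ok]) == 0) {
    structure(0, flat = TRUE)
  } else {
    suppressWarnings(stats::cor(labs[ok], width[ok], method = "spearman"))
  }
  attr(res, "trend") <- trend
  attr(res, "window") <- window
  class(res) <- c("transition_profile", "data.frame")
  res
}
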