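#' Optimal rigid transform between paired point sets (Kabsch)
#'
#' Least-squares rigid alignment of paired 2-D points: both sets are
#' centered, the cross-covariance is factored by singular value
#' decomposition, and the rotation is `V diag(1, det(V U')) U'` so that the
#' result is a proper rotation (no reflection) unless `allow_reflection`.
#'
#' @param source,target n x 2 matrices of paired points (row i of source
#'   corresponds to row i of target).
#' @param allow_reflection Permit an improper (det = -1) transform
#'   (default FALSE; serial sections share chirality).
#' @return A `rigid_transform`: list with `R` (2x2), `t` (length 2), and
#'   `reflection` flag. Maps x to `R x + t`.
#' @export
kabsch <- function(source, target, allow_reflection = FALSE) {
  source <- as.matrix(source); target <- as.matrix(target)
  stop_if(nrow(source) != nrow(target), "point sets must be paired")
  stop_if(nrow(source) < 2L, "need at least 2 point pairs")
  pm <- colMeans(source); qm <- colMeans(target)
  P <- sweep(source, 2L, pm); Q <- sweep(target, 2L, qm)
  stop_if(max(abs(P)) == 0 && max(abs(Q)) == 0, "all points coincident")
  H <- crossprod(P, Q)
  sv <- svd(H)
  s <- det(sv$v %*% t(sv$u))
  D <- diag(c(1, if (allow_reflection) 1 else sign(s)))
  R <- sv$v %*% D %*% t(sv$u)
  structure(list(R = R, t = as.numeric(qm - R %*% pm),
                 reflection = det(R) < 0),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform A `rigid_transform`.
#' @param points n x 2 matrix.
#' @return Transformed n x 2 matrix.
#' @export
apply_transform <- function(transform, points) {
  sweep(as.matrix(points) %*% t(transform$R), 2L, -transform$t)
}

#' Invert a rigid transform
#' @param transform A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Ri <- t(transform$R)
  structure(list(R = Ri, t = as.numeric(-Ri %*% transform$t),
                 reflection = transform$reflection),
            class = "rigid_transform")
}

#' Rotation angle of a rigid transform
#' @param transform A `rigid_transform`.
#' @return Angle in degrees in (-180, 180].
#' @export
transform_angle <- function(transform) {
  atan2(transform$R[2L, 1L], transform$R[1L, 1L]) * 180 / pi
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rotation", round(transform_angle(x), 3),
      "deg, translation (", paste(round(x$t, 3), collapse = ", "), ")\n")
  invisible(x)
}

#' Write / read a rigid transform as a 6-number text record
#' @param transform A `rigid_transform`.
#' @param path Output path.
#' @export
write_transform <- function(transform, path) {
  writeLines(paste(c(transform$R[1, ], transform$R[2, ], transform$t),
                   collapse = "\t"), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  v <- as.numeric(strsplit(readLines(path, n = 1L), "\t")[[1L]])
  structure(list(R = matrix(v[1:4], 2L, 2L, byrow = TRUE), t = v[5:6],
                 reflection = det(matrix(v[1:4], 2L, 2L, byrow = TRUE)) < 0),
            class = "rigid_transform")
}

#' Iterative closest point rigid registration
#'
#' Alternates nearest-neighbor correspondence (each source point to its
#' closest target point) with a [kabsch()] fit until the root-mean-square
#' correspondence distance stops improving. Deterministic.
#'
#' @param source,target n x 2 point clouds (not paired).
#' @param max_iter Maximum iterations per start (default 100).
#' @param tol Convergence tolerance on RMSD improvement (default 1e-6).
#' @param init_angles Coarse grid of initial rotations (degrees) about the
#'   source centroid; the start reaching the lowest final RMSD wins.
#'   Regular spot grids have lattice-registration local minima, so a single
#'   identity start is not reliable beyond a few degrees.
#' @param allow_reflection Passed to [kabsch()].
#' @return A `rigid_transform` with attributes `rmsd`, `converged`,
#'   `n_iter`. Non-convergence is reported in the attributes, not as an
#'   error.
#' @export
icp_align <- function(source, target, max_iter = 100L, tol = 1e-6,
                      init_angles = seq(-180, 175, by = 5),
                      coarse_n = 500L, allow_reflection = FALSE) {
  source <- as.matrix(source); target <- as.matrix(target)
  stop_if(nrow(source) < 3L || nrow(target) < 3L,
          "both clouds need at least 3 points")
  src_cen <- colMeans(source)
  starts <- lapply(init_angles, function(ang) {
    th <- ang * pi / 180
    R0 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
    structure(list(R = R0,
                   t = as.numeric(colMeans(target) - R0 %*% src_cen),
                   reflection = FALSE),
              class = "rigid_transform")
  })
  # screen starts on deterministically thinned clouds, refine the best few
  thin <- function(m) {
    if (nrow(m) <= coarse_n) return(m)
    m[seq(1L, nrow(m), length.out = coarse_n), , drop = FALSE]
  }
  src_c <- thin(source); tgt_c <- thin(target)
  coarse <- vapply(starts, function(init)
    attr(icp_run(src_c, tgt_c, init, max_iter, tol, allow_reflection),
         "rmsd"), 1)
  best <- NULL
  for (i in utils::head(order(coarse), 3L)) {
    fit <- icp_run(source, target, starts[[i]], max_iter, tol,
                   allow_reflection)
    if (is.null(best) || attr(fit, "rmsd") < attr(best, "rmsd")) best <- fit
  }
  best
}

icp_run <- function(source, target, init, max_iter, tol, allow_reflection) {
  cur <- apply_transform(init, source)
  rmsd_prev <- Inf
  fit <- init
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    d2 <- cross_dist2(cur, target)
    nn <- max.col(-d2, ties.method = "first")
    fit <- kabsch(source, target[nn, , drop = FALSE], allow_reflection)
    cur <- apply_transform(fit, source)
    rmsd <- sqrt(mean(rowSums((cur - target[nn, , drop = FALSE])^2)))
    n_iter <- it
    if (is.finite(rmsd_prev) && abs(rmsd_prev - rmsd) < tol) {
      converged <- TRUE
      rmsd_prev <- rmsd
      break
    }
    rmsd_prev <- rmsd
  }
  attr(fit, "rmsd") <- rmsd_prev
  attr(fit, "converged") <- converged
  attr(fit, "n_iter") <- n_iter
  fit
}

# median nearest-neighbor distance: the grid pitch estimator
estimate_pitch <- function(xy) {
  d2 <- cross_dist2(xy, xy)
  diag(d2) <- Inf
  stats::median(sqrt(apply(d2, 1L, min)))
}

#' Transfer gene scores from an aligned source slice to target spots
#'
#' Source spots are mapped through the rigid transform; each target spot
#' receives the inverse-distance-weighted mean of its at most `k` nearest
#' transformed source spots within `radius` (default: one estimated target
#' grid pitch). A coincident source spot (distance 0) dominates exactly.
#' Target spots with no in-radius source are reported unmatched and carry
#' no transferred values.
#'
#' @param source_scores genes x source-spots matrix.
#' @param transform `rigid_transform` mapping source onto target
#'   coordinates (e.g. from [icp_align()]).
#' @param source_spots,target_spots `spot_grid`s.
#' @param k Neighbors used for interpolation (default 4).
#' @param radius Matching radius; default one target grid pitch.
#' @return A `slice_overlap`: list with `scores` (genes x matched targets),
#'   `matched` and `unmatched` target barcodes, and `radius`.
#' @export
transfer_scores <- function(source_scores, transform, source_spots,
                            target_spots, k = 4L, radius = NULL) {
  src_xy <- apply_transform(transform, cbind(source_spots$x, source_spots$y))
  tgt_xy <- cbind(target_spots$x, target_spots$y)
  radius <- radius %||% estimate_pitch(tgt_xy)
  stop_if(!all(source_spots$barcode %in% colnames(source_scores)),
          "source scores missing some source barcodes")
  S <- source_scores[, source_spots$barcode, drop = FALSE]

  d2 <- cross_dist2(tgt_xy, src_xy)
  out <- matrix(NA_real_, nrow(S), nrow(tgt_xy),
                dimnames = list(rownames(S), target_spots$barcode))
  matched <- logical(nrow(tgt_xy))
  for (i in seq_len(nrow(tgt_xy))) {
    di <- d2[i, ]
    cand <- which(di <= radius^2)
    if (length(cand) == 0L) next
    cand <- cand[order(di[cand])][seq_len(min(k, length(cand)))]
    d <- sqrt(di[cand])
    w <- if (any(d == 0)) as.numeric(d == 0) else 1 / d
    out[, i] <- as.numeric(S[, cand, drop = FALSE] %*% (w / sum(w)))
    matched[i] <- TRUE
  }
  stop_if(!any(matched), "no target spot matched a source spot")
  structure(list(scores = out[, matched, drop = FALSE],
                 matched = target_spots$barcode[matched],
                 unmatched = target_spots$barcode[!matched],
                 radius = radius),
            class = "slice_overlap")
}

#' @export
print.slice_overlap <- function(x, ...) {
  cat("slice_overlap:", length(x$matched), "matched,",
      length(x$unmatched), "unmatched target spots (radius",
      round(x$radius, 2), ")\n")
  invisible(x)
}

#' Correlate two marks' spatial profiles per gene
#'
#' Pearson correlation across matched spots between two marks, per gene,
#' with a loess-smoothed trend for plotting and a coarse classification:
#' complementary (r < -`threshold`), co-occurring (r > `threshold`),
#' independent otherwise. Constant profiles yield `NA` correlations.
#'
#' @param score_a,score_b genes x spots matrices over the same spots (e.g.
#'   a mark and a transferred second mark).
#' @param threshold Classification threshold on |r| (default 0.3).
#' @return data.frame gene, r, class.
#' @export
mark_relationship <- function(score_a, score_b, threshold = 0.3) {
  common <- intersect(colnames(score_a), colnames(score_b))
  stop_if(length(common) < 3L, "need at least 3 matched spots")
  genes <- intersect(rownames(score_a), rownames(score_b))
  r <- vapply(genes, function(g) {
    a <- score_a[g, common]; b <- score_b[g, common]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 1)
  cls <- ifelse(is.na(r), "undefined",
                ifelse(r < -threshold, "complementary",
                       ifelse(r > threshold, "co-occurring", "independent")))
  data.frame(gene = genes, r = as.numeric(r), class = cls,
             stringsAsFactors = FALSE)
}

#' Loess-smoothed relationship curve for one gene
#'
#' @param a,b Per-spot score vectors of the two marks (matched spots).
#' @param span Loess span (default 0.75).
#' @return data.frame x, fitted -- b smoothed as a function of a, ordered
#'   by x, suitable for plotting over the scatter.
#' @export
mark_loess_curve <- function(a, b, span = 0.75) {
  ord <- order(a)
  fit <- stats::loess(b ~ a, data = data.frame(a = a, b = b), span = span)
  data.frame(x = a[ord], fitted = stats::predict(fit)[ord])
}
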