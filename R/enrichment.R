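#' PAGE enrichment score for one gene set
#'
#' Parametric Analysis of Gene Set Enrichment: given per-gene fold changes,
#' the score of a gene set of size m with set mean `S_m` is
#' `Z = (S_m - mu) * sqrt(m) / delta`, where `mu` and `delta` are the mean
#' and standard deviation of the fold changes over all genes.
#'
#' @param fold_changes Named numeric vector of per-gene (log) fold changes.
#' @param gene_set Character vector of member gene names.
#' @return The raw PAGE score (numeric scalar).
#' @export
page_score <- function(fold_changes, gene_set) {
  stop_if(length(gene_set) < 1L, "gene set must be non-empty")
  stop_if(!all(gene_set %in% names(fold_changes)),
          "gene set members missing from fold changes")
  mu <- mean(fold_changes)
  delta <- stats::sd(fold_changes)
  stop_if(!is.finite(delta) || delta == 0,
          "fold-change standard deviation is zero")
  m <- length(gene_set)
  s_m <- mean(fold_changes[gene_set])
  (s_m - mu) * sqrt(m) / delta
}

# log2 fold change of per-gene mean score in a cluster vs all other spots
cluster_fold_changes <- function(scores, in_cluster, eps = 1e-9) {
  a <- rowMeans(scores[, in_cluster, drop = FALSE])
  b <- rowMeans(scores[, !in_cluster, drop = FALSE])
  stats::setNames(log2((a + eps) / (b + eps)), rownames(scores))
}

#' Map co-localization modules to clusters by PAGE
#'
#' For every (module, cluster) pair, computes the PAGE score of the module's
#' gene set on the cluster-vs-rest log2 fold changes, z-normalizes each
#' module's scores across clusters, and discretizes at `z >= z_cutoff`.
#'
#' The discretized map additionally requires the raw PAGE score (itself an
#' approximately standard-normal statistic under the null) to clear the
#' cutoff: row-wise z-normalization rescales any row to unit variance, so
#' without this guard a module with no enrichment anywhere would still map
#' to whichever cluster tops its noise.
#'
#' @param scores genes x spots gene score matrix.
#' @param assign A `cluster_assignment` over the spots.
#' @param modules A `module_assignment` (gene -> module).
#' @param z_cutoff Cutoff on the z-normalized score (default 0.7).
#' @param z_axis Normalization axis: "clusters" (z across clusters within a
#'   module, default) or "modules".
#' @param eps Pseudocount for fold changes (default 1e-9).
#' @return An `enrichment_matrix`: list with `raw`, `z` and `binary`
#'   modules x clusters matrices.
#' @export
enrichment_map <- function(scores, assign, modules, z_cutoff = 0.7,
                           z_axis = c("clusters", "modules"), eps = 1e-9) {
  z_axis <- match.arg(z_axis)
  stop_if(attr(assign, "K") < 2L, "need at least 2 clusters")
  bc <- colnames(scores)
  stop_if(!all(bc %in% names(assign)), "cluster labels missing for some spots")
  lab <- unclass(assign)[bc]
  labs <- sort(unique(lab))
  mods <- sort(unique(as.integer(modules)))
  raw <- matrix(NA_real_, length(mods), length(labs),
                dimnames = list(paste0("M", mods), as.character(labs)))
  for (ci in seq_along(labs)) {
    fc <- cluster_fold_changes(scores, lab == labs[ci], eps)
    for (mi in seq_along(mods)) {
      set <- names(modules)[as.integer(modules) == mods[mi]]
      raw[mi, ci] <- page_score(fc, set)
    }
  }
  z <- if (z_axis == "clusters") t(scale(t(raw))) else scale(raw)
  z[!is.finite(z)] <- 0
  structure(list(raw = raw, z = z,
                 binary = (z >= z_cutoff & raw >= z_cutoff) * 1L,
                 z_cutoff = z_cutoff, z_axis = z_axis),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat("enrichment_matrix:", nrow(x$raw), "modules x", ncol(x$raw),
      "clusters (z cutoff", x$z_cutoff, "across", x$z_axis, ")\n")
  print(round(x$z, 2))
  invisible(x)
}
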