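#' @importFrom data.table data.table as.data.table setkeyv setnames tstrsplit := .N .SD fread fwrite
#' @importFrom stats fisher.test p.adjust hclust cutree cor sd wilcox.test
#'   dist median setNames quantile loess predict rpois runif
#' @importFrom utils head
NULL

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# deterministic sign convention for eigen/singular vectors:
# the largest-magnitude loading is made positive
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (length(i) && v[i] < 0) -v else v
}

# squared Euclidean cross-distances between rows of a (n x d) and b (m x d)
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
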