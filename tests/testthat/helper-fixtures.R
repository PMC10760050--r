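# Shared fixture builders and independent oracles.

# write a fragments TSV and return its path
write_frag_file <- function(lines, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".tsv.gz" else ".tsv")
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  writeLines(lines, con)
  close(con)
  path
}

# small regular grid spot set
grid_spots <- function(n_rows = 5, n_cols = 5, pitch = 20) {
  make_tissue_layout(n_rows, n_cols, pitch)
}

# a spatial_network built by hand from an edge list (indices into barcodes)
manual_network <- function(barcodes, edges) {
  structure(list(
    nodes = barcodes,
    edges = data.frame(from = edges[, 1], to = edges[, 2],
                       length = rep(1, nrow(edges))),
    k = NA, max_dist = NA), class = "spatial_network")
}

# Independent one-sided Fisher oracle: hypergeometric enumeration over all
# 2x2 tables with the margins of the both-orientations edge table.
# Enrichment of the [1,1] cell.
fisher_oracle_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, n - c1, r1)
  sum(probs[support >= a])
}

# edge table of a binary labeling on a manual/spatial network, matching the
# package's construction (recomputed independently here)
edge_table <- function(binary, net) {
  f <- binary[net$edges$from] == 1
  t <- binary[net$edges$to] == 1
  hh <- sum(f & t); ll <- sum(!f & !t)
  m <- nrow(net$edges) - hh - ll
  matrix(c(2 * hh, m, m, 2 * ll), 2, 2)
}

# all 0/1 labelings of n nodes
all_labelings <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(m) <- NULL
  m
}

# asymmetric on-tissue cloud used for registration tests
tissue_cloud <- function(seed = 1) {
  mini <- simulate_embryo_mini(seed)
  sp <- mini$spots
  sp[sp$region != "background", ]
}
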