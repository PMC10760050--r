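#' Build a genome tile matrix from fragments
#'
#' Counts Tn5 insertion events into fixed-width genome tiles. Each fragment
#' contributes two insertions -- one at `start` and one at `end - 1` (BED
#' half-open convention) -- each weighted by the fragment's duplicate count.
#' Fragments whose barcode is absent from the spot grid are dropped (with a
#' message reporting how many).
#'
#' @param frags A `fragment_set`.
#' @param spots A `spot_grid`; columns of the result follow `spots$barcode`.
#' @param tile_bp Tile width in bp (default 5000).
#' @return A `tile_matrix`: list with sparse `counts` (tiles x spots),
#'   `tiles` (data.frame chrom/start/end) and `barcodes`.
#' @export
build_tile_matrix <- function(frags, spots, tile_bp = 5000L) {
  stop_if(tile_bp <= 0, "tile_bp must be positive")
  barcodes <- spots$barcode
  keep <- frags$barcode %in% barcodes
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message(n_drop, " fragments dropped (barcode not in spot grid)")
  fr <- frags[keep, ]
  ins <- insertion_table(fr)

  chroms <- sort(unique(ins$chrom))
  if (length(chroms) == 0L) chroms <- character()
  # per-chromosome tile layout sized by the furthest insertion
  tile_list <- lapply(chroms, function(ch) {
    maxpos <- max(ins$pos[ins$chrom == ch])
    n <- floor(maxpos / tile_bp) + 1L
    data.frame(chrom = ch, start = (seq_len(n) - 1L) * tile_bp,
               end = seq_len(n) * tile_bp, stringsAsFactors = FALSE)
  })
  tiles <- if (length(tile_list)) do.call(rbind, tile_list) else
    data.frame(chrom = character(), start = integer(), end = integer())
  offset <- c(0L, cumsum(vapply(tile_list, nrow, 1L)))
  names(offset) <- c(chroms, "")

  i <- offset[match(ins$chrom, chroms)] + floor(ins$pos / tile_bp) + 1L
  j <- match(ins$barcode, barcodes)
  counts <- Matrix::sparseMatrix(
    i = i, j = j, x = as.numeric(ins$count),
    dims = c(nrow(tiles), length(barcodes)))
  colnames(counts) <- barcodes
  structure(list(counts = counts, tiles = tiles, barcodes = barcodes,
                 tile_bp = as.integer(tile_bp)),
            class = "tile_matrix")
}

#' @export
print.tile_matrix <- function(x, ...) {
  cat("tile_matrix:", nrow(x$tiles), "tiles x", length(x$barcodes),
      "spots,", x$tile_bp, "bp tiles, total insertions", sum(x$counts), "\n")
  invisible(x)
}

# expand fragments to one row per insertion (start and end-1), keeping counts
insertion_table <- function(frags) {
  data.table::data.table(
    chrom = rep(frags$chrom, 2L),
    pos = c(frags$start, frags$end - 1L),
    barcode = rep(frags$barcode, 2L),
    count = rep(frags$count, 2L))
}

#' Compute gene activity scores from fragments
#'
#' Distance-weighted insertion counting around each gene. The gene window is
#' the gene body extended `upstream_bp` upstream of the TSS (strand-aware).
#' An insertion inside the window has weight 1; outside, the weight decays as
#' `exp(-d / decay_bp)` with `d` the distance to the window, and is 0 beyond
#' `max_dist_bp`. Weights are multiplied by the fragment duplicate count.
#'
#' @param frags A `fragment_set`.
#' @param genes A `gene_model`.
#' @param spots A `spot_grid` defining the column order.
#' @param upstream_bp Upstream extension of the gene window (default 5000).
#' @param decay_bp Exponential decay length scale (default 5000).
#' @param max_dist_bp Maximal distance contributing signal (default 1e5).
#' @return A dense genes x spots matrix of non-negative scores with gene
#'   names as rownames and barcodes as colnames.
#' @export
compute_gene_scores <- function(frags, genes, spots, upstream_bp = 5000L,
                                decay_bp = 5000L, max_dist_bp = 100000L) {
  stop_if(nrow(genes) == 0L, "empty gene model")
  barcodes <- spots$barcode
  fr <- frags[frags$barcode %in% barcodes, ]
  ins <- insertion_table(fr)
  ins[, spot := match(barcode, barcodes)]
  data.table::setkeyv(ins, c("chrom", "pos"))

  score <- matrix(0, nrow(genes), length(barcodes),
                  dimnames = list(genes$name, barcodes))
  for (ch in unique(genes$chrom)) {
    sub <- ins[chrom == ch]
    if (nrow(sub) == 0L) next
    pos <- sub$pos
    gi <- which(genes$chrom == ch)
    for (g in gi) {
      wstart <- if (genes$strand[g] == "+") genes$start[g] - upstream_bp else genes$start[g]
      wend <- if (genes$strand[g] == "+") genes$end[g] else genes$end[g] + upstream_bp
      lo <- wstart - max_dist_bp
      hi <- wend - 1L + max_dist_bp
      i0 <- findInterval(lo - 1L, pos) + 1L
      i1 <- findInterval(hi, pos)
      if (i1 < i0) next
      idx <- i0:i1
      p <- pos[idx]
      d <- pmax(0, pmax(wstart - p, p - (wend - 1L)))
      w <- ifelse(d == 0, 1, exp(-d / decay_bp)) * sub$count[idx]
      agg <- rowsum(w, sub$spot[idx])
      score[g, as.integer(rownames(agg))] <-
        score[g, as.integer(rownames(agg))] + agg[, 1L]
    }
  }
  score
}

#' Write a genes x spots matrix as TSV
#' @param scores Matrix with rownames (genes) and colnames (barcodes).
#' @param path Output TSV path.
#' @export
write_score_matrix <- function(scores, path) {
  dt <- data.table::as.data.table(scores, keep.rownames = "gene")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a genes x spots matrix from TSV
#' @param path TSV written by [write_score_matrix()].
#' @return Numeric matrix, genes in rows.
#' @export
read_score_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1L])
  rownames(m) <- dt[[1L]]
  m
}
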