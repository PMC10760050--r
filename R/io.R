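#' Read a fragments file
#'
#' Reads a 5-column tab-separated fragments file (chrom, start, end, barcode,
#' count; BED-style 0-based half-open coordinates), optionally gzip
#' compressed, and returns a validated, coordinate-sorted fragment table.
#'
#' @param path Path to the fragments TSV(.gz).
#' @return A `fragment_set`: a `data.table` with columns `chrom`, `start`,
#'   `end`, `barcode`, `count`, sorted by `(chrom, start, end)`.
#' @export
read_fragments <- function(path) {
  stop_if(!file.exists(path), "fragments file not found: ", path)
  dt <- suppressWarnings(
    if (grepl("\\.gz$", path)) {
      con <- gzfile(path, "r")
      on.exit(close(con), add = TRUE)
      lines <- readLines(con)
      if (length(lines) == 0L) data.table::data.table()
      else data.table::fread(text = lines, header = FALSE, sep = "\t",
                             fill = TRUE)
    } else {
      data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
    })
  if (nrow(dt) == 0L) {
    return(fragment_set(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      barcode = character(), count = integer())))
  }
  stop_if(ncol(dt) != 5L, "expected 5 tab-separated columns, got ", ncol(dt))
  data.table::setnames(dt, c("chrom", "start", "end", "barcode", "count"))
  dt[, `:=`(chrom = as.character(chrom), barcode = as.character(barcode))]
  suppressWarnings({
    s_num <- as.numeric(dt$start); e_num <- as.numeric(dt$end)
  })
  dt[, `:=`(start = s_num, end = e_num)]
  bad <- which(is.na(dt$start) | is.na(dt$end) |
                 dt$start != floor(dt$start) | dt$end != floor(dt$end))
  stop_if(length(bad) > 0L,
          "non-integer or missing coordinates at line ", bad[1L])
  fragment_set(dt, source_lines = seq_len(nrow(dt)))
}

#' Construct a fragment set
#'
#' Validates fragment records (start < end, count >= 1) and returns them in
#' genome-sorted order.
#'
#' @param df data.frame-like with columns chrom, start, end, barcode, count.
#' @param source_lines Optional original line numbers used in error messages.
#' @return A `fragment_set` data.table.
#' @export
fragment_set <- function(df, source_lines = NULL) {
  dt <- data.table::as.data.table(df)
  stop_if(!all(c("chrom", "start", "end", "barcode", "count") %in% names(dt)),
          "fragment table needs columns chrom, start, end, barcode, count")
  if (nrow(dt) > 0L) {
    ln <- source_lines %||% seq_len(nrow(dt))
    bad <- which(dt$start >= dt$end)
    stop_if(length(bad) > 0L,
            "start >= end at line ", ln[bad[1L]],
            " (", dt$chrom[bad[1L]], ":", dt$start[bad[1L]], "-", dt$end[bad[1L]], ")")
    bad <- which(is.na(dt$count) | dt$count < 1)
    stop_if(length(bad) > 0L, "count < 1 at line ", ln[bad[1L]])
    bad <- which(dt$start < 0)
    stop_if(length(bad) > 0L, "negative coordinate at line ", ln[bad[1L]])
  }
  dt[, `:=`(start = as.integer(start), end = as.integer(end),
            count = as.integer(count))]
  data.table::setkeyv(dt, c("chrom", "start", "end"))
  data.table::setattr(dt, "class", c("fragment_set", class(data.table::data.table())))
  dt[]
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set:", nrow(x), "records,",
      length(unique(x$barcode)), "barcodes, total count", sum(x$count), "\n")
  if (nrow(x)) print(data.table::as.data.table(utils::head(x, 5L)))
  invisible(x)
}

#' Construct a spot grid
#'
#' A spot grid holds per-barcode array positions and physical coordinates
#' (micrometers) for one tissue slice.
#'
#' @param barcode Character vector of unique spot barcodes.
#' @param x,y Physical coordinates in micrometers.
#' @param row,col Integer array indices (defaults derived from rank of y/x).
#' @param on_tissue Logical; spots off tissue are dropped from analyses.
#' @param region Optional region label per spot (used by synthetic layouts).
#' @return A `spot_grid` data.frame.
#' @export
spot_grid <- function(barcode, x, y, row = NULL, col = NULL,
                      on_tissue = TRUE, region = NULL) {
  stop_if(anyDuplicated(barcode) > 0L, "barcodes must be unique")
  stop_if(!all(is.finite(x)) || !all(is.finite(y)),
          "physical coordinates must be finite")
  n <- length(barcode)
  df <- data.frame(
    barcode = as.character(barcode),
    row = as.integer(row %||% match(y, sort(unique(y)))),
    col = as.integer(col %||% match(x, sort(unique(x)))),
    x = as.numeric(x), y = as.numeric(y),
    on_tissue = rep_len(as.logical(on_tissue), n),
    stringsAsFactors = FALSE)
  if (!is.null(region)) df$region <- as.character(region)
  stop_if(!any(df$on_tissue), "a spot grid needs at least one on-tissue spot")
  class(df) <- c("spot_grid", "data.frame")
  df
}

#' Read a spot position table
#'
#' @param path CSV with columns barcode, row, col, x_um, y_um, on_tissue
#'   (extra columns, e.g. region, are carried through).
#' @param drop_off_tissue Drop spots flagged off tissue (default TRUE).
#' @return A `spot_grid`.
#' @export
read_spot_grid <- function(path, drop_off_tissue = TRUE) {
  stop_if(!file.exists(path), "spot table not found: ", path)
  df <- data.table::fread(path, header = TRUE)
  need <- c("barcode", "row", "col", "x_um", "y_um", "on_tissue")
  stop_if(!all(need %in% names(df)),
          "spot table needs columns ", paste(need, collapse = ", "))
  if (drop_off_tissue) df <- df[as.logical(df$on_tissue), ]
  spot_grid(df$barcode, df$x_um, df$y_um, df$row, df$col,
            as.logical(df$on_tissue),
            region = if ("region" %in% names(df)) df$region else NULL)
}

#' Write a spot grid to CSV
#' @param spots A `spot_grid`.
#' @param path Output CSV path.
#' @export
write_spot_grid <- function(spots, path) {
  out <- data.frame(barcode = spots$barcode, row = spots$row, col = spots$col,
                    x_um = spots$x, y_um = spots$y, on_tissue = spots$on_tissue)
  if (!is.null(spots$region)) out$region <- spots$region
  data.table::fwrite(out, path)
  invisible(path)
}

#' Construct a gene model
#'
#' Minimal transcript model: one interval per gene with a strand-aware TSS
#' and a promoter window of `TSS +/- promoter_bp`.
#'
#' @param name Unique gene names.
#' @param chrom Chromosome per gene.
#' @param strand "+" or "-".
#' @param start,end 0-based half-open transcript interval.
#' @param promoter_bp Promoter half-width around the TSS (default 2000).
#' @return A `gene_model` data.frame with derived `tss`, `promoter_start`,
#'   `promoter_end` columns.
#' @export
gene_model <- function(name, chrom, strand, start, end, promoter_bp = 2000L) {
  stop_if(anyDuplicated(name) > 0L, "gene names must be unique")
  stop_if(!all(strand %in% c("+", "-")), "strand must be '+' or '-'")
  stop_if(any(start >= end), "gene start must be < end")
  tss <- ifelse(strand == "+", start, end - 1L)
  df <- data.frame(name = as.character(name), chrom = as.character(chrom),
                   strand = as.character(strand),
                   start = as.integer(start), end = as.integer(end),
                   tss = as.integer(tss),
                   promoter_start = pmax(0L, as.integer(tss - promoter_bp)),
                   promoter_end = as.integer(tss + promoter_bp + 1L),
                   stringsAsFactors = FALSE)
  attr(df, "promoter_bp") <- as.integer(promoter_bp)
  class(df) <- c("gene_model", "data.frame")
  df
}

#' Read a gene model from BED-like TSV
#'
#' Accepts 6-column BED (chrom, start, end, name, score, strand) or BED12
#' (extra columns ignored).
#'
#' @param path Input path.
#' @param promoter_bp Promoter half-width (default 2000).
#' @return A `gene_model`.
#' @export
read_gene_model <- function(path, promoter_bp = 2000L) {
  stop_if(!file.exists(path), "gene model not found: ", path)
  df <- data.table::fread(path, header = FALSE, sep = "\t")
  stop_if(ncol(df) < 6L, "gene model needs at least 6 BED columns")
  stop_if(nrow(df) == 0L, "empty gene model")
  gene_model(df[[4L]], df[[1L]], df[[6L]], df[[2L]], df[[3L]], promoter_bp)
}

#' Write a gene model as 6-column BED
#' @param genes A `gene_model`.
#' @param path Output path.
#' @export
write_gene_model <- function(genes, path) {
  data.table::fwrite(
    data.frame(genes$chrom, genes$start, genes$end, genes$name, 0L, genes$strand),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}
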