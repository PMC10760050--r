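#' Construct a binned signal track
#'
#' A `signal_track` stores per-chromosome insertion counts in fixed-width
#' bins (default 100 bp) together with a binarized flag per bin
#' (`count >= cutoff`).
#'
#' @param bins Named list of numeric vectors, one per chromosome; element
#'   `i` is the signal of bin `[(i-1)*bin_bp, i*bin_bp)`.
#' @param bin_bp Bin width in bp.
#' @param cutoff Binarization cutoff (flag = signal >= cutoff), default 5.
#' @return A `signal_track` object.
#' @export
signal_track <- function(bins, bin_bp = 100L, cutoff = 5) {
  stop_if(is.null(names(bins)) || any(names(bins) == ""),
          "bins must be a named per-chromosome list")
  stop_if(any(vapply(bins, function(b) any(b < 0), TRUE)),
          "signal must be non-negative")
  structure(list(bins = lapply(bins, as.numeric),
                 bin_bp = as.integer(bin_bp),
                 cutoff = cutoff,
                 binarized = lapply(bins, function(b) as.integer(b >= cutoff))),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", length(x$bins), "chromosome(s),",
      sum(lengths(x$bins)), "bins of", x$bin_bp, "bp, cutoff", x$cutoff, "\n")
  invisible(x)
}

# bin insertion events of a fragment subset into a signal_track
bin_insertions <- function(frags, bin_bp = 100L, cutoff = 5,
                           chrom_lengths = NULL, weight = 1) {
  ins <- insertion_table(frags)
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else
    sort(unique(ins$chrom))
  bins <- lapply(chroms, function(ch) {
    sub <- ins[ins$chrom == ch, ]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      if (nrow(sub)) max(sub$pos) + 1 else bin_bp
    n <- as.integer(ceiling(len / bin_bp))
    v <- numeric(n)
    if (nrow(sub)) {
      idx <- floor(sub$pos / bin_bp) + 1L
      agg <- rowsum(as.numeric(sub$count), idx)
      v[as.integer(rownames(agg))] <- agg[, 1L]
    }
    v * weight
  })
  names(bins) <- chroms
  signal_track(bins, bin_bp, cutoff)
}

#' Write a binned signal track as bedGraph
#'
#' @param track A `signal_track`, or a data.frame with columns chrom, start,
#'   end, value (genome-ordered, non-overlapping).
#' @param path Output path.
#' @param drop_zero Omit zero bins (default TRUE, conventional for bedGraph).
#' @export
write_bedgraph <- function(track, path, drop_zero = TRUE) {
  if (inherits(track, "signal_track")) {
    df <- do.call(rbind, lapply(names(track$bins), function(ch) {
      v <- track$bins[[ch]]
      data.frame(chrom = ch,
                 start = (seq_along(v) - 1L) * track$bin_bp,
                 end = seq_along(v) * track$bin_bp,
                 value = v, stringsAsFactors = FALSE)
    }))
  } else df <- as.data.frame(track)
  check_ordered_intervals(df)
  if (drop_zero) df <- df[df$value != 0, , drop = FALSE]
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file
#' @param path bedGraph path.
#' @return data.frame with columns chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  df <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  as.data.frame(df)
}

check_ordered_intervals <- function(df) {
  stop_if(any(df$start >= df$end), "intervals must have start < end")
  sp <- split(df, df$chrom)
  for (s in sp) {
    o <- order(s$start)
    stop_if(!identical(o, seq_len(nrow(s))), "intervals must be genome-ordered")
    if (nrow(s) > 1L)
      stop_if(any(s$start[-1L] < s$end[-nrow(s)]), "intervals must not overlap")
  }
  invisible(TRUE)
}

#' Write a domain set as BED6
#'
#' Enriched intervals only; name column carries `level:state`, score carries
#' the domain height (capped at 1000 per BED convention).
#'
#' @param domains A `domain_set` (see [decode_domains()]).
#' @param path Output path.
#' @param level Which annotation level to write ("domain" or "bin").
#' @export
write_domains_bed <- function(domains, path, level = "domain") {
  df <- as.data.frame(domains)
  df <- df[df$level == level & df$state == "enriched", , drop = FALSE]
  check_ordered_intervals(df)
  out <- data.frame(df$chrom, df$start, df$end,
                    paste0(df$level, ":", df$state),
                    pmin(1000, round(df$height)), ".")
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read enriched domains from BED6
#' @param path BED path written by [write_domains_bed()].
#' @return data.frame chrom, start, end, level, state, width, height.
#' @export
read_domains_bed <- function(path) {
  df <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"))
  parts <- data.table::tstrsplit(df$name, ":", fixed = TRUE)
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    level = parts[[1L]], state = parts[[2L]],
                    width = df$end - df$start, height = df$score,
                    stringsAsFactors = FALSE)
  check_ordered_intervals(out)
  out
}
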