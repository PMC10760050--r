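#' Fit a two-state Bernoulli hidden Markov model to binarized tracks
#'
#' Expectation-maximization (Baum-Welch) on the binarized bins of one or
#' more tracks, fitted jointly across all sequences. Two hidden states model
#' background and enriched chromatin; after fitting, states are ordered so
#' that state 2 has the higher emission probability ("enriched").
#' Initialization is deterministic (data-independent starting values), so
#' the fit is reproducible regardless of `seed`.
#'
#' @param tracks A `signal_track` or list of them; the `binarized` bins are
#'   used.
#' @param n_states Number of hidden states (only 2 supported).
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Stop when the log-likelihood gain drops below `tol`
#'   (default 1e-6).
#' @param seed Accepted for interface uniformity; the fit is deterministic.
#' @return A `bin_hmm`: list with `emission` (per-state P(signal)),
#'   `transition`, `init`, `loglik`, `n_iter`.
#' @export
fit_bin_hmm <- function(tracks, n_states = 2L, max_iter = 100L, tol = 1e-6,
                        seed = NULL) {
  stop_if(n_states != 2L, "only 2 hidden states are supported")
  seqs <- binarized_sequences(tracks)
  total <- sum(lengths(seqs))
  stop_if(total < 2L, "not enough bins to fit")
  ones <- sum(vapply(seqs, sum, 1))
  stop_if(ones == 0L, "all-zero input: nothing to segment")
  stop_if(ones == total, "all-one input: nothing to segment")

  e <- c(0.1, 0.9)
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2L, 2L)
  pi0 <- c(0.5, 0.5)
  prev <- -Inf
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    g0 <- numeric(2L); gs <- numeric(2L); gx <- numeric(2L)
    xs <- matrix(0, 2L, 2L); ll <- 0
    for (s in seqs) {
      fb <- fb_bernoulli(s, e, A, pi0)
      ll <- ll + fb$loglik
      g0 <- g0 + fb$gamma0; gs <- gs + fb$gamma_sum
      gx <- gx + fb$gamma_x_sum; xs <- xs + fb$xi_sum
    }
    n_iter <- it
    e <- pmin(1 - 1e-8, pmax(1e-8, gx / gs))
    A <- xs / rowSums(xs)
    pi0 <- g0 / sum(g0)
    if (is.finite(prev) && ll - prev < tol) break
    prev <- ll
  }
  if (e[1L] > e[2L]) {  # order states: 2 = enriched
    e <- rev(e); pi0 <- rev(pi0); A <- A[2:1, 2:1]
  }
  structure(list(emission = e, transition = A, init = pi0,
                 loglik = prev, n_iter = n_iter, n_states = 2L),
            class = "bin_hmm")
}

binarized_sequences <- function(tracks) {
  if (inherits(tracks, "signal_track")) tracks <- list(tracks)
  unlist(lapply(tracks, function(tr) tr$binarized), recursive = FALSE)
}

#' @export
print.bin_hmm <- function(x, ...) {
  cat("bin_hmm: emission P(signal) =", round(x$emission, 4),
      "| mean dwell =", round(1 / (1 - diag(x$transition)), 1), "bins\n")
  invisible(x)
}

#' Decode nucleosome- and domain-level chromatin states
#'
#' Bin-level states are obtained by Viterbi decoding of the binarized track
#' under a fitted [fit_bin_hmm()] model. Domain-level states aggregate bins
#' into blocks of `domain_block` bins: a block is enriched iff a majority
#' (>= `block_majority` of `domain_block`) of its bins decode as enriched.
#' Runs of enriched blocks separated by at most `max_gap_blocks` background
#' blocks are merged into a single domain, whose width spans the merged run
#' (gaps included) and whose height is the maximal raw signal within.
#'
#' @param track A `signal_track`.
#' @param model A fitted `bin_hmm`.
#' @param domain_block Bins per domain-level block (default 5, i.e. 500 bp
#'   for 100 bp bins).
#' @param block_majority Enriched bins required per enriched block
#'   (default 3).
#' @param max_gap_blocks Background blocks bridgeable inside one domain
#'   (default 1).
#' @return A `domain_set` data.frame: chrom, start, end, level ("bin" or
#'   "domain"), state ("background"/"enriched"), width, height. Intervals of
#'   each level tile the track.
#' @export
decode_domains <- function(track, model, domain_block = 5L,
                           block_majority = 3L, max_gap_blocks = 1L) {
  bb <- track$bin_bp
  out <- list()
  for (ch in names(track$bins)) {
    x <- track$binarized[[ch]]
    raw <- track$bins[[ch]]
    stop_if(length(x) < domain_block,
            "track shorter than one domain block on ", ch)
    st <- viterbi_bernoulli(x, model$emission, model$transition, model$init)
    enr <- st == 2L

    out[[length(out) + 1L]] <- runs_to_intervals(enr, ch, bb, raw, "bin")

    n_blocks <- ceiling(length(enr) / domain_block)
    block_id <- rep(seq_len(n_blocks), each = domain_block)[seq_along(enr)]
    benr <- as.vector(rowsum(as.integer(enr), block_id)) >= block_majority
    benr <- merge_gaps(benr, max_gap_blocks)
    # expand block states back to bins so intervals stay bin-granular
    bin_state <- rep(benr, each = domain_block)[seq_along(enr)]
    out[[length(out) + 1L]] <- runs_to_intervals(bin_state, ch, bb, raw, "domain")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("domain_set", "data.frame")
  res
}

# bridge FALSE-runs of length <= max_gap between TRUE-runs
merge_gaps <- function(flag, max_gap) {
  if (max_gap <= 0L || !any(flag)) return(flag)
  r <- rle(flag)
  n <- length(r$values)
  for (i in seq_len(n)) {
    if (!r$values[i] && r$lengths[i] <= max_gap &&
        i > 1L && i < n && r$values[i - 1L] && r$values[i + 1L])
      r$values[i] <- TRUE
  }
  inverse.rle(r)
}

runs_to_intervals <- function(state, chrom, bin_bp, raw, level) {
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  height <- vapply(seq_along(starts), function(i)
    max(raw[(starts[i] + 1L):ends[i]]), 0)
  data.frame(chrom = chrom, start = starts * bin_bp, end = ends * bin_bp,
             level = level,
             state = ifelse(r$values, "enriched", "background"),
             width = (ends - starts) * bin_bp, height = height,
             stringsAsFactors = FALSE)
}

#' Assign called domains to gene promoters
#'
#' For each gene, finds the widest enriched domain-level interval
#' overlapping its promoter (TSS +/- the gene model's promoter half-width);
#' ties are broken by proximity of the domain midpoint to the TSS. Genes
#' with no overlapping domain get width 0.
#'
#' @param domains A `domain_set` (or data.frame of enriched intervals).
#' @param genes A `gene_model`.
#' @return A `gene_domain_table` data.frame: gene, width, height, broad
#'   (width >= `broad_cutoff`).
#' @param broad_cutoff Broad-domain width cutoff in bp (default 5000).
#' @export
assign_domains_to_genes <- function(domains, genes, broad_cutoff = 5000L) {
  dd <- as.data.frame(domains)
  if ("level" %in% names(dd)) dd <- dd[dd$level == "domain", , drop = FALSE]
  if ("state" %in% names(dd)) dd <- dd[dd$state == "enriched", , drop = FALSE]
  width <- numeric(nrow(genes)); height <- numeric(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    di <- which(dd$chrom == ch)
    if (length(di) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(genes$promoter_start[gi] + 1L, genes$promoter_end[gi]),
      IRanges::IRanges(dd$start[di] + 1L, dd$end[di]))
    if (length(ov) == 0L) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    for (q in unique(qh)) {
      hits <- di[sh[qh == q]]
      w <- dd$end[hits] - dd$start[hits]
      mid <- (dd$start[hits] + dd$end[hits]) / 2
      prox <- abs(mid - genes$tss[gi[q]])
      best <- hits[order(-w, prox)][1L]
      width[gi[q]] <- dd$end[best] - dd$start[best]
      height[gi[q]] <- if ("height" %in% names(dd)) dd$height[best] else NA_real_
    }
  }
  res <- data.frame(gene = genes$name, width = width, height = height,
                    broad = width >= broad_cutoff, stringsAsFactors = FALSE)
  class(res) <- c("gene_domain_table", "data.frame")
  res
}

# two-sided rank-sum p; exact by enumeration of group assignments for small
# samples (ties make the asymptotic wilcox.test approximation unreliable
# there), asymptotic otherwise
rank_sum_p <- function(a, b, max_enum = 20000) {
  na <- length(a)
  n <- na + length(b)
  if (choose(n, na) <= max_enum) {
    r <- rank(c(a, b))
    obs <- sum(r[seq_len(na)])
    sums <- utils::combn(n, na, function(i) sum(r[i]))
    eps <- 1e-9
    p <- 2 * min(mean(sums <= obs + eps), mean(sums >= obs - eps))
    min(1, p)
  } else {
    suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided")$p.value)
  }
}

#' Compare promoter domain width and height between gene sets
#'
#' Contrasts three gene sets per track/cluster: the spatial genes, the
#' "active" genes (genes whose promoter carries an enriched domain, spatial
#' genes excluded) and all genes. Reports medians and two-sided Wilcoxon
#' rank-sum p-values for width and height of each pairwise contrast.
#'
#' @param table A `gene_domain_table` for one cluster.
#' @param spatial_genes Character vector of spatial gene names.
#' @param universe Optional restriction of the gene universe (default all
#'   genes in `table`).
#' @return List with `medians` (data.frame set/n/median_width/median_height)
#'   and `tests` (data.frame contrast/measure/p_value; `NA` when a set has
#'   fewer than 2 members, with the reason in `note`).
#' @export
compare_gene_sets <- function(table, spatial_genes, universe = NULL) {
  tab <- as.data.frame(table)
  if (!is.null(universe)) tab <- tab[tab$gene %in% universe, , drop = FALSE]
  sets <- list(
    spatial = tab[tab$gene %in% spatial_genes, , drop = FALSE],
    active = tab[tab$width > 0 & !(tab$gene %in% spatial_genes), , drop = FALSE],
    all = tab)
  medians <- do.call(rbind, lapply(names(sets), function(s)
    data.frame(set = s, n = nrow(sets[[s]]),
               median_width = stats::median(sets[[s]]$width),
               median_height = stats::median(sets[[s]]$height))))
  contrasts <- list(c("spatial", "active"), c("spatial", "all"),
                    c("active", "all"))
  tests <- do.call(rbind, lapply(contrasts, function(ct) {
    do.call(rbind, lapply(c("width", "height"), function(ms) {
      a <- sets[[ct[1L]]][[ms]]; b <- sets[[ct[2L]]][[ms]]
      if (length(a) < 2L || length(b) < 2L)
        return(data.frame(contrast = paste(ct, collapse = " vs "),
                          measure = ms, p_value = NA_real_,
                          note = "set with < 2 members"))
      data.frame(contrast = paste(ct, collapse = " vs "), measure = ms,
                 p_value = rank_sum_p(a, b), note = "")
    }))
  }))
  list(medians = medians, tests = tests)
}
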