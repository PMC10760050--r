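#' Regular spot grid partitioned into tissue regions
#'
#' Builds an `n_rows` x `n_cols` grid with physical pitch `pitch`
#' micrometers and labels each spot by the first disk-shaped region that
#' contains it ("background" otherwise). The layout is deterministic;
#' `seed` is carried in the output for provenance.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param pitch Spot pitch in micrometers (default 20).
#' @param regions List of `list(center = c(x, y), radius, label)`; labels
#'   must be distinct.
#' @param seed Stored with the layout.
#' @return A `spot_grid` with a `region` column and attributes `regions`,
#'   `pitch`, `seed`.
#' @export
make_tissue_layout <- function(n_rows, n_cols, pitch = 20,
                               regions = list(), seed = NULL) {
  labs <- vapply(regions, `[[`, "", "label")
  stop_if(anyDuplicated(labs) > 0L, "region labels must be distinct")
  grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  x <- (grid$col - 1) * pitch
  y <- (grid$row - 1) * pitch
  region <- rep("background", nrow(grid))
  for (r in regions) {
    d <- sqrt((x - r$center[1L])^2 + (y - r$center[2L])^2)
    hit <- region == "background" & d <= r$radius
    region[hit] <- r$label
  }
  sp <- spot_grid(sprintf("S%05d", seq_len(nrow(grid))), x, y,
                  grid$row, grid$col, TRUE, region)
  attr(sp, "regions") <- regions
  attr(sp, "pitch") <- pitch
  attr(sp, "seed") <- seed
  sp
}

#' Synthetic gene model with spatial and housekeeping genes
#'
#' Lays genes on two synthetic chromosomes at fixed spacing. Spatial genes
#' are assigned round-robin to the given regions and carry a maximal
#' promoter-domain width; housekeeping genes carry a fixed narrow peak.
#'
#' @param region_labels Region labels receiving spatial genes.
#' @param genes_per_region Spatial genes per region.
#' @param n_housekeeping Number of housekeeping genes.
#' @param spacing Distance between gene starts in bp (default 60000).
#' @param gene_length Transcript length (default 10000).
#' @param max_width Maximal broad-domain width of spatial genes in bp
#'   (default 20000; recycled per gene).
#' @param hk_width Housekeeping peak width (default 1500).
#' @param promoter_bp Promoter half-width (default 2000).
#' @return A `gene_model` with extra columns `role` ("spatial" or
#'   "housekeeping"), `region`, `max_width_bp` and attribute
#'   `chrom_lengths`.
#' @export
make_synthetic_genes <- function(region_labels, genes_per_region = 4L,
                                 n_housekeeping = 60L, spacing = 60000L,
                                 gene_length = 10000L, max_width = 20000L,
                                 hk_width = 1500L, promoter_bp = 2000L) {
  n_spatial <- length(region_labels) * genes_per_region
  n <- n_spatial + n_housekeeping
  role <- c(rep("spatial", n_spatial), rep("housekeeping", n_housekeeping))
  region <- c(rep(region_labels, each = genes_per_region),
              rep(NA_character_, n_housekeeping))
  per_chrom <- ceiling(n / 2)
  chrom <- rep(c("chrS1", "chrS2"), each = per_chrom)[seq_len(n)]
  slot <- c(seq_len(per_chrom), seq_len(n - per_chrom))
  start <- (slot - 1L) * spacing + 25000L
  strand <- rep(c("+", "-"), length.out = n)
  gm <- gene_model(sprintf("gene%03d", seq_len(n)), chrom, strand,
                   start, start + gene_length, promoter_bp)
  gm$role <- role
  gm$region <- region
  gm$max_width_bp <- ifelse(role == "spatial",
                            rep_len(max_width, n), hk_width)
  attr(gm, "chrom_lengths") <- stats::setNames(
    rep((per_chrom + 1L) * spacing, 2L), c("chrS1", "chrS2"))
  class(gm) <- c("gene_model", "data.frame")
  gm
}

# expected promoter-anchored domain of a gene at physical distance d from
# its region center: the activating mark shrinks linearly to zero at d0,
# the repressive mark grows complementarily up to rep_max
planted_width <- function(d, max_width, d0, mark, rep_max = 10000) {
  if (mark == "activating") max_width * pmax(0, 1 - d / d0)
  else rep_max * pmin(1, d / d0)
}

# promoter-anchored interval of width w (downstream of TSS, strand-aware)
domain_anchor <- function(gene, w) {
  if (gene$strand == "+") c(gene$tss, gene$tss + w)
  else c(gene$tss - w + 1, gene$tss + 1)
}

#' Simulate a fragment set for one mark with planted domain structure
#'
#' For each spot and spatial gene, fragments are placed uniformly over a
#' promoter-anchored domain whose width follows the planted linear profile
#' (activating mark: `max_width * max(0, 1 - d/d0)` with `d` the spot's
#' distance from the gene's region center; repressive mark: complementary
#' growth `rep_max * min(1, d/d0)`). Housekeeping genes carry the same
#' narrow activating peak everywhere; all genes receive uniform local
#' background. Fragment numbers are Poisson.
#'
#' @param spots A `spot_grid` from [make_tissue_layout()].
#' @param genes A `gene_model` from [make_synthetic_genes()].
#' @param mark "activating" or "repressive".
#' @param rate_kb Fragments per kb of planted domain per spot (default 2).
#' @param hk_rate Fragments per spot in a housekeeping peak (default 2).
#' @param bg_rate Background fragments per spot per gene locus
#'   (default 0.3, spread over the gene +/- `bg_span`).
#' @param bg_span Background half-span around a gene (default 20000).
#' @param d0 Distance (micrometers) at which the activating width reaches 0;
#'   default 1.5 times the gene's region radius.
#' @param rep_max Maximal repressive-domain width (default 10000).
#' @param frag_len Simulated fragment length (default 300).
#' @param depth Global depth multiplier applied to all rates (default 1;
#'   must be positive).
#' @param seed Random seed.
#' @return A `fragment_set`; planted per-gene width functions are
#'   recoverable from the gene model and layout via [planted_truth()].
#' @export
simulate_fragments <- function(spots, genes, mark = c("activating", "repressive"),
                               rate_kb = 2, hk_rate = 2, bg_rate = 0.3,
                               bg_span = 20000L, d0 = NULL, rep_max = 10000,
                               frag_len = 300L, depth = 1, seed = 1L) {
  mark <- match.arg(mark)
  stop_if(depth <= 0, "depth must be positive")
  regions <- attr(spots, "regions")
  with_seed(seed, {
    parts <- vector("list", nrow(genes))
    for (g in seq_len(nrow(genes))) {
      gene <- genes[g, ]
      lam_bg <- rep(bg_rate * depth, nrow(spots))
      bg_lo <- max(0, gene$start - bg_span)
      bg_hi <- gene$end + bg_span
      pieces <- list(sim_uniform_frags(lam_bg, bg_lo, bg_hi, spots$barcode,
                                       gene$chrom, frag_len))
      if (gene$role == "housekeeping") {
        if (mark == "activating") {
          iv <- domain_anchor(gene, gene$max_width_bp)
          pieces[[2L]] <- sim_uniform_frags(rep(hk_rate * depth, nrow(spots)),
                                            iv[1L], iv[2L], spots$barcode,
                                            gene$chrom, frag_len)
        }
      } else {
        reg <- Filter(function(r) r$label == gene$region, regions)[[1L]]
        d <- sqrt((spots$x - reg$center[1L])^2 + (spots$y - reg$center[2L])^2)
        d0g <- d0 %||% (1.5 * reg$radius)
        w <- planted_width(d, gene$max_width_bp, d0g, mark, rep_max)
        lam <- rate_kb * depth * w / 1000
        active <- which(lam > 0)
        if (length(active)) {
          n <- stats::rpois(length(active), lam[active])
          tot <- sum(n)
          if (tot > 0) {
            wf <- rep(w[active], n)
            sp <- rep(active, n)
            off <- floor(stats::runif(tot) * pmax(1, wf - frag_len))
            a0 <- if (gene$strand == "+") gene$tss else gene$tss - wf + 1
            st <- as.integer(a0 + off)
            pieces[[2L]] <- data.table::data.table(
              chrom = gene$chrom, start = st, end = st + frag_len,
              barcode = spots$barcode[sp], count = 1L)
          }
        }
      }
      parts[[g]] <- data.table::rbindlist(pieces)
    }
    fragment_set(data.table::rbindlist(parts))
  })
}

# Poisson number of fragments per spot, uniform starts in [lo, hi - frag_len)
sim_uniform_frags <- function(lambda, lo, hi, barcodes, chrom, frag_len) {
  n <- stats::rpois(length(lambda), lambda)
  tot <- sum(n)
  if (tot == 0) return(data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    barcode = character(), count = integer()))
  st <- as.integer(lo + floor(stats::runif(tot) * max(1, hi - lo - frag_len)))
  data.table::data.table(chrom = chrom, start = st, end = st + frag_len,
                         barcode = rep(barcodes, n), count = 1L)
}

#' Planted ground truth for a synthetic dataset
#'
#' Collects, per gene and spot, the planted domain width (activating mark)
#' from the layout and gene model, plus the spatial-gene identities.
#'
#' @param spots Layout from [make_tissue_layout()].
#' @param genes Genes from [make_synthetic_genes()].
#' @param d0 As in [simulate_fragments()].
#' @param rep_max As in [simulate_fragments()].
#' @return List with `spatial_genes`, `gene_region` (named vector),
#'   `width` (genes x spots planted activating widths), `width_rep`.
#' @export
planted_truth <- function(spots, genes, d0 = NULL, rep_max = 10000) {
  regions <- attr(spots, "regions")
  sg <- genes$name[genes$role == "spatial"]
  W <- matrix(0, nrow(genes), nrow(spots),
              dimnames = list(genes$name, spots$barcode))
  Wr <- W
  for (g in which(genes$role == "spatial")) {
    reg <- Filter(function(r) r$label == genes$region[g], regions)[[1L]]
    d <- sqrt((spots$x - reg$center[1L])^2 + (spots$y - reg$center[2L])^2)
    d0g <- d0 %||% (1.5 * reg$radius)
    W[g, ] <- planted_width(d, genes$max_width_bp[g], d0g, "activating")
    Wr[g, ] <- planted_width(d, genes$max_width_bp[g], d0g, "repressive", rep_max)
  }
  list(spatial_genes = sg,
       gene_region = stats::setNames(genes$region, genes$name),
       width = W, width_rep = Wr)
}

#' Rigidly transformed second slice of a spot grid
#'
#' Rotates the grid by `angle` degrees about its centroid, translates it,
#' adds Gaussian positional jitter, and randomly drops spots. The exact
#' planted transform (original -> new coordinates) is returned for oracle
#' comparisons.
#'
#' @param spots A `spot_grid`.
#' @param angle Rotation in degrees, |angle| <= 180.
#' @param translation Length-2 translation in micrometers.
#' @param jitter_sd Positional jitter standard deviation (default 0).
#' @param dropout Fraction of spots dropped independently (default 0;
#'   must be < 1).
#' @param seed Random seed.
#' @return List with `spots` (new `spot_grid`, barcodes prefixed "s2_")
#'   and `transform` (the planted `rigid_transform`).
#' @export
make_second_slice <- function(spots, angle = 0, translation = c(0, 0),
                              jitter_sd = 0, dropout = 0, seed = 1L) {
  stop_if(abs(angle) > 180, "|angle| must be <= 180 degrees")
  stop_if(dropout >= 1, "dropout must be < 1")
  xy <- cbind(spots$x, spots$y)
  cen <- colMeans(xy)
  th <- angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  t_full <- as.numeric(cen + translation - R %*% cen)
  planted <- structure(list(R = R, t = t_full, reflection = FALSE),
                       class = "rigid_transform")
  with_seed(seed, {
    new_xy <- apply_transform(planted, xy)
    if (jitter_sd > 0)
      new_xy <- new_xy + matrix(stats::rnorm(length(new_xy), 0, jitter_sd),
                                ncol = 2L)
    keep <- if (dropout > 0) stats::runif(nrow(new_xy)) >= dropout else
      rep(TRUE, nrow(new_xy))
    sp2 <- spot_grid(paste0("s2_", spots$barcode[keep]),
                     new_xy[keep, 1L], new_xy[keep, 2L],
                     spots$row[keep], spots$col[keep], TRUE,
                     region = if (!is.null(spots$region)) spots$region[keep])
    attr(sp2, "source_barcode") <- spots$barcode[keep]
    list(spots = sp2, transform = planted)
  })
}

#' The "embryo-mini" synthetic preset
#'
#' A small complete dataset exercising every pipeline stage: a 32 x 32 spot
#' grid with 8 disk regions, 3 spatial genes per region plus housekeeping
#' genes, activating and repressive fragment sets, and a rotated, jittered,
#' thinned second slice carrying the repressive mark.
#'
#' @param seed Random seed (drives all fragment sampling).
#' @param n_rows,n_cols Grid size (default 32 x 32).
#' @param genes_per_region Spatial genes per region (default 3).
#' @param n_housekeeping Housekeeping genes (default 56).
#' @param angle,jitter_sd,dropout Second-slice parameters (defaults 15
#'   degrees, 1 um, 0.05).
#' @return List with `spots`, `genes`, `frags_act`, `frags_rep`, `slice2`
#'   (spots + planted transform), `truth` (from [planted_truth()]), and the
#'   generation `params`.
#' @export
simulate_embryo_mini <- function(seed = 1L, n_rows = 32L, n_cols = 32L,
                                 genes_per_region = 3L, n_housekeeping = 56L,
                                 angle = 15, jitter_sd = 1, dropout = 0.05) {
  pitch <- 20
  ext <- c((n_cols - 1) * pitch, (n_rows - 1) * pitch)
  # irregular arrangement: tissue outlines should carry no rotational
  # symmetry, as real sections do not
  cen <- list(c(.22, .25), c(.52, .12), c(.80, .22), c(.13, .56),
              c(.82, .50), c(.30, .80), c(.62, .86), c(.88, .78))
  rad <- c(80, 70, 90, 75, 100, 85, 70, 90)
  labels <- c("heart", "liver", "forebrain", "midbrain", "hindbrain",
              "limb", "meninges", "cartilage")
  regions <- lapply(seq_along(cen), function(i)
    list(center = cen[[i]] * ext, radius = rad[i], label = labels[i]))
  spots <- make_tissue_layout(n_rows, n_cols, pitch, regions, seed)
  genes <- make_synthetic_genes(labels, genes_per_region, n_housekeeping,
                                max_width = 20000L)
  frags_act <- simulate_fragments(spots, genes, "activating", seed = seed)
  frags_rep <- simulate_fragments(spots, genes, "repressive",
                                  seed = seed + 1L)
  slice2 <- make_second_slice(spots, angle = angle, translation = c(150, -80),
                              jitter_sd = jitter_sd, dropout = dropout,
                              seed = seed + 2L)
  list(spots = spots, genes = genes, frags_act = frags_act,
       frags_rep = frags_rep, slice2 = slice2,
       truth = planted_truth(spots, genes),
       params = list(seed = seed, n_rows = n_rows, n_cols = n_cols,
                     pitch = pitch, regions = regions, angle = angle,
                     jitter_sd = jitter_sd, dropout = dropout))
}

#' Benchmark preset for spatial-gene recovery
#'
#' 45 x 45 grid (2025 spots), 4 disk regions each covering roughly 14% of
#' the slide, 30 planted spatial genes distributed over the regions among
#' 300 genes total.
#'
#' @param seed Random seed.
#' @return Same structure as [simulate_embryo_mini()] minus the second
#'   slice.
#' @export
simulate_spatial_benchmark <- function(seed = 1L) {
  pitch <- 20
  n <- 45L
  ext <- (n - 1) * pitch
  cen <- list(c(.28, .28), c(.72, .28), c(.28, .72), c(.72, .72))
  regions <- lapply(seq_along(cen), function(i)
    list(center = cen[[i]] * ext, radius = 185,
         label = paste0("region", i)))
  spots <- make_tissue_layout(n, n, pitch, regions, seed)
  labs <- vapply(regions, `[[`, "", "label")
  genes <- make_synthetic_genes(rep(labs, times = c(8L, 8L, 7L, 7L)),
                                genes_per_region = 1L,
                                n_housekeeping = 270L,
                                max_width = 20000L)
  frags <- simulate_fragments(spots, genes, "activating", seed = seed)
  list(spots = spots, genes = genes, frags_act = frags,
       truth = planted_truth(spots, genes),
       params = list(seed = seed, n_rows = n, n_cols = n, pitch = pitch,
                     regions = regions))
}

#' Transition preset: one tissue with planted width gradients
#'
#' A 40 x 40 grid with a single "heart" region; its spatial genes carry an
#' activating domain shrinking linearly from 20 kb at the region center to
#' ~2 kb at the far edge of the slide, and a repressive domain growing
#' complementarily from 0 to 10 kb.
#'
#' @param seed Random seed.
#' @param n_genes_heart Heart spatial genes (default 3).
#' @param n_housekeeping Housekeeping genes (default 27).
#' @return List with `spots`, `genes`, `frags_act`, `frags_rep`, `d0`,
#'   `truth`.
#' @export
simulate_transition_tissue <- function(seed = 1L, n_genes_heart = 3L,
                                       n_housekeeping = 27L) {
  pitch <- 20
  n <- 40L
  ext <- (n - 1) * pitch
  regions <- list(list(center = c(.3, .3) * ext, radius = 120,
                       label = "heart"))
  spots <- make_tissue_layout(n, n, pitch, regions, seed)
  genes <- make_synthetic_genes("heart", genes_per_region = n_genes_heart,
                                n_housekeeping = n_housekeeping,
                                max_width = 20000L)
  # width reaches ~2 kb at the far corner of the slide (10% of d0 short of 0)
  dmax <- max(sqrt((spots$x - regions[[1L]]$center[1L])^2 +
                     (spots$y - regions[[1L]]$center[2L])^2))
  d0 <- dmax / 0.9
  frags_act <- simulate_fragments(spots, genes, "activating", d0 = d0,
                                  seed = seed)
  frags_rep <- simulate_fragments(spots, genes, "repressive", d0 = d0,
                                  seed = seed + 1L)
  list(spots = spots, genes = genes, frags_act = frags_act,
       frags_rep = frags_rep, d0 = d0,
       truth = planted_truth(spots, genes, d0 = d0))
}

#' Simulate a binarized pseudobulk track with planted domain widths
#'
#' Directly generates a per-bin insertion-count track containing one domain
#' per requested width on one synthetic chromosome, with Poisson counts at
#' `depth` mean insertions per enriched bin (background `bg_depth`), or the
#' noiseless expectation when `noiseless = TRUE`.
#'
#' @param widths_bp Planted domain widths (bp, multiples of `bin_bp`).
#' @param gap_bp Gap between planted domains (default 30000).
#' @param depth Mean insertions per enriched 100 bp bin (default 10).
#' @param bg_depth Mean insertions per background bin (default 0.2).
#' @param bin_bp Bin width (default 100).
#' @param cutoff Binarization cutoff (default 5).
#' @param noiseless Use exact expectations instead of Poisson draws.
#' @param seed Random seed.
#' @return A `signal_track` with attribute `domains` (data.frame start/end
#'   of the planted intervals).
#' @export
simulate_domain_track <- function(widths_bp, gap_bp = 30000L, depth = 10,
                                  bg_depth = 0.2, bin_bp = 100L, cutoff = 5,
                                  noiseless = FALSE, seed = 1L) {
  nb_gap <- gap_bp / bin_bp
  nb <- widths_bp / bin_bp
  total <- as.integer(sum(nb) + nb_gap * (length(nb) + 1L))
  enr <- logical(total)
  pos <- nb_gap
  planted <- data.frame(start = integer(0), end = integer(0))
  for (w in nb) {
    enr[(pos + 1L):(pos + w)] <- TRUE
    planted <- rbind(planted,
                     data.frame(start = pos * bin_bp, end = (pos + w) * bin_bp))
    pos <- pos + w + nb_gap
  }
  v <- if (noiseless) ifelse(enr, depth, 0)
  else with_seed(seed, stats::rpois(total, ifelse(enr, depth, bg_depth)))
  tr <- signal_track(list(chrS1 = as.numeric(v)), bin_bp, cutoff)
  attr(tr, "domains") <- planted
  tr
}
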