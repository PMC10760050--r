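two_cluster_scores <- function(n_per = 60, seed = 24) {
  set.seed(seed)
  bc <- sprintf("s%03d", seq_len(2 * n_per))
  sc <- cbind(matrix(rnorm(5 * n_per, 0, 0.3), 5, n_per),
              matrix(rnorm(5 * n_per, 4, 0.3), 5, n_per))
  dimnames(sc) <- list(sprintf("g%d", 1:5), bc)
  sc
}

test_that("diffusion map separates planted clusters along DC1", {
  sc <- two_cluster_scores()
  dcs <- diffusion_map(sc, 2)
  side <- rep(c(0, 1), each = 60)
  lab <- as.integer(dcs[, "DC1"] > 0)
  err <- min(mean(lab != side), mean(lab == side))
  expect_lte(err, 0.02)
})

test_that("diffusion map is deterministic and duplicates coincide", {
  sc <- two_cluster_scores()
  sc2 <- cbind(sc, dup = sc[, 1])
  colnames(sc2)[ncol(sc2)] <- "dup"
  dcs <- diffusion_map(sc2, 2)
  expect_equal(dcs["dup", ], dcs[colnames(sc2)[1], ], tolerance = 1e-8)
  expect_identical(diffusion_map(sc2, 2), dcs)
})

field_fixture <- function(n = 100, seed = 25) {
  set.seed(seed)
  sp <- spot_grid(sprintf("s%03d", 1:n), runif(n, 0, 500), runif(n, 0, 500))
  dcs <- matrix(rnorm(2 * n), n, 2,
                dimnames = list(sp$barcode, c("DC1", "DC2")))
  list(spots = sp, dcs = dcs)
}

test_that("pseudo distance matches its definition and bounds", {
  fx <- field_fixture()
  ref <- fx$spots$barcode[1:10]
  pd <- pseudo_distance(fx$spots, fx$dcs, ref)
  # direct recomputation from the definition
  cen_xy <- colMeans(cbind(fx$spots$x, fx$spots$y)[1:10, ])
  cen_dc <- colMeans(fx$dcs[1:10, ])
  S <- sqrt((fx$spots$x - cen_xy[1])^2 + (fx$spots$y - cen_xy[2])^2)
  D <- sqrt(rowSums(sweep(fx$dcs, 2, cen_dc)^2))
  nm <- function(v) (v - min(v)) / diff(range(v))
  expect_equal(pd$pseudo_distance, unname(nm(S) + nm(D)), tolerance = 1e-12)
  expect_true(all(pd$pseudo_distance >= 0 & pd$pseudo_distance <= 2))

  # a spot at both centroids has distance 0; the double maximum scores 2
  i0 <- which.min(pd$pseudo_distance)
  expect_equal(pd$S_norm[which.min(S)], 0)
  expect_equal(max(pd$pseudo_distance) <= 2, TRUE)
})

test_that("pseudo distance is invariant to rigid motions of either space", {
  fx <- field_fixture()
  ref <- fx$spots$barcode[1:10]
  pd0 <- pseudo_distance(fx$spots, fx$dcs, ref)

  th <- 70 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy2 <- t(R %*% t(cbind(fx$spots$x, fx$spots$y))) + 40
  sp2 <- spot_grid(fx$spots$barcode, xy2[, 1], xy2[, 2])
  pd1 <- pseudo_distance(sp2, fx$dcs, ref)
  expect_equal(pd1$pseudo_distance, pd0$pseudo_distance, tolerance = 1e-9)

  dcs2 <- fx$dcs %*% R   # orthogonal transform of diffusion space
  rownames(dcs2) <- rownames(fx$dcs)
  pd2 <- pseudo_distance(fx$spots, dcs2, ref)
  expect_equal(pd2$pseudo_distance, pd0$pseudo_distance, tolerance = 1e-9)
})

test_that("equidistance groups follow the stated bin conventions", {
  pd <- stats::setNames(seq(0, 1.9, by = 0.1), sprintf("s%02d", 1:20))
  g <- equidistance_groups(pd, 20)
  expect_equal(unname(g), 1:20)

  # a value exactly on an interior edge goes to the higher bin
  pd2 <- stats::setNames(c(0, 0.5, 1), c("a", "b", "c"))
  g2 <- equidistance_groups(pd2, 2)
  expect_equal(unname(g2), c(1L, 2L, 2L))

  expect_equal(unname(equidistance_groups(pd, 1)), rep(1L, 20))
  expect_error(equidistance_groups(rep(1, 5)), "constant")

  # monotone: larger distance never gets a smaller group
  set.seed(26)
  pd3 <- stats::setNames(runif(200), sprintf("x%03d", 1:200))
  g3 <- equidistance_groups(pd3, 20)
  expect_true(all(diff(g3[order(pd3)]) >= 0))
})

test_that("group width equals a brute-force recount of significant bins", {
  # group g carries exactly 200 - 10 * g significant bins: 5 spots per
  # group, 2 insertions per spot per covered bin
  n_groups <- 5
  frags <- list()
  groups <- integer(0)
  for (g in seq_len(n_groups)) {
    bcs <- sprintf("g%d_s%d", g, 1:5)
    groups <- c(groups, stats::setNames(rep(g, 5), bcs))
    nb <- 200 - 10 * g
    pos <- (seq_len(nb) - 1L) * 100L
    frags[[g]] <- data.frame(chrom = "chr1",
                             start = rep(pos, each = 5),
                             end = rep(pos, each = 5) + 60L,
                             barcode = rep(bcs, nb), count = 1L)
  }
  fr <- fragment_set(do.call(rbind, frags))
  win <- list(chrom = "chr1", start = 0L, end = 20000L)
  prof <- group_domain_width(fr, groups, win)
  expect_equal(prof$width_bp, (200 - 10 * seq_len(n_groups)) * 100)
  expect_equal(attr(prof, "trend"), -1)

  # brute-force recount for one group
  g2 <- fr[fr$barcode %in% names(groups)[groups == 2], ]
  ins <- c(g2$start, g2$end - 1L)
  cnt <- table(floor(ins[ins >= 0 & ins < 20000] / 100))
  scaled <- as.numeric(cnt)   # equal group sizes: scaling is identity
  expect_equal(prof$width_bp[2], sum(scaled >= 5) * 100)
})

test_that("flat signal yields a zero trend with a flag", {
  bcs <- sprintf("s%02d", 1:20)
  groups <- stats::setNames(rep(1:4, each = 5), bcs)
  fr <- fragment_set(data.frame(chrom = "chr1",
                                start = rep(c(0, 100, 200), 20),
                                end = rep(c(0, 100, 200), 20) + 50,
                                barcode = rep(bcs, each = 3), count = 2L))
  prof <- group_domain_width(fr, groups, list(chrom = "chr1", start = 0,
                                              end = 1000))
  expect_equal(sd(prof$width_bp), 0)
  tr <- attr(prof, "trend")
  expect_equal(as.numeric(tr), 0)
  expect_true(attr(tr, "flat"))
})

test_that("undersized groups are excluded from the width trend", {
  bcs <- c(sprintf("a%d", 1:6), sprintf("b%d", 1:6), "lone")
  groups <- stats::setNames(c(rep(1L, 6), rep(2L, 6), 3L), bcs)
  fr <- fragment_set(data.frame(chrom = "chr1", start = 0, end = 50,
                                barcode = bcs, count = 5L))
  prof <- group_domain_width(fr, groups, list(chrom = "chr1", start = 0,
                                              end = 1000))
  expect_true(is.na(prof$width_bp[prof$group == 3]))
  expect_false(any(is.na(prof$width_bp[prof$group != 3])))
})
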