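rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

test_that("kabsch recovers exact rotations and translations", {
  set.seed(18)
  src <- matrix(rnorm(100), 50, 2)
  tgt <- t(rot2(90) %*% t(src))
  k <- kabsch(src, tgt)
  expect_equal(transform_angle(k), 90, tolerance = 1e-9)
  expect_lt(max(abs(k$t)), 1e-9)

  k2 <- kabsch(src, sweep(src, 2, c(-5, 3)))
  expect_equal(k2$R, diag(2), tolerance = 1e-12)
  expect_equal(k2$t, c(5, -3), tolerance = 1e-12)

  # random planted transform, no noise: RMSD < 1e-9
  planted <- rot2(37.3)
  tgt3 <- sweep(t(planted %*% t(src)), 2, -c(2.2, -7.7))
  k3 <- kabsch(src, tgt3)
  back <- apply_transform(k3, src)
  expect_lt(sqrt(mean(rowSums((back - tgt3)^2))), 1e-9)

  expect_error(kabsch(matrix(1, 5, 2), matrix(1, 5, 2)), "coincident")
})

test_that("kabsch output is orthogonal with unit determinant", {
  set.seed(19)
  for (i in 1:10) {
    src <- matrix(rnorm(20), 10, 2)
    tgt <- matrix(rnorm(20), 10, 2)
    k <- kabsch(src, tgt)
    expect_equal(crossprod(k$R), diag(2), tolerance = 1e-9)
    expect_equal(det(k$R), 1, tolerance = 1e-9)
    inv <- invert_transform(k)
    expect_equal(apply_transform(inv, apply_transform(k, src)), src,
                 tolerance = 1e-9)
  }
})

test_that("transforms survive a text round-trip", {
  k <- structure(list(R = rot2(12), t = c(1.5, -2.25), reflection = FALSE),
                 class = "rigid_transform")
  f <- tempfile()
  write_transform(k, f)
  k2 <- read_transform(f)
  expect_equal(k2$R, k$R, tolerance = 1e-12)
  expect_equal(k2$t, k$t, tolerance = 1e-12)
})

test_that("ICP is exact on identical and noiselessly transformed clouds", {
  cloud <- tissue_cloud()
  xy <- cbind(cloud$x, cloud$y)
  fit0 <- icp_align(xy, xy)
  expect_lt(abs(transform_angle(fit0)), 1e-9)
  expect_lt(attr(fit0, "rmsd"), 1e-9)
  expect_true(attr(fit0, "converged"))

  s2 <- make_second_slice(cloud, angle = 20, translation = c(40, -25),
                          jitter_sd = 0, dropout = 0, seed = 1)
  fit <- icp_align(xy, cbind(s2$spots$x, s2$spots$y))
  expect_equal(transform_angle(fit), 20, tolerance = 1e-6)
  expect_lt(attr(fit, "rmsd"), 1e-9)
})

test_that("ICP recovers a 20-degree rotation under jitter within 0.5 deg", {
  cloud <- tissue_cloud()
  xy <- cbind(cloud$x, cloud$y)
  extent <- max(apply(xy, 2, function(v) diff(range(v))))
  s2 <- make_second_slice(cloud, angle = 20, translation = c(150, -80),
                          jitter_sd = 0.005 * extent, dropout = 0, seed = 2)
  fit <- icp_align(xy, cbind(s2$spots$x, s2$spots$y))
  expect_lt(abs(transform_angle(fit) - 20), 0.5)
})

test_that("disjoint clouds converge with a large flagged RMSD", {
  set.seed(20)
  a <- matrix(rnorm(60, sd = 30), 30, 2)
  b <- matrix(rnorm(60, mean = 300, sd = 2), 30, 2)
  fit <- icp_align(a, b)
  expect_true(is.finite(attr(fit, "rmsd")))
  expect_gt(attr(fit, "rmsd"), 10)
})

test_that("score transfer interpolates by inverse distance", {
  src <- spot_grid(c("p", "q"), c(0, 20), c(0, 0))
  tgt <- spot_grid(c("t1", "t2"), c(0, 10), c(0, 0))
  scores <- matrix(c(2, 4), 1, 2, dimnames = list("g", c("p", "q")))
  id <- structure(list(R = diag(2), t = c(0, 0), reflection = FALSE),
                  class = "rigid_transform")
  ov <- transfer_scores(scores, id, src, tgt, k = 4, radius = 25)
  # coincident source dominates; midway target averages 2 and 4
  expect_equal(ov$scores["g", "t1"], 2)
  expect_equal(ov$scores["g", "t2"], 3)

  # out-of-radius targets are unmatched
  tgt2 <- spot_grid(c("t1", "far"), c(0, 500), c(0, 0))
  ov2 <- transfer_scores(scores, id, src, tgt2, radius = 25)
  expect_equal(ov2$unmatched, "far")
})

test_that("transfer is equivariant under a common rigid motion", {
  cloud <- tissue_cloud()
  set.seed(22)
  sub <- cloud[sample(nrow(cloud), 120), ]
  src <- spot_grid(paste0("s", seq_len(nrow(sub))), sub$x + 3, sub$y - 2)
  tgt <- spot_grid(paste0("t", seq_len(nrow(sub))), sub$x, sub$y)
  scores <- matrix(rnorm(2 * nrow(sub)), 2, nrow(sub),
                   dimnames = list(c("g1", "g2"), src$barcode))
  fit <- icp_align(cbind(src$x, src$y), cbind(tgt$x, tgt$y))
  ov <- transfer_scores(scores, fit, src, tgt)

  extra <- rot2(33)
  mv <- function(sp) {
    xy <- t(extra %*% t(cbind(sp$x, sp$y))) + 7
    spot_grid(sp$barcode, xy[, 1], xy[, 2])
  }
  src2 <- mv(src); tgt2 <- mv(tgt)
  fit2 <- icp_align(cbind(src2$x, src2$y), cbind(tgt2$x, tgt2$y))
  ov2 <- transfer_scores(scores, fit2, src2, tgt2)
  expect_equal(ov2$scores, ov$scores, tolerance = 1e-6)
  expect_equal(ov2$matched, ov$matched)
})

test_that("planted two-slice pairs match nearly all overlapping spots", {
  cloud <- tissue_cloud()
  xy <- cbind(cloud$x, cloud$y)
  s2 <- make_second_slice(cloud, angle = 25, translation = c(100, 60),
                          jitter_sd = 2, dropout = 0, seed = 3)
  fit <- icp_align(cbind(s2$spots$x, s2$spots$y), xy)
  scores <- matrix(rnorm(nrow(s2$spots)), 1, nrow(s2$spots),
                   dimnames = list("g", s2$spots$barcode))
  ov <- transfer_scores(scores, fit, s2$spots, cloud)
  expect_gte(length(ov$matched) / nrow(cloud), 0.95)
})

test_that("mark relationships classify planted correlation structure", {
  set.seed(23)
  n <- 500
  a <- matrix(rnorm(3 * n), 3, n,
              dimnames = list(c("gneg", "gind", "gpos"), sprintf("s%03d", 1:n)))
  b <- rbind(gneg = -a["gneg", ],
             gind = rnorm(n),
             gpos = a["gpos", ])
  colnames(b) <- colnames(a)
  rel <- mark_relationship(a, b)
  expect_equal(rel$r[rel$gene == "gneg"], -1)
  expect_equal(rel$class[rel$gene == "gneg"], "complementary")
  expect_equal(rel$r[rel$gene == "gpos"], 1)
  expect_equal(rel$class[rel$gene == "gpos"], "co-occurring")
  expect_lt(abs(rel$r[rel$gene == "gind"]), 0.15)
  expect_equal(rel$class[rel$gene == "gind"], "independent")

  # constant profile: undefined correlation reported as missing
  b2 <- b; b2["gind", ] <- 5
  rel2 <- mark_relationship(a, b2)
  expect_true(is.na(rel2$r[rel2$gene == "gind"]))

  curve <- mark_loess_curve(a["gpos", ], b["gpos", ])
  expect_equal(nrow(curve), n)
  expect_false(is.unsorted(curve$x))
})
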