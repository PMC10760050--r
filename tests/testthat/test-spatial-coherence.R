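test_that("spatial network applies the distance filter and symmetrizes", {
  sp <- spot_grid(c("a", "b", "c"), c(0, 10, 100), c(0, 0, 0))
  net <- build_spatial_network(sp, k = 10, max_dist = 40)
  expect_equal(nrow(net$edges), 1L)
  expect_setequal(c(net$edges$from, net$edges$to), c(1L, 2L))
  expect_equal(net$edges$length, 10)

  expect_equal(nrow(build_spatial_network(sp, k = 0)$edges), 0L)
  expect_error(build_spatial_network(sp, k = -1), "non-negative")
})

test_that("grid interior spots link to 8 neighbors within 40 um", {
  sp <- grid_spots(7, 7, pitch = 20)
  net <- build_spatial_network(sp, k = 10, max_dist = 40)
  # brute-force neighbor enumeration
  xy <- cbind(sp$x, sp$y)
  deg <- integer(nrow(sp))
  for (e in seq_len(nrow(net$edges))) {
    deg[net$edges$from[e]] <- deg[net$edges$from[e]] + 1L
    deg[net$edges$to[e]] <- deg[net$edges$to[e]] + 1L
  }
  interior <- sp$row > 1 & sp$row < 7 & sp$col > 1 & sp$col < 7
  expected <- vapply(seq_len(nrow(sp)), function(i) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    sum(d > 0 & d < 40)
  }, 1)
  expect_true(all(deg[interior] == 8))
  expect_equal(deg, as.integer(expected))
})

test_that("rank binarization selects the top fraction deterministically", {
  b <- binarize_gene(stats::setNames(1:10, letters[1:10]), fraction = 0.3)
  expect_equal(names(b)[b == 1], c("h", "i", "j"))

  const <- binarize_gene(rep(2, 8))
  expect_true(all(const == 0))
  expect_true(attr(const, "constant"))

  # ties at the threshold: exactly ceiling(0.3 * n) ones, earliest first
  scores <- c(5, 3, 3, 3, 1, 1, 1, 1, 1, 1)
  b2 <- binarize_gene(scores, fraction = 0.3)
  expect_equal(sum(b2), 3L)
  expect_equal(which(b2 == 1), c(1L, 2L, 3L))
})

test_that("binspect edge table and odds ratio follow the 4-cycle example", {
  net <- manual_network(letters[1:4],
                        cbind(c(1, 2, 3, 4), c(2, 3, 4, 1)))
  b <- c(1, 1, 0, 0)
  r <- binspect_test(b, net)
  expect_equal(r$table, matrix(c(2, 2, 2, 2), 2, 2), ignore_attr = TRUE)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, fisher_oracle_p(r$table), tolerance = 1e-12)

  # all-high labeling: no contrast
  r1 <- binspect_test(rep(1, 4), net)
  expect_true(is.na(r1$odds_ratio))
  expect_equal(r1$p_value, 1)

  # two non-adjacent high spots on a path: depletion of high-high edges
  path <- manual_network(letters[1:4], cbind(1:3, 2:4))
  r2 <- binspect_test(c(1, 0, 1, 0), path)
  expect_equal(r2$odds_ratio, 0)
  expect_gte(r2$p_value, 0.5)
})

test_that("binspect p-values equal hypergeometric enumeration on all labelings", {
  nets <- list(
    path5 = manual_network(letters[1:5], cbind(1:4, 2:5)),
    cycle6 = manual_network(letters[1:6], cbind(1:6, c(2:6, 1))),
    star6 = manual_network(letters[1:6], cbind(rep(1, 5), 2:6)),
    two_tri = manual_network(letters[1:6],
                             cbind(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4))),
    dense8 = manual_network(letters[1:5],
                            cbind(c(1, 1, 1, 2, 2, 3, 3, 4),
                                  c(2, 3, 4, 3, 5, 4, 5, 5))))
  for (net in nets) {
    labs <- all_labelings(length(net$nodes))
    for (i in seq_len(nrow(labs))) {
      b <- labs[i, ]
      r <- binspect_test(b, net)
      expect_equal(r$p_value, fisher_oracle_p(edge_table(b, net)),
                   tolerance = 1e-12)
    }
  }
})

test_that("BH ranking adjusts, orders, truncates, and breaks ties stably", {
  res <- data.frame(gene = c("g1", "g2", "g3"),
                    odds_ratio = c(3, 2, 1),
                    p_value = c(0.01, 0.02, 0.03))
  rk <- rank_spatial_genes(res, top_n = Inf)
  expect_equal(rk$adj_p_value, rep(0.03, 3))
  expect_equal(rk$gene, c("g1", "g2", "g3"))  # raw p breaks the tie

  set.seed(8)
  res2 <- data.frame(gene = sprintf("g%03d", 1:500),
                     odds_ratio = runif(500, 0.5, 4),
                     p_value = runif(500))
  rk2 <- rank_spatial_genes(res2, top_n = 200)
  expect_equal(nrow(rk2), 200L)
  expect_equal(rk2$rank, 1:200)
  expect_true(all(diff(rk2$adj_p_value) >= 0))

  # identical p: descending odds ratio then name decides
  res3 <- data.frame(gene = c("b", "a", "c"), odds_ratio = c(2, 2, 5),
                     p_value = 0.04)
  expect_equal(rank_spatial_genes(res3, 3)$gene, c("c", "a", "b"))
})

test_that("network smoothing averages over closed neighborhoods", {
  # star + isolated node: the isolated node keeps its own value
  net <- manual_network(letters[1:4], cbind(c(1, 1), c(2, 3)))
  scores <- matrix(c(3, 6, 9, 5), 1, 4,
                   dimnames = list("g", letters[1:4]))
  sm <- spatchrom:::smooth_over_network(scores, net)
  expect_equal(sm[1, "a"], mean(c(3, 6, 9)))
  expect_equal(sm[1, "b"], mean(c(3, 6)))
  expect_equal(sm[1, "d"], 5)
})

test_that("co-localization modules separate planted spatial programs", {
  sp <- grid_spots(10, 10)
  net <- build_spatial_network(sp, 10, 40)
  left <- as.numeric(sp$col <= 5)
  set.seed(12)
  noise <- function() rnorm(100, sd = 0.05)
  scores <- rbind(gA1 = 10 * left + noise(),
                  gA2 = 8 * left + noise(),
                  gB1 = 10 * (1 - left) + noise(),
                  gB2 = 7 * (1 - left) + noise())
  colnames(scores) <- sp$barcode
  mod <- spatial_cor_modules(scores, net, k_modules = 2)
  expect_equal(unname(unclass(mod)[c("gA1", "gA2")]),
               rep(unclass(mod)[["gA1"]], 2))
  expect_equal(unname(unclass(mod)[c("gB1", "gB2")]),
               rep(unclass(mod)[["gB1"]], 2))
  expect_false(unclass(mod)[["gA1"]] == unclass(mod)[["gB1"]])

  # a duplicated gene always lands in the same module as its copy
  scores2 <- rbind(scores, gA1copy = scores["gA1", ])
  mod2 <- spatial_cor_modules(scores2, net, 2)
  expect_equal(unclass(mod2)[["gA1copy"]], unclass(mod2)[["gA1"]])
})

test_that("metagenes are per-spot means of z-scored member genes", {
  set.seed(13)
  scores <- matrix(rnorm(30, 10, 3), 3, 10,
                   dimnames = list(c("g1", "g2", "g3"), sprintf("s%02d", 1:10)))
  # single-gene module equals that gene's z-score
  m1 <- metagene(stats::setNames(1L, "g1"), scores)
  expect_equal(as.numeric(m1),
               as.numeric(scale(scores["g1", ])), tolerance = 1e-12)

  # gene plus its exact copy is identical to the single-gene case
  scores2 <- rbind(scores, g1copy = scores["g1", ])
  m2 <- metagene(stats::setNames(c(1L, 1L), c("g1", "g1copy")), scores2)
  expect_equal(as.numeric(m2), as.numeric(m1), tolerance = 1e-12)

  # three-gene module against direct recomputation
  assign <- stats::setNames(c(1L, 1L, 1L), c("g1", "g2", "g3"))
  m3 <- metagene(assign, scores)
  direct <- colMeans(t(apply(scores, 1, scale)))
  expect_equal(as.numeric(m3), direct, tolerance = 1e-12)
})

test_that("permuting spot positions destroys planted spatial coherence", {
  mini <- simulate_embryo_mini(3, n_rows = 24, n_cols = 24,
                               genes_per_region = 1, n_housekeeping = 8)
  sc <- compute_gene_scores(mini$frags_act, mini$genes, mini$spots)
  net <- build_spatial_network(mini$spots, 10, 40)
  planted <- mini$truth$spatial_genes
  res <- binspect(sc[planted, , drop = FALSE], net)
  expect_true(all(res$odds_ratio > 2))

  set.seed(21)
  ors <- replicate(8, {
    perm <- sample(ncol(sc))
    scp <- sc[planted, perm, drop = FALSE]
    colnames(scp) <- colnames(sc)
    median(binspect(scp, net)$odds_ratio)
  })
  expect_true(median(ors) >= 0.8 && median(ors) <= 1.25)
})
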