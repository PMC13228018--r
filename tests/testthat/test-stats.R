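# Bray-Curtis, clustering, PERMANOVA, dispersion homogeneity, rank
# tests, dual correlations and ordinations.  vegan and base stats serve
# as independent cross-checks of the from-scratch implementations.

test_that("Bray-Curtis matches hand arithmetic and vegan", {
  m <- rbind(a = c(6, 0, 2), b = c(2, 2, 2))
  expect_equal(bray_curtis(m)["a", "b"], 6 / 14)
  expect_equal(bray_curtis(rbind(a = c(2, 0), b = c(0, 2)))["a", "b"], 1)
  expect_equal(bray_curtis(rbind(a = c(1, 2), b = c(1, 2)))["a", "b"], 0)
  expect_equal(bray_curtis(rbind(a = c(0, 0), b = c(0, 0)))["a", "b"], 0)
  expect_error(bray_curtis(rbind(c(-1, 0), c(0, 1))), "negative")
  skip_if_not_installed("vegan")
  set.seed(4)
  x <- matrix(rpois(60, 8), 10, 6,
              dimnames = list(paste0("g", 1:10), NULL))
  expect_equal(bray_curtis(x),
               as.matrix(vegan::vegdist(x, "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("hierarchical clustering joins closest pairs and keeps ultrametric heights", {
  d <- matrix(c(0, .1, .8,
                .1, 0, .9,
                .8, .9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h <- hcluster(d)
  expect_equal(h$hclust$height[1], 0.1)     # (A,B) joined first
  expect_equal(h$hclust$height[2], 0.85)    # average linkage
  # ultrametric input is reproduced exactly by average linkage
  du <- matrix(c(0, .2, .6, .6,
                 .2, 0, .6, .6,
                 .6, .6, 0, .3,
                 .6, .6, .3, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  h2 <- hcluster(du)$hclust
  co <- stats::cophenetic(h2)
  expect_equal(as.matrix(co)[LETTERS[1:4], LETTERS[1:4]], du,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_match(hcluster(d)$newick, "^\\(")
})

test_that("PERMANOVA F and R2 agree with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(11)
  for (rep in 1:3) {
    x <- matrix(rpois(10 * 5, 10), 10, 5,
                dimnames = list(paste0("g", 1:10), NULL))
    labels <- sample(rep(c("u", "v"), each = 5))
    d <- bray_curtis(x)
    mine <- permanova(d, labels, seed = 1)
    ref <- vegan::adonis2(stats::as.dist(d) ~ grp,
                          data = data.frame(grp = labels),
                          permutations = 99)
    expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
    expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)
  }
})

test_that("PERMANOVA decomposes sums of squares and bounds R2", {
  set.seed(12)
  x <- matrix(rnorm(16 * 4), 16, 4)
  rownames(x) <- paste0("g", 1:16)
  d <- as.matrix(stats::dist(x))
  labels <- rep(c("a", "b", "c", "d"), each = 4)
  pm <- permanova(d, labels, n_perm = 99, seed = 3,
                  exhaustive_limit = 1)
  expect_lt(abs(pm$ss[["between"]] + pm$ss[["within"]] -
                  pm$ss[["total"]]) / pm$ss[["total"]], 1e-9)
  expect_gte(pm$R2, 0)
  expect_lte(pm$R2, 1)
  expect_false(pm$exhaustive)
  # same seed, same p
  pm2 <- permanova(d, labels, n_perm = 99, seed = 3,
                   exhaustive_limit = 1)
  expect_identical(pm$p_value, pm2$p_value)
})

test_that("exhaustive PERMANOVA on separated clusters attains the minimum p", {
  x <- rbind(matrix(rnorm(8, 0, .01), 4, 2),
             matrix(rnorm(8, 10, .01), 4, 2))
  rownames(x) <- paste0("g", 1:8)
  d <- as.matrix(stats::dist(x))
  labels <- rep(c("a", "b"), each = 4)
  pm <- permanova(d, labels, seed = 1)
  expect_true(pm$exhaustive)
  expect_equal(pm$n_permutations, choose(8, 4))
  # observed F is maximal for exactly the two complementary labelings
  expect_equal(pm$p_value, 2 / choose(8, 4))
})

test_that("equal pairwise distances make the permutation test powerless", {
  d <- matrix(1, 6, 6) - diag(6)
  dimnames(d) <- list(paste0("g", 1:6), paste0("g", 1:6))
  pm <- permanova(d, rep(c("a", "b"), each = 3), seed = 1)
  expect_equal(pm$p_value, 1)
  expect_error(permanova(d, rep("a", 6), seed = 1), "2 groups")
})

test_that("dispersion homogeneity flags unequal spread and degenerate input", {
  set.seed(21)
  tight <- matrix(rnorm(20, 0, 0.01), 10, 2)
  wide <- matrix(rnorm(20, 0, 5), 10, 2)
  x <- rbind(tight, wide)
  rownames(x) <- paste0("g", 1:20)
  d <- as.matrix(stats::dist(x))
  labels <- rep(c("t", "w"), each = 10)
  bd <- beta_dispersion(d, labels, n_perm = 999, seed = 2)
  expect_lt(bd$p_value, 0.01)
  expect_lt(bd$group_dispersions$t, bd$group_dispersions$w)
  # identical points: dispersions all zero, reported p = 1 with flag
  d0 <- matrix(0, 6, 6, dimnames = list(paste0("g", 1:6),
                                        paste0("g", 1:6)))
  bd0 <- beta_dispersion(d0, rep(c("a", "b"), 3), seed = 1)
  expect_true(bd0$degenerate)
  expect_equal(bd0$p_value, 1)
})

test_that("dispersion distances agree with vegan::betadisper on Euclidean input", {
  skip_if_not_installed("vegan")
  set.seed(22)
  x <- matrix(rnorm(24), 12, 2)
  rownames(x) <- paste0("g", 1:12)
  d <- as.matrix(stats::dist(x))
  labels <- rep(c("a", "b"), each = 6)
  bd <- beta_dispersion(d, labels, n_perm = 99, seed = 1)
  ref <- vegan::betadisper(stats::as.dist(d), labels, type = "centroid")
  expect_equal(bd$distances, unname(ref$distances), tolerance = 1e-8)
})

test_that("Kruskal-Wallis H matches hand computation and base R", {
  kd <- kruskal_dunn(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(kd$H, 2.4)
  vals <- c(3, 3, 5, 7, 7, 9, 11, 2)
  labs <- c("x", "x", "x", "y", "y", "y", "z", "z")
  kd2 <- kruskal_dunn(vals, labs)
  ref <- stats::kruskal.test(vals, factor(labs))
  expect_equal(kd2$H, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(kd2$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("identical groups give H = 0 and Dunn is Bonferroni-adjusted over all pairs", {
  kd0 <- kruskal_dunn(rep(1, 6), rep(c("a", "b"), 3))
  expect_equal(kd0$H, 0)
  expect_equal(kd0$p_value, 1)
  kd3 <- kruskal_dunn(c(1, 2, 8, 9, 4, 5), rep(c("a", "b", "c"), each = 2))
  expect_equal(nrow(kd3$pairwise), 3L)
  expect_equal(kd3$pairwise$p_adj,
               pmin(1, kd3$pairwise$p_raw * 3))
  expect_true(all(kd3$pairwise$p_adj >= kd3$pairwise$p_raw))
})

test_that("H is invariant under monotone transforms", {
  set.seed(31)
  vals <- rnorm(18)
  labs <- rep(c("a", "b", "c"), each = 6)
  h1 <- kruskal_dunn(vals, labs)$H
  h2 <- kruskal_dunn(exp(vals), labs)$H
  h3 <- kruskal_dunn(vals^3, labs)$H
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_equal(h1, h3, tolerance = 1e-12)
})

test_that("dual correlation reports only under joint significance", {
  x <- 1:20
  dc <- dual_correlation(x, x)
  expect_equal(dc$pearson_r, 1)
  expect_equal(dc$spearman_rho, 1)
  expect_true(dc$reported)
  # monotone nonlinear: rho = 1, r < 1
  y <- exp(seq(0, 6, length.out = 50))
  dc2 <- dual_correlation(seq(0, 6, length.out = 50), y)
  expect_equal(dc2$spearman_rho, 1)
  expect_lt(dc2$pearson_r, 1)
  expect_true(dc2$reported)
  dc3 <- dual_correlation(1:10, rep(2, 10))
  expect_true(dc3$degenerate)
  expect_false(dc3$reported)
})

test_that("correlation p-values track cor.test t approximations", {
  set.seed(41)
  x <- rnorm(25)
  y <- x + rnorm(25, 0, 2)
  dc <- dual_correlation(x, y)
  expect_equal(dc$pearson_p,
               stats::cor.test(x, y)$p.value, tolerance = 1e-10)
  expect_equal(dc$pearson_r, unname(stats::cor.test(x, y)$estimate),
               tolerance = 1e-12)
  expect_equal(dc$spearman_rho, stats::cor(x, y, method = "spearman"),
               tolerance = 1e-12)
})

test_that("exact permutation correlation p-values work for tiny n", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  dc <- dual_correlation(x, y, exact_permutation = TRUE)
  expect_gt(dc$pearson_p, 0)
  expect_lte(dc$pearson_p, 1)
  expect_error(dual_correlation(1:12, 12:1, exact_permutation = TRUE),
               "n <= 10")
})

test_that("PCA explains collinear data on one axis and drops constants", {
  x <- cbind(a = 1:8, b = 2 * (1:8) + 3)
  rownames(x) <- paste0("g", 1:8)
  p <- pca_ordination(x)
  expect_equal(p$explained[1], 1, tolerance = 1e-12)
  x2 <- cbind(x, const = 5)
  expect_warning(p2 <- pca_ordination(x2), "constant")
  expect_equal(ncol(p2$loadings), 2L)
  expect_true(all(diff(p$explained) <= 1e-12))
})

test_that("PCoA of Euclidean distances recovers the configuration", {
  set.seed(51)
  x <- matrix(rnorm(30), 10, 3)
  rownames(x) <- paste0("g", 1:10)
  d <- as.matrix(stats::dist(x))
  p <- pcoa_ordination(d)
  expect_equal(p$negative_eigenvalue_mass, 0, tolerance = 1e-9)
  rec <- as.matrix(stats::dist(p$coordinates))
  expect_equal(rec, d, tolerance = 1e-8, ignore_attr = TRUE)
  # Bray-Curtis is generally non-Euclidean: negative mass is reported
  set.seed(52)
  m <- matrix(rpois(80, 3), 16, 5,
              dimnames = list(paste0("g", 1:16), NULL))
  p2 <- pcoa_ordination(bray_curtis(m))
  expect_gte(p2$negative_eigenvalue_mass, 0)
  expect_true(all(p2$explained <= 1))
})
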