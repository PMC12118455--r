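# The statistical layer is checked against closed forms, brute-force
# enumeration, and the reference implementations in stats/vegan/ape.

test_that("Bray-Curtis matches the closed form and its boundary cases", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 0), c(0, 2, 3)), 1) # disjoint supports
  expect_equal(bray_curtis(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("Bray-Curtis is symmetric, bounded and zero on identity for random probability vectors", {
  set.seed(42)
  for (i in 1:50) {
    x <- runif(20); x <- x / sum(x)
    y <- runif(20); y <- y / sum(y)
    bc <- bray_curtis(x, y)
    expect_equal(bc, bray_curtis(y, x))
    expect_gte(bc, 0)
    expect_lte(bc, 1)
    expect_equal(bray_curtis(x, x), 0)
  }
})

test_that("distance matrices agree with vegan::vegdist", {
  skip_if_not_installed("vegan")
  set.seed(7)
  u <- matrix(runif(5 * 30), 5, 30)
  u <- u / rowSums(u)
  rownames(u) <- paste0("s", 1:5)
  dm <- bray_curtis_matrix(u)
  ref <- as.matrix(vegan::vegdist(u, method = "bray"))
  expect_equal(unname(dm$D), unname(ref), tolerance = 1e-12)
})

test_that("PCoA embeds Euclidean distances exactly and handles degenerate input", {
  # 3 collinear points: one positive eigenvalue, 1-D coordinates reproduce D
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  ord <- pcoa_ordination(D)
  expect_equal(sum(ord$eigenvalues > 1e-8), 1L)
  emb <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(emb), unname(D), tolerance = 1e-8)

  # distances from random 2-D points reconstruct exactly
  set.seed(11)
  pts <- matrix(rnorm(16), 8, 2)
  D2 <- as.matrix(dist(pts))
  ord2 <- pcoa_ordination(D2)
  expect_equal(unname(as.matrix(dist(ord2$coordinates))), unname(D2),
               tolerance = 1e-8)
  expect_true(all(diff(ord2$eigenvalues) <= 1e-8)) # decreasing

  # all-zero distances: no positive eigenvalues
  ordz <- pcoa_ordination(matrix(0, 4, 4))
  expect_length(ordz$eigenvalues, 0)
  expect_error(pcoa_ordination(matrix(0, 2, 2)), "3 samples")
})

test_that("PCoA agrees with ape::pcoa on a random Bray-Curtis matrix", {
  skip_if_not_installed("ape")
  set.seed(3)
  u <- matrix(runif(6 * 40), 6, 40)
  u <- u / rowSums(u)
  dm <- bray_curtis_matrix(u)
  ord <- pcoa_ordination(dm)
  ref <- ape::pcoa(as.dist(dm$D))
  npos <- min(length(ord$eigenvalues), sum(ref$values$Eigenvalues > 1e-10))
  expect_equal(ord$eigenvalues[1:npos], ref$values$Eigenvalues[1:npos],
               tolerance = 1e-6)
  for (k in 1:npos) { # eigenvectors defined up to sign
    expect_equal(abs(ord$coordinates[, k]), abs(ref$vectors[, k]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("PERMANOVA pseudo-F matches vegan::adonis2 and enumeration matches the oracle", {
  set.seed(5)
  u <- matrix(runif(8 * 25), 8, 25)
  u <- u / rowSums(u)
  dm <- bray_curtis_matrix(u)
  groups <- rep(c("a", "b"), each = 4)

  res <- permanova(dm, groups, n_perm = 99, seed = 1)
  skip_if_not_installed("vegan")
  ref <- vegan::adonis2(as.dist(dm$D) ~ g,
                        data = data.frame(g = groups), permutations = 99)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)

  ex <- permanova(dm, groups, exact = TRUE)
  oracle <- brute_force_permanova(dm$D, groups)
  expect_equal(ex$pseudo_F, oracle$F, tolerance = 1e-12)
  expect_equal(ex$p_value, oracle$p, tolerance = 1e-12)
})

test_that("PERMANOVA separates tight clusters and degrades to p = 1 on identical samples", {
  # two tight, well-separated clusters of 3
  pts <- rbind(matrix(rnorm(6, 0, 0.005), 3), matrix(rnorm(6, 1, 0.005), 3))
  D <- as.matrix(dist(pts))
  groups <- rep(c("a", "b"), each = 3)
  ex <- permanova(D, groups, exact = TRUE)
  expect_lte(ex$p_value, 0.1) # 2/20 assignments tie the observed split
  expect_error(permanova(D, c("a", "a", "a", "a", "a", "b")), ">= 2 samples")

  Dz <- matrix(0, 6, 6)
  expect_equal(permanova(Dz, groups, n_perm = 19)$p_value, 1)
})

test_that("PERMANOVA p is seed-reproducible and invariant to sample reordering", {
  set.seed(9)
  u <- matrix(runif(10 * 20), 10, 20)
  rownames(u) <- paste0("s", 1:10)
  dm <- bray_curtis_matrix(u)
  groups <- rep(c("a", "b"), each = 5)
  p1 <- permanova(dm, groups, n_perm = 199, seed = 4)$p_value
  p2 <- permanova(dm, groups, n_perm = 199, seed = 4)$p_value
  expect_identical(p1, p2)
  perm <- sample(10)
  p3 <- permanova(dm$D[perm, perm], groups[perm], n_perm = 199, seed = 4)$p_value
  expect_lt(abs(p1 - p3), 0.1) # same null distribution, resampled
  f1 <- permanova(dm, groups, n_perm = 9, seed = 1)$pseudo_F
  f3 <- permanova(dm$D[perm, perm], groups[perm], n_perm = 9, seed = 1)$pseudo_F
  expect_equal(f1, f3, tolerance = 1e-12)
})

test_that("Wilcoxon rank-sum: exact enumeration, textbook case, and approximation accuracy", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4), alternative = "less")
  expect_true(res$exact)
  expect_equal(res$p_value, 1 / 6)

  # identical multisets: one-sided p >= 0.5 (tied case uses the approximation)
  res2 <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3), alternative = "less")
  expect_gte(res2$p_value, 0.5)

  # approximation within 0.01 of the exact path for tie-free n = 6 + 6
  set.seed(21)
  for (i in 1:40) {
    x <- sample(seq(0.01, 1, by = 0.01), 6)
    y <- sample(setdiff(seq(0.01, 1, by = 0.01), x), 6)
    exact <- wilcoxon_rank_sum(x, y, alternative = "less")
    expect_true(exact$exact)
    # force the approximate path by appending a far tie-free pair
    approx_p <- metameth:::wilcoxon_normal_approx_p(x, y, "less")
    expect_lt(abs(exact$p_value - approx_p), 0.01)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("Wilcoxon agrees with stats::wilcox.test", {
  set.seed(33)
  for (i in 1:20) {
    x <- rnorm(7)
    y <- rnorm(9)
    for (alt in c("less", "greater", "two.sided")) {
      mine <- wilcoxon_rank_sum(x, y, alternative = alt)
      ref <- stats::wilcox.test(x, y, alternative = alt, exact = FALSE,
                                correct = TRUE)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    }
  }
})

test_that("paired t-test matches stats::t.test and rejects degenerate input", {
  res <- paired_t_test(c(2, 0, 2, 0), c(1, 1, 1, 1))
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  expect_error(paired_t_test(1:5, 1:5), "zero variance")
  set.seed(14)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8)
    for (alt in c("two.sided", "less", "greater")) {
      mine <- paired_t_test(a, b, alternative = alt)
      ref <- stats::t.test(a, b, paired = TRUE, alternative = alt)
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("one-way ANOVA matches brute-force sums of squares and handles degeneracy", {
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$p_value, 1)
  expect_warning(res <- one_way_anova(list(c(0, 0), c(1, 1))), "within-group")
  expect_equal(res$p_value, 0)
  set.seed(8)
  groups <- list(rnorm(5), rnorm(7, 1), rnorm(6, 0.5))
  mine <- one_way_anova(groups)
  df <- data.frame(y = unlist(groups),
                   g = rep(letters[1:3], lengths(groups)))
  ref <- summary(stats::aov(y ~ g, data = df))[[1]]
  expect_equal(mine$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("correlation matches brute-force moments and stats::cor.test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlation_test(x, 2 * x + 1)$r, 1)
  set.seed(2)
  xr <- rnorm(20)
  res <- correlation_test(xr, xr^3, method = "spearman")
  expect_equal(res$r, 1)
  expect_lt(correlation_test(xr, xr^3, method = "pearson")$r, 1)
  for (i in 1:50) {
    a <- rnorm(15); b <- rnorm(15)
    r_brute <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(correlation_test(a, b)$r, r_brute, tolerance = 1e-10)
    ref <- stats::cor.test(a, b)
    expect_equal(correlation_test(a, b)$p_value, ref$p.value, tolerance = 1e-10)
    refs <- stats::cor.test(a, b, method = "spearman", exact = FALSE)
    expect_equal(correlation_test(a, b, method = "spearman")$r,
                 unname(refs$estimate), tolerance = 1e-10)
  }
  expect_error(correlation_test(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("methDiff degenerates gracefully and excludes singleton individuals", {
  u <- matrix(rep(c(0.5, 0.5, 0, 0), each = 6), 6, 4)
  rownames(u) <- paste0("s", 1:6)
  md <- methdiff(u, rep(c("i1", "i2", "i3"), each = 2), n_perm = 49, seed = 1)
  expect_equal(md$wilcoxon$p_value, 1)
  expect_equal(md$permanova$p_value, 1)
  expect_true(all(md$distance$D == 0))

  set.seed(77)
  u2 <- matrix(runif(5 * 8), 5, 8)
  u2 <- u2 / rowSums(u2)
  md2 <- methdiff(u2, c("i1", "i1", "i2", "i2", "i3"), n_perm = 49, seed = 1)
  expect_identical(md2$excluded_individuals, "i3")
  expect_length(md2$within, 2L)  # one within pair per retained individual
  expect_length(md2$between, 4L) # i1 x i2 pairs only
})
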