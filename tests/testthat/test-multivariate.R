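# Distances, PERMANOVA, Mantel, envfit, Spearman, group tests.

test_that("distance metrics match their definitions", {
  x <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(as.numeric(pairwise_distances(x, "euclidean")), 5)
  y <- rbind(a = c(2, 0), b = c(0, 2))
  expect_equal(as.numeric(pairwise_distances(y, "bray_curtis")), 1)
  z <- rbind(a = c(1, 2), b = c(1, 2))
  expect_equal(as.numeric(pairwise_distances(z, "euclidean")), 0)
  expect_error(pairwise_distances(rbind(c(-1, 0), c(1, 1)), "bray_curtis"),
               "non-negative")
  expect_error(pairwise_distances(x[1, , drop = FALSE]), ">= 2 samples")
})

test_that("one-way pseudo-F on Euclidean 1-D distances equals ANOVA F", {
  set.seed(21)
  for (i in 1:3) {
    y <- rnorm(15)
    g <- sample(rep(c("a", "b", "c"), 5))
    res <- permanova(dist(y), data.frame(g = g), "g", n_perm = 49, seed = i)
    f_classic <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
    expect_equal(res$terms$pseudo_f, f_classic, tolerance = 1e-9)
  }
})

test_that("pseudo-F agrees with the vegan implementation", {
  s <- small_simulation()
  hel <- t(counts_matrix(hellinger(s$counts)))
  d <- pairwise_distances(hel, "euclidean")
  meta <- s$design[match(rownames(hel), s$design$sample_id), ]
  mine <- permanova(d, meta, "tree", n_perm = 99, seed = 1)
  ref <- vegan::adonis2(d ~ tree, data = meta, permutations = 99)
  expect_equal(mine$terms$pseudo_f, ref$F[1], tolerance = 1e-9)
  expect_equal(mine$terms$r2, ref$R2[1], tolerance = 1e-9)
})

test_that("exact enumeration of 3+3 labels equals the brute-force oracle", {
  set.seed(8)
  y <- rnorm(6)
  g <- rep(c("a", "b"), each = 3)
  res <- permanova(dist(y), data.frame(g = g), "g", permutations = "exact")
  expect_equal(res$n_perm, 20)

  # oracle: classical ANOVA F over every one of the 20 label splits
  f_of <- function(lab) summary(stats::aov(y ~ factor(lab)))[[1]]$`F value`[1]
  splits <- utils::combn(6, 3, simplify = FALSE)
  fs <- vapply(splits, function(ix) {
    lab <- rep("b", 6)
    lab[ix] <- "a"
    f_of(lab)
  }, numeric(1))
  p_oracle <- mean(fs >= f_of(g) - 1e-12)
  expect_identical(res$terms$p_value, p_oracle)
})

test_that("two-way PERMANOVA decomposes a clean 2x2 design", {
  # response separated along factor A only; balanced orthogonal design
  a <- rep(c("a1", "a2"), each = 8)
  b <- rep(c("b1", "b2"), 8)
  set.seed(31)
  y <- ifelse(a == "a1", 0, 10) + rnorm(16, sd = 0.1)
  res <- permanova(dist(y), data.frame(a = a, b = b), c("a", "b"),
                   n_perm = 199, seed = 1)
  terms <- res$terms
  expect_gt(terms$pseudo_f[terms$term == "a"],
            100 * terms$pseudo_f[terms$term == "b"])
  expect_equal(terms$p_value[terms$term == "a"], 1 / 200)
  expect_gt(terms$p_value[terms$term == "b"], 0.1)
  expect_error(permanova(dist(y), data.frame(a = rep("x", 16)), "a"),
               "single level")
})

test_that("permutation p-values respect the (b+1)/(m+1) floor", {
  # groups separated far beyond within-group spread: p at the floor
  y <- c(rnorm(6), rnorm(6) + 1000)
  g <- rep(c("a", "b"), each = 6)
  res <- permanova(dist(y), data.frame(g = g), "g", n_perm = 199, seed = 2)
  expect_equal(res$terms$p_value, 1 / 200)
})

test_that("Mantel statistic and invariances behave", {
  set.seed(41)
  x <- matrix(rnorm(20), 10, 2)
  d1 <- dist(x)
  res_same <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_equal(res_same$statistic, 1)
  res_scaled <- mantel_test(d1, 2 * as.matrix(d1), n_perm = 99, seed = 1)
  expect_equal(res_scaled$statistic, 1)

  d2 <- dist(matrix(rnorm(20), 10, 2))
  mine <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  ref <- vegan::mantel(d1, d2, permutations = 99)
  expect_equal(mine$statistic, ref$statistic, tolerance = 1e-9)

  # joint relabelling leaves r unchanged
  p <- sample(10)
  m1 <- as.matrix(d1)[p, p]
  m2 <- as.matrix(d2)[p, p]
  expect_equal(mantel_test(m1, m2, n_perm = 9, seed = 1)$statistic,
               mine$statistic)
  expect_error(mantel_test(d1, dist(matrix(rnorm(8), 4, 2))), "size")
})

test_that("Mantel null behaviour on independent configurations", {
  set.seed(51)
  ok <- vapply(1:100, function(i) {
    d1 <- dist(matrix(rnorm(40), 20, 2))
    d2 <- dist(matrix(rnorm(40), 20, 2))
    res <- mantel_test(d1, d2, n_perm = 99, seed = i)
    abs(res$statistic) < 0.3 && res$p_value > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("envfit recovers axis-aligned and noisy gradients", {
  set.seed(61)
  coords <- matrix(rnorm(60), 30, 2)
  res <- envfit_vector(coords, coords[, 1], n_perm = 99, seed = 1)
  expect_equal(res$r2, 1)
  expect_equal(abs(res$direction), c(1, 0), tolerance = 1e-9)

  noisy <- coords[, 1] + rnorm(30, sd = 0.1 * sd(coords[, 1]))
  res_n <- envfit_vector(coords, noisy, n_perm = 99, seed = 1)
  expect_gte(res_n$r2, 0.9)
  ref <- vegan::envfit(coords, data.frame(v = noisy), permutations = 99)
  expect_equal(res_n$r2, unname(ref$vectors$r), tolerance = 1e-9)

  const <- envfit_vector(coords, rep(1, 30), n_perm = 99, seed = 1)
  expect_true(is.na(const$r2))
  expect_error(envfit_vector(coords, c(NA, rnorm(29))), "missing")
})

test_that("Spearman correlation matches rank arithmetic and cor.test", {
  expect_equal(spearman_cor(1:10, 1:10)$rho, 1)
  expect_equal(spearman_cor(1:10, 10:1)$rho, -1)
  expect_equal(spearman_cor(1:5, c(1, 3, 2, 5, 4))$rho, 0.8)

  set.seed(71)
  x <- rnorm(30)
  y <- x + rnorm(30)
  mine <- spearman_cor(x, y)
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(mine$rho, unname(ref$estimate))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)

  expect_true(is.na(spearman_cor(rep(1, 5), 1:5)$rho))
  expect_error(spearman_cor(1:2, 1:2), "n >= 3")
})

test_that("group tests reduce to known identities", {
  # one factor, two groups: F equals the squared two-sample t statistic
  set.seed(81)
  v <- rnorm(20)
  g <- rep(c("a", "b"), each = 10)
  res <- group_tests(v, data.frame(g = g), "g")
  t_stat <- stats::t.test(v ~ g, var.equal = TRUE)$statistic
  expect_equal(res$statistic[res$test == "anova_F"], unname(t_stat)^2,
               tolerance = 1e-9)

  # all values identical: H = 0
  res0 <- group_tests(rep(2, 12), data.frame(g = rep(c("a", "b"), 6)), "g")
  expect_equal(res0$statistic[res0$test == "kruskal_wallis_H"], 0)

  # balanced noise-free 2x2 with means along A: interaction SS = 0
  a <- rep(c("a1", "a2"), each = 8)
  b <- rep(c("b1", "b2"), 8)
  v2 <- ifelse(a == "a1", 0, 1)
  res2 <- group_tests(v2, data.frame(a = a, b = b), c("a", "b"))
  expect_equal(res2$ss[res2$term == "a"], 4, tolerance = 1e-9)
  expect_lt(abs(res2$ss[res2$term == "a:b"]), 1e-9)
  expect_lt(abs(res2$ss[res2$term == "b"]), 1e-9)
  expect_error(group_tests(v2, data.frame(a = rep("x", 16)), "a"),
               "single level")
})

test_that("two-way Type II sums of squares match car::Anova", {
  set.seed(91)
  # mildly unbalanced two-way layout with noise
  a <- factor(c(rep("a1", 9), rep("a2", 11)))
  b <- factor(rep(c("b1", "b2"), 10))
  v <- as.numeric(a == "a2") + 0.5 * as.numeric(b == "b2") + rnorm(20)
  mine <- group_tests(v, data.frame(a = a, b = b), c("a", "b"))
  ref <- car::Anova(stats::lm(v ~ a * b), type = 2)
  for (term in c("a", "b", "a:b")) {
    i <- match(term, mine$term)
    j <- match(term, rownames(ref))
    expect_equal(mine$statistic[i], ref$`F value`[j], tolerance = 1e-9)
    expect_equal(mine$ss[i], ref$`Sum Sq`[j], tolerance = 1e-9)
    expect_equal(mine$p_value[i], ref$`Pr(>F)`[j], tolerance = 1e-9)
  }
})
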